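# Independent brute-force oracles for the incremental analysis.

nmb_tol <- function(nmb) 1e-9 * max(1, abs(max(nmb)))

# net monetary benefit argmax; ties broken by higher QALYs, then lower cost
nmb_argmax <- function(df, lambda) {
  nmb <- lambda * df$qalys - df$costs
  win <- which(nmb >= max(nmb) - nmb_tol(nmb))
  win <- win[order(-df$qalys[win], df$costs[win])]
  df$tool[win[1]]
}

# frontier by exhaustive lambda sweep: a strategy is on the frontier iff it
# uniquely maximises NMB for some willingness-to-pay lambda > 0
frontier_oracle <- function(df) {
  n <- nrow(df)
  lams <- c()
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      dq <- df$qalys[j] - df$qalys[i]
      if (dq != 0) {
        l <- (df$costs[j] - df$costs[i]) / dq
        if (l > 0) lams <- c(lams, l)
      }
    }
  }
  lams <- sort(unique(lams))
  probe <- c(min(c(lams, 1)) / 2,
             if (length(lams) > 1) (lams[-1] + lams[-length(lams)]) / 2,
             max(c(lams, 1)) * 2 + 1)
  members <- unique(unlist(lapply(probe, function(l) {
    nmb <- l * df$qalys - df$costs
    win <- which(nmb >= max(nmb) - nmb_tol(nmb))
    if (length(win) == 1) df$tool[win]
  })))
  members
}

# strictly dominated strategies by pairwise comparison
dominated_oracle <- function(df) {
  n <- nrow(df)
  df$tool[vapply(seq_len(n), function(i) {
    any(df$qalys >= df$qalys[i] & df$costs <= df$costs[i] &
          (df$qalys > df$qalys[i] | df$costs < df$costs[i]))
  }, logical(1))]
}
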