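#' Load and validate model parameters
#'
#' Reads a YAML parameter file into a validated `trauma_params` object.
#' The file must contain the sections `clinical`, `utility`, `cost`,
#' `economics`, `survival_model`, `tools` and `psa`; unknown keys anywhere
#' are rejected so typos cannot silently fall back to defaults. The package
#' ships a default file (2017/18 English cost year) available via
#' `default_parameters()`.
#'
#' @param path Path to a YAML parameter file, or `NULL` for the packaged
#'   default.
#' @return A `trauma_params` object: a named list with elements
#'   `clinical` (transfer probabilities, relative risks, hazard ratios),
#'   `utility`, `cost` (treatment band tables as data frames), `economics`,
#'   `survival_model`, `tools` (data frame with `label`, `sensitivity`,
#'   `specificity`) and `psa`.
#' @export
#' @examples
#' p <- default_parameters()
#' p$clinical$transfer$fn  # 0.325
load_parameters <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_params.yaml", package = "traumatriage")
  }
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  raw <- yaml::yaml.load_file(path)
  params_from_list(raw)
}

#' @rdname load_parameters
#' @export
default_parameters <- function() load_parameters(NULL)

#' Build a trauma_params object from a plain list
#'
#' @param raw Nested list with the same layout as the YAML file.
#' @return A validated `trauma_params`.
#' @export
params_from_list <- function(raw) {
  check_keys(raw, c("clinical", "utility", "cost", "economics",
                    "survival_model", "tools", "psa"), "top level")
  cl <- raw$clinical
  check_keys(cl, c("transfer", "rr_death30_local_iss16", "rr_death30_local_issLT16",
                   "rr_death30_local_iss9to15", "p_death_30d_1yr_iss16",
                   "rr_1yr_local_iss16", "p_death_30d_1yr_issLT16",
                   "rr_1yr_local_iss9to15", "hr_longterm_iss16",
                   "hr_longterm_issLT16"), "clinical")
  check_keys(cl$transfer, c("tp", "fn", "tn", "fp"), "clinical$transfer")
  check_keys(raw$utility, c("u_iss9plus", "ara_constant", "ara_age", "ara_age2",
                            "ara_male", "ref_age", "ref_male_prop"), "utility")
  check_keys(raw$cost, c("transfer_cost", "mtc_admit_iss16", "mtc_admit_iss9to15",
                         "blunt_treatment_bands", "penetrating_treatment_bands",
                         "post_discharge_6mo", "longterm_mult_iss16",
                         "longterm_mult_issLT16"), "cost")
  check_keys(raw$economics, c("discount_rate", "maicers", "horizon_age_cap"),
             "economics")
  check_keys(raw$survival_model, c("form", "coefficients"), "survival_model")
  check_keys(raw$psa, c("se_frac", "tool_ess"), "psa")

  tools <- do.call(rbind, lapply(raw$tools, function(t) {
    check_keys(t, c("label", "sensitivity", "specificity"), "tools entry")
    data.frame(label = t$label, sensitivity = t$sensitivity,
               specificity = t$specificity, stringsAsFactors = FALSE)
  }))
  cost <- raw$cost
  cost$blunt_treatment_bands <- band_table(cost$blunt_treatment_bands, "blunt")
  cost$penetrating_treatment_bands <-
    band_table(cost$penetrating_treatment_bands, "penetrating")

  params <- structure(list(
    clinical = cl,
    utility = raw$utility,
    cost = cost,
    economics = raw$economics,
    survival_model = list(
      form = raw$survival_model$form,
      coefficients = unlist(raw$survival_model$coefficients)
    ),
    tools = tools,
    psa = raw$psa
  ), class = "trauma_params")
  validate_parameters(params)
  params
}

band_table <- function(bands, what) {
  tab <- do.call(rbind, lapply(bands, function(b) {
    check_keys(b, c("lo", "hi", "cost"), paste(what, "band"))
    data.frame(lo = b$lo, hi = b$hi, cost = b$cost)
  }))
  tab[order(tab$lo), , drop = FALSE]
}

check_keys <- function(x, allowed, where) {
  if (is.null(x)) stop("missing section: ", where, call. = FALSE)
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop("unknown key(s) in ", where, ": ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(allowed, names(x))
  if (length(missing)) {
    stop("missing required key(s) in ", where, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Validate a trauma_params object
#'
#' Checks every invariant: probabilities in \[0,1\], relative risks and
#' hazard ratios non-negative, costs non-negative, treatment band tables
#' covering ISS 0--75 without gaps or overlaps, and a survival model whose
#' coefficients are complete for its form.
#'
#' @param params A `trauma_params`.
#' @return The object, invisibly, or an error.
#' @export
validate_parameters <- function(params) {
  cl <- params$clinical
  probs <- c(unlist(cl$transfer), cl$p_death_30d_1yr_iss16,
             cl$p_death_30d_1yr_issLT16, params$utility$u_iss9plus,
             params$utility$ref_male_prop,
             params$tools$sensitivity, params$tools$specificity)
  if (any(probs < 0 | probs > 1)) {
    stop("probability outside [0, 1] in parameters", call. = FALSE)
  }
  ratios <- c(cl$rr_death30_local_iss16, cl$rr_death30_local_issLT16,
              cl$rr_death30_local_iss9to15, cl$rr_1yr_local_iss16,
              cl$rr_1yr_local_iss9to15, cl$hr_longterm_iss16,
              cl$hr_longterm_issLT16,
              params$cost$longterm_mult_iss16, params$cost$longterm_mult_issLT16)
  if (any(ratios < 0)) stop("negative relative risk/hazard ratio", call. = FALSE)
  costs <- c(params$cost$transfer_cost, params$cost$mtc_admit_iss16,
             params$cost$mtc_admit_iss9to15, params$cost$post_discharge_6mo,
             params$cost$blunt_treatment_bands$cost,
             params$cost$penetrating_treatment_bands$cost)
  if (any(costs < 0)) stop("negative cost parameter", call. = FALSE)
  for (tab in list(params$cost$blunt_treatment_bands,
                   params$cost$penetrating_treatment_bands)) {
    if (tab$lo[1] != 0 || tab$hi[nrow(tab)] < 75 ||
        (nrow(tab) > 1 && any(tab$lo[-1] != tab$hi[-nrow(tab)]))) {
      stop("treatment band table has a gap, overlap, or does not cover ISS 0-75",
           call. = FALSE)
    }
  }
  ec <- params$economics
  if (ec$discount_rate < 0) stop("negative discount rate", call. = FALSE)
  if (any(ec$maicers <= 0)) stop("MAICERs must be positive", call. = FALSE)
  if (ec$horizon_age_cap <= 0) stop("horizon age cap must be positive", call. = FALSE)
  if (!identical(params$survival_model$form, "logit_linear")) {
    stop("unsupported survival model form: ", params$survival_model$form,
         call. = FALSE)
  }
  needed <- c("intercept", "age", "iss", "gcs", "male")
  have <- names(params$survival_model$coefficients)
  if (!all(needed %in% have)) {
    stop("survival model coefficients missing: ",
         paste(setdiff(needed, have), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(params$tools$label)) {
    stop("duplicate tool labels", call. = FALSE)
  }
  if (params$psa$se_frac <= 0 || params$psa$tool_ess <= 0) {
    stop("psa settings must be positive", call. = FALSE)
  }
  invisible(params)
}

#' Save parameters to YAML
#'
#' Round-trips losslessly through [load_parameters()].
#'
#' @param params A `trauma_params`.
#' @param path Output file path.
#' @export
save_parameters <- function(params, path) {
  raw <- unclass(params)
  raw$tools <- lapply(seq_len(nrow(params$tools)), function(i) {
    as.list(params$tools[i, , drop = FALSE])
  })
  raw$cost$blunt_treatment_bands <-
    lapply(seq_len(nrow(params$cost$blunt_treatment_bands)),
           function(i) as.list(params$cost$blunt_treatment_bands[i, ]))
  raw$cost$penetrating_treatment_bands <-
    lapply(seq_len(nrow(params$cost$penetrating_treatment_bands)),
           function(i) as.list(params$cost$penetrating_treatment_bands[i, ]))
  raw$survival_model$coefficients <- as.list(params$survival_model$coefficients)
  writeLines(yaml::as.yaml(raw, precision = 15L), path)
  invisible(path)
}

#' @export
print.trauma_params <- function(x, ...) {
  cat("<trauma_params>\n")
  cat("  tools:", nrow(x$tools), " discount:", x$economics$discount_rate,
      " horizon cap:", x$economics$horizon_age_cap, "\n")
  cat("  transfer tp/fn/tn/fp:",
      paste(unlist(x$clinical$transfer), collapse = "/"), "\n")
  invisible(x)
}

#' Interpolate a relative risk for partial MTC benefit
#'
#' Linear interpolation on the relative-risk scale between no effect
#' (RR = 1) and the full effect: `1 + fraction * (rr_full - 1)`. Used by
#' the scenario analyses in which patients with ISS 9--15 receive a stated
#' fraction of the MTC benefit observed for ISS >= 16.
#'
#' @param rr_full The full-effect relative risk (>= 1).
#' @param fraction Benefit fraction in \[0, 1\].
#' @return A relative risk in `[1, rr_full]`.
#' @export
#' @examples
#' interpolated_rr(1.64, 0.5)  # 1.32
interpolated_rr <- function(rr_full, fraction) {
  if (any(fraction < 0 | fraction > 1)) {
    stop("benefit fraction must be in [0, 1]", call. = FALSE)
  }
  if (any(rr_full < 1)) stop("rr_full must be >= 1", call. = FALSE)
  1 + fraction * (rr_full - 1)
}

#' PSA distribution specs for every uncertain parameter
#'
#' Builds the moment-matched uncertainty distributions used by the PSA:
#' Beta for probabilities and the injury utility, Gamma for costs,
#' Lognormal for relative risks, hazard ratios and cost multipliers, and
#' Beta with an effective sample size (`psa$tool_ess`) for tool
#' sensitivity/specificity. Standard errors default to `psa$se_frac` of the
#' mean. Parameters whose point value sits on a boundary of its family's
#' support (e.g. an RR of exactly 1, or a zero cost) are kept fixed.
#'
#' @param params A `trauma_params`.
#' @return Named list of `dist_spec` objects; names are dotted paths into
#'   the parameter object (e.g. `"clinical.transfer.fn"`), with
#'   `tools.sens.<i>` / `tools.spec.<i>` for the tools.
#' @export
psa_distributions <- function(params) {
  f <- params$psa$se_frac
  ess <- params$psa$tool_ess
  d <- list()
  prob_or_fixed <- function(m) {
    if (m <= 0 || m >= 1) dist_fixed(m) else dist_beta_mom(m, f * m)
  }
  ratio_or_fixed <- function(m) {
    if (m <= 1) dist_fixed(m) else dist_lnorm_mom(m, f * m)
  }
  cost_or_fixed <- function(m) {
    if (m <= 0) dist_fixed(m) else dist_gamma_mom(m, f * m)
  }
  cl <- params$clinical
  for (k in c("tp", "fn", "tn", "fp")) {
    d[[paste0("clinical.transfer.", k)]] <- prob_or_fixed(cl$transfer[[k]])
  }
  for (k in c("rr_death30_local_iss16", "rr_1yr_local_iss16",
              "hr_longterm_iss16", "hr_longterm_issLT16")) {
    d[[paste0("clinical.", k)]] <- ratio_or_fixed(cl[[k]])
  }
  for (k in c("p_death_30d_1yr_iss16", "p_death_30d_1yr_issLT16")) {
    d[[paste0("clinical.", k)]] <- prob_or_fixed(cl[[k]])
  }
  d[["utility.u_iss9plus"]] <- prob_or_fixed(params$utility$u_iss9plus)
  co <- params$cost
  for (k in c("transfer_cost", "mtc_admit_iss16", "mtc_admit_iss9to15",
              "post_discharge_6mo")) {
    d[[paste0("cost.", k)]] <- cost_or_fixed(co[[k]])
  }
  for (tab in c("blunt_treatment_bands", "penetrating_treatment_bands")) {
    for (i in seq_len(nrow(co[[tab]]))) {
      d[[paste0("cost.", tab, ".", i)]] <- cost_or_fixed(co[[tab]]$cost[i])
    }
  }
  d[["cost.longterm_mult_iss16"]] <- ratio_or_fixed(co$longterm_mult_iss16)
  d[["cost.longterm_mult_issLT16"]] <- ratio_or_fixed(co$longterm_mult_issLT16)
  for (i in seq_len(nrow(params$tools))) {
    d[[paste0("tools.sens.", i)]] <- dist_beta_ess(params$tools$sensitivity[i], ess)
    d[[paste0("tools.spec.", i)]] <- dist_beta_ess(params$tools$specificity[i], ess)
  }
  d
}

#' Draw one PSA parameter set
#'
#' Replaces every uncertain quantity in `params` with one draw from its
#' `dist_spec`. Draws failing validation are redrawn (with a warning) up to
#' 100 times. Uses the current RNG state.
#'
#' @param params A `trauma_params` (point estimates).
#' @param dists Output of [psa_distributions()]; recomputed if omitted.
#' @return A `trauma_params` with drawn values.
#' @export
draw_parameters <- function(params, dists = psa_distributions(params)) {
  for (attempt in 1:100) {
    drawn <- params
    for (nm in names(dists)) {
      v <- dist_draw(dists[[nm]])
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      if (parts[1] == "tools") {
        i <- as.integer(parts[3])
        col <- if (parts[2] == "sens") "sensitivity" else "specificity"
        drawn$tools[[col]][i] <- v
      } else if (length(parts) == 3 && parts[2] %in%
                 c("blunt_treatment_bands", "penetrating_treatment_bands")) {
        drawn$cost[[parts[2]]]$cost[as.integer(parts[3])] <- v
      } else if (length(parts) == 3) {
        drawn[[parts[1]]][[parts[2]]][[parts[3]]] <- v
      } else {
        drawn[[parts[1]]][[parts[2]]] <- v
      }
    }
    ok <- tryCatch({ validate_parameters(drawn); TRUE },
                   error = function(e) FALSE)
    if (ok) return(drawn)
    warning("invalid PSA draw; resampling", call. = FALSE)
  }
  stop("could not draw a valid parameter set after 100 attempts", call. = FALSE)
}
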