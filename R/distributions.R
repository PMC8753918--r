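#' Parameter uncertainty distributions
#'
#' Light-weight distribution specifications used in the probabilistic
#' sensitivity analysis (PSA). Each spec carries a family and its
#' family-specific parameters; moment-matched constructors guarantee that
#' the analytic mean of the distribution equals the deterministic point
#' estimate, so a PSA with all draws replaced by their means reproduces the
#' deterministic analysis.
#'
#' @param family One of `"fixed"`, `"beta"`, `"gamma"`, `"lognormal"`,
#'   `"dirichlet"`.
#' @param ... Family-specific parameters (see the constructors below).
#' @return An object of class `dist_spec`.
#' @export
dist_spec <- function(family, ...) {
  family <- match.arg(family, c("fixed", "beta", "gamma", "lognormal", "dirichlet"))
  pars <- list(...)
  spec <- structure(list(family = family, pars = pars), class = "dist_spec")
  validate_dist_spec(spec)
  spec
}

validate_dist_spec <- function(spec) {
  p <- spec$pars
  ok <- switch(spec$family,
    fixed = is.numeric(p$value) && length(p$value) == 1L,
    beta = all(c(p$shape1, p$shape2) > 0),
    gamma = all(c(p$shape, p$rate) > 0),
    lognormal = is.finite(p$meanlog) && p$sdlog >= 0,
    dirichlet = length(p$alpha) >= 2L && all(p$alpha > 0)
  )
  if (!isTRUE(ok)) {
    stop("invalid parameters for ", spec$family, " distribution spec", call. = FALSE)
  }
  invisible(spec)
}

#' @rdname dist_spec
#' @param value Point value for a degenerate (non-varying) parameter.
#' @export
dist_fixed <- function(value) dist_spec("fixed", value = value)

#' Moment-matched Beta spec
#'
#' @param mean Point estimate in (0, 1).
#' @param se Standard error; must satisfy `se^2 < mean * (1 - mean)`.
#' @export
dist_beta_mom <- function(mean, se) {
  stopifnot(mean > 0, mean < 1, se > 0)
  if (se^2 >= mean * (1 - mean)) {
    stop("standard error too large for a Beta with mean ", mean, call. = FALSE)
  }
  nu <- mean * (1 - mean) / se^2 - 1
  dist_spec("beta", shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Beta spec from a mean and an effective sample size
#'
#' Used for triage tool sensitivity/specificity, where uncertainty reflects
#' the size of the derivation cohort rather than a reported standard error:
#' `Beta(mean * ess, (1 - mean) * ess)`.
#'
#' @param mean Point estimate in (0, 1).
#' @param ess Effective sample size (> 0).
#' @export
dist_beta_ess <- function(mean, ess) {
  stopifnot(mean > 0, mean < 1, ess > 0)
  dist_spec("beta", shape1 = mean * ess, shape2 = (1 - mean) * ess)
}

#' Moment-matched Gamma spec (costs)
#' @inheritParams dist_beta_mom
#' @export
dist_gamma_mom <- function(mean, se) {
  stopifnot(mean > 0, se > 0)
  dist_spec("gamma", shape = (mean / se)^2, rate = mean / se^2)
}

#' Moment-matched Lognormal spec (relative risks, hazard ratios)
#' @inheritParams dist_beta_mom
#' @export
dist_lnorm_mom <- function(mean, se) {
  stopifnot(mean > 0, se > 0)
  s2 <- log(1 + se^2 / mean^2)
  dist_spec("lognormal", meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Analytic mean of a distribution spec
#' @param spec A `dist_spec`.
#' @return The exact expectation (a vector for dirichlet).
#' @export
dist_mean <- function(spec) {
  p <- spec$pars
  switch(spec$family,
    fixed = p$value,
    beta = p$shape1 / (p$shape1 + p$shape2),
    gamma = p$shape / p$rate,
    lognormal = exp(p$meanlog + p$sdlog^2 / 2),
    dirichlet = p$alpha / sum(p$alpha)
  )
}

#' Draw from a distribution spec
#'
#' Uses the current RNG state; seed management belongs to the caller.
#'
#' @param spec A `dist_spec`.
#' @param n Number of draws.
#' @export
dist_draw <- function(spec, n = 1L) {
  p <- spec$pars
  switch(spec$family,
    fixed = rep(p$value, n),
    beta = stats::rbeta(n, p$shape1, p$shape2),
    gamma = stats::rgamma(n, shape = p$shape, rate = p$rate),
    lognormal = stats::rlnorm(n, p$meanlog, p$sdlog),
    dirichlet = {
      k <- length(p$alpha)
      g <- matrix(stats::rgamma(n * k, shape = p$alpha), ncol = k, byrow = TRUE)
      g / rowSums(g)
    }
  )
}

#' @export
print.dist_spec <- function(x, ...) {
  cat("<dist_spec ", x$family, ": ",
      paste(names(x$pars), unlist(x$pars), sep = "=", collapse = ", "),
      ">\n", sep = "")
  invisible(x)
}
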