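#' Log-likelihood of a tray well pattern
#'
#' Binomial-Poisson likelihood underlying MPN estimation: organisms are
#' assumed Poisson-distributed in the assayed fluid at concentration `lambda`
#' per mL, wells are independent, and a well containing volume v is sterile
#' (negative) with probability exp(-lambda * v). For counts of positive wells
#' p out of n in each size class the log-likelihood is
#'
#'   sum over classes of  p * log(1 - exp(-lambda * v)) - (n - p) * lambda * v
#'
#' up to the constant binomial coefficients, which are omitted.
#'
#' @param lambda Concentration of organisms per mL of assayed fluid; must be
#'   positive. Vectorized.
#' @param p_large,p_small Positive large/small well counts.
#' @param geometry A [tray_geometry()].
#' @return Log-likelihood value(s); `-Inf` where a positive well is observed
#'   but the positivity probability underflows to 0.
#' @examples
#' tray_log_likelihood(0.01, p_large = 1, p_small = 0)
#' @export
tray_log_likelihood <- function(lambda, p_large, p_small,
                                geometry = tray_geometry()) {
  validate_tray_counts(p_large, p_small, geometry)
  if (any(!is.finite(lambda)) || any(lambda <= 0)) {
    stop("`lambda` must be positive and finite", call. = FALSE)
  }
  ll <- numeric(length(lambda))
  for (cls in list(c(geometry$n_large, p_large, geometry$v_large),
                   c(geometry$n_small, p_small, geometry$v_small))) {
    n <- cls[1]; p <- cls[2]; v <- cls[3]
    if (n == 0) next
    # log(1 - exp(-x)) via log1p/expm1 keeps precision at both extremes
    pos <- if (p > 0) p * log(-expm1(-lambda * v)) else 0
    ll <- ll + pos - (n - p) * lambda * v
  }
  ll
}

# Score (derivative of tray_log_likelihood in lambda). Strictly decreasing in
# lambda, positive at 0+ whenever any well is positive, and tends to minus the
# total negative-well volume as lambda grows — hence a unique root.
tray_score <- function(lambda, p_large, p_small, geometry) {
  s <- 0
  for (cls in list(c(geometry$n_large, p_large, geometry$v_large),
                   c(geometry$n_small, p_small, geometry$v_small))) {
    n <- cls[1]; p <- cls[2]; v <- cls[3]
    if (n == 0) next
    if (p > 0) s <- s + p * v * exp(-lambda * v) / (-expm1(-lambda * v))
    s <- s - (n - p) * v
  }
  s
}

#' Maximum-likelihood MPN estimate for one tray
#'
#' Classifies the tray and, when the well pattern is informative, maximizes
#' [tray_log_likelihood()] in the per-mL concentration. A tray with no
#' positive wells carries only the information "concentration below the
#' detection limit" (`status = "nondetect"`); a tray with every well positive
#' only "above the upper limit" (`status = "overrange"`); neither receives a
#' numeric MPN here — substitution policy for censored trays belongs to the
#' sample-level pipeline, not the estimator. Otherwise the unique root of the
#' monotone score function is found by [stats::uniroot()] on the log-lambda
#' scale to a relative tolerance of 1e-8, and the MPN is reported per
#' `geometry$reference_volume` (per 100 mL for the default preset, for which
#' quantifiable estimates span approximately 1 to 2419.6).
#'
#' @inheritParams tray_log_likelihood
#' @param conf_level If non-`NULL`, a profile-likelihood confidence level to
#'   attach via [mpn_confint()].
#' @return An object of class `tray_estimate`: a list with `status` (one of
#'   `"nondetect"`, `"quantifiable"`, `"overrange"`), `mpn` (per reference
#'   volume; `NA` unless quantifiable), `lambda` (per mL), `ci_low`/`ci_high`
#'   when requested, and the `geometry`.
#' @examples
#' mpn_estimate(p_large = 1, p_small = 0)    # ~1.0 MPN/100 mL
#' mpn_estimate(p_large = 49, p_small = 48)  # overrange
#' @export
mpn_estimate <- function(p_large, p_small, geometry = tray_geometry(),
                         conf_level = NULL) {
  validate_tray_counts(p_large, p_small, geometry)
  n_pos <- p_large + p_small
  n_tot <- geometry$n_large + geometry$n_small
  est <- if (n_pos == 0) {
    list(status = "nondetect", mpn = NA_real_, lambda = NA_real_)
  } else if (n_pos == n_tot) {
    list(status = "overrange", mpn = NA_real_, lambda = NA_real_)
  } else {
    lam <- solve_mpn_lambda(p_large, p_small, geometry)
    list(status = "quantifiable", mpn = lam * geometry$reference_volume,
         lambda = lam)
  }
  est$geometry <- geometry
  class(est) <- "tray_estimate"
  if (!is.null(conf_level) && est$status == "quantifiable") {
    ci <- mpn_confint(p_large, p_small, level = conf_level,
                      geometry = geometry)
    est$ci_low <- ci[[1]]
    est$ci_high <- ci[[2]]
    est$conf_level <- conf_level
  }
  est
}

#' @export
print.tray_estimate <- function(x, ...) {
  if (x$status == "quantifiable") {
    cat(sprintf("<tray_estimate> %.4g MPN per %g mL (quantifiable)\n",
                x$mpn, x$geometry$reference_volume))
    if (!is.null(x$ci_low)) {
      cat(sprintf("  %g%% profile-likelihood CI: [%.4g, %.4g]\n",
                  100 * x$conf_level, x$ci_low, x$ci_high))
    }
  } else {
    cat(sprintf("<tray_estimate> %s\n", x$status))
  }
  invisible(x)
}

# Root of the score function on the log-lambda scale; bracket spans
# [1e-9, 1e3] organisms per mL, far beyond any tray's quantifiable band.
solve_mpn_lambda <- function(p_large, p_small, geometry,
                             lower = 1e-9, upper = 1e3) {
  f <- function(loglam) tray_score(exp(loglam), p_large, p_small, geometry)
  lo <- log(lower); hi <- log(upper)
  if (f(lo) <= 0) return(lower)
  if (f(hi) >= 0) return(upper)
  r <- stats::uniroot(f, c(lo, hi), tol = 1e-10)
  exp(r$root)
}

#' Profile-likelihood confidence interval for a tray MPN
#'
#' Inverts the likelihood-ratio statistic: the interval is the set of
#' concentrations whose log-likelihood lies within qchisq(level, 1)/2 of the
#' maximum, scaled to the geometry's reference volume. For censored trays a
#' two-sided interval does not exist; a one-sided bound is returned instead
#' (an upper bound for an all-negative tray, a lower bound for an all-positive
#' tray) and flagged via the `"one_sided"` attribute.
#'
#' @inheritParams tray_log_likelihood
#' @param level Confidence level in `[0, 1)`; `level = 0` collapses to the
#'   MLE.
#' @return Named numeric vector `c(low, high)` in MPN per reference volume,
#'   with attribute `one_sided` (`NA`, `"upper"` or `"lower"`).
#' @examples
#' mpn_confint(p_large = 1, p_small = 0)  # contains 1.0
#' @export
mpn_confint <- function(p_large, p_small, level = 0.95,
                        geometry = tray_geometry()) {
  validate_tray_counts(p_large, p_small, geometry)
  if (length(level) != 1 || is.na(level) || level < 0 || level >= 1) {
    stop("`level` must lie in [0, 1)", call. = FALSE)
  }
  ref <- geometry$reference_volume
  crit <- stats::qchisq(level, df = 1) / 2
  n_pos <- p_large + p_small
  n_tot <- geometry$n_large + geometry$n_small
  ll <- function(lam) tray_log_likelihood(lam, p_large, p_small, geometry)

  if (n_pos == 0) {
    # ll(lambda) = -lambda * V, supremum 0 at lambda -> 0+
    v_tot <- tray_total_volume(geometry)
    out <- c(low = 0, high = ref * crit / v_tot)
    attr(out, "one_sided") <- "upper"
    return(out)
  }
  if (n_pos == n_tot) {
    # ll increasing with supremum 0 at lambda -> Inf
    f <- function(loglam) ll(exp(loglam)) + crit
    lo <- log(1e-12)
    if (f(lo) > 0) {
      low <- 0
    } else {
      low <- exp(stats::uniroot(f, c(lo, log(1e6)), tol = 1e-10)$root)
    }
    out <- c(low = ref * low, high = Inf)
    attr(out, "one_sided") <- "lower"
    return(out)
  }

  lam_hat <- solve_mpn_lambda(p_large, p_small, geometry)
  if (level == 0) {
    out <- c(low = ref * lam_hat, high = ref * lam_hat)
    attr(out, "one_sided") <- NA_character_
    return(out)
  }
  target <- ll(lam_hat) - crit
  g <- function(loglam) ll(exp(loglam)) - target
  lo_bracket <- log(1e-12)
  low <- if (g(lo_bracket) >= 0) 0 else {
    exp(stats::uniroot(g, c(lo_bracket, log(lam_hat)), tol = 1e-10)$root)
  }
  hi_bracket <- log(1e6)
  high <- if (g(hi_bracket) >= 0) Inf else {
    exp(stats::uniroot(g, c(log(lam_hat), hi_bracket), tol = 1e-10)$root)
  }
  out <- c(low = ref * low, high = ref * high)
  attr(out, "one_sided") <- NA_character_
  out
}
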