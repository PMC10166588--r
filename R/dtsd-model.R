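#' Dual-trace signal detection (DTSD) model parameters
#'
#' Bundle the three ingredients of the DTSD model of confidence-rating ROC
#' data: an equal-variance signal detection component with sensitivity
#' `d_prime` (the continuous "global" trace), an all-or-none high-threshold
#' component with detect rate `ht` (the discrete "local" trace), and a
#' strictly increasing vector of decision criteria that carve the internal
#' strength axis into `K = length(criteria) + 1` ordered response
#' categories, from most-confident-"normal" to most-confident-"abnormal".
#'
#' The model predicts, at each criterion `c`,
#' `fpr = Phi(-c)` and `tpr = ht + (1 - ht) * Phi(d_prime - c)`:
#' high-threshold detections occur only on signal (abnormal) trials and are
#' expressed at the highest confidence, so the theoretical ROC is a mixture
#' of a curvilinear SDT arc and a linear component with intercept `ht` at
#' zero false positives.
#'
#' @param d_prime Sensitivity of the continuous component (standardized
#'   mean separation of the signal and noise strength distributions).
#'   Unconstrained in sign; fitted values can be slightly negative.
#' @param ht Probability in `[0, 1)` that a signal trial is detected by the
#'   all-or-none high-threshold process.
#' @param criteria Numeric vector of strictly increasing decision criteria
#'   (length `K - 1` for `K` response categories, `K >= 2`).
#' @return An object of class `"dtsd_params"`.
#' @examples
#' p <- dtsd_params(d_prime = 1.5, ht = 0.2, criteria = qnorm(1:19 / 20))
#' cumulative_rates(p)
#' @export
dtsd_params <- function(d_prime, ht, criteria) {
  stopifnot(is.numeric(d_prime), length(d_prime) == 1L, is.finite(d_prime),
            is.numeric(ht), length(ht) == 1L, is.finite(ht),
            is.numeric(criteria), length(criteria) >= 1L,
            all(is.finite(criteria)))
  if (ht < 0 || ht >= 1)
    stop("`ht` must lie in [0, 1), got ", format(ht), call. = FALSE)
  if (length(criteria) > 1L && any(diff(criteria) <= 0))
    stop("`criteria` must be strictly increasing", call. = FALSE)
  structure(
    list(d_prime = as.numeric(d_prime), ht = as.numeric(ht),
         criteria = as.numeric(criteria)),
    class = "dtsd_params"
  )
}

#' @export
print.dtsd_params <- function(x, ...) {
  cat("DTSD parameters\n")
  cat("  d' (global, continuous):", format(x$d_prime, digits = 4), "\n")
  cat("  HT (local, threshold):  ", format(x$ht, digits = 4), "\n")
  cat("  criteria (", length(x$criteria), "):",
      paste(format(x$criteria, digits = 3), collapse = " "), "\n")
  invisible(x)
}

as_dtsd_params <- function(x) {
  if (inherits(x, "dtsd_params")) return(x)
  if (is.list(x) && all(c("d_prime", "ht", "criteria") %in% names(x)))
    return(dtsd_params(x$d_prime, x$ht, x$criteria))
  stop("cannot interpret object as DTSD parameters", call. = FALSE)
}

#' Theoretical cumulative hit and false-alarm rates
#'
#' Evaluate the DTSD model's operating points: for each decision criterion
#' `c_k`, the false-positive rate `Phi(-c_k)` and the true-positive rate
#' `ht + (1 - ht) * Phi(d_prime - c_k)`. Points are returned ordered by
#' descending criterion so that both rates are nondecreasing, the
#' convention used when sweeping an empirical ROC from the
#' "sure abnormal" end of the scale.
#'
#' @param params A [dtsd_params()] object.
#' @return A data frame with columns `fpr` and `tpr`, one row per
#'   criterion.
#' @export
cumulative_rates <- function(params) {
  params <- as_dtsd_params(params)
  cr <- sort(params$criteria, decreasing = TRUE)
  data.frame(
    fpr = pnorm(-cr),
    tpr = params$ht + (1 - params$ht) * pnorm(params$d_prime - cr)
  )
}

#' Predicted category probabilities for one trial class
#'
#' Multinomial response probabilities over the `K` ordered confidence
#' categories (most-confident-"normal" first, most-confident-"abnormal"
#' last) implied by a DTSD parameter set. On signal trials the
#' high-threshold mass `ht` is placed in the single most-confident
#' "abnormal" category; the remaining `1 - ht` of the mass follows the
#' equal-variance SDT component. Noise trials are pure SDT. Differencing
#' the cumulative sums of these vectors from the abnormal end reproduces
#' [cumulative_rates()] exactly.
#'
#' @param params A [dtsd_params()] object.
#' @param is_signal Logical; `TRUE` for signal (abnormal) trials, `FALSE`
#'   for noise (normal) trials.
#' @return Numeric probability vector of length `K` summing to 1.
#' @export
category_probabilities <- function(params, is_signal) {
  params <- as_dtsd_params(params)
  stopifnot(is.logical(is_signal), length(is_signal) == 1L)
  mu <- if (is_signal) params$d_prime else 0
  base <- diff(c(0, pnorm(params$criteria - mu), 1))
  if (!is_signal) return(base)
  p <- (1 - params$ht) * base
  p[length(p)] <- p[length(p)] + params$ht
  p
}

#' Theoretical ROC curve on a dense criterion grid
#'
#' Convenience wrapper evaluating [cumulative_rates()] on an evenly spaced
#' criterion grid, for plotting smooth model ROCs or computing model AUC.
#'
#' @param d_prime,ht DTSD component parameters (see [dtsd_params()]).
#' @param n Number of grid points.
#' @param lim Criterion range, swept symmetrically.
#' @return A `roc_curve` object (see [roc_curve()]).
#' @export
theoretical_roc <- function(d_prime, ht, n = 512L, lim = 6) {
  cr <- seq(-lim, lim, length.out = n)
  r <- cumulative_rates(dtsd_params(d_prime, ht, cr))
  roc_curve(r$fpr, r$tpr)
}

#' ROC curve object
#'
#' An ordered set of (false-positive rate, true-positive rate) operating
#' points, optionally carrying the per-category response counts the points
#' were computed from (absent for theoretical curves).
#'
#' @param fpr,tpr Numeric vectors of equal length with values in `[0, 1]`,
#'   nondecreasing when ordered by criterion.
#' @param counts_noise,counts_signal Optional integer vectors of
#'   per-category response counts (length = number of points + 1).
#' @return An object of class `"roc_curve"`: a data frame with columns
#'   `fpr`, `tpr` and attributes `counts_noise`, `counts_signal`.
#' @export
roc_curve <- function(fpr, tpr, counts_noise = NULL, counts_signal = NULL) {
  stopifnot(is.numeric(fpr), is.numeric(tpr), length(fpr) == length(tpr))
  if (length(fpr) == 0L) stop("ROC curve must have at least one point", call. = FALSE)
  if (any(fpr < -1e-12 | fpr > 1 + 1e-12) || any(tpr < -1e-12 | tpr > 1 + 1e-12))
    stop("ROC rates must lie in [0, 1]", call. = FALSE)
  out <- data.frame(fpr = pmin(pmax(fpr, 0), 1), tpr = pmin(pmax(tpr, 0), 1))
  attr(out, "counts_noise") <- counts_noise
  attr(out, "counts_signal") <- counts_signal
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Trapezoidal area under an empirical ROC curve
#'
#' Anchors the curve at (0, 0) and (1, 1), sorts the operating points by
#' false-positive rate, and integrates by the trapezoid rule.
#'
#' @param roc A [roc_curve()] object or a data frame with `fpr`, `tpr`.
#' @return AUC in `[0, 1]`.
#' @export
auc_empirical <- function(roc) {
  stopifnot(is.data.frame(roc), all(c("fpr", "tpr") %in% names(roc)))
  if (nrow(roc) == 0L) stop("empty ROC curve", call. = FALSE)
  ord <- order(roc$fpr, roc$tpr)
  x <- c(0, roc$fpr[ord], 1)
  y <- c(0, roc$tpr[ord], 1)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Binary d-prime from hit and false-alarm rates
#'
#' `qnorm(hit) - qnorm(fa)`, with the standard continuity correction for
#' extreme rates: observed rates of 0 and 1 are replaced by `1/(2n)` and
#' `1 - 1/(2n)` where `n` is the number of trials behind the rate. Extreme
#' rates are common in small rating datasets, and without the correction
#' the statistic is infinite.
#'
#' @param hit_rate,fa_rate Proportions in `[0, 1]`.
#' @param n_signal,n_noise Trial counts behind each rate, used only for
#'   the continuity correction (default 20, the per-class trial count of a
#'   typical 40-trial session).
#' @return The sensitivity estimate d'.
#' @export
dprime_binary <- function(hit_rate, fa_rate, n_signal = 20L, n_noise = 20L) {
  stopifnot(hit_rate >= 0, hit_rate <= 1, fa_rate >= 0, fa_rate <= 1)
  clamp <- function(r, n) pmin(pmax(r, 1 / (2 * n)), 1 - 1 / (2 * n))
  qnorm(clamp(hit_rate, n_signal)) - qnorm(clamp(fa_rate, n_noise))
}

#' Export a theoretical ROC as a two-column CSV
#'
#' @param roc A [roc_curve()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_roc_csv <- function(roc, path) {
  utils::write.csv(as.data.frame(roc)[, c("fpr", "tpr")], path,
                   row.names = FALSE)
  invisible(path)
}
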