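#' Highest-density interval of a posterior sample
#'
#' The shortest contiguous interval containing `mass` of the draws: all
#' windows of `ceiling(mass * n)` consecutive order statistics are
#' scanned and the narrowest returned. For unimodal posteriors this is
#' the usual HDI; it is shorter than the equal-tailed interval whenever
#' the distribution is skewed.
#'
#' @param draws Numeric vector of at least 100 posterior draws.
#' @param mass Probability mass in `(0, 1)` (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  stopifnot(is.numeric(draws), length(draws) >= 100L)
  if (!is.finite(mass) || mass <= 0 || mass >= 1)
    stop("`mass` must lie in (0, 1)", call. = FALSE)
  x <- sort(draws)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  lo <- seq_len(n - m)
  w <- x[lo + m] - x[lo]
  i <- which.min(w)
  c(lower = x[i], upper = x[i + m])
}

# negative log likelihood of one (noise, signal) count pair under the
# DTSD multinomial, parameterized unconstrained:
# par = (d', probit(ht), c1, log increments...)
dtsd_nll <- function(par, counts_noise, counts_signal) {
  K <- length(counts_noise)
  if (any(!is.finite(par))) return(1e10)
  d <- par[1]
  ht <- pnorm(par[2])
  cr <- par[3] + c(0, cumsum(exp(par[seq.int(4, K + 1)])))
  # exp() underflow can tie adjacent criteria: penalize instead of erroring
  if (ht >= 1 || any(diff(cr) <= 0) || any(!is.finite(cr))) return(1e10)
  p <- dtsd_params(d, ht, cr)
  pn <- pmax(category_probabilities(p, FALSE), 1e-12)
  ps <- pmax(category_probabilities(p, TRUE), 1e-12)
  -(sum(counts_noise * log(pn)) + sum(counts_signal * log(ps)))
}

#' Maximum-likelihood DTSD fit to one ROC's category counts
#'
#' Maximizes the multinomial likelihood of [category_probabilities()]
#' over d', HT and the ordered criteria, on an unconstrained scale
#' (probit link for HT, log increments for the criteria). Because the
#' likelihood surface of small rating datasets is multimodal and often
#' nearly flat in HT, the optimizer is restarted from `n_starts` random
#' initial values with d' in `[0, 3]` and HT in `[0, 0.6]`; the best
#' likelihood wins, ties broken toward the smaller d'. Standard errors
#' come from the observed information (numerical Hessian) with
#' delta-method transformation for HT; they are `NA` when the
#' information matrix is singular, which is common for sparse counts —
#' the instability of MLE on small samples is precisely what the
#' hierarchical model is designed to avoid.
#'
#' @param counts_noise,counts_signal Per-category response counts.
#' @param n_starts Number of random restarts (default 16).
#' @param seed Seed for the restart draws.
#' @return A list with the fitted [dtsd_params()], `se` and `ci95` for
#'   `d_prime` and `ht`, the achieved `logLik`, and `convergence` (0 =
#'   at least one start converged).
#' @export
fit_mle <- function(counts_noise, counts_signal, n_starts = 16L,
                    seed = 1L) {
  stopifnot(length(counts_noise) == length(counts_signal),
            length(counts_noise) >= 2L,
            sum(counts_noise) > 0, sum(counts_signal) > 0)
  K <- length(counts_noise)
  set.seed(seed)
  # criteria start: normal quantiles of the pooled empirical cumulative
  pool <- counts_noise + counts_signal + 0.5
  cum <- cumsum(pool)[seq_len(K - 1)] / sum(pool)
  cr0 <- qnorm(pmin(pmax(cum, 1e-3), 1 - 1e-3))
  cr0 <- cummax(cr0 + seq_len(K - 1) * 1e-6)   # enforce strict order
  inc0 <- log(pmax(diff(cr0), 1e-3))
  best <- NULL
  conv_any <- FALSE
  for (s in seq_len(n_starts)) {
    d0 <- runif(1, 0, 3)
    h0 <- qnorm(pmax(runif(1, 0, 0.6), 1e-3))
    par0 <- c(d0, h0, cr0[1], inc0)
    fit <- tryCatch(
      optim(par0, dtsd_nll, counts_noise = counts_noise,
            counts_signal = counts_signal, method = "BFGS",
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    conv_any <- conv_any || fit$convergence == 0
    if (is.null(best) || fit$value < best$value - 1e-8 ||
        (abs(fit$value - best$value) <= 1e-8 && fit$par[1] < best$par[1]))
      best <- fit
  }
  if (is.null(best))
    stop("MLE optimization failed from all ", n_starts, " starts",
         call. = FALSE)
  par <- best$par
  cr <- par[3] + c(0, cumsum(exp(par[seq.int(4, K + 1)])))
  est <- dtsd_params(par[1], pnorm(par[2]), cr)
  se <- c(d_prime = NA_real_, ht = NA_real_)
  H <- tryCatch(optimHess(par, dtsd_nll, counts_noise = counts_noise,
                          counts_signal = counts_signal),
                error = function(e) NULL)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(diag(V)[1:2] > 0)) {
      se["d_prime"] <- sqrt(V[1, 1])
      se["ht"] <- dnorm(par[2]) * sqrt(V[2, 2])   # delta method
    }
  }
  ci <- rbind(d_prime = est$d_prime + c(-1, 1) * 1.96 * se["d_prime"],
              ht = pmin(pmax(est$ht + c(-1, 1) * 1.96 * se["ht"], 0), 1))
  colnames(ci) <- c("lower", "upper")
  list(params = est, se = se, ci95 = ci, logLik = -best$value,
       convergence = if (conv_any) 0L else 1L)
}
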