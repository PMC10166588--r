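#' Hierarchical model specification
#'
#' Settings for the hierarchical Bayesian DTSD fit: which fixed effects
#' enter the general linear model on each parameter, the MCMC budget,
#' and the priors. Both DTSD parameters get the same design; effects are
#' estimated on link scales (identity for d', probit for HT) so the
#' linear model is well defined while HT stays a probability.
#'
#' Sampler profiles: `"full"` mirrors a publication-scale run (4 chains,
#' 5,000 warm-up + 5,000 kept draws per chain, 20,000 post-warmup draws
#' in total), `"recovery"` the recovery-study scale (3,000 + 3,000 per
#' chain, 12,000 kept), and `"fast"` a light profile (1,000 + 1,000 per
#' chain, 4,000 kept) for iteration and continuous testing.
#'
#' @param fixed_effects Character subset of
#'   `c("intercept", "group", "condition", "interaction")`; terms absent
#'   from the data are dropped automatically.
#' @param n_chains Number of MCMC chains (>= 2).
#' @param n_warmup,n_samples Warm-up and kept iterations per chain.
#' @param profile Convenience presets overriding `n_warmup`/`n_samples`
#'   when those are `NULL`.
#' @param prior_config Named list of prior settings:
#'   `fixed_sd` (sd of the Normal prior on link-scale fixed effects),
#'   `ranef_sd` (scale of the Half-Normal prior on random-effect sds),
#'   `crit_first` (mean, sd of the first population criterion),
#'   `crit_inc_sd` (Half-Normal scale of the positive criterion
#'   increments), `crit_shift_sd` (Half-Normal scale of the
#'   between-subject criterion shift sd).
#' @param seed RNG seed passed to the sampler.
#' @return Object of class `"hierarchical_spec"`.
#' @export
hierarchical_spec <- function(fixed_effects = c("intercept", "group",
                                                "condition", "interaction"),
                              n_chains = 4L, n_warmup = NULL,
                              n_samples = NULL,
                              profile = c("fast", "recovery", "full"),
                              prior_config = list(), seed = 1L) {
  profile <- match.arg(profile)
  preset <- switch(profile,
                   full = c(5000L, 5000L),
                   recovery = c(3000L, 3000L),
                   fast = c(1000L, 1000L))
  if (is.null(n_warmup)) n_warmup <- preset[1]
  if (is.null(n_samples)) n_samples <- preset[2]
  stopifnot(n_chains >= 2L, n_warmup > 0L, n_samples > 0L,
            all(fixed_effects %in% c("intercept", "group", "condition",
                                     "interaction")),
            "intercept" %in% fixed_effects)
  pc <- utils::modifyList(
    list(fixed_sd = 1, ranef_sd = 0.5, crit_first = c(-1.5, 1),
         crit_inc_sd = 0.2, crit_shift_sd = 0.5),
    prior_config)
  structure(list(fixed_effects = fixed_effects,
                 n_chains = as.integer(n_chains),
                 n_warmup = as.integer(n_warmup),
                 n_samples = as.integer(n_samples),
                 profile = profile, prior_config = pc,
                 seed = as.integer(seed)),
            class = "hierarchical_spec")
}

# JAGS program for the hierarchical DTSD model. Data layer: per
# subject-by-condition cell, multinomial category counts for noise and
# signal trials. Cell parameters: d' = X beta_d + u_d[subject],
# probit(HT) = X beta_h + u_h[subject]. Criteria: population-level
# ordered vector (first point + positive increments) plus a
# subject-level additive shift, shared across conditions within
# subject. Tiny probability floors guard against underflow in extreme
# tails during burn-in.
hbm_model_string <- function(pc) {
  sprintf("
model {
  for (i in 1:N) {
    yn[i,1:K] ~ dmulti(pn[i,1:K], nn[i])
    ys[i,1:K] ~ dmulti(ps[i,1:K], ns[i])
    d[i] <- inprod(X[i,], bd[]) + ud[subj[i]]
    ht[i] <- phi(inprod(X[i,], bh[]) + uh[subj[i]])
    pn[i,1] <- max(phi(c[subj[i],1]), 1e-10)
    pr[i,1] <- phi(c[subj[i],1] - d[i])
    for (k in 2:(K-1)) {
      pn[i,k] <- max(phi(c[subj[i],k]) - phi(c[subj[i],k-1]), 1e-10)
      pr[i,k] <- phi(c[subj[i],k] - d[i]) - phi(c[subj[i],k-1] - d[i])
    }
    pn[i,K] <- max(1 - phi(c[subj[i],K-1]), 1e-10)
    pr[i,K] <- 1 - phi(c[subj[i],K-1] - d[i])
    for (k in 1:(K-1)) { ps[i,k] <- max((1 - ht[i]) * pr[i,k], 1e-10) }
    ps[i,K] <- max(ht[i] + (1 - ht[i]) * pr[i,K], 1e-10)
  }
  mu_c[1] ~ dnorm(%g, %g)
  for (k in 2:(K-1)) {
    minc[k-1] ~ dnorm(0, %g) T(0,)
    mu_c[k] <- mu_c[k-1] + minc[k-1]
  }
  sd_c ~ dnorm(0, %g) T(0,)
  # non-centered subject effects: better mixing when the data only
  # weakly identify the group-level scales
  for (s in 1:S) {
    zd[s] ~ dnorm(0, 1)
    zh[s] ~ dnorm(0, 1)
    zc[s] ~ dnorm(0, 1)
    ud[s] <- sd_d * zd[s]
    uh[s] <- sd_h * zh[s]
    for (k in 1:(K-1)) { c[s,k] <- mu_c[k] + sd_c * zc[s] }
  }
  for (p in 1:P) {
    bd[p] ~ dnorm(0, %g)
    bh[p] ~ dnorm(0, %g)
  }
  sd_d ~ dnorm(0, %g) T(0,)
  sd_h ~ dnorm(0, %g) T(0,)
}",
          pc$crit_first[1], 1 / pc$crit_first[2]^2,
          1 / pc$crit_inc_sd^2, 1 / pc$crit_shift_sd^2,
          1 / pc$fixed_sd^2, 1 / pc$fixed_sd^2,
          1 / pc$ranef_sd^2, 1 / pc$ranef_sd^2)
}

# Build the cell table and design matrix from a trial table.
hbm_design <- function(trials, spec, n_bins, n_points) {
  trials <- validate_trials(trials, n_points)
  subj <- sort(unique(trials$subject_id))
  if (length(subj) < 2L)
    stop("hierarchical fit needs at least 2 subjects", call. = FALSE)
  conds <- sort(unique(trials$condition))
  groups <- sort(unique(trials$group))
  cells <- unique(trials[, c("subject_id", "group", "condition")])
  cells <- cells[order(cells$subject_id, cells$condition), , drop = FALSE]
  K <- n_bins
  yn <- ys <- matrix(0L, nrow(cells), K)
  for (i in seq_len(nrow(cells))) {
    sub <- trials[trials$subject_id == cells$subject_id[i] &
                    trials$condition == cells$condition[i], , drop = FALSE]
    if (!all(c("normal", "abnormal") %in% sub$pathology))
      stop("subject ", cells$subject_id[i], " lacks a pathology class in ",
           "condition ", cells$condition[i], call. = FALSE)
    cnt <- bin_ratings(sub, K, n_points)
    yn[i, ] <- cnt$counts_noise
    ys[i, ] <- cnt$counts_signal
  }
  fe <- spec$fixed_effects
  X <- matrix(1, nrow(cells), 1, dimnames = list(NULL, "intercept"))
  if ("group" %in% fe && length(groups) > 1L)
    X <- cbind(X, group = as.integer(cells$group == groups[1]))
  if ("condition" %in% fe && length(conds) > 1L)
    X <- cbind(X, condition = as.integer(cells$condition == conds[2]))
  if ("interaction" %in% fe && all(c("group", "condition") %in% colnames(X)))
    X <- cbind(X, interaction = X[, "group"] * X[, "condition"])
  list(cells = cells, yn = yn, ys = ys, X = X,
       subj = match(cells$subject_id, subj), subjects = subj,
       groups = groups, conds = conds, K = K)
}

#' Fit the hierarchical Bayesian DTSD model
#'
#' Fits the multi-layer model by MCMC (JAGS): a multinomial trial layer
#' per subject-by-condition cell, subject random effects on both DTSD
#' parameters, a general linear model of the design factors on the
#' population level, and subject-shifted population criteria shared
#' across conditions within subject. Population effects are reported on
#' the link scale and, for HT, also on the probability scale (evaluated
#' at the typical subject, random effects at zero). Convergence is
#' checked with the Gelman-Rubin statistic; the fit fails loudly when
#' any monitored population parameter has R-hat above 1.05.
#'
#' @param trials Trial table (see [validate_trials()]).
#' @param spec A [hierarchical_spec()].
#' @param n_bins,n_points Rating binning (see [bin_ratings()]).
#' @return Object of class `"dtsd_hbm"`: a list with `summary` (data
#'   frame of effect, mean, hdi_low, hdi_high, rhat, ess), `draws`
#'   (named list of posterior draw vectors), `design`, and `spec`.
#' @export
fit_hbm <- function(trials, spec = hierarchical_spec(), n_bins = 20L,
                    n_points = 90L) {
  stopifnot(inherits(spec, "hierarchical_spec"))
  dz <- hbm_design(trials, spec, n_bins, n_points)
  dat <- list(yn = dz$yn, ys = dz$ys, nn = rowSums(dz$yn),
              ns = rowSums(dz$ys), X = dz$X, subj = dz$subj,
              N = nrow(dz$yn), K = dz$K, S = length(dz$subjects),
              P = ncol(dz$X))
  inits <- lapply(seq_len(spec$n_chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = derive_seed(spec$seed, ch))
  })
  jm <- rjags::jags.model(textConnection(hbm_model_string(spec$prior_config)),
                          data = dat, inits = inits,
                          n.chains = spec$n_chains,
                          n.adapt = min(500L, spec$n_warmup), quiet = TRUE)
  stats::update(jm, spec$n_warmup, progress.bar = "none")
  sm <- rjags::coda.samples(jm, c("bd", "bh", "sd_d", "sd_h", "ud", "uh"),
                            n.iter = spec$n_samples, progress.bar = "none")
  # JAGS drops the index on length-1 vectors ("bd" not "bd[1]")
  vn <- coda::varnames(sm)
  nd <- function(base, i) {
    ix <- paste0(base, "[", i, "]")
    if (ix %in% vn) ix else base
  }
  mon <- c(vapply(seq_len(ncol(dz$X)), function(i) nd("bd", i), ""),
           vapply(seq_len(ncol(dz$X)), function(i) nd("bh", i), ""),
           "sd_d", "sd_h")
  gd <- coda::gelman.diag(sm[, mon, drop = FALSE], autoburnin = FALSE,
                          multivariate = FALSE)
  rhat <- gd$psrf[, 1]
  if (any(rhat > 1.05)) {
    bad <- names(rhat)[rhat > 1.05]
    stop("MCMC did not converge (R-hat > 1.05): ",
         paste(sprintf("%s=%.3f", bad, rhat[bad]), collapse = ", "),
         call. = FALSE)
  }
  ess <- coda::effectiveSize(sm[, mon, drop = FALSE])
  dr <- as.matrix(sm)
  P <- ncol(dz$X)
  terms <- colnames(dz$X)
  draws <- list()
  for (p in seq_len(P)) {
    draws[[paste0("d_prime.", terms[p])]] <- dr[, nd("bd", p)]
    draws[[paste0("ht_link.", terms[p])]] <- dr[, nd("bh", p)]
  }
  # HT effects on the probability scale at the typical subject
  eta0 <- dr[, nd("bh", 1)]
  draws[["ht.intercept"]] <- pnorm(eta0)
  for (p in seq_len(P)[-1]) {
    draws[[paste0("ht.", terms[p])]] <-
      pnorm(eta0 + dr[, nd("bh", p)]) - pnorm(eta0)
  }
  draws[["sd.d_prime"]] <- dr[, "sd_d"]
  draws[["sd.ht_link"]] <- dr[, "sd_h"]
  summ <- do.call(rbind, lapply(names(draws), function(nm) {
    h <- hdi(draws[[nm]])
    data.frame(effect = nm, mean = mean(draws[[nm]]),
               hdi_low = h[["lower"]], hdi_high = h[["upper"]],
               stringsAsFactors = FALSE)
  }))
  diag_tab <- data.frame(param = mon, rhat = rhat[mon], ess = ess[mon],
                         row.names = NULL)
  # per-subject posterior means on the natural scale
  subj_eff <- data.frame(
    subject_id = dz$subjects,
    u_d = vapply(seq_along(dz$subjects),
                 function(s) mean(dr[, nd("ud", s)]), numeric(1)),
    u_h = vapply(seq_along(dz$subjects),
                 function(s) mean(dr[, nd("uh", s)]), numeric(1)))
  structure(list(summary = summ, draws = draws, convergence = diag_tab,
                 subject_effects = subj_eff, design = dz, spec = spec),
            class = "dtsd_hbm")
}

#' @export
print.dtsd_hbm <- function(x, ...) {
  cat("Hierarchical Bayesian DTSD fit (", length(x$design$subjects),
      " subjects, ", nrow(x$design$cells), " cells)\n", sep = "")
  s <- x$summary
  s$mean <- round(s$mean, 3); s$hdi_low <- round(s$hdi_low, 3)
  s$hdi_high <- round(s$hdi_high, 3)
  print(s, row.names = FALSE)
  cat("max R-hat:", round(max(x$convergence$rhat), 4), "\n")
  invisible(x)
}

#' Export a hierarchical fit's population summary as CSV
#'
#' Flat table `effect, mean, hdi_low, hdi_high` plus the convergence
#' diagnostics (`param, rhat, ess`) as a second file, and optionally the
#' raw population-level posterior draws (one column per effect) as a
#' third, so downstream tools can recompute any posterior functional.
#'
#' @param fit A [fit_hbm()] result.
#' @param dir Output directory.
#' @param draws Also write `posterior_draws.csv` (default `TRUE`).
#' @return Written paths, invisibly.
#' @export
write_hbm_summary <- function(fit, dir, draws = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "posterior_summary.csv")
  p2 <- file.path(dir, "convergence.csv")
  utils::write.csv(fit$summary, p1, row.names = FALSE)
  utils::write.csv(fit$convergence, p2, row.names = FALSE)
  paths <- c(p1, p2)
  if (draws) {
    p3 <- file.path(dir, "posterior_draws.csv")
    utils::write.csv(as.data.frame(fit$draws), p3, row.names = FALSE)
    paths <- c(paths, p3)
  }
  invisible(paths)
}
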