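test_that("hdi matches analytic normal quantiles and handles skew", {
  set.seed(3)
  z <- rnorm(10000)
  h <- hdi(z)
  expect_equal(h[["lower"]], -1.96, tolerance = 0.1)
  expect_equal(h[["upper"]], 1.96, tolerance = 0.1)
  # constant draws collapse to a point
  expect_equal(unname(hdi(rep(2.5, 500))), c(2.5, 2.5))
  # exponential draws: HDI starts at ~0 and beats the equal-tailed interval
  e <- rexp(10000)
  he <- hdi(e)
  expect_lt(he[["lower"]], 0.05)
  eq_tail <- unname(diff(quantile(e, c(0.025, 0.975))))
  expect_lt(he[["upper"]] - he[["lower"]], eq_tail)
  # agreement with the coda implementation
  hc <- coda::HPDinterval(coda::as.mcmc(z))
  expect_equal(unname(h), unname(hc[1, ]), tolerance = 1e-10)
  expect_error(hdi(z, mass = 1.2), "mass")
  expect_error(hdi(rnorm(10)), "100")
})

test_that("MLE recovers generating parameters from large samples", {
  set.seed(17)
  truth <- dtsd_params(1.5, 0.2, qnorm(1:19 / 20))
  cn <- as.vector(rmultinom(1, 10000, category_probabilities(truth, FALSE)))
  cs <- as.vector(rmultinom(1, 10000, category_probabilities(truth, TRUE)))
  fit <- fit_mle(cn, cs)
  expect_equal(fit$params$d_prime, 1.5, tolerance = 0.1)
  expect_equal(fit$params$ht, 0.2, tolerance = 0.1)
  expect_equal(fit$convergence, 0L)
  expect_true(all(diff(fit$params$criteria) > 0))
  # standard errors present and small at this n
  expect_lt(fit$se[["d_prime"]], 0.1)
})

test_that("MLE on chance data returns a null model", {
  cn <- rep(50L, 8)
  fit <- fit_mle(cn, cn, seed = 2)
  expect_equal(fit$params$d_prime, 0, tolerance = 0.05)
  expect_lt(fit$params$ht, 0.05)
})

test_that("MLE likelihood dominates a brute-force grid with profiled criteria", {
  # small 4-category ROC so the 50x50 (d', ht) grid stays cheap
  set.seed(23)
  truth <- dtsd_params(1.2, 0.25, c(-0.8, 0, 0.9))
  cn <- as.vector(rmultinom(1, 60, category_probabilities(truth, FALSE)))
  cs <- as.vector(rmultinom(1, 60, category_probabilities(truth, TRUE)))
  fit <- fit_mle(cn, cs, seed = 3)
  # oracle: profile the criteria by direct optimization at fixed (d', ht)
  profile_ll <- function(d, h) {
    nll <- function(th) {
      cr <- th[1] + c(0, cumsum(exp(th[-1])))
      if (any(diff(cr) <= 0) || any(!is.finite(cr))) return(1e10)
      p <- dtsd_params(d, h, cr)
      -sum(cn * log(pmax(category_probabilities(p, FALSE), 1e-12))) -
        sum(cs * log(pmax(category_probabilities(p, TRUE), 1e-12)))
    }
    -optim(c(-0.5, log(0.8), log(0.8)), nll, method = "BFGS")$value
  }
  grid <- expand.grid(d = seq(0, 3, length.out = 50),
                      h = seq(0, 0.6, length.out = 50))
  best_grid <- max(mapply(profile_ll, grid$d, grid$h))
  expect_gte(fit$logLik, best_grid - 1e-4)
})

test_that("hierarchical fit recovers a null condition effect", {
  # same parameters in both conditions: the effect HDI must contain 0
  des <- simulation_design(
    n_subjects = 10L, n_signal_trials = 60L, n_noise_trials = 60L,
    cell_params = data.frame(group = "g", condition = c("a", "b"),
                             d_prime = 1.0, ht = 0.1),
    subject_sd = c(d_prime = 0.1, ht = 0.1), n_bins = 6L,
    criteria = qnorm(1:5 / 6), seed = 61L)
  trials <- simulate_ratings(des)
  fit <- fit_hbm(trials,
                 hierarchical_spec(c("intercept", "condition"),
                                   profile = "fast", seed = 62L),
                 n_bins = 6L)
  s <- fit$summary
  dd <- s[s$effect == "d_prime.condition", ]
  dh <- s[s$effect == "ht.condition", ]
  expect_lt(dd$hdi_low, 0); expect_gt(dd$hdi_high, 0)
  expect_lt(dh$hdi_low, 0); expect_gt(dh$hdi_high, 0)
  # intercepts near the generating values
  expect_equal(s$mean[s$effect == "d_prime.intercept"], 1.0,
               tolerance = 0.3)
  expect_true(all(fit$convergence$rhat < 1.05))
  # HT posterior stays a probability
  expect_true(all(fit$draws$ht.intercept >= 0 &
                    fit$draws$ht.intercept < 1))
  # summary, diagnostics and draws export to flat CSVs
  dir <- withr::local_tempdir()
  paths <- write_hbm_summary(fit, dir)
  expect_true(all(file.exists(paths)))
  dr <- read.csv(file.path(dir, "posterior_draws.csv"))
  expect_equal(nrow(dr), length(fit$draws$ht.intercept))
})

test_that("posterior means are stable when the chains run longer", {
  des <- small_design(n_subjects = 6L, n_trials = 40L, n_bins = 6L,
                      seed = 71L)
  des$criteria <- qnorm(1:5 / 6)
  trials <- simulate_ratings(des)
  f1 <- fit_hbm(trials, hierarchical_spec("intercept", n_warmup = 1000L,
                                          n_samples = 2000L, seed = 72L),
                n_bins = 6L)
  f2 <- fit_hbm(trials, hierarchical_spec("intercept", n_warmup = 1000L,
                                          n_samples = 4000L, seed = 73L),
                n_bins = 6L)
  m1 <- f1$summary$mean[f1$summary$effect == "d_prime.intercept"]
  m2 <- f2$summary$mean[f2$summary$effect == "d_prime.intercept"]
  expect_lt(abs(m1 - m2), 0.02)
  h1 <- f1$summary$mean[f1$summary$effect == "ht.intercept"]
  h2 <- f2$summary$mean[f2$summary$effect == "ht.intercept"]
  expect_lt(abs(h1 - h2), 0.02)
})

test_that("degenerate subjects are absorbed by the criteria prior, not excluded", {
  # one subject rates everything at the scale extremes
  des <- small_design(n_subjects = 4L, n_trials = 15L, n_bins = 6L,
                      seed = 81L)
  des$criteria <- qnorm(1:5 / 6)
  trials <- simulate_ratings(des)
  one <- trials$subject_id == trials$subject_id[1]
  trials$rating[one] <- ifelse(trials$pathology[one] == "abnormal", 90L, 1L)
  fit <- fit_hbm(trials, hierarchical_spec("intercept", profile = "fast",
                                           seed = 82L), n_bins = 6L)
  expect_true(all(is.finite(fit$summary$mean)))
  # missing pathology class is a hard error, with the subject named
  bad <- trials[!(one & trials$pathology == "normal"), ]
  expect_error(fit_hbm(bad, hierarchical_spec("intercept",
                                              profile = "fast")),
               "lacks a pathology class")
})
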