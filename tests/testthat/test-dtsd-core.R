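test_that("parameter validation rejects invalid HT and unordered criteria", {
  expect_error(dtsd_params(1, 1, 0), "ht")
  expect_error(dtsd_params(1, -0.1, 0), "ht")
  expect_error(dtsd_params(1, 0.2, c(0.5, 0.5)), "increasing")
  expect_error(dtsd_params(1, 0.2, c(1, 0)), "increasing")
  expect_s3_class(dtsd_params(-0.2, 0, 0), "dtsd_params")
})

test_that("cumulative rates follow the closed form", {
  # null model: chance diagonal
  r0 <- cumulative_rates(dtsd_params(0, 0, qnorm(1:19 / 20)))
  expect_equal(r0$tpr, r0$fpr)
  # single criterion at 0 with d'=1.5, ht=0.2
  r1 <- cumulative_rates(dtsd_params(1.5, 0.2, 0))
  expect_equal(r1$fpr, 0.5)
  expect_equal(r1$tpr, 0.2 + 0.8 * pnorm(1.5), tolerance = 1e-10)
  # threshold saturation: ht near 1 pushes all tpr to 1
  r2 <- cumulative_rates(dtsd_params(0.3, 1 - 1e-9, c(-1, 0, 1)))
  expect_true(all(abs(r2$tpr - 1) < 1e-8))
  # zero-false-positive intercept equals ht as the criterion grows
  r3 <- cumulative_rates(dtsd_params(1.5, 0.2, 8))
  expect_lt(r3$fpr, 1e-8)
  expect_equal(r3$tpr, 0.2, tolerance = 1e-6)
  # rates ordered nondecreasing
  rr <- cumulative_rates(dtsd_params(1.2, 0.15, sort(rnorm(10))))
  expect_true(all(diff(rr$fpr) >= 0) && all(diff(rr$tpr) >= 0))
})

test_that("category probabilities normalize and match cumulative rates", {
  set.seed(42)
  for (i in 1:20) {
    p <- dtsd_params(runif(1, -0.5, 2.5), runif(1, 0, 0.6),
                     sort(rnorm(sample(2:19, 1))))
    ps <- category_probabilities(p, TRUE)
    pn <- category_probabilities(p, FALSE)
    expect_equal(sum(ps), 1, tolerance = 1e-12)
    expect_equal(sum(pn), 1, tolerance = 1e-12)
    # cumulative sums from the abnormal end reproduce the rates exactly
    K <- length(ps)
    r <- cumulative_rates(p)
    expect_equal(cumsum(rev(ps))[seq_len(K - 1)], r$tpr, tolerance = 1e-12)
    expect_equal(cumsum(rev(pn))[seq_len(K - 1)], r$fpr, tolerance = 1e-12)
  }
  # null model: signal and noise identical for symmetric criteria
  p0 <- dtsd_params(0, 0, seq(-2, 2, by = 0.5))
  expect_equal(category_probabilities(p0, TRUE),
               category_probabilities(p0, FALSE))
})

test_that("empirical AUC matches trapezoid cases and quadrature", {
  # chance curve
  expect_equal(auc_empirical(roc_curve(c(0.2, 0.5, 0.8), c(0.2, 0.5, 0.8))),
               0.5)
  # perfect discrimination
  expect_equal(auc_empirical(roc_curve(0, 1)), 1.0)
  expect_error(auc_empirical(data.frame(fpr = numeric(), tpr = numeric())),
               "empty")
  # dense theoretical curve vs numerical integration of the closed form:
  # AUC = integral over criteria of tpr(c) * phi(c) dc
  d <- 1.5; ht <- 0.2
  oracle <- integrate(function(cc) (ht + (1 - ht) * pnorm(d - cc)) * dnorm(cc),
                      -Inf, Inf)$value
  expect_equal(auc_empirical(theoretical_roc(d, ht, n = 4096, lim = 8)),
               oracle, tolerance = 1e-3)
})

test_that("binary d-prime inverts the normal model with continuity correction", {
  expect_equal(dprime_binary(0.5, 0.5), 0)
  expect_equal(dprime_binary(0.9466, 0.5), 1.613, tolerance = 1e-3)
  # monotone: hit > fa implies positive d'
  set.seed(7)
  h <- runif(30); f <- runif(30)
  ok <- h > f
  expect_true(all(dprime_binary(h[ok], f[ok]) > 0))
  # extreme rates are finite after correction
  expect_true(is.finite(dprime_binary(1, 0, n_signal = 20, n_noise = 20)))
  expect_equal(dprime_binary(1, 0.5, n_signal = 20),
               qnorm(1 - 1 / 40) - qnorm(0.5))
})

test_that("HT-free model gives an ROC symmetric about the minor diagonal", {
  # equal-variance SDT: tpr at criterion c equals 1 - fpr at (d' - c)
  d <- 1.3
  cr <- seq(-4, 4, length.out = 201)
  r <- cumulative_rates(dtsd_params(d, 0, cr))
  r_ref <- cumulative_rates(dtsd_params(d, 0, d - rev(cr)))
  expect_equal(r$tpr, rev(1 - r_ref$fpr), tolerance = 1e-12)
  expect_equal(r$fpr, rev(1 - r_ref$tpr), tolerance = 1e-12)
})

test_that("theoretical AUC increases in d-prime and in HT", {
  dg <- seq(0, 2.5, by = 0.5)
  auc_d <- vapply(dg, function(d)
    auc_empirical(theoretical_roc(d, 0.2)), numeric(1))
  expect_true(all(diff(auc_d) > 0))
  hg <- seq(0, 0.8, by = 0.2)
  auc_h <- vapply(hg, function(h)
    auc_empirical(theoretical_roc(1.0, h)), numeric(1))
  expect_true(all(diff(auc_h) > 0))
})

test_that("tpr dominates fpr whenever both components are nonnegative", {
  set.seed(11)
  for (i in 1:25) {
    r <- cumulative_rates(dtsd_params(runif(1, 0, 3), runif(1, 0, 0.9),
                                      sort(rnorm(8))))
    expect_true(all(r$tpr >= r$fpr - 1e-12))
  }
})
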