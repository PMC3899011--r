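test_that("single-d regression reproduces closed-form least squares", {
  # (9, 5, 3) with d = 1 -> log points (log 8, log 4, log 2): exactly linear
  fit <- fit_linear_given_d(overlap_curve(c(9, 5, 3)), d = 1)
  expect_equal(fit$beta, log(0.5), tolerance = 1e-12)
  expect_equal(fit$alpha, log(16), tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  # noiseless geometric curve at d = 0
  geo <- overlap_curve(1000 * 0.5^(1:6))
  g <- fit_linear_given_d(geo, d = 0)
  expect_equal(g$r2, 1, tolerance = 1e-12)
  expect_equal(g$beta, log(0.5), tolerance = 1e-10)
  expect_equal(g$residual_sd, 0, tolerance = 1e-10)

  # published cadmium example: adjusted R-squared at d = 233
  cd <- fit_linear_given_d(cd_curve(), d = 233)
  expect_equal(round(cd$adj_r2, 3), 0.993)

  expect_error(fit_linear_given_d(overlap_curve(c(9, 5, 3)), d = 3), "y_k <= d")
  expect_error(fit_linear_given_d(overlap_curve(c(9, 5)), d = 1), "3 curve points")
})

test_that("regression agrees with stats::lm across the d grid to 1e-10", {
  curve <- cd_curve()
  for (d in c(0, 1, 50, 100, 200, 233, 234, 280, 284)) {
    ours <- fit_linear_given_d(curve, d)
    ref <- lm_log_fit(curve$y, curve$k, d)
    expect_equal(ours$alpha, ref$alpha, tolerance = 1e-10)
    expect_equal(ours$beta, ref$beta, tolerance = 1e-10)
    expect_equal(ours$r2, ref$r2, tolerance = 1e-10)
    expect_equal(ours$adj_r2, ref$adj_r2, tolerance = 1e-10)
    expect_equal(ours$residual_sd, ref$residual_sd, tolerance = 1e-10)
  }
  # the grid-search profile is the same computation
  fit <- soflr_fit(curve)
  at <- fit$profile[fit$profile$d == 233, ]
  expect_equal(at$adj_r2, lm_log_fit(curve$y, curve$k, 233)$adj_r2,
               tolerance = 1e-10)
})

test_that("grid search recovers the exact d on noiseless decay curves", {
  fit <- soflr_fit(overlap_curve(c(8, 4, 2)))
  expect_identical(fit$d_hat, 0L)
  expect_equal(fit$r2, 1, tolerance = 1e-9)

  k <- 1:6
  fit2 <- soflr_fit(overlap_curve(50 + 1000 * 0.3^k))
  expect_identical(fit2$d_hat, 50L)
  expect_equal(fit2$p_hat, 0.3, tolerance = 1e-6)
  expect_equal(fit2$T_hat, 1000, tolerance = 1e-4)

  # the true d attains R-squared 1 for several parameter combinations
  for (cfg in list(c(10, 400, 0.5), c(233, 2500, 0.52), c(0, 120, 0.7))) {
    y <- cfg[1] + cfg[2] * cfg[3]^(1:7)
    f <- soflr_fit(overlap_curve(y))
    expect_identical(f$d_hat, as.integer(cfg[1]))
    expect_equal(f$adj_r2, 1, tolerance = 1e-8)
  }

  expect_error(soflr_fit(overlap_curve(c(0.9, 0.5, 0.2))), "candidate range")
})

test_that("d selection is invariant to the logarithm base", {
  curve <- cd_curve()
  fit <- soflr_fit(curve)
  adj10 <- vapply(0:284, function(d) {
    lm_log_fit(curve$y, curve$k, d, base = 10)$adj_r2
  }, numeric(1))
  expect_identical(fit$d_hat, as.integer(which.max(adj10) - 1L))
  expect_equal(max(adj10), fit$adj_r2, tolerance = 1e-12)
})

test_that("predictions decay monotonically to the driver asymptote", {
  fit <- soflr_fit(overlap_curve(10 + 100 * 0.5^(1:6)))
  expect_identical(fit$d_hat, 10L)
  expect_equal(predict_common_genes(fit, 3), 22.5, tolerance = 1e-6)
  expect_equal(predict_common_genes(fit, 1e6), fit$d_hat, tolerance = 1e-6)
  pred <- predict_common_genes(fit, 1:30)
  expect_true(all(diff(pred) < 0))

  # in-sample log-scale residual at the last observed point stays within the
  # largest observed residual
  cd <- soflr_fit(cd_curve())
  res_all <- abs(log(cd$curve$y - cd$d_hat) - (cd$alpha + cd$beta * cd$curve$k))
  res6 <- abs(log(cd$curve$y[6] - cd$d_hat) - (cd$alpha + cd$beta * 6))
  expect_lte(res6, max(res_all))
})

test_that("required isolates reduces to the point prediction when noiseless", {
  fit <- soflr_fit(overlap_curve(1000 * 0.5^(1:6)))
  expect_identical(fit$d_hat, 0L)
  req <- required_isolates(fit, tol = 0.5)
  # smallest x with 1000 * 0.5^x < 0.5
  expect_identical(req$n_required, 11L)
  expect_lt(req$ci_upper - fit$d_hat, 0.5)
  expect_gte(req$ci_lower, fit$d_hat)
})

test_that("required isolates is monotone in tolerance and confidence", {
  set.seed(19)
  for (rep in 1:5) {
    d <- sample(0:50, 1); Tg <- runif(1, 200, 2000); p <- runif(1, 0.3, 0.7)
    y <- d + Tg * p^(1:7) * exp(rnorm(7, 0, 0.05))
    fit <- soflr_fit(overlap_curve(sort(y, decreasing = TRUE)))
    tols <- c(0.25, 0.5, 1, 2)
    ns <- vapply(tols, function(tl) {
      required_isolates(fit, tol = tl)$n_required
    }, integer(1))
    expect_true(all(diff(ns) <= 0)) # looser tolerance never needs more
    confs <- c(0.8, 0.9, 0.95, 0.99)
    nc <- vapply(confs, function(cf) {
      required_isolates(fit, confidence = cf)$n_required
    }, integer(1))
    expect_true(all(diff(nc) >= 0)) # higher confidence never needs fewer
  }
})

test_that("4PL comparator handles flat curves and recovers its own model", {
  flat <- fit_4pl(overlap_curve(rep(42, 5)))
  expect_equal(unname(flat$coef["lower_asymptote"]), 42)
  expect_equal(unname(flat$coef["upper_asymptote"]), 42)

  k <- 1:8
  y <- 100 + (2000 - 100) / (1 + (k / 2)^1.5)
  fit <- fit_4pl(overlap_curve(y))
  expect_equal(unname(fit$coef["lower_asymptote"]), 100, tolerance = 1e-4)
  expect_equal(unname(fit$coef["upper_asymptote"]), 2000, tolerance = 1e-4)
  expect_equal(unname(fit$coef["inflection"]), 2, tolerance = 1e-4)
  expect_equal(unname(fit$coef["slope"]), 1.5, tolerance = 1e-4)
  expect_equal(predict(fit, k), y, tolerance = 1e-6)

  expect_error(fit_4pl(overlap_curve(c(3, 2, 1))), "at least 4")
})

test_that("tidy, glance and plots expose the fit", {
  fit <- soflr_fit(cd_curve())
  td <- tidy(fit)
  expect_setequal(td$term, c("d_hat", "alpha", "beta", "T_hat", "p_hat"))
  gl <- glance(fit)
  expect_equal(gl$adj_r2, fit$adj_r2)
  expect_s3_class(plot_d_profile(fit), "ggplot")
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
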