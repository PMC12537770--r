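tt_10min <- seq(0, 24, by = 1/6)

test_that("growth_curve validates its inputs", {
  expect_error(growth_curve(1:3, c(0.1, 0.2, 0.3)), "at least 4")
  expect_error(growth_curve(c(0, 1, 1, 2), c(1, 2, 3, 4)), "strictly increasing")
  expect_error(growth_curve(0:3, c(0.1, NA, 0.3, 0.4)), "finite")
  expect_error(growth_curve(0:3, c(0.1, 0.2)), "same length")
})

test_that("noiseless logistic data is recovered to high precision", {
  cases <- expand.grid(K = c(0.1, 0.5, 1.0, 2.0), r = c(0.1, 0.5, 1.5))
  for (i in seq_len(nrow(cases))) {
    K <- cases$K[i]; r <- cases$r[i]; N0 <- 0.05 * K
    fit <- fit_logistic(growth_curve(tt_10min, oracle_logistic(tt_10min, K, r, N0)))
    expect_true(fit$converged)
    expect_equal(unname(coef(fit)), c(K, r, N0), tolerance = 1e-6)
    expect_lt(fit$sse, 1e-10)
  }
})

test_that("noisy-curve rate estimate matches the grid-search oracle", {
  # oracle: coarse SSE grid search over (K, r, N0) on the identical data
  # (seed 42, sigma 0.01, K=1, r=0.5, N0=0.01) located the optimum at
  # r = 0.505 with grid resolution 0.005
  set.seed(42)
  od <- oracle_logistic(tt_10min, 1, 0.5, 0.01) + rnorm(length(tt_10min), 0, 0.01)
  fit <- fit_logistic(growth_curve(tt_10min, od))
  expect_true(fit$converged)
  expect_lt(abs(fit$r - 0.505), 0.01)
  # NLS optimum cannot be worse than the best grid point it bracketed
  expect_lte(fit$sse, 0.0147353 + 1e-6)
})

test_that("flat or declining series report no growth instead of erroring", {
  flat <- fit_logistic(growth_curve(tt_10min, rep(0.006, length(tt_10min))))
  expect_false(flat$converged)
  expect_match(flat$reason, "no growth detected")
  expect_equal(flat$max_od, 0.006)
  declining <- fit_logistic(growth_curve(0:23, 0.5 * exp(-0.1 * (0:23))))
  expect_false(declining$converged)
})

test_that("parameter recovery: median r error under measurement noise stays small", {
  set.seed(7)
  errs <- replicate(50, {
    K <- runif(1, 0.5, 1.5); r <- runif(1, 0.3, 1.0); N0 <- runif(1, 0.005, 0.05)
    od <- pmax(oracle_logistic(tt_10min, K, r, N0) + rnorm(length(tt_10min), 0, 0.01), 0)
    fit <- fit_logistic(growth_curve(tt_10min, od))
    if (fit$converged) abs(fit$r - r) / r else NA_real_
  })
  expect_true(all(!is.na(errs)))
  expect_lt(median(errs), 0.05)
})

test_that("logistic_fit methods are coherent", {
  od <- oracle_logistic(tt_10min, 1, 0.5, 0.01)
  fit <- fit_logistic(growth_curve(tt_10min, od, sample_id = "A1"))
  expect_equal(predict(fit, tt_10min), fitted(fit))
  expect_equal(residuals(fit), od - fitted(fit))
  expect_output(print(fit), "Logistic fit")
  expect_output(summary(fit), "doubling time")
})

test_that("spent-media difference is the ratio minus one and is monotone", {
  expect_identical(spent_media_difference(0.8, 0.8), 0)
  expect_identical(spent_media_difference(0.4, 0.8), -0.5)
  expect_equal(spent_media_difference(1.2, 0.8), 0.5)
  expect_error(spent_media_difference(0.5, 0), "positive")
  # strictly increasing in growth_in_spent
  xs <- seq(0.1, 2, by = 0.1)
  expect_true(all(diff(spent_media_difference(xs, 0.8)) > 0))
  # zero whenever arguments are equal
  expect_equal(spent_media_difference(xs, xs), rep(0, length(xs)))
})

test_that("one-standard-deviation prediction rule, including boundaries", {
  gs <- function(m, s) structure(list(strain_id = "s", mean_r = m, sd_r = s,
                                      n_replicates = 5L),
                                 class = "growth_rate_summary")
  expect_identical(predict_pairwise_outcome(gs(0.9, 0.05), gs(0.5, 0.1)),
                   "competitor_excludes_focal")
  expect_identical(predict_pairwise_outcome(gs(0.55, 0.05), gs(0.5, 0.1)),
                   "coexist")
  # boundary: difference exactly one focal SD counts as within
  expect_identical(predict_pairwise_outcome(gs(0.6, 0.05), gs(0.5, 0.1)),
                   "coexist")
  expect_identical(predict_pairwise_outcome(gs(0.4, 0.05), gs(0.5, 0.1)),
                   "focal_excludes_competitor")
  # swapping arguments reflects the label
  swap <- c(competitor_excludes_focal = "focal_excludes_competitor",
            focal_excludes_competitor = "competitor_excludes_focal",
            coexist = "coexist")
  set.seed(11)
  for (i in 1:25) {
    a <- gs(runif(1, 0.2, 1), runif(1, 0.01, 0.2))
    b <- gs(runif(1, 0.2, 1), runif(1, 0.01, 0.2))
    expect_identical(predict_pairwise_outcome(a, b),
                     unname(swap[predict_pairwise_outcome(b, a)]))
  }
  one_rep <- growth_rate_summary("x", 0.5)
  expect_error(predict_pairwise_outcome(one_rep, gs(0.5, 0.1)), "sd_r undefined")
})

test_that("growth_rate_summary aggregates replicate rates", {
  s <- growth_rate_summary("ecoli", c(0.68, 0.72, 0.70, 0.69, 0.71))
  expect_equal(s$mean_r, 0.7)
  expect_equal(s$sd_r, sd(c(0.68, 0.72, 0.70, 0.69, 0.71)))
  expect_equal(s$n_replicates, 5L)
})

test_that("blank correction subtracts a constant and floors at 1e-6", {
  expect_equal(blank_correct(c(0.5, 0.05), 0.04), c(0.46, 0.01))
  expect_equal(blank_correct(c(0.03), 0.05), 1e-6)
})

test_that("fit_plate fits every well and carries the map through", {
  truth <- data.frame(strain_id = c("a", "b"), K = c(1, 0.6),
                      r = c(0.6, 0.3), N0 = c(0.01, 0.01))
  synth <- gen_od_curves(truth, replicates = 3, od_noise_sd = 0.005, seed = 3)
  fits <- fit_plate(synth$plate, synth$map)
  expect_equal(nrow(fits), 6L)
  expect_true(all(fits$converged))
  expect_setequal(fits$sample_id, synth$map$well)
  ra <- fits$r_fit[fits$strain_id == "a"]
  rb <- fits$r_fit[fits$strain_id == "b"]
  expect_true(all(abs(ra - 0.6) / 0.6 < 0.1))
  expect_true(all(abs(rb - 0.3) / 0.3 < 0.1))
})
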