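test_that("the offset/scale map is exact on affine data and flags
           degenerate model values", {
  f <- fit_linear_map(1:5, 3 + 2 * (1:5))
  expect_equal(f$offset, 3)
  expect_equal(f$scale, 2)
  expect_equal(f$mse, 0)
  expect_equal(f$r2, 1)
  expect_false(f$degenerate)
  # constant model values: scale undefined by convention 0, R2 = 0
  g <- fit_linear_map(rep(2, 4), c(1, 2, 3, 4))
  expect_true(g$degenerate)
  expect_equal(g$scale, 0)
  expect_equal(g$offset, 2.5)
  expect_equal(g$r2, 0)
  expect_error(fit_linear_map(1:3, 1:4), "equal length")
  expect_error(fit_linear_map(1:2, 1:2), "at least 3")
})

test_that("closed-form least squares attains the brute-force grid minimum", {
  withr::local_seed(51)
  x <- rnorm(20)
  z <- 1.3 + 0.7 * x + rnorm(20, sd = 0.3)
  f <- fit_linear_map(x, z)
  # cross-check against lm and against an explicit 2-parameter grid
  lm_fit <- lm(z ~ x)
  expect_equal(f$offset, unname(coef(lm_fit)[1]))
  expect_equal(f$scale, unname(coef(lm_fit)[2]))
  grid_min <- oracle_linear_mse(x, z,
                                seq(f$offset - 0.1, f$offset + 0.1,
                                    length.out = 101),
                                seq(f$scale - 0.1, f$scale + 0.1,
                                    length.out = 101))
  expect_lt(f$mse, grid_min + 1e-8)
})

test_that("weighted least squares honors the weights", {
  x <- c(1, 2, 3, 10)
  z <- c(2, 4, 6, 0)
  w <- c(1, 1, 1, 0) # drop the discordant point
  f <- fit_linear_map(x, z, weights = w)
  expect_equal(f$scale, 2, tolerance = 1e-12)
  expect_equal(f$mse, 0, tolerance = 1e-12)
  expect_error(fit_linear_map(x, z, weights = c(-1, 1, 1, 1)), "nonnegative")
})

test_that("BIC follows n log(MSE) + k log(n) with natural logarithms", {
  expect_equal(bic_mse(1, n = 10, k = 0), 0)
  expect_equal(bic_mse(0.47, n = 48, k = 3), 48 * log(0.47) + 3 * log(48))
  # equal MSE, one extra parameter: penalty log(n)
  expect_equal(bic_mse(0.3, 48, 3) - bic_mse(0.3, 48, 2), log(48))
  expect_error(bic_mse(0, 10, 2), "degenerate")
  # strictly increasing in MSE
  expect_gt(bic_mse(0.5, 48, 3), bic_mse(0.4, 48, 3))
})

test_that("pattern-level data validation enforces the schema", {
  good <- tibble::tibble(condition = 0.5,
                         pattern = c("XXXXX", "XYXYX", "YYYYX"),
                         value = c(1, 2, 3))
  expect_silent(validate_pattern_data(good))
  expect_error(validate_pattern_data(good[, -3]), "missing column")
  bad <- good
  bad$pattern[2] <- "XYXYY" # does not end in X
  expect_error(validate_pattern_data(bad), "ending in X")
  dup <- dplyr::bind_rows(good, good[1, ])
  expect_error(validate_pattern_data(dup), "duplicated")
  expect_error(validate_pattern_data(good[0, ]), "no rows")
})

test_that("grid search recovers itself on noiseless self-generated data and
           reports a minimum at the grid optimum", {
  theo <- simulate_pattern_surprise("transition", "leaky",
                                    param_grid = c(4, 8, 16, 32),
                                    n_reps = 40, seed = 52)
  data <- theo[theo$param == 8, c("condition", "pattern", "mean_surprise")]
  names(data)[3] <- "value"
  fit <- fit_observer_grid(data, "transition", "leaky",
                           param_grid = c(4, 8, 16, 32), n_reps = 40,
                           seed = 52)
  expect_equal(fit$best_param, 8)
  expect_lt(fit$best$mse, 1e-20) # same seed: exact self-recovery
  expect_equal(fit$best$r2, 1, tolerance = 1e-8)
  expect_equal(fit$n, 48L)
  expect_equal(fit$k, 3L)
  # the recorded best is the grid minimum
  expect_equal(min(fit$grid$mse), fit$grid$mse[fit$grid$param == 8])
})

test_that("argmin ties break toward the smallest parameter", {
  theo <- tibble::tibble(
    param = rep(c(2, 5), each = 3),
    condition = rep(0.5, 6),
    pattern = rep(c("XXXXX", "XYXYX", "YYYYX"), 2),
    mean_surprise = rep(c(1, 2, 3), 2), # identical values for both params
    n = 10
  )
  data <- tibble::tibble(condition = 0.5,
                         pattern = c("XXXXX", "XYXYX", "YYYYX"),
                         value = c(2, 4, 6))
  fit <- seqsurprise:::fit_observer_grid_theo(data, theo, "item", "leaky")
  expect_equal(fit$best_param, 2)
})

test_that("perfect-integration fits have no internal parameter", {
  theo <- simulate_pattern_surprise("item", "perfect", n_reps = 30,
                                    seed = 53)
  data <- theo[, c("condition", "pattern", "mean_surprise")]
  names(data)[3] <- "value"
  fit <- seqsurprise:::fit_observer_grid_theo(data, theo, "item", "perfect")
  expect_equal(fit$k, 2L)
  expect_true(is.na(fit$best_param))
})

test_that("key mismatches between data and simulation are reported", {
  theo <- simulate_pattern_surprise("item", "leaky", param_grid = 8,
                                    n_reps = 5, seed = 54)
  data <- tibble::tibble(condition = 0.9, pattern = "XXXXX", value = 1)
  data <- dplyr::bind_rows(
    data,
    tibble::tibble(condition = 0.9, pattern = c("XYXYX", "YYXXX"),
                   value = c(1, 2))
  )
  expect_error(
    seqsurprise:::fit_observer_grid_theo(data, theo, "item", "leaky"),
    "not produced by the simulation"
  )
})

test_that("leave-one-out self-prediction error is at the Monte-Carlo floor
           and tidiers summarize fits", {
  theo_data <- simulate_pattern_surprise("transition", "leaky",
                                         param_grid = 16, n_reps = 60,
                                         seed = 55)
  data <- theo_data[, c("condition", "pattern", "mean_surprise")]
  names(data)[3] <- "value"
  loo <- loo_accuracy(data, "transition", "leaky",
                      param_grid = c(8, 16, 24), n_reps = 60, seed = 56)
  expect_equal(nrow(loo$per_point), 48L)
  expect_lt(loo$mean_error, 0.06) # different seed: pure Monte-Carlo error
  expect_true(all(loo$per_point$error >= 0))

  fit <- fit_observer_grid(data, "transition", "leaky",
                           param_grid = c(8, 16, 24), n_reps = 60,
                           seed = 56)
  td <- tidy(fit)
  expect_equal(names(td), c("param", "mse", "r2", "offset", "scale"))
  gl <- glance(fit)
  expect_equal(gl$nobs, 48L)
  gl_loo <- glance(loo)
  expect_equal(gl_loo$mean_error, loo$mean_error)
  lin <- fit_linear_map(1:5, 2 * (1:5))
  expect_equal(tidy(lin)$estimate, c(0, 2))
  expect_equal(glance(lin)$r.squared, 1)
})

test_that("the BIC comparison table ranks models relative to the best", {
  theo_data <- simulate_pattern_surprise("transition", "leaky",
                                         param_grid = 16, n_reps = 40,
                                         seed = 57)
  data <- theo_data[, c("condition", "pattern", "mean_surprise")]
  names(data)[3] <- "value"
  fits <- list(
    trans_leaky = fit_observer_grid(data, "transition", "leaky",
                                    param_grid = c(8, 16), n_reps = 40,
                                    seed = 58),
    item_leaky = fit_observer_grid(data, "item", "leaky",
                                   param_grid = c(8, 16), n_reps = 40,
                                   seed = 58)
  )
  tab <- bic_table(fits)
  expect_equal(nrow(tab), 2L)
  expect_equal(min(tab$delta_bic), 0)
  # data generated from the transition family must favor it
  expect_equal(tab$model[1], "trans_leaky")
})
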