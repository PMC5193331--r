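# Experiment pipelines at reduced problem sizes; the full-size study
# conditions are exercised in test-acceptance.R.

test_that("surprise trees contain every full pattern cell, plus weighted
           shorter patterns", {
  tree <- squires_tree(observer("transition", "leaky", omega = 16),
                       n_reps = 20, seed = 31)
  full <- tree[tree$length == 5, ]
  expect_equal(nrow(full), 16 * 3)
  expect_true(all(full$n > 0))
  expect_true(all(endsWith(full$pattern, "X")))
  expect_setequal(unique(full$condition), c(0.3, 0.5, 0.7))
  # shorter patterns are frequency-weighted averages of length-5 cells
  l4 <- tree[tree$length == 4 & tree$condition == 0.5, ]
  for (i in seq_len(nrow(l4))) {
    members <- full[full$condition == 0.5 &
                      substr(full$pattern, 2, 5) == l4$pattern[i], ]
    expect_equal(l4$mean_surprise[i],
                 sum(members$mean_surprise * members$n) / sum(members$n))
    expect_equal(l4$n[i], sum(members$n))
  }
  # the root (length 1, pattern "X") aggregates everything
  root <- tree[tree$length == 1 & tree$condition == 0.5, ]
  expect_equal(root$n, sum(full$n[full$condition == 0.5]))
})

test_that("trees support the length-4 pattern dialect", {
  tree4 <- squires_tree(observer("item", "leaky", omega = 12),
                        n_reps = 10, pattern_len = 4, seed = 32)
  full <- tree4[tree4$length == 4, ]
  expect_equal(nrow(full), 8 * 3)
})

test_that("streak summaries classify every cell and respect the cap", {
  st <- huettel_streaks(observer("transition", "leaky", omega = 6),
                        n_stim = 2e4, seed = 33)
  expect_setequal(unique(st$streak), c("repetition", "alternation"))
  expect_setequal(unique(st$outcome), c("continued", "violated"))
  expect_true(all(st$length >= 2 & st$length <= 8))
  expect_true(all(st$n > 0))
  # violations are more surprising than continuations: cell by cell for
  # repetition streaks, on average for alternation streaks (odd-length
  # alternation runs end on a repetition pair whose evidence supports the
  # violation, so their per-cell gap wobbles with parity)
  wide <- tidyr::pivot_wider(tibble::as_tibble(st),
                             id_cols = c("streak", "length"),
                             names_from = "outcome",
                             values_from = "mean_surprise")
  gap <- wide$violated - wide$continued
  expect_true(all(gap[wide$streak == "repetition"] > 0))
  expect_gt(mean(gap[wide$streak == "alternation"]), 0)
})

test_that("R/A summaries cover the 16 codes in canonical order", {
  ra <- cho_patterns(observer("transition", "leaky", omega = 3),
                     n_stim = 2e4, seed = 34)
  expect_equal(as.character(ra$code), seqsurprise:::RA_LEVELS)
  expect_true(all(ra$n > 0))
})

test_that("entropy curves cover the sweep and respond to the leak", {
  cur <- falk_entropy_curve("transition", omega = c(2, 8),
                            p_alt = seq(0.1, 0.9, by = 0.2),
                            n_reps = 500, seed = 35)
  expect_equal(nrow(cur), 2 * 5)
  expect_true(all(cur$mean_entropy >= 0 & cur$mean_entropy <= 1))
  expect_true(all(cur$n == 500))
  # both generation modes and both readout modes run
  cur2 <- falk_entropy_curve("alternation", omega = 4, p_alt = c(0.4, 0.6),
                             n_reps = 200, seed = 36,
                             mode = "average_over_sequence",
                             generation = "exact_ratio")
  expect_equal(nrow(cur2), 2L)
})

test_that("batch entropy equals per-sequence observer predictions", {
  # the vectorized recursion must agree with predict_next sequence by
  # sequence, for every statistic
  withr::local_seed(37)
  ymat <- seqsurprise:::alt_sequence_matrix(0.6, 21, 10, "bernoulli")
  for (stat in c("item", "alternation", "transition")) {
    h_batch <- seqsurprise:::batch_entropy(ymat, stat, 16,
                                           mode = "last_prediction")
    h_single <- vapply(seq_len(nrow(ymat)), function(i) {
      predict_next(seq_tbl(ymat[i, ]),
                   observer(stat, "leaky", omega = 16))$entropy
    }, 0)
    expect_equal(h_batch, h_single, tolerance = 1e-12)
  }
})

test_that("exact-ratio generation fixes the number of alternations", {
  withr::local_seed(38)
  ymat <- seqsurprise:::alt_sequence_matrix(0.6, 21, 50, "exact_ratio")
  n_alt <- apply(ymat, 1, function(r) sum(diff(r) != 0))
  expect_true(all(n_alt == round(0.6 * 20)))
})

test_that("the change-point demonstration contrasts the three inference
           styles", {
  demo <- changepoint_demo(seed = 39, n_stim = 200, change_at = 100,
                           resolution = 25)
  expect_s3_class(demo, "changepoint_demo")
  expect_equal(nrow(demo$sequence), 200L)
  expect_setequal(unique(demo$traces$model),
                  c("perfect", "leaky", "dynamic"))
  post <- demo$posteriors
  expect_true(all(c("trial", "dim", "theta", "w", "model") %in% names(post)))
  # final leaky posterior mean of theta_x_given_y sits nearer the
  # second-regime value (1/3) than the perfect-integration one, which
  # blends both halves
  mean_final <- function(model) {
    sl <- post[post$model == model & post$trial == 200 &
                 post$dim == "theta_x_given_y", ]
    sum(sl$theta * sl$w)
  }
  expect_lt(abs(mean_final("leaky") - 1 / 3),
            abs(mean_final("perfect") - 1 / 3))
})

test_that("experiment outputs are deterministic given the seed", {
  a <- squires_tree(observer("item", "leaky", omega = 10), n_reps = 5,
                    seed = 40)
  b <- squires_tree(observer("item", "leaky", omega = 10), n_reps = 5,
                    seed = 40)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  ca <- cho_patterns(observer("item", "perfect"), n_stim = 3000, seed = 41)
  cb <- cho_patterns(observer("item", "perfect"), n_stim = 3000, seed = 41)
  expect_identical(tibble::as_tibble(ca), tibble::as_tibble(cb))
})
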