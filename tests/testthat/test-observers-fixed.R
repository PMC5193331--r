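test_that("conjugate posterior adds one pseudocount per dimension", {
  p0 <- beta_posterior(c(n_x = 0, n_y = 0))
  expect_equal(p0$shape1, 1)
  expect_equal(p0$shape2, 1)
  p1 <- beta_posterior(count_events(seq_from_string("XXXXXX"), "item"))
  expect_equal(p1$shape1, 7)
  expect_equal(p1$shape2, 1)
  # posterior mode of Beta(7, 1) is 1, checked by grid maximization
  expect_equal(oracle_beta_mode(7, 1), 1)
  expect_equal(oracle_beta_mode(3, 2), (3 - 1) / (3 + 2 - 2), tolerance = 1e-4)
  pt <- beta_posterior(count_events(seq_from_string("XXXXXXX"), "transition"))
  expect_equal(pt$shape1[pt$dim == "theta_y_given_x"], 1)
  expect_equal(pt$shape2[pt$dim == "theta_y_given_x"], 7)
  expect_error(beta_posterior(c(n_x = -1, n_y = 0)), "nonnegative")
})

test_that("predictive equals the Laplace posterior mean, matching integration", {
  flat <- beta_posterior(c(n_x = 0, n_y = 0))
  expect_equal(predictive_fixed(flat), 0.5)
  p <- beta_posterior(c(n_x = 6, n_y = 0))
  expect_equal(predictive_fixed(p), 7 / 8)
  expect_equal(predictive_fixed(p), oracle_predictive_item(6, 0),
               tolerance = 1e-8)
  # transition statistic after XXXXXXX, conditioned on the last X
  pt <- beta_posterior(count_events(seq_from_string("XXXXXXX"), "transition"))
  expect_equal(predictive_fixed(pt, last_symbol = "X"), 7 / 8)
  expect_equal(predictive_fixed(pt, last_symbol = "X"),
               1 - oracle_predictive_item(0, 6), tolerance = 1e-8)
  expect_error(predictive_fixed(pt), "last_symbol")
})

test_that("fixed-belief conjugate posterior matches grid integration", {
  y <- sim_item_seq(0.6, 40, seed = 9)
  counts <- count_events(y, "item")
  post <- beta_posterior(counts)
  m <- 4000L
  g <- (seq_len(m) - 0.5) / m
  raw <- g^counts$n_x * (1 - g)^counts$n_y
  grid_dens <- raw / sum(raw)
  conj_dens <- dbeta(g, post$shape1, post$shape2)
  conj_dens <- conj_dens / sum(conj_dens)
  expect_lt(max(abs(grid_dens - conj_dens) / conj_dens), 1e-8)
})

test_that("the perfect item observer follows the Laplace rule sequence", {
  tr <- run_observer(seq_from_string("XXXX"), observer("item", "perfect"))
  expect_equal(tr$p_pred, c(1 / 2, 2 / 3, 3 / 4, 4 / 5))
  expect_equal(tr$surprise, -log2(tr$p_pred))
  expect_equal(nrow(tr), 4L)
})

test_that("the alternation observer equals an item observer on the recoded
           sequence, for every integration scheme", {
  y <- sim_item_seq(0.5, 120, seed = 10)
  rec <- seq_tbl(recode_alternation(y)$code)
  schemes <- list(
    observer("alternation", "perfect"),
    observer("alternation", "leaky", omega = 5),
    observer("alternation", "windowed", n = 12)
  )
  items <- list(
    observer("item", "perfect"),
    observer("item", "leaky", omega = 5),
    observer("item", "windowed", n = 12)
  )
  for (i in seq_along(schemes)) {
    tr_alt <- run_observer(y, schemes[[i]])
    tr_item <- run_observer(rec, items[[i]])
    # prediction at original trial t corresponds to recoded position t - 1;
    # for the windowed scheme the item window must count pairs
    if (schemes[[i]]$integration == "windowed") {
      tr_item <- run_observer(rec, observer("item", "windowed", n = 11))
    }
    expect_equal(tr_alt$p_pred[-(1:2)], tr_item$p_pred[-1], tolerance = 1e-12)
  }
})

test_that("perfect item predictions are exchangeable in the history;
           leaky and windowed predictions are not", {
  y <- symbols_of(sim_item_seq(0.5, 30, seed = 11))
  perm <- withr::with_seed(1, sample(29L))
  y_perm <- c(y[perm], y[30])
  p_last <- function(yy, obs) run_observer(seq_tbl(yy), obs)$p_pred[30]
  # same multiset of first 29 symbols, same perfect prediction for trial 30
  expect_equal(p_last(y, observer("item", "perfect")),
               p_last(y_perm, observer("item", "perfect")))
  # order matters under forgetting: move all Xs early vs late
  y_sorted <- c(sort(y[1:29]), y[30])
  y_rev <- c(rev(sort(y[1:29])), y[30])
  expect_false(isTRUE(all.equal(
    p_last(y_sorted, observer("item", "leaky", omega = 5)),
    p_last(y_rev, observer("item", "leaky", omega = 5))
  )))
  expect_false(isTRUE(all.equal(
    p_last(y_sorted, observer("item", "windowed", n = 10)),
    p_last(y_rev, observer("item", "windowed", n = 10))
  )))
})

test_that("repetition streaks yield stronger expectations than alternation
           streaks of equal length under transition learning", {
  obs <- observer("transition", "perfect")
  for (k in 1:6) {
    rep_seq <- seq_from_string(strrep("X", 2 * k + 1))
    alt_seq <- seq_from_string(paste(rep(c("X", "Y"), length.out = 2 * k + 1),
                                     collapse = ""))
    p_rep <- predict_next(rep_seq, obs)$p_x        # expects X again
    p_alt <- predict_next(alt_seq, obs)$p_y        # expects the alternation
    expect_gt(p_rep, p_alt)
    # evidence ratio: 2k consistent transitions vs k
    expect_equal(p_rep, (2 * k + 1) / (2 * k + 2))
    expect_equal(p_alt, (k + 1) / (k + 2))
  }
})

test_that("windowed prediction traces equal perfect ones when the window
           covers the sequence", {
  y <- sim_item_seq(0.3, 60, seed = 12)
  for (stat in c("item", "transition", "alternation")) {
    expect_identical(
      run_observer(y, observer(stat, "windowed", n = 60))$p_pred,
      run_observer(y, observer(stat, "perfect"))$p_pred
    )
  }
})

test_that("long-run mean surprise on a fair coin approaches one bit as the
           leak vanishes", {
  y <- sim_item_seq(0.5, 1e5, seed = 13)
  tr <- run_observer(y, observer("transition", "leaky", omega = 16))
  expect_true(all(tr$p_pred > 0 & tr$p_pred < 1))
  # the cross-entropy of a forgetful observer on a fair coin sits slightly
  # above 1 bit (its predictions fluctuate around 1/2); the excess shrinks
  # as integration lengthens
  m16 <- mean(tr$surprise)
  expect_gt(m16, 1)
  expect_lt(m16, 1.05)
  m200 <- mean(run_observer(y, observer("transition", "leaky",
                                        omega = 200))$surprise)
  expect_lt(m200, m16)
  expect_equal(m200, 1, tolerance = 0.02)
})

test_that("observer specification validates its single free parameter", {
  expect_error(observer("item", "leaky"), "requires `omega`")
  expect_error(observer("item", "perfect", omega = 3), "do not apply")
  expect_error(observer("item", "dynamic", p_change = 1), "< 1")
  expect_error(observer("item", "windowed", n = 0), "integer")
  o <- observer("transition", "dynamic", p_change = 0.013)
  expect_equal(o$resolution, 50L)
  expect_equal(seqsurprise:::observer_k(o), 1L)
  expect_equal(seqsurprise:::observer_k(observer("item", "perfect")), 0L)
})
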