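test_that("confidence binning pools extremes and expands when sparse", {
  # balanced: ~uniform ratings need no expansion
  set.seed(1)
  ratings <- sample(1:9, 300, replace = TRUE)
  b <- bin_confidence(ratings)
  expect_equal(b$low_ratings, 1:3)
  expect_equal(b$high_ratings, 7:9)
  expect_true(all(b$labels[ratings %in% 4:6] == "Medium"))

  # concentrated high: Low expands inward through 4 (then 5) to reach 50
  ratings2 <- rep(4:9, c(30, 30, 60, 60, 60, 60))
  b2 <- bin_confidence(ratings2)
  expect_true(4 %in% b2$low_ratings)
  expect_gte(b2$counts[["Low"]], 50)

  # hand-traced fixture: counts per rating 10,10,10,40,60,40,30,20,10
  ratings3 <- rep(1:9, c(10, 10, 10, 40, 60, 40, 30, 20, 10))
  b3 <- bin_confidence(ratings3)
  expect_equal(b3$low_ratings, 1:4)
  expect_equal(b3$counts[["Low"]], 70)
  expect_equal(b3$high_ratings, 7:9)
  expect_equal(b3$counts[["High"]], 60)

  expect_error(bin_confidence(rep(5, 60)), "insufficient|cannot reach")
  expect_error(bin_confidence(c(0, 5)), "1..9")
})

test_that("missing ratings are excluded from binning", {
  ratings <- c(rep(1:9, each = 20), rep(NA, 10))
  b <- bin_confidence(ratings)
  expect_true(all(b$labels[is.na(ratings)] == "excluded"))
})

test_that("the discriminator separates a separable toy problem", {
  set.seed(2)
  X <- rbind(matrix(rnorm(100, 3), 50), matrix(rnorm(100, -3), 50))
  lab <- rep(c(1L, 0L), each = 50)
  fit <- train_window(X, lab)
  y <- drop(X %*% fit$weights) + fit$bias
  expect_equal(mean((y > 0) == (lab == 1)), 1)
  expect_equal(az(y, lab), 1.0)
  expect_error(train_window(X, rep(1L, 100)), "both classes")
})

test_that("learned weights align with the Bayes direction for isotropic classes", {
  set.seed(3)
  n <- 400
  X <- cbind(rnorm(n) + rep(c(1, -1), each = n / 2), rnorm(n))
  lab <- rep(c(1L, 0L), each = n / 2)
  fit <- train_window(X, lab)
  ang <- acos(abs(fit$weights[1]) / sqrt(sum(fit$weights^2))) * 180 / pi
  expect_lt(ang, 15)
})

test_that("null features give small weights and chance LOO Az", {
  set.seed(4)
  X <- matrix(rnorm(100 * 8), 100, 8)
  lab <- sample(rep(0:1, 50))
  fit <- train_window(X, lab)
  expect_lt(sqrt(sum(fit$weights^2)), 1)
  cv <- loo_az(X, lab)
  expect_gt(cv$az, 0.25)
  expect_lt(cv$az, 0.75)
})

test_that("Az agrees with pair counting, including the worked example", {
  scores <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2)
  labels <- c(1, 1, 1, 0, 0, 0)
  expect_equal(az(scores, labels), 8 / 9)
  expect_equal(az(c(2, 3, 0, 1), c(1, 1, 0, 0)), 1.0)
  set.seed(6)
  for (i in 1:50) {
    n1 <- sample(2:50, 1); n0 <- sample(2:50, 1)
    s <- c(rnorm(n1, 0.3), rnorm(n0))
    s <- round(s, 1)  # force ties
    l <- rep(c(1, 0), c(n1, n0))
    expect_equal(az(s, l), az_pair_count(s, l), tolerance = 1e-12)
  }
})

test_that("Az agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  s <- c(rnorm(30, 0.5), rnorm(25))
  l <- rep(c(1, 0), c(30, 25))
  ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(az(s, l), ref, tolerance = 1e-12)
})

test_that("identical score distributions sit at chance on average", {
  set.seed(7)
  azs <- replicate(200, az(rnorm(40), rep(0:1, 20)))
  expect_lt(abs(mean(azs) - 0.5), 0.02)
})

test_that("permutation Az threshold edge cases and determinism", {
  set.seed(8)
  X <- matrix(rnorm(60 * 4), 60, 4)
  lab <- rep(0:1, 30)
  expect_warning(thr_min <- bootstrap_az_threshold(X, lab, n_perm = 60,
                                                   alpha = 1, seed = 1),
                 "unstable")
  expect_equal(as.numeric(thr_min), min(attr(thr_min, "null_az")))
  t1 <- bootstrap_az_threshold(X, lab, n_perm = 120, seed = 2)
  t2 <- bootstrap_az_threshold(X, lab, n_perm = 120, seed = 2)
  expect_identical(as.numeric(t1), as.numeric(t2))
  expect_gt(as.numeric(t1), 0.5)
})

test_that("forward model reproduces algebraic identities", {
  set.seed(9)
  a0 <- rnorm(12)
  y <- rnorm(30)
  X <- a0 %*% t(y)          # rank-1, noiseless
  expect_equal(forward_model(X, y), a0)
  # y orthogonal to every row: projection is zero
  y2 <- c(1, -1, rep(0, 28))
  X2 <- matrix(rep(rnorm(12), 30), 12, 30)   # constant rows
  expect_equal(forward_model(X2, y2), rep(0, 12))
  expect_error(forward_model(X2, rep(0, 30)), "degenerate")
})

test_that("peak-window selection respects the pre-response margin", {
  centres <- seq(0, 900, by = 10)
  az_mono <- seq_along(centres) / length(centres)
  pk <- select_peak_window(az_mono, centres, mean_rt_ms = 900,
                           margin_ms = 100, win_ms = 60)
  # last admissible window end at 800 ms -> centre 770
  expect_equal(as.numeric(pk), 770)
  az_tie <- rep(0, length(centres))
  az_tie[centres %in% c(400, 600)] <- 1
  expect_equal(as.numeric(select_peak_window(az_tie, centres, 2000, 100)),
               400)
  expect_error(select_peak_window(az_mono, centres, mean_rt_ms = 100),
               "admissible")
})

test_that("applying weights is linear and respects the bias", {
  fx <- fixture_small_epochs()
  ep <- fx$epochs
  n_ch <- dim(ep)[2]
  y0 <- apply_weights(ep, rep(0, n_ch), bias = 2.5, centre_ms = 700)
  expect_equal(y0, rep(2.5, dim(ep)[1]))
  w <- rnorm(n_ch)
  y1 <- apply_weights(ep, w, 0, centre_ms = 700)
  y3 <- apply_weights(ep, 3 * w, 0, centre_ms = 700)
  expect_equal(y3, 3 * y1)
  expect_equal(sd(y3), 3 * sd(y1))
  expect_error(apply_weights(ep, rep(0, n_ch + 1), 0, centre_ms = 700),
               "channels")
})

test_that("sliding discrimination honours window geometry and sign convention", {
  fx <- fixture_small_epochs()
  bins <- bin_confidence(fx$trials$rating, min_per_group = 30)
  res <- suppressMessages(
    sliding_discriminate(fx$epochs, bins, range_ms = c(600, 600),
                         az_method = "training")
  )
  expect_length(res$window_centres_ms, 1L)
  # centres whose full window would leave the epoch are skipped
  expect_message(
    res2 <- sliding_discriminate(fx$epochs, bins, range_ms = c(-100, 0),
                                 az_method = "training"),
    "skipped"
  )
  expect_true(all(res2$window_centres_ms - 30 >= min(fx$epochs$times_ms)))
  # High maps to positive: mean y(High) > mean y(Low) on training data
  for (k in seq_along(res2$window_centres_ms)) {
    hi <- mean(res2$y_train[bins$labels == "High", k])
    lo <- mean(res2$y_train[bins$labels == "Low", k])
    expect_gt(hi, lo)
  }
})

test_that("training separation peaks near the planted latency", {
  fx <- fixture_small_epochs()
  bins <- bin_confidence(fx$trials$rating, min_per_group = 30)
  res <- sliding_discriminate(fx$epochs, bins, range_ms = c(100, 960),
                              az_method = "training")
  expect_lte(abs(res$window_centres_ms[which.max(res$az)] - 700), 60)
})
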