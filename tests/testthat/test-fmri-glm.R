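test_that("a unit stick regressor reproduces the sampled HRF", {
  ev <- stick_events("imp", onsets = 0)
  des <- build_design(ev, n_volumes = 16, tr_s = 2)
  x <- des$X[, "imp"]
  pk <- des$frame_times[which.max(x)]
  expect_gte(pk, 4)
  expect_lte(pk, 6)
  expect_lt(min(x), 0)                   # later undershoot
  expect_gt(which.min(x), which.max(x))
  # matches direct sampling of the HRF at frame times (up to stick width)
  href <- hrf_double_gamma(des$frame_times)
  expect_gt(cor(x, href), 0.999)
})

test_that("a long boxcar equals the sum of abutting sticks", {
  ev_box <- tibble::tibble(regressor = "box", onset_s = 20, duration_s = 10,
                           amplitude = 1, parametric = FALSE)
  sticks <- tibble::tibble(regressor = "sticks",
                           onset_s = 20 + 0.1 * (0:99), duration_s = 0.1,
                           amplitude = 1, parametric = FALSE)
  d1 <- build_design(ev_box, 60, 2)
  d2 <- build_design(sticks, 60, 2)
  expect_equal(unname(d1$X[, 1]), unname(d2$X[, 1]), tolerance = 1e-8)
})

test_that("events beyond the scan are dropped and zero columns rejected", {
  ev <- stick_events("a", onsets = c(10, 500))
  expect_warning(des <- build_design(ev, 50, 2), "dropped")
  expect_equal(sum(des$events$regressor == "a"), 1)
  ev0 <- stick_events("z", onsets = 130)   # after the last frame
  expect_warning(expect_error(build_design(ev0, 50, 2), "zero column"),
                 "dropped")
})

test_that("parametric amplitudes are mean-centred before convolution", {
  ev <- stick_events("par", onsets = c(10, 30, 50), amplitude = c(1, 2, 3))
  des <- build_design(ev, 60, 2)
  # centring makes the column orthogonal to the same regressor with
  # constant amplitude over a long run in expectation; directly: the
  # convolved train integrates to ~0
  expect_lt(abs(sum(des$X[, 1])), 1e-6 * sum(abs(des$X[, 1])) + 1e-6)
})

test_that("voxelwise OLS is exact, invariant and rank-checked", {
  set.seed(51)
  ev <- stick_events("conf", onsets = seq(4, 100, 8), amplitude = rnorm(13))
  des <- build_design(ev, 60, 2)
  X <- des$X
  beta_true <- c(3, -2)
  Y <- cbind(100 + X %*% beta_true[1], 50 + X %*% beta_true[2])
  fit <- fit_glm(Y, des)
  expect_equal(unname(fit$beta["conf", ]), beta_true, tolerance = 1e-10)
  # permuting volume order of Y and X together leaves betas unchanged
  perm <- sample(60)
  des_p <- des
  des_p$X <- X[perm, , drop = FALSE]
  fit_p <- fit_glm(Y[perm, , drop = FALSE], des_p)
  expect_equal(fit_p$beta, fit$beta)
  # adding a constant to Y moves only the intercept
  fit_c <- fit_glm(Y + 7, des)
  expect_equal(fit_c$beta, fit$beta)
  # duplicated column: error names the offenders
  des_d <- des
  des_d$X <- cbind(des_d$X, conf2 = des_d$X[, 1])
  expect_error(fit_glm(Y, des_d), "conf2")
})

test_that("variance inflation factors match their closed forms", {
  n <- 200
  set.seed(52)
  # orthonormal columns, also orthogonal to the intercept
  A <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4]
  des <- list(X = A, n_volumes = n)
  colnames(des$X) <- c("a", "b", "c")
  expect_equal(unname(vif(des)), rep(1, 3), tolerance = 1e-10)
  # two columns with exact correlation 0.9, third orthogonal
  x1 <- A[, 1]
  x2 <- 0.9 * A[, 1] + sqrt(1 - 0.81) * A[, 2]
  des2 <- list(X = cbind(a = x1, b = x2, c = A[, 3]))
  v <- vif(des2)
  expect_equal(unname(v[1]), 1 / (1 - 0.81), tolerance = 1e-8)
  expect_equal(unname(v[2]), 1 / (1 - 0.81), tolerance = 1e-8)
  expect_equal(unname(v[3]), 1, tolerance = 1e-10)
  # duplicated column: infinite for both
  des3 <- list(X = cbind(a = x1, b = x1))
  expect_true(all(is.infinite(vif(des3))))
})

test_that("cluster extraction obeys connectivity semantics", {
  z <- array(0, c(9, 9, 9))
  z[4:6, 4:6, 4:6] <- 5
  cl <- cluster_extract(z)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size, 27)
  expect_equal(cl$sign, "positive")
  # two voxels touching only at a vertex
  z2 <- array(0, c(5, 5, 5))
  z2[2, 2, 2] <- 3
  z2[3, 3, 3] <- 3
  expect_equal(nrow(cluster_extract(z2, min_size = 1, connectivity = 26)), 1)
  expect_equal(nrow(cluster_extract(z2, min_size = 1, connectivity = 6)), 2)
  # negative excursions cluster separately
  z3 <- array(0, c(5, 5, 5))
  z3[1:2, 1, 1] <- -4
  z3[4:5, 5, 5] <- 4
  cl3 <- cluster_extract(z3, min_size = 1)
  expect_setequal(cl3$sign, c("positive", "negative"))
})

test_that("cluster extraction matches an independent label-propagation oracle", {
  set.seed(53)
  for (i in 1:5) {
    z <- array(rnorm(1000), c(10, 10, 10))
    for (conn in c(6, 26)) {
      cl <- cluster_extract(z, z_min = 1.2, min_size = 1,
                            connectivity = conn)
      sizes <- sort(cl$size[cl$sign == "positive"])
      expect_equal(sizes, cluster_sizes_oracle(z, 1.2, conn))
    }
  }
})

test_that("percent signal change follows its arithmetic definition", {
  ts <- rep(100, 40)
  psc0 <- percent_signal_change(ts, onsets_s = c(20, 40), tr_s = 2)
  expect_true(all(psc0$psc == 0))
  ts2 <- rep(100, 40)
  ts2[14] <- 102                         # one volume, 13 * 2 s = 24 s
  psc <- percent_signal_change(ts2, onsets_s = 20, tr_s = 2)
  expect_equal(psc$psc[psc$time_s == 6], (102 - 100) / mean(ts2))
  expect_equal(psc$psc[psc$time_s == 0], 0)
  expect_error(percent_signal_change(rep(-1, 40), 20), "positive")
  expect_warning(percent_signal_change(ts, onsets_s = 2), "window")
})

test_that("PPI designs are built and degenerate psychology is detectable", {
  n_vol <- 100
  set.seed(54)
  seed_ts <- rnorm(n_vol)
  onsets <- seq(10, 180, 10)
  dts <- runif(length(onsets), 0.5, 1.2)
  des <- ppi_design(seed_ts, onsets, dts, n_vol)
  expect_setequal(colnames(des$X), c("task", "physio", "psych", "interaction"))
  expect_equal(mean(des$X[, "physio"]), 0)
  expect_equal(mean(des$X[, "psych"]), 0, tolerance = 1e-12)
  # constant seed: demeaning kills physiological and interaction columns
  expect_error(ppi_design(rep(0, n_vol), onsets, dts, n_vol), "degenerate")
  des_c <- ppi_design(rep(5, n_vol), onsets, dts, n_vol)
  expect_equal(unname(des_c$X[, "interaction"]), rep(0, n_vol))
  # whole-scan "decision": past the initial haemodynamic transient the
  # psychological column is constant, so the interaction is exactly
  # proportional to the physiological column there (the degenerate case)
  des_d <- ppi_design(seed_ts, 0, n_vol * 2, n_vol)
  plateau <- 25:n_vol
  expect_equal(sd(des_d$X[plateau, "psych"]), 0, tolerance = 1e-8)
  expect_equal(abs(cor(des_d$X[plateau, "interaction"],
                       des_d$X[plateau, "physio"])), 1, tolerance = 1e-8)
})

test_that("interaction recovers planted coupling modulation", {
  n_vol <- 150
  set.seed(55)
  seed_ts <- rnorm(n_vol)
  onsets <- seq(10, 280, 16)
  dts <- runif(length(onsets), 0.6, 1.4)
  des <- ppi_design(seed_ts, onsets, dts, n_vol)
  y <- 2 * des$X[, "interaction"] + 0.5 * des$X[, "physio"] +
    rnorm(n_vol, sd = 0.3)
  fit <- fit_glm(cbind(y), des)
  expect_gt(fit$beta["interaction", 1], 0)
  expect_gt(fit$z["interaction", 1], 3)
})

test_that("permutation cluster threshold is seeded and monotone in pct", {
  set.seed(56)
  ev <- stick_events("conf", onsets = seq(4, 150, 6), amplitude = rnorm(25))
  des <- build_design(ev, 90, 2)
  dat <- gen_bold_dataset(des, active_vox = integer(0), noise_sd = 1,
                          dims = c(10, 10, 10), smooth_fwhm_vox = 2.5,
                          seed = 57)
  thr1 <- suppressWarnings(
    permutation_cluster_threshold(dat$bold, ev, "conf", n_perm = 20,
                                  seed = 58))
  thr2 <- suppressWarnings(
    permutation_cluster_threshold(dat$bold, ev, "conf", n_perm = 20,
                                  seed = 58))
  expect_identical(as.numeric(thr1), as.numeric(thr2))
  sizes <- attr(thr1, "null_sizes")
  if (length(sizes) > 0) {
    q50 <- quantile(sizes, 0.5, type = 7)
    q95 <- quantile(sizes, 0.95, type = 7)
    expect_lte(q50, q95)
  }
  expect_error(
    permutation_cluster_threshold(dat$bold, ev, "nope", n_perm = 5),
    "unknown regressor")
  ev_const <- stick_events("conf", onsets = seq(4, 150, 6), amplitude = 1)
  expect_error(
    permutation_cluster_threshold(dat$bold, ev_const, "conf", n_perm = 5),
    "parametric")
})

test_that("high-pass cosine basis has the declared resolution", {
  B <- dct_basis(200, 2, cutoff_s = 100)
  expect_equal(ncol(B), 8)               # 2 * 400 s / 100 s
  expect_equal(nrow(B), 200)
  # adding drift confounds leaves task betas nearly unchanged on clean data
  ev <- stick_events("conf", onsets = seq(4, 380, 8),
                     amplitude = rnorm(48))
  des <- build_design(ev, 200, 2)
  y <- 100 + 2 * des$X[, 1]
  f0 <- fit_glm(cbind(y), des)
  f1 <- fit_glm(cbind(y), add_confounds(des, B))
  expect_equal(f1$beta["conf", 1], f0$beta["conf", 1], tolerance = 1e-6)
})
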