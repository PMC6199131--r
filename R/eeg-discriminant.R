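#' Bin 9-point confidence ratings into Low / Medium / High groups
#'
#' Initial groups pool the three lowest (1-3) and three highest (7-9)
#' ratings; 4-6 form the Medium pool. If a group holds fewer than
#' `min_per_group` trials, the nearest Medium rating bin is moved into it
#' (4, then 5, ... for Low; 6, then 5, ... for High) until the minimum is
#' met; a rating bin can only be claimed once. Trials with missing ratings
#' are excluded.
#'
#' @param ratings Integer ratings 1-9 (NA = excluded).
#' @param min_per_group Minimum trials required in the Low and High groups.
#'
#' @return An object of class `confidence_bins`: per-trial `labels`
#'   (factor Low/Medium/High/excluded), the rating sets `low_ratings` and
#'   `high_ratings`, and per-group `counts`.
#' @export
bin_confidence <- function(ratings, min_per_group = 50L) {
  ok <- !is.na(ratings)
  if (any(ok & (ratings < 1 | ratings > 9))) stop("ratings must be in 1..9")
  tab <- tabulate(ratings[ok], nbins = 9L)
  if (sum(tab) < 2L * min_per_group) {
    stop("insufficient data: fewer than 2 * min_per_group valid trials")
  }
  low_set <- 1:3
  high_set <- 7:9
  pool <- c(4L, 5L, 6L)                 # inward-from-middle expansion order
  count <- function(set) sum(tab[set])
  repeat {
    moved <- FALSE
    if (count(low_set) < min_per_group && length(pool) > 0L) {
      low_set <- c(low_set, pool[1L]); pool <- pool[-1L]; moved <- TRUE
    }
    if (count(high_set) < min_per_group && length(pool) > 0L) {
      high_set <- c(high_set, pool[length(pool)])
      pool <- pool[-length(pool)]; moved <- TRUE
    }
    if (count(low_set) >= min_per_group && count(high_set) >= min_per_group) break
    if (!moved) {
      stop("cannot reach `min_per_group` trials in both confidence groups")
    }
  }
  labels <- factor(rep("excluded", length(ratings)),
                   levels = c("Low", "Medium", "High", "excluded"))
  labels[ok & ratings %in% low_set] <- "Low"
  labels[ok & ratings %in% high_set] <- "High"
  labels[ok & !(ratings %in% c(low_set, high_set))] <- "Medium"
  structure(
    list(labels = labels,
         low_ratings = sort(low_set), high_ratings = sort(high_set),
         counts = c(Low = count(low_set), Medium = sum(tab) - count(low_set) -
                      count(high_set), High = count(high_set))),
    class = "confidence_bins"
  )
}

#' @export
print.confidence_bins <- function(x, ...) {
  cat(sprintf("Confidence bins: Low = {%s} (%d), High = {%s} (%d), Medium (%d)\n",
              paste(x$low_ratings, collapse = ","), x$counts["Low"],
              paste(x$high_ratings, collapse = ","), x$counts["High"],
              x$counts["Medium"]))
  invisible(x)
}

ridge_lambda <- function(X, lambda_scale = 3) {
  lambda_scale * mean(apply(X, 2, var))
}

#' Train a single-window linear discriminator
#'
#' Penalised logistic regression fit by iteratively reweighted least squares
#' (IRLS): the weight vector maximises the Bernoulli likelihood with a small
#' shrinkage ridge penalty (default 3 times the mean feature variance) on the weights
#' (never the intercept) to stabilise separable or ill-conditioned windows.
#' Convergence: max absolute step below `tol` or `maxit` iterations.
#'
#' @param Xw Feature matrix, trials x features (typically one window-mean
#'   value per channel).
#' @param labels 0/1 per trial (1 = the class mapped to positive decision
#'   values).
#' @param lambda_scale Ridge penalty as a fraction of mean feature variance.
#' @param maxit,tol IRLS stopping rule.
#'
#' @return A list with `weights` (per feature), `bias`, and `lambda`.
#' @export
train_window <- function(Xw, labels, lambda_scale = 3, maxit = 100L,
                         tol = 1e-6) {
  Xw <- as.matrix(Xw)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  lambda <- ridge_lambda(Xw, lambda_scale)
  beta <- irls_logistic_cpp(Xw, labels, lambda, maxit, tol)
  list(weights = beta[-1L], bias = beta[1L], lambda = lambda)
}

#' Area under the ROC curve
#'
#' Az by trapezoidal integration of the empirical ROC curve; tied scores
#' advance both rates together, so ties receive half credit (equivalently,
#' the Mann-Whitney statistic).
#'
#' @param scores Decision values.
#' @param labels 0/1; 1 is the positive class.
#' @return Az in `[0, 1]`.
#' @export
az <- function(scores, labels) {
  az_roc_cpp(as.numeric(scores), as.integer(labels))
}

#' Leave-one-out cross-validated Az
#'
#' For each trial the discriminator is retrained on the remaining trials and
#' the held-out trial is scored; Az is computed on the held-out scores.
#'
#' @inheritParams train_window
#' @return A list with `az` and `y_loo` (held-out decision values, one per
#'   trial).
#' @export
loo_az <- function(Xw, labels, lambda_scale = 3, maxit = 100L,
                   tol = 1e-6) {
  Xw <- as.matrix(Xw)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  lambda <- ridge_lambda(Xw, lambda_scale)
  y_loo <- loo_scores_cpp(Xw, labels, lambda, maxit, tol)
  list(az = az(y_loo, labels), y_loo = y_loo)
}

#' Permutation threshold for the leave-one-out Az
#'
#' Null distribution of the LOO Az obtained by shuffling trial labels
#' (without replacement) and rerunning the identical leave-one-out test
#' `n_perm` times; the significance threshold is the `1 - alpha` quantile of
#' that distribution.
#'
#' @inheritParams train_window
#' @param n_perm Number of label shuffles (values below 100 give an unstable
#'   tail and trigger a warning).
#' @param alpha Significance level (`alpha = 1` returns the distribution
#'   minimum).
#' @param seed Integer seed for the shuffles.
#' @return The Az threshold, with the permutation Az values attached as
#'   attribute `"null_az"`.
#' @export
bootstrap_az_threshold <- function(Xw, labels, n_perm = 500L, alpha = 0.01,
                                   seed = NULL, lambda_scale = 3,
                                   maxit = 100L, tol = 1e-6) {
  if (n_perm < 100L) warning("n_perm < 100: the null tail will be unstable")
  Xw <- as.matrix(Xw)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  lambda <- ridge_lambda(Xw, lambda_scale)
  null_az <- with_seed(seed,
    perm_loo_az_cpp(Xw, labels, n_perm, lambda, maxit, tol))
  thr <- unname(quantile(null_az, 1 - alpha, type = 7))
  attr(thr, "null_az") <- null_az
  thr
}

#' Forward model (scalp projection) of a discriminant component
#'
#' Given sensor data `X` (channels x observations) and the component time
#' course / amplitudes `y`, the forward model `a = X y / (y' y)` is the
#' channel pattern whose coupling with `y` best explains the data, and is
#' what a scalp map of the component should display.
#'
#' @param X Channels x observations matrix.
#' @param y Component values, one per observation.
#' @param centre Subtract the mean of `y` and the per-channel means of `X`
#'   first, so the projection reflects trial-to-trial fluctuations rather
#'   than mean activity. The default `FALSE` is the plain algebraic form.
#' @return Per-channel coupling vector `a`.
#' @export
forward_model <- function(X, y, centre = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(ncol(X) == length(y))
  if (centre) {
    X <- X - rowMeans(X)
    y <- y - mean(y)
  }
  yy <- sum(y^2)
  if (yy == 0) stop("degenerate component: y is identically zero")
  drop(X %*% y) / yy
}

#' Forward model at the peak discrimination window
#'
#' Convenience wrapper: extracts the window features at the selected peak
#' centre and computes the (mean-centred) forward model of the stored
#' training component amplitudes there — the scalp map of the confidence
#' component.
#'
#' @param result A [sliding_discriminate()] result.
#' @param epochs The epochs the result was computed from.
#' @param centre_ms Window centre (defaults to the Az-maximal window).
#' @param baseline Must match the discrimination call.
#' @return A tibble with `channel` and `a` (coupling per channel).
#' @export
forward_model_peak <- function(result, epochs, centre_ms = NULL,
                               baseline = TRUE) {
  stopifnot(inherits(result, "discriminant_result"))
  centre_ms <- centre_ms %||%
    result$window_centres_ms[which.max(result$az)]
  k <- match(centre_ms, result$window_centres_ms)
  if (is.na(k)) stop("`centre_ms` is not one of the analysed windows")
  if (baseline) epochs <- baseline_correct(epochs)
  feat <- window_feature(epochs, centre_ms, result$win_ms)
  a <- forward_model(t(feat), result$y_train[, k], centre = TRUE)
  tibble::tibble(channel = result$channel_names, a = a)
}

window_feature <- function(epochs, centre_ms, win_ms) {
  half <- win_ms / 2
  sel <- epochs$times_ms >= centre_ms - half & epochs$times_ms <= centre_ms + half
  # trials x channels mean over the window samples
  apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
}

baseline_correct <- function(epochs, baseline_ms = c(-100, 0)) {
  sel <- epochs$times_ms >= baseline_ms[1] & epochs$times_ms < baseline_ms[2]
  if (!any(sel)) return(epochs)
  bl <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - array(bl, dim = dim(epochs$data))
  epochs
}

#' Sliding-window High vs Low confidence discrimination
#'
#' Trains a linear discriminator in short overlapping windows (default 60 ms
#' windows centred every 10 ms between -100 and 1000 ms; centres whose full
#' window would leave the epoch are skipped). Per window, features are the
#' per-channel mean over the window samples; the discriminator is trained on
#' High vs Low trials (after per-trial baseline correction over the 100 ms
#' prestimulus interval), with High mapped to positive decision values.
#' Component amplitudes `y` are stored for every trial, including Medium and
#' excluded trials, and discrimination performance is summarised per window
#' as the leave-one-out Az (or the in-sample training Az).
#'
#' @param epochs An [eeg_epochs()] object.
#' @param bins A [bin_confidence()] result aligned with the epochs.
#' @param win_ms,step_ms Window length and spacing of window centres (ms).
#' @param range_ms Centre range to consider.
#' @param baseline Apply 100 ms prestimulus baseline correction first.
#' @param az_method `"loo"` (leave-one-out, default) or `"training"`.
#' @param lambda_scale,maxit,tol Passed to [train_window()].
#'
#' @return An object of class `discriminant_result`: `window_centres_ms`,
#'   `az`, `weights` (channels x windows), `bias`, `y_train` (trials x
#'   windows), `y_loo` (trials x windows, High/Low trials only, when
#'   `az_method = "loo"`), `labels`, `channel_names`, `win_ms`.
#' @export
sliding_discriminate <- function(epochs, bins, win_ms = 60, step_ms = 10,
                                 range_ms = c(-100, 1000), baseline = TRUE,
                                 az_method = c("loo", "training"),
                                 lambda_scale = 3, maxit = 100L,
                                 tol = 1e-6) {
  az_method <- match.arg(az_method)
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (length(bins$labels) != dim(epochs$data)[1]) {
    stop("`bins` must label every trial in `epochs`")
  }
  if (baseline) epochs <- baseline_correct(epochs)
  half <- win_ms / 2
  centres <- seq(range_ms[1], range_ms[2], by = step_ms)
  inside <- centres - half >= min(epochs$times_ms) &
    centres + half <= max(epochs$times_ms)
  if (!all(inside)) {
    message(sprintf("%d window centres outside the epoch were skipped",
                    sum(!inside)))
  }
  centres <- centres[inside]
  if (length(centres) == 0L) stop("no admissible window centres")
  hl <- bins$labels %in% c("Low", "High")
  lab_hl <- as.integer(bins$labels[hl] == "High")
  if (length(unique(lab_hl)) < 2L) stop("High and Low bins must both be present")
  n_trials <- dim(epochs$data)[1]
  n_ch <- dim(epochs$data)[2]
  n_w <- length(centres)
  W <- matrix(NA_real_, n_ch, n_w)
  bias <- numeric(n_w)
  azv <- numeric(n_w)
  y_train <- matrix(NA_real_, n_trials, n_w)
  y_loo <- if (az_method == "loo") matrix(NA_real_, n_trials, n_w) else NULL
  for (k in seq_len(n_w)) {
    feat <- window_feature(epochs, centres[k], win_ms)
    fit <- train_window(feat[hl, , drop = FALSE], lab_hl, lambda_scale,
                        maxit, tol)
    y_all <- drop(feat %*% fit$weights) + fit$bias
    # sign convention: High-confidence trials map to positive values
    if (mean(y_all[hl][lab_hl == 1]) < mean(y_all[hl][lab_hl == 0])) {
      fit$weights <- -fit$weights
      fit$bias <- -fit$bias
      y_all <- -y_all
    }
    W[, k] <- fit$weights
    bias[k] <- fit$bias
    y_train[, k] <- y_all
    if (az_method == "loo") {
      cv <- loo_az(feat[hl, , drop = FALSE], lab_hl, lambda_scale, maxit, tol)
      azv[k] <- cv$az
      y_loo[hl, k] <- cv$y_loo
    } else {
      azv[k] <- az(y_all[hl], lab_hl)
    }
  }
  structure(
    list(window_centres_ms = centres, az = azv, weights = W, bias = bias,
         y_train = y_train, y_loo = y_loo, labels = bins$labels,
         channel_names = epochs$channel_names, win_ms = win_ms,
         az_method = az_method),
    class = "discriminant_result"
  )
}

#' @export
print.discriminant_result <- function(x, ...) {
  k <- which.max(x$az)
  cat(sprintf("Sliding discriminant: %d windows (%g ms, %s Az)\n",
              length(x$window_centres_ms), x$win_ms, x$az_method))
  cat(sprintf("  max Az = %.3f at %g ms\n", x$az[k], x$window_centres_ms[k]))
  invisible(x)
}

#' @rdname sliding_discriminate
#' @param x A `discriminant_result`.
#' @param ... Unused.
#' @export
tidy.discriminant_result <- function(x, ...) {
  tibble::tibble(window_centre_ms = x$window_centres_ms, az = x$az)
}

#' Plot the discrimination timecourse
#'
#' @param object A `discriminant_result`.
#' @param threshold Optional Az significance threshold to draw.
#' @param ... Unused.
#' @export
autoplot.discriminant_result <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(tidy(object),
                       ggplot2::aes(x = .data$window_centre_ms, y = .data$az)) +
    ggplot2::geom_line(colour = "#d95f02") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "Window centre (ms)", y = "Az (High vs Low confidence)") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}

#' Select the peak discrimination window before the response
#'
#' Returns the admissible window centre with maximal Az, where admissible
#' means the window ends at least `margin_ms` before the mean response time
#' (keeping the selected component clear of motor-execution activity).
#' Ties go to the earliest admissible centre.
#'
#' @param az Per-window Az values.
#' @param window_centres_ms Matching window centres (ms).
#' @param mean_rt_ms Mean response time (ms).
#' @param margin_ms Required gap between window end and mean RT.
#' @param win_ms Window length (ms).
#' @return The selected centre (ms), with the window's Az as attribute
#'   `"az"`.
#' @export
select_peak_window <- function(az, window_centres_ms, mean_rt_ms,
                               margin_ms = 100, win_ms = 60) {
  stopifnot(length(az) == length(window_centres_ms))
  adm <- window_centres_ms + win_ms / 2 <= mean_rt_ms - margin_ms
  if (!any(adm)) stop("no admissible window ends early enough before mean RT")
  az_adm <- ifelse(adm, az, -Inf)
  k <- which.max(az_adm)                # first (earliest) maximum
  out <- window_centres_ms[k]
  attr(out, "az") <- az[k]
  out
}

#' Apply trained discriminant weights to epochs
#'
#' Projects every trial (including Medium-confidence and excluded trials)
#' through a spatial filter trained at one window, yielding the trial-level
#' confidence component amplitude `y_CONF = w . x_window + b`.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param weights Per-channel weights.
#' @param bias Intercept of the trained discriminator.
#' @param centre_ms Window centre (ms).
#' @param win_ms Window length (ms).
#' @param baseline Apply the prestimulus baseline correction first (must
#'   match how the weights were trained).
#' @return Numeric vector of per-trial component amplitudes.
#' @export
apply_weights <- function(epochs, weights, bias = 0, centre_ms,
                          win_ms = 60, baseline = TRUE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (length(weights) != dim(epochs$data)[2]) {
    stop("`weights` length must equal the number of channels")
  }
  if (baseline) epochs <- baseline_correct(epochs)
  feat <- window_feature(epochs, centre_ms, win_ms)
  drop(feat %*% weights) + bias
}
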