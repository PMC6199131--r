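#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, via the standard symmetric tridiagonal eigenproblem whose
#' eigenvectors are the Slepian sequences. Tapers are unit-energy; signs are
#' fixed so each taper's average (or, for antisymmetric tapers, its initial
#' lobe) is positive.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (half-bandwidth `W = nw / n` cycles per
#'   sample).
#' @param k Number of tapers.
#' @return An `n x k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw, k) {
  stopifnot(n >= 2, k >= 1, nw > 0)
  w <- nw / n
  i <- seq_len(n) - 1
  A <- matrix(0, n, n)
  diag(A) <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- i[-1] * (n - i[-1]) / 2
  A[cbind(2:n, 1:(n - 1))] <- off
  A[cbind(1:(n - 1), 2:n)] <- off
  e <- eigen(A, symmetric = TRUE)
  tap <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    s <- sum(tap[, j])
    flip <- if (abs(s) > 1e-8) s < 0 else tap[2, j] < 0
    if (flip) tap[, j] <- -tap[, j]
  }
  tap
}

#' Multitaper prestimulus alpha power
#'
#' Estimates single-trial oscillatory power in a frequency band over a fixed
#' prestimulus window (default: 8-12 Hz over the 400 ms epoch beginning at
#' -500 ms). Each epoch segment is demeaned, tapered with DPSS sequences
#' (default two tapers, +/- 4 Hz smoothing), Fourier transformed, and power
#' is averaged across tapers and across the frequency bins inside the band.
#' With unit-energy tapers the estimate is on the scale of variance per bin,
#' so white noise of variance `s^2` gives expected band power `s^2`.
#'
#' @param epochs An [eeg_epochs()] object whose time axis covers the window.
#' @param band Frequency band in Hz.
#' @param window_ms Analysis window relative to stimulus onset (ms).
#' @param n_tapers Number of DPSS tapers.
#' @param smoothing_hz Half-bandwidth of spectral smoothing in Hz (sets the
#'   time-bandwidth product together with the window length).
#'
#' @return A trials x channels matrix of raw band power, with channel names
#'   as column names.
#' @export
multitaper_alpha <- function(epochs, band = c(8, 12),
                             window_ms = c(-500, -100), n_tapers = 2L,
                             smoothing_hz = 4) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  sel <- epochs$times_ms >= window_ms[1] & epochs$times_ms < window_ms[2]
  n_samp <- sum(sel)
  need <- (window_ms[2] - window_ms[1]) * epochs$sfreq / 1000
  if (n_samp < need) {
    stop("epoch does not cover the requested prestimulus window")
  }
  fs <- epochs$sfreq
  t_len <- n_samp / fs
  nw <- smoothing_hz * t_len
  tapers <- dpss_tapers(n_samp, nw, n_tapers)
  freqs <- (seq_len(n_samp) - 1) * fs / n_samp
  band_bins <- which(freqs >= band[1] & freqs <= band[2])
  if (length(band_bins) == 0L) stop("no frequency bins inside `band`")
  d <- dim(epochs$data)
  n_trials <- d[1]; n_ch <- d[2]
  seg <- epochs$data[, , sel, drop = FALSE]
  # flatten to samples x (trials*channels) for a single batched FFT per taper
  X <- matrix(aperm(seg, c(3, 1, 2)), n_samp, n_trials * n_ch)
  X <- sweep(X, 2, colMeans(X))
  pow <- matrix(0, n_samp, ncol(X))
  for (j in seq_len(n_tapers)) {
    pow <- pow + Mod(mvfft(X * tapers[, j]))^2 / n_tapers
  }
  band_pow <- colMeans(pow[band_bins, , drop = FALSE])
  out <- matrix(band_pow, n_trials, n_ch)
  colnames(out) <- epochs$channel_names
  out
}

#' Select the peak occipitoparietal electrode and convert to dB
#'
#' Picks, from a candidate occipitoparietal set, the electrode with the
#' highest across-trial mean band power, and expresses each trial's power in
#' decibels relative to that electrode's across-trial mean:
#' `dB = 10 log10(power / mean power)`. Trials with nonpositive power are
#' excluded (dB set to NA) with a warning.
#'
#' @param power Trials x channels power matrix (named columns), as from
#'   [multitaper_alpha()].
#' @param occipitoparietal_set Candidate channel labels; defaults to all
#'   `P*`, `PO*` and `O*` channels present.
#'
#' @return A tibble of class `alpha_power` with columns `trial`, `power`,
#'   `power_db`; the selected electrode is attribute `"electrode"`.
#' @export
select_and_normalise <- function(power, occipitoparietal_set = NULL) {
  stopifnot(is.matrix(power), !is.null(colnames(power)))
  if (is.null(occipitoparietal_set)) {
    occipitoparietal_set <- grep("^(P|PO|O)[0-9z]", colnames(power),
                                 value = TRUE)
  }
  occipitoparietal_set <- intersect(occipitoparietal_set, colnames(power))
  if (length(occipitoparietal_set) == 0L) {
    stop("`occipitoparietal_set` must name at least one channel")
  }
  means <- colMeans(power[, occipitoparietal_set, drop = FALSE])
  electrode <- occipitoparietal_set[which.max(means)]
  p <- power[, electrode]
  bad <- !(p > 0)
  if (any(bad)) {
    warning(sprintf("%d trials with nonpositive power excluded", sum(bad)))
    p[bad] <- NA_real_
  }
  db <- 10 * log10(p / mean(p, na.rm = TRUE))
  out <- tibble::new_tibble(
    tibble::tibble(trial = seq_along(p), power = unname(p),
                   power_db = unname(db)),
    class = "alpha_power"
  )
  attr(out, "electrode") <- electrode
  out
}

#' Compare the confidence component across High vs Low alpha-power trials
#'
#' Splits each subject's trials at the median alpha power (with an odd trial
#' count the median trial goes to the Low half), averages the confidence
#' component amplitude `y_CONF` within each half, and compares the
#' per-subject means with a paired t-test. A null result here indicates the
#' confidence component is not merely tracking prestimulus attentional
#' state.
#'
#' @param data A data frame with columns `subject`, `alpha_db` (or any
#'   per-trial alpha measure) and `y_conf`.
#' @param min_per_half Minimum trials required in each half.
#'
#' @return A list of class `alpha_split`: per-subject means tibble, the mean
#'   High-Low difference, and the paired `t` and `p` (NA with fewer than two
#'   subjects).
#' @export
split_by_alpha <- function(data, min_per_half = 10L) {
  stopifnot(all(c("subject", "alpha_db", "y_conf") %in% names(data)))
  per_subj <- data |>
    dplyr::filter(!is.na(.data$alpha_db), !is.na(.data$y_conf)) |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      rk <- rank(df$alpha_db, ties.method = "first")
      low <- rk <= ceiling(n / 2)       # odd n: median trial goes Low
      if (sum(low) < min_per_half || sum(!low) < min_per_half) {
        warning("subject with fewer than `min_per_half` trials per half dropped")
        return(tibble::tibble())
      }
      tibble::tibble(mean_low = mean(df$y_conf[low]),
                     mean_high = mean(df$y_conf[!low]))
    }) |>
    dplyr::ungroup()
  diff <- per_subj$mean_high - per_subj$mean_low
  if (nrow(per_subj) >= 2L && sd(diff) > 0) {
    tt <- t.test(per_subj$mean_high, per_subj$mean_low, paired = TRUE)
    t_stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    t_stat <- NA_real_; p <- NA_real_
  }
  structure(
    list(per_subject = per_subj, mean_diff = mean(diff), t = t_stat, p = p),
    class = "alpha_split"
  )
}
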