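#' Epoched multichannel EEG container
#'
#' A light container for epoched EEG: a trials x channels x time voltage
#' array with its time axis (ms, uniform 1 ms spacing) and channel labels.
#'
#' @param data Numeric array, trials x channels x time (microvolts).
#' @param times_ms Strictly increasing time axis in ms, one value per sample.
#' @param channel_names Channel labels, one per channel.
#' @param sfreq Sampling frequency in Hz.
#'
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, times_ms, channel_names,
                       sfreq = 1000) {
  stopifnot(length(dim(data)) == 3L)
  if (dim(data)[3] != length(times_ms)) {
    stop("third dimension of `data` must match `times_ms`")
  }
  if (dim(data)[2] != length(channel_names)) {
    stop("second dimension of `data` must match `channel_names`")
  }
  dt <- diff(times_ms)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9) {
    stop("`times_ms` must be strictly increasing with uniform spacing")
  }
  structure(
    list(data = data, times_ms = as.numeric(times_ms),
         channel_names = as.character(channel_names), sfreq = sfreq),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("EEG epochs: %d trials x %d channels x %d samples (%g Hz), %g..%g ms\n",
              d[1], d[2], d[3], x$sfreq, min(x$times_ms), max(x$times_ms)))
  invisible(x)
}

#' @export
dim.eeg_epochs <- function(x) dim(x$data)

# 64-channel 10-20-style montage used by the generator; the occipitoparietal
# subset (P*, PO*, O*) matters for the alpha-power analyses.
montage_64 <- function() {
  c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2",
    "FT9", "FT10", "TP9", "TP10")
}

# 1/f ("pink") noise: white Gaussian noise spectrally shaped so the amplitude
# spectrum falls off as 1/sqrt(f), then rescaled to unit SD per channel.
pink_noise <- function(n_samples, n_series) {
  white <- matrix(rnorm(n_samples * n_series), n_samples, n_series)
  f <- seq_len(n_samples) - 1
  f <- pmin(f, n_samples - f)            # two-sided frequency index
  shape <- ifelse(f == 0, 0, 1 / sqrt(f))
  spec <- mvfft(white) * shape
  x <- Re(mvfft(spec, inverse = TRUE)) / n_samples
  sds <- sqrt(colMeans(x^2))
  sweep(x, 2, pmax(sds, .Machine$double.eps), "/")
}

#' Generate synthetic EEG epochs with a planted confidence component
#'
#' Builds trials x channels x time epochs in which a confidence-scaled
#' component is planted: per trial, the (standardised) latent confidence
#' multiplies a fixed unit-norm scalp topography and a Gaussian temporal
#' kernel centred at `component_latency_ms` (SD `component_sd_ms`),
#' emulating a discriminating component peaking late in the decision period.
#' On top of this sit per-channel 1/f pink noise with SD `1/snr` and,
#' optionally, a 10 Hz prestimulus sinusoid whose per-trial amplitude models
#' fluctuating occipitoparietal alpha power.
#'
#' @param trials A `trial_table` (one row per trial, in epoch order).
#' @param truth The matching `ground_truth` (supplies the latent confidence).
#' @param snr Signal-to-noise ratio: the noise SD is `1/snr`, with the
#'   planted component's trial-to-trial SD at its spatiotemporal peak fixed
#'   at `component_scale`. `snr = Inf` gives noiseless epochs.
#' @param alpha_power_per_trial Optional per-trial amplitude (microvolts) of
#'   the 10 Hz prestimulus oscillation (random phase per trial), applied on
#'   occipitoparietal channels. `NULL` (default) adds none.
#' @param n_channels Number of channels (64 uses the built-in montage).
#' @param prestim_ms,poststim_ms Epoch span relative to stimulus onset;
#'   use `prestim_ms = 500` or more when prestimulus spectral analyses are
#'   planned.
#' @param component_latency_ms,component_sd_ms Centre and SD of the Gaussian
#'   temporal kernel of the planted component.
#' @param component_scale Amplitude of the planted component: the per-trial
#'   component amplitude is `component_scale` times the standardised latent
#'   confidence (so its trial-to-trial SD at the spatiotemporal peak equals
#'   `component_scale` microvolts against unit-SD noise at `snr = 1`). The
#'   default of 1.6 yields peak single-trial discrimination in the Az ~0.9
#'   range typical of a clean confidence-discriminating component; set to 0
#'   to plant no component (null data).
#' @param topography Optional unit-norm per-channel pattern; by default a
#'   smooth centroparietal pattern is used.
#' @param seed Integer seed.
#'
#' @return An `eeg_epochs` object with attributes `true_topography` (the
#'   planted unit-norm pattern) and `latent_confidence` (the standardised
#'   per-trial amplitudes actually planted).
#' @export
gen_eeg_epochs <- function(trials, truth, snr = 1,
                           alpha_power_per_trial = NULL,
                           n_channels = 64, prestim_ms = 100,
                           poststim_ms = 1000,
                           component_latency_ms = 700, component_sd_ms = 80,
                           component_scale = 1.6, topography = NULL,
                           seed = NULL) {
  if (snr <= 0) stop("`snr` must be > 0")
  n_trials <- nrow(trials)
  latent <- truth$latent_confidence
  if (length(latent) != n_trials) {
    stop("trial count mismatch between `trials` and `truth`")
  }
  if (!is.null(alpha_power_per_trial) &&
      length(alpha_power_per_trial) != n_trials) {
    stop("`alpha_power_per_trial` must have one value per trial")
  }
  times <- seq(-prestim_ms, poststim_ms, by = 1)
  n_t <- length(times)
  ch_names <- if (n_channels == 64) montage_64() else
    paste0("CH", seq_len(n_channels))
  if (is.null(topography)) {
    # smooth bump over the channel axis, strongest centroparietally
    idx <- seq_len(n_channels)
    topography <- exp(-((idx - 0.72 * n_channels) / (0.18 * n_channels))^2)
  }
  topography <- topography / sqrt(sum(topography^2))
  s <- sd(latent[is.finite(latent)])
  if (!is.finite(s) || s <= 0) {
    stop("latent confidence must have positive, finite variance")
  }
  lat_std <- latent / s
  lat_std[!is.finite(lat_std)] <- 0
  kernel <- exp(-((times - component_latency_ms)^2) / (2 * component_sd_ms^2))
  noise_sd <- if (is.infinite(snr)) 0 else 1 / snr
  op_idx <- grep("^(P|PO|O)[0-9z]", ch_names)
  if (length(op_idx) == 0L) op_idx <- seq_len(n_channels)
  with_seed(seed, {
    dat <- array(0, dim = c(n_trials, n_channels, n_t))
    amp <- component_scale * lat_std
    prestim_mask <- times < 0
    for (i in seq_len(n_trials)) {
      tr <- tcrossprod(topography, amp[i] * kernel)   # channels x time
      if (noise_sd > 0) {
        tr <- tr + t(pink_noise(n_t, n_channels)) * noise_sd
      }
      if (!is.null(alpha_power_per_trial)) {
        phase <- runif(1, 0, 2 * pi)
        osc <- alpha_power_per_trial[i] *
          sin(2 * pi * 10 * times / 1000 + phase) * prestim_mask
        tr[op_idx, ] <- tr[op_idx, ] + rep(osc, each = length(op_idx))
      }
      dat[i, , ] <- tr
    }
    out <- eeg_epochs(dat, times, ch_names)
    attr(out, "true_topography") <- topography
    attr(out, "latent_confidence") <- amp
    out
  })
}

#' Read or write epoched EEG as a raw array plus JSON sidecar
#'
#' The voltage array is stored column-major as little-endian doubles in a
#' gzip-compressed `<prefix>.dat`, with dimensions, time axis, channel
#' labels and sampling rate in a `<prefix>.json` sidecar.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param prefix Path prefix (without extension).
#' @return `write_eeg_epochs()` returns `prefix` invisibly;
#'   `read_eeg_epochs()` returns the reconstructed [eeg_epochs()].
#' @export
write_eeg_epochs <- function(epochs, prefix) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  con <- gzfile(paste0(prefix, ".dat"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(epochs$data), con, size = 8, endian = "little")
  sidecar <- list(dims = dim(epochs$data), sfreq = epochs$sfreq,
                  times_ms = epochs$times_ms,
                  channel_names = epochs$channel_names)
  jsonlite::write_json(sidecar, paste0(prefix, ".json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_eeg_epochs
#' @export
read_eeg_epochs <- function(prefix) {
  sidecar <- jsonlite::read_json(paste0(prefix, ".json"),
                                 simplifyVector = TRUE)
  n <- prod(sidecar$dims)
  con <- gzfile(paste0(prefix, ".dat"), "rb")
  on.exit(close(con), add = TRUE)
  dat <- readBin(con, what = "double", n = n, size = 8, endian = "little")
  eeg_epochs(array(dat, dim = sidecar$dims), sidecar$times_ms,
             sidecar$channel_names, sidecar$sfreq)
}
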