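#' Generate a synthetic 4D BOLD dataset with known ground truth
#'
#' Builds voxel time series as `baseline + X_interest * beta_voxel + noise`
#' where `X_interest` is one column of a [build_design()] design. Only the
#' voxels in `active_vox` carry a nonzero effect on the regressor of
#' interest, so activation maps can be scored against a known target. Noise
#' is white Gaussian per voxel; an optional Gaussian spatial smoothing of
#' the noise field (applied per volume and globally rescaled back to unit
#' SD) reproduces the spatial correlation that smoothed real data carry,
#' which is what makes cluster-extent inference non-trivial.
#'
#' @param design A `glm_design` whose rows define the volumes.
#' @param regressor_of_interest Column of the design carrying the effect.
#' @param effect_size Beta value given to every active voxel (recycled over
#'   `active_vox`).
#' @param active_vox Linear voxel indices (into the `dims` grid) of the
#'   active cluster; `NULL` or empty for null data.
#' @param noise_sd White-noise standard deviation (`>= 0`).
#' @param dims Spatial dimensions of the volume.
#' @param baseline Mean signal level added to every voxel.
#' @param smooth_fwhm_vox FWHM (in voxels) of the optional Gaussian spatial
#'   smoothing of the noise; 0 disables it.
#' @param seed Integer seed; the dataset is a pure function of the
#'   arguments.
#' @param out_dir If given, the volume is written as NIfTI
#'   (`bold.nii.gz`) and the design's events as a BIDS-style
#'   `events.tsv` (onset, duration, trial_type, modulation) there.
#'
#' @return A list: `bold` (4D array x,y,z,time), `truth` (list with
#'   `beta` per-voxel effect vector, `active_vox`, `regressor`, `seed`),
#'   and the paths written (if any).
#' @export
gen_bold_dataset <- function(design, regressor_of_interest = NULL,
                             effect_size = 1, active_vox = NULL,
                             noise_sd = 1, dims = c(20, 20, 20),
                             baseline = 100, smooth_fwhm_vox = 0,
                             seed = NULL, out_dir = NULL) {
  stopifnot(inherits(design, "glm_design"))
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  n_vol <- design$n_volumes
  if (nrow(design$X) != n_vol) stop("design rows must equal n_volumes")
  regressor_of_interest <- regressor_of_interest %||% colnames(design$X)[1]
  xcol <- design$X[, regressor_of_interest]
  n_vox <- prod(dims)
  beta <- numeric(n_vox)
  if (length(active_vox) > 0L) {
    stopifnot(all(active_vox >= 1L), all(active_vox <= n_vox))
    beta[active_vox] <- rep_len(effect_size, length(active_vox))
  }
  bold <- with_seed(seed, {
    noise <- matrix(rnorm(n_vol * n_vox, sd = noise_sd), n_vol, n_vox)
    if (smooth_fwhm_vox > 0 && noise_sd > 0) {
      noise <- smooth_noise_3d(noise, dims, smooth_fwhm_vox)
      noise <- noise * (noise_sd / sd(noise))
    }
    Y <- baseline + outer(xcol, beta) + noise
    array(t(Y), dim = c(dims, n_vol))
  })
  truth <- list(beta = beta, active_vox = active_vox,
                regressor = regressor_of_interest, seed = seed)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    nii_path <- file.path(out_dir, "bold.nii.gz")
    RNifti::writeNifti(RNifti::asNifti(bold, pixdim = c(3, 3, 3, design$tr_s)),
                       nii_path)
    ev_path <- file.path(out_dir, "events.tsv")
    write_events_tsv(design$events, ev_path)
    paths <- c(bold = nii_path, events = ev_path)
  }
  list(bold = bold, truth = truth, paths = paths)
}

# Separable Gaussian smoothing of per-volume noise fields: each spatial axis
# is filtered with a truncated, row-normalised Gaussian matrix, applied to
# all volumes at once via reshapes.
smooth_noise_3d <- function(noise, dims, fwhm_vox) {
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  smat <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-d^2 / (2 * sigma^2))
    k / rowSums(k)
  }
  n_vol <- nrow(noise)
  arr <- array(t(noise), dim = c(dims, n_vol))
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:4, ax))
    arr <- aperm(arr, perm)
    dm <- dim(arr)
    arr <- array(smat(dm[1]) %*% matrix(arr, dm[1]), dim = dm)
    arr <- aperm(arr, order(perm))
  }
  t(matrix(arr, prod(dims), n_vol))
}

#' Write a BIDS-style events table
#'
#' Columns: `onset`, `duration`, `trial_type`, `modulation`.
#'
#' @param events An event table as used by [build_design()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  out <- data.frame(onset = events$onset_s, duration = events$duration_s,
                    trial_type = events$regressor,
                    modulation = events$amplitude)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE)
  tibble::tibble(regressor = df$trial_type, onset_s = df$onset,
                 duration_s = df$duration, amplitude = df$modulation)
}
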