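#' Canonical double-gamma haemodynamic response function
#'
#' The standard difference-of-gammas HRF (response gamma with shape 6,
#' undershoot gamma with shape 16, both rate 1 per second, undershoot ratio
#' 1/6), normalised to unit peak.
#'
#' @param t Time in seconds.
#' @param peak_delay,undershoot_delay Gamma shapes of the response and
#'   undershoot lobes (seconds to mode + 1).
#' @param ratio Response-to-undershoot amplitude ratio.
#' @return HRF values at `t`.
#' @export
hrf_double_gamma <- function(t, peak_delay = 6, undershoot_delay = 16,
                             ratio = 6) {
  h <- dgamma(t, shape = peak_delay, rate = 1) -
    dgamma(t, shape = undershoot_delay, rate = 1) / ratio
  h / max(dgamma(seq(0, 32, by = 0.01), shape = peak_delay, rate = 1) -
            dgamma(seq(0, 32, by = 0.01), shape = undershoot_delay,
                   rate = 1) / ratio)
}

#' Build an event-based GLM design matrix
#'
#' Each regressor is an amplitude-weighted stick/boxcar train laid out on a
#' fine time grid (default 0.1 s), convolved with the double-gamma HRF and
#' sampled at the volume acquisition times. Parametric regressors have their
#' event amplitudes mean-centred before convolution (so they model
#' trial-to-trial variation orthogonal to the mean stimulus response);
#' unmodulated regressors keep amplitude 1. Events extending beyond the scan
#' are dropped with a warning.
#'
#' @param events A data frame with columns `regressor` (name), `onset_s`,
#'   `duration_s`, `amplitude`, and optionally `parametric` (logical;
#'   default: TRUE for any regressor whose amplitudes vary).
#' @param n_volumes Number of volumes.
#' @param tr_s Repetition time in seconds.
#' @param oversample_s Fine-grid resolution for convolution.
#' @param hrf HRF function of time in seconds.
#'
#' @return An object of class `glm_design`: `X` (n_volumes x regressors),
#'   `frame_times`, `tr_s`, plus the fine-grid kernel metadata needed to
#'   rebuild single regressors.
#' @export
build_design <- function(events, n_volumes, tr_s = 2.0, oversample_s = 0.1,
                         hrf = hrf_double_gamma) {
  stopifnot(all(c("regressor", "onset_s", "duration_s", "amplitude") %in%
                  names(events)))
  if (any(!is.finite(events$amplitude))) stop("amplitudes must be finite")
  scan_end <- n_volumes * tr_s
  beyond <- events$onset_s >= scan_end
  if (any(beyond)) {
    warning(sprintf("%d events at/after scan end dropped", sum(beyond)))
    events <- events[!beyond, ]
  }
  if (any(events$onset_s < 0)) stop("onsets must be >= 0")
  if (nrow(events) == 0L) stop("design has an all-zero column set: no events remain within the scan")
  if (!"parametric" %in% names(events)) {
    events <- events |>
      dplyr::group_by(.data$regressor) |>
      dplyr::mutate(parametric = length(unique(.data$amplitude)) > 1L) |>
      dplyr::ungroup()
  }
  frame_times <- (seq_len(n_volumes) - 1) * tr_s
  names_u <- unique(events$regressor)
  cols <- vapply(names_u, function(nm) {
    ev <- events[events$regressor == nm, ]
    convolve_events(ev, n_volumes, tr_s, oversample_s, hrf)
  }, numeric(n_volumes))
  colnames(cols) <- names_u
  if (any(colSums(abs(cols)) == 0)) {
    stop("design contains an all-zero column: ",
         paste(names_u[colSums(abs(cols)) == 0], collapse = ", "))
  }
  structure(
    list(X = cols, frame_times = frame_times, tr_s = tr_s,
         oversample_s = oversample_s, hrf = hrf, n_volumes = n_volumes,
         events = events),
    class = "glm_design"
  )
}

# Stick/boxcar train on the fine grid, convolved with the HRF, sampled at
# frame times. Parametric amplitudes are mean-centred first.
convolve_events <- function(ev, n_volumes, tr_s, oversample_s, hrf) {
  amp <- ev$amplitude
  if (isTRUE(ev$parametric[1])) amp <- amp - mean(amp)
  scan_end <- n_volumes * tr_s
  n_fine <- ceiling(scan_end / oversample_s)
  train <- numeric(n_fine)
  for (j in seq_len(nrow(ev))) {
    i0 <- floor(ev$onset_s[j] / oversample_s + 1e-6) + 1L
    n_bins <- max(1L, round(ev$duration_s[j] / oversample_s))
    idx <- i0:min(n_fine, i0 + n_bins - 1L)
    train[idx] <- train[idx] + amp[j]
  }
  kern <- hrf(seq(0, 32, by = oversample_s))
  conv <- convolve(train, rev(kern), type = "open")[seq_len(n_fine)]
  frame_idx <- pmin(n_fine, floor((seq_len(n_volumes) - 1) * tr_s /
                                    oversample_s) + 1L)
  conv[frame_idx]
}

#' @export
print.glm_design <- function(x, ...) {
  cat(sprintf("GLM design: %d volumes (TR %g s) x %d regressors: %s\n",
              x$n_volumes, x$tr_s, ncol(x$X),
              paste(colnames(x$X), collapse = ", ")))
  invisible(x)
}

#' Add confound columns to a design
#'
#' Confounds (motion parameters, cosine drift terms, ...) enter the model
#' unconvolved.
#'
#' @param design A [build_design()] result.
#' @param confounds Matrix (or data frame) with `n_volumes` rows.
#' @return The design with columns appended.
#' @export
add_confounds <- function(design, confounds) {
  confounds <- as.matrix(confounds)
  stopifnot(nrow(confounds) == design$n_volumes)
  if (is.null(colnames(confounds))) {
    colnames(confounds) <- paste0("confound", seq_len(ncol(confounds)))
  }
  design$X <- cbind(design$X, confounds)
  design
}

#' Discrete-cosine high-pass basis
#'
#' Cosine drift regressors implementing a high-pass filter with the given
#' cutoff period; include them as confounds.
#'
#' @param n_volumes,tr_s Scan geometry.
#' @param cutoff_s High-pass cutoff period in seconds.
#' @return A matrix of cosine basis functions (possibly zero columns).
#' @export
dct_basis <- function(n_volumes, tr_s = 2.0, cutoff_s = 100) {
  t_total <- n_volumes * tr_s
  k_max <- floor(2 * t_total / cutoff_s)
  if (k_max < 1L) return(matrix(numeric(0), n_volumes, 0))
  t_idx <- seq_len(n_volumes) - 0.5
  out <- vapply(seq_len(k_max), function(k) {
    cos(pi * k * t_idx / n_volumes)
  }, numeric(n_volumes))
  colnames(out) <- paste0("dct", seq_len(k_max))
  out
}

#' Fit a voxelwise GLM
#'
#' Ordinary least squares per voxel with an intercept added automatically;
#' per-regressor t statistics are converted to Z scores by matching
#' cumulative probabilities at the residual degrees of freedom.
#'
#' @param bold A 4D array (x, y, z, time) or a time x voxels matrix.
#' @param design A [build_design()] result (optionally with confounds).
#' @return An object of class `glm_fit`: `beta` (regressors x voxels), `z`,
#'   `t`, `df`, `dims` (spatial dims when the input was 4D),
#'   `regressor_names`.
#' @export
fit_glm <- function(bold, design) {
  dims <- NULL
  if (length(dim(bold)) == 4L) {
    dims <- dim(bold)[1:3]
    Y <- t(matrix(bold, prod(dims), dim(bold)[4]))
  } else {
    Y <- as.matrix(bold)
  }
  X <- design$X
  stopifnot(nrow(Y) == nrow(X))
  Xi <- cbind(`(Intercept)` = 1, X)
  qrx <- qr(Xi)
  if (qrx$rank < ncol(Xi)) {
    bad <- colnames(Xi)[qrx$pivot[(qrx$rank + 1):ncol(Xi)]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  xtx_inv <- chol2inv(qr.R(qrx))[order(qrx$pivot), order(qrx$pivot)]
  beta <- xtx_inv %*% crossprod(Xi, Y)
  rownames(beta) <- colnames(Xi)
  resid <- Y - Xi %*% beta
  df <- nrow(Y) - ncol(Xi)
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(outer(diag(xtx_inv), sigma2))
  t_stat <- beta / se
  z <- t_to_z(t_stat, df)
  keep <- -1L  # drop the intercept row from the maps
  structure(
    list(beta = beta[keep, , drop = FALSE], t = t_stat[keep, , drop = FALSE],
         z = z[keep, , drop = FALSE], df = df, dims = dims,
         regressor_names = colnames(X)),
    class = "glm_fit"
  )
}

# t -> z by matching tail probabilities, computed on the log scale so very
# large statistics do not saturate to Inf prematurely.
t_to_z <- function(t_stat, df) {
  sign(t_stat) * qnorm(pt(abs(t_stat), df, lower.tail = FALSE, log.p = TRUE),
                       lower.tail = FALSE, log.p = TRUE)
}

#' Extract a 3D statistical map from a fit
#'
#' @param fit A [fit_glm()] result on 4D input.
#' @param regressor Regressor name.
#' @param statistic `"z"` or `"beta"`.
#' @return A 3D array.
#' @export
stat_map <- function(fit, regressor, statistic = c("z", "beta")) {
  statistic <- match.arg(statistic)
  stopifnot(!is.null(fit$dims))
  row <- match(regressor, fit$regressor_names)
  if (is.na(row)) stop("unknown regressor: ", regressor)
  array(fit[[statistic]][row, ], dim = fit$dims)
}

#' Variance inflation factors of a design
#'
#' `VIF_j = 1 / (1 - R^2_j)`, with `R^2_j` from regressing column `j` on all
#' other columns plus an intercept. Values above 5-10 indicate problematic
#' collinearity; perfectly collinear columns report `Inf`.
#'
#' @param design A [build_design()] result.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(design) {
  X <- design$X
  if (ncol(X) < 2L) stop("need at least 2 regressors")
  vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> stats::setNames(colnames(X))
}

neighbour_offsets <- function(connectivity) {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  switch(as.character(connectivity),
         "6" = offs[rowSums(abs(offs)) == 1, , drop = FALSE],
         "18" = offs[rowSums(abs(offs)) <= 2, , drop = FALSE],
         "26" = offs,
         stop("connectivity must be 6, 18 or 26"))
}

#' Extract suprathreshold clusters from a Z map
#'
#' Connected components of `|z| >= z_min`, clustered separately for positive
#' and negative excursions (default 26-neighbour connectivity, i.e.
#' vertex-touching voxels connect), filtered to a minimum extent.
#'
#' @param z A 3D Z-score array.
#' @param z_min Per-voxel threshold.
#' @param min_size Minimum cluster extent in voxels.
#' @param connectivity 6, 18 or 26.
#' @param signs Which excursion signs to cluster (`"both"`, `"positive"`,
#'   `"negative"`).
#' @return A tibble of class `cluster_set` with one row per cluster:
#'   `sign`, `size`, `peak_z`, `peak_x/y/z`, and a list-column `voxels` of
#'   linear indices.
#' @export
cluster_extract <- function(z, z_min = 2.57, min_size = 5L,
                            connectivity = 26L,
                            signs = c("both", "positive", "negative")) {
  signs <- match.arg(signs)
  stopifnot(length(dim(z)) == 3L, all(is.finite(z)))
  offs <- neighbour_offsets(connectivity)
  parts <- list()
  if (signs %in% c("both", "positive")) {
    parts$pos <- connected_components(z >= z_min, z, offs, "positive")
  }
  if (signs %in% c("both", "negative")) {
    parts$neg <- connected_components(z <= -z_min, z, offs, "negative")
  }
  res <- dplyr::bind_rows(parts)
  res <- res[res$size >= min_size, , drop = FALSE]
  tibble::new_tibble(res, class = "cluster_set")
}

connected_components <- function(mask, z, offs, sign_label) {
  dims <- dim(mask)
  idx <- which(mask)
  empty <- tibble::tibble(sign = character(), size = integer(),
                          peak_z = numeric(), peak_x = integer(),
                          peak_y = integer(), peak_z_coord = integer(),
                          voxels = list())
  if (length(idx) == 0L) return(empty)
  labels <- array(0L, dims)
  comp <- 0L
  members_list <- list()
  coords <- arrayInd(idx, dims)
  in_mask <- array(FALSE, dims)
  in_mask[idx] <- TRUE
  for (v in seq_along(idx)) {
    if (labels[idx[v]] != 0L) next
    comp <- comp + 1L
    stack <- matrix(coords[v, ], 1L)
    labels[idx[v]] <- comp
    members <- idx[v]
    while (nrow(stack) > 0L) {
      cur <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      nb <- sweep(offs, 2, cur, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      if (nrow(nb) == 0L) next
      lin <- nb[, 1] + (nb[, 2] - 1L) * dims[1] +
        (nb[, 3] - 1L) * dims[1] * dims[2]
      new <- lin[in_mask[lin] & labels[lin] == 0L]
      if (length(new) > 0L) {
        labels[new] <- comp
        members <- c(members, new)
        stack <- rbind(stack, arrayInd(new, dims))
      }
    }
    members_list[[comp]] <- members
  }
  peaks <- vapply(members_list, function(m) m[which.max(abs(z[m]))],
                  integer(1))
  pc <- arrayInd(peaks, dims)
  tibble::tibble(
    sign = sign_label,
    size = vapply(members_list, length, integer(1)),
    peak_z = z[peaks],
    peak_x = pc[, 1], peak_y = pc[, 2], peak_z_coord = pc[, 3],
    voxels = lapply(members_list, sort)
  )
}

#' Amplitude-permutation cluster-size threshold
#'
#' Builds the null distribution of suprathreshold cluster sizes by shuffling
#' the per-event amplitude sequence of the parametric regressor of interest,
#' rebuilding the design, refitting the GLM and recording the sizes of all
#' positive clusters passing the per-voxel threshold and minimum extent.
#' Sizes are pooled across all iterations and the corrected extent threshold
#' is the `pct`-th percentile of the pooled distribution. If no cluster
#' forms in any iteration the minimum extent is returned with a warning.
#'
#' @param bold 4D BOLD array.
#' @param events Event table as for [build_design()].
#' @param regressor_of_interest Name of the parametric regressor whose
#'   amplitudes are shuffled.
#' @param n_perm Number of permutations.
#' @param z_min,min_size,connectivity Cluster definition.
#' @param pct Percentile of the pooled size distribution.
#' @param confounds Optional confound matrix added to every design.
#' @param seed Integer seed.
#' @param tr_s Repetition time.
#' @return The cluster-extent threshold (voxels), with the pooled null sizes
#'   as attribute `"null_sizes"` and the per-iteration maximum size (0 when
#'   an iteration produced no cluster) as attribute `"null_max_sizes"` —
#'   the latter supports a max-statistic threshold
#'   (`quantile(attr(thr, "null_max_sizes"), pct / 100)`), which controls
#'   the familywise rate more strictly than the pooled rule.
#' @export
permutation_cluster_threshold <- function(bold, events, regressor_of_interest,
                                          n_perm = 200L, z_min = 2.57,
                                          min_size = 5L, pct = 95,
                                          connectivity = 26L,
                                          confounds = NULL, seed = NULL,
                                          tr_s = 2.0) {
  n_volumes <- dim(bold)[4]
  of_interest <- events$regressor == regressor_of_interest
  if (!any(of_interest)) stop("unknown regressor: ", regressor_of_interest)
  amps <- events$amplitude[of_interest]
  if (length(unique(amps)) < 2L) {
    stop("regressor of interest must be parametric (varying amplitudes)")
  }
  dims3 <- dim(bold)[1:3]
  Y <- t(matrix(bold, prod(dims3), n_volumes))
  per_iter <- with_seed(seed, {
    lapply(seq_len(n_perm), function(p) {
      ev <- events
      ev$amplitude[of_interest] <- sample(amps)
      des <- build_design(ev, n_volumes, tr_s)
      if (!is.null(confounds)) des <- add_confounds(des, confounds)
      fit <- fit_glm(Y, des)
      zmap <- array(fit$z[regressor_of_interest, ], dims3)
      cl <- cluster_extract(zmap, z_min, min_size, connectivity,
                            signs = "positive")
      cl$size
    })
  })
  sizes <- unlist(per_iter)
  if (length(sizes) == 0L) {
    warning("no suprathreshold clusters in any permutation; ",
            "returning min_size")
    thr <- min_size
  } else {
    thr <- unname(quantile(sizes, pct / 100, type = 7))
  }
  attr(thr, "null_sizes") <- sizes
  attr(thr, "null_max_sizes") <- vapply(per_iter, function(s) {
    if (length(s) == 0L) 0L else max(s)
  }, integer(1))
  thr
}

#' Psychophysiological interaction (PPI) design
#'
#' Builds the four task regressors of a PPI model: (1) an unmodulated,
#' HRF-convolved stick regressor at stimulus onsets; (2) the physiological
#' regressor, the demeaned seed-region time course (unconvolved); (3) the
#' psychological regressor, an HRF-convolved boxcar train whose per-trial
#' duration is the decision time, zero-centred after convolution; (4) the
#' interaction, the elementwise product of (2) and (3). A significant
#' interaction indicates voxels whose coupling with the seed strengthens
#' during the decision period.
#'
#' @param seed_ts Seed-region time course, one value per volume.
#' @param onsets_s Stimulus onsets (seconds).
#' @param decision_times_s Per-trial decision durations (seconds).
#' @param n_volumes,tr_s Scan geometry.
#' @return A `glm_design` with columns `task`, `physio`, `psych`,
#'   `interaction`.
#' @export
ppi_design <- function(seed_ts, onsets_s, decision_times_s, n_volumes,
                       tr_s = 2.0) {
  if (length(seed_ts) != n_volumes) {
    stop("`seed_ts` must have one value per volume")
  }
  if (all(seed_ts == 0)) stop("degenerate seed: all-zero time course")
  stopifnot(length(onsets_s) == length(decision_times_s))
  ev_task <- tibble::tibble(regressor = "task", onset_s = onsets_s,
                            duration_s = 0.1, amplitude = 1,
                            parametric = FALSE)
  ev_psych <- tibble::tibble(regressor = "psych", onset_s = onsets_s,
                             duration_s = decision_times_s, amplitude = 1,
                             parametric = FALSE)
  des <- build_design(dplyr::bind_rows(ev_task, ev_psych), n_volumes, tr_s)
  physio <- seed_ts - mean(seed_ts)
  psych <- des$X[, "psych"] - mean(des$X[, "psych"])
  X <- cbind(task = des$X[, "task"], physio = physio, psych = psych,
             interaction = physio * psych)
  des$X <- X
  des$events <- dplyr::bind_rows(ev_task, ev_psych)
  des
}

#' Percent signal change around event onsets
#'
#' For each event, the region time course in a peristimulus window (default
#' -4 to 10 s) is expressed as deviation from the trial's pre-onset baseline
#' (mean over the 4 s before onset) scaled by the run-mean signal:
#' `psc(t) = (x(t) - baseline) / mean(x)`. Onsets are aligned to the
#' nearest volume; trial timecourses are averaged within condition bins.
#'
#' @param ts Region-averaged BOLD time course, one value per volume.
#' @param onsets_s Event onsets in seconds.
#' @param bins Optional per-event condition labels (e.g. component-amplitude
#'   tertiles); defaults to one bin.
#' @param window_s Peristimulus window (seconds, relative to onset).
#' @param baseline_s Length of the pre-onset baseline window (seconds).
#' @param tr_s Repetition time.
#' @return A tibble of class `psc` with columns `bin`, `time_s`, `psc`,
#'   `n_trials`. Events without a full window are dropped with a warning.
#' @export
percent_signal_change <- function(ts, onsets_s, bins = NULL,
                                  window_s = c(-4, 10), baseline_s = 4,
                                  tr_s = 2.0) {
  run_mean <- mean(ts)
  if (run_mean <= 0) stop("run-mean signal must be positive")
  n_vol <- length(ts)
  if (is.null(bins)) bins <- rep("all", length(onsets_s))
  stopifnot(length(bins) == length(onsets_s))
  rel_vols <- seq(floor(window_s[1] / tr_s), ceiling(window_s[2] / tr_s))
  n_base <- max(1L, round(baseline_s / tr_s))
  rows <- purrr::map2(onsets_s, bins, function(on, b) {
    centre <- round(on / tr_s) + 1L       # nearest volume, 1-based
    vols <- centre + rel_vols
    base_vols <- centre - seq_len(n_base)
    if (min(c(vols, base_vols)) < 1L || max(vols) > n_vol) return(NULL)
    baseline <- mean(ts[base_vols])
    tibble::tibble(bin = b, time_s = rel_vols * tr_s,
                   psc = (ts[vols] - baseline) / run_mean)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L) {
    warning(sprintf("%d events without a full window dropped", dropped))
  }
  if (dropped == length(rows)) {
    return(tibble::new_tibble(
      tibble::tibble(bin = character(), time_s = numeric(),
                     n_trials = integer(), psc = numeric()),
      class = "psc"
    ))
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$bin, .data$time_s) |>
    dplyr::summarise(n_trials = dplyr::n(), psc = mean(.data$psc),
                     .groups = "drop")
  tibble::new_tibble(out, class = "psc")
}

#' Plot percent-signal-change timecourses
#'
#' @param object A `psc` tibble.
#' @param ... Unused.
#' @export
autoplot.psc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$psc,
                                       colour = .data$bin)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "Time from onset (s)", y = "BOLD change (fraction)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
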