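# Shared fixtures, built once per test run. Expensive objects are memoised in
# this environment; everything is generated in code from fixed seeds.
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Standard behavioural session at the grid-centre parameters.
fixture_behaviour <- function() {
  memo("behaviour", gen_behaviour(n_trials = 300, seed = 101))
}

# Small, fast epochs for unit tests: 16 channels, reduced trial count.
fixture_small_epochs <- function() {
  memo("small_epochs", {
    beh <- fixture_behaviour()
    idx <- 1:120
    trials <- beh$trials[idx, ]
    truth <- beh$truth
    truth$latent_confidence <- truth$latent_confidence[idx]
    list(
      epochs = gen_eeg_epochs(trials, truth, snr = 1, n_channels = 16,
                              seed = 202),
      trials = trials, truth = truth
    )
  })
}

# Mann-Whitney pair-counting oracle for the ROC area (ties get half credit).
az_pair_count <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Independent connected-components oracle: iterative minimum-label
# propagation until fixpoint (different algorithm from the package's BFS).
cluster_sizes_oracle <- function(z, z_min, connectivity) {
  dims <- dim(z)
  mask <- z >= z_min
  lab <- array(0, dims)
  lab[mask] <- seq_len(sum(mask))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  repeat {
    changed <- FALSE
    for (v in which(mask)) {
      co <- arrayInd(v, dims)
      for (k in seq_len(nrow(offs))) {
        nb <- co + offs[k, ]
        if (any(nb < 1) || any(nb > dims)) next
        l2 <- lab[nb[1], nb[2], nb[3]]
        if (l2 > 0 && l2 < lab[v]) {
          lab[v] <- l2
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  sort(as.integer(table(lab[lab > 0])))
}

# Minimal event table helpers for the GLM tests.
stick_events <- function(name, onsets, amplitude = 1, duration = 0.1,
                         parametric = length(unique(amplitude)) > 1) {
  tibble::tibble(regressor = name, onset_s = onsets, duration_s = duration,
                 amplitude = amplitude, parametric = parametric)
}
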