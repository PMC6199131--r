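#' Generate synthetic behaviour with known ground truth
#'
#' Simulates a full behavioural session of the confidence-rating task:
#' choices, response times and latent balance-of-evidence confidence come
#' from the race model; 9-point confidence ratings are a noisy, rounded
#' affine map of the latent confidence, chosen to span the whole scale; a
#' small random fraction of trials is marked invalid (missing rating),
#' mirroring typical discarded-trial rates. Trials not answered before the
#' response deadline are invalid with missing choice.
#'
#' @param params A [race_params()] object; defaults to the centre of the
#'   standard fitting grid.
#' @param n_trials Total number of trials, split evenly over `n_runs`.
#' @param rating_noise_sd SD of the Gaussian noise added to the latent
#'   rating before rounding, on the 1-9 scale. The default of 1 produces
#'   ratings spread over the full scale.
#' @param missing_frac Fraction of trials with a missing rating (invalid).
#' @param n_runs Number of runs/blocks.
#' @param deadline_ms Response deadline; slower trials are treated as missed.
#' @param seed Integer seed; the output is a pure function of the arguments.
#'
#' @return A list with `trials`, a tibble of class `trial_table` with columns
#'   `trial_index` (0-based within run), `run_id`, `direction`, `choice`,
#'   `accuracy`, `rt_ms`, `rating`, `valid`; and `truth`, a `ground_truth`
#'   list holding the per-trial latent confidence (`delta_e`), the generating
#'   parameters and the seed.
#' @export
gen_behaviour <- function(params = race_params(), n_trials = 320,
                          rating_noise_sd = 1, missing_frac = 0.04,
                          n_runs = 2, deadline_ms = 1500, seed = NULL) {
  if (n_trials < 1) stop("`n_trials` must be >= 1")
  if (rating_noise_sd < 0) stop("`rating_noise_sd` must be >= 0")
  with_seed(seed, {
    directions <- sample(c(-1L, 1L), n_trials, replace = TRUE)
    sim <- race_simulate(params, directions)
    missed <- !sim$crossed | (!is.na(sim$rt_ms) & sim$rt_ms > deadline_ms)
    rating <- rating_from_latent(sim$delta_e, rating_noise_sd)
    drop_rating <- runif(n_trials) < missing_frac
    rating[drop_rating | missed] <- NA_integer_
    run_id <- rep(seq_len(n_runs), length.out = n_trials)
    run_id <- sort(run_id)
    trial_index <- unlist(lapply(table(run_id), function(k) seq_len(k) - 1L),
                          use.names = FALSE)
    trials <- tibble::new_tibble(
      tibble::tibble(
        trial_index = as.integer(trial_index),
        run_id = as.integer(run_id),
        direction = sim$direction,
        choice = ifelse(missed, NA_integer_, sim$choice),
        accuracy = ifelse(missed, NA_integer_, sim$accuracy),
        rt_ms = ifelse(missed, NA_real_, sim$rt_ms),
        rating = rating,
        valid = !missed & !is.na(rating)
      ),
      class = "trial_table"
    )
    truth <- structure(
      list(latent_confidence = sim$delta_e, params = params,
           rating_noise_sd = rating_noise_sd, seed = seed),
      class = "ground_truth"
    )
    list(trials = trials, truth = truth)
  })
}

# Affine map of latent confidence onto the 1..9 scale (span the scale), plus
# Gaussian noise, rounded and clipped. Monotone when noise_sd = 0.
rating_from_latent <- function(latent, noise_sd) {
  ok <- is.finite(latent)
  out <- rep(NA_integer_, length(latent))
  if (!any(ok)) return(out)
  rng <- range(latent[ok])
  scaled <- if (diff(rng) > 0) {
    1 + 8 * (latent[ok] - rng[1]) / diff(rng)
  } else {
    rep(5, sum(ok))
  }
  noisy <- scaled + rnorm(sum(ok), sd = noise_sd)
  out[ok] <- as.integer(pmin(9L, pmax(1L, round(noisy))))
  out
}

#' Read or write a trial table as CSV
#'
#' The on-disk column order is fixed: `trial_index, run_id, direction,
#' choice, accuracy, rt_ms, rating, valid`.
#'
#' @param trials A `trial_table` tibble.
#' @param path File path.
#' @return `read_trial_table()` returns a `trial_table` tibble;
#'   `write_trial_table()` returns `path` invisibly.
#' @export
write_trial_table <- function(trials, path) {
  cols <- c("trial_index", "run_id", "direction", "choice", "accuracy",
            "rt_ms", "rating", "valid")
  write.table(trials[, cols], path, sep = ",", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE)
  df$valid <- as.logical(df$valid)
  tibble::new_tibble(tibble::as_tibble(df), class = "trial_table")
}
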