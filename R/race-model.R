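#' Race-model parameter set
#'
#' Bundles the parameters of the two-accumulator race model of perceptual
#' choice. Each accumulator integrates evidence in 1 ms steps towards a common
#' threshold; the stimulus-congruent accumulator draws increments with mean
#' `mu_congr` and the incongruent one with mean `mu_congr / r` (a mean ratio
#' above 1 favours the correct response), both with standard deviation
#' `sigma`.
#' Response time is the threshold-crossing time plus the non-decision time
#' `ndt_ms`; confidence is read out as the balance of evidence `delta_e`,
#' the distance between the threshold and the losing accumulator at the
#' moment of decision.
#'
#' @param sigma Increment standard deviation (a.u. per ms), `>= 0`.
#' @param theta Decision threshold (a.u.), `> 0`.
#' @param ndt_ms Non-decision time added to the crossing time (ms), `>= 0`.
#' @param r Ratio of congruent to incongruent increment means, `> 0`
#'   (values `> 1` make the correct accumulator faster on average).
#' @param mu_congr Mean increment of the stimulus-congruent accumulator
#'   (a.u. per ms). Fixed at 0.1 by convention; exposed for closed-form tests.
#' @param dt_ms Accumulation step (ms); the model is defined at 1 ms.
#' @param max_accum_ms Maximum accumulation time before a trial is flagged as
#'   not having crossed the threshold.
#'
#' @return An object of class `race_params`.
#' @export
race_params <- function(sigma = 0.8, theta = 76, ndt_ms = 350, r = 1.4,
                        mu_congr = 0.1, dt_ms = 1, max_accum_ms = 1500) {
  if (sigma < 0) stop("`sigma` must be >= 0")
  if (r <= 0) stop("`r` must be > 0")
  if (theta <= 0) stop("`theta` must be > 0")
  if (ndt_ms < 0) stop("`ndt_ms` must be >= 0")
  structure(
    list(sigma = sigma, theta = theta, ndt_ms = ndt_ms, r = r,
         mu_congr = mu_congr, mu_incongr = mu_congr / r,
         dt_ms = dt_ms, max_accum_ms = as.integer(max_accum_ms)),
    class = "race_params"
  )
}

#' @export
print.race_params <- function(x, ...) {
  cat("Race model parameters\n")
  cat(sprintf("  sigma = %g, theta = %g, nDT = %g ms, r = %g\n",
              x$sigma, x$theta, x$ndt_ms, x$r))
  cat(sprintf("  mu_congr = %g, mu_incongr = %g, dt = %g ms, max = %d ms\n",
              x$mu_congr, x$mu_incongr, x$dt_ms, x$max_accum_ms))
  invisible(x)
}

#' Simulate the race model
#'
#' Runs one race per trial: both accumulators start at zero and add an
#' independent Gaussian increment each millisecond until one reaches the
#' threshold. The winning accumulator sets the choice, the crossing time plus
#' the non-decision time sets the response time, and the balance of evidence
#' `delta_e = theta - (losing accumulator at decision)` is the model's
#' trial-level confidence. Trials that do not cross within `max_accum_ms` are
#' flagged `crossed = FALSE` with missing choice, RT and `delta_e`.
#'
#' @param params A [race_params()] object.
#' @param directions Integer vector of stimulus directions, `-1` or `+1`,
#'   one per trial.
#' @param seed Optional integer seed; the simulation is a pure function of
#'   `(params, directions, seed)`.
#'
#' @return A tibble of class `race_sim` with columns `direction`, `choice`,
#'   `accuracy`, `rt_ms`, `delta_e`, `crossed`.
#' @export
race_simulate <- function(params, directions, seed = NULL) {
  stopifnot(inherits(params, "race_params"))
  if (length(directions) < 1L) stop("`directions` must be nonempty")
  if (!all(directions %in% c(-1L, 1L))) {
    stop("`directions` must be -1 or +1")
  }
  n <- length(directions)
  max_steps <- as.integer(round(params$max_accum_ms / params$dt_ms))
  sim <- with_seed(seed, race_sim_rng(n, params$mu_congr, params$mu_incongr,
                                      params$sigma, params$theta, max_steps))
  choice <- ifelse(sim$winner == 1L, directions, -directions)
  tibble::new_tibble(
    tibble::tibble(
      direction = as.integer(directions),
      choice = as.integer(choice),
      accuracy = as.integer(choice == directions),
      rt_ms = sim$rt_steps * params$dt_ms + params$ndt_ms,
      delta_e = sim$delta_e,
      crossed = sim$crossed
    ),
    class = "race_sim"
  )
}

# CRN variant used by the grid search: increments are supplied, not drawn, so
# the same noise is reused at every grid point.
race_simulate_crn <- function(params, z_congr, z_incongr) {
  sim <- race_sim_crn(z_congr, z_incongr, params$mu_congr, params$mu_incongr,
                      params$sigma, params$theta)
  tibble::tibble(
    accuracy = as.integer(sim$winner == 1L),
    rt_ms = sim$rt_steps * params$dt_ms + params$ndt_ms,
    delta_e = sim$delta_e,
    crossed = sim$crossed
  )
}

# Signed response times: correct trials keep their RT, error trials are
# mirrored to negative values, pooling both classes into one distribution.
signed_rt <- function(rt_ms, accuracy) {
  ifelse(accuracy == 1L, rt_ms, -rt_ms)
}

#' Kolmogorov-Smirnov log-likelihood of behaviour under a simulated model
#'
#' Scores how well a simulated trial set reproduces observed behaviour.
#' Correct- and error-trial RTs are pooled into a single signed distribution
#' by mirroring error RTs to negative values; the two signed samples are
#' compared with a two-sample Kolmogorov-Smirnov test (asymptotic p-value),
#' and a Gaussian penalty on the accuracy mismatch (SD 0.1) is added:
#' `LL = log(KS_p) - (acc_data - acc_model)^2 / 0.1^2`.
#'
#' @param data A data frame of observed trials with columns `rt_ms` and
#'   `accuracy` (invalid trials should be removed beforehand; rows with
#'   missing RT or accuracy are dropped).
#' @param sim A `race_sim` (or any data frame with `rt_ms`, `accuracy`,
#'   `crossed`); trials with `crossed = FALSE` are excluded.
#'
#' @return The log-likelihood (scalar, `<= 0`); `-Inf` when the KS p-value
#'   underflows to zero.
#' @export
race_log_likelihood <- function(data, sim) {
  keep_d <- !is.na(data$rt_ms) & !is.na(data$accuracy)
  d_rt <- data$rt_ms[keep_d]
  d_acc <- data$accuracy[keep_d]
  crossed <- if ("crossed" %in% names(sim)) sim$crossed else rep(TRUE, nrow(sim))
  m_rt <- sim$rt_ms[crossed]
  m_acc <- sim$accuracy[crossed]
  if (length(d_rt) < 2L || length(m_rt) < 2L) {
    stop("both `data` and `sim` must contain at least two usable trials")
  }
  x <- signed_rt(d_rt, d_acc)
  y <- signed_rt(m_rt, m_acc)
  ks_p <- suppressWarnings(ks.test(x, y, exact = FALSE)$p.value)
  acc_pen <- (mean(d_acc) - mean(m_acc))^2 / 0.1^2
  if (ks_p <= 0) return(-Inf)
  log(ks_p) - acc_pen
}

#' Default race-model search grid
#'
#' The standard grid: `sigma` 0.6 to 1 by 0.1, `theta` 55 to 97 by 7,
#' `ndt_ms` 250 to 450 by 50, `r` 1.2 to 1.6 by 0.05. Rows are ordered
#' sigma-major (sigma slowest, r fastest), which also defines the tie-break
#' order of the fit.
#'
#' @return A tibble with columns `sigma`, `theta`, `ndt_ms`, `r`.
#' @export
race_default_grid <- function() {
  tidyr::expand_grid(
    sigma = seq(0.6, 1.0, by = 0.1),
    theta = seq(55, 97, by = 7),
    ndt_ms = seq(250, 450, by = 50),
    r = seq(1.2, 1.6, by = 0.05)
  )
}

#' Fit the race model by grid-search maximum likelihood
#'
#' Simulates `n_sim` trials at every grid point and scores each against the
#' observed behaviour with [race_log_likelihood()]. Common random numbers are
#' used across grid points (one increment array drawn from `seed`, reused
#' everywhere) so that differences in likelihood reflect the parameters and
#' not simulation noise. The best point is the likelihood argmax; exact ties
#' go to the earlier row in grid order.
#'
#' @param data Observed trials (`rt_ms`, `accuracy`; valid trials only).
#' @param grid A parameter grid as from [race_default_grid()].
#' @param n_sim Simulated trials per grid point.
#' @param seed Integer seed for the shared increment noise.
#' @param mu_congr,dt_ms,max_accum_ms Fixed model constants.
#'
#' @return An object of class `race_fit`: `best_params` ([race_params()]),
#'   `ll_grid` (the grid with log-likelihood, model accuracy and the fraction
#'   of non-crossing trials per point), `n_sim`, `seed`.
#' @export
race_fit_grid <- function(data, grid = race_default_grid(), n_sim = 500,
                          seed = NULL, mu_congr = 0.1, dt_ms = 1,
                          max_accum_ms = 1500) {
  stopifnot(nrow(grid) >= 1L, n_sim >= 1L)
  if (nrow(data) < 2L) stop("`data` must contain valid trials")
  max_steps <- as.integer(round(max_accum_ms / dt_ms))
  z <- with_seed(seed, list(
    congr = matrix(rnorm(max_steps * n_sim), max_steps, n_sim),
    incongr = matrix(rnorm(max_steps * n_sim), max_steps, n_sim)
  ))
  res <- purrr::pmap(grid, function(sigma, theta, ndt_ms, r) {
    p <- race_params(sigma = sigma, theta = theta, ndt_ms = ndt_ms, r = r,
                     mu_congr = mu_congr, dt_ms = dt_ms,
                     max_accum_ms = max_accum_ms)
    sim <- race_simulate_crn(p, z$congr, z$incongr)
    ll <- if (sum(sim$crossed) >= 2L) race_log_likelihood(data, sim) else -Inf
    tibble::tibble(
      ll = ll,
      acc_model = mean(sim$accuracy[sim$crossed]),
      frac_not_crossed = mean(!sim$crossed)
    )
  })
  ll_grid <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  if (!any(is.finite(ll_grid$ll))) {
    stop("fit failure: no grid point yielded a finite log-likelihood")
  }
  best <- which.max(ll_grid$ll)  # first maximum in sigma-major order
  best_params <- race_params(
    sigma = ll_grid$sigma[best], theta = ll_grid$theta[best],
    ndt_ms = ll_grid$ndt_ms[best], r = ll_grid$r[best],
    mu_congr = mu_congr, dt_ms = dt_ms, max_accum_ms = max_accum_ms
  )
  structure(
    list(best_params = best_params, ll_grid = ll_grid, n_sim = n_sim,
         seed = seed),
    class = "race_fit"
  )
}

#' @export
print.race_fit <- function(x, ...) {
  cat(sprintf("Race-model grid fit (%d points, %d sims/point)\n",
              nrow(x$ll_grid), x$n_sim))
  print(x$best_params)
  cat(sprintf("  max LL = %.3f\n", max(x$ll_grid$ll)))
  invisible(x)
}

#' @rdname race_fit_grid
#' @param x A `race_fit` object.
#' @param ... Unused.
#' @export
tidy.race_fit <- function(x, ...) {
  p <- x$best_params
  tibble::tibble(
    term = c("sigma", "theta", "ndt_ms", "r"),
    estimate = c(p$sigma, p$theta, p$ndt_ms, p$r)
  )
}

#' @rdname race_fit_grid
#' @export
glance.race_fit <- function(x, ...) {
  best <- which.max(x$ll_grid$ll)
  tibble::tibble(
    log_lik = x$ll_grid$ll[best],
    acc_model = x$ll_grid$acc_model[best],
    frac_not_crossed = x$ll_grid$frac_not_crossed[best],
    n_grid = nrow(x$ll_grid),
    n_sim = x$n_sim
  )
}

#' Defective response-time quantiles
#'
#' Summarises an RT distribution separately for correct and error responses:
#' within each response class, quantiles of the class RT sample (type-7
#' linear interpolation) are paired with the class's overall proportion of
#' trials, the usual "defective CDF" display of choice-RT data. A class with
#' fewer than `min_n` trials is omitted with a warning.
#'
#' @param rts Response times (ms).
#' @param accuracy 0/1 per trial.
#' @param probs Quantile probabilities.
#' @param min_n Minimum trials for a class to be summarised.
#'
#' @return A tibble of class `rt_quantiles` with columns `response`
#'   (`"correct"`/`"error"`), `prob`, `rt_q`, `class_proportion`.
#' @export
rt_quantiles <- function(rts, accuracy, probs = c(.1, .3, .5, .7, .9),
                         min_n = 5L) {
  keep <- !is.na(rts) & !is.na(accuracy)
  rts <- rts[keep]
  accuracy <- accuracy[keep]
  n_tot <- length(rts)
  out <- purrr::map(c(correct = 1L, error = 0L), function(a) {
    cls <- rts[accuracy == a]
    if (length(cls) < min_n) {
      warning(sprintf("response class with accuracy=%d has < %d trials; omitted",
                      a, min_n))
      return(NULL)
    }
    tibble::tibble(
      prob = probs,
      rt_q = unname(quantile(cls, probs, type = 7)),
      class_proportion = length(cls) / n_tot
    )
  })
  res <- dplyr::bind_rows(out, .id = "response")
  tibble::new_tibble(res, class = "rt_quantiles")
}

#' Plot defective RT quantiles
#'
#' Correct-response quantiles are drawn at their class proportion (upward),
#' error quantiles at theirs (conventionally read downward).
#'
#' @param object An `rt_quantiles` tibble.
#' @param ... Unused.
#' @export
autoplot.rt_quantiles <- function(object, ...) {
  df <- dplyr::mutate(
    object,
    y = ifelse(.data$response == "correct", .data$class_proportion,
               .data$class_proportion)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rt_q, y = .data$y,
                                   shape = .data$response)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(ggplot2::aes(group = interaction(.data$response,
                                                        .data$prob)),
                       linewidth = 0.2, colour = "grey60") +
    ggplot2::labs(x = "RT quantile (ms)", y = "Response proportion",
                  shape = NULL) +
    ggplot2::theme_minimal()
}
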