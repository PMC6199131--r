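#' Subject-wise correlation with group-level inference
#'
#' Computes a Pearson correlation per subject and tests the subject-level
#' coefficients against zero with a one-sample t-test — the standard
#' random-effects summary for trial-level associations (e.g. confidence
#' rating vs accuracy). Subjects with zero variance in either variable are
#' dropped with a warning.
#'
#' @param data A data frame with one row per trial.
#' @param x,y Unquoted column names of the two trial-level variables.
#' @param subject Unquoted subject identifier column.
#' @param min_trials Minimum usable trials per subject.
#'
#' @return A list of class `groupwise_cor`: `per_subject` tibble of
#'   coefficients, `mean_r`, `t`, `df`, `p`.
#' @export
groupwise_correlation <- function(data, x, y, subject, min_trials = 10L) {
  per_subject <- data |>
    dplyr::group_by({{ subject }}) |>
    dplyr::group_modify(function(df, key) {
      xs <- dplyr::pull(df, {{ x }})
      ys <- dplyr::pull(df, {{ y }})
      ok <- stats::complete.cases(xs, ys)
      if (sum(ok) < min_trials) return(tibble::tibble(r = NA_real_))
      if (sd(xs[ok]) == 0 || sd(ys[ok]) == 0) {
        warning("subject with zero-variance input dropped")
        return(tibble::tibble(r = NA_real_))
      }
      tibble::tibble(r = cor(xs[ok], ys[ok]))
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$r))
  if (nrow(per_subject) < 3L) stop("need at least 3 usable subjects")
  if (sd(per_subject$r) < 1e-10) {
    # identical coefficients: the t statistic diverges
    t_stat <- sign(mean(per_subject$r)) * Inf
    df <- nrow(per_subject) - 1L
    p <- if (mean(per_subject$r) == 0) 1 else 0
  } else {
    tt <- t.test(per_subject$r)
    t_stat <- unname(tt$statistic)
    df <- unname(tt$parameter)
    p <- tt$p.value
  }
  structure(
    list(per_subject = per_subject, mean_r = mean(per_subject$r),
         t = t_stat, df = df, p = p),
    class = "groupwise_cor"
  )
}

#' @export
print.groupwise_cor <- function(x, ...) {
  cat(sprintf("Subject-averaged R = %.3f; t(%d) = %.2f, p = %.3g (n = %d subjects)\n",
              x$mean_r, x$df, x$t, x$p, nrow(x$per_subject)))
  invisible(x)
}

#' @rdname groupwise_correlation
#' @param x A `groupwise_cor` object.
#' @param ... Unused.
#' @export
tidy.groupwise_cor <- function(x, ...) {
  tibble::tibble(mean_r = x$mean_r, t = x$t, df = x$df, p = x$p,
                 n_subjects = nrow(x$per_subject))
}

#' Serial autocorrelation of a trial series
#'
#' Regresses the value on the current trial onto the values of the
#' immediately preceding `n_lags` trials (plus an intercept) and returns the
#' coefficient of determination — a check for slow, multi-trial fluctuations
#' (e.g. sustained attention) in ratings or component amplitudes. Lags never
#' cross run boundaries: the first `n_lags` trials of each run contribute no
#' observation.
#'
#' @param values Per-trial values, in trial order.
#' @param run_id Optional run identifier per trial.
#' @param n_lags Number of preceding trials used as predictors.
#' @return The regression R-squared, or NA (with a warning) for a constant
#'   series.
#' @export
serial_autocorrelation <- function(values, run_id = NULL, n_lags = 5L) {
  n <- length(values)
  if (n < n_lags + 10L) stop("need at least n_lags + 10 trials")
  if (is.null(run_id)) run_id <- rep(1L, n)
  if (sd(values, na.rm = TRUE) == 0) {
    warning("constant series: R^2 undefined")
    return(NA_real_)
  }
  rows <- which(seq_len(n) > n_lags)
  rows <- rows[vapply(rows, function(i) {
    all(run_id[(i - n_lags):i] == run_id[i])
  }, logical(1))]
  X <- vapply(seq_len(n_lags), function(l) values[rows - l],
              numeric(length(rows)))
  fit <- lm(values[rows] ~ X)
  summary(fit)$r.squared
}

#' Choice repetition bias as a function of neural confidence
#'
#' Tests whether the confidence component amplitude on trial *t* modulates
#' the probability of repeating the same choice on trial *t+1*
#' (`P_REPEAT`), separately for consecutive-trial pairs whose stimulus
#' direction repeats (`same`) vs reverses (`opposite`). Per subject, trials
#' are split into rank-based tertiles of `y_conf` (ties to the lower bin);
#' to decouple the effect from accuracy, correct and error trials are
#' equalised within each tertile by random removal of the excess class,
#' averaging `P_REPEAT` over `n_perm` random removals. Pairs never span run
#' boundaries. Group inference is a one-way repeated-measures ANOVA over
#' tertiles (per relation) with Bonferroni-corrected paired t post-hocs.
#'
#' @param data A data frame with columns `subject`, `run_id`, `trial_index`,
#'   `direction`, `choice`, `accuracy`, `y_conf` (one row per valid trial).
#' @param n_perm Number of random equalisation draws.
#' @param min_pairs Minimum pairs per cell; subjects below it are excluded
#'   from that cell with a warning.
#' @param seed Integer seed.
#'
#' @return A list of class `repetition_bias`: `cells` (subject x tertile x
#'   relation `p_repeat`), `anova` (per relation: F, df, p), `posthoc`
#'   (Bonferroni-corrected paired t-tests between tertiles, per relation).
#' @export
repetition_bias <- function(data, n_perm = 500L, min_pairs = 5L,
                            seed = NULL) {
  need <- c("subject", "run_id", "trial_index", "direction", "choice",
            "accuracy", "y_conf")
  stopifnot(all(need %in% names(data)))
  with_seed(seed, {
    cells <- data |>
      dplyr::group_by(.data$subject) |>
      dplyr::group_modify(function(df, key) {
        df <- dplyr::arrange(df, .data$run_id, .data$trial_index)
        tert <- tertile_bins(df$y_conf)
        # consecutive pairs within runs
        i <- seq_len(nrow(df) - 1L)
        ok <- df$run_id[i] == df$run_id[i + 1L] &
          df$trial_index[i + 1L] == df$trial_index[i] + 1L
        i <- i[ok]
        rel <- ifelse(df$direction[i + 1L] == df$direction[i],
                      "same", "opposite")
        rep_choice <- df$choice[i + 1L] == df$choice[i]
        acc <- df$accuracy[i]
        bin <- tert[i]
        grid <- tidyr::expand_grid(tertile = 1:3,
                                   relation = c("same", "opposite"))
        purrr::pmap_dfr(grid, function(tertile, relation) {
          in_bin <- which(bin == tertile)
          vals <- vapply(seq_len(n_perm), function(p) {
            keep <- equalise_classes(acc[in_bin])
            sel <- in_bin[keep][rel[in_bin[keep]] == relation]
            if (length(sel) < min_pairs) return(NA_real_)
            mean(rep_choice[sel])
          }, numeric(1))
          if (all(is.na(vals))) {
            warning("cell with fewer than `min_pairs` pairs excluded")
            return(tibble::tibble(tertile = tertile, relation = relation,
                                  p_repeat = NA_real_))
          }
          tibble::tibble(tertile = tertile, relation = relation,
                         p_repeat = mean(vals, na.rm = TRUE))
        })
      }) |>
      dplyr::ungroup()
    anova_tbl <- cells |>
      dplyr::filter(!is.na(.data$p_repeat)) |>
      dplyr::group_by(.data$relation) |>
      dplyr::group_modify(function(df, key) rm_anova_1way(df)) |>
      dplyr::ungroup()
    posthoc <- cells |>
      dplyr::filter(!is.na(.data$p_repeat)) |>
      dplyr::group_by(.data$relation) |>
      dplyr::group_modify(function(df, key) posthoc_paired(df)) |>
      dplyr::ungroup()
    structure(list(cells = cells, anova = anova_tbl, posthoc = posthoc),
              class = "repetition_bias")
  })
}

# Rank-based thirds; tied ranks resolve to the lower bin via first-occurrence
# ranking of the sorted order.
tertile_bins <- function(x) {
  n <- length(x)
  rk <- rank(x, ties.method = "first")
  cut_points <- c(floor(n / 3), floor(2 * n / 3))
  1L + (rk > cut_points[1]) + (rk > cut_points[2])
}

# Randomly drop the excess of whichever accuracy class is larger, so correct
# and error trials are equally represented. Returns a logical keep mask.
equalise_classes <- function(acc) {
  keep <- rep(TRUE, length(acc))
  n1 <- sum(acc == 1L); n0 <- sum(acc == 0L)
  if (n1 == n0) return(keep)
  excess_class <- if (n1 > n0) 1L else 0L
  idx <- which(acc == excess_class)
  drop <- sample(idx, abs(n1 - n0))
  keep[drop] <- FALSE
  keep
}

# One-way repeated-measures ANOVA on a subject x tertile table (complete
# cases only).
rm_anova_1way <- function(df) {
  wide <- tidyr::pivot_wider(df, id_cols = "subject",
                             names_from = "tertile",
                             values_from = "p_repeat")
  wide <- wide[stats::complete.cases(wide), ]
  long <- tidyr::pivot_longer(wide, -"subject", names_to = "tertile",
                              values_to = "p_repeat")
  long$tertile <- factor(long$tertile)
  long$subject <- factor(long$subject)
  fit <- aov(p_repeat ~ tertile + Error(subject / tertile), data = long)
  s <- summary(fit)[["Error: subject:tertile"]][[1]]
  tibble::tibble(F = s[["F value"]][1], df1 = s[["Df"]][1],
                 df2 = s[["Df"]][2], p = s[["Pr(>F)"]][1],
                 n_subjects = nrow(wide))
}

posthoc_paired <- function(df) {
  wide <- tidyr::pivot_wider(df, id_cols = "subject",
                             names_from = "tertile",
                             values_from = "p_repeat")
  wide <- wide[stats::complete.cases(wide), ]
  pairs <- list(c("1", "2"), c("1", "3"), c("2", "3"))
  purrr::map_dfr(pairs, function(pr) {
    tt <- t.test(wide[[pr[1]]], wide[[pr[2]]], paired = TRUE)
    tibble::tibble(comparison = paste(pr, collapse = " vs "),
                   t = unname(tt$statistic),
                   p_bonferroni = min(1, tt$p.value * 3))
  })
}

#' Percentage bend correlation
#'
#' Robust correlation (Wilcox, 1994) with bend constant `beta`: deviations
#' from a robust centre are winsorised through `psi(u) = max(-1, min(1, u))`
#' with scale set by the `floor((1 - beta) n + 0.5)`-th ordered absolute
#' deviation from the median, making the coefficient resistant to marginal
#' outliers. The test statistic `T = r sqrt((n - 2) / (1 - r^2))` is
#' referred to a t distribution with `n - 2` df.
#'
#' @param x,y Numeric vectors.
#' @param beta Bend constant in `[0, 0.5)`.
#' @return A list of class `pb_cor`: `r`, `t`, `p`, `n`.
#' @export
percentage_bend_correlation <- function(x, y, beta = 0.2) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5L) stop("need at least 5 complete pairs")
  bend <- function(v) {
    m <- floor((1 - beta) * n + 0.5)
    omhat <- sort(abs(v - median(v)))[m]
    if (omhat <= 0) stop("zero scale: input is (nearly) constant")
    psi <- (v - median(v)) / omhat
    i1 <- sum(psi < -1); i2 <- sum(psi > 1)
    sv <- ifelse(abs(psi) <= 1, v, 0)
    loc <- (sum(sv) + omhat * (i2 - i1)) / (n - i1 - i2)
    pmax(-1, pmin(1, (v - loc) / omhat))
  }
  a <- bend(x); b <- bend(y)
  r <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(abs(t_stat), n - 2, lower.tail = FALSE)
  structure(list(r = r, t = t_stat, p = p, n = n), class = "pb_cor")
}

#' @export
print.pb_cor <- function(x, ...) {
  cat(sprintf("Percentage bend correlation: R = %.3f, t(%d) = %.2f, p = %.3g\n",
              x$r, x$n - 2, x$t, x$p))
  invisible(x)
}

#' Correct-minus-error difference of a trial-level quantity
#'
#' The mean over correct trials minus the mean over error trials — the
#' per-subject contrast used to compare confidence measures (ratings, model
#' balance of evidence, component amplitudes) on a common footing across
#' subjects.
#'
#' @param values Per-trial values.
#' @param accuracy 0/1 per trial.
#' @return The difference, or NA (with a warning) when a class is missing.
#' @export
correct_error_diff <- function(values, accuracy) {
  ok <- stats::complete.cases(values, accuracy)
  values <- values[ok]; accuracy <- accuracy[ok]
  if (!any(accuracy == 1L) || !any(accuracy == 0L)) {
    warning("one response class is missing; difference undefined")
    return(NA_real_)
  }
  mean(values[accuracy == 1L]) - mean(values[accuracy == 0L])
}

#' Three-variable mediation path model with bootstrap inference
#'
#' Fits the OLS path model `M = a X`, `Y = c' X + b M` (with intercepts),
#' where the indirect effect of `X` on `Y` through the mediator `M` is
#' `a b` and the total effect decomposes exactly as `c = c' + a b`.
#' Percentile bootstrap over rows (subjects) gives two-sided p-values and
#' confidence intervals for every path and for the indirect effect.
#'
#' @param data A data frame with one row per subject.
#' @param x,m,y Unquoted column names of predictor, mediator and outcome.
#' @param n_boot Bootstrap replicates.
#' @param conf_level Confidence level for percentile intervals.
#' @param seed Integer seed.
#'
#' @return An object of class `mediation_result` with `paths` (tibble of
#'   `term`, `estimate`, `ci_low`, `ci_high`, `p`) and scalars `a`, `b`,
#'   `c_prime`, `c_total`, `indirect`.
#' @export
mediation <- function(data, x, m, y, n_boot = 5000L, conf_level = 0.95,
                      seed = NULL) {
  X <- dplyr::pull(data, {{ x }})
  M <- dplyr::pull(data, {{ m }})
  Y <- dplyr::pull(data, {{ y }})
  ok <- stats::complete.cases(X, M, Y)
  if (!all(ok)) stop("missing values are not allowed")
  n <- length(X)
  if (abs(cor(X, M)) > 0.999) {
    stop("unstable model: X and M are (nearly) collinear")
  }
  paths_of <- function(xi, mi, yi) {
    a <- cov(xi, mi) / var(xi)
    fit <- stats::lm.fit(cbind(1, xi, mi), yi)
    b <- unname(fit$coefficients[3])
    c_prime <- unname(fit$coefficients[2])
    c_total <- cov(xi, yi) / var(xi)
    c(a = a, b = b, c_prime = c_prime, c_total = c_total, indirect = a * b)
  }
  est <- paths_of(X, M, Y)
  boot <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
    apply(idx, 2, function(i) paths_of(X[i], M[i], Y[i]))
  })
  alpha <- 1 - conf_level
  ci <- apply(boot, 1, quantile, probs = c(alpha / 2, 1 - alpha / 2))
  pvals <- apply(boot, 1, function(v) {
    min(1, 2 * min(mean(v <= 0), mean(v >= 0)))
  })
  paths <- tibble::tibble(
    term = c("a", "b", "c_prime", "c_total", "indirect"),
    estimate = unname(est),
    ci_low = ci[1, ], ci_high = ci[2, ], p = unname(pvals)
  )
  structure(
    list(paths = paths, a = unname(est["a"]), b = unname(est["b"]),
         c_prime = unname(est["c_prime"]), c_total = unname(est["c_total"]),
         indirect = unname(est["indirect"]), n = n, n_boot = n_boot),
    class = "mediation_result"
  )
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation (n = %d, %d bootstrap samples)\n", x$n, x$n_boot))
  print(x$paths)
  invisible(x)
}

#' Tidy or summarise a mediation fit
#'
#' @param x A `mediation_result` object.
#' @param ... Unused.
#' @return `tidy()` returns the path table; `glance()` a one-row summary.
#' @export
tidy.mediation_result <- function(x, ...) x$paths

#' @rdname tidy.mediation_result
#' @export
glance.mediation_result <- function(x, ...) {
  tibble::tibble(indirect = x$indirect, c_total = x$c_total,
                 c_prime = x$c_prime, n = x$n, n_boot = x$n_boot)
}
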