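#' Percentage recovery summary
#'
#' Recoveries are `100 * predicted / nominal`; the summary reports their
#' count, mean, sample standard deviation (n - 1 divisor) and relative
#' standard deviation `100 * sd / mean`. All statistics are computed at full
#' precision; round only for display.
#'
#' @param predicted Predicted (found) amounts, µg/mL.
#' @param nominal Nominal (taken/added) amounts, µg/mL; strictly positive,
#'   same length as `predicted`.
#' @return A one-row tibble of `n`, `mean_recovery`, `sd_recovery`,
#'   `rsd_recovery`, with the per-sample recoveries attached as attribute
#'   `"recoveries"`.
#' @export
#' @examples
#' recovery_summary(c(4.02, 3.99, 4.05), c(4, 4, 4))
recovery_summary <- function(predicted, nominal) {
  if (length(predicted) != length(nominal)) {
    abort("`predicted` and `nominal` must have the same length.",
          class = "specmix_invalid_input")
  }
  if (any(nominal <= 0)) {
    abort("`nominal` amounts must be strictly positive.",
          class = "specmix_invalid_input")
  }
  rec <- 100 * predicted / nominal
  n <- length(rec)
  m <- mean(rec)
  s <- if (n >= 2) sd(rec) else NA_real_
  out <- tibble(
    n = n,
    mean_recovery = m,
    sd_recovery = s,
    rsd_recovery = if (m > 0) 100 * s / m else NA_real_
  )
  attr(out, "recoveries") <- rec
  out
}

#' Limits of detection and quantitation
#'
#' ICH-style limits from the calibration relationship:
#' `LOD = 3.3 * SD / |slope|`, `LOQ = 10 * SD / |slope|`, where `SD` is the
#' residual standard deviation of the predicted-versus-nominal regression
#' over the linearity range and `slope` its slope.
#'
#' @param sd_resid Residual standard deviation of the calibration line.
#' @param slope Slope of the calibration line; must be non-zero.
#' @return A one-row tibble of `lod`, `loq` (µg/mL).
#' @export
#' @examples
#' lod_loq(0.1, 1)
lod_loq <- function(sd_resid, slope) {
  if (!is.finite(slope) || slope == 0) {
    abort("`slope` must be non-zero.", class = "specmix_invalid_input")
  }
  if (sd_resid < 0) {
    abort("`sd_resid` must be non-negative.", class = "specmix_invalid_input")
  }
  tibble(lod = 3.3 * sd_resid / abs(slope),
         loq = 10 * sd_resid / abs(slope))
}

#' Predicted-versus-nominal linearity merits
#'
#' Ordinary least-squares line of predicted on nominal concentration over
#' the linearity range; its residual standard deviation (s_{y/x}, divisor
#' n - 2) and slope feed [lod_loq()].
#'
#' @inheritParams recovery_summary
#' @return A one-row tibble of `slope`, `intercept`, `sd_resid`, `r_squared`.
#' @export
linearity_merits <- function(predicted, nominal) {
  if (length(predicted) != length(nominal) || length(predicted) < 3) {
    abort("Need at least 3 matched predicted/nominal pairs.",
          class = "specmix_invalid_input")
  }
  fit <- lm(predicted ~ nominal)
  tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    sd_resid = summary(fit)$sigma,
    r_squared = summary(fit)$r.squared
  )
}

merit_design <- function(levels, reps, n_components) {
  conc <- matrix(rep(rep(levels, each = reps), n_components),
                 ncol = n_components)
  d <- as.data.frame(conc)
  names(d) <- paste0("conc_", seq_len(n_components))
  dplyr::bind_cols(tibble(sample_id = seq_len(nrow(d))), as_tibble(d))
}

#' Accuracy protocol: triplicate assays at three levels
#'
#' Simulates `reps` replicate mixtures at each concentration level (default
#' 4, 8 and 16 µg/mL of each drug, inside the 1-17 µg/mL linearity range),
#' predicts them with the fitted model, and pools the recoveries per
#' component.
#'
#' @param model A fitted `calib_model`.
#' @param components Component list used to simulate the assay spectra.
#' @param noise A [noise_model()] (seeded if stochastic).
#' @param levels Assay levels, µg/mL.
#' @param reps Replicates per level.
#' @param wavelengths Wavelength grid; defaults to the model's.
#' @return A list with `results` (tibble of `component`, `level`, `rep`,
#'   `nominal`, `predicted`, `recovery`) and `summary` (per-component
#'   [recovery_summary()] rows).
#' @export
accuracy_protocol <- function(model, components, noise,
                              levels = c(4, 8, 16), reps = 3,
                              wavelengths = model$wavelengths %||% default_grid()) {
  if (any(levels < 1 | levels > 17)) {
    warn("Some assay levels lie outside the 1-17 µg/mL linearity range.")
  }
  d <- merit_design(levels, reps, length(components))
  set <- simulate_mixtures(d, components, noise, wavelengths)
  pred <- predict_matrix(model, set)
  nominal <- conc_matrix(d)
  comp_names <- model$components
  results <- purrr::map_dfr(seq_along(comp_names), function(j) {
    nom_j <- nominal[, j]
    tibble(
      component = comp_names[j],
      level = rep(levels, each = reps),
      rep = rep(seq_len(reps), times = length(levels)),
      nominal = nom_j,
      predicted = pred[, j],
      recovery = 100 * pred[, j] / nom_j
    )
  })
  summary <- results |>
    dplyr::group_by(.data$component) |>
    dplyr::group_modify(~ recovery_summary(.x$predicted, .x$nominal)) |>
    dplyr::ungroup()
  list(results = results, summary = summary)
}

#' Precision protocol: repeatability and intermediate precision
#'
#' Runs the accuracy layout within one day (`reps` replicates of each level,
#' one noise draw per day) and over `days` successive days with day-specific
#' noise draws and an optional day-specific baseline shift
#' (`between_day_sd` of the noise model). Repeatability RSD is computed from
#' day 1's recoveries; intermediate-precision RSD pools all days.
#'
#' @inheritParams accuracy_protocol
#' @param days Number of days (1 or 3 in the standard protocol).
#' @param day_seeds Integer seed per day; defaults to `noise$seed + 0:(days-1)`.
#' @return A list with `results` (per component/day/level/rep) and `summary`
#'   (tibble of `component`, `repeatability_rsd`, `intermediate_rsd`).
#' @export
precision_protocol <- function(model, components, noise,
                               levels = c(4, 8, 16), reps = 3, days = 3,
                               day_seeds = NULL,
                               wavelengths = model$wavelengths %||% default_grid()) {
  if (is.null(day_seeds)) {
    if (is.null(noise$seed)) {
      abort("Provide `day_seeds` or a seeded noise model.",
            class = "specmix_missing_seed")
    }
    day_seeds <- noise$seed + seq_len(days) - 1L
  }
  if (length(day_seeds) != days) {
    abort("One seed per day is required.", class = "specmix_missing_seed")
  }
  results <- purrr::map_dfr(seq_len(days), function(day) {
    day_offset <- if (noise$between_day_sd > 0) {
      withr::with_seed(day_seeds[day] + 10000L,
                       rnorm(1, sd = noise$between_day_sd))
    } else 0
    day_noise <- noise_model(
      noise_sd = noise$noise_sd,
      baseline_offset = noise$baseline_offset + day_offset,
      baseline_slope = noise$baseline_slope,
      multiplicative_sd = noise$multiplicative_sd,
      seed = day_seeds[day]
    )
    acc <- accuracy_protocol(model, components, day_noise,
                             levels = levels, reps = reps,
                             wavelengths = wavelengths)
    dplyr::mutate(acc$results, day = day, .before = 1)
  })
  summary <- results |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(
      repeatability_rsd = {
        r <- .data$recovery[.data$day == 1]
        if (sd(r) == 0) 0 else 100 * sd(r) / mean(r)
      },
      intermediate_rsd = {
        r <- .data$recovery
        if (sd(r) == 0) 0 else 100 * sd(r) / mean(r)
      }
    )
  list(results = results, summary = summary)
}

#' Standard-addition selectivity analysis
#'
#' Known amounts of pure drug are spiked into a formulation matrix; the
#' recovery of each spike is `100 * pure_found / pure_added`. The summary
#' mean and RSD are computed from the unrounded per-row recoveries.
#'
#' @param data A data frame with columns `pure_added` and `pure_found`
#'   (µg/mL); optional `base_taken`, `base_found` columns are carried
#'   through.
#' @return A list with `rows` (input plus `percent_recovery`) and `summary`
#'   (one-row [recovery_summary()] tibble).
#' @export
#' @examples
#' standard_addition(data.frame(pure_added = c(3, 5, 7),
#'                              pure_found = c(3.02, 4.98, 7.09)))
standard_addition <- function(data) {
  data <- as_tibble(data)
  if (!all(c("pure_added", "pure_found") %in% names(data))) {
    abort("`data` needs `pure_added` and `pure_found` columns.",
          class = "specmix_invalid_input")
  }
  if (any(data$pure_added <= 0)) {
    abort("`pure_added` must be strictly positive.",
          class = "specmix_invalid_input")
  }
  rows <- dplyr::mutate(data,
                        percent_recovery = 100 * .data$pure_found / .data$pure_added)
  list(rows = rows,
       summary = recovery_summary(data$pure_found, data$pure_added))
}

#' Two-sample t and F comparison against a reference method
#'
#' Pooled-variance two-sample t test (df = n1 + n2 - 2) on the mean
#' recoveries and a variance-ratio F test (larger variance over smaller,
#' df ordered accordingly), both judged against two-sided t and upper-tail F
#' critical values at the stated significance level. A method pair is
#' "not significant" when both statistics fall below their critical values.
#'
#' @param sample1,sample2 Numeric vectors of percentage recoveries
#'   (length >= 2 each).
#' @param alpha Significance level; default 0.05 (95% confidence).
#' @return A one-row tibble with sample sizes, means, variances, `t_statistic`,
#'   `t_critical`, `f_statistic`, `f_critical`, the degrees of freedom and
#'   logical `t_significant`, `f_significant` verdicts.
#' @export
#' @examples
#' compare_methods(c(99.6, 100.4, 99.8, 100.1, 100.2),
#'                 c(100.0, 100.3, 99.7, 99.9, 100.4))
compare_methods <- function(sample1, sample2, alpha = 0.05) {
  n1 <- length(sample1); n2 <- length(sample2)
  if (n1 < 2 || n2 < 2) {
    abort("Both samples need at least 2 observations.",
          class = "specmix_invalid_input")
  }
  v1 <- var(sample1); v2 <- var(sample2)
  if (v1 == 0 && v2 == 0) {
    abort("Both samples have zero variance; t is undefined.",
          class = "specmix_invalid_input")
  }
  df_t <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df_t
  t_stat <- (mean(sample1) - mean(sample2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  if (v1 >= v2) {
    f_stat <- v1 / v2; df_f <- c(n1 - 1, n2 - 1)
  } else {
    f_stat <- v2 / v1; df_f <- c(n2 - 1, n1 - 1)
  }
  t_crit <- qt(1 - alpha / 2, df_t)
  f_crit <- qf(1 - alpha, df_f[1], df_f[2])
  tibble(
    n1 = n1, n2 = n2,
    mean1 = mean(sample1), mean2 = mean(sample2),
    var1 = v1, var2 = v2,
    t_statistic = t_stat, t_df = df_t, t_critical = t_crit,
    t_significant = abs(t_stat) > t_crit,
    f_statistic = f_stat, f_df1 = df_f[1], f_df2 = df_f[2],
    f_critical = f_crit, f_significant = f_stat > f_crit,
    alpha = alpha
  )
}
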