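#' Leave-one-out cross-validation over latent-variable counts
#'
#' For every candidate number of latent variables `a = 1..max_latent` and
#' every calibration sample, the model is refitted without that sample and
#' the sample is predicted; RMSECV per component is
#' `sqrt(sum(e_i^2) / n)`. A 0-latent baseline (predicting the training-fold
#' mean concentration) is reported alongside. CLS has no latent-variable
#' axis and is rejected; its single LOO error is available through
#' [loo_rmse_cls()].
#'
#' @param conc Calibration concentrations (design tibble or matrix).
#' @param spectra Calibration spectra ([spectra_set()] or matrix).
#' @param method `"pcr"` or `"pls"`.
#' @param max_latent Largest candidate; at most `min(n - 2, p)` so every
#'   training fold supports the fit.
#' @return A `cv_result` object: `$table` (tibble of `n_latent`, `component`,
#'   `rmsecv`), `$pooled` (tibble of `n_latent`, `rmsecv` pooled over
#'   components and samples), `$method`, `$n_cal`.
#' @export
#' @examples
#' d <- dplyr::filter(split_design(generate_design()), role == "calibration")
#' s <- simulate_mixtures(d, default_components(), noise_model(seed = 7))
#' loo_rmsecv(d, s, method = "pls", max_latent = 4)
loo_rmsecv <- function(conc, spectra, method = c("pcr", "pls"), max_latent) {
  if (identical(tolower(method[1]), "cls")) {
    abort("CLS has no latent-variable axis; use loo_rmse_cls() for its LOO error.",
          class = "specmix_invalid_method")
  }
  method <- match.arg(method)
  C <- as_conc_matrix(conc)
  A <- as_abs_matrix(spectra)
  n <- nrow(A); p <- ncol(A)
  if (max_latent > min(n - 2, p) || max_latent < 1) {
    abort(sprintf("`max_latent` must be in [1, min(n - 2, p)] = [1, %d].",
                  min(n - 2, p)),
          class = "specmix_invalid_latent")
  }
  comp_names <- colnames(C) %||% paste0("comp_", seq_len(ncol(C)))
  colnames(C) <- comp_names
  fitter <- if (method == "pcr") fit_pcr else fit_pls
  m <- ncol(C)
  # errors[i, j, a+1]: left-out residual of sample i, component j, a LVs
  errors <- array(NA_real_, c(n, m, max_latent + 1L))
  for (i in seq_len(n)) {
    Ctr <- C[-i, , drop = FALSE]
    Atr <- A[-i, , drop = FALSE]
    errors[i, , 1L] <- colMeans(Ctr) - C[i, ]
    for (a in seq_len(max_latent)) {
      fit <- fitter(Ctr, Atr, n_latent = a)
      pred <- sweep(A[i, , drop = FALSE], 2, fit$x_center) %*% fit$B +
        rep(fit$y_center, each = 1)
      errors[i, , a + 1L] <- pred - C[i, ]
    }
  }
  tab <- tidyr::expand_grid(n_latent = 0:max_latent, component = comp_names)
  tab$rmsecv <- purrr::pmap_dbl(tab, function(n_latent, component) {
    j <- match(component, comp_names)
    sqrt(mean(errors[, j, n_latent + 1L]^2))
  })
  pooled <- tibble(
    n_latent = 0:max_latent,
    rmsecv = vapply(0:max_latent,
                    function(a) sqrt(mean(errors[, , a + 1L]^2)),
                    numeric(1))
  )
  structure(list(table = tab, pooled = pooled, method = method, n_cal = n),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s leave-one-out, n = %d\n",
              toupper(x$method), x$n_cal))
  print(x$pooled)
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$table

#' @export
glance.cv_result <- function(x, ...) {
  tibble(method = x$method, n_cal = x$n_cal,
         best_n_latent = select_n_latent(x, rule = "global_min"),
         min_rmsecv = min(x$pooled$rmsecv[x$pooled$n_latent > 0]))
}

#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$n_latent, y = .data$rmsecv,
                               colour = .data$component)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(object$table$n_latent)) +
    ggplot2::labs(x = "Number of latent variables", y = "RMSECV (µg/mL)",
                  title = sprintf("%s leave-one-out RMSECV", toupper(object$method))) +
    ggplot2::theme_minimal()
}

#' Select the number of latent variables from an RMSECV curve
#'
#' `"global_min"` picks the smallest candidate attaining the minimum pooled
#' RMSECV; `"one_se_like_fratio"` (default) is a Haaland-Thomas-style
#' parsimony rule: the smallest candidate whose pooled RMSECV is within a
#' factor `fratio` (default 1.25) of the minimum. The 0-latent baseline is
#' never selected.
#'
#' @param cv A `cv_result` from [loo_rmsecv()].
#' @param rule `"one_se_like_fratio"` or `"global_min"`.
#' @param fratio Tolerance factor of the parsimony rule.
#' @return The chosen latent-variable count (integer).
#' @export
select_n_latent <- function(cv, rule = c("one_se_like_fratio", "global_min"),
                            fratio = 1.25) {
  rule <- match.arg(rule)
  pooled <- if (inherits(cv, "cv_result")) cv$pooled else as_tibble(cv)
  pooled <- pooled[pooled$n_latent >= 1, , drop = FALSE]
  if (nrow(pooled) == 0) {
    abort("Empty cross-validation result.", class = "specmix_invalid_input")
  }
  best <- min(pooled$rmsecv)
  if (rule == "global_min") {
    as.integer(pooled$n_latent[which(pooled$rmsecv == best)[1]])
  } else {
    as.integer(pooled$n_latent[which(pooled$rmsecv <= fratio * best)[1]])
  }
}

#' Leave-one-out prediction error of CLS
#'
#' CLS has no complexity axis, but its predictive error can still be
#' estimated by leave-one-out: refit without each sample, predict it, and
#' pool the residuals.
#'
#' @inheritParams loo_rmsecv
#' @param intercept Passed to [fit_cls()].
#' @return A tibble of `component`, `rmsecv`.
#' @export
loo_rmse_cls <- function(conc, spectra, intercept = FALSE) {
  C <- as_conc_matrix(conc)
  A <- as_abs_matrix(spectra)
  comp_names <- colnames(C) %||% paste0("comp_", seq_len(ncol(C)))
  n <- nrow(A)
  errs <- matrix(NA_real_, n, ncol(C))
  for (i in seq_len(n)) {
    fit <- fit_cls(C[-i, , drop = FALSE], A[-i, , drop = FALSE],
                   intercept = intercept)
    errs[i, ] <- A[i, , drop = FALSE] %*% fit$B - C[i, ]
  }
  tibble(component = comp_names,
         rmsecv = sqrt(colMeans(errs^2)))
}

#' Calibration / prediction error summary (RMSEC, RMSEP)
#'
#' Per-component root-mean-square residual `sqrt(sum((c_hat - c)^2) / n)`
#' on the stated set; divisor `n`, the common chemometric convention.
#'
#' @param model A fitted `calib_model`.
#' @param conc True concentrations of the set (design tibble or matrix).
#' @param spectra Spectra of the set.
#' @param set `"calibration"` (RMSEC) or `"prediction"` (RMSEP) — a label
#'   recorded in the output.
#' @return A tibble of `component`, `rmse`, `set`.
#' @export
error_summary <- function(model, conc, spectra,
                          set = c("calibration", "prediction")) {
  set <- match.arg(set)
  C <- as_conc_matrix(conc)
  if (nrow(C) == 0) {
    abort("Empty set.", class = "specmix_invalid_input")
  }
  comp_names <- colnames(C) %||% model$components
  Chat <- predict_matrix(model, spectra)
  res <- Chat - C
  tibble(component = comp_names,
         rmse = sqrt(colMeans(res^2)),
         set = set)
}
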