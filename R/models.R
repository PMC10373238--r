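as_abs_matrix <- function(x) {
  if (inherits(x, "spectra_set")) x$absorbance else as.matrix(x)
}

as_conc_matrix <- function(x) {
  if (is.data.frame(x)) conc_matrix(x) else as.matrix(x)
}

# fix sign so the largest-magnitude element of v is positive; returns +-1
sign_fix <- function(v) {
  s <- sign(v[which.max(abs(v))])
  if (s == 0) 1 else s
}

new_calib_model <- function(method, components, wavelengths, x_center,
                            y_center, B, n_latent, internals, n_cal) {
  structure(
    list(method = method, components = components, wavelengths = wavelengths,
         x_center = x_center, y_center = y_center, B = B,
         n_latent = n_latent, internals = internals, n_cal = n_cal),
    class = "calib_model"
  )
}

#' Classical least squares (CLS) calibration
#'
#' Direct calibration of the Beer-Lambert model `A = C K`: the pure-component
#' absorptivity matrix is estimated by ordinary least squares,
#' `K = (C'C)^-1 C'A`, and prediction for a spectrum `a` is the least-norm
#' solve `c = a K' (K K')^-1`. CLS requires every absorbing species to be
#' represented in the calibration concentrations; an optional intercept row
#' models a constant background.
#'
#' @param conc Calibration concentrations: design tibble with `conc_*`
#'   columns or an n-by-m matrix (µg/mL).
#' @param spectra Calibration spectra: [spectra_set()] or n-by-p matrix (AU).
#' @param intercept Add a constant background row to `K`? Default `FALSE`.
#' @return A `calib_model` object (method `"cls"`); `$internals$K` holds the
#'   estimated absorptivity spectra (components by wavelengths).
#' @export
#' @examples
#' fit_cls(matrix(1:2), matrix(c(0.1, 0.2, 0.2, 0.4), 2))
fit_cls <- function(conc, spectra, intercept = FALSE) {
  C <- as_conc_matrix(conc)
  A <- as_abs_matrix(spectra)
  wl <- if (inherits(spectra, "spectra_set")) spectra$wavelengths else NULL
  comp_names <- colnames(C) %||% paste0("comp_", seq_len(ncol(C)))
  if (nrow(C) != nrow(A)) {
    abort("`conc` and `spectra` must have the same number of samples.",
          class = "specmix_invalid_input")
  }
  if (nrow(C) < ncol(C)) {
    abort("CLS needs at least as many samples as components.",
          class = "specmix_invalid_input")
  }
  Caug <- if (intercept) cbind(C, background = 1) else C
  qrC <- qr(Caug)
  if (qrC$rank < ncol(Caug)) {
    dropped <- colnames(Caug)[qrC$pivot[seq(qrC$rank + 1, ncol(Caug))]] %||%
      "unknown"
    abort(sprintf(
      "Singular calibration design: collinear concentration column(s): %s.",
      paste(dropped, collapse = ", ")),
      class = "specmix_singular_design")
  }
  K <- solve(crossprod(Caug), crossprod(Caug, A))
  rownames(K) <- colnames(Caug) %||% c(comp_names, if (intercept) "background")
  Bfull <- t(K) %*% solve(tcrossprod(K))
  B <- Bfull[, seq_len(ncol(C)), drop = FALSE]
  colnames(B) <- comp_names
  new_calib_model("cls", comp_names, wl,
                  x_center = rep(0, ncol(A)),
                  y_center = setNames(rep(0, ncol(C)), comp_names),
                  B = B, n_latent = NULL,
                  internals = list(K = K, intercept = intercept),
                  n_cal = nrow(A))
}

#' Principal component regression (PCR) calibration
#'
#' Column-centres both blocks, takes the leading `n_latent` singular
#' directions of the centred absorbance matrix, regresses the centred
#' concentrations on the scores, and folds the result back into a single
#' coefficient matrix. Singular-vector signs are fixed so the
#' largest-magnitude loading element is positive, making fits deterministic.
#'
#' @inheritParams fit_cls
#' @param n_latent Number of principal components (latent variables),
#'   `1 <= n_latent <= min(n - 1, p)` and at most the numerical rank of the
#'   centred absorbance matrix (relative singular-value threshold 1e-10).
#' @return A `calib_model` (method `"pcr"`).
#' @export
fit_pcr <- function(conc, spectra, n_latent) {
  C <- as_conc_matrix(conc)
  A <- as_abs_matrix(spectra)
  wl <- if (inherits(spectra, "spectra_set")) spectra$wavelengths else NULL
  comp_names <- colnames(C) %||% paste0("comp_", seq_len(ncol(C)))
  n <- nrow(A); p <- ncol(A)
  check_n_latent(n_latent, n, p)
  x_center <- colMeans(A)
  y_center <- setNames(colMeans(C), comp_names)
  Ac <- sweep(A, 2, x_center)
  Cc <- sweep(C, 2, y_center)
  sv <- svd(Ac)
  rank <- sum(sv$d > 1e-10 * sv$d[1])
  if (n_latent > rank) {
    abort(sprintf(
      "n_latent = %d exceeds the numerical rank (%d) of the centred spectra.",
      n_latent, rank),
      class = "specmix_invalid_latent")
  }
  idx <- seq_len(n_latent)
  U <- sv$u[, idx, drop = FALSE]
  V <- sv$v[, idx, drop = FALSE]
  d <- sv$d[idx]
  signs <- vapply(idx, function(j) sign_fix(V[, j]), numeric(1))
  U <- sweep(U, 2, signs, `*`)
  V <- sweep(V, 2, signs, `*`)
  # scores T = U d; regression of Cc on T is diag(1/d) U' Cc
  Q <- (1 / d) * crossprod(U, Cc)   # n_latent x m
  B <- V %*% Q
  colnames(B) <- comp_names
  new_calib_model("pcr", comp_names, wl, x_center, y_center, B,
                  n_latent = n_latent,
                  internals = list(loadings = V, singular_values = d,
                                   scores = sweep(U, 2, d, `*`)),
                  n_cal = n)
}

#' Partial least squares (PLS2) calibration via NIPALS
#'
#' Column-centres both blocks and extracts latent variables one at a time:
#' the weight vector `w` (unit norm) maximises covariance between spectral
#' scores and the concentration block, scores are `t = X w`, loadings
#' `p = X't/(t't)` and `q = C't/(t't)`, after which both blocks are
#' deflated. The inner u-t iteration converges at relative tolerance 1e-12
#' (max 500 iterations). The final coefficient matrix is
#' `B = W (P'W)^-1 Q'`.
#'
#' @inheritParams fit_pcr
#' @param tol Relative convergence tolerance of the inner NIPALS iteration.
#' @param max_iter Iteration cap per latent variable.
#' @return A `calib_model` (method `"pls"`).
#' @export
fit_pls <- function(conc, spectra, n_latent, tol = 1e-12, max_iter = 500) {
  C <- as_conc_matrix(conc)
  A <- as_abs_matrix(spectra)
  wl <- if (inherits(spectra, "spectra_set")) spectra$wavelengths else NULL
  comp_names <- colnames(C) %||% paste0("comp_", seq_len(ncol(C)))
  n <- nrow(A); p <- ncol(A)
  check_n_latent(n_latent, n, p)
  x_center <- colMeans(A)
  y_center <- setNames(colMeans(C), comp_names)
  X <- sweep(A, 2, x_center)
  Y <- sweep(C, 2, y_center)
  W <- matrix(0, p, n_latent)
  P <- matrix(0, p, n_latent)
  Q <- matrix(0, ncol(C), n_latent)
  for (a in seq_len(n_latent)) {
    yvar <- apply(Y, 2, function(col) sum(col^2))
    if (max(yvar) < 1e-28) {
      abort(sprintf(
        "No concentration variance left when extracting latent variable %d.", a),
        class = "specmix_invalid_latent")
    }
    u <- Y[, which.max(yvar)]
    converged <- FALSE
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(X, u)
      w <- w / sqrt(sum(w^2))
      tt <- as.vector(X %*% w)
      q <- crossprod(Y, tt) / sum(tt^2)
      if (ncol(Y) == 1L) { converged <- TRUE } else {
        u <- as.vector(Y %*% q) / sum(q^2)
        if (sqrt(sum((tt - t_old)^2)) <= tol * sqrt(sum(tt^2))) {
          converged <- TRUE
        }
        t_old <- tt
      }
      if (converged) break
    }
    if (!converged) {
      abort(sprintf(
        "NIPALS did not converge for latent variable %d within %d iterations.",
        a, max_iter),
        class = "specmix_no_convergence")
    }
    s <- sign_fix(w)
    w <- s * w; tt <- s * tt; q <- s * q
    pp <- crossprod(X, tt) / sum(tt^2)
    X <- X - tcrossprod(tt, pp)
    Y <- Y - tcrossprod(tt, q)
    W[, a] <- w; P[, a] <- pp; Q[, a] <- q
  }
  B <- W %*% solve(crossprod(P, W)) %*% t(Q)
  colnames(B) <- comp_names
  new_calib_model("pls", comp_names, wl, x_center, y_center, B,
                  n_latent = n_latent,
                  internals = list(weights = W, loadings = P, y_loadings = Q),
                  n_cal = n)
}

check_n_latent <- function(n_latent, n, p) {
  max_lv <- min(n - 1, p)
  if (!is.numeric(n_latent) || length(n_latent) != 1L ||
      n_latent != round(n_latent) || n_latent < 1 || n_latent > max_lv) {
    abort(sprintf(
      "`n_latent` must be an integer in [1, min(n - 1, p)] = [1, %d]; got %s.",
      max_lv, format(n_latent)),
      class = "specmix_invalid_latent")
  }
  invisible(TRUE)
}

#' @export
print.calib_model <- function(x, ...) {
  cat(sprintf("<calib_model> %s: %d component(s), %d wavelengths%s, n_cal = %d\n",
              toupper(x$method), length(x$components), nrow(x$B),
              if (is.null(x$n_latent)) "" else
                sprintf(", %d latent variable(s)", x$n_latent),
              x$n_cal))
  invisible(x)
}

#' Predict concentrations from spectra
#'
#' Applies the fitted model's centring and coefficient matrix:
#' `c_hat = (a - x_center) B + y_center`, one row per sample.
#'
#' @param object A `calib_model`.
#' @param newdata A [spectra_set()] (its grid must equal the model's) or a
#'   samples-by-wavelengths matrix.
#' @param ... Unused.
#' @return A tibble with `sample_id` plus one concentration column (µg/mL)
#'   per component.
#' @export
predict.calib_model <- function(object, newdata, ...) {
  if (inherits(newdata, "spectra_set") && !is.null(object$wavelengths)) {
    if (length(newdata$wavelengths) != length(object$wavelengths) ||
        any(newdata$wavelengths != object$wavelengths)) {
      off <- c(setdiff(newdata$wavelengths, object$wavelengths),
               setdiff(object$wavelengths, newdata$wavelengths))
      abort(sprintf(
        "Wavelength grid mismatch between model and spectra (e.g. %s nm).",
        paste(head(off, 5), collapse = ", ")),
        class = "specmix_grid_mismatch")
    }
  }
  A <- as_abs_matrix(newdata)
  if (ncol(A) != nrow(object$B)) {
    abort(sprintf("Spectra have %d wavelengths but the model expects %d.",
                  ncol(A), nrow(object$B)),
          class = "specmix_grid_mismatch")
  }
  Chat <- sweep(A, 2, object$x_center) %*% object$B
  Chat <- sweep(Chat, 2, object$y_center, `+`)
  ids <- if (inherits(newdata, "spectra_set")) newdata$sample_ids else
    rownames(A) %||% paste0("S", seq_len(nrow(A)))
  dplyr::bind_cols(tibble(sample_id = ids),
                   as_tibble(as.data.frame(Chat)))
}

predict_matrix <- function(object, newdata) {
  out <- predict(object, newdata)
  as.matrix(out[, -1, drop = FALSE])
}

#' @export
tidy.calib_model <- function(x, ...) {
  wl <- x$wavelengths %||% seq_len(nrow(x$B))
  tidyr::pivot_longer(
    dplyr::bind_cols(tibble(wavelength_nm = wl),
                     as_tibble(as.data.frame(x$B))),
    -"wavelength_nm", names_to = "component", values_to = "coefficient"
  )
}

#' @export
glance.calib_model <- function(x, ...) {
  tibble(
    method = x$method,
    n_components = length(x$components),
    n_wavelengths = nrow(x$B),
    n_latent = x$n_latent %||% NA_integer_,
    n_cal = x$n_cal
  )
}

#' @export
autoplot.calib_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$wavelength_nm, y = .data$coefficient,
                               colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Wavelength (nm)",
                  y = "Regression coefficient (µg/mL per AU)",
                  title = sprintf("%s coefficient spectra", toupper(object$method))) +
    ggplot2::theme_minimal()
}
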