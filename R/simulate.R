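conc_matrix <- function(design, n_components = NULL) {
  if (is.matrix(design)) return(design)
  cols <- grep("^conc_", names(design), value = TRUE)
  if (length(cols) == 0) {
    abort("Design must carry conc_* columns (or be a matrix).",
          class = "specmix_invalid_design")
  }
  m <- as.matrix(design[cols])
  colnames(m) <- cols
  m
}

#' Simulate mixture absorption spectra under Beer-Lambert additivity
#'
#' For each design row the noiseless spectrum is the concentration-weighted
#' sum of the component absorptivity spectra plus the configured baseline;
#' seeded Gaussian instrument noise is added on top. Identical seeds yield
#' bit-identical output; the global RNG state is left untouched.
#'
#' @param design Design tibble with `conc_1`, `conc_2`, ... columns (one per
#'   component) — e.g. from [generate_design()] — or a samples-by-components
#'   concentration matrix.
#' @param components List of [gaussian_component()] objects, one per design
#'   factor, in column order.
#' @param noise A [noise_model()].
#' @param wavelengths Wavelength grid (nm).
#' @return A [spectra_set()]; sample ids are `S<sample_id>` when the design
#'   carries `sample_id`, else `S1..Sn`.
#' @export
#' @examples
#' d <- split_design(generate_design())
#' s <- simulate_mixtures(d, default_components(), noise_model(seed = 1))
simulate_mixtures <- function(design, components,
                              noise = noise_model(seed = NULL, noise_sd = 0),
                              wavelengths = default_grid()) {
  C <- conc_matrix(design)
  if (length(components) != ncol(C)) {
    abort(sprintf(
      "Design has %d concentration columns but %d components were given.",
      ncol(C), length(components)),
      class = "specmix_component_mismatch")
  }
  stopifnot(inherits(noise, "noise_model"))
  K <- t(vapply(components, pure_spectrum, numeric(length(wavelengths)),
                wavelengths = wavelengths))
  A <- C %*% K
  A <- A + noise$baseline_offset +
    noise$baseline_slope * rep(wavelengths - wavelengths[1], each = nrow(A))
  A <- add_instrument_noise(A, noise)
  ids <- if (is.data.frame(design) && "sample_id" %in% names(design)) {
    paste0("S", design$sample_id)
  } else {
    paste0("S", seq_len(nrow(A)))
  }
  spectra_set(wavelengths, A, ids)
}

add_instrument_noise <- function(A, noise, seed_offset = 0L) {
  if (noise$noise_sd == 0 && noise$multiplicative_sd == 0) return(A)
  withr::with_seed(noise$seed + seed_offset, {
    if (noise$multiplicative_sd > 0) {
      A <- A * (1 + matrix(rnorm(length(A), sd = noise$multiplicative_sd),
                           nrow(A)))
    }
    if (noise$noise_sd > 0) {
      A <- A + matrix(rnorm(length(A), sd = noise$noise_sd), nrow(A))
    }
    A
  })
}

#' Simulate mixtures over a plasma-like interferent background
#'
#' Adds the noise model's interferent spectrum, scaled by its nominal level
#' with an optional per-sample uniform jitter, to every simulated mixture.
#' The interferent absorbs in the same region as the analytes, so classical
#' least squares — which assumes every absorbing species is in the model —
#' degrades, while PCR/PLS can absorb the extra variance with one more
#' latent variable.
#'
#' @inheritParams simulate_mixtures
#' @return A [spectra_set()].
#' @export
simulate_plasma_set <- function(design, components, noise,
                                wavelengths = default_grid()) {
  stopifnot(inherits(noise, "noise_model"))
  if (is.null(noise$interferent)) {
    abort("`noise` must carry an interferent component for a plasma set.",
          class = "specmix_missing_interferent")
  }
  C <- conc_matrix(design)
  base_noise <- noise_model(noise_sd = 0, baseline_offset = noise$baseline_offset,
                            baseline_slope = noise$baseline_slope)
  set <- simulate_mixtures(design, components, base_noise, wavelengths)
  n <- nrow(set$absorbance)
  levels <- rep(noise$interferent_level, n)
  if (noise$interferent_jitter > 0 && noise$interferent_level > 0) {
    levels <- withr::with_seed(noise$seed + 1L, {
      noise$interferent_level *
        (1 + runif(n, -noise$interferent_jitter, noise$interferent_jitter))
    })
  }
  bg <- pure_spectrum(noise$interferent, wavelengths)
  A <- set$absorbance + outer(levels, bg)
  A <- add_instrument_noise(A, noise)
  spectra_set(wavelengths, A, set$sample_ids)
}
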