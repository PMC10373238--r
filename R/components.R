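#' Gaussian-band pure-component model
#'
#' A pure component's absorptivity spectrum at unit concentration is a sum of
#' Gaussian bands: `a(lambda) = sum_k h_k * exp(-(lambda - c_k)^2 / (2 s_k^2))`
#' with height `h` in AU·mL/µg, centre `c` and width `s` in nm. Gaussian
#' band sums are a standard surrogate for smooth UV absorption envelopes;
#' the mixture models only rely on Beer-Lambert linearity, not on the exact
#' band shape.
#'
#' @param name Component name.
#' @param bands A data frame with columns `center_nm`, `sigma_nm`, `height`
#'   (one row per band). Heights must be non-negative and sigmas positive.
#' @return An object of class `pure_component`.
#' @export
#' @examples
#' gaussian_component("drug", data.frame(center_nm = 310, sigma_nm = 10, height = 1))
gaussian_component <- function(name, bands) {
  bands <- as_tibble(bands)
  need <- c("center_nm", "sigma_nm", "height")
  if (!all(need %in% names(bands))) {
    abort(paste0("`bands` needs columns: ", paste(need, collapse = ", "), "."),
          class = "specmix_invalid_component")
  }
  if (any(bands$height < 0) || any(bands$sigma_nm <= 0)) {
    abort("Band heights must be >= 0 and sigmas > 0.",
          class = "specmix_invalid_component")
  }
  structure(list(name = name, bands = bands), class = "pure_component")
}

#' @export
print.pure_component <- function(x, ...) {
  cat(sprintf("<pure_component> %s: %d band(s) at %s nm\n",
              x$name, nrow(x$bands),
              paste(x$bands$center_nm, collapse = ", ")))
  invisible(x)
}

#' Evaluate a pure-component absorptivity spectrum on a grid
#'
#' @param component A [gaussian_component()].
#' @param wavelengths Numeric wavelength grid (nm).
#' @return Numeric vector of absorptivities (AU·mL/µg), one per wavelength.
#' @export
pure_spectrum <- function(component, wavelengths = default_grid()) {
  stopifnot(inherits(component, "pure_component"))
  b <- component$bands
  out <- rep(0, length(wavelengths))
  for (k in seq_len(nrow(b))) {
    out <- out + b$height[k] *
      exp(-(wavelengths - b$center_nm[k])^2 / (2 * b$sigma_nm[k]^2))
  }
  out
}

#' Default two-drug component models
#'
#' Surrogate absorptivity models for a favipiravir-like component (main band
#' near 323 nm) and a remdesivir-like component (main band near 246 nm),
#' shaped so the two pure spectra overlap over roughly 230-280 nm — the
#' spectral-overlap regime that motivates multivariate rather than
#' single-wavelength calibration. Heights are scaled so mixtures in the
#' 1-17 µg/mL design range stay below ~1.2 AU.
#'
#' @return A named list of two [gaussian_component()] objects.
#' @export
default_components <- function() {
  list(
    FV = gaussian_component("FV", tibble(
      center_nm = c(323, 245),
      sigma_nm = c(16, 25),
      height = c(0.055, 0.030)
    )),
    RV = gaussian_component("RV", tibble(
      center_nm = c(246, 275),
      sigma_nm = c(14, 25),
      height = c(0.062, 0.018)
    ))
  )
}

#' Default plasma-like interferent component
#'
#' Broad featureless background rising towards short wavelengths, mimicking
#' residual absorbance of endogenous plasma components after protein
#' precipitation. Used by [simulate_plasma_set()].
#'
#' @return A [gaussian_component()].
#' @export
plasma_interferent <- function() {
  gaussian_component("plasma", tibble(
    center_nm = c(225, 265),
    sigma_nm = c(18, 45),
    height = c(0.050, 0.020)
  ))
}

#' Instrument noise / background model
#'
#' Describes the stochastic and systematic parts added on top of the
#' Beer-Lambert mixture signal: iid Gaussian absorbance noise, a constant
#' baseline offset, a linear baseline slope, an optional multiplicative
#' noise term, an optional interferent component with per-sample level
#' jitter, and a between-day baseline component used by the precision
#' protocol. Any stochastic term requires a seed so every simulation is
#' reproducible.
#'
#' @param noise_sd SD of additive Gaussian noise (AU); default 0.002 AU,
#'   typical photometric noise of a bench-top UV-Vis instrument.
#' @param baseline_offset Constant baseline (AU).
#' @param baseline_slope Linear baseline (AU/nm), anchored at the grid start.
#' @param multiplicative_sd SD of a relative (signal-proportional) noise
#'   term; 0 disables it.
#' @param interferent Optional [gaussian_component()] added to every sample.
#' @param interferent_level Nominal interferent level (µg/mL-equivalent).
#' @param interferent_jitter Fractional uniform jitter of the interferent
#'   level per sample (e.g. 0.15 = ±15%).
#' @param between_day_sd SD of a day-specific constant baseline shift (AU).
#' @param seed Integer seed; required whenever any stochastic term is active.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(noise_sd = 0.002, baseline_offset = 0,
                        baseline_slope = 0, multiplicative_sd = 0,
                        interferent = NULL, interferent_level = 0,
                        interferent_jitter = 0, between_day_sd = 0,
                        seed = NULL) {
  if (noise_sd < 0 || multiplicative_sd < 0 || between_day_sd < 0 ||
      interferent_jitter < 0) {
    abort("Noise SDs and jitter must be non-negative.",
          class = "specmix_invalid_noise")
  }
  stochastic <- noise_sd > 0 || multiplicative_sd > 0 ||
    (interferent_jitter > 0 && interferent_level > 0) || between_day_sd > 0
  if (stochastic && is.null(seed)) {
    abort("A `seed` is required whenever the noise model is stochastic.",
          class = "specmix_missing_seed")
  }
  if (!is.null(interferent)) stopifnot(inherits(interferent, "pure_component"))
  structure(
    list(noise_sd = noise_sd, baseline_offset = baseline_offset,
         baseline_slope = baseline_slope,
         multiplicative_sd = multiplicative_sd,
         interferent = interferent, interferent_level = interferent_level,
         interferent_jitter = interferent_jitter,
         between_day_sd = between_day_sd,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "noise_model"
  )
}
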