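#' Construct a spectra set
#'
#' Container for a set of absorption spectra sharing one wavelength grid:
#' a samples-by-wavelengths absorbance matrix plus the grid in nm.
#'
#' @param wavelengths Strictly increasing numeric vector of wavelengths (nm).
#' @param absorbance Numeric matrix, one row per sample, one column per
#'   wavelength; all values finite.
#' @param sample_ids Character vector of sample identifiers; defaults to
#'   rownames of `absorbance` or `S1, S2, ...`.
#' @return An object of class `spectra_set`.
#' @export
#' @examples
#' spectra_set(220:222, matrix(0.1, 2, 3))
spectra_set <- function(wavelengths, absorbance,
                        sample_ids = NULL) {
  wavelengths <- as.numeric(wavelengths)
  if (anyNA(wavelengths) || any(diff(wavelengths) <= 0)) {
    abort("`wavelengths` must be strictly increasing and free of NAs.",
          class = "specmix_invalid_spectra")
  }
  absorbance <- as.matrix(absorbance)
  if (ncol(absorbance) != length(wavelengths)) {
    abort(sprintf(
      "absorbance has %d columns but the grid has %d wavelengths.",
      ncol(absorbance), length(wavelengths)),
      class = "specmix_invalid_spectra")
  }
  if (!all(is.finite(absorbance))) {
    abort("All absorbance values must be finite.",
          class = "specmix_invalid_spectra")
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(absorbance) %||% paste0("S", seq_len(nrow(absorbance)))
  }
  if (length(sample_ids) != nrow(absorbance)) {
    abort("`sample_ids` length must equal the number of spectra.",
          class = "specmix_invalid_spectra")
  }
  dimnames(absorbance) <- list(sample_ids, NULL)
  structure(
    list(wavelengths = wavelengths, absorbance = absorbance,
         sample_ids = as.character(sample_ids)),
    class = "spectra_set"
  )
}

#' Default instrument wavelength grid, 220-400 nm at 1 nm
#'
#' @return Numeric vector of 181 wavelengths (nm).
#' @export
default_grid <- function() seq(220, 400, by = 1)

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d spectra x %d wavelengths (%g-%g nm)\n",
              nrow(x$absorbance), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
as_tibble.spectra_set <- function(x, ...) {
  tibble(
    sample_id = rep(x$sample_ids, each = length(x$wavelengths)),
    wavelength_nm = rep(x$wavelengths, times = length(x$sample_ids)),
    absorbance = as.vector(t(x$absorbance))
  )
}

#' Subset a spectra set by sample
#'
#' @param set A [spectra_set()].
#' @param ids Character sample ids or integer positions to keep.
#' @return A [spectra_set()] with the selected samples, order preserved as
#'   given in `ids`.
#' @export
subset_samples <- function(set, ids) {
  stopifnot(inherits(set, "spectra_set"))
  if (is.character(ids)) {
    idx <- match(ids, set$sample_ids)
    if (anyNA(idx)) {
      abort(sprintf("Unknown sample ids: %s.",
                    paste(ids[is.na(idx)], collapse = ", ")),
            class = "specmix_invalid_spectra")
    }
  } else {
    idx <- as.integer(ids)
  }
  spectra_set(set$wavelengths, set$absorbance[idx, , drop = FALSE],
              set$sample_ids[idx])
}

#' Write / read spectra as delimited text
#'
#' CSV dialect: header row, first column `wavelength_nm` (strictly
#' increasing), one further column per sample holding absorbances (AU),
#' `.` decimal separator.
#'
#' @param set A [spectra_set()].
#' @param path File path.
#' @return `write_spectra()` returns `path` invisibly; `read_spectra()`
#'   returns a [spectra_set()].
#' @export
write_spectra <- function(set, path) {
  stopifnot(inherits(set, "spectra_set"))
  wide <- as.data.frame(t(set$absorbance))
  names(wide) <- set$sample_ids
  out <- dplyr::bind_cols(tibble(wavelength_nm = set$wavelengths), wide)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  df <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_double()))
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    p <- probs[1, ]
    abort(sprintf(
      "Parse error in '%s' at row %d, column %d: expected %s, got '%s'.",
      path, p$row, p$col, p$expected, p$actual),
      class = "specmix_parse_error")
  }
  if (ncol(df) < 2) {
    abort("Spectra file needs a wavelength column plus at least one sample.",
          class = "specmix_parse_error")
  }
  wl <- df[[1]]
  if (anyNA(wl) || anyNA(as.matrix(df))) {
    bad <- which(is.na(as.matrix(df)), arr.ind = TRUE)[1, ]
    abort(sprintf("Non-numeric or missing cell at row %d, column %d of '%s'.",
                  bad[1], bad[2], path),
          class = "specmix_parse_error")
  }
  if (anyDuplicated(wl)) {
    abort(sprintf("Duplicated wavelength %g nm in '%s'.",
                  wl[anyDuplicated(wl)], path),
          class = "specmix_parse_error")
  }
  if (any(diff(wl) <= 0)) {
    abort(sprintf("Wavelength column of '%s' is not strictly increasing (row %d).",
                  path, which(diff(wl) <= 0)[1] + 1L),
          class = "specmix_parse_error")
  }
  spectra_set(wl, t(as.matrix(df[-1])), sample_ids = names(df)[-1])
}

#' Wavelength mask
#'
#' A set of closed `[lo, hi]` nm intervals to keep; everything outside is
#' treated as an uninformative noise region and dropped by [apply_mask()].
#'
#' @param intervals A list of length-2 numeric vectors `c(lo, hi)`, or a
#'   two-column matrix with one interval per row.
#' @return An object of class `wavelength_mask`.
#' @export
#' @examples
#' wavelength_mask(list(c(240, 400)))
wavelength_mask <- function(intervals) {
  if (is.matrix(intervals)) {
    intervals <- split(intervals, seq_len(nrow(intervals)))
  }
  intervals <- lapply(intervals, as.numeric)
  ok <- vapply(intervals, function(iv) length(iv) == 2 && iv[1] <= iv[2],
               logical(1))
  if (length(intervals) == 0 || !all(ok)) {
    abort("Mask intervals must each be c(lo, hi) with lo <= hi.",
          class = "specmix_invalid_mask")
  }
  structure(list(intervals = intervals), class = "wavelength_mask")
}

#' Restrict a spectra set to the informative wavelength region
#'
#' Keeps exactly the wavelengths lying inside one of the mask's closed
#' intervals. Idempotent, and commutes with sample subsetting.
#'
#' @param set A [spectra_set()].
#' @param mask A [wavelength_mask()] or anything accepted by it.
#' @return A [spectra_set()] on the reduced grid.
#' @export
#' @examples
#' s <- spectra_set(default_grid(), matrix(0.1, 1, 181))
#' apply_mask(s, wavelength_mask(list(c(240, 400))))
apply_mask <- function(set, mask) {
  stopifnot(inherits(set, "spectra_set"))
  if (!inherits(mask, "wavelength_mask")) mask <- wavelength_mask(mask)
  keep <- rep(FALSE, length(set$wavelengths))
  for (iv in mask$intervals) {
    keep <- keep | (set$wavelengths >= iv[1] & set$wavelengths <= iv[2])
  }
  if (!any(keep)) {
    abort("Mask excludes every wavelength of the grid.",
          class = "specmix_empty_mask")
  }
  spectra_set(set$wavelengths[keep],
              set$absorbance[, keep, drop = FALSE],
              set$sample_ids)
}

#' @export
autoplot.spectra_set <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavelength_nm,
                                   y = .data$absorbance,
                                   group = .data$sample_id,
                                   colour = .data$sample_id)) +
    ggplot2::geom_line(show.legend = nrow(object$absorbance) <= 10) +
    ggplot2::labs(x = "Wavelength (nm)", y = "Absorbance (AU)") +
    ggplot2::theme_minimal()
}
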