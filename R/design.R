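#' Five-level, two-factor mixture design specification
#'
#' A multilevel (Brereton-style) calibration design for two co-analysed
#' components is described by a centre concentration, a step between adjacent
#' levels, and a cyclic generator of coded levels. The second factor's coded
#' column is the generator rotated left by one position, which balances the
#' levels and makes the two coded columns orthogonal.
#'
#' The default generator reproduces the 25-run layout used to calibrate
#' binary favipiravir/remdesivir mixtures: centre 9 µg/mL, step 4 µg/mL,
#' real levels \{1, 5, 9, 13, 17\} µg/mL.
#'
#' @param center Centre concentration (µg/mL) mapped to coded level 0.
#' @param step Concentration increment (µg/mL) per coded unit; must be > 0
#'   and small enough that `center - 2 * step > 0` (all real levels positive
#'   for the default five-level generator).
#' @param generator Integer vector of coded levels, length `n_levels^2`,
#'   containing each coded level exactly `n_levels` times and starting at 0.
#' @param n_levels Number of distinct concentration levels per factor.
#'
#' @return An object of class `design_spec`.
#' @seealso [generate_design()], [split_design()]
#' @export
#' @examples
#' design_spec()
design_spec <- function(center = 9, step = 4,
                        generator = five_level_generator(),
                        n_levels = 5) {
  if (!is.numeric(center) || length(center) != 1L) {
    abort("`center` must be a single number.", class = "specmix_invalid_design")
  }
  if (!is.numeric(step) || length(step) != 1L || step <= 0) {
    abort("`step` must be a single positive number.",
          class = "specmix_invalid_design")
  }
  generator <- as.numeric(generator)
  n_runs <- n_levels^2
  if (length(generator) != n_runs) {
    abort(
      sprintf("`generator` must have length n_levels^2 = %d, not %d.",
              n_runs, length(generator)),
      class = "specmix_invalid_design"
    )
  }
  lv <- sort(unique(generator))
  counts <- table(generator)
  if (length(lv) != n_levels || any(counts != n_levels)) {
    abort(
      paste0("`generator` must contain each of ", n_levels,
             " coded levels exactly ", n_levels, " times."),
      class = "specmix_invalid_design"
    )
  }
  # coded levels for an odd number of levels are the centred integers
  if (n_levels %% 2 == 1 && !isTRUE(all.equal(lv, seq(-(n_levels - 1) / 2,
                                                      (n_levels - 1) / 2)))) {
    abort("`generator` coded levels must be centred consecutive integers.",
          class = "specmix_invalid_design")
  }
  if (generator[1] != 0) {
    abort("The first generator entry must be the coded centre level 0.",
          class = "specmix_invalid_design")
  }
  if (center + step * min(generator) <= 0) {
    abort("All real concentrations must be positive: center + step * min(coded) <= 0.",
          class = "specmix_invalid_design")
  }
  structure(
    list(center = center, step = step, generator = generator,
         n_levels = n_levels, n_factors = 2L),
    class = "design_spec"
  )
}

#' Default cyclic generator of the 25-run, five-level design
#'
#' Coded levels (in \{-2, -1, 0, 1, 2\}) of the first factor of the default
#' 25-mixture layout; the second factor uses the same sequence rotated left
#' by one position.
#'
#' @return Integer vector of length 25.
#' @export
five_level_generator <- function() {
  c(0L, 0L, -2L, -2L, 2L, -1L, 2L, 0L, -1L, -1L, 1L, 2L, 1L,
    0L, 2L, 2L, -2L, 1L, -2L, 0L, 1L, 1L, -1L, -2L, -1L)
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf(
    "<design_spec> %d-level, %d-factor; center %g, step %g (levels %s)\n",
    x$n_levels, x$n_factors, x$center, x$step,
    paste(x$center + x$step * sort(unique(x$generator)), collapse = ", ")
  ))
  invisible(x)
}

#' Generate the mixture calibration design
#'
#' Expands a [design_spec()] into the full run table: the first factor's
#' coded column is the generator, the second factor's is the generator
#' rotated left by one, and real concentrations are
#' `center + step * coded`.
#'
#' @param spec A [design_spec()].
#' @return A tibble with columns `sample_id` (1-based), `coded_1`, `coded_2`,
#'   `conc_1`, `conc_2` (µg/mL).
#' @export
#' @examples
#' generate_design(design_spec())
generate_design <- function(spec = design_spec()) {
  stopifnot(inherits(spec, "design_spec"))
  g1 <- spec$generator
  g2 <- c(g1[-1], g1[1])
  tibble(
    sample_id = seq_along(g1),
    coded_1 = g1,
    coded_2 = g2,
    conc_1 = spec$center + spec$step * g1,
    conc_2 = spec$center + spec$step * g2
  )
}

#' Split a design into calibration and validation sets
#'
#' The default `"odd_even"` scheme assigns odd sample ids to the calibration
#' set and even ids to the validation set (13 vs 12 samples for the 25-run
#' design). Alternatively supply the calibration sample ids explicitly; the
#' remaining ids form the validation set.
#'
#' @param design A design tibble from [generate_design()].
#' @param scheme `"odd_even"` or an integer vector of calibration sample ids.
#' @return The design tibble with an added `role` column
#'   (`"calibration"` / `"validation"`).
#' @export
#' @examples
#' split_design(generate_design())
split_design <- function(design, scheme = "odd_even") {
  stopifnot(is.data.frame(design), "sample_id" %in% names(design))
  ids <- design$sample_id
  if (is.character(scheme) && length(scheme) == 1L) {
    if (scheme != "odd_even") {
      abort(sprintf("Unknown split scheme '%s'.", scheme),
            class = "specmix_invalid_split")
    }
    cal_ids <- ids[ids %% 2 == 1]
  } else {
    cal_ids <- unique(as.integer(scheme))
    bad <- setdiff(cal_ids, ids)
    if (length(bad) > 0) {
      abort(
        sprintf("Calibration ids not in the design: %s.",
                paste(bad, collapse = ", ")),
        class = "specmix_invalid_split"
      )
    }
  }
  role <- ifelse(ids %in% cal_ids, "calibration", "validation")
  if (!any(role == "validation")) {
    warn("All samples assigned to the calibration set; validation set is empty.")
  }
  dplyr::mutate(design, role = role)
}

#' Read / write a design table
#'
#' Delimited-text interchange format with header
#' `sample_id,comp1_ug_mL,comp2_ug_mL,role`.
#'
#' @param design A split design tibble.
#' @param path File path.
#' @return `write_design()` returns `path` invisibly; `read_design()` returns
#'   a design tibble with `conc_1`, `conc_2`, `role` columns.
#' @export
write_design <- function(design, path) {
  out <- tibble(
    sample_id = design$sample_id,
    comp1_ug_mL = design$conc_1,
    comp2_ug_mL = design$conc_2,
    role = if ("role" %in% names(design)) design$role else NA_character_
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("sample_id", "comp1_ug_mL", "comp2_ug_mL")
  if (!all(need %in% names(df))) {
    abort(paste0("Design file must have columns: ",
                 paste(need, collapse = ", "), "."),
          class = "specmix_parse_error")
  }
  tibble(
    sample_id = as.integer(df$sample_id),
    conc_1 = df$comp1_ug_mL,
    conc_2 = df$comp2_ug_mL,
    role = if ("role" %in% names(df)) df$role else NA_character_
  )
}
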