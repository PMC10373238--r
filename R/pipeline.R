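#' Default pipeline configuration
#'
#' Returns the configuration list driving [run_pipeline()]: the 25-run
#' five-level design (centre 9, step 4 µg/mL), odd/even calibration split,
#' 220-400 nm grid, full-range mask, default two-drug components,
#' homoscedastic instrument noise (0.002 AU) with a mandatory seed, all
#' three calibration methods, parsimony latent-variable selection, a
#' plasma-interferent scenario and the example eco-scale penalty
#' itemizations.
#'
#' @param seed Integer seed recorded in the noise configuration.
#' @return A named list; see [run_pipeline()].
#' @export
default_config <- function(seed = 101) {
  list(
    design = list(center = 9, step = 4),
    split = "odd_even",
    wavelengths = list(min = 220, max = 400, step = 1),
    mask = list(c(220, 400)),
    components = "default",
    noise = list(noise_sd = 0.002, seed = seed),
    methods = c("cls", "pcr", "pls"),
    cv = list(max_latent = 8, rule = "one_se_like_fratio"),
    plasma = list(enabled = TRUE, interferent_level = 1.0,
                  interferent_jitter = 0.15),
    ecoscale = "example"
  )
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort("`config` must be a list or the path to a YAML file.",
          class = "specmix_invalid_config")
  }
  config
}

validate_config <- function(config) {
  noise <- config$noise %||% list()
  if ((noise$noise_sd %||% 0) > 0 && is.null(noise$seed)) {
    abort("Config error: a stochastic noise model requires `noise$seed`.",
          class = "specmix_missing_seed")
  }
  if ((config$plasma$enabled %||% FALSE) && is.null(noise$seed)) {
    abort("Config error: the plasma scenario requires `noise$seed`.",
          class = "specmix_missing_seed")
  }
  invisible(config)
}

config_components <- function(config) {
  if (identical(config$components, "default") || is.null(config$components)) {
    return(default_components())
  }
  purrr::imap(config$components, function(bands, nm) {
    gaussian_component(nm, dplyr::bind_rows(lapply(bands, as_tibble)))
  })
}

write_csv_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  readr::write_csv(df, tmp)
  file.rename(tmp, path)
  invisible(path)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
          class = "specmix_pipeline_error", parent = e)
  })
}

#' Run the full calibration pipeline
#'
#' Executes the end-to-end study on synthetic spectra: design generation and
#' calibration/validation split, mixture simulation, wavelength masking,
#' CLS/PCR/PLS fitting (with leave-one-out RMSECV latent-variable selection
#' for PCR/PLS), prediction of the validation set, per-sample recovery
#' tables and summary statistics, RMSEC/RMSEP, an optional plasma
#' interferent scenario, and eco-scale scores. All tabular outputs are
#' written as delimited text (atomically: temp file then rename); the run is
#' a pure function of the configuration.
#'
#' @param config A configuration list (see [default_config()]) or the path
#'   to a YAML file with the same structure.
#' @param out_dir Output directory; created if missing. `NULL` skips all
#'   file output.
#' @return Invisibly, a list with elements `design`, `spectra`, `models`,
#'   `cv`, `selected`, `recoveries`, `recovery_summaries`, `errors`,
#'   `plasma`, `greenness`.
#' @export
#' @examples
#' res <- run_pipeline(default_config(seed = 1), out_dir = NULL)
#' res$recovery_summaries
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  config <- validate_config(read_config(config))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(df, name) {
    if (!is.null(out_dir)) write_csv_atomic(df, file.path(out_dir, name))
  }

  design <- pipeline_stage("design", {
    spec <- design_spec(center = config$design$center %||% 9,
                        step = config$design$step %||% 4)
    split_design(generate_design(spec), config$split %||% "odd_even")
  })
  emit(dplyr::select(dplyr::rename(design, comp1_ug_mL = "conc_1",
                                   comp2_ug_mL = "conc_2"),
                     "sample_id", "comp1_ug_mL", "comp2_ug_mL", "role"),
       "design.csv")

  wlc <- config$wavelengths %||% list(min = 220, max = 400, step = 1)
  grid <- seq(wlc$min, wlc$max, by = wlc$step)
  components <- config_components(config)
  noise <- pipeline_stage("noise", do.call(noise_model, config$noise %||% list()))

  spectra <- pipeline_stage("simulate",
    simulate_mixtures(design, components, noise, grid))
  masked <- pipeline_stage("mask",
    apply_mask(spectra, wavelength_mask(config$mask %||% list(c(wlc$min, wlc$max)))))
  if (!is.null(out_dir)) {
    pipeline_stage("write_spectra",
      write_spectra(masked, file.path(out_dir, "spectra.csv")))
  }

  cal <- design$role == "calibration"
  comp_names <- names(components) %||% paste0("comp_", seq_along(components))
  named_conc <- function(d) {
    C <- conc_matrix(d)
    colnames(C) <- comp_names
    C
  }
  d_cal <- named_conc(design[cal, ]); d_val <- named_conc(design[!cal, ])
  s_cal <- subset_samples(masked, which(cal))
  s_val <- subset_samples(masked, which(!cal))

  methods <- tolower(config$methods %||% c("cls", "pcr", "pls"))
  cv_rule <- config$cv$rule %||% "one_se_like_fratio"
  max_latent <- min(config$cv$max_latent %||% 8,
                    sum(cal) - 2, length(masked$wavelengths))

  cv <- list(); selected <- list(); models <- list()
  for (m in methods) {
    if (m == "cls") {
      models[[m]] <- pipeline_stage("fit_cls", fit_cls(d_cal, s_cal))
    } else {
      cv[[m]] <- pipeline_stage(paste0("crossval_", m),
        loo_rmsecv(d_cal, s_cal, method = m, max_latent = max_latent))
      selected[[m]] <- select_n_latent(cv[[m]], rule = cv_rule)
      emit(cv[[m]]$table, sprintf("rmsecv_%s.csv", m))
      fitter <- if (m == "pcr") fit_pcr else fit_pls
      models[[m]] <- pipeline_stage(paste0("fit_", m),
        fitter(d_cal, s_cal, n_latent = selected[[m]]))
    }
  }

  nominal <- list(calibration = d_cal, validation = d_val)
  sets <- list(calibration = s_cal, validation = s_val)
  ids <- list(calibration = design$sample_id[cal],
              validation = design$sample_id[!cal])
  recoveries <- purrr::map_dfr(methods, function(m) {
    purrr::map_dfr(names(sets), function(role) {
      pred <- predict_matrix(models[[m]], sets[[role]])
      purrr::map_dfr(seq_along(models[[m]]$components), function(j) {
        nom_j <- nominal[[role]][, j]
        tibble(method = m, set = role,
               sample_id = ids[[role]],
               component = models[[m]]$components[j],
               nominal = nom_j,
               predicted = pred[, j],
               recovery = 100 * pred[, j] / nom_j)
      })
    })
  })
  emit(recoveries, "recoveries.csv")

  recovery_summaries <- recoveries |>
    dplyr::group_by(.data$method, .data$set, .data$component) |>
    dplyr::group_modify(~ recovery_summary(.x$predicted, .x$nominal)) |>
    dplyr::ungroup()
  emit(recovery_summaries, "recovery_summary.csv")

  errors <- purrr::map_dfr(methods, function(m) {
    dplyr::bind_rows(
      dplyr::mutate(error_summary(models[[m]], d_cal, s_cal, "calibration"),
                    method = m, .before = 1),
      dplyr::mutate(error_summary(models[[m]], d_val, s_val, "prediction"),
                    method = m, .before = 1)
    )
  })
  emit(errors, "error_summary.csv")

  plasma <- NULL
  if (config$plasma$enabled %||% FALSE) {
    plasma <- pipeline_stage("plasma", {
      pl_noise <- noise_model(
        noise_sd = noise$noise_sd,
        interferent = plasma_interferent(),
        interferent_level = config$plasma$interferent_level %||% 1,
        interferent_jitter = config$plasma$interferent_jitter %||% 0.15,
        seed = noise$seed + 500L
      )
      pset <- simulate_plasma_set(design, components, pl_noise, grid)
      pmask <- apply_mask(pset, wavelength_mask(config$mask %||%
                                                  list(c(wlc$min, wlc$max))))
      p_cal <- subset_samples(pmask, which(cal))
      p_val <- subset_samples(pmask, which(!cal))
      p_models <- list(
        cls = fit_cls(d_cal, p_cal),
        pcr = fit_pcr(d_cal, p_cal, n_latent = (selected$pcr %||% 2) + 1),
        pls = fit_pls(d_cal, p_cal, n_latent = (selected$pls %||% 2) + 1)
      )
      purrr::map_dfr(names(p_models), function(m) {
        dplyr::mutate(error_summary(p_models[[m]], d_val, p_val, "prediction"),
                      method = m, scenario = "plasma", .before = 1)
      })
    })
    emit(plasma, "plasma_error_summary.csv")
  }

  greenness <- NULL
  if (!is.null(config$ecoscale)) {
    greenness <- pipeline_stage("greenness", {
      pen <- if (identical(config$ecoscale, "example")) {
        readr::read_csv(specmix_example("ecoscale_penalties.csv"),
                        show_col_types = FALSE)
      } else {
        as_tibble(config$ecoscale)
      }
      pen |>
        dplyr::group_by(.data$method) |>
        dplyr::group_modify(~ glance(eco_scale(.x))) |>
        dplyr::ungroup()
    })
    emit(greenness, "greenness.csv")
  }

  invisible(list(design = design, spectra = masked, models = models,
                 cv = cv, selected = selected, recoveries = recoveries,
                 recovery_summaries = recovery_summaries, errors = errors,
                 plasma = plasma, greenness = greenness))
}

#' Path to a bundled example data file
#'
#' Bundled files include published per-sample recovery tables for the
#' favipiravir/remdesivir UV assay (`validation_recoveries.csv`,
#' `standard_addition.csv`, `plasma_recoveries.csv`), an illustrative
#' eco-scale penalty itemization (`ecoscale_penalties.csv`) and a default
#' pipeline configuration (`default_config.yaml`).
#'
#' @param file File name; with no argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
specmix_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "specmix")))
  }
  path <- system.file("extdata", file, package = "specmix")
  if (path == "") {
    abort(sprintf("No bundled example file '%s'.", file),
          class = "specmix_invalid_input")
  }
  path
}
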