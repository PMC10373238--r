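# Shared fixtures: the published 25-run design and small simulation helpers.

# The 25-run five-level layout (µg/mL), exactly as published: odd rows form
# the calibration set.
published_design <- function() {
  fv <- c(9, 9, 1, 1, 17, 5, 17, 9, 5, 5, 13, 17, 13,
          9, 17, 17, 1, 13, 1, 9, 13, 13, 5, 1, 5)
  tibble::tibble(sample_id = 1:25, conc_1 = fv, conc_2 = c(fv[-1], fv[1]))
}

reference_table <- function(file) {
  readr::read_csv(specmix_example(file), show_col_types = FALSE)
}

# a two-band + one-band toy pair, cheaper than the defaults for stress loops
toy_components <- function() {
  list(
    A = gaussian_component("A", tibble::tibble(
      center_nm = c(320, 250), sigma_nm = c(15, 15), height = c(0.05, 0.02))),
    B = gaussian_component("B", tibble::tibble(
      center_nm = 248, sigma_nm = 14, height = 0.06))
  )
}

split_sets <- function(design = split_design(generate_design()),
                       components = default_components(),
                       noise = noise_model(noise_sd = 0),
                       wavelengths = default_grid()) {
  set <- simulate_mixtures(design, components, noise, wavelengths)
  cal <- design$role == "calibration"
  list(design = design,
       cal = design[cal, ], val = design[!cal, ],
       s_all = set,
       s_cal = subset_samples(set, which(cal)),
       s_val = subset_samples(set, which(!cal)))
}

conc_of <- function(d) as.matrix(d[c("conc_1", "conc_2")])

# minimum-norm least-squares oracle via the SVD pseudoinverse
pinv_coef <- function(X, Y, tol = 1e-10) {
  sv <- svd(X)
  keep <- sv$d > tol * sv$d[1]
  sv$v[, keep, drop = FALSE] %*%
    ((1 / sv$d[keep]) * crossprod(sv$u[, keep, drop = FALSE], Y))
}
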