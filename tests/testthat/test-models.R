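test_that("CLS recovers exact proportionality on a tiny one-component system", {
  fit <- fit_cls(matrix(c(1, 2)), matrix(c(0.1, 0.2, 0.2, 0.4), 2, 2))
  expect_equal(unname(fit$internals$K), matrix(c(0.1, 0.2), 1, 2))
  pred <- predict(fit, matrix(c(0.3, 0.6), 1, 2))
  expect_equal(pred[[2]], 3.0)
})

test_that("CLS equals a brute-force normal-equations solve on small instances", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      n <- 5; m <- 2; p <- 5
      C <- matrix(runif(n * m, 1, 10), n, m)
      A <- matrix(runif(n * p), n, p)
      fit <- fit_cls(C, A)
      K_oracle <- solve(t(C) %*% C) %*% t(C) %*% A
      expect_equal(unname(fit$internals$K), K_oracle, tolerance = 1e-12)
    }
  })
})

test_that("all three models are exact on noiseless data in the model span", {
  sets <- split_sets()  # noiseless default design
  truth <- conc_of(sets$design)
  models <- list(cls = fit_cls(sets$cal, sets$s_cal),
                 pcr = fit_pcr(sets$cal, sets$s_cal, 2),
                 pls = fit_pls(sets$cal, sets$s_cal, 2))
  for (m in models) {
    pred <- as.matrix(predict(m, sets$s_all)[, -1])
    expect_lt(max(abs(pred - truth)), 1e-8)
    rec <- 100 * pred / truth
    expect_equal(unname(rec), matrix(100, 25, 2), tolerance = 1e-9)
  }
  # PCR with the full mixture rank matches CLS predictions
  expect_equal(predict(models$pcr, sets$s_val)[, -1],
               predict(models$cls, sets$s_val)[, -1], tolerance = 1e-8)
})

test_that("full-rank PCR equals the minimum-norm least-squares solution", {
  withr::with_seed(31, {
    n <- 8; p <- 12; m <- 2
    C <- matrix(runif(n * m, 1, 10), n, m)
    A <- matrix(rnorm(n * p), n, p)
  })
  fit <- fit_pcr(C, A, n_latent = n - 1)   # centred rank is n - 1
  Ac <- scale(A, scale = FALSE)
  Cc <- scale(C, scale = FALSE)
  expect_equal(unname(fit$B), unname(pinv_coef(Ac, Cc)), tolerance = 1e-10)
})

test_that("PCR and PLS predictions converge at full rank on a noisy set", {
  sets <- split_sets(noise = noise_model(seed = 13))
  full <- min(nrow(sets$cal) - 1, length(sets$s_cal$wavelengths))
  pcr <- fit_pcr(sets$cal, sets$s_cal, full)
  pls <- fit_pls(sets$cal, sets$s_cal, full)
  d <- abs(as.matrix(predict(pcr, sets$s_val)[, -1]) -
             as.matrix(predict(pls, sets$s_val)[, -1]))
  expect_lt(max(d), 1e-6)
})

test_that("single-component PLS with one latent variable matches the closed-form score regression", {
  withr::with_seed(17, {
    n <- 10; p <- 30
    k <- exp(-((1:p) - 15)^2 / 50)
    c1 <- runif(n, 1, 17)
    A <- outer(c1, k)
  })
  pls <- fit_pls(matrix(c1), A, 1)
  # oracle: univariate regression of centred c on the first score direction
  Xc <- scale(A, scale = FALSE); yc <- c1 - mean(c1)
  w <- crossprod(Xc, yc); w <- w / sqrt(sum(w^2))
  tt <- Xc %*% w
  pred_oracle <- mean(c1) + tt * sum(tt * yc) / sum(tt^2)
  expect_equal(unname(as.matrix(predict(pls, A)[, -1])), unname(pred_oracle),
               tolerance = 1e-8)
  cls <- fit_cls(matrix(c1), A)
  expect_equal(predict(pls, A)[, -1], predict(cls, A)[, -1], tolerance = 1e-8)
})

test_that("degenerate fits are rejected with informative errors", {
  sets <- split_sets()
  C2 <- cbind(conc_of(sets$cal)[, 1], conc_of(sets$cal)[, 1])
  expect_error(fit_cls(C2, sets$s_cal), class = "specmix_singular_design")
  expect_error(fit_pcr(sets$cal, sets$s_cal, 0),
               class = "specmix_invalid_latent")
  expect_error(fit_pls(sets$cal, sets$s_cal, 13),
               class = "specmix_invalid_latent")
  expect_error(fit_pcr(sets$cal, sets$s_cal, 5),   # beyond noiseless rank
               class = "specmix_invalid_latent")
})

test_that("prediction honours centring, batching and the wavelength grid", {
  sets <- split_sets(noise = noise_model(seed = 23))
  pls <- fit_pls(sets$cal, sets$s_cal, 2)
  # centring identity: the mean calibration spectrum maps to the mean conc
  mean_spec <- matrix(colMeans(sets$s_cal$absorbance), 1)
  expect_equal(unname(as.matrix(predict(pls, mean_spec)[, -1])[1, ]),
               unname(colMeans(conc_of(sets$cal))), tolerance = 1e-10)
  # CLS of a zero spectrum returns zero concentrations
  cls <- fit_cls(sets$cal, sets$s_cal)
  expect_equal(unname(as.matrix(predict(cls, matrix(0, 1, 181))[, -1])[1, ]),
               c(0, 0))
  # batch prediction equals per-sample prediction
  batch <- as.matrix(predict(pls, sets$s_val)[, -1])
  rows <- t(vapply(seq_len(12), function(i) {
    as.matrix(predict(pls, sets$s_val$absorbance[i, , drop = FALSE])[, -1])[1, ]
  }, numeric(2)))
  expect_equal(unname(batch), unname(rows))
  # grid mismatch is refused
  masked <- apply_mask(sets$s_val, list(c(240, 400)))
  expect_error(predict(pls, masked), class = "specmix_grid_mismatch")
})

test_that("prediction error does not improve as instrument noise doubles", {
  design <- split_design(generate_design())
  comps <- toy_components()
  cal <- design$role == "calibration"
  truth <- conc_of(design[!cal, ])
  grid <- seq(220, 400, by = 4)   # coarser grid keeps the stress loop fast
  base <- simulate_mixtures(design, comps, noise_model(noise_sd = 0), grid)
  sds <- c(0.001, 0.002, 0.004)
  withr::with_seed(99, {
    rmsep <- vapply(1:200, function(rep) {
      E <- matrix(rnorm(length(base$absorbance)), nrow(base$absorbance))
      vapply(sds, function(s) {
        A <- base$absorbance + s * E
        fit <- fit_pls(design[cal, ], A[cal, ], 2)
        pred <- sweep(A[!cal, ], 2, fit$x_center) %*% fit$B +
          rep(fit$y_center, each = sum(!cal))
        sqrt(mean((pred - truth)^2))
      }, numeric(1))
    }, numeric(3))
  })
  means <- rowMeans(rmsep)
  expect_true(means[1] <= means[2] && means[2] <= means[3])
})

test_that("model accessors expose a tidy surface", {
  sets <- split_sets(noise = noise_model(seed = 2))
  pls <- fit_pls(sets$cal, sets$s_cal, 2)
  td <- tidy(pls)
  expect_named(td, c("wavelength_nm", "component", "coefficient"))
  expect_equal(nrow(td), 181 * 2)
  g <- glance(pls)
  expect_equal(g$method, "pls")
  expect_equal(g$n_latent, 2)
  expect_s3_class(autoplot(pls), "ggplot")
})
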