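# A "cytoplasmic-consistent world": nuclear rates zeroed so that the full
# model's observable totals equal the cytoplasmic sub-model's predictions.
cyto_world_params <- function() {
  m <- build_default_model(12, 18)
  p <- default_params(m)
  p[grep("binding\\.k$", names(p))] <- 0
  p[grep("^transcription", names(p))] <- 0
  p["hif1b_in.k"] <- 0
  p
}

test_that("residuals are zero when predictions equal observations", {
  spec <- synthetic_spec(cv = 0, spread = 1, seed = 1)
  ds <- generate_dataset(sample_params(spec), spec)
  m <- spec$model
  r <- residuals_model(m, ds$params, ds$truth, observation_mapping("full"),
                       init = initial_state(m))
  expect_lt(max(abs(r$residual)), 1e-6)
  expect_identical(nrow(r), 6L * 12L)
})

test_that("residual weighting handles zeros and missing cells", {
  m <- cytoplasmic_model(build_default_model(0, 0))
  p <- default_params(m)
  data <- data.frame(time = c(0, 1), check.names = FALSE)
  data[["HIF1A protein"]] <- c(1, 0)
  data[["HIF2A protein"]] <- c(1, NA)
  mp <- observation_mapping("cytoplasmic")[1:2]
  expect_warning(
    r <- residuals_model(m, p, data, mp,
                         init = initial_state(m, hif1b = 0,
                                              hif2a_protein = 1)),
    "absolute residual")
  # the zero-observation entry is absolute: residual = predicted
  z <- r[r$column == "HIF1A protein" & r$time == 1, ]
  expect_equal(z$residual, z$predicted)
  # missing HIF2A cell skipped
  expect_identical(nrow(r[r$column == "HIF2A protein", ]), 1L)
  # absolute weighting: residual = predicted - observed
  ra <- suppressWarnings(
    residuals_model(m, p, data, mp, weighting = "absolute",
                    init = initial_state(m, hif1b = 0, hif2a_protein = 1)))
  expect_equal(ra$residual, ra$predicted - ra$observed)
})

test_that("residuals on noisy synthetic data are noise-consistent", {
  spec <- synthetic_spec(cv = 0.1, spread = 1, seed = 2)
  ds <- generate_dataset(sample_params(spec), spec)
  m <- spec$model
  r <- residuals_model(m, ds$params, ds$data, observation_mapping("full"),
                       init = initial_state(m))
  # proportional residuals of truth params against 10% noise: RMS near 0.1
  expect_lt(sqrt(mean(r$residual^2)), 0.25)
  expect_gt(sqrt(mean(r$residual^2)), 0.02)
})

test_that("cytoplasmic fit from the truth start has near-zero loss", {
  # hif2a_protein = 1 puts the synthetic world on the unscaled axis the
  # cytoplasmic step fits on (hydroxylation is nonlinear, so the scale of
  # the HIF2A axis matters -- the very reason the HIF2A reactions are
  # re-freed in the second step)
  spec <- synthetic_spec(base_params = cyto_world_params(), cv = 0,
                         spread = 1, seed = 3, hif2a_protein = 1)
  ds <- generate_dataset(spec$base_params, spec)
  cm <- cytoplasmic_model(build_default_model(0, 0))
  truth_cyto <- spec$base_params[cm$param_names]
  fit <- fit_cytoplasmic(ds$data, params0 = truth_cyto,
                         config = fit_config(iter_max = 5, eval_max = 20))
  expect_lt(fit$loss, 1e-6)
  expect_identical(sort(fit$free), sort(cm$param_names))
})

test_that("nuclear step freezes cytoplasmic parameters bit-identically", {
  data <- table2()
  cyto <- fit_cytoplasmic(data, config = fit_config(iter_max = 3,
                                                    eval_max = 10))
  nuc <- fit_nuclear(data, cyto, config = fit_config(iter_max = 2,
                                                     eval_max = 8))
  expect_identical(nuc$params[nuc$frozen], cyto$params[nuc$frozen])
  # the free set is exactly the nuclear reactions plus the three HIF2A
  # cytoplasmic reactions
  expect_true(all(c("hif2a_mrna_to_protein.k", "hif2a_protein_out.k",
                    "phd_to_hif2a_protein.kcat",
                    "phd_to_hif2a_protein.km_hif",
                    "phd_to_hif2a_protein.km_o2") %in% nuc$free))
  expect_false(any(c("hif1a_mrna_to_protein.k", "hif1a_protein_out.k",
                     "phd_to_hif1a_protein.kcat", "phd_in.k",
                     "hif1a_mrna_in.k") %in% nuc$free))
  expect_true(all(grepl("binding", nuc$free) | grepl("transcription",
                  nuc$free) | grepl("hif1b|gene_mrna|hif2a|phd_to_hif2a",
                  nuc$free)))
  # freeing a frozen cytoplasmic parameter is a configuration error
  expect_error(
    fit_nuclear(data, cyto,
                config = fit_config(free = c("hif1a_protein_out.k"),
                                    iter_max = 1)),
    "frozen cytoplasmic")
})

test_that("nuclear fit started at the truth has near-zero loss", {
  spec <- synthetic_spec(cv = 0, spread = 1, seed = 12)
  ds <- generate_dataset(spec$base_params, spec)
  cfg <- fit_config(iter_max = 4)
  nuc <- fit_nuclear(ds$data, spec$base_params, config = cfg,
                     model = spec$model, params0 = spec$base_params)
  expect_lt(nuc$loss, 1e-6)
})

test_that("fits are reproducible under identical config and seed", {
  spec <- synthetic_spec(base_params = cyto_world_params(), cv = 0.05,
                         spread = 1, seed = 4)
  ds <- generate_dataset(spec$base_params, spec)
  cfg <- fit_config(iter_max = 4, eval_max = 15, restarts = 1, seed = 99)
  f1 <- fit_cytoplasmic(ds$data, config = cfg)
  f2 <- fit_cytoplasmic(ds$data, config = cfg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loss, f2$loss)
})

test_that("objective trace is non-increasing and loss is reproducible", {
  data <- table2()
  fit <- fit_cytoplasmic(data, config = fit_config(iter_max = 8,
                                                   eval_max = 30))
  expect_true(all(diff(fit$objective_trace) <= 0))
  # stored loss equals the recomputed objective at the fitted parameters
  m <- cytoplasmic_model(build_default_model(0, 0))
  r <- residuals_model(m, fit$params, data,
                       observation_mapping("cytoplasmic"),
                       init = initial_state(m, hif1b = 0,
                                            hif2a_protein = 1),
                       rtol = 1e-6, atol = 1e-9)
  expect_equal(fit$loss, sum(r$residual^2), tolerance = 1e-8)
})

test_that("fit_cytoplasmic rejects non-cytoplasmic free parameters", {
  expect_error(
    fit_cytoplasmic(table2(),
                    config = fit_config(free = "hif1b_in.k", iter_max = 1)),
    "not cytoplasmic")
  expect_error(fit_cytoplasmic(table2()[, 1:3]), "lacks column")
})
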