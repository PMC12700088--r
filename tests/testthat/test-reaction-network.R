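test_that("default model has the full 15-species network", {
  m <- build_default_model(12, 18)
  expect_length(m$species, 15L)
  expect_setequal(m$species, hif_species())
  expect_identical(m$hre1_total, 12)
  expect_identical(m$hre2_total, 18)
  ids <- vapply(m$reactions, `[[`, character(1), "id")
  expect_true(all(c("hif1a_mrna_to_protein", "hif2a_mrna_to_protein",
                    "hif1a_protein_out", "hif2a_protein_out",
                    "phd_to_hif1a_protein", "phd_to_hif2a_protein",
                    "hif1b_in", "hif1b_out") %in% ids))
  kinds <- vapply(m$reactions, `[[`, character(1), "kind")
  expect_identical(sum(kinds == "mm_hydroxylation"), 2L)
  expect_identical(sum(kinds == "reversible_binding"), 6L)
  # 2 translations + 2 PHD inductions + 4 transcriptions
  expect_identical(sum(kinds == "catalytic_production"), 8L)
  # reversible reactions carry exactly one forward constant and one .kd key
  for (r in m$reactions[kinds == "reversible_binding"]) {
    expect_named(r$params, c("k", "kd"))
    expect_match(r$params[["kd"]], "\\.kd$")
  }
  for (r in m$reactions[kinds == "mm_hydroxylation"])
    expect_named(r$params, c("kcat", "km_hif", "km_o2"))
  expect_error(build_default_model(-1, 0), "non-negative")
  expect_error(build_default_model(2.5, 0), "integer")
})

test_that("default parameters are 1 with kd at 1e-4", {
  m <- build_default_model(12, 18)
  p <- default_params(m)
  kd <- grepl("\\.kd$", names(p))
  expect_true(all(p[kd] == 1e-4))
  expect_true(all(p[!kd] == 1))
  expect_length(p[kd], 6L)
})

test_that("zero HRE counts leave the target gene at its basal level", {
  m <- build_default_model(0, 0)
  p <- default_params(m)
  tr <- simulate_model(m, p, init = initial_state(m), t_grid = c(0, 24, 48))
  # basal inflow k=1, outflow k=1, init 1 -> steady at 1 under any O2
  expect_equal(tr$Gene_mRNA, rep(1, 3), tolerance = 1e-8)
  tr2 <- simulate_model(m, p, init = initial_state(m),
                        protocol = oxygen_protocol(c(0, 10), c(1, 5)),
                        t_grid = c(0, 24, 48))
  expect_equal(tr2$Gene_mRNA, rep(1, 3), tolerance = 1e-8)
})

test_that("reactions touching an absent HRE class carry zero flux", {
  m <- build_default_model(1, 0)
  p <- random_params(m)
  s <- initial_state(m)
  hre2_rx <- Filter(function(r) any(r$roles %in%
                                      c("HRE2", "HIF1AB_HRE2", "HIF2AB_HRE2")),
                    m$reactions)
  expect_length(hre2_rx, 4L)  # 2 bindings + 2 transcription reactions
  for (r in hre2_rx[vapply(hre2_rx, function(r)
    r$kind == "reversible_binding", logical(1))]) {
    f <- mass_action_flux(r, s, p)
    expect_equal(unname(f["forward"]), 0)
    expect_equal(unname(f["reverse"]), 0)
  }
  tr <- simulate_model(m, p, init = s, t_grid = c(0, 10, 48))
  expect_true(all(tr$occupied_HRE1 <= 1 + 1e-9))
  expect_true(all(tr$HRE2 == 0))
})

test_that("mm_hydroxylation_flux follows the two-substrate MM form", {
  expect_identical(mm_hydroxylation_flux(1, 0, 1, 1, 1, 1), 0)
  # half-saturation in HIF, O2 saturated
  expect_equal(mm_hydroxylation_flux(0.5, 1e9, 1, 2, 0.5, 1), 1.0,
               tolerance = 1e-8)
  set.seed(42)
  for (i in 1:20) {
    x <- stats::runif(6, 0.01, 5)
    expect_equal(
      mm_hydroxylation_flux(x[1], x[2], x[3], x[4], x[5], x[6]),
      x[4] * x[3] * (x[1] / (x[5] + x[1])) * (x[2] / (x[6] + x[2])))
  }
  # km_o2 -> 0 limit reduces to single-substrate MM in the alpha subunit
  single <- 2 * 1 * (0.3 / (0.7 + 0.3))
  expect_equal(mm_hydroxylation_flux(0.3, 0.8, 1, 2, 0.7, 1e-12), single,
               tolerance = 1e-9)
  expect_error(mm_hydroxylation_flux(-1, 1, 1, 1, 1, 1), "non-negative")
  expect_error(mm_hydroxylation_flux(1, 1, 1, 1, 0, 1), "positive")
})

test_that("mass_action_flux covers each reaction kind", {
  m <- build_default_model(12, 18)
  rx <- m$reactions
  names(rx) <- vapply(rx, `[[`, character(1), "id")
  s <- initial_state(m)
  p <- default_params(m)

  s["HIF1A_mrna"] <- 0
  expect_equal(mass_action_flux(rx$hif1a_mrna_out, s, p), 0)
  expect_equal(mass_action_flux(rx$hif1a_mrna_in, s, p), 1)

  # detailed-balance point: [A]=kd, [AB]=[B] -> net zero
  s["HIF1A_protein"] <- 1e-4; s["HIF1B"] <- 0.7; s["HIF1AB"] <- 0.7
  f <- mass_action_flux(rx$hif1a_hif1b_binding, s, p)
  expect_equal(unname(f["forward"] - f["reverse"]), 0, tolerance = 1e-18)

  # direct arithmetic on a reversible reaction
  p["hif1a_hif1b_binding.k"] <- 3
  s["HIF1A_protein"] <- 0.2; s["HIF1B"] <- 0.5; s["HIF1AB"] <- 0.1
  f <- mass_action_flux(rx$hif1a_hif1b_binding, s, p)
  expect_equal(unname(f["forward"]), 0.3)
  expect_equal(unname(f["reverse"]), 3e-5)

  expect_error(mass_action_flux(rx$phd_to_hif1a_protein, s, p),
               "mm_hydroxylation_flux")
  expect_error(mass_action_flux(rx$hif1b_in, s, p["hif1a_mrna_in.k"]),
               "hif1b_in.k")
})

test_that("rhs equals the per-reaction accumulation oracle", {
  m <- build_default_model(12, 18)
  set.seed(1)
  for (i in 1:25) {
    s <- random_state(m)
    p <- random_params(m)
    o2 <- stats::runif(1, 0, 3)
    expect_equal(model_rhs(s, p, o2, model = m), oracle_rhs(m, s, p, o2),
                 tolerance = 1e-12)
  }
  # all rate constants zero -> zero vector
  p0 <- default_params(m); p0[] <- 0
  expect_equal(unname(model_rhs(initial_state(m), p0, 1, model = m)),
               rep(0, 15))
  # HRE pool untouched when binding constants are zero
  p1 <- default_params(m)
  p1[grepl("hre[12]_binding", names(p1))] <- 0
  d <- model_rhs(initial_state(m), p1, 1, model = m)
  expect_identical(unname(d["HRE1"]), 0)
  expect_identical(unname(d["HRE2"]), 0)
})

test_that("rhs conserves each HRE pool exactly", {
  m <- build_default_model(7, 9)
  set.seed(2)
  for (i in 1:50) {
    d <- model_rhs(random_state(m), random_params(m), stats::runif(1, 0, 2),
                   model = m)
    # zero up to roundoff of the accumulated fluxes
    expect_lt(abs(d["HRE1"] + d["HIF1AB_HRE1"] + d["HIF2AB_HRE1"]), 1e-11)
    expect_lt(abs(d["HRE2"] + d["HIF1AB_HRE2"] + d["HIF2AB_HRE2"]), 1e-11)
  }
})

test_that("total_alpha sums free and bound alpha subunits", {
  m <- build_default_model(12, 18)
  s <- initial_state(m)
  expect_equal(unname(total_alpha(s)),
               c(1, 5.26))  # complexes all zero at t = 0
  set.seed(3)
  for (i in 1:20) {
    s <- random_state(m)
    tot <- total_alpha(s)
    expect_equal(unname(tot["hif1a_total"]),
                 sum(s[c("HIF1A_protein", "HIF1AB", "HIF1AB_HRE1",
                         "HIF1AB_HRE2")]))
    expect_equal(unname(tot["hif2a_total"]),
                 sum(s[c("HIF2A_protein", "HIF2AB", "HIF2AB_HRE1",
                         "HIF2AB_HRE2")]))
  }
})

test_that("state and parameter validation reject bad input", {
  m <- build_default_model(12, 18)
  s <- initial_state(m)
  p <- default_params(m)
  expect_error(model_rhs(s[-1], p, 1, model = m), "missing species")
  expect_error(model_rhs(s, p[-1], 1, model = m), "missing parameter")
  s2 <- s; s2["HIF1B"] <- -1
  expect_error(model_rhs(s2, p, 1, model = m), "non-negative")
  expect_error(model_rhs(s, p, -1, model = m), "o2")
})
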