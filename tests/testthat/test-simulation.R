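test_that("zero rate constants give a constant trajectory", {
  m <- build_default_model(12, 18)
  p <- default_params(m); p[] <- 0
  s <- initial_state(m)
  tr <- simulate_model(m, p, init = s, t_grid = c(0, 5, 17, 48))
  for (sp in hif_species())
    expect_equal(tr[[sp]], rep(unname(s[[sp]]), 4), tolerance = 1e-12)
})

test_that("isolated first-order decay matches exp(-kt) to 1e-6", {
  m <- build_default_model(0, 0)
  for (k in c(0.08, 0.5, 2)) {
    p <- decay_only_params(m, k)
    s <- initial_state(m, hif1b = 0, hif2a_protein = 0, gene_mrna = 0)
    s[c("HIF1A_mrna", "HIF2A_mrna", "PHD_protein")] <- 0
    s["HIF1A_protein"] <- 1
    tr <- simulate_model(m, p, init = s, t_grid = c(0, 0.5, 1, 2, 5, 10))
    expect_equal(tr$HIF1A_protein, exp(-k * tr$time), tolerance = 1e-6)
    # the order-2 stiff stepper is held to a looser bound
    tr2 <- simulate_model(m, p, init = s, t_grid = c(0, 0.5, 1, 2, 5, 10),
                          method = "ros23")
    expect_equal(tr2$HIF1A_protein, exp(-k * tr2$time), tolerance = 1e-5)
  }
})

test_that("isolated reversible binding reaches the closed-form equilibrium", {
  m <- build_default_model(0, 0)
  p <- default_params(m); p[] <- 0
  cases <- list(c(a = 1, b = 60, kd = 1e-4),
                c(a = 2, b = 0.5, kd = 0.3),
                c(a = 5, b = 5, kd = 1))
  for (cs in cases) {
    p["hif1a_hif1b_binding.k"] <- 2
    p["hif1a_hif1b_binding.kd"] <- cs[["kd"]]
    s <- initial_state(m, hif1b = cs[["b"]], hif2a_protein = 0,
                       gene_mrna = 0)
    s[c("HIF1A_mrna", "HIF2A_mrna", "PHD_protein")] <- 0
    s["HIF1A_protein"] <- cs[["a"]]
    tr <- simulate_model(m, p, init = s, t_grid = c(0, 2000))
    ab_eq <- oracle_binding_equilibrium(cs[["a"]], cs[["b"]], cs[["kd"]])
    expect_equal(tr$HIF1AB[2], ab_eq, tolerance = 1e-4)
    # equilibrium satisfies [A][B]/[AB] = kd
    expect_equal(tr$HIF1A_protein[2] * tr$HIF1B[2] / tr$HIF1AB[2],
                 cs[["kd"]], tolerance = 1e-3)
  }
})

test_that("HRE pools are conserved along trajectories", {
  m <- build_default_model(12, 18)
  set.seed(7)
  for (i in 1:5) {
    p <- random_params(m)
    tr <- simulate_model(m, p, init = initial_state(m))
    hre1 <- tr$HRE1 + tr$HIF1AB_HRE1 + tr$HIF2AB_HRE1
    hre2 <- tr$HRE2 + tr$HIF1AB_HRE2 + tr$HIF2AB_HRE2
    expect_lt(max(abs(hre1 - 12)), 1e-6 * 12)
    expect_lt(max(abs(hre2 - 18)), 1e-6 * 18)
    expect_gt(min(as.matrix(tr[, hif_species()])), -1e-9)
  }
})

test_that("halving integrator tolerances changes outputs by < 0.1%", {
  m <- build_default_model(12, 18)
  p <- default_params(m)
  tr1 <- simulate_model(m, p, rtol = 1e-8, atol = 1e-10)
  tr2 <- simulate_model(m, p, rtol = 5e-9, atol = 5e-11)
  rel <- abs(as.matrix(tr1[, hif_species()]) -
             as.matrix(tr2[, hif_species()])) /
    pmax(abs(as.matrix(tr1[, hif_species()])), 1e-6)
  expect_lt(max(rel), 1e-3)
})

test_that("oxygen protocol steps take effect at the stated times", {
  m <- build_default_model(0, 0)
  p <- default_params(m); p[] <- 0
  p["phd_to_hif1a_protein.kcat"] <- 1
  p["phd_to_hif1a_protein.km_hif"] <- 1
  p["phd_to_hif1a_protein.km_o2"] <- 1
  s <- initial_state(m, hif1b = 0, hif2a_protein = 0, gene_mrna = 0)
  s[c("HIF1A_mrna", "HIF2A_mrna")] <- 0
  s["HIF1A_protein"] <- 1
  # no oxygen until t = 5, then plenty: decay starts only after the step
  tr <- simulate_model(m, p, init = s,
                       protocol = oxygen_protocol(c(0, 5), c(0, 1e9)),
                       t_grid = c(0, 4.9, 5, 10))
  expect_equal(tr$HIF1A_protein[tr$time == 4.9], 1, tolerance = 1e-9)
  expect_lt(tr$HIF1A_protein[tr$time == 10], 1)
  expect_error(oxygen_protocol(c(0, 5, 5), c(1, 1, 1)), "increasing")
  expect_error(oxygen_protocol(2, 1), "<= 0")
  expect_equal(o2_level_from_percent(0.3), 1 / 3)
  expect_equal(o2_level_from_percent(0.9), 1)
})

test_that("integration failure reports time and last valid state", {
  m <- build_default_model(12, 18)
  p <- default_params(m)
  p["gene_mrna_in.k"] <- 1e300  # blow up immediately
  expect_error(
    simulate_model(m, p, init = initial_state(m), t_grid = c(0, 48),
                   max_steps = 100),
    "integration failed at t")
})

test_that("titration is monotone and saturates at extreme HIF1B", {
  m <- build_default_model(12, 18)
  p <- default_params(m)
  res <- titrate_hif1b(m, p, levels = c(1, 30, 60), t_grid = c(0, 2, 8, 16))
  g16 <- vapply(res, function(tr) tr$Gene_mRNA_fold[tr$time == 16],
                numeric(1))
  expect_true(all(diff(g16) > 0))  # non-decreasing in the level
  # unlimited beta: every site occupied at late times
  hi <- titrate_hif1b(m, p, levels = 1e6, t_grid = c(0, 48))[[1]]
  expect_lt(hi$free_HRE1[2], 1e-3)
  expect_lt(hi$free_HRE2[2], 1e-3)
  # no beta and no beta inflow: gene stays at baseline 1
  p0 <- p; p0["hif1b_in.k"] <- 0
  lo <- titrate_hif1b(m, p0, levels = 0, t_grid = c(0, 16, 48))[[1]]
  expect_equal(lo$Gene_mRNA_fold, rep(1, 3), tolerance = 1e-8)
  # per-level parameter lists are accepted
  two <- titrate_hif1b(m, list(p, p0), levels = c(30, 0),
                       t_grid = c(0, 16))
  expect_length(two, 2L)
  expect_error(titrate_hif1b(m, list(p), levels = c(1, 30)), "one parameter")
})

test_that("gene induction is monotone in HRE counts", {
  p <- default_params(build_default_model(1, 1))
  f <- vapply(c(1, 5, 20), function(n) {
    predict_gene(p, n, n, hif1b_init = 60, t_obs = 16)[[1]]
  }, numeric(1))
  expect_true(all(diff(f) > 0))
})

test_that("induction above baseline is linear in HRE count when beta is in excess", {
  # weak binding + huge HIF1B: occupancy ~ proportional to site count
  m1 <- build_default_model(1, 0)
  p <- default_params(m1)
  p[grep("hre[12]_binding\\.k$", names(p))] <- 1e-4
  gain <- vapply(c(1, 2, 10, 30), function(n) {
    pg <- predict_gene(p, n, 0, hif1b_init = 1e5, t_obs = 16)
    pg[[1]] - 1
  }, numeric(1))
  per_site <- gain / c(1, 2, 10, 30)
  expect_lt(max(per_site) / min(per_site) - 1, 0.05)
})

test_that("predict_gene normalizes to 1 at 0 h and rejects bad counts", {
  p <- default_params(build_default_model(12, 18))
  f <- predict_gene(p, 12, 18, 60)
  expect_identical(unname(f["0h"]), 1)
  expect_named(f, c("0h", "2h", "8h", "16h"))
  expect_error(predict_gene(p, -3, 18, 60), "non-negative")
})
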