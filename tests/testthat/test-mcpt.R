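RT300 <- 0.0019872041 * 300
LN10 <- log(10)

test_that("membrane self-energy reproduces its closed forms", {
  # deep burial plateau
  expect_equal(membrane_self_energy(40, 25), 15)
  expect_equal(membrane_self_energy(0, 25), 0)
  # Gaussian solvent switch
  expect_equal(membrane_self_energy(40, 6), 15 * exp(-1))
  # sparse-contact attenuation
  expect_equal(membrane_self_energy(20, 25), 15 * exp(-0.2 * 8))
  expect_error(membrane_self_energy(-1, 5), "non-negative")
  expect_error(membrane_self_energy(5, 0), "positive")
})

test_that("self-energy composes neighbour and membrane contributions", {
  expect_equal(self_energy(list(n_p = 0, n_np = 0, n_mem = 0,
                                r_min = 10)), 0)
  expect_equal(self_energy(list(n_p = 4, n_np = 0, n_mem = 0,
                                r_min = 10)), -0.6)
  env <- list(n_p = 2, n_np = 3, n_mem = 40, r_min = 25)
  expect_equal(self_energy(env),
               -0.15 * 2 + 0.35 * 3 + 15)
})

test_that("self-energy is monotone in burial, and so are the pKa shifts", {
  u <- sapply(0:40, function(n) self_energy(
    list(n_p = 1, n_np = 2, n_mem = n, r_min = 25)))
  expect_true(all(diff(u) >= 0))
  pka_acid <- sapply(u, function(g) pka_in_protein("ASP", g)$pka_b)
  pka_base <- sapply(u, function(g) pka_in_protein("LYS", g)$pka_b)
  expect_true(all(diff(pka_acid) >= 0))
  expect_true(all(diff(pka_base) <= 0))
})

test_that("in-protein pKa shifts follow the sign rule", {
  expect_equal(pka_in_protein("ASP", 0)$pka_b, 4.0)
  unit <- LN10 * RT300  # self-energy worth exactly one pH unit
  expect_equal(pka_in_protein("ASP", unit)$pka_b, 5.0)
  expect_equal(pka_in_protein("LYS", unit)$pka_b, 9.5)
  expect_equal(pka_in_protein("HIS", unit)$pka_b, 5.5)
  expect_error(pka_in_protein("ALA", 1), "non-ionizable")
})

test_that("configuration energies follow the closed form", {
  expect_equal(charge_config_energy(c(0, 0), c(4, 10.5), 7), 0)
  # one charged Asp with pKa_b = pH - 1
  expect_equal(charge_config_energy(-1, 6, 7), -LN10 * RT300)
  # two unit charges 10 A apart at eps_eff = 40
  k <- matrix(c(0, 332 / (40 * 10), 332 / (40 * 10), 0), 2, 2)
  expect_equal(charge_config_energy(c(-1, 1), c(7, 7), 7, k),
               -332 / 400)
  expect_equal(charge_config_energy(c(-1, -1), c(7, 7), 7, k),
               332 / 400)
})

test_that("a system without ionizable sites returns the neutral state", {
  cg <- coarse_grain(make_bundle(fixture_spec(
    n_helices = 1, helix_length = 6, sequence = "LEU")))
  ion <- mcpt_sample(cg, NULL, steps = 100, seed = 1)
  expect_equal(nrow(ion$residues), 0)
  expect_equal(ion$g_elec_min, 0)
  expect_equal(electrostatic_folding_term(ion), 0)
})

test_that("sampling is bit-reproducible for a fixed seed", {
  cg <- make_titration_system(3, c(4, 6.5, 10.5),
                              positions = rbind(c(0, 0, 0), c(6, 0, 0),
                                                c(0, 7, 0)))
  i1 <- mcpt_sample(cg, NULL, steps = 20000, seed = 99)
  i2 <- mcpt_sample(cg, NULL, steps = 20000, seed = 99)
  expect_identical(i1$residues, i2$residues)
  expect_identical(i1$g_elec_min, i2$g_elec_min)
  expect_identical(i1$config_freq, i2$config_freq)
})

test_that("single-site titration follows Henderson-Hasselbalch", {
  cg <- make_titration_system(1, 4.0)
  phs <- seq(1, 7, by = 1)
  for (i in seq_along(phs)) {
    ion <- mcpt_sample(cg, NULL, ph = phs[i], steps = 2e5,
                       seed = 100 + i)
    hh <- 1 / (1 + 10^(4.0 - phs[i]))
    expect_lt(abs(abs(ion$residues$q_mc) - hh), 0.02)
  }
  # strong ionization limit: pH = pKa + 3
  ion <- mcpt_sample(cg, NULL, ph = 7, steps = 2e5, seed = 41)
  expect_lt(abs(ion$residues$q_mc - (-0.999)), 0.002)
})

test_that("distant sites titrate independently", {
  # far enough that the screened Coulomb coupling (332 / (40 r)) is
  # negligible against RT
  cg <- make_titration_system(2, c(6.8, 7.3), kinds = c("acid", "base"),
                              positions = rbind(c(0, 0, 0),
                                                c(500, 0, 0)))
  ion <- mcpt_sample(cg, NULL, ph = 7, steps = 2e5, seed = 5)
  p1 <- 1 / (1 + 10^(6.8 - 7))       # acid charged fraction
  p2 <- 1 / (1 + 10^(7 - 7.3))       # base charged fraction
  joint <- ion$config_freq[["cc"]]
  expect_lt(abs(joint - p1 * p2), 0.02)
})

test_that("a close opposite pair is enriched beyond independence", {
  cg <- make_titration_system(2, c(7, 7), kinds = c("acid", "base"),
                              positions = rbind(c(0, 0, 0), c(4, 0, 0)))
  ion <- mcpt_sample(cg, NULL, ph = 7, steps = 1e5, seed = 13)
  # exact Boltzmann over the 4 configurations using the sampler's own
  # Hamiltonian (site terms at the reported pKa_b plus the pair coupling)
  k12 <- 332 / (40 * 4)
  h <- -LN10 * RT300 *
    c(-1, +1) * (ion$residues$pka_b - 7)
  e <- c(nn = 0, cn = h[1], nc = h[2], cc = h[1] + h[2] - k12)
  p <- exp(-e / RT300) / sum(exp(-e / RT300))
  expect_gt(ion$config_freq[["cc"]],
            (p[["cn"]] + p[["cc"]]) * (p[["nc"]] + p[["cc"]]))
  for (nm in names(p)) {
    expect_lt(abs(ion$config_freq[[nm]] - p[[nm]]), 0.02)
  }
})

test_that("the electrostatic folding term assembles and superposes", {
  cg <- make_titration_system(2, c(4, 10.5))
  ion <- mcpt_sample(cg, NULL, ph = 7, steps = 50000, seed = 3)
  # no environment: pKa_b = pKa_w, so the pKa-shift sum vanishes and
  # only the (mean-field) folded charge-charge term remains
  expect_close(electrostatic_folding_term(ion), ion$g_qq_mf, tol = 1e-9)
  expect_equal(electrostatic_folding_term(ion, qq_unfolded = 2,
                                          q_dev = 0.5),
               electrostatic_folding_term(ion) - 2 + 0.5)

  # hand-built single-residue term: Q = -1, pKa_b - pKa_w = +1
  ion1 <- structure(list(
    residues = data.frame(chain = "A", resno = 1, resid = "ASP",
                          pka_w = 4, dg_self = LN10 * RT300, pka_b = 5,
                          q_mc = -1),
    g_qq_mf = 0, g_qq_mean = 0, temperature = 300),
    class = "flip_ionization")
  expect_equal(electrostatic_folding_term(ion1), LN10 * RT300)

  # additivity over independent residues
  ion2 <- ion1
  ion2$residues <- rbind(ion1$residues,
                         transform(ion1$residues, resno = 2, q_mc = 1,
                                   pka_b = 3.5, pka_w = 4))
  expect_close(electrostatic_folding_term(ion2),
               electrostatic_folding_term(ion1) +
                 (-LN10 * RT300 * 1 * (3.5 - 4)))
})
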