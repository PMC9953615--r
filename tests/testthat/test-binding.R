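test_that("ligand tables validate and round-trip", {
  lig <- make_toy_lipid(headgroup_charge = -1, tail_length = 10)
  expect_equal(nrow(lig$atoms), 11)
  expect_lt(abs(sum(lig$atoms$charge) - (-1)), 1e-9)
  f <- tempfile(fileext = ".tsv")
  write_ligand(lig, f)
  lig2 <- read_ligand(f)
  expect_equal(lig2$atoms$charge, lig$atoms$charge)
  expect_close(as.matrix(lig2$atoms[, c("x", "y", "z")]),
               as.matrix(lig$atoms[, c("x", "y", "z")]), tol = 1e-9)
  unlink(f)
  bad <- lig$atoms
  expect_error(read_ligand(bad, total_charge = -2), "sum to")
  expect_error(read_ligand(bad[, 1:4]), "lacks column")
})

test_that("the effective potential honours its gates and identities", {
  prot <- make_bundle(fixture_spec(n_helices = 2, helix_length = 8,
                                   channel_radius = 6))
  lig <- make_toy_lipid(headgroup_charge = -1, tail_length = 3)
  lig$atoms$x <- lig$atoms$x + 3  # sit near the bundle

  # uncharged state: only the (charge-free) intramolecular term remains,
  # which is itself zero, so bound and unbound coincide at 0
  expect_equal(pdlds_potential(prot, lig, charged = FALSE), 0)
  expect_equal(pdlds_potential(NULL, lig, charged = FALSE,
                               bound = FALSE), 0)

  # eps_p = eps_w kills every solvation-difference term: the bound
  # potential reduces to charge-dipole + intra + full ligand solvation
  u_eq <- pdlds_potential(prot, lig, eps_p = 80, eps_w = 80)
  lxyz <- as.matrix(lig$atoms[, c("x", "y", "z")])
  pxyz <- as.matrix(prot$atoms[, c("x", "y", "z")])
  expect_true(is.finite(u_eq))
  expect_error(pdlds_potential(prot, lig, eps_p = 100, eps_w = 80),
               "eps_w >= eps_p")
})

test_that("the charge-dipole term matches a hand Coulomb sum", {
  # one +1 ligand charge 5 A from a +/- backbone dipole pair
  lig <- read_ligand(data.frame(name = "Q1", element = "P",
                                x = 0, y = 0, z = 0, charge = 1))
  at <- data.frame(
    eleno = 1:2, elety = c("C", "O"), resid = "GLY", chain = "A",
    resno = 1, x = c(5, 6.2), y = 0, z = 0, o = 1, b = 0,
    elesy = c("C", "O"))
  prot <- structure(list(atoms = at, het = at[0, ]),
                    class = "flip_structure")
  # package table: C +0.45, O -0.45; eps_p = 4
  hand <- (332 * 1 * 0.45 / 5 + 332 * 1 * (-0.45) / 6.2) / 4
  got <- pdlds_potential(prot, lig, eps_p = 4, eps_w = 80)
  # subtract the protein-free contribution to isolate the dipole term
  alone <- pdlds_potential(NULL, lig, charged = TRUE,
                           eps_p = 4, eps_w = 80, bound = FALSE)
  born_diff <- got - alone - hand
  # the remainder is the burial-dependent Born correction: one context
  # atom (the C at 5 A) sits inside the 6 A contact radius
  g_ctx <- -166 * 1 / (2 * (1 + 1 / 10))
  g_free <- -166 * 1 / 2
  expect_close(born_diff, (g_ctx - g_free) * (1 / 4 - 1 / 80),
               tol = 1e-9)
})

test_that("linear-response averaging follows the half-sum rule", {
  expect_equal(lra_electrostatic(3, 3, 3, 3), 0)
  expect_equal(lra_electrostatic(10, 2, 4, 0), 4)
  lam <- 2.5
  expect_equal(lra_electrostatic(10 * lam, 2 * lam, 4 * lam, 0),
               4 * lam)
})

test_that("the scaled vdW closure reproduces its arithmetic", {
  expect_equal(binding_free_energy(0, 0, 0), 0)
  expect_equal(binding_free_energy(0, -8, 0, beta = 0.25), -2)
  expect_equal(binding_free_energy(-3, 4, 0, beta = 0.25), -2)
  expect_equal(binding_free_energy(5, 100, 100, beta = 0.25), 5)
  expect_error(binding_free_energy(0, 0, 0, beta = 2), "beta")
})

test_that("ensembles are deterministic and degenerate correctly", {
  prot <- make_bundle(fixture_spec(n_helices = 2, helix_length = 8,
                                   channel_radius = 6))
  lig <- make_toy_lipid(tail_length = 3)
  e1 <- configuration_ensemble(prot, lig, n_conf = 5, jitter = 0.3,
                               seed = 17)
  e2 <- configuration_ensemble(prot, lig, n_conf = 5, jitter = 0.3,
                               seed = 17)
  expect_identical(e1$dg_bind, e2$dg_bind)
  expect_identical(e1$u_bound_charged, e2$u_bound_charged)

  # jitter 0: any ensemble size equals the single-point evaluation
  e0a <- configuration_ensemble(prot, lig, n_conf = 1, jitter = 0, seed = 1)
  e0b <- configuration_ensemble(prot, lig, n_conf = 7, jitter = 0, seed = 9)
  expect_close(e0a$dg_bind, e0b$dg_bind)
  expect_close(e0a$u_bound_charged,
               pdlds_potential(prot, lig, charged = TRUE))
  # invariant of the result container
  expect_close(e0a$dg_bind,
               e0a$dg_elec + e0a$beta * (e0a$vdw_bound - e0a$vdw_unbound))
})

test_that("zero ligand charge removes the electrostatic binding term", {
  prot <- make_bundle(fixture_spec(n_helices = 2, helix_length = 8,
                                   channel_radius = 6))
  lig0 <- make_toy_lipid(headgroup_charge = 0, tail_length = 4)
  e <- configuration_ensemble(prot, lig0, n_conf = 4, jitter = 0.2,
                              seed = 3)
  expect_equal(e$dg_elec, 0)
  expect_close(e$dg_bind, 0.25 * e$vdw_bound)
  # beta continuity: beta = 0 leaves only the electrostatic part
  e0 <- configuration_ensemble(prot, lig0, n_conf = 4, jitter = 0.2,
                               seed = 3, beta = 0)
  expect_equal(e0$dg_bind, e0$dg_elec)
})

test_that("a far-separated ligand does not bind", {
  prot <- make_bundle(fixture_spec(n_helices = 2, helix_length = 8,
                                   channel_radius = 6))
  lig <- make_toy_lipid(headgroup_charge = -1, tail_length = 4)
  lig$atoms$z <- lig$atoms$z + 60  # > 30 A from every protein atom
  e <- configuration_ensemble(prot, lig, n_conf = 5, jitter = 0.2,
                              seed = 8)
  expect_lt(abs(e$dg_bind), 0.05)
})
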