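test_that("hydrophobic burial reward follows its clamped closed form", {
  cg <- make_titration_system(2, c(4, 10.5))  # all-polar system
  expect_equal(hydrophobic_term(cg, NULL), c(0, 0))

  cg1 <- coarse_grain(make_bundle(fixture_spec(
    n_helices = 1, helix_length = 5, sequence = "LEU")))
  # hand-set counts through env_table injection
  et <- data.frame(n_p = 0, n_np = 3, n_mem = 0, r_min = Inf)
  et <- et[rep(1, 5), ]
  expect_equal(hydrophobic_term(cg1, NULL, env_table = et),
               rep(-0.6, 5))
  et$n_np <- 20
  et2 <- et; et2$n_np <- 8
  expect_equal(hydrophobic_term(cg1, NULL, env_table = et),
               hydrophobic_term(cg1, NULL, env_table = et2))
})

test_that("polar desolvation penalises only buried polar residues", {
  cg <- make_titration_system(1, 4.0)  # polar pseudo-residue
  et <- data.frame(n_p = 0, n_np = 0, n_mem = 0, r_min = 5)
  expect_equal(polar_term(cg, NULL, env_table = et), 0)
  et$n_mem <- 30
  expect_equal(polar_term(cg, NULL, env_table = et),
               0.05 * 30 * exp(-((5 - 18) / 12)^2))
  et$r_min <- 25  # fully buried: switch saturates at 1
  expect_equal(polar_term(cg, NULL, env_table = et), 1.5)

  cgl <- coarse_grain(make_bundle(fixture_spec(
    n_helices = 1, helix_length = 3, sequence = "LEU")))
  etl <- data.frame(n_p = 0, n_np = 0, n_mem = 30, r_min = 25)[rep(1, 3), ]
  expect_equal(polar_term(cgl, NULL, env_table = etl), rep(0, 3))
})

test_that("the 8-6 potential bottoms out at exactly -eps and vanishes far", {
  cg <- make_titration_system(2, c(4, 4))
  r0 <- 2.4 + 2.4  # ASP + ASP contact radii
  cg$X.x <- c(0, r0)  # pair at the minimum distance
  v <- vdw_terms(cg, eps_ss = 0.1)
  expect_close(sum(v$side_side), -0.1)
  expect_close(v$side_side[1], v$side_side[2])  # halved onto partners

  cg$X.x <- c(0, 50)
  cg$CA.x <- cg$N.x <- cg$C.x <- cg$O.x <- cg$X.x
  v <- vdw_terms(cg)
  expect_equal(sum(abs(v$side_side)), 0)
  expect_equal(sum(abs(v$main_side)), 0)
})

test_that("vdW energies are symmetric and clashes stay finite", {
  pair <- toy_pair(helix_length = 8)
  cg <- coarse_grain(pair$a)
  v1 <- vdw_terms(cg)
  cg_rev <- cg[rev(seq_len(nrow(cg))), ]
  class(cg_rev) <- class(cg)
  v2 <- vdw_terms(cg_rev)
  expect_close(v1$side_side, rev(v2$side_side), tol = 1e-9)

  clash <- make_titration_system(2, c(4, 4))
  clash$X.x <- c(0, 0.1)
  expect_warning(v <- vdw_terms(clash), "clash")
  expect_true(all(is.finite(v$side_side)))
})

test_that("ideal helices show i->i+4 backbone hydrogen bonds", {
  cg <- coarse_grain(make_bundle(fixture_spec(
    n_helices = 1, helix_length = 12, sequence = "LEU")))
  hs <- hb_and_solvation_terms(cg, NULL)
  # every donor from residue 5 onward reaches the carbonyl 4 back
  expect_true(all(hs$hb[5:12] < 0))
  expect_close(sum(hs$hb), -1.0 * 8)  # 8 bonds at -1 kcal/mol each

  # fully extended chain: no donors in the window
  ext <- cg
  for (site in c("N", "CA", "C", "O", "X", "D")) {
    ext[[paste0(site, ".x")]] <- seq(0, by = 3.8, length.out = 12)
    ext[[paste0(site, ".y")]] <- 0
    ext[[paste0(site, ".z")]] <- 0
  }
  ext$N.y <- 1.2; ext$O.y <- -1.2
  expect_equal(sum(abs(hb_and_solvation_terms(ext, NULL)$hb)), 0)

  # backbone outside the slab pays no solvation penalty
  env <- build_membrane_grid(cg, z_lo = -50, z_hi = -40)
  expect_equal(sum(hb_and_solvation_terms(cg, env)$solv), 0)
})

test_that("ledger assembly applies the published scaling coefficients", {
  z <- rep(0, 4)
  led <- total_folding_energy(z, z, z, z, z, z, z)
  expect_equal(led$dg_fold, 0)
  led <- total_folding_energy(z, z, z, rep(2.5, 4), z, z, z)
  expect_equal(led$dg_fold, 0.10 * 10)
  led <- total_folding_energy(z, z, z, z, rep(2.5, 4), rep(2.5, 4), z)
  expect_equal(led$dg_fold, 0.25 * 10 + 0.15 * 10)
  expect_error(total_folding_energy(z, NULL, z, z, z, z, z), "missing")
})

test_that("scaled components double when raw components double", {
  z <- rep(1.3, 5)
  l1 <- total_folding_energy(z, z, z, z, z, z, z)
  l2 <- total_folding_energy(z, z, z, 2 * z, 2 * z, 2 * z, z)
  scaled1 <- l1$dg_fold - sum(z) * 4  # minus elec, polar, hyd, main-side
  scaled2 <- l2$dg_fold - sum(z) * 4
  expect_close(scaled2, 2 * scaled1)
})

test_that("per-residue entries conserve the structure totals", {
  pair <- toy_pair()
  for (s in list(pair$a, pair$b)) {
    cg <- coarse_grain(s)
    env <- build_membrane_grid(cg)
    led <- cg_folding_energy(cg, env, steps = 5000, seed = 7)
    expect_close(sum(led$per_residue$total), led$dg_fold, tol = 1e-6)
    for (comp in c("elec", "polar", "hyd", "vdw_side", "solv_cg",
                   "hb_cg", "vdw_main_side")) {
      expect_close(sum(led$per_residue[[comp]]),
                   unname(led$totals[comp]), tol = 1e-6)
    }
  }
})

test_that("the non-membrane terms are rigid-motion invariant", {
  pair <- toy_pair(helix_length = 10)
  cg <- coarse_grain(pair$a)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1),
                3, 3)
  cg2 <- cg
  for (site in c("N", "CA", "C", "O", "X", "D")) {
    cols <- paste(site, c("x", "y", "z"), sep = ".")
    cg2[, cols] <- sweep(as.matrix(cg[, cols]) %*% t(rot), 2,
                         c(5, -3, 0), "+")
  }
  v1 <- vdw_terms(cg); v2 <- vdw_terms(cg2)
  expect_close(v1$side_side, v2$side_side)
  expect_close(v1$main_side, v2$main_side)
  h1 <- hb_and_solvation_terms(cg, NULL)
  h2 <- hb_and_solvation_terms(cg2, NULL)
  expect_close(h1$hb, h2$hb)
})

test_that("the full ledger is invariant under in-plane translation", {
  pair <- toy_pair(helix_length = 10)
  a <- pair$a
  b <- a
  b$atoms$x <- b$atoms$x + 7.3
  b$atoms$y <- b$atoms$y - 4.1
  cga <- coarse_grain(a); cgb <- coarse_grain(b)
  la <- cg_folding_energy(cga, build_membrane_grid(cga),
                          steps = 5000, seed = 21)
  lb <- cg_folding_energy(cgb, build_membrane_grid(cgb),
                          steps = 5000, seed = 21)
  expect_close(la$dg_fold, lb$dg_fold, tol = 1e-6)
})

test_that("difference decomposition is local and conservative", {
  pair <- toy_pair(helix_length = 10)
  cg <- coarse_grain(pair$a)
  env <- build_membrane_grid(cg)
  ion <- mcpt_sample(cg, env, steps = 5000, seed = 2)
  la <- cg_folding_energy(cg, env, ion = ion)
  expect_equal(sum(abs(decompose_difference(la, la, Inf)$d_total)), 0)

  # perturb one residue's side-chain centre
  cg2 <- cg
  k <- 15
  cg2$X.x[k] <- cg2$X.x[k] + 2
  lb <- cg_folding_energy(cg2, env, ion = ion)
  d <- decompose_difference(la, lb, Inf)
  expect_close(sum(d$d_total), lb$dg_fold - la$dg_fold, tol = 1e-6)
  # the perturbed residue or an interaction partner dominates
  xk <- cg_xyz(cg, "X")[k, ]
  dx <- sqrt(colSums((t(cg_xyz(cg, "X")) - xk)^2))
  expect_true(dx[which(cg$chain == d$chain[1] &
                         cg$resno == d$resno[1])] <= 12)
  # mismatched residue sets are rejected
  lc <- cg_folding_energy(coarse_grain(toy_pair(helix_length = 6)$a),
                          NULL, steps = 1000, seed = 1)
  expect_error(decompose_difference(la, lc), "different residue")
})
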