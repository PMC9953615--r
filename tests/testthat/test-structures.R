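test_that("minimal PDB inputs parse with correct annotations", {
  s <- read_structure(pdb_ala_text())
  rt <- residue_table(s)
  expect_equal(nrow(rt), 1)
  expect_equal(nrow(s$atoms), 5)
  expect_false(rt$ionizable)

  s <- read_structure(pdb_asp_text())
  rt <- residue_table(s)
  expect_true(rt$ionizable)
  expect_equal(rt$pka_w, 4.0)
  expect_true(rt$polar)
})

test_that("structured errors name the offending residue or line", {
  expect_error(read_structure(pdb_missing_backbone_text()),
               "GLY A:2.*CA|missing backbone")
  bad <- c(pdb_ala_text()[1:3], "ATOM      9 XX   ALA A   1     bad", "END")
  expect_error(read_structure(bad), "line 4")
})

test_that("write->read round-trip preserves residues and coordinates", {
  b <- make_bundle(fixture_spec(n_helices = 2, helix_length = 8,
                                channel_radius = 6))
  f <- tempfile(fileext = ".pdb")
  write_structure(b, f)
  s2 <- read_structure(f)
  expect_equal(nrow(s2$atoms), nrow(b$atoms))
  expect_equal(s2$atoms$resno, b$atoms$resno)
  expect_equal(s2$atoms$resid, b$atoms$resid)
  expect_equal(s2$atoms$elety, b$atoms$elety)
  expect_close(as.matrix(s2$atoms[, c("x", "y", "z")]),
               as.matrix(b$atoms[, c("x", "y", "z")]), tol = 1e-3)
  unlink(f)
})

test_that("altloc records resolve to the highest-occupancy copy", {
  lines <- pdb_ala_text()
  # duplicate the CB with an altloc pair at different occupancy
  cb_a <- "ATOM      5 CB  AALA A   1       1.900  -0.800   1.200  0.40  0.00           C"
  cb_b <- "ATOM      6 CB  BALA A   1       9.000   9.000   9.000  0.60  0.00           C"
  lines <- c(lines[1:4], cb_a, cb_b, "END")
  s <- read_structure(lines)
  cb <- s$atoms[s$atoms$elety == "CB", ]
  expect_equal(nrow(cb), 1)
  expect_equal(cb$x, 9.0)
})

test_that("coarse-graining places X and D by the centroid/shift rules", {
  leu <- coarse_grain(read_structure(pdb_leu_text()))
  side <- rbind(c(2.0, -1.0, 1.0), c(3.5, -1.2, 1.1),
                c(4.2, -0.1, 1.9), c(4.1, -2.5, 1.5))
  expect_close(cg_xyz(leu, "X")[1, ], colMeans(side))

  s <- read_structure(pdb_asp_text())
  side <- rbind(c(2.0, -1.0, 1.0), c(3.5, -1.2, 1.1),
                c(4.2, -0.3, 1.6), c(4.0, -2.3, 0.7))
  grp <- rbind(c(3.5, -1.2, 1.1), c(4.2, -0.3, 1.6), c(4.0, -2.3, 0.7))
  full <- coarse_grain(s, shift_fraction = 1)
  expect_close(cg_xyz(full, "X")[1, ], colMeans(grp))
  half <- coarse_grain(s, shift_fraction = 0.5)
  expect_close(cg_xyz(half, "X")[1, ],
               (colMeans(side) + colMeans(grp)) / 2)
  # D on the CA-X segment, at the midpoint
  expect_close(cg_xyz(half, "D")[1, ],
               (c(1.46, 0, 0) + cg_xyz(half, "X")[1, ]) / 2)
})

test_that("coarse-graining is idempotent on the X sites", {
  cg <- coarse_grain(toy_pair(helix_length = 6)$a)
  # rebuild a structure whose only side-chain heavy atom is X itself
  at <- NULL
  for (i in seq_len(nrow(cg))) {
    for (site in c("N", "CA", "C", "O")) {
      at <- rbind(at, data.frame(eleno = 0, elety = site,
                                 resid = cg$resid[i], chain = cg$chain[i],
                                 resno = cg$resno[i],
                                 x = cg[[paste0(site, ".x")]][i],
                                 y = cg[[paste0(site, ".y")]][i],
                                 z = cg[[paste0(site, ".z")]][i],
                                 o = 1, b = 0, elesy = substr(site, 1, 1)))
    }
    at <- rbind(at, data.frame(eleno = 0, elety = "CB",
                               resid = cg$resid[i], chain = cg$chain[i],
                               resno = cg$resno[i],
                               x = cg$X.x[i], y = cg$X.y[i], z = cg$X.z[i],
                               o = 1, b = 0, elesy = "C"))
  }
  s2 <- structure(list(atoms = at, het = at[0, ]), class = "flip_structure")
  cg2 <- coarse_grain(s2)
  expect_close(cg_xyz(cg2, "X"), cg_xyz(cg, "X"))
})

test_that("superposition matches the eigen-decomposition oracle", {
  a <- matrix(c(0, 0, 0, 1.5, 0, 0, 0.4, 2.1, -0.3), 3, 3, byrow = TRUE)
  expect_equal(superpose_rmsd(a, a)$rmsd, 0)
  shifted <- sweep(a, 2, c(3, -2, 7), "+")
  expect_close(superpose_rmsd(a, shifted, fit = TRUE)$rmsd, 0)
  expect_equal(superpose_rmsd(a, shifted, fit = FALSE)$rmsd,
               sqrt(sum(c(3, -2, 7)^2)))

  set.seed(11)
  for (rep in 1:5) {
    b <- a + matrix(rnorm(9, sd = 0.4), 3, 3)
    expect_close(superpose_rmsd(a, b)$rmsd, quaternion_rmsd(a, b))
    # symmetry
    expect_close(superpose_rmsd(a, b)$rmsd, superpose_rmsd(b, a)$rmsd)
  }
  expect_error(superpose_rmsd(a, a[1:2, ]), "length")
})

test_that("CA distances follow Euclid and fixture geometry", {
  lines <- c(pdb_residue_text("ALA", list(CB = c(1, 1, 1))),
             pdb_atom_line(7, "N", "GLY", "A", 2, -1, 3, 0),
             pdb_atom_line(8, "CA", "GLY", "A", 2, 4.46, 4, 0),
             pdb_atom_line(9, "C", "GLY", "A", 2, 0, 5, 0),
             "END")
  s <- read_structure(lines)
  # CA1 = (1.46, 0, 0), CA2 = (4.46, 4, 0): a 3-4-5 triangle
  expect_close(ca_distance(s, "A:1", "A:2"), 5)
  expect_equal(ca_distance(s, "A:1", "A:1"), 0)
  expect_error(ca_distance(s, "B:9", "A:1"), "selector")

  pair <- toy_pair()
  d_closed <- ca_distance(pair$a, "A:10", "C:10")
  d_open <- ca_distance(pair$b, "A:10", "C:10")
  expect_gt(d_open, d_closed)
})
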