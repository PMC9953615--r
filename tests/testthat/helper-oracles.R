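# Independent oracles and tiny text fixtures used across the suite.

# --- quaternion (Horn) best-fit RMSD: eigen-decomposition route,
#     independent of the svd-Kabsch implementation under test
quaternion_rmsd <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  n <- nrow(a)
  a0 <- sweep(a, 2, colMeans(a))
  b0 <- sweep(b, 2, colMeans(b))
  m <- crossprod(a0, b0)
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,       -sxx - syy + szz),
    4, 4, byrow = TRUE)
  lmax <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(a0^2) + sum(b0^2) - 2 * lmax) / n
  sqrt(max(msd, 0))
}

# --- brute-force minimax oracle on an 8-connected grid: a path with
#     maximum <= T exists iff start and end are connected in the
#     subgraph of cells <= T, so try every candidate threshold in
#     ascending order with an exhaustive flood fill. Independent of the
#     widest-path search under test.
brute_force_minimax <- function(g, start, end) {
  n <- nrow(g); m <- ncol(g)
  flood_connected <- function(thr) {
    ok <- g <= thr
    if (!ok[start[1], start[2]] || !ok[end[1], end[2]]) return(FALSE)
    reach <- matrix(FALSE, n, m)
    reach[start[1], start[2]] <- TRUE
    repeat {
      grew <- FALSE
      for (i in 1:n) for (j in 1:m) {
        if (reach[i, j] || !ok[i, j]) next
        i0 <- max(1, i - 1); i1 <- min(n, i + 1)
        j0 <- max(1, j - 1); j1 <- min(m, j + 1)
        if (any(reach[i0:i1, j0:j1])) {
          reach[i, j] <- TRUE
          grew <- TRUE
        }
      }
      if (!grew) break
    }
    reach[end[1], end[2]]
  }
  for (thr in sort(unique(as.numeric(g)))) {
    if (flood_connected(thr)) return(thr - g[start[1], start[2]])
  }
  stop("no connecting threshold found")
}

# --- minimal hand-written PDB records
pdb_atom_line <- function(serial, name, resn, chain, resi, x, y, z,
                          occ = 1, b = 0, elem = substr(name, 1, 1)) {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resn, chain, resi, x, y, z, occ, b, elem)
}

# a single residue with explicit side-chain coordinates
pdb_residue_text <- function(resn, side_atoms, chain = "A", resi = 1,
                             serial0 = 0) {
  bb <- list(N = c(0, 0, 0), CA = c(1.46, 0, 0), C = c(2.0, 1.4, 0),
             O = c(1.5, 2.5, 0))
  atoms <- c(bb, side_atoms)
  lines <- character(0)
  for (i in seq_along(atoms)) {
    lines <- c(lines, pdb_atom_line(serial0 + i, names(atoms)[i], resn,
                                    chain, resi, atoms[[i]][1],
                                    atoms[[i]][2], atoms[[i]][3]))
  }
  lines
}

pdb_ala_text <- function() {
  c(pdb_residue_text("ALA", list(CB = c(1.9, -0.8, 1.2))), "END")
}

pdb_asp_text <- function() {
  side <- list(CB = c(2.0, -1.0, 1.0), CG = c(3.5, -1.2, 1.1),
               OD1 = c(4.2, -0.3, 1.6), OD2 = c(4.0, -2.3, 0.7))
  c(pdb_residue_text("ASP", side), "END")
}

pdb_leu_text <- function() {
  side <- list(CB = c(2.0, -1.0, 1.0), CG = c(3.5, -1.2, 1.1),
               CD1 = c(4.2, -0.1, 1.9), CD2 = c(4.1, -2.5, 1.5))
  c(pdb_residue_text("LEU", side), "END")
}

# dipeptide with one missing CA in residue 2 (invalid backbone)
pdb_missing_backbone_text <- function() {
  l1 <- pdb_residue_text("ALA", list(CB = c(1.9, -0.8, 1.2)))
  l2 <- c(pdb_atom_line(10, "N", "GLY", "A", 2, 4, 0, 0),
          pdb_atom_line(11, "C", "GLY", "A", 2, 6, 1, 0))
  c(l1, l2, "END")
}

# small default fixture shared by several files
toy_pair <- function(...) make_two_state_pair(fixture_spec(...))

expect_close <- function(x, y, tol = 1e-9) {
  expect_true(all(abs(x - y) <= tol),
              label = sprintf("max|diff| = %g", max(abs(x - y))))
}
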