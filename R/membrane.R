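## Implicit membrane: a uniform lattice of pseudo-atoms filling a slab,
## with protein-excluded points removed, plus an implicit solvent lattice
## (the same lattice outside the slab) used only for the distance-to-solvent
## of the self-energy switch.

#' Build the implicit membrane grid around a structure
#'
#' Fills the membrane slab `z_lo <= z <= z_hi` with a cubic lattice of
#' membrane pseudo-atoms and removes every point within `exclusion` of a
#' protein heavy atom, so no grid particle is constructed inside or against
#' the protein. Lattice points of the same bounding box lying outside the
#' slab represent bulk solvent; they are used to measure each residue's
#' distance to the nearest solvent and are excluded from the protein
#' interior with a fixed 2 Angstrom contact radius.
#'
#' The membrane normal is the z axis: input structures must be membrane
#' oriented (slab-aligned frames, as cryo-EM membrane-protein coordinates
#' conventionally are).
#'
#' @param s a `flip_cg`, a `flip_structure`, or `NULL` for an empty box.
#' @param z_lo,z_hi slab bounds in Angstrom (`z_lo < z_hi`).
#' @param spacing lattice constant in Angstrom (default 3).
#' @param exclusion protein exclusion radius for membrane points in
#'   Angstrom (default 4).
#' @param xy_box optional `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   protein xy bounding box plus `margin`.
#' @param margin box margin around the protein in Angstrom (default 12).
#' @param solvent_depth thickness of the solvent lattice beyond each slab
#'   face in Angstrom (default 12).
#' @return an object of class `flip_membrane`: list with `points` and
#'   `solvent` coordinate matrices and the grid parameters.
#' @export
build_membrane_grid <- function(s = NULL, z_lo = -15, z_hi = 15,
                                spacing = 3, exclusion = 4,
                                xy_box = NULL, margin = 12,
                                solvent_depth = 12) {
  if (z_lo >= z_hi) stop("z_lo must be < z_hi")
  if (spacing <= 0) stop("spacing must be positive")
  heavy <- .heavy_coords(s)
  if (is.null(xy_box)) {
    if (is.null(heavy) || nrow(heavy) == 0) {
      xy_box <- c(-15, 15, -15, 15)
    } else {
      xy_box <- c(min(heavy[, 1]) - margin, max(heavy[, 1]) + margin,
                  min(heavy[, 2]) - margin, max(heavy[, 2]) + margin)
    }
  }
  xs <- seq(xy_box[1], xy_box[2], by = spacing)
  ys <- seq(xy_box[3], xy_box[4], by = spacing)
  zs_mem <- seq(z_lo, z_hi, by = spacing)
  z_span <- if (is.null(heavy) || nrow(heavy) == 0) c(z_lo, z_hi) else
    range(heavy[, 3])
  zs_all <- seq(min(z_lo - solvent_depth, z_span[1] - solvent_depth),
                max(z_hi + solvent_depth, z_span[2] + solvent_depth),
                by = spacing)
  zs_solv <- zs_all[zs_all < z_lo - 1e-9 | zs_all > z_hi + 1e-9]
  grid3 <- function(zs) {
    as.matrix(expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE))
  }
  mem <- grid3(zs_mem)
  solv <- grid3(zs_solv)
  if (!is.null(heavy) && nrow(heavy) > 0) {
    mem <- mem[.min_dist(mem, heavy) > exclusion, , drop = FALSE]
    solv <- solv[.min_dist(solv, heavy) > 2.0, , drop = FALSE]
  }
  if (nrow(mem) == 0)
    warning("membrane grid is empty after protein exclusion")
  structure(list(points = mem, solvent = solv,
                 z_lo = z_lo, z_hi = z_hi, spacing = spacing,
                 exclusion = exclusion, xy_box = xy_box),
            class = "flip_membrane")
}

.heavy_coords <- function(s) {
  if (is.null(s)) return(NULL)
  if (inherits(s, "flip_cg")) {
    rbind(cg_xyz(s, "N"), cg_xyz(s, "CA"), cg_xyz(s, "C"),
          cg_xyz(s, "O")[is.finite(cg_xyz(s, "O")[, 1]), , drop = FALSE],
          cg_xyz(s, "X"))
  } else if (inherits(s, "flip_structure")) {
    as.matrix(s$atoms[, c("x", "y", "z")])
  } else if (is.matrix(s)) {
    s
  } else stop("cannot extract coordinates from object of class ",
              paste(class(s), collapse = "/"))
}

# minimum distance from each row of a to any row of b (chunked)
.min_dist <- function(a, b) {
  if (is.null(b) || nrow(b) == 0) return(rep(Inf, nrow(a)))
  out <- rep(Inf, nrow(a))
  step <- 20000L
  for (i0 in seq(1, nrow(a), by = step)) {
    i1 <- min(i0 + step - 1, nrow(a))
    d <- .cdist(a[i0:i1, , drop = FALSE], b)
    out[i0:i1] <- apply(d, 1, min)
  }
  out
}

#' Per-residue environment counts
#'
#' Counts, within `cutoff` of residue `i`'s side-chain centre X: the X
#' centres of other polar residues (`n_p`), of other nonpolar residues
#' (`n_np`) and the membrane grid points (`n_mem`); and measures `r_min`,
#' the distance from X to the nearest solvent lattice point.
#'
#' @param cg a `flip_cg`.
#' @param env a `flip_membrane`, or `NULL` for pure water (no membrane:
#'   `n_mem = 0`, `r_min = Inf`).
#' @param i residue row index in `cg`.
#' @param cutoff neighbour cutoff in Angstrom (default 10).
#' @return list with integer `n_p`, `n_np`, `n_mem` and numeric `r_min`.
#' @export
residue_environment <- function(cg, env, i, cutoff = 10) {
  if (cutoff <= 0) stop("cutoff must be positive")
  n <- nrow(cg)
  if (i < 1 || i > n) stop("residue index out of range: ", i)
  x <- cg_xyz(cg, "X")
  xi <- x[i, , drop = FALSE]
  d <- as.numeric(.cdist(xi, x))
  near <- which(d <= cutoff & seq_len(n) != i)
  n_p <- sum(cg$polar[near])
  n_np <- length(near) - n_p
  if (is.null(env)) {
    n_mem <- 0L
    r_min <- Inf
  } else {
    n_mem <- if (nrow(env$points) == 0) 0L else
      sum(.cdist(xi, env$points) <= cutoff)
    r_min <- if (nrow(env$solvent) == 0) Inf else
      min(.cdist(xi, env$solvent))
  }
  list(n_p = as.integer(n_p), n_np = as.integer(n_np),
       n_mem = as.integer(n_mem), r_min = r_min)
}

#' Environment table for all residues
#'
#' Vectorised convenience over [residue_environment()].
#'
#' @inheritParams residue_environment
#' @return data frame with one row per residue: `n_p, n_np, n_mem, r_min`.
#' @export
environment_table <- function(cg, env, cutoff = 10) {
  x <- cg_xyz(cg, "X")
  n <- nrow(cg)
  d <- .cdist(x, x)
  diag(d) <- Inf
  near <- d <= cutoff
  n_p <- as.integer(near %*% cg$polar)
  n_tot <- as.integer(rowSums(near))
  if (is.null(env) || nrow(env$points) == 0) {
    n_mem <- integer(n)
  } else {
    n_mem <- integer(n)
    for (i in seq_len(n))
      n_mem[i] <- sum(.cdist(x[i, , drop = FALSE], env$points) <= cutoff)
  }
  r_min <- if (is.null(env)) rep(Inf, n) else .min_dist(x, env$solvent)
  data.frame(n_p = n_p, n_np = n_tot - n_p, n_mem = n_mem, r_min = r_min)
}

#' Export the membrane grid as PDB pseudo-atoms
#'
#' Writes the membrane points as dummy HETATM records for visual
#' inspection.
#'
#' @param env a `flip_membrane`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_membrane_grid <- function(env, file) {
  p <- env$points
  n <- nrow(p)
  bio3d::write.pdb(file = file, xyz = as.numeric(t(p)),
                   type = rep("HETATM", n),
                   resno = seq_len(n), resid = rep("MEM", n),
                   chain = rep("M", n), eleno = seq_len(n),
                   elety = rep("DUM", n), o = rep(1, n), b = rep(0, n))
  invisible(file)
}

#' @export
print.flip_membrane <- function(x, ...) {
  cat("flip_membrane: slab [", x$z_lo, ",", x$z_hi, "] A, spacing",
      x$spacing, "A;", nrow(x$points), "membrane points,",
      nrow(x$solvent), "solvent points\n")
  invisible(x)
}
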