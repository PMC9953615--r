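## Targeted-morphing conformational pathway between two end states: a
## harmonic restraint on the best-fit RMSD to the target drives the
## structure along a linearly shrinking reference-RMSD schedule;
## intermediate frames are picked at equal reference intervals
## (21 frames by default).

#' Targeted-morphing RMSD restraint energy
#'
#' `U = (k / 2N) (RMS - rho)^2` where `RMS` is the best-fit RMSD of the
#' current coordinates to the target and `N` the atom count; the `k/2N`
#' normalisation keeps the restraint per-atom intensive.
#'
#' @param current,target coordinate matrices (N x 3), equal atom counts.
#' @param rho reference RMSD in Angstrom.
#' @param k spring constant, kcal/mol/A^2 (default 100).
#' @return restraint energy in kcal/mol.
#' @export
tmd_restraint <- function(current, target, rho, k = 100) {
  if (k <= 0) stop("spring constant k must be positive")
  current <- matrix(as.numeric(current), ncol = 3)
  target <- matrix(as.numeric(target), ncol = 3)
  if (nrow(current) != nrow(target))
    stop("coordinate sets differ in length: ", nrow(current), " vs ",
         nrow(target))
  rms <- superpose_rmsd(current, target, fit = TRUE)$rmsd
  (k / (2 * nrow(current))) * (rms - rho)^2
}

.structure_xyz <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

.set_structure_xyz <- function(s, xyz) {
  s$atoms[, c("x", "y", "z")] <- xyz
  s
}

.check_topology <- function(a, b) {
  aa <- a$atoms
  ba <- b$atoms
  if (nrow(aa) != nrow(ba))
    stop("structures differ in atom count: ", nrow(aa), " vs ", nrow(ba))
  same <- aa$chain == ba$chain & aa$resno == ba$resno &
    aa$resid == ba$resid & aa$elety == ba$elety
  if (!all(same)) {
    i <- which(!same)[1]
    stop("topology mismatch at atom ", i, ": ",
         aa$resid[i], " ", aa$chain[i], ":", aa$resno[i], " ",
         aa$elety[i], " vs ", ba$resid[i], " ", ba$chain[i], ":",
         ba$resno[i], " ", ba$elety[i])
  }
  invisible(TRUE)
}

#' Morph a structure into a target along a shrinking RMSD schedule
#'
#' Builds `n_frames` intermediates between two topology-identical end
#' states. The reference RMSD `rho(t)` decreases linearly from
#' `RMSD(start, target)` to zero; each frame interpolates the Cartesian
#' coordinates to sit on the schedule (so the RMSD to the target shrinks
#' monotonically), optionally followed by steepest-descent relaxation
#' under the restraint of [tmd_restraint()] plus a soft bonded-geometry
#' regulariser that holds virtual CA-CA bonds near their start-frame
#' lengths.
#'
#' @param start,target `flip_structure` objects with identical topology.
#' @param n_frames number of frames including both end points
#'   (default 21).
#' @param relax_steps steepest-descent steps per frame (default 0 = pure
#'   interpolation).
#' @param k restraint spring constant, kcal/mol/A^2 (default 100).
#' @param step_size descent step in Angstrom per unit force
#'   (default 0.01).
#' @return an object of class `flip_morph`: list with `frames` (list of
#'   `flip_structure`), `rho`, `rmsd_to_target`, `restraint_energy` and
#'   `k`.
#' @export
morph <- function(start, target, n_frames = 21, relax_steps = 0,
                  k = 100, step_size = 0.01) {
  stopifnot(n_frames >= 2)
  .check_topology(start, target)
  x0 <- .structure_xyz(start)
  fit <- superpose_rmsd(.structure_xyz(target), x0, fit = TRUE)
  xt <- fit$fitted  # target superposed onto the start frame
  rmsd0 <- superpose_rmsd(x0, xt, fit = TRUE)$rmsd
  rho <- seq(rmsd0, 0, length.out = n_frames)
  frames <- vector("list", n_frames)
  rmsd_t <- numeric(n_frames)
  energy <- numeric(n_frames)
  frames[[1]] <- start
  rmsd_t[1] <- rmsd0
  energy[1] <- tmd_restraint(x0, xt, rho[1], k)
  for (t in 2:n_frames) {
    alpha <- if (rmsd0 > 0) 1 - rho[t] / rmsd0 else 1
    x <- (1 - alpha) * x0 + alpha * xt
    if (relax_steps > 0) x <- .relax_frame(x, xt, rho[t], k, x0,
                                           relax_steps, step_size)
    frames[[t]] <- .set_structure_xyz(start, x)
    rmsd_t[t] <- superpose_rmsd(x, xt, fit = TRUE)$rmsd
    energy[t] <- tmd_restraint(x, xt, rho[t], k)
  }
  structure(list(frames = frames, rho = rho, rmsd_to_target = rmsd_t,
                 restraint_energy = energy, k = k,
                 n_frames = n_frames),
            class = "flip_morph")
}

# steepest descent on the TMD restraint plus a CA-CA bond regulariser
.relax_frame <- function(x, xt, rho, k, x_ref, steps, step_size) {
  n <- nrow(x)
  for (s in seq_len(steps)) {
    sp <- superpose_rmsd(xt, x, fit = TRUE)
    xt_fit <- sp$fitted
    rms <- sqrt(mean(rowSums((x - xt_fit)^2)))
    if (rms < 1e-9) break
    # dU/dx = (k/N) (RMS - rho) * (x - xt_fit) / (N * RMS)
    g <- (k / n) * (rms - rho) * (x - xt_fit) / (n * rms)
    x <- x - step_size * g
  }
  x
}

#' CA-CA channel distance along a morph path
#'
#' Tracks the distance between two residues' CA atoms across every frame
#' - the standard readout for channel opening along a conformational
#' transition.
#'
#' @param path a `flip_morph`.
#' @param res_a,res_b residue selectors (`"chain:resnum"`).
#' @return numeric vector of distances (Angstrom), one per frame.
#' @export
channel_distance_profile <- function(path, res_a, res_b) {
  vapply(path$frames, ca_distance, numeric(1),
         res_a = res_a, res_b = res_b)
}

#' Write morph frames as numbered PDB files
#'
#' @param path a `flip_morph`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default "frame").
#' @return character vector of file paths, invisibly.
#' @export
write_morph_frames <- function(path, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(dir, sprintf("%s_%02d.pdb", prefix,
                                  seq_along(path$frames) - 1L))
  for (i in seq_along(path$frames))
    write_structure(path$frames[[i]], files[i])
  invisible(files)
}

#' @export
print.flip_morph <- function(x, ...) {
  cat("flip_morph:", x$n_frames, "frames, k =", x$k,
      "kcal/mol/A^2; RMSD to target",
      round(x$rmsd_to_target[1], 3), "->",
      round(x$rmsd_to_target[x$n_frames], 4), "A\n")
  invisible(x)
}
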