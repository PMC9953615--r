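## Deterministic synthetic generators: ideal transmembrane helix bundles,
## two-state conformational pairs, toy lipids and isolated titration
## systems. These emulate, at toy scale, a multi-helix transmembrane
## bundle with ionizable residues at controlled burial depths, a
## two-state pair related by a rigid sub-domain motion, and a
## polar-headgroup lipid - enough structure to exercise every pipeline
## stage in seconds.

## Ideal-helix backbone torsions. Solved once (Newton on the screw
## parameters of the internal-coordinate chain with standard bond
## lengths/angles) so the CA trace has exactly 1.5 A rise and 100 deg
## twist per residue; H-bond N(i+4)...O(i) comes out at 2.95 A.
.HELIX_PHI <- -63.5588880790 * pi / 180
.HELIX_PSI <- -41.4327611412 * pi / 180
.HELIX_TAU <- 109.7478620670 * pi / 180  # N-CA-C angle

.DEG <- pi / 180

# backbone N/CA/C/O for an ideal helix of nres residues, axis ~ +z
.helix_backbone <- function(nres) {
  n <- ca <- cc <- matrix(0, nres, 3)
  n[1, ] <- c(0, 0, 0)
  ca[1, ] <- c(1.458, 0, 0)
  cc[1, ] <- .nerf(c(0, 1, 0), n[1, ], ca[1, ], 1.525, .HELIX_TAU, 0)
  for (i in 2:nres) {
    n[i, ] <- .nerf(n[i - 1, ], ca[i - 1, ], cc[i - 1, ], 1.329,
                    116.2 * .DEG, .HELIX_PSI)
    ca[i, ] <- .nerf(ca[i - 1, ], cc[i - 1, ], n[i, ], 1.458,
                     121.7 * .DEG, pi)
    cc[i, ] <- .nerf(cc[i - 1, ], n[i, ], ca[i, ], 1.525, .HELIX_TAU,
                     .HELIX_PHI)
  }
  o <- matrix(0, nres, 3)
  for (i in seq_len(nres))
    o[i, ] <- .nerf(n[i, ], ca[i, ], cc[i, ], 1.231, 120.8 * .DEG,
                    .HELIX_PSI + pi)
  # align the helix axis with +z and centre the CA trace at the origin
  axis <- .helix_axis(ca)
  rot <- .rotation_onto(axis, c(0, 0, 1))
  shift <- colMeans(ca)
  fix <- function(m) tcrossprod(sweep(m, 2, shift), rot)
  list(N = fix(n), CA = fix(ca), C = fix(cc), O = fix(o))
}

# screw axis of a CA trace (unit vector) from consecutive-window Kabsch
.helix_axis <- function(ca) {
  n <- nrow(ca)
  a <- ca[1:(n - 1), , drop = FALSE]
  b <- ca[2:n, , drop = FALSE]
  sp <- superpose_rmsd(a, b, fit = TRUE)
  r <- sp$rotation
  ev <- eigen(r)
  ax <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  # orient along the rise
  if (sum(ax * (ca[n, ] - ca[1, ])) < 0) ax <- -ax
  ax / .vnorm(ax)
}

# rotation matrix taking unit vector a onto unit vector b
.rotation_onto <- function(a, b) {
  a <- a / .vnorm(a)
  b <- b / .vnorm(b)
  v <- .cross3(a, b)
  c_ <- sum(a * b)
  if (abs(c_ + 1) < 1e-12) {
    # opposite: rotate 180 about any perpendicular
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- .cross3(a, p)
    v <- v / .vnorm(v)
    return(2 * tcrossprod(v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

.default_sequence <- function(len, helix_index) {
  seqs <- rep("LEU", len)
  seqs[seq(4, len, by = 7)] <- "THR"
  mid <- ceiling(len / 2)
  seqs[mid] <- if (helix_index %% 2 == 1) "ASP" else "LYS"
  seqs
}

#' Specification of a synthetic helix-bundle fixture
#'
#' @param n_helices number of transmembrane helices (default 4).
#' @param helix_length residues per helix (default 20).
#' @param channel_radius radius of the circle the helix axes sit on,
#'   Angstrom (default 8).
#' @param sequence either `NULL` (default pattern: leucine background,
#'   threonine every 7th position, one ionizable residue mid-helix,
#'   alternating Asp/Lys between helices), a character vector recycled
#'   over every helix, or a list of per-helix vectors.
#' @param move_chains chains displaced in state B (default the first).
#' @param translation state-B rigid translation of the moved chains; by
#'   default 5 Angstrom radially outward.
#' @param rotation state-B rotation angle about the moved helix's own
#'   axis, degrees (default 0).
#' @param seed integer seed recorded with the fixture (generation is
#'   fully deterministic).
#' @return a list of class `flip_fixture_spec`.
#' @export
fixture_spec <- function(n_helices = 4, helix_length = 20,
                         channel_radius = 8, sequence = NULL,
                         move_chains = NULL, translation = NULL,
                         rotation = 0, seed = 1) {
  structure(list(n_helices = n_helices, helix_length = helix_length,
                 channel_radius = channel_radius, sequence = sequence,
                 move_chains = move_chains, translation = translation,
                 rotation = rotation, seed = seed),
            class = "flip_fixture_spec")
}

#' Build an ideal membrane-spanning helix bundle
#'
#' Helices (backbone N, CA, C, O plus one pseudo side-chain heavy atom
#' CB per non-glycine residue) stand on a circle of radius
#' `channel_radius`, axes along z and centred on the membrane mid-plane,
#' one chain per helix (A, B, ...). The construction is deterministic.
#'
#' @param spec a [fixture_spec()] (or arguments forwarded to it).
#' @param ... convenience: forwarded to [fixture_spec()] when `spec` is
#'   missing.
#' @return a `flip_structure`.
#' @export
make_bundle <- function(spec = fixture_spec(...), ...) {
  stopifnot(inherits(spec, "flip_fixture_spec"))
  nh <- spec$n_helices
  if (nh < 1) stop("need at least one helix")
  if (nh > 1) {
    chord <- 2 * spec$channel_radius * sin(pi / nh)
    if (chord < 7)
      stop("helices overlap: centre-centre distance ", round(chord, 2),
           " A < 7 A; increase channel_radius")
  }
  bb <- .helix_backbone(spec$helix_length)
  rows <- list()
  eleno <- 0L
  for (h in seq_len(nh)) {
    seqs <- .helix_sequence(spec, h)
    phi <- 2 * pi * (h - 1) / nh
    centre <- if (nh == 1) c(0, 0, 0) else
      spec$channel_radius * c(cos(phi), sin(phi), 0)
    for (i in seq_len(spec$helix_length)) {
      res <- seqs[i]
      at <- list(N = bb$N[i, ], CA = bb$CA[i, ], C = bb$C[i, ],
                 O = bb$O[i, ])
      if (res != "GLY") {
        # pseudo side chain: 1.53 A radially outward from CA
        ca <- bb$CA[i, ]
        radial <- c(ca[1], ca[2], 0)
        radial <- if (.vnorm(radial) < 1e-9) c(1, 0, 0) else
          radial / .vnorm(radial)
        at$CB <- ca + 1.53 * radial
      }
      for (a in names(at)) {
        eleno <- eleno + 1L
        rows[[eleno]] <- data.frame(
          eleno = eleno, elety = a, resid = res,
          chain = LETTERS[h], resno = i,
          x = at[[a]][1] + centre[1], y = at[[a]][2] + centre[2],
          z = at[[a]][3] + centre[3],
          o = 1, b = 0, elesy = substr(a, 1, 1),
          stringsAsFactors = FALSE)
      }
    }
  }
  at <- do.call(rbind, rows)
  s <- structure(list(atoms = at, het = at[0, ]),
                 class = "flip_structure")
  .validate_backbone(s)
  s
}

.helix_sequence <- function(spec, h) {
  len <- spec$helix_length
  sq <- spec$sequence
  if (is.null(sq)) return(.default_sequence(len, h))
  if (is.list(sq)) sq <- sq[[((h - 1) %% length(sq)) + 1]]
  rep_len(toupper(sq), len)
}

#' Build a two-state conformational pair
#'
#' State A is the bundle of [make_bundle()]; state B displaces the
#' designated helices rigidly (default: the first chain translated 5
#' Angstrom radially outward, opening the channel by a known amount).
#' Topology is identical between the states.
#'
#' @param spec a [fixture_spec()].
#' @return list with elements `a` and `b` (both `flip_structure`) and
#'   `translation` (the applied shift).
#' @export
make_two_state_pair <- function(spec = fixture_spec()) {
  a <- make_bundle(spec)
  chains <- spec$move_chains %||% "A"
  shift <- spec$translation
  if (is.null(shift)) {
    # radially outward from the bundle centre for the first moved chain
    at <- a$atoms
    idx <- at$chain == chains[1]
    cen <- colMeans(as.matrix(at[idx, c("x", "y", "z")]))
    radial <- c(cen[1], cen[2], 0)
    radial <- if (.vnorm(radial) < 1e-9) c(1, 0, 0) else
      radial / .vnorm(radial)
    shift <- 5 * radial
  }
  rot <- diag(3)
  if (spec$rotation != 0) {
    th <- spec$rotation * .DEG
    rot <- matrix(c(cos(th), sin(th), 0,
                    -sin(th), cos(th), 0,
                    0, 0, 1), 3, 3)
  }
  b <- if (spec$rotation == 0 && all(shift == 0)) a else
    .transform_structure(a, rotation = rot, translation = shift,
                         chains = chains)
  list(a = a, b = b, translation = shift, chains = chains)
}

#' Build a toy lipid ligand
#'
#' A linear pseudo-lipid along -z: charged head bead(s) followed by
#' neutral tail beads at 1.5 Angstrom spacing. Partial charges sum
#' exactly to `headgroup_charge`.
#'
#' @param headgroup_charge net charge in e (default -1).
#' @param tail_length number of neutral tail beads (default 10).
#' @param head_beads number of head beads sharing the charge
#'   (default 1).
#' @return a `flip_ligand`.
#' @export
make_toy_lipid <- function(headgroup_charge = -1, tail_length = 10,
                           head_beads = 1) {
  if (tail_length < 0) stop("tail_length must be >= 0")
  if (head_beads < 1) stop("need at least one head bead")
  n <- head_beads + tail_length
  z <- -1.5 * (seq_len(n) - 1)
  charge <- c(rep(headgroup_charge / head_beads, head_beads),
              rep(0, tail_length))
  atoms <- data.frame(
    name = c(sprintf("P%d", seq_len(head_beads)),
             if (tail_length > 0) sprintf("C%d", seq_len(tail_length))),
    element = c(rep("P", head_beads), rep("C", tail_length)),
    x = 0, y = 0, z = z, charge = charge,
    stringsAsFactors = FALSE)
  structure(list(atoms = atoms, total_charge = headgroup_charge),
            class = "flip_ligand")
}

#' Build an isolated titration system
#'
#' Pseudo-residues with prescribed aqueous pKas at given positions and no
#' other interactions - the harness for validating the proton-transfer
#' sampler against closed-form titration behaviour.
#'
#' @param n_sites number of ionizable sites.
#' @param pka_values aqueous pKas (recycled to `n_sites`).
#' @param positions n x 3 matrix of site coordinates (default: sites
#'   spaced 100 Angstrom apart on the x axis, effectively independent).
#' @param kinds "acid" or "base" per site; default inferred from the pKa
#'   (acid below 7).
#' @return a `flip_cg` containing only the ionizable pseudo-residues.
#' @export
make_titration_system <- function(n_sites, pka_values,
                                  positions = NULL, kinds = NULL) {
  pka_values <- rep_len(pka_values, n_sites)
  if (is.null(positions))
    positions <- cbind(100 * (seq_len(n_sites) - 1), 0, 0)
  positions <- matrix(positions, ncol = 3)
  if (nrow(positions) != n_sites)
    stop("positions must have one row per site")
  if (is.null(kinds)) kinds <- ifelse(pka_values < 7, "acid", "base")
  kinds <- rep_len(kinds, n_sites)
  resid <- ifelse(kinds == "acid", "ASP", "LYS")
  cg <- data.frame(chain = "A", resno = seq_len(n_sites), resid = resid,
                   ionizable = TRUE, pka_w = pka_values, polar = TRUE,
                   stringsAsFactors = FALSE)
  for (site in c("N", "CA", "C", "O", "X", "D")) {
    cg[[paste0(site, ".x")]] <- positions[, 1]
    cg[[paste0(site, ".y")]] <- positions[, 2]
    cg[[paste0(site, ".z")]] <- positions[, 3]
  }
  class(cg) <- c("flip_cg", "data.frame")
  cg
}
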