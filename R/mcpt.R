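## Ionization electrostatics: environment self-energies, in-protein pKas,
## and Metropolis Monte-Carlo proton transfer (MCPT) over protonation
## configurations.

#' Membrane contribution to the ionization self-energy
#'
#' Penalty for charging an ionizable group surrounded by membrane grid
#' points. A deeply buried site (more than `n_sat` membrane neighbours,
#' farther than `r_switch` from solvent) pays the full constant
#' `b_mem` = 15 kcal/mol. Approaching the solvent attenuates the penalty
#' through a Gaussian switch of width `r_width`; sparse membrane contact
#' (`0 < n_mem <= n_sat`) attenuates it exponentially at rate `rate`, so
#' the penalty grows monotonically with burial and vanishes at
#' `n_mem = 0`. The printed branch conditions of the source model are
#' typographically ambiguous; this monotone reading is the one implemented
#' (see the package vignette).
#'
#' @param n_mem number of membrane grid points around the site.
#' @param r_min distance to the nearest solvent point, Angstrom.
#' @param b_mem plateau constant, kcal/mol (default 15).
#' @param r_switch solvent switching distance, Angstrom (default 18).
#' @param r_width Gaussian width of the solvent switch, Angstrom
#'   (default 12).
#' @param n_sat membrane-neighbour saturation count (default 28).
#' @param rate exponential attenuation rate per missing neighbour
#'   (default 0.2).
#' @return energy in kcal/mol.
#' @export
membrane_self_energy <- function(n_mem, r_min, b_mem = 15,
                                 r_switch = 18, r_width = 12,
                                 n_sat = 28, rate = 0.2) {
  if (any(n_mem < 0)) stop("n_mem must be non-negative")
  if (any(r_min <= 0)) stop("r_min must be positive")
  base <- ifelse(n_mem > n_sat, b_mem,
                 b_mem * exp(-rate * (n_sat - n_mem)))
  out <- ifelse(r_min > r_switch, base,
                base * exp(-((r_min - r_switch) / r_width)^2))
  ifelse(n_mem == 0, 0, out)
}

#' Ionization self-energy of a residue environment
#'
#' Charging cost of an ionizable group in its current surroundings: a
#' per-neighbour polar term (stabilising, default -0.15 kcal/mol), a
#' per-neighbour nonpolar term (destabilising, default +0.35 kcal/mol) and
#' the membrane grid term of [membrane_self_energy()]. The neighbour
#' potentials are calibration knobs of this implementation; only the
#' membrane plateau constant is fixed by the source model.
#'
#' @param env a list with `n_p`, `n_np`, `n_mem`, `r_min` (see
#'   [residue_environment()]).
#' @param u_p polar neighbour potential, kcal/mol (default -0.15).
#' @param u_np nonpolar neighbour potential, kcal/mol (default +0.35).
#' @param ... passed to [membrane_self_energy()].
#' @return self-energy in kcal/mol.
#' @export
self_energy <- function(env, u_p = -0.15, u_np = 0.35, ...) {
  u_p * env$n_p + u_np * env$n_np +
    membrane_self_energy(env$n_mem, env$r_min, ...)
}

#' In-protein pKa from the self-energy shift
#'
#' Shifts the aqueous reference pKa by `dg_self / (2.3 R T)` in the
#' direction that disfavours the charged form: acids (Asp/Glu) shift up,
#' bases (Arg/Lys/His) shift down when the environment penalises charging
#' (`dg_self > 0`).
#'
#' @param resid 3-letter residue code (must be ionizable).
#' @param dg_self self-energy in kcal/mol.
#' @param temperature Kelvin (default 300).
#' @param pka_w aqueous reference pKa; defaults to the package table.
#' @return list with `resid`, `pka_w`, `dg_self`, `pka_b`.
#' @export
pka_in_protein <- function(resid, dg_self, temperature = 300,
                           pka_w = NULL) {
  resid <- toupper(resid)
  if (!.is_ionizable(resid))
    stop("pka_in_protein called on non-ionizable residue: ", resid)
  if (is.null(pka_w)) pka_w <- .pka_w_of(resid)
  sgn <- .ion_sign_of(resid)
  shift <- dg_self / (.LN10 * .RGAS * temperature)
  list(resid = resid, pka_w = pka_w, dg_self = dg_self,
       pka_b = pka_w - sgn * shift)
}

#' Electrostatic free energy of one charge configuration
#'
#' `-2.3 R T sum_i q_i (pKa_b_i - pH)` plus the pairwise charge-charge
#' interaction of the charged sites.
#'
#' @param q numeric vector of site charges (0/-1 for acids, 0/+1 for
#'   bases).
#' @param pka_b in-protein pKas, same order as `q`.
#' @param ph solution pH.
#' @param qq_matrix symmetric matrix of pairwise couplings `k_ij`
#'   (kcal/mol per unit charge product); the interaction of a
#'   configuration is `sum_{i<j} k_ij q_i q_j`. `NULL` means no coupling.
#' @param temperature Kelvin (default 300).
#' @return energy in kcal/mol.
#' @export
charge_config_energy <- function(q, pka_b, ph, qq_matrix = NULL,
                                 temperature = 300) {
  e <- -.LN10 * .RGAS * temperature * sum(q * (pka_b - ph))
  if (!is.null(qq_matrix) && length(q) > 1) {
    e <- e + 0.5 * as.numeric(t(q) %*% qq_matrix %*% q)
  }
  e
}

# screened-Coulomb coupling matrix on X-X distances, zero diagonal
.qq_matrix <- function(x_coords, eps_eff = 40) {
  d <- .cdist(x_coords, x_coords)
  k <- 332 / (eps_eff * d)
  diag(k) <- 0
  k
}

#' Monte-Carlo proton transfer sampling of ionization states
#'
#' Metropolis sampling over protonation configurations of the ionizable
#' residues. Each step attempts either (a) a proton exchange between one
#' site and the bulk solvent (toggling its charge), or (b) a proton
#' transfer between a pair of sites. Site energies follow
#' [charge_config_energy()] with in-protein pKas derived from the residue
#' environments, and couplings are screened Coulomb on X-X distances. The
#' chain stops early once the sliding-window mean of the electrostatic
#' free energy stabilises; averages are taken after discarding the initial
#' burn-in fraction.
#'
#' @param cg a `flip_cg`.
#' @param env a `flip_membrane` or `NULL` (pure water).
#' @param ph solution pH (default 7).
#' @param temperature Kelvin (default 300).
#' @param steps maximum Monte-Carlo steps (default 2e5).
#' @param seed integer seed; the run is bit-reproducible for a fixed seed.
#' @param u_p,u_np neighbour self-energy potentials (kcal/mol).
#' @param eps_eff effective dielectric of the charge-charge coupling
#'   (default 40).
#' @param cutoff environment cutoff, Angstrom (default 10).
#' @param window convergence window in steps (default 2000).
#' @param tol convergence tolerance on the window mean, kcal/mol
#'   (default 0.01).
#' @param min_steps never stop before this many steps; default
#'   (`NULL`) is burn-in plus 20 windows, so averages always rest on a
#'   substantial post-burn-in sample.
#' @param burn_in fraction of the run discarded before averaging
#'   (default 0.2).
#' @return an object of class `flip_ionization`: list with `residues`
#'   (data frame: chain, resno, resid, pka_w, dg_self, pka_b, q_mc),
#'   `g_elec_min`, `g_qq_mean`, `g_qq_mf`, `acceptance`, `steps_run`,
#'   `config_freq` (for up to 12 sites), plus the run settings.
#' @export
mcpt_sample <- function(cg, env = NULL, ph = 7, temperature = 300,
                        steps = 2e5, seed = 1,
                        u_p = -0.15, u_np = 0.35, eps_eff = 40,
                        cutoff = 10, window = 2000, tol = 0.01,
                        min_steps = NULL, burn_in = 0.2) {
  stopifnot(steps >= 1)
  ion <- which(cg$ionizable)
  empty <- structure(list(
    residues = data.frame(chain = character(), resno = integer(),
                          resid = character(), pka_w = numeric(),
                          dg_self = numeric(), pka_b = numeric(),
                          q_mc = numeric()),
    g_elec_min = 0, g_qq_mean = 0, g_qq_mf = 0, acceptance = NA_real_,
    steps_run = 0L, config_freq = NULL, ph = ph,
    temperature = temperature, seed = seed), class = "flip_ionization")
  if (length(ion) == 0) return(empty)

  et <- environment_table(cg, env, cutoff = cutoff)
  dg_self <- self_energy(et[ion, , drop = FALSE], u_p = u_p, u_np = u_np)
  sgn <- .ion_sign_of(cg$resid[ion])
  rt <- .RGAS * temperature
  pka_b <- cg$pka_w[ion] - sgn * dg_self / (.LN10 * rt)
  n <- length(ion)
  k <- .qq_matrix(cg_xyz(cg, "X")[ion, , drop = FALSE], eps_eff)

  # site energy of being charged (excluding pair term):
  h <- -.LN10 * rt * sgn * (pka_b - ph)

  set.seed(as.integer(seed %% .Machine$integer.max))
  q <- numeric(n)            # all neutral start
  e <- 0
  e_min <- 0
  acc <- 0L
  q_sum <- numeric(n)
  qq_sum <- 0
  n_samp <- 0L
  burn <- floor(burn_in * steps)
  if (is.null(min_steps)) min_steps <- burn + 20L * window
  track_cfg <- n <= 12
  cfg_counts <- if (track_cfg) integer(2^n) else NULL
  pow2 <- if (track_cfg) 2^(seq_len(n) - 1) else NULL

  prev_mean <- NA_real_
  win_sum <- 0
  t_run <- 0L
  e_qq <- 0
  converged <- FALSE

  # pre-draw randomness in blocks for speed
  block <- 10000L
  while (t_run < steps && !converged) {
    nb <- min(block, steps - t_run)
    u_move <- stats::runif(nb)
    u_acc <- stats::runif(nb)
    s1 <- sample.int(n, nb, replace = TRUE)
    s2 <- if (n > 1) sample.int(n, nb, replace = TRUE) else s1
    for (b in seq_len(nb)) {
      i <- s1[b]
      if (n == 1 || u_move[b] < 0.5) {
        # toggle site i against bulk
        dq <- if (q[i] == 0) sgn[i] else -q[i]
        de_qq <- dq * sum(k[i, ] * q)
        de <- (if (q[i] == 0) h[i] else -h[i]) + de_qq
        if (de <= 0 || u_acc[b] < exp(-de / rt)) {
          q[i] <- q[i] + dq
          e <- e + de
          e_qq <- e_qq + de_qq
          acc <- acc + 1L
        }
      } else {
        j <- s2[b]
        if (j != i) {
          # proton transfer i -> j: i releases a proton (becomes / stays
          # deprotonated), j takes it up. Deprotonated means charged for
          # acids, neutral for bases.
          i_can <- (sgn[i] < 0 && q[i] == 0) || (sgn[i] > 0 && q[i] != 0)
          j_can <- (sgn[j] < 0 && q[j] != 0) || (sgn[j] > 0 && q[j] == 0)
          if (i_can && j_can) {
            dqi <- -1  # deprotonation of i: charge drops by 1
            dqj <- 1   # protonation of j: charge rises by 1
            de_qq <- dqi * sum(k[i, ] * q) + dqj * sum(k[j, ] * q) +
              dqi * dqj * k[i, j]
            de <- (if (q[i] == 0) h[i] else -h[i]) +
              (if (q[j] == 0) h[j] else -h[j]) + de_qq
            if (de <= 0 || u_acc[b] < exp(-de / rt)) {
              q[i] <- q[i] + dqi
              q[j] <- q[j] + dqj
              e <- e + de
              e_qq <- e_qq + de_qq
              acc <- acc + 1L
            }
          }
        }
      }
      t_run <- t_run + 1L
      if (e < e_min) e_min <- e
      if (t_run > burn) {
        q_sum <- q_sum + q
        qq_sum <- qq_sum + e_qq
        n_samp <- n_samp + 1L
        if (track_cfg) {
          idx <- sum(pow2[q != 0]) + 1L
          cfg_counts[idx] <- cfg_counts[idx] + 1L
        }
      }
      win_sum <- win_sum + e
      if (t_run %% window == 0) {
        m <- win_sum / window
        win_sum <- 0
        if (!is.na(prev_mean) && t_run >= min_steps && t_run > burn &&
            abs(m - prev_mean) < tol) {
          converged <- TRUE
          break
        }
        prev_mean <- m
      }
    }
  }

  q_mc <- if (n_samp > 0) q_sum / n_samp else q
  res <- data.frame(chain = cg$chain[ion], resno = cg$resno[ion],
                    resid = cg$resid[ion], pka_w = cg$pka_w[ion],
                    dg_self = dg_self, pka_b = pka_b, q_mc = q_mc,
                    stringsAsFactors = FALSE)
  cfg <- NULL
  if (track_cfg && n_samp > 0) {
    cfg <- cfg_counts / n_samp
    names(cfg) <- vapply(seq_along(cfg) - 1L, function(m) {
      paste(ifelse(bitwAnd(m, pow2) > 0, "c", "n"), collapse = "")
    }, character(1))
  }
  structure(list(residues = res, g_elec_min = e_min,
                 g_qq_mean = if (n_samp > 0) qq_sum / n_samp else 0,
                 g_qq_mf = 0.5 * as.numeric(t(q_mc) %*% k %*% q_mc),
                 acceptance = acc / max(t_run, 1),
                 steps_run = t_run, config_freq = cfg,
                 ph = ph, temperature = temperature, seed = seed),
            class = "flip_ionization")
}

#' Electrostatic side-chain contribution to the folding free energy
#'
#' Assembles `-2.3 R T sum_i Q_i^MC (pKa_b_i - pKa_w_i) + dG_QQ_folded -
#' dG_QQ_unfolded + dG_Qdev` from a sampled ionization state. By default
#' the folded charge-charge term is the mean-field value at the averaged
#' charges (which makes the per-residue decomposition sum exactly to the
#' total); set `qq = "ensemble"` for the Monte-Carlo ensemble average.
#'
#' @param ion a `flip_ionization`.
#' @param qq_unfolded unfolded-state charge-charge term, kcal/mol
#'   (default 0: extended fully solvated chain).
#' @param q_dev protonation-deviation penalty on unfolding, kcal/mol
#'   (default 0).
#' @param qq which folded charge-charge estimate to use: "meanfield"
#'   (default) or "ensemble".
#' @return energy in kcal/mol.
#' @export
electrostatic_folding_term <- function(ion, qq_unfolded = 0, q_dev = 0,
                                       qq = c("meanfield", "ensemble")) {
  qq <- match.arg(qq)
  r <- ion$residues
  if (nrow(r) == 0) return(0)
  rt <- .RGAS * ion$temperature
  g_qq_f <- if (qq == "meanfield") ion$g_qq_mf else ion$g_qq_mean
  -.LN10 * rt * sum(r$q_mc * (r$pka_b - r$pka_w)) +
    g_qq_f - qq_unfolded + q_dev
}

#' @export
print.flip_ionization <- function(x, ...) {
  cat("flip_ionization:", nrow(x$residues), "sites, pH", x$ph,
      ", T", x$temperature, "K,", x$steps_run, "steps; min G_elec",
      round(x$g_elec_min, 3), "kcal/mol\n")
  if (nrow(x$residues) > 0) print(x$residues, digits = 4)
  invisible(x)
}
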