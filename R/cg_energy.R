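## Assembly of the total CG folding free energy and its per-residue
## decomposition:
##   dG_fold = elec + polar + hyd + c1*vdw_side + c2*solv_cg + c3*hb_cg
##             + vdw_main_side
## with c1 = 0.10, c2 = 0.25, c3 = 0.15.
##
## The electrostatic term comes from the MCPT module. The hydrophobic,
## polar, van der Waals, hydrogen-bond and solvation forms below are
## minimal documented surrogates for the unpublished CG force-field
## terms: each has the sign and monotonicity the downstream analysis
## relies on, and each is unit-tested against its closed form.

# Gaussian solvent switch shared with the membrane self-energy
.solvent_switch <- function(r_min, r_switch = 18, r_width = 12) {
  ifelse(r_min > r_switch, 1, exp(-((r_min - r_switch) / r_width)^2))
}

#' Hydrophobic side-chain term
#'
#' Burial reward for nonpolar side chains: `-k_hyd * min(n_np + n_mem,
#' n_sat)` per nonpolar residue, zero for polar/ionizable residues. The
#' saturation count `n_sat` caps the reward for deeply packed cores.
#'
#' @param cg a `flip_cg`.
#' @param env a `flip_membrane` or `NULL`.
#' @param k_hyd reward per buried neighbour, kcal/mol (default 0.2).
#' @param n_sat saturation count (default 8).
#' @param cutoff neighbour cutoff, Angstrom (default 10).
#' @param env_table optional precomputed [environment_table()].
#' @return numeric vector of per-residue energies (kcal/mol).
#' @export
hydrophobic_term <- function(cg, env = NULL, k_hyd = 0.2, n_sat = 8,
                             cutoff = 10, env_table = NULL) {
  et <- if (is.null(env_table)) environment_table(cg, env, cutoff) else
    env_table
  ifelse(cg$polar, 0, -k_hyd * pmin(et$n_np + et$n_mem, n_sat))
}

#' Polar side-chain desolvation term
#'
#' Penalty for burying a polar side chain in the membrane: `+k_pol *
#' n_mem * switch(r_min)` for polar residues (ionizables included), zero
#' for nonpolar residues. The switch is the same Gaussian solvent
#' attenuation as the membrane self-energy, so the penalty fades near the
#' slab surface.
#'
#' @inheritParams hydrophobic_term
#' @param k_pol penalty per membrane neighbour, kcal/mol (default 0.05).
#' @return numeric vector of per-residue energies (kcal/mol).
#' @export
polar_term <- function(cg, env = NULL, k_pol = 0.05, cutoff = 10,
                       env_table = NULL) {
  et <- if (is.null(env_table)) environment_table(cg, env, cutoff) else
    env_table
  ifelse(cg$polar, k_pol * et$n_mem * .solvent_switch(et$r_min), 0)
}

# 8-6 soft pair potential with minimum -eps at r0; capped below r_cap
.pot86 <- function(r, r0, eps, r_cap = 0.5) {
  r <- pmax(r, r_cap)
  s <- r0 / r
  eps * (3 * s^8 - 4 * s^6)
}

#' Side-chain van der Waals terms
#'
#' Pairwise 8-6 soft potential between side-chain centres X (side-side)
#' and between X and the backbone atoms of non-adjacent residues
#' (main-side). The potential minimum is exactly `-eps_pair` at the sum
#' of the per-class contact radii. Each pair energy is halved onto the
#' two partner residues. Distances below 0.5 Angstrom are capped (finite
#' clash energy) with a warning.
#'
#' @param cg a `flip_cg`.
#' @param eps_ss side-side well depth, kcal/mol (default 0.10).
#' @param eps_ms main-side well depth, kcal/mol (default 0.05).
#' @param r0_table per-residue contact radii, Angstrom; defaults to the
#'   package table.
#' @param r0_bb backbone atom contact radius, Angstrom (default 1.7).
#' @param cutoff interaction cutoff, Angstrom (default 10).
#' @return list with numeric vectors `side_side` and `main_side`
#'   (per-residue, kcal/mol).
#' @export
vdw_terms <- function(cg, eps_ss = 0.10, eps_ms = 0.05,
                      r0_table = .VDW_R0, r0_bb = 1.7, cutoff = 10) {
  n <- nrow(cg)
  r0 <- r0_table[cg$resid]
  r0[is.na(r0)] <- .VDW_R0_DEFAULT
  x <- cg_xyz(cg, "X")
  ss <- numeric(n)
  ms <- numeric(n)
  d <- .cdist(x, x)
  if (any(d[upper.tri(d)] < 0.5))
    warning("steric clash between side-chain centres; energy capped")
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (d[i, j] > cutoff) next
      e <- .pot86(d[i, j], r0[i] + r0[j], eps_ss)
      ss[i] <- ss[i] + e / 2
      ss[j] <- ss[j] + e / 2
    }
  }
  bb_sites <- c("N", "CA", "C", "O")
  bb <- lapply(bb_sites, function(a) cg_xyz(cg, a))
  for (a in seq_along(bb_sites)) {
    bbx <- bb[[a]]
    ok <- is.finite(bbx[, 1])
    if (!any(ok)) next
    dab <- .cdist(x, bbx[ok, , drop = FALSE])
    jidx <- which(ok)
    for (i in seq_len(n)) {
      same_chain <- cg$chain[jidx] == cg$chain[i]
      adjacent <- same_chain & abs(cg$resno[jidx] - cg$resno[i]) <= 1
      sel <- which(!adjacent & dab[i, ] <= cutoff)
      if (length(sel) == 0) next
      e <- .pot86(dab[i, sel], r0[i] + r0_bb, eps_ms)
      ms[i] <- ms[i] + sum(e) / 2
      for (kk in seq_along(sel))
        ms[jidx[sel[kk]]] <- ms[jidx[sel[kk]]] + e[kk] / 2
    }
  }
  list(side_side = ss, main_side = ms)
}

#' Backbone hydrogen-bond and main-chain solvation terms
#'
#' Hydrogen bonds are detected between the backbone N of residue i and
#' the carbonyl O of residue j (same chain, `i - j >= 3`) when the N-O
#' distance falls in the donor-acceptor window 2.6-3.4 Angstrom and the
#' C-O...N acceptor angle is at least 120 degrees (the conventional
#' near-linear geometry, which selects the canonical helical i->i+4 bond
#' over the bent i->i+3 contact); each bond contributes `-e_hb`, split
#' between donor and acceptor residues. Main-chain solvation is a desolvation
#' penalty proportional to the number of membrane grid points around the
#' CA: `+k_solv * n_mem(CA)`; a backbone in water costs nothing.
#'
#' @param cg a `flip_cg`.
#' @param env a `flip_membrane` or `NULL`.
#' @param e_hb energy per hydrogen bond, kcal/mol (default 1.0).
#' @param hb_window donor-acceptor distance window, Angstrom.
#' @param k_solv penalty per membrane neighbour of the backbone, kcal/mol
#'   (default 0.05).
#' @param cutoff membrane neighbour cutoff, Angstrom (default 10).
#' @return list with numeric vectors `hb` and `solv` (per-residue,
#'   kcal/mol).
#' @export
hb_and_solvation_terms <- function(cg, env = NULL, e_hb = 1.0,
                                   hb_window = c(2.6, 3.4),
                                   k_solv = 0.05, cutoff = 10) {
  n <- nrow(cg)
  hb <- numeric(n)
  nxyz <- cg_xyz(cg, "N")
  oxyz <- cg_xyz(cg, "O")
  cxyz <- cg_xyz(cg, "C")
  ok_o <- is.finite(oxyz[, 1])
  if (any(ok_o)) {
    d <- .cdist(nxyz, oxyz)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (!ok_o[j]) next
        if (cg$chain[i] != cg$chain[j]) next
        if (cg$resno[i] - cg$resno[j] < 3) next
        if (d[i, j] < hb_window[1] || d[i, j] > hb_window[2]) next
        u <- cxyz[j, ] - oxyz[j, ]
        v <- nxyz[i, ] - oxyz[j, ]
        cosang <- sum(u * v) / (.vnorm(u) * .vnorm(v))
        if (cosang > -0.5) next  # require C-O...N >= 120 degrees
        hb[i] <- hb[i] - e_hb / 2
        hb[j] <- hb[j] - e_hb / 2
      }
    }
  }
  solv <- numeric(n)
  if (!is.null(env) && nrow(env$points) > 0) {
    ca <- cg_xyz(cg, "CA")
    for (i in seq_len(n))
      solv[i] <- k_solv *
        sum(.cdist(ca[i, , drop = FALSE], env$points) <= cutoff)
  }
  list(hb = hb, solv = solv)
}

#' Assemble the total folding free energy ledger
#'
#' Applies the scaling coefficients c1 = 0.10 (side-chain vdW), c2 = 0.25
#' (main-chain solvation) and c3 = 0.15 (hydrogen bonds) and sums all
#' components per residue and over the structure.
#'
#' @param elec,polar,hyd,vdw_side,solv_cg,hb_cg,vdw_main_side per-residue
#'   numeric vectors of equal length (kcal/mol, unscaled).
#' @param residues optional residue annotation data frame (chain, resno,
#'   resid) carried into the ledger.
#' @param c1,c2,c3 scaling coefficients (defaults 0.10, 0.25, 0.15).
#' @return an object of class `flip_ledger`: list with `per_residue`
#'   (data frame of scaled per-residue components and `total`), `totals`
#'   (named vector of structure-level components), `coefficients` and
#'   `dg_fold`.
#' @export
total_folding_energy <- function(elec, polar, hyd, vdw_side, solv_cg,
                                 hb_cg, vdw_main_side, residues = NULL,
                                 c1 = 0.10, c2 = 0.25, c3 = 0.15) {
  comp <- list(elec = elec, polar = polar, hyd = hyd,
               vdw_side = vdw_side, solv_cg = solv_cg, hb_cg = hb_cg,
               vdw_main_side = vdw_main_side)
  miss <- names(comp)[vapply(comp, is.null, logical(1))]
  if (length(miss) > 0)
    stop("missing energy component(s): ", paste(miss, collapse = ", "))
  len <- unique(vapply(comp, length, integer(1)))
  if (length(len) != 1)
    stop("energy components differ in length")
  per <- data.frame(elec = elec, polar = polar, hyd = hyd,
                    vdw_side = c1 * vdw_side, solv_cg = c2 * solv_cg,
                    hb_cg = c3 * hb_cg, vdw_main_side = vdw_main_side)
  per$total <- rowSums(per)
  if (!is.null(residues)) per <- cbind(residues, per)
  totals <- colSums(per[, c("elec", "polar", "hyd", "vdw_side",
                            "solv_cg", "hb_cg", "vdw_main_side",
                            "total")])
  structure(list(per_residue = per, totals = totals,
                 coefficients = c(c1 = c1, c2 = c2, c3 = c3),
                 dg_fold = unname(totals["total"])),
            class = "flip_ledger")
}

#' Full CG folding free energy of a structure
#'
#' Convenience wrapper running the environment counts, the MCPT
#' electrostics, and every component term, then assembling the ledger via
#' [total_folding_energy()]. The per-residue electrostatic entry is
#' `-2.3RT q_i (pKa_b_i - pKa_w_i)` plus half the mean-field
#' charge-charge energy of each charged pair, so the entries sum exactly
#' to the structure-level electrostatic term.
#'
#' @param cg a `flip_cg`.
#' @param env a `flip_membrane` or `NULL`.
#' @param ion an optional precomputed `flip_ionization`; if `NULL` one is
#'   sampled with `...` settings.
#' @param cutoff neighbour cutoff, Angstrom.
#' @param params named list of term parameters (`k_hyd`, `n_sat`,
#'   `k_pol`, `eps_ss`, `eps_ms`, `e_hb`, `k_solv`, `c1`, `c2`, `c3`);
#'   unnamed entries keep their defaults.
#' @param ... passed to [mcpt_sample()] when `ion` is `NULL`.
#' @return a `flip_ledger` with an `ionization` attribute.
#' @export
cg_folding_energy <- function(cg, env = NULL, ion = NULL, cutoff = 10,
                              params = list(), ...) {
  p <- utils::modifyList(list(k_hyd = 0.2, n_sat = 8, k_pol = 0.05,
                              eps_ss = 0.10, eps_ms = 0.05, e_hb = 1.0,
                              k_solv = 0.05, c1 = 0.10, c2 = 0.25,
                              c3 = 0.15), params)
  et <- environment_table(cg, env, cutoff)
  if (is.null(ion)) ion <- mcpt_sample(cg, env, cutoff = cutoff, ...)
  n <- nrow(cg)
  elec <- numeric(n)
  if (nrow(ion$residues) > 0) {
    rt <- .RGAS * ion$temperature
    idx <- which(cg$ionizable)
    r <- ion$residues
    elec[idx] <- -.LN10 * rt * r$q_mc * (r$pka_b - r$pka_w)
    if (length(idx) > 1) {
      k <- .qq_matrix(cg_xyz(cg, "X")[idx, , drop = FALSE],
                      eps_eff = list(...)$eps_eff %||% 40)
      elec[idx] <- elec[idx] + 0.5 * as.numeric(k %*% r$q_mc) * r$q_mc
    }
  }
  hyd <- hydrophobic_term(cg, env, p$k_hyd, p$n_sat, cutoff, et)
  pol <- polar_term(cg, env, p$k_pol, cutoff, et)
  vdw <- vdw_terms(cg, p$eps_ss, p$eps_ms, cutoff = cutoff)
  hs <- hb_and_solvation_terms(cg, env, p$e_hb, k_solv = p$k_solv,
                               cutoff = cutoff)
  led <- total_folding_energy(elec, pol, hyd, vdw$side_side, hs$solv,
                              hs$hb, vdw$main_side,
                              residues = cg[, c("chain", "resno", "resid")],
                              c1 = p$c1, c2 = p$c2, c3 = p$c3)
  attr(led, "ionization") <- ion
  led
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank per-residue energy changes between two states
#'
#' Differences each scaled ledger component per residue between two
#' conformational states and ranks entries by absolute change, labelling
#' the dominant component - the standard readout for asking which
#' residues pay for a transition barrier.
#'
#' @param a,b `flip_ledger` objects over the same residue set.
#' @param top_n number of rows to return (default 10; `Inf` for all).
#' @return data frame: `chain, resno, resid`, per-component deltas,
#'   `d_total`, `dominant` (component of largest absolute change), sorted
#'   by `abs(d_total)` decreasing.
#' @export
decompose_difference <- function(a, b, top_n = 10) {
  pa <- a$per_residue
  pb <- b$per_residue
  key_cols <- intersect(c("chain", "resno", "resid"), names(pa))
  if (length(key_cols) > 0) {
    if (!identical(pa[key_cols], pb[key_cols]))
      stop("ledgers cover different residue sets")
  } else if (nrow(pa) != nrow(pb)) {
    stop("ledgers cover different residue sets")
  }
  comps <- c("elec", "polar", "hyd", "vdw_side", "solv_cg", "hb_cg",
             "vdw_main_side")
  d <- pb[comps] - pa[comps]
  names(d) <- paste0("d_", comps)
  d$d_total <- pb$total - pa$total
  d$dominant <- comps[max.col(abs(as.matrix(d[paste0("d_", comps)])))]
  out <- cbind(if (length(key_cols)) pa[key_cols], d)
  out <- out[order(-abs(out$d_total)), ]
  rownames(out) <- NULL
  utils::head(out, top_n)
}

#' @export
print.flip_ledger <- function(x, ...) {
  cat("flip_ledger:", nrow(x$per_residue), "residues; dG_fold =",
      round(x$dg_fold, 3), "kcal/mol\n")
  print(round(x$totals, 3))
  invisible(x)
}
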