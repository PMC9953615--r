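## The coupled two-dimensional free-energy landscape over (conformation
## index, lipid-transport position), its least-energy (minimax) path and
## barrier readouts.

#' Place a ligand at a ladder of positions along the channel axis
#'
#' Rigidly translates the ligand so its geometric centre sits at
#' `center + offset * axis` for each offset, and flags poses whose atoms
#' clash with the protein (any contact below `clash`).
#'
#' @param frame a `flip_structure`.
#' @param ligand a `flip_ligand`.
#' @param axis channel axis vector (normalised internally); default the
#'   membrane normal `c(0, 0, 1)`.
#' @param offsets numeric vector of signed displacements along the axis,
#'   Angstrom (sorted).
#' @param center axis origin; default the protein geometric centre.
#' @param clash clash distance in Angstrom (default 1.5).
#' @return list of `flip_ligand` poses, each with attributes `offset` and
#'   `clash` (logical).
#' @export
place_ligand_ladder <- function(frame, ligand, axis = c(0, 0, 1),
                                offsets = seq(-15, 15, by = 5),
                                center = NULL, clash = 1.5) {
  if (.vnorm(axis) == 0) stop("channel axis must be non-zero")
  if (is.unsorted(offsets)) stop("offsets must be sorted increasing")
  axis <- axis / .vnorm(axis)
  pxyz <- .structure_xyz(frame)
  if (is.null(center)) center <- colMeans(pxyz)
  lcen <- colMeans(.lig_xyz(ligand))
  poses <- lapply(offsets, function(off) {
    pose <- .translate_ligand(ligand, center + off * axis - lcen)
    d <- .cdist(.lig_xyz(pose), pxyz)
    attr(pose, "offset") <- off
    attr(pose, "clash") <- any(d < clash)
    pose
  })
  if (all(vapply(poses, function(p) attr(p, "clash"), logical(1))))
    stop("every ligand pose clashes with the protein; widen the offsets")
  poses
}

#' Couple a conformational profile with binding energies into a 2D map
#'
#' `G(i, j) = G_conf(i) + G_bind(i, j)`, calibrated so the reference cell
#' is zero.
#'
#' @param conf_g per-frame conformational free energies (length n),
#'   kcal/mol.
#' @param bind_g n x m matrix of binding free energies per (frame,
#'   offset); `Inf` marks an excluded cell.
#' @param reference reference cell `c(i, j)` for calibration (default the
#'   minimum-G cell of the first column).
#' @param conf_labels,offsets optional axis annotations.
#' @return an object of class `flip_landscape`: list with matrix `G`,
#'   `conf_labels`, `offsets`, `reference`.
#' @export
build_landscape <- function(conf_g, bind_g, reference = NULL,
                            conf_labels = NULL, offsets = NULL) {
  bind_g <- as.matrix(bind_g)
  n <- length(conf_g)
  if (nrow(bind_g) != n)
    stop("bind_g has ", nrow(bind_g), " rows but conf_g has length ", n)
  g <- sweep(bind_g, 1, conf_g, "+")
  if (is.null(reference)) {
    i <- which.min(g[, 1])
    reference <- c(i, 1)
  }
  gref <- g[reference[1], reference[2]]
  if (!is.finite(gref)) stop("reference cell has non-finite energy")
  g <- g - gref
  structure(list(G = g,
                 conf_labels = conf_labels %||% seq_len(n),
                 offsets = offsets %||% seq_len(ncol(g)),
                 reference = reference),
            class = "flip_landscape")
}

.neighbors8 <- function(i, j, n, m) {
  di <- rep(c(-1L, 0L, 1L), each = 3)
  dj <- rep(c(-1L, 0L, 1L), times = 3)
  keep <- !(di == 0 & dj == 0)
  ii <- i + di[keep]
  jj <- j + dj[keep]
  ok <- ii >= 1 & ii <= n & jj >= 1 & jj <= m
  cbind(ii[ok], jj[ok])
}

#' Least-energy (minimax) path across the landscape
#'
#' Finds the route between two cells over 8-connected lattice moves that
#' minimises the maximum free energy crossed; ties are broken by the
#' lower path integral of G and then by lexicographic cell order, so the
#' result is deterministic. The barrier is the path maximum minus the
#' start-cell energy.
#'
#' @param land a `flip_landscape` (or a bare numeric matrix).
#' @param start,end cells `c(i, j)`.
#' @return an object of class `flip_path`: list with `cells` (k x 2
#'   matrix), `barrier`, `peak` (cell of the path maximum), `max_g` and
#'   `sum_g`.
#' @export
least_energy_path <- function(land, start, end) {
  g <- if (inherits(land, "flip_landscape")) land$G else as.matrix(land)
  n <- nrow(g)
  m <- ncol(g)
  if (identical(as.integer(start), as.integer(end)))
    stop("start and end cells coincide")
  id <- function(i, j) (j - 1L) * n + i
  INF <- Inf
  best_max <- matrix(INF, n, m)
  best_sum <- matrix(INF, n, m)
  parent <- matrix(NA_integer_, n, m)
  visited <- matrix(FALSE, n, m)
  s <- as.integer(start)
  e <- as.integer(end)
  if (!is.finite(g[s[1], s[2]])) stop("start cell is excluded")
  best_max[s[1], s[2]] <- g[s[1], s[2]]
  best_sum[s[1], s[2]] <- g[s[1], s[2]]
  repeat {
    # pick unvisited cell with smallest (max, sum, index) key
    cand <- which(!visited & is.finite(best_max))
    if (length(cand) == 0) stop("end cell unreachable from start")
    key_max <- best_max[cand]
    sel <- cand[key_max == min(key_max)]
    if (length(sel) > 1) {
      key_sum <- best_sum[sel]
      sel <- sel[key_sum == min(key_sum)]
    }
    cur <- min(sel)  # lexicographic (column-major) tie-break
    ci <- ((cur - 1L) %% n) + 1L
    cj <- ((cur - 1L) %/% n) + 1L
    visited[cur] <- TRUE
    if (ci == e[1] && cj == e[2]) break
    nb <- .neighbors8(ci, cj, n, m)
    for (r in seq_len(nrow(nb))) {
      vi <- nb[r, 1]
      vj <- nb[r, 2]
      if (visited[vi, vj] || !is.finite(g[vi, vj])) next
      nmax <- max(best_max[ci, cj], g[vi, vj])
      nsum <- best_sum[ci, cj] + g[vi, vj]
      if (nmax < best_max[vi, vj] ||
          (nmax == best_max[vi, vj] && nsum < best_sum[vi, vj])) {
        best_max[vi, vj] <- nmax
        best_sum[vi, vj] <- nsum
        parent[vi, vj] <- id(ci, cj)
      }
    }
  }
  # reconstruct
  cells <- matrix(e, 1, 2)
  cur <- id(e[1], e[2])
  while (!is.na(parent[cur])) {
    cur <- parent[cur]
    ci <- ((cur - 1L) %% n) + 1L
    cj <- ((cur - 1L) %/% n) + 1L
    cells <- rbind(c(ci, cj), cells)
  }
  gpath <- g[cells]
  pk <- which.max(gpath)
  structure(list(cells = cells,
                 barrier = max(gpath) - g[s[1], s[2]],
                 peak = cells[pk, ],
                 max_g = max(gpath),
                 sum_g = sum(gpath)),
            class = "flip_path")
}

#' Barriers of a one-dimensional free-energy profile
#'
#' For each local maximum of the ordered profile, the barrier is the peak
#' value minus the minimum reached since the previous peak (the preceding
#' running minimum), the standard readout of successive transition
#' barriers along a reaction profile.
#'
#' @param profile numeric vector of free energies (kcal/mol), ordered
#'   along the reaction coordinate.
#' @return data frame with columns `peak_index`, `peak_value`, `barrier`;
#'   zero rows for a profile without interior maxima.
#' @export
profile_barriers <- function(profile) {
  n <- length(profile)
  if (n < 2) stop("profile needs at least 2 values")
  out <- data.frame(peak_index = integer(), peak_value = numeric(),
                    barrier = numeric())
  run_min <- profile[1]
  i <- 2
  while (i <= n) {
    nxt <- if (i < n) profile[i + 1] else -Inf
    if (profile[i] > profile[i - 1] && profile[i] > nxt) {
      out <- rbind(out, data.frame(peak_index = i,
                                   peak_value = profile[i],
                                   barrier = profile[i] - run_min))
      run_min <- Inf  # reset: track the minimum after this peak
    }
    run_min <- min(run_min, profile[i])
    i <- i + 1
  }
  out
}

#' Export a landscape as a long-format table
#'
#' @param land a `flip_landscape`.
#' @return data frame with columns `frame`, `offset_index`, `offset`,
#'   `G`.
#' @export
landscape_table <- function(land) {
  n <- nrow(land$G)
  m <- ncol(land$G)
  data.frame(frame = rep(seq_len(n), m),
             offset_index = rep(seq_len(m), each = n),
             offset = rep(land$offsets, each = n),
             G = as.numeric(land$G))
}

#' Heat-map of a landscape with an optional path overlay
#'
#' Uses ggplot2 when available; silently returns `NULL` otherwise.
#'
#' @param land a `flip_landscape`.
#' @param path optional `flip_path` to overlay.
#' @return a ggplot object or `NULL`.
#' @export
plot_landscape <- function(land, path = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) return(NULL)
  tab <- landscape_table(land)
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = frame, y = offset,
                                         fill = G)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "G (kcal/mol)") +
    ggplot2::labs(x = "conformation (frame)",
                  y = "lipid position along channel axis (A)") +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    pd <- data.frame(frame = path$cells[, 1],
                     offset = land$offsets[path$cells[, 2]])
    p <- p + ggplot2::geom_path(data = pd,
                                ggplot2::aes(x = frame, y = offset),
                                inherit.aes = FALSE,
                                linetype = "dashed", linewidth = 0.8)
  }
  p
}

#' @export
print.flip_path <- function(x, ...) {
  cat("flip_path:", nrow(x$cells), "cells; barrier =",
      round(x$barrier, 3), "kcal/mol, peak at (",
      x$peak[1], ",", x$peak[2], ")\n")
  invisible(x)
}

#' @export
print.flip_landscape <- function(x, ...) {
  cat("flip_landscape:", nrow(x$G), "frames x", ncol(x$G),
      "positions; G range [", round(min(x$G), 2), ",",
      round(max(x$G), 2), "] kcal/mol, reference cell (",
      x$reference[1], ",", x$reference[2], ")\n")
  invisible(x)
}
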