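## All-atom structure I/O and the coarse-grained (CG) mapping.
##
## An all-atom structure is a light wrapper around an atom table (one row
## per ATOM record, bio3d column conventions): list(atoms, het) with class
## "flip_structure". Protein ATOM records live in $atoms; waters and hetero
## ligands are kept apart in $het.

#' Read a protein structure from PDB text or file
#'
#' Parses PDB-format coordinates (via bio3d), resolves alternate locations
#' to the highest-occupancy copy, separates waters/hetero groups from the
#' protein, orders residues by (chain, residue number) and validates that
#' every protein residue carries the N, CA and C backbone atoms.
#'
#' @param pdb either a path to a PDB file or a character vector of PDB-format
#'   lines (anything containing a newline or more than one element is treated
#'   as text).
#' @return an object of class `flip_structure`: a list with `atoms` (protein
#'   atom data frame with columns `eleno, elety, resid, chain, resno, x, y,
#'   z, o, b, elesy`) and `het` (non-protein records, same columns).
#' @export
read_structure <- function(pdb) {
  is_text <- length(pdb) > 1 || grepl("\n", pdb) ||
    grepl("^(ATOM|HETATM|HEADER|REMARK|MODEL|CRYST)", pdb[1])
  if (is_text) {
    lines <- unlist(strsplit(pdb, "\n", fixed = TRUE))
    file <- tempfile(fileext = ".pdb")
    on.exit(unlink(file), add = TRUE)
    writeLines(lines, file)
  } else {
    file <- pdb
    if (!file.exists(file)) stop("no such PDB file: ", file)
    lines <- readLines(file, warn = FALSE)
  }
  .check_pdb_records(lines)
  p <- bio3d::read.pdb(file, verbose = FALSE, rm.alt = FALSE)
  at <- p$atom
  if (!any(at$type == "ATOM")) stop("PDB input contains no ATOM record")
  if (any(!is.na(at$insert) & at$insert != ""))
    stop("insertion codes are not supported; renumber residues first")
  at$chain[is.na(at$chain)] <- "A"
  ## altloc: keep highest-occupancy copy of each (chain, resno, elety)
  alt <- !is.na(at$alt) & at$alt != ""
  if (any(alt)) {
    at$o[is.na(at$o)] <- 1
    key <- paste(at$chain, at$resno, at$elety)
    ord <- order(key, -at$o)
    at <- at[ord, ]
    at <- at[!duplicated(paste(at$chain, at$resno, at$elety)), ]
  }
  prot <- at[at$type == "ATOM", , drop = FALSE]
  het <- at[at$type != "ATOM", , drop = FALSE]
  prot <- prot[order(prot$chain, prot$resno, prot$eleno), , drop = FALSE]
  keep <- c("eleno", "elety", "resid", "chain", "resno",
            "x", "y", "z", "o", "b", "elesy")
  for (k in keep) if (is.null(prot[[k]])) prot[[k]] <- NA
  prot <- prot[, keep]
  het <- het[, keep]
  rownames(prot) <- NULL
  rownames(het) <- NULL
  s <- structure(list(atoms = prot, het = het), class = "flip_structure")
  .validate_backbone(s)
  s
}

.check_pdb_records <- function(lines) {
  rec <- grep("^(ATOM|HETATM)", lines)
  for (i in rec) {
    ln <- lines[i]
    if (nchar(ln) < 54) stop("unparseable PDB record at line ", i,
                             " (truncated coordinates)")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)) || any(!is.finite(xyz)))
      stop("unparseable PDB record at line ", i,
           " (non-numeric coordinates)")
  }
  invisible(TRUE)
}

.validate_backbone <- function(s) {
  at <- s$atoms
  key <- paste(at$chain, at$resno)
  for (bb in c("N", "CA", "C")) {
    has <- unique(key[at$elety == bb])
    missing <- setdiff(unique(key), has)
    if (length(missing) > 0) {
      r <- at[key == missing[1], ][1, ]
      stop("residue ", r$resid, " ", r$chain, ":", r$resno,
           " is missing backbone atom ", bb)
    }
  }
  if (any(!is.finite(c(at$x, at$y, at$z))))
    stop("non-finite coordinates in structure")
  invisible(TRUE)
}

#' Write a structure to a PDB file
#'
#' @param s a `flip_structure`.
#' @param file output path.
#' @param het include the non-protein records as HETATM (default `TRUE`).
#' @return the path, invisibly.
#' @export
write_structure <- function(s, file, het = TRUE) {
  stopifnot(inherits(s, "flip_structure"))
  at <- s$atoms
  if (het && nrow(s$het) > 0) at <- rbind(at, s$het)
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = file, xyz = xyz,
                   type = c(rep("ATOM", nrow(s$atoms)),
                            rep("HETATM", nrow(at) - nrow(s$atoms))),
                   resno = at$resno, resid = at$resid, chain = at$chain,
                   eleno = seq_len(nrow(at)), elety = at$elety,
                   o = ifelse(is.na(at$o), 1, at$o),
                   b = ifelse(is.na(at$b), 0, at$b))
  invisible(file)
}

#' Residue table of a structure
#'
#' One row per protein residue, with ionizable annotation and reference
#' aqueous pKa where applicable.
#'
#' @param s a `flip_structure`.
#' @param pka_table named vector of aqueous reference pKas; default covers
#'   Asp/Glu/His/Lys/Arg.
#' @return data frame with columns `chain, resno, resid, ionizable, pka_w,
#'   polar`.
#' @export
residue_table <- function(s, pka_table = .PKA_W) {
  at <- s$atoms
  key <- paste(at$chain, at$resno)
  first <- !duplicated(key)
  rt <- data.frame(chain = at$chain[first], resno = at$resno[first],
                   resid = toupper(at$resid[first]),
                   stringsAsFactors = FALSE)
  rt$ionizable <- .is_ionizable(rt$resid, names(pka_table))
  rt$pka_w <- ifelse(rt$ionizable, .pka_w_of(rt$resid, pka_table), NA_real_)
  rt$polar <- .is_polar(rt$resid)
  rt
}

.res_split <- function(s) {
  at <- s$atoms
  split(at, factor(paste(at$chain, at$resno),
                   levels = unique(paste(at$chain, at$resno))))
}

.atom_xyz <- function(df, elety) {
  r <- df[df$elety == elety, c("x", "y", "z")]
  if (nrow(r) == 0) return(NULL)
  as.numeric(r[1, ])
}

#' Map an all-atom structure to the coarse-grained representation
#'
#' Each residue keeps its explicit backbone and gains a single side-chain
#' interaction centre X plus a dummy atom D at the side-chain/main-chain
#' boundary. X is the geometric centre of the side-chain heavy atoms; for
#' ionizable residues it is displaced from that centre toward the centre of
#' the ionizable functional group by `shift_fraction` of their separation,
#' emphasising a consistent treatment of the charge-bearing moiety. For
#' glycine X coincides with CA. D is the midpoint of CA and X.
#'
#' @param s a `flip_structure`.
#' @param shift_fraction unitless in \[0, 1\]: 0 leaves X at the side-chain
#'   centroid, 1 moves it onto the ionizable-group centroid. Default 0.5.
#' @param pka_table named aqueous pKa table (also defines the ionizable set).
#' @return an object of class `flip_cg`: a data frame with one row per
#'   residue and columns `chain, resno, resid, ionizable, pka_w, polar`,
#'   backbone coordinates `N.*, CA.*, C.*, O.*` and the CG sites `X.*, D.*`.
#' @export
coarse_grain <- function(s, shift_fraction = 0.5, pka_table = .PKA_W) {
  stopifnot(inherits(s, "flip_structure"))
  if (shift_fraction < 0 || shift_fraction > 1)
    stop("shift_fraction must be in [0, 1]")
  rt <- residue_table(s, pka_table)
  res <- .res_split(s)
  n <- length(res)
  coords <- matrix(NA_real_, n, 18)
  colnames(coords) <- as.vector(outer(c("x", "y", "z"),
                                      c("N", "CA", "C", "O", "X", "D"),
                                      function(a, b) paste(b, a, sep = ".")))
  for (i in seq_len(n)) {
    df <- res[[i]]
    ca <- .atom_xyz(df, "CA")
    for (bb in c("N", "CA", "C", "O")) {
      v <- .atom_xyz(df, bb)
      if (!is.null(v)) coords[i, paste(bb, c("x", "y", "z"), sep = ".")] <- v
    }
    side <- df[!(df$elety %in% .BACKBONE_ATOMS) &
                 !(df$elesy %in% c("H", "D")) &
                 !grepl("^H", df$elety), , drop = FALSE]
    if (nrow(side) == 0) {
      x <- ca
    } else {
      x <- colMeans(side[, c("x", "y", "z")])
      if (rt$ionizable[i]) {
        grp <- .ION_GROUP[[rt$resid[i]]]
        gi <- side[side$elety %in% grp, c("x", "y", "z"), drop = FALSE]
        if (nrow(gi) > 0) {
          g <- colMeans(gi)
          x <- x + shift_fraction * (g - x)
        }
      }
    }
    coords[i, c("X.x", "X.y", "X.z")] <- as.numeric(x)
    coords[i, c("D.x", "D.y", "D.z")] <- as.numeric((ca + x) / 2)
  }
  cg <- cbind(rt, as.data.frame(coords))
  class(cg) <- c("flip_cg", "data.frame")
  cg
}

#' Extract a coordinate block from a CG structure
#'
#' @param cg a `flip_cg`.
#' @param site one of "N", "CA", "C", "O", "X", "D".
#' @return numeric matrix (n_residues x 3).
#' @export
cg_xyz <- function(cg, site = "X") {
  cols <- paste(site, c("x", "y", "z"), sep = ".")
  as.matrix(cg[, cols, drop = FALSE])
}

.resolve_selector <- function(s, sel) {
  if (is.character(sel) && grepl(":", sel)) {
    parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
    chain <- parts[1]
    resno <- as.integer(parts[2])
  } else if (is.numeric(sel)) {
    chain <- NULL
    resno <- as.integer(sel)
  } else {
    stop("unresolvable residue selector: ", sel)
  }
  at <- if (inherits(s, "flip_structure")) s$atoms else s
  hit <- at$resno == resno
  if (!is.null(chain)) hit <- hit & at$chain == chain
  if (!any(hit)) stop("residue selector not found in structure: ", sel)
  at[hit, , drop = FALSE]
}

#' Distance between the CA atoms of two residues
#'
#' @param s a `flip_structure`.
#' @param res_a,res_b residue selectors, either `"chain:resnum"` strings or
#'   plain residue numbers (first matching chain).
#' @return Euclidean CA-CA distance in Angstrom.
#' @export
ca_distance <- function(s, res_a, res_b) {
  a <- .resolve_selector(s, res_a)
  b <- .resolve_selector(s, res_b)
  ca_a <- a[a$elety == "CA", c("x", "y", "z")][1, ]
  ca_b <- b[b$elety == "CA", c("x", "y", "z")][1, ]
  if (anyNA(ca_a)) stop("no CA atom for selector: ", res_a)
  if (anyNA(ca_b)) stop("no CA atom for selector: ", res_b)
  .vnorm(as.numeric(ca_a) - as.numeric(ca_b))
}

#' @export
print.flip_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat("flip_structure:", nrow(x$atoms), "protein atoms,",
      nrow(rt), "residues,",
      length(unique(rt$chain)), "chain(s);",
      sum(rt$ionizable), "ionizable\n")
  invisible(x)
}

#' @export
print.flip_cg <- function(x, ...) {
  cat("flip_cg:", nrow(x), "residues (",
      sum(x$ionizable), "ionizable,", sum(x$polar), "polar )\n")
  invisible(NextMethod())
}

# rigid transform helper: rotate (3x3) then translate rows of structure
# coordinates; chains = NULL means all atoms
.transform_structure <- function(s, rotation = diag(3),
                                 translation = c(0, 0, 0),
                                 chains = NULL, center = NULL) {
  at <- s$atoms
  idx <- if (is.null(chains)) seq_len(nrow(at)) else which(at$chain %in% chains)
  xyz <- as.matrix(at[idx, c("x", "y", "z")])
  if (is.null(center)) center <- colMeans(xyz)
  xyz <- sweep(xyz, 2, center)
  xyz <- tcrossprod(xyz, rotation)
  xyz <- sweep(xyz, 2, center + translation, "+")
  at[idx, c("x", "y", "z")] <- xyz
  s$atoms <- at
  s
}
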