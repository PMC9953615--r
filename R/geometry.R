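## Small geometric primitives shared by the modules.

.vnorm <- function(v) sqrt(sum(v^2))

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# pairwise Euclidean distances between rows of a (n x 3) and b (m x 3)
.cdist <- function(a, b) {
  a <- matrix(a, ncol = 3)
  b <- matrix(b, ncol = 3)
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# place atom d given predecessors a-b-c, bond length r, bond angle theta
# (at c) and torsion chi (a-b-c-d); standard internal-coordinate chain
# extension
.nerf <- function(a, b, c, r, theta, chi) {
  bc <- c - b
  bc <- bc / .vnorm(bc)
  n <- .cross3(b - a, bc)
  n <- n / .vnorm(n)
  m <- .cross3(n, bc)
  d2 <- r * c(-cos(theta), sin(theta) * cos(chi), sin(theta) * sin(chi))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Optimal superposition and RMSD of two coordinate sets
#'
#' Computes the root-mean-square deviation between two conformations of the
#' same atom set, optionally after removing the optimal rigid-body
#' rotation/translation (Kabsch superposition via singular value
#' decomposition).
#'
#' @param a,b numeric matrices (n x 3) of Cartesian coordinates in Angstrom,
#'   row i of `a` corresponding to row i of `b`.
#' @param fit if `TRUE` (default) return the least-squares best-fit RMSD and
#'   the fitted transform; if `FALSE` return the raw RMSD in the input frames.
#' @return a list with elements `rmsd` (Angstrom), and when `fit = TRUE` also
#'   `rotation` (3 x 3), `translation` (length 3) and `fitted` (the
#'   transformed copy of `a`), such that `fitted = a %*% t(rotation) +
#'   translation` superposes `a` onto `b`.
#' @export
superpose_rmsd <- function(a, b, fit = TRUE) {
  a <- matrix(as.numeric(a), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  if (nrow(a) != nrow(b))
    stop("coordinate sets differ in length: ", nrow(a), " vs ", nrow(b))
  if (nrow(a) < 1) stop("empty coordinate sets")
  if (!fit) {
    return(list(rmsd = sqrt(mean(rowSums((a - b)^2)))))
  }
  ca <- colMeans(a)
  cb <- colMeans(b)
  a0 <- sweep(a, 2, ca)
  b0 <- sweep(b, 2, cb)
  h <- crossprod(a0, b0)
  s <- svd(h)
  d <- sign(det(tcrossprod(s$v, s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- tcrossprod(a0, rot)
  rmsd <- sqrt(mean(rowSums((fitted - b0)^2)))
  fitted <- sweep(fitted, 2, cb, "+")
  list(rmsd = rmsd,
       rotation = rot,
       translation = as.numeric(cb - rot %*% ca),
       fitted = fitted)
}

#' Best-fit RMSD between two coordinate sets
#'
#' Convenience scalar wrapper around [superpose_rmsd()].
#'
#' @inheritParams superpose_rmsd
#' @return RMSD in Angstrom.
#' @export
rmsd_fit <- function(a, b, fit = TRUE) superpose_rmsd(a, b, fit = fit)$rmsd
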