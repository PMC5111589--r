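# C-alpha anisotropic network model: Hessian construction, eigen
# decomposition with trivial/nontrivial labelling, and extension of C-alpha
# mode vectors to all-atom displacement fields.

#' Build the anisotropic-network Hessian
#'
#' Standard ANM on the C-alpha trace: every pair within `cutoff` is joined by
#' a Hookean spring of uniform stiffness; the 3x3 superelement for pair (i,j)
#' is -(gamma/d^2) * d_ij d_ij^T and diagonal blocks are minus the row sums,
#' so rigid translations are exact zero modes by construction.
#'
#' @param structure a `Structure` (or an n x 3 C-alpha coordinate matrix).
#' @param cutoff interaction cutoff in Angstrom (default 10).
#' @param gamma spring constant (arbitrary stiffness units, default 1).
#' @return 3N x 3N symmetric matrix with attribute `ca_xyz`.
#' @export
build_hessian <- function(structure, cutoff = 10, gamma = 1) {
  X <- if (inherits(structure, "Structure")) select_calpha(structure) else structure
  n <- nrow(X)
  if (n < 2) stop("need at least 2 C-alpha atoms for an elastic network")
  if (n >= 3 && qr(sweep(X, 2, colMeans(X)))$rank < 2)
    stop("degenerate (collinear) C-alpha geometry")
  H <- matrix(0, 3 * n, 3 * n)
  pr <- cpp_neighbor_pairs(X, cutoff)
  for (k in seq_len(nrow(pr))) {
    i <- pr[k, 1]; j <- pr[k, 2]
    dv <- X[j, ] - X[i, ]
    d2 <- sum(dv * dv)
    blk <- -(gamma / d2) * tcrossprod(dv)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- H[ii, jj] + blk
    H[jj, ii] <- H[jj, ii] + blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  attr(H, "ca_xyz") <- X
  H
}

#' Diagonalize the elastic Hessian into a ModeSet
#'
#' Eigenpairs in ascending eigenvalue order.  A connected, non-collinear
#' network has exactly six zero modes (rigid translations and rotations);
#' modes are flagged trivial when their eigenvalue is below 1e-6 times the
#' first nontrivial eigenvalue.  More than six near-zero modes (relative to
#' the largest eigenvalue) indicates a disconnected network and is an error.
#'
#' @param hessian a [build_hessian()] matrix.
#' @param k number of modes to retain (>= 7; default 12).
#' @return object of class `ModeSet`: `values`, `vectors` (3N x k, columns
#'   unit norm), `trivial` logical flags, `labels` ("m1".."mk"), `ca_xyz`.
#' @export
compute_modes <- function(hessian, k = 12) {
  if (k < 7) stop("k must be at least 7 (modes 1-6 are trivial)")
  e <- eigen(hessian, symmetric = TRUE)
  vals <- rev(e$values)
  vecs <- e$vectors[, rev(seq_len(ncol(e$vectors))), drop = FALSE]
  if (min(vals) < -1e-6 * max(abs(vals)))
    stop("Hessian has a significantly negative eigenvalue; not positive semidefinite")
  vals[vals < 0] <- 0
  nzero <- sum(vals < 1e-9 * max(vals))
  if (nzero > 6)
    stop("more than 6 near-zero modes (", nzero,
         "): elastic network is disconnected or geometrically degenerate ",
         "(e.g. a planar C-alpha arrangement)")
  if (nzero < 6)
    stop("fewer than 6 near-zero modes: network lacks rigid-body invariance")
  k <- min(k, length(vals))
  trivial <- vals < 1e-6 * vals[7]
  ms <- structure(list(values = vals[seq_len(k)],
                       vectors = vecs[, seq_len(k), drop = FALSE],
                       trivial = trivial[seq_len(k)],
                       labels = paste0("m", seq_len(k)),
                       ca_xyz = attr(hessian, "ca_xyz")),
                  class = "ModeSet")
  fix_mode_signs(ms)
}

## deterministic default sign: largest-magnitude component positive
fix_mode_signs <- function(modeset) {
  for (j in seq_along(modeset$values)) {
    v <- modeset$vectors[, j]
    if (v[which.max(abs(v))] < 0) modeset$vectors[, j] <- -v
  }
  modeset
}

#' @export
print.ModeSet <- function(x, ...) {
  cat(sprintf("ModeSet: %d modes over %d C-alpha sites; %d trivial; ",
              length(x$values), nrow(x$ca_xyz), sum(x$trivial)))
  cat("lowest nontrivial eigenvalues:",
      paste(signif(x$values[!x$trivial][1:min(3, sum(!x$trivial))], 3),
            collapse = ", "), "\n")
  invisible(x)
}

#' C-alpha displacement field of one mode
#'
#' @param modeset a `ModeSet`.
#' @param mode mode number (1-based, matching the "m7" labelling).
#' @return n x 3 matrix of per-residue displacements (unit Euclidean norm
#'   over all components).
#' @export
mode_field <- function(modeset, mode) {
  stopifnot(mode >= 1, mode <= length(modeset$values))
  matrix(modeset$vectors[, mode], ncol = 3, byrow = TRUE)
}

#' Extend a C-alpha mode to an all-atom displacement field
#'
#' Every atom inherits the displacement of its residue's C-alpha
#' (rigid-residue extension); the field is renormalized to unit norm.
#'
#' @param structure the all-atom `Structure` the mode refers to.
#' @param mode either an n_res x 3 matrix of C-alpha displacements or a
#'   `ModeSet` plus `mode_index`.
#' @param mode_index mode number when `mode` is a `ModeSet`.
#' @return n_atoms x 3 unit-norm displacement matrix.
#' @export
extend_mode_to_atoms <- function(structure, mode, mode_index = NULL) {
  if (inherits(mode, "ModeSet")) mode <- mode_field(mode, mode_index)
  a <- structure$atoms
  chain <- a$chain[1]
  ca <- a[a$name == "CA" & a$chain == chain, ]
  if (nrow(ca) != nrow(mode))
    stop("mode defined on ", nrow(mode), " C-alpha sites but structure has ",
         nrow(ca), " residues")
  idx <- match(paste(a$chain, a$resno), paste(ca$chain, ca$resno))
  if (anyNA(idx)) stop("residue ", a$resno[which(is.na(idx))[1]],
                       " has no C-alpha atom; cannot extend mode")
  V <- mode[idx, , drop = FALSE]
  V / sqrt(sum(V ^ 2))
}

#' Orient mode signs against a closure coordinate
#'
#' Fixes the sign of the lowest nontrivial mode so that motion in the "+"
#' direction decreases the active-site distance d_cc (closing motion);
#' other modes keep the default largest-component-positive convention.
#'
#' @param modeset a `ModeSet`.
#' @param structure a `Structure`.
#' @param dcc_residues length-2 residue numbers of the distance pair.
#' @param chain optional chain id.
#' @export
orient_modes <- function(modeset, structure, dcc_residues, chain = NULL) {
  ca <- select_calpha(structure, chain = chain)
  resno <- as.integer(rownames(ca))
  ia <- match(dcc_residues[1], resno)
  ib <- match(dcc_residues[2], resno)
  if (is.na(ia) || is.na(ib)) stop("d_cc residues not found in C-alpha trace")
  m7 <- which(!modeset$trivial)[1]
  V <- mode_field(modeset, m7)
  dv <- ca[ia, ] - ca[ib, ]
  ddot <- sum(dv * (V[ia, ] - V[ib, ]))   # d/dstep of |r_a - r_b|, up to 1/d
  if (ddot > 0) modeset$vectors[, m7] <- -modeset$vectors[, m7]
  modeset
}
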