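# Independent oracles used to verify the implementation.  These deliberately
# do NOT share code with the package internals they check.

## floppy modes of a body-bar framework by dense linear algebra:
## 6n - rank of the constraint Jacobian at a generic realization
oracle_jacobian_floppy <- function(n, edges, centers = NULL) {
  if (is.null(centers)) centers <- matrix(stats::rnorm(3 * n, sd = 5), n, 3)
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  rows <- list()
  for (k in seq_len(nrow(edges))) {
    u <- edges$bu[k]; v <- edges$bv[k]
    for (b in seq_len(edges$bars[k])) {
      a <- centers[u, ] + stats::rnorm(3)      # generic attachment points
      bb <- centers[v, ] + stats::rnorm(3)
      d <- a - bb
      r <- numeric(6 * n)
      r[(6 * u - 5):(6 * u)] <- c(d, cr(a - centers[u, ], d))
      r[(6 * v - 5):(6 * v)] <- -c(d, cr(bb - centers[v, ], d))
      rows[[length(rows) + 1L]] <- r
    }
  }
  J <- do.call(rbind, rows)
  6L * n - qr(J, tol = 1e-8)$rank
}

## quaternion (Horn) method for optimal superposition RMSD -- independent of
## the package's SVD-based Kabsch
oracle_quaternion_rmsd <- function(P, Q) {
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(P0, Q0)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P0 ^ 2) + sum(Q0 ^ 2) - 2 * lam) / nrow(P)
  sqrt(max(0, msd))
}

## random rigid motion applied to an n x 3 coordinate matrix
random_rigid_motion <- function(X, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax ^ 2))
  th <- stats::runif(1, 10, 170)
  R <- domainflex::rotation_matrix(ax, th)
  shift <- stats::rnorm(3, sd = 20)
  sweep(X %*% t(R), 2, shift, "+")
}

apply_rigid_motion <- function(structure, seed = NULL) {
  domainflex::set_coords(structure, random_rigid_motion(domainflex::coords(structure), seed))
}

## random unit vector
runit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v ^ 2))
}

## random PlaneFrame pair for property tests
random_frames <- function() {
  f1 <- list(normal = runit(), center = stats::rnorm(3, sd = 10))
  f2 <- list(normal = runit(), center = stats::rnorm(3, sd = 10))
  list(f1 = f1, f2 = f2)
}

## random small body-bar multigraph
random_framework <- function(max_bodies = 12) {
  n <- sample(3:max_bodies, 1)
  ne <- sample(2:(2 * n), 1)
  edges <- unique(data.frame(bu = sample(n, ne, replace = TRUE),
                             bv = sample(n, ne, replace = TRUE)))
  edges <- edges[edges$bu != edges$bv, , drop = FALSE]
  if (nrow(edges) == 0L)
    edges <- data.frame(bu = 1L, bv = 2L)
  edges$bars <- sample(1:6, nrow(edges), replace = TRUE)
  list(n = n, edges = edges)
}

## tiny hand-written PDB fixture: 3 glycine residues, backbone only
mini_pdb_text <- function() {
  s <- domainflex::make_peptide_chain(3, -57, -47)
  domainflex::write_structure(s)
}

## small hinge toy shared across tests (cached per session)
toy_cache <- new.env(parent = emptyenv())
get_toy <- function() {
  if (is.null(toy_cache$toy)) toy_cache$toy <- domainflex::make_hinge_toy()
  toy_cache$toy
}
get_toy_context <- function() {
  if (is.null(toy_cache$ctx)) {
    toy <- get_toy()
    nw <- domainflex::build_network(toy$structure,
                                    extra_hbonds = toy$extra_constraints)
    dec <- domainflex::decompose_rigid_clusters(nw)
    H <- domainflex::build_hessian(toy$structure)
    md <- domainflex::compute_modes(H, 12)
    toy_cache$ctx <- list(toy = toy, network = nw, decomposition = dec,
                          modes = md)
  }
  toy_cache$ctx
}

## local cross product (the package keeps its own internal)
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
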