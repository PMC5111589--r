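# Small vector/rotation helpers shared across modules.  All coordinates are
# Angstrom, all user-facing angles degrees, internal angles radians.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[[2]] * b[[3]] - a[[3]] * b[[2]],
    a[[3]] * b[[1]] - a[[1]] * b[[3]],
    a[[1]] * b[[2]] - a[[2]] * b[[1]])
}

deg <- function(x) x * 180 / pi
rad <- function(x) x * pi / 180

## angle at vertex b of triple a-b-c, degrees
angle3 <- function(a, b, c) {
  u <- a - b
  v <- c - b
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu < 1e-9 || nv < 1e-9) stop("zero-length vector in angle computation")
  deg(acos(max(-1, min(1, sum(u * v) / (nu * nv)))))
}

#' Rotation matrix about an axis
#'
#' Rodrigues rotation by `theta` degrees about `axis`.
#' @param axis length-3 axis vector (normalized internally).
#' @param theta angle in degrees.
#' @return 3 x 3 proper rotation matrix.
#' @export
rotation_matrix <- function(axis, theta) {
  a <- unitv(axis)
  th <- rad(theta)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation minimising the RMSD of
#' `P %*% R + t` onto `Q`, and returns the fit.
#'
#' @param P,Q n x 3 coordinate matrices (moving, fixed) with matched rows.
#' @return list with `R` (3 x 3 rotation), `t` (length-3 translation),
#'   `rmsd`, and `Pfit` (= transformed `P`).
#' @export
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3, nrow(P) >= 3)
  cp <- colMeans(P)
  cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp)
  Q0 <- sweep(Q, 2, cq)
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  Pfit <- P0 %*% t(R)
  Pfit <- sweep(Pfit, 2, cq, "+")
  list(R = R, t = cq - as.vector(R %*% cp), rmsd = sqrt(mean(rowSums((Pfit - Q) ^ 2))),
       Pfit = Pfit)
}
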