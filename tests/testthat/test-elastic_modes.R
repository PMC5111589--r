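test_that("two-site Hessian matches the closed form", {
  X <- rbind(c(0, 0, 0), c(3, 4, 0))
  H <- build_hessian(X, cutoff = 10, gamma = 2)
  d <- c(3, 4, 0) / 5
  blk <- 2 * tcrossprod(d)
  expect_equal(H[1:3, 4:6], -blk, tolerance = 1e-12)
  expect_equal(H[1:3, 1:3], blk, tolerance = 1e-12)
  expect_equal(H, t(H))
})

test_that("Hessian has exact translation invariance and symmetry", {
  h <- make_helix(10)
  H <- build_hessian(h)
  expect_lt(max(abs(H - t(H))), 1e-12)
  n <- nrow(select_calpha(h))
  for (k in 1:3) {
    tvec <- rep(0, 3 * n)
    tvec[seq(k, 3 * n, by = 3)] <- 1
    expect_lt(max(abs(H %*% tvec)), 1e-10)
  }
  expect_error(build_hessian(cbind(0:5, 0, 0)), "collinear")
})

test_that("connected fixtures have exactly six trivial modes", {
  for (s in list(make_helix(10), make_sheet(3, 5),
                 make_peptide_chain(8, -57, -47))) {
    H <- build_hessian(s)
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    ev <- rev(ev)
    ev[ev < 0] <- 0
    expect_equal(sum(ev < 1e-8 * ev[7]), 6L, info = s$label)
    md <- compute_modes(H, 8)
    expect_equal(sum(md$trivial), 6L)
    expect_false(md$trivial[7])
  }
})

test_that("disconnected input is rejected with more than six zero modes", {
  h <- make_helix(8)
  far <- make_helix(8)
  a2 <- far$atoms
  a2$x <- a2$x + 100
  a2$resno <- a2$resno + 100L
  a2$serial <- a2$serial + nrow(h$atoms)
  both <- new_structure(rbind(h$atoms, a2))
  expect_error(compute_modes(build_hessian(both)), "disconnected")
})

test_that("toy hinge is the softest nontrivial mode", {
  ctx <- get_toy_context()
  toy <- ctx$toy
  md <- ctx$modes
  ca <- select_calpha(toy$structure)
  res <- as.integer(rownames(ca))
  hin <- matrix(0, nrow(ca), 3)
  for (i in which(res %in% toy$dom2_residues))
    hin[i, ] <- cross3(toy$axis, ca[i, ] - toy$pivot)
  v <- as.vector(t(hin))
  v <- v / sqrt(sum(v ^ 2))
  Vt <- md$vectors[, 1:6]
  v <- v - Vt %*% (t(Vt) %*% v)        # remove rigid-body content
  v <- v / sqrt(sum(v ^ 2))
  expect_gt(abs(sum(v * md$vectors[, 7])), 0.8)
})

test_that("eigenvectors are orthonormal with nonnegative eigenvalues", {
  md <- get_toy_context()$modes
  G <- crossprod(md$vectors)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  expect_true(all(md$values >= 0))
  expect_false(is.unsorted(md$values))
})

test_that("mode shapes are rotation-invariant up to sign", {
  toy <- get_toy()
  H1 <- build_hessian(toy$structure)
  m1 <- compute_modes(H1, 9)
  R <- rotation_matrix(c(1, 2, 3), 35)
  rot <- set_coords(toy$structure, coords(toy$structure) %*% t(R))
  m2 <- compute_modes(build_hessian(rot), 9)
  expect_equal(m1$values[7:9], m2$values[7:9], tolerance = 1e-8)
  for (k in 7:8) {
    v1 <- matrix(m1$vectors[, k], ncol = 3, byrow = TRUE) %*% t(R)
    ov <- abs(sum(v1 * matrix(m2$vectors[, k], ncol = 3, byrow = TRUE)))
    expect_gt(ov, 0.99)
  }
})

test_that("rigid-residue extension behaves as specified", {
  toy <- get_toy()
  n_res <- nrow(select_calpha(toy$structure))
  ## translation mode: identical displacement on every atom
  tm <- matrix(rep(c(1, 0, 0), each = n_res), ncol = 3)
  V <- extend_mode_to_atoms(toy$structure, tm)
  expect_equal(nrow(V), nrow(toy$structure$atoms))
  expect_lt(max(abs(sweep(V, 2, V[1, ]))), 1e-12)
  expect_equal(sum(V ^ 2), 1)                       # unit norm
  ## structure with a residue missing its C-alpha is rejected
  broken <- toy$structure
  broken$atoms <- broken$atoms[!(broken$atoms$resno == 2 &
                                   broken$atoms$name == "CA"), ]
  expect_error(extend_mode_to_atoms(broken, tm), "C-alpha")
})
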