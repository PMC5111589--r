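test_that("sheet_frame matches closed forms on the unit square", {
  sq <- rbind("1" = c(0, 0, 0), "2" = c(1, 0, 0), "3" = c(1, 1, 0),
              "4" = c(0, 1, 0))
  f <- sheet_frame(sq, 1:4)
  expect_equal(f$normal, c(0, 0, 1))
  expect_equal(unname(f$center), c(0.5, 0.5, 0))
  ## reversing the perimeter order flips the normal (cross-product
  ## antisymmetry); note a bare p3/p4 swap instead degenerates the
  ## quadrilateral into parallel diagonals
  f2 <- sheet_frame(sq[4:1, ], 4:1)
  expect_equal(f2$normal, c(0, 0, -1))
  expect_error(sheet_frame(sq[c(1, 2, 4, 3), ], c(1, 2, 4, 3)), "collinear")
  ## collinear diagonals are rejected
  line <- rbind("1" = c(0, 0, 0), "2" = c(1, 0, 0), "3" = c(2, 0, 0),
                "4" = c(3, 0, 0))
  expect_error(sheet_frame(line, 1:4), "collinear")
})

test_that("tilt matches closed forms and is symmetric", {
  f0 <- list(normal = c(0, 0, 1), center = c(0, 0, 0))
  expect_equal(tilt(f0, f0), 0)
  f45 <- list(normal = c(0, 1, 1) / sqrt(2), center = c(5, 0, 0))
  expect_equal(tilt(f0, f45), 45)
  set.seed(5)
  for (k in 1:100) {
    fr <- random_frames()
    expect_equal(tilt(fr$f1, fr$f2), tilt(fr$f2, fr$f1), tolerance = 1e-10)
    expect_gte(tilt(fr$f1, fr$f2), 0)
    expect_lte(tilt(fr$f1, fr$f2), 180)
  }
})

test_that("twist follows the right-hand rule and is antisymmetric", {
  f1 <- list(normal = c(0, 0, 1), center = c(0, 0, 0))
  f2 <- list(normal = c(0, 0, 1), center = c(1, 0, 0))
  expect_equal(twist(f1, f2), 0)
  ## rotation-matrix oracle: rotate n1 by a known angle about r12
  set.seed(6)
  for (k in 1:100) {
    e <- runit()
    n1 <- runit()
    if (abs(sum(n1 * e)) > 0.95) next
    delta <- stats::runif(1, -170, 170)
    g1 <- list(normal = n1, center = c(0, 0, 0))
    g2 <- list(normal = as.vector(rotation_matrix(e, delta) %*% n1),
               center = 4 * e)
    expect_equal(twist(g1, g2), delta, tolerance = 1e-8)
    ## antisymmetry when the two normals are exchanged about the same axis
    h1 <- list(normal = g2$normal, center = g1$center)
    h2 <- list(normal = g1$normal, center = g2$center)
    expect_equal(twist(h1, h2), -delta, tolerance = 1e-8)
    ## full order reversal also reverses the axis, so the two sign flips
    ## cancel (as for a conventional torsion under chain reversal)
    expect_equal(twist(g2, g1), twist(g1, g2), tolerance = 1e-8)
  }
  ## degenerate: normal parallel to the interplane axis
  fpar <- list(normal = c(1, 0, 0), center = c(0, 0, 0))
  expect_error(twist(fpar, f2), "undefined")
})

test_that("dcc matches the Euclidean closed form", {
  atoms <- data.frame(serial = 1:2, name = "CA", element = "C",
                      resno = c(1L, 2L), resname = "GLY", chain = "A",
                      x = c(0, 3), y = c(0, 4), z = 0)
  s <- new_structure(atoms)
  expect_equal(dcc(s, 1, 2), 5)
  expect_equal(dcc(s, 1, 1), 0)
  expect_error(dcc(s, 1, 9), "9")
})

test_that("pseudodihedral cosine discriminates extended from helical chains", {
  helix <- make_helix(12)
  cx <- cos_xi(helix)
  expect_true(all(is.na(cx[c(1, 11, 12)])))        # first and last two
  expect_equal(mean(cx, na.rm = TRUE), -0.7, tolerance = 0.1)
  zig <- make_helix(12, rise = 3.3, turn = 180, radius = 0.5)
  expect_equal(mean(cos_xi(zig), na.rm = TRUE), 1, tolerance = 0.05)
  expect_true(all(abs(cx[!is.na(cx)]) <= 1))
  short <- make_peptide_chain(3, -57, -47)
  expect_error(cos_xi(short), "at least 4")
})

test_that("flexibility profile is zero for a rigid trajectory", {
  h <- make_helix(10)
  tr <- new_trajectory(h, list(coords(h), random_rigid_motion(coords(h), 3),
                               random_rigid_motion(coords(h), 4)))
  prof <- pseudodihedral_profile(tr)
  expect_true(all(prof$rms_cos_xi[!is.na(prof$rms_cos_xi)] < 1e-10))
  expect_error(pseudodihedral_profile(new_trajectory(h, list(coords(h)))),
               "at least 2")
})

test_that("domain_rmsd removes rigid motion and matches the quaternion oracle", {
  toy <- get_toy()
  dom <- toy$config$domains[[1]]
  X <- coords(toy$structure)
  ## conformer 2 = rigidly moved copy -> RMSD 0
  tr <- new_trajectory(toy$structure, list(X, random_rigid_motion(X, 11)))
  r <- domain_rmsd(tr, dom)
  expect_equal(r[1], 0, tolerance = 1e-9)
  expect_lt(r[2], 1e-6)
  ## single displaced C-alpha: equals the independent quaternion value
  cai <- which(toy$structure$atoms$name == "CA" &
                 toy$structure$atoms$resno %in% dom$residues)
  X2 <- X
  X2[cai[4], ] <- X2[cai[4], ] + c(1, 0, 0)
  tr2 <- new_trajectory(toy$structure, list(X, X2))
  expect_equal(domain_rmsd(tr2, dom)[2],
               oracle_quaternion_rmsd(X2[cai, ], X[cai, ]),
               tolerance = 1e-9)
  expect_error(domain_rmsd(tr2, domain_definition("t", rbind(c(1, 2)))),
               "at least 3")
})

test_that("sheet angles: closed form, rigid nullity, and hinge-motion bounds", {
  atoms <- data.frame(serial = 1:3, name = "CA", element = "C",
                      resno = 1:3, resname = "GLY", chain = "A",
                      x = c(1, 0, 0), y = c(0, 0, 1), z = 0)
  s <- new_structure(atoms)
  tr <- new_trajectory(s, list(coords(s), random_rigid_motion(coords(s), 2)))
  st <- sheet_angle_stats(tr, list(c(1, 2, 3)))
  expect_equal(st$mean_deg, 90, tolerance = 1e-9)
  expect_lt(st$sd_deg, 1e-9)
  ## sheet geometry stays constant through the toy hinge motion
  toy <- get_toy()
  q <- toy$config$domains[[1]]$sheet_quad
  st2 <- sheet_angle_stats(toy$trajectory, list(q[1:3], q[2:4]))
  expect_true(all(st2$sd_deg < 1e-8))
})

test_that("all measures are invariant under global rigid motion", {
  toy <- get_toy()
  s <- toy$structure
  s2 <- apply_rigid_motion(s, 21)
  q1 <- toy$config$domains[[1]]$sheet_quad
  q2 <- toy$config$domains[[2]]$sheet_quad
  g1 <- list(sheet_frame(s, q1), sheet_frame(s, q2))
  g2 <- list(sheet_frame(s2, q1), sheet_frame(s2, q2))
  expect_equal(tilt(g2[[1]], g2[[2]]), tilt(g1[[1]], g1[[2]]),
               tolerance = 1e-9)
  expect_equal(twist(g2[[1]], g2[[2]]), twist(g1[[1]], g1[[2]]),
               tolerance = 1e-9)
  rr <- toy$config$dcc_residues
  expect_equal(dcc(s2, rr[1], rr[2]), dcc(s, rr[1], rr[2]), tolerance = 1e-9)
  expect_equal(cos_xi(s2), cos_xi(s), tolerance = 1e-9)
})

test_that("measures recover the toy ground truth, with noise scaling", {
  toy <- get_toy()
  ms <- measure_series(toy$trajectory, toy$config)
  expect_lt(max(abs(ms$tilt_D1_D2 - toy$truth$tilt)), 1)
  expect_lt(max(abs(ms$dcc - toy$truth$dcc)), 0.1)
  expect_lt(max(ms$rmsd_D1, ms$rmsd_D2), 1e-6)
  ## noisy generator: errors grow with sigma but stay bounded
  noisy <- make_hinge_toy(noise_sd = 0.1, seed = 3)
  msn <- measure_series(noisy$trajectory, noisy$config)
  err <- max(abs(msn$tilt_D1_D2 - noisy$truth$tilt))
  expect_gt(err, 1e-6)
  expect_lt(err, 8)    # bound measured at sigma = 0.1 before freezing
})
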