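test_that("relaxation is a fixed point on a satisfying conformer", {
  ctx <- get_toy_context()
  rx <- relax_to_constraints(ctx$toy$structure, ctx$decomposition, ctx$network)
  expect_lt(max(abs(coords(rx) - coords(ctx$toy$structure))), 1e-6)
})

test_that("relaxation restores displaced cluster geometry and resolves clashes", {
  ctx <- get_toy_context()
  toy <- ctx$toy
  cfg <- simulation_config()
  ## break internal geometry: kick one atom of the largest cluster by 1 A
  cl <- ctx$decomposition$cluster
  big <- which(cl == 1)
  X <- coords(toy$structure)
  X[big[5], ] <- X[big[5], ] + c(1, 0, 0)
  rx <- relax_to_constraints(set_coords(toy$structure, X),
                             ctx$decomposition, ctx$network, cfg)
  X0 <- coords(toy$structure)
  Xr <- coords(rx)
  for (c0 in 1:2) {
    idx <- which(cl == c0)
    expect_lt(kabsch(Xr[idx, ], X0[idx, ])$rmsd, cfg$template_tol)
  }
})

test_that("forced steric overlap is pushed back beyond the clash limit", {
  ## two rigid diatomic fragments forced 1 A apart
  atoms <- data.frame(
    serial = 1:4, name = c("CB", "CG", "CB", "CG"), element = "C",
    resno = c(1L, 1L, 4L, 4L), resname = "ALA", chain = "A",
    x = c(0, 1.5, 10, 11.5), y = 0, z = 0)
  s <- suppressWarnings(new_structure(atoms))
  nw <- suppressWarnings(build_network(s, include_tethers = FALSE))
  dec <- decompose_rigid_clusters(nw)
  X <- coords(s)
  X[3:4, 1] <- X[3:4, 1] - 9      # now CG(1) at x=1.5, CB(4) at x=1
  cfg <- simulation_config(max_iter = 500)
  rx <- relax_to_constraints(set_coords(s, X), dec, nw, cfg)
  d <- sqrt(sum((coords(rx)[2, ] - coords(rx)[3, ]) ^ 2))
  expect_gte(d, 2 * 1.7 - cfg$clash_tol - 0.51 * cfg$template_tol)
})

test_that("perturb_start is deterministic, amplitude-scaled and identity at zero", {
  ctx <- get_toy_context()
  toy <- ctx$toy
  expect_identical(perturb_start(toy$structure, 1, 0), toy$structure)
  p1 <- perturb_start(toy$structure, 42, 0.2, ctx$network, ctx$decomposition)
  p2 <- perturb_start(toy$structure, 42, 0.2, ctx$network, ctx$decomposition)
  expect_identical(coords(p1), coords(p2))
  ## C-alpha RMSD from input within the empirically measured band
  cai <- which(toy$structure$atoms$name == "CA")
  rmsds <- vapply(1:8, function(sd) {
    p <- perturb_start(toy$structure, sd, 0.2, ctx$network, ctx$decomposition)
    sqrt(mean(rowSums((coords(p)[cai, ] - coords(toy$structure)[cai, ]) ^ 2)))
  }, 0)
  expect_true(all(rmsds > 0.05 & rmsds < 0.5))
})

test_that("mode_follow records the right conformers and is reproducible", {
  ctx <- get_toy_context()
  cfg0 <- simulation_config(n_steps = 0, save_every = 100, n_starts = 1)
  tr0 <- mode_follow(ctx$toy$structure, ctx$network, ctx$decomposition,
                     ctx$modes, 7, 1, cfg0)
  expect_equal(n_conformers(tr0), 1L)
  cfg <- simulation_config(n_steps = 300, save_every = 100, n_starts = 1)
  tr <- mode_follow(ctx$toy$structure, ctx$network, ctx$decomposition,
                    ctx$modes, 7, 1, cfg)
  expect_equal(tr$meta$step, c(0L, 100L, 200L, 300L))
  tr2 <- mode_follow(ctx$toy$structure, ctx$network, ctx$decomposition,
                     ctx$modes, 7, 1, cfg)
  expect_identical(tr$coords, tr2$coords)    # bit-identical rerun
  expect_error(mode_follow(ctx$toy$structure, ctx$network, ctx$decomposition,
                           ctx$modes, 3, 1, cfg), "trivial")
})

test_that("C-alpha RMSD grows monotonically along m7 before any stall", {
  ctx <- get_toy_context()
  cfg <- simulation_config(n_steps = 1500, save_every = 100, n_starts = 1)
  for (dir in c(1, -1)) {
    tr <- mode_follow(ctx$toy$structure, ctx$network, ctx$decomposition,
                      ctx$modes, 7, dir, cfg)
    cai <- which(tr$topology$atoms$name == "CA")
    rmsd <- vapply(seq_len(n_conformers(tr)), function(i)
      sqrt(mean(rowSums((tr$coords[[i]][cai, ] -
                           tr$coords[[1]][cai, ]) ^ 2))), 0)
    expect_gt(rmsd[length(rmsd)], 1)           # substantial net motion
    expect_true(all(diff(rmsd) > -0.05))       # monotone within tolerance
  }
})

test_that("constraints hold at every saved conformer", {
  ctx <- get_toy_context()
  cfg <- simulation_config(n_steps = 600, save_every = 100, n_starts = 1)
  tr <- mode_follow(ctx$toy$structure, ctx$network, ctx$decomposition,
                    ctx$modes, 7, 1, cfg)
  X0 <- coords(ctx$toy$structure)
  cl <- ctx$decomposition$cluster
  bonds <- ctx$network$bonds
  a <- ctx$toy$structure$atoms
  radii <- c(C = 1.70, N = 1.55, O = 1.52)[a$element]
  d0 <- sqrt(rowSums((X0[bonds$i, ] - X0[bonds$j, ]) ^ 2))
  for (i in seq_len(n_conformers(tr))) {
    X <- tr$coords[[i]]
    ## rigid-cluster internal geometry
    for (c0 in 1:2) {
      idx <- which(cl == c0)
      expect_lt(kabsch(X[idx, ], X0[idx, ])$rmsd, cfg$template_tol)
    }
    ## covalent bond conservation
    d <- sqrt(rowSums((X[bonds$i, ] - X[bonds$j, ]) ^ 2))
    expect_lt(max(abs(d - d0)), 3 * cfg$template_tol)
    ## steric feasibility for far-in-sequence, different-cluster pairs
    DM <- as.matrix(dist(X))
    pr <- which(upper.tri(DM) & DM < 3.4, arr.ind = TRUE)
    if (nrow(pr)) {
      ok <- abs(a$resno[pr[, 1]] - a$resno[pr[, 2]]) > 2 &
        cl[pr[, 1]] != cl[pr[, 2]]
      pr <- pr[ok, , drop = FALSE]
      if (nrow(pr)) {
        d <- DM[pr]
        lim <- radii[pr[, 1]] + radii[pr[, 2]] - cfg$clash_tol
        expect_gte(min(d - lim), -0.51 * cfg$template_tol)
      }
    }
  }
})

test_that("run_all_modes produces the requested trajectory grid", {
  ctx <- get_toy_context()
  cfg <- simulation_config(n_steps = 100, save_every = 100, n_starts = 1)
  t2 <- run_all_modes(ctx$toy$structure, ctx$network, ctx$decomposition,
                      ctx$modes, cfg, modes = 7)
  expect_length(t2, 2L)
  cfg3 <- simulation_config(n_steps = 100, save_every = 100, n_starts = 3)
  t6 <- run_all_modes(ctx$toy$structure, ctx$network, ctx$decomposition,
                      ctx$modes, cfg3, modes = 7)
  expect_length(t6, 6L)
  runs <- attr(t6, "runs")
  expect_equal(sort(unique(runs$seed)), cfg3$seed + 0:2)
  expect_error(run_all_modes(ctx$toy$structure, ctx$network,
                             ctx$decomposition, ctx$modes, cfg, modes = 7:20),
               "fewer than")
})
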