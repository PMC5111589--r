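test_that("pebble-game floppy counts match the Jacobian oracle on random frameworks", {
  set.seed(2024)
  for (t in 1:25) {
    fw <- random_framework(12)
    pf <- pebble_floppy_count(fw$n, fw$edges)$floppy
    jf <- oracle_jacobian_floppy(fw$n, fw$edges)
    expect_equal(pf, jf,
                 info = sprintf("framework %d (n=%d, edges=%d)", t, fw$n,
                                nrow(fw$edges)))
  }
})

test_that("canonical small frameworks decompose as expected", {
  ## fully constrained triangle of bodies (6 bars everywhere): one cluster
  tri <- data.frame(bu = c(1, 2, 1), bv = c(2, 3, 3), bars = 6L)
  expect_equal(pebble_floppy_count(3, tri)$floppy, 6L)
  ## two bodies joined by a single rotatable (5-bar) joint:
  ## one internal degree of freedom beyond the trivial six
  hinge <- data.frame(bu = 1, bv = 2, bars = 5L)
  expect_equal(pebble_floppy_count(2, hinge)$floppy, 7L)
})

test_that("rigidified toy domains collapse to one cluster each", {
  ctx <- get_toy_context()
  dec <- ctx$decomposition
  expect_gte(dec$floppy, 6L)
  ct <- cluster_table(ctx$network, dec)
  for (dom in ctx$toy$config$domains) {
    cl <- ct$cluster[ct$resno %in% dom$residues]
    expect_gte(max(table(cl)) / length(cl), 0.9)
  }
  ## the two domains are distinct clusters (the linker is flexible)
  c1 <- names(which.max(table(ct$cluster[ct$resno %in%
                                           ctx$toy$config$domains[[1]]$residues])))
  c2 <- names(which.max(table(ct$cluster[ct$resno %in%
                                           ctx$toy$config$domains[[2]]$residues])))
  expect_false(c1 == c2)
})

test_that("adding a bar never splits a cluster (rigidity monotonicity)", {
  toy <- get_toy()
  nw1 <- build_network(toy$structure, extra_hbonds = toy$extra_constraints)
  dec1 <- decompose_rigid_clusters(nw1)
  ## add one more constraint between the two domains
  ca <- which(toy$structure$atoms$name == "CA")
  extra2 <- rbind(toy$extra_constraints,
                  data.frame(donor = ca[2], acceptor = ca[length(ca) - 2],
                             energy = -5))
  nw2 <- build_network(toy$structure, extra_hbonds = extra2)
  dec2 <- decompose_rigid_clusters(nw2)
  ## every same-cluster pair under dec1 remains same-cluster under dec2
  for (cl in unique(dec1$cluster)) {
    members <- which(dec1$cluster == cl)
    expect_equal(length(unique(dec2$cluster[members])), 1L)
  }
})

test_that("decomposition is invariant under atom input order", {
  toy <- get_toy()
  s <- toy$structure
  set.seed(7)
  perm <- sample(nrow(s$atoms))
  a2 <- s$atoms[perm, ]
  a2$serial <- seq_len(nrow(a2))
  s2 <- new_structure(a2, label = "permuted")
  key <- function(st) paste(st$atoms$chain, st$atoms$resno, st$atoms$name)
  nw1 <- build_network(s)
  nw2 <- build_network(s2)
  d1 <- decompose_rigid_clusters(nw1)
  d2 <- decompose_rigid_clusters(nw2)
  ## compare partitions as label-free equivalence relations
  part <- function(st, dec) split(key(st), dec$cluster)
  norm <- function(p) unname(sort(vapply(p, function(g)
    paste(sort(g), collapse = "|"), "")))
  expect_equal(norm(part(s, d1)), norm(part(s2, d2)))
})
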