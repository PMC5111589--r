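test_that("PDB text round-trips through write/read at PDB precision", {
  txt <- mini_pdb_text()
  s <- read_structure(txt)
  expect_s3_class(s, "Structure")
  expect_equal(sum(s$atoms$name == "CA"), 3)
  s2 <- read_structure(write_structure(s))
  expect_lt(max(abs(coords(s2) - coords(s))), 1e-3)
  expect_equal(s2$atoms$resno, s$atoms$resno)
})

test_that("degenerate and malformed inputs are rejected with clear errors", {
  water <- c(
    "HETATM    1  O   HOH A 501      10.000  10.000  10.000  1.00  0.00           O",
    "END")
  expect_error(read_structure(water), "no protein atoms")
  bad <- c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.458   xxx     0.000  1.00  0.00           C")
  expect_error(read_structure(bad), "line 2")
})

test_that("altloc resolution keeps highest occupancy, ties by letter", {
  lines <- c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AGLY A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BGLY A   1       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      4  C  AGLY A   1       3.000   0.000   0.000  0.50  0.00           C",
    "ATOM      5  C  BGLY A   1       4.000   0.000   0.000  0.50  0.00           C")
  s <- read_structure(lines)
  expect_equal(s$atoms$x[s$atoms$name == "CA"], 2.0)  # higher occupancy
  expect_equal(s$atoms$x[s$atoms$name == "C"], 3.0)   # tie -> altloc A
})

test_that("multi-model writing preserves topology, ordering and coordinates", {
  toy <- get_toy()
  traj <- toy$trajectory
  txt <- write_conformers(traj)
  expect_equal(sum(grepl("^MODEL", txt)), n_conformers(traj))
  back <- read_trajectory(txt)
  expect_equal(n_conformers(back), n_conformers(traj))
  expect_lt(max(abs(back$coords[[3]] - traj$coords[[3]])), 1e-3)
  expect_equal(back$topology$atoms$name, traj$topology$atoms$name)
  ## topology mismatch across conformers is rejected
  expect_error(
    new_trajectory(traj$topology, list(traj$coords[[1]],
                                       traj$coords[[2]][-1, ])),
    "topology mismatch")
})

test_that("C-alpha selection is order-preserving and names missing residues", {
  h <- make_helix(10)
  m <- select_calpha(h)
  expect_equal(nrow(m), 10)
  expect_equal(rownames(m), as.character(1:10))
  m2 <- select_calpha(h, c(7, 3, 5))
  expect_equal(rownames(m2), c("7", "3", "5"))
  expect_error(select_calpha(h, c(3, 99)), "99")
})

test_that("domain configuration validates its invariants and round-trips JSON", {
  expect_error(domain_definition("a", rbind(c(1, 10)), sheet_quad = c(2, 2, 4, 5)),
               "distinct")
  expect_error(domain_definition("a", rbind(c(1, 10), c(5, 15))), "overlap")
  cfg <- analysis_config(
    list(domain_definition("a", rbind(c(1, 10)), sheet_quad = c(2, 4, 7, 9),
                           angle_triples = list(c(2, 4, 6)), active_site = 3),
         domain_definition("b", rbind(c(11, 20)), sheet_quad = c(12, 14, 17, 19))),
    dcc_residues = c(3, 15))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    domains = list(
      list(name = "a", intervals = list(c(1, 10)), sheet_quad = c(2, 4, 7, 9),
           angle_triples = list(c(2, 4, 6)), active_site = 3),
      list(name = "b", intervals = list(c(11, 20)),
           sheet_quad = c(12, 14, 17, 19))),
    dcc_residues = c(3, 15)), path, auto_unbox = FALSE)
  cfg2 <- read_analysis_config(path)
  expect_equal(cfg2$domains$a$sheet_quad, cfg$domains$a$sheet_quad)
  expect_equal(cfg2$dcc_residues, cfg$dcc_residues)
  ## validation errors name the missing residue
  h <- make_helix(10)
  bad <- analysis_config(list(domain_definition("a", rbind(c(1, 10)),
                                                sheet_quad = c(2, 4, 7, 42))))
  expect_error(validate_config(h, bad), "42")
})
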