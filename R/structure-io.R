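# Structure and Trajectory containers plus fixed-width PDB reading/writing.
# Residue numbering is author (PDB) numbering throughout; coordinates are
# Angstrom.  Altloc policy: keep the highest-occupancy conformer, ties broken
# by altloc letter.

AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL", "MSE", "SEC", "PYL")

#' Construct a Structure from an atom table
#'
#' The atom table is the universal currency of the package: one row per atom
#' with serial, atom name, element, author residue number, residue name,
#' chain id and Cartesian coordinates in Angstrom.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`, `resno`,
#'   `resname`, `chain`, `x`, `y`, `z` (and optionally `occ`).
#' @param label provenance label (file name, fixture name, ...).
#' @return object of class `Structure`.
#' @export
new_structure <- function(atoms, label = "structure") {
  need <- c("serial", "name", "element", "resno", "resname", "chain",
            "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty structure: no protein atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in structure")
  atoms$serial <- as.integer(atoms$serial)
  atoms$resno <- as.integer(atoms$resno)
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate atom (chain, residue, name) after altloc resolution: ",
         key[which(duplicated(key))[1]])
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, label = label), class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("Structure '%s': %d atoms, %d residues, chains %s\n",
              x$label, nrow(a), length(unique(paste(a$chain, a$resno))),
              paste(unique(a$chain), collapse = ",")))
  invisible(x)
}

#' Coordinates of a Structure as an n x 3 matrix
#' @param structure a `Structure`.
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a Structure
#' @param structure a `Structure`.
#' @param xyz n x 3 matrix matching the atom table.
#' @export
set_coords <- function(structure, xyz) {
  stopifnot(nrow(xyz) == nrow(structure$atoms), ncol(xyz) == 3)
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

parse_pdb_atoms <- function(lines, lineno) {
  rec <- substr(lines, 1, 6)
  serial <- suppressWarnings(as.integer(substr(lines, 7, 11)))
  name <- trimws(substr(lines, 13, 16))
  altloc <- substr(lines, 17, 17)
  resname <- trimws(substr(lines, 18, 20))
  chain <- substr(lines, 22, 22)
  resno <- suppressWarnings(as.integer(substr(lines, 23, 26)))
  x <- suppressWarnings(as.numeric(substr(lines, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(lines, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(lines, 47, 54)))
  occ <- suppressWarnings(as.numeric(substr(lines, 55, 60)))
  occ[is.na(occ)] <- 1
  elem <- trimws(substr(lines, 77, 78))
  bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(resno))
  if (length(bad))
    stop(sprintf("malformed PDB record at line %d: '%s'",
                 lineno[bad[1]], substr(lines[bad[1]], 1, 40)))
  ## infer element from atom name when the element column is blank
  noel <- elem == ""
  if (any(noel)) {
    nm <- gsub("[0-9']", "", name[noel])
    elem[noel] <- toupper(substr(nm, 1, 1))
    two <- substr(nm, 1, 2) %in% c("SE", "FE", "ZN", "MG", "CL", "BR")
    elem[noel][two] <- substr(nm[two], 1, 2)
  }
  data.frame(record = trimws(rec), serial = serial, name = name,
             altloc = altloc, element = elem, resno = resno,
             resname = resname, chain = chain, x = x, y = y, z = z,
             occ = occ, stringsAsFactors = FALSE)
}

resolve_altloc <- function(df) {
  has <- df$altloc != " " & df$altloc != ""
  if (!any(has)) {
    df$altloc <- NULL
    return(df)
  }
  key <- paste(df$chain, df$resno, df$name)
  ## order by occupancy (desc) then altloc letter (asc); keep first per key
  o <- order(key, -df$occ, df$altloc)
  df <- df[o, ]
  df <- df[!duplicated(paste(df$chain, df$resno, df$name)), ]
  df <- df[order(df$serial), ]
  df$altloc <- NULL
  df
}

#' Read a protein structure from PDB-format text
#'
#' Reads ATOM records of the first MODEL (use [read_trajectory()] for
#' multi-model files).  HETATM records and waters are dropped; hydrogens are
#' kept if present.  Alternate locations are resolved to the
#' highest-occupancy conformer (ties by altloc letter).
#'
#' @param source path to a PDB file, or a character vector of PDB lines.
#' @param keep_hydrogens keep hydrogen atoms (default TRUE).
#' @return a [new_structure()] `Structure`.
#' @export
read_structure <- function(source, keep_hydrogens = TRUE) {
  lines <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source))
    readLines(source) else unlist(strsplit(source, "\n", fixed = TRUE))
  label <- if (length(source) == 1L && file.exists(source)) basename(source) else "pdb-text"
  ## truncate to first model if MODEL records present
  endm <- grep("^ENDMDL", lines)
  if (length(endm)) lines <- lines[seq_len(endm[1] - 1L)]
  sel <- grep("^ATOM  |^HETATM", lines)
  if (!length(sel)) stop("no protein atoms found in input")
  df <- parse_pdb_atoms(lines[sel], sel)
  df <- df[df$record == "ATOM" & df$resname %in% AMINO3, ]
  if (nrow(df) == 0L) stop("no protein atoms found in input")
  if (!keep_hydrogens) df <- df[df$element != "H", ]
  df <- resolve_altloc(df)
  df$record <- NULL
  df$occ <- NULL
  if (!any(df$name == "CA")) stop("no protein atoms: structure has no C-alpha atoms")
  new_structure(df, label = label)
}

#' Construct a Trajectory
#'
#' An ordered set of conformers sharing one topology.  Coordinates are held
#' as a list of n x 3 matrices; per-conformer metadata records the generating
#' mode, direction, step index and seed.
#'
#' @param topology `Structure` giving the shared atom table.
#' @param coord_list list of n x 3 coordinate matrices.
#' @param meta data.frame with one row per conformer; a `step` column is
#'   required and must be strictly increasing.
#' @export
new_trajectory <- function(topology, coord_list,
                           meta = data.frame(step = seq_along(coord_list) - 1L)) {
  stopifnot(inherits(topology, "Structure"), length(coord_list) >= 1L)
  n <- nrow(topology$atoms)
  ok <- vapply(coord_list, function(m) is.matrix(m) && nrow(m) == n && ncol(m) == 3,
               logical(1))
  if (!all(ok)) stop("conformer topology mismatch: all conformers must share atom count/order")
  if (nrow(meta) != length(coord_list)) stop("meta must have one row per conformer")
  if (is.unsorted(meta$step, strictly = TRUE)) stop("step indices must be strictly increasing")
  structure(list(topology = topology, coords = coord_list, meta = meta),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d conformers x %d atoms (steps %d..%d)\n",
              length(x$coords), nrow(x$topology$atoms),
              min(x$meta$step), max(x$meta$step)))
  invisible(x)
}

#' Number of conformers in a trajectory
#' @param traj a `Trajectory`.
#' @export
n_conformers <- function(traj) length(traj$coords)

#' Extract one conformer as a Structure
#' @param traj a `Trajectory`.
#' @param i conformer index (1-based).
#' @export
conformer <- function(traj, i) {
  stopifnot(i >= 1L, i <= length(traj$coords))
  set_coords(traj$topology, traj$coords[[i]])
}

#' Read a multi-model PDB file as a Trajectory
#' @param source path or character vector of PDB lines.
#' @export
read_trajectory <- function(source) {
  lines <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source))
    readLines(source) else unlist(strsplit(source, "\n", fixed = TRUE))
  starts <- grep("^MODEL", lines)
  if (!length(starts)) {
    s <- read_structure(lines)
    return(new_trajectory(s, list(coords(s))))
  }
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts)) stop("unbalanced MODEL/ENDMDL records")
  models <- lapply(seq_along(starts), function(i)
    read_structure(lines[(starts[i] + 1L):(ends[i] - 1L)]))
  topo <- models[[1]]
  cl <- lapply(models, function(s) {
    if (nrow(s$atoms) != nrow(topo$atoms) ||
        !all(s$atoms$name == topo$atoms$name & s$atoms$resno == topo$atoms$resno))
      stop("conformer topology mismatch across MODEL blocks")
    coords(s)
  })
  new_trajectory(topo, cl)
}

format_pdb_atoms <- function(atoms) {
  nm <- atoms$name
  ## PDB name justification: element right-aligned in cols 13-14
  nm4 <- ifelse(nchar(nm) >= 4, substr(nm, 1, 4),
                ifelse(nchar(atoms$element) == 2, sprintf("%-4s", nm),
                       sprintf(" %-3s", nm)))
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$serial %% 100000L, nm4, atoms$resname, atoms$chain,
          atoms$resno, atoms$x, atoms$y, atoms$z, 1, 0, atoms$element)
}

#' Write a Structure as PDB text
#' @param structure a `Structure`.
#' @param path optional output file; if NULL the text is returned.
#' @export
write_structure <- function(structure, path = NULL) {
  txt <- c(format_pdb_atoms(structure$atoms), "END")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Write a Trajectory as multi-model PDB text
#'
#' One MODEL/ENDMDL block per conformer with the atom ordering of the shared
#' topology preserved.
#'
#' @param trajectory a `Trajectory`.
#' @param path optional output file; if NULL the text is returned.
#' @export
write_conformers <- function(trajectory, path = NULL) {
  stopifnot(inherits(trajectory, "Trajectory"))
  topo <- trajectory$topology
  blocks <- lapply(seq_along(trajectory$coords), function(i) {
    s <- set_coords(topo, trajectory$coords[[i]])
    c(sprintf("MODEL     %4d", i), format_pdb_atoms(s$atoms), "ENDMDL")
  })
  txt <- c(unlist(blocks), "END")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Select ordered C-alpha coordinates
#'
#' @param structure a `Structure`.
#' @param residues residue numbers (author numbering); NULL selects every
#'   residue that has a C-alpha, in chain/sequence order.
#' @param chain restrict to one chain id (default: first chain).
#' @return matrix of C-alpha coordinates, one row per requested residue, with
#'   residue numbers as rownames.  Order follows the request.
#' @export
select_calpha <- function(structure, residues = NULL, chain = NULL) {
  a <- structure$atoms
  if (is.null(chain)) chain <- a$chain[1]
  ca <- a[a$name == "CA" & a$chain == chain, ]
  if (is.null(residues)) residues <- ca$resno
  idx <- match(residues, ca$resno)
  if (anyNA(idx))
    stop("residue ", residues[which(is.na(idx))[1]],
         " has no C-alpha atom in chain ", chain)
  m <- as.matrix(ca[idx, c("x", "y", "z")])
  rownames(m) <- residues
  m
}

ca_indices <- function(structure) which(structure$atoms$name == "CA")

#' Define a domain for the measures layer
#'
#' Holds the residue intervals of a structural domain together with the
#' residues used by the sheet-plane and sheet-angle measures: the four
#' "quadrilateral" residues (alternating central residues of two adjacent
#' antiparallel strands of the core beta-sheet, ordered p1,p2 along strand 1
#' then p3,p4 along strand 2) and up to three residue triples whose vertex
#' angles monitor sheet geometry.
#'
#' @param name domain label (e.g. "a", "b", "b'", "a'").
#' @param intervals 2-column matrix (or list of length-2 vectors) of residue
#'   ranges, non-overlapping.
#' @param sheet_quad four distinct residue numbers, or NULL.
#' @param angle_triples list of length-3 residue-number vectors, or NULL.
#' @param active_site residue numbers of functional-site residues, or NULL.
#' @export
domain_definition <- function(name, intervals, sheet_quad = NULL,
                              angle_triples = NULL, active_site = NULL) {
  if (is.list(intervals)) intervals <- do.call(rbind, intervals)
  intervals <- matrix(as.integer(intervals), ncol = 2)
  if (any(intervals[, 2] < intervals[, 1])) stop("interval end before start")
  res <- unlist(apply(intervals, 1, function(r) r[1]:r[2], simplify = FALSE))
  if (anyDuplicated(res)) stop("overlapping residue intervals in domain ", name)
  if (!is.null(sheet_quad)) {
    sheet_quad <- as.integer(sheet_quad)
    if (length(sheet_quad) != 4L || anyDuplicated(sheet_quad))
      stop("sheet_quad must be 4 distinct residue numbers")
  }
  if (!is.null(angle_triples)) {
    angle_triples <- lapply(angle_triples, as.integer)
    if (any(vapply(angle_triples, length, 1L) != 3L))
      stop("each angle triple must have 3 residues")
  }
  structure(list(name = name, intervals = intervals, residues = res,
                 sheet_quad = sheet_quad, angle_triples = angle_triples,
                 active_site = as.integer(active_site)),
            class = "DomainDefinition")
}

#' Assemble an analysis configuration
#'
#' @param domains list of [domain_definition()] objects.
#' @param dcc_residues length-2 residue-number vector for the active-site
#'   C-alpha distance (e.g. c(61, 406) for yPDI).
#' @param domain_pairs 2-column character matrix of adjacent domain names for
#'   tilt/twist; defaults to consecutive pairs of `domains` that have quads.
#' @param chain chain id used for residue lookups.
#' @export
analysis_config <- function(domains, dcc_residues = NULL, domain_pairs = NULL,
                            chain = NULL) {
  stopifnot(is.list(domains), length(domains) >= 1L)
  nm <- vapply(domains, function(d) d$name, "")
  names(domains) <- nm
  if (is.null(domain_pairs)) {
    with_quad <- nm[vapply(domains, function(d) !is.null(d$sheet_quad), TRUE)]
    if (length(with_quad) >= 2L)
      domain_pairs <- cbind(with_quad[-length(with_quad)], with_quad[-1])
  }
  structure(list(domains = domains, dcc_residues = dcc_residues,
                 domain_pairs = domain_pairs, chain = chain),
            class = "AnalysisConfig")
}

#' Read an analysis configuration from JSON
#'
#' Expected layout: `domains` (array of objects with name, intervals,
#' sheet_quad, angle_triples, active_site), `dcc_residues`, optional
#' `domain_pairs` and `chain`.
#'
#' @param path JSON file path.
#' @export
read_analysis_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  as_rows <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.matrix(x)) return(lapply(seq_len(nrow(x)), function(i) x[i, ]))
    if (!is.list(x)) return(list(x))
    x
  }
  doms <- lapply(j$domains, function(d)
    domain_definition(d$name, as_rows(d$intervals),
                      sheet_quad = d$sheet_quad,
                      angle_triples = as_rows(d$angle_triples),
                      active_site = d$active_site))
  dp <- if (!is.null(j$domain_pairs)) do.call(rbind, j$domain_pairs)
  analysis_config(doms, dcc_residues = unlist(j$dcc_residues),
                  domain_pairs = dp, chain = j$chain)
}

#' Check that a configuration resolves against a structure
#'
#' Verifies that every configured residue exists and has a C-alpha atom.
#' @param structure a `Structure`.
#' @param config an `AnalysisConfig`.
#' @return TRUE invisibly; errors name the missing residue.
#' @export
validate_config <- function(structure, config) {
  chain <- if (is.null(config$chain)) structure$atoms$chain[1] else config$chain
  have <- structure$atoms$resno[structure$atoms$name == "CA" &
                                  structure$atoms$chain == chain]
  for (d in config$domains) {
    need <- unique(c(d$sheet_quad, unlist(d$angle_triples), d$active_site))
    miss <- setdiff(need, have)
    if (length(miss))
      stop("configured residue ", miss[1], " of domain '", d$name,
           "' missing C-alpha in structure ", structure$label)
  }
  if (!is.null(config$dcc_residues)) {
    miss <- setdiff(config$dcc_residues, have)
    if (length(miss)) stop("d_cc residue ", miss[1], " missing C-alpha")
  }
  invisible(TRUE)
}
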