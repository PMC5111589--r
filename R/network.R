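# Bars-and-bodies constraint network: covalent bonds from distance rules with
# rotatable/locked classification, Mayo-style hydrogen bonds filtered at
# E_cut, and hydrophobic tethers between close apolar carbon/sulfur pairs.
#
# Bar multiplicities (body-bar molecular model): locked covalent bonds merge
# their atoms into one body; rotatable single bonds are 5-bar joints (one
# torsional degree of freedom survives); hydrogen bonds 5 bars; hydrophobic
# tethers 2 bars.

COV_RADIUS <- c(C = 0.77, N = 0.70, O = 0.66, S = 1.04, H = 0.31, SE = 1.17,
                P = 1.07)
VDW_RADIUS <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, SE = 1.90,
                P = 1.80)

cov_radius <- function(el) {
  r <- COV_RADIUS[el]
  r[is.na(r)] <- 0.77
  unname(r)
}

vdw_radius <- function(el) {
  r <- VDW_RADIUS[el]
  r[is.na(r)] <- 1.70
  unname(r)
}

## side-chain bonds that are locked (double/partial-double/resonant), keyed
## by residue name; peptide C-N and carbonyl C-O are handled separately
LOCKED_SIDECHAIN <- list(
  ARG = list(c("NE", "CZ"), c("CZ", "NH1"), c("CZ", "NH2")),
  ASP = list(c("CG", "OD1"), c("CG", "OD2")),
  GLU = list(c("CD", "OE1"), c("CD", "OE2")),
  ASN = list(c("CG", "OD1"), c("CG", "ND2")),
  GLN = list(c("CD", "OE1"), c("CD", "NE2")),
  HIS = list(c("CG", "ND1"), c("ND1", "CE1"), c("CE1", "NE2"),
             c("NE2", "CD2"), c("CD2", "CG")),
  PHE = list(c("CG", "CD1"), c("CD1", "CE1"), c("CE1", "CZ"), c("CZ", "CE2"),
             c("CE2", "CD2"), c("CD2", "CG")),
  TYR = list(c("CG", "CD1"), c("CD1", "CE1"), c("CE1", "CZ"), c("CZ", "CE2"),
             c("CE2", "CD2"), c("CD2", "CG")),
  TRP = list(c("CG", "CD1"), c("CD1", "NE1"), c("NE1", "CE2"), c("CE2", "CD2"),
             c("CD2", "CG"), c("CD2", "CE3"), c("CE3", "CZ3"), c("CZ3", "CH2"),
             c("CH2", "CZ2"), c("CZ2", "CE2")))

## all heavy-atom pairs within covalent range -> data.frame(i, j, locked)
covalent_bonds <- function(structure) {
  a <- structure$atoms
  X <- coords(structure)
  pr <- cpp_neighbor_pairs(X, 2.6)
  if (nrow(pr) == 0L) return(data.frame(i = integer(), j = integer(),
                                        locked = logical()))
  i <- pr[, 1]; j <- pr[, 2]
  d <- sqrt(rowSums((X[i, , drop = FALSE] - X[j, , drop = FALSE]) ^ 2))
  keep <- d <= cov_radius(a$element[i]) + cov_radius(a$element[j]) + 0.4 &
    d > 0.4 & !(a$element[i] == "H" & a$element[j] == "H")
  i <- i[keep]; j <- j[keep]
  locked <- logical(length(i))
  same_res <- a$chain[i] == a$chain[j] & a$resno[i] == a$resno[j]
  ## peptide bond C(i)-N(i+1)
  pep <- (a$name[i] == "C" & a$name[j] == "N" & !same_res) |
         (a$name[i] == "N" & a$name[j] == "C" & !same_res)
  locked[pep] <- TRUE
  ## carbonyl / terminal carboxylate
  co <- same_res & ((a$name[i] == "C" & a$name[j] %in% c("O", "OXT")) |
                    (a$name[j] == "C" & a$name[i] %in% c("O", "OXT")))
  locked[co] <- TRUE
  ## locked side-chain bonds by residue template
  for (rn in names(LOCKED_SIDECHAIN)) {
    sel <- same_res & a$resname[i] == rn
    if (!any(sel)) next
    for (b in LOCKED_SIDECHAIN[[rn]]) {
      hit <- sel & ((a$name[i] == b[1] & a$name[j] == b[2]) |
                    (a$name[i] == b[2] & a$name[j] == b[1]))
      locked[hit] <- TRUE
    }
  }
  data.frame(i = i, j = j, locked = locked)
}

## ideal hydrogen position on a donor from its heavy neighbours: 1.0 A along
## the negated sum of unit vectors to bonded heavy atoms
ideal_hydrogen <- function(X, donor, neighbors) {
  if (!length(neighbors)) return(NULL)
  v <- -colSums(matrix(t(apply(X[neighbors, , drop = FALSE], 1, function(p)
    unitv(p - X[donor, ]))), ncol = 3))
  if (vnorm(v) < 1e-6) return(NULL)
  X[donor, ] + unitv(v)
}

#' Detect hydrogen bonds with a Mayo-style energy
#'
#' Geometric donor-acceptor detection on heavy atoms.  Donors are nitrogens
#' and hydroxyl/thiol oxygens and sulfurs with at least one bonded heavy
#' atom; acceptors are oxygens (and histidine ring nitrogens).  The energy is
#' the simplified Mayo form
#' `E = V0 * (5 (R0/R)^12 - 6 (R0/R)^10) * cos^2(theta)` with V0 = 8
#' kcal/mol, R0 = 2.8 A, R the donor-acceptor distance and theta the
#' donor-H-acceptor angle; hydrogens are placed ideally from heavy-atom
#' geometry when absent.  Candidates require R <= 4.5 A and theta > 90
#' degrees.
#'
#' @param structure a `Structure`.
#' @param max_da maximum donor-acceptor distance (default 4.5 A).
#' @return data.frame of donor/acceptor atom indices and residues, distance,
#'   angle, and `energy` (kcal/mol), sorted by energy (strongest first).
#' @export
detect_hbonds <- function(structure, max_da = 4.5) {
  a <- structure$atoms
  X <- coords(structure)
  bonds <- covalent_bonds(structure)
  heavy <- a$element != "H"
  nb <- vector("list", nrow(a))
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    if (heavy[j]) nb[[i]] <- c(nb[[i]], j)
    if (heavy[i]) nb[[j]] <- c(nb[[j]], i)
  }
  hyd <- vector("list", nrow(a))          # explicit hydrogens per heavy atom
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    if (a$element[j] == "H") hyd[[i]] <- c(hyd[[i]], j)
    if (a$element[i] == "H") hyd[[j]] <- c(hyd[[j]], i)
  }
  is_donor <- (a$element == "N" & lengths(nb) >= 1) |
    (a$element == "O" & a$name %in% c("OG", "OG1", "OH")) |
    (a$element == "S" & a$name == "SG")
  is_acc <- a$element == "O" |
    (a$resname == "HIS" & a$name %in% c("ND1", "NE2"))
  don <- which(is_donor)
  acc <- which(is_acc)
  if (!length(don) || !length(acc))
    return(data.frame(donor = integer(), acceptor = integer(),
                      energy = numeric()))
  pr <- cpp_neighbor_pairs(X, max_da)
  cand <- rbind(pr, pr[, 2:1])
  cand <- cand[is_donor[cand[, 1]] & is_acc[cand[, 2]], , drop = FALSE]
  out <- list()
  bonded_key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
  for (k in seq_len(nrow(cand))) {
    d0 <- cand[k, 1]; ac <- cand[k, 2]
    if (d0 == ac) next
    if (a$chain[d0] == a$chain[ac] && abs(a$resno[d0] - a$resno[ac]) < 2 &&
        a$name[d0] == "N" && a$name[ac] == "O") next   # local backbone
    if (paste(min(d0, ac), max(d0, ac)) %in% bonded_key) next
    R <- vnorm(X[ac, ] - X[d0, ])
    if (R > max_da || R < 2.2) next
    Hs <- hyd[[d0]]
    Hpos <- if (length(Hs)) lapply(Hs, function(h) X[h, ]) else {
      p <- ideal_hydrogen(X, d0, nb[[d0]])
      if (is.null(p)) list() else list(p)
    }
    if (!length(Hpos)) next
    best <- -Inf
    for (hp in Hpos) {
      th <- angle3(X[d0, ], hp, X[ac, ])
      if (th > best) best <- th
    }
    if (best <= 90) next
    r10 <- (2.8 / R) ^ 10
    E <- 8 * (5 * r10 * (2.8 / R) ^ 2 - 6 * r10) * cos(rad(best)) ^ 2
    out[[length(out) + 1L]] <- data.frame(
      donor = d0, acceptor = ac, donor_res = a$resno[d0],
      acceptor_res = a$resno[ac], dist = R, angle = best, energy = E)
  }
  if (!length(out)) return(data.frame(donor = integer(), acceptor = integer(),
                                      energy = numeric()))
  hb <- do.call(rbind, out)
  hb[order(hb$energy), ]
}

## apolar carbon/sulfur atoms: C or S bonded to no N/O
apolar_atoms <- function(structure, bonds) {
  a <- structure$atoms
  polar_nb <- rep(FALSE, nrow(a))
  pol <- a$element %in% c("N", "O")
  polar_nb[bonds$i[pol[bonds$j]]] <- TRUE
  polar_nb[bonds$j[pol[bonds$i]]] <- TRUE
  which(a$element %in% c("C", "S") & !polar_nb)
}

detect_tethers <- function(structure, bonds, pad = 0.25) {
  ap <- apolar_atoms(structure, bonds)
  if (length(ap) < 2) return(data.frame(i = integer(), j = integer()))
  a <- structure$atoms
  X <- coords(structure)
  pr <- cpp_neighbor_pairs(X[ap, , drop = FALSE], 2 * 1.8 + pad + 0.1)
  if (nrow(pr) == 0L) return(data.frame(i = integer(), j = integer()))
  i <- ap[pr[, 1]]; j <- ap[pr[, 2]]
  d <- sqrt(rowSums((X[i, , drop = FALSE] - X[j, , drop = FALSE]) ^ 2))
  keep <- d <= vdw_radius(a$element[i]) + vdw_radius(a$element[j]) + pad &
    (a$chain[i] != a$chain[j] | abs(a$resno[i] - a$resno[j]) >= 2)
  data.frame(i = i[keep], j = j[keep])
}

#' Build the bars-and-bodies constraint network
#'
#' Covalent bonds come from element distance rules and are classified locked
#' (peptide, carbonyl, resonant side-chain groups) or rotatable; atoms joined
#' by locked bonds merge into one rigid body.  Hydrogen bonds with energy
#' at most `e_cut` enter as 5-bar constraints, hydrophobic tethers as 2-bar
#' constraints, rotatable covalent bonds as 5-bar joints.
#'
#' @param structure a `Structure`.
#' @param e_cut hydrogen-bond energy threshold in kcal/mol (default -2; more
#'   negative = fewer, stronger bonds retained).
#' @param include_tethers include hydrophobic tethers (default TRUE).
#' @param extra_hbonds optional data.frame(donor, acceptor, energy) of
#'   additional constraints treated as hydrogen bonds (used by synthetic
#'   fixtures to rigidify toy domains).
#' @return object of class `ConstraintNetwork`: atom table reference, bar
#'   table (`i`, `j`, `type`, `bars`, `energy`), per-atom `body` ids, and the
#'   body multigraph.
#' @export
build_network <- function(structure, e_cut = -2, include_tethers = TRUE,
                          extra_hbonds = NULL) {
  a <- structure$atoms
  n <- nrow(a)
  bonds <- covalent_bonds(structure)
  hb <- detect_hbonds(structure)
  if (!is.null(extra_hbonds)) {
    eh <- data.frame(donor = extra_hbonds$donor, acceptor = extra_hbonds$acceptor,
                     donor_res = a$resno[extra_hbonds$donor],
                     acceptor_res = a$resno[extra_hbonds$acceptor],
                     dist = NA_real_, angle = NA_real_,
                     energy = extra_hbonds$energy)
    hb <- rbind(hb[, names(eh)], eh)
  }
  hb <- hb[hb$energy <= e_cut, , drop = FALSE]
  te <- if (include_tethers) detect_tethers(structure, bonds) else
    data.frame(i = integer(), j = integer())

  bars <- rbind(
    data.frame(i = bonds$i, j = bonds$j,
               type = ifelse(bonds$locked, "locked", "covalent"),
               bars = ifelse(bonds$locked, 6L, 5L), energy = NA_real_),
    if (nrow(hb)) data.frame(i = hb$donor, j = hb$acceptor, type = "hbond",
                             bars = 5L, energy = hb$energy),
    if (nrow(te)) data.frame(i = te$i, j = te$j, type = "hydrophobic",
                             bars = 2L, energy = NA_real_))
  bars <- bars[bars$i != bars$j, , drop = FALSE]

  ## bodies: union-find over locked bonds
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  lk <- bars[bars$type == "locked", , drop = FALSE]
  if (nrow(lk)) for (k in seq_len(nrow(lk))) {
    ri <- find(lk$i[k]); rj <- find(lk$j[k])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  root <- vapply(seq_len(n), find, 1L)
  body <- match(root, sort(unique(root)))

  ## body multigraph: inter-body bars only, deterministic order
  inter <- bars[body[bars$i] != body[bars$j], , drop = FALSE]
  bg <- if (nrow(inter)) data.frame(bu = pmin(body[inter$i], body[inter$j]),
                                    bv = pmax(body[inter$i], body[inter$j]),
                                    bars = inter$bars, type = inter$type)
        else data.frame(bu = integer(), bv = integer(), bars = integer(),
                        type = character())
  bg <- bg[order(bg$bu, bg$bv, match(bg$type, c("covalent", "locked", "hbond",
                                                "hydrophobic"))), , drop = FALSE]
  ## warn on a disconnected covalent graph
  comps <- graph_components(n, bonds)
  if (max(comps) > 1L)
    warning("protein covalent graph has ", max(comps), " disconnected components")

  structure(list(atoms = a, bars = bars, body = body, body_graph = bg,
                 n_bodies = max(body), e_cut = e_cut,
                 hbonds = hb, tethers = te, bonds = bonds,
                 structure = structure),
            class = "ConstraintNetwork")
}

#' @export
print.ConstraintNetwork <- function(x, ...) {
  cat(sprintf(paste0("ConstraintNetwork: %d atoms, %d bodies; bars: %d covalent",
                     " (%d locked), %d hbond (E_cut = %g), %d hydrophobic\n"),
              nrow(x$atoms), x$n_bodies,
              sum(x$bars$type %in% c("covalent", "locked")),
              sum(x$bars$type == "locked"), sum(x$bars$type == "hbond"),
              x$e_cut, sum(x$bars$type == "hydrophobic")))
  invisible(x)
}

## connected components of the covalent graph (atom level)
graph_components <- function(n, bonds) {
  comp <- integer(n)
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$i[k]]] <- c(adj[[bonds$i[k]]], bonds$j[k])
    adj[[bonds$j[k]]] <- c(adj[[bonds$j[k]]], bonds$i[k])
  }
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      stack <- c(stack, adj[[v]][comp[adj[[v]]] == 0L])
    }
  }
  comp
}

#' Dump a constraint network as text
#'
#' One bar record per line: type, atom serials, energy.
#' @param network a `ConstraintNetwork`.
#' @param path optional file.
#' @export
write_network <- function(network, path = NULL) {
  b <- network$bars
  a <- network$atoms
  txt <- sprintf("%-12s %6d %6d %2d %s", b$type, a$serial[b$i], a$serial[b$j],
                 b$bars, ifelse(is.na(b$energy), ".",
                                sprintf("%.3f", b$energy)))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}
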