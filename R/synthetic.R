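# Synthetic fixtures with known ground truth: ideal helices, planar
# antiparallel sheets, torsion-built peptide chains, and a hinged two-domain
# toy whose tilt/twist/d_cc series are known analytically.  Fixtures carry
# C-alpha plus minimal backbone (N, C, O) atoms.

## ideal backbone internal coordinates (Engh-Huber-like)
.BB <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
            n_ca_c = 111.2, ca_c_n = 116.2, c_n_ca = 121.7, ca_c_o = 120.5)

## NeRF: place atom D given A-B-C, |CD|, angle BCD (deg), torsion ABCD (deg)
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- rad(angle); tor <- rad(torsion)
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

atoms_df <- function(pos, name, element, resno, resname = "GLY", chain = "A") {
  data.frame(serial = seq_along(resno), name = name, element = element,
             resno = as.integer(resno), resname = resname, chain = chain,
             x = vapply(pos, `[`, 0, 1), y = vapply(pos, `[`, 0, 2),
             z = vapply(pos, `[`, 0, 3), stringsAsFactors = FALSE)
}

#' Build an ideal-geometry peptide backbone from torsions
#'
#' Chain of N, CA, C, O atoms grown by the NeRF construction with ideal bond
#' lengths and angles and the given backbone torsions.  phi = -57, psi = -47
#' gives an ideal alpha helix; phi = -139, psi = 135 an extended strand.
#'
#' @param n_residues number of residues (>= 2).
#' @param phi,psi,omega backbone torsions in degrees (scalar, applied to every
#'   residue).
#' @param chain chain id.
#' @param resno_start first residue number.
#' @return a `Structure` of glycine residues.
#' @export
make_peptide_chain <- function(n_residues, phi = -57, psi = -47, omega = 180,
                               chain = "A", resno_start = 1L) {
  stopifnot(n_residues >= 2)
  N <- c(0, 0, 0); CA <- c(.BB$n_ca, 0, 0)
  C <- nerf_place(c(0, -1, 0), N, CA, .BB$ca_c, .BB$n_ca_c, psi - 180)
  pos <- list(); name <- character(); resno <- integer()
  add <- function(p, nm, i) {
    pos[[length(pos) + 1L]] <<- p; name <<- c(name, nm); resno <<- c(resno, i)
  }
  prev <- list(N = N, CA = CA, C = C)
  for (i in seq_len(n_residues)) {
    O <- nerf_place(prev$N, prev$CA, prev$C, .BB$c_o, .BB$ca_c_o, psi + 180)
    add(prev$N, "N", i); add(prev$CA, "CA", i); add(prev$C, "C", i); add(O, "O", i)
    if (i == n_residues) break
    Nn <- nerf_place(prev$N, prev$CA, prev$C, .BB$c_n, .BB$ca_c_n, psi)
    CAn <- nerf_place(prev$CA, prev$C, Nn, .BB$n_ca, .BB$c_n_ca, omega)
    Cn <- nerf_place(prev$C, Nn, CAn, .BB$ca_c, .BB$n_ca_c, phi)
    prev <- list(N = Nn, CA = CAn, C = Cn)
  }
  elem <- substr(name, 1, 1)
  df <- atoms_df(pos, name, elem, resno + resno_start - 1L, chain = chain)
  new_structure(df, label = sprintf("peptide-chain phi=%g psi=%g", phi, psi))
}

## Reconstruct minimal backbone (N, C, O) around an ordered C-alpha trace.
## C_i and N_{i+1} are placed in the plane spanned by the CA_i->CA_{i+1} axis
## and the local chain normal, with offsets solved from ideal bond lengths at
## the canonical 3.8 A CA-CA distance; O_i bisects the C_i angles.  Geometry
## is exact for bonds, approximate for angles - sufficient for the covalent
## network, not for hydrogen-bond fidelity (use make_peptide_chain for that).
backbone_from_ca <- function(ca, chain = "A", resno = NULL, resname = "GLY") {
  n <- nrow(ca)
  stopifnot(n >= 2)
  if (is.null(resno)) resno <- seq_len(n)
  u <- t(apply(ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE], 1, unitv))
  ## local normal from curvature, propagated where degenerate
  p <- matrix(NA_real_, n - 1, 3)
  for (i in seq_len(n - 1)) {
    cv <- if (i < n - 1) cross3(u[i, ], u[i + 1, ]) else
      if (i > 1) cross3(u[i - 1, ], u[i, ]) else c(0, 0, 0)
    if (vnorm(cv) > 1e-6) {
      p[i, ] <- unitv(cross3(cv, u[i, ]))
    } else {
      ref <- if (abs(u[i, 3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      p[i, ] <- unitv(ref - sum(ref * u[i, ]) * u[i, ])
    }
  }
  pos <- list(); name <- character(); rn <- integer()
  add <- function(pp, nm, i) {
    pos[[length(pos) + 1L]] <<- pp; name <<- c(name, nm); rn <<- c(rn, i)
  }
  seglen <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE]) ^ 2))
  for (i in seq_len(n)) {
    sc_n <- if (i < n) seglen[i] / 3.8 else 1        # scale of segment i -> i+1
    sc_p <- if (i > 1) seglen[i - 1] / 3.8 else 1    # scale of segment i-1 -> i
    Ni <- if (i == 1) ca[1, ] - 1.195 * u[1, ] + 0.835 * p[1, ] else
      ca[i, ] - 1.195 * sc_p * u[i - 1, ] + 0.835 * p[i - 1, ]
    Ci <- if (i < n) ca[i, ] + 1.276 * sc_n * u[i, ] + 0.835 * p[i, ] else
      ca[n, ] + 1.276 * u[n - 1, ] + 0.835 * p[n - 1, ]
    Nnext <- if (i < n) ca[i + 1, ] - 1.195 * sc_n * u[i, ] + 0.835 * p[i, ] else
      Ci + c(1.33, 0, 0)
    Oi <- Ci + .BB$c_o * unitv(unitv(Ci - ca[i, ]) + unitv(Ci - Nnext))
    add(Ni, "N", i); add(ca[i, ], "CA", i); add(Ci, "C", i); add(Oi, "O", i)
  }
  elem <- substr(name, 1, 1)
  atoms_df(pos, name, elem, resno[rn], resname = resname, chain = chain)
}

#' Ideal helical C-alpha trace with minimal backbone
#'
#' C-alpha atoms on a mathematical helix (defaults: 1.5 A rise, 100 degrees
#' per residue, 2.3 A radius - canonical alpha-helix values); N, C, O placed
#' around the trace by geometric reconstruction.  turn = 180 with a large
#' rise gives a planar extended zigzag.
#'
#' @param n_residues number of residues (>= 4).
#' @param rise rise per residue, Angstrom.
#' @param turn rotation per residue, degrees.
#' @param radius helix radius, Angstrom.
#' @param backbone also place N, C, O atoms (default TRUE).
#' @return a `Structure`; the exact C-alpha trace is available via
#'   [select_calpha()].
#' @export
make_helix <- function(n_residues, rise = 1.5, turn = 100, radius = 2.3,
                       backbone = TRUE) {
  if (n_residues < 4) stop("helix fixture needs at least 4 residues")
  t <- (seq_len(n_residues) - 1) * rad(turn)
  ca <- cbind(radius * cos(t), radius * sin(t), rise * (seq_len(n_residues) - 1))
  df <- if (backbone) backbone_from_ca(ca) else
    atoms_df(lapply(seq_len(n_residues), function(i) ca[i, ]), "CA", "C",
             seq_len(n_residues))
  s <- new_structure(df, label = sprintf("ideal-helix n=%d rise=%g turn=%g",
                                         n_residues, rise, turn))
  attr(s, "helix_params") <- c(rise = rise, turn = turn, radius = radius)
  s
}

#' Planar antiparallel C-alpha sheet with known normal
#'
#' Strands run along +/- x alternately at y = 0, spacing, 2*spacing, ...,
#' with a beta-pleat of alternating +/- `pleat` in z.  The mean construction
#' plane is z = 0 with normal (0, 0, 1); because the measurement
#' quadrilateral takes alternating residues (same pleat sign), its plane is
#' exactly parallel to the construction plane.  Residues are numbered
#' sequentially along the chain path (strand 1 forward, strand 2 backward,
#' ...).  The pleat also keeps the C-alpha set non-coplanar, which an
#' elastic-network model needs (a strictly planar network has spurious
#' out-of-plane zero modes).
#'
#' @param n_strands number of strands (>= 2).
#' @param strand_length residues per strand.
#' @param spacing inter-strand distance, Angstrom (default 4.8).
#' @param step intra-strand C-alpha spacing, Angstrom (default 3.4).
#' @param pleat alternating out-of-plane displacement, Angstrom (default
#'   0.4; 0 gives a strictly flat sheet).
#' @param backbone also place N, C, O atoms.
#' @return a `Structure` with attributes `sheet_normal` (ground truth) and
#'   `central_quad` (residue numbers of an alternating central quadrilateral).
#' @export
make_sheet <- function(n_strands = 2, strand_length = 4, spacing = 4.8,
                       step = 3.4, pleat = 0.4, backbone = TRUE) {
  stopifnot(n_strands >= 2, strand_length >= 2)
  ca <- NULL
  resmat <- matrix(0L, n_strands, strand_length)  # residue number by (strand, pos)
  r <- 0L
  for (s in seq_len(n_strands)) {
    cols <- seq_len(strand_length)
    if (s %% 2 == 0) cols <- rev(cols)
    for (k in cols) {
      r <- r + 1L
      resmat[s, k] <- r
      ca <- rbind(ca, c((k - 1) * step, (s - 1) * spacing,
                        pleat * (-1) ^ k))
    }
  }
  df <- if (backbone) backbone_from_ca(ca) else
    atoms_df(lapply(seq_len(nrow(ca)), function(i) ca[i, ]), "CA", "C",
             seq_len(nrow(ca)))
  s <- new_structure(df, label = sprintf("ideal-sheet %dx%d", n_strands,
                                         strand_length))
  ## alternating central residues of strands 1 and 2, in perimeter order
  ## (p1, p2 forward along strand 1; p3, p4 back along strand 2) so the
  ## diagonals p3-p1 and p4-p2 cross
  mid <- max(1L, (strand_length - 1L) %/% 2L)
  mid2 <- min(mid + 2L, strand_length)
  quad <- c(resmat[1, mid], resmat[1, mid2], resmat[2, mid2], resmat[2, mid])
  attr(s, "sheet_normal") <- c(0, 0, 1)
  attr(s, "central_quad") <- quad
  attr(s, "residue_grid") <- resmat
  s
}

#' Hinged two-domain toy with analytic ground truth
#'
#' Two rigid sheet-containing domains joined by a 4-residue linker.  The
#' trajectory applies a prescribed hinge-rotation schedule to domain 2 as an
#' exact rigid-body motion (plus optional Gaussian coordinate noise), so the
#' tilt/twist/d_cc series are known in closed form from the schedule and are
#' returned alongside the frames.
#'
#' @param schedule numeric vector of hinge angles in degrees, one per frame
#'   (frame 1 is usually 0 = the reference conformation).  Positive angles
#'   close the two marker sites toward each other (book-like hinge).
#' @param axis hinge rotation axis (default y, perpendicular to the
#'   domain-joining x direction, giving a closing-book motion; an axis along
#'   x would give a pure twist instead).
#' @param n_strands,strand_length sheet size per domain.
#' @param gap linker span between the domains along x, Angstrom.
#' @param noise_sd Gaussian noise sigma in Angstrom added to every coordinate
#'   of every frame (default 0 = exact rigid motion).
#' @param seed RNG seed used when noise_sd > 0.
#' @return list with `structure` (reference conformation), `trajectory`
#'   (`Trajectory` over the schedule), `config` (an [analysis_config()] with
#'   the two domains, their quads and the d_cc residue pair), `truth`
#'   (data.frame of frame, angle, tilt, twist, dcc), `pivot`/`axis`/
#'   `dom2_residues` (the hinge definition), and `extra_constraints`
#'   (cross-strand C-alpha pairs that rigidify each domain when passed to
#'   [build_network()] as `extra_hbonds`).
#' @export
make_hinge_toy <- function(schedule = seq(0, 30, by = 2), axis = c(0, -1, 0),
                           n_strands = 3, strand_length = 5, gap = 12,
                           noise_sd = 0, seed = 1L) {
  stopifnot(all(is.finite(schedule)), noise_sd >= 0)
  axis <- unitv(axis)
  sheet <- make_sheet(n_strands, strand_length)
  nres_dom <- n_strands * strand_length
  a1 <- sheet$atoms                              # domain 1 at origin
  ## domain 2: same sheet shifted +x by gap + strand extent
  extent <- (strand_length - 1) * 3.4
  shift <- extent + gap
  a2 <- sheet$atoms
  a2$x <- a2$x + shift
  a2$resno <- a2$resno + nres_dom + 4L
  ## 4-residue linker running diagonally from the chain end of domain 1
  ## (last strand) to the chain start of domain 2 (first strand); the
  ## diagonal matters: a collinear linker would leave an exact zero-energy
  ## torsion of domain 2 about the linker line in the elastic network
  p_end <- unlist(a1[a1$name == "CA" & a1$resno == nres_dom, c("x", "y", "z")])
  p_sta <- unlist(a2[a2$name == "CA" & a2$resno == nres_dom + 5L,
                     c("x", "y", "z")])
  frac <- (1:4) / 5
  lca <- cbind(p_end[1] + frac * (p_sta[1] - p_end[1]),
               p_end[2] + frac * (p_sta[2] - p_end[2]),
               p_end[3] + frac * (p_sta[3] - p_end[3]) + c(0.5, -0.5, 0.5, -0.5))
  path <- backbone_from_ca(rbind(p_end, lca, p_sta))
  lk <- path[path$resno %in% 2:5, ]              # the linker proper
  lk$resno <- lk$resno + nres_dom - 1L
  ## rebuild the junction atoms from the path so the chain is contiguous:
  ## C/O of domain 1's last residue and N of domain 2's first residue
  for (nm in c("C", "O")) {
    r <- path[path$resno == 1L & path$name == nm, c("x", "y", "z")]
    a1[a1$resno == nres_dom & a1$name == nm, c("x", "y", "z")] <- r
  }
  a2[a2$resno == nres_dom + 5L & a2$name == "N", c("x", "y", "z")] <-
    path[path$resno == 6L & path$name == "N", c("x", "y", "z")]
  atoms <- rbind(a1, lk, a2)
  atoms$serial <- seq_len(nrow(atoms))
  ref <- new_structure(atoms, label = "hinge-toy")
  ## cross-strand C-alpha constraints that rigidify each sheet when passed
  ## to build_network(extra_hbonds = ...): same-column residues of adjacent
  ## strands, 5-bar each (stand-ins for the interstrand hydrogen bonds the
  ## minimal backbone geometry cannot realise)
  grid_res <- attr(sheet, "residue_grid")
  xpairs <- list()
  for (s in 2:n_strands) for (k in seq_len(strand_length)) {
    xpairs[[length(xpairs) + 1L]] <- c(grid_res[s - 1, k], grid_res[s, k])
    xpairs[[length(xpairs) + 1L]] <-
      c(grid_res[s - 1, k], grid_res[s, k]) + nres_dom + 4L
  }
  xp <- do.call(rbind, xpairs)
  ca_idx_of <- function(r) which(atoms$name == "CA" & atoms$resno == r)
  extra <- data.frame(donor = vapply(xp[, 1], ca_idx_of, 1L),
                      acceptor = vapply(xp[, 2], ca_idx_of, 1L),
                      energy = -5)

  dom2_res <- (nres_dom + 5L):(2L * nres_dom + 4L)
  quad1 <- attr(sheet, "central_quad")
  quad2 <- quad1 + nres_dom + 4L
  site1 <- quad1[1]                              # "active site" markers
  site2 <- quad2[1]
  config <- analysis_config(
    list(domain_definition("D1", rbind(c(1L, nres_dom)), sheet_quad = quad1,
                           active_site = site1),
         domain_definition("D2", rbind(c(dom2_res[1], dom2_res[length(dom2_res)])),
                           sheet_quad = quad2, active_site = site2)),
    dcc_residues = c(site1, site2))

  pivot <- as.vector((p_end + p_sta) / 2)        # hinge point mid-linker
  X0 <- coords(ref)
  move <- ref$atoms$resno %in% dom2_res
  if (noise_sd > 0) set.seed(seed)
  frames <- lapply(schedule, function(ang) {
    R <- rotation_matrix(axis, ang)
    X <- X0
    X[move, ] <- sweep(sweep(X[move, , drop = FALSE], 2, pivot) %*% t(R), 2,
                       pivot, "+")
    if (noise_sd > 0) X <- X + matrix(stats::rnorm(length(X), 0, noise_sd),
                                      ncol = 3)
    X
  })
  traj <- new_trajectory(ref, frames,
                         meta = data.frame(step = seq_along(schedule) - 1L,
                                           hinge_angle = schedule))

  ## analytic ground truth: rotate the reference frame-2 normal/center/site
  f1 <- sheet_frame(ref, quad1)
  f2 <- sheet_frame(ref, quad2)
  site1_xyz <- select_calpha(ref, site1)[1, ]
  site2_xyz <- select_calpha(ref, site2)[1, ]
  truth <- do.call(rbind, lapply(seq_along(schedule), function(k) {
    R <- rotation_matrix(axis, schedule[k])
    n2 <- as.vector(R %*% f2$normal)
    c2 <- as.vector(R %*% (f2$center - pivot)) + pivot
    s2 <- as.vector(R %*% (site2_xyz - pivot)) + pivot
    f2k <- list(normal = n2, center = c2)
    data.frame(frame = k, angle = schedule[k],
               tilt = tilt(f1, f2k),
               twist = twist(f1, f2k),
               dcc = vnorm(s2 - site1_xyz))
  }))
  list(structure = ref, trajectory = traj, config = config, truth = truth,
       pivot = pivot, axis = axis, dom2_residues = dom2_res,
       extra_constraints = extra)
}

#' Fit helix parameters to an ordered C-alpha trace
#'
#' Estimates axis, rise per residue, turn per residue and radius from the
#' trace geometry (axis from averaged curvature cross products).  Used as an
#' independent check of the helix generators.
#'
#' @param ca n x 3 matrix of consecutive C-alpha positions (n >= 5).
#' @return list(axis, rise, turn, radius).
#' @export
helix_fit <- function(ca) {
  n <- nrow(ca)
  stopifnot(n >= 5)
  d <- ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE]
  u <- d[-1, , drop = FALSE] - d[-(n - 1), , drop = FALSE]
  ax <- colMeans(t(vapply(seq_len(nrow(u) - 1),
                          function(i) cross3(u[i, ], u[i + 1, ]), numeric(3))))
  ax <- unitv(ax)
  rise <- mean(d %*% ax)
  ## in-plane coordinates and least-squares circumcenter (Kasa fit; exact for
  ## points on a circle - the raw centroid of a partial arc is biased)
  ref <- if (abs(ax[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- unitv(cross3(ax, ref))
  e2 <- cross3(ax, e1)
  q <- cbind(ca %*% e1, ca %*% e2)
  A <- cbind(2 * q, 1)
  beta <- qr.solve(A, rowSums(q ^ 2))
  cen2 <- beta[1:2]
  radius <- sqrt(beta[3] + sum(cen2 ^ 2))
  v <- sweep(q, 2, cen2)
  turns <- vapply(seq_len(n - 1), function(i)
    deg(atan2(v[i, 1] * v[i + 1, 2] - v[i, 2] * v[i + 1, 1],
              sum(v[i, ] * v[i + 1, ]))), 0)
  list(axis = ax, rise = abs(rise), turn = mean(turns), radius = radius)
}
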