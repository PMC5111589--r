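# Quantitative motion measures: beta-sheet plane frames, interdomain tilt
# and dihedral twist, active-site distance d_cc, per-residue pseudodihedral
# flexibility, per-domain RMSD and sheet-angle statistics.  All operate on a
# Structure or Trajectory, whether generated here or read from an external
# multi-model PDB.

#' Beta-sheet plane frame from a residue quadrilateral
#'
#' The domain orientation is represented by the plane of its core beta-sheet.
#' Four C-alpha atoms (alternating central residues of two adjacent
#' antiparallel strands, in perimeter order p1..p4) define a quadrilateral;
#' the unit normal is the normalized cross product of its diagonals,
#' n = (p3 - p1) x (p4 - p2), and the center is the centroid of the four
#' atoms.
#'
#' @param structure a `Structure` (or an n x 3 C-alpha matrix with residue
#'   numbers as rownames).
#' @param quad four distinct residue numbers in perimeter order.
#' @return list of class `PlaneFrame`: `normal` (unit 3-vector), `center`
#'   (Angstrom), `quad`.
#' @export
sheet_frame <- function(structure, quad) {
  stopifnot(length(quad) == 4L, !anyDuplicated(quad))
  p <- if (inherits(structure, "Structure")) select_calpha(structure, quad)
       else structure[as.character(quad), , drop = FALSE]
  d1 <- p[3, ] - p[1, ]
  d2 <- p[4, ] - p[2, ]
  cp <- cross3(d1, d2)
  if (vnorm(cp) < 1e-6 * vnorm(d1) * vnorm(d2))
    stop("sheet quadrilateral has near-collinear diagonals; cannot define a normal")
  structure(list(normal = unitv(cp), center = colMeans(p), quad = quad),
            class = "PlaneFrame")
}

## frames along a trajectory with temporal sign continuity: each frame's
## normal is flipped if its dot product with the previous frame's is negative
sheet_frames <- function(traj, quad) {
  frames <- vector("list", n_conformers(traj))
  prev <- NULL
  for (i in seq_along(frames)) {
    f <- sheet_frame(conformer(traj, i), quad)
    if (!is.null(prev) && sum(f$normal * prev) < 0) f$normal <- -f$normal
    prev <- f$normal
    frames[[i]] <- f
  }
  frames
}

#' Interdomain tilt angle
#'
#' Unsigned angle between the two sheet-plane normals,
#' cos(theta) = n1 . n2, in \[0, 180\] degrees.
#'
#' @param frame1,frame2 `PlaneFrame` objects (or lists with `normal`).
#' @return tilt in degrees.
#' @export
tilt <- function(frame1, frame2) {
  d <- sum(unitv(frame1$normal) * unitv(frame2$normal))
  deg(acos(max(-1, min(1, d))))
}

#' Interdomain dihedral twist
#'
#' Signed dihedral between the plane containing (n1, r12) and the plane
#' containing (n2, r12), where r12 joins the two sheet centers.  Computed
#' from the projections of the normals onto the plane perpendicular to r12;
#' the sign follows the right-hand rule about r12.  Range (-180, 180\].
#'
#' @param frame1,frame2 `PlaneFrame` objects.
#' @return twist in degrees.
#' @export
twist <- function(frame1, frame2) {
  r12 <- frame2$center - frame1$center
  if (vnorm(r12) < 1e-9) stop("twist undefined: coincident plane centers")
  e <- unitv(r12)
  u <- frame1$normal - sum(frame1$normal * e) * e
  v <- frame2$normal - sum(frame2$normal * e) * e
  if (vnorm(u) < 1e-6 || vnorm(v) < 1e-6)
    stop("twist undefined: plane normal parallel to the interplane axis")
  deg(atan2(sum(cross3(u, v) * e), sum(u * v)))
}

#' Active-site C-alpha distance d_cc
#'
#' Euclidean distance between the C-alpha atoms of two residues; with the
#' active-site cysteines of the catalytic domains this is the principal
#' open/closed indicator of the structure.
#'
#' @param structure a `Structure`.
#' @param res_a,res_b residue numbers (author numbering).
#' @param chain optional chain id.
#' @return distance in Angstrom.
#' @export
dcc <- function(structure, res_a, res_b, chain = NULL) {
  p <- select_calpha(structure, c(res_a, res_b), chain = chain)
  vnorm(p[2, ] - p[1, ])
}

## cos(xi_i) for one conformer's ordered C-alpha trace.
## Pseudo-bonds q_i = r_{i+1} - r_i; xi_i is the angle between the
## projections of q_{i-1} and q_{i+1} onto the plane normal to q_i (q_{i-1}
## is NOT negated, so xi = 180 deg minus the conventional virtual torsion:
## near 0 for extended chain, |xi| > 90 for helix, cos xi ~ -0.7).
## Undefined for the first residue and the last two.
cos_xi_trace <- function(ca) {
  n <- nrow(ca)
  if (n < 4) stop("pseudodihedral needs a chain of at least 4 C-alpha atoms")
  q <- ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE]   # q_i, i = 1..n-1
  out <- rep(NA_real_, n)
  for (i in 2:(n - 2)) {
    e <- unitv(q[i, ])
    u <- q[i - 1, ] - sum(q[i - 1, ] * e) * e
    v <- q[i + 1, ] - sum(q[i + 1, ] * e) * e
    nu <- vnorm(u); nv <- vnorm(v)
    out[i] <- if (nu < 1e-9 || nv < 1e-9) NA_real_ else
      max(-1, min(1, sum(u * v) / (nu * nv)))
  }
  out
}

#' Per-conformer cos(xi) values for a structure
#'
#' @param structure a `Structure`; the C-alpha trace of `chain` in sequence
#'   order is used.
#' @param chain optional chain id.
#' @return named numeric vector of cos(xi_i) per residue (NA for the first
#'   and last two residues, where xi is undefined).
#' @export
cos_xi <- function(structure, chain = NULL) {
  ca <- select_calpha(structure, chain = chain)
  v <- cos_xi_trace(ca)
  names(v) <- rownames(ca)
  v
}

#' Per-residue pseudodihedral flexibility profile
#'
#' For every conformer the pseudodihedral cosine cos(xi_i) is computed at
#' each interior residue; the flexibility measure at residue i is the
#' root-mean-square deviation (about the mean) of cos(xi_i) across all
#' supplied conformers.  Pass several trajectories (e.g. modes m7..m10) to
#' pool their conformers before taking the RMS.
#'
#' @param trajectory a `Trajectory`, or a list of trajectories to pool.
#' @param chain optional chain id.
#' @return data.frame with `resno`, `mean_cos_xi`, `rms_cos_xi`.
#' @export
pseudodihedral_profile <- function(trajectory, chain = NULL) {
  trajs <- if (inherits(trajectory, "Trajectory")) list(trajectory) else trajectory
  stopifnot(length(trajs) >= 1L)
  if (sum(vapply(trajs, n_conformers, 1L)) < 2L)
    stop("pseudodihedral profile needs at least 2 conformers")
  rows <- list()
  for (tr in trajs) for (i in seq_len(n_conformers(tr)))
    rows[[length(rows) + 1L]] <- cos_xi(conformer(tr, i), chain = chain)
  M <- do.call(rbind, rows)
  mu <- colMeans(M)
  dev <- sweep(M, 2, mu)
  rms <- sqrt(colMeans(dev ^ 2))
  data.frame(resno = as.integer(colnames(M)), mean_cos_xi = mu,
             rms_cos_xi = rms, row.names = NULL)
}

#' Per-domain C-alpha RMSD along a trajectory
#'
#' Each conformer's domain C-alpha set is optimally superposed (Kabsch) onto
#' the first conformer before the RMSD is taken, so rigid-body domain motion
#' contributes zero and the value reports internal distortion only.
#'
#' @param trajectory a `Trajectory`.
#' @param domain a [domain_definition()].
#' @param chain optional chain id.
#' @return numeric vector, one RMSD (Angstrom) per conformer.
#' @export
domain_rmsd <- function(trajectory, domain, chain = NULL) {
  res <- domain$residues
  if (length(res) < 3) stop("domain_rmsd needs at least 3 residues")
  ref <- select_calpha(conformer(trajectory, 1), res, chain = chain)
  vapply(seq_len(n_conformers(trajectory)), function(i) {
    p <- select_calpha(conformer(trajectory, i), res, chain = chain)
    kabsch(p, ref)$rmsd
  }, 0)
}

#' Sheet-angle statistics along a trajectory
#'
#' For each configured residue triple the angle at the middle residue is
#' computed in every conformer; constancy of these angles through a motion
#' indicates that the sheet moves as a rigid unit.
#'
#' @param trajectory a `Trajectory`.
#' @param triples list of length-3 residue-number vectors (or a single
#'   vector).
#' @param chain optional chain id.
#' @return data.frame with `triple` (label), `mean_deg`, `sd_deg`.
#' @export
sheet_angle_stats <- function(trajectory, triples, chain = NULL) {
  if (!is.list(triples)) triples <- list(triples)
  out <- lapply(triples, function(tr) {
    stopifnot(length(tr) == 3L)
    a <- vapply(seq_len(n_conformers(trajectory)), function(i) {
      p <- select_calpha(conformer(trajectory, i), tr, chain = chain)
      angle3(p[1, ], p[2, ], p[3, ])
    }, 0)
    data.frame(triple = paste(tr, collapse = "-"), mean_deg = mean(a),
               sd_deg = stats::sd(a))
  })
  do.call(rbind, out)
}

#' Per-conformer measure table for a trajectory
#'
#' Computes d_cc, per-domain-pair tilt/twist (with temporal normal-sign
#' continuity) and per-domain RMSD for every conformer, producing the tidy
#' table written by the pipeline.
#'
#' @param trajectory a `Trajectory`.
#' @param config an [analysis_config()].
#' @return data.frame, one row per conformer (class `MeasureSeries`).
#' @export
measure_series <- function(trajectory, config) {
  nc <- n_conformers(trajectory)
  out <- trajectory$meta
  if (!is.null(config$dcc_residues))
    out$dcc <- vapply(seq_len(nc), function(i)
      dcc(conformer(trajectory, i), config$dcc_residues[1],
          config$dcc_residues[2], chain = config$chain), 0)
  frames <- list()
  for (d in config$domains)
    if (!is.null(d$sheet_quad)) frames[[d$name]] <- sheet_frames(trajectory, d$sheet_quad)
  if (!is.null(config$domain_pairs)) {
    for (r in seq_len(nrow(config$domain_pairs))) {
      d1 <- config$domain_pairs[r, 1]; d2 <- config$domain_pairs[r, 2]
      if (is.null(frames[[d1]]) || is.null(frames[[d2]])) next
      lab <- paste0(d1, "_", d2)
      out[[paste0("tilt_", lab)]] <- vapply(seq_len(nc), function(i)
        tilt(frames[[d1]][[i]], frames[[d2]][[i]]), 0)
      out[[paste0("twist_", lab)]] <- vapply(seq_len(nc), function(i)
        twist(frames[[d1]][[i]], frames[[d2]][[i]]), 0)
    }
  }
  for (d in config$domains)
    out[[paste0("rmsd_", d$name)]] <- domain_rmsd(trajectory, d,
                                                  chain = config$chain)
  class(out) <- c("MeasureSeries", class(out))
  out
}
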