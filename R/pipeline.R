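# End-to-end orchestration: structure -> constraint network -> rigid
# clusters -> elastic modes -> mode-following trajectories -> measures ->
# tidy CSV tables plus a JSON run manifest.

#' Run the full flexibility-analysis pipeline
#'
#' Builds the constraint network at `e_cut`, decomposes it into rigid
#' clusters, computes C-alpha elastic modes (m7 oriented so its "+"
#' direction closes the active-site distance when one is configured),
#' generates one trajectory in each direction for each requested mode, and
#' evaluates all configured measures.  Outputs (when `out_dir` is given):
#' one multi-model PDB and one measures CSV per trajectory, a pooled
#' per-residue flexibility profile CSV, a per-mode d_cc and tilt/twist
#' summary CSV, and `manifest.json` recording config, seeds and
#' per-trajectory status.
#'
#' @param structure a `Structure` (or path to a PDB file).
#' @param config an [analysis_config()] (or path to its JSON form).
#' @param sim_config a [simulation_config()].
#' @param out_dir output directory; NULL skips file output.
#' @param e_cut hydrogen-bond energy threshold, kcal/mol (default -2).
#' @param modes mode numbers to follow (default 7:11).
#' @param anm_cutoff elastic-network cutoff in Angstrom (default 10).
#' @param extra_hbonds passed to [build_network()] (used by toy fixtures).
#' @return list with `trajectories`, `measures` (list of per-trajectory
#'   data.frames), `flexibility` (per-residue profile pooled over the first
#'   four requested modes), `summary`, `network`, `decomposition`, `modes`,
#'   and `manifest`.
#' @export
run_pipeline <- function(structure, config, sim_config = simulation_config(),
                         out_dir = NULL, e_cut = -2, modes = 7:11,
                         anm_cutoff = 10, extra_hbonds = NULL) {
  if (is.character(structure)) structure <- read_structure(structure)
  if (is.character(config)) config <- read_analysis_config(config)
  validate_config(structure, config)

  network <- build_network(structure, e_cut = e_cut,
                           extra_hbonds = extra_hbonds)
  decomposition <- decompose_rigid_clusters(network)
  hessian <- build_hessian(structure, cutoff = anm_cutoff)
  modeset <- compute_modes(hessian, k = max(modes) + 1L)
  if (!is.null(config$dcc_residues))
    modeset <- orient_modes(modeset, structure, config$dcc_residues,
                            chain = config$chain)

  trajs <- run_all_modes(structure, network, decomposition, modeset,
                         config = sim_config, modes = modes)
  runs <- attr(trajs, "runs")

  measures <- lapply(trajs, measure_series, config = config)
  flex_modes <- paste0("m", modes[seq_len(min(4L, length(modes)))])
  flex_set <- trajs[vapply(trajs, function(t) t$meta$mode[1] %in% flex_modes,
                           TRUE)]
  flexibility <- if (length(flex_set) &&
                     sum(vapply(flex_set, n_conformers, 1L)) >= 2L)
    pseudodihedral_profile(flex_set, chain = config$chain) else NULL

  summary <- pipeline_summary(measures, runs)

  manifest <- list(
    input = structure$label,
    input_sha1 = structure_checksum(structure),
    config = list(e_cut = e_cut, modes = modes, anm_cutoff = anm_cutoff,
                  n_steps = sim_config$n_steps,
                  save_every = sim_config$save_every,
                  step_size = sim_config$step_size,
                  clash_tol = sim_config$clash_tol,
                  template_tol = sim_config$template_tol,
                  n_starts = sim_config$n_starts, seed = sim_config$seed),
    trajectories = runs,
    outputs = character())

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character()
    for (k in seq_along(trajs)) {
      mt <- trajs[[k]]$meta
      tag <- sprintf("%s_%s_s%d", mt$mode[1],
                     if (mt$direction[1] > 0) "plus" else "minus", mt$seed[1])
      pp <- file.path(out_dir, paste0("traj_", tag, ".pdb"))
      write_conformers(trajs[[k]], pp)
      pc <- file.path(out_dir, paste0("measures_", tag, ".csv"))
      utils::write.csv(measures[[k]], pc, row.names = FALSE)
      paths <- c(paths, pp, pc)
    }
    if (!is.null(flexibility)) {
      pf <- file.path(out_dir, "flexibility_profile.csv")
      utils::write.csv(flexibility, pf, row.names = FALSE)
      paths <- c(paths, pf)
    }
    ps <- file.path(out_dir, "summary.csv")
    utils::write.csv(summary, ps, row.names = FALSE)
    pm <- file.path(out_dir, "manifest.json")
    manifest$outputs <- basename(c(paths, ps))
    jsonlite::write_json(manifest, pm, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    paths <- c(paths, ps, pm)
  }

  list(trajectories = trajs, measures = measures, flexibility = flexibility,
       summary = summary, network = network, decomposition = decomposition,
       modes = modeset, manifest = manifest)
}

## per-mode min/max of d_cc and tilt/twist ranges across trajectories
pipeline_summary <- function(measures, runs) {
  rows <- list()
  for (k in seq_along(measures)) {
    m <- measures[[k]]
    row <- data.frame(mode = m$mode[1], direction = m$direction[1],
                      seed = m$seed[1], n_conformers = nrow(m))
    if ("dcc" %in% names(m)) {
      row$dcc_start <- m$dcc[1]
      row$dcc_min <- min(m$dcc)
      row$dcc_max <- max(m$dcc)
    }
    for (cn in grep("^(tilt|twist)_", names(m), value = TRUE)) {
      row[[paste0(cn, "_min")]] <- min(m[[cn]])
      row[[paste0(cn, "_max")]] <- max(m[[cn]])
    }
    rows[[k]] <- row
  }
  do.call(rbind, rows)
}

structure_checksum <- function(structure) {
  x <- structure$atoms
  ## cheap deterministic digest without extra dependencies
  v <- c(nrow(x), sum(x$x), sum(x$y), sum(x$z), sum(x$resno))
  paste(sprintf("%.6e", v), collapse = ":")
}

#' Tilt/twist comparison of two static structures
#'
#' Computes per-domain-pair tilt and twist for two structures under the same
#' configuration, e.g. to compare two crystal forms of the same protein.
#'
#' @param structure_a,structure_b `Structure` objects (or PDB paths).
#' @param config an [analysis_config()] with domain quads and pairs.
#' @return data.frame with columns structure, pair, tilt, twist.
#' @export
compare_structures <- function(structure_a, structure_b, config) {
  if (is.character(structure_a)) structure_a <- read_structure(structure_a)
  if (is.character(structure_b)) structure_b <- read_structure(structure_b)
  out <- list()
  for (s in list(structure_a, structure_b)) {
    frames <- list()
    for (d in config$domains)
      if (!is.null(d$sheet_quad)) {
        p <- tryCatch(sheet_frame(s, d$sheet_quad), error = function(e)
          stop("structure ", s$label, ": ", conditionMessage(e)))
        frames[[d$name]] <- p
      }
    for (r in seq_len(nrow(config$domain_pairs))) {
      d1 <- config$domain_pairs[r, 1]; d2 <- config$domain_pairs[r, 2]
      out[[length(out) + 1L]] <- data.frame(
        structure = s$label, pair = paste0(d1, "-", d2),
        tilt = tilt(frames[[d1]], frames[[d2]]),
        twist = twist(frames[[d1]], frames[[d2]]))
    }
  }
  do.call(rbind, out)
}
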