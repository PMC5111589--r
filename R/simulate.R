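# Froda-style biased geometric simulation: step the structure along a fixed
# elastic mode and re-enforce rigid-cluster geometry and steric feasibility
# after every step.  Rigid clusters are maintained as overlapping "ghost"
# templates (cluster atoms plus their covalently bonded first shell); each
# relaxation iteration refits every template rigidly and moves atoms to the
# averaged fitted positions, then projects clashing nonbonded pairs apart.

#' Simulation configuration
#'
#' @param n_steps conformational steps per trajectory (default 5000; the
#'   production range is 2000-5000).
#' @param save_every record the full structure every this many steps
#'   (default 100), plus step 0.
#' @param step_size bias displacement per step, in Angstrom of RMS C-alpha
#'   motion along the mode (default 0.01).
#' @param clash_tol Angstrom subtracted from the van der Waals radius sum in
#'   the steric criterion, applied to pairs at least 4 bonds apart
#'   (default 0.5).
#' @param template_tol convergence tolerance on rigid-template deviation in
#'   Angstrom (default 0.1).
#' @param max_iter relaxation iteration cap per step (default 200).
#' @param n_starts number of perturbed starting conditions (default 5).
#' @param start_amplitude RMS C-alpha amplitude of the start perturbation in
#'   Angstrom (default 0.2).
#' @param stall_gain C-alpha-RMSD gain per 100 steps below which the
#'   trajectory is flagged as having reached its asymptote (default 0.01).
#' @param seed base RNG seed (randomness enters only through
#'   [perturb_start()]).
#' @export
simulation_config <- function(n_steps = 5000, save_every = 100,
                              step_size = 0.01, clash_tol = 0.5,
                              template_tol = 0.1, max_iter = 200L,
                              n_starts = 5L, start_amplitude = 0.2,
                              stall_gain = 0.01, seed = 1L) {
  stopifnot(n_steps >= 0, save_every >= 1, n_steps == 0 || n_steps >= save_every,
            step_size > 0, n_starts >= 1)
  structure(list(n_steps = as.integer(n_steps),
                 save_every = as.integer(save_every), step_size = step_size,
                 clash_tol = clash_tol, template_tol = template_tol,
                 max_iter = as.integer(max_iter), n_starts = as.integer(n_starts),
                 start_amplitude = start_amplitude, stall_gain = stall_gain,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

## Precompute the relaxation problem pieces shared by every call:
## ghost index/template lists (template geometry = the reference structure
## the network was built from), bond-distance exclusions (< 4 bonds),
## grandfathered initial contacts, vdW radii.
relax_problem <- function(network, decomposition) {
  a <- network$atoms
  n <- nrow(a)
  X <- coords(network$structure)
  bonds <- network$bonds
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$i[k]]] <- c(adj[[bonds$i[k]]], bonds$j[k])
    adj[[bonds$j[k]]] <- c(adj[[bonds$j[k]]], bonds$i[k])
  }
  cl <- decomposition$cluster
  ghosts <- lapply(split(seq_len(n), cl), function(members) {
    shell <- unique(unlist(adj[members]))
    sort(unique(c(members, shell)))
  })
  names(ghosts) <- NULL
  templates <- lapply(ghosts, function(idx) X[idx, , drop = FALSE])

  ## pairs closer than 4 bonds (graph distance <= 3)
  excl <- vector("list", n)
  for (s in seq_len(n)) {
    d1 <- adj[[s]]
    d2 <- unique(unlist(adj[d1]))
    d3 <- unique(unlist(adj[d2]))
    near <- setdiff(unique(c(d1, d2, d3)), s)
    excl[[s]] <- near[near > s]
  }
  ep <- cbind(rep(seq_len(n), lengths(excl)), unlist(excl))
  if (is.null(ep) || length(ep) == 0L) ep <- matrix(integer(), 0, 2)
  radii <- vdw_radius(a$element)
  ## grandfather pairs already inside the steric limit in the input
  pr0 <- cpp_neighbor_pairs(X, 2 * max(radii))
  if (nrow(pr0)) {
    i <- pr0[, 1]; j <- pr0[, 2]
    d0 <- sqrt(rowSums((X[i, , drop = FALSE] - X[j, , drop = FALSE]) ^ 2))
    viol <- d0 < radii[i] + radii[j] - 0.5 & cl[i] != cl[j]
    if (any(viol)) ep <- rbind(ep, cbind(i[viol], j[viol]))
  }
  storage.mode(ep) <- "integer"
  list(ghost_idx = lapply(ghosts, as.integer), ghost_templ = templates,
       excl_pairs = ep, cluster = as.integer(cl), radii = radii)
}

#' Relax a conformer onto its rigidity and steric constraints
#'
#' Iteratively refits every rigid-cluster template to the current atom
#' positions, moves atoms toward the (averaged) fitted templates, and pushes
#' apart nonbonded pairs closer than their van der Waals sum minus the clash
#' tolerance.  Terminates when the maximum template deviation is below the
#' template tolerance and no significant clash remains.
#'
#' @param conformer `Structure` to relax (same topology as the network).
#' @param decomposition a [decompose_rigid_clusters()] result.
#' @param network the [build_network()] result for the same topology.
#' @param config a [simulation_config()].
#' @param problem optional precomputed [relax_problem()] internals.
#' @return relaxed `Structure`; attributes `iterations`, `max_template_dev`,
#'   `worst_clash`.  Errors on non-convergence, carrying the worst violation.
#' @export
relax_to_constraints <- function(conformer, decomposition, network,
                                 config = simulation_config(),
                                 problem = NULL) {
  if (nrow(conformer$atoms) != nrow(network$atoms))
    stop("conformer topology does not match the constraint network")
  if (is.null(problem)) problem <- relax_problem(network, decomposition)
  r <- cpp_relax(coords(conformer), problem$ghost_idx, problem$ghost_templ,
                 problem$excl_pairs, problem$cluster, problem$radii,
                 config$clash_tol, config$template_tol, config$max_iter)
  if (!r$converged)
    stop(sprintf(paste0("relaxation failed to converge in %d iterations ",
                        "(max template deviation %.3f A, worst clash %.3f A)"),
                 config$max_iter, r$max_template_dev, r$worst_clash))
  out <- set_coords(conformer, r$coords)
  attr(out, "iterations") <- r$iterations
  attr(out, "max_template_dev") <- r$max_template_dev
  attr(out, "worst_clash") <- r$worst_clash
  out
}

#' Randomly perturbed starting structure
#'
#' Applies a residue-rigid random displacement (every atom of a residue moves
#' with its C-alpha) scaled to the requested RMS amplitude, then relaxes back
#' onto the constraints.  Deterministic given the seed.
#'
#' @param structure a `Structure`.
#' @param seed RNG seed.
#' @param amplitude RMS C-alpha displacement in Angstrom (0 returns the input
#'   unchanged).
#' @param network,decomposition constraint context for the relaxation.
#' @param config a [simulation_config()].
#' @export
perturb_start <- function(structure, seed, amplitude = 0.2, network = NULL,
                          decomposition = NULL, config = simulation_config()) {
  if (amplitude == 0) return(structure)
  if (is.null(network) || is.null(decomposition))
    stop("perturb_start with amplitude > 0 needs network and decomposition")
  a <- structure$atoms
  reskey <- paste(a$chain, a$resno)
  ures <- unique(reskey)
  set.seed(as.integer(seed))
  D <- matrix(stats::rnorm(3 * length(ures)), ncol = 3)
  D <- D * amplitude / sqrt(mean(rowSums(D ^ 2)))
  X <- coords(structure) + D[match(reskey, ures), , drop = FALSE]
  relax_to_constraints(set_coords(structure, X), decomposition, network,
                       config = config)
}

#' Follow one elastic mode through geometric simulation
#'
#' Runs `n_steps` iterations of (bias displacement along the fixed mode
#' vector, constraint relaxation), recording the all-atom structure at step 0
#' and every `save_every` steps.  The mode vector is extended to all atoms
#' (rigid-residue) and scaled to unit RMS C-alpha displacement, so
#' `step_size` is the RMS C-alpha bias per step; it is never recomputed
#' during the run.  If the C-alpha RMSD from the start grows by less than
#' `stall_gain` over 100 steps the trajectory is flagged "asymptote"
#' but recording continues.
#'
#' @param structure starting `Structure`.
#' @param network,decomposition constraint context ([build_network()],
#'   [decompose_rigid_clusters()]).
#' @param modeset a [compute_modes()] `ModeSet`.
#' @param mode mode number (7 = lowest nontrivial).
#' @param direction +1 or -1.
#' @param config a [simulation_config()].
#' @param problem optional precomputed internals (reused across trajectories).
#' @return a `Trajectory`; `meta` carries step, mode, direction, seed and
#'   attributes `stalled`/`status` record the asymptote flag and any
#'   truncation.
#' @export
mode_follow <- function(structure, network, decomposition, modeset, mode,
                        direction = 1, config = simulation_config(),
                        problem = NULL) {
  stopifnot(direction %in% c(-1, 1))
  if (modeset$trivial[mode])
    stop("mode m", mode, " is trivial (rigid-body); choose a nontrivial mode")
  if (is.null(problem)) problem <- relax_problem(network, decomposition)
  V <- extend_mode_to_atoms(structure, modeset, mode)
  cai <- ca_indices(structure)
  V <- V / sqrt(mean(rowSums(V[cai, , drop = FALSE] ^ 2)))  # unit RMS on CA
  r <- cpp_mode_follow(coords(structure), direction * V, config$step_size,
                       config$n_steps, config$save_every, cai,
                       problem$ghost_idx, problem$ghost_templ,
                       problem$excl_pairs, problem$cluster, problem$radii,
                       config$clash_tol, config$template_tol, config$max_iter,
                       config$stall_gain)
  meta <- data.frame(step = r$steps, mode = paste0("m", mode),
                     direction = direction, seed = config$seed)
  tr <- new_trajectory(structure, r$coords, meta)
  attr(tr, "stalled") <- r$stalled
  attr(tr, "status") <- r$status
  tr
}

#' Run trajectories for the five lowest nontrivial modes, both directions
#'
#' The production protocol: one trajectory in each direction for each of
#' modes m7..m11 (10 trajectories), optionally replicated over `n_starts`
#' perturbed starting conditions with distinct seeds.  Per-trajectory
#' failures are recorded in the result status, not propagated.
#'
#' @param structure starting `Structure`.
#' @param network,decomposition constraint context.
#' @param modeset a `ModeSet` with at least 11 modes.
#' @param config a [simulation_config()]; `n_starts` > 1 replicates each
#'   mode/direction over perturbed starts.
#' @param modes mode numbers to follow (default 7:11).
#' @return list of `Trajectory` objects with a `runs` attribute data.frame
#'   (mode, direction, start, seed, status, stalled).
#' @export
run_all_modes <- function(structure, network, decomposition, modeset,
                          config = simulation_config(), modes = 7:11) {
  if (length(modeset$values) < max(modes))
    stop("modeset has fewer than ", max(modes), " modes")
  problem <- relax_problem(network, decomposition)
  grid <- expand.grid(direction = c(1, -1), mode = modes,
                      start = seq_len(config$n_starts))
  trajs <- vector("list", nrow(grid))
  runs <- list()
  for (k in seq_len(nrow(grid))) {
    m <- grid$mode[k]; dir <- grid$direction[k]; s <- grid$start[k]
    seed_k <- config$seed + (s - 1L)
    cfg <- config
    cfg$seed <- seed_k
    res <- tryCatch({
      st <- if (config$n_starts > 1L)
        perturb_start(structure, seed_k, config$start_amplitude, network,
                      decomposition, cfg) else structure
      mode_follow(st, network, decomposition, modeset, m, dir, cfg,
                  problem = problem)
    }, error = function(e) e)
    ok <- inherits(res, "Trajectory")
    runs[[k]] <- data.frame(mode = paste0("m", m), direction = dir, start = s,
                            seed = seed_k,
                            status = if (ok) attr(res, "status") else
                              paste("error:", conditionMessage(res)),
                            stalled = if (ok) attr(res, "stalled") else NA)
    trajs[[k]] <- if (ok) res else NULL
  }
  keep <- !vapply(trajs, is.null, TRUE)
  out <- trajs[keep]
  attr(out, "runs") <- do.call(rbind, runs)
  out
}
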