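# (6,6) body-bar pebble game.  Bodies carry 6 pebbles (rigid-body degrees of
# freedom in 3D); a bar between two bodies is independent iff 7 pebbles can
# be gathered on its endpoints (Lee-Streinu pebble game for the (6,6)-sparse
# matroid, which by Tay's theorem is the generic body-bar rigidity matroid).
# Floppy modes = 6 * bodies - independent bars (includes the 6 trivial
# rigid-body motions per connected component).  Two bodies are mutually rigid
# iff an extra bar between them would be redundant; rigid clusters are the
# union-find closure of that test over all constrained body pairs.

PebbleGame <- function(n) {
  env <- new.env(parent = emptyenv())
  env$n <- n
  env$pebbles <- rep(6L, n)
  env$out <- vector("list", n)       # directed out-neighbour multisets
  env
}

## DFS from x for a free pebble, not taking pebbles from `blocked` vertices;
## on success the pebble is moved to x (path edges reversed) and TRUE returned
pg_find_pebble <- function(g, x, blocked) {
  n <- g$n
  visited <- rep(FALSE, n)
  visited[blocked] <- TRUE
  parent <- integer(n)
  stack <- x
  visited[x] <- TRUE
  found <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (w in g$out[[v]]) {
      if (visited[w]) next
      visited[w] <- TRUE
      parent[w] <- v
      if (g$pebbles[w] > 0L) { found <- w; break }
      stack <- c(stack, w)
    }
    if (found) break
  }
  if (!found) return(FALSE)
  ## reverse the path x -> ... -> found
  w <- found
  while (w != x) {
    v <- parent[w]
    k <- match(w, g$out[[v]])
    g$out[[v]] <- g$out[[v]][-k]       # remove v->w
    g$out[[w]] <- c(g$out[[w]], v)     # add w->v
    w <- v
  }
  g$pebbles[found] <- g$pebbles[found] - 1L
  g$pebbles[x] <- g$pebbles[x] + 1L
  TRUE
}

## gather pebbles so that pebbles(u) + pebbles(v) >= 7 if possible
pg_gather <- function(g, u, v) {
  while (g$pebbles[u] + g$pebbles[v] < 7L) {
    if (g$pebbles[u] < 6L && pg_find_pebble(g, u, c(u, v))) next
    if (g$pebbles[v] < 6L && pg_find_pebble(g, v, c(u, v))) next
    return(FALSE)
  }
  TRUE
}

## insert one bar u-v; returns TRUE if independent (accepted)
pg_insert_bar <- function(g, u, v) {
  if (u == v) return(FALSE)
  if (!pg_gather(g, u, v)) return(FALSE)
  if (g$pebbles[u] == 0L) { tmp <- u; u <- v; v <- tmp }
  g$pebbles[u] <- g$pebbles[u] - 1L
  g$out[[u]] <- c(g$out[[u]], v)
  TRUE
}

## would one more bar u-v be redundant? (TRUE = mutually rigid pair)
pg_rigid_pair <- function(g, u, v) {
  if (u == v) return(TRUE)
  !pg_gather(g, u, v)
}

## Run the game on a body multigraph given as data.frame(bu, bv, bars).
## Edges are processed in table order (callers sort deterministically).
run_pebble_game <- function(n_bodies, edges) {
  g <- PebbleGame(n_bodies)
  independent <- 0L
  for (k in seq_len(nrow(edges))) {
    u <- edges$bu[k]; v <- edges$bv[k]
    for (b in seq_len(edges$bars[k]))
      if (pg_insert_bar(g, u, v)) independent <- independent + 1L
  }
  list(game = g, independent = independent,
       floppy = 6L * n_bodies - independent)
}

#' Decompose a constraint network into rigid clusters
#'
#' Runs the (6,6) body-bar pebble game over the body multigraph (bars sorted
#' by ascending body index, covalent before hydrogen-bond before hydrophobic,
#' so the decomposition is independent of atom input order) and unions every
#' constrained body pair that the game proves mutually rigid.
#'
#' @param network a [build_network()] `ConstraintNetwork`.
#' @return object of class `RigidClusterDecomposition`: per-atom `cluster`
#'   labels (1 = largest cluster), `cluster_sizes` (atoms per cluster),
#'   `floppy` (total floppy modes, >= 6 for a connected network) and
#'   `internal_dof` (floppy minus 6 per connected component).
#' @export
decompose_rigid_clusters <- function(network) {
  nb <- network$n_bodies
  edges <- network$body_graph
  res <- run_pebble_game(nb, edges)
  g <- res$game

  ## union-find over rigid body pairs (test every distinct constrained pair)
  parent <- seq_len(nb)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  pairs <- unique(edges[, c("bu", "bv")])
  for (k in seq_len(nrow(pairs))) {
    u <- pairs$bu[k]; v <- pairs$bv[k]
    ru <- find(u); rv <- find(v)
    if (ru == rv) next
    if (pg_rigid_pair(g, u, v)) parent[max(ru, rv)] <- min(ru, rv)
  }
  broot <- vapply(seq_len(nb), find, 1L)
  bcl <- match(broot, unique(broot))

  atom_cluster <- bcl[network$body]
  sizes <- sort(table(atom_cluster), decreasing = TRUE)
  relabel <- match(atom_cluster, as.integer(names(sizes)))
  sizes <- as.integer(sizes)

  ## connected components of the body multigraph, for the trivial-DOF count
  bonds_b <- data.frame(i = edges$bu, j = edges$bv)
  comp <- graph_components(nb, bonds_b)
  n_comp <- max(comp)

  structure(list(cluster = relabel, cluster_sizes = sizes,
                 n_clusters = length(sizes), floppy = res$floppy,
                 independent_bars = res$independent,
                 internal_dof = res$floppy - 6L * n_comp,
                 n_bodies = nb, body = network$body),
            class = "RigidClusterDecomposition")
}

#' @export
print.RigidClusterDecomposition <- function(x, ...) {
  cat(sprintf(paste0("RigidClusterDecomposition: %d clusters over %d bodies;",
                     " largest %d atoms; floppy modes %d (internal %d)\n"),
              x$n_clusters, x$n_bodies, x$cluster_sizes[1], x$floppy,
              x$internal_dof))
  invisible(x)
}

#' Floppy-mode count of an explicit body-bar framework
#'
#' Convenience wrapper used for small frameworks given directly as a body
#' multigraph rather than built from a structure.
#'
#' @param n_bodies number of bodies.
#' @param edges data.frame with `bu`, `bv`, `bars` (bar multiplicity).
#' @return list(floppy, independent).
#' @export
pebble_floppy_count <- function(n_bodies, edges) {
  r <- run_pebble_game(n_bodies, edges)
  list(floppy = r$floppy, independent = r$independent)
}

#' Per-atom cluster assignment as a data.frame
#'
#' @param network a `ConstraintNetwork`.
#' @param decomposition its [decompose_rigid_clusters()] result.
#' @export
cluster_table <- function(network, decomposition) {
  data.frame(serial = network$atoms$serial, name = network$atoms$name,
             resno = network$atoms$resno, chain = network$atoms$chain,
             body = network$body, cluster = decomposition$cluster)
}
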