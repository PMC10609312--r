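#' Build a weighted residue-interaction graph
#'
#' Edges connect spatial contacts only; the weight of a contact is
#' `-log(max(coupling, eps))`, so strong coupling (|GNM correlation| or
#' any-edge NRI probability near 1) gives near-zero weight and the
#' minimum-weight path is the maximum-coupling signalling route.
#'
#' @param coupling symmetric N x N matrix in \[0, 1\] (values are clipped);
#'   e.g. `abs(cross_correlation(...))` or [edge_probability()] expanded to
#'   residues.
#' @param contacts N x N 0/1 adjacency (e.g. from a distance cutoff).
#' @param eps coupling floor; also caps the weight at `-log(eps)`.
#' @param residues node names (consensus numbering), default `1:N`.
#' @return A `residue_graph`: tibble of undirected edges (`from`, `to`,
#'   `coupling`, `weight`) with a `nodes` attribute.
#' @export
build_graph <- function(coupling, contacts, eps = 1e-4, residues = NULL) {
  N <- nrow(coupling)
  if (!all(dim(contacts) == dim(coupling))) abort_allonet("coupling and contacts must be congruent.")
  coupling <- pmin(pmax(abs(coupling), 0), 1 - 1e-9)
  if (all(coupling[contacts > 0 & !diag(N)] == 0)) abort_allonet("all-zero coupling on the contact set.")
  residues <- residues %||% seq_len(N)
  idx <- which(upper.tri(contacts) & contacts > 0, arr.ind = TRUE)
  vals <- coupling[idx]
  edges <- tibble::tibble(
    from = residues[idx[, 1]],
    to = residues[idx[, 2]],
    coupling = vals,
    weight = -log(pmax(vals, eps))
  )
  attr(edges, "nodes") <- residues
  class(edges) <- c("residue_graph", class(tibble::tibble()))
  edges
}

# adjacency list representation with deterministic neighbour order
graph_adjlist <- function(g) {
  nodes <- sort(unique(c(g$from, g$to, attr(g, "nodes"))))
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (r in seq_len(nrow(g))) {
    a <- as.character(g$from[r]); b <- as.character(g$to[r])
    adj[[a]] <- rbind(adj[[a]], c(g$to[r], g$weight[r]))
    adj[[b]] <- rbind(adj[[b]], c(g$from[r], g$weight[r]))
  }
  lapply(adj, function(m) {
    if (is.null(m)) return(m)
    m[order(m[, 1]), , drop = FALSE]
  })
}

# Dijkstra distances from one source over the adjacency list
dijkstra_dist <- function(adj, source) {
  nodes <- as.integer(names(adj))
  dist <- stats::setNames(rep(Inf, length(nodes)), names(adj))
  dist[as.character(source)] <- 0
  done <- stats::setNames(rep(FALSE, length(nodes)), names(adj))
  repeat {
    open <- which(!done & is.finite(dist))
    if (length(open) == 0) break
    u <- open[which.min(dist[open])]
    done[u] <- TRUE
    nb <- adj[[u]]
    if (!is.null(nb)) {
      for (r in seq_len(nrow(nb))) {
        v <- as.character(as.integer(nb[r, 1]))
        alt <- dist[u] + nb[r, 2]
        if (alt < dist[v] - 1e-12) dist[v] <- alt
      }
    }
  }
  dist
}

# lexicographically smallest minimum-weight path with fewest hops:
# walk forward along tight edges, preferring fewer remaining hops, then the
# smallest next node.
reconstruct_path <- function(adj, dist_to_sink, source, sink, tol = 1e-9) {
  # minimum remaining hops along tight edges, by relaxation
  hops <- stats::setNames(rep(Inf, length(adj)), names(adj))
  hops[as.character(sink)] <- 0
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (u in names(adj)) {
      nb <- adj[[u]]
      if (is.null(nb) || !is.finite(dist_to_sink[u])) next
      for (r in seq_len(nrow(nb))) {
        v <- as.character(as.integer(nb[r, 1]))
        tight <- abs(nb[r, 2] + dist_to_sink[v] - dist_to_sink[u]) <= tol * max(1, abs(dist_to_sink[u]))
        if (tight && hops[v] + 1 < hops[u]) {
          hops[u] <- hops[v] + 1
          changed <- TRUE
        }
      }
    }
  }
  path <- source
  u <- as.character(source)
  while (as.integer(u) != sink) {
    nb <- adj[[u]]
    cand <- integer(0)
    for (r in seq_len(nrow(nb))) {
      v <- as.character(as.integer(nb[r, 1]))
      tight <- abs(nb[r, 2] + dist_to_sink[v] - dist_to_sink[u]) <= tol * max(1, abs(dist_to_sink[u]))
      if (tight && hops[v] == hops[u] - 1) cand <- c(cand, as.integer(v))
    }
    u <- as.character(min(cand))
    path <- c(path, as.integer(u))
  }
  path
}

#' Shortest signalling pathways between residue sets
#'
#' One minimum-weight (Dijkstra) path per (source, sink) pair, with ties
#' broken by fewer hops and then the lexicographically smallest node
#' sequence; unreachable sinks are skipped with a warning. Defaults follow
#' the allosteric analysis: sources are the conserved substrate-recognition
#' residues (consensus 11 and 117), sinks the I-Loop.
#'
#' @param g a [build_graph()] result.
#' @param sources,sinks consensus residue sets.
#' @return A `path_set`: tibble with columns `source`, `sink`, `weight`,
#'   `length`, `path` (list of integer vectors).
#' @export
allosteric_paths <- function(g, sources = c(11, 117), sinks = iloop_positions()) {
  adj <- graph_adjlist(g)
  nodes <- as.integer(names(adj))
  missing <- setdiff(c(sources, sinks), nodes)
  sources <- intersect(sources, nodes); sinks <- intersect(sinks, nodes)
  if (length(missing) > 0) {
    warn_allonet(sprintf("%d source/sink residue(s) not in graph: %s",
                         length(missing), paste(missing, collapse = ", ")))
  }
  if (length(sources) == 0 || length(sinks) == 0) abort_allonet("no usable sources or sinks.")
  rows <- list()
  for (snk in sinks) {
    dist <- dijkstra_dist(adj, snk)              # undirected: dist to sink
    for (src in sources) {
      if (src == snk) next
      if (!is.finite(dist[as.character(src)])) {
        warn_allonet(sprintf("sink %d unreachable from source %d; pair skipped.", snk, src))
        next
      }
      p <- reconstruct_path(adj, dist, src, snk)
      rows[[length(rows) + 1]] <- tibble::tibble(
        source = src, sink = snk,
        weight = unname(dist[as.character(src)]),
        length = length(p) - 1, path = list(p))
    }
  }
  if (length(rows) == 0) abort_allonet("no reachable (source, sink) pairs.")
  out <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$source, .data$sink)
  class(out) <- c("path_set", class(tibble::tibble()))
  out
}

#' Residue occurrence frequency across pathways
#'
#' How often each residue appears across the path set; high-frequency
#' residues mark the load-bearing relays of the signalling network.
#'
#' @param paths a `path_set`.
#' @return A tibble with columns `residue`, `count`, sorted by count.
#' @export
residue_frequency <- function(paths) {
  if (nrow(paths) == 0) abort_allonet("empty path set.")
  tibble::tibble(residue = unlist(lapply(paths$path, unique))) |>
    dplyr::count(.data$residue, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$residue)
}

#' The most likely pathway of a path set
#'
#' The path maximizing the mean occurrence frequency of its member
#' residues; ties break by smaller total weight, then by lexicographically
#' smaller node sequence (so the result is invariant to path-set order).
#'
#' @param paths a `path_set`.
#' @param freq optional precomputed [residue_frequency()].
#' @return One-row `path_set` tibble.
#' @export
top_pathway <- function(paths, freq = residue_frequency(paths)) {
  counts <- stats::setNames(freq$count, freq$residue)
  mean_freq <- vapply(paths$path, function(p) mean(counts[as.character(p)]), numeric(1))
  ord <- order(-mean_freq, paths$weight,
               vapply(paths$path, function(p) paste(sprintf("%06d", p), collapse = ","),
                      character(1)))
  paths[ord[1], ]
}

#' Contact adjacency from coordinates
#'
#' @param coords N x 3 matrix.
#' @param cutoff contact cutoff in Angstrom.
#' @return 0/1 adjacency matrix (zero diagonal).
#' @export
contact_adjacency <- function(coords, cutoff = 7.3) {
  D <- pair_dists(coords)
  A <- (D <= cutoff) * 1
  diag(A) <- 0
  A
}
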