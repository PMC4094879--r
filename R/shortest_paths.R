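#' Single-source shortest paths (Dijkstra)
#'
#' Exact single-source shortest-path distances over the weighted PPI
#' graph, with a canonical predecessor per node: among all neighbours
#' `u` of `v` lying on some shortest path to `v` (i.e.
#' `dist(u) + w(u, v) == dist(v)`), the lexicographically smallest
#' identifier is recorded. This makes path reconstruction deterministic
#' when several shortest paths tie.
#'
#' @param graph a `ppi_graph`.
#' @param source a node identifier present in the graph.
#' @return a list with `dist` (named numeric; `Inf` for unreachable
#'   nodes) and `pred` (named character; `NA` for the source and
#'   unreachable nodes).
#' @export
dijkstra_from <- function(graph, source) {
  s <- match(source, graph$nodes)
  if (is.na(s))
    stop_input("source node not in graph: ", source)
  res <- cpp_dijkstra(graph$ptr, graph$nbr, graph$wt,
                      length(graph$nodes), s - 1L)
  dist <- setNames(res$dist, graph$nodes)
  pred <- setNames(ifelse(is.na(res$pred), NA_character_,
                          graph$nodes[res$pred]), graph$nodes)
  list(dist = dist, pred = pred)
}

# Walk canonical predecessors from t back to s; returns node IDs from
# s to t, or NULL when t is unreachable.
walk_path <- function(graph, sssp, s_name, t_name) {
  if (!is.finite(sssp$dist[[t_name]])) return(NULL)
  nodes <- t_name
  v <- t_name
  while (v != s_name) {
    v <- sssp$pred[[v]]
    nodes <- c(v, nodes)
  }
  nodes
}

#' Shortest paths between all pairs of seed genes
#'
#' Computes one canonical shortest path per unordered seed pair
#' `{s, t}` (taking `s < t` lexicographically, with the path rooted at
#' `s`). Pairs in different connected components are skipped and
#' counted in the `disconnected_pairs` attribute.
#'
#' @param graph a `ppi_graph`.
#' @param seeds a `seed_set` or character vector of seed identifiers.
#' @return a list of path records, each with `source`, `target`,
#'   `nodes` (ordered from source to target), `total_weight`, and
#'   `inner_nodes` (the path without its endpoints). Attributes:
#'   `disconnected_pairs`, `pairs_total`.
#' @export
seed_pair_paths <- function(graph, seeds) {
  ss <- seed_set(seeds, graph)
  members <- ss$members
  if (length(members) < 2L)
    stop_seeds("need at least 2 seed genes present in the graph (got ",
               length(members), ")")
  paths <- list()
  disconnected <- 0L
  k <- length(members)
  for (i in seq_len(k - 1L)) {
    s <- members[i]
    sssp <- dijkstra_from(graph, s)
    for (j in seq(i + 1L, k)) {
      t <- members[j]
      nodes <- walk_path(graph, sssp, s, t)
      if (is.null(nodes)) {
        disconnected <- disconnected + 1L
        next
      }
      paths[[length(paths) + 1L]] <- list(
        source = s,
        target = t,
        nodes = nodes,
        total_weight = unname(sssp$dist[[t]]),
        inner_nodes = nodes[-c(1L, length(nodes))]
      )
    }
  }
  structure(paths,
            disconnected_pairs = disconnected,
            pairs_total = (k * (k - 1L)) %/% 2L)
}
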