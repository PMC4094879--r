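#' Accumulate path betweenness from seed-pair paths
#'
#' The statistic is the number of seed-pair shortest paths on which a
#' gene appears as an inner node. This is a raw path count, not
#' classical betweenness centrality: there is no normalization, no
#' fractional split across tied paths, and only seed pairs (not all
#' node pairs) contribute.
#'
#' @param paths a list of path records from [seed_pair_paths()].
#' @return an object of class `betweenness_table`: `counts` (named
#'   integer vector over genes with count > 0) and `pairs_used` (number
#'   of connected seed pairs).
#' @export
accumulate_betweenness <- function(paths) {
  inner <- unlist(lapply(paths, `[[`, "inner_nodes"), use.names = FALSE)
  counts <- if (length(inner)) {
    tab <- table(inner)
    setNames(as.integer(tab), names(tab))
  } else {
    setNames(integer(0), character(0))
  }
  structure(list(counts = counts, pairs_used = length(paths)),
            class = "betweenness_table")
}

#' @export
print.betweenness_table <- function(x, ...) {
  cat("Betweenness over", x$pairs_used, "seed-pair paths:",
      length(x$counts), "genes with count > 0\n")
  invisible(x)
}

#' Select candidate genes
#'
#' Candidates are the genes with betweenness greater than zero, minus
#' the seed genes themselves (seeds may accumulate betweenness as inner
#' nodes of other pairs' paths, but are never reported as candidates).
#' Sorted by descending betweenness, then ascending gene identifier.
#'
#' @param table a `betweenness_table`.
#' @param seeds a `seed_set` or character vector of seed identifiers.
#' @return data.frame with columns `gene`, `betweenness`.
#' @export
select_candidates <- function(table, seeds) {
  counts <- table$counts
  members <- if (inherits(seeds, "seed_set")) seeds$members else as.character(seeds)
  counts <- counts[counts > 0L]
  counts <- counts[!(names(counts) %in% members)]
  ord <- order(-counts, names(counts))
  data.frame(gene = names(counts)[ord],
             betweenness = unname(counts[ord]),
             stringsAsFactors = FALSE)
}

# Fast whole-graph betweenness for a sorted member vector, via the
# compiled path engine. mode "canonical" counts the single canonical
# path per pair; mode "all" counts a pair once for every node lying on
# any of its shortest paths.
betweenness_counts <- function(graph, members, mode = c("canonical", "all")) {
  mode <- match.arg(mode)
  idx <- match(members, graph$nodes)
  if (anyNA(idx)) stop_input("seed members missing from graph")
  idx <- sort(idx)
  res <- cpp_seed_betweenness(graph$ptr, graph$nbr, graph$wt,
                              length(graph$nodes), idx - 1L,
                              mode == "all")
  list(counts = setNames(res$counts, graph$nodes),
       pairs_connected = res$pairs_connected,
       pairs_total = res$pairs_total,
       inner_total = res$inner_total)
}
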