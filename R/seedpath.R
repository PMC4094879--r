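#' Prioritize disease genes by seed-pair shortest paths
#'
#' Fits the full prioritization model: computes one shortest path per
#' pair of seed genes (Dijkstra over weights `1000 - score`), scores
#' every gene by the number of those paths on which it is an inner
#' node, selects non-seed genes with positive betweenness as
#' candidates, and estimates each candidate's permutation FDR against
#' random same-size seed sets drawn uniformly from the graph.
#'
#' @param graph a `ppi_graph` from [build_graph()] or
#'   [read_ppi_graph()].
#' @param seeds a `seed_set` or character vector of seed identifiers;
#'   identifiers absent from the graph are dropped (and reported in the
#'   diagnostics).
#' @param n_permutations number of random seed sets (default 1000).
#' @param fdr_threshold significance cutoff; candidates with
#'   `fdr < fdr_threshold` (strict) are flagged (default 0.05).
#' @param rng_seed integer root seed for the permutation draw.
#' @param mode `"canonical"` (default) counts the single canonical
#'   shortest path per seed pair, breaking ties by lexicographically
#'   smallest predecessor; `"all"` counts a pair for every gene lying
#'   on any of its shortest paths.
#' @param pseudo_count use the `(r + 1) / (n + 1)` FDR variant (default
#'   `FALSE`, the plain exceedance fraction).
#' @param id_map optional data.frame (or named character vector)
#'   mapping protein identifiers to display gene names.
#' @return an object of class `seedpath` with components `candidates`
#'   (data.frame: `gene`, `gene_name`, `betweenness`, `fdr`,
#'   `significant`), `seeds` (the resolved `seed_set`), `observed` (the
#'   `betweenness_table`), and `diagnostics`.
#' @seealso [run_pipeline()] for the file-to-report wrapper;
#'   [summary.seedpath()], [coef.seedpath()], [plot.seedpath()].
#' @examples
#' fx <- figure1_fixture()
#' fit <- seedpath(fx$graph, fx$seeds, n_permutations = 50, rng_seed = 1)
#' fit$candidates
#' @export
seedpath <- function(graph, seeds, n_permutations = 1000L,
                     fdr_threshold = 0.05, rng_seed = 1L,
                     mode = c("canonical", "all"),
                     pseudo_count = FALSE, id_map = NULL) {
  mode <- match.arg(mode)
  config <- permutation_config(n_permutations, rng_seed, fdr_threshold,
                               pseudo_count)
  ss <- seed_set(seeds, graph)
  if (length(ss$members) < 2L)
    stop_seeds("need at least 2 seed genes present in the graph (got ",
               length(ss$members), ")")

  if (mode == "canonical") {
    paths <- seed_pair_paths(graph, ss)
    observed <- accumulate_betweenness(paths)
    pairs_connected <- length(paths)
    disconnected <- attr(paths, "disconnected_pairs")
  } else {
    bc <- betweenness_counts(graph, ss$members, mode = "all")
    counts <- bc$counts[bc$counts > 0L]
    observed <- structure(list(counts = counts,
                               pairs_used = bc$pairs_connected),
                          class = "betweenness_table")
    pairs_connected <- bc$pairs_connected
    disconnected <- bc$pairs_total - bc$pairs_connected
  }

  cand <- select_candidates(observed, ss)
  if (nrow(cand) > 0L) {
    sets <- draw_permutation_sets(graph, length(ss$members), config)
    perm <- permutation_betweenness(graph, sets, cand$gene, mode = mode)
    records <- compute_fdr(cand, perm, config)
  } else {
    records <- data.frame(gene = character(), betweenness = integer(),
                          fdr = numeric(), significant = logical(),
                          stringsAsFactors = FALSE)
  }
  records$gene_name <- map_gene_names(records$gene, id_map)
  records <- records[, c("gene", "gene_name", "betweenness", "fdr",
                         "significant")]
  rownames(records) <- NULL

  structure(
    list(
      candidates = records,
      seeds = ss,
      observed = observed,
      config = config,
      mode = mode,
      diagnostics = list(
        n_nodes = length(graph$nodes),
        n_edges = nrow(graph$edges),
        seeds_found = length(ss$members),
        seeds_dropped = length(ss$dropped),
        pairs_connected = pairs_connected,
        pairs_disconnected = disconnected,
        n_candidates = nrow(records),
        n_significant = sum(records$significant),
        n_permutations = config$n_permutations,
        rng_seed = config$rng_seed,
        fdr_threshold = config$fdr_threshold,
        mode = mode,
        pseudo_count = config$pseudo_count
      ),
      call = match.call()
    ),
    class = "seedpath"
  )
}

map_gene_names <- function(genes, id_map) {
  if (length(genes) == 0L) return(character(0))
  if (is.null(id_map)) return(rep("", length(genes)))
  if (is.data.frame(id_map)) {
    map <- setNames(as.character(id_map[[2L]]), as.character(id_map[[1L]]))
  } else {
    map <- id_map
  }
  out <- unname(map[genes])
  out[is.na(out)] <- ""
  out
}

#' Read an identifier-mapping file
#'
#' Two-column TSV `protein_id<TAB>gene_name`, no header required (a
#' header line is tolerated and skipped if its first field is
#' `protein_id`).
#'
#' @param path path to the mapping file.
#' @return data.frame with columns `protein_id`, `gene_name`.
#' @export
read_id_map <- function(path) {
  if (!file.exists(path)) stop_io("cannot read id-map file: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character",
                          col.names = c("protein_id", "gene_name"),
                          quote = "", comment.char = "#")
  if (nrow(df) > 0L && df$protein_id[1L] == "protein_id")
    df <- df[-1L, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @export
print.seedpath <- function(x, ...) {
  d <- x$diagnostics
  cat("Seed-pair shortest-path gene prioritization\n")
  cat("  graph: ", d$n_nodes, " nodes, ", d$n_edges, " edges\n", sep = "")
  cat("  seeds: ", d$seeds_found, " in graph",
      if (d$seeds_dropped) paste0(" (", d$seeds_dropped, " dropped)") else "",
      "; ", d$pairs_connected, " connected pairs",
      if (d$pairs_disconnected) paste0(" (", d$pairs_disconnected,
                                       " disconnected)") else "",
      "\n", sep = "")
  cat("  candidates: ", d$n_candidates, " with betweenness > 0; ",
      d$n_significant, " significant at FDR < ", d$fdr_threshold,
      " (", d$n_permutations, " permutations)\n", sep = "")
  invisible(x)
}

#' Summarize a prioritization fit
#'
#' @param object a `seedpath` object.
#' @param ... unused.
#' @return `object`, invisibly; prints diagnostics and the significant
#'   candidate table.
#' @export
summary.seedpath <- function(object, ...) {
  print(object)
  sig <- apply_threshold(object$candidates, object$config$fdr_threshold)
  if (nrow(sig) > 0L) {
    cat("\nSignificant candidates (FDR < ",
        object$config$fdr_threshold, "):\n", sep = "")
    print(sig, row.names = FALSE)
  } else {
    cat("\nNo significant candidates.\n")
  }
  invisible(object)
}

#' Observed betweenness of the candidate genes
#'
#' @param object a `seedpath` object.
#' @param ... unused.
#' @return named integer vector (candidate gene -> betweenness),
#'   sorted as in the candidate table.
#' @export
coef.seedpath <- function(object, ...) {
  setNames(object$candidates$betweenness, object$candidates$gene)
}

#' @export
as.data.frame.seedpath <- function(x, ...) x$candidates

#' Betweenness against permutation FDR
#'
#' Scatter of each candidate's observed betweenness (log-ish axis
#' friendly) against its permutation FDR, with the significance
#' threshold drawn as a horizontal line.
#'
#' @param x a `seedpath` object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.seedpath <- function(x, ...) {
  cand <- x$candidates
  if (nrow(cand) == 0L) {
    warning("no candidates to plot")
    return(invisible(x))
  }
  graphics::plot(cand$betweenness, cand$fdr,
                 xlab = "observed betweenness",
                 ylab = "permutation FDR",
                 pch = ifelse(cand$significant, 19, 1),
                 col = ifelse(cand$significant, "firebrick", "grey40"),
                 ...)
  graphics::abline(h = x$config$fdr_threshold, lty = 2, col = "grey60")
  invisible(x)
}
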