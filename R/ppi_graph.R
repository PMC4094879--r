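#' Convert a STRING combined score to an edge weight
#'
#' Interaction confidence scores `Q` are integers in `[150, 999]`; the
#' corresponding edge weight is `W = 1000 - Q`, so high-confidence
#' interactions become short edges and shortest paths prefer chains of
#' strong evidence. Valid scores map to weights in `[1, 850]`.
#'
#' @param score integer vector of combined scores in `[150, 999]`.
#' @return integer vector of edge weights `1000 - score`.
#' @examples
#' edge_weight(980) # 20
#' edge_weight(c(150, 999)) # 850, 1
#' @export
edge_weight <- function(score) {
  score <- as.integer(score)
  if (length(score) == 0L || anyNA(score) ||
      any(score < 150L) || any(score > 999L)) {
    stop_input("combined scores must be integers in [150, 999]")
  }
  1000L - score
}

#' Parse a STRING-dialect links file
#'
#' Reads whitespace- or tab-separated rows of
#' `protein1 protein2 combined_score`. A header line is auto-detected
#' (non-integer third field on the first row) unless `header` is given.
#' Self-loops are dropped with a warning; rows whose score falls outside
#' `[150, 999]` are rejected (default) or clamped into range; malformed
#' rows abort the run once more than `max_errors` of them accumulate.
#' Both orientations of a pair (`A B` and `B A`) are kept here;
#' deduplication happens in [build_graph()].
#'
#' @param path path to the links file.
#' @param header `TRUE`, `FALSE`, or `NA` (auto-detect).
#' @param min_score minimum accepted score (default 150, the floor of
#'   the STRING score range).
#' @param on_invalid what to do with scores outside `[min_score, 999]`:
#'   `"reject"` drops the row, `"clamp"` moves the score to the nearest
#'   bound.
#' @param max_errors abort after this many malformed rows.
#' @return a data.frame with columns `protein_a`, `protein_b`, `score`,
#'   carrying attributes `n_self_loops`, `n_out_of_range`,
#'   `n_malformed`.
#' @export
read_links <- function(path, header = NA, min_score = 150L,
                       on_invalid = c("reject", "clamp"),
                       max_errors = 100L) {
  on_invalid <- match.arg(on_invalid)
  min_score <- as.integer(min_score)
  if (is.na(min_score) || min_score < 150L || min_score > 999L)
    stop_input("min_score must be in [150, 999]")
  if (!file.exists(path)) stop_io("cannot read links file: ", path)
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) stop_io("cannot read links file: ",
                                                path, " (", conditionMessage(e), ")"))
  line_no <- seq_along(lines)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- line_no[keep]
  if (length(lines) == 0L)
    return(empty_records())

  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)

  # header auto-detection: first row whose third field is not an integer
  if (is.na(header)) {
    f1 <- fields[[1L]]
    header <- nf[1L] >= 3L && !grepl("^[0-9]+$", f1[3L])
  }
  if (isTRUE(header)) {
    fields <- fields[-1L]
    nf <- nf[-1L]
    line_no <- line_no[-1L]
  }
  if (length(fields) == 0L)
    return(empty_records())

  third <- vapply(fields, function(f) if (length(f) >= 3L) f[3L] else NA_character_,
                  character(1))
  bad <- nf < 3L | is.na(third) | !grepl("^[0-9]+$", third)
  if (any(bad)) {
    bad_lines <- line_no[bad]
    if (sum(bad) > max_errors) {
      stop_io(sum(bad), " malformed rows (first at line ", bad_lines[1L],
              "), exceeding the error cap of ", max_errors)
    }
    warning(sum(bad), " malformed row(s) skipped (lines ",
            paste(utils::head(bad_lines, 5L), collapse = ", "),
            if (sum(bad) > 5L) ", ..." else "", ")", call. = FALSE)
  }
  fields <- fields[!bad]
  if (length(fields) == 0L)
    return(empty_records(n_malformed = sum(bad)))

  a <- vapply(fields, `[`, character(1), 1L)
  b <- vapply(fields, `[`, character(1), 2L)
  score <- as.integer(vapply(fields, `[`, character(1), 3L))

  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-loop row(s) dropped", call. = FALSE)
    a <- a[!self]; b <- b[!self]; score <- score[!self]
  }

  out_of_range <- score < min_score | score > 999L
  if (any(out_of_range)) {
    if (on_invalid == "reject") {
      warning(sum(out_of_range), " row(s) with score outside [",
              min_score, ", 999] rejected", call. = FALSE)
      a <- a[!out_of_range]; b <- b[!out_of_range]
      score <- score[!out_of_range]
    } else {
      score <- pmin(pmax(score, min_score), 999L)
    }
  }

  structure(
    data.frame(protein_a = a, protein_b = b, score = score,
               stringsAsFactors = FALSE),
    n_self_loops = sum(self),
    n_out_of_range = sum(out_of_range),
    n_malformed = sum(bad)
  )
}

empty_records <- function(n_self_loops = 0L, n_out_of_range = 0L,
                          n_malformed = 0L) {
  structure(
    data.frame(protein_a = character(), protein_b = character(),
               score = integer(), stringsAsFactors = FALSE),
    n_self_loops = n_self_loops, n_out_of_range = n_out_of_range,
    n_malformed = n_malformed
  )
}

#' Build the undirected weighted PPI graph
#'
#' Nodes are all proteins appearing in at least one record; each
#' unordered pair gets one edge with weight `1000 - score`. When the
#' same pair occurs with conflicting scores (for example both
#' orientations of a STRING row), the maximum score -- i.e. the minimum
#' weight -- wins and the conflict is counted.
#'
#' @param records a data.frame as returned by [read_links()] (columns
#'   `protein_a`, `protein_b`, `score`).
#' @return an object of class `ppi_graph`: node identifiers (sorted),
#'   an edge table, and a compressed adjacency used by the path engine.
#' @export
build_graph <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("protein_a", "protein_b", "score") %in% names(records)))
    stop_input("records must have columns protein_a, protein_b, score")
  if (nrow(records) == 0L)
    stop_network("empty network: no interaction records")

  a <- as.character(records$protein_a)
  b <- as.character(records$protein_b)
  score <- edge_weight(records$score)   # validates range ...
  score <- 1000L - score                # ... then back to scores
  if (any(a == b)) stop_input("self-loop records must be filtered before graph build")

  nodes <- sort(unique(c(a, b)))
  ia <- match(a, nodes)
  ib <- match(b, nodes)
  from <- pmin(ia, ib)
  to <- pmax(ia, ib)

  # max-score merge per unordered pair
  ord <- order(from, to, -score)
  from <- from[ord]; to <- to[ord]; score <- score[ord]
  dup <- duplicated(paste(from, to))
  n_conflicts <- 0L
  if (any(dup)) {
    key <- paste(from, to)
    kept_score <- score[!dup][match(key[dup], key[!dup])]
    n_conflicts <- sum(kept_score != score[dup])
    if (n_conflicts > 0L)
      message(n_conflicts, " duplicate pair(s) with conflicting scores merged (max score kept)")
    from <- from[!dup]; to <- to[!dup]; score <- score[!dup]
  }
  weight <- 1000L - score

  new_ppi_graph(nodes, from, to, weight, n_conflicts = n_conflicts)
}

# Assemble the ppi_graph object and its CSR adjacency from a validated
# edge list (1-based indices, from < to).
new_ppi_graph <- function(nodes, from, to, weight, n_conflicts = 0L) {
  n <- length(nodes)
  ii <- c(from, to)
  jj <- c(to, from)
  ww <- c(weight, weight)
  o <- order(ii, jj)
  deg <- tabulate(ii, nbins = n)
  structure(
    list(
      nodes = nodes,
      edges = data.frame(from = from, to = to, weight = weight,
                         score = 1000L - weight),
      ptr = c(0L, cumsum(deg)),
      nbr = jj[o] - 1L,
      wt = ww[o],
      n_conflicts = n_conflicts
    ),
    class = "ppi_graph"
  )
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat("Weighted PPI graph:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  cat("Edge weights in [", min(x$edges$weight), ", ",
      max(x$edges$weight), "] (weight = 1000 - combined score)\n", sep = "")
  invisible(x)
}

#' Number of nodes / edges of a PPI graph
#' @param graph a `ppi_graph`.
#' @return integer count.
#' @export
n_nodes <- function(graph) length(graph$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(graph) nrow(graph$edges)

#' Edge table with node identifiers
#'
#' @param graph a `ppi_graph`.
#' @return data.frame with columns `protein_a`, `protein_b` (with
#'   `protein_a < protein_b`), `score`, `weight`.
#' @export
edge_table <- function(graph) {
  data.frame(protein_a = graph$nodes[graph$edges$from],
             protein_b = graph$nodes[graph$edges$to],
             score = graph$edges$score,
             weight = graph$edges$weight,
             stringsAsFactors = FALSE)
}

#' Write a graph back to the STRING links dialect
#'
#' Each undirected edge is written once, as
#' `protein1 protein2 combined_score` under a header line; re-parsing
#' the file reproduces the graph exactly.
#'
#' @param graph a `ppi_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_links <- function(graph, path) {
  et <- edge_table(graph)
  lines <- c("protein1 protein2 combined_score",
             paste(et$protein_a, et$protein_b, et$score))
  writeLines(lines, path)
  invisible(path)
}

#' Read a links file and build the graph in one step
#'
#' @inheritParams read_links
#' @param ... passed on to [read_links()].
#' @return a `ppi_graph`.
#' @export
read_ppi_graph <- function(path, ...) {
  build_graph(read_links(path, ...))
}
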