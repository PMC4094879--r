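#' Read a seed-gene list
#'
#' One protein identifier per line; blank lines and `#` comments (whole
#' line or trailing) are ignored. Duplicate identifiers are collapsed.
#'
#' @param path path to the seed list.
#' @return character vector of unique identifiers, in file order.
#' @export
read_seeds <- function(path) {
  if (!file.exists(path)) stop_io("cannot read seeds file: ", path)
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) stop_io("cannot read seeds file: ",
                                                path, " (", conditionMessage(e), ")"))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}

#' Resolve seed genes against a graph
#'
#' Splits a seed list into the members present in the graph (sorted, so
#' downstream pair enumeration is deterministic) and the identifiers
#' that had to be dropped because they are absent from the network.
#'
#' @param ids character vector of seed identifiers (or an existing
#'   `seed_set`, returned unchanged).
#' @param graph a `ppi_graph`.
#' @return an object of class `seed_set` with elements `members`
#'   (sorted, unique, all present in the graph) and `dropped`.
#' @export
seed_set <- function(ids, graph) {
  if (inherits(ids, "seed_set")) return(ids)
  ids <- unique(as.character(ids))
  present <- ids %in% graph$nodes
  structure(
    list(members = sort(ids[present]), dropped = sort(ids[!present])),
    class = "seed_set"
  )
}

#' @export
print.seed_set <- function(x, ...) {
  cat("Seed set:", length(x$members), "genes in graph")
  if (length(x$dropped))
    cat(" (", length(x$dropped), " dropped: not in network)", sep = "")
  cat("\n")
  invisible(x)
}
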