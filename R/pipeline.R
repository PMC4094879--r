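#' Run the full file-to-report prioritization pipeline
#'
#' Parses the links and seeds files, builds the weighted graph, fits
#' the prioritization model ([seedpath()]), and writes the candidate
#' table plus a JSON diagnostics sidecar. All candidates are reported
#' with a significance flag (not only the sub-threshold set), so the
#' table can be re-thresholded without rerunning the permutations.
#'
#' @param links_file STRING-dialect links file.
#' @param seeds_file seed list, one identifier per line (`#` comments
#'   allowed).
#' @param output path of the output TSV; the diagnostics sidecar is
#'   written next to it as `<output>.json`. `NULL` skips writing.
#' @param id_map_file optional two-column TSV `protein_id<TAB>gene_name`.
#' @param n_permutations,fdr_threshold,rng_seed,mode,pseudo_count
#'   passed to [seedpath()].
#' @param min_score minimum accepted combined score (see
#'   [read_links()]).
#' @param quiet suppress progress messages.
#' @return the fitted `seedpath` object, invisibly.
#' @export
run_pipeline <- function(links_file, seeds_file, output = NULL,
                         id_map_file = NULL, n_permutations = 1000L,
                         fdr_threshold = 0.05, rng_seed = 1L,
                         mode = c("canonical", "all"),
                         pseudo_count = FALSE, min_score = 150L,
                         quiet = FALSE) {
  mode <- match.arg(mode)
  say <- function(...) if (!quiet) message(...)

  records <- read_links(links_file, min_score = min_score)
  say("parsed ", nrow(records), " interaction records")
  graph <- build_graph(records)
  say("graph: ", length(graph$nodes), " nodes, ", nrow(graph$edges), " edges")

  ids <- read_seeds(seeds_file)
  ss <- seed_set(ids, graph)
  if (length(ss$members) < 2L)
    stop_seeds("seeds file yields fewer than 2 identifiers present in ",
               "the graph (", length(ss$members), " of ", length(ids), ")")
  say("seeds: ", length(ss$members), " in graph, ",
      length(ss$dropped), " dropped")

  id_map <- if (!is.null(id_map_file)) read_id_map(id_map_file) else NULL

  fit <- seedpath(graph, ss, n_permutations = n_permutations,
                  fdr_threshold = fdr_threshold, rng_seed = rng_seed,
                  mode = mode, pseudo_count = pseudo_count,
                  id_map = id_map)
  say("candidates: ", fit$diagnostics$n_candidates, "; significant: ",
      fit$diagnostics$n_significant)

  if (!is.null(output)) {
    write_report(fit, output)
    say("wrote ", output, " and ", paste0(output, ".json"))
  }
  invisible(fit)
}

#' Write the candidate report and diagnostics sidecar
#'
#' The TSV has header `gene gene_name betweenness fdr significant`
#' (tab-separated); FDR values are printed in plain decimal notation at
#' the resolution of the permutation count, making reruns with the same
#' inputs and RNG seed byte-identical. The sidecar `<path>.json` holds
#' the run diagnostics.
#'
#' @param fit a `seedpath` object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(fit, path) {
  cand <- fit$candidates
  fdr_chr <- format(cand$fdr, trim = TRUE, scientific = FALSE, digits = 15)
  lines <- c("gene\tgene_name\tbetweenness\tfdr\tsignificant",
             if (nrow(cand) > 0L)
               paste(cand$gene, cand$gene_name, cand$betweenness, fdr_chr,
                     ifelse(cand$significant, "TRUE", "FALSE"), sep = "\t"))
  writeLines(lines, path)
  jsonlite::write_json(fit$diagnostics, paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
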