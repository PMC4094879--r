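# Evaluate `expr` under a private RNG state seeded with `seed`,
# restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  expr
}

#' Permutation test configuration
#'
#' @param n_permutations number of random seed sets (default 1000).
#' @param rng_seed integer root seed; every permutation derives its own
#'   sub-seed from it, so each is reproducible in isolation and results
#'   do not depend on evaluation order.
#' @param fdr_threshold significance cutoff in `(0, 1]`; candidates
#'   with FDR strictly below it are flagged (default 0.05).
#' @param pseudo_count if `TRUE`, use the `(r + 1) / (n + 1)` estimator
#'   instead of the plain exceedance fraction `r / n`. Default `FALSE`:
#'   the FDR is the raw fraction of permutations whose betweenness
#'   strictly exceeds the observed value, with ties contributing
#'   nothing.
#' @return an object of class `permutation_config`.
#' @export
permutation_config <- function(n_permutations = 1000L, rng_seed = 1L,
                               fdr_threshold = 0.05,
                               pseudo_count = FALSE) {
  n_permutations <- as.integer(n_permutations)
  if (is.na(n_permutations) || n_permutations < 1L)
    stop_input("n_permutations must be a positive integer")
  if (!is.numeric(fdr_threshold) || fdr_threshold <= 0 || fdr_threshold > 1)
    stop_input("fdr_threshold must be in (0, 1]")
  structure(list(n_permutations = n_permutations,
                 rng_seed = as.integer(rng_seed),
                 fdr_threshold = fdr_threshold,
                 pseudo_count = isTRUE(pseudo_count)),
            class = "permutation_config")
}

#' Draw random seed sets for the permutation null
#'
#' Each set holds `seed_count` distinct nodes drawn uniformly without
#' replacement from all graph nodes (real seeds are eligible like any
#' other node). One sub-seed per permutation is derived from the root
#' seed, making each set reproducible independently of the others.
#'
#' @param graph a `ppi_graph`.
#' @param seed_count size of each set (the size of the real seed set).
#' @param config a [permutation_config()].
#' @return list of character vectors; attribute `sub_seeds` records the
#'   per-permutation seeds.
#' @export
draw_permutation_sets <- function(graph, seed_count, config) {
  n <- length(graph$nodes)
  seed_count <- as.integer(seed_count)
  if (seed_count > n)
    stop_input("seed_count (", seed_count, ") exceeds node count (", n, ")")
  sub_seeds <- with_seed(config$rng_seed,
                         sample.int(.Machine$integer.max,
                                    config$n_permutations))
  sets <- lapply(sub_seeds, function(s) {
    with_seed(s, graph$nodes[sample.int(n, seed_count)])
  })
  attr(sets, "sub_seeds") <- sub_seeds
  sets
}

#' Betweenness of candidate genes under each permutation
#'
#' Reruns the shortest-path betweenness computation with every random
#' set as the seed set and returns, for each gene of interest, its
#' betweenness under each permutation (0 when it lies on no path).
#'
#' @param graph a `ppi_graph`.
#' @param sets list of node sets from [draw_permutation_sets()].
#' @param genes character vector of genes to track (the real run's
#'   candidates).
#' @param mode path counting mode, as in [seedpath()].
#' @return integer matrix, `length(genes)` rows x `length(sets)`
#'   columns, rownames `genes`.
#' @export
permutation_betweenness <- function(graph, sets, genes,
                                    mode = c("canonical", "all")) {
  mode <- match.arg(mode)
  idx <- match(genes, graph$nodes)
  if (anyNA(idx)) stop_input("tracked genes missing from graph")
  out <- matrix(0L, nrow = length(genes), ncol = length(sets),
                dimnames = list(genes, NULL))
  for (i in seq_along(sets)) {
    bc <- betweenness_counts(graph, sets[[i]], mode = mode)
    out[, i] <- unname(bc$counts[idx])
  }
  out
}

#' Permutation FDR of each candidate gene
#'
#' For candidate `p` with observed betweenness `b(p)`, the FDR is the
#' fraction of permutations whose betweenness strictly exceeds `b(p)`:
#' `FDR(p) = #\{i : b_i(p) > b(p)\} / n`. Ties count as zero, so the
#' statistic favors significance; the `pseudo_count` option of
#' [permutation_config()] switches to the `(r + 1) / (n + 1)` variant.
#'
#' @param observed named integer vector of observed betweenness for the
#'   candidate genes (or a data.frame with columns `gene`,
#'   `betweenness`).
#' @param permuted matrix from [permutation_betweenness()] whose rows
#'   cover every observed gene.
#' @param config a [permutation_config()].
#' @return data.frame with columns `gene`, `betweenness`, `fdr`,
#'   `significant`, sorted by ascending FDR, then descending
#'   betweenness, then gene identifier.
#' @export
compute_fdr <- function(observed, permuted, config = permutation_config()) {
  if (is.data.frame(observed))
    observed <- setNames(as.integer(observed$betweenness), observed$gene)
  genes <- names(observed)
  if (!all(genes %in% rownames(permuted)))
    stop_input("permuted matrix is missing genes from the observed table")
  perm <- permuted[genes, , drop = FALSE]
  n <- ncol(perm)
  exceed <- rowSums(perm > observed[genes])
  fdr <- if (config$pseudo_count) (exceed + 1) / (n + 1) else exceed / n
  out <- data.frame(gene = genes,
                    betweenness = unname(observed[genes]),
                    fdr = unname(fdr),
                    stringsAsFactors = FALSE)
  out$significant <- out$fdr < config$fdr_threshold
  out[order(out$fdr, -out$betweenness, out$gene), , drop = FALSE]
}

#' Filter candidate records by the FDR threshold
#'
#' Keeps records whose FDR is strictly below the threshold (a record at
#' exactly the threshold is excluded), sorted by ascending FDR, then
#' descending betweenness, then gene identifier.
#'
#' @param records data.frame with columns `gene`, `betweenness`, `fdr`.
#' @param threshold significance cutoff (default 0.05).
#' @return the filtered, re-sorted data.frame.
#' @export
apply_threshold <- function(records, threshold = 0.05) {
  keep <- records$fdr < threshold
  out <- records[keep, , drop = FALSE]
  out <- out[order(out$fdr, -out$betweenness, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
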