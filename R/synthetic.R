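# Synthetic networks with known ground truth. These emulate the STRING
# links dialect (scores in [150, 999]) so every stage of the pipeline,
# parsers included, can be exercised without any download.

records_df <- function(a, b, score) {
  data.frame(protein_a = a, protein_b = b, score = as.integer(score),
             stringsAsFactors = FALSE)
}

#' Seven-node worked-example graph
#'
#' A small fixture pinning the published worked example: nodes `a`..`g`
#' where the unique shortest path from `a` to `d` is `a-e-f-g-d`, the
#' `a`-`e` edge has weight 20 (combined score 980), and every
#' alternative `a`-to-`d` route is strictly heavier. With seeds
#' `{a, d}`, genes `e`, `f`, `g` each receive betweenness 1.
#'
#' @return a list with `graph` (a `ppi_graph`), `seeds` (`c("a", "d")`)
#'   and `records` (the interaction records used to build the graph).
#' @export
figure1_fixture <- function() {
  rec <- records_df(
    a = c("a", "e", "f", "g", "a", "b", "c", "a", "b"),
    b = c("e", "f", "g", "d", "b", "c", "d", "d", "f"),
    score = c(980, 980, 980, 980, 600, 600, 600, 300, 500)
  )
  list(graph = build_graph(rec), seeds = c("a", "d"), records = rec)
}

#' Random scored network (Erdos-Renyi style)
#'
#' Each of the `choose(n, 2)` node pairs is an edge independently with
#' probability `edge_probability`; scores are drawn uniformly from
#' `score_range`. Fully deterministic for a fixed `rng_seed` (the
#' caller's RNG state is left untouched). If `file` is given, the
#' network is also written in the STRING links dialect; the file and
#' the returned graph are consistent (round-trip safe).
#'
#' @param n_nodes number of nodes.
#' @param edge_probability edge probability in `(0, 1]`.
#' @param score_range integer interval inside `[150, 999]`.
#' @param rng_seed integer seed.
#' @param file optional output path for the links file.
#' @param prefix node-name prefix.
#' @return a list with `graph`, `records`, and `file` (`NULL` when not
#'   written).
#' @export
random_network <- function(n_nodes, edge_probability,
                           score_range = c(150L, 999L), rng_seed = 1L,
                           file = NULL, prefix = "n") {
  if (edge_probability <= 0 || edge_probability > 1)
    stop_input("edge_probability must be in (0, 1]")
  score_range <- as.integer(score_range)
  if (score_range[1L] < 150L || score_range[2L] > 999L ||
      score_range[1L] > score_range[2L])
    stop_input("score_range must be an interval inside [150, 999]")
  nodes <- sprintf("%s%03d", prefix, seq_len(n_nodes))
  pairs <- utils::combn(n_nodes, 2L)
  rec <- with_seed(rng_seed, {
    keep <- stats::runif(ncol(pairs)) <= edge_probability
    if (!any(keep)) stop_network("specification yields zero edges")
    i <- pairs[1L, keep]
    j <- pairs[2L, keep]
    score <- sample(seq(score_range[1L], score_range[2L]), sum(keep),
                    replace = TRUE)
    records_df(nodes[i], nodes[j], score)
  })
  graph <- build_graph(rec)
  if (!is.null(file)) write_links(graph, file)
  list(graph = graph, records = rec, file = file)
}

#' Planted-connector network with known ground truth
#'
#' Builds a graph in which a set of "seed" genes is pairwise connected
#' only through designated "connector" genes by high-score (low-weight)
#' edges, on top of a sparse low-score background. Seeds are attached
#' round-robin to connectors and the connectors form a high-score
#' clique, so the cheapest route between any two seeds runs through one
#' or two connectors; every background detour costs at least two edges
#' of weight `1000 - max(background_score_range)` and is strictly
#' heavier. Ground truth: every connector has observed betweenness >= 1
#' and no background gene lies on any seed-pair shortest path.
#'
#' @param n_seeds number of planted seed genes (>= 2).
#' @param n_connectors number of connector genes (>= 1).
#' @param n_background number of background genes.
#' @param intra_score score of module edges (seed-connector and
#'   connector-connector), default 980.
#' @param background_score_range score interval for background edges,
#'   default `c(300, 400)` so background edges weigh 600 to 700.
#' @param background_edge_probability edge probability among background
#'   genes; the default keeps most background pairs within two cheap
#'   hops, so no background route ever improves by cutting through the
#'   module.
#' @param attach_per_node how many random background genes each module
#'   gene (seed or connector) is linked to, keeping the graph connected
#'   so random seed sets drawn anywhere in it have finite paths. The
#'   attachments use the weakest possible score (150, weight 850):
#'   they tie the module into the network without making it a shortcut
#'   for background traffic.
#' @param rng_seed integer seed.
#' @return a list with `graph`, `seeds`, `connectors`, `background`,
#'   and `records`.
#' @export
planted_module_network <- function(n_seeds = 6L, n_connectors = 3L,
                                   n_background = 40L,
                                   intra_score = 980L,
                                   background_score_range = c(300L, 400L),
                                   background_edge_probability = 0.2,
                                   attach_per_node = 2L,
                                   rng_seed = 42L) {
  if (n_seeds < 2L || n_connectors < 1L)
    stop_input("need at least 2 seeds and 1 connector")
  if (max(background_score_range) >= intra_score)
    stop_input("intra-module score must exceed the background score range")
  if (n_background < attach_per_node)
    stop_input("infeasible: fewer background genes than attachments per node")
  seeds <- sprintf("s%02d", seq_len(n_seeds))
  connectors <- sprintf("c%02d", seq_len(n_connectors))
  background <- sprintf("b%03d", seq_len(n_background))

  a <- character(0); b <- character(0); score <- integer(0)
  add <- function(x, y, s) {
    a <<- c(a, x); b <<- c(b, y); score <<- c(score, as.integer(s))
  }

  # module wiring: seeds round-robin onto connectors; connector clique
  owner <- rep_len(connectors, n_seeds)
  add(seeds, owner, rep(intra_score, n_seeds))
  if (n_connectors >= 2L) {
    cp <- utils::combn(connectors, 2L)
    add(cp[1L, ], cp[2L, ], rep(intra_score, ncol(cp)))
  }

  with_seed(rng_seed, {
    lo <- background_score_range[1L]; hi <- background_score_range[2L]
    # sparse background
    bp <- utils::combn(n_background, 2L)
    keep <- stats::runif(ncol(bp)) <= background_edge_probability
    if (any(keep)) {
      add(background[bp[1L, keep]], background[bp[2L, keep]],
          sample(lo:hi, sum(keep), replace = TRUE))
    }
    # weakest-score attachments of module genes into the background:
    # weight 850 each, so any background detour through the module
    # costs at least 1700 plus the module hops
    for (g in c(seeds, connectors)) {
      tgt <- sample(background, attach_per_node)
      add(rep(g, attach_per_node), tgt, rep(150L, attach_per_node))
    }
  })

  rec <- records_df(a, b, score)
  list(graph = build_graph(rec), seeds = seeds, connectors = connectors,
       background = background, records = rec)
}
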