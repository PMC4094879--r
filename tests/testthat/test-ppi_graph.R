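test_that("edge weight is 1000 minus the combined score", {
  expect_identical(edge_weight(980L), 20L)
  expect_identical(edge_weight(c(999L, 150L)), c(1L, 850L))
  # strictly decreasing in the score
  q <- 150:999
  expect_true(all(diff(edge_weight(q)) < 0))
  expect_error(edge_weight(149L), "150")
  expect_error(edge_weight(1000L), "999")
})

test_that("links parser maps rows to records and filters self-loops", {
  path <- write_temp_lines(c("P1 P2 980", "P1 P1 500", "P2\tP3\t400"))
  expect_warning(rec <- read_links(path), "self-loop")
  expect_identical(rec$protein_a, c("P1", "P2"))
  expect_identical(rec$protein_b, c("P2", "P3"))
  expect_identical(rec$score, c(980L, 400L))
  expect_identical(attr(rec, "n_self_loops"), 1L)
})

test_that("header auto-detection skips a non-numeric third field", {
  path <- write_temp_lines(c("protein1 protein2 combined_score",
                             "A B 900"))
  rec <- read_links(path)
  expect_identical(nrow(rec), 1L)
  # explicit override: treat the header row as data (and fail on it)
  expect_warning(rec2 <- read_links(path, header = FALSE), "malformed")
  expect_identical(nrow(rec2), 1L)
})

test_that("out-of-range scores are rejected or clamped per config", {
  path <- write_temp_lines(c("A B 100", "A C 900", "B C 1000"))
  expect_warning(rec <- read_links(path), "outside")
  expect_identical(nrow(rec), 1L)
  rec2 <- read_links(path, on_invalid = "clamp")
  expect_identical(rec2$score, c(150L, 900L, 999L))
  # a raised floor drops weak interactions
  expect_warning(rec3 <- read_links(path, min_score = 950L,
                                    on_invalid = "reject"), "outside")
  expect_identical(nrow(rec3), 0L)
})

test_that("malformed rows warn with line numbers and abort past the cap", {
  path <- write_temp_lines(c("A B 900", "broken row", "C D xyz", "D E 800"))
  expect_warning(rec <- read_links(path), "2 malformed")
  expect_identical(nrow(rec), 2L)
  expect_error(suppressWarnings(read_links(path, max_errors = 1L)),
               class = "seedpath_io_error")
  expect_error(read_links(tempfile("absent")), class = "seedpath_io_error")
})

test_that("graph build merges orientations and keeps the max score", {
  # both orientations of one pair collapse to a single edge
  path <- write_temp_lines(c("A B 900", "B A 900"))
  g <- build_graph(read_links(path))
  expect_identical(n_edges(g), 1L)
  expect_identical(edge_table(g)$weight, 100L)

  # conflicting scores: maximum score = minimum weight wins
  g2 <- suppressMessages(build_graph(records(c("A", "B"), c("B", "A"),
                                             c(900, 850))))
  expect_identical(n_edges(g2), 1L)
  expect_identical(edge_table(g2)$score, 900L)
  expect_identical(edge_table(g2)$weight, 100L)

  # direct application of the weight rule on a two-edge graph
  g3 <- build_graph(records(c("A", "B"), c("B", "C"), c(900, 800)))
  expect_identical(n_nodes(g3), 3L)
  et <- edge_table(g3)
  expect_identical(et$weight[et$protein_a == "A"], 100L)
  expect_identical(et$weight[et$protein_a == "B"], 200L)

  expect_error(build_graph(records(character(), character(), integer())),
               class = "seedpath_network_error")
})

test_that("graph invariants hold: weight range, W + Q = 1000, edge count", {
  for (seed in 1:5) {
    net <- random_network(20, 0.3, rng_seed = seed)
    et <- edge_table(net$graph)
    expect_true(all(et$weight >= 1L & et$weight <= 850L))
    expect_true(all(et$weight + et$score == 1000L))
    expect_lte(n_edges(net$graph), nrow(net$records))
  }
})

test_that("adjacency is symmetric: weight lookup matches both directions", {
  net <- random_network(15, 0.4, rng_seed = 3)
  g <- net$graph
  et <- edge_table(g)
  for (i in sample(nrow(et), 5)) {
    u <- et$protein_a[i]; v <- et$protein_b[i]
    duv <- dijkstra_from(g, u)$dist[[v]]
    dvu <- dijkstra_from(g, v)$dist[[u]]
    expect_identical(duv, dvu)
    expect_lte(duv, et$weight[i])
  }
})

test_that("writing and re-parsing a graph round-trips exactly", {
  for (seed in c(2, 7)) {
    net <- random_network(25, 0.2, rng_seed = seed)
    path <- withr::local_tempfile(fileext = ".txt")
    write_links(net$graph, path)
    g2 <- read_ppi_graph(path)
    expect_identical(g2$nodes, net$graph$nodes)
    expect_identical(edge_table(g2), edge_table(net$graph))
  }
})
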