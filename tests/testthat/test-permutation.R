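test_that("permutation sets are sized, distinct-membered and reproducible", {
  net <- random_network(30, 0.2, rng_seed = 4)
  cfg <- permutation_config(n_permutations = 50, rng_seed = 7)
  sets <- draw_permutation_sets(net$graph, 6, cfg)
  expect_length(sets, 50L)
  expect_true(all(vapply(sets, function(s) length(s) == 6 && !anyDuplicated(s),
                         logical(1))))
  # same root seed -> identical list; different -> different draw
  sets2 <- draw_permutation_sets(net$graph, 6, cfg)
  expect_identical(sets, sets2)
  sets3 <- draw_permutation_sets(net$graph, 6,
                                 permutation_config(50, rng_seed = 8))
  expect_false(identical(sets[[1]], sets3[[1]]))
  # forced full set when seed_count equals the node count
  full <- draw_permutation_sets(net$graph, 30, permutation_config(3, 1))
  expect_true(all(vapply(full, function(s) setequal(s, net$graph$nodes),
                         logical(1))))
  expect_error(draw_permutation_sets(net$graph, 31, cfg),
               class = "seedpath_input_error")
})

test_that("node inclusion frequency matches the hypergeometric rate", {
  net <- random_network(100, 0.05, rng_seed = 12)
  cfg <- permutation_config(n_permutations = 1000, rng_seed = 99)
  sets <- draw_permutation_sets(net$graph, 10, cfg)
  freq <- table(factor(unlist(sets), levels = net$graph$nodes)) / 1000
  sigma <- sqrt(0.1 * 0.9 / 1000)
  expect_true(all(abs(freq - 0.1) <= 4 * sigma))
})

test_that("FDR is the strict exceedance fraction", {
  # hand-counted example: ties at the observed value contribute nothing
  perm <- matrix(c(5L, 3L, 1L, 4L), nrow = 1, dimnames = list("g", NULL))
  out <- compute_fdr(c(g = 3L), perm, permutation_config(4, 1))
  expect_identical(out$fdr, 0.5)

  perm0 <- matrix(0L, nrow = 1, ncol = 10, dimnames = list("g", NULL))
  expect_identical(compute_fdr(c(g = 5L), perm0,
                               permutation_config(10, 1))$fdr, 0)

  perm1 <- matrix(7L, nrow = 1, ncol = 10, dimnames = list("g", NULL))
  expect_identical(compute_fdr(c(g = 0L), perm1,
                               permutation_config(10, 1))$fdr, 1)

  # the optional pseudo-count variant shifts to (r + 1) / (n + 1)
  out_pc <- compute_fdr(c(g = 3L), perm,
                        permutation_config(4, 1, pseudo_count = TRUE))
  expect_identical(out_pc$fdr, 3 / 5)

  expect_error(compute_fdr(c(h = 1L), perm, permutation_config(4, 1)),
               class = "seedpath_input_error")
})

test_that("FDR values are multiples of 1/n and lie in [0, 1]", {
  net <- random_network(60, 0.08, rng_seed = 21)
  fit <- seedpath(net$graph, sort(net$graph$nodes)[1:8],
                  n_permutations = 40, rng_seed = 2)
  fdr <- fit$candidates$fdr
  expect_true(all(fdr >= 0 & fdr <= 1))
  expect_true(all(abs(fdr * 40 - round(fdr * 40)) < 1e-9))
})

test_that("raising the observed betweenness never increases the FDR", {
  perm <- matrix(sample(0:10, 200, replace = TRUE), nrow = 1,
                 dimnames = list("g", NULL))
  cfg <- permutation_config(200, 1)
  fdrs <- vapply(0:10, function(b)
    compute_fdr(setNames(as.integer(b), "g"), perm, cfg)$fdr, numeric(1))
  expect_true(all(diff(fdrs) <= 0))
})

test_that("a permutation identical to the real seeds reproduces observed counts", {
  fx <- figure1_fixture()
  obs <- accumulate_betweenness(seed_pair_paths(fx$graph, fx$seeds))
  perm <- permutation_betweenness(fx$graph, list(fx$seeds),
                                  names(obs$counts))
  expect_identical(perm[, 1], obs$counts[rownames(perm)])
})

test_that("permutation results do not depend on evaluation order", {
  net <- random_network(40, 0.1, rng_seed = 6)
  cfg <- permutation_config(20, rng_seed = 5)
  sets <- draw_permutation_sets(net$graph, 5, cfg)
  genes <- net$graph$nodes[1:10]
  fwd <- permutation_betweenness(net$graph, sets, genes)
  rev_ <- permutation_betweenness(net$graph, rev(sets), genes)
  expect_identical(fwd, rev_[, ncol(rev_):1])
})

test_that("threshold filter is strict and sorts like the report", {
  rec <- data.frame(
    gene = c("a", "b", "c", "d", "e"),
    betweenness = c(10L, 5L, 7L, 7L, 1L),
    fdr = c(0.05, 0.047, 0.01, 0.01, 0.2),
    stringsAsFactors = FALSE
  )
  out <- apply_threshold(rec, 0.05)
  # fdr == 0.05 exactly is excluded; 0.047 retained
  expect_identical(out$gene, c("c", "d", "b"))
  expect_identical(nrow(apply_threshold(rec[0, ], 0.05)), 0L)
})
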