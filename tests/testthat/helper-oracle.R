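# Brute-force oracles, independent of the package's path engine: they
# work from the plain edge table (node names) by exhaustive simple-path
# enumeration, feasible on graphs with <= 8 nodes.

oracle_adjacency <- function(et) {
  nodes <- sort(unique(c(et$protein_a, et$protein_b)))
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(et))) {
    a <- et$protein_a[i]; b <- et$protein_b[i]; w <- et$weight[i]
    adj[[a]] <- rbind(adj[[a]], data.frame(nbr = b, w = w))
    adj[[b]] <- rbind(adj[[b]], data.frame(nbr = a, w = w))
  }
  adj
}

# Minimum path weight from s to every node, by enumerating every simple
# path out of s.
oracle_distances_from <- function(et, s) {
  adj <- oracle_adjacency(et)
  nodes <- names(adj)
  best <- setNames(rep(Inf, length(nodes)), nodes)
  dfs <- function(v, visited, cost) {
    if (cost < best[[v]]) best[[v]] <<- cost
    nb <- adj[[v]]
    for (i in seq_len(NROW(nb))) {
      u <- nb$nbr[i]
      if (!(u %in% visited)) dfs(u, c(visited, u), cost + nb$w[i])
    }
  }
  dfs(s, s, 0)
  best
}

# All distinct shortest s -> t paths (node vectors), by cost-ordered
# enumeration of simple paths: partial paths are expanded cheapest
# first, so the first path that reaches t is optimal and everything
# costlier than the optimum is pruned unexpanded.
oracle_shortest_paths <- function(et, s, t) {
  adj <- oracle_adjacency(et)
  found <- list()
  best <- Inf
  queue <- list(list(path = s, cost = 0))
  costs <- 0
  while (length(queue) > 0L) {
    i <- which.min(costs)
    cur <- queue[[i]]
    queue <- queue[-i]; costs <- costs[-i]
    if (cur$cost > best) break   # nothing cheaper remains
    v <- cur$path[length(cur$path)]
    if (v == t) {
      if (cur$cost < best) best <- cur$cost
      found[[length(found) + 1L]] <- cur$path
      next
    }
    nb <- adj[[v]]
    for (j in seq_len(NROW(nb))) {
      u <- nb$nbr[j]
      nc <- cur$cost + nb$w[j]
      if (!(u %in% cur$path) && nc <= best) {
        queue[[length(queue) + 1L]] <- list(path = c(cur$path, u), cost = nc)
        costs <- c(costs, nc)
      }
    }
  }
  list(weight = best, paths = found)
}

# Canonical path, derived by independently applying the tie rule to the
# oracle distances: walking back from t, the predecessor of v is the
# lexicographically smallest neighbour u with dist(u) + w(u,v) == dist(v).
oracle_canonical_path <- function(et, s, t) {
  dist <- oracle_distances_from(et, s)
  if (!is.finite(dist[[t]])) return(NULL)
  adj <- oracle_adjacency(et)
  path <- t
  v <- t
  while (v != s) {
    nb <- adj[[v]]
    on_sp <- nb$nbr[dist[nb$nbr] + nb$w == dist[[v]]]
    v <- sort(on_sp)[1L]
    path <- c(v, path)
  }
  path
}

# Betweenness recount from oracle canonical paths.
oracle_betweenness <- function(et, seeds) {
  seeds <- sort(seeds)
  counts <- setNames(integer(0), character(0))
  pairs_used <- 0L
  k <- length(seeds)
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    p <- oracle_canonical_path(et, seeds[i], seeds[j])
    if (is.null(p)) next
    pairs_used <- pairs_used + 1L
    inner <- p[-c(1L, length(p))]
    for (g in inner) counts[g] <- (if (g %in% names(counts)) counts[[g]] else 0L) + 1L
  }
  list(counts = counts, pairs_used = pairs_used)
}
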