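# Independent brute-force oracles used to cross-check the package's
# algorithms, plus small fixture builders. The oracles deliberately
# avoid the package's own graph code paths (and igraph): plain-R BFS,
# subset enumeration, dense linear algebra.

# Random directed network fixture (plain edge sampling, no generator).
random_test_network <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- runif(nrow(pairs)) < p
  edges <- pairs[keep, , drop = FALSE]
  if (nrow(edges) == 0L) edges <- pairs[1, , drop = FALSE]
  ppi_network(tibble::tibble(from = edges$from, to = edges$to, score = 950L,
                             from_contextualization = FALSE),
              nodes = nodes)
}

# Adjacency list out-neighbours from a ppi_network's edge table.
edge_adj <- function(net) {
  split(net$edges$to, factor(net$edges$from, levels = net$nodes))
}

# Hop distance from `from` to every node by plain BFS.
oracle_bfs <- function(net, from) {
  adj <- edge_adj(net)
  dist <- setNames(rep(Inf, length(net$nodes)), net$nodes)
  dist[from] <- 0
  frontier <- from
  while (length(frontier) > 0L) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(dist[nxt])]
    if (length(nxt) == 0L) break
    dist[nxt] <- dist[frontier[1]] + 1  # all frontier nodes share a distance
    frontier <- nxt
  }
  dist
}

# Reciprocal-sum shortest-path scores over reachable seeds, per
# candidate, by one BFS per candidate.
oracle_sp <- function(net, seeds) {
  candidates <- sort(setdiff(net$nodes, seeds))
  res <- lapply(candidates, function(x) {
    d <- oracle_bfs(net, x)[intersect(seeds, net$nodes)]
    reach <- is.finite(d)
    total <- sum(d[reach])
    data.frame(node = x, reachable_dps = sum(reach),
               sp = if (total > 0) 1 / total else 0)
  })
  do.call(rbind, res)
}

# Steady state of the restart walk by dense linear solve:
# P = r (I - (1 - r) A)^{-1} P0, A column-normalized over out-edges.
oracle_rw <- function(net, seeds, r) {
  n <- length(net$nodes)
  idx <- setNames(seq_len(n), net$nodes)
  A <- matrix(0, n, n)
  outdeg <- table(factor(net$edges$from, levels = net$nodes))
  for (i in seq_len(nrow(net$edges))) {
    u <- net$edges$from[i]; v <- net$edges$to[i]
    A[idx[v], idx[u]] <- 1 / as.numeric(outdeg[u])
  }
  p0 <- numeric(n)
  seeds <- intersect(seeds, net$nodes)
  p0[idx[seeds]] <- 1 / length(seeds)
  p <- solve(diag(n) - (1 - r) * A, r * p0)
  setNames(p, net$nodes)
}

# All maximal cliques (>= min_size) by exhaustive subset enumeration on
# the undirected projection. Feasible up to ~15 nodes.
oracle_cliques <- function(net, min_size = 3) {
  nodes <- net$nodes
  M <- matrix(FALSE, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  M[cbind(net$edges$from, net$edges$to)] <- TRUE
  M <- M | t(M)
  is_clique <- function(members) {
    sub <- M[members, members, drop = FALSE]
    all(sub[upper.tri(sub)])
  }
  n <- length(nodes)
  cliques <- list()
  for (mask in seq_len(2^n - 1L)) {
    members <- nodes[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
    if (length(members) >= min_size && is_clique(members)) {
      cliques[[length(cliques) + 1L]] <- sort(members)
    }
  }
  # keep maximal ones only
  keep <- vapply(seq_along(cliques), function(i) {
    !any(vapply(seq_along(cliques), function(j) {
      i != j && all(cliques[[i]] %in% cliques[[j]])
    }, logical(1)))
  }, logical(1))
  cliques[keep]
}

# Build an interaction tibble directly (all directional, acting a->b).
make_interactions <- function(from, to, score = 950L,
                              is_directional = TRUE, a_is_acting = TRUE) {
  tibble::tibble(
    item_id_a = from, item_id_b = to,
    mode = "binding", action = NA_character_,
    is_directional = is_directional, a_is_acting = a_is_acting,
    score = as.integer(score)
  )
}

write_tsv_lines <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}
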