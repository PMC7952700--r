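test_that("shortest-path scores apply the reciprocal distance sum", {
  # X -> A -> Y1 and X -> Y2: d(X, Y1) = 2, d(X, Y2) = 1 => SP(X) = 1/3
  net <- build_raw_network(make_interactions(c("X", "A", "X"),
                                             c("A", "Y1", "Y2")))
  sp <- shortest_path_scores(net, c("Y1", "Y2"))
  expect_equal(sp$sp[sp$node == "X"], 1 / 3)
  expect_equal(sp$sp[sp$node == "A"], 1)     # adjacent to the one reachable seed
  expect_equal(sp$reachable_dps[sp$node == "X"], 2L)

  # candidate adjacent to the single seed scores exactly 1
  one <- build_raw_network(make_interactions("C", "S"))
  expect_equal(shortest_path_scores(one, "S")$sp, 1)

  expect_error(shortest_path_scores(net, "nope"), "no seed")
})

test_that("shortest-path scores match the per-pair BFS oracle", {
  for (seed in 1:30) {
    net <- random_test_network(n = sample(10:50, 1), p = 0.08, seed = seed)
    seeds <- sample(net$nodes, 3)
    got <- shortest_path_scores(net, seeds)
    want <- oracle_sp(net, seeds)
    expect_equal(got$node, want$node)
    expect_equal(got$sp, want$sp, tolerance = 1e-12)
    expect_equal(got$reachable_dps, want$reachable_dps)
  }
})

test_that("unreachable-seed policies rank as documented", {
  # B reaches both seeds; A reaches one closely
  net <- build_raw_network(make_interactions(c("A", "B", "B"),
                                             c("S1", "S1", "S2")))
  cf <- shortest_path_scores(net, c("S1", "S2"), unreachable = "count-first")
  ex <- shortest_path_scores(net, c("S1", "S2"), unreachable = "exclude")
  pe <- shortest_path_scores(net, c("S1", "S2"), unreachable = "penalty")
  expect_equal(cf$sp[cf$node == "A"], 1)          # reachable-only sum
  expect_equal(ex$sp[ex$node == "A"], 1)
  expect_equal(pe$sp[pe$node == "A"], 1 / (1 + 4))  # |nodes| = 4 penalty
  expect_equal(pe$sp[pe$node == "B"], 1 / 2)
})

test_that("adding a shortcut edge never lowers a shortest-path score", {
  base <- random_test_network(15, 0.1, 99)
  seeds <- sample(base$nodes, 3)
  before <- shortest_path_scores(base, seeds, unreachable = "exclude")
  # add an edge from a candidate straight to a seed
  cand <- setdiff(base$nodes, seeds)[1]
  extra <- dplyr::bind_rows(base$edges,
    tibble::tibble(from = cand, to = seeds[1], score = 950L,
                   from_contextualization = FALSE))
  extra <- extra[!duplicated(paste(extra$from, extra$to)), ]
  after <- shortest_path_scores(ppi_network(extra, nodes = base$nodes),
                                seeds, unreachable = "exclude")
  joined <- merge(before, after, by = "node", suffixes = c("_b", "_a"))
  ok <- joined$reachable_dps_a > joined$reachable_dps_b |
        joined$sp_a >= joined$sp_b - 1e-12
  expect_true(all(ok))
})

test_that("restart walk reduces to the seed distribution at r = 1", {
  net <- random_test_network(12, 0.15, 4)
  seeds <- net$nodes[1:3]
  rw <- random_walk_scores(net, seeds, r = 1)
  expect_equal(rw$rw[rw$node %in% seeds], rep(1 / 3, 3))
  expect_equal(sum(rw$rw), 1)
})

test_that("restart walk equals the closed-form solve on a 2-node chain", {
  # A -> B, seed {A}: P = 0.7 P0 + 0.3 A P solved by hand
  net <- build_raw_network(make_interactions("A", "B"))
  rw <- random_walk_scores(net, "A", r = 0.7, tol = 1e-14)
  want <- oracle_rw(net, "A", r = 0.7)
  expect_equal(setNames(rw$rw, rw$node)[c("A", "B")], want[c("A", "B")],
               tolerance = 1e-8)
  expect_equal(rw$rw[rw$node == "A"], 0.7, tolerance = 1e-8)
  expect_equal(rw$rw[rw$node == "B"], 0.21, tolerance = 1e-8)  # 0.3 * 0.7
})

test_that("restart walk matches the dense linear solve on random graphs", {
  for (seed in 1:30) {
    net <- random_test_network(n = sample(5:20, 1), p = 0.2, seed = 1000 + seed)
    seeds <- sample(net$nodes, 2)
    got <- random_walk_scores(net, seeds, r = 0.7, tol = 1e-12)
    want <- oracle_rw(net, seeds, r = 0.7)
    expect_equal(setNames(got$rw, got$node), want[got$node], tolerance = 1e-7)
  }
})

test_that("walk probability is conserved on dangling-free graphs", {
  tested <- 0L
  for (seed in 1:8) {
    net <- random_test_network(15, 0.3, 2000 + seed)
    outdeg <- table(factor(net$edges$from, levels = net$nodes))
    if (any(outdeg == 0)) next  # conservation holds only without leakage
    rw <- random_walk_scores(net, net$nodes[1:2], r = 0.7)
    expect_equal(sum(rw$rw), 1, tolerance = 1e-9)
    tested <- tested + 1L
  }
  expect_gt(tested, 2L)
})

test_that("non-convergence raises an error carrying the residual", {
  net <- random_test_network(15, 0.3, 77)
  expect_error(random_walk_scores(net, net$nodes[1], r = 0.1, tol = 1e-14,
                                  max_iter = 2),
               "residual")
})

test_that("rank combination multiplies competition ranks and excludes seeds", {
  sp <- structure(
    tibble::tibble(node = c("a", "b", "c"), reachable_dps = 2L,
                   sp = c(0.5, 0.9, 0.2)),
    unreachable_policy = "count-first")
  rw <- tibble::tibble(node = c("a", "b", "c", "s"), rw = c(0.3, 0.1, 0.2, 0.4))
  res <- combine_ranks(sp, rw, dps = "s")
  expect_false("s" %in% res$node)
  expect_equal(res$cs, res$rank_sp * res$rank_rw)
  # a: sp rank 2, rw rank 1 -> cs 2; b: 1 * 3 = 3; c: 3 * 2 = 6
  expect_equal(res$node, c("a", "b", "c"))
  expect_equal(res$cs, c(2, 3, 6))
  expect_equal(res$rank, 1:3)

  expect_error(combine_ranks(sp, rw[1:2, ], dps = "s"), "different candidate")
})

test_that("final order equals a brute-force sort over rank products", {
  set.seed(8)
  for (rep in 1:20) {
    n <- 8
    nodes <- paste0("n", 1:n)
    sp_val <- sample(seq(0.1, 2, length.out = n))
    rw_val <- sample(seq(0.01, 1, length.out = n))
    sp <- structure(tibble::tibble(node = nodes, reachable_dps = 1L, sp = sp_val),
                    unreachable_policy = "exclude")
    rw <- tibble::tibble(node = nodes, rw = rw_val)
    res <- combine_ranks(sp, rw, dps = character(0))
    # oracle: competition ranks from score sorts, product, order by (cs, node)
    r1 <- rank(-sp_val, ties.method = "min")
    r2 <- rank(-rw_val, ties.method = "min")
    want <- nodes[order(r1 * r2, nodes)]
    expect_equal(res$node, want)
    expect_true(all(res$cs == res$rank_sp * res$rank_rw))
  }
})

test_that("clique expansion substitutes the best-ranked member protein", {
  mk_rank <- function(nodes) {
    structure(tibble::tibble(rank = seq_along(nodes), node = nodes,
                             reachable_dps = 1L, sp = 1, rank_sp = 1L,
                             rw = 1, rank_rw = 1L, cs = 1),
              metadata = list(expanded = FALSE),
              class = c("prynt_ranking", class(tibble::tibble())))
  }
  part <- assign_disjoint_cliques(list(c("P", "Q")), min_clique_size = 2)
  gid <- names(attr(part, "groups"))
  collapsed <- mk_rank(c("x1", gid, "x2"))
  raw <- mk_rank(c("Q", "x1", "P", "x2"))  # Q outranks P
  out <- expand_cliques(collapsed, part, raw)
  expect_equal(out$node, c("x1", "Q", "x2"))
  expect_equal(out$rank, 1:3)
  expect_equal(out$clique_members_dropped[out$node == "Q"], 1L)
  expect_equal(out$in_clique[out$node == "Q"], gid)

  # no groups: identity apart from the bookkeeping columns
  none <- assign_disjoint_cliques(list())
  same <- expand_cliques(collapsed, none, raw)
  expect_equal(same$node, collapsed$node)

  # output length = candidates - (members - groups)
  part2 <- assign_disjoint_cliques(list(c("P", "Q"), c("R", "S", "T")),
                                   min_clique_size = 2)
  gids <- names(attr(part2, "groups"))
  coll2 <- mk_rank(c("x1", gids[1], "x2", gids[2]))
  raw2 <- mk_rank(c("Q", "x1", "P", "x2", "T", "R", "S"))
  out2 <- expand_cliques(coll2, part2, raw2)
  expect_equal(nrow(out2), 4L)
  expect_equal(nrow(out2), nrow(coll2))  # one representative per super-node
})

test_that("direct baseline counts seed out-neighbours", {
  # hub with out-edges to 3 of 5 seeds
  seeds <- paste0("S", 1:5)
  ints <- make_interactions(c(rep("H", 3), "I", "S4"),
                            c(seeds[1:3], "S4", "I"))
  net <- build_raw_network(ints)
  d <- direct_scores(net, seeds)
  expect_equal(d$direct[d$node == "H"], 3L)
  expect_equal(d$direct[d$node == "I"], 1L)
  expect_equal(d$node[1], "H")

  # matches a plain neighbour-count oracle on a random graph
  net2 <- random_test_network(20, 0.15, 5)
  sds <- sample(net2$nodes, 5)
  got <- direct_scores(net2, sds)
  want <- vapply(got$node, function(x) {
    length(intersect(net2$edges$to[net2$edges$from == x], sds))
  }, integer(1))
  expect_equal(got$direct, unname(want))
  expect_true(all(diff(got$direct) <= 0))
})

test_that("seed proteins never appear among ranked candidates", {
  study <- generate_study(synthetic_spec(n_background_nodes = 80, rng_seed = 12))
  for (v in c("raw", "dp_c")) {
    net <- build_variant(study$interactions, v, dps = study$dps)
    res <- prioritize(net, study$dps)
    expect_length(intersect(res$node, study$dps$id), 0)
    expect_equal(res$rank, seq_len(nrow(res)))
    expect_true(all(res$cs == res$rank_sp * res$rank_rw))
  }
})
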