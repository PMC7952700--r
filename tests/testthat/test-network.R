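test_that("raw construction filters on confidence, directionality and self-loops", {
  ints <- make_interactions(
    from = c("A", "B", "A", "A"), to = c("B", "A", "A", "C"),
    score = c(950L, 950L, 990L, 990L),
    is_directional = c(TRUE, TRUE, TRUE, FALSE))
  net <- build_raw_network(ints, min_score = 900)
  expect_setequal(paste(net$edges$from, net$edges$to), c("A B", "B A"))
  expect_setequal(net$nodes, c("A", "B"))

  # nothing survives an unreachable threshold
  expect_error(build_raw_network(ints, min_score = 1000), "no interaction survives")

  # orientation: acting partner is the source
  flipped <- make_interactions("A", "B", a_is_acting = FALSE)
  net2 <- build_raw_network(flipped)
  expect_equal(net2$edges$from, "B")
  expect_equal(net2$edges$to, "A")
})

test_that("raising the confidence threshold never gains edges", {
  set.seed(11)
  n <- 40
  ints <- make_interactions(
    from = sample(sprintf("N%02d", 1:20), n, TRUE),
    to = sample(sprintf("N%02d", 1:20), n, TRUE),
    score = sample(0:999, n, TRUE))
  ints <- ints[ints$item_id_a != ints$item_id_b, ]
  counts <- vapply(c(0, 250, 500, 750, 900, 999), function(th) {
    tryCatch(nrow(build_raw_network(ints, min_score = th)$edges),
             error = function(e) 0L)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("seed injection adds incident edges regardless of confidence and is idempotent", {
  ints <- make_interactions(c("A", "B", "X"), c("B", "C", "A"),
                            score = c(950L, 950L, 300L))
  net <- build_raw_network(ints, min_score = 900)
  expect_false("X" %in% net$nodes)

  with_x <- add_deregulated_proteins(net, ints, dps = "X")
  expect_true("X" %in% with_x$nodes)
  added <- with_x$edges[with_x$edges$from == "X", ]
  expect_equal(added$to, "A")
  expect_true(added$from_contextualization)

  # idempotent: injecting again changes nothing
  twice <- add_deregulated_proteins(with_x, ints, dps = "X")
  expect_equal(twice$edges, with_x$edges)
  expect_equal(twice$nodes, with_x$nodes)

  # a seed already present with all incident edges above threshold: no change
  same <- add_deregulated_proteins(net, ints, dps = "C")
  expect_equal(same$edges, net$edges)

  # a seed absent from the interaction table stays absent but is reported
  rep_net <- suppressMessages(add_deregulated_proteins(net, ints, dps = "ZZ"))
  expect_false("ZZ" %in% rep_net$nodes)
  report <- attr(rep_net, "dp_report")
  expect_equal(report$status[report$dp == "ZZ"], "absent")
})

test_that("maximal clique detection works on the undirected projection", {
  # K4 on A-D (directed one way only) plus pendant D-E
  k4 <- t(utils::combn(c("A", "B", "C", "D"), 2))
  ints <- make_interactions(c(k4[, 1], "D"), c(k4[, 2], "E"))
  net <- build_raw_network(ints)
  cl <- find_cliques(net, min_clique_size = 3)
  expect_equal(cl, list(c("A", "B", "C", "D")))
  expect_equal(find_cliques(net, min_clique_size = 5), list())

  tri <- build_raw_network(make_interactions(c("A", "B", "C"), c("B", "C", "A")))
  expect_equal(find_cliques(tri, min_clique_size = 4), list())

  # agrees with exhaustive subset enumeration on random graphs
  for (seed in 1:8) {
    g <- random_test_network(12, 0.25, seed)
    got <- find_cliques(g, min_clique_size = 3)
    want <- oracle_cliques(g, min_size = 3)
    key <- function(l) sort(vapply(l, paste, character(1), collapse = "|"))
    expect_equal(key(got), key(want))
  }
})

test_that("disjoint assignment is greedy by size with deterministic tie-breaks", {
  part <- assign_disjoint_cliques(list(c("A", "B", "C", "D"), c("C", "D", "E")),
                                  min_clique_size = 3)
  groups <- attr(part, "groups")
  expect_equal(length(groups), 1L)          # {E} remainder is too small
  expect_equal(groups[[1]], c("A", "B", "C", "D"))

  two <- assign_disjoint_cliques(list(c("A", "B", "C"), c("X", "Y", "Z")))
  expect_equal(length(attr(two, "groups")), 2L)

  # groups are pairwise disjoint whatever the overlap structure
  set.seed(3)
  cliques <- replicate(10, sample(LETTERS[1:12], sample(3:6, 1)), simplify = FALSE)
  p <- assign_disjoint_cliques(cliques)
  expect_equal(anyDuplicated(p$member), 0L)

  # protected nodes are never absorbed
  prot <- assign_disjoint_cliques(list(c("A", "B", "C", "D")), protected = "A")
  expect_false("A" %in% prot$member)
})

test_that("clique collapse rewires edges to super-nodes and conserves counts", {
  ints <- make_interactions(c("A", "B", "B", "C"), c("B", "C", "A", "B"))
  net <- build_raw_network(ints)
  part <- assign_disjoint_cliques(list(c("B", "C")), min_clique_size = 2)
  col <- collapse_cliques(net, part)
  g <- attr(part, "groups")
  expect_equal(length(col$nodes), 2L)  # A + one super-node
  expect_setequal(paste(col$edges$from, col$edges$to),
                  c(paste("A", names(g)), paste(names(g), "A")))

  # conservation: |collapsed| = |original| - |grouped| + |groups|
  for (seed in 1:5) {
    gnet <- random_test_network(15, 0.3, seed)
    cls <- find_cliques(gnet, 3)
    if (length(cls) == 0L) next
    p <- assign_disjoint_cliques(cls, 3)
    cc <- collapse_cliques(gnet, p)
    expect_equal(length(cc$nodes),
                 length(gnet$nodes) - nrow(p) + length(attr(p, "groups")))
    # every collapsed edge has a witness edge in the source network
    to_group <- setNames(p$group, p$member)
    lift <- function(x) ifelse(x %in% names(to_group), to_group[x], x)
    src_keys <- paste(lift(gnet$edges$from), lift(gnet$edges$to))
    expect_true(all(paste(cc$edges$from, cc$edges$to) %in% src_keys))
    # no super-node keeps an edge to one of its own members
    expect_false(any(mapply(function(f, t) {
      (f %in% names(cc$members) && t %in% cc$members[[f]]) ||
      (t %in% names(cc$members) && f %in% cc$members[[t]])
    }, cc$edges$from, cc$edges$to)))
  }

  # empty partition collapses to the identity
  none <- assign_disjoint_cliques(list())
  same <- collapse_cliques(net, none)
  expect_equal(same$edges, net$edges)
  expect_setequal(same$nodes, net$nodes)

  # partition members must exist in the network
  bad <- assign_disjoint_cliques(list(c("Q", "R", "S")))
  expect_error(collapse_cliques(net, bad), "not present")
})

test_that("variant construction composes the contextualizations", {
  study <- generate_study(synthetic_spec(n_background_nodes = 60, n_dps = 5,
                                         rng_seed = 5))
  ints <- study$interactions
  dps <- study$dps

  raw <- build_variant(ints, "raw")
  raw2 <- build_raw_network(ints)
  expect_equal(raw$edges, raw2$edges)

  dp <- build_variant(ints, "dp", dps = dps)
  expect_true(nrow(dp$edges) >= nrow(raw$edges))

  # seeds stay addressable: never absorbed into super-nodes
  dpc <- build_variant(ints, "dp_c", dps = dps)
  expect_true(all(dps$id %in% c(dpc$nodes, setdiff(dps$id, dpc$source_network$nodes))))
  expect_false(any(dps$id %in% unlist(dpc$members)))

  cv <- build_variant(ints, "c", dps = dps)
  expect_equal(length(cv$nodes),
               length(cv$source_network$nodes) - sum(lengths(cv$members)) +
                 length(cv$members))
})

test_that("networks and partitions survive TSV serialization", {
  net <- random_test_network(10, 0.2, 21)
  tf <- tempfile(fileext = ".tsv")
  write_network_tsv(net, tf)
  back <- read_network_tsv(tf)
  expect_setequal(back$nodes, net$nodes)
  expect_equal(dplyr::arrange(back$edges, from, to),
               dplyr::arrange(net$edges, from, to))
})
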