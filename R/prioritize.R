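# Candidate prioritization: reciprocal shortest-path scoring, random
# walk with restart, rank-product combination, clique expansion and the
# direct-neighbour baseline. Candidates are all network nodes except
# the seed (deregulated) proteins, which are excluded from the output
# ranking but do participate as intermediate hops and transit states.

#' Reciprocal shortest-path scores
#'
#' For each candidate protein x the score is the reciprocal of the
#' summed directed hop distances from x to the seed proteins:
#' \deqn{SP(x) = 1 / \sum_y d(x, y)}
#' where d(x, y) is the minimum number of interactions on a directed
#' path from x to seed y. A candidate adjacent to the single seed
#' scores 1; larger is better.
#'
#' Seeds unreachable from a candidate make the sum ill-defined; the
#' `unreachable` policy decides the convention:
#' \describe{
#'   \item{`"count-first"`}{(default) sum over reachable seeds only and
#'     rank primarily by how many seeds are reachable (descending),
#'     secondarily by the score — "closer to more seeds is better"
#'     without an arbitrary penalty constant. Candidates reaching no
#'     seed score 0 and go last.}
#'   \item{`"penalty"`}{unreachable seeds contribute a distance equal
#'     to the node count.}
#'   \item{`"exclude"`}{sum over reachable seeds only; ranking uses the
#'     score alone.}
#' }
#'
#' @param net a [ppi_network()] (possibly collapsed).
#' @param dps seed set ([dp_set()] or character); at least one member
#'   must be a node of `net`.
#' @param unreachable policy for seeds with no directed path from a
#'   candidate; see Details.
#' @return tibble (`node`, `reachable_dps`, `sp`) over all non-seed
#'   nodes, with attribute `unreachable_policy`.
#' @export
shortest_path_scores <- function(net, dps,
                                 unreachable = c("count-first", "penalty", "exclude")) {
  stopifnot(inherits(net, "ppi_network"))
  unreachable <- match.arg(unreachable)
  members <- dp_members(dps)
  seeds <- intersect(members, net$nodes)
  if (length(seeds) == 0L) abort("no seed protein is present in the network")
  candidates <- setdiff(net$nodes, members)

  g <- as_igraph(net)
  d <- igraph::distances(g, v = candidates, to = seeds, mode = "out",
                         weights = NA)  # unweighted hop counts
  d <- matrix(d, nrow = length(candidates),
              dimnames = list(candidates, seeds))
  reachable <- is.finite(d)
  n_reach <- rowSums(reachable)

  total <- switch(unreachable,
    "count-first" = ,
    "exclude" = rowSums(ifelse(reachable, d, 0)),
    "penalty" = rowSums(ifelse(reachable, d, length(net$nodes)))
  )
  sp <- unname(ifelse(total > 0, 1 / total, 0))
  # a candidate whose only reachable seeds are at distance 0 cannot occur
  # (seeds are excluded from candidates), so total == 0 <=> n_reach == 0
  # under count-first/exclude.
  out <- tibble(node = candidates, reachable_dps = as.integer(n_reach), sp = sp)
  structure(out[order(out$node), ], unreachable_policy = unreachable)
}

#' Random walk with restart scores
#'
#' Simulates a walker that starts on the seed proteins and at each step
#' either moves along an outgoing interaction chosen uniformly at
#' random (probability 1 − r) or restarts on the seeds (probability r):
#' \deqn{P_{t+1} = (1 - r) A P_t + r P_0}
#' where A is the column-normalized adjacency matrix over out-edges and
#' P0 puts mass 1/|seeds| on every seed present in the network. The
#' iteration runs from P0 until the L1 change drops below `tol`; the
#' steady-state visiting probability scores each node.
#'
#' Dangling nodes (out-degree 0) have an all-zero column in A, so the
#' walk loses the mass sitting on them each step and the probabilities
#' sum to less than 1; the restart term keeps re-injecting mass. With
#' `dangling = "teleport"` that lost mass is instead redistributed to
#' the restart distribution.
#'
#' @param net a [ppi_network()].
#' @param dps seed set; members absent from the network are ignored
#'   (at least one must be present).
#' @param r restart probability in (0, 1]; default 0.7.
#' @param tol L1 convergence threshold (default 1e-10).
#' @param max_iter iteration cap (default 10000); non-convergence is an
#'   error carrying the last residual.
#' @param dangling `"none"` (default; mass on out-degree-0 nodes leaks)
#'   or `"teleport"` (leaked mass follows the restart distribution).
#' @return tibble (`node`, `rw`) over all nodes (seeds included), with
#'   attributes `iterations` and `residual`.
#' @export
random_walk_scores <- function(net, dps, r = 0.7, tol = 1e-10,
                               max_iter = 10000,
                               dangling = c("none", "teleport")) {
  stopifnot(inherits(net, "ppi_network"))
  dangling <- match.arg(dangling)
  assert_scalar_number(r, "r", lower = 0, upper = 1, lower_open = TRUE)
  assert_scalar_number(tol, "tol", lower = 0, lower_open = TRUE)
  members <- dp_members(dps)
  seeds <- intersect(members, net$nodes)
  if (length(seeds) == 0L) abort("no seed protein is present in the network")

  nodes <- net$nodes
  n <- length(nodes)
  idx <- setNames(seq_len(n), nodes)
  from <- idx[net$edges$from]
  to <- idx[net$edges$to]
  outdeg <- tabulate(from, nbins = n)
  # A[v, u] = 1 / outdeg(u) for each edge u -> v: column-stochastic
  # over out-edges, the walker travels along interaction direction.
  A <- Matrix::sparseMatrix(i = to, j = from, x = 1 / outdeg[from],
                            dims = c(n, n))
  p0 <- numeric(n)
  p0[idx[seeds]] <- 1 / length(seeds)
  is_dangling <- outdeg == 0L

  p <- p0
  residual <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    walked <- as.numeric(A %*% p)
    if (dangling == "teleport") {
      walked <- walked + sum(p[is_dangling]) * p0
    }
    p_next <- (1 - r) * walked + r * p0
    residual <- sum(abs(p_next - p))
    p <- p_next
    if (residual < tol) break
  }
  if (residual >= tol) {
    abort(sprintf("random walk did not converge in %d iterations (L1 residual %.3e)",
                  max_iter, residual))
  }
  structure(tibble(node = nodes, rw = p)[order(nodes), ],
            iterations = iter, residual = residual, r = r)
}

#' Combine shortest-path and random-walk rankings by rank product
#'
#' Candidates are ranked from higher to lower SP score (rank_sp) and
#' from higher to lower RW score (rank_rw); the combined score is the
#' rank product
#' \deqn{CS = rank_{sp} \times rank_{rw}}
#' and the final ranking orders candidates by ascending CS (smaller is
#' better). Seed proteins never appear among the candidates. Score
#' ties receive competition ("1224") ranks; final-order ties on CS are
#' broken by node identifier for determinism.
#'
#' @param sp_scores tibble from [shortest_path_scores()].
#' @param rw_scores tibble from [random_walk_scores()].
#' @param dps the seed set used for both score sets.
#' @return a `prynt_ranking`: tibble (`rank`, `node`, `reachable_dps`,
#'   `sp`, `rank_sp`, `rw`, `rank_rw`, `cs`) ordered by `rank`, with a
#'   `metadata` attribute.
#' @export
combine_ranks <- function(sp_scores, rw_scores, dps) {
  members <- dp_members(dps)
  rw <- rw_scores[!rw_scores$node %in% members, , drop = FALSE]
  if (!setequal(sp_scores$node, rw$node)) {
    abort("SP and RW score tables cover different candidate sets")
  }
  policy <- attr(sp_scores, "unreachable_policy") %||% "count-first"
  df <- dplyr::inner_join(sp_scores, rw[, c("node", "rw")], by = "node")

  rank_sp <- if (policy == "count-first") {
    competition_rank(-df$reachable_dps, -df$sp)
  } else {
    competition_rank(-df$sp)
  }
  rank_rw <- competition_rank(-df$rw)
  cs <- as.numeric(rank_sp) * as.numeric(rank_rw)

  df$rank_sp <- rank_sp
  df$rank_rw <- rank_rw
  df$cs <- cs
  df <- df[order(df$cs, df$node), ]
  df$rank <- seq_len(nrow(df))
  out <- df[, c("rank", "node", "reachable_dps", "sp", "rank_sp",
                "rw", "rank_rw", "cs")]
  meta <- list(
    n_candidates = nrow(out),
    n_seeds = length(members),
    unreachable_policy = policy,
    r = attr(rw_scores, "r"),
    rw_iterations = attr(rw_scores, "iterations"),
    rw_residual = attr(rw_scores, "residual"),
    expanded = FALSE
  )
  new_prynt_ranking(out, meta)
}

new_prynt_ranking <- function(tbl, metadata) {
  structure(as_tibble(tbl), metadata = metadata,
            class = c("prynt_ranking", class(as_tibble(tbl))))
}

#' @export
print.prynt_ranking <- function(x, ...) {
  m <- attr(x, "metadata")
  cat(sprintf("<prynt_ranking> %d candidate(s), %d seed(s)%s\n",
              nrow(x), m$n_seeds %||% NA_integer_,
              if (isTRUE(m$expanded)) ", clique-expanded" else ""))
  NextMethod()
}

#' Expand clique super-nodes back to protein-level candidates
#'
#' A ranking computed on a collapsed network places clique super-nodes
#' among the candidates. Each super-node is replaced by exactly one
#' member protein — the member with the best final rank in a reference
#' prioritization run on the uncollapsed network with the same seeds —
#' and the remaining members are dropped. Members absent from the
#' reference ranking fall back to lexicographic order. Protein-level
#' ranks are renumbered 1..N preserving the collapsed order.
#'
#' @param result `prynt_ranking` computed on the collapsed network.
#' @param partition the `clique_partition` that produced the collapse.
#' @param raw_result `prynt_ranking` computed on the corresponding
#'   uncollapsed network with identical seeds.
#' @return a protein-level `prynt_ranking`; the chosen representatives
#'   keep their super-node's position. Columns gain `in_clique` (the
#'   group id or NA) and `clique_members_dropped`.
#' @export
expand_cliques <- function(result, partition, raw_result) {
  stopifnot(inherits(result, "prynt_ranking"),
            inherits(partition, "clique_partition"),
            inherits(raw_result, "prynt_ranking"))
  groups <- attr(partition, "groups")
  ref_rank <- setNames(raw_result$rank, raw_result$node)

  rows <- vector("list", nrow(result))
  for (i in seq_len(nrow(result))) {
    row <- result[i, , drop = FALSE]
    node <- row$node
    if (node %in% names(groups)) {
      members <- groups[[node]]
      rr <- ref_rank[members]
      ranked <- members[!is.na(rr)]
      if (length(ranked) > 0L) {
        best <- ranked[order(rr[ranked], ranked)][1L]
      } else if (length(members) > 0L) {
        best <- sort(members)[1L]
      } else {
        warn(sprintf("clique super-node '%s' has no rankable member; dropped", node))
        next  # leave rows[[i]] NULL; bind_rows skips it
      }
      row$node <- best
      row$in_clique <- node
      row$clique_members_dropped <- length(members) - 1L
    } else {
      row$in_clique <- NA_character_
      row$clique_members_dropped <- 0L
    }
    rows[[i]] <- row
  }
  out <- dplyr::bind_rows(rows)
  out$rank <- seq_len(nrow(out))
  meta <- attr(result, "metadata")
  meta$expanded <- TRUE
  new_prynt_ranking(out, meta)
}

#' Direct-neighbour baseline ranking
#'
#' Scores each candidate by the number of seed proteins among its
#' direct out-neighbours (out-degree centrality restricted to seeds)
#' and ranks descending — the "guilt-by-association" baseline the
#' closeness-based scores are compared against.
#'
#' @param net a [ppi_network()].
#' @param dps seed set.
#' @return tibble (`rank`, `node`, `direct`) ordered by rank; ties get
#'   competition ranks, final order breaks ties by node id.
#' @export
direct_scores <- function(net, dps) {
  stopifnot(inherits(net, "ppi_network"))
  members <- dp_members(dps)
  seeds <- intersect(members, net$nodes)
  if (length(seeds) == 0L) abort("no seed protein is present in the network")
  candidates <- setdiff(net$nodes, members)
  to_seed <- net$edges[net$edges$to %in% seeds, , drop = FALSE]
  counts <- table(factor(to_seed$from[!duplicated(paste0(to_seed$from, "\r", to_seed$to))],
                         levels = candidates))
  df <- tibble(node = candidates, direct = as.integer(counts[candidates]))
  df$rank <- competition_rank(-df$direct)
  df <- df[order(df$rank, df$node), ]
  df[, c("rank", "node", "direct")]
}

#' Run the full prioritization on a network
#'
#' Convenience wrapper: computes shortest-path and random-walk scores,
#' combines them by rank product, and — when `net` is a collapsed
#' network — runs a second pass on the stored uncollapsed network to
#' pick clique representatives and returns the protein-level ranking.
#'
#' @inheritParams random_walk_scores
#' @inheritParams shortest_path_scores
#' @return a `prynt_ranking`.
#' @examples
#' ints <- tibble::tibble(
#'   item_id_a = c("S", "A", "B", "B"), item_id_b = c("A", "B", "S", "C"),
#'   is_directional = TRUE, a_is_acting = TRUE, score = 950L)
#' net <- build_raw_network(ints)
#' prioritize(net, dps = "S")
#' @export
prioritize <- function(net, dps, r = 0.7, tol = 1e-10, max_iter = 10000,
                       unreachable = c("count-first", "penalty", "exclude"),
                       dangling = c("none", "teleport")) {
  unreachable <- match.arg(unreachable)
  dangling <- match.arg(dangling)
  rank_one <- function(network) {
    sp <- shortest_path_scores(network, dps, unreachable = unreachable)
    rw <- random_walk_scores(network, dps, r = r, tol = tol,
                             max_iter = max_iter, dangling = dangling)
    combine_ranks(sp, rw, dps)
  }
  result <- rank_one(net)
  if (inherits(net, "collapsed_ppi_network")) {
    partition <- attr(net, "partition")
    if (is.null(partition)) {
      groups <- net$members
      tab <- tibble(group = rep(names(groups), lengths(groups)),
                    member = unlist(groups, use.names = FALSE))
      partition <- structure(tab, groups = groups,
                             class = c("clique_partition", class(tab)))
    }
    raw_result <- rank_one(net$source_network)
    result <- expand_cliques(result, partition, raw_result)
  }
  result
}
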