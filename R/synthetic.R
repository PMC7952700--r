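# Synthetic study generator: directed random background networks with
# planted cliques, seed (DP) sets and reference candidate lists with
# known overlap structure, so every algorithmic stage can be exercised
# and benchmarked without external downloads. The generated interaction
# tables use the same columns the parsers read, so synthetic data
# exercises the real construction code path.

#' Specify a synthetic study
#'
#' The defaults define the package's standard simulation conditions: a
#' 150-node directed Erdős–Rényi background (edge probability 0.02)
#' with 4 planted cliques of 5–8 proteins wired near the seeds, 10
#' seed proteins, 20 reference candidates of which a fraction
#' `planted_overlap_fraction` is wired 1–2 hops from the seeds, and
#' about a third of seed-incident interactions pushed below the
#' default confidence threshold (so seed injection has real signal).
#'
#' @param n_background_nodes total number of proteins.
#' @param edge_probability probability of each ordered background pair
#'   being an interaction.
#' @param n_planted_cliques number of planted (fully mutually
#'   interacting, disjoint) cliques.
#' @param clique_size_range integer range (min, max) of planted clique
#'   sizes; at least 3.
#' @param n_dps number of seed (deregulated) proteins, drawn outside
#'   the planted cliques.
#' @param n_reference number of reference disease candidates.
#' @param planted_overlap_fraction fraction of reference candidates
#'   wired close (1–2 hops) to the seeds; 0 gives a pure null study.
#' @param dp_lowscore_fraction fraction of seed-incident interactions
#'   whose confidence is set below the 900 threshold, emulating true
#'   interactions that raw filtering discards.
#' @param rng_seed integer seed; everything downstream is
#'   deterministic given the spec.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_background_nodes = 150,
                           edge_probability = 0.02,
                           n_planted_cliques = 4,
                           clique_size_range = c(5, 8),
                           n_dps = 10,
                           n_reference = 20,
                           planted_overlap_fraction = 0.8,
                           dp_lowscore_fraction = 0.35,
                           rng_seed = 1) {
  assert_scalar_number(n_background_nodes, "n_background_nodes", lower = 1)
  assert_scalar_number(edge_probability, "edge_probability", lower = 0, upper = 1)
  assert_scalar_number(n_planted_cliques, "n_planted_cliques", lower = 0)
  assert_scalar_number(n_dps, "n_dps", lower = 0)
  assert_scalar_number(n_reference, "n_reference", lower = 0)
  assert_scalar_number(planted_overlap_fraction, "planted_overlap_fraction",
                       lower = 0, upper = 1)
  assert_scalar_number(dp_lowscore_fraction, "dp_lowscore_fraction",
                       lower = 0, upper = 1)
  stopifnot(length(clique_size_range) == 2L,
            clique_size_range[1] <= clique_size_range[2])
  if (clique_size_range[1] < 3) abort("planted cliques must have at least 3 members")
  if (n_planted_cliques * clique_size_range[2] + n_dps > n_background_nodes) {
    abort("spec infeasible: planted cliques plus seeds exceed the node budget")
  }
  structure(list(
    n_background_nodes = as.integer(n_background_nodes),
    edge_probability = edge_probability,
    n_planted_cliques = as.integer(n_planted_cliques),
    clique_size_range = as.integer(clique_size_range),
    n_dps = as.integer(n_dps),
    n_reference = as.integer(n_reference),
    planted_overlap_fraction = planted_overlap_fraction,
    dp_lowscore_fraction = dp_lowscore_fraction,
    rng_seed = as.integer(rng_seed)
  ), class = "synthetic_spec")
}

synthetic_interactions <- function(from, to, score) {
  tibble(
    item_id_a = from, item_id_b = to,
    mode = "activation", action = NA_character_,
    is_directional = TRUE, a_is_acting = TRUE,
    score = as.integer(score)
  )
}

# Background + planted cliques; assumes the RNG is already seeded.
gen_network_impl <- function(spec) {
  n <- spec$n_background_nodes
  nodes <- sprintf("P%04d", seq_len(n))

  # disjoint planted cliques
  sizes <- if (spec$n_planted_cliques > 0L) {
    sample(seq(spec$clique_size_range[1], spec$clique_size_range[2]),
           spec$n_planted_cliques, replace = TRUE)
  } else integer(0)
  pool <- sample(nodes)
  clique_members <- list()
  taken <- 0L
  for (s in sizes) {
    clique_members[[length(clique_members) + 1L]] <- sort(pool[taken + seq_len(s)])
    taken <- taken + s
  }

  # directed Erdos-Renyi background over all ordered pairs
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- runif(nrow(pairs)) < spec$edge_probability
  bg <- pairs[keep, , drop = FALSE]

  # planted cliques: every ordered pair inside a clique interacts
  cl_edges <- purrr::map(clique_members, function(m) {
    e <- expand.grid(from = m, to = m, stringsAsFactors = FALSE)
    e[e$from != e$to, , drop = FALSE]
  })
  cl <- dplyr::bind_rows(cl_edges)

  edges <- dplyr::bind_rows(bg, cl)
  if (nrow(edges) > 0L) {
    edges <- edges[!duplicated(paste0(edges$from, "\r", edges$to)), , drop = FALSE]
  }
  score <- sample(900:999, nrow(edges), replace = TRUE)
  list(
    interactions = synthetic_interactions(edges$from, edges$to, score),
    nodes = nodes,
    clique_members = clique_members
  )
}

#' Generate a synthetic directed network with planted cliques
#'
#' @param spec a [synthetic_spec()].
#' @return list with `interactions` (tibble in the parser's column
#'   layout), `network` (the corresponding [ppi_network()]) and
#'   `truth` (node roster and planted clique membership).
#' @examples
#' net <- generate_network(synthetic_spec(n_background_nodes = 30, rng_seed = 7))
#' net$network
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$rng_seed)
  g <- gen_network_impl(spec)
  list(
    interactions = g$interactions,
    network = build_raw_network(g$interactions, min_score = 0),
    truth = list(nodes = g$nodes, clique_members = g$clique_members,
                 rng_seed = spec$rng_seed)
  )
}

#' Generate a complete synthetic study
#'
#' Builds a network via [generate_network()]'s machinery and plants a
#' full study on it:
#' \itemize{
#'   \item seed proteins drawn outside the planted cliques, with
#'     synthetic p-values;
#'   \item every member of each planted clique given reciprocal
#'     high-confidence interactions with two seeds, so
#'     clique members crowd the top of a naive ranking and clique
#'     consolidation has something to consolidate;
#'   \item `planted_overlap_fraction` of the reference candidates wired
#'     1–2 hops from the seeds (reciprocal interactions with 1–3
#'     seeds); the remainder drawn uniformly from the other non-seed
#'     proteins, so a fraction of 0 yields a pure null study whose
#'     expected precision is the chance level
#'     `n_reference / (nodes - n_dps)`;
#'   \item `dp_lowscore_fraction` of seed-incident interactions pushed
#'     below confidence 900, so they vanish from the raw network and
#'     reappear under seed injection.
#' }
#'
#' @param spec a [synthetic_spec()].
#' @return list with `interactions`, `network` (unfiltered), `dps` (a
#'   [dp_set()]), `reference` (a `reference_candidates` table) and
#'   `truth` (planted reference ids, clique membership, seed roster).
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$rng_seed)
  g <- gen_network_impl(spec)
  nodes <- g$nodes
  clique_nodes <- unique(unlist(g$clique_members))
  if (length(g$interactions$score) == 0L) abort("generated network has no edge")

  dps <- sample(setdiff(nodes, clique_nodes), spec$n_dps)
  interactions <- g$interactions

  # wire planted cliques near the seeds
  if (length(g$clique_members) > 0L && length(dps) >= 1L) {
    wires <- purrr::map(g$clique_members, function(m) {
      anchors <- m  # the whole complex sits next to the seeds
      targets <- sample(dps, min(2L, length(dps)))
      e <- expand.grid(a = anchors, b = targets, stringsAsFactors = FALSE)
      dplyr::bind_rows(
        synthetic_interactions(e$a, e$b, sample(930:999, nrow(e), replace = TRUE)),
        synthetic_interactions(e$b, e$a, sample(930:999, nrow(e), replace = TRUE))
      )
    })
    interactions <- dplyr::bind_rows(interactions, dplyr::bind_rows(wires))
  }

  # reference candidates: planted (wired close to seeds) + uniform rest
  non_dp <- setdiff(nodes, dps)
  n_planted <- round(spec$planted_overlap_fraction * spec$n_reference)
  plantable <- setdiff(non_dp, clique_nodes)
  planted <- sample(plantable, min(n_planted, length(plantable)))
  rest_pool <- setdiff(non_dp, planted)
  rest <- sample(rest_pool, min(spec$n_reference - length(planted), length(rest_pool)))
  reference_ids <- c(planted, rest)

  if (length(planted) > 0L && length(dps) >= 1L) {
    wires <- purrr::map(planted, function(p) {
      targets <- sample(dps, sample(1:min(3L, length(dps)), 1L))
      dplyr::bind_rows(
        synthetic_interactions(p, targets, sample(930:999, length(targets), replace = TRUE)),
        synthetic_interactions(targets, p, sample(930:999, length(targets), replace = TRUE))
      )
    })
    interactions <- dplyr::bind_rows(interactions, dplyr::bind_rows(wires))
  }

  # dedupe ordered pairs, keeping the latest (wired) record
  rev_ix <- rev(seq_len(nrow(interactions)))
  interactions <- interactions[rev_ix, ][
    !duplicated(paste0(interactions$item_id_a[rev_ix], "\r",
                       interactions$item_id_b[rev_ix])), ]
  interactions <- interactions[order(interactions$item_id_a, interactions$item_id_b), ]

  # push a fraction of seed-incident interactions below the threshold
  if (spec$dp_lowscore_fraction > 0) {
    incident <- which(interactions$item_id_a %in% dps |
                      interactions$item_id_b %in% dps)
    downgrade <- incident[runif(length(incident)) < spec$dp_lowscore_fraction]
    interactions$score[downgrade] <-
      as.integer(sample(100:899, length(downgrade), replace = TRUE))
  }

  pvals <- signif(runif(length(dps), 1e-6, 0.05), 3)
  scores <- sort(round(runif(length(reference_ids), 1, 100), 2), decreasing = TRUE)
  shuffled <- sample(reference_ids)

  list(
    interactions = interactions,
    network = build_raw_network(interactions, min_score = 0),
    dps = dp_set(dps, pvalues = pvals, dataset_name = "synthetic"),
    reference = reference_candidates(shuffled, scores, disease_name = "synthetic"),
    truth = list(
      nodes = nodes,
      planted_reference = planted,
      clique_members = g$clique_members,
      dps = dps,
      chance_precision = spec$n_reference / (spec$n_background_nodes - spec$n_dps),
      rng_seed = spec$rng_seed
    )
  )
}

#' Write a synthetic study in the formats the parsers read
#'
#' @param study output of [generate_study()].
#' @param dir output directory (created if needed); writes
#'   `interactions.tsv`, `dp.tsv`, `reference.tsv`.
#' @return the directory, invisibly.
#' @export
write_study_tsv <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_interactions(study$interactions, file.path(dir, "interactions.tsv"))
  readr::write_tsv(tibble(id = study$dps$id, pvalue = study$dps$pvalue),
                   file.path(dir, "dp.tsv"), progress = FALSE)
  readr::write_tsv(tibble(id = study$reference$id,
                          inference_score = study$reference$inference_score),
                   file.path(dir, "reference.tsv"), progress = FALSE)
  invisible(dir)
}

#' Mean precision of the pipeline across simulated studies
#'
#' Runs the full pipeline (variant construction, prioritization,
#' precision evaluation) on `n_seeds` independently generated studies
#' for each requested network variant, and returns one row per seed
#' and variant. Used for the planted-vs-null benchmarks and the
#' variant-ordering comparison.
#'
#' @param spec a [synthetic_spec()]; its `rng_seed` offsets the
#'   per-replicate seeds (replicate i uses `rng_seed + i - 1`).
#' @param variants network variants to run (see [build_variant()]).
#' @param n_seeds number of simulated studies.
#' @param k_max precision-curve depth.
#' @param min_score,min_clique_size construction parameters.
#' @param r restart probability.
#' @return tibble (`seed`, `variant`, `auc`, `auc_normalized`,
#'   `precision_at_k`, `k`, `n_candidates`, `chance`).
#' @export
simulate_precision <- function(spec, variants = "dp_c", n_seeds = 100,
                               k_max = 100, min_score = 900,
                               min_clique_size = 3, r = 0.7) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rows <- list()
  for (i in seq_len(n_seeds)) {
    s <- spec
    s$rng_seed <- spec$rng_seed + i - 1L
    study <- generate_study(s)
    for (v in variants) {
      net <- build_variant(study$interactions, variant = v, dps = study$dps,
                           min_score = min_score,
                           min_clique_size = min_clique_size)
      ranking <- prioritize(net, study$dps, r = r)
      pc <- precision_curve(ranking, study$reference, k_max = k_max)
      rows[[length(rows) + 1L]] <- tibble(
        seed = s$rng_seed, variant = v,
        auc = attr(pc, "auc"),
        auc_normalized = attr(pc, "auc_normalized"),
        precision_at_k = pc$precision[nrow(pc)],
        k = attr(pc, "k_max"),
        n_candidates = nrow(ranking),
        chance = study$truth$chance_precision
      )
    }
  }
  dplyr::bind_rows(rows)
}
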