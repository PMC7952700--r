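# Construction of the directed PPI network and its contextualized
# variants: raw (confidence + directionality filtering), +DP (seed
# injection regardless of confidence), +C (maximal-clique consolidation
# into super-nodes), and +DP+C.

#' Construct a `ppi_network` from an edge table
#'
#' Low-level constructor. Most users build networks with
#' [build_raw_network()] or [build_variant()].
#'
#' @param edges tibble with columns `from`, `to`, integer `score` and
#'   logical `from_contextualization`. Self-loops and duplicate ordered
#'   pairs are rejected.
#' @param nodes node identifiers; defaults to the edge endpoints.
#'   Must contain every endpoint (isolated nodes allowed).
#' @return an object of class `ppi_network`: a list with elements
#'   `edges` (tibble) and `nodes` (character).
#' @export
ppi_network <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges))
  if (!"from_contextualization" %in% names(edges)) {
    edges$from_contextualization <- FALSE
  }
  if (!"score" %in% names(edges)) edges$score <- 999L
  edges <- as_tibble(edges[, c("from", "to", "score", "from_contextualization")])
  if (any(edges$from == edges$to)) abort("self-loop edge(s) are not allowed")
  if (anyDuplicated(edge_key(edges)) > 0L) {
    abort("duplicate ordered edge pair(s) are not allowed")
  }
  endpoints <- unique(c(edges$from, edges$to))
  if (is.null(nodes)) {
    nodes <- sort(endpoints)
  } else {
    nodes <- unique(as.character(nodes))
    if (!all(endpoints %in% nodes)) abort("every edge endpoint must be in `nodes`")
  }
  structure(list(edges = edges, nodes = nodes), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<%s> %d node(s), %d directed edge(s)%s\n",
              paste(class(x), collapse = "/"),
              length(x$nodes), nrow(x$edges),
              if (any(x$edges$from_contextualization))
                sprintf(" (%d injected)", sum(x$edges$from_contextualization))
              else ""))
  invisible(x)
}

#' Convert a `ppi_network` to an igraph graph
#'
#' @param net a `ppi_network`.
#' @param directed keep edge direction (default) or project to the
#'   undirected simple graph used for clique detection.
#' @return an igraph object with vertex names.
#' @export
as_igraph <- function(net, directed = TRUE) {
  stopifnot(inherits(net, "ppi_network"))
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     directed = TRUE,
                                     vertices = data.frame(name = net$nodes))
  if (!directed) {
    g <- igraph::as_undirected(g, mode = "collapse")
  }
  g
}

# Orient interaction records: acting protein -> acted-on protein.
# a_is_acting TRUE (or NA: no acting annotation) keeps a -> b; FALSE
# flips to b -> a.
orient_interactions <- function(interactions) {
  flip <- !is.na(interactions$a_is_acting) & !interactions$a_is_acting
  tibble(
    from = as.character(ifelse(flip, interactions$item_id_b, interactions$item_id_a)),
    to = as.character(ifelse(flip, interactions$item_id_a, interactions$item_id_b)),
    score = as.integer(interactions$score)
  )
}

# Drop self-loops, merge duplicate ordered pairs (max score, any flag).
dedupe_edges <- function(edges) {
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  if (nrow(edges) == 0L) return(as_tibble(edges))
  edges |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(score = max(.data$score),
                     from_contextualization = all(.data$from_contextualization),
                     .groups = "drop")
}

#' Build the raw directed PPI network
#'
#' Keeps directional interaction records whose confidence reaches
#' `min_score` (on the internal 0–999 scale), orients each edge from
#' the acting protein to the acted-on protein, and removes self-loops
#' and duplicate ordered pairs. The node set is the set of endpoints of
#' the surviving edges.
#'
#' @param interactions interaction tibble from [read_string_actions()]
#'   (or [generate_network()]).
#' @param min_score confidence threshold, internal 0–999 scale; edges
#'   with `score >= min_score` survive (the STRING "highest confidence"
#'   cutoff 900 by default; pass 901 for a strictly-greater reading).
#' @param directional_only keep only records flagged directional
#'   (default TRUE — the ranking strategies rely on edge direction).
#' @return a [ppi_network()].
#' @examples
#' ints <- tibble::tibble(
#'   item_id_a = c("A", "B", "A", "A"), item_id_b = c("B", "A", "A", "C"),
#'   is_directional = c(TRUE, TRUE, TRUE, FALSE),
#'   a_is_acting = TRUE, score = c(950L, 950L, 990L, 990L))
#' build_raw_network(ints, min_score = 900)
#' @export
build_raw_network <- function(interactions, min_score = 900,
                              directional_only = TRUE) {
  validate_interactions(interactions)
  assert_scalar_number(min_score, "min_score", lower = 0)
  keep <- interactions$score >= min_score
  if (directional_only) {
    keep <- keep & !is.na(interactions$is_directional) & interactions$is_directional
  }
  surviving <- interactions[keep, , drop = FALSE]
  edges <- orient_interactions(surviving)
  edges$from_contextualization <- FALSE
  edges <- dedupe_edges(edges)
  if (nrow(edges) == 0L) {
    abort(sprintf("no interaction survives filtering (min_score = %s%s)",
                  format(min_score),
                  if (directional_only) ", directional only" else ""))
  }
  ppi_network(edges)
}

#' Inject deregulated proteins regardless of confidence (+DP)
#'
#' Adds every directional interaction incident to a seed protein back
#' into the network irrespective of its confidence score. Added edges
#' are flagged `from_contextualization`. Seeds with no interaction
#' record at all remain absent and are listed in the `dp_report`
#' attribute of the result. Idempotent.
#'
#' @param net a [ppi_network()] (typically the raw network).
#' @param interactions the unfiltered interaction tibble.
#' @param dps a [dp_set()] or character vector of seed identifiers.
#' @return a `ppi_network` with attribute `dp_report`: a tibble
#'   (`dp`, `status`) where status is `"in_network"`, `"injected"` or
#'   `"absent"`.
#' @export
add_deregulated_proteins <- function(net, interactions, dps) {
  stopifnot(inherits(net, "ppi_network"))
  validate_interactions(interactions)
  members <- dp_members(dps)

  directional <- !is.na(interactions$is_directional) & interactions$is_directional
  incident <- directional & (interactions$item_id_a %in% members |
                             interactions$item_id_b %in% members)
  new_edges <- orient_interactions(interactions[incident, , drop = FALSE])
  new_edges <- new_edges[new_edges$from != new_edges$to, , drop = FALSE]
  new_edges$from_contextualization <- TRUE

  add <- new_edges[!edge_key(new_edges) %in% edge_key(net$edges), , drop = FALSE]
  add <- dedupe_edges(add)
  edges <- dplyr::bind_rows(net$edges, add)
  out <- ppi_network(edges, nodes = union(net$nodes, unique(c(edges$from, edges$to))))

  status <- dplyr::case_when(
    members %in% net$nodes ~ "in_network",
    members %in% out$nodes ~ "injected",
    TRUE ~ "absent"
  )
  attr(out, "dp_report") <- tibble(dp = members, status = status)
  absent <- members[status == "absent"]
  if (length(absent) > 0L) {
    inform(sprintf("%d seed protein(s) have no interaction record and stay absent: %s",
                   length(absent), paste(head(absent, 5L), collapse = ", ")))
  }
  out
}

#' Enumerate maximal cliques of the undirected projection
#'
#' A clique is a set of proteins that all interact with each other;
#' edge direction is ignored inside cliques. Returns the maximal
#' cliques (no clique is a subset of another) with at least
#' `min_clique_size` members.
#'
#' @param net a [ppi_network()].
#' @param min_clique_size smallest clique reported (default 3, the
#'   smallest non-trivial clique).
#' @return list of character vectors (members sorted), ordered by
#'   decreasing size then lexicographically — the order
#'   [assign_disjoint_cliques()] consumes.
#' @export
find_cliques <- function(net, min_clique_size = 3) {
  stopifnot(inherits(net, "ppi_network"))
  if (length(net$nodes) == 0L) abort("network is empty")
  g <- as_igraph(net, directed = FALSE)
  cl <- igraph::max_cliques(g, min = min_clique_size)
  cl <- lapply(cl, function(v) sort(igraph::V(g)$name[v]))
  order_cliques(cl)
}

# Decreasing size, ties by lexicographically smallest member vector.
order_cliques <- function(cliques) {
  if (length(cliques) == 0L) return(cliques)
  keys <- vapply(cliques, function(m) paste(m, collapse = "\r"), character(1))
  cliques[order(-lengths(cliques), keys)]
}

#' Assign proteins to disjoint clique groups
#'
#' Maximal cliques overlap; grouping requires each protein to belong to
#' at most one clique. Cliques are taken greedily in order of
#' decreasing size (ties broken by lexicographically smallest member),
#' members already claimed by an earlier group are removed, and the
#' clique is kept only if at least `min_clique_size` members remain.
#'
#' @param cliques list of member vectors from [find_cliques()].
#' @param min_clique_size smallest group kept (default 3).
#' @param protected node identifiers never absorbed into a group
#'   (used to keep seed proteins addressable in collapsed networks).
#' @return a `clique_partition`: tibble (`group`, `member`) with
#'   attribute `groups` (named list group -> members).
#' @export
assign_disjoint_cliques <- function(cliques, min_clique_size = 3,
                                    protected = character(0)) {
  cliques <- order_cliques(lapply(cliques, function(m) setdiff(m, protected)))
  claimed <- character(0)
  groups <- list()
  for (members in cliques) {
    remaining <- setdiff(members, claimed)
    if (length(remaining) >= min_clique_size) {
      groups[[length(groups) + 1L]] <- sort(remaining)
      claimed <- c(claimed, remaining)
    }
  }
  names(groups) <- sprintf("clique_%03d", seq_along(groups))
  tab <- if (length(groups) == 0L) {
    tibble(group = character(0), member = character(0))
  } else {
    tibble(group = rep(names(groups), lengths(groups)),
           member = unlist(groups, use.names = FALSE))
  }
  structure(tab, groups = groups, min_clique_size = min_clique_size,
            class = c("clique_partition", class(tab)))
}

#' @export
print.clique_partition <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("<clique_partition> %d group(s) covering %d protein(s)%s\n",
              length(g), nrow(x),
              if (length(g) > 0)
                sprintf(", mean size %.1f", mean(lengths(g))) else ""))
  invisible(x)
}

#' Collapse clique groups into super-nodes (+C)
#'
#' Replaces each clique group by a single super-node. A directed edge
#' (u, G) exists iff some member g of G has edge (u, g) in the source
#' network, and symmetrically for (G, u) and (G, H); edges internal to
#' a group are dropped and duplicates merged (a merged edge keeps the
#' maximum witness score). Proteins isolated by the collapse stay in
#' the node set, so node count = ungrouped proteins + groups.
#'
#' @param net a [ppi_network()].
#' @param partition a `clique_partition` from
#'   [assign_disjoint_cliques()]; every member must be a node of `net`.
#' @return a `collapsed_ppi_network` (also a `ppi_network`) with extra
#'   elements `members` (back-map group -> member proteins) and
#'   `source_network` (the uncollapsed input, kept so clique
#'   super-nodes can later be expanded back to protein candidates).
#' @export
collapse_cliques <- function(net, partition) {
  stopifnot(inherits(net, "ppi_network"), inherits(partition, "clique_partition"))
  groups <- attr(partition, "groups")
  missing <- setdiff(partition$member, net$nodes)
  if (length(missing) > 0L) {
    abort(sprintf("partition member(s) not present in the network: %s",
                  paste(head(missing, 5L), collapse = ", ")))
  }
  to_group <- setNames(partition$group, partition$member)
  relabel <- function(x) unname(ifelse(x %in% names(to_group), to_group[x], x))

  edges <- net$edges
  edges$from <- relabel(edges$from)
  edges$to <- relabel(edges$to)
  edges <- dedupe_edges(edges)  # drops now-internal (self-loop) edges
  nodes <- unique(c(setdiff(net$nodes, partition$member), names(groups)))

  out <- ppi_network(edges, nodes = nodes)
  out$members <- groups
  out$source_network <- net
  class(out) <- c("collapsed_ppi_network", class(out))
  out
}

#' Build a contextualized network variant
#'
#' Composes the construction steps into the four variants of the
#' method: `"raw"` (confidence/directionality filtering only), `"dp"`
#' (raw + seed injection regardless of confidence), `"c"` (raw +
#' maximal-clique consolidation) and `"dp_c"` (both; seed injection
#' precedes clique detection by default, so injected edges can create
#' cliques). Seed proteins are never absorbed into clique super-nodes:
#' they must stay addressable as distinct nodes to seed the ranking
#' algorithms.
#'
#' @param interactions full interaction tibble.
#' @param variant one of `"raw"`, `"dp"`, `"c"`, `"dp_c"`.
#' @param dps seed set ([dp_set()] or character); required for `"dp"`
#'   and `"dp_c"`, used for seed protection in `"c"`.
#' @param min_score,directional_only passed to [build_raw_network()].
#' @param min_clique_size passed to clique detection/assignment.
#' @param cliques_after_dp for `"dp_c"`: detect cliques after seed
#'   injection (default TRUE) or on the pre-injection network.
#' @return a `ppi_network` (`raw`, `dp`) or `collapsed_ppi_network`
#'   (`c`, `dp_c`) with attribute `partition` for the collapsed
#'   variants.
#' @export
build_variant <- function(interactions,
                          variant = c("raw", "dp", "c", "dp_c"),
                          dps = NULL, min_score = 900, min_clique_size = 3,
                          directional_only = TRUE, cliques_after_dp = TRUE) {
  variant <- match.arg(variant)
  if (variant %in% c("dp", "dp_c") && is.null(dps)) {
    abort(sprintf("variant '%s' needs a seed set `dps`", variant))
  }
  raw <- build_raw_network(interactions, min_score = min_score,
                           directional_only = directional_only)
  protected <- if (is.null(dps)) character(0) else dp_members(dps)

  net <- switch(variant,
    raw = raw,
    dp = add_deregulated_proteins(raw, interactions, dps),
    c = raw,
    dp_c = add_deregulated_proteins(raw, interactions, dps)
  )
  if (variant %in% c("c", "dp_c")) {
    clique_base <- if (variant == "dp_c" && !cliques_after_dp) raw else net
    cliques <- find_cliques(clique_base, min_clique_size = min_clique_size)
    partition <- assign_disjoint_cliques(cliques, min_clique_size = min_clique_size,
                                         protected = protected)
    # members found on the pre-injection network are guaranteed in `net`
    net <- collapse_cliques(net, partition)
    attr(net, "partition") <- partition
  }
  attr(net, "variant") <- variant
  net
}

#' Serialize a network (and partition) as edge-list TSV
#'
#' @param net a `ppi_network`.
#' @param path output TSV (`from`, `to`, `score`,
#'   `from_contextualization`); isolated nodes are listed in companion
#'   header comments.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  isolated <- setdiff(net$nodes, unique(c(net$edges$from, net$edges$to)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(isolated) > 0L) {
    writeLines(sprintf("# isolated_nodes: %s", paste(isolated, collapse = ",")), con)
  }
  writeLines(paste(c("from", "to", "score", "from_contextualization"),
                   collapse = "\t"), con)
  if (nrow(net$edges) > 0L) {
    writeLines(paste(net$edges$from, net$edges$to, net$edges$score,
                     ifelse(net$edges$from_contextualization, "t", "f"),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a network serialized by [write_network_tsv()]
#'
#' @param path edge-list TSV.
#' @return a `ppi_network`.
#' @export
read_network_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("network file not found: '%s'", path))
  first <- readLines(path, n = 1L)
  isolated <- character(0)
  if (startsWith(first, "# isolated_nodes:")) {
    isolated <- strsplit(trimws(sub("# isolated_nodes:", "", first)), ",")[[1L]]
  }
  edges <- readr::read_tsv(path, comment = "#",
                           col_types = readr::cols(from = "c", to = "c",
                                                   score = "i",
                                                   from_contextualization = "c"),
                           progress = FALSE)
  edges$from_contextualization <- as_string_logical(edges$from_contextualization)
  ppi_network(edges, nodes = unique(c(edges$from, edges$to, isolated)))
}

#' Serialize a clique partition as TSV
#'
#' @param partition a `clique_partition`.
#' @param path output TSV (`group`, `member`).
#' @return `path`, invisibly.
#' @export
write_partition_tsv <- function(partition, path) {
  stopifnot(inherits(partition, "clique_partition"))
  readr::write_tsv(as_tibble(partition), path, progress = FALSE)
  invisible(path)
}
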