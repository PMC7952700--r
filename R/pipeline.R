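# End-to-end pipeline: build -> rank -> expand -> evaluate, with file
# outputs and provenance metadata. The command-line entry point at
# inst/cli/prynt.R is a thin wrapper over these functions.

#' Assemble a pipeline configuration
#'
#' Collects file paths and parameters for [run_pipeline()]. Defaults
#' mirror the method's standard settings: restart probability 0.7,
#' confidence threshold 900, minimum clique size 3, evaluation depth
#' 100, reference lists truncated to their top 500.
#'
#' @param actions path to the interaction TSV (see
#'   [read_string_actions()]).
#' @param dp path to the deregulated-protein list.
#' @param outdir output directory.
#' @param aliases optional identifier-mapping TSV.
#' @param reference optional reference-candidate TSV for evaluation.
#' @param nonspecific_reference optional second reference list for
#'   cross-specificity.
#' @param decoys optional directory of decoy reference TSVs for
#'   overall specificity.
#' @param variant network variant (default `"dp_c"`, the fully
#'   contextualized network).
#' @param min_score,min_clique_size,directional_only construction
#'   parameters.
#' @param r,tol,max_iter random-walk parameters.
#' @param k_max evaluation depth.
#' @param top_n reference-list truncation.
#' @param unreachable,dangling policy flags (see
#'   [shortest_path_scores()], [random_walk_scores()]).
#' @param score_scale interaction score dialect.
#' @param rng_seed recorded in the metadata (the pipeline itself is
#'   deterministic).
#' @return a `prynt_config` list.
#' @export
prynt_config <- function(actions, dp, outdir,
                         aliases = NULL, reference = NULL,
                         nonspecific_reference = NULL, decoys = NULL,
                         variant = "dp_c", min_score = 900,
                         min_clique_size = 3, directional_only = TRUE,
                         r = 0.7, tol = 1e-10, max_iter = 10000,
                         k_max = 100, top_n = 500,
                         unreachable = "count-first", dangling = "none",
                         score_scale = "auto", rng_seed = 1) {
  cfg <- list(actions = actions, dp = dp, outdir = outdir,
              aliases = aliases, reference = reference,
              nonspecific_reference = nonspecific_reference, decoys = decoys,
              variant = variant, min_score = min_score,
              min_clique_size = min_clique_size,
              directional_only = directional_only,
              r = r, tol = tol, max_iter = max_iter,
              k_max = k_max, top_n = top_n,
              unreachable = unreachable, dangling = dangling,
              score_scale = score_scale, rng_seed = rng_seed)
  structure(cfg, class = "prynt_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Flat-key JSON; keys are [prynt_config()] arguments. Values given in
#' `overrides` (e.g. parsed command-line flags) take precedence over
#' the file.
#'
#' @param path JSON file.
#' @param overrides named list of values overriding the file.
#' @return a `prynt_config`.
#' @export
read_prynt_config <- function(path, overrides = list()) {
  if (!file.exists(path)) abort(sprintf("config file not found: '%s'", path))
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- modifyList(vals, overrides[!vapply(overrides, is.null, logical(1))])
  do.call(prynt_config, vals)
}

#' Write a ranking as TSV
#'
#' Columns: rank, node, gene_symbol, sp, rank_sp, rw, rank_rw, cs,
#' in_clique, clique_members_dropped. The gene symbol is looked up by
#' reverse application of the alias mapping when one is supplied.
#'
#' @param ranking a `prynt_ranking`.
#' @param path output TSV.
#' @param mapping optional alias table ([read_id_mapping()]).
#' @return `path`, invisibly.
#' @export
write_ranking_tsv <- function(ranking, path, mapping = NULL) {
  stopifnot(inherits(ranking, "prynt_ranking"))
  out <- as_tibble(ranking)
  out$gene_symbol <- if (is.null(mapping)) {
    NA_character_
  } else {
    mapping$alias[match(out$node, mapping$id)]
  }
  if (!"in_clique" %in% names(out)) out$in_clique <- NA_character_
  if (!"clique_members_dropped" %in% names(out)) out$clique_members_dropped <- 0L
  cols <- c("rank", "node", "gene_symbol", "sp", "rank_sp", "rw", "rank_rw",
            "cs", "in_clique", "clique_members_dropped")
  readr::write_tsv(out[, cols], path, progress = FALSE)
  invisible(path)
}

#' Run the full prioritization pipeline
#'
#' Reads the inputs, builds the requested network variant, ranks the
#' candidates, evaluates against reference lists when provided, and
#' writes: `network.tsv` (+ `partition.tsv` for collapsed variants),
#' `ranked.tsv`, `report.tsv` (when a reference list is given) and
#' `run_metadata.json` (parameters, input MD5 checksums, seed, package
#' version). On error all outputs written so far are removed.
#'
#' @param config a `prynt_config` (or path to a JSON config).
#' @return invisibly, a list with the result objects and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_prynt_config(config)
  stopifnot(inherits(config, "prynt_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(path) { written <<- c(written, path); path }

  log_line <- function(fmt, ...) {
    message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), sprintf(fmt, ...))
  }

  tryCatch({
    log_line("reading interactions from %s", config$actions)
    interactions <- read_string_actions(config$actions,
                                        score_scale = config$score_scale)
    mapping <- if (!is.null(config$aliases)) read_id_mapping(config$aliases)
    dps <- read_dp_list(config$dp, mapping = mapping)

    log_line("building variant '%s' (min_score %s, min_clique_size %s)",
             config$variant, config$min_score, config$min_clique_size)
    net <- build_variant(interactions, variant = config$variant, dps = dps,
                         min_score = config$min_score,
                         min_clique_size = config$min_clique_size,
                         directional_only = config$directional_only)
    write_network_tsv(net, emit(file.path(config$outdir, "network.tsv")))
    partition <- attr(net, "partition")
    if (!is.null(partition)) {
      write_partition_tsv(partition,
                          emit(file.path(config$outdir, "partition.tsv")))
    }

    log_line("ranking %d candidate(s)", length(setdiff(net$nodes, dps$id)))
    ranking <- prioritize(net, dps, r = config$r, tol = config$tol,
                          max_iter = config$max_iter,
                          unreachable = config$unreachable,
                          dangling = config$dangling)
    write_ranking_tsv(ranking, emit(file.path(config$outdir, "ranked.tsv")),
                      mapping = mapping)

    report <- NULL
    if (!is.null(config$reference)) {
      reference <- read_reference_candidates(config$reference,
                                             top_n = config$top_n)
      pc <- precision_curve(ranking, reference, k_max = config$k_max)
      report <- tibble(metric = c("precision_auc", "precision_auc_normalized",
                                  sprintf("precision_at_%d", attr(pc, "k_max"))),
                       value = c(attr(pc, "auc"), attr(pc, "auc_normalized"),
                                 pc$precision[nrow(pc)]))
      if (!is.null(config$nonspecific_reference)) {
        nonspec <- read_reference_candidates(config$nonspecific_reference,
                                             top_n = config$top_n)
        cs <- cross_specificity(ranking, reference, nonspec, k_max = config$k_max)
        report <- dplyr::bind_rows(report, tibble(
          metric = c("nonspecific_auc", "cross_delta"),
          value = c(cs$nonspecific_auc, cs$cross_delta)))
      }
      if (!is.null(config$decoys)) {
        decoy_files <- list.files(config$decoys, pattern = "\\.tsv$",
                                  full.names = TRUE)
        decoys <- purrr::map(decoy_files, read_reference_candidates,
                             top_n = config$top_n)
        names(decoys) <- basename(decoy_files)
        os <- overall_specificity(ranking, reference, decoys,
                                  k_max = config$k_max)
        report <- dplyr::bind_rows(report, tibble(
          metric = c("specific_rank", "n_specificity_lists"),
          value = c(os$specific_rank, os$n_lists)))
      }
      readr::write_tsv(report, emit(file.path(config$outdir, "report.tsv")),
                       progress = FALSE)
      log_line("evaluation written (precision AUC %.3f)", report$value[1])
    }

    inputs <- c(actions = config$actions, dp = config$dp,
                aliases = config$aliases, reference = config$reference,
                nonspecific_reference = config$nonspecific_reference)
    inputs <- inputs[!vapply(inputs, is.null, logical(1))]
    meta <- list(
      parameters = unclass(config),
      input_md5 = as.list(tools::md5sum(unlist(inputs))),
      rng_seed = config$rng_seed,
      package_version = as.character(utils::packageVersion("prynt")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    jsonlite::write_json(meta, emit(file.path(config$outdir, "run_metadata.json")),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
    log_line("done: %d file(s) in %s", length(written), config$outdir)

    invisible(list(network = net, ranking = ranking, report = report,
                   files = written))
  }, error = function(e) {
    unlink(written)
    abort(sprintf("pipeline failed (partial outputs removed): %s",
                  conditionMessage(e)), parent = e)
  })
}
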