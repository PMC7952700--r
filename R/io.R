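# Readers and writers for the tabular formats the tool touches:
# STRING-style protein.actions interaction tables, alias/ID mappings,
# deregulated-protein (DP) lists and reference disease-candidate lists.
# Everything is UTF-8, tab-delimited; lines starting with '#' are ignored.

#' Read a STRING-style `protein.actions` interaction table
#'
#' Parses a tab-delimited interaction file with the `protein.actions`
#' column layout (`item_id_a`, `item_id_b`, `mode`, `action`,
#' `is_directional`, `a_is_acting`, `score`). Confidence scores are
#' normalized to the integer 0–999 scale used throughout the package:
#' STRING mirrors ship either integer scores (0–999) or fractional
#' scores (0–1), and `score_scale` selects between them.
#'
#' @param path path to a tab-delimited interaction file. Lines starting
#'   with `#` are skipped.
#' @param score_scale `"auto"` (default) treats a score column whose
#'   maximum is at most 1 as fractional, otherwise integer;
#'   `"integer"` and `"fraction"` force one dialect.
#' @return a tibble of interactions with columns `item_id_a`,
#'   `item_id_b`, `mode`, `action`, `is_directional`, `a_is_acting`
#'   and integer `score` (0–999).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("item_id_a\titem_id_b\tmode\taction\tis_directional\ta_is_acting\tscore",
#'              "P1\tP2\tactivation\tactivation\tt\tt\t950"), tf)
#' read_string_actions(tf)
#' @export
read_string_actions <- function(path, score_scale = c("auto", "integer", "fraction")) {
  score_scale <- match.arg(score_scale)
  if (!file.exists(path)) abort(sprintf("interaction file not found: '%s'", path))
  raw <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("item_id_a", "item_id_b", "is_directional", "score")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    abort(sprintf("interaction file '%s' is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  for (opt in c("mode", "action", "a_is_acting")) {
    if (!opt %in% names(raw)) raw[[opt]] <- NA_character_
  }

  score_num <- suppressWarnings(as.numeric(raw$score))
  bad <- which(is.na(score_num) & !is.na(raw$score) & raw$score != "")
  if (length(bad) > 0L) {
    abort(sprintf("unparseable score in '%s' at data row(s): %s",
                  path, paste(head(bad, 5L), collapse = ", ")))
  }
  fractional <- switch(score_scale,
    auto = all(score_num <= 1, na.rm = TRUE),
    fraction = TRUE,
    integer = FALSE
  )
  if (fractional) score_num <- round(score_num * 1000)

  empty <- which(is.na(raw$item_id_a) | raw$item_id_a == "" |
                 is.na(raw$item_id_b) | raw$item_id_b == "")
  if (length(empty) > 0L) {
    abort(sprintf("empty interactor identifier in '%s' at data row(s): %s",
                  path, paste(head(empty, 5L), collapse = ", ")))
  }

  out <- tibble(
    item_id_a = raw$item_id_a,
    item_id_b = raw$item_id_b,
    mode = raw$mode,
    action = raw$action,
    is_directional = as_string_logical(raw$is_directional),
    a_is_acting = as_string_logical(raw$a_is_acting),
    score = as.integer(round(score_num))
  )
  validate_interactions(out, context = path)
  out
}

# Invariants shared by parsed and synthetic interaction tables.
validate_interactions <- function(x, context = "interactions") {
  stopifnot(is.data.frame(x))
  needed <- c("item_id_a", "item_id_b", "is_directional", "score")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0L) {
    abort(sprintf("%s: missing column(s) %s", context,
                  paste(missing, collapse = ", ")))
  }
  out_of_range <- which(is.na(x$score) | x$score < 0L | x$score > 999L)
  if (length(out_of_range) > 0L) {
    abort(sprintf(
      "%s: score outside the internal 0-999 scale at row(s): %s",
      context, paste(head(out_of_range, 5L), collapse = ", ")))
  }
  invisible(x)
}

#' Write an interaction table back to TSV
#'
#' Inverse of [read_string_actions()]: writing and re-reading yields an
#' identical record list (integer score dialect).
#'
#' @param interactions a tibble as returned by [read_string_actions()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(interactions, path) {
  validate_interactions(interactions)
  out <- interactions
  out$is_directional <- ifelse(out$is_directional, "t", "f")
  out$a_is_acting <- ifelse(is.na(out$a_is_acting), "",
                            ifelse(out$a_is_acting, "t", "f"))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a two-column identifier mapping (alias -> canonical ID)
#'
#' The canonical node identifier space is the interaction table's own
#' (STRING protein IDs for real data); gene-symbol DP lists are
#' translated through a mapping like this one. The mapping must be a
#' function: an alias mapping to two different canonical IDs is an
#' error. Applying the mapping is idempotent: identifiers that already
#' are canonical pass through unchanged.
#'
#' @param path TSV with two columns, alias and canonical identifier
#'   (header optional; extra columns ignored).
#' @return a tibble with columns `alias`, `id`.
#' @export
read_id_mapping <- function(path) {
  if (!file.exists(path)) abort(sprintf("mapping file not found: '%s'", path))
  raw <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 2L) abort(sprintf("mapping file '%s' needs at least 2 columns", path))
  # Header optional: accept named columns or positional first two.
  if (all(c("alias", "id") %in% names(raw))) {
    m <- tibble(alias = raw$alias, id = raw$id)
  } else {
    m <- tibble(alias = raw[[1L]], id = raw[[2L]])
  }
  m <- dplyr::distinct(m)
  dup <- m$alias[duplicated(m$alias)]
  if (length(dup) > 0L) {
    abort(sprintf("mapping is not a function: alias(es) map to several ids: %s",
                  paste(head(unique(dup), 5L), collapse = ", ")))
  }
  m
}

#' Translate identifiers through a mapping
#'
#' @param ids character vector of identifiers.
#' @param mapping tibble with columns `alias`, `id`
#'   (see [read_id_mapping()]), or `NULL` for the identity mapping.
#' @return character vector: mapped where the alias is known, unchanged
#'   where the identifier is already canonical (present in `id`), and
#'   `NA` where unmapped.
#' @export
map_ids <- function(ids, mapping = NULL) {
  if (is.null(mapping)) return(ids)
  hit <- match(ids, mapping$alias)
  out <- mapping$id[hit]
  already <- is.na(hit) & ids %in% mapping$id
  out[already] <- ids[already]
  out
}

#' Construct a deregulated-protein (DP) seed set
#'
#' @param members character vector of canonical node identifiers
#'   (deduplicated).
#' @param pvalues optional numeric vector (same length as `members`
#'   before deduplication, or named by member) of p-values in (0, 1].
#' @param dataset_name label for the proteomic dataset.
#' @param unmapped character vector of input identifiers that could not
#'   be translated to the canonical space (kept for reporting).
#' @return a `dp_set`: a tibble with columns `id` and `pvalue`, plus
#'   attributes `dataset_name` and `unmapped`.
#' @export
dp_set <- function(members, pvalues = NULL, dataset_name = "dp_set",
                   unmapped = character(0)) {
  members <- as.character(members)
  if (length(members) == 0L) abort("a DP set must have at least one member")
  if (!is.null(pvalues)) {
    if (!is.null(names(pvalues))) {
      pvalues <- unname(pvalues[members])
    }
    if (length(pvalues) != length(members)) {
      abort("`pvalues` must align with `members` (same length or named)")
    }
    bad <- which(!is.na(pvalues) & (pvalues <= 0 | pvalues > 1))
    if (length(bad) > 0L) abort("p-values must lie in (0, 1]")
  } else {
    pvalues <- rep(NA_real_, length(members))
  }
  keep <- !duplicated(members)
  out <- tibble(id = members[keep], pvalue = pvalues[keep])
  structure(out, dataset_name = dataset_name, unmapped = unique(unmapped),
            class = c("dp_set", class(out)))
}

#' @export
print.dp_set <- function(x, ...) {
  cat(sprintf("<dp_set '%s'> %d seed protein(s), %d unmapped input id(s)\n",
              attr(x, "dataset_name"), nrow(x), length(attr(x, "unmapped"))))
  NextMethod()
}

# Accept a dp_set, a data frame with an id column, or a character vector.
dp_members <- function(dps) {
  if (inherits(dps, "dp_set") || (is.data.frame(dps) && "id" %in% names(dps))) {
    return(as.character(dps$id))
  }
  if (is.character(dps)) return(unique(dps))
  abort("`dps` must be a dp_set, a data frame with an `id` column, or a character vector")
}

#' Read a deregulated-protein list
#'
#' One identifier per row (column `id`), optional `pvalue` column.
#' Identifiers are translated through `mapping`; identifiers with no
#' translation are collected in the result's `unmapped` attribute —
#' never silently dropped. Duplicate rows are deduplicated.
#'
#' @param path TSV with columns `id` and optionally `pvalue` (a
#'   headerless single-column file is also accepted).
#' @param mapping optional alias table from [read_id_mapping()].
#' @param dataset_name label stored on the result; defaults to the file
#'   name.
#' @return a [dp_set()].
#' @export
read_dp_list <- function(path, mapping = NULL, dataset_name = NULL) {
  if (!file.exists(path)) abort(sprintf("DP list not found: '%s'", path))
  dataset_name <- dataset_name %||% sub("\\.[^.]*$", "", basename(path))
  raw <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!"id" %in% names(raw)) {
    if (ncol(raw) == 1L) {
      # headerless single-column list: first line was data
      ids <- c(names(raw), raw[[1L]])
      raw <- tibble(id = ids)
    } else {
      abort(sprintf("DP list '%s' must have an `id` column", path))
    }
  }
  ids <- raw$id
  pvals <- if ("pvalue" %in% names(raw)) suppressWarnings(as.numeric(raw$pvalue)) else NULL
  mapped <- map_ids(ids, mapping)
  unmapped <- unique(ids[is.na(mapped)])
  keep <- !is.na(mapped)
  if (!any(keep)) {
    abort(sprintf("DP list '%s': no identifier could be mapped to the network namespace",
                  path))
  }
  if (length(unmapped) > 0L) {
    inform(sprintf("DP list '%s': %d identifier(s) unmapped (kept in the report): %s",
                   dataset_name, length(unmapped),
                   paste(head(unmapped, 5L), collapse = ", ")))
  }
  dp_set(mapped[keep],
         pvalues = if (is.null(pvals)) NULL else pvals[keep],
         dataset_name = dataset_name, unmapped = unmapped)
}

#' Read a reference disease-candidate list
#'
#' Reads a CTD-style export (columns `id`, `inference_score`), sorts it
#' non-increasingly by inference score (stable for ties) and keeps the
#' `top_n` strongest candidates. When the file holds fewer rows than
#' `top_n` all rows are returned with a warning.
#'
#' @param path TSV with columns `id` and `inference_score`.
#' @param top_n number of candidates to keep (default 500, the
#'   conventional list size for comparable evaluations).
#' @param disease_name label stored on the result; defaults to the file
#'   name.
#' @return a `reference_candidates` tibble with columns `id`,
#'   `inference_score`, attribute `disease_name`.
#' @export
read_reference_candidates <- function(path, top_n = 500, disease_name = NULL) {
  if (!file.exists(path)) abort(sprintf("reference candidate list not found: '%s'", path))
  assert_scalar_number(top_n, "top_n", lower = 1)
  disease_name <- disease_name %||% sub("\\.[^.]*$", "", basename(path))
  raw <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(c("id", "inference_score"), names(raw))
  if (length(missing) > 0L) {
    abort(sprintf("reference list '%s' is missing column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  score <- suppressWarnings(as.numeric(raw$inference_score))
  if (anyNA(score)) abort(sprintf("reference list '%s': unparseable inference_score", path))
  if (nrow(raw) < top_n) {
    warn(sprintf("reference list '%s' has only %d row(s); top_n = %d requested",
                 path, nrow(raw), as.integer(top_n)))
  }
  reference_candidates(raw$id, score, disease_name = disease_name, top_n = top_n)
}

#' @rdname read_reference_candidates
#' @param ids,scores vectors building a reference list directly.
#' @export
reference_candidates <- function(ids, scores, disease_name = "reference",
                                 top_n = Inf) {
  ord <- order(-scores)  # stable: ties keep input order
  out <- tibble(id = as.character(ids)[ord], inference_score = scores[ord])
  out <- head(out, min(top_n, nrow(out)))
  structure(out, disease_name = disease_name,
            class = c("reference_candidates", class(out)))
}

#' @export
print.reference_candidates <- function(x, ...) {
  cat(sprintf("<reference_candidates '%s'> %d candidate(s)\n",
              attr(x, "disease_name"), nrow(x)))
  NextMethod()
}
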