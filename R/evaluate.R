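# Evaluation of a candidate ranking against reference disease-candidate
# lists: precision-at-k curves, trapezoidal AUC, cross-specificity and
# overall specificity against decoy diseases.

ranking_nodes <- function(ranking) {
  if (inherits(ranking, "prynt_ranking") ||
      (is.data.frame(ranking) && "node" %in% names(ranking))) {
    return(as.character(ranking$node))
  }
  if (is.character(ranking)) return(ranking)
  abort("`ranking` must be a prynt_ranking, a data frame with a `node` column, or a character vector")
}

reference_ids <- function(reference) {
  if (is.data.frame(reference) && "id" %in% names(reference)) {
    return(unique(as.character(reference$id)))
  }
  if (is.character(reference)) return(unique(reference))
  abort("`reference` must be a reference_candidates table or a character vector of ids")
}

#' Precision-at-k curve against a reference candidate list
#'
#' Precision at k is the fraction of the top-k ranked candidates that
#' appear in the reference list; the curve runs over k = 1..K and its
#' area is estimated by the trapezoidal rule over k. The raw area
#' (maximum K − 1 for a ranking entirely inside the reference) is
#' reported together with a normalized variant, area / (K − 1), for
#' readability; only relative comparisons are ever made.
#'
#' @param ranking a `prynt_ranking` (ordered best first), a data frame
#'   with a `node` column, or a character vector of candidate ids.
#' @param reference a `reference_candidates` table or character vector
#'   of reference ids; internal order is irrelevant.
#' @param k_max depth of the curve (default 100, the conventional
#'   evaluation depth); truncated to the ranking length.
#' @return a `precision_curve`: tibble (`k`, `hits`, `precision`) with
#'   attributes `auc`, `auc_normalized`, `k_max`, `reference_name`,
#'   `n_reference`.
#' @examples
#' precision_curve(c("A", "B", "C", "D"), reference = c("A", "C"), k_max = 4)
#' @export
precision_curve <- function(ranking, reference, k_max = 100) {
  nodes <- ranking_nodes(ranking)
  if (length(nodes) == 0L) abort("`ranking` is empty")
  assert_scalar_number(k_max, "k_max", lower = 1)
  ref <- reference_ids(reference)
  if (length(ref) == 0L) {
    warn("empty reference list: precision is identically zero")
  }
  k <- seq_len(min(k_max, length(nodes)))
  hits <- cumsum(nodes[k] %in% ref)
  precision <- hits / k
  auc <- trapezoid_area(k, precision)
  out <- tibble(k = k, hits = as.integer(hits), precision = precision)
  structure(out,
            auc = auc,
            auc_normalized = if (length(k) > 1L) auc / (max(k) - 1) else NA_real_,
            k_max = max(k),
            reference_name = attr(reference, "disease_name") %||% "reference",
            n_reference = length(ref),
            class = c("precision_curve", class(out)))
}

#' Area under a precision curve
#'
#' @param curve a `precision_curve`.
#' @param normalized return area / (K − 1) instead of the raw
#'   trapezoidal area.
#' @return a single number.
#' @export
precision_auc <- function(curve, normalized = FALSE) {
  stopifnot(inherits(curve, "precision_curve"))
  if (normalized) attr(curve, "auc_normalized") else attr(curve, "auc")
}

#' @export
print.precision_curve <- function(x, ...) {
  cat(sprintf("<precision_curve vs '%s'> K = %d, AUC = %.3f (normalized %.3f)\n",
              attr(x, "reference_name"), attr(x, "k_max"),
              attr(x, "auc"), attr(x, "auc_normalized")))
  NextMethod()
}

#' Cross-specificity of a ranking
#'
#' Compares the precision AUC obtained against the matching disease's
#' reference list with the AUC against another disease's list. A
#' positive difference indicates the ranking is specific to its own
#' disease.
#'
#' @param ranking candidate ranking (see [precision_curve()]).
#' @param specific_ref reference list of the disease under study.
#' @param nonspecific_ref reference list of the other disease.
#' @param k_max curve depth (default 100).
#' @return a `specificity_report` tibble with one row: `specific_auc`,
#'   `nonspecific_auc`, `cross_delta`.
#' @export
cross_specificity <- function(ranking, specific_ref, nonspecific_ref, k_max = 100) {
  a_spec <- precision_auc(precision_curve(ranking, specific_ref, k_max))
  a_non <- precision_auc(precision_curve(ranking, nonspecific_ref, k_max))
  out <- tibble(specific_auc = a_spec, nonspecific_auc = a_non,
                cross_delta = a_spec - a_non)
  structure(out, class = c("specificity_report", class(out)))
}

#' Overall specificity against decoy diseases
#'
#' Ranks the precision AUC of the matching (specific) disease among
#' the AUCs obtained against many decoy diseases' reference lists.
#' Competition ranking: `specific_rank` = 1 + number of decoy AUCs
#' strictly greater than the specific AUC, so ties share the better
#' rank; a specific method is expected to land near rank 1 of
#' `n_lists` = decoys + 1.
#'
#' @param ranking candidate ranking.
#' @param specific_ref the matching disease's reference list.
#' @param decoy_refs list of reference lists for the decoy diseases.
#' @param k_max curve depth (default 100).
#' @return a `specificity_report` tibble with one row: `specific_auc`,
#'   `specific_rank`, `n_lists`; attribute `decoy_aucs` holds the
#'   per-decoy AUC tibble.
#' @export
overall_specificity <- function(ranking, specific_ref, decoy_refs, k_max = 100) {
  if (length(decoy_refs) == 0L) abort("`decoy_refs` must hold at least one reference list")
  a_spec <- precision_auc(precision_curve(ranking, specific_ref, k_max))
  decoy_aucs <- vapply(decoy_refs, function(ref) {
    precision_auc(precision_curve(ranking, ref, k_max))
  }, numeric(1))
  names(decoy_aucs) <- names(decoy_refs) %||%
    paste0("decoy_", seq_along(decoy_refs))
  rank <- 1L + sum(decoy_aucs > a_spec)
  out <- tibble(specific_auc = a_spec, specific_rank = rank,
                n_lists = length(decoy_aucs) + 1L)
  structure(out,
            decoy_aucs = tibble(decoy = names(decoy_aucs), auc = unname(decoy_aucs)),
            class = c("specificity_report", class(out)))
}

#' Experimental (p-value) baseline ranking
#'
#' The reference practice of ranking the deregulated proteins
#' themselves by their p-value, most significant first. Unlike the
#' network methods, the candidates here are the seed proteins.
#'
#' @param dps a [dp_set()] with p-values.
#' @return tibble (`rank`, `node`, `pvalue`) sorted ascending by
#'   p-value (ties by node id).
#' @export
pvalue_ranking <- function(dps) {
  if (!inherits(dps, "dp_set") || all(is.na(dps$pvalue))) {
    abort("`dps` must be a dp_set carrying p-values")
  }
  df <- tibble(node = dps$id, pvalue = dps$pvalue)
  df <- df[order(df$pvalue, df$node), ]
  tibble(rank = seq_len(nrow(df)), node = df$node, pvalue = df$pvalue)
}
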