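# broom-style tidy()/glance() methods and ggplot2 autoplot() methods
# for the result objects.

#' Tidy a prioritization result
#'
#' @param x a `prynt_ranking`.
#' @param ... unused.
#' @return the ranking as a plain tibble.
#' @method tidy prynt_ranking
#' @export
tidy.prynt_ranking <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  attr(out, "metadata") <- NULL
  out
}

#' One-row summary of a prioritization result
#'
#' @param x a `prynt_ranking`.
#' @param ... unused.
#' @return tibble with candidate/seed counts, the restart probability,
#'   random-walk convergence diagnostics and the unreachable-seed
#'   policy.
#' @method glance prynt_ranking
#' @export
glance.prynt_ranking <- function(x, ...) {
  m <- attr(x, "metadata")
  tibble(
    n_candidates = nrow(x),
    n_seeds = m$n_seeds %||% NA_integer_,
    r = m$r %||% NA_real_,
    rw_iterations = m$rw_iterations %||% NA_integer_,
    rw_residual = m$rw_residual %||% NA_real_,
    unreachable_policy = m$unreachable_policy %||% NA_character_,
    expanded = isTRUE(m$expanded)
  )
}

#' Tidy a precision curve
#'
#' @param x a `precision_curve`.
#' @param ... unused.
#' @return tibble (`k`, `hits`, `precision`).
#' @method tidy precision_curve
#' @export
tidy.precision_curve <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' One-row summary of a precision curve
#'
#' @param x a `precision_curve`.
#' @param ... unused.
#' @return tibble with `k_max`, `auc`, `auc_normalized`,
#'   `n_reference`, `reference_name`.
#' @method glance precision_curve
#' @export
glance.precision_curve <- function(x, ...) {
  tibble(
    k_max = attr(x, "k_max"),
    auc = attr(x, "auc"),
    auc_normalized = attr(x, "auc_normalized"),
    n_reference = attr(x, "n_reference"),
    reference_name = attr(x, "reference_name")
  )
}

#' Plot a precision curve
#'
#' @param object a `precision_curve`.
#' @param ... unused.
#' @return a ggplot: precision against ranking depth k, AUC in the
#'   subtitle.
#' @method autoplot precision_curve
#' @export
autoplot.precision_curve <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$precision)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "ranking depth k", y = "precision at k",
      title = sprintf("Precision vs '%s'", attr(object, "reference_name")),
      subtitle = sprintf("trapezoidal AUC = %.2f (normalized %.3f)",
                         attr(object, "auc"), attr(object, "auc_normalized"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot an overall-specificity report
#'
#' @param object a `specificity_report` from [overall_specificity()].
#' @param ... unused.
#' @return a ggplot: histogram of decoy AUCs with the specific
#'   disease's AUC marked.
#' @method autoplot specificity_report
#' @export
autoplot.specificity_report <- function(object, ...) {
  decoys <- attr(object, "decoy_aucs")
  if (is.null(decoys)) {
    abort("autoplot needs a report from overall_specificity()")
  }
  ggplot2::ggplot(decoys, ggplot2::aes(x = .data$auc)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$specific_auc, colour = "firebrick") +
    ggplot2::labs(
      x = "precision AUC", y = "decoy diseases",
      title = sprintf("Specific AUC ranks %d of %d",
                      object$specific_rank, object$n_lists)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
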