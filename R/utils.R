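# Shared internal helpers: ranking, integration, small validators.

#' Competition ("1224") rank over one or more sort keys
#'
#' Ranks rows by the keys in order (first key primary). Ties on all keys
#' share the smallest (best) rank. Keys are ranked ascending; negate a
#' numeric key to rank descending.
#'
#' @param ... equal-length atomic vectors used as sort keys.
#' @return integer vector of ranks, same length as the keys.
#' @keywords internal
#' @noRd
competition_rank <- function(...) {
  keys <- data.frame(..., stringsAsFactors = FALSE)
  ord <- do.call(order, keys)
  sorted <- keys[ord, , drop = FALSE]
  first <- !duplicated(sorted)
  pos <- seq_len(nrow(keys))
  ranks_sorted <- pos[first][cumsum(first)]
  out <- integer(nrow(keys))
  out[ord] <- ranks_sorted
  out
}

# Ordered-pair key for edge tables; zero-length safe (paste0 would
# recycle a lone separator on empty input).
edge_key <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  paste0(df$from, "\r", df$to)
}

# Trapezoidal area under y over x (x strictly increasing).
trapezoid_area <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1L) + y[-1L]) / 2)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 lower_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lower_open) x > lower else x >= lower) && x <= upper
  if (!ok) {
    abort(sprintf("`%s` must be a single number in %s%s, %s]",
                  name, if (lower_open) "(" else "[",
                  format(lower), format(upper)))
  }
  invisible(x)
}

# Coerce t/f, true/false, 0/1 columns (STRING dialects differ) to logical.
as_string_logical <- function(x) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("t", "true", "1", "yes")] <- TRUE
  out[v %in% c("f", "false", "0", "no")] <- FALSE
  out
}
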