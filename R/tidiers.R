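#' Tidy a Kovats deviation report
#'
#' @param x A [ki_deviation_report()].
#' @param ... Unused.
#' @return The per-compound deviation tibble, sorted by decreasing |deltaKI|.
#' @method tidy ki_deviation_report
#' @export
tidy.ki_deviation_report <- function(x, ...) x$table

#' @rdname tidy.ki_deviation_report
#' @return For `glance()`: a one-row tibble `n`, `min_abs`, `max_abs`,
#'   `max_rel_pct`.
#' @method glance ki_deviation_report
#' @export
glance.ki_deviation_report <- function(x, ...) x$summary

#' Tidy an aroma projection
#'
#' @param x An `aroma_projection` ([project_notes()], [project_varieties()]).
#' @param ... Unused.
#' @return Edge tibble `from`, `to`, `weight` (shared compound ids dropped).
#' @method tidy aroma_projection
#' @export
tidy.aroma_projection <- function(x, ...) {
  select(as_tibble(x), "from", "to", "weight")
}

#' @rdname tidy.aroma_projection
#' @return For `glance()`: one row with `level`, `n_nodes`, `n_edges`,
#'   `mean_weight`, `density` (edges over possible pairs) and `complete`.
#' @method glance aroma_projection
#' @export
glance.aroma_projection <- function(x, ...) {
  n_nodes <- length(attr(x, "nodes"))
  n_pairs <- choose(n_nodes, 2)
  tibble(
    level = attr(x, "level"),
    n_nodes = n_nodes,
    n_edges = nrow(x),
    mean_weight = if (nrow(x) > 0) mean(x$weight) else NA_real_,
    density = if (n_pairs > 0) nrow(x) / n_pairs else NA_real_,
    complete = n_pairs > 0 && nrow(x) == n_pairs
  )
}
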