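# broom-style accessors for the package's fitted/derived objects.

#' Tidy a search result
#'
#' @param x A `search_result`.
#' @param ... Unused.
#' @return A plain tibble of hits (`gene_id`, `r`, `p`, `lag`, `n_used`) in
#'   ranking order.
#' @method tidy search_result
#' @export
tidy.search_result <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' One-row summary of a search result
#'
#' @param x A `search_result`.
#' @param ... Unused.
#' @return A one-row tibble: mode, cutoff, hit count, strongest `|r|`,
#'   smallest p, constant windows skipped.
#' @method glance search_result
#' @export
glance.search_result <- function(x, ...) {
  tibble(
    mode = attr(x, "mode"),
    cutoff = attr(x, "params")$cutoff,
    n_hits = nrow(x),
    max_abs_r = if (nrow(x) > 0) max(abs(x$r)) else NA_real_,
    min_p = if (nrow(x) > 0) min(x$p) else NA_real_,
    n_skipped = attr(x, "n_skipped")
  )
}

#' Plot the hit curves of a search result
#'
#' Draws the expression profiles of the top hits with the query overlaid
#' (both z-scored so shapes are comparable), the panel users eyeball to judge
#' a cutoff.
#'
#' @param object A `search_result`.
#' @param data The expression tibble the search ran on.
#' @param max_curves Most curves to draw (default 50, best-ranked first).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot search_result
#' @export
autoplot.search_result <- function(object, data, max_curves = 50L, ...) {
  validate_expr(data)
  ids <- head(object$gene_id, max_curves)
  zscore <- function(v) (v - mean(v)) / sd(v)
  curves <- data |>
    filter(.data$gene_id %in% ids) |>
    tidy_expression() |>
    group_by(.data$gene_id) |>
    mutate(value = zscore(.data$value)) |>
    ungroup()
  q <- tibble(position = seq_len(ncol(data) - 1L),
              value = zscore(query_values(attr(object, "query"))))
  ggplot2::ggplot(curves, ggplot2::aes(
    x = .data$position, y = .data$value, group = .data$gene_id
  )) +
    ggplot2::geom_line(alpha = 0.35, colour = "steelblue") +
    ggplot2::geom_line(data = q, ggplot2::aes(group = NULL),
                       colour = "black", linewidth = 1.1) +
    ggplot2::labs(
      title = sprintf("%s search: %d hits (query in black)",
                      attr(object, "mode"), nrow(object)),
      x = "time point", y = "z-scored expression"
    ) +
    ggplot2::theme_minimal()
}

#' Tidy a k-means profile clustering
#'
#' @param x A `profile_kmeans`.
#' @param ... Unused.
#' @return The label tibble (`gene_id`, `cluster`).
#' @method tidy profile_kmeans
#' @export
tidy.profile_kmeans <- function(x, ...) {
  x$labels
}

#' One-row summary of a k-means profile clustering
#'
#' @param x A `profile_kmeans`.
#' @param ... Unused.
#' @return A one-row tibble: `k`, `inertia`, `iterations`, `seed`.
#' @method glance profile_kmeans
#' @export
glance.profile_kmeans <- function(x, ...) {
  tibble(k = x$k, inertia = x$inertia, iterations = x$iterations, seed = x$seed)
}

#' Plot the cluster centroids of a k-means fit
#'
#' One facet per cluster showing its centroid profile -- the panel-grid
#' overview used to browse the extracted expression patterns.
#'
#' @param object A `profile_kmeans`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot profile_kmeans
#' @export
autoplot.profile_kmeans <- function(object, ...) {
  sizes <- dplyr::count(object$labels, .data$cluster)
  cent <- as_tibble(object$centroids) |>
    mutate(cluster = seq_len(object$k)) |>
    tidyr::pivot_longer(-"cluster", names_to = "timepoint", values_to = "value") |>
    group_by(.data$cluster) |>
    mutate(position = row_number()) |>
    ungroup() |>
    left_join(sizes, by = "cluster") |>
    mutate(panel = sprintf("cluster %d (n = %d)", .data$cluster, .data$n))
  ggplot2::ggplot(cent, ggplot2::aes(x = .data$position, y = .data$value)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "time point",
                  y = if (object$standardized) "z-scored expression" else "expression") +
    ggplot2::theme_minimal()
}

unclass_result <- function(x) {
  class(x) <- setdiff(class(x), "search_result")
  attr(x, "query") <- NULL
  attr(x, "params") <- NULL
  attr(x, "mode") <- NULL
  attr(x, "n_skipped") <- NULL
  attr(x, "lag_profile") <- NULL
  x
}
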