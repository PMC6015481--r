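# Fig-style category palette: similar = red, opposite = purple,
# delayed = yellow, advanced = blue.
category_colors <- c(
  center = "grey20",
  similar = "#d62728",
  opposite = "#9467bd",
  delayed = "#e6b800",
  advanced = "#1f77b4"
)

#' Build a capped heat-map view of a search result
#'
#' Takes the top-ranked `min(cap, hits)` genes in result order (the same order
#' [write_result_csv()] writes) and prepares their expression values for
#' display. Rows are scaled per gene: `"zscore"` (default, symmetric diverging
#' palette), `"minmax"` to \[0, 1\], or `"raw"`. At most `cap` rows (default
#' 500) are kept.
#'
#' @param result A `search_result`.
#' @param data The expression tibble the search ran on.
#' @param cap Maximum number of rows (>= 1).
#' @param scaling Per-row display scaling.
#' @return A `heatmap_view`: `row_ids` (ranking order), `values` (long tibble
#'   of scaled values), `cap`, `scaling`. Plot with [autoplot()], write with
#'   [export_heatmap()]. An empty result gives an empty view with a warning.
#' @export
build_heatmap <- function(result, data, cap = 500L,
                          scaling = c("zscore", "minmax", "raw")) {
  stopifnot(inherits(result, "search_result"), cap >= 1)
  scaling <- match.arg(scaling)
  validate_expr(data)

  ids <- head(result$gene_id, cap)
  if (length(ids) == 0) {
    warn("empty search result: heat map has no rows")
    values <- tibble(gene_id = character(), timepoint = character(),
                     position = integer(), value = double())
  } else {
    m <- expr_values(data)[ids, , drop = FALSE]
    m <- switch(scaling,
      zscore = (m - rowMeans(m)) / apply(m, 1, sd),
      minmax = {
        rng <- apply(m, 1, range)
        (m - rng[1, ]) / ifelse(rng[2, ] > rng[1, ], rng[2, ] - rng[1, ], 1)
      },
      raw = m
    )
    values <- as_tibble(m) |>
      mutate(gene_id = ids, .before = 1) |>
      tidyr::pivot_longer(-"gene_id", names_to = "timepoint", values_to = "value") |>
      mutate(position = match(.data$timepoint, expr_timepoints(data)),
             .after = "timepoint")
  }
  structure(
    list(row_ids = ids, values = values, cap = as.integer(cap), scaling = scaling),
    class = "heatmap_view"
  )
}

#' @export
print.heatmap_view <- function(x, ...) {
  cat(sprintf("<heatmap_view: %d rows (cap %d), %s scaling>\n",
              length(x$row_ids), x$cap, x$scaling))
  invisible(x)
}

#' @method autoplot heatmap_view
#' @export
autoplot.heatmap_view <- function(object, ...) {
  df <- object$values |>
    mutate(gene_id = factor(.data$gene_id, levels = rev(object$row_ids)))
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$position, y = .data$gene_id, fill = .data$value
  )) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "time point", y = NULL, fill = object$scaling) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
  if (object$scaling == "zscore") {
    # red = high expression, blue = low
    p <- p + ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                           high = "#b2182b", midpoint = 0)
  } else {
    p <- p + ggplot2::scale_fill_gradient(low = "#2166ac", high = "#b2182b")
  }
  p
}

#' Write a heat-map view to an image file
#'
#' @param view A `heatmap_view`.
#' @param path Output path; the extension selects the device (`.png`, `.svg`).
#' @return `path` invisibly, or `NULL` (with no file written) for an empty view.
#' @export
export_heatmap <- function(view, path) {
  stopifnot(inherits(view, "heatmap_view"))
  if (length(view$row_ids) == 0) {
    warn("empty heat-map view: no file written")
    return(invisible(NULL))
  }
  h <- max(2, min(10, 0.12 * length(view$row_ids)))
  ggplot2::ggsave(path, autoplot(view), width = 6, height = h, dpi = 100,
                  limitsize = FALSE)
  invisible(path)
}

#' Build a query-centred correlation network
#'
#' Merges brush, contrast and shift results into a star graph: one centre node
#' (the searched gene, or the gene most similar to a drawn curve) and one node
#' per hit, connected to the centre by an edge weighted with the hit's
#' correlation. Node categories follow the search modes: `similar` (red,
#' brush), `opposite` (purple, contrast), `delayed` (yellow, shift with
#' positive lag) and `advanced` (blue, shift with negative lag). A gene found
#' by several modes keeps the mode with the larger `|r|` (ties: brush over
#' contrast over shift); a hit identical to the centre gene is represented by
#' the centre node itself.
#'
#' @param brush,contrast,shift `search_result` objects for the three modes,
#'   all from the same query. Pass an empty result for a mode not run.
#' @param center_label Centre node ID. Defaults to the query gene's ID when
#'   the query was a gene, otherwise to the top-ranked brush hit.
#' @return A `network_view`: `nodes` (id, category, color, r, lag) and
#'   `edges` (source, target, weight, category) tibbles. Plot with
#'   [autoplot()]; write with [export_network_json()] /
#'   [export_network_graphml()].
#' @export
build_network <- function(brush, contrast, shift, center_label = NULL) {
  results <- list(brush = brush, contrast = contrast, shift = shift)
  purrr::walk(results, function(r) stopifnot(inherits(r, "search_result")))

  queries <- purrr::map(results, function(r) query_values(attr(r, "query")))
  if (!all(purrr::map_lgl(queries[-1], function(q) isTRUE(all.equal(q, queries[[1]]))))) {
    cs_abort("the three search results were not produced from the same query",
             class = "curvesearch_validation_error")
  }

  hits <- bind_rows(
    brush |> as_tibble() |> mutate(category = "similar", priority = 1L),
    contrast |> as_tibble() |> mutate(category = "opposite", priority = 2L),
    shift |> as_tibble() |>
      mutate(category = dplyr::if_else(.data$lag > 0, "delayed", "advanced"),
             priority = 3L)
  )

  if (is.null(center_label)) {
    src <- query_source(attr(brush, "query"))
    center_label <- if (startsWith(src, "gene:")) {
      sub("^gene:", "", src)
    } else if (nrow(brush) > 0) {
      brush$gene_id[1]
    } else {
      "query"
    }
  }

  hits <- hits |>
    filter(.data$gene_id != center_label) |>
    arrange(desc(abs(.data$r)), .data$priority) |>
    distinct(.data$gene_id, .keep_all = TRUE)

  nodes <- bind_rows(
    tibble(id = center_label, category = "center", r = NA_real_, lag = NA_integer_),
    tibble(id = hits$gene_id, category = hits$category, r = hits$r,
           lag = as.integer(hits$lag))
  ) |>
    mutate(color = unname(category_colors[.data$category]))

  edges <- tibble(
    source = rep(center_label, nrow(hits)),
    target = hits$gene_id,
    weight = hits$r,
    category = hits$category
  )

  structure(list(nodes = nodes, edges = edges, center = center_label),
            class = "network_view")
}

#' @export
print.network_view <- function(x, ...) {
  cat(sprintf("<network_view: centre '%s', %d nodes, %d edges>\n",
              x$center, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @method autoplot network_view
#' @export
autoplot.network_view <- function(object, ...) {
  n <- nrow(object$edges)
  hits <- object$nodes |> filter(.data$category != "center")
  theta <- if (n > 0) seq(0, 2 * pi, length.out = n + 1)[seq_len(n)] else numeric(0)
  pos <- bind_rows(
    tibble(id = object$center, x = 0, y = 0),
    tibble(id = hits$id, x = cos(theta), y = sin(theta))
  ) |>
    left_join(object$nodes, by = "id")
  seg <- object$edges |>
    left_join(select(pos, "id", "x", "y"), by = c(target = "id"))

  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = 0, y = 0, xend = .data$x, yend = .data$y,
                   linewidth = abs(.data$weight)),
      colour = "grey70"
    ) +
    ggplot2::geom_point(
      data = pos,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$category), size = 4
    ) +
    ggplot2::geom_text(
      data = pos,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$id),
      vjust = -1.2, size = 2.5
    ) +
    ggplot2::scale_colour_manual(values = category_colors) +
    ggplot2::scale_linewidth(range = c(0.2, 1.2), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Export a network view as Cytoscape-compatible JSON
#'
#' Writes an `elements` object with `nodes` and `edges` arrays whose `data`
#' records carry `id`, `source`, `target`, `weight` and `category`, loadable
#' by Cytoscape.
#'
#' @param view A `network_view`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_network_json <- function(view, path) {
  stopifnot(inherits(view, "network_view"))
  nodes <- purrr::pmap(view$nodes, function(id, category, r, lag, color) {
    list(data = list(id = id, category = category, color = color,
                     r = if (is.na(r)) NULL else r,
                     lag = if (is.na(lag)) NULL else lag))
  })
  edges <- purrr::pmap(view$edges, function(source, target, weight, category) {
    list(data = list(id = paste0(source, "->", target), source = source,
                     target = target, weight = weight, category = category))
  })
  jsonlite::write_json(
    list(elements = list(nodes = nodes, edges = edges)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Export a network view as GraphML
#'
#' @inheritParams export_network_json
#' @return `path`, invisibly.
#' @export
export_network_graphml <- function(view, path) {
  stopifnot(inherits(view, "network_view"))
  vert <- view$nodes |>
    mutate(r = ifelse(is.na(.data$r), 0, .data$r),
           lag = ifelse(is.na(.data$lag), 0L, .data$lag)) |>
    rename(name = "id")
  g <- igraph::graph_from_data_frame(view$edges, directed = FALSE, vertices = vert)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export node and edge tables as TSV
#'
#' @param view A `network_view`.
#' @param nodes_path,edges_path Output paths.
#' @return Invisibly, the two paths.
#' @export
export_network_tables <- function(view, nodes_path, edges_path) {
  stopifnot(inherits(view, "network_view"))
  readr::write_tsv(view$nodes, nodes_path, progress = FALSE)
  readr::write_tsv(view$edges, edges_path, progress = FALSE)
  invisible(c(nodes_path, edges_path))
}
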