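# Runs `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# k-means++ seeding: first centre uniform, each next drawn with probability
# proportional to the squared distance to the nearest centre already chosen.
kmeanspp_centers <- function(m, k) {
  n <- nrow(m)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  if (k > 1) {
    d2 <- rowSums((m - m[rep(centers[1], n), , drop = FALSE])^2)
    for (j in 2:k) {
      if (all(d2 == 0)) {
        cs_abort("fewer distinct profiles than clusters requested",
                 class = "curvesearch_validation_error")
      }
      centers[j] <- sample.int(n, 1L, prob = d2)
      d2 <- pmin(d2, rowSums((m - m[rep(centers[j], n), , drop = FALSE])^2))
    }
  }
  m[centers, , drop = FALSE]
}

#' K-means clustering of expression profiles
#'
#' The comparison baseline to curve search: partitions genes into `k` groups
#' by Euclidean proximity of their time profiles. Rows are z-scored per gene
#' by default so that profile *shape*, not magnitude, drives the clustering --
#' on standardized rows Euclidean distance is a monotone function of Pearson
#' correlation, aligning this mode with the correlation-based searches.
#' Initialisation is k-means++ under the caller's seed with `n_start`
#' restarts (best inertia kept), followed by Lloyd iterations (at most 300).
#' Results are deterministic for a fixed seed.
#'
#' @param data Expression tibble (post-QC).
#' @param k Number of clusters, `1 <= k <=` gene count.
#' @param seed Integer seed controlling initialisation.
#' @param standardize Z-score each row first (default `TRUE`).
#' @param n_start Number of k-means++ restarts (default 5).
#' @return A `profile_kmeans` object: `labels` (tibble of `gene_id`,
#'   `cluster` in 1..k), `centroids` (k x T matrix, in the standardized space
#'   when `standardize = TRUE`), `inertia` (total within-cluster sum of
#'   squares), plus `k` and `seed`. Works with [tidy()], [glance()],
#'   [autoplot()].
#' @export
kmeans_profiles <- function(data, k, seed = 1L, standardize = TRUE, n_start = 5L) {
  validate_expr(data)
  m <- expr_values(data)
  if (k < 1 || k > nrow(m)) {
    cs_abort(sprintf("k must be between 1 and the gene count (%d)", nrow(m)),
             class = "curvesearch_validation_error")
  }
  if (standardize) {
    sds <- apply(m, 1, sd)
    if (any(sds == 0)) {
      cs_abort("constant rows cannot be z-scored; run qc_filter() first",
               class = "curvesearch_validation_error")
    }
    m <- (m - rowMeans(m)) / sds
  }

  fit <- with_local_seed(seed, {
    best <- NULL
    for (i in seq_len(n_start)) {
      init <- kmeanspp_centers(m, k)
      km <- suppressWarnings(
        kmeans(m, centers = init, iter.max = 300L, algorithm = "Lloyd")
      )
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })

  structure(
    list(
      k = as.integer(k),
      labels = tibble(gene_id = rownames(m), cluster = as.integer(fit$cluster)),
      centroids = unname(fit$centers) |> `colnames<-`(colnames(m)),
      inertia = fit$tot.withinss,
      seed = as.integer(seed),
      standardized = standardize,
      iterations = fit$iter
    ),
    class = "profile_kmeans"
  )
}

#' @export
print.profile_kmeans <- function(x, ...) {
  cat(sprintf("<profile_kmeans: k = %d, %d genes, inertia %.4g (seed %d)>\n",
              x$k, nrow(x$labels), x$inertia, x$seed))
  invisible(x)
}

#' Export cluster panels and labels
#'
#' Writes one plot panel per cluster (member curves in grey, centroid
#' overlaid) plus a TSV of gene-to-cluster labels -- the panel-per-category
#' presentation conventionally used to browse k-means expression patterns.
#'
#' @param result A `profile_kmeans` object.
#' @param data The expression tibble it was fitted on.
#' @param dir Output directory (created if needed).
#' @param device `"png"` or `"svg"`.
#' @return Invisibly, the written file paths (`k` panels + 1 label TSV).
#' @export
cluster_panel_export <- function(result, data, dir, device = c("png", "svg")) {
  stopifnot(inherits(result, "profile_kmeans"))
  device <- match.arg(device)
  validate_expr(data)
  if (!setequal(result$labels$gene_id, data$gene_id)) {
    cs_abort("cluster result does not match this matrix's genes",
             class = "curvesearch_validation_error")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  label_path <- file.path(dir, "cluster_labels.tsv")
  readr::write_tsv(result$labels, label_path, progress = FALSE)

  display <- data
  if (result$standardized) {
    m <- expr_values(data)
    m <- (m - rowMeans(m)) / apply(m, 1, sd)
    display[, -1] <- as_tibble(m)
  }
  long <- tidy_expression(display) |>
    left_join(result$labels, by = "gene_id")
  cent <- as_tibble(result$centroids) |>
    mutate(cluster = seq_len(result$k)) |>
    tidyr::pivot_longer(-"cluster", names_to = "timepoint", values_to = "value") |>
    mutate(position = match(.data$timepoint, expr_timepoints(data)))

  panel_paths <- purrr::map_chr(seq_len(result$k), function(cl) {
    p <- ggplot2::ggplot(
      filter(long, .data$cluster == cl),
      ggplot2::aes(x = .data$position, y = .data$value, group = .data$gene_id)
    ) +
      ggplot2::geom_line(alpha = 0.3, colour = "grey40") +
      ggplot2::geom_line(
        data = filter(cent, .data$cluster == cl),
        ggplot2::aes(group = NULL), colour = "firebrick", linewidth = 1
      ) +
      ggplot2::labs(
        title = sprintf("Cluster %d (%d genes)", cl, sum(result$labels$cluster == cl)),
        x = "time point", y = if (result$standardized) "z-scored expression" else "expression"
      ) +
      ggplot2::theme_minimal()
    path <- file.path(dir, sprintf("cluster_%02d.%s", cl, device))
    ggplot2::ggsave(path, p, width = 4, height = 3, dpi = 100)
    path
  })
  invisible(c(panel_paths, label_path))
}

#' Pivot an expression tibble to long format
#'
#' @param data Expression tibble.
#' @return Tibble with columns `gene_id`, `timepoint`, `position`, `value`.
#' @export
tidy_expression <- function(data) {
  validate_expr(data, allow_missing = TRUE)
  labels <- expr_timepoints(data)
  data |>
    tidyr::pivot_longer(-1, names_to = "timepoint", values_to = "value") |>
    rename(gene_id = 1) |>
    mutate(position = match(.data$timepoint, labels), .after = "timepoint")
}
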