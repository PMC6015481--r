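#' Run the full search pipeline and write its artifacts
#'
#' One-call orchestration of the workflow: quality filtering, query
#' construction (from sketch points, a predefined pattern, or an existing
#' gene), the requested search modes, and the exports -- one ranked CSV per
#' mode, a capped heat map for the first mode, and (when all three modes are
#' run) the query-centred network as Cytoscape JSON and GraphML. A
#' machine-readable run summary (QC counts, per-mode hit counts, parameters)
#' is written as JSON; progress is logged to the console.
#'
#' Exactly one of `query_points`, `pattern`, `query_gene` must be given.
#'
#' @param data Expression tibble, or the path of a TSV readable by
#'   [read_expression_tsv()].
#' @param out_dir Output directory (created if needed).
#' @param query_points Data frame of sketch points (or a curve file path).
#' @param pattern Predefined pattern name (see [predefined_pattern()]).
#' @param query_gene Gene ID to use as the query.
#' @param modes Search modes to run.
#' @param cutoff,max_lag,min_overlap,p_adjust Search parameters, as in
#'   [shift_search()].
#' @param missing_policy,entropy_threshold,n_bins QC parameters, as in
#'   [qc_filter()].
#' @param heatmap_cap Heat-map row cap (default 500).
#' @param write_heatmap_image Also render the heat map to PNG (default
#'   `FALSE`; the view is always summarised in the run summary).
#' @param quiet Suppress log messages.
#' @return Invisibly, a list: `results` (per-mode `search_result`s),
#'   `qc` (the QC report), `files` (paths written), `summary` (the run
#'   summary list).
#' @export
run_search <- function(data, out_dir,
                       query_points = NULL, pattern = NULL, query_gene = NULL,
                       modes = c("brush", "contrast", "shift"),
                       cutoff = 0.8, max_lag = 6L, min_overlap = 3L,
                       p_adjust = "none",
                       missing_policy = "drop", entropy_threshold = 0.1,
                       n_bins = 10L, heatmap_cap = 500L,
                       write_heatmap_image = FALSE, quiet = FALSE) {
  sources <- c(points = !is.null(query_points), pattern = !is.null(pattern),
               gene = !is.null(query_gene))
  if (sum(sources) != 1L) {
    cs_abort("give exactly one query source: query_points, pattern, or query_gene",
             class = "curvesearch_validation_error")
  }
  modes <- match.arg(modes, c("brush", "contrast", "shift"), several.ok = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  if (is.character(data) && length(data) == 1L) {
    say("reading expression matrix from %s", data)
    data <- read_expression_tsv(data)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  filtered <- qc_filter(data, missing_policy = missing_policy,
                        entropy_threshold = entropy_threshold, n_bins = n_bins)
  qc <- qc_report(filtered)
  say("QC: %d genes in, %d retained (%d missing, %d low entropy dropped)",
      qc$n_input, qc$n_retained, qc$n_dropped_missing, qc$n_dropped_low_entropy)

  t_n <- ncol(filtered) - 1L
  query <- if (!is.null(query_points)) {
    pts <- if (is.character(query_points)) read_curve_points(query_points) else query_points
    resample_curve(pts, t_n)
  } else if (!is.null(pattern)) {
    predefined_pattern(pattern, t_n)
  } else {
    gene_as_query(filtered, query_gene)
  }
  say("query source: %s (%d time points)", query_source(query), t_n)

  results <- search_genes(filtered, query, modes = modes, cutoff = cutoff,
                          max_lag = max_lag, min_overlap = min_overlap,
                          p_adjust = p_adjust)
  files <- character(0)
  for (mode in names(results)) {
    say("%s search: %d hits", mode, nrow(results[[mode]]))
    path <- file.path(out_dir, sprintf("search_%s.csv", mode))
    write_result_csv(results[[mode]], filtered, path)
    files <- c(files, path)
  }

  hm <- suppressWarnings(build_heatmap(results[[1]], filtered, cap = heatmap_cap))
  if (write_heatmap_image && length(hm$row_ids) > 0) {
    hm_path <- file.path(out_dir, "heatmap.png")
    export_heatmap(hm, hm_path)
    files <- c(files, hm_path)
  }

  net <- NULL
  if (all(c("brush", "contrast", "shift") %in% names(results))) {
    net <- build_network(results$brush, results$contrast, results$shift)
    json_path <- file.path(out_dir, "network.json")
    graphml_path <- file.path(out_dir, "network.graphml")
    export_network_json(net, json_path)
    export_network_graphml(net, graphml_path)
    files <- c(files, json_path, graphml_path)
  }

  summary <- list(
    parameters = list(modes = modes, cutoff = cutoff, max_lag = max_lag,
                      min_overlap = min_overlap, p_adjust = p_adjust,
                      entropy_threshold = entropy_threshold,
                      missing_policy = missing_policy,
                      heatmap_cap = heatmap_cap),
    query_source = query_source(query),
    n_timepoints = t_n,
    qc = list(n_input = qc$n_input, n_retained = qc$n_retained,
              n_dropped_missing = qc$n_dropped_missing,
              n_dropped_low_entropy = qc$n_dropped_low_entropy),
    hits = lapply(results, nrow),
    heatmap_rows = length(hm$row_ids),
    network_nodes = if (is.null(net)) NULL else nrow(net$nodes)
  )
  summary_path <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, summary_path)

  invisible(list(results = results, qc = qc, heatmap = hm, network = net,
                 files = files, summary = summary))
}
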