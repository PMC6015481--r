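#' Read a time-series expression matrix from TSV
#'
#' Reads the de-facto flat layout for time-course expression data: a UTF-8,
#' tab-delimited file with a header row, the first column holding gene IDs and
#' every remaining column one ordered time point. Cells matching a missing
#' token are flagged as missing (`NA`); the matrix may therefore contain
#' missing values until [qc_filter()] is applied.
#'
#' @param path Path to a tab-separated file.
#' @param missing_tokens Character vector of cell values to treat as missing.
#' @return A tibble: `gene_id` plus one numeric column per time point, in file
#'   order. Missing cells are `NA`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\t0h\t4h\t8h", "g1\t1\t2\t3", "g2\t3\tNA\t1"), tf)
#' read_expression_tsv(tf)
#' @export
read_expression_tsv <- function(path, missing_tokens = c("", "NA", "NaN", "null")) {
  if (!file.exists(path)) {
    cs_abort(sprintf("file not found: %s", path), class = "curvesearch_io_error")
  }
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) - 1L < 3L) {
    cs_abort("expression file needs at least 3 time-point columns after the gene ID column",
             class = "curvesearch_validation_error")
  }
  spec <- do.call(readr::cols, c(
    list(readr::col_character()),
    rep(list(readr::col_double()), length(header) - 1L)
  ))
  data <- suppressWarnings(readr::read_tsv(
    path,
    na = missing_tokens, col_types = spec,
    progress = FALSE, show_col_types = FALSE
  ))
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    cs_abort(
      sprintf(
        "malformed expression file: line %d (%s)",
        probs$row[1],
        if ("expected" %in% names(probs)) paste("expected", probs$expected[1]) else "parse failure"
      ),
      class = "curvesearch_parse_error"
    )
  }
  names(data)[1] <- "gene_id"
  data$gene_id <- as.character(data$gene_id)
  validate_expr(data, allow_missing = TRUE)
  data
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_tsv()]: round-trips well-formed matrices
#' exactly. Missing values are written as `NA`.
#'
#' @param data Expression tibble (`gene_id` + time-point columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(data, path) {
  validate_expr(data, allow_missing = TRUE)
  readr::write_tsv(data, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Quality-filter an expression matrix
#'
#' Two-stage filter applied before any search. First, missing values are
#' handled: under `missing_policy = "drop"` every gene with at least one
#' missing value is removed; under `"interpolate"`, interior missing runs
#' covering at most 20% of the time points are filled by linear interpolation
#' over the time index, and genes that still have missing values (including any
#' leading or trailing gap) are dropped. Second, each remaining profile's
#' Shannon entropy is computed over `n_bins` equal-width bins spanning that
#' row's own range, and rows below `entropy_threshold` bits -- constant rows
#' have entropy 0 -- are dropped, since Pearson correlation is undefined or
#' meaningless for them.
#'
#' @param data Expression tibble, possibly with `NA` values.
#' @param missing_policy `"drop"` (default) or `"interpolate"`.
#' @param entropy_threshold Minimum row entropy in bits to retain a gene.
#'   The default 0.1 removes constants and near-constants only.
#' @param n_bins Number of equal-width bins for the entropy estimate.
#' @return The filtered tibble, with a `"qc_report"` attribute; retrieve it
#'   with [qc_report()]. The report accounts for every input gene.
#' @examples
#' m <- tibble::tibble(gene_id = c("flat", "ramp"),
#'                     t1 = c(1, 1), t2 = c(1, 2), t3 = c(1, 3))
#' kept <- qc_filter(m)
#' qc_report(kept)
#' @export
qc_filter <- function(data, missing_policy = c("drop", "interpolate"),
                      entropy_threshold = 0.1, n_bins = 10L) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(entropy_threshold >= 0, n_bins >= 2)
  validate_expr(data, allow_missing = TRUE)

  m <- expr_values(data)
  t_n <- ncol(m)
  n_input <- nrow(m)

  drop_missing <- character(0)
  if (missing_policy == "interpolate") {
    for (i in seq_len(nrow(m))) {
      miss <- !is.finite(m[i, ])
      if (!any(miss)) next
      # leading/trailing gaps are never interpolated; neither are wide gaps
      if (miss[1] || miss[t_n] || sum(miss) > 0.2 * t_n) {
        drop_missing <- c(drop_missing, rownames(m)[i])
      } else {
        idx <- seq_len(t_n)
        m[i, miss] <- approx(idx[!miss], m[i, !miss], xout = idx[miss])$y
      }
    }
  } else {
    keep <- apply(is.finite(m), 1, all)
    drop_missing <- rownames(m)[!keep]
  }
  m <- m[setdiff(rownames(m), drop_missing), , drop = FALSE]

  ent <- apply(m, 1, row_entropy, n_bins = n_bins)
  drop_entropy <- rownames(m)[ent < entropy_threshold]
  m <- m[setdiff(rownames(m), drop_entropy), , drop = FALSE]

  if (nrow(m) == 0) {
    cs_abort("empty matrix after QC: every gene was filtered out",
             class = "curvesearch_qc_error")
  }

  report <- structure(
    list(
      n_input = n_input,
      n_retained = nrow(m),
      n_dropped_missing = length(drop_missing),
      n_dropped_low_entropy = length(drop_entropy),
      dropped = tibble(
        gene_id = c(drop_missing, drop_entropy),
        reason = rep(c("missing", "low_entropy"),
                     c(length(drop_missing), length(drop_entropy)))
      )
    ),
    class = "qc_report"
  )

  out <- data[match(rownames(m), data$gene_id), , drop = FALSE]
  out[, -1] <- as_tibble(m)
  attr(out, "qc_report") <- report
  out
}

#' Retrieve the QC report attached by [qc_filter()]
#'
#' @param data A tibble returned by [qc_filter()].
#' @return A `qc_report`: input/retained/dropped counts plus a tibble of
#'   dropped gene IDs with reason codes (`missing`, `low_entropy`).
#' @export
qc_report <- function(data) {
  rep <- attr(data, "qc_report")
  if (is.null(rep)) {
    cs_abort("no QC report attached; was this tibble produced by qc_filter()?",
             class = "curvesearch_validation_error")
  }
  rep
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "QC report: %d genes in, %d retained (%d dropped: %d missing, %d low entropy)\n",
    x$n_input, x$n_retained, x$n_dropped_missing + x$n_dropped_low_entropy,
    x$n_dropped_missing, x$n_dropped_low_entropy
  ))
  invisible(x)
}

#' Export a search result table as CSV
#'
#' One row per hit, in ranking order, with columns `gene_id`, `p_value`,
#' `correlation`, `lag` (0 for brush and contrast hits) followed by the gene's
#' full time-series expression values from `data`. RFC-4180 CSV.
#'
#' @param result A `search_result` (see [brush_search()]).
#' @param data The expression tibble the search ran on.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(result, data, path) {
  stopifnot(inherits(result, "search_result"))
  validate_expr(data)
  missing <- setdiff(result$gene_id, data$gene_id)
  if (length(missing) > 0) {
    cs_abort(
      sprintf("result references genes absent from the matrix: %s",
              paste(head(missing, 5), collapse = ", ")),
      class = "curvesearch_internal_error"
    )
  }
  tab <- result |>
    as_tibble() |>
    select(gene_id = "gene_id", p_value = "p", correlation = "r", lag = "lag") |>
    left_join(data, by = "gene_id")
  readr::write_csv(tab, path, progress = FALSE)
  invisible(path)
}
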