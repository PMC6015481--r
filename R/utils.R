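# Internal validation helpers shared across modules. An expression table is a
# tibble whose first column (`gene_id`, character) identifies the gene and whose
# remaining columns are ordered numeric time points.

cs_abort <- function(message, class, ...) {
  abort(message, class = c(class, "curvesearch_error"), ...)
}

# Extract the numeric value block as a matrix with gene_id rownames.
expr_values <- function(data) {
  stopifnot(is.data.frame(data), ncol(data) >= 2)
  m <- as.matrix(data[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(data[[1]])
  m
}

expr_timepoints <- function(data) {
  names(data)[-1]
}

# Validate an expression table; `allow_missing` distinguishes pre- from post-QC.
validate_expr <- function(data, allow_missing = FALSE) {
  if (!is.data.frame(data) || ncol(data) < 2) {
    cs_abort("expression data must be a data frame with a gene ID column and time-point columns",
             class = "curvesearch_validation_error")
  }
  ids <- as.character(data[[1]])
  if (anyNA(ids) || any(!nzchar(ids))) {
    cs_abort("gene IDs must be non-empty", class = "curvesearch_validation_error")
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    cs_abort(
      sprintf("duplicate gene IDs: %s", paste(head(dup, 5), collapse = ", ")),
      class = "curvesearch_validation_error"
    )
  }
  if (ncol(data) - 1L < 3L) {
    cs_abort("an expression matrix needs at least 3 time-point columns",
             class = "curvesearch_validation_error")
  }
  m <- expr_values(data)
  if (!allow_missing && !all(is.finite(m))) {
    cs_abort("expression values must all be finite after QC; run qc_filter() first",
             class = "curvesearch_validation_error")
  }
  invisible(data)
}

# Shannon entropy (bits) of one profile over `n_bins` equal-width bins spanning
# the row's own range. Constant rows have zero range and entropy 0 by definition.
row_entropy <- function(x, n_bins = 10L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) {
    return(0)
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), nbins = n_bins)
  p <- counts[counts > 0] / length(x)
  -sum(p * log2(p))
}

new_query_vector <- function(values, source, labels = NULL) {
  out <- tibble(
    position = seq_along(values),
    value = as.numeric(values)
  )
  if (!is.null(labels)) out$timepoint <- labels
  structure(out, class = c("query_vector", class(out)), source = source)
}

query_values <- function(query) {
  if (inherits(query, "query_vector")) return(query$value)
  if (is.numeric(query)) return(as.numeric(query))
  cs_abort("query must be a query_vector (see resample_curve()) or a numeric vector",
           class = "curvesearch_validation_error")
}

query_source <- function(query) {
  attr(query, "source") %||% "numeric"
}
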