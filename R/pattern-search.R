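#' Pearson correlation coefficient
#'
#' Product-moment correlation between two equal-length numeric vectors,
#' computed directly from centred sums. Errors (rather than silently returning
#' 0 or NA) if either vector is constant, since the coefficient is then
#' undefined.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return The correlation, in \[-1, 1\].
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    cs_abort("x and y must have equal length", class = "curvesearch_validation_error")
  }
  if (length(x) < 3) {
    cs_abort("correlation needs at least 3 point pairs",
             class = "curvesearch_insufficient_points_error")
  }
  xc <- x - mean(x)
  yc <- y - mean(y)
  ssx <- sum(xc^2)
  ssy <- sum(yc^2)
  if (ssx == 0 || ssy == 0) {
    cs_abort("correlation undefined: input vector is constant",
             class = "curvesearch_undefined_correlation_error")
  }
  r <- sum(xc * yc) / sqrt(ssx * ssy)
  max(-1, min(1, r))
}

#' Two-sided p-value for a Pearson correlation
#'
#' The exact test under bivariate normality: `t = r * sqrt((n - 2) / (1 - r^2))`
#' referred to the t distribution with `n - 2` degrees of freedom, two-sided.
#' `|r| = 1` gives `p = 0` in the limit.
#'
#' @param r Correlation in \[-1, 1\].
#' @param n Number of point pairs used (>= 3).
#' @return p-value in \[0, 1\].
#' @examples
#' pearson_pvalue(0.8, 4)  # 0.2
#' @export
pearson_pvalue <- function(r, n) {
  if (any(n < 3)) {
    cs_abort("p-value needs at least 3 point pairs",
             class = "curvesearch_insufficient_points_error")
  }
  r <- pmax(-1, pmin(1, r))
  p <- ifelse(
    abs(r) >= 1, 0,
    2 * pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), df = n - 2)
  )
  pmin(1, p)
}

# Correlation of every matrix row against one vector, vectorised.
# Rows (or the query) with zero variance on the window give NA.
row_correlations <- function(m, q) {
  qc <- q - mean(q)
  ssq <- sum(qc^2)
  mc <- m - rowMeans(m)
  ssm <- rowSums(mc^2)
  r <- as.numeric(mc %*% qc) / sqrt(ssm * ssq)
  r[ssm == 0 | ssq == 0] <- NA_real_
  pmax(-1, pmin(1, r))
}

new_search_result <- function(hits, query, mode, params, n_skipped = 0L) {
  hits <- arrange(hits, desc(abs(.data$r)), .data$p, .data$gene_id)
  structure(
    hits,
    class = c("search_result", class(tibble())),
    query = query, mode = mode, params = params, n_skipped = n_skipped
  )
}

check_query_against <- function(data, query) {
  q <- query_values(query)
  t_n <- ncol(data) - 1L
  if (length(q) != t_n) {
    cs_abort(sprintf("query has %d values but the matrix has %d time points",
                     length(q), t_n),
             class = "curvesearch_validation_error")
  }
  if (var(q) == 0) {
    cs_abort("constant query", class = "curvesearch_constant_query_error")
  }
  q
}

finalize_hits <- function(hits, p_adjust) {
  if (p_adjust == "BH") hits$p_adj <- stats::p.adjust(hits$p, method = "BH")
  hits
}

#' Brush search: genes co-expressed with the query
#'
#' The default search mode. Every gene is scored against the query by Pearson
#' correlation at zero lag; genes with `r >= cutoff` are reported, ranked by
#' `|r|` descending (ties: smaller p, then gene ID). Constant rows, should any
#' survive QC, are skipped with a warning count in the result's diagnostics.
#'
#' @param data Expression tibble (post-QC).
#' @param query A `query_vector` or numeric vector of length `T`.
#' @param cutoff Minimum correlation `c` in \[0, 1\] for a gene to be reported.
#' @param p_adjust `"none"` (default; raw p-values are reported) or `"BH"` to
#'   add a Benjamini-Hochberg adjusted `p_adj` column.
#' @return A `search_result`: a tibble with columns `gene_id`, `r`, `p`, `lag`
#'   (always 0 here) and `n_used`, carrying the query and parameters as
#'   attributes. Works with [tidy()], [glance()], [autoplot()].
#' @seealso [contrast_search()], [shift_search()]
#' @export
brush_search <- function(data, query, cutoff = 0.8, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  validate_expr(data)
  stopifnot(cutoff >= 0, cutoff <= 1)
  q <- check_query_against(data, query)
  t_n <- length(q)

  r <- row_correlations(expr_values(data), q)
  keep <- !is.na(r) & r >= cutoff
  r_kept <- r[keep]
  hits <- tibble(
    gene_id = data$gene_id[keep],
    r = r_kept,
    p = pearson_pvalue(r_kept, t_n),
    lag = 0L,
    n_used = t_n
  )
  new_search_result(finalize_hits(hits, p_adjust), query, "brush",
                    list(cutoff = cutoff, p_adjust = p_adjust),
                    n_skipped = sum(is.na(r)))
}

#' Contrast search: genes with the opposite expression pattern
#'
#' Reports genes anti-correlated with the query (`r <= -cutoff`) at zero lag --
#' e.g. candidate targets of a repressing transcription factor. Equivalent,
#' hit for hit, to a brush search with the negated query.
#'
#' @inheritParams brush_search
#' @return A `search_result` whose hits all have `r <= -cutoff` and `lag = 0`.
#' @export
contrast_search <- function(data, query, cutoff = 0.8, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  validate_expr(data)
  stopifnot(cutoff >= 0, cutoff <= 1)
  q <- check_query_against(data, query)
  t_n <- length(q)

  r <- row_correlations(expr_values(data), q)
  keep <- !is.na(r) & r <= -cutoff
  r_kept <- r[keep]
  hits <- tibble(
    gene_id = data$gene_id[keep],
    r = r_kept,
    p = pearson_pvalue(r_kept, t_n),
    lag = 0L,
    n_used = t_n
  )
  new_search_result(finalize_hits(hits, p_adjust), query, "contrast",
                    list(cutoff = cutoff, p_adjust = p_adjust),
                    n_skipped = sum(is.na(r)))
}

#' Full lag-correlation profile for every gene
#'
#' For each gene and each nonzero integer lag `s` with `|s| <= max_lag`,
#' correlates the overlapping `T - |s|` points where the gene runs `s` steps
#' later in time than the query: positive `s` means the gene is delayed
#' (follows the query), negative `s` that it is advanced (precedes it). The
#' overlap is the truncated window, as in standard cross-correlation; nothing
#' is padded or wrapped.
#'
#' @inheritParams brush_search
#' @param max_lag Largest lag magnitude `L` to scan (default 6).
#' @param min_overlap Minimum overlap length; `T - max_lag` must be at least
#'   this (default 3).
#' @return A tibble with one row per gene and lag: `gene_id`, `lag`, `r`,
#'   `n_used`. `r` is `NA` where either window is constant.
#' @export
shift_lag_profile <- function(data, query, max_lag = 6L, min_overlap = 3L) {
  validate_expr(data)
  stopifnot(max_lag >= 1, min_overlap >= 3)
  q <- check_query_against(data, query)
  t_n <- length(q)
  if (t_n - max_lag < min_overlap) {
    cs_abort(sprintf(
      "invalid lag range: max_lag %d leaves overlaps below min_overlap %d on %d time points",
      max_lag, min_overlap, t_n
    ), class = "curvesearch_invalid_lag_range_error")
  }
  m <- expr_values(data)
  lags <- setdiff(seq(-max_lag, max_lag), 0L)
  purrr::map_dfr(lags, function(s) {
    k <- abs(s)
    if (s > 0) {
      r <- row_correlations(m[, (k + 1):t_n, drop = FALSE], q[1:(t_n - k)])
    } else {
      r <- row_correlations(m[, 1:(t_n - k), drop = FALSE], q[(k + 1):t_n])
    }
    tibble(gene_id = rownames(m), lag = s, r = r, n_used = t_n - k)
  })
}

#' Shift search: time-delayed or time-advanced co-expression
#'
#' Scans lags `-max_lag..-1, +1..+max_lag` (never 0: exact zero-lag matches
#' belong to [brush_search()]) and keeps, per gene, the single lag with the
#' highest correlation; ties prefer the smaller `|s|`, then delayed (`+`) over
#' advanced (`-`). Genes whose best `r >= cutoff` are reported with that lag;
#' p-values use the overlap length `T - |s|`.
#'
#' @inheritParams shift_lag_profile
#' @param cutoff Minimum correlation at the best lag.
#' @param p_adjust `"none"` or `"BH"`.
#' @param all_lags If `TRUE`, attach the full per-lag correlation profile
#'   (as returned by [shift_lag_profile()]) in the `"lag_profile"` attribute.
#' @return A `search_result` with one row per reported gene, its best `lag`
#'   in `[-max_lag, max_lag] \ {0}` and `n_used = T - |lag|`.
#' @export
shift_search <- function(data, query, cutoff = 0.8, max_lag = 6L, min_overlap = 3L,
                         p_adjust = c("none", "BH"), all_lags = FALSE) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(cutoff >= 0, cutoff <= 1)
  profile <- shift_lag_profile(data, query, max_lag = max_lag, min_overlap = min_overlap)
  n_skipped <- sum(is.na(profile$r))

  best <- profile |>
    filter(!is.na(.data$r)) |>
    group_by(.data$gene_id) |>
    arrange(desc(.data$r), abs(.data$lag), desc(.data$lag), .by_group = TRUE) |>
    slice_head(n = 1L) |>
    ungroup()

  hits <- best |>
    filter(.data$r >= cutoff) |>
    mutate(p = pearson_pvalue(.data$r, .data$n_used), lag = as.integer(.data$lag)) |>
    select("gene_id", "r", "p", "lag", "n_used")

  out <- new_search_result(
    finalize_hits(hits, p_adjust), query, "shift",
    list(cutoff = cutoff, max_lag = max_lag, min_overlap = min_overlap,
         p_adjust = p_adjust),
    n_skipped = n_skipped
  )
  if (all_lags) attr(out, "lag_profile") <- profile
  out
}

#' Run one or more search modes in a single call
#'
#' @inheritParams shift_search
#' @param modes Character vector among `"brush"`, `"contrast"`, `"shift"`.
#' @return A named list of `search_result` objects, one per mode.
#' @export
search_genes <- function(data, query, modes = c("brush", "contrast", "shift"),
                         cutoff = 0.8, max_lag = 6L, min_overlap = 3L,
                         p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  modes <- match.arg(modes, several.ok = TRUE)
  setNames(lapply(modes, function(mode) {
    switch(mode,
      brush = brush_search(data, query, cutoff, p_adjust),
      contrast = contrast_search(data, query, cutoff, p_adjust),
      shift = shift_search(data, query, cutoff, max_lag, min_overlap, p_adjust)
    )
  }), modes)
}

#' @export
`[.search_result` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("gene_id", "r", "p", "lag") %in% names(out))) {
    for (a in c("query", "mode", "params", "n_skipped")) {
      attr(out, a) <- attr(x, a)
    }
    class(out) <- unique(c("search_result", class(out)))
  }
  out
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result: mode %s, %d hits (cutoff %g)%s>\n",
              attr(x, "mode"), nrow(x), attr(x, "params")$cutoff,
              if (attr(x, "n_skipped") > 0)
                sprintf(", %d constant windows skipped", attr(x, "n_skipped"))
              else ""))
  NextMethod()
}
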