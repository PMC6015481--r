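#' Resample a drawn curve onto the experiment's time points
#'
#' Turns a free-hand polyline -- an ordered set of (x, y) points in arbitrary
#' canvas units -- into a query vector aligned with the `T` time points of an
#' expression matrix. Points are sorted by x, points sharing an x are averaged,
#' and the resulting polyline is evaluated by piecewise-linear interpolation at
#' `T` positions equally spaced from `min(x)` to `max(x)` inclusive. The x
#' scale is immaterial: any affine rescaling of the canvas yields the same
#' query. Values are returned as drawn, unnormalised, because Pearson
#' correlation is invariant to positive affine rescaling of the query.
#'
#' @param points A data frame with columns `x` and `y` (at least 2 rows), or a
#'   two-column matrix.
#' @param n_timepoints Number of time points `T` to sample (>= 3).
#' @return A `query_vector`: a tibble with columns `position` (1..T) and
#'   `value`, carrying its provenance in the `"source"` attribute.
#' @examples
#' resample_curve(data.frame(x = c(0, 1), y = c(0, 1)), n_timepoints = 5)
#' @export
resample_curve <- function(points, n_timepoints) {
  points <- as.data.frame(points)
  if (ncol(points) == 2 && !all(c("x", "y") %in% names(points))) {
    names(points) <- c("x", "y")
  }
  stopifnot(all(c("x", "y") %in% names(points)))
  if (nrow(points) < 2) {
    cs_abort("a drawn curve needs at least 2 points", class = "curvesearch_validation_error")
  }
  if (!all(is.finite(points$x)) || !all(is.finite(points$y))) {
    cs_abort("curve coordinates must be finite", class = "curvesearch_validation_error")
  }
  if (n_timepoints < 3) {
    cs_abort("n_timepoints must be at least 3", class = "curvesearch_validation_error")
  }

  # average y over duplicated x, then sort: deterministic and order-independent
  pts <- points |>
    group_by(x = .data$x) |>
    summarise(y = mean(.data$y), .groups = "drop") |>
    arrange(.data$x)
  if (nrow(pts) < 2) {
    cs_abort("degenerate curve: all points share one x position",
             class = "curvesearch_degenerate_curve_error")
  }

  xout <- seq(min(pts$x), max(pts$x), length.out = n_timepoints)
  values <- approx(pts$x, pts$y, xout = xout, method = "linear")$y
  if (var(values) == 0) {
    cs_abort("constant query: the resampled curve has no variation",
             class = "curvesearch_constant_query_error")
  }
  new_query_vector(values, source = "drawn")
}

#' Predefined query patterns
#'
#' The built-in pattern library: `increasing` is a linear ramp from 0 to 1,
#' `decreasing` its reversal, `pulse` a single triangular peak at the middle
#' time point, and `circadian` a sine wave with a period of `period_points`
#' samples. The circadian default of 6 corresponds to a 24-h rhythm sampled
#' every 4 h, so a 12-point, 48-h course spans exactly two full cycles.
#'
#' @param name One of `"increasing"`, `"decreasing"`, `"pulse"`, `"circadian"`.
#' @param n_timepoints Number of time points `T` (>= 3).
#' @param period_points Samples per period for the circadian pattern (>= 2).
#' @return A `query_vector`.
#' @examples
#' predefined_pattern("circadian", n_timepoints = 12)
#' @export
predefined_pattern <- function(name = c("increasing", "decreasing", "pulse", "circadian"),
                               n_timepoints, period_points = 6L) {
  name <- match.arg(name)
  if (n_timepoints < 3) {
    cs_abort("n_timepoints must be at least 3", class = "curvesearch_validation_error")
  }
  t_idx <- seq_len(n_timepoints) - 1L
  values <- switch(name,
    increasing = t_idx / (n_timepoints - 1L),
    decreasing = rev(t_idx / (n_timepoints - 1L)),
    pulse = {
      mid <- (n_timepoints - 1L) / 2
      1 - abs(t_idx - mid) / mid
    },
    circadian = {
      if (period_points < 2) {
        cs_abort("period_points must be at least 2", class = "curvesearch_validation_error")
      }
      sin(2 * pi * t_idx / period_points)
    }
  )
  new_query_vector(values, source = paste0("predefined:", name))
}

#' Use an existing gene's profile as the query
#'
#' Looks up `gene_id` in the matrix and returns its row as a query vector; the
#' source records the ID so result views can mark that gene as the network's
#' centre node.
#'
#' @param data Expression tibble.
#' @param gene_id Gene identifier present in `data`.
#' @return A `query_vector` with source `"gene:<id>"`.
#' @export
gene_as_query <- function(data, gene_id) {
  validate_expr(data)
  i <- match(gene_id, data$gene_id)
  if (is.na(i)) {
    near <- data$gene_id[agrepl(gene_id, data$gene_id, ignore.case = TRUE)]
    cs_abort(
      sprintf("gene '%s' not found%s", gene_id,
              if (length(near) > 0)
                paste0("; near matches: ", paste(head(near, 5), collapse = ", "))
              else ""),
      class = "curvesearch_lookup_error"
    )
  }
  values <- as.numeric(expr_values(data)[i, ])
  if (var(values) == 0) {
    cs_abort(sprintf("gene '%s' has a constant profile and cannot be a query", gene_id),
             class = "curvesearch_constant_query_error")
  }
  new_query_vector(values, source = paste0("gene:", gene_id),
                   labels = expr_timepoints(data))
}

#' Read a drawn curve from a two-column file
#'
#' Accepts the on-disk forms of a sketch: a two-column (x, y) CSV or TSV with
#' or without a header, or a JSON array of `[x, y]` pairs.
#'
#' @param path Path to the curve file; format inferred from the extension
#'   (`.json` vs delimited text).
#' @return A data frame with columns `x` and `y`, ready for [resample_curve()].
#' @export
read_curve_points <- function(path) {
  if (!file.exists(path)) {
    cs_abort(sprintf("file not found: %s", path), class = "curvesearch_io_error")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    pts <- jsonlite::fromJSON(path)
    pts <- as.data.frame(pts)
    names(pts) <- c("x", "y")[seq_len(ncol(pts))]
  } else {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
    has_header <- !grepl("^[-+0-9.eE \t,]+$", first)
    pts <- utils::read.delim(path, sep = delim, header = has_header)
    names(pts) <- c("x", "y")
  }
  pts[c("x", "y")]
}

#' @export
print.query_vector <- function(x, ...) {
  cat(sprintf("<query_vector: %d time points, source %s>\n", nrow(x), query_source(x)))
  NextMethod()
}
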