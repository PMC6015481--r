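# Ratio helpers for annotating search output against curated
# transcription-factor target lists, plus a bundled worked example.

#' Per-pattern TF regulation ratios
#'
#' Given counts of search hits that curated annotation recognises as targets
#' of particular transcription factors, computes the percentage of recognised
#' hits regulated by each factor -- the standard way to summarise how strongly
#' a search mode's output is enriched for a shared regulator.
#'
#' @param counts A tibble with one row per (search pattern, TF) pair and
#'   columns `pattern`, `n_hits` (genes the search returned), `n_recognized`
#'   (of those, genes present in the annotation database) and `n_regulated`
#'   (of the recognised, genes annotated as targets of `tf`).
#' @return `counts` with an added `ratio_pct` column,
#'   `100 * n_regulated / n_recognized`.
#' @seealso [pooled_regulation_ratio()], [tf_target_counts_example()]
#' @export
tf_regulation_ratios <- function(counts) {
  stopifnot(all(c("pattern", "n_recognized", "n_regulated") %in% names(counts)))
  counts |>
    as_tibble() |>
    mutate(ratio_pct = 100 * .data$n_regulated / .data$n_recognized)
}

#' Pooled regulation ratio across search patterns
#'
#' The single headline figure: of all genes returned across the search
#' patterns, the percentage recognised as targets of the shared transcription
#' factors -- computed as the sum of per-pattern recognised counts over the
#' sum of per-pattern hit counts.
#'
#' @inheritParams tf_regulation_ratios
#' @return A one-row tibble with `n_hits_total`, `n_recognized_total` and
#'   `pooled_pct`.
#' @export
pooled_regulation_ratio <- function(counts) {
  stopifnot(all(c("pattern", "n_hits", "n_recognized") %in% names(counts)))
  per_pattern <- counts |>
    as_tibble() |>
    distinct(.data$pattern, .data$n_hits, .data$n_recognized)
  tibble(
    n_hits_total = sum(per_pattern$n_hits),
    n_recognized_total = sum(per_pattern$n_recognized),
    pooled_pct = 100 * sum(per_pattern$n_recognized) / sum(per_pattern$n_hits)
  )
}

#' Bundled example of TF target counts
#'
#' A small worked-example table shipped with the package: hit counts of the
#' three search modes for a yeast cell-cycle query, cross-referenced against
#' curated target annotations of the cell-cycle transcription factors TEC1p
#' and STE12p (alone and jointly).
#'
#' @return A tibble with columns `pattern`, `n_hits`, `n_recognized`, `tf`,
#'   `n_regulated`, suitable for [tf_regulation_ratios()] and
#'   [pooled_regulation_ratio()].
#' @export
tf_target_counts_example <- function() {
  path <- system.file("extdata", "tf_target_counts.tsv", package = "curvesearch",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
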