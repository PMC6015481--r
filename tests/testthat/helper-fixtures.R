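# Small deterministic fixtures built in code.

expr_tibble <- function(values, gene_ids = NULL) {
  m <- matrix(unlist(values, use.names = FALSE), nrow = length(values), byrow = TRUE)
  ids <- gene_ids %||% names(values) %||% paste0("g", seq_len(nrow(m)))
  blank <- is.na(ids) | !nzchar(ids)
  ids[blank] <- paste0("g", seq_len(nrow(m)))[blank]
  colnames(m) <- paste0("t", seq_len(ncol(m)))
  tibble::as_tibble(m) |> dplyr::mutate(gene_id = ids, .before = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A 5-gene, 6-timepoint matrix with recognisable shapes.
tiny_matrix <- function() {
  expr_tibble(list(
    up     = c(0, 1, 2, 3, 4, 5),
    down   = c(5, 4, 3, 2, 1, 0),
    wave   = c(0, 1, 0, -1, 0, 1),
    up2    = c(2, 4, 6, 8, 10, 12),   # affine copy of `up`
    bumpy  = c(1, 3, 0, 4, 2, 5)
  ))
}

random_matrix <- function(n_genes, t_n, seed) {
  set.seed(seed)
  expr_tibble(lapply(seq_len(n_genes), function(i) rnorm(t_n)),
              gene_ids = sprintf("rg%03d", seq_len(n_genes)))
}
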