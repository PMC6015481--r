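# Independent brute-force reimplementation of the three search modes: naive
# per-gene loops on stats::cor / stats::cor.test, no vectorisation, no shared
# code with the package internals. Used as the ground-truth oracle.

oracle_rank <- function(df) {
  df[order(-abs(df$r), df$p, df$gene_id), , drop = FALSE]
}

oracle_zero_lag <- function(data, q, cutoff, sign = +1) {
  rows <- list()
  for (i in seq_len(nrow(data))) {
    x <- as.numeric(data[i, -1])
    if (sd(x) == 0) next
    r <- stats::cor(x, q)
    ok <- if (sign > 0) r >= cutoff else r <= -cutoff
    if (ok) {
      p <- stats::cor.test(x, q)$p.value
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = data$gene_id[i], r = r, p = p, lag = 0L,
        n_used = length(q), stringsAsFactors = FALSE
      )
    }
  }
  oracle_rank(do.call(rbind, c(rows, list(data.frame(
    gene_id = character(), r = double(), p = double(),
    lag = integer(), n_used = integer()
  )))))
}

oracle_brush <- function(data, q, cutoff) oracle_zero_lag(data, q, cutoff, +1)
oracle_contrast <- function(data, q, cutoff) oracle_zero_lag(data, q, cutoff, -1)

oracle_shift <- function(data, q, cutoff, max_lag) {
  t_n <- length(q)
  rows <- list()
  for (i in seq_len(nrow(data))) {
    x <- as.numeric(data[i, -1])
    best <- NULL
    for (s in setdiff(seq(-max_lag, max_lag), 0)) {
      k <- abs(s)
      if (s > 0) {
        xi <- x[(k + 1):t_n]; qi <- q[1:(t_n - k)]
      } else {
        xi <- x[1:(t_n - k)]; qi <- q[(k + 1):t_n]
      }
      if (sd(xi) == 0 || sd(qi) == 0) next
      r <- stats::cor(xi, qi)
      better <- is.null(best) ||
        r > best$r ||
        (r == best$r &&
           (abs(s) < abs(best$lag) ||
              (abs(s) == abs(best$lag) && s > best$lag)))
      if (better) best <- list(r = r, lag = s, n = t_n - k, x = xi, q = qi)
    }
    if (!is.null(best) && best$r >= cutoff) {
      p <- stats::cor.test(best$x, best$q)$p.value
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = data$gene_id[i], r = best$r, p = p,
        lag = best$lag, n_used = best$n, stringsAsFactors = FALSE
      )
    }
  }
  oracle_rank(do.call(rbind, c(rows, list(data.frame(
    gene_id = character(), r = double(), p = double(),
    lag = integer(), n_used = integer()
  )))))
}

expect_matches_oracle <- function(result, oracle, tol = 1e-12) {
  expect_identical(result$gene_id, oracle$gene_id)
  expect_identical(as.integer(result$lag), as.integer(oracle$lag))
  expect_identical(as.integer(result$n_used), as.integer(oracle$n_used))
  if (nrow(result) > 0) {
    expect_lt(max(abs(result$r - oracle$r)), tol)
    expect_lt(max(abs(result$p - oracle$p)), 1e-9)
  }
}
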