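test_that("pearson_r matches hand-computed and reference values", {
  x <- c(1, 5, 2, 8, 3)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 1)), 0)
  for (seed in 1:5) {
    set.seed(seed)
    a <- rnorm(20); b <- rnorm(20)
    expect_equal(pearson_r(a, b), stats::cor(a, b), tolerance = 1e-14)
  }
})

test_that("pearson_r rejects undefined cases rather than returning 0", {
  expect_error(pearson_r(rep(1, 5), 1:5),
               class = "curvesearch_undefined_correlation_error")
  expect_error(pearson_r(1:4, 1:5), class = "curvesearch_validation_error")
  expect_error(pearson_r(1:2, 2:1),
               class = "curvesearch_insufficient_points_error")
})

test_that("pearson_pvalue is the exact two-sided t-test on r", {
  expect_equal(pearson_pvalue(0, 10), 1)
  # closed form for df = 2: F(t) = 1/2 + t / (2 sqrt(t^2 + 2))
  expect_equal(pearson_pvalue(0.8, 4), 0.2, tolerance = 1e-12)
  expect_equal(pearson_pvalue(1, 7), 0)
  expect_equal(pearson_pvalue(-1, 7), 0)
  for (seed in 1:5) {
    set.seed(seed)
    a <- rnorm(12); b <- rnorm(12)
    ct <- stats::cor.test(a, b)
    expect_equal(pearson_pvalue(unname(ct$estimate), 12), ct$p.value,
                 tolerance = 1e-12)
  }
  expect_error(pearson_pvalue(0.5, 2),
               class = "curvesearch_insufficient_points_error")
})

test_that("pearson_pvalue decreases in |r| at fixed n and in n at fixed |r|", {
  rs <- seq(0.05, 0.95, by = 0.05)
  p_by_r <- pearson_pvalue(rs, 10)
  expect_true(all(diff(p_by_r) < 0))
  ns <- seq(4, 30, by = 2)
  p_by_n <- vapply(ns, function(n) pearson_pvalue(0.5, n), 0)
  expect_true(all(diff(p_by_n) < 0))
})

test_that("a gene queried against itself is the top brush hit with r = 1", {
  m <- random_matrix(30, 10, seed = 3)
  q <- gene_as_query(m, "rg007")
  res <- brush_search(m, q, cutoff = 0.8)
  expect_equal(res$gene_id[1], "rg007")
  expect_equal(res$r[1], 1)
  expect_equal(res$lag, rep(0L, nrow(res)))
})

test_that("cutoff 1 admits exactly the affinely identical profiles", {
  m <- tiny_matrix()
  res <- brush_search(m, gene_as_query(m, "up"), cutoff = 1)
  expect_setequal(res$gene_id, c("up", "up2"))
})

test_that("all three modes agree hit-for-hit with the brute-force oracle", {
  for (seed in 1:3) {
    m <- random_matrix(50, 12, seed = seed)
    set.seed(seed + 100)
    q <- rnorm(12)
    b <- brush_search(m, q, cutoff = 0.3)
    expect_matches_oracle(b, oracle_brush(m, q, 0.3))
    co <- contrast_search(m, q, cutoff = 0.3)
    expect_matches_oracle(co, oracle_contrast(m, q, 0.3))
    s <- shift_search(m, q, cutoff = 0.3, max_lag = 4)
    expect_matches_oracle(s, oracle_shift(m, q, 0.3, 4))
  }
})

test_that("raising the cutoff can only shrink the hit set, in every mode", {
  m <- random_matrix(80, 12, seed = 9)
  set.seed(900)
  q <- rnorm(12)
  cuts <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  for (fn in list(
    function(c) brush_search(m, q, cutoff = c)$gene_id,
    function(c) contrast_search(m, q, cutoff = c)$gene_id,
    function(c) shift_search(m, q, cutoff = c, max_lag = 4)$gene_id
  )) {
    sets <- lapply(cuts, fn)
    for (i in seq_along(cuts)[-1]) {
      expect_true(all(sets[[i]] %in% sets[[i - 1]]))
    }
  }
})

test_that("contrast search equals brush search on the negated query", {
  m <- random_matrix(60, 12, seed = 5)
  set.seed(500)
  q <- rnorm(12)
  co <- contrast_search(m, q, cutoff = 0.4)
  b_neg <- brush_search(m, -q, cutoff = 0.4)
  expect_identical(co$gene_id, b_neg$gene_id)
  expect_equal(co$r, -b_neg$r, tolerance = 1e-14)
  expect_equal(co$p, b_neg$p, tolerance = 1e-14)
})

test_that("a gene never appears in its own contrast results for positive cutoffs", {
  m <- random_matrix(20, 10, seed = 7)
  for (id in m$gene_id[1:5]) {
    co <- contrast_search(m, gene_as_query(m, id), cutoff = 0.3)
    expect_false(id %in% co$gene_id)
  }
})

test_that("results are invariant to positive affine maps of the query and swap under negation", {
  m <- random_matrix(60, 12, seed = 13)
  set.seed(1300)
  q <- rnorm(12)
  for (mode in list(brush_search, contrast_search,
                    function(d, qq, cutoff) shift_search(d, qq, cutoff, max_lag = 4))) {
    base <- mode(m, q, cutoff = 0.4)
    scaled <- mode(m, 2.5 * q + 7, cutoff = 0.4)
    expect_identical(scaled$gene_id, base$gene_id)
    expect_equal(scaled$r, base$r, tolerance = 1e-12)
  }
  b <- brush_search(m, q, cutoff = 0.4)
  co_neg <- contrast_search(m, -3 * q + 1, cutoff = 0.4)
  expect_identical(co_neg$gene_id, b$gene_id)
  expect_equal(co_neg$r, -b$r, tolerance = 1e-12)
})

test_that("a gene delayed by one step is found at lag +1 on the overlap", {
  set.seed(21)
  q <- rnorm(12)
  delayed <- c(rnorm(1), q[1:11])  # tail of the query, one step later
  m <- expr_tibble(c(list(delayed = delayed),
                     lapply(1:20, function(i) rnorm(12))))
  res <- shift_search(m, q, cutoff = 0.9, max_lag = 3)
  expect_true("delayed" %in% res$gene_id)
  hit <- res[res$gene_id == "delayed", ]
  expect_equal(hit$lag, 1L)
  expect_equal(hit$n_used, 11L)
  expect_gt(hit$r, 0.999)
})

test_that("shift search scans exactly the nonzero lags up to max_lag", {
  m <- random_matrix(10, 18, seed = 2)
  set.seed(200)
  q <- rnorm(18)
  prof <- shift_lag_profile(m, q, max_lag = 6)
  expect_setequal(unique(prof$lag), setdiff(-6:6, 0))
  expect_equal(unique(prof$n_used[prof$lag == 6]), 12L)
  res <- shift_search(m, q, cutoff = 0, max_lag = 6)
  expect_false(any(res$lag == 0))
  expect_true(all(abs(res$lag) <= 6))
})

test_that("lag ranges leaving too little overlap are rejected", {
  m <- random_matrix(5, 8, seed = 1)
  set.seed(10)
  q <- rnorm(8)
  expect_error(shift_search(m, q, max_lag = 6),
               class = "curvesearch_invalid_lag_range_error")
  expect_silent(shift_search(m, q, max_lag = 5))
})

test_that("hits are ranked by |r|, then p, then gene ID, and pass the cutoff rule", {
  m <- random_matrix(100, 12, seed = 31)
  set.seed(3100)
  q <- rnorm(12)
  for (res in list(brush_search(m, q, cutoff = 0.2),
                   contrast_search(m, q, cutoff = 0.2),
                   shift_search(m, q, cutoff = 0.2, max_lag = 4))) {
    key <- order(-abs(res$r), res$p, res$gene_id)
    expect_equal(key, seq_len(nrow(res)))
  }
  expect_true(all(brush_search(m, q, cutoff = 0.2)$r >= 0.2))
  expect_true(all(contrast_search(m, q, cutoff = 0.2)$r <= -0.2))
})

test_that("the BH flag appends adjusted p-values without changing the hits", {
  m <- random_matrix(50, 12, seed = 17)
  set.seed(1700)
  q <- rnorm(12)
  raw <- brush_search(m, q, cutoff = 0.3)
  bh <- brush_search(m, q, cutoff = 0.3, p_adjust = "BH")
  expect_identical(bh$gene_id, raw$gene_id)
  expect_equal(bh$p_adj, stats::p.adjust(raw$p, "BH"))
})

test_that("search_genes runs the requested modes with shared parameters", {
  m <- random_matrix(40, 12, seed = 19)
  set.seed(1900)
  q <- rnorm(12)
  all3 <- search_genes(m, q, cutoff = 0.4, max_lag = 4)
  expect_named(all3, c("brush", "contrast", "shift"))
  expect_equal(tidy(all3$brush), tidy(brush_search(m, q, cutoff = 0.4)))
})
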