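# Shared fixture: a matrix engineered so brush/contrast/shift hit known genes.
view_fixture <- function() {
  set.seed(77)
  q <- as.numeric(scale(rnorm(12)))
  genes <- list(
    simA = q + rnorm(12, sd = 0.02),
    simB = q + rnorm(12, sd = 0.05),
    opp1 = -q + rnorm(12, sd = 0.02),
    del1 = c(rnorm(1, sd = 0.1), q[1:11]) + rnorm(12, sd = 0.02),
    adv2 = c(q[3:12], rnorm(2, sd = 0.1)) + rnorm(12, sd = 0.02)
  )
  bg <- lapply(1:30, function(i) rnorm(12))
  names(bg) <- sprintf("bg%02d", 1:30)
  list(m = expr_tibble(c(genes, bg)), q = q)
}

run_three <- function(m, q, cutoff = 0.9) {
  list(
    brush = brush_search(m, q, cutoff = cutoff),
    contrast = contrast_search(m, q, cutoff = cutoff),
    shift = shift_search(m, q, cutoff = cutoff, max_lag = 3)
  )
}

test_that("the heat map keeps the 500 best-ranked genes of a larger result", {
  sim <- generate_matrix(
    t_n = 10,
    families = list(synthetic_family("fam", "ramp", n_members = 600, sigma = 0.2)),
    n_background = 0, seed = 12
  )
  res <- brush_search(sim$expr, predefined_pattern("increasing", 10), cutoff = 0)
  expect_gt(nrow(res), 500)
  hm <- build_heatmap(res, sim$expr)
  expect_length(hm$row_ids, 500L)
  expect_identical(hm$row_ids, res$gene_id[1:500])
})

test_that("small results keep all rows in ranking order and match the CSV order", {
  fx <- view_fixture()
  res <- brush_search(fx$m, fx$q, cutoff = 0.9)
  hm <- build_heatmap(res, fx$m, cap = 500)
  expect_identical(hm$row_ids, res$gene_id)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_result_csv(res, fx$m, tf)
  csv_order <- readr::read_csv(tf, show_col_types = FALSE)$gene_id
  expect_identical(hm$row_ids, csv_order)
})

test_that("per-row scalings produce finite display values; plots build", {
  fx <- view_fixture()
  res <- brush_search(fx$m, fx$q, cutoff = 0.9)
  for (scaling in c("zscore", "minmax", "raw")) {
    hm <- build_heatmap(res, fx$m, scaling = scaling)
    expect_true(all(is.finite(hm$values$value)))
    expect_s3_class(autoplot(hm), "ggplot")
  }
  hm <- build_heatmap(res, fx$m, scaling = "minmax")
  rng <- range(hm$values$value)
  expect_gte(rng[1], 0)
  expect_lte(rng[2], 1)
})

test_that("an empty result yields an empty view with a warning and no image file", {
  fx <- view_fixture()
  res <- brush_search(fx$m, fx$q, cutoff = 1)
  res <- res[0, ]
  expect_warning(hm <- build_heatmap(res, fx$m), "empty")
  expect_length(hm$row_ids, 0)
  path <- withr::local_tempfile(fileext = ".png")
  expect_warning(out <- export_heatmap(hm, path), "empty")
  expect_null(out)
  expect_false(file.exists(path))
})

test_that("heat-map export writes an image for non-empty views", {
  fx <- view_fixture()
  res <- brush_search(fx$m, fx$q, cutoff = 0.9)
  hm <- build_heatmap(res, fx$m)
  path <- withr::local_tempfile(fileext = ".png")
  export_heatmap(hm, path)
  expect_true(file.size(path) > 0)
})

test_that("the network maps modes and lag signs onto the four categories", {
  fx <- view_fixture()
  rs <- run_three(fx$m, fx$q)
  net <- build_network(rs$brush, rs$contrast, rs$shift, center_label = "query")
  expect_equal(nrow(net$nodes), 1L + nrow(rs$brush) + nrow(rs$contrast) + nrow(rs$shift))
  cats <- table(net$nodes$category)
  expect_equal(unname(cats["center"]), 1L)
  expect_true(all(c("simA", "simB") %in%
                    net$nodes$id[net$nodes$category == "similar"]))
  expect_true("opp1" %in% net$nodes$id[net$nodes$category == "opposite"])
  expect_equal(net$nodes$category[net$nodes$id == "del1"], "delayed")
  expect_equal(net$nodes$category[net$nodes$id == "adv2"], "advanced")
  # Colour semantics: red similar, purple opposite, yellow delayed, blue advanced
  cols <- setNames(net$nodes$color, net$nodes$category)
  expect_equal(unname(cols["similar"]), "#d62728")
  expect_equal(unname(cols["opposite"]), "#9467bd")
  expect_equal(unname(cols["delayed"]), "#e6b800")
  expect_equal(unname(cols["advanced"]), "#1f77b4")
})

test_that("the network is always a star with exhaustive, disjoint categories", {
  fx <- view_fixture()
  rs <- run_three(fx$m, fx$q, cutoff = 0.6)
  net <- build_network(rs$brush, rs$contrast, rs$shift, center_label = "query")
  expect_equal(nrow(net$edges), nrow(net$nodes) - 1L)
  expect_true(all(net$edges$source == "query"))
  non_center <- net$nodes[net$nodes$category != "center", ]
  expect_true(all(non_center$category %in%
                    c("similar", "opposite", "delayed", "advanced")))
  expect_false(anyDuplicated(net$nodes$id) > 0)
})

test_that("node count equals 1 + the deduplicated union of hits (brute force)", {
  fx <- view_fixture()
  rs <- run_three(fx$m, fx$q, cutoff = 0.5)
  net <- build_network(rs$brush, rs$contrast, rs$shift, center_label = "hub")
  union_ids <- setdiff(
    unique(c(rs$brush$gene_id, rs$contrast$gene_id, rs$shift$gene_id)),
    "hub"
  )
  expect_equal(nrow(net$nodes), 1L + length(union_ids))
  # dedup keeps the higher-|r| mode per gene
  for (id in union_ids) {
    rows <- rbind(
      if (id %in% rs$brush$gene_id)
        data.frame(cat = "similar", r = rs$brush$r[rs$brush$gene_id == id]),
      if (id %in% rs$contrast$gene_id)
        data.frame(cat = "opposite", r = rs$contrast$r[rs$contrast$gene_id == id]),
      if (id %in% rs$shift$gene_id)
        data.frame(cat = ifelse(rs$shift$lag[rs$shift$gene_id == id] > 0,
                                "delayed", "advanced"),
                   r = rs$shift$r[rs$shift$gene_id == id])
    )
    expect_equal(net$nodes$r[net$nodes$id == id], rows$r[which.max(abs(rows$r))])
  }
})

test_that("all-empty results give a single centre node and no edges", {
  fx <- view_fixture()
  rs <- run_three(fx$m, fx$q, cutoff = 1)
  empty <- lapply(rs, function(r) {
    out <- r[r$r > 2, ]
    out
  })
  net <- build_network(empty$brush, empty$contrast, empty$shift,
                       center_label = "center")
  expect_equal(nrow(net$nodes), 1L)
  expect_equal(nrow(net$edges), 0L)
})

test_that("a gene query centres the network on that gene, excluded from hits", {
  m <- random_matrix(40, 12, seed = 44)
  q <- gene_as_query(m, "rg010")
  rs <- list(
    brush = brush_search(m, q, cutoff = 0.7),
    contrast = contrast_search(m, q, cutoff = 0.7),
    shift = shift_search(m, q, cutoff = 0.7, max_lag = 3)
  )
  net <- build_network(rs$brush, rs$contrast, rs$shift)
  expect_equal(net$center, "rg010")
  expect_false("rg010" %in% net$edges$target)
})

test_that("mismatched queries across results are rejected", {
  m <- random_matrix(20, 12, seed = 45)
  set.seed(45)
  q1 <- rnorm(12); q2 <- rnorm(12)
  b <- brush_search(m, q1, cutoff = 0.5)
  co <- contrast_search(m, q2, cutoff = 0.5)
  s <- shift_search(m, q1, cutoff = 0.5, max_lag = 3)
  expect_error(build_network(b, co, s), class = "curvesearch_validation_error")
})

test_that("network exports are readable back (Cytoscape JSON, GraphML, TSV)", {
  fx <- view_fixture()
  rs <- run_three(fx$m, fx$q)
  net <- build_network(rs$brush, rs$contrast, rs$shift, center_label = "query")

  jf <- withr::local_tempfile(fileext = ".json")
  export_network_json(net, jf)
  parsed <- jsonlite::fromJSON(jf, simplifyVector = FALSE)
  expect_length(parsed$elements$nodes, nrow(net$nodes))
  expect_length(parsed$elements$edges, nrow(net$edges))
  first_edge <- parsed$elements$edges[[1]]$data
  expect_true(all(c("id", "source", "target", "weight", "category") %in%
                    names(first_edge)))

  gf <- withr::local_tempfile(fileext = ".graphml")
  export_network_graphml(net, gf)
  g <- igraph::read_graph(gf, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))

  nf <- withr::local_tempfile(fileext = ".tsv")
  ef <- withr::local_tempfile(fileext = ".tsv")
  export_network_tables(net, nf, ef)
  expect_equal(nrow(readr::read_tsv(nf, show_col_types = FALSE)), nrow(net$nodes))
  expect_s3_class(autoplot(net), "ggplot")
})
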