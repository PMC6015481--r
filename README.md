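# curvesearch

Search time-series gene expression data with a hand-drawn curve.

Biologists often know the temporal expression pattern they are looking for —
"rises through the cell cycle", "peaks every 24 hours" — but extracting the
genes that follow it from a matrix of thousands of profiles usually means
driving a clustering algorithm with abstract parameters, and hoping the
pattern of interest lands in its own cluster. `curvesearch` inverts the
workflow: you supply the anticipated curve (a sketched polyline, a predefined
pattern, or an existing gene's profile) and the package retrieves every gene
that matches it, in three modes:

- **brush** — co-expressed genes, positively correlated with the query at the
  same time points;
- **contrast** — genes with the opposite (inverted) pattern, e.g. targets of a
  repressor;
- **shift** — genes with the same shape displaced by an integer number of
  sampling intervals (time-delayed or time-advanced), e.g. downstream or
  upstream genes in a cascade.

## The statistic

The query polyline is resampled by piecewise-linear interpolation onto the
experiment's *T* time points, giving a query vector *q*. Each gene profile
*x* is scored with the Pearson correlation coefficient

    r = Σ (x_i − x̄)(q_i − q̄) / sqrt( Σ (x_i − x̄)² · Σ (q_i − q̄)² )

and a two-sided p-value from the exact test t = r·√((n−2)/(1−r²)) with n−2
degrees of freedom. Brush reports genes with `r ≥ c`, contrast those with
`r ≤ −c`, where the cutoff `c` (default 0.8) plays the role of a slider: raise
it if too many genes come back. Shift mode scans every nonzero lag `s` with
`|s| ≤ 6` (configurable), correlating the overlapping `T − |s|` points where
the gene runs `s` steps later than the query — positive lags are time-delayed
genes, negative lags time-advanced — and reports each gene at its
best-correlated lag. K-means profile clustering (`kmeans_profiles()`) is
included as the conventional comparison baseline, and a synthetic-data module
plants co-expressed, inverted and lagged families with known truth so that
every claim the package makes about recovery is testable.

Results come back as tibbles and flow into three views: an exportable ranked
CSV table, a heat map capped at 500 rows, and a query-centred star network
whose node colours follow the four hit categories (red similar, purple
opposite, yellow delayed, blue advanced), exportable as Cytoscape JSON and
GraphML.

## Worked example

```r
library(curvesearch)

# a yeast-layout benchmark: 18 time points, planted similar / inverted /
# lagged sine families (20 genes each) in 500 background genes
sim   <- yeast_preset(n_per_family = 20, n_background = 500, seed = 1)
expr  <- qc_filter(sim$expr)
qc_report(expr)
#> QC report: 560 genes in, 560 retained (0 dropped: 0 missing, 0 low entropy)

query <- predefined_pattern("circadian", n_timepoints = 18)  # 24-h sine
hits  <- search_genes(expr, query, cutoff = 0.9)

glance(hits$brush)
#> # A tibble: 1 × 6
#>   mode  cutoff n_hits max_abs_r    min_p n_skipped
#>   <chr>  <dbl>  <int>     <dbl>    <dbl>     <int>
#> 1 brush    0.9     20     0.997 1.25e-19         0

head(tidy(hits$shift), 4)
#> # A tibble: 4 × 5
#>   gene_id          r        p   lag n_used
#>   <chr>        <dbl>    <dbl> <int>  <int>
#> 1 similar_007  0.998 2.96e-13     6     12
#> 2 lagged_008   0.998 5.17e-18     2     16
#> 3 inverted_001 0.998 1.97e-16     3     15
#> 4 similar_003  0.997 9.41e-13    -6     12
```

The brush search recovers exactly the 20 planted co-expressed genes
(`n_hits = 20`), the strongest at r = 0.997 with p ≈ 1e−19 over the 18
points. The shift table shows `lagged_008` found at its true lag +2,
correlated 0.998 over the 16 overlapping points — and also illustrates a
property of periodic queries: a 24-h sine matches itself again at a
full-period lag (±6 samples), so zero-lag family members reappear at |lag| 6,
and an anti-phase (inverted) gene matches at a half-period shift. For
periodic patterns the lag is identifiable only up to the period; the vignette
discusses this.

```r
net <- build_network(hits$brush, hits$contrast, hits$shift, center_label = "query")
net
#> <network_view: centre 'query', 61 nodes, 60 edges>
autoplot(net)                      # star graph, Fig-style category colours
export_network_json(net, "network.json")
```

A thin command-line wrapper over these functions ships at
`inst/cli/curvesearch.R` (subcommands `search`, `cluster`, `simulate`).

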