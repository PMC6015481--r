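---
title: "Methods: curve-driven search of time-course expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curve-driven search of time-course expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvesearch)
```

## The model

`curvesearch` treats pattern retrieval as a correlation problem. A query
vector $q \in \mathbb{R}^T$, aligned with the experiment's $T$ ordered time
points, is compared with every gene profile $x$ by the Pearson
product-moment correlation

$$ r(x, q) = \frac{\sum_i (x_i - \bar x)(q_i - \bar q)}
                  {\sqrt{\sum_i (x_i - \bar x)^2 \sum_i (q_i - \bar q)^2}}. $$

Pearson $r$ measures *shape* agreement up to a positive affine map: scaling
or shifting either profile leaves it unchanged, and negating one profile
negates it. This is exactly the invariance a sketch-driven search needs — the
absolute scale of a hand-drawn curve is meaningless — and it is why the
package applies no log transform or row normalisation before scoring: they
would not change a single $r$.

The three modes are defined on top of this single statistic:

* **brush** reports genes with $r \ge c$ at zero lag;
* **contrast** reports genes with $r \le -c$ at zero lag, and is exactly
  equivalent to a brush search with the negated query (a tested identity);
* **shift** scans every integer lag $s$ with $1 \le |s| \le L$, correlating
  the $T - |s|$ overlapping points where the gene runs $s$ steps later in
  time than the query. Positive $s$ means the gene *follows* the query
  (time-delayed, a candidate downstream gene); negative $s$ that it
  *precedes* it (time-advanced, candidate upstream). The series is truncated
  to the overlap, as in standard cross-correlation — nothing is padded or
  wrapped, because a measured time course simply ends.

Significance is the exact test for a correlation under bivariate normality:
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n - 2$ degrees of freedom, two-sided, where
$n$ is the number of point pairs actually correlated ($T$ at zero lag,
$T - |s|$ for a shifted hit, so shifted hits are penalised for their shorter
overlap). Profiles are short, so these p-values are best read as a ranking
aid rather than literal error probabilities; hits are filtered on $r$ only
and p is reported alongside. An optional Benjamini–Hochberg column
(`p_adjust = "BH"`) is available but off by default, since the raw per-gene
values are what the result table conventionally shows.

## From sketch to query vector

A drawn curve arrives as an ordered polyline of $(x, y)$ points in arbitrary
canvas units. `resample_curve()` sorts the points by $x$, averages points
that share an $x$ (a deterministic, order-independent rule for the
backtracking strokes a mouse produces), then evaluates the piecewise-linear
interpolant at $T$ positions equally spaced over the drawn $x$-range.
Piecewise-linear interpolation was chosen over smoothing or regression fits
as the most literal reading of "connect the sketch and sample it"; it adds no
assumptions and keeps the resampling exactly invariant to affine rescaling of
the canvas axes (a tested property — screen geometry must not matter).

Degenerate sketches fail loudly: all points at one $x$, or a resampled vector
with zero variance, raise typed errors rather than propagating an undefined
correlation.

The predefined patterns are an increasing ramp, its reversal, a triangular
pulse, and a sine with a configurable period expressed in *samples*. The
circadian default is 6 samples per period, i.e. a 24-h rhythm at 4-h
sampling, so a 12-point 48-h course contains exactly two cycles.

## Quality control

Two filters run before any search. Missing values: by default any gene with
a missing entry is dropped; an opt-in interpolation policy fills *interior*
gaps covering at most 20% of the time points by linear interpolation, and
still drops genes with leading/trailing gaps (extrapolating the ends of a
time course would invent data). Low-information profiles: each row's Shannon
entropy is computed over 10 equal-width bins spanning that row's own range,
and rows below 0.1 bits are removed. Constant rows have entropy 0 and always
fail; a profile with a single outlying point among eleven identical values
sits at about 0.41 bits and survives the default threshold. The rationale is
deliberately conservative: the filter exists to remove rows for which Pearson
correlation is undefined (zero variance) or dominated by quantisation, not to
second-guess the biology. Both the bin count and the threshold are exposed as
arguments, and the QC report accounts for every input gene by ID and reason.

## Choosing the best lag

Shift mode keeps one row per gene — the lag table stays one-row-per-gene like
the other modes, with the full lag profile available via
`shift_lag_profile()` or `all_lags = TRUE`. The retained lag is the one
*maximising the signed correlation* $r$; ties prefer the smaller $|s|$, then
the delayed ($+$) over the advanced ($-$) direction, making output
deterministic. Maximising signed $r$ rather than $|r|$ is a deliberate
choice: the mode's purpose is to find the *same* shape displaced in time, and
for periodic profiles an anti-phase lag can tie a full-period lag in $|r|$
while meaning the opposite pattern. Anti-correlated matches belong to
contrast mode, where they are reported explicitly.

Two consequences of periodic queries are worth keeping in mind when reading
shift results: the lag of a periodic pattern is identifiable only up to its
period (a gene in phase with a 6-sample-period sine also matches at
$s = \pm 6$), and a half-period shift of a sine is indistinguishable from
inversion. Neither is an artifact of the implementation; both follow from
the mathematics of the patterns themselves.

Genes whose overlap window is constant at some lag have no defined
correlation there; those windows are skipped and counted in the result's
diagnostics rather than silently scored 0.

## Result views

Hits are ranked by $|r|$ descending, ties by p ascending, then gene ID. The
CSV export, the heat map and the network all consume this one ranking, so the
views never disagree about order. The heat map takes at most 500 rows (the
top-ranked prefix) — a display cap, not a statistical one — and scales each
row for display (z-score by default, with a diverging red-high/blue-low
palette; min–max and raw scaling are options). The network is a star: the
centre is the searched gene, or the top brush hit when the query was drawn,
and each hit is a leaf coloured by category (red similar, purple opposite,
yellow delayed, blue advanced), with edge weight $r$. A gene found by
several modes keeps the mode with larger $|r|$ (ties: brush, then contrast,
then shift), so the category partition is disjoint and exhaustive. Exports
are Cytoscape-compatible JSON, GraphML (via igraph) and plain TSV tables.

## K-means comparison mode

`kmeans_profiles()` is the baseline the search modes are meant to complement.
Rows are z-scored per gene by default so Euclidean distance becomes a
monotone function of correlation distance — i.e. the clustering groups by
shape, like the searches do; the flag `standardize = FALSE` restores
magnitude-sensitive clustering. Initialisation is k-means++ under a
caller-supplied seed with 5 restarts (best within-cluster sum of squares
kept), followed by Lloyd iterations capped at 300. Everything downstream of
the seed is deterministic, a tested guarantee. The package does not choose
$k$ for the user: the point of the comparison mode is precisely that a
user-anticipated pattern need not correspond to any cluster at any $k$ — a
family of time-shifted copies of one pattern is scattered across clusters
(the lag-ladder demonstration in the test suite), while a single shift
search recovers it.

## The synthetic-data generator

`generate_matrix()` plants gene families with known truth: each member is a
base pattern (ramp, sine, pulse, random walk, or a user-supplied profile)
shifted by an integer lag, optionally negated, plus Gaussian noise with
standard deviation expressed as a fraction of the base pattern's range
(default 0.05, i.e. 5% of signal amplitude — tight co-expression, appropriate
for testing recovery of clearly planted structure). The overhang a shift
leaves at the series boundary is filled with fresh noise, not wrapped: a
truncated time course is what real experiments produce, and wrapping would
make lagged copies of periodic patterns trivially perfect. Background genes
are i.i.d. standard Gaussian. The `yeast_preset()` mimics the shape of a
classic cell-cycle matrix (6187 genes × 18 time points by default); the
`circadian_preset()` produces the 12-point, 48-h, 4-h-interval layout, with
rhythmic genes as 24-h sines at integer phase offsets 0–5 recorded in the
truth table. Circadian phases are applied analytically (the sine is evaluated
at the shifted phase over the whole course) rather than by truncation, since
a rhythm, unlike a transient pattern, is defined at every time point; a
phase-3 gene is therefore exactly anti-phase, and a phase-$s$ gene exactly a
$s$-sample shift of phase 0.

What the generator does *not* emulate: intensity-dependent variance, probe
effects or dye bias of real microarrays, count noise of RNA-seq, correlated
background genes, or missingness mechanisms. Recovery rates on this
synthetic structure therefore demonstrate the correctness of the machinery —
that each mode finds exactly the structure it is defined to find at the
stated noise level — not expected sensitivity on any particular platform's
data.

## Numerical choices and problem sizes

Correlations are computed by a vectorised centred-sums kernel and clamped to
$[-1, 1]$ against floating-point overshoot; $|r| = 1$ maps to $p = 0$. The
test suite checks this kernel hit-for-hit (within $10^{-12}$ on $r$) against
an independent naive-loop implementation built on `stats::cor` /
`stats::cor.test`, on matrices of up to 50 genes, and property-style suites
(cutoff monotonicity, contrast/brush negation symmetry, affine invariance,
seed determinism) run on generated cases under fixed seeds. Recovery
benchmarks use 20-member families in 400 background genes over 20 seeds —
large enough for stable rates, small enough that the whole suite runs in
well under a minute of compute. The minimum series length is $T = 3$, the
smallest $n$ for which the correlation test is defined; shift searches
additionally require $T - L \ge 3$ overlapping points.

## Known limitations

Pearson correlation sees only linear association between the aligned values:
monotone-but-curved agreement is down-weighted, single outliers can inflate
or deflate $r$ on short series, and a pattern present at a non-integer lag
falls between the scanned shifts. Nonlinear or local similarity measures
(Spearman, dynamic time warping, local-alignment scores) are out of scope by
design — the package's contract is the transparent, affine-invariant,
field-standard statistic, with its limitations stated rather than patched.
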