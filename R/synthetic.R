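# Base pattern library shared by the generator and the predefined queries.
base_pattern_values <- function(pattern, t_n, period_points = 6L) {
  t_idx <- seq_len(t_n) - 1L
  switch(pattern,
    ramp = t_idx / (t_n - 1L),
    sine = sin(2 * pi * t_idx / period_points),
    pulse = {
      mid <- (t_n - 1L) / 2
      1 - abs(t_idx - mid) / mid
    },
    random_walk = cumsum(rnorm(t_n)),
    cs_abort(sprintf("unknown base pattern '%s'", pattern),
             class = "curvesearch_validation_error")
  )
}

#' Describe one planted gene family
#'
#' A family is a set of noisy copies of one base pattern, each optionally
#' shifted in time and/or inverted. Noise is parameterised as a fraction of
#' the base pattern's range so that `sigma` is comparable across patterns.
#'
#' @param name Family label used in the truth table.
#' @param pattern `"ramp"`, `"sine"`, `"pulse"` or `"random_walk"`, or a
#'   numeric vector giving the base profile directly.
#' @param n_members Number of genes in the family.
#' @param sigma Noise standard deviation as a fraction of the base pattern's
#'   range (default 0.05).
#' @param lags Integer lag per member (recycled); positive = delayed.
#' @param inverted Logical per member (recycled); `TRUE` negates the profile.
#' @param period_points Samples per period for the `"sine"` pattern.
#' @return A `synthetic_family` specification list.
#' @export
synthetic_family <- function(name, pattern = "ramp", n_members = 20L,
                             sigma = 0.05, lags = 0L, inverted = FALSE,
                             period_points = 6L) {
  stopifnot(sigma >= 0, n_members >= 0)
  structure(
    list(name = name, pattern = pattern, n_members = as.integer(n_members),
         sigma = sigma, lags = rep_len(as.integer(lags), n_members),
         inverted = rep_len(inverted, n_members),
         period_points = as.integer(period_points)),
    class = "synthetic_family"
  )
}

#' Generate a synthetic time-course expression matrix with known truth
#'
#' Emulates the statistical structure that curve searches assume in real
#' time-course data: families of co-expressed genes (noisy copies of a base
#' pattern), inverted families, and time-shifted families, embedded in a
#' background of i.i.d. Gaussian noise genes. Each family member is its base
#' pattern shifted by its lag -- the overhang left by the shift is filled
#' with fresh noise of the same `sigma`, never wrapped, as in a truncated
#' biological time course -- negated if inverted, plus Gaussian noise with
#' standard deviation `sigma` times the base pattern's range. Deterministic
#' for a fixed seed.
#'
#' @param t_n Number of time points (>= 3). 18 matches a classic yeast
#'   cell-cycle layout; 12 a 48-h, 4-h-interval circadian layout.
#' @param families List of [synthetic_family()] specifications.
#' @param n_background Number of pure-noise genes.
#' @param seed Integer seed.
#' @return A list with `expr` (expression tibble: `gene_id` + `t1..tT`) and
#'   `truth` (tibble: `gene_id`, `family` -- `"background"` for noise genes --
#'   `lag`, `inverted`), covering every generated gene exactly once.
#' @examples
#' sim <- generate_matrix(
#'   t_n = 12,
#'   families = list(synthetic_family("wave", "sine", n_members = 5)),
#'   n_background = 20, seed = 1
#' )
#' dplyr::count(sim$truth, family)
#' @export
generate_matrix <- function(t_n = 18L, families = list(), n_background = 200L,
                            seed = 1L) {
  stopifnot(t_n >= 3, n_background >= 0)
  if (inherits(families, "synthetic_family")) families <- list(families)
  for (fam in families) {
    stopifnot(inherits(fam, "synthetic_family"))
    if (any(abs(fam$lags) > t_n - 3L)) {
      cs_abort(sprintf("family '%s' has a lag too large for %d time points",
                       fam$name, t_n),
               class = "curvesearch_validation_error")
    }
  }

  with_local_seed(seed, {
    rows <- list()
    truth <- list()
    for (fam in families) {
      base <- if (is.numeric(fam$pattern)) {
        stopifnot(length(fam$pattern) == t_n)
        as.numeric(fam$pattern)
      } else {
        base_pattern_values(fam$pattern, t_n, fam$period_points)
      }
      rng <- diff(range(base))
      noise_sd <- fam$sigma * rng
      for (i in seq_len(fam$n_members)) {
        s <- fam$lags[i]
        v <- numeric(t_n)
        if (s >= 0) {
          if (s > 0) v[seq_len(s)] <- mean(base) + rnorm(s, sd = noise_sd)
          v[(s + 1):t_n] <- base[seq_len(t_n - s)]
        } else {
          k <- -s
          v[seq_len(t_n - k)] <- base[(k + 1):t_n]
          v[(t_n - k + 1):t_n] <- mean(base) + rnorm(k, sd = noise_sd)
        }
        if (fam$inverted[i]) v <- -v
        v <- v + rnorm(t_n, sd = noise_sd)
        id <- sprintf("%s_%03d", fam$name, i)
        rows[[id]] <- v
        truth[[id]] <- tibble(gene_id = id, family = fam$name,
                              lag = s, inverted = fam$inverted[i])
      }
    }
    for (i in seq_len(n_background)) {
      id <- sprintf("bg_%04d", i)
      rows[[id]] <- rnorm(t_n)
      truth[[id]] <- tibble(gene_id = id, family = "background",
                            lag = 0L, inverted = FALSE)
    }
    if (length(rows) == 0) {
      cs_abort("nothing to generate: no families and no background",
               class = "curvesearch_validation_error")
    }
    m <- do.call(rbind, rows)
    colnames(m) <- paste0("t", seq_len(t_n))
    expr <- as_tibble(m) |> mutate(gene_id = names(rows), .before = 1)
    list(expr = expr, truth = bind_rows(truth))
  })
}

#' Yeast-layout preset: 18 time points
#'
#' A ready-made benchmark mimicking the shape of a classic yeast cell-cycle
#' expression matrix (6187 genes over 18 time points by default): one
#' co-expressed sine family, one inverted family, one lag ladder (lags 0..5 of
#' the same pattern), and Gaussian background genes filling up the total.
#'
#' @param n_per_family Members per planted family (default 20).
#' @param n_background Background gene count (default fills to 6187 total).
#' @param sigma Family noise level (fraction of signal range, default 0.05).
#' @param seed Integer seed.
#' @return As [generate_matrix()].
#' @export
yeast_preset <- function(n_per_family = 20L, n_background = NULL, sigma = 0.05,
                         seed = 1L) {
  if (is.null(n_background)) n_background <- 6187L - 3L * n_per_family
  generate_matrix(
    t_n = 18L,
    families = list(
      synthetic_family("similar", "sine", n_per_family, sigma),
      synthetic_family("inverted", "sine", n_per_family, sigma, inverted = TRUE),
      synthetic_family("lagged", "sine", n_per_family, sigma,
                       lags = rep_len(1:3, n_per_family))
    ),
    n_background = n_background, seed = seed
  )
}

#' Circadian-layout preset: 12 points spanning 48 h at 4-h intervals
#'
#' Rhythmic genes are sine waves with a 24-h period (6 samples at 4-h
#' sampling, so two full cycles over the course) at random integer phase
#' offsets drawn from 0..5 samples, recorded as lags in the truth table; a
#' phase of 3 samples (12 h) is exactly anti-phase. Because the pattern is
#' periodic and the phase shift is analytic, a phase-s gene is also an exact
#' s-sample time shift of the phase-0 gene. Background genes are i.i.d.
#' Gaussian.
#'
#' @param n_rhythmic Rhythmic gene count (default 40).
#' @param n_background Background gene count (default 1000).
#' @param sigma Noise level (fraction of signal range, default 0.05).
#' @param seed Integer seed.
#' @return As [generate_matrix()]; `truth$lag` holds each rhythmic gene's
#'   phase offset in samples, `truth$family` is `"rhythmic"` or
#'   `"background"`.
#' @export
circadian_preset <- function(n_rhythmic = 40L, n_background = 1000L,
                             sigma = 0.05, seed = 1L) {
  stopifnot(n_rhythmic >= 0, n_background >= 0)
  t_n <- 12L
  with_local_seed(seed, {
    t_idx <- seq_len(t_n) - 1L
    rows <- list()
    truth <- list()
    phases <- if (n_rhythmic > 0) sample(0:5, n_rhythmic, replace = TRUE) else integer(0)
    for (i in seq_len(n_rhythmic)) {
      base <- sin(2 * pi * (t_idx - phases[i]) / 6)
      v <- base + rnorm(t_n, sd = sigma * 2)
      id <- sprintf("rhy_%03d", i)
      rows[[id]] <- v
      truth[[id]] <- tibble(gene_id = id, family = "rhythmic",
                            lag = phases[i], inverted = FALSE)
    }
    for (i in seq_len(n_background)) {
      id <- sprintf("bg_%04d", i)
      rows[[id]] <- rnorm(t_n)
      truth[[id]] <- tibble(gene_id = id, family = "background",
                            lag = 0L, inverted = FALSE)
    }
    m <- do.call(rbind, rows)
    colnames(m) <- paste0("t", seq_len(t_n))
    expr <- as_tibble(m) |> mutate(gene_id = names(rows), .before = 1)
    list(expr = expr, truth = bind_rows(truth))
  })
}

#' Write a synthetic dataset (matrix + truth table) to disk
#'
#' @param sim A list as returned by [generate_matrix()] or a preset.
#' @param matrix_path Output TSV for the expression matrix.
#' @param truth_path Output TSV for the truth table.
#' @return Invisibly, the two paths.
#' @export
write_synthetic <- function(sim, matrix_path, truth_path) {
  stopifnot(is.list(sim), all(c("expr", "truth") %in% names(sim)))
  write_expression_tsv(sim$expr, matrix_path)
  readr::write_tsv(sim$truth, truth_path, progress = FALSE)
  invisible(c(matrix_path, truth_path))
}
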