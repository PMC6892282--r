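# Synthetic-set accuracy harness: pairs of random 64-bit integer sets with
# exact planted intersections, streamed through the same Wang-hash insert
# path as k-mers (uniform random inputs make the hash behave ideally), used
# to measure Jaccard estimation error across sketch flavours and sizes.

#' Intersection size for a target Jaccard
#'
#' Solving J = i / (size_a + size_b - i) for i gives
#' i = J (size_a + size_b) / (1 + J), rounded to the nearest integer. A
#' target is feasible only if i <= min(size_a, size_b); since a set c times
#' larger than the other forces J <= 1/c, infeasible targets raise a
#' feasibility error citing that bound.
#'
#' @param size_a,size_b set cardinalities.
#' @param target_j desired Jaccard coefficient.
#' @return integer intersection size.
#' @export
intersection_for_jaccard <- function(size_a, size_b, target_j) {
  stopifnot(size_a >= 1, size_b >= 1, target_j >= 0, target_j <= 1)
  i <- round(target_j * (size_a + size_b) / (1 + target_j))
  if (i > min(size_a, size_b)) {
    c_ratio <- max(size_a, size_b) / min(size_a, size_b)
    abort_feasibility(sprintf(
      "target Jaccard %.6g infeasible for sizes %g and %g: J(A,B) <= 1/c = %.6g when one set is c = %g times larger",
      target_j, size_a, size_b, 1 / c_ratio, c_ratio))
  }
  i
}

#' Generate a pair of random 64-bit integer sets
#'
#' |A| = size_a, |B| = size_b and |A intersect B| hits the requested target
#' Jaccard exactly up to the integer rounding of the intersection size. The
#' values are images of disjoint counter blocks under a 64-bit bijective
#' mix, so cardinalities are exact by construction (no collisions are
#' possible) while the values are uniform pseudo-random 64-bit integers.
#'
#' @inheritParams intersection_for_jaccard
#' @param seed integer seed; the same seed reproduces the same pair.
#' @return list with hex64 vectors `a` and `b`, the planted `intersection`
#'   size and the achieved `jaccard`.
#' @export
make_set_pair <- function(size_a, size_b, target_j, seed = 1L) {
  i <- intersection_for_jaccard(size_a, size_b, target_j)
  if (size_a + size_b > 2^21)
    abort_format("make_set_pair materializes both sets; keep size_a + size_b <= 2^21 (the streaming benchmark has no such limit)")
  sets <- cpp_make_set_pair(size_a, size_b, i, seed, 0)
  list(a = sets$a, b = sets$b, intersection = i,
       jaccard = i / (size_a + size_b - i))
}

#' The synthetic accuracy grid
#'
#' Reconstructs the study grid: larger-set sizes 2^14, 2^18 and 2^22, size
#' ratios 2^0 to 2^12 (powers of 8), and target Jaccard coefficients from
#' 0.00022 to 0.818, keeping the 36 feasible combinations (a set c times
#' larger than its partner caps J at 1/c).
#'
#' @param size_log2 log2 of the larger set sizes.
#' @param ratio_log2 log2 of the size ratios.
#' @param target_j target Jaccard coefficients.
#' @return tibble with one row per feasible cell: size_a, size_b,
#'   target_j, intersection, true_j.
#' @export
accuracy_grid <- function(size_log2 = c(14L, 18L, 22L),
                          ratio_log2 = c(0L, 3L, 6L, 9L, 12L),
                          target_j = c(0.00022, 0.0465, 0.111, 0.33, 0.6, 0.818)) {
  cells <- expand.grid(size_log2 = size_log2, ratio_log2 = ratio_log2,
                       target_j = target_j, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(r) {
    na <- 2^cells$size_log2[r]
    nb <- na / 2^cells$ratio_log2[r]
    i <- tryCatch(intersection_for_jaccard(na, nb, cells$target_j[r]),
                  kmersketch_infeasible = function(e) NA_real_)
    if (is.na(i)) return(NULL)
    tibble::tibble(size_a = na, size_b = nb, ratio_log2 = cells$ratio_log2[r],
                   target_j = cells$target_j[r], intersection = i,
                   true_j = i / (na + nb - i))
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

hll_jaccard_from_regs <- function(ra, rb, p, estimator = "mle") {
  mk <- function(regs) {
    sk <- hll_sketch(p = p)
    sk$registers <- regs
    sk
  }
  a <- mk(ra); b <- mk(rb)
  est <- switch(estimator, mle = function(s) as.numeric(estimate_mle(s)),
                original = estimate_original)
  ca <- est(a); cb <- est(b); cu <- est(hll_union(a, b))
  if (cu <= 0) return(0)
  min(max(ca + cb - cu, 0) / cu, 1)
}

#' Jaccard estimation error over the synthetic grid
#'
#' For every grid cell and trial, generates the set pair, sketches both
#' sets with every method at every sketch size (HLL with 2^log2_bytes
#' registers; bottom-k MinHash with s = 2^log2_bytes / 8, i.e. the same
#' byte budget at 8 bytes per retained hash), estimates the Jaccard
#' coefficient, and aggregates estimate - true_j per cell, method and
#' size. Fully reproducible from `seed`.
#'
#' @param grid cells from [accuracy_grid()] (the default full grid).
#' @param sketch_log2_bytes log2 sketch sizes in bytes (default 10, 12,
#'   14, 16).
#' @param methods subset of "hll", "minhash", "exact" ("exact" recomputes
#'   J from the materialized sets — errors are identically 0 — and is
#'   limited to cells small enough to materialize).
#' @param trials trials per cell (default 100).
#' @param seed root seed; per-trial seeds are derived from it and the cell
#'   index.
#' @param estimator HLL cardinality estimator (default "mle").
#' @return tibble with one row per cell x method x sketch size: the cell
#'   descriptors plus mean_abs_error, mse, max_abs_error.
#' @export
accuracy_experiment <- function(grid = accuracy_grid(),
                                sketch_log2_bytes = c(10L, 12L, 14L, 16L),
                                methods = c("hll", "minhash"),
                                trials = 100L, seed = 1L,
                                estimator = "mle") {
  stopifnot(trials >= 1)
  methods <- match.arg(methods, c("hll", "minhash", "exact"), several.ok = TRUE)
  ps <- as.integer(sketch_log2_bytes)
  ss <- as.integer(2^ps / 8)
  out <- list()
  for (ci in seq_len(nrow(grid))) {
    cell <- grid[ci, ]
    err <- array(NA_real_,
                 c(trials, length(ps), 2L),
                 dimnames = list(NULL, ps, c("hll", "minhash")))
    for (t in seq_len(trials)) {
      tr <- cpp_pair_trial(cell$size_a, cell$size_b, cell$intersection,
                           seed, (ci - 1L) * 100000 + t, ps, ss)
      for (si in seq_along(ps)) {
        if ("hll" %in% methods)
          err[t, si, "hll"] <- hll_jaccard_from_regs(
            tr$hll_a[[si]], tr$hll_b[[si]], ps[si], estimator) - cell$true_j
        if ("minhash" %in% methods) {
          cmp <- cpp_bk_compare(tr$bk_a[[si]], tr$bk_b[[si]], ss[si])
          err[t, si, "minhash"] <- cmp$shared / cmp$x_size - cell$true_j
        }
      }
    }
    for (m in methods) {
      for (si in seq_along(ps)) {
        e <- if (m == "exact") exact_errors(cell, trials, seed, ci)
             else err[, si, m]
        out[[length(out) + 1L]] <- tibble::tibble(
          size_a = cell$size_a, size_b = cell$size_b,
          target_j = cell$target_j, true_j = cell$true_j,
          method = m, log2_bytes = ps[si], trials = trials,
          mean_abs_error = mean(abs(e)), mse = mean(e^2),
          max_abs_error = max(abs(e)))
      }
    }
  }
  do.call(rbind, out)
}

# exact-mode oracle: recompute J by set arithmetic on the materialized pair
exact_errors <- function(cell, trials, seed, ci) {
  if (cell$size_a + cell$size_b > 2^21)
    abort_format("exact mode needs materializable sets (size_a + size_b <= 2^21)")
  vapply(seq_len(trials), function(t) {
    sets <- cpp_make_set_pair(cell$size_a, cell$size_b, cell$intersection,
                              seed, (ci - 1L) * 100000 + t)
    j <- length(intersect(sets$a, sets$b)) / length(union(sets$a, sets$b))
    j - cell$true_j
  }, numeric(1))
}

#' Empirical relative standard error of the harmonic-mean estimator
#'
#' Inserts n distinct random 64-bit values per trial into an HLL with
#' m = 2^p registers and measures the relative standard error of
#' [estimate_original()] across trials; the theoretical scaling is
#' 1.03896 / sqrt(m) in the mid-cardinality regime (n well above 2.5 m and
#' far from saturation). The fitted constant is the mean of RSE * sqrt(m)
#' across the requested register counts.
#'
#' @param p register-index widths (default 10, i.e. m = 1024).
#' @param n items per trial (default 1e6).
#' @param trials trials per m (default 500; at least 30 are required for a
#'   meaningful standard error).
#' @param seed root seed.
#' @return tibble with one row per m: p, m, rse, rse_sqrt_m; the mean
#'   fitted constant is attached as attribute `"constant"`.
#' @export
rse_constant_experiment <- function(p = 10L, n = 1e6, trials = 500L, seed = 1L) {
  if (trials < 30L)
    abort_format("trials must be >= 30 for a stable relative standard error")
  rows <- lapply(as.integer(p), function(pp) {
    m <- 2^pp
    if (n < 10 * m || n > 1000 * m)
      warning(sprintf(
        "n = %g is outside the mid-range regime [10m, 1000m] for m = %d", n, m))
    est <- vapply(seq_len(trials), function(t) {
      sk <- hll_sketch(p = pp)
      sk$registers <- cpp_random_hll(n, seed, pp * 100000 + t, pp)
      estimate_original(sk)
    }, numeric(1))
    rse <- sqrt(mean((est / n - 1)^2))
    tibble::tibble(p = pp, m = m, rse = rse, rse_sqrt_m = rse * sqrt(m))
  })
  out <- do.call(rbind, rows)
  attr(out, "constant") <- mean(out$rse_sqrt_m)
  out
}

#' Census of secant iteration counts for the MLE estimator
#'
#' Builds HLL sketches from random integer sets across a log-spaced range
#' of cardinalities and a range of register widths, runs [estimate_mle()]
#' on each, and reports the maximum number of secant iterations needed at
#' the estimator's 1e-9 relative tolerance. Seed-reproducible; empty
#' sketches would contribute 0 iterations.
#'
#' @param cardinalities set sizes (default 40 log-spaced values from 1e1
#'   to 1e8).
#' @param p register-index widths (default 8, 10, 12, 14, 16).
#' @param reps sketches per (cardinality, p) combination (default 5, for
#'   1000 sketches in all).
#' @param seed root seed.
#' @return list with `max_iterations` and a tibble `table` of n, p, rep,
#'   iterations, estimate.
#' @export
secant_iteration_census <- function(cardinalities = round(10^seq(1, 8, length.out = 40)),
                                    p = c(8L, 10L, 12L, 14L, 16L),
                                    reps = 5L, seed = 1L) {
  combo <- expand.grid(n = cardinalities, p = as.integer(p),
                       rep = seq_len(reps), KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(combo)), function(r) {
    sk <- hll_sketch(p = combo$p[r])
    sk$registers <- cpp_random_hll(combo$n[r], seed, r, combo$p[r])
    est <- estimate_mle(sk)
    tibble::tibble(n = combo$n[r], p = combo$p[r], rep = combo$rep[r],
                   iterations = attr(est, "iterations"),
                   estimate = as.numeric(est))
  })
  tab <- do.call(rbind, rows)
  list(max_iterations = max(tab$iterations), table = tab)
}
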