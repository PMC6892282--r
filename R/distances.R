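# Similarity/distance reports from cardinalities, for pairs and all-pairs
# collections; plus the exact hash-set mode used as ground truth.

#' Mash distance from a Jaccard coefficient
#'
#' d = -(1/k) * ln(2J / (1 + J)), the standard k-mer proxy for one minus
#' average nucleotide identity (ANI). J = 0 is capped at distance 1, and
#' the ANI proxy is 1 - d clamped to \[0, 1\]. Monotone decreasing in J.
#'
#' @param j Jaccard coefficient(s) in \[0, 1\].
#' @param k k-mer length used to compute J.
#' @return Mash distance(s), >= 0.
#' @examples
#' mash_distance(1, 21)    # 0
#' mash_distance(0.5, 21)  # ~0.0193
#' @export
mash_distance <- function(j, k) {
  stopifnot(all(j >= 0 & j <= 1), k >= 1)
  ifelse(j > 0, pmin(-(1 / k) * log(2 * j / (1 + j)), 1), 1)
}

pair_from_cardinalities <- function(ca, cb, cu, ci, k) {
  ci <- max(ci, 0)
  j <- if (cu > 0) min(ci / cu, 1) else 0
  d <- mash_distance(j, k)
  structure(list(
    card_a = ca, card_b = cb, card_union = cu, card_intersection = ci,
    jaccard = j,
    containment = if (ca > 0) min(ci / ca, 1) else 0,
    overlap = if (min(ca, cb) > 0) min(ci / min(ca, cb), 1) else 0,
    mash_distance = d,
    ani = max(min(1 - d, 1), 0),
    k = k), class = "pair_statistics")
}

#' @export
print.pair_statistics <- function(x, ...) {
  cat(sprintf(paste0("<pair_statistics> |A|=%.6g |B|=%.6g |A|B|=%.6g ",
                     "|A:B|=%.6g\n  J=%.6g containment=%.6g overlap=%.6g ",
                     "mash=%.6g ani=%.6g\n"),
              x$card_a, x$card_b, x$card_union, x$card_intersection,
              x$jaccard, x$containment, x$overlap, x$mash_distance, x$ani))
  invisible(x)
}

#' @export
as.data.frame.pair_statistics <- function(x, ...) {
  as.data.frame(x[c("card_a", "card_b", "card_union", "card_intersection",
                    "jaccard", "containment", "overlap", "mash_distance",
                    "ani")])
}

#' Similarity statistics for a pair of sketches
#'
#' Computes the four cardinalities |A|, |B|, |A union B|, |A intersect B|
#' and the derived Jaccard, containment (|A:B|/|A|), overlap
#' (|A:B|/min(|A|,|B|)), Mash distance and ANI proxy. For HLL sketches the
#' `estimator` picks the cardinality method; "jmle" fills the intersection
#' directly from the joint MLE while "original"/"mle" use
#' inclusion-exclusion on the union sketch. Bottom-k pairs combine the
#' bottom-k Jaccard with the classic order-statistic cardinality estimator;
#' Bloom pairs use the occupancy estimators. Deterministic given the inputs.
#'
#' @param a,b two compatible sketches (`hll_sketch`, `bottomk_sketch` or
#'   `bloom_sketch`).
#' @param estimator for HLL pairs: "mle" (default), "original" or "jmle".
#' @param mode for Bloom pairs: see [bloom_cardinality()].
#' @return a `pair_statistics` object.
#' @export
pair_statistics <- function(a, b, estimator = c("mle", "original", "jmle"),
                            mode = "collision_aware") {
  estimator <- match.arg(estimator)
  check_compatible(a, b)
  if (inherits(a, "hll_sketch")) {
    if (estimator == "jmle") {
      jm <- estimate_jmle(a, b)
      return(pair_from_cardinalities(jm$card_a, jm$card_b, jm$card_union,
                                     jm$card_intersection, a$k))
    }
    est <- switch(estimator, mle = function(s) as.numeric(estimate_mle(s)),
                  original = estimate_original)
    ca <- est(a); cb <- est(b); cu <- est(hll_union(a, b))
    return(pair_from_cardinalities(ca, cb, cu, max(ca + cb - cu, 0), a$k))
  }
  if (inherits(a, "bottomk_sketch")) {
    j <- bk_jaccard(a, b)
    # cardinalities from the classic bottom-k estimator (exact while the
    # sketch is not yet full); the intersection follows from J and the union
    ca <- cpp_bk_cardinality(a$values, a$s)
    cb <- cpp_bk_cardinality(b$values, b$s)
    cu <- cpp_bk_cardinality(bk_union(a, b)$values, a$s)
    return(pair_from_cardinalities(ca, cb, cu, j * cu, a$k))
  }
  if (inherits(a, "bloom_sketch")) {
    cc <- bloom_pair_cardinalities(a, b, mode)
    return(pair_from_cardinalities(cc[["card_a"]], cc[["card_b"]],
                                   cc[["card_union"]],
                                   cc[["card_intersection"]], a$k))
  }
  abort_incompatible("unsupported sketch type")
}

#' Exact Jaccard between two sequence files
#'
#' Hash-set mode: the canonical k-mer sets of both inputs are materialized
#' and compared exactly, with no sketching. Serves as the ground-truth
#' oracle for every sketched mode.
#'
#' @param path_a,path_b FASTA/FASTQ files (optionally gzipped).
#' @param k k-mer length (default 31); @param canonical canonicalize
#'   (default TRUE).
#' @return a `pair_statistics` object with exact cardinalities.
#' @export
exact_jaccard <- function(path_a, path_b, k = 31L, canonical = TRUE) {
  check_k(k)
  sa <- read_sequences(path_a)
  sb <- read_sequences(path_b)
  cc <- cpp_exact_pair_seqs(sa, sb, as.integer(k), isTRUE(canonical))
  pair_from_cardinalities(cc[1], cc[2], cc[3], cc[4], as.integer(k))
}

#' All-pairs distance table
#'
#' Emits the n(n-1)/2 upper-triangle records for a named list of compatible
#' sketches, in deterministic i < j order regardless of how work is
#' scheduled internally. Permuting the inputs permutes labels but never the
#' set of pair values.
#'
#' @param sketches named list (>= 2) of compatible sketches.
#' @param estimator,mode passed to [pair_statistics()].
#' @return a tibble with columns query, reference, card_a, card_b,
#'   card_union, card_intersection, jaccard, containment, overlap,
#'   mash_distance, ani.
#' @export
all_pairs <- function(sketches, estimator = "mle", mode = "collision_aware") {
  n <- length(sketches)
  if (n < 2) abort_format("all_pairs needs at least two sketches")
  nms <- names(sketches)
  if (is.null(nms)) nms <- paste0("input", seq_len(n))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  rows <- lapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    ps <- tryCatch(
      pair_statistics(sketches[[i]], sketches[[j]], estimator = estimator,
                      mode = mode),
      kmersketch_incompatible = function(e) abort_incompatible(
        sprintf("incompatible sketch pair (%s, %s): %s", nms[i], nms[j],
                conditionMessage(e))))
    cbind(data.frame(query = nms[i], reference = nms[j],
                     stringsAsFactors = FALSE),
          as.data.frame(ps))
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Write distance results
#'
#' `write_dist_tsv()` writes the all-pairs tibble as a TSV with floats in
#' `%.8g`. `write_phylip()` writes a square PHYLIP distance matrix (count
#' line, then one row per input with the name padded to >= 10 characters
#' and mash distances, 0 on the diagonal).
#'
#' @param pairs tibble from [all_pairs()].
#' @param path output file.
#' @param names input names, in order (for PHYLIP).
#' @return `path`, invisibly.
#' @export
write_dist_tsv <- function(pairs, path) {
  df <- as.data.frame(pairs)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.8g", x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dist_tsv
#' @export
write_phylip <- function(pairs, names, path) {
  n <- length(names)
  D <- matrix(0, n, n, dimnames = list(names, names))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$query[r]; j <- pairs$reference[r]
    D[i, j] <- D[j, i] <- pairs$mash_distance[r]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d", n), con)
  for (i in seq_len(n)) {
    nm <- substr(names[i], 1, 10)
    writeLines(paste0(formatC(nm, width = 10, flag = "-"),
                      paste(sprintf("%.8g", D[i, ]), collapse = " ")), con)
  }
  invisible(path)
}
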