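# Baseline and auxiliary sketches: bottom-k MinHash (Mash-style), Bloom
# filters with naive and collision-aware cardinality estimates, and the
# count-min sketch used to filter error k-mers out of sequencing reads.

#' Create a bottom-k MinHash sketch
#'
#' Keeps the s smallest distinct 64-bit hash values seen (set semantics).
#' At 8 bytes per retained hash, a bottom-k sketch with s = bytes/8 matches
#' the byte budget of an HLL with that many registers.
#'
#' @param s capacity: number of retained hashes.
#' @param k,canonical k-mer metadata (as in [hll_sketch()]).
#' @return an object of class `bottomk_sketch`.
#' @export
bottomk_sketch <- function(s, k = 31L, canonical = TRUE) {
  if (!is.numeric(s) || length(s) != 1L || s < 1 || s != trunc(s))
    abort_format("s must be a single positive integer")
  check_k(k)
  structure(list(s = as.integer(s), values = raw(0), k = as.integer(k),
                 canonical = isTRUE(canonical), hash = "wang64"),
            class = "bottomk_sketch")
}

#' @export
print.bottomk_sketch <- function(x, ...) {
  cat(sprintf("<bottomk_sketch> s=%d (%d values held), k=%d\n",
              x$s, bk_size(x), x$k))
  invisible(x)
}

#' Bottom-k sketch operations
#'
#' `bk_insert()` adds hash values, keeping the s smallest distinct ones;
#' `bk_union()` is the bottom-s of the multiset union (commutative,
#' associative, idempotent); `bk_values()` exposes the held values as
#' hex64; `bk_size()` counts them.
#'
#' @param sketch,a,b `bottomk_sketch` objects (`a`, `b` must share s and
#'   metadata).
#' @param hashes hex64 vector (or numeric < 2^53) of hash values.
#' @return the updated/combined sketch.
#' @export
bk_insert <- function(sketch, hashes) {
  stopifnot(inherits(sketch, "bottomk_sketch"))
  sketch$values <- cpp_bk_insert(sketch$values, sketch$s, as_hex64(hashes))
  sketch
}

#' @rdname bk_insert
#' @export
bk_union <- function(a, b) {
  check_compatible(a, b)
  a$values <- cpp_bk_union(a$values, b$values, a$s)
  a
}

#' @rdname bk_insert
#' @export
bk_values <- function(sketch) cpp_bk_values_hex(sketch$values)

#' @rdname bk_insert
#' @export
bk_size <- function(sketch) length(sketch$values) %/% 8L

#' Bottom-k Jaccard estimate
#'
#' Takes X, the bottom-s of the union of the two sketches, and returns the
#' fraction of X present in both sketches (the Mash estimator). Exact
#' whenever s >= the true union cardinality, since the sketches then hold
#' the full sets.
#'
#' @param a,b compatible `bottomk_sketch` objects.
#' @return Jaccard estimate in \[0, 1\]; two empty sketches raise an
#'   undefined-value error.
#' @export
bk_jaccard <- function(a, b) {
  check_compatible(a, b)
  cmp <- cpp_bk_compare(a$values, b$values, a$s)
  if (cmp$x_size == 0)
    abort_undefined("bottom-k Jaccard is undefined for two empty sketches")
  cmp$shared / cmp$x_size
}

# Bloom filter ------------------------------------------------------------

#' Create a Bloom-filter sketch
#'
#' A bit array of 2^b bits with h index functions, all derived from a single
#' 64-bit hash by block rotation. A Bloom filter is the baseline approximate
#' set the HLL is compared against: with enough bits it degenerates to exact
#' linear counting.
#'
#' @param b log2 of the bit count (>= 3).
#' @param h number of index functions derived per item (default 1).
#' @param k,canonical k-mer metadata.
#' @return an object of class `bloom_sketch`.
#' @export
bloom_sketch <- function(b, h = 1L, k = 31L, canonical = TRUE) {
  if (!is.numeric(b) || length(b) != 1L || b < 3 || b > 34 || b != trunc(b))
    abort_format("b must be a single integer in 3..34")
  if (!is.numeric(h) || length(h) != 1L || h < 1 || h > 8 || h != trunc(h))
    abort_format("h must be a single integer in 1..8")
  check_k(k)
  structure(list(b = as.integer(b), h = as.integer(h),
                 bits = raw(2^(b - 3)), k = as.integer(k),
                 canonical = isTRUE(canonical), hash = "wang64"),
            class = "bloom_sketch")
}

#' @export
print.bloom_sketch <- function(x, ...) {
  cat(sprintf("<bloom_sketch> 2^%d bits, h=%d, %d set\n",
              x$b, x$h, cpp_popcount(x$bits)))
  invisible(x)
}

#' Bloom filter operations
#'
#' @param sketch a `bloom_sketch`.
#' @param hashes hex64 vector (or numeric < 2^53) of hash values.
#' @return the updated sketch.
#' @export
bloom_insert <- function(sketch, hashes) {
  stopifnot(inherits(sketch, "bloom_sketch"))
  sketch$bits <- cpp_bloom_insert(sketch$bits, sketch$b, sketch$h, as_hex64(hashes))
  sketch
}

#' Cardinality estimate from a Bloom filter
#'
#' With X set bits out of 2^b: the naive mode ignores collisions and returns
#' X / h; the collision-aware mode inverts the expected-occupancy map,
#' -(2^b / h) * ln(1 - X / 2^b). A completely full filter carries no finite
#' information in collision-aware mode and raises a saturation error.
#'
#' @param sketch a `bloom_sketch`.
#' @param mode "collision_aware" (default) or "naive".
#' @return estimated cardinality (double >= 0).
#' @export
bloom_cardinality <- function(sketch, mode = c("collision_aware", "naive")) {
  mode <- match.arg(mode)
  X <- cpp_popcount(sketch$bits)
  nbits <- 2^sketch$b
  if (mode == "naive") return(X / sketch$h)
  if (X >= nbits)
    stop_ks("Bloom filter is saturated; collision-aware estimate is infinite",
            "kmersketch_saturated")
  -(nbits / sketch$h) * log1p(-X / nbits)
}

#' Pairwise cardinalities from two Bloom filters
#'
#' The union filter is the bitwise OR; |A|, |B| and |A union B| come from
#' [bloom_cardinality()] and the intersection by inclusion-exclusion,
#' floored at 0.
#'
#' @param a,b compatible `bloom_sketch` objects.
#' @param mode estimation mode, see [bloom_cardinality()].
#' @return named numeric: `card_a`, `card_b`, `card_union`,
#'   `card_intersection`.
#' @export
bloom_pair_cardinalities <- function(a, b, mode = c("collision_aware", "naive")) {
  mode <- match.arg(mode)
  check_compatible(a, b)
  u <- a
  u$bits <- cpp_raw_or(a$bits, b$bits)
  ca <- bloom_cardinality(a, mode)
  cb <- bloom_cardinality(b, mode)
  cu <- bloom_cardinality(u, mode)
  c(card_a = ca, card_b = cb, card_union = cu,
    card_intersection = max(ca + cb - cu, 0))
}

# Count-min sketch ---------------------------------------------------------

#' Create a count-min sketch
#'
#' A d x w grid of counters giving one-sided (never under-) estimates of
#' item multiplicities; used at sketching time to keep k-mers seen fewer
#' than `min_count` times (likely sequencing errors) out of the HLL.
#' Updates are conservative: only the rows at the current minimum are
#' incremented, which tightens the overestimate.
#'
#' @param d number of rows (default 4).
#' @param w row width, a power of two (default 2^20).
#' @return an object of class `cms_sketch`.
#' @export
cms_sketch <- function(d = 4L, w = 2^20) {
  if (!is.numeric(d) || length(d) != 1L || d < 1 || d > 8 || d != trunc(d))
    abort_format("d must be a single integer in 1..8")
  if (!is.numeric(w) || length(w) != 1L || w < 2 || 2^round(log2(w)) != w)
    abort_format("w must be a power of two")
  structure(list(d = as.integer(d), w = as.integer(w),
                 counters = matrix(0L, as.integer(d), as.integer(w))),
            class = "cms_sketch")
}

#' @export
print.cms_sketch <- function(x, ...) {
  cat(sprintf("<cms_sketch> %d x %d counters, %d non-zero\n",
              x$d, x$w, sum(x$counters != 0L)))
  invisible(x)
}

#' Add keys to a count-min sketch
#'
#' Conservative-update increment; the returned estimate is the min over
#' rows after the update, which is always >= the true multiplicity of the
#' key. Counters saturate at the integer maximum rather than wrapping.
#'
#' @param cms a `cms_sketch`.
#' @param keys hex64 vector (or numeric < 2^53) of (hashed) keys; keys are
#'   re-mixed per row internally.
#' @return list with the updated `cms` and `counts`, the estimate after
#'   each insertion.
#' @export
cms_add <- function(cms, keys) {
  stopifnot(inherits(cms, "cms_sketch"))
  res <- cpp_cms_add(cms$counters, as_hex64(keys))
  cms$counters <- res$counters
  list(cms = cms, counts = res$counts)
}
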