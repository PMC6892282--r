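#' Create a HyperLogLog sketch
#'
#' An HLL sketch is an array of m = 2^p one-byte registers. A 64-bit hash
#' h is split into a p-bit prefix (the register index, taken from the most
#' significant bits) and a q = 64 - p bit suffix; the register keeps the
#' maximum of rho = LZC(suffix) + 1 over all hashes routed to it. Storing
#' LZC + 1 leaves 0 unambiguous as "never updated" and is the value the
#' estimators consume directly. Register values never exceed q + 1, so they
#' fit in 6 bits of each byte, and the sketch occupies exactly m bytes.
#'
#' @param p register-index width in bits, 4-24 (the sketch holds 2^p
#'   one-byte registers, so p = 10 is a 1-kB sketch — the default).
#' @param k k-mer length recorded in the sketch metadata (default 31).
#' @param canonical whether k-mers were canonicalized (default TRUE).
#' @return an object of class `hll_sketch`.
#' @examples
#' sk <- hll_sketch(p = 10)
#' sk <- hll_insert(sk, wang_hash(1:100))
#' estimate_original(sk)
#' @export
hll_sketch <- function(p = 10L, k = 31L, canonical = TRUE) {
  if (!is.numeric(p) || length(p) != 1L || p < 4 || p > 24 || p != trunc(p))
    abort_format("p must be a single integer in 4..24")
  check_k(k)
  structure(
    list(p = as.integer(p), q = 64L - as.integer(p), m = 2L^as.integer(p),
         registers = raw(2^p), k = as.integer(k),
         canonical = isTRUE(canonical), hash = "wang64"),
    class = "hll_sketch")
}

#' @export
print.hll_sketch <- function(x, ...) {
  cat(sprintf("<hll_sketch> p=%d (m=%d registers, %d bytes), k=%d, %s\n",
              x$p, x$m, x$m, x$k,
              if (x$canonical) "canonical" else "stranded"))
  cat(sprintf("  non-empty registers: %d / %d\n",
              sum(x$registers != as.raw(0)), x$m))
  invisible(x)
}

#' Insert hash values into an HLL sketch
#'
#' `hashes` are already-hashed 64-bit values (the sequence and benchmark
#' pipelines apply the Wang hash before insertion). Insertion is idempotent
#' and order-independent: registers only ever grow, via max.
#'
#' @param sketch an `hll_sketch`.
#' @param hashes hex64 vector (or numeric < 2^53) of hash values.
#' @return the updated sketch.
#' @export
hll_insert <- function(sketch, hashes) {
  stopifnot(inherits(sketch, "hll_sketch"))
  sketch$registers <- cpp_hll_insert(sketch$registers, sketch$p, as_hex64(hashes))
  sketch
}

#' Union of two HLL sketches
#'
#' The sketch of a union of sets is exactly the element-wise maximum of the
#' two register arrays — not an approximation. Commutative, associative and
#' idempotent; the sketches must agree on p, k, canonicalization and hash.
#'
#' @param a,b compatible `hll_sketch` objects.
#' @return an `hll_sketch` for the union.
#' @export
hll_union <- function(a, b) {
  check_compatible(a, b)
  a$registers <- cpp_raw_max(a$registers, b$registers)
  a
}

#' Histogram of register values
#'
#' Counts C_v of registers equal to v for v = 0..q+1; the multiplicity
#' vector consumed by the likelihood-based estimators. Sums to m.
#'
#' @param sketch an `hll_sketch`.
#' @return integer vector of length q + 2, named "0".."q+1".
#' @export
register_histogram <- function(sketch) {
  stopifnot(inherits(sketch, "hll_sketch"))
  h <- cpp_reg_hist(sketch$registers, sketch$q)
  names(h) <- as.character(0:(sketch$q + 1L))
  h
}

check_compatible <- function(a, b) {
  for (cls in c("hll_sketch", "bottomk_sketch", "bloom_sketch")) {
    if (inherits(a, cls) && !inherits(b, cls))
      abort_incompatible("sketches are of different types")
  }
  same <- function(f) identical(a[[f]], b[[f]])
  fields <- intersect(c("p", "s", "b", "h", "k", "canonical", "hash"),
                      union(names(a), names(b)))
  for (f in fields) {
    if (!same(f))
      abort_incompatible(sprintf(
        "incompatible sketches: field '%s' differs (%s vs %s)",
        f, format(a[[f]]), format(b[[f]])))
  }
  invisible(TRUE)
}

# Sketch file format: magic "HLLS", version byte, p, k, flags (bit 0 =
# canonical), then the m raw register bytes. All fields are single bytes, so
# the layout is endianness-free; registers are written verbatim.
SKETCH_MAGIC <- charToRaw("HLLS")
SKETCH_VERSION <- as.raw(1)

#' Write / read an HLL sketch file
#'
#' A small self-describing binary format (magic "HLLS", a version byte, p,
#' k and a flags byte, followed by the m register bytes). The round trip is
#' byte-exact; truncated or foreign files raise a format error rather than
#' being misread.
#'
#' @param sketch an `hll_sketch`.
#' @param path file path.
#' @return `load_sketch()` returns the `hll_sketch`; `save_sketch()` returns
#'   `path` invisibly.
#' @export
save_sketch <- function(sketch, path) {
  stopifnot(inherits(sketch, "hll_sketch"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(SKETCH_MAGIC, con)
  writeBin(c(SKETCH_VERSION, as.raw(sketch$p), as.raw(sketch$k),
             as.raw(as.integer(sketch$canonical))), con)
  writeBin(sketch$registers, con)
  invisible(path)
}

#' @rdname save_sketch
#' @export
load_sketch <- function(path) {
  if (!file.exists(path)) abort_format(paste0("no such sketch file: ", path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (length(magic) < 4L || !identical(magic, SKETCH_MAGIC))
    abort_format(paste0("not a sketch file (bad magic): ", path))
  hdr <- readBin(con, "raw", 4L)
  if (length(hdr) < 4L) abort_format(paste0("truncated sketch header: ", path))
  if (hdr[1] != SKETCH_VERSION)
    abort_format(sprintf("unsupported sketch version %d in %s",
                         as.integer(hdr[1]), path))
  p <- as.integer(hdr[2]); k <- as.integer(hdr[3])
  canonical <- as.integer(hdr[4]) != 0L
  sk <- hll_sketch(p = p, k = k, canonical = canonical)
  regs <- readBin(con, "raw", sk$m)
  if (length(regs) != sk$m)
    abort_format(sprintf("truncated sketch file %s: expected %d register bytes, got %d",
                         path, sk$m, length(regs)))
  if (length(readBin(con, "raw", 1L)) != 0L)
    abort_format(paste0("trailing bytes after registers in ", path))
  sk$registers <- regs
  sk
}
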