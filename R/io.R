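# Sequence input and the sketch-building front ends.

#' Read sequences from a FASTA or FASTQ file
#'
#' The format is auto-detected from the first non-blank character ('>' =
#' FASTA, '@' = FASTQ) after transparent gzip decompression; quality lines
#' are parsed and discarded. All records in one file are treated as a single
#' k-mer collection downstream. An empty file yields an empty set with a
#' warning rather than an error.
#'
#' @param path file path (plain or gzip-compressed).
#' @return named character vector of sequences.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) abort_format(paste0("no such file: ", path))
  first <- ""
  con <- gzfile(path, "rt")
  on.exit(close(con), add = TRUE)
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) break
    if (nzchar(trimws(line))) { first <- substr(trimws(line), 1, 1); break }
  }
  if (first == "") {
    warning(sprintf("empty input file '%s'; treating as an empty sequence set",
                    path))
    return(character(0))
  }
  fmt <- switch(first, ">" = "fasta", "@" = "fastq",
                abort_format(sprintf(
                  "cannot detect format of '%s' (first character '%s' is neither '>' nor '@')",
                  path, first)))
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = fmt),
    error = function(e) abort_format(sprintf(
      "malformed %s record in '%s': %s", toupper(fmt), path,
      conditionMessage(e))))
  out <- as.character(seqs)
  names(out) <- names(seqs)
  out
}

#' Sketch a sequence file
#'
#' Streams every canonical k-mer of the file through the Wang hash into a
#' sketch of the requested flavour. With `min_count > 1` (meant for FASTQ
#' input, where infrequent k-mers are usually sequencing errors) each k-mer
#' is first counted in a count-min sketch and only inserted once its
#' estimated count reaches `min_count`.
#'
#' @param path FASTA/FASTQ file, optionally gzipped.
#' @param k k-mer length (default 31); @param p HLL register-index width
#'   (default 10, a 1-kB sketch).
#' @param method "hll" (default), "minhash" (bottom-k with s = 2^p / 8,
#'   matching the HLL byte budget) or "bloom" (2^(p+3) bits = 2^p bytes).
#' @param canonical canonicalize k-mers (default TRUE).
#' @param min_count count-min threshold; 1 (default) disables the filter.
#' @param cms_rows,cms_log2_width count-min dimensions (defaults 4 and 20).
#' @param bloom_h index functions per item for "bloom" (default 1).
#' @return a sketch object of the matching class.
#' @export
sketch_file <- function(path, k = 31L, p = 10L,
                        method = c("hll", "minhash", "bloom"),
                        canonical = TRUE, min_count = 1L,
                        cms_rows = 4L, cms_log2_width = 20L, bloom_h = 1L) {
  method <- match.arg(method)
  check_k(k)
  seqs <- unname(read_sequences(path))
  k <- as.integer(k); p <- as.integer(p)
  mc <- as.integer(min_count)
  cr <- as.integer(cms_rows); cw <- as.integer(cms_log2_width)
  can <- isTRUE(canonical)
  if (method == "hll") {
    sk <- hll_sketch(p = p, k = k, canonical = can)
    sk$registers <- cpp_sketch_seqs_hll(seqs, k, can, p, mc, cr, cw)
    return(sk)
  }
  if (method == "minhash") {
    s <- max(2^p %/% 8L, 1L)
    sk <- bottomk_sketch(s = s, k = k, canonical = can)
    sk$values <- cpp_sketch_seqs_bk(seqs, k, can, s, mc, cr, cw)
    return(sk)
  }
  b <- p + 3L
  sk <- bloom_sketch(b = b, h = as.integer(bloom_h), k = k, canonical = can)
  sk$bits <- cpp_sketch_seqs_bloom(seqs, k, can, b, as.integer(bloom_h),
                                   mc, cr, cw)
  sk
}

#' Default sketch file name for an input
#'
#' `input.hll.k{k}.p{p}` next to the input file.
#' @param path input file; @param k,p sketch parameters.
#' @return character path.
#' @export
sketch_path <- function(path, k = 31L, p = 10L) {
  sprintf("%s.hll.k%d.p%d", path, as.integer(k), as.integer(p))
}
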