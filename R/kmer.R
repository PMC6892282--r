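#' Encode k-mers as 2-bit codes
#'
#' Packs a DNA word over \{A,C,G,T\} into a 64-bit code, two bits per base
#' (A=0, C=1, G=2, T=3), most significant base first. The encoding is
#' injective for a fixed k, so codes can stand in for k-mers everywhere
#' downstream.
#'
#' @param kmers character vector of equal-length DNA words (length 1-32).
#'   Lowercase is accepted; any other character raises an ambiguous-base
#'   error.
#' @return hex64 character vector of codes.
#' @examples
#' encode_kmer("ACG")           # "0000000000000006"
#' hex64_value(encode_kmer("CGT"))  # 27
#' @export
encode_kmer <- function(kmers) {
  if (length(kmers) && length(unique(nchar(kmers))) != 1L)
    abort_format("all k-mers in one call must share the same length")
  tryCatch(cpp_encode_kmers(kmers),
           error = function(e) stop_ks(conditionMessage(e), "kmersketch_ambiguous_base"))
}

#' @rdname encode_kmer
#' @param codes hex64 vector of k-mer codes.
#' @param k k-mer length the codes were built with.
#' @export
decode_kmer <- function(codes, k) cpp_decode_kmers(as_hex64(codes), k)

#' Canonical form of a k-mer code
#'
#' The canonical code is the integer minimum of a k-mer code and the code of
#' its reverse complement, so a k-mer and its reverse complement map to the
#' same representative. Idempotent and strand-symmetric.
#'
#' @inheritParams decode_kmer
#' @return hex64 vector of canonical codes.
#' @examples
#' canonical_code(encode_kmer("TTT"), 3)  # code of AAA
#' @export
canonical_code <- function(codes, k) cpp_canonical_codes(as_hex64(codes), k)

#' @rdname canonical_code
#' @export
revcomp_code <- function(codes, k) cpp_revcomp_codes(as_hex64(codes), k)

#' Canonical k-mer codes of a sequence
#'
#' Slides a k-wide window over the sequence and emits one (canonical) code
#' per window. Lowercase bases are treated as their uppercase forms; windows
#' containing any non-ACGT character (N, IUPAC ambiguity codes, ...) are
#' skipped and the window restarts after the offending base. A sequence
#' shorter than k yields an empty vector.
#'
#' @param sequence a single nucleotide string.
#' @param k k-mer length (1-32), default 31.
#' @param canonical treat a k-mer and its reverse complement as equal
#'   (default TRUE).
#' @return hex64 vector of codes, one per valid window.
#' @examples
#' kmer_codes("ACGTA", k = 3)      # 3 windows
#' kmer_codes("ACGNACG", k = 3)    # windows never span the N
#' @export
kmer_codes <- function(sequence, k = 31L, canonical = TRUE) {
  check_k(k)
  cpp_seq_kmer_codes(sequence, as.integer(k), isTRUE(canonical))
}

#' Thomas Wang's 64-bit reversible integer hash
#'
#' The published seven-step invert/add/shift mix (shift constants 21, 24,
#' 3/8, 14, 2/4, 28, 31), all arithmetic modulo 2^64. The map is a bijection
#' on 64-bit words; `wang_hash_inverse()` undoes it exactly.
#'
#' @param x hex64 vector (or numeric < 2^53).
#' @return hex64 vector of hashed (or un-hashed) values.
#' @examples
#' wang_hash(0)                       # "77cfa1eef01bca90"
#' wang_hash_inverse(wang_hash(42)) == as_hex64(42)
#' @export
wang_hash <- function(x) cpp_wang_hash(as_hex64(x), FALSE)

#' @rdname wang_hash
#' @export
wang_hash_inverse <- function(x) cpp_wang_hash(as_hex64(x), TRUE)

#' Leading-zero count of a fixed-width bit string
#'
#' For `x` viewed as a q-bit string: q when x = 0, otherwise
#' q - 1 - floor(log2(x)). Values at or above 2^q violate the contract and
#' raise an error.
#'
#' @param x hex64 vector (or numeric < 2^53) of values in [0, 2^q).
#' @param q bit width, 1-64.
#' @return integer vector in \[0, q\].
#' @examples
#' lzc(0, 32)   # 32
#' lzc(1, 8)    # 7
#' lzc(255, 8)  # 0
#' @export
lzc <- function(x, q) cpp_lzc(as_hex64(x), as.integer(q))

check_k <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > 32 || k != trunc(k))
    abort_format("k must be a single integer in 1..32")
  invisible(as.integer(k))
}
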