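#' 64-bit values as hex strings
#'
#' Base R has no exact 64-bit integer type, so k-mer codes and hash values
#' are represented at the R level as 16-character lowercase hex strings
#' ("hex64"). Numeric input is accepted wherever a hex64 is expected as long
#' as it is a non-negative whole number below 2^53 (the exactly representable
#' range of a double).
#'
#' @param x numeric vector of non-negative whole numbers < 2^53, or a
#'   character vector of hex strings (1-16 hex digits).
#' @return `as_hex64()`: a character vector of 16-digit lowercase hex
#'   strings. `hex64_value()`: a numeric vector, exact only below 2^53.
#' @examples
#' as_hex64(c(0, 6, 255))
#' hex64_value("00000000000000ff")
#' @export
as_hex64 <- function(x) {
  if (is.character(x)) {
    bad <- !grepl("^[0-9a-fA-F]{1,16}$", x)
    if (any(bad)) abort_format(paste0("not a hex64 value: '", x[bad][1], "'"))
    return(tolower(formatC(x, width = 16, flag = "0")))
  }
  if (!is.numeric(x) || any(x < 0) || any(x != trunc(x)) || any(x >= 2^53))
    abort_format("numeric hex64 input must be whole, >= 0 and < 2^53")
  c1 <- x %/% 2^48
  c2 <- (x %/% 2^32) %% 2^16
  c3 <- (x %/% 2^16) %% 2^16
  c4 <- x %% 2^16
  paste0(sprintf("%04x", as.integer(c1)), sprintf("%04x", as.integer(c2)),
         sprintf("%04x", as.integer(c3)), sprintf("%04x", as.integer(c4)))
}

#' @rdname as_hex64
#' @export
hex64_value <- function(x) {
  x <- as_hex64(x)
  v <- 0
  for (i in 0:3)  # 16-bit chunks keep strtoi inside integer range
    v <- v * 2^16 + strtoi(substr(x, 4 * i + 1, 4 * i + 4), 16L)
  if (any(v >= 2^53))
    warning("hex64 value at or above 2^53; numeric conversion is inexact")
  v
}
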