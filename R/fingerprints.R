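#' Construct a binary fingerprint
#'
#' Fingerprints are 0/1 integer vectors of fixed length (1024 bits by
#' default, the length used throughout the screen).
#'
#' @param bits Vector coercible to 0/1 integers, or a vector of set-bit
#'   positions when `from_positions = TRUE` (1-based).
#' @param length Total number of bits when building from positions.
#' @param from_positions Interpret `bits` as positions of set bits.
#' @return Integer vector of class `fingerprint` with attribute `popcount`.
#' @export
fingerprint <- function(bits, length = 1024L, from_positions = FALSE) {
  if (from_positions) {
    stopifnot(length > 0, all(bits >= 1), all(bits <= length))
    v <- integer(length)
    v[as.integer(bits)] <- 1L
  } else {
    v <- as.integer(bits)
    if (anyNA(v) || !all(v %in% c(0L, 1L))) {
      stop("fingerprint bits must be 0 or 1")
    }
  }
  structure(v, popcount = sum(v), class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint: %d bits, %d set>\n", length(x), fp_popcount(x)))
  invisible(x)
}

#' Number of set bits in a fingerprint
#' @param fp Fingerprint or plain 0/1 vector.
#' @return Integer popcount.
#' @export
fp_popcount <- function(fp) {
  pc <- attr(fp, "popcount")
  if (is.null(pc)) pc <- sum(as.integer(fp))
  as.integer(pc)
}

# Serialisation: lowercase hex, most-significant bit of each nibble first,
# so bit 1 of the fingerprint is the 8-weight bit of the first hex digit.

#' Encode a fingerprint as lowercase hex
#' @param fp Fingerprint; length must be a multiple of 4.
#' @return Single hex string of `length(fp)/4` characters.
#' @export
fp_to_hex <- function(fp) {
  v <- as.integer(fp)
  stopifnot(length(v) %% 4L == 0L)
  m <- matrix(v, nrow = 4L)
  nib <- as.integer(c(8L, 4L, 2L, 1L) %*% m)
  paste(strsplit("0123456789abcdef", "")[[1]][nib + 1L], collapse = "")
}

#' Decode a hex string into a fingerprint
#' @param hex Hex string (case-insensitive).
#' @param length Declared fingerprint length; must equal `4 * nchar(hex)`.
#' @return `fingerprint` object.
#' @export
hex_to_fp <- function(hex, length = 1024L) {
  hex <- tolower(trimws(hex))
  if (!grepl("^[0-9a-f]*$", hex)) stop("invalid hex fingerprint string")
  if (nchar(hex) * 4L != length) {
    stop(sprintf("decoded fingerprint length %d != declared length %d",
                 nchar(hex) * 4L, length))
  }
  nib <- match(strsplit(hex, "")[[1]], strsplit("0123456789abcdef", "")[[1]]) - 1L
  bits_mat <- vapply(c(8L, 4L, 2L, 1L),
                     function(w) as.integer(bitwAnd(nib, w) > 0L),
                     integer(length(nib)))
  # row per nibble, MSB-first columns; flatten nibble-wise
  fingerprint(as.integer(t(bits_mat)))
}
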