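#' Tanimoto coefficient of two fingerprints
#'
#' `T = c / (a + b - c)` with `a`, `b` the set-bit counts and `c` the shared
#' set bits.  Two all-zero fingerprints have `T = 1` by convention (an
#' all-zero against a nonzero fingerprint gives 0), avoiding 0/0.
#'
#' @param fp1,fp2 Fingerprints of equal length (0/1 vectors).
#' @return Tanimoto coefficient in `[0, 1]`.
#' @export
tanimoto <- function(fp1, fp2) {
  if (length(fp1) != length(fp2)) {
    stop(sprintf("fingerprint length mismatch: %d vs %d",
                 length(fp1), length(fp2)))
  }
  a <- sum(as.integer(fp1))
  b <- sum(as.integer(fp2))
  c <- sum(as.integer(fp1) & as.integer(fp2))
  if (a + b == 0L) return(1)
  c / (a + b - c)
}

#' Stack fingerprints into a 0/1 matrix
#' @param fingerprints List of equal-length fingerprints; names become
#'   rownames.
#' @return Integer matrix, one fingerprint per row.
#' @export
fp_matrix <- function(fingerprints) {
  if (any(vapply(fingerprints, is.null, logical(1)))) {
    stop("all items must carry a fingerprint")
  }
  len <- unique(lengths(fingerprints))
  if (length(len) != 1) stop("fingerprints differ in length")
  m <- do.call(rbind, lapply(fingerprints, as.integer))
  rownames(m) <- names(fingerprints)
  m
}

#' Pairwise Tanimoto similarity matrix
#'
#' Computed by one cross-product over the bit matrix; exactly symmetric with
#' a unit diagonal for nonzero fingerprints (and for all-zero ones, by the
#' [tanimoto()] convention).
#'
#' @param fingerprints List of fingerprints (named for dimnames).
#' @return Symmetric numeric matrix of Tanimoto coefficients.
#' @export
similarity_matrix <- function(fingerprints) {
  if (length(fingerprints) < 2) stop("need at least 2 fingerprints")
  m <- fp_matrix(fingerprints)
  shared <- tcrossprod(m)
  pop <- rowSums(m)
  union <- outer(pop, pop, `+`) - shared
  s <- ifelse(union == 0, 1, shared / ifelse(union == 0, 1, union))
  # exact symmetry and unit diagonal regardless of float noise
  s <- (s + t(s)) / 2
  diag(s) <- 1
  dimnames(s) <- list(rownames(m), rownames(m))
  s
}

#' Tanimoto distance matrix
#' @param sim Similarity matrix from [similarity_matrix()], or a list of
#'   fingerprints.
#' @return Distance matrix `1 - T` with a zero diagonal.
#' @export
tanimoto_distance <- function(sim) {
  if (is.list(sim)) sim <- similarity_matrix(sim)
  d <- 1 - sim
  diag(d) <- 0
  d
}
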