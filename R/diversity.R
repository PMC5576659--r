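## Increment of Diversity (ID) on composition count vectors.
## The diversity of a count vector X = (n_1..n_s), N = sum n_i, is
##   D(X) = N log N - sum_i n_i log n_i        (natural log, 0 log 0 = 0)
## and the increment of diversity between two sources is
##   ID(X, Y) = D(X + Y) - D(X) - D(Y) >= 0.

#' Diversity measure of a count vector
#'
#' `D(X) = N log N - sum n_i log n_i` (natural log; terms with `n_i = 0`
#' contribute 0).  `D` is nonnegative, zero iff all mass sits in one
#' category, and 1-homogeneous: `D(kX) = k D(X)`.
#'
#' @param x nonnegative numeric count vector with `sum(x) > 0`.
#' @return nonnegative scalar (nats).
#' @export
diversity <- function(x) {
  if (!is.numeric(x) || any(x < 0)) {
    stop("counts must be nonnegative numbers", call. = FALSE)
  }
  N <- sum(x)
  if (N <= 0) stop("all-zero count vector has no diversity", call. = FALSE)
  nz <- x[x > 0]
  max(0, N * log(N) - sum(nz * log(nz)))
}

#' Increment of diversity between two count vectors
#'
#' `ID(X,Y) = D(X+Y) - D(X) - D(Y)`: a symmetric, nonnegative dissimilarity
#' between compositions that vanishes when the compositions are
#' proportional (in particular `ID(X,X) = 0`).
#'
#' @param x,y nonnegative count vectors of equal dimension.
#' @return nonnegative scalar.
#' @export
increment_of_diversity <- function(x, y) {
  if (length(x) != length(y)) {
    stop("dimension mismatch between diversity sources", call. = FALSE)
  }
  max(0, diversity(x + y) - diversity(x) - diversity(y))
}

#' Two-dimensional ID feature of a segment composition
#'
#' Compresses a segment's 21-letter composition into the pair
#' `(ID(segment, positive source), ID(segment, negative source))`, the
#' distances of its composition to the binding and non-binding training
#' compositions.  Sources must be built from training-fold segments only.
#'
#' @param seg_counts count vector (or a matrix with one row per segment)
#'   over the same alphabet as the sources.
#' @param positive_source,negative_source training count vectors.
#' @return numeric 2-vector, or an `n x 2` matrix for matrix input, columns
#'   `id_pos`, `id_neg`.
#' @export
id_features <- function(seg_counts, positive_source, negative_source) {
  if (length(positive_source) != length(negative_source)) {
    stop("dimension mismatch between sources", call. = FALSE)
  }
  if (is.matrix(seg_counts)) {
    if (ncol(seg_counts) != length(positive_source)) {
      stop("dimension mismatch between segments and sources", call. = FALSE)
    }
    out <- cbind(
      id_pos = id_against_source(seg_counts, positive_source),
      id_neg = id_against_source(seg_counts, negative_source)
    )
    return(out)
  }
  if (length(seg_counts) != length(positive_source)) {
    stop("dimension mismatch between segment and sources", call. = FALSE)
  }
  if (sum(seg_counts) <= 0) stop("empty segment composition", call. = FALSE)
  c(
    id_pos = increment_of_diversity(seg_counts, positive_source),
    id_neg = increment_of_diversity(seg_counts, negative_source)
  )
}

# vectorized ID of each row of a count matrix against one fixed source
id_against_source <- function(counts, source) {
  if (any(rowSums(counts) <= 0)) {
    stop("empty segment composition", call. = FALSE)
  }
  xlogx <- function(m) ifelse(m > 0, m * log(m), 0)
  Ns <- rowSums(counts)
  M <- sum(source)
  d_seg <- Ns * log(Ns) - rowSums(xlogx(counts))
  d_src <- diversity(source)
  mixed <- sweep(counts, 2L, source, "+")
  d_mix <- (Ns + M) * log(Ns + M) - rowSums(xlogx(mixed))
  pmax(0, d_mix - d_seg - d_src)
}

#' Letter composition counts of segments
#'
#' Tallies, per segment string, the occurrences of each alphabet letter
#' (including the padding letter).
#'
#' @param segments character vector of strings.
#' @param alphabet letter vector, default the 21-letter residue alphabet.
#' @return integer matrix `n x A` with `colnames = alphabet`.
#' @export
composition_counts <- function(segments, alphabet = metseg_alphabet("residue21")) {
  idx <- seg_index_matrix(segments, alphabet)
  out <- t(apply(idx, 2L, tabulate, nbins = length(alphabet)))
  if (ncol(idx) == 1L) out <- matrix(out, nrow = 1L)
  colnames(out) <- alphabet
  out
}
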