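BASES <- c("A", "C", "G", "T")

#' Encode k-mers as base-4 integer indices
#'
#' Canonical encoding used throughout the package: A=0, C=1, G=2, T=3 with the
#' leftmost base most significant, giving a bijection between the `4^k` k-mers
#' and `[0, 4^k)`. `U` is silently mapped to `T` so RNA sequences are accepted.
#'
#' @param kmer character vector of k-mers over `{A,C,G,T,U}`.
#' @param k k-mer length; every element of `kmer` must have `nchar == k`.
#' @return integer vector of indices in `[0, 4^k)`.
#' @examples
#' kmer_index(c("AAA", "ACG", "TTT"), 3) # 0, 6, 63
#' @export
kmer_index <- function(kmer, k) {
  kmer <- chartr("U", "T", toupper(kmer))
  if (any(nchar(kmer) != k))
    stop("k-mer length differs from k = ", k)
  m <- matrix(match(unlist(strsplit(kmer, "", fixed = TRUE)), BASES) - 1L,
              nrow = k)
  if (anyNA(m))
    stop("invalid sequence: k-mers must contain only A, C, G, T or U")
  as.integer(4L^((k - 1L):0L) %*% m)
}

#' Decode base-4 indices back to k-mer strings
#'
#' Inverse of [kmer_index()].
#'
#' @param idx integer vector of indices in `[0, 4^k)`.
#' @param k k-mer length.
#' @return character vector of k-mers.
#' @export
kmer_from_index <- function(idx, k) {
  if (any(idx < 0 | idx >= 4^k)) stop("index out of range for k = ", k)
  digits <- sapply((k - 1L):0L, function(p) (idx %/% 4L^p) %% 4L)
  if (length(idx) == 1L) digits <- matrix(digits, nrow = 1L)
  apply(digits, 1L, function(d) paste(BASES[d + 1L], collapse = ""))
}

#' Reverse complement of a nucleotide string
#' @param seq character scalar over `{A,C,G,T,U,N}`.
#' @return reverse-complemented string (DNA alphabet).
#' @export
revcomp <- function(seq) {
  x <- chartr("U", "T", toupper(seq))
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

# Rolling k-mer indices of a sequence: element s (1-based) is the index of the
# k-mer starting at position s-1 (0-based). Length nchar(seq) - k + 1.
seq_kmer_indices <- function(seq, k) {
  b <- match(strsplit(chartr("U", "T", toupper(seq)), "", fixed = TRUE)[[1]],
             BASES) - 1L
  if (anyNA(b)) stop("invalid sequence: only A, C, G, T, U supported")
  n <- length(b)
  if (n < k) return(integer(0))
  idx <- numeric(n - k + 1L)
  powers <- 4^((k - 1):0)
  cur <- sum(b[1:k] * powers)
  idx[1] <- cur
  hi <- 4^(k - 1)
  if (n > k) {
    for (s in 2:(n - k + 1L)) {
      cur <- (cur - b[s - 1L] * hi) * 4 + b[s + k - 1L]
      idx[s] <- cur
    }
  }
  as.integer(idx)
}
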