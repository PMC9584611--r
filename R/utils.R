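#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#' Accepts the alphabet ACGTN.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Complement (no reversal) of DNA strings
#' @param x character vector of DNA sequences.
#' @return character vector of complements.
#' @export
complement_seq <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::complement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between two equal-length strings.
hamming_dist <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}

# All Hamming-1 neighbours of a barcode over ACGT (3 * nchar strings).
hamming1_neighbors <- function(bc) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(bc, "", fixed = TRUE)[[1]]
  out <- character(0)
  for (i in seq_along(chars)) {
    for (b in bases[bases != chars[i]]) {
      v <- chars
      v[i] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}

# Wilson score interval for a binomial proportion.
wilson_ci <- function(k, n, conf = 0.95) {
  if (n <= 0) stop("n must be positive")
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Draw random DNA of given lengths (uses the current RNG stream).
random_dna <- function(n, len) {
  if (n == 0) return(character(0))
  bases <- c("A", "C", "G", "T")
  vapply(rep(len, length.out = n), function(l) {
    paste(sample(bases, l, replace = TRUE), collapse = "")
  }, character(1))
}
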