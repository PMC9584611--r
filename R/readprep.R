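#' Demultiplex read pairs by in-primer 6-nt index
#'
#' Assigns each read pair to a sample by exact match of the 6-nt index at
#' the start of R1, trying the 0-, 1- and 2-nt random-stagger offsets in
#' that order (first exact hit wins). The matched stagger and index are
#' trimmed from R1. Pairs matching no index go to the `undetermined`
#' stream. Demultiplexing partitions the input: per-sample counts plus
#' undetermined equal the total.
#'
#' @param r1,r2 character vectors of read sequences (paired, same length).
#' @param index_table named character vector, sample name -> 6-nt index.
#' @param q1,q2 optional quality strings (trimmed alongside R1).
#' @param offsets stagger offsets to try, in order.
#' @return a list with `samples` (per-sample lists of `r1`, `r2`, `q1`,
#'   `q2`, `idx` into the input), `undetermined` (input indices) and
#'   `counts`.
#' @export
demultiplex <- function(r1, r2, index_table, q1 = NULL, q2 = NULL,
                        offsets = 0:2) {
  if (length(r1) != length(r2)) stop("r1 and r2 must be paired")
  if (anyDuplicated(index_table)) stop("duplicate index in index table")
  if (length(index_table) > 0 && any(nchar(index_table) != 6L))
    stop("indexes must be 6 nt")
  n <- length(r1)
  sample_of <- rep(NA_integer_, n)
  offset_of <- rep(NA_integer_, n)
  for (o in offsets) {
    un <- which(is.na(sample_of))
    if (length(un) == 0) break
    key <- substr(r1[un], o + 1L, o + 6L)
    m <- match(key, index_table)
    hit <- !is.na(m)
    sample_of[un[hit]] <- m[hit]
    offset_of[un[hit]] <- o
  }
  samples <- lapply(seq_along(index_table), function(s) {
    i <- which(sample_of == s)
    trim <- offset_of[i] + 6L
    list(r1 = substring(r1[i], trim + 1L),
         r2 = r2[i],
         q1 = if (!is.null(q1)) substring(q1[i], trim + 1L),
         q2 = if (!is.null(q2)) q2[i],
         idx = i)
  })
  names(samples) <- names(index_table)
  und <- which(is.na(sample_of))
  counts <- c(vapply(samples, function(s) length(s$idx), integer(1)),
              undetermined = length(und))
  list(samples = samples, undetermined = und, counts = counts)
}

#' Merge paired-end reads by overlap
#'
#' Reverse-complements R2 and scans all suffix(R1)/prefix(revcomp(R2))
#' overlaps of at least `min_overlap` nt, picking the one with the most
#' matching bases (ties broken towards the longest overlap). A pair is
#' rejected when no overlap reaches `min_overlap` with a mismatch rate at
#' or below `max_mismatch_rate`. Disagreeing overlap bases are resolved by
#' the higher base quality (ties keep the R1 base); `N` never counts as a
#' match and always loses the consensus. The merged quality is the
#' pairwise maximum at agreeing positions.
#'
#' @param r1,r2 character vectors of read sequences.
#' @param q1,q2 quality strings (Sanger Phred+33); default constant.
#' @param min_overlap minimum acceptable overlap in nt (default 30).
#' @param max_mismatch_rate maximum mismatch fraction in the overlap.
#' @return a list with `merged` (character, NA for rejected pairs),
#'   `quality`, `overlap` (chosen overlap lengths) and `rejected` (logical).
#' @export
merge_pairs <- function(r1, r2, q1 = NULL, q2 = NULL,
                        min_overlap = 30L, max_mismatch_rate = 0.1) {
  n <- length(r1)
  if (length(r2) != n) stop("r1 and r2 must be paired")
  if (is.null(q1)) q1 <- strrep("I", nchar(r1))
  if (is.null(q2)) q2 <- strrep("I", nchar(r2))

  key <- paste(r1, q1, r2, q2, sep = "\r")
  uk <- !duplicated(key)
  map <- match(key, key[uk])
  r2rc <- revcomp(r2[uk])
  q2r <- vapply(strsplit(q2[uk], "", fixed = TRUE),
                function(x) paste(rev(x), collapse = ""), character(1))

  res <- mapply(function(a, b, qa, qb) {
    merge_one_pair(a, b, qa, qb, min_overlap, max_mismatch_rate)
  }, r1[uk], r2rc, q1[uk], q2r, SIMPLIFY = FALSE, USE.NAMES = FALSE)

  merged <- vapply(res, function(x) x$seq, character(1))[map]
  quality <- vapply(res, function(x) x$qual, character(1))[map]
  overlap <- vapply(res, function(x) x$overlap, integer(1))[map]
  list(merged = merged, quality = quality, overlap = overlap,
       rejected = is.na(merged))
}

# Merge one (R1, revcomp(R2)) pair; exhaustive overlap scan.
merge_one_pair <- function(a, b, qa, qb, min_overlap, max_mismatch_rate) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  la <- length(ra)
  lb <- length(rb)
  rawN <- charToRaw("N")
  best_o <- NA_integer_
  best_matches <- -1L
  max_o <- min(la, lb)
  if (max_o >= min_overlap) {
    for (o in min_overlap:max_o) {
      x <- ra[(la - o + 1L):la]
      y <- rb[1:o]
      matches <- sum(x == y & x != rawN)
      if ((o - matches) / o <= max_mismatch_rate &&
          (matches > best_matches ||
           (matches == best_matches && !is.na(best_o) && o > best_o))) {
        best_matches <- matches
        best_o <- o
      }
    }
  }
  if (is.na(best_o))
    return(list(seq = NA_character_, qual = NA_character_,
                overlap = NA_integer_))
  o <- best_o
  qra <- charToRaw(qa)
  qrb <- charToRaw(qb)
  ax <- ra[(la - o + 1L):la]
  bx <- rb[1:o]
  aq <- qra[(la - o + 1L):la]
  bq <- qrb[1:o]
  cons <- ax
  consq <- pmax(as.integer(aq), as.integer(bq))
  agree <- ax == bx & ax != rawN
  dis <- which(!agree)
  for (i in dis) {
    # N always loses; otherwise higher quality wins, ties keep R1
    if (ax[i] == rawN && bx[i] != rawN) {
      cons[i] <- bx[i]; consq[i] <- as.integer(bq[i])
    } else if (bx[i] == rawN && ax[i] != rawN) {
      cons[i] <- ax[i]; consq[i] <- as.integer(aq[i])
    } else if (as.integer(bq[i]) > as.integer(aq[i])) {
      cons[i] <- bx[i]; consq[i] <- as.integer(bq[i])
    } else {
      cons[i] <- ax[i]; consq[i] <- as.integer(aq[i])
    }
  }
  seq <- rawToChar(c(ra[seq_len(la - o)], cons, rb[(o + 1L):lb]))
  qual <- rawToChar(c(qra[seq_len(la - o)], as.raw(consq),
                      qrb[(o + 1L):lb]))
  list(seq = seq, qual = qual, overlap = o)
}

#' Orient merged reads to the sense strand
#'
#' Votes with shared k-mers against the reference: a read is kept as-is
#' when its forward k-mer sharing beats its reverse complement's, flipped
#' otherwise, and discarded as unalignable when neither orientation shares
#' at least `min_frac` of its k-mers with the reference.
#'
#' @param seqs character vector of merged reads.
#' @param ref an [amplicon_reference()].
#' @param k k-mer size for the vote.
#' @param min_frac minimum shared-k-mer fraction to accept an orientation.
#' @return a list with `seq` (oriented reads, NA for discarded),
#'   `flipped` (logical) and `discarded` (logical).
#' @export
orient_to_sense <- function(seqs, ref, k = 11L, min_frac = 0.3) {
  ref_kmers <- unique(substring(ref$sense_sequence,
                                1:(nchar(ref$sense_sequence) - k + 1L),
                                k:nchar(ref$sense_sequence)))
  uk <- !duplicated(seqs)
  map <- match(seqs, seqs[uk])
  useqs <- seqs[uk]
  frac <- function(s) {
    if (nchar(s) < k) return(0)
    km <- substring(s, 1:(nchar(s) - k + 1L), k:nchar(s))
    mean(km %in% ref_kmers)
  }
  fwd <- vapply(useqs, frac, numeric(1), USE.NAMES = FALSE)
  rc <- revcomp(useqs)
  rev <- vapply(rc, frac, numeric(1), USE.NAMES = FALSE)
  out <- ifelse(fwd >= rev, useqs, rc)
  flipped <- rev > fwd
  discarded <- pmax(fwd, rev) < min_frac
  out[discarded] <- NA_character_
  list(seq = out[map], flipped = flipped[map], discarded = discarded[map])
}
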