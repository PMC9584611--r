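#' Alignment scoring scheme
#'
#' Defaults suited to full-length amplicon reads: match +2, mismatch -3,
#' gap open -5, gap extend -2 (a length-k gap costs 5 + 2k).
#'
#' @param match,mismatch,gap_open,gap_extend scores.
#' @return a named list.
#' @export
alignment_scoring <- function(match = 2, mismatch = -3,
                              gap_open = -5, gap_extend = -2) {
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend)
}

#' Globally align a read to the amplicon reference
#'
#' Needleman-Wunsch with affine gaps (Gotoh). `N` in the reference (the
#' barcode slot) is a wildcard that matches any read base; `N` in the read
#' scores as a mismatch. Ties are broken deterministically: substitution
#' preferred over gap, reference gap over read gap, gap extension over gap
#' opening. Reads whose alignment identity (matches over alignment
#' columns) falls below `min_identity` are flagged unalignable.
#'
#' A fast path serves reads identical to the reference or equal-length
#' reads with at most three substitutions, for which the all-diagonal
#' alignment is provably optimal under the default scoring.
#'
#' @param read character scalar, sense-oriented read.
#' @param ref an [amplicon_reference()] or a plain reference string.
#' @param scoring an [alignment_scoring()] list.
#' @param min_identity identity floor below which the read is flagged.
#' @return a list of class `supf_alignment`: `score`, `aligned_read`,
#'   `aligned_ref`, `identity`, `unalignable`.
#' @export
align_read <- function(read, ref, scoring = alignment_scoring(),
                       min_identity = 0.6) {
  ref_seq <- if (inherits(ref, "amplicon_reference")) ref$sense_sequence
             else ref
  aln <- NULL
  default_scores <- identical(scoring, alignment_scoring())
  if (nchar(read) == nchar(ref_seq)) {
    rr <- charToRaw(read)
    rf <- charToRaw(ref_seq)
    rawN <- charToRaw("N")
    mm <- sum(rr != rf & rf != rawN)
    # diagonal is strictly optimal while 5*mm < 2*(gap pair cost + 1)
    if (mm == 0L || (default_scores && mm <= 3L)) {
      nmatch <- length(rr) - mm
      aln <- list(score = nmatch * scoring$match + mm * scoring$mismatch,
                  aligned_read = read, aligned_ref = ref_seq)
    }
  }
  if (is.null(aln)) {
    aln <- gotoh_align_cpp(read, ref_seq, scoring$match, scoring$mismatch,
                           scoring$gap_open, scoring$gap_extend)
  }
  cols <- nchar(aln$aligned_read)
  ar <- charToRaw(aln$aligned_read)
  af <- charToRaw(aln$aligned_ref)
  rawN <- charToRaw("N")
  ident <- sum((ar == af | af == rawN) & ar != charToRaw("-")) / cols
  structure(list(score = aln$score,
                 aligned_read = aln$aligned_read,
                 aligned_ref = aln$aligned_ref,
                 identity = ident,
                 unalignable = ident < min_identity),
            class = "supf_alignment")
}

#' Extract normalized variant observations from an alignment
#'
#' Walks the alignment columns; non-match columns are grouped into single
#' observations, with runs separated by at most `merge_gap` matching
#' columns merged into one complex observation — so CC>TT is one
#' dinucleotide substitution and GAG>AAA (whose middle base matches) is
#' one 3-nt replacement. Pure indels are left-aligned against the
#' reference. Positions are supF coordinates of the leftmost affected
#' reference base (for pure insertions, of the base the insertion
#' precedes). Leading/trailing read gaps are treated as missing coverage,
#' not deletions, and observations outside the analysis window are
#' dropped.
#'
#' @param aln a `supf_alignment` from [align_read()].
#' @param ref an [amplicon_reference()].
#' @param merge_gap maximum run of matching columns bridged when merging
#'   adjacent differences (default 1, reproducing triplet calls).
#' @return a list with `variants` (data.frame position, ref, alt) and
#'   `covered` (supF index range covered by the read, as sequence indices).
#' @export
extract_read_variants <- function(aln, ref, merge_gap = 1L) {
  ar <- strsplit(aln$aligned_read, "", fixed = TRUE)[[1]]
  af <- strsplit(aln$aligned_ref, "", fixed = TRUE)[[1]]
  ncol <- length(ar)
  ref_index <- cumsum(af != "-")  # reference index at each column (0 before)

  # leading/trailing read gaps = partial coverage
  nonread <- ar == "-"
  first_base <- match(FALSE, nonread)
  last_base <- ncol + 1L - match(FALSE, rev(nonread))
  if (is.na(first_base)) {
    return(list(variants = empty_variants(), covered = c(NA_integer_,
                                                         NA_integer_)))
  }
  covered <- c(ref_index[first_base], ref_index[last_base])
  if (covered[1] == 0L) covered[1] <- 1L

  is_match <- (ar == af | af == "N") & ar != "-"
  diff_col <- which(!is_match)
  diff_col <- diff_col[diff_col >= first_base & diff_col <= last_base]
  if (length(diff_col) == 0)
    return(list(variants = empty_variants(), covered = covered))

  # group difference columns, bridging <= merge_gap matching columns
  grp <- cumsum(c(1L, diff(diff_col) > merge_gap + 1L))
  vars <- lapply(split(diff_col, grp), function(cols) {
    span <- min(cols):max(cols)
    ref_a <- paste(af[span][af[span] != "-"], collapse = "")
    alt_a <- paste(ar[span][ar[span] != "-"], collapse = "")
    ri <- ref_index[min(cols)]
    if (af[min(cols)] == "-") ri <- ri + 1L  # insertion precedes next base
    data.frame(index = ri, ref = ref_a, alt = alt_a,
               stringsAsFactors = FALSE)
  })
  v <- do.call(rbind, vars)
  rownames(v) <- NULL

  # left-align pure indels against the reference
  refchars <- strsplit(ref$sense_sequence, "", fixed = TRUE)[[1]]
  for (k in seq_len(nrow(v))) {
    if (nchar(v$ref[k]) > 0 && nchar(v$alt[k]) > 0) next
    allele <- if (nchar(v$ref[k]) > 0) v$ref[k] else v$alt[k]
    i <- v$index[k]
    achars <- strsplit(allele, "", fixed = TRUE)[[1]]
    while (i > 1L && refchars[i - 1L] == achars[length(achars)]) {
      achars <- c(refchars[i - 1L], achars[-length(achars)])
      i <- i - 1L
    }
    v$index[k] <- i
    if (nchar(v$ref[k]) > 0) v$ref[k] <- paste(achars, collapse = "")
    else v$alt[k] <- paste(achars, collapse = "")
  }

  # supF coordinates; drop observations outside the analysis window
  win_idx <- map_coordinate(ref, ref$analysis_window)
  inside <- v$index >= win_idx[1] & v$index <= win_idx[2]
  v <- v[inside, , drop = FALSE]
  if (nrow(v) == 0)
    return(list(variants = empty_variants(), covered = covered))
  v$position <- index_to_position(ref, v$index)
  out <- v[order(v$index), c("position", "ref", "alt")]
  rownames(out) <- NULL
  list(variants = out, covered = covered)
}

empty_variants <- function() {
  data.frame(position = integer(0), ref = character(0), alt = character(0),
             stringsAsFactors = FALSE)
}

#' Aggregate per-read variants into a per-barcode profile
#'
#' Groups identical observations across the reads of one barcode and
#' computes each observation's variant frequency VF = supporting reads /
#' reads covering the site. Profiles from groups with 9 or fewer reads are
#' ineligible for calling; observations reach called status at
#' VF >= `vf_call` (default 0.1). All VFs are retained for diagnostics.
#'
#' @param barcode barcode sequence of the group.
#' @param read_variants list (one element per read) of results from
#'   [extract_read_variants()].
#' @param ref an [amplicon_reference()].
#' @param vf_call calling threshold on VF (inclusive).
#' @param min_reads minimum reads per barcode for calling eligibility
#'   (default 10, the more-than-9-reads rule).
#' @return a list of class `barcode_profile`: `barcode`, `read_count`,
#'   `eligible`, `variants` (data.frame position, ref, alt, supporting,
#'   depth, vf, called).
#' @export
aggregate_barcode <- function(barcode, read_variants, ref,
                              vf_call = 0.1, min_reads = 10L) {
  read_count <- length(read_variants)
  eligible <- read_count >= min_reads
  tabs <- lapply(read_variants, `[[`, "variants")
  allv <- do.call(rbind, tabs)
  if (is.null(allv) || nrow(allv) == 0) {
    vtab <- data.frame(position = integer(0), ref = character(0),
                       alt = character(0), supporting = integer(0),
                       depth = integer(0), vf = numeric(0),
                       called = logical(0), stringsAsFactors = FALSE)
    return(structure(list(barcode = barcode, read_count = read_count,
                          eligible = eligible, variants = vtab),
                     class = "barcode_profile"))
  }
  key <- paste(allv$position, allv$ref, allv$alt, sep = "\r")
  tab <- table(key)
  uniq <- allv[!duplicated(key), , drop = FALSE]
  ukey <- key[!duplicated(key)]
  supporting <- as.integer(tab[ukey])

  # per-variant depth: reads whose covered index range spans the variant
  covs <- t(vapply(read_variants, `[[`, integer(2), "covered"))
  vidx <- map_coordinate(ref, uniq$position)
  vend <- vidx + pmax(nchar(uniq$ref), 1L) - 1L
  depth <- vapply(seq_along(vidx), function(k) {
    sum(!is.na(covs[, 1]) & covs[, 1] <= vidx[k] & covs[, 2] >= vend[k])
  }, integer(1))

  vf <- supporting / depth
  vtab <- data.frame(position = uniq$position, ref = uniq$ref,
                     alt = uniq$alt, supporting = supporting,
                     depth = depth, vf = vf,
                     called = eligible & vf >= vf_call,
                     stringsAsFactors = FALSE)
  vtab <- vtab[order(vtab$position, vtab$ref, vtab$alt), , drop = FALSE]
  rownames(vtab) <- NULL
  structure(list(barcode = barcode, read_count = read_count,
                 eligible = eligible, variants = vtab),
            class = "barcode_profile")
}

#' Retain variants concordant across duplicate PCR replicates
#'
#' A (barcode, variant) is kept only when called in both replicate profile
#' sets; its VF is reported as the replicate mean. Identical inputs return
#' themselves.
#'
#' @param rec1,rec2 mutation-record data.frames (from [call_mutations()])
#'   for the two replicates.
#' @return a concordant mutation-record data.frame.
#' @export
merge_replicates <- function(rec1, rec2) {
  if (nrow(rec1) > 0 && nrow(rec2) > 0 &&
      length(intersect(rec1$barcode, rec2$barcode)) == 0)
    warning("replicates share no barcodes; returning empty set")
  key1 <- paste(rec1$barcode, rec1$position, rec1$ref, rec1$alt, sep = "\r")
  key2 <- paste(rec2$barcode, rec2$position, rec2$ref, rec2$alt, sep = "\r")
  common <- intersect(key1, key2)
  out <- rec1[match(common, key1), , drop = FALSE]
  out$vf <- (rec1$vf[match(common, key1)] + rec2$vf[match(common, key2)]) / 2
  out <- out[order(out$barcode, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
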