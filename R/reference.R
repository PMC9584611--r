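#' Amplicon reference for the barcoded supF assay
#'
#' Container for the sense-strand (non-transcribed) amplicon sequence, the
#' anchored barcode slot, and the supF coordinate system. Coordinates are
#' 1-based on the supF gene with negative positions upstream of position 1
#' and no position 0, so the window -19..214 spans 233 positions.
#'
#' @param sense_sequence amplicon sequence, 5'->3' on the non-transcribed
#'   strand. The barcode slot must be a run of `barcode_length` `N`s flanked
#'   by the two anchors.
#' @param supf_offset 1-based index in `sense_sequence` of supF position 1.
#' @param upstream_anchor,downstream_anchor the 6-nt anchor hexamers flanking
#'   the barcode slot (defaults `GGCGAT` / `ATCGAA`).
#' @param barcode_length barcode slot width in nt (default 12).
#' @param analysis_window,supf_window,barcode_region coordinate intervals
#'   (length-2 integer vectors, endpoints nonzero). `barcode_region` and
#'   `supf_window` partition `analysis_window` at the -20/-19 boundary.
#' @return an object of class `amplicon_reference`.
#' @export
amplicon_reference <- function(sense_sequence,
                               supf_offset,
                               upstream_anchor = "GGCGAT",
                               downstream_anchor = "ATCGAA",
                               barcode_length = 12L,
                               analysis_window = c(-67L, 214L),
                               supf_window = c(-19L, 214L),
                               barcode_region = c(-67L, -20L)) {
  sense_sequence <- toupper(sense_sequence)
  stopifnot(nchar(upstream_anchor) == 6L, nchar(downstream_anchor) == 6L)
  for (w in list(analysis_window, supf_window, barcode_region)) {
    if (any(w == 0L)) stop("coordinate intervals must exclude position 0")
    if (w[1] > w[2]) stop("interval start must not exceed end")
  }
  if (supf_window[1] < analysis_window[1] || supf_window[2] > analysis_window[2])
    stop("supf_window must be contained in analysis_window")
  if (!(barcode_region[2] == -20L && supf_window[1] == -19L &&
        barcode_region[1] == analysis_window[1] &&
        supf_window[2] == analysis_window[2]))
    stop("barcode_region and supf_window must partition analysis_window at -20/-19")

  up_hits <- gregexpr(upstream_anchor, sense_sequence, fixed = TRUE)[[1]]
  dn_hits <- gregexpr(downstream_anchor, sense_sequence, fixed = TRUE)[[1]]
  if (length(up_hits) != 1L || up_hits[1] == -1L)
    stop("upstream anchor must occur exactly once in the reference")
  if (length(dn_hits) != 1L || dn_hits[1] == -1L)
    stop("downstream anchor must occur exactly once in the reference")
  if (dn_hits[1] - (up_hits[1] + 6L) != barcode_length)
    stop("anchors must be separated by exactly barcode_length positions")
  slot <- substr(sense_sequence, up_hits[1] + 6L, dn_hits[1] - 1L)
  if (slot != strrep("N", barcode_length))
    stop("barcode slot between the anchors must be N placeholders")

  ref <- structure(list(
    sense_sequence = sense_sequence,
    upstream_anchor = upstream_anchor,
    downstream_anchor = downstream_anchor,
    barcode_length = as.integer(barcode_length),
    supf_offset = as.integer(supf_offset),
    analysis_window = as.integer(analysis_window),
    supf_window = as.integer(supf_window),
    barcode_region = as.integer(barcode_region),
    slot_start = as.integer(up_hits[1] + 6L),
    slot_end = as.integer(dn_hits[1] - 1L),
    anchor_index_range = c(as.integer(up_hits[1]), as.integer(dn_hits[1] + 5L))
  ), class = "amplicon_reference")

  idx <- map_coordinate(ref, ref$analysis_window)
  if (idx[1] < 1L || idx[2] > nchar(sense_sequence))
    stop("analysis window does not fit inside the reference sequence")
  ref
}

#' @export
print.amplicon_reference <- function(x, ...) {
  cat("amplicon_reference:", nchar(x$sense_sequence), "nt;",
      "analysis window", paste(x$analysis_window, collapse = ".."),
      sprintf("(%d positions);", window_length(x$analysis_window)),
      "barcode slot", x$barcode_length, "nt at",
      paste(x$barcode_region, collapse = ".."), "\n")
  invisible(x)
}

#' Map supF coordinates to sequence indices
#'
#' Converts supF coordinates (nonzero integers, negative upstream of position
#' 1) to 1-based indices into the sense sequence. The mapping is a bijection
#' on the analysis window and positions -1 and 1 are adjacent indices.
#'
#' @param ref an [amplicon_reference()].
#' @param pos integer vector of supF coordinates.
#' @return integer vector of 1-based indices into `ref$sense_sequence`.
#' @export
map_coordinate <- function(ref, pos) {
  pos <- as.integer(pos)
  if (any(pos == 0L)) stop("position 0 does not exist in supF coordinates")
  if (any(pos < ref$analysis_window[1] | pos > ref$analysis_window[2]))
    stop("position outside the analysis window")
  ifelse(pos > 0L, ref$supf_offset + pos - 1L, ref$supf_offset + pos)
}

#' Map sequence indices back to supF coordinates
#'
#' Inverse of [map_coordinate()].
#'
#' @param ref an [amplicon_reference()].
#' @param idx integer vector of 1-based sequence indices.
#' @return integer vector of supF coordinates (NA outside the window).
#' @export
index_to_position <- function(ref, idx) {
  idx <- as.integer(idx)
  pos <- ifelse(idx >= ref$supf_offset,
                idx - ref$supf_offset + 1L,
                idx - ref$supf_offset)
  pos[pos < ref$analysis_window[1] | pos > ref$analysis_window[2]] <- NA_integer_
  pos
}

#' Number of positions in a supF coordinate interval
#'
#' Counts positions in a closed interval of supF coordinates, skipping the
#' nonexistent position 0 when the interval straddles it: -19..214 holds
#' 233 positions.
#'
#' @param interval length-2 integer vector with nonzero endpoints,
#'   start <= end.
#' @return integer count of positions.
#' @export
window_length <- function(interval) {
  a <- as.integer(interval[1])
  b <- as.integer(interval[2])
  if (a == 0L || b == 0L) stop("interval endpoints must be nonzero")
  if (a > b) stop("interval start must not exceed end")
  b - a + 1L - as.integer(a < 0L && b > 0L)
}

#' Transform bases or contexts between strand views
#'
#' Identity when `from == to`; reverse complement when switching between the
#' non-transcribed and transcribed view. An involution that preserves string
#' length: the context of a C>T in TCA reads TGA with a G>A on the other
#' strand.
#'
#' @param x character vector over ACGT.
#' @param from,to strand views, `"non_transcribed"` or `"transcribed"`.
#' @return transformed character vector.
#' @export
strand_transform <- function(x, from = "non_transcribed", to = "transcribed") {
  views <- c("non_transcribed", "transcribed")
  from <- match.arg(from, views)
  to <- match.arg(to, views)
  if (any(grepl("[^ACGT]", x))) stop("strand_transform requires ACGT strings")
  if (from == to) x else revcomp(x)
}

#' Default synthetic amplicon reference
#'
#' A deterministic synthetic 355-nt amplicon emulating the assay's read
#' layout: a primer prefix, the analysis window -67..214, and a primer
#' suffix. The barcode slot is N12 between the GGCGAT/ATCGAA anchors, with
#' the barcoding-oligo flanks around it, and the documented local sequence
#' features of the supF region (TTACC at 53-57, GTTCC at 67-71, GAG at
#' 73-75, TTCGAA at 115-120 and 123-128) stamped in. The remaining sequence
#' is seeded-random, so this is a synthetic stand-in, not the real supF
#' gene; real-data users should load their own reference with
#' [read_reference()].
#'
#' @return an [amplicon_reference()].
#' @export
supf_reference <- function() {
  total_len <- 355L
  supf_offset <- 105L  # index of supF position 1; index 38 = position -67

  base <- withr::with_seed(83780L, {
    paste(sample(c("A", "C", "G", "T"), total_len, replace = TRUE),
          collapse = "")
  })
  chars <- strsplit(base, "", fixed = TRUE)[[1]]

  stamp <- function(chars, start, seq) {
    s <- strsplit(seq, "", fixed = TRUE)[[1]]
    chars[start:(start + length(s) - 1L)] <- s
    chars
  }
  # barcoding-oligo flanks around the N12 slot (anchor hexamers included)
  chars <- stamp(chars, 33L, "GGCCTCAGCGAATTGCAAGCTTCTAGAAGGCGAT")  # ends ..66
  chars <- stamp(chars, 67L, strrep("N", 12L))                       # slot 67..78
  chars <- stamp(chars, 79L, "ATCGAATTCGGATCCTTTCTCAACGTAA")         # 79..106
  # local supF-region motifs (supF position p -> index supf_offset + p - 1)
  pos_idx <- function(p) supf_offset + p - 1L
  chars <- stamp(chars, pos_idx(53L), "TTACC")
  chars <- stamp(chars, pos_idx(67L), "GTTCC")
  chars <- stamp(chars, pos_idx(73L), "GAG")
  chars <- stamp(chars, pos_idx(115L), "TTCGAA")
  chars <- stamp(chars, pos_idx(123L), "TTCGAA")

  # remove spurious anchor occurrences created by the random fill
  seq1 <- paste(chars, collapse = "")
  protected <- c(33:106, pos_idx(53L):(pos_idx(53L) + 4L),
                 pos_idx(67L):(pos_idx(67L) + 4L),
                 pos_idx(73L):(pos_idx(73L) + 2L),
                 pos_idx(115L):(pos_idx(115L) + 5L),
                 pos_idx(123L):(pos_idx(123L) + 5L))
  for (anchor in c("GGCGAT", "ATCGAA")) {
    repeat {
      hits <- gregexpr(anchor, paste(chars, collapse = ""), fixed = TRUE)[[1]]
      hits <- hits[hits != -1L]
      keep <- if (anchor == "GGCGAT") 61L else 79L
      spurious <- hits[hits != keep]
      if (length(spurious) == 0L) break
      h <- spurious[1]
      free <- setdiff(h:(h + 5L), protected)
      if (length(free) == 0L) stop("cannot break spurious anchor hit")
      i <- free[1]
      chars[i] <- setdiff(c("A", "C", "G", "T"), chars[i])[1]
    }
  }

  amplicon_reference(paste(chars, collapse = ""), supf_offset = supf_offset)
}

#' Load an amplicon reference from a FASTA file
#'
#' Reads a single-record FASTA (sense strand, barcode slot as N12 between
#' the anchors) and wraps it in an [amplicon_reference()].
#'
#' @param path FASTA file path.
#' @param supf_offset 1-based index of supF position 1 in the record.
#' @param ... passed to [amplicon_reference()].
#' @return an [amplicon_reference()].
#' @export
read_reference <- function(path, supf_offset, ...) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 1L) stop("reference FASTA must contain exactly one record")
  amplicon_reference(as.character(seqs[[1]]), supf_offset = supf_offset, ...)
}

#' Write an amplicon reference to FASTA
#' @param ref an [amplicon_reference()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  x <- Biostrings::DNAStringSet(ref$sense_sequence)
  names(x) <- "amplicon"
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Insert a concrete barcode into the reference's N12 slot.
barcoded_sequence <- function(ref, barcode) {
  if (any(nchar(barcode) != ref$barcode_length))
    stop("barcode length mismatch")
  paste0(substr(ref$sense_sequence, 1L, ref$slot_start - 1L),
         barcode,
         substr(ref$sense_sequence, ref$slot_end + 1L,
                nchar(ref$sense_sequence)))
}
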