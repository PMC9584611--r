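#' Extract the 12-nt barcode from merged reads
#'
#' Anchored pattern matching: returns the 12 characters strictly between
#' the first exact occurrence of the upstream anchor (GGCGAT) and the
#' immediately following exact downstream anchor (ATCGAA) when they are
#' exactly 12 nt apart; otherwise no-extract (NA). In strict mode no
#' substitutions are allowed in the anchors; `max_anchor_mismatch = 1`
#' enables a relaxed scan (one substitution per anchor) for sensitivity
#' studies.
#'
#' @param seqs character vector of sense-oriented merged reads.
#' @param ref an [amplicon_reference()].
#' @param max_anchor_mismatch allowed substitutions per anchor (0 strict).
#' @return character vector of extracted barcodes, NA where no extract.
#' @export
extract_barcode <- function(seqs, ref, max_anchor_mismatch = 0L) {
  bl <- ref$barcode_length
  if (max_anchor_mismatch == 0L) {
    pat <- paste0(ref$upstream_anchor, "([ACGTN]{", bl, "})",
                  ref$downstream_anchor)
    m <- regexec(pat, seqs)
    out <- vapply(regmatches(seqs, m), function(x) {
      if (length(x) == 2L) x[2] else NA_character_
    }, character(1))
    return(out)
  }
  vapply(seqs, function(s) {
    extract_barcode_relaxed(s, ref, max_anchor_mismatch)
  }, character(1), USE.NAMES = FALSE)
}

# Sliding-window anchored extraction allowing mismatches in the anchors.
extract_barcode_relaxed <- function(s, ref, max_mm) {
  bl <- ref$barcode_length
  up <- charToRaw(ref$upstream_anchor)
  dn <- charToRaw(ref$downstream_anchor)
  rs <- charToRaw(s)
  span <- 6L + bl + 6L
  if (length(rs) < span) return(NA_character_)
  for (i in 1:(length(rs) - span + 1L)) {
    if (sum(rs[i:(i + 5L)] != up) <= max_mm &&
        sum(rs[(i + 6L + bl):(i + 5L + bl + 6L)] != dn) <= max_mm)
      return(rawToChar(rs[(i + 6L):(i + 5L + bl)]))
  }
  NA_character_
}

#' Build a barcode whitelist
#'
#' With a known list, returns it unchanged. Otherwise performs a
#' directional collapse of the observed barcode counts — any barcode
#' within Hamming distance 1 of an at-least-twice-as-abundant barcode is
#' absorbed into it — and keeps barcodes whose accumulated counts reach
#' `min_count`. Barcodes containing N are never whitelisted.
#'
#' @param counts named integer vector, barcode -> observed read count, or
#'   a character vector of observed barcodes to be tabulated.
#' @param min_count minimum accumulated count (default 10, matching the
#'   more-than-9-reads calling filter).
#' @param known_list optional character vector of true barcodes.
#' @return a list of class `barcode_whitelist` with `barcodes` and
#'   `counts`.
#' @export
build_whitelist <- function(counts, min_count = 10L, known_list = NULL) {
  if (!is.null(known_list)) {
    if (anyDuplicated(known_list)) stop("known_list contains duplicates")
    return(structure(list(barcodes = known_list,
                          counts = setNames(rep(NA_integer_,
                                                length(known_list)),
                                            known_list)),
                     class = "barcode_whitelist"))
  }
  if (is.character(counts) && is.null(names(counts)))
    counts <- table(counts)
  counts <- counts[!grepl("N", names(counts), fixed = TRUE)]
  if (length(counts) == 0) stop("no usable barcodes for whitelist building")
  cnt <- as.integer(counts)
  names(cnt) <- names(counts)
  ord <- order(-cnt, names(cnt))
  cnt <- cnt[ord]

  accepted <- character(0)
  acc_env <- new.env(hash = TRUE, parent = emptyenv())
  observed <- cnt  # original observed counts drive the 2x rule
  accumulated <- cnt
  absorbed_into <- setNames(rep(NA_character_, length(cnt)), names(cnt))
  for (bc in names(cnt)) {
    nb <- hamming1_neighbors(bc)
    target <- NA_character_
    best <- -Inf
    for (x in nb) {
      if (exists(x, envir = acc_env, inherits = FALSE) &&
          observed[[x]] >= 2L * observed[[bc]] && observed[[x]] > best) {
        target <- x
        best <- observed[[x]]
      }
    }
    if (!is.na(target)) {
      accumulated[[target]] <- accumulated[[target]] + accumulated[[bc]]
      absorbed_into[[bc]] <- target
    } else {
      assign(bc, TRUE, envir = acc_env)
      accepted <- c(accepted, bc)
    }
  }
  keep <- accepted[accumulated[accepted] >= min_count]
  if (length(keep) == 0) stop("whitelist construction produced no barcodes")
  structure(list(barcodes = sort(keep),
                 counts = accumulated[sort(keep)]),
            class = "barcode_whitelist")
}

#' Correct observed barcodes against a whitelist
#'
#' Exact whitelist members map to themselves; otherwise an observed
#' barcode maps to the unique whitelist entry at Hamming distance 1, and
#' is unassigned (NA) when zero or several entries are that close.
#' Idempotent on whitelist members.
#'
#' @param observed character vector of observed 12-nt barcodes.
#' @param wl a `barcode_whitelist` from [build_whitelist()].
#' @return character vector of corrected barcodes (NA = unassigned).
#' @export
correct_barcode <- function(observed, wl) {
  uo <- unique(observed)
  wlset <- wl$barcodes
  corr <- setNames(rep(NA_character_, length(uo)), uo)
  exact <- uo %in% wlset
  corr[exact] <- uo[exact]
  for (bc in uo[!exact]) {
    if (is.na(bc) || nchar(bc) != nchar(wlset[1])) next
    hits <- hamming1_neighbors(bc)
    hits <- hits[hits %in% wlset]
    if (length(hits) == 1L) corr[[bc]] <- hits
  }
  unname(corr[observed])
}

#' Group reads by corrected barcode
#'
#' @param corrected character vector of corrected barcode assignments
#'   (NA = unassigned, dropped).
#' @return named list of integer index vectors, one per distinct barcode;
#'   group sizes sum to the number of assigned reads.
#' @export
group_by_barcode <- function(corrected) {
  keep <- !is.na(corrected)
  split(which(keep), corrected[keep])
}
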