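#' The six variant type labels
#' @return character vector of the six mutually exclusive type labels.
#' @export
variant_types <- function() {
  c("SNS", "DNS", "one_Del", "Del", "Del_in", "INS")
}

#' Classify variant observations into the six types
#'
#' Single-nucleotide substitution (SNS), tandem dinucleotide substitution
#' (DNS), one-nucleotide deletion (one_Del), longer deletion (Del),
#' insertion (INS), and deletion-with-insertion (Del_in, covering all
#' length-changing replacements and same-length replacements of 3 nt or
#' more, such as the triplet GAG>AAA). The six categories are exhaustive
#' and mutually exclusive; both alleles empty is an error.
#'
#' @param ref_allele,alt_allele character vectors of reference and
#'   alternate alleles (empty string = none).
#' @return character vector of type labels.
#' @export
classify_type <- function(ref_allele, alt_allele) {
  lr <- nchar(ref_allele)
  la <- nchar(alt_allele)
  if (any(lr == 0 & la == 0)) stop("observation with both alleles empty")
  out <- character(length(lr))
  out[lr == 1 & la == 1] <- "SNS"
  out[lr == 2 & la == 2] <- "DNS"
  out[lr == 1 & la == 0] <- "one_Del"
  out[lr > 1 & la == 0] <- "Del"
  out[lr == 0 & la > 0] <- "INS"
  rest <- out == ""
  out[rest] <- "Del_in"
  out
}

#' Discriminate true mutations from baseline sequencing errors by VF
#'
#' Bipartitions called variants at the VF threshold (default 0.4,
#' inclusive): `true_mutation` at or above, `sub_threshold` below. Both
#' partitions are preserved; per-position sub-threshold rates are the
#' standard diagnostic for position-specific base-calling errors.
#'
#' @param records mutation-record data.frame with a `vf` column.
#' @param vf_true threshold separating true mutations from errors.
#' @return `records` with a `status` column added (idempotent).
#' @export
discriminate <- function(records, vf_true = 0.4) {
  records$status <- ifelse(records$vf >= vf_true,
                           "true_mutation", "sub_threshold")
  records
}

#' Assign variants to amplicon regions
#'
#' Splits the analysis window at the -20/-19 boundary near the supF start:
#' positions at or left of -20 fall in the barcode cloning region,
#' positions from -19 on in the supF region. Multi-base observations are
#' assigned by their leftmost position.
#'
#' @param position integer vector of supF coordinates (leftmost base).
#' @return character vector, `"barcode_region"` or `"supf_region"`.
#' @export
assign_region <- function(position) {
  ifelse(position <= -20L, "barcode_region", "supf_region")
}

#' Build the mutation-record table from barcode profiles
#'
#' Collects called variants across profiles and annotates type, region
#' and VF status, yielding one row per (barcode, variant).
#'
#' @param profiles list of `barcode_profile` objects.
#' @param vf_true VF threshold for true-mutation status.
#' @return data.frame with columns barcode, position, ref, alt, type, vf,
#'   region, status.
#' @export
call_mutations <- function(profiles, vf_true = 0.4) {
  rows <- lapply(profiles, function(p) {
    v <- p$variants[p$variants$called, , drop = FALSE]
    if (nrow(v) == 0) return(NULL)
    data.frame(barcode = p$barcode, position = v$position, ref = v$ref,
               alt = v$alt, vf = v$vf, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(barcode = character(0), position = integer(0),
                      ref = character(0), alt = character(0),
                      type = character(0), vf = numeric(0),
                      region = character(0), status = character(0),
                      stringsAsFactors = FALSE))
  }
  rec <- do.call(rbind, rows)
  rec$type <- classify_type(rec$ref, rec$alt)
  rec <- discriminate(rec, vf_true = vf_true)
  rec$region <- assign_region(rec$position)
  rec <- rec[order(rec$barcode, rec$position, rec$ref, rec$alt),
             c("barcode", "position", "ref", "alt", "type", "vf",
               "region", "status")]
  rownames(rec) <- NULL
  rec
}
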