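#' NGS mutation frequency
#'
#' The fraction of barcodes carrying at least one true mutation inside the
#' window (default the supF window -19..214) over the total number of
#' classified barcodes, with a Wilson score confidence interval.
#'
#' @param records mutation-record data.frame (see [call_mutations()]).
#' @param total_barcodes total number of classified barcodes.
#' @param window supF coordinate interval for the numerator.
#' @param status which record status counts (default `true_mutation`).
#' @param conf confidence level for the interval.
#' @return a list with `frequency`, `n_mutated`, `total`, `ci`.
#' @export
mutation_frequency <- function(records, total_barcodes,
                               window = c(-19L, 214L),
                               status = "true_mutation", conf = 0.95) {
  if (total_barcodes <= 0) stop("total_barcodes must be positive")
  sel <- records$status %in% status &
    records$position >= window[1] & records$position <= window[2]
  n_mut <- length(unique(records$barcode[sel]))
  list(frequency = n_mut / total_barcodes,
       n_mutated = n_mut,
       total = total_barcodes,
       ci = wilson_ci(n_mut, total_barcodes, conf))
}

#' The 192 substitution-in-context class labels
#'
#' All 12 substitution types (4 reference bases x 3 alternates) in all 16
#' flanking-base combinations, as labels like `T[C>T]A`.
#'
#' @return character vector of 192 class labels.
#' @export
spectrum_classes <- function() {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (ref in bases) for (alt in setdiff(bases, ref))
    for (p5 in bases) for (p3 in bases)
      out <- c(out, paste0(p5, "[", ref, ">", alt, "]", p3))
  sort(out)
}

trinuc_label <- function(p5, ref, alt, p3) paste0(p5, "[", ref, ">", alt, "]", p3)

#' Strand-resolved trinucleotide mutation spectrum
#'
#' Counts the SNS records in the 192 substitution-in-context classes, in
#' two strand views: the non-transcribed view takes context and alleles
#' directly from the sense sequence; the transcribed view is the reverse
#' complement transform of each record (a C>T at TCA appears as G>A at
#' TGA). Each SNS contributes one count per view, so the two views are
#' mutually derivable by [strand_transform()] and each totals the SNS
#' record count.
#'
#' @param records mutation-record data.frame; non-SNS rows are ignored.
#' @param ref an [amplicon_reference()].
#' @return an object of class `trinuc_spectrum`: data.frame with columns
#'   `strand`, `context`, `ref`, `alt`, `class`, `count` (384 rows).
#' @export
build_spectrum <- function(records, ref) {
  sns <- records[records$type == "SNS", , drop = FALSE]
  classes <- spectrum_classes()
  counts_nt <- setNames(integer(length(classes)), classes)
  if (nrow(sns) > 0) {
    idx <- map_coordinate(ref, sns$position)
    if (any(idx <= 1L | idx >= nchar(ref$sense_sequence)))
      stop("SNS flank outside the reference sequence")
    p5 <- substring(ref$sense_sequence, idx - 1L, idx - 1L)
    p3 <- substring(ref$sense_sequence, idx + 1L, idx + 1L)
    refb <- substring(ref$sense_sequence, idx, idx)
    if (any(refb != sns$ref))
      stop("SNS ref allele does not match the reference")
    lab <- trinuc_label(p5, refb, sns$alt, p3)
    t1 <- table(lab)
    counts_nt[names(t1)] <- as.integer(t1)
  }
  # transcribed view: reverse-complement transform of each class label
  flip_class <- function(cl) {
    p5 <- substr(cl, 1, 1); rb <- substr(cl, 3, 3)
    ab <- substr(cl, 5, 5); p3 <- substr(cl, 7, 7)
    ctx <- strand_transform(paste0(p5, rb, p3))
    alt <- strand_transform(ab)
    trinuc_label(substr(ctx, 1, 1), substr(ctx, 2, 2), alt, substr(ctx, 3, 3))
  }
  flipped <- vapply(classes, flip_class, character(1))
  counts_tr <- setNames(integer(length(classes)), classes)
  counts_tr[flipped] <- counts_nt[classes]

  parse_ctx <- function(cl) c(paste0(substr(cl, 1, 1), substr(cl, 3, 3),
                                     substr(cl, 7, 7)),
                              substr(cl, 3, 3), substr(cl, 5, 5))
  meta <- t(vapply(classes, parse_ctx, character(3)))
  out <- rbind(
    data.frame(strand = "non_transcribed", context = meta[, 1],
               ref = meta[, 2], alt = meta[, 3], class = classes,
               count = as.integer(counts_nt), stringsAsFactors = FALSE),
    data.frame(strand = "transcribed", context = meta[, 1],
               ref = meta[, 2], alt = meta[, 3], class = classes,
               count = as.integer(counts_tr), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  structure(out, class = c("trinuc_spectrum", "data.frame"))
}

#' Mutation type and substitution breakdowns
#'
#' Proportions over the six variant types, over the 12 SNS substitution
#' classes, and over the DNS sequence classes. Each table sums to 1.
#'
#' @param records mutation-record data.frame.
#' @return a list of named numeric vectors `type_prop`, `sns_prop`,
#'   `dns_prop` (empty inputs give empty tables).
#' @export
summarize_types <- function(records) {
  if (nrow(records) == 0)
    return(list(type_prop = numeric(0), sns_prop = numeric(0),
                dns_prop = numeric(0)))
  type_tab <- table(factor(records$type, levels = variant_types()))
  sns <- records[records$type == "SNS", , drop = FALSE]
  sns_tab <- if (nrow(sns) > 0) table(paste0(sns$ref, ">", sns$alt))
             else table(character(0))
  dns <- records[records$type == "DNS", , drop = FALSE]
  dns_tab <- if (nrow(dns) > 0) table(paste0(dns$ref, ">", dns$alt))
             else table(character(0))
  prop <- function(tab) {
    if (sum(tab) == 0) return(numeric(0))
    p <- as.numeric(tab) / sum(tab)
    names(p) <- names(tab)
    p
  }
  list(type_prop = prop(type_tab), sns_prop = prop(sns_tab),
       dns_prop = prop(dns_tab))
}

#' Per-barcode multi-mutation profile
#'
#' Counts true mutations per barcode, stratifies type and SNS-substitution
#' breakdowns into single-mutation versus multi-mutation barcodes, and
#' tabulates pairwise type combinations within multi-mutation barcodes.
#'
#' @param records mutation-record data.frame; only `true_mutation` rows
#'   are profiled.
#' @return a list with `per_barcode` (data.frame barcode, n_mut, types),
#'   `count_table` (mutations-per-barcode distribution), `single` and
#'   `multiple` (type summaries from [summarize_types()]), and
#'   `combinations` (6x6 symmetric matrix of within-barcode type pairs).
#' @export
multi_mutation_profile <- function(records) {
  rec <- records[records$status == "true_mutation", , drop = FALSE]
  if (nrow(rec) == 0) {
    return(list(per_barcode = data.frame(barcode = character(0),
                                         n_mut = integer(0),
                                         types = character(0),
                                         stringsAsFactors = FALSE),
                count_table = table(integer(0)),
                single = summarize_types(rec[0, , drop = FALSE]),
                multiple = summarize_types(rec[0, , drop = FALSE]),
                combinations = matrix(0L, 6, 6,
                                      dimnames = list(variant_types(),
                                                      variant_types()))))
  }
  sp <- split(rec, rec$barcode)
  per_barcode <- data.frame(
    barcode = names(sp),
    n_mut = vapply(sp, nrow, integer(1)),
    types = vapply(sp, function(x)
      paste(sort(x$type), collapse = "+"), character(1)),
    stringsAsFactors = FALSE)
  rownames(per_barcode) <- NULL
  multi_bc <- per_barcode$barcode[per_barcode$n_mut > 1]
  comb <- matrix(0L, 6, 6, dimnames = list(variant_types(), variant_types()))
  for (bc in multi_bc) {
    tt <- sp[[bc]]$type
    for (a in seq_len(length(tt) - 1L)) for (b in (a + 1L):length(tt)) {
      t1 <- sort(c(tt[a], tt[b]))
      comb[t1[1], t1[2]] <- comb[t1[1], t1[2]] + 1L
    }
  }
  list(per_barcode = per_barcode,
       count_table = table(per_barcode$n_mut),
       single = summarize_types(
         rec[!rec$barcode %in% multi_bc, , drop = FALSE]),
       multiple = summarize_types(
         rec[rec$barcode %in% multi_bc, , drop = FALSE]),
       combinations = comb)
}

#' Inter-SNS distance versus the sequence-based null
#'
#' Observed: all within-barcode pairwise distances between true-mutation
#' SNSs (coordinate-gap aware, i.e. measured on sequence indices so the
#' missing position 0 costs nothing). Null: the exact distribution of
#' distances between pairs drawn uniformly without replacement from the
#' eligible-site set, enumerated over all site pairs; defaults to all C/G
#' positions in the window, matching the observation that multi-mutation
#' substitutions come almost exclusively from C or G.
#'
#' @param records mutation-record data.frame.
#' @param ref an [amplicon_reference()].
#' @param window supF coordinate interval for the eligible-site set.
#' @param eligible `"CG"` (default), `"all"`, or an integer vector of supF
#'   positions.
#' @return a list with `observed` (numeric distances), `observed_mean`,
#'   `null_distances`, `null_mean`, and `rank_test` (Wilcoxon rank-sum of
#'   observed against the null enumeration; NULL when no multi-SNS
#'   barcode exists).
#' @export
inter_sns_distance <- function(records, ref, window = ref$supf_window,
                               eligible = "CG") {
  sns <- records[records$type == "SNS" &
                   records$status == "true_mutation", , drop = FALSE]
  obs <- numeric(0)
  if (nrow(sns) > 0) {
    sp <- split(map_coordinate(ref, sns$position), sns$barcode)
    for (ix in sp) {
      if (length(ix) < 2) next
      d <- abs(as.numeric(dist(ix)))
      obs <- c(obs, d)
    }
  }
  sites <- if (is.numeric(eligible)) {
    map_coordinate(ref, as.integer(eligible))
  } else {
    win_idx <- map_coordinate(ref, window)
    idx <- seq(win_idx[1], win_idx[2])
    base <- substring(ref$sense_sequence, idx, idx)
    if (identical(eligible, "CG")) idx[base %in% c("C", "G")] else idx
  }
  if (length(sites) < 2) stop("need at least two eligible sites")
  null_d <- as.numeric(dist(sites))
  rank_test <- if (length(obs) > 0)
    suppressWarnings(wilcox.test(obs, null_d, alternative = "less"))
  else NULL
  list(observed = obs,
       observed_mean = if (length(obs) > 0) mean(obs) else NA_real_,
       null_distances = null_d,
       null_mean = mean(null_d),
       rank_test = rank_test)
}

#' Bar plot of a trinucleotide spectrum
#'
#' One panel per strand view, 192 classes on the horizontal axis, in the
#' conventional substitution-type colouring. Requires ggplot2.
#'
#' @param spectrum a `trinuc_spectrum` from [build_spectrum()].
#' @return a ggplot object.
#' @export
plot_spectrum <- function(spectrum) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_spectrum requires the ggplot2 package")
  df <- as.data.frame(spectrum)
  df$substitution <- paste0(df$ref, ">", df$alt)
  ggplot2::ggplot(df, ggplot2::aes(x = class, y = count,
                                   fill = substitution)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~strand, ncol = 1) +
    ggplot2::theme_minimal(base_size = 7) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5)) +
    ggplot2::labs(x = "trinucleotide context", y = "SNS count")
}
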