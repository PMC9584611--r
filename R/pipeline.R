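#' Pipeline configuration
#'
#' Bundles every tunable of the analysis: input paths or in-memory reads,
#' the reference, the sample sheet, and the printed assay parameters —
#' minimum merge overlap 30 nt, anchor strictness 0, more-than-9-reads
#' barcode filter, VF calling threshold 0.1, VF true-mutation threshold
#' 0.4, and the coordinate windows. The configuration is serialisable and
#' echoed into every output directory.
#'
#' @param reads optional in-memory read bundle (`r1`, `r2`, optional `q1`,
#'   `q2`), e.g. a `supf_readsim`.
#' @param fastq1,fastq2 optional FASTQ paths (used when `reads` is NULL).
#' @param ref an [amplicon_reference()].
#' @param sample_sheet named character vector, sample name -> 6-nt index.
#' @param whitelist optional known barcode whitelist (character vector).
#' @param min_overlap minimum read-pair overlap (nt).
#' @param max_mismatch_rate maximum mismatch fraction in the overlap.
#' @param anchor_mismatch allowed substitutions per anchor (0 = strict).
#' @param min_reads_per_bc minimum reads per barcode for calling (10 =
#'   the more-than-9-reads rule); also the whitelist count floor.
#' @param vf_call VF threshold for emitting a call (inclusive).
#' @param vf_true VF threshold for true-mutation status (inclusive).
#' @param merge_gap matching-column bridge when merging adjacent
#'   differences into complex observations.
#' @param eligible_sites eligible-site set for the distance null.
#' @param seed integer seed recorded with the run.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(reads = NULL, fastq1 = NULL, fastq2 = NULL,
                            ref = supf_reference(),
                            sample_sheet = c(sample1 = default_indexes(1L)),
                            whitelist = NULL,
                            min_overlap = 30L,
                            max_mismatch_rate = 0.1,
                            anchor_mismatch = 0L,
                            min_reads_per_bc = 10L,
                            vf_call = 0.1,
                            vf_true = 0.4,
                            merge_gap = 1L,
                            eligible_sites = "CG",
                            seed = 1L) {
  structure(list(reads = reads, fastq1 = fastq1, fastq2 = fastq2,
                 ref = ref, sample_sheet = sample_sheet,
                 whitelist = whitelist,
                 min_overlap = as.integer(min_overlap),
                 max_mismatch_rate = max_mismatch_rate,
                 anchor_mismatch = as.integer(anchor_mismatch),
                 min_reads_per_bc = as.integer(min_reads_per_bc),
                 vf_call = vf_call, vf_true = vf_true,
                 merge_gap = as.integer(merge_gap),
                 eligible_sites = eligible_sites,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Performs every threshold, range and input check and reports the full
#' list of problems (never just the first).
#'
#' @param config a [pipeline_config()].
#' @return character vector of error messages; empty means the
#'   configuration is valid.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  for (nm in c("vf_call", "vf_true", "max_mismatch_rate")) {
    v <- config[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1)
      add(sprintf("%s must be in [0, 1]", nm))
  }
  if (is.numeric(config$vf_call) && is.numeric(config$vf_true) &&
      config$vf_call > config$vf_true)
    add("vf_call must not exceed vf_true")
  if (config$min_overlap < 1L) add("min_overlap must be >= 1")
  if (config$min_reads_per_bc < 1L) add("min_reads_per_bc must be >= 1")
  if (!inherits(config$ref, "amplicon_reference"))
    add("ref must be an amplicon_reference")
  if (length(config$sample_sheet) == 0) add("sample sheet is empty")
  if (anyDuplicated(config$sample_sheet))
    add("sample sheet contains duplicate indexes")
  if (is.null(config$reads)) {
    for (p in c("fastq1", "fastq2")) {
      if (is.null(config[[p]])) add(sprintf("%s path missing", p))
      else if (!file.exists(config[[p]]))
        add(sprintf("%s does not exist: %s", p, config[[p]]))
    }
  }
  errs
}

#' Run the full analysis pipeline
#'
#' Orchestrates demultiplex, pair merging, sense orientation, barcode
#' extraction and whitelist correction, per-barcode variant calling,
#' classification, discrimination, and the spectrum/summary statistics,
#' with per-stage read and barcode accounting. Deterministic given the
#' configuration.
#'
#' @param config a [pipeline_config()].
#' @return a list of class `pipeline_result`: per-sample results (each
#'   with `whitelist`, `n_barcodes`, `profiles`, `records`, `spectrum`,
#'   `type_summary`, `frequency`, `multi`), plus `accounting` and
#'   `config`.
#' @export
run_pipeline <- function(config) {
  errs <- validate_config(config)
  if (length(errs) > 0)
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  ref <- config$ref

  if (!is.null(config$reads)) {
    r1 <- config$reads$r1
    r2 <- config$reads$r2
    q1 <- config$reads$q1 %||% strrep("I", nchar(r1))
    q2 <- config$reads$q2 %||% strrep("I", nchar(r2))
  } else {
    f1 <- read_fastq(config$fastq1)
    f2 <- read_fastq(config$fastq2)
    r1 <- f1$seq; q1 <- f1$qual
    r2 <- f2$seq; q2 <- f2$qual
  }
  if (length(r1) == 0) stop("empty input: no read pairs to analyse")

  accounting <- list(input_pairs = length(r1))
  dmx <- demultiplex(r1, r2, config$sample_sheet, q1 = q1, q2 = q2)
  accounting$demultiplex <- dmx$counts

  results <- list()
  for (sname in names(dmx$samples)) {
    s <- dmx$samples[[sname]]
    acc <- list(pairs = length(s$idx))
    if (length(s$idx) == 0) {
      results[[sname]] <- list(empty = TRUE, accounting = acc)
      next
    }
    mg <- merge_pairs(s$r1, s$r2, s$q1, s$q2,
                      min_overlap = config$min_overlap,
                      max_mismatch_rate = config$max_mismatch_rate)
    acc$merged <- sum(!mg$rejected)
    acc$merge_rejected <- sum(mg$rejected)
    merged <- mg$merged[!mg$rejected]

    ori <- orient_to_sense(merged, ref)
    acc$oriented <- sum(!ori$discarded)
    acc$orient_discarded <- sum(ori$discarded)
    sense <- ori$seq[!ori$discarded]

    usense <- unique(sense)
    ubcs <- extract_barcode(usense, ref,
                            max_anchor_mismatch = config$anchor_mismatch)
    bcs <- ubcs[match(sense, usense)]
    acc$barcode_extracted <- sum(!is.na(bcs))
    acc$barcode_no_extract <- sum(is.na(bcs))

    wl <- if (!is.null(config$whitelist))
      build_whitelist(NULL, known_list = config$whitelist)
    else build_whitelist(table(bcs[!is.na(bcs)]),
                         min_count = config$min_reads_per_bc)
    corrected <- correct_barcode(bcs, wl)
    acc$barcode_assigned <- sum(!is.na(corrected))
    acc$barcode_unassigned <- sum(is.na(corrected)) - sum(is.na(bcs))

    groups <- group_by_barcode(corrected)
    acc$barcode_groups <- length(groups)

    # align unique read sequences once, then attribute per group
    useq <- unique(sense)
    read_var <- lapply(useq, function(sq) {
      aln <- align_read(sq, ref)
      if (aln$unalignable)
        return(list(variants = empty_variants(),
                    covered = c(NA_integer_, NA_integer_),
                    unalignable = TRUE))
      c(extract_read_variants(aln, ref, merge_gap = config$merge_gap),
        list(unalignable = FALSE))
    })
    seq_map <- match(sense, useq)
    unaln <- vapply(read_var, `[[`, logical(1), "unalignable")
    acc$unalignable_reads <- sum(unaln[seq_map], na.rm = TRUE)

    profiles <- lapply(names(groups), function(bc) {
      ridx <- groups[[bc]]
      rv <- read_var[seq_map[ridx]]
      rv <- rv[!vapply(rv, `[[`, logical(1), "unalignable")]
      aggregate_barcode(bc, rv, ref, vf_call = config$vf_call,
                        min_reads = config$min_reads_per_bc)
    })
    names(profiles) <- names(groups)

    records <- call_mutations(profiles, vf_true = config$vf_true)
    true_rec <- records[records$status == "true_mutation", , drop = FALSE]
    n_bc <- length(profiles)
    results[[sname]] <- list(
      whitelist = wl,
      n_barcodes = n_bc,
      profiles = profiles,
      records = records,
      spectrum = build_spectrum(true_rec, ref),
      type_summary = summarize_types(true_rec),
      frequency = if (n_bc > 0)
        mutation_frequency(records, n_bc, window = ref$supf_window)
      else NULL,
      multi = multi_mutation_profile(records),
      accounting = acc)
  }
  structure(list(samples = results,
                 accounting = accounting,
                 config_echo = config_echo(config)),
            class = "pipeline_result")
}

# Serialisable echo of the configuration (paths and scalars only).
config_echo <- function(config) {
  list(sample_sheet = as.list(config$sample_sheet),
       min_overlap = config$min_overlap,
       max_mismatch_rate = config$max_mismatch_rate,
       anchor_mismatch = config$anchor_mismatch,
       min_reads_per_bc = config$min_reads_per_bc,
       vf_call = config$vf_call,
       vf_true = config$vf_true,
       merge_gap = config$merge_gap,
       eligible_sites = config$eligible_sites,
       seed = config$seed,
       reference_length = nchar(config$ref$sense_sequence),
       analysis_window = config$ref$analysis_window)
}

#' Write pipeline results to an output directory
#'
#' Emits, per sample, the mutation-record TSV, the 192-context spectrum
#' TSV and a summary JSON, plus the resolved configuration echo (YAML) and
#' the per-stage accounting. Output is deterministic: rerunning the same
#' configuration reproduces byte-identical summaries.
#'
#' @param result a `pipeline_result` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(result$config_echo, file.path(out_dir, "config.yaml"))
  jsonlite::write_json(result$accounting,
                       file.path(out_dir, "accounting.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (sname in names(result$samples)) {
    s <- result$samples[[sname]]
    if (isTRUE(s$empty)) next
    base <- file.path(out_dir, sname)
    utils::write.table(s$records, paste0(base, "_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(s$spectrum),
                       paste0(base, "_spectrum.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary <- list(
      n_barcodes = s$n_barcodes,
      n_records = nrow(s$records),
      n_true_mutations = sum(s$records$status == "true_mutation"),
      mutation_frequency = s$frequency$frequency,
      type_proportions = as.list(s$type_summary$type_prop),
      accounting = s$accounting)
    jsonlite::write_json(summary, paste0(base, "_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(out_dir)
}

#' Export mutation records as a minimal VCF-like table
#'
#' One row per record: CHROM = `amplicon`, POS = supF coordinate, REF,
#' ALT, INFO carrying VF, barcode and group depth.
#'
#' @param records mutation-record data.frame.
#' @param profiles the profiles list from the pipeline result (for depth).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf_like <- function(records, profiles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2-like",
               "##INFO=<ID=VF,Type=Float>",
               "##INFO=<ID=BC,Type=String>",
               "##INFO=<ID=DP,Type=Integer>",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(records) > 0) {
    dp <- vapply(records$barcode, function(bc)
      profiles[[bc]]$read_count, integer(1))
    writeLines(sprintf(
      "amplicon\t%d\t.\t%s\t%s\t.\t%s\tVF=%g;BC=%s;DP=%d",
      records$position,
      ifelse(records$ref == "", ".", records$ref),
      ifelse(records$alt == "", ".", records$alt),
      ifelse(records$status == "true_mutation", "PASS", "SubThreshold"),
      records$vf, records$barcode, dp), con)
  }
  invisible(path)
}
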