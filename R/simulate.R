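#' Generate a barcoded plasmid library
#'
#' Draws `n_barcodes` unique random 12-mers (alphabet ACGT) and inserts each
#' into the reference's N12 slot between the anchors. Barcodes containing an
#' anchor hexamer are rejected during sampling so that anchored extraction
#' stays well-posed on truth data.
#'
#' @param n_barcodes number of distinct barcodes (lineages) to generate.
#' @param ref an [amplicon_reference()].
#' @param seed integer seed; the library is deterministic given the seed.
#' @return a list of class `supf_library` with elements `barcodes`
#'   (character), `sequences` (barcoded sense sequences, one per barcode)
#'   and `ref`.
#' @export
generate_library <- function(n_barcodes, ref = supf_reference(), seed = 1L) {
  n_barcodes <- as.integer(n_barcodes)
  bl <- ref$barcode_length
  if (4^bl <= n_barcodes * 10)
    stop("barcode space too small for the requested library size")
  barcodes <- withr::with_seed(seed, {
    out <- character(0)
    tries <- 0L
    while (length(out) < n_barcodes) {
      tries <- tries + 1L
      if (tries > 1000L) stop("barcode generation failed to converge")
      need <- n_barcodes - length(out)
      mat <- matrix(sample(c("A", "C", "G", "T"), need * bl, replace = TRUE),
                    nrow = need)
      cand <- apply(mat, 1L, paste, collapse = "")
      cand <- cand[!grepl(ref$upstream_anchor, cand, fixed = TRUE) &
                   !grepl(ref$downstream_anchor, cand, fixed = TRUE)]
      out <- unique(c(out, cand))
    }
    out[seq_len(n_barcodes)]
  })
  structure(list(barcodes = barcodes,
                 sequences = barcoded_sequence(ref, barcodes),
                 ref = ref),
            class = "supf_library")
}

#' Mutagenesis model for the simulator
#'
#' Per-molecule Bernoulli lesion model emulating the UV mutation signature:
#' C>T single-nucleotide substitutions at dipyrimidine (TC/CC) sites, CC>TT
#' tandem dinucleotide substitutions, GAG>AAA triplet replacements, 1-nt
#' deletions, and a spontaneous background. Probabilities are per eligible
#' site per molecule; `dose` scales the lesion classes (not the background).
#' `strand_bias` is the fraction of lesions placed on the non-transcribed
#' strand (lesions on the transcribed strand appear as G>A / GG>AA /
#' CTC>TTT on the sense sequence).
#'
#' @param p_sns_dipyrimidine per-site probability of a C>T at a TC/CC site.
#' @param p_dns_cc_tt per-site probability of a tandem CC>TT.
#' @param p_delin_triplet per-site probability of a GAG>AAA triplet event.
#' @param p_one_del per-molecule probability of a single 1-nt deletion.
#' @param p_background per-site spontaneous substitution rate (any position,
#'   random alternative base; not scaled by `dose`).
#' @param strand_bias fraction of lesions on the non-transcribed strand.
#' @param dose arbitrary dose scalar multiplying the lesion probabilities.
#' @return a list of class `mutagenesis_model`.
#' @export
mutagenesis_model <- function(p_sns_dipyrimidine = 3e-4,
                              p_dns_cc_tt = 2e-5,
                              p_delin_triplet = 2e-5,
                              p_one_del = 1e-5,
                              p_background = 0,
                              strand_bias = 0.5,
                              dose = 1) {
  probs <- c(p_sns_dipyrimidine, p_dns_cc_tt, p_delin_triplet,
             p_one_del, p_background, strand_bias)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (dose < 0) stop("dose must be nonnegative")
  structure(list(p_sns_dipyrimidine = p_sns_dipyrimidine,
                 p_dns_cc_tt = p_dns_cc_tt,
                 p_delin_triplet = p_delin_triplet,
                 p_one_del = p_one_del,
                 p_background = p_background,
                 strand_bias = strand_bias,
                 dose = dose),
            class = "mutagenesis_model")
}

#' Eligible lesion sites for a mutagenesis model
#'
#' Enumerates, on the reference, the sites each event class can hit inside
#' `window`: dipyrimidine C sites (sense C preceded by C/T for the
#' non-transcribed strand; sense G followed by A/G for the transcribed
#' strand), CC/GG tandems, GAG/CTC triplets. Anchors and the barcode slot
#' are always excluded.
#'
#' @param ref an [amplicon_reference()].
#' @param window supF coordinate interval (default the analysis window).
#' @return a data.frame with columns `class` (`sns`, `dns`, `delin`),
#'   `strand`, `position` (supF coordinate of the leftmost affected base),
#'   `ref`, `alt`.
#' @export
eligible_sites <- function(ref, window = ref$analysis_window) {
  chars <- strsplit(ref$sense_sequence, "", fixed = TRUE)[[1]]
  idx_range <- map_coordinate(ref, window)
  idx <- seq(idx_range[1], idx_range[2])
  masked <- seq(ref$anchor_index_range[1], ref$anchor_index_range[2])

  ok1 <- function(i) all(!(i %in% masked)) && !anyNA(chars[i]) &&
    all(chars[i] != "N")
  rows <- list()
  add <- function(class, strand, i, ref_a, alt_a) {
    rows[[length(rows) + 1L]] <<- data.frame(
      class = class, strand = strand,
      position = index_to_position(ref, i),
      ref = ref_a, alt = alt_a, stringsAsFactors = FALSE)
  }
  for (i in idx) {
    b <- chars[i]
    if (b == "C" && i > 1L && chars[i - 1L] %in% c("C", "T") && ok1(i))
      add("sns", "non_transcribed", i, "C", "T")
    if (b == "G" && i < length(chars) && chars[i + 1L] %in% c("A", "G") && ok1(i))
      add("sns", "transcribed", i, "G", "A")
    if (i < idx_range[2]) {
      b2 <- chars[i + 1L]
      if (b == "C" && b2 == "C" && ok1(c(i, i + 1L)))
        add("dns", "non_transcribed", i, "CC", "TT")
      if (b == "G" && b2 == "G" && ok1(c(i, i + 1L)))
        add("dns", "transcribed", i, "GG", "AA")
    }
    if (i + 2L <= idx_range[2]) {
      tri <- paste(chars[i:(i + 2L)], collapse = "")
      if (tri == "GAG" && ok1(i:(i + 2L)))
        add("delin", "non_transcribed", i, "GAG", "AAA")
      if (tri == "CTC" && ok1(i:(i + 2L)))
        add("delin", "transcribed", i, "CTC", "TTT")
    }
  }
  if (length(rows) == 0)
    return(data.frame(class = character(0), strand = character(0),
                      position = integer(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Inject mutations into a barcoded library
#'
#' Samples Bernoulli lesion events per molecule at the model's eligible
#' sites and returns the mutated library together with a ground-truth
#' table. Events never touch the anchors or the barcode slot; overlapping
#' events within one molecule are resolved by keeping the first-drawn event.
#' With `dose = 0` and zero background the truth table is empty.
#'
#' @param library a `supf_library` from [generate_library()].
#' @param model a [mutagenesis_model()].
#' @param seed integer seed.
#' @param window supF coordinate interval in which events are placed
#'   (default the analysis window).
#' @return a list of class `supf_mutlib`: `library`, `mutated_sequences`
#'   (one per barcode), and `truth` (data.frame barcode, position, ref,
#'   alt, type).
#' @export
apply_mutagenesis <- function(library, model, seed = 1L,
                              window = library$ref$analysis_window) {
  ref <- library$ref
  sites <- eligible_sites(ref, window)
  n_bc <- length(library$barcodes)
  chars_ref <- strsplit(ref$sense_sequence, "", fixed = TRUE)[[1]]

  # per-class site probability; strand_bias splits the lesion budget
  site_prob <- function(cls, strand) {
    p <- switch(cls,
                sns = model$p_sns_dipyrimidine,
                dns = model$p_dns_cc_tt,
                delin = model$p_delin_triplet)
    w <- if (strand == "non_transcribed") 2 * model$strand_bias
         else 2 * (1 - model$strand_bias)
    min(1, p * model$dose * w)
  }

  truth <- withr::with_seed(seed, {
    events <- list()
    if (nrow(sites) > 0) {
      p_site <- mapply(site_prob, sites$class, sites$strand)
      hit <- matrix(runif(n_bc * nrow(sites)) < rep(p_site, each = n_bc),
                    nrow = n_bc)
      wh <- which(hit, arr.ind = TRUE)
      if (nrow(wh) > 0) {
        events[[length(events) + 1L]] <- data.frame(
          barcode = library$barcodes[wh[, 1L]],
          position = sites$position[wh[, 2L]],
          ref = sites$ref[wh[, 2L]],
          alt = sites$alt[wh[, 2L]],
          stringsAsFactors = FALSE)
      }
    }
    # single 1-nt deletions, uniform over unmasked window positions;
    # recorded left-aligned so truth matches normalized variant records
    del_mol <- which(runif(n_bc) < min(1, model$p_one_del * model$dose))
    if (length(del_mol) > 0) {
      idx_range <- map_coordinate(ref, window)
      cand <- setdiff(seq(idx_range[1], idx_range[2]),
                      seq(ref$anchor_index_range[1], ref$anchor_index_range[2]))
      pick <- sample(cand, length(del_mol), replace = TRUE)
      pick <- vapply(pick, function(i) {
        while (i > 1L && chars_ref[i - 1L] == chars_ref[i]) i <- i - 1L
        i
      }, integer(1))
      events[[length(events) + 1L]] <- data.frame(
        barcode = library$barcodes[del_mol],
        position = index_to_position(ref, pick),
        ref = chars_ref[pick],
        alt = "",
        stringsAsFactors = FALSE)
    }
    # spontaneous background substitutions, any unmasked window position
    if (model$p_background > 0) {
      idx_range <- map_coordinate(ref, window)
      cand <- setdiff(seq(idx_range[1], idx_range[2]),
                      seq(ref$anchor_index_range[1], ref$anchor_index_range[2]))
      hit <- matrix(runif(n_bc * length(cand)) < model$p_background,
                    nrow = n_bc)
      wh <- which(hit, arr.ind = TRUE)
      if (nrow(wh) > 0) {
        i <- cand[wh[, 2L]]
        alts <- vapply(chars_ref[i], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1L)
        }, character(1))
        events[[length(events) + 1L]] <- data.frame(
          barcode = library$barcodes[wh[, 1L]],
          position = index_to_position(ref, i),
          ref = chars_ref[i],
          alt = unname(alts),
          stringsAsFactors = FALSE)
      }
    }
    if (length(events) == 0) {
      data.frame(barcode = character(0), position = integer(0),
                 ref = character(0), alt = character(0),
                 stringsAsFactors = FALSE)
    } else {
      ev <- do.call(rbind, events)
      # keep events in the same molecule at least 3 positions apart so
      # that distinct lesions stay distinct observations (the variant
      # extractor merges differences separated by <= 1 matching base)
      ev$start <- map_coordinate(ref, ev$position)
      ev$end <- ev$start + pmax(nchar(ev$ref), 1L) - 1L
      keep <- rep(TRUE, nrow(ev))
      sp <- split(seq_len(nrow(ev)), ev$barcode)
      for (ii in sp) {
        if (length(ii) < 2L) next
        taken <- integer(0)
        for (k in ii) {
          span <- (ev$start[k] - 2L):(ev$end[k] + 2L)
          if (any(span %in% taken)) keep[k] <- FALSE
          else taken <- c(taken, ev$start[k]:ev$end[k])
        }
      }
      ev <- ev[keep, , drop = FALSE]
      ev <- ev[order(ev$barcode, ev$start), , drop = FALSE]
      ev$start <- NULL
      ev$end <- NULL
      rownames(ev) <- NULL
      ev
    }
  })
  truth$type <- if (nrow(truth) > 0) classify_type(truth$ref, truth$alt)
                else character(0)

  mutated <- library$sequences
  if (nrow(truth) > 0) {
    sp <- split(truth, truth$barcode)
    bc_idx <- match(names(sp), library$barcodes)
    for (k in seq_along(sp)) {
      mutated[bc_idx[k]] <- apply_variants(ref, mutated[bc_idx[k]], sp[[k]])
    }
  }
  structure(list(library = library, mutated_sequences = mutated,
                 truth = truth),
            class = "supf_mutlib")
}

# Apply a variant table (position/ref/alt in supF coordinates) to one
# barcoded sense sequence; applied right-to-left so indices stay valid.
apply_variants <- function(ref, seq, variants) {
  if (nrow(variants) == 0) return(seq)
  idx <- map_coordinate(ref, variants$position)
  ord <- order(idx, decreasing = TRUE)
  for (k in ord) {
    i <- idx[k]
    rl <- nchar(variants$ref[k])
    if (rl > 0 &&
        substr(seq, i, i + rl - 1L) != variants$ref[k])
      stop("variant ref allele does not match the sequence")
    seq <- paste0(substr(seq, 1L, i - 1L),
                  variants$alt[k],
                  substr(seq, i + rl, nchar(seq)))
  }
  seq
}

#' Read-simulation configuration
#'
#' Controls paired-end read synthesis: 200-bp reads, per-barcode coverage
#' (default uniform 200-250 read pairs), the per-base miscall rate, per-
#' position per-read miscall overrides (emulating position-specific
#' base-calling errors such as the supF positions 55/69), the 6-nt sample
#' index, the 0/1/2-nt random stagger on the index primer, and the mutant
#' fraction of molecules within a mutated barcode (1 = fixed mutation,
#' 0.5 = heteroduplex-derived colony).
#'
#' @param read_length read length in nt.
#' @param min_overlap expected minimum pair overlap in nt (validated
#'   against the amplicon length).
#' @param coverage length-2 range (uniform integer) or a single fixed
#'   per-barcode read-pair count.
#' @param p_seq_error per-base miscall probability (uniform random other
#'   base).
#' @param position_error_overrides named list/vector, supF position ->
#'   per-read miscall probability at that position. The miscalled base is
#'   `C` unless the reference base is `C`, then `T`.
#' @param index 6-nt sample index sequence.
#' @param random_prefix logical; prepend 0/1/2 random nucleotides to the
#'   index read.
#' @param mutant_fraction fraction of a mutated barcode's molecules that
#'   carry its mutations.
#' @return a list of class `read_sim_config`.
#' @export
read_sim_config <- function(read_length = 200L,
                            min_overlap = 30L,
                            coverage = c(200L, 250L),
                            p_seq_error = 0,
                            position_error_overrides = list(),
                            index = default_indexes(1L),
                            random_prefix = TRUE,
                            mutant_fraction = 1) {
  if (p_seq_error < 0 || p_seq_error > 1) stop("p_seq_error must be in [0, 1]")
  if (mutant_fraction < 0 || mutant_fraction > 1)
    stop("mutant_fraction must be in [0, 1]")
  if (any(coverage < 1)) stop("coverage must be >= 1")
  if (nchar(index) != 6L) stop("index must be a 6-nt sequence")
  ov <- unlist(position_error_overrides)
  if (length(ov) > 0 && (any(ov < 0 | ov > 1) || is.null(names(ov))))
    stop("position_error_overrides must be named probabilities in [0, 1]")
  structure(list(read_length = as.integer(read_length),
                 min_overlap = as.integer(min_overlap),
                 coverage = as.integer(coverage),
                 p_seq_error = p_seq_error,
                 position_error_overrides = as.list(ov),
                 index = index,
                 random_prefix = isTRUE(random_prefix),
                 mutant_fraction = mutant_fraction),
            class = "read_sim_config")
}

#' Pre-designed multiplexing indexes
#'
#' Deterministic 6-nt sample indexes with pairwise Hamming distance >= 3,
#' built by a greedy scan of all hexamers in lexicographic order, so exact-
#' match demultiplexing is unambiguous even with one or two miscalls.
#'
#' @param n number of indexes to return.
#' @return character vector of `n` hexamers.
#' @export
default_indexes <- function(n) {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(rep(list(bases), 6L), stringsAsFactors = FALSE)
  all6 <- do.call(paste0, rev(grid))  # lexicographic order
  kept <- character(0)
  for (x in all6) {
    if (length(kept) == as.integer(n)) break
    if (all(vapply(kept, function(k) hamming_dist(k, x) >= 3L, logical(1))))
      kept <- c(kept, x)
  }
  if (length(kept) < n) stop("not enough indexes available")
  kept
}

#' Synthesize paired-end reads from a mutated library
#'
#' For each barcode, draws a coverage, samples mutant molecules at the
#' configured mutant fraction, injects per-base and position-specific
#' sequencing errors into the sequenced fragment, and splits it into a
#' 200-bp read pair: R1 = random 0/1/2-nt stagger + 6-nt index + fragment
#' 5' end; R2 = reverse complement of the fragment 3' end. Base qualities
#' are synthetic constant Phred 40.
#'
#' @param mutlib a `supf_mutlib` from [apply_mutagenesis()].
#' @param cfg a [read_sim_config()].
#' @param seed integer seed.
#' @return a list of class `supf_readsim`: `r1`, `r2`, `q1`, `q2`, `ids`,
#'   `truth` (truth table with per-barcode `mutant_fraction` and
#'   `coverage` columns), `barcode_coverage`, `cfg`.
#' @export
synthesize_reads <- function(mutlib, cfg = read_sim_config(), seed = 1L) {
  ref <- mutlib$library$ref
  L <- nchar(ref$sense_sequence)
  if (L >= 2L * cfg$read_length - cfg$min_overlap)
    stop("amplicon too long for the configured read length and overlap")
  n_bc <- length(mutlib$library$barcodes)
  mutated_bc <- unique(mutlib$truth$barcode)

  out <- withr::with_seed(seed, {
    cov <- if (length(cfg$coverage) == 2L)
      sample(cfg$coverage[1]:cfg$coverage[2], n_bc, replace = TRUE)
    else rep(cfg$coverage[1], n_bc)

    is_mut <- mutlib$library$barcodes %in% mutated_bc
    n_mut_reads <- integer(n_bc)
    n_mut_reads[is_mut] <- rbinom(sum(is_mut), cov[is_mut],
                                  cfg$mutant_fraction)

    frag <- c(rep(mutlib$library$sequences, cov - n_mut_reads),
              rep(mutlib$mutated_sequences, n_mut_reads))
    bc_of <- c(rep(mutlib$library$barcodes, cov - n_mut_reads),
               rep(mutlib$library$barcodes, n_mut_reads))
    ord <- sample.int(length(frag))
    frag <- frag[ord]
    bc_of <- bc_of[ord]
    nfr <- length(frag)

    # position-specific per-read miscall overrides
    for (pstr in names(cfg$position_error_overrides)) {
      p <- as.integer(pstr)
      e <- cfg$position_error_overrides[[pstr]]
      i <- map_coordinate(ref, p)
      flip <- which(runif(nfr) < e)
      if (length(flip) > 0) {
        cur <- substr(frag[flip], i, i)
        alt <- ifelse(cur == "C", "T", "C")
        substr(frag[flip], i, i) <- alt
      }
    }
    # uniform per-base miscalls
    if (cfg$p_seq_error > 0) {
      nerr <- rbinom(nfr, nchar(frag), cfg$p_seq_error)
      for (k in which(nerr > 0)) {
        pos <- sample.int(nchar(frag[k]), nerr[k])
        for (i in pos) {
          cur <- substr(frag[k], i, i)
          substr(frag[k], i, i) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
        }
      }
    }

    npre <- if (cfg$random_prefix) sample(0:2, nfr, replace = TRUE)
            else rep(0L, nfr)
    pre <- character(nfr)
    pre[npre > 0] <- random_dna(sum(npre > 0), npre[npre > 0])
    r1 <- substr(paste0(pre, cfg$index, frag), 1L, cfg$read_length)
    r2 <- substr(revcomp(frag), 1L, cfg$read_length)
    list(r1 = r1, r2 = r2, bc_of = bc_of, cov = cov)
  })

  truth <- mutlib$truth
  cov_map <- setNames(out$cov, mutlib$library$barcodes)
  if (nrow(truth) > 0) {
    truth$mutant_fraction <- cfg$mutant_fraction
    truth$coverage <- unname(cov_map[truth$barcode])
  } else {
    truth$mutant_fraction <- numeric(0)
    truth$coverage <- integer(0)
  }

  q <- strrep("I", nchar(out$r1))
  structure(list(r1 = out$r1, r2 = out$r2,
                 q1 = q, q2 = strrep("I", nchar(out$r2)),
                 ids = sprintf("sim_%06d", seq_along(out$r1)),
                 source_barcode = out$bc_of,
                 truth = truth,
                 barcode_coverage = cov_map,
                 cfg = cfg),
            class = "supf_readsim")
}

#' Write simulated reads as a FASTQ pair
#'
#' @param sim a `supf_readsim` from [synthesize_reads()].
#' @param prefix output path prefix; writes `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq` (add `.gz` via `compress`).
#' @param compress write gzip-compressed FASTQ.
#' @return character vector of the two paths, invisibly.
#' @export
write_fastq_pair <- function(sim, prefix, compress = FALSE) {
  ext <- if (compress) ".fastq.gz" else ".fastq"
  p1 <- paste0(prefix, "_R1", ext)
  p2 <- paste0(prefix, "_R2", ext)
  write_fastq(sim$r1, sim$q1, sim$ids, p1)
  write_fastq(sim$r2, sim$q2, sim$ids, p2)
  invisible(c(p1, p2))
}

# FASTQ I/O through Biostrings (Sanger Phred+33).
write_fastq <- function(seqs, quals, ids, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
  names(x) <- ids
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

read_fastq <- function(path) {
  # Biostrings warns about dropping its own internal quality mcols
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  list(seq = unname(as.character(x)),
       qual = unname(as.character(Biostrings::quality(x))),
       ids = names(x))
}

#' Write a simulation truth table as TSV
#' @param sim a `supf_readsim`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(sim, path) {
  utils::write.table(sim$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
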