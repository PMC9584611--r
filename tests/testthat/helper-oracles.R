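# Independent brute-force oracles used to validate the implementation.
# These deliberately re-derive results by enumeration or naive scanning,
# not by calling the code paths they check.

# --- alignment oracle: top-down recursion over (i, j, last-op) ----------

# Best completion score aligning read[i+1..n] vs ref[j+1..m] given the
# previous operation ("start", "M", "D", "I"); affine gaps (a length-k gap
# costs open + k * ext). 'N' in ref matches anything; 'N' in read
# mismatches.
oracle_align_score <- function(read, ref, sc = alignment_scoring()) {
  n <- nchar(read)
  m <- nchar(ref)
  rch <- strsplit(read, "", fixed = TRUE)[[1]]
  fch <- strsplit(ref, "", fixed = TRUE)[[1]]
  memo <- new.env(hash = TRUE, parent = emptyenv())
  sub_sc <- function(a, b) {
    if (b == "N") sc$match
    else if (a == "N") sc$mismatch
    else if (a == b) sc$match else sc$mismatch
  }
  rec <- function(i, j, last) {
    if (i == n && j == m) return(0)
    key <- paste(i, j, last)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    if (i < n && j < m)
      best <- max(best, sub_sc(rch[i + 1], fch[j + 1]) + rec(i + 1, j + 1, "M"))
    if (j < m) {
      cost <- sc$gap_extend + if (last == "D") 0 else sc$gap_open
      best <- max(best, cost + rec(i, j + 1, "D"))
    }
    if (i < n) {
      cost <- sc$gap_extend + if (last == "I") 0 else sc$gap_open
      best <- max(best, cost + rec(i + 1, j, "I"))
    }
    memo[[key]] <- best
    best
  }
  rec(0, 0, "start")
}

# Enumerate every co-optimal alignment (as aligned read/ref string pairs),
# capped to avoid pathological blowup.
oracle_optimal_alignments <- function(read, ref, sc = alignment_scoring(),
                                      cap = 5000L) {
  n <- nchar(read)
  m <- nchar(ref)
  rch <- strsplit(read, "", fixed = TRUE)[[1]]
  fch <- strsplit(ref, "", fixed = TRUE)[[1]]
  memo <- new.env(hash = TRUE, parent = emptyenv())
  sub_sc <- function(a, b) {
    if (b == "N") sc$match
    else if (a == "N") sc$mismatch
    else if (a == b) sc$match else sc$mismatch
  }
  rec <- function(i, j, last) {
    if (i == n && j == m) return(0)
    key <- paste(i, j, last)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    if (i < n && j < m)
      best <- max(best, sub_sc(rch[i + 1], fch[j + 1]) + rec(i + 1, j + 1, "M"))
    if (j < m) {
      cost <- sc$gap_extend + if (last == "D") 0 else sc$gap_open
      best <- max(best, cost + rec(i, j + 1, "D"))
    }
    if (i < n) {
      cost <- sc$gap_extend + if (last == "I") 0 else sc$gap_open
      best <- max(best, cost + rec(i + 1, j, "I"))
    }
    memo[[key]] <- best
    best
  }
  out <- list()
  walk <- function(i, j, last, ar, af) {
    if (length(out) >= cap) return()
    if (i == n && j == m) {
      out[[length(out) + 1L]] <<- list(aligned_read = ar, aligned_ref = af)
      return()
    }
    target <- rec(i, j, last)
    if (i < n && j < m &&
        sub_sc(rch[i + 1], fch[j + 1]) + rec(i + 1, j + 1, "M") == target)
      walk(i + 1, j + 1, "M", paste0(ar, rch[i + 1]), paste0(af, fch[j + 1]))
    if (j < m) {
      cost <- sc$gap_extend + if (last == "D") 0 else sc$gap_open
      if (cost + rec(i, j + 1, "D") == target)
        walk(i, j + 1, "D", paste0(ar, "-"), paste0(af, fch[j + 1]))
    }
    if (i < n) {
      cost <- sc$gap_extend + if (last == "I") 0 else sc$gap_open
      if (cost + rec(i + 1, j, "I") == target)
        walk(i + 1, j, "I", paste0(ar, rch[i + 1]), paste0(af, "-"))
    }
  }
  walk(0, 0, "start", "", "")
  out
}

# Normalise an aligned string pair to a canonical set of variant tuples
# "index:ref>alt" (runs of non-match columns bridged across <= merge_gap
# matching columns; pure indels left-aligned against the plain reference).
# Shared small pure function applied to alignments from either route.
variant_tuples <- function(aligned_read, aligned_ref, plain_ref,
                           merge_gap = 1L) {
  ar <- strsplit(aligned_read, "", fixed = TRUE)[[1]]
  af <- strsplit(aligned_ref, "", fixed = TRUE)[[1]]
  ref_index <- cumsum(af != "-")
  is_match <- (ar == af | af == "N") & ar != "-"
  dc <- which(!is_match)
  if (length(dc) == 0) return(character(0))
  grp <- cumsum(c(1L, diff(dc) > merge_gap + 1L))
  refchars <- strsplit(plain_ref, "", fixed = TRUE)[[1]]
  vapply(split(dc, grp), function(cols) {
    span <- min(cols):max(cols)
    ra <- paste(af[span][af[span] != "-"], collapse = "")
    aa <- paste(ar[span][ar[span] != "-"], collapse = "")
    i <- ref_index[min(cols)]
    if (af[min(cols)] == "-") i <- i + 1L
    if (nchar(ra) == 0 || nchar(aa) == 0) {
      allele <- if (nchar(ra) > 0) ra else aa
      ach <- strsplit(allele, "", fixed = TRUE)[[1]]
      while (i > 1L && refchars[i - 1L] == ach[length(ach)]) {
        ach <- c(refchars[i - 1L], ach[-length(ach)])
        i <- i - 1L
      }
      if (nchar(ra) > 0) ra <- paste(ach, collapse = "")
      else aa <- paste(ach, collapse = "")
    }
    paste0(i, ":", ra, ">", aa)
  }, character(1), USE.NAMES = FALSE)
}

# --- naive merge oracle: substr-based double loop -----------------------

oracle_merge <- function(a, b_rc, qa, qb_rc, min_overlap, max_mm_rate) {
  la <- nchar(a)
  lb <- nchar(b_rc)
  best <- NULL
  o_max <- min(la, lb)
  if (o_max >= min_overlap) {
    for (o in min_overlap:o_max) {
      matches <- 0L
      for (p in 1:o) {
        x <- substr(a, la - o + p, la - o + p)
        y <- substr(b_rc, p, p)
        if (x == y && x != "N") matches <- matches + 1L
      }
      if ((o - matches) / o <= max_mm_rate &&
          (is.null(best) || matches > best$matches ||
           (matches == best$matches && o > best$o)))
        best <- list(o = o, matches = matches)
    }
  }
  if (is.null(best)) return(NULL)
  o <- best$o
  cons <- character(o)
  for (p in 1:o) {
    x <- substr(a, la - o + p, la - o + p)
    y <- substr(b_rc, p, p)
    qx <- utf8ToInt(substr(qa, la - o + p, la - o + p))
    qy <- utf8ToInt(substr(qb_rc, p, p))
    cons[p] <- if (x == "N" && y != "N") y
    else if (y == "N" && x != "N") x
    else if (qy > qx) y else x
  }
  list(seq = paste0(substr(a, 1, la - o), paste(cons, collapse = ""),
                    substr(b_rc, o + 1, lb)),
       overlap = o)
}

# --- barcode correction oracle: full distance scan ----------------------

oracle_correct <- function(observed, whitelist) {
  d <- vapply(whitelist, function(w) {
    sum(strsplit(observed, "")[[1]] != strsplit(w, "")[[1]])
  }, integer(1))
  if (any(d == 0)) return(observed)
  hits <- whitelist[d == 1]
  if (length(hits) == 1) hits else NA_character_
}

# --- shared fixtures ----------------------------------------------------

# Small clean simulation reused across test files.
small_clean_sim <- function(n_bc = 40, coverage = 15L, seed = 101) {
  ref <- supf_reference()
  lib <- generate_library(n_bc, ref, seed = seed)
  mod <- mutagenesis_model(p_sns_dipyrimidine = 0.003, p_dns_cc_tt = 0.01,
                           p_delin_triplet = 0.05, p_one_del = 0.05,
                           dose = 1)
  ml <- apply_mutagenesis(lib, mod, seed = seed + 1)
  sim <- synthesize_reads(ml, read_sim_config(coverage = coverage),
                          seed = seed + 2)
  list(ref = ref, lib = lib, ml = ml, sim = sim)
}

random_dna_str <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# One concrete barcoded amplicon sequence (uses the current RNG stream).
barcoded_sequence_for_test <- function(ref) {
  bc <- random_dna_str(ref$barcode_length)
  sub(strrep("N", ref$barcode_length), bc, ref$sense_sequence, fixed = TRUE)
}
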