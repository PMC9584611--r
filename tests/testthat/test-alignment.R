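test_that("trivial alignments behave as expected", {
  ref <- supf_reference()
  s <- ref$sense_sequence
  a <- align_read(s, ref)
  expect_identical(a$aligned_read, s)
  expect_false(grepl("-", a$aligned_read, fixed = TRUE))
  expect_identical(a$identity, 1)
  # single substitution -> exactly one mismatch column
  s2 <- s
  substr(s2, 150, 150) <- setdiff(c("A", "C", "G", "T"),
                                  substr(s, 150, 150))[1]
  a2 <- align_read(s2, ref)
  ar <- strsplit(a2$aligned_read, "")[[1]]
  af <- strsplit(a2$aligned_ref, "")[[1]]
  expect_identical(sum(ar != af & af != "N"), 1L)
  expect_identical(a2$score, a$score - 5)  # lost match, gained mismatch
})

test_that("alignment scores and variants match the brute-force oracle", {
  sc <- alignment_scoring()
  withr::with_seed(81, {
    for (rep in 1:200) {
      read <- random_dna_str(sample(1:12, 1))
      ref <- random_dna_str(sample(1:12, 1))
      got <- align_read(read, ref, min_identity = 0)
      want <- oracle_align_score(read, ref, sc)
      expect_identical(got$score, want)
      # gap-stripped alignment reproduces the inputs
      expect_identical(gsub("-", "", got$aligned_read), read)
      expect_identical(gsub("-", "", got$aligned_ref), ref)
      # the chosen alignment's normalized variants appear among the
      # variant decompositions of the co-optimal alignment set
      opts <- oracle_optimal_alignments(read, ref, sc)
      got_v <- paste(sort(variant_tuples(got$aligned_read, got$aligned_ref,
                                         ref)), collapse = ";")
      opt_v <- vapply(opts, function(o)
        paste(sort(variant_tuples(o$aligned_read, o$aligned_ref, ref)),
              collapse = ";"), character(1))
      expect_true(got_v %in% opt_v)
    }
  })
})

test_that("a 12-nt insertion toy case scores like exhaustive enumeration", {
  sc <- alignment_scoring()
  ref <- "ACGTACGTACGT"
  read <- "ACGTAACGTACGT"  # one inserted A
  got <- align_read(read, ref, min_identity = 0)
  expect_identical(got$score, oracle_align_score(read, ref, sc))
  expect_identical(got$score, 12 * sc$match + sc$gap_open + sc$gap_extend)
})

test_that("low-identity reads are flagged unalignable", {
  ref <- supf_reference()
  withr::with_seed(82, {
    junk <- random_dna_str(80)
    expect_true(align_read(junk, ref)$unalignable)
  })
})

test_that("variant extraction merges tandems and bridged triplets", {
  ref <- supf_reference()
  # GAG -> AAA at positions 73-75 is ONE 3-nt replacement observation
  idx <- map_coordinate(ref, 73L)
  expect_identical(substr(ref$sense_sequence, idx, idx + 2L), "GAG")
  mut <- ref$sense_sequence
  substr(mut, idx, idx + 2L) <- "AAA"
  v <- extract_read_variants(align_read(mut, ref), ref)$variants
  expect_identical(nrow(v), 1L)
  expect_identical(v$position, 73L)
  expect_identical(v$ref, "GAG")
  expect_identical(v$alt, "AAA")
  expect_identical(classify_type(v$ref, v$alt), "Del_in")
  # CC -> TT is one dinucleotide observation, not two SNSs
  sites <- eligible_sites(ref, ref$supf_window)
  cc <- sites[sites$class == "dns" & sites$strand == "non_transcribed", ][1, ]
  i <- map_coordinate(ref, cc$position)
  mut2 <- ref$sense_sequence
  substr(mut2, i, i + 1L) <- "TT"
  v2 <- extract_read_variants(align_read(mut2, ref), ref)$variants
  expect_identical(nrow(v2), 1L)
  expect_identical(v2$ref, "CC")
  expect_identical(v2$alt, "TT")
  # two substitutions three positions apart stay separate observations
  mut3 <- ref$sense_sequence
  i3 <- map_coordinate(ref, 100L)
  for (off in c(0L, 3L)) {
    b <- substr(mut3, i3 + off, i3 + off)
    substr(mut3, i3 + off, i3 + off) <- setdiff(c("A", "C", "G", "T"), b)[1]
  }
  v3 <- extract_read_variants(align_read(mut3, ref), ref)$variants
  expect_identical(nrow(v3), 2L)
})

test_that("deletions left-align to the start of homopolymer runs", {
  ref <- supf_reference()
  chars <- strsplit(ref$sense_sequence, "")[[1]]
  # find a homopolymer run of length >= 2 inside the supF window
  win <- map_coordinate(ref, ref$supf_window)
  run_start <- NA
  for (i in seq(win[1] + 5L, win[2] - 5L)) {
    if (chars[i] == chars[i + 1L] && chars[i - 1L] != chars[i]) {
      run_start <- i
      break
    }
  }
  expect_false(is.na(run_start))
  run_len <- 1L
  while (chars[run_start + run_len] == chars[run_start]) run_len <- run_len + 1L
  # delete each base of the run in turn: all shifted representations
  # must normalise to the same leftmost observation
  for (del_at in run_start:(run_start + run_len - 1L)) {
    mut <- paste0(substr(ref$sense_sequence, 1L, del_at - 1L),
                  substring(ref$sense_sequence, del_at + 1L))
    v <- extract_read_variants(align_read(mut, ref), ref)$variants
    expect_identical(nrow(v), 1L)
    expect_identical(map_coordinate(ref, v$position), run_start)
    expect_identical(v$alt, "")
  }
})

test_that("extracted variants reconstruct the read (round-trip)", {
  fix <- small_clean_sim(n_bc = 25, coverage = 5L, seed = 91)
  ref <- fix$ref
  mut_bc <- unique(fix$ml$truth$barcode)
  for (bc in head(mut_bc, 10)) {
    mseq <- fix$ml$mutated_sequences[match(bc, fix$lib$barcodes)]
    v <- extract_read_variants(align_read(mseq, ref), ref)$variants
    rebuilt <- supfmut:::apply_variants(ref,
                                        supfmut:::barcoded_sequence(ref, bc),
                                        v)
    expect_identical(rebuilt, mseq)
  }
})
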