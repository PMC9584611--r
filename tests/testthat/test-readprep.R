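test_that("demultiplexing tries the 0/1/2-nt stagger offsets in order", {
  idx <- default_indexes(2)
  body <- strrep("ACGT", 20)
  mism <- idx[1]
  substr(mism, 3, 3) <- setdiff(c("C", "G", "T"), substr(mism, 3, 3))[1]
  r1 <- c(paste0(idx[1], body),          # offset 0
          paste0("G", idx[1], body),     # offset 1
          paste0("TG", idx[2], body),    # offset 2
          paste0("TTT", idx[1], body),   # offset 3: unassigned
          paste0(mism, body))            # 1 mismatch in the index
  r2 <- rep(body, 5)
  # the mismatched index must not match either index at any offset
  for (o in 0:2) expect_false(substr(r1[5], o + 1, o + 6) %in% idx)
  dmx <- demultiplex(r1, r2, c(s1 = idx[1], s2 = idx[2]))
  expect_identical(dmx$samples$s1$idx, c(1L, 2L))
  expect_identical(dmx$samples$s2$idx, 3L)
  expect_identical(dmx$undetermined, c(4L, 5L))
  # stagger and index trimmed from R1
  expect_identical(dmx$samples$s1$r1, c(body, body))
  # partition property
  expect_identical(sum(dmx$counts), length(r1))
  # empty index table leaves everything undetermined
  dmx0 <- demultiplex(r1, r2, setNames(character(0), character(0)))
  expect_identical(length(dmx0$undetermined), 5L)
  expect_error(demultiplex(r1, r2, c(a = idx[1], b = idx[1])), "duplicate")
})

test_that("pair merging needs 30 bp overlap and yields the right length", {
  withr::with_seed(51, {
    frag <- random_dna_str(70)
    a <- substr(frag, 1, 50)
    b30 <- revcomp(substr(frag, 21, 70))  # overlap exactly 30
    m <- merge_pairs(a, b30)
    expect_false(m$rejected)
    expect_identical(m$merged, frag)
    expect_identical(nchar(m$merged), 50L + 50L - 30L)
    expect_identical(m$overlap, 30L)
    # best overlap 29 nt -> rejected
    frag2 <- random_dna_str(71)
    a2 <- substr(frag2, 1, 50)
    b29 <- revcomp(substr(frag2, 22, 71))
    expect_true(merge_pairs(a2, b29)$rejected)
  })
})

test_that("overlap disagreements resolve by quality, R1 on ties, N loses", {
  withr::with_seed(52, {
    frag <- random_dna_str(70)
    a <- substr(frag, 1, 50)
    brc <- substring(frag, 11)  # 60 nt; overlap 40 at fragment 11..50
    # disagreement at fragment position 40 (brc position 30)
    substr(brc, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                   substr(brc, 30, 30))[1]
    qa <- strrep("I", 50)
    qb_hi <- paste0(strrep("I", 29), "J", strrep("I", 30))
    m_hi <- merge_pairs(a, revcomp(brc),
                        q1 = qa,
                        q2 = vapply(strsplit(qb_hi, ""), function(x)
                          paste(rev(x), collapse = ""), character(1)))
    expect_identical(m_hi$overlap, 40L)
    expect_identical(substr(m_hi$merged, 40, 40), substr(brc, 30, 30))
    # equal quality keeps the R1 base
    m_tie <- merge_pairs(a, revcomp(brc))
    expect_identical(substr(m_tie$merged, 40, 40), substr(frag, 40, 40))
    # an N in R1 always loses the consensus
    aN <- a
    substr(aN, 45, 45) <- "N"
    mN <- merge_pairs(aN, revcomp(substring(frag, 11)))
    expect_identical(substr(mN$merged, 45, 45), substr(frag, 45, 45))
  })
})

test_that("merging agrees with the exhaustive substr-scan oracle", {
  withr::with_seed(53, {
    for (rep in 1:60) {
      frag <- random_dna_str(sample(65:80, 1))
      a <- substr(frag, 1, 50)
      b_rc <- substr(frag, nchar(frag) - 49, nchar(frag))
      # up to two random mismatches somewhere in R2
      for (k in seq_len(sample(0:2, 1))) {
        p <- sample(50, 1)
        substr(b_rc, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      qa <- strrep("I", 50)
      got <- merge_pairs(a, revcomp(b_rc), q1 = qa, q2 = qa)
      want <- oracle_merge(a, b_rc, qa, qa, 30L, 0.1)
      if (is.null(want)) {
        expect_true(got$rejected)
      } else {
        expect_identical(got$merged, want$seq)
        expect_identical(got$overlap, want$overlap)
      }
    }
  })
})

test_that("merging commutes with orientation normalization on clean pairs", {
  withr::with_seed(54, {
    ref <- supf_reference()
    frag <- barcoded_sequence_for_test(ref)
    a <- substr(frag, 1, 200)
    b <- revcomp(substring(frag, nchar(frag) - 199))
    fwd <- merge_pairs(a, b)$merged
    swapped <- merge_pairs(b, a)$merged
    ori <- orient_to_sense(c(fwd, swapped), ref)
    expect_identical(ori$seq[1], ori$seq[2])
  })
})

test_that("orientation restores antisense reads and discards junk", {
  ref <- supf_reference()
  withr::with_seed(55, {
    lib <- generate_library(3, ref, seed = 56)
    s <- lib$sequences[1]
    res <- orient_to_sense(c(s, revcomp(s), random_dna_str(300)), ref)
    expect_identical(res$seq[1], s)
    expect_identical(res$seq[2], s)  # involution back to sense
    expect_true(res$flipped[2])
    expect_true(res$discarded[3])
  })
})
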