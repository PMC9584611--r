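test_that("anchored extraction takes exactly 12 nt between exact anchors", {
  ref <- supf_reference()
  bc <- "ACGTACGTACGT"
  read <- paste0("TTTT", ref$upstream_anchor, bc, ref$downstream_anchor,
                 "GGGG")
  expect_identical(extract_barcode(read, ref), bc)
  # anchor with one substitution -> no extract in strict mode
  mut <- sub("GGCGAT", "GGCGAC", read, fixed = TRUE)
  expect_identical(extract_barcode(mut, ref), NA_character_)
  # ... but recovered in relaxed mode
  expect_identical(extract_barcode(mut, ref, max_anchor_mismatch = 1L), bc)
  # anchors 11 nt apart (1-nt deletion in barcode) -> no extract
  read11 <- paste0("TTTT", ref$upstream_anchor, substr(bc, 1, 11),
                   ref$downstream_anchor, "GGGG")
  expect_identical(extract_barcode(read11, ref), NA_character_)
  # leftmost valid anchor pair wins
  two <- paste0(read, "AA", ref$upstream_anchor, "TTTTTTTTTTTT",
                ref$downstream_anchor)
  expect_identical(extract_barcode(two, ref), bc)
})

test_that("sliding-window oracle confirms strict anchored extraction", {
  ref <- supf_reference()
  withr::with_seed(61, {
    for (rep in 1:25) {
      read <- barcoded_sequence_for_test(ref)
      # possibly damage one random base
      p <- sample(nchar(read), 1)
      substr(read, p, p) <- sample(c("A", "C", "G", "T"), 1)
      got <- extract_barcode(read, ref)
      # oracle: scan all placements of anchor..12..anchor
      want <- NA_character_
      for (i in 1:(nchar(read) - 23)) {
        if (substr(read, i, i + 5) == ref$upstream_anchor &&
            substr(read, i + 18, i + 23) == ref$downstream_anchor) {
          want <- substr(read, i + 6, i + 17)
          break
        }
      }
      expect_identical(got, want)
    }
  })
})

test_that("whitelist separates truth from errors and collapses neighbours", {
  withr::with_seed(62, {
    truth <- replicate(20, random_dna_str(12))
    counts <- setNames(rep(200L, 20), truth)
    # low-count error barcodes
    errs <- replicate(5, random_dna_str(12))
    errs <- setdiff(errs, truth)
    counts <- c(counts, setNames(rep(3L, length(errs)), errs))
    wl <- build_whitelist(counts, min_count = 10L)
    expect_setequal(wl$barcodes, truth)
    # directional collapse: a Hamming-1 neighbour at 5 is absorbed into 300
    x <- truth[1]
    xp <- supfmut:::hamming1_neighbors(x)[1]
    counts2 <- setNames(c(300L, 5L), c(x, xp))
    wl2 <- build_whitelist(counts2, min_count = 10L)
    expect_identical(wl2$barcodes, x)
    expect_identical(unname(wl2$counts[x]), 305L)
    # brute-force check of the absorb decision
    expect_identical(sum(strsplit(x, "")[[1]] != strsplit(xp, "")[[1]]), 1L)
    # a known list is returned unchanged
    wl3 <- build_whitelist(NULL, known_list = truth)
    expect_identical(wl3$barcodes, truth)
    # N-containing barcodes are never whitelisted
    withN <- setNames(c(100L, 100L), c(truth[1], "ACGTNACGTACG"))
    expect_identical(build_whitelist(withN, min_count = 10L)$barcodes,
                     truth[1])
  })
})

test_that("barcode correction matches brute-force distance enumeration", {
  withr::with_seed(63, {
    wl_bc <- unique(replicate(30, random_dna_str(12)))
    wl <- build_whitelist(NULL, known_list = wl_bc)
    # exact member -> itself (idempotence)
    expect_identical(correct_barcode(wl_bc[1], wl), wl_bc[1])
    expect_identical(correct_barcode(correct_barcode(wl_bc[1], wl), wl),
                     wl_bc[1])
    # Hamming-1 from a unique entry -> corrected
    obs1 <- supfmut:::hamming1_neighbors(wl_bc[1])[5]
    if (!obs1 %in% wl_bc)
      expect_identical(correct_barcode(obs1, wl), wl_bc[1])
    # equidistant between two entries -> unassigned
    a <- "AAAAAAAAAAAA"
    b <- "CAAAAAAAAAAC"
    mid <- "CAAAAAAAAAAA"  # Hamming 1 from both
    wl_amb <- build_whitelist(NULL, known_list = c(a, b))
    expect_identical(correct_barcode(mid, wl_amb), NA_character_)
    # randomized agreement with the brute-force oracle
    for (rep in 1:200) {
      obs <- if (runif(1) < 0.5) {
        x <- sample(wl_bc, 1)
        n <- supfmut:::hamming1_neighbors(x)
        n[sample(length(n), 1)]
      } else random_dna_str(12)
      expect_identical(correct_barcode(obs, wl), oracle_correct(obs, wl_bc))
    }
  })
})

test_that("grouping partitions assigned reads by corrected barcode", {
  groups <- group_by_barcode(c("A", "B", "A", NA, "A", "B"))
  expect_identical(lengths(groups), c(A = 3L, B = 2L))
  expect_identical(group_by_barcode(c(NA_character_, NA_character_)),
                   setNames(list(), character(0)))
  # simulated clean data: one group per true barcode
  fix <- small_clean_sim(n_bc = 30, coverage = 12L, seed = 71)
  res <- run_pipeline(pipeline_config(reads = fix$sim, ref = fix$ref,
                                      sample_sheet = c(s1 = fix$sim$cfg$index)))
  expect_identical(res$samples$s1$n_barcodes, 30L)
  expect_setequal(res$samples$s1$whitelist$barcodes, fix$lib$barcodes)
})
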