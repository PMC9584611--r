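test_that("the substitution-in-context representation has 192 classes", {
  cls <- spectrum_classes()
  expect_identical(length(cls), 192L)
  expect_identical(anyDuplicated(cls), 0L)
})

test_that("spectrum bookkeeping conserves counts across both views", {
  ref <- supf_reference()
  sites <- eligible_sites(ref, ref$supf_window)
  nt <- sites[sites$class == "sns" & sites$strand == "non_transcribed", ]
  rec <- data.frame(barcode = sprintf("BC%02d", seq_len(8)),
                    position = nt$position[1:8], ref = "C", alt = "T",
                    type = "SNS", vf = 1, region = "supf_region",
                    status = "true_mutation", stringsAsFactors = FALSE)
  sp <- build_spectrum(rec, ref)
  for (v in c("non_transcribed", "transcribed"))
    expect_identical(sum(sp$count[sp$strand == v]), 8L)
  # a C>T in a TCA context lands in T[C>T]A and, flipped, in T[G>A]A
  i <- map_coordinate(ref, rec$position[1])
  ctx <- substr(ref$sense_sequence, i - 1L, i + 1L)
  lab_nt <- paste0(substr(ctx, 1, 1), "[C>T]", substr(ctx, 3, 3))
  flip <- strand_transform(ctx)
  lab_tr <- paste0(substr(flip, 1, 1), "[G>A]", substr(flip, 3, 3))
  expect_gte(sp$count[sp$strand == "non_transcribed" & sp$class == lab_nt], 1L)
  expect_gte(sp$count[sp$strand == "transcribed" & sp$class == lab_tr], 1L)
})

test_that("the transcribed view equals the strand transform of the other", {
  fix <- small_clean_sim(n_bc = 60, coverage = 12L, seed = 121)
  res <- run_pipeline(pipeline_config(reads = fix$sim, ref = fix$ref,
                                      sample_sheet = c(s1 = fix$sim$cfg$index)))
  sp <- res$samples$s1$spectrum
  nt <- sp[sp$strand == "non_transcribed", ]
  tr <- sp[sp$strand == "transcribed", ]
  flip_label <- function(cl) {
    ctx <- strand_transform(paste0(substr(cl, 1, 1), substr(cl, 3, 3),
                                   substr(cl, 7, 7)))
    paste0(substr(ctx, 1, 1), "[", substr(ctx, 2, 2), ">",
           strand_transform(substr(cl, 5, 5)), "]", substr(ctx, 3, 3))
  }
  for (k in which(nt$count > 0)) {
    expect_identical(tr$count[tr$class == flip_label(nt$class[k])],
                     nt$count[k])
  }
  expect_identical(sum(nt$count),
                   sum(res$samples$s1$records$type == "SNS" &
                         res$samples$s1$records$status == "true_mutation"))
})

test_that("type summaries are proportions that sum to one", {
  rec <- data.frame(barcode = c("A", "B", "C", "D"),
                    position = c(10L, 20L, 30L, 40L),
                    ref = c("C", "CC", "GAG", "C"),
                    alt = c("T", "TT", "AAA", "T"),
                    type = c("SNS", "DNS", "Del_in", "SNS"),
                    vf = 1, region = "supf_region",
                    status = "true_mutation", stringsAsFactors = FALSE)
  ts <- summarize_types(rec)
  expect_equal(sum(ts$type_prop), 1)
  expect_equal(unname(ts$type_prop["SNS"]), 0.5)
  expect_equal(sum(ts$sns_prop), 1)
  expect_equal(unname(ts$sns_prop["C>T"]), 1)
  expect_equal(unname(ts$dns_prop["CC>TT"]), 1)
  # all-SNS input -> SNS proportion 1
  ts2 <- summarize_types(rec[rec$type == "SNS", ])
  expect_equal(unname(ts2$type_prop["SNS"]), 1)
  # empty input -> empty tables
  expect_length(summarize_types(rec[0, ])$type_prop, 0)
})

test_that("multi-mutation profiling counts and combines correctly", {
  rec <- data.frame(barcode = c("A", "A", "A", "B"),
                    position = c(10L, 50L, 90L, 10L),
                    ref = "C", alt = "T", type = "SNS", vf = 1,
                    region = "supf_region", status = "true_mutation",
                    stringsAsFactors = FALSE)
  mp <- multi_mutation_profile(rec)
  expect_identical(mp$per_barcode$n_mut[mp$per_barcode$barcode == "A"], 3L)
  expect_identical(mp$per_barcode$types[mp$per_barcode$barcode == "A"],
                   "SNS+SNS+SNS")
  expect_identical(unname(mp$combinations["SNS", "SNS"]), 3L)  # C(3,2)
  expect_identical(as.integer(mp$count_table[c("1", "3")]), c(1L, 1L))
  # all-single input leaves the multiple stratum empty
  mp2 <- multi_mutation_profile(rec[c(1, 4), ])
  expect_length(mp2$multiple$type_prop, 0)
  expect_identical(sum(mp2$combinations), 0L)
})

test_that("mutation frequency is a windowed barcode fraction", {
  rec <- data.frame(barcode = sprintf("BC%03d", 1:50),
                    position = 100L, ref = "C", alt = "T", type = "SNS",
                    vf = 1, region = "supf_region",
                    status = "true_mutation", stringsAsFactors = FALSE)
  f <- mutation_frequency(rec, 10000)
  expect_identical(f$frequency, 5e-3)
  expect_true(f$ci["lower"] < 5e-3 && f$ci["upper"] > 5e-3)
  # invariant to record order and barcode relabeling
  f2 <- mutation_frequency(rec[sample(50), ], 10000)
  expect_identical(f2$frequency, f$frequency)
  # no mutated barcodes -> 0; records outside the window do not count
  expect_identical(mutation_frequency(rec[0, ], 100)$frequency, 0)
  rec_bc <- rec
  rec_bc$position <- -30L
  expect_identical(mutation_frequency(rec_bc, 100)$frequency, 0)
  expect_error(mutation_frequency(rec, 0), "positive")
})

test_that("the distance null equals exhaustive pair enumeration", {
  ref <- supf_reference()
  # null mean over eligible sites {1,2,3}: distances {1,1,2}, mean 4/3
  rec0 <- data.frame(barcode = character(0), position = integer(0),
                     ref = character(0), alt = character(0),
                     type = character(0), vf = numeric(0),
                     region = character(0), status = character(0),
                     stringsAsFactors = FALSE)
  d3 <- inter_sns_distance(rec0, ref, eligible = c(1L, 2L, 3L))
  expect_equal(d3$null_mean, 4 / 3)
  expect_length(d3$observed, 0)
  # 20-site toy window: exact equality with the brute-force average
  sites20 <- c(seq(-10L, -1L), seq(1L, 10L))
  d20 <- inter_sns_distance(rec0, ref, eligible = sites20)
  idx <- map_coordinate(ref, sites20)
  brute <- c()
  for (a in 1:19) for (b in (a + 1):20)
    brute <- c(brute, abs(idx[a] - idx[b]))
  expect_identical(sort(d20$null_distances), sort(as.numeric(brute)))
  expect_equal(d20$null_mean, mean(brute))
  # symmetric under site-set reversal
  d20r <- inter_sns_distance(rec0, ref, eligible = rev(sites20))
  expect_equal(sort(d20r$null_distances), sort(d20$null_distances))
  # observed distances are coordinate-gap aware: positions 10 and 25
  rec2 <- data.frame(barcode = "A", position = c(10L, 25L), ref = "C",
                     alt = "T", type = "SNS", vf = 1,
                     region = "supf_region", status = "true_mutation",
                     stringsAsFactors = FALSE)
  d2 <- inter_sns_distance(rec2, ref)
  expect_identical(d2$observed, 15)
  # ... and -1 to 1 is distance 1 (no position 0)
  rec3 <- rec2
  rec3$position <- c(-1L, 1L)
  expect_identical(inter_sns_distance(rec3, ref)$observed, 1)
})
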