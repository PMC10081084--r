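test_that("a 30x+ het insertion yields ample split reads on both sides", {
  inf <- tsd_run()$inf
  expect_gte(sum(inf$split$side == "5prime"), 5)
  expect_gte(sum(inf$split$side == "3prime"), 5)
  expect_gt(nrow(inf$discordant), 0)
})

test_that("wild-type reads yield no informative reads (negative control)", {
  tr <- tsd_run()
  g <- tr$sc$genome
  wt <- structure(list(hapA = g$chromosomes, hapB = g$chromosomes),
                  class = "DiploidGenome")
  rs <- simulate_short_reads(wt, 600, sub_error = 0, seed = 8)
  aln <- map_reads(tr$idx, rs)
  inf <- extract_informative_reads(aln, rs, "transgene", tr$idx)
  expect_equal(nrow(inf$split), 0)
  expect_equal(nrow(inf$discordant), 0)
})

test_that("min_clip above the read length empties the split list only", {
  tr <- tsd_run()
  inf_all <- tr$inf
  inf_hi <- extract_informative_reads(tr$aln, tr$reads, "transgene", tr$idx,
                                      min_clip = 200)
  expect_equal(nrow(inf_hi$split), 0)
  expect_equal(nrow(inf_hi$discordant), nrow(inf_all$discordant))
})

test_that("flank consensus from error-free reads is byte-exact and calls the TSD", {
  tr <- tsd_run()
  f5 <- build_flank_consensus(tr$inf, "5prime")
  f3 <- build_flank_consensus(tr$inf, "3prime")
  g <- tr$sc$genome$chromosomes
  site <- tr$sc$event$site
  chrom <- tr$sc$event$chrom
  expect_gte(nchar(f5), 25)
  expect_gte(nchar(f3), 25)
  expect_identical(as.character(f5),
                   substr(g[[chrom]], site + 4 - nchar(f5) + 1, site + 4))
  expect_identical(as.character(f3),
                   substr(g[[chrom]], site + 1, site + nchar(f3)))
  tsd <- detect_tsd(f5, f3)
  expect_true(tsd$present_5prime)
  expect_true(tsd$present_3prime)
})

test_that("flank consensus tolerates 1% substitution error at deep support", {
  sc <- tsd_run()$sc
  win <- junction_window_diploid(sc$diploid, radius = 2000)
  Lw <- sum(nchar(win$hapA)) + sum(nchar(win$hapB))
  rs <- simulate_short_reads(win, round(80 * Lw / 600), sub_error = 0.01,
                             seed = 17)
  idx <- index_reference(reference_with_construct(sc$diploid))
  aln <- map_reads(idx, rs)
  inf <- extract_informative_reads(aln, rs, "transgene", idx)
  f5 <- build_flank_consensus(inf, "5prime")
  g <- sc$genome$chromosomes
  truth <- substr(g[[sc$event$chrom]], sc$event$site + 4 - nchar(f5) + 1,
                  sc$event$site + 4)
  expect_gte(oracle_global_identity(as.character(f5), truth), 0.99)
})

test_that("insufficient support raises an evidence error with the count", {
  inf <- insertra:::empty_informative(20)
  inf$split <- data.frame(
    read_id = c("a", "b"), anchor_ref = "transgene",
    anchor_class = "construct", clip_side = "left", clip_len = 30L,
    clip_target = "chrA", clip_target_pos = 0L, construct_pos = 0L,
    side = "5prime", tail_seq = c("ACGTTTAA", "ACGTTTAA"),
    tail_anchor = "right", stringsAsFactors = FALSE)
  err <- tryCatch(build_flank_consensus(inf, "5prime"),
                  insertra_evidence_error = function(e) conditionMessage(e))
  expect_match(err, "2")
})

test_that("detect_tsd flags constructed negatives and rejects empty motifs", {
  set.seed(28)
  call <- detect_tsd("ACGTACGTCCGG", "GGCCACGTACGT")
  expect_false(call$present_5prime)
  expect_false(call$present_3prime)
  expect_error(detect_tsd("ACGTTTAA", "TTAAGGCC", motif = ""),
               class = "insertra_parameter_error")
  expect_error(detect_tsd("AC", "TTAAGG"), class = "insertra_parameter_error")
})
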