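test_that("a single anchored read assembles to itself", {
  set.seed(21)
  anchor <- rand_dna(600)
  read <- paste0(rand_dna(1500), anchor, rand_dna(1500))
  asm <- assemble_long_reads(c(r1 = read), c(a = anchor))
  expect_identical(asm$contig, read)
  expect_equal(asm$n_anchored, 1)
})

test_that("error-free tiling reads reconstruct the insertion haplotype", {
  sc <- tsd_run()$sc
  dip <- sc$diploid
  hap <- dip$hapA[[sc$event$chrom]]
  cl <- nchar(sc$construct$full_sequence)
  # 8 kb error-free reads tiling the insertion at 1.5 kb steps; anchors are
  # the two construct cassettes, so every read across the construct anchors
  starts <- seq(sc$event$site - 9000, sc$event$site + cl - 1000, by = 1500)
  starts <- pmax(starts, 0)
  reads <- stats::setNames(substring(hap, starts + 1, starts + 8000),
                           sprintf("t%02d", seq_along(starts)))
  anchors <- c(marker = construct_feature(sc$construct, "marker"),
               payload = construct_feature(sc$construct, "payload"))
  asm <- assemble_long_reads(reads, anchors)
  expect_true(grepl(sc$construct$full_sequence, asm$contig, fixed = TRUE))
  # contains >= 4 kb of each true flank
  flank5 <- substr(hap, sc$event$site - 4000 + 1, sc$event$site + 4)
  flank3 <- substr(hap, sc$event$site + 4 + cl + 1, sc$event$site + 8 + cl + 4000)
  expect_true(grepl(flank5, asm$contig, fixed = TRUE))
  expect_true(grepl(flank3, asm$contig, fixed = TRUE))
  # conservation: contig never longer than the sum of its reads
  expect_lte(nchar(asm$contig), sum(nchar(reads)))
})

test_that("8% error reads at ~10x local depth polish to >= 0.98 identity", {
  amb <- amb_run()
  sc <- amb$sc
  hap <- sc$diploid$hapA[[sc$event$chrom]]
  cl <- nchar(sc$construct$full_sequence)
  truth_span <- substr(hap, sc$event$site + 5, sc$event$site + 4 + cl)
  d <- insertra:::cpp_best_diags(amb$asm$contig, truth_span, 13L, 3L)
  r <- insertra:::cpp_align_hint(truth_span, amb$asm$contig,
                                 as.integer(d$diag[1]), 500L, 2L, -3L, 5L, 2L)
  expect_gte(r$aln_length, 0.95 * cl)
  expect_gte(r$identity, 0.98)
})

test_that("assembly without anchored reads raises an evidence error", {
  set.seed(22)
  reads <- stats::setNames(replicate(5, rand_dna(2000)), paste0("r", 1:5))
  expect_error(assemble_long_reads(reads, c(a = rand_dna(600))),
               class = "insertra_evidence_error")
})
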