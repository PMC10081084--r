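test_that("digestion cuts at motif positions and conserves the template", {
  d <- digest("AAATTTAAA", list(motif = "TTTAAA", cut_offset = 3))
  expect_equal(d$fragments$length, c(6, 3))
  expect_identical(paste(d$fragments$seq, collapse = ""), "AAATTTAAA")

  none <- digest("ACGTACGTAC", enzyme_preset("DraI"))
  expect_equal(nrow(none$fragments), 1)
  expect_identical(none$fragments$seq, "ACGTACGTAC")

  circ1 <- digest("AAATTTAAAGG", list(motif = "TTTAAA", cut_offset = 3),
                  circular = TRUE)
  expect_equal(nrow(circ1$fragments), 1)
  expect_equal(circ1$fragments$length, 11)

  # conservation invariant over random sequences with random cutters
  set.seed(13)
  for (i in 1:20) {
    s <- rand_dna(sample(200:2000, 1))
    enz <- list(motif = rand_dna(4), cut_offset = sample(0:4, 1))
    dd <- digest(s, enz)
    expect_equal(sum(dd$fragments$length), nchar(s))
    expect_identical(paste(dd$fragments$seq, collapse = ""), s)
  }
})

test_that("non-palindromic motifs cut on both strands", {
  set.seed(23)
  # GACGTC is palindromic; GGATCC is too; use a truly asymmetric motif
  enz <- list(motif = "GGGAAA", cut_offset = 2)
  s <- paste0(rand_dna(50), "GGGAAA", rand_dna(50), "TTTCCC", rand_dna(50))
  d <- digest(s, enz)
  expect_equal(length(d$cut_positions), 2)
})

test_that("in-silico Southern counts one band per insertion", {
  tr <- tsd_run()
  sc <- tr$sc
  probe <- substr(construct_feature(sc$construct, "payload"), 1, 499)

  wt <- southern_blot(sc$genome, enzyme_preset("DraI"), probe)
  expect_length(wt, 0)

  single <- southern_blot(sc$diploid$hapA, enzyme_preset("DraI"), probe)
  expect_length(single, 1)
  single_scai <- southern_blot(sc$diploid$hapA, enzyme_preset("ScaI"), probe)
  expect_length(single_scai, 1)

  # second insertion on the other chromosome -> two bands
  g2 <- structure(list(chromosomes = sc$diploid$hapA,
                       annotations = sc$genome$annotations[0, ]),
                  class = "HostGenome")
  s2 <- Biostrings::start(Biostrings::matchPattern(
    "TTAA", Biostrings::DNAString(g2$chromosomes[["chrB"]])))[5] - 1L
  dbl <- insert_transgene(g2, sc$construct, "chrB", s2, "het")
  both <- southern_blot(dbl$diploid$hapA, enzyme_preset("DraI"), probe)
  expect_length(both, 2)
})

test_that("inverse PCR recovers the true flank and honours primer contracts", {
  tr <- tsd_run()
  sc <- tr$sc
  fl <- recover_flanks_ipcr(sc$diploid)
  g <- sc$genome$chromosomes
  site <- sc$event$site
  truth5 <- substr(g[[sc$event$chrom]], site + 4 - nchar(fl$flank5) + 1,
                   site + 4)
  truth3 <- substr(g[[sc$event$chrom]], site + 1, site + nchar(fl$flank3))
  expect_identical(fl$flank5, truth5)
  expect_identical(fl$flank3, truth3)

  amp <- fl$amplicons$amp5
  expect_true(startsWith(amp$sequence, amp$primer_pair[["fwd"]]))
  expect_true(endsWith(amp$sequence, revcomp(amp$primer_pair[["rev"]])))

  expect_error(inverse_pcr(sc$diploid$hapA[["chrA"]], enzyme_preset("DraI"),
                           "ACGTACGTACGTACGTACGTA", "TGCATGCATGCATGCATGCAT"),
               class = "insertra_primer_error")
  expect_error(recover_flanks_ipcr(sc$diploid, max_product = 300),
               class = "insertra_assay_failure")
})

test_that("dot plots show identity, reverse-complement symmetry and insertions", {
  set.seed(24)
  s <- rand_dna(800)
  dp <- dotplot_matrix(s, s, k = 15)
  diag_pts <- dp[dp$strand == "+" & dp$pos_a == dp$pos_b, ]
  expect_equal(nrow(diag_pts), 800 - 15 + 1)

  dprc <- dotplot_matrix(s, revcomp(s), k = 15)
  expect_true(all(dprc$strand == "-"))
  expect_equal(nrow(dprc), 800 - 15 + 1)

  # transpose symmetry
  ab <- dotplot_matrix(s, substr(s, 100, 400), k = 15)
  ba <- dotplot_matrix(substr(s, 100, 400), s, k = 15)
  expect_setequal(paste(ab$pos_a, ab$pos_b, ab$strand),
                  paste(ba$pos_b, ba$pos_a, ba$strand))

  # an insertion splits the diagonal by exactly its length
  ins <- paste0(substr(s, 1, 400), rand_dna(150), substr(s, 401, 800))
  dpi <- dotplot_matrix(s, ins, k = 15)
  left <- dpi[dpi$strand == "+" & dpi$pos_a < 380, ]
  right <- dpi[dpi$strand == "+" & dpi$pos_a > 420, ]
  expect_true(all(left$pos_b == left$pos_a))
  expect_true(all(right$pos_b == right$pos_a + 150))

  expect_error(dotplot_matrix(s, s, k = 9), class = "insertra_parameter_error")
})
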