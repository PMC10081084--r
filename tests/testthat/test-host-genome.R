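test_that("annotations round-trip through BED and intervals extract correctly", {
  g <- small_genome()
  fam <- attr(g, "family")
  a1 <- g$annotations[1, ]
  expect_identical(genome_substring(g, a1$chrom, a1$start, a1$end), fam[1])

  tf <- withr::local_tempfile(fileext = ".bed")
  write_truth_bed(g, tf)
  back <- read_truth_bed(tf)
  expect_equal(back$start, g$annotations$start)
  expect_equal(back$end, g$annotations$end)
  expect_equal(back$chrom, g$annotations$chrom)
  expect_equal(back$name, g$annotations$name)
})

test_that("planted repeat copies align to the family ancestor at >= 0.90 identity", {
  g <- small_genome(divergence = 0.04)
  anc <- attr(attr(g, "family"), "ancestor")
  ann <- g$annotations
  ids <- vapply(seq_len(nrow(ann)), function(i)
    oracle_global_identity(
      genome_substring(g, ann$chrom[i], ann$start[i], ann$end[i]), anc),
    numeric(1))
  expect_true(all(ids >= 0.90))
})

test_that("selected reference windows occur exactly once genome-wide", {
  g <- small_genome()
  loci <- select_reference_loci(g, n_loci = 15, seed = 4)
  expect_equal(nrow(loci), 15)
  counts <- vapply(loci$seq, function(s)
    count_occ <- sum(Biostrings::vcountPattern(
      s, Biostrings::DNAStringSet(g$chromosomes))) +
      sum(Biostrings::vcountPattern(
        insertra::revcomp(s), Biostrings::DNAStringSet(g$chromosomes))),
    numeric(1))
  expect_true(all(counts == 1))
  # pairwise non-overlapping
  for (i in seq_len(nrow(loci) - 1)) {
    same <- loci$ref == loci$ref[i]
    same[i] <- FALSE
    expect_true(all(loci$start[same] >= loci$end[i] |
                    loci$end[same] <= loci$start[i]))
  }
  expect_identical(loci, select_reference_loci(g, n_loci = 15, seed = 4))
})

test_that("layout violations are rejected", {
  expect_error(build_host_genome(list(chromosomes = list(
    c1 = list(bg_length = 100, elements = list(
      list(name = "x", seq = "ACGTACGTAC", at = 5),
      list(name = "y", seq = "ACGTACGTAC", at = 10)))))),
    class = "insertra_layout_error")
  expect_error(build_host_genome(list()), class = "insertra_parameter_error")
  expect_error(genome_substring(small_genome(), "chrA", -1, 5),
               class = "insertra_bounds_error")
})
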