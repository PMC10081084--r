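test_that("SAM output round-trips through the parser", {
  g <- small_genome()
  dip <- structure(list(hapA = g$chromosomes, hapB = g$chromosomes),
                   class = "DiploidGenome")
  rs <- simulate_short_reads(dip, 50, seed = 6)
  idx <- index_reference(g)
  aln <- map_reads(idx, rs)
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, rs, f)

  lines <- readLines(f)
  expect_true(any(startsWith(lines, "@SQ")))
  expect_true(all(grepl("NH:i:\\d+", lines[!startsWith(lines, "@")])))

  back <- read_sam(f)
  expect_equal(nrow(back), nrow(aln))
  expect_equal(back$start, aln$start)
  expect_equal(back$cigar, aln$cigar)
  expect_equal(back$mapq, aln$mapq)
  expect_equal(back$n_best, aln$n_best)
  expect_equal(sort(names(attr(back, "ref_lengths"))),
               sort(names(attr(aln, "ref_lengths"))))
  # SEQ restored to original read orientation
  seqs <- stats::setNames(rs$seq, rs$id)
  expect_identical(unname(seqs[back$read_id]), back$seq)
})

test_that("informative reads can be extracted from a SAM file", {
  tr <- tsd_run()
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(tr$aln, tr$reads, f)
  back <- read_sam(f)
  inf <- extract_informative_reads(back, construct_names = "transgene",
                                   index = tr$idx)
  expect_gt(nrow(inf$split), 0)
  expect_setequal(unique(inf$split$side), c("5prime", "3prime"))
})
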