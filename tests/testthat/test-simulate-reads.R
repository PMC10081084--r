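wt_diploid <- function() {
  g <- small_genome()
  structure(list(hapA = g$chromosomes, hapB = g$chromosomes,
                 genome = g), class = "DiploidGenome")
}

test_that("error-free reads are exact substrings of their haplotype of origin", {
  dip <- wt_diploid()
  rs <- simulate_short_reads(dip, 200, sub_error = 0, seed = 2)
  for (i in sample(nrow(rs), 30)) {
    r <- rs[i, ]
    frag <- substr(dip[[r$hap]][[r$chrom]], r$start + 1,
                   r$start + nchar(r$seq))
    if (r$strand == "-") frag <- revcomp(frag)
    expect_identical(r$seq, frag)
  }
  lr <- simulate_long_reads(dip, 20, length_mean = 3000, length_sd = 500,
                            error_rate = 0, seed = 3)
  for (i in seq_len(nrow(lr))) {
    r <- lr[i, ]
    frag <- substr(dip[[r$hap]][[r$chrom]], r$start + 1,
                   r$start + nchar(r$seq))
    if (r$strand == "-") frag <- revcomp(frag)
    expect_identical(r$seq, frag)
  }
})

test_that("FASTQ output is byte-identical under the same seed", {
  dip <- wt_diploid()
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(simulate_short_reads(dip, 100, seed = 9), f1)
  write_fastq(simulate_short_reads(dip, 100, seed = 9), f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_fastq(f1)
  expect_equal(nrow(back), 200)
  expect_true(all(nchar(back$seq) == nchar(back$qual)))
})

test_that("pairs are symmetric and realized depth matches the target", {
  dip <- wt_diploid()
  Ldip <- sum(nchar(dip$hapA)) + sum(nchar(dip$hapB))
  n_pairs <- round(30 * Ldip / 600)  # 30x diploid depth
  rs <- simulate_short_reads(dip, n_pairs, seed = 4)
  ids <- stats::setNames(rs$mate_id, rs$id)
  expect_true(all(ids[ids[rs$id]] == rs$id))
  # oracle: depth over a unique 10 kb window from truth intervals alone
  sel <- rs$chrom == "chrA" & rs$start + 150 > 25000 & rs$start < 35000
  cov <- IRanges::coverage(IRanges::IRanges(rs$start[sel] + 1L, width = 150L),
                           width = 36000)
  depth <- mean(as.numeric(cov[25001:35000]))
  expect_gt(depth, 30 * 0.8)
  expect_lt(depth, 30 * 1.2)
})

test_that("long reads honour the length/error regime and anchoring", {
  sc <- tsd_run()$sc
  dip <- sc$diploid
  mk <- sc$construct$features[sc$construct$features$name == "marker", ]
  ai <- list(chrom = sc$event$chrom, start = sc$site + 4 + mk$start,
             end = sc$site + 4 + mk$end)
  lr <- simulate_long_reads(dip, 30, error_rate = 0, seed = 5,
                            anchor_n = 5, anchor_interval = ai)
  marker <- construct_feature(sc$construct, "marker")
  for (i in 1:5) {
    r <- lr[i, ]
    expect_identical(r$hap, "hapA")
    sq <- if (r$strand == "-") revcomp(r$seq) else r$seq
    expect_true(grepl(marker, sq, fixed = TRUE))
  }
  # an anchored error-free read spans the 5' junction: TTAA + ITR5 head
  r1 <- lr[1, ]
  sq <- if (r1$strand == "-") revcomp(r1$seq) else r1$seq
  expect_true(grepl(paste0("TTAA", substr(sc$construct$itr5, 1, 30)), sq,
                    fixed = TRUE))
  # low-coverage regime arithmetic: total bases / diploid length
  dep <- sum(nchar(lr$seq)) / (sum(nchar(dip$hapA)) + sum(nchar(dip$hapB)))
  expect_lt(dep, 10)
  expect_error(simulate_long_reads(dip, 0, seed = 1),
               class = "insertra_parameter_error")
  expect_error(simulate_long_reads(dip, 5, error_rate = 0.5, seed = 1),
               class = "insertra_parameter_error")
  expect_error(simulate_short_reads(dip, 10, sub_error = 0.2, seed = 1),
               class = "insertra_parameter_error")
})
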