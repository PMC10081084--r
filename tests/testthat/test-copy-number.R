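toy_alignments <- function(rows, ref_lengths) {
  structure(rows, ref_lengths = ref_lengths,
            class = c("alignments", "data.frame"))
}

test_that("feature depth handles trivial and empty coverage", {
  aln <- toy_alignments(data.frame(
    read_id = "r1", ref = "c1", strand = 0L, start = 100L, end = 120L,
    cigar = "20M", score = 40L, identity = 1, aln_length = 20L,
    n_best = 1L, mapq = 40L, qstart = 0L, qend = 20L,
    stringsAsFactors = FALSE), c(c1 = 1000L))
  expect_equal(feature_depth(aln, list(ref = "c1", start = 100, end = 120)), 1)
  expect_equal(feature_depth(aln, list(ref = "c1", start = 500, end = 600)), 0)
  expect_error(feature_depth(aln, list(ref = "c1", start = 900, end = 1100)),
               class = "insertra_bounds_error")
})

test_that("copy-number estimates are uniform-input-exact and scale invariant", {
  tab <- data.frame(
    name = c(sprintf("l%d", 1:6), "m"), ref = "c1",
    start = 0, end = 20,
    class = c(rep("2n", 6), "n"),
    mean_depth = c(rep(10, 6), 10), stringsAsFactors = FALSE)
  est <- estimate_copy_number(tab)
  expect_true(all(est$cn_estimate == 2.0))

  tab2 <- tab
  tab2$mean_depth <- c(rep(10, 6), 5)
  est2 <- estimate_copy_number(tab2)
  tab3 <- tab2
  tab3$mean_depth <- tab3$mean_depth * 7.3
  est3 <- estimate_copy_number(tab3)
  expect_equal(est2$cn_estimate, est3$cn_estimate)
  # 2n features' own median is exactly 2 by construction
  expect_equal(median(est2$cn_estimate[est2$class == "2n"]), 2.0)

  expect_error(estimate_copy_number(tab[1:4, ]),
               class = "insertra_parameter_error")
  tab0 <- tab
  tab0$mean_depth <- 0
  expect_error(estimate_copy_number(tab0), class = "insertra_data_error")
})

test_that("het 30x simulation recovers the n/2n/3n dosage classes", {
  est <- cn_run()$est
  cls <- tapply(est$cn_estimate, est$class, mean)
  expect_lt(abs(cls[["n"]] - 1), 0.25)
  expect_lt(abs(cls[["2n"]] - 2), 0.25)
  expect_lt(abs(cls[["3n"]] - 3), 0.4)
  expect_true(all(est$consistent[est$class == "n"]))
  # simulated 30x unique loci land in the Poisson band around 30
  expect_lt(abs(attr(est, "reference_2n_depth") - 30), 3)
})

test_that("homozygous insertions double the marker dosage", {
  sc <- copy_number_scenario(seed = 4, zygosity = "hom")
  dip <- sc$diploid
  Ldip <- sum(nchar(dip$hapA)) + sum(nchar(dip$hapB))
  rs <- simulate_short_reads(dip, round(30 * Ldip / 600), seed = 104)
  idx <- index_reference(reference_with_construct(dip))
  aln <- map_reads(idx, rs, band = 25, seed_step = 2)
  feats <- rbind(
    construct_class_features(sc$construct, include = c("marker", "payload")),
    select_reference_loci(sc$genome, seed = 4)[,
      c("name", "ref", "start", "end", "class")])
  est <- estimate_copy_number(feature_coverage_table(aln, feats))
  expect_lt(abs(mean(est$cn_estimate[est$class == "n"]) - 2), 0.35)
})

test_that("repeat-inflated transgene flanks are flagged, flat profiles are not", {
  cr <- cn_run()
  ev <- cr$sc$event
  base <- attr(cr$est, "reference_2n_depth")
  prof <- depth_profile(cr$aln, ev$chrom, ev$site - 3000, ev$site + 3000)
  fl <- flag_repetitive_flanks(prof, base)
  expect_gt(nrow(fl), 0)
  # flagged intervals overlap annotated repeat elements around the site
  ann <- cr$sc$genome$annotations
  rep_ann <- ann[ann$family %in% c("mainrep", "filler") & ann$chrom == ev$chrom, ]
  overlaps <- vapply(seq_len(nrow(fl)), function(i)
    any(rep_ann$start < fl$end[i] & fl$start[i] < rep_ann$end), logical(1))
  expect_true(all(overlaps))

  flat <- structure(list(ref = "x", start = 0, depth = rep(base, 1000)),
                    class = "DepthProfile")
  expect_equal(nrow(flag_repetitive_flanks(flat, base)), 0)
  expect_equal(nrow(flag_repetitive_flanks(prof, base,
                                           fold_threshold = Inf)), 0)
  expect_error(flag_repetitive_flanks(prof, 0),
               class = "insertra_parameter_error")
})
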