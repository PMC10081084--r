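test_that("candidate ranking filters, orders totally, and checks the TTAA", {
  amb <- amb_run()
  cand <- amb$cand
  expect_gte(nrow(cand), 12)
  expect_true(all(cand$identity >= 0.90))
  expect_true(all(cand$aln_length >= 700))
  expect_true(all(cand$has_ttaa))
  expect_equal(cand$rank, seq_len(nrow(cand)))

  # permutation invariance of the ranking
  set.seed(27)
  perm <- amb$hits[sample(nrow(amb$hits)), ]
  cand2 <- rank_candidate_loci(perm, amb$sc$genome,
                               junction_offset = amb$fl$junction_offset)
  expect_equal(cand2, cand)

  # threshold degeneracy: exact identity keeps only the true locus
  strict <- rank_candidate_loci(amb$hits, amb$sc$genome, t_identity = 0.999,
                                junction_offset = amb$fl$junction_offset)
  expect_equal(nrow(strict), 1)
  expect_equal(strict$chrom, amb$sc$event$chrom)
  expect_true(strict$start <= amb$sc$site && amb$sc$site <= strict$end)

  expect_equal(nrow(rank_candidate_loci(amb$hits[0, ], amb$sc$genome)), 0)
})

test_that("require_ttaa keeps exactly the copies whose motif survived", {
  set.seed(25)
  # constructed: 6 identical repeat copies, TTAA mutated out in all but 3
  base <- paste0(rand_dna(400), "TTAA", rand_dna(396))
  broken <- base
  substr(broken, 401, 404) <- "GGCC"
  els <- lapply(1:6, function(i)
    list(name = sprintf("c:%d", i), seq = if (i <= 3) base else broken,
         at = i * 3000, family = "c", copy = i))
  g <- build_host_genome(list(chromosomes = list(
    z = list(bg_length = 25000, elements = els)), seed = 2))
  idx <- index_reference(g)
  hits <- local_search(idx, base, min_score = 300)
  cand <- rank_candidate_loci(hits, g, junction_offset = 404,
                              require_ttaa = TRUE, ttaa_tol = 2)
  expect_equal(nrow(cand), 3)
  cand_all <- rank_candidate_loci(hits, g, junction_offset = 404,
                                  require_ttaa = FALSE, ttaa_tol = 2)
  expect_equal(sum(cand_all$has_ttaa), 3)
})

test_that("long-read evidence resolves the planted locus among 12 candidates", {
  amb <- amb_run()
  res <- amb$res
  expect_false(res$ambiguous)
  rl <- res$resolved_locus
  expect_equal(rl$evidence_tier, "long_read_resolved")
  expect_equal(rl$chrom, amb$sc$event$chrom)
  expect_true(rl$start <= amb$sc$site && amb$sc$site <= rl$end)
  # the resolving unique segment overlaps the planted island
  isl <- amb$sc$island
  seg <- res$segments
  expect_true(any(seg$ref == isl$chrom & seg$start < isl$end &
                  isl$start < seg$end))
  # resolved locus is always one of the flank candidates
  expect_true(any(res$candidates$chrom == rl$chrom &
                  res$candidates$start == rl$start))
})

test_that("a contig without unique sequence leaves the ambiguity standing", {
  set.seed(26)
  amb <- amb_run()
  # truncate the contig to the construct span plus < unique_flank_min of arm
  span <- amb$res$construct_span
  short <- substr(amb$asm$contig, max(1, span[1] - 300), span[2] + 300)
  res <- integrate_long_read_evidence(
    amb$cand, short, amb$gidx, amb$sc$construct,
    anchors = stats::setNames(construct_feature(amb$sc$construct, "marker"),
                              "marker"))
  expect_true(res$ambiguous)
  expect_null(res$resolved_locus)

  expect_error(integrate_long_read_evidence(
    amb$cand, rand_dna(5000), amb$gidx, amb$sc$construct,
    anchors = stats::setNames(construct_feature(amb$sc$construct, "marker"),
                              "marker")),
    class = "insertra_evidence_error")
})

test_that("signal-count percentages use half-away-from-zero rounding", {
  out <- summarize_signal_counts(data.frame(
    label = c("transgenic", "wild_type", "none"),
    positive = c(59, 38, 0), total = c(63, 54, 10)))
  expect_equal(out$percentage, c(94, 70, 0))
  expect_equal(summarize_signal_counts(
    data.frame(label = "half", positive = 1, total = 8))$percentage, 13)
  expect_error(summarize_signal_counts(
    data.frame(label = "bad", positive = 1, total = 0)),
    class = "insertra_parameter_error")
  expect_error(summarize_signal_counts(
    data.frame(label = "bad", positive = 5, total = 4)),
    class = "insertra_parameter_error")
})
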