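# Shared fixtures, memoized across test files (expensive simulations are
# built once per test session).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Biostrings-based independent identity oracle (global alignment)
oracle_global_identity <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

# Biostrings-based independent optimal local alignment score oracle
oracle_local_score <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = mat, gapOpening = 5, gapExtension = 2))
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# small two-chromosome genome carrying a 750 bp repeat family whose
# ancestor has a TTAA planted at offset 373 (shielded from divergence)
small_genome <- function(divergence = 0, seed = 7) {
  set.seed(1000 + seed)
  anc <- paste0(rand_dna(373), "TTAA", rand_dna(373))
  fam <- make_repeat_family(n_copies = 12, divergence = divergence,
                            seed = seed, ancestor = anc,
                            protect = c(373, 377))
  els_a <- lapply(1:8, function(i)
    list(name = sprintf("rep:%d", i), seq = fam[i], at = 1000 + i * 2500,
         family = "rep", copy = i))
  els_b <- lapply(9:12, function(i)
    list(name = sprintf("rep:%d", i), seq = fam[i], at = 1000 + (i - 8) * 2500,
         family = "rep", copy = i))
  g <- build_host_genome(list(
    chromosomes = list(
      chrA = list(bg_length = 30000, elements = els_a),
      chrB = list(bg_length = 15000, elements = els_b)),
    seed = seed + 1))
  attr(g, "family") <- fam
  g
}

# full junction/TSD analysis on the clean-background scenario
tsd_run <- function() fixture("tsd_run", function() {
  sc <- tsd_scenario(seed = 3)
  win <- junction_window_diploid(sc$diploid, radius = 3000)
  Lw <- sum(nchar(win$hapA)) + sum(nchar(win$hapB))
  reads <- simulate_short_reads(win, round(60 * Lw / 600), sub_error = 0,
                                seed = 7)
  idx <- index_reference(reference_with_construct(sc$diploid))
  aln <- map_reads(idx, reads)
  inf <- extract_informative_reads(aln, reads, "transgene", idx)
  list(sc = sc, win = win, reads = reads, idx = idx, aln = aln, inf = inf)
})

# one full copy-number run at 30x
cn_run <- function() fixture("cn_run", function() {
  sc <- copy_number_scenario(seed = 1)
  dip <- sc$diploid
  Ldip <- sum(nchar(dip$hapA)) + sum(nchar(dip$hapB))
  reads <- simulate_short_reads(dip, round(30 * Ldip / 600), seed = 101)
  idx <- index_reference(reference_with_construct(dip))
  aln <- map_reads(idx, reads, band = 25, seed_step = 2)
  feats <- rbind(
    construct_class_features(sc$construct),
    select_reference_loci(sc$genome, seed = 1)[,
      c("name", "ref", "start", "end", "class")])
  est <- estimate_copy_number(feature_coverage_table(aln, feats))
  list(sc = sc, reads = reads, idx = idx, aln = aln, feats = feats, est = est)
})

# one full ambiguity-resolution run
amb_run <- function() fixture("amb_run", function() {
  sc <- ambiguity_scenario(seed = 1)
  fl <- recover_flanks_ipcr(sc$diploid)
  gidx <- index_reference(sc$genome)
  hits <- local_search(gidx, fl$query, min_score = 300, band = 150)
  cand <- rank_candidate_loci(hits, sc$genome,
                              junction_offset = fl$junction_offset)
  mk <- sc$construct$features[sc$construct$features$name == "marker", ]
  lr <- simulate_long_reads(
    sc$diploid, 300, seed = 501, anchor_n = 20,
    anchor_interval = list(chrom = sc$event$chrom,
                           start = sc$site + 4 + mk$start,
                           end = sc$site + 4 + mk$end))
  marker <- construct_feature(sc$construct, "marker")
  asm <- assemble_long_reads(lr, c(marker = marker))
  res <- integrate_long_read_evidence(cand, asm$contig, gidx, sc$construct,
                                      anchors = c(marker = marker))
  list(sc = sc, fl = fl, gidx = gidx, hits = hits, cand = cand, lr = lr,
       asm = asm, res = res)
})
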