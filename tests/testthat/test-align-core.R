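test_that("smith_waterman reproduces hand-checkable scores", {
  r <- smith_waterman("ACGT", "ACGT")
  expect_equal(r$score, 8)
  expect_equal(r$identity, 1.0)
  # best single-match alignment between disjoint alphabets
  expect_equal(smith_waterman("ACGT", "TTTT")$score, 2)
  expect_error(smith_waterman("", "ACGT"), class = "insertra_parameter_error")
})

test_that("smith_waterman equals an independent full-DP reference on random pairs", {
  set.seed(42)
  for (i in 1:100) {
    a <- rand_dna(30); b <- rand_dna(30)
    expect_equal(smith_waterman(a, b)$score, oracle_local_score(a, b))
  }
})

test_that("k-mer index has the expected arithmetic and self-consistency", {
  s <- rand_dna(100)
  idx <- index_reference(c(ref = s), k = 15)
  info <- insertra:::cpp_index_info(idx$ptr)
  expect_equal(info$n_positions, 100 - 15 + 1)

  mono <- index_reference(c(m = strrep("A", 60)), k = 15)
  expect_equal(insertra:::cpp_index_info(mono$ptr)$n_kmers, 1)

  for (p in c(0, 17, 85)) {
    km <- substr(s, p + 1, p + 15)
    hit <- query_kmer(idx, km)
    expect_true(p %in% hit$pos)
  }
})

test_that("map_read places unique reads at their origin with mapq > 0", {
  g <- small_genome()
  idx <- index_reference(g)
  read <- genome_substring(g, "chrA", 25000, 25150)  # unique background
  rec <- map_read(idx, read)
  expect_equal(nrow(rec), 1)
  expect_gt(rec$mapq, 0)
  expect_equal(rec$ref, "chrA")
  expect_equal(rec$start, 25000)
  expect_equal(rec$n_best, 1)

  # reverse complement flips strand but keeps locus and score
  rec2 <- map_read(idx, revcomp(read))
  expect_equal(rec2$start, rec$start)
  expect_equal(rec2$score, rec$score)
  expect_equal(rec2$strand, 1 - rec$strand)
})

test_that("reads inside identical repeat copies get all placements and mapq 0", {
  g0 <- small_genome(divergence = 0)   # 12 byte-identical copies
  idx <- index_reference(g0)
  read <- substr(attr(g0, "family")[1], 101, 250)
  rec <- map_read(idx, read)
  expect_equal(nrow(rec), 12)
  expect_true(all(rec$mapq == 0))
  expect_true(all(rec$n_best == 12))
})

test_that("chimeric construct/genome reads are soft-clipped at the junction", {
  g <- small_genome()
  cons_seq <- rand_dna(2000)
  idx <- index_reference(g)
  chim <- paste0(substr(cons_seq, 1, 60),
                 genome_substring(g, "chrA", 25000, 25090))
  rec <- map_read(idx, chim)
  expect_equal(rec$ref[1], "chrA")
  ops <- insertra:::cigar_ops(rec$cigar[1])
  expect_true(any(ops$op == "S" & ops$len >= 40))
  # query-consuming ops always sum to the read length
  expect_equal(sum(ops$len[ops$op %in% c("M", "I", "S")]), nchar(chim))
})

test_that("local_search finds all repeat copies and respects min_score", {
  g <- small_genome(divergence = 0.04)
  idx <- index_reference(g)
  q <- attr(g, "family")[1]
  hits <- local_search(idx, q, min_score = 200)
  strong <- hits[hits$identity >= 0.90 & hits$aln_length >= 700, ]
  expect_gte(nrow(strong), 12)

  # hit count is monotonically non-increasing in min_score
  ns <- vapply(c(100, 400, 800, 1200), function(ms)
    nrow(local_search(idx, q, min_score = ms)), numeric(1))
  expect_true(all(diff(ns) <= 0))

  # query with no shared k-mer
  expect_equal(nrow(local_search(idx, strrep("ACGT", 10), min_score = 20)), 0)

  # query = reference itself
  self <- local_search(index_reference(c(r = q)), q, min_score = 50)
  expect_equal(self$identity[1], 1.0)
  expect_equal(self$aln_length[1], nchar(q))
})

test_that("map_reads best score equals direct alignment against the source window", {
  g <- small_genome()
  idx <- index_reference(g)
  set.seed(9)
  for (i in 1:20) {
    st <- sample(22000:34000, 1)
    len <- sample(100:300, 1)
    read <- genome_substring(g, "chrA", st, st + len)
    # plant a couple of substitutions
    ch <- strsplit(read, "")[[1]]
    for (p in sample(len, 2)) ch[p] <- sample(setdiff(c("A","C","G","T"), ch[p]), 1)
    read <- paste(ch, collapse = "")
    rec <- map_read(idx, read)
    window <- genome_substring(g, "chrA", max(0, st - 400),
                               min(nchar(g$chromosomes[["chrA"]]), st + len + 400))
    expect_equal(rec$score[1], smith_waterman(read, window)$score)
  }
})
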