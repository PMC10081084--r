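test_that("zero divergence yields identical copies and seeds are reproducible", {
  fam <- make_repeat_family(100, 3, 0, seed = 11)
  expect_length(fam, 3)
  expect_equal(nchar(fam), rep(100, 3))
  expect_length(unique(fam), 1)

  a <- make_repeat_family(750, 12, 0.04, seed = 5)
  b <- make_repeat_family(750, 12, 0.04, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, make_repeat_family(750, 12, 0.04, seed = 6)))
})

test_that("pairwise identity matches the divergence model (alignment oracle)", {
  set.seed(1)
  fam <- make_repeat_family(750, 12, 0.04, seed = 7)
  pairs <- combn(12, 2)
  ids <- vapply(seq_len(ncol(pairs)), function(j)
    oracle_global_identity(fam[pairs[1, j]], fam[pairs[2, j]]), numeric(1))
  expect_gte(mean(ids), 0.90)
  expect_lte(mean(ids), 0.95)
  # model: P(differ) = 2d(1-d) + (2/3)d^2
  d <- 0.04
  expected <- 1 - (2 * d * (1 - d) + (2 / 3) * d^2)
  expect_equal(mean(ids), expected, tolerance = 0.01)
})

test_that("protected intervals are shielded from substitutions", {
  anc <- paste0(rand_dna(373), "TTAA", rand_dna(373))
  fam <- make_repeat_family(n_copies = 20, divergence = 0.2, seed = 3,
                            ancestor = anc, protect = c(373, 377))
  expect_true(all(substr(fam, 374, 377) == "TTAA"))
})

test_that("invalid parameters raise parameter errors", {
  expect_error(make_repeat_family(10, 3, 0.01, seed = 1),
               class = "insertra_parameter_error")
  expect_error(make_repeat_family(100, 0, 0.01, seed = 1),
               class = "insertra_parameter_error")
  expect_error(make_repeat_family(100, 3, 0.5, seed = 1),
               class = "insertra_parameter_error")
})
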