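make_simple_construct <- function(payload_len = 500, seed = 5) {
  build_construct(list(
    list(name = "itr5", role = "itr5", class = "spacer", length = 40),
    list(name = "marker", role = "marker", class = "n", length = 300),
    list(name = "payload", class = "n", length = payload_len),
    list(name = "itr3", role = "itr3", class = "spacer", length = 30)),
    seed = seed)
}

test_that("construct assembly conserves length and ITR placement", {
  cons <- make_simple_construct()
  expect_equal(nchar(cons$full_sequence), 40 + 300 + 500 + 30)
  expect_true(startsWith(cons$full_sequence, cons$itr5))
  expect_true(endsWith(cons$full_sequence, cons$itr3))

  empty <- make_simple_construct(payload_len = 0)
  expect_true(startsWith(empty$full_sequence, empty$itr5))
  expect_true(endsWith(empty$full_sequence, empty$itr3))

  expect_error(build_construct(list(
    list(name = "itr5", role = "itr5", class = "spacer", length = 40),
    list(name = "itr3", role = "itr3", class = "spacer", length = 30)),
    seed = 1), class = "insertra_config_error")
})

test_that("3n features occur exactly twice in host + construct references", {
  sc <- copy_number_scenario(seed = 2)
  combined <- Biostrings::DNAStringSet(c(sc$genome$chromosomes,
                                         transgene = sc$construct$full_sequence))
  for (f in c("promoter", "terminator")) {
    sq <- construct_feature(sc$construct, f)
    expect_equal(sum(Biostrings::vcountPattern(sq, combined)), 2)
  }
  # the n-class marker occurs exactly once
  expect_equal(sum(Biostrings::vcountPattern(
    construct_feature(sc$construct, "marker"), combined)), 1)
})

test_that("insertion duplicates the TTAA and excision restores the genome", {
  g <- small_genome()
  cons <- make_simple_construct()
  chr <- g$chromosomes[["chrA"]]
  site <- as.integer(regexpr("TTAA", chr, fixed = TRUE)) - 1L
  ins <- insert_transgene(g, cons, "chrA", site, "het")

  modified <- ins$diploid$hapA[["chrA"]]
  L <- nchar(cons$full_sequence)
  expect_identical(substr(modified, site + 1, site + 4), "TTAA")
  expect_identical(substr(modified, site + 5, site + 4 + L),
                   cons$full_sequence)
  expect_identical(substr(modified, site + 5 + L, site + 8 + L), "TTAA")
  expect_equal(nchar(modified) - nchar(chr), L + 4)
  expect_identical(ins$diploid$hapB[["chrA"]], chr)

  expect_identical(excise_transgene(ins$diploid)[["chrA"]], chr)

  hom <- insert_transgene(g, cons, "chrA", site, "hom")
  expect_identical(hom$diploid$hapA[["chrA"]], hom$diploid$hapB[["chrA"]])
})

test_that("insertion inside an annotated repeat records the family truth", {
  g <- small_genome()
  cons <- make_simple_construct()
  a1 <- g$annotations[1, ]
  site <- a1$start + 373L  # the protected TTAA of the repeat ancestor
  expect_identical(genome_substring(g, a1$chrom, site, site + 4), "TTAA")
  ins <- insert_transgene(g, cons, a1$chrom, site, "het")
  expect_identical(ins$event$family, "rep")
  expect_equal(ins$event$copy, a1$copy)
})

test_that("bad insertion sites raise motif/bounds errors", {
  g <- small_genome()
  cons <- make_simple_construct()
  chr <- g$chromosomes[["chrA"]]
  non_ttaa <- which(strsplit(substr(chr, 1, 200), "")[[1]] == "C")[1]
  expect_error(insert_transgene(g, cons, "chrA", non_ttaa, "het"),
               class = "insertra_motif_error")
  expect_error(insert_transgene(g, cons, "chrA", nchar(chr) - 2, "het"),
               class = "insertra_bounds_error")
})
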