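#' @useDynLib insertra, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom rnorm runif median
#' @importFrom utils write.table read.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

# condition constructor: every package error carries a machine-readable class
insertra_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "insertra_error")))
}

#' Derive a child seed from a top-level seed and a stage tag
#'
#' All generators in the package draw their randomness from a single
#' top-level seed fanned out to per-stage child seeds. The derivation is a
#' deterministic 31-bit polynomial hash of the stage tag combined with the
#' seed, so independent stages never share an RNG stream and the whole
#' simulation is reproducible from one integer.
#'
#' @param seed integer top-level seed.
#' @param tag character stage label, e.g. `"short_reads"`.
#' @return an integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
derive_seed <- function(seed, tag) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    insertra_abort("seed must be a single number", "insertra_parameter_error")
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  for (c in utf8ToInt(tag)) h <- (h * 31 + c) %% m
  as.integer((h %% (m - 2)) + 1)
}

#' Generate a random DNA sequence
#'
#' @param n length in bp.
#' @param exclude_motifs character vector of motifs that must not occur;
#'   occurrences are resampled until the sequence is clean.
#' @return a single uppercase A/C/G/T string.
#' @export
random_dna <- function(n, exclude_motifs = NULL) {
  s <- paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
  scrub_motifs(s, exclude_motifs)
}

# resample any window matching one of the motifs until none remain
scrub_motifs <- function(s, motifs) {
  if (is.null(motifs) || length(motifs) == 0) return(s)
  for (iter in 1:100) {
    hit <- FALSE
    for (m in motifs) {
      locs <- gregexpr(m, s, fixed = TRUE)[[1]]
      if (locs[1] == -1) next
      hit <- TRUE
      ch <- strsplit(s, "")[[1]]
      for (p in locs) {
        w <- nchar(m)
        ch[p:(p + w - 1)] <- sample(DNA_BASES, w, replace = TRUE)
      }
      s <- paste(ch, collapse = "")
    }
    if (!hit) return(s)
  }
  insertra_abort("could not scrub motifs from sequence", "insertra_layout_error")
}

#' Reverse complement
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# parse a CIGAR string into an ops data.frame(len, op)
cigar_ops <- function(cigar) {
  m <- gregexpr("\\d+[MIDS]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("\\d+[MIDS]", cigar))[[1]]
  if (length(toks) == 0)
    insertra_abort(paste0("bad CIGAR: ", cigar), "insertra_format_error")
  data.frame(
    len = as.integer(sub("[MIDS]$", "", toks)),
    op = sub("^\\d+", "", toks),
    stringsAsFactors = FALSE
  )
}

cigar_ref_len <- function(cigar) {
  ops <- cigar_ops(cigar)
  sum(ops$len[ops$op %in% c("M", "D")])
}

cigar_query_len <- function(cigar) {
  ops <- cigar_ops(cigar)
  sum(ops$len[ops$op %in% c("M", "I", "S")])
}

# count occurrences of pattern over both strands of a set of sequences
count_genome_occurrences <- function(pattern, seqs) {
  subject <- Biostrings::DNAStringSet(unlist(seqs, use.names = FALSE))
  fw <- sum(Biostrings::vcountPattern(pattern, subject))
  rc <- sum(Biostrings::vcountPattern(revcomp(pattern), subject))
  if (pattern == revcomp(pattern)) fw else fw + rc
}
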