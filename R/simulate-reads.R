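# Read simulators. Both draw fragments uniformly over the two haplotypes
# proportional to sequence length and record the generating interval
# (truth_origin) for every read, so downstream accuracy can always be
# scored against planted truth. Base qualities are constant (Q30 short,
# Q12 long): the depth analyses are quality-agnostic.

haplotype_pool <- function(diploid) {
  pool <- list()
  for (hap in c("hapA", "hapB")) {
    seqs <- diploid[[hap]]
    for (cn in names(seqs))
      pool[[length(pool) + 1]] <- list(hap = hap, chrom = cn,
                                       seq = seqs[[cn]], len = nchar(seqs[[cn]]))
  }
  pool
}

# vectorised substitution errors at a fixed per-base rate
apply_sub_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n_err <- rbinom(length(seqs), nchar(seqs), rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    ch <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(length(ch), n_err[i])
    for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate Illumina-like paired-end reads
#'
#' Fragments of length `N(insert_mean, insert_sd)` are drawn uniformly over
#' both haplotypes; the two mates are the fragment ends, the second mate
#' reverse-complemented, with independent substitution errors at rate
#' `sub_error`. Defaults emulate a 350 bp insert, 2 x 150 bp library.
#'
#' @param diploid `DiploidGenome`.
#' @param n_pairs number of read pairs (> 0).
#' @param insert_mean,insert_sd fragment length distribution (bp).
#' @param read_len read length (bp).
#' @param sub_error per-base substitution rate in `[0, 0.05]`.
#' @param seed integer seed (byte-identical output for identical seeds).
#' @return a `ReadSet`: data.frame with id, seq, qual, mate_id and the
#'   truth origin (hap, chrom, start, strand); attribute `platform =
#'   "short_paired"`.
#' @export
simulate_short_reads <- function(diploid, n_pairs, insert_mean = 350,
                                 insert_sd = 35, read_len = 150,
                                 sub_error = 0.001, seed = 1) {
  if (!is.numeric(n_pairs) || n_pairs <= 0)
    insertra_abort("n_pairs must be positive", "insertra_parameter_error")
  if (sub_error < 0 || sub_error > 0.05)
    insertra_abort("sub_error must be in [0, 0.05]", "insertra_parameter_error")
  set.seed(derive_seed(seed, "short_reads"))
  pool <- haplotype_pool(diploid)
  lens <- vapply(pool, function(p) p$len, numeric(1))
  src <- sample.int(length(pool), n_pairs, replace = TRUE, prob = lens)
  flen <- pmax(read_len, round(rnorm(n_pairs, insert_mean, insert_sd)))

  out <- vector("list", length(pool))
  for (pi in seq_along(pool)) {
    sel <- which(src == pi)
    if (length(sel) == 0) next
    p <- pool[[pi]]
    fl <- pmin(flen[sel], p$len)
    start <- floor(runif(length(sel)) * (p$len - fl + 1))   # 0-based
    frag1 <- substring(p$seq, start + 1, start + read_len)
    frag2 <- substring(p$seq, start + fl - read_len + 1, start + fl)
    out[[pi]] <- data.frame(
      pair = sel, hap = p$hap, chrom = p$chrom,
      start1 = start, start2 = start + fl - read_len,
      seq1 = frag1, seq2 = frag2, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  tab <- tab[order(tab$pair), , drop = FALSE]
  r1 <- apply_sub_errors(tab$seq1, sub_error)
  r2 <- apply_sub_errors(revcomp(tab$seq2), sub_error)
  ids1 <- sprintf("sr%06d/1", tab$pair)
  ids2 <- sprintf("sr%06d/2", tab$pair)
  reads <- data.frame(
    id = c(ids1, ids2),
    seq = c(r1, r2),
    qual = strrep(rawToChar(as.raw(63L)), nchar(c(r1, r2))),  # Q30 '?'
    mate_id = c(ids2, ids1),
    hap = c(tab$hap, tab$hap),
    chrom = c(tab$chrom, tab$chrom),
    start = c(tab$start1, tab$start2),
    strand = rep(c("+", "-"), each = nrow(tab)),
    stringsAsFactors = FALSE)
  reads <- reads[order(reads$id), , drop = FALSE]
  rownames(reads) <- NULL
  structure(reads, platform = "short_paired", read_len = read_len,
            class = c("ReadSet", "data.frame"))
}

# inject a mixture of substitutions and short indels at total rate `rate`
apply_long_read_errors <- function(seqs, rate, mix) {
  if (rate <= 0) return(seqs)
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[i], "")[[1]]
    n_err <- rbinom(1, length(ch), rate)
    if (n_err == 0) next
    pos <- sample.int(length(ch), n_err)
    type <- sample(c("sub", "ins", "del"), n_err, replace = TRUE, prob = mix)
    for (j in seq_len(n_err)) {
      p <- pos[j]
      if (type[j] == "sub") ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
      else if (type[j] == "del") ch[p] <- ""
      else ch[p] <- paste0(ch[p], sample(DNA_BASES, 1))
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate Nanopore-like long reads
#'
#' Read lengths are `N(length_mean, length_sd)` (clamped at 500 bp);
#' errors are a mixture of substitutions and 1 bp insertions/deletions with
#' the split given by `error_mix` (default 40/30/30). Optionally the first
#' `anchor_n` reads are drawn by rejection so that each fully spans the
#' interval `anchor_interval` on haplotype A — the standard trick to
#' guarantee junction-spanning reads at the low genome-wide coverage
#' (< 10x) typical of a MinION run.
#'
#' @param diploid `DiploidGenome`.
#' @param n_reads total number of reads.
#' @param length_mean,length_sd read length distribution (bp); default ~8 kb.
#' @param error_rate total per-base error rate in `[0, 0.15]`.
#' @param error_mix length-3 numeric, proportions sub/ins/del.
#' @param seed integer seed.
#' @param anchor_n number of reads forced to span `anchor_interval`.
#' @param anchor_interval list(chrom=, start=, end=) on haplotype A;
#'   defaults to the construct's marker-bearing head when the diploid
#'   carries an insertion.
#' @return a `ReadSet` with `platform = "long"`.
#' @export
simulate_long_reads <- function(diploid, n_reads, length_mean = 8000,
                                length_sd = 2000, error_rate = 0.08,
                                error_mix = c(0.4, 0.3, 0.3), seed = 1,
                                anchor_n = 0, anchor_interval = NULL) {
  if (!is.numeric(n_reads) || n_reads <= 0)
    insertra_abort("n_reads must be positive", "insertra_parameter_error")
  if (error_rate < 0 || error_rate > 0.15)
    insertra_abort("error_rate must be in [0, 0.15]", "insertra_parameter_error")
  set.seed(derive_seed(seed, "long_reads"))
  pool <- haplotype_pool(diploid)
  lens <- vapply(pool, function(p) p$len, numeric(1))
  keyof <- vapply(pool, function(p) paste(p$hap, p$chrom), character(1))

  rows <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    L <- max(500, round(rnorm(1, length_mean, length_sd)))
    if (i <= anchor_n && !is.null(anchor_interval)) {
      ai <- anchor_interval
      pi <- match(paste("hapA", ai$chrom), keyof)
      span <- ai$end - ai$start
      L <- max(L, span + 1000)
      L <- min(L, pool[[pi]]$len)
      lo <- max(0, ai$end - L)
      hi <- min(ai$start, pool[[pi]]$len - L)
      start <- floor(runif(1, lo, hi + 1))
    } else {
      pi <- sample.int(length(pool), 1, prob = lens)
      L <- min(L, pool[[pi]]$len)
      start <- floor(runif(1) * (pool[[pi]]$len - L + 1))
    }
    strand <- sample(c("+", "-"), 1)
    rows[[i]] <- data.frame(
      idx = i, hap = pool[[pi]]$hap, chrom = pool[[pi]]$chrom,
      start = start, len = L, strand = strand, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  frag <- character(nrow(tab))
  for (key in unique(paste(tab$hap, tab$chrom))) {
    sel <- which(paste(tab$hap, tab$chrom) == key)
    sq <- diploid[[tab$hap[sel[1]]]][[tab$chrom[sel[1]]]]
    frag[sel] <- substring(sq, tab$start[sel] + 1, tab$start[sel] + tab$len[sel])
  }
  frag <- apply_long_read_errors(frag, error_rate, error_mix)
  rc <- tab$strand == "-"
  frag[rc] <- revcomp(frag[rc])
  reads <- data.frame(
    id = sprintf("lr%05d", tab$idx),
    seq = frag,
    qual = strrep(rawToChar(as.raw(45L)), nchar(frag)),  # Q12 '-'
    mate_id = NA_character_,
    hap = tab$hap, chrom = tab$chrom, start = tab$start,
    strand = tab$strand, stringsAsFactors = FALSE)
  rownames(reads) <- NULL
  structure(reads, platform = "long", class = c("ReadSet", "data.frame"))
}

#' Write a ReadSet as 4-line FASTQ
#' @param reads `ReadSet`.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$seq)
  names(ss) <- reads$id
  q <- Biostrings::BStringSet(reads$qual)
  # constructor warns about dropping (empty) metadata columns; irrelevant
  qs <- suppressWarnings(
    Biostrings::QualityScaledDNAStringSet(ss, Biostrings::PhredQuality(q)))
  Biostrings::writeQualityScaledXStringSet(qs, filepath = path)
  invisible(path)
}

#' Read a FASTQ file into a minimal ReadSet (no truth origin)
#' @param path FASTQ file.
#' @export
read_fastq <- function(path) {
  # reader re-attaches (empty) metadata and warns; irrelevant here
  qs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = names(qs), seq = as.character(qs),
             qual = as.character(Biostrings::quality(qs)),
             stringsAsFactors = FALSE)
}
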