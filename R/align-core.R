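# Minimal self-contained read mapper and local-similarity search.
# Seed (exact k-mers) -> cluster colinear seeds by diagonal -> banded
# affine-gap Smith-Waterman extension. One substitution scheme (match +2,
# mismatch -3, gap open 5, gap extend 2; a gap of length L costs
# open + L*extend) is shared by every identity computation in the package.

#' Default alignment scoring
#' @return list(match, mismatch, gap_open, gap_extend); penalties positive.
#' @export
default_scoring <- function() {
  list(match = 2L, mismatch = -3L, gap_open = 5L, gap_extend = 2L)
}

#' Optimal local alignment (full-matrix affine-gap Smith-Waterman)
#'
#' @param a,b non-empty DNA strings.
#' @param scoring see [default_scoring()].
#' @return list with `score`, `identity` (matches / alignment columns),
#'   `aln_length`, `cigar` (relative to `a`, soft clips at the ends) and
#'   0-based half-open aligned intervals `a_start/a_end/b_start/b_end`.
#' @export
smith_waterman <- function(a, b, scoring = default_scoring()) {
  if (!nzchar(a) || !nzchar(b))
    insertra_abort("empty sequence", "insertra_parameter_error")
  cpp_sw(a, b, scoring$match, scoring$mismatch,
         scoring$gap_open, scoring$gap_extend)
}

#' Pairwise identity by global (end-to-end) affine-gap alignment
#' @param a,b DNA strings.
#' @param scoring see [default_scoring()].
#' @return fraction of matching columns over all alignment columns.
#' @export
pairwise_identity <- function(a, b, scoring = default_scoring()) {
  cpp_nw(a, b, scoring$match, scoring$mismatch,
         scoring$gap_open, scoring$gap_extend)$identity
}

#' Build an exact k-mer index over a set of reference sequences
#'
#' Indexes the forward strand only; queries are searched in both
#' orientations by reverse-complementing the read. k-mers occurring more
#' than `max_occ` times are skipped at query time (repeat masking).
#'
#' @param sequences named character vector (or `HostGenome`).
#' @param k k-mer size, 8..31 (default 15).
#' @param max_occ per-k-mer occurrence cap.
#' @return object of class `KmerIndex`. Holds an external pointer: rebuild
#'   rather than serialize.
#' @export
index_reference <- function(sequences, k = 15, max_occ = 256) {
  if (inherits(sequences, "HostGenome")) sequences <- sequences$chromosomes
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    insertra_abort("sequences must be named", "insertra_parameter_error")
  if (k < 8 || k > 31)
    insertra_abort("k must be in [8, 31]", "insertra_parameter_error")
  ptr <- cpp_build_index(names(sequences), unname(sequences),
                         as.integer(k), as.integer(max_occ))
  structure(list(ptr = ptr, k = as.integer(k),
                 ref_names = names(sequences),
                 ref_lengths = stats::setNames(nchar(sequences), names(sequences)),
                 sequences = sequences),
            class = "KmerIndex")
}

#' @export
print.KmerIndex <- function(x, ...) {
  info <- cpp_index_info(x$ptr)
  cat(sprintf("KmerIndex: k=%d, %d reference(s), %.0f indexed positions\n",
              info$k, info$n_ref, info$n_positions))
  invisible(x)
}

#' Positions of one exact k-mer in the index (forward strand)
#' @param index `KmerIndex`.
#' @param kmer string of length `k`.
#' @return data.frame(ref, pos) with 0-based positions.
#' @export
query_kmer <- function(index, kmer) {
  r <- cpp_query_kmer(index$ptr, kmer)
  data.frame(ref = index$ref_names[r$ref], pos = r$pos,
             stringsAsFactors = FALSE)
}

#' Map reads against an indexed reference
#'
#' Seed-and-extend with banded affine-gap Smith-Waterman. For every read
#' the best-scoring alignment of EVERY locus tying the maximum score is
#' returned; `n_best` is the tie count and `mapq` is 40 for a unique best
#' locus and 0 otherwise (the pipeline only needs the unique/ambiguous
#' distinction). Unaligned read ends appear as soft clips (`S`).
#'
#' @param index `KmerIndex`.
#' @param reads character vector of read sequences, or a `ReadSet`.
#' @param ids read identifiers (defaults to the ReadSet ids or `names`).
#' @param scoring see [default_scoring()].
#' @param band extension band half-width around the seed diagonal.
#' @param min_seeds minimum seeds per candidate locus.
#' @param max_loci candidate loci examined per read.
#' @param seed_step seed sampling stride (0 = automatic).
#' @return data.frame of class `alignments`: read_id, ref, strand (0 fwd /
#'   1 rev), start/end (0-based half-open on the reference), cigar (for the
#'   oriented read), score, identity, aln_length, n_best, mapq,
#'   qstart/qend (on the oriented read). Attribute `ref_lengths` carries
#'   the reference dimensions.
#' @export
map_reads <- function(index, reads, ids = NULL, scoring = default_scoring(),
                      band = 50, min_seeds = 2, max_loci = 64, seed_step = 0) {
  if (inherits(reads, "ReadSet") || is.data.frame(reads)) {
    if (is.null(ids)) ids <- reads$id
    reads <- reads$seq
  }
  if (is.null(ids)) ids <- if (!is.null(names(reads))) names(reads) else
    sprintf("read%06d", seq_along(reads))
  if (any(nchar(reads) < index$k))
    insertra_abort("read shorter than k", "insertra_parameter_error")
  aln <- cpp_map_reads(index$ptr, unname(reads), unname(ids),
                       scoring$match, scoring$mismatch, scoring$gap_open,
                       scoring$gap_extend, as.integer(band),
                       as.integer(min_seeds), as.integer(max_loci),
                       as.integer(seed_step))
  structure(aln, ref_lengths = index$ref_lengths,
            class = c("alignments", "data.frame"))
}

#' Map a single read; returns an empty data.frame when unmappable
#' @inheritParams map_reads
#' @param read one read sequence.
#' @export
map_read <- function(index, read, ...) {
  map_reads(index, reads = read, ids = "read", ...)
}

#' BLAST-like local similarity search
#'
#' Unlike [map_reads()] this reports every locus whose extended alignment
#' scores at least `min_score`, not only the ties for best — the tool for
#' "where else in the genome does this flanking sequence occur".
#' Hits are sorted by score descending, ties broken by (ref, ref_start).
#'
#' @param index `KmerIndex`.
#' @param query query sequence (length >= k).
#' @param min_score minimum alignment score to report.
#' @param band extension band half-width.
#' @param min_seeds minimum seeds per candidate locus.
#' @param max_loci candidate cap.
#' @param chain_gap max positional gap when chaining seed clusters (bp).
#' @param scoring see [default_scoring()].
#' @return data.frame of class `search_hits`: ref, strand, ref_start,
#'   ref_end, qstart, qend (forward-query coordinates, 0-based half-open),
#'   score, identity, aln_length.
#' @export
local_search <- function(index, query, min_score = 60, band = 100,
                         min_seeds = 2, max_loci = 200, chain_gap = 1500,
                         scoring = default_scoring()) {
  if (nchar(query) < index$k)
    insertra_abort("query shorter than k", "insertra_parameter_error")
  hits <- cpp_local_search(index$ptr, query, scoring$match, scoring$mismatch,
                           scoring$gap_open, scoring$gap_extend,
                           as.integer(band), as.integer(min_score),
                           as.integer(min_seeds), as.integer(max_loci),
                           0L, as.integer(chain_gap))
  structure(hits, class = c("search_hits", "data.frame"))
}

#' All exact shared k-mers between two sequences (dot plot backend)
#' @param a,b sequences.
#' @param k k-mer size (>= 11 for dot plots, >= 8 here).
#' @return data.frame pos_a, pos_b, strand.
#' @export
kmer_matches <- function(a, b, k = 15) {
  cpp_kmer_matches(a, b, as.integer(k))
}

# ---------------------------------------------------------------------------
# SAM text I/O (minimal dialect: what the package itself emits)

#' Write alignments as SAM
#'
#' 1-based POS, soft clips as S ops, `NH:i:` tag carrying the number of
#' equally-best loci. Reverse-strand records store the reverse-complemented
#' read sequence, per the SAM convention.
#'
#' @param alignments `alignments` data.frame from [map_reads()].
#' @param reads `ReadSet` (or data.frame with id/seq/qual) supplying
#'   sequences.
#' @param path output SAM file.
#' @export
write_sam <- function(alignments, reads, path) {
  rl <- attr(alignments, "ref_lengths")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (rn in names(rl))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", rn, rl[[rn]]), con)
  if (nrow(alignments) == 0) return(invisible(path))
  seqs <- stats::setNames(reads$seq, reads$id)
  quals <- if (!is.null(reads$qual)) stats::setNames(reads$qual, reads$id) else NULL
  sq <- seqs[alignments$read_id]
  qu <- if (!is.null(quals)) quals[alignments$read_id] else strrep("I", nchar(sq))
  rev <- alignments$strand == 1
  sq[rev] <- revcomp(sq[rev])
  qu[rev] <- vapply(strsplit(qu[rev], ""), function(x)
    paste(rev(x), collapse = ""), character(1))
  flag <- ifelse(rev, 16L, 0L)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNH:i:%d",
                   alignments$read_id, flag, alignments$ref,
                   alignments$start + 1L, alignments$mapq, alignments$cigar,
                   sq, qu, alignments$n_best)
  writeLines(lines, con)
  invisible(path)
}

#' Read a SAM text file into an `alignments` data.frame
#'
#' Parses the subset of SAM this package writes (and any standards-
#' compliant file restricted to M/I/D/S CIGARs). Reverse-strand SEQ fields
#' are restored to the original read orientation in the returned `seq`.
#'
#' @param path SAM file.
#' @return `alignments` data.frame with an additional `seq` column.
#' @export
read_sam <- function(path) {
  ln <- readLines(path)
  hdr <- ln[startsWith(ln, "@")]
  body <- ln[!startsWith(ln, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  rl <- stats::setNames(
    as.integer(sub(".*\tLN:(\\d+).*", "\\1", sq)),
    sub(".*\tSN:([^\t]+).*", "\\1", sq))
  if (length(body) == 0) {
    out <- data.frame(read_id = character(0), ref = character(0),
                      strand = integer(0), start = integer(0),
                      cigar = character(0), mapq = integer(0),
                      n_best = integer(0), seq = character(0),
                      stringsAsFactors = FALSE)
    return(structure(out, ref_lengths = rl,
                     class = c("alignments", "data.frame")))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  bad <- vapply(f, length, integer(1)) < 11
  if (any(bad))
    insertra_abort("malformed SAM record", "insertra_format_error")
  flag <- as.integer(vapply(f, `[[`, "", 2))
  strand <- ifelse(bitwAnd(flag, 16L) > 0, 1L, 0L)
  seqf <- vapply(f, `[[`, "", 10)
  seqf[strand == 1] <- revcomp(seqf[strand == 1])
  nh <- vapply(f, function(x) {
    t <- grep("^NH:i:", x[-(1:11)], value = TRUE)
    if (length(t) > 0) as.integer(sub("NH:i:", "", t[1])) else 1L
  }, integer(1))
  cig <- vapply(f, `[[`, "", 6)
  out <- data.frame(
    read_id = vapply(f, `[[`, "", 1),
    ref = vapply(f, `[[`, "", 3),
    strand = strand,
    start = as.integer(vapply(f, `[[`, "", 4)) - 1L,
    cigar = cig,
    mapq = as.integer(vapply(f, `[[`, "", 5)),
    n_best = nh,
    seq = seqf,
    stringsAsFactors = FALSE)
  out$end <- out$start + vapply(cig, cigar_ref_len, numeric(1))
  structure(out, ref_lengths = rl, class = c("alignments", "data.frame"))
}
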