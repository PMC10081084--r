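# Greedy overlap-layout-consensus assembly of anchored long reads.
# At desk scale (tens to a few hundred reads around one insertion) greedy
# merging of the best suffix-prefix overlap is near-optimal and easy to
# verify; the consensus is then polished by majority-vote pileup.

# try to find a dovetail overlap between oriented sequences a and b.
# Returns NULL or list(score, merged, type).
find_overlap <- function(a, b, min_overlap, min_identity, scoring,
                         k = 13, band = 200, slack = 30) {
  diags <- cpp_best_diags(a, b, as.integer(k), 5L)
  if (!nrow(diags)) return(NULL)
  la <- nchar(a); lb <- nchar(b)
  for (i in seq_len(nrow(diags))) {
    if (diags$count[i] < 3) next
    d <- diags$diag[i]
    r <- cpp_align_hint(b, a, as.integer(d), as.integer(band),
                        scoring$match, scoring$mismatch,
                        scoring$gap_open, scoring$gap_extend)
    if (r$score <= 0) next
    if (r$aln_length < min_overlap) next
    if (r$identity < min_identity) next
    contained_b <- r$a_start <= slack && r$a_end >= lb - slack
    contained_a <- r$b_start <= slack && r$b_end >= la - slack
    if (contained_a && contained_b) {
      return(list(score = r$score, merged = if (la >= lb) a else b,
                  type = "contain"))
    }
    if (contained_b)
      return(list(score = r$score, merged = a, type = "contain_b"))
    if (contained_a)
      return(list(score = r$score, merged = b, type = "contain_a"))
    # dovetail: suffix of a overlaps prefix of b
    if (r$b_end >= la - slack && r$a_start <= slack && r$a_end < lb) {
      merged <- paste0(substr(a, 1, r$b_end), substr(b, r$a_end + 1, lb))
      return(list(score = r$score, merged = merged, type = "dovetail_ab"))
    }
    # dovetail the other way: suffix of b overlaps prefix of a
    if (r$a_end >= lb - slack && r$b_start <= slack && r$b_end < la) {
      merged <- paste0(substr(b, 1, r$a_end), substr(a, r$b_end + 1, la))
      return(list(score = r$score, merged = merged, type = "dovetail_ba"))
    }
  }
  NULL
}

contains_anchor <- function(seq, anchor, scoring, min_identity = 0.7) {
  d <- cpp_best_diags(seq, anchor, 13L, 3L)
  if (!nrow(d) || d$count[1] < 3) return(FALSE)
  r <- cpp_align_hint(anchor, seq, as.integer(d$diag[1]), 300L,
                      scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extend)
  r$aln_length >= 0.5 * nchar(anchor) && !is.na(r$identity) &&
    r$identity >= min_identity
}

#' Greedy assembly of anchor-containing long reads into a contig
#'
#' Selects the reads that contain one of the `anchors` (construct marker
#' sequences, searched at a permissive >= 0.75 identity to tolerate
#' long-read error), orients them to the anchor strand, then repeatedly
#' merges the pair with the highest-scoring suffix-prefix overlap of at
#' least `min_overlap` bp and `min_identity` identity. The resulting draft
#' is polished by `polish_rounds` rounds of majority-vote pileup against
#' its member reads. Returns the longest contig still containing an anchor.
#'
#' @param reads long-read `ReadSet` or character vector of sequences.
#' @param anchors named character vector of anchor sequences.
#' @param min_overlap minimum overlap length (default 500 bp).
#' @param min_identity minimum overlap identity (default 0.8).
#' @param anchor_identity minimum identity for anchor detection.
#' @param scoring see [default_scoring()].
#' @param polish_rounds majority-vote polish iterations (default 2).
#' @param band alignment band for overlap/polish alignments.
#' @return object of class `assembly`: list(contig, n_anchored, members,
#'   n_contigs).
#' @export
assemble_long_reads <- function(reads, anchors, min_overlap = 500,
                                min_identity = 0.8, anchor_identity = 0.75,
                                scoring = default_scoring(),
                                polish_rounds = 2, band = 300) {
  if (inherits(reads, "ReadSet") || is.data.frame(reads)) {
    ids <- reads$id
    seqs <- reads$seq
  } else {
    seqs <- reads
    ids <- if (!is.null(names(reads))) names(reads) else
      sprintf("read%04d", seq_along(reads))
  }
  if (is.null(names(anchors)))
    names(anchors) <- sprintf("anchor%d", seq_along(anchors))

  # anchor detection via local search over an index of the reads
  ridx <- index_reference(stats::setNames(seqs, ids), k = 13, max_occ = 1024)
  sel <- character(0)
  orient <- character(0)
  for (an in names(anchors)) {
    hits <- local_search(ridx, anchors[[an]], min_score = 60,
                         band = 150, chain_gap = 500, scoring = scoring)
    if (!nrow(hits)) next
    hits <- hits[hits$identity >= anchor_identity &
                 hits$aln_length >= 0.3 * nchar(anchors[[an]]), , drop = FALSE]
    for (j in seq_len(nrow(hits))) {
      id <- hits$ref[j]
      if (id %in% sel) next
      sel <- c(sel, id)
      orient <- c(orient, if (hits$strand[j] == 0) "+" else "-")
    }
  }
  if (length(sel) == 0)
    insertra_abort("no reads contain an anchor sequence",
                   "insertra_evidence_error")
  pool <- stats::setNames(seqs[match(sel, ids)], sel)
  flip <- orient == "-"
  pool[flip] <- revcomp(pool[flip])

  contigs <- lapply(seq_along(pool), function(i)
    list(seq = pool[[i]], members = names(pool)[i]))

  # pairwise overlap cache
  n <- length(contigs)
  repeat {
    best <- NULL; bi <- bj <- 0
    nc <- length(contigs)
    if (nc < 2) break
    for (i in seq_len(nc - 1)) {
      for (j in (i + 1):nc) {
        ov <- find_overlap(contigs[[i]]$seq, contigs[[j]]$seq,
                           min_overlap, min_identity, scoring, band = band)
        if (!is.null(ov) && (is.null(best) || ov$score > best$score)) {
          best <- ov; bi <- i; bj <- j
        }
      }
    }
    if (is.null(best)) break
    merged <- list(seq = best$merged,
                   members = c(contigs[[bi]]$members, contigs[[bj]]$members))
    contigs <- c(contigs[-c(bi, bj)], list(merged))
  }

  # pick the longest contig containing an anchor
  lens <- vapply(contigs, function(ct) nchar(ct$seq), numeric(1))
  anch <- vapply(contigs, function(ct)
    any(vapply(anchors, function(a)
      contains_anchor(ct$seq, a, scoring), logical(1))), logical(1))
  if (!any(anch))
    insertra_abort("assembly lost its anchors", "insertra_evidence_error")
  pick <- which(anch)[which.max(lens[anch])]
  contig <- contigs[[pick]]$seq
  members <- contigs[[pick]]$members

  if (length(members) > 1 && polish_rounds > 0) {
    for (r in seq_len(polish_rounds)) {
      p <- cpp_polish(contig, unname(pool[members]), 13L,
                      as.integer(band + 100), scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extend)
      if (identical(p$sequence, contig)) break
      contig <- p$sequence
    }
  }
  structure(list(contig = contig, n_anchored = length(pool),
                 members = members, n_contigs = length(contigs)),
            class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("assembly: contig %d bp from %d read(s) (%d anchored, %d contig(s) total)\n",
              nchar(x$contig), length(x$members), x$n_anchored, x$n_contigs))
  invisible(x)
}

#' Write a contig (or any named sequences) as FASTA
#' @param contig character vector (named or not).
#' @param path output file.
#' @param name sequence name used when `contig` is unnamed.
#' @export
write_contig_fasta <- function(contig, path, name = "contig") {
  if (is.null(names(contig)))
    names(contig) <- if (length(contig) == 1) name else
      paste0(name, "_", seq_along(contig))
  write_genome_fasta(contig, path)
}
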