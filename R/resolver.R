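# Candidate-locus ranking from flank evidence and resolution of
# repeat-induced ambiguity with a long-read contig.

#' Rank candidate insertion loci from flank search hits
#'
#' Filters local-search hits of the recovered flank(s) by identity and
#' alignment length, checks for the TTAA motif at the junction-proximal
#' position of each hit (within a +/- `ttaa_tol` bp window), and ranks by
#' score (ties broken by (chrom, start) so the ranking is a total order
#' independent of input order).
#'
#' @param hits `search_hits` data.frame from [local_search()].
#' @param genome `HostGenome` or named character vector.
#' @param t_identity identity threshold (default 0.90).
#' @param t_length alignment-length threshold in bp (default 700).
#' @param require_ttaa drop candidates without the junction TTAA.
#' @param junction_offset query coordinate (0-based) of the junction point
#'   within the flank query: `nchar(query)` for a 5' flank that ends at
#'   the junction, `0` for a 3' flank that starts at it, or the interior
#'   offset for a combined 5'+3' query.
#' @param motif duplicated target motif (default `"TTAA"`).
#' @param ttaa_tol motif search tolerance around the mapped junction (bp).
#' @return `CandidateLocus` data.frame: chrom, start, end, strand,
#'   identity, aln_length, score, has_ttaa, evidence_tier, rank.
#' @export
rank_candidate_loci <- function(hits, genome, t_identity = 0.90,
                                t_length = 700, require_ttaa = TRUE,
                                junction_offset = NULL, motif = "TTAA",
                                ttaa_tol = 4) {
  seqs <- if (inherits(genome, "HostGenome")) genome$chromosomes else genome
  if (!nrow(hits)) return(empty_candidates())
  keep <- hits$identity >= t_identity & hits$aln_length >= t_length
  h <- hits[keep, , drop = FALSE]
  if (!nrow(h)) return(empty_candidates())
  has <- vapply(seq_len(nrow(h)), function(i) {
    jq <- if (is.null(junction_offset)) h$qend[i] else junction_offset
    jq <- min(max(jq, h$qstart[i]), h$qend[i])
    # map the junction query coordinate onto the reference (linear approx.)
    jr <- if (h$strand[i] == 0) h$ref_start[i] + (jq - h$qstart[i])
          else h$ref_end[i] - (jq - h$qstart[i])
    L <- nchar(seqs[[h$ref[i]]])
    lo <- max(0, jr - nchar(motif) - ttaa_tol)
    hi <- min(L, jr + nchar(motif) + ttaa_tol)
    grepl(motif, substr(seqs[[h$ref[i]]], lo + 1, hi), fixed = TRUE)
  }, logical(1))
  h$has_ttaa <- has
  if (require_ttaa) h <- h[h$has_ttaa, , drop = FALSE]
  if (!nrow(h)) return(empty_candidates())
  ord <- order(-h$score, h$ref, h$ref_start)
  h <- h[ord, , drop = FALSE]
  out <- data.frame(
    chrom = h$ref, start = h$ref_start, end = h$ref_end,
    strand = h$strand, identity = h$identity, aln_length = h$aln_length,
    score = h$score, has_ttaa = h$has_ttaa,
    evidence_tier = "flank_only", rank = seq_len(nrow(h)),
    stringsAsFactors = FALSE)
  class(out) <- c("CandidateLocus", "data.frame")
  out
}

empty_candidates <- function() {
  out <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), strand = integer(0),
                    identity = numeric(0), aln_length = integer(0),
                    score = numeric(0), has_ttaa = logical(0),
                    evidence_tier = character(0), rank = integer(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("CandidateLocus", "data.frame")
  out
}

#' Resolve candidate ambiguity with a long-read contig
#'
#' Aligns the contig's flank arms (the parts outside its construct span)
#' to the genome and derives "unique islands": maximal runs of arm
#' positions covered by exactly one hit of identity >= `min_identity`,
#' at least `unique_flank_min` bp long. A candidate is resolved when such
#' an island maps within `link_window` bp of it. If exactly one candidate
#' is resolved the report is unambiguous; with zero or several the
#' ambiguity stands (resolved candidates are flagged). When islands exist
#' but none links to any flank candidate, the best island is reported as a
#' novel locus with the `flank_discordant` flag.
#'
#' @param candidates `CandidateLocus` data.frame.
#' @param contig assembled contig sequence (must contain the anchor).
#' @param genome_index `KmerIndex` over the host genome.
#' @param construct `TransgeneConstruct` (locates the construct span in
#'   the contig).
#' @param anchors anchor sequences used to verify the contig.
#' @param unique_flank_min minimum unique run (default 500 bp).
#' @param link_window candidate-to-island linkage window (default 25 kb).
#' @param min_identity hit identity floor (default 0.90).
#' @param scoring see [default_scoring()].
#' @return object of class `ResolutionReport`: list(candidates, ambiguous,
#'   resolved_locus, segments, novel_locus, flank_discordant).
#' @export
integrate_long_read_evidence <- function(candidates, contig, genome_index,
                                         construct, anchors = NULL,
                                         unique_flank_min = 500,
                                         link_window = 25000,
                                         min_identity = 0.90,
                                         scoring = default_scoring()) {
  if (is.null(anchors)) anchors <- construct$full_sequence
  sc <- scoring
  if (!any(vapply(anchors, function(a)
    contains_anchor(contig, a, sc), logical(1))))
    insertra_abort("contig does not contain a construct anchor",
                   "insertra_evidence_error")

  # locate the construct span in the contig
  cidx <- index_reference(c(contig = contig), k = 13)
  ch <- local_search(cidx, construct$full_sequence, min_score = 200,
                     band = 400, chain_gap = 3000, scoring = sc)
  if (!nrow(ch))
    insertra_abort("cannot locate the construct span in the contig",
                   "insertra_evidence_error")
  span <- c(ch$ref_start[1], ch$ref_end[1])
  arms <- list()
  if (span[1] >= unique_flank_min)
    arms$arm5 <- substr(contig, 1, span[1])
  if (nchar(contig) - span[2] >= unique_flank_min)
    arms$arm3 <- substr(contig, span[2] + 1, nchar(contig))

  segments <- list()
  for (an in names(arms)) {
    arm <- arms[[an]]
    hits <- local_search(genome_index, arm, min_score = 100, band = 200,
                         chain_gap = 2000, max_loci = 300, scoring = sc)
    if (!nrow(hits)) next
    hits <- hits[hits$identity >= min_identity, , drop = FALSE]
    if (!nrow(hits)) next
    cov <- IRanges::coverage(
      IRanges::IRanges(hits$qstart + 1L, hits$qend), width = nchar(arm))
    uniq <- IRanges::slice(cov, lower = 1, upper = 1, rangesOnly = TRUE)
    uniq <- uniq[IRanges::width(uniq) >= unique_flank_min]
    for (u in seq_along(uniq)) {
      us <- IRanges::start(uniq)[u] - 1L  # back to 0-based
      ue <- IRanges::end(uniq)[u]
      covering <- which(hits$qstart <= us & hits$qend >= ue)
      if (length(covering) != 1) next
      hv <- hits[covering, ]
      # project the unique run onto the reference
      if (hv$strand == 0) {
        rs <- hv$ref_start + (us - hv$qstart); re <- rs + (ue - us)
      } else {
        re <- hv$ref_end - (us - hv$qstart); rs <- re - (ue - us)
      }
      dist_junction <- if (an == "arm5") nchar(arm) - ue else us
      segments[[length(segments) + 1]] <- data.frame(
        arm = an, ref = hv$ref, start = rs, end = re,
        length = ue - us, identity = hv$identity,
        distance_to_junction = dist_junction, stringsAsFactors = FALSE)
    }
  }
  segs <- if (length(segments)) do.call(rbind, segments) else
    data.frame(arm = character(0), ref = character(0), start = integer(0),
               end = integer(0), length = integer(0), identity = numeric(0),
               distance_to_junction = integer(0), stringsAsFactors = FALSE)

  cand <- candidates
  cand$resolved <- FALSE
  if (nrow(cand) && nrow(segs)) {
    for (i in seq_len(nrow(cand))) {
      near <- segs$ref == cand$chrom[i] &
        segs$start < cand$end[i] + link_window &
        cand$start[i] < segs$end + link_window
      cand$resolved[i] <- any(near)
    }
  }
  n_res <- sum(cand$resolved)
  resolved_locus <- NULL
  novel <- NULL
  flank_discordant <- FALSE
  if (n_res == 1) {
    resolved_locus <- cand[cand$resolved, , drop = FALSE]
    resolved_locus$evidence_tier <- "long_read_resolved"
  } else if (n_res == 0 && nrow(segs) > 0 && nrow(cand) > 0) {
    flank_discordant <- TRUE
    best <- segs[which.max(segs$length), , drop = FALSE]
    novel <- best
  }
  structure(list(
    candidates = cand,
    ambiguous = n_res != 1,
    resolved_locus = resolved_locus,
    segments = segs,
    novel_locus = novel,
    flank_discordant = flank_discordant,
    construct_span = span), class = "ResolutionReport")
}

#' @export
print.ResolutionReport <- function(x, ...) {
  cat(sprintf("ResolutionReport: %d candidate(s), ambiguous = %s\n",
              nrow(x$candidates), x$ambiguous))
  if (!is.null(x$resolved_locus))
    cat(sprintf("  resolved locus: %s:%d-%d (%s)\n",
                x$resolved_locus$chrom, x$resolved_locus$start,
                x$resolved_locus$end, x$resolved_locus$evidence_tier))
  if (nrow(x$segments))
    cat(sprintf("  %d unique flank segment(s), longest %d bp\n",
                nrow(x$segments), max(x$segments$length)))
  invisible(x)
}

#' Percentage summaries of signal tallies
#'
#' `percentage = round(100 * positive / total)` with halves rounded away
#' from zero — e.g. 59 of 63 gives 94, 38 of 54 gives 70 (the convention
#' used when reporting FISH signal counts).
#'
#' @param tallies data.frame(label, positive, total).
#' @return data.frame(label, percentage).
#' @export
summarize_signal_counts <- function(tallies) {
  if (any(tallies$total <= 0))
    insertra_abort("total must be positive", "insertra_parameter_error")
  if (any(tallies$positive < 0 | tallies$positive > tallies$total))
    insertra_abort("positive must be in [0, total]", "insertra_parameter_error")
  data.frame(label = tallies$label,
             percentage = floor(100 * tallies$positive / tallies$total + 0.5),
             stringsAsFactors = FALSE)
}
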