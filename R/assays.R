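# Deterministic emulations of the classical molecular assays used to
# characterize a transgene insertion: restriction digestion with Southern
# probing, inverse PCR, and k-mer dot plots.

#' Named restriction enzyme presets
#'
#' Enzymes are modeled as (motif, cut_offset) pairs — the offset is the cut
#' position within the motif on the top strand. `DraI` (TTT^AAA) and
#' `ScaI` (AGT^ACT) are shipped because blunt six-cutters with
#' palindromic sites are the standard choice for insertion-number blots.
#'
#' @param name `"DraI"` or `"ScaI"`, or omit for the full preset list.
#' @return list(name, motif, cut_offset) or list of such.
#' @export
enzyme_preset <- function(name = NULL) {
  presets <- list(
    DraI = list(name = "DraI", motif = "TTTAAA", cut_offset = 3L),
    ScaI = list(name = "ScaI", motif = "AGTACT", cut_offset = 3L))
  if (is.null(name)) return(presets)
  if (!name %in% names(presets))
    insertra_abort(sprintf("unknown enzyme preset '%s'", name),
                   "insertra_parameter_error")
  presets[[name]]
}

# top-strand cut positions for one enzyme over one sequence.
# Non-palindromic motifs are searched on both strands: a bottom-strand
# site at top-strand position p (occurrence of revcomp(motif)) cuts the
# top strand at p + (width - offset).
enzyme_cuts <- function(sequence, enzyme) {
  motif <- enzyme$motif
  off <- enzyme$cut_offset
  w <- nchar(motif)
  subject <- Biostrings::DNAString(sequence)
  fw <- Biostrings::start(Biostrings::matchPattern(motif, subject)) - 1L
  cuts <- fw + off
  rcm <- revcomp(motif)
  if (!identical(rcm, motif)) {
    rv <- Biostrings::start(Biostrings::matchPattern(rcm, subject)) - 1L
    cuts <- c(cuts, rv + (w - off))
  }
  sort(unique(cuts))
}

#' Restriction digestion of a linear or circular molecule
#'
#' Cuts at every motif occurrence (both strands for non-palindromic
#' motifs) and returns the fragments 5'->3' in order. Fragments tile the
#' source exactly: their lengths sum to the input length and concatenating
#' them in order restores a linear input byte-exactly.
#'
#' @param sequence the molecule (A/C/G/T string).
#' @param enzymes one enzyme (list(motif, cut_offset)) or a list of them;
#'   see [enzyme_preset()].
#' @param circular treat the molecule as circular.
#' @return object of class `FragmentPrediction`: list with `fragments`
#'   data.frame(start, end, length, seq) in source coordinates (for a
#'   circular molecule the wrap fragment has `end <= start` and its
#'   sequence wraps the origin), `cut_positions`, `circular`,
#'   `source_length`.
#' @export
digest <- function(sequence, enzymes, circular = FALSE) {
  if (!is.null(enzymes$motif)) enzymes <- list(enzymes)
  L <- nchar(sequence)
  cuts <- sort(unique(unlist(lapply(enzymes, function(e)
    enzyme_cuts(sequence, e)))))
  cuts <- cuts[cuts > 0 & cuts < L]
  if (!circular) {
    bounds <- c(0, cuts, L)
    st <- bounds[-length(bounds)]
    en <- bounds[-1]
    frag <- data.frame(start = st, end = en, length = en - st,
                       stringsAsFactors = FALSE)
    frag$seq <- substring(sequence, st + 1, en)
  } else {
    if (length(cuts) == 0) {
      frag <- data.frame(start = 0, end = L, length = L,
                         seq = sequence, stringsAsFactors = FALSE)
    } else if (length(cuts) == 1) {
      # one cut linearizes the circle into a single full-length fragment
      st <- cuts[1]
      frag <- data.frame(start = st, end = st, length = L,
                         seq = paste0(substr(sequence, st + 1, L),
                                      substr(sequence, 1, st)),
                         stringsAsFactors = FALSE)
    } else {
      st <- cuts
      en <- c(cuts[-1], cuts[1])
      sq <- ifelse(en > st,
                   substring(sequence, st + 1, en),
                   paste0(substring(sequence, st + 1, L),
                          substring(sequence, 1, en)))
      frag <- data.frame(start = st, end = en,
                         length = ifelse(en > st, en - st, L - st + en),
                         seq = sq, stringsAsFactors = FALSE)
    }
  }
  structure(list(fragments = frag, cut_positions = cuts,
                 circular = circular, source_length = L),
            class = "FragmentPrediction")
}

#' @export
print.FragmentPrediction <- function(x, ...) {
  cat(sprintf("FragmentPrediction: %d fragment(s) from %d bp %s molecule\n",
              nrow(x$fragments), x$source_length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Probe-positive fragments of a digestion (in-silico Southern lane)
#'
#' A fragment is probe-positive when a local alignment of the probe
#' against it covers at least `min_overlap` bp at `min_identity` identity
#' or better. Returns the positive fragment sizes sorted ascending — the
#' in-silico analogue of band sizes on a blot; a single insertion gives a
#' single band per digest, a double insertion two, wild type none.
#'
#' @param prediction `FragmentPrediction`.
#' @param probe probe sequence (length >= `min_overlap`).
#' @param min_overlap minimum aligned bp (default 100).
#' @param min_identity minimum alignment identity (default 0.90).
#' @param scoring see [default_scoring()].
#' @return sorted integer vector of positive fragment lengths, with the
#'   fragment table in attribute `"fragments"`.
#' @export
southern_probe_fragments <- function(prediction, probe, min_overlap = 100,
                                     min_identity = 0.90,
                                     scoring = default_scoring()) {
  if (nchar(probe) < min_overlap)
    insertra_abort("probe shorter than min_overlap", "insertra_parameter_error")
  frs <- prediction$fragments
  idx <- index_reference(stats::setNames(
    frs$seq, sprintf("frag%04d", seq_len(nrow(frs)))), k = 13)
  hits <- local_search(idx, probe, min_score = floor(min_overlap),
                       band = 100, scoring = scoring)
  pos <- logical(nrow(frs))
  if (nrow(hits)) {
    hits <- hits[hits$identity >= min_identity &
                 hits$aln_length >= min_overlap, , drop = FALSE]
    pos[match(unique(hits$ref),
              sprintf("frag%04d", seq_len(nrow(frs))))] <- TRUE
  }
  sizes <- sort(frs$length[pos])
  attr(sizes, "fragments") <- frs[pos, c("start", "end", "length")]
  sizes
}

#' In-silico Southern blot of a genome
#'
#' Digests every chromosome separately and pools the probe-positive
#' fragment sizes.
#'
#' @param genome `HostGenome` or named character vector of sequences.
#' @param enzyme enzyme definition (see [enzyme_preset()]).
#' @param probe probe sequence.
#' @param ... passed to [southern_probe_fragments()].
#' @return sorted vector of positive fragment sizes over all chromosomes.
#' @export
southern_blot <- function(genome, enzyme, probe, ...) {
  seqs <- if (inherits(genome, "HostGenome")) genome$chromosomes else genome
  sizes <- unlist(lapply(seqs, function(s)
    as.integer(southern_probe_fragments(digest(s, enzyme), probe, ...))))
  sort(unname(sizes))
}

#' In-silico inverse PCR across an insertion junction
#'
#' Digest the haplotype, select the unique fragment on which both primers
#' sit (forward primer on the top strand, reverse primer as its reverse
#' complement), self-circularize it, and walk the circle forward from the
#' forward primer to the reverse primer binding site. With outward-facing
#' primers the walk crosses the ligated fragment ends, so the amplicon
#' contains the genomic flank spanning the junction.
#'
#' @param haplotype the insertion-bearing chromosome sequence.
#' @param enzyme enzyme definition (list(motif, cut_offset)).
#' @param fwd_primer,rev_primer primer sequences (each must occur exactly
#'   once on the selected fragment).
#' @param facing_out require the amplicon to cross the circularization
#'   joint (an outward-facing primer pair); error if it does not.
#' @param max_product maximum amplifiable product (default 10 kb);
#'   exceeding it raises an `insertra_assay_failure` condition.
#' @return object of class `Amplicon`: list(sequence, primer_pair,
#'   template_description, fragment(start,end), crossed_joint).
#' @export
inverse_pcr <- function(haplotype, enzyme, fwd_primer, rev_primer,
                        facing_out = TRUE, max_product = 10000) {
  pred <- digest(haplotype, enzyme)
  frs <- pred$fragments
  rc_rev <- revcomp(rev_primer)
  nf <- Biostrings::vcountPattern(fwd_primer,
                                  Biostrings::DNAStringSet(frs$seq))
  nr <- Biostrings::vcountPattern(rc_rev,
                                  Biostrings::DNAStringSet(frs$seq))
  cand <- which(nf > 0 & nr > 0)
  if (length(cand) == 0)
    insertra_abort("no fragment carries both primers", "insertra_primer_error")
  if (length(cand) > 1)
    insertra_abort("primer pair is not unique to one fragment",
                   "insertra_primer_error")
  if (nf[cand] != 1 || nr[cand] != 1)
    insertra_abort("a primer occurs more than once on its fragment",
                   "insertra_primer_error")
  fseq <- frs$seq[cand]
  FL <- nchar(fseq)
  f0 <- as.integer(regexpr(fwd_primer, fseq, fixed = TRUE)) - 1L
  r0 <- as.integer(regexpr(rc_rev, fseq, fixed = TRUE)) - 1L
  r_end <- r0 + nchar(rc_rev)
  crossed <- r_end <= f0
  amplicon <- if (!crossed) substr(fseq, f0 + 1, r_end)
              else paste0(substr(fseq, f0 + 1, FL), substr(fseq, 1, r_end))
  if (facing_out && !crossed)
    insertra_abort("primer pair does not face outward across the joint",
                   "insertra_primer_error")
  if (nchar(amplicon) > max_product)
    insertra_abort(sprintf("product of %d bp exceeds max_product %d",
                           nchar(amplicon), max_product),
                   "insertra_assay_failure")
  structure(list(
    sequence = amplicon,
    primer_pair = c(fwd = fwd_primer, rev = rev_primer),
    template_description = sprintf(
      "circularized %s fragment [%d,%d) of %d bp template",
      if (is.null(enzyme$name)) enzyme$motif else enzyme$name,
      frs$start[cand], frs$end[cand], nchar(haplotype)),
    fragment = c(start = frs$start[cand], end = frs$end[cand]),
    crossed_joint = crossed), class = "Amplicon")
}

#' k-mer dot-plot matrix of two sequences
#'
#' Every exact shared k-mer in both orientations, as (pos_a, pos_b,
#' strand) triples — the classical whole-sequence comparison picture
#' (identity = main diagonal, reverse complement = anti-diagonal, an
#' insertion = a gap splitting the diagonal).
#'
#' @param seq_a,seq_b sequences.
#' @param k k-mer size (>= 11).
#' @return data.frame of class `dotplot`: pos_a, pos_b, strand, with
#'   sequence lengths in attributes.
#' @export
dotplot_matrix <- function(seq_a, seq_b, k = 15) {
  if (k < 11)
    insertra_abort("k must be >= 11 for dot plots", "insertra_parameter_error")
  m <- cpp_kmer_matches(seq_a, seq_b, as.integer(k))
  structure(m, len_a = nchar(seq_a), len_b = nchar(seq_b), k = k,
            class = c("dotplot", "data.frame"))
}

#' Write a dot plot as TSV
#' @param dp `dotplot` data.frame.
#' @param path output file.
#' @export
write_dotplot_tsv <- function(dp, path) {
  write.table(dp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
plot.dotplot <- function(x, ...) {
  plus <- x$strand == "+"
  graphics::plot(NA, xlim = c(0, attr(x, "len_a")),
                 ylim = c(0, attr(x, "len_b")),
                 xlab = "sequence A (bp)", ylab = "sequence B (bp)", ...)
  graphics::points(x$pos_a[plus], x$pos_b[plus], pch = ".", col = "black")
  graphics::points(x$pos_a[!plus], x$pos_b[!plus], pch = ".", col = "red")
  invisible(x)
}
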