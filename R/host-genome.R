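#' Build a synthetic host genome from a chromosome layout
#'
#' A genome spec is a list with elements:
#' \describe{
#'   \item{chromosomes}{named list; each entry is a list with `bg_length`
#'     (total random background bp) and `elements`, a list of placements
#'     `list(name=, seq=, at=, family=, copy=)` where `at` is the 0-based
#'     start of the element in the final chromosome coordinate system.
#'     Elements must not overlap; background fills the gaps.}
#'   \item{seed}{integer seed for the background sequence.}
#'   \item{exclude_motifs}{optional motifs scrubbed from background.}
#' }
#' Every element is recorded as a truth annotation `(chrom, start, end, name,
#' family, copy)` in 0-based half-open coordinates (BED dialect).
#'
#' @param spec genome spec list (see Details).
#' @return an object of class `HostGenome`: list with `chromosomes` (named
#'   character vector) and `annotations` (data.frame).
#' @export
build_host_genome <- function(spec) {
  if (is.null(spec$chromosomes) || length(spec$chromosomes) < 1)
    insertra_abort("spec must name at least one chromosome", "insertra_parameter_error")
  if (anyDuplicated(names(spec$chromosomes)))
    insertra_abort("chromosome names must be unique", "insertra_parameter_error")
  seed <- if (is.null(spec$seed)) 1L else spec$seed
  set.seed(derive_seed(seed, "host_genome"))

  chroms <- character(0)
  ann <- list()
  for (cn in names(spec$chromosomes)) {
    cs <- spec$chromosomes[[cn]]
    els <- cs$elements
    if (is.null(els)) els <- list()
    if (length(els) > 0) {
      ord <- order(vapply(els, function(e) e$at, numeric(1)))
      els <- els[ord]
    }
    pieces <- character(0)
    cursor <- 0          # final-coordinate position reached so far
    bg_used <- 0
    for (e in els) {
      len <- nchar(e$seq)
      if (e$at < cursor)
        insertra_abort(sprintf(
          "element '%s' at %d overlaps previous element ending at %d on %s",
          e$name, e$at, cursor, cn), "insertra_layout_error")
      gap <- e$at - cursor
      if (gap > 0) {
        pieces <- c(pieces, random_dna(gap, spec$exclude_motifs))
        bg_used <- bg_used + gap
      }
      pieces <- c(pieces, e$seq)
      ann[[length(ann) + 1]] <- data.frame(
        chrom = cn, start = as.integer(e$at), end = as.integer(e$at + len),
        name = e$name,
        family = if (is.null(e$family)) NA_character_ else e$family,
        copy = if (is.null(e$copy)) NA_integer_ else e$copy,
        stringsAsFactors = FALSE)
      cursor <- e$at + len
    }
    if (bg_used > cs$bg_length)
      insertra_abort(sprintf("background of %s exhausted (%d > %d)",
                             cn, bg_used, cs$bg_length), "insertra_layout_error")
    tail_bg <- cs$bg_length - bg_used
    if (tail_bg > 0)
      pieces <- c(pieces, random_dna(tail_bg, spec$exclude_motifs))
    chroms[cn] <- paste(pieces, collapse = "")
  }
  annotations <- if (length(ann) > 0) do.call(rbind, ann) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               name = character(0), family = character(0), copy = integer(0),
               stringsAsFactors = FALSE)
  genome <- structure(
    list(chromosomes = chroms, annotations = annotations, seed = seed),
    class = "HostGenome")
  validate_host_genome(genome)
  genome
}

validate_host_genome <- function(genome) {
  seqs <- genome$chromosomes
  if (any(nchar(seqs) == 0))
    insertra_abort("empty chromosome sequence", "insertra_layout_error")
  if (any(grepl("[^ACGT]", seqs)))
    insertra_abort("chromosomes must use uppercase A/C/G/T only",
                   "insertra_layout_error")
  a <- genome$annotations
  if (nrow(a) > 0) {
    lens <- nchar(seqs)[a$chrom]
    if (any(a$start < 0 | a$end > lens | a$start >= a$end))
      insertra_abort("annotation interval outside its chromosome",
                     "insertra_layout_error")
  }
  invisible(genome)
}

#' @export
print.HostGenome <- function(x, ...) {
  cat("HostGenome:", length(x$chromosomes), "chromosome(s),",
      sum(nchar(x$chromosomes)), "bp total\n")
  for (cn in names(x$chromosomes))
    cat(sprintf("  %s  %d bp, %d annotated element(s)\n", cn,
                nchar(x$chromosomes[[cn]]), sum(x$annotations$chrom == cn)))
  invisible(x)
}

#' Extract the sequence of an annotated interval (0-based half-open)
#' @param genome a `HostGenome` or named character vector of sequences.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @return the interval sequence.
#' @export
genome_substring <- function(genome, chrom, start, end) {
  seqs <- if (inherits(genome, "HostGenome")) genome$chromosomes else genome
  L <- nchar(seqs[[chrom]])
  if (start < 0 || end > L || start >= end)
    insertra_abort("interval outside chromosome", "insertra_bounds_error")
  substr(seqs[[chrom]], start + 1, end)
}

#' Write genome FASTA (60-column wrapped)
#' @param genome `HostGenome` or named character vector.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- if (inherits(genome, "HostGenome")) genome$chromosomes else genome
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = 60)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write truth annotations as BED (0-based half-open)
#' @param genome `HostGenome` (or an annotations data.frame).
#' @param path output BED file.
#' @export
write_truth_bed <- function(genome, path) {
  a <- if (inherits(genome, "HostGenome")) genome$annotations else genome
  gr <- GenomicRanges::GRanges(
    seqnames = a$chrom,
    ranges = IRanges::IRanges(start = a$start + 1, end = a$end),
    name = a$name)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a BED file back into a 0-based annotations data.frame
#' @param path BED file.
#' @export
read_truth_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else NA_character_,
    stringsAsFactors = FALSE)
}
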