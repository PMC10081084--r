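#' Insert a transgene at a TTAA motif with target-site duplication
#'
#' Models piggyBac integration: the construct lands at a TTAA motif and the
#' motif is duplicated so that the modified haplotype reads
#' `left + TTAA + construct + TTAA + right` (the wild-type chromosome is
#' `left + TTAA + right`). A heterozygous insertion modifies haplotype A
#' only; a homozygous one modifies both.
#'
#' @param genome `HostGenome`.
#' @param construct `TransgeneConstruct`.
#' @param chrom chromosome name.
#' @param site 0-based start of the TTAA motif on the chromosome.
#' @param zygosity `"het"` or `"hom"`.
#' @return list with `diploid` (class `DiploidGenome`: `hapA`, `hapB` named
#'   sequence vectors plus the construct) and `event` (class
#'   `InsertionEvent`).
#' @export
insert_transgene <- function(genome, construct, chrom, site,
                             zygosity = c("het", "hom")) {
  zygosity <- match.arg(zygosity)
  seqs <- genome$chromosomes
  if (!chrom %in% names(seqs))
    insertra_abort(sprintf("unknown chromosome '%s'", chrom),
                   "insertra_parameter_error")
  L <- nchar(seqs[[chrom]])
  if (site < 0 || site + 4 > L)
    insertra_abort("site within 4 bp of chromosome end", "insertra_bounds_error")
  motif <- substr(seqs[[chrom]], site + 1, site + 4)
  if (motif != "TTAA")
    insertra_abort(sprintf("no TTAA at %s:%d (found %s)", chrom, site, motif),
                   "insertra_motif_error")

  modified <- paste0(
    substr(seqs[[chrom]], 1, site + 4),          # left + TTAA
    construct$full_sequence,
    "TTAA",                                      # duplicated motif
    substr(seqs[[chrom]], site + 5, L))          # right

  hapA <- seqs
  hapA[[chrom]] <- modified
  hapB <- seqs
  if (zygosity == "hom") hapB[[chrom]] <- modified

  # does the site fall inside an annotated repeat copy?
  a <- genome$annotations
  inside <- a$chrom == chrom & a$start <= site & site + 4 <= a$end
  fam <- if (any(inside)) a$family[which(inside)[1]] else NA_character_
  cp <- if (any(inside)) a$copy[which(inside)[1]] else NA_integer_

  event <- structure(list(
    chrom = chrom, site = site, zygosity = zygosity, tsd = "TTAA",
    construct_length = nchar(construct$full_sequence),
    family = fam, copy = cp), class = "InsertionEvent")

  diploid <- structure(list(
    hapA = hapA, hapB = hapB, construct = construct,
    construct_name = "transgene", event = event,
    genome = genome), class = "DiploidGenome")
  list(diploid = diploid, event = event)
}

#' Excise the transgene plus one TSD copy, restoring the original chromosome
#'
#' The insertion round-trip invariant: removing the construct and exactly
#' one copy of the duplicated TTAA from the modified haplotype reconstructs
#' the pre-insertion chromosome byte-identically.
#'
#' @param diploid `DiploidGenome` from [insert_transgene()].
#' @return named character vector of restored chromosomes (haplotype A).
#' @export
excise_transgene <- function(diploid) {
  ev <- diploid$event
  seqs <- diploid$hapA
  s <- seqs[[ev$chrom]]
  cut_from <- ev$site + 4                       # end of the left TTAA
  cut_len <- ev$construct_length + 4            # construct + duplicated TTAA
  seqs[[ev$chrom]] <- paste0(substr(s, 1, cut_from),
                             substr(s, cut_from + cut_len + 1, nchar(s)))
  seqs
}

#' @export
print.InsertionEvent <- function(x, ...) {
  cat(sprintf("InsertionEvent: %s:%d (%s, TSD %s, construct %d bp)\n",
              x$chrom, x$site, x$zygosity, x$tsd, x$construct_length))
  if (!is.na(x$family))
    cat(sprintf("  inside repeat family '%s' copy %d\n", x$family, x$copy))
  invisible(x)
}

#' @export
print.DiploidGenome <- function(x, ...) {
  cat("DiploidGenome:", length(x$hapA), "chromosome(s); hapA",
      sum(nchar(x$hapA)), "bp, hapB", sum(nchar(x$hapB)), "bp\n")
  print(x$event)
  invisible(x)
}

#' Reference sequences for read mapping: host chromosomes plus the construct
#' as an extra contig (the alignment target used for junction and
#' copy-number analysis).
#' @param diploid `DiploidGenome`.
#' @return named character vector.
#' @export
reference_with_construct <- function(diploid) {
  c(diploid$genome$chromosomes,
    stats::setNames(diploid$construct$full_sequence, diploid$construct_name))
}

#' Write the planted-truth insertion event as JSON
#' @param event `InsertionEvent`.
#' @param path output file.
#' @export
write_truth_json <- function(event, path) {
  jsonlite::write_json(
    list(chrom = event$chrom, site = event$site, zygosity = event$zygosity,
         tsd = event$tsd, construct_length = event$construct_length),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
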