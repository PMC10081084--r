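# Coverage-class copy-number analysis: depth at features with expected
# dosage classes n / 2n / 3n, normalized by the median depth of single-copy
# (2n) reference loci, plus flagging of multi-mapping-inflated repeat
# flanks around the insertion.

# IRanges coverage over one reference from alignment records
alignment_ranges <- function(alignments, ref, min_mapq = 0) {
  sel <- alignments$ref == ref & alignments$mapq >= min_mapq
  a <- alignments[sel, , drop = FALSE]
  if (!nrow(a)) return(IRanges::IRanges())
  w <- if (!is.null(a$end)) a$end - a$start else
    vapply(a$cigar, cigar_ref_len, numeric(1))
  IRanges::IRanges(start = a$start + 1L, width = as.integer(w))
}

#' Mean read depth over a feature interval
#'
#' Depth is the per-position count of alignments whose reference span
#' (M/D CIGAR ops) covers the position. `min_mapq = 1` (the default)
#' counts only uniquely placed reads; `min_mapq = 0` counts every
#' best-scoring placement, which is the right statistic for features whose
#' sequence legitimately occurs at more than one reference location (each
#' copy then sees the reads of all copies — dosage, not noise).
#' `trim` shrinks the measured interval by that many bp on each side; with
#' `trim = read_length - 1` every counted read lies fully inside the
#' feature, removing the boundary bias that junction-context reads
#' introduce at multi-copy features.
#'
#' @param alignments `alignments` data.frame.
#' @param feature list/vector with `ref`, `start`, `end` (0-based
#'   half-open).
#' @param min_mapq minimum mapping quality counted.
#' @param trim bp trimmed from each interval end (applied only when the
#'   trimmed interval keeps >= 20 bp).
#' @return mean depth (reads per base) over the (trimmed) interval.
#' @export
feature_depth <- function(alignments, feature, min_mapq = 1, trim = 0) {
  ref <- feature$ref
  start <- as.numeric(feature$start)
  end <- as.numeric(feature$end)
  rl <- attr(alignments, "ref_lengths")
  if (!ref %in% names(rl))
    insertra_abort(sprintf("unknown reference '%s'", ref),
                   "insertra_bounds_error")
  if (start < 0 || end > rl[[ref]] || start >= end)
    insertra_abort("feature interval outside reference", "insertra_bounds_error")
  if (trim > 0 && (end - trim) - (start + trim) >= 20) {
    start <- start + trim
    end <- end - trim
  }
  cov <- IRanges::coverage(alignment_ranges(alignments, ref, min_mapq),
                           width = rl[[ref]])
  mean(as.numeric(cov[(start + 1):end]))
}

#' Select single-copy (2n) reference loci
#'
#' Draws `n_loci` non-overlapping windows of `locus_length` bp from the
#' unannotated (background) parts of the genome, keeping only windows whose
#' sequence occurs exactly once genome-wide (checked by exhaustive
#' substring counting over both strands). These play the role of the
#' arbitrarily chosen 20-bp autosomal regions used as 2n coverage
#' references.
#'
#' @param genome `HostGenome`.
#' @param n_loci number of loci (default 15).
#' @param locus_length window length (default 20 bp).
#' @param seed integer seed (deterministic selection).
#' @param max_tries sampling attempts before giving up.
#' @return data.frame(name, ref, start, end, class="2n", seq).
#' @export
select_reference_loci <- function(genome, n_loci = 15, locus_length = 20,
                                  seed = 1, max_tries = 2000) {
  set.seed(derive_seed(seed, "reference_loci"))
  seqs <- genome$chromosomes
  ann <- genome$annotations
  chosen <- list()
  tries <- 0
  while (length(chosen) < n_loci && tries < max_tries) {
    tries <- tries + 1
    cn <- sample(names(seqs), 1, prob = nchar(seqs))
    L <- nchar(seqs[[cn]])
    if (L < locus_length) next
    st <- floor(runif(1) * (L - locus_length + 1))
    en <- st + locus_length
    # outside annotated elements
    if (nrow(ann) > 0 &&
        any(ann$chrom == cn & ann$start < en & st < ann$end)) next
    # non-overlapping with already chosen loci
    clash <- any(vapply(chosen, function(x)
      x$ref == cn && x$start < en && st < x$end, logical(1)))
    if (clash) next
    sq <- substr(seqs[[cn]], st + 1, en)
    if (count_genome_occurrences(sq, seqs) != 1) next
    chosen[[length(chosen) + 1]] <- list(ref = cn, start = st, end = en, seq = sq)
  }
  if (length(chosen) < n_loci)
    insertra_abort(sprintf("found only %d unique loci after %d tries",
                           length(chosen), tries), "insertra_layout_error")
  data.frame(
    name = sprintf("locus2n_%02d", seq_len(n_loci)),
    ref = vapply(chosen, `[[`, "", "ref"),
    start = vapply(chosen, function(x) as.integer(x$start), integer(1)),
    end = vapply(chosen, function(x) as.integer(x$end), integer(1)),
    class = "2n",
    seq = vapply(chosen, `[[`, "", "seq"),
    stringsAsFactors = FALSE)
}

#' Depth table for a set of classed features
#'
#' Computes mean depth per feature. Features longer than
#' `2 * (read_len - 1) + 20` bp are measured over their core
#' (interval trimmed by `read_len - 1`) counting all best placements;
#' short features (e.g. 20 bp single-copy loci, which cannot multi-map)
#' are measured untrimmed.
#'
#' @param alignments `alignments` data.frame.
#' @param features data.frame(name, ref, start, end, class) with class in
#'   n/2n/3n/unknown.
#' @param read_len read length used for the core trim.
#' @return `FeatureCoverage` data.frame: features + `mean_depth`.
#' @export
feature_coverage_table <- function(alignments, features, read_len = 150) {
  trim <- read_len - 1
  features$mean_depth <- vapply(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    use_trim <- (f$end - f$start) > 2 * trim + 20
    feature_depth(alignments, f, min_mapq = 0,
                  trim = if (use_trim) trim else 0)
  }, numeric(1))
  class(features) <- c("FeatureCoverage", "data.frame")
  features
}

#' Classed construct features as a depth-analysis table
#'
#' Returns the construct features carrying a dosage class (n / 3n) as
#' intervals on the construct contig of the mapping reference, ready to be
#' combined with [select_reference_loci()] output. ITR arms are excluded
#' by default: they abut the insertion junctions, where split-read mapping
#' systematically depresses depth.
#'
#' @param construct `TransgeneConstruct`.
#' @param ref_name construct contig name in the mapping reference.
#' @param include feature names to keep.
#' @return data.frame(name, ref, start, end, class).
#' @export
construct_class_features <- function(construct, ref_name = "transgene",
                                     include = c("marker", "payload",
                                                 "promoter", "terminator")) {
  cf <- construct$features
  cf <- cf[cf$name %in% include & cf$class %in% c("n", "3n"), , drop = FALSE]
  data.frame(name = cf$name, ref = ref_name, start = cf$start, end = cf$end,
             class = cf$class, stringsAsFactors = FALSE)
}

#' Estimate copy number from classed feature depths
#'
#' The 2n reference depth is the median of the 2n-class feature depths
#' (median rather than mean: robust to a reference locus accidentally
#' overlapping unannotated repeats). Then
#' `cn_estimate = 2 * mean_depth / reference_2n_depth` for every feature,
#' and each feature with a numeric expected class gets a consistency
#' verdict `|cn_estimate - class_value| <= tolerance`.
#'
#' @param coverages `FeatureCoverage` data.frame (needs >= 5 features of
#'   class 2n).
#' @param tolerance verdict tolerance in copies (default 0.5).
#' @return the table with `cn_estimate`, `class_value`, `consistent`
#'   columns and attribute `reference_2n_depth`.
#' @export
estimate_copy_number <- function(coverages, tolerance = 0.5) {
  two_n <- coverages$mean_depth[coverages$class == "2n"]
  if (length(two_n) < 5)
    insertra_abort("need >= 5 features of class 2n", "insertra_parameter_error")
  ref2n <- median(two_n)
  if (ref2n <= 0)
    insertra_abort("2n reference depth is zero", "insertra_data_error")
  coverages$cn_estimate <- 2 * coverages$mean_depth / ref2n
  cv <- c(n = 1, `2n` = 2, `3n` = 3)
  coverages$class_value <- unname(cv[coverages$class])
  coverages$consistent <- ifelse(
    is.na(coverages$class_value), NA,
    abs(coverages$cn_estimate - coverages$class_value) <= tolerance)
  attr(coverages, "reference_2n_depth") <- ref2n
  coverages
}

#' Per-base depth profile over a window (all alignments, mapq included)
#'
#' Counts EVERY best-scoring alignment including mapq-0 multi-mappers:
#' this is the statistic in which repeat-derived multi-mapping inflates
#' the apparent coverage of repetitive transgene-flanking sequence.
#'
#' @param alignments `alignments` data.frame.
#' @param ref reference name.
#' @param start,end 0-based half-open window.
#' @return object of class `DepthProfile`: list(ref, start, depth vector).
#' @export
depth_profile <- function(alignments, ref, start, end) {
  rl <- attr(alignments, "ref_lengths")
  if (!ref %in% names(rl) || start < 0 || end > rl[[ref]] || start >= end)
    insertra_abort("window outside reference", "insertra_bounds_error")
  cov <- IRanges::coverage(alignment_ranges(alignments, ref, 0),
                           width = rl[[ref]])
  structure(list(ref = ref, start = start,
                 depth = as.numeric(cov[(start + 1):end])),
            class = "DepthProfile")
}

#' Flag repeat-inflated intervals in a depth profile
#'
#' Maximal runs of positions whose all-alignment depth exceeds
#' `fold_threshold` times the 2n baseline, merged when separated by less
#' than `merge_gap` bp.
#'
#' @param profile `DepthProfile`.
#' @param baseline the 2n reference depth (> 0).
#' @param fold_threshold fold-change threshold (default 2).
#' @param merge_gap merge runs separated by fewer than this many bp.
#' @return data.frame(ref, start, end) of flagged intervals (0-based
#'   half-open genome coordinates); zero rows when nothing is flagged.
#' @export
flag_repetitive_flanks <- function(profile, baseline, fold_threshold = 2,
                                   merge_gap = 10) {
  if (baseline <= 0)
    insertra_abort("baseline must be positive", "insertra_parameter_error")
  hot <- profile$depth > fold_threshold * baseline
  if (!any(hot))
    return(data.frame(ref = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  r <- IRanges::reduce(IRanges::IRanges(which(hot)), min.gapwidth = merge_gap)
  data.frame(ref = profile$ref,
             start = profile$start + IRanges::start(r) - 1L,
             end = profile$start + IRanges::end(r),
             stringsAsFactors = FALSE)
}
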