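# Junction evidence: informative-read extraction, junction-anchored flank
# consensus and target-site-duplication calls.

# oriented read sequence for an alignment record (cigar coordinates)
oriented_read <- function(seq, strand) {
  if (strand == 1) revcomp(seq) else seq
}

#' Extract informative reads at construct-genome junctions
#'
#' Split criterion: a primary alignment on one reference class
#' (construct vs genome) carrying a soft clip of at least `min_clip` bp
#' whose clipped sequence maps to the other class. Discordant criterion:
#' the two mates of a pair align to different classes. Each record is
#' labeled `5prime` or `3prime` by the construct coordinate of its
#' construct-side anchor (before vs after the construct midpoint).
#'
#' @param alignments `alignments` data.frame (from [map_reads()] or
#'   [read_sam()]).
#' @param reads `ReadSet` (or data.frame id/seq [,mate_id]) with the read
#'   sequences; may be omitted when `alignments` carries a `seq` column.
#' @param construct_names reference names belonging to the construct class.
#' @param index combined `KmerIndex` (genome + construct) used to place
#'   clipped tails.
#' @param min_clip minimum clip length (default 20 bp: shorter clips cannot
#'   be placed reliably).
#' @return object of class `InformativeReadSet`: list with `split`
#'   (read_id, anchor_ref, anchor_class, clip_side, side, construct_pos,
#'   tail sequence + junction offset columns) and `discordant`
#'   (read_id, mate_id, refs, side).
#' @export
extract_informative_reads <- function(alignments, reads = NULL,
                                      construct_names, index,
                                      min_clip = 20) {
  if (!nrow(alignments)) {
    return(empty_informative(min_clip))
  }
  if (is.null(reads)) {
    if (is.null(alignments$seq))
      insertra_abort("need read sequences (reads= or a seq column)",
                     "insertra_format_error")
    reads <- data.frame(id = alignments$read_id[!duplicated(alignments$read_id)],
                        stringsAsFactors = FALSE)
    reads$seq <- alignments$seq[match(reads$id, alignments$read_id)]
  }
  seqs <- stats::setNames(reads$seq, reads$id)
  mates <- if (!is.null(reads$mate_id)) stats::setNames(reads$mate_id, reads$id)
           else NULL
  is_construct <- function(ref) ref %in% construct_names
  clen <- sum(attr(alignments, "ref_lengths")[construct_names])

  # primary = first record per read (records are tied; unique reads have one)
  prim <- alignments[!duplicated(alignments$read_id), , drop = FALSE]

  split_rows <- list()
  for (i in seq_len(nrow(prim))) {
    rec <- prim[i, ]
    ops <- cigar_ops(rec$cigar)
    lead <- if (ops$op[1] == "S") ops$len[1] else 0L
    trail <- if (ops$op[nrow(ops)] == "S") ops$len[nrow(ops)] else 0L
    if (max(lead, trail) < min_clip) next
    orc <- oriented_read(seqs[[rec$read_id]], rec$strand)
    for (side_clip in c("left", "right")) {
      cl <- if (side_clip == "left") lead else trail
      if (cl < min_clip) next
      tail_seq <- if (side_clip == "left") substr(orc, 1, cl) else
        substr(orc, nchar(orc) - cl + 1, nchar(orc))
      if (nchar(tail_seq) < index$k) next
      hit <- map_reads(index, tail_seq, ids = "clip", min_seeds = 1)
      if (!nrow(hit)) next
      hit <- hit[1, ]
      if (is_construct(rec$ref) == is_construct(hit$ref)) next
      cpos <- if (is_construct(rec$ref)) {
        if (side_clip == "left") rec$start else rec$end
      } else hit$start
      side <- if (cpos < clen / 2) "5prime" else "3prime"
      # junction-anchored genomic tail for consensus building:
      # construct-anchored records contribute their clipped (genomic) tail;
      # genome-anchored records contribute their aligned genomic portion.
      if (is_construct(rec$ref)) {
        gen_tail <- tail_seq
        anchored_at <- if (side_clip == "left") "right" else "left"
      } else {
        # aligned (genomic) portion, bounded by the soft clips
        gen_tail <- substr(orc, lead + 1, nchar(orc) - trail)
        anchored_at <- if (side_clip == "right") "right" else "left"
      }
      split_rows[[length(split_rows) + 1]] <- data.frame(
        read_id = rec$read_id, anchor_ref = rec$ref,
        anchor_class = if (is_construct(rec$ref)) "construct" else "genome",
        clip_side = side_clip, clip_len = cl,
        clip_target = hit$ref, clip_target_pos = hit$start,
        construct_pos = cpos, side = side,
        tail_seq = gen_tail, tail_anchor = anchored_at,
        stringsAsFactors = FALSE)
    }
  }
  split <- if (length(split_rows)) do.call(rbind, split_rows) else NULL

  disc_rows <- NULL
  if (!is.null(mates)) {
    pr <- prim[prim$read_id %in% names(mates), , drop = FALSE]
    cls <- stats::setNames(is_construct(pr$ref), pr$read_id)
    both <- pr$read_id[mates[pr$read_id] %in% pr$read_id]
    seen <- character(0)
    rows <- list()
    for (id in both) {
      mid <- mates[[id]]
      if (mid %in% seen) next
      seen <- c(seen, id)
      if (cls[[id]] == cls[[mid]]) next
      cid <- if (cls[[id]]) id else mid
      cpos <- pr$start[pr$read_id == cid][1]
      rows[[length(rows) + 1]] <- data.frame(
        read_id = id, mate_id = mid,
        ref = pr$ref[pr$read_id == id][1],
        mate_ref = pr$ref[pr$read_id == mid][1],
        side = if (cpos < clen / 2) "5prime" else "3prime",
        stringsAsFactors = FALSE)
    }
    disc_rows <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  out <- empty_informative(min_clip)
  if (!is.null(split)) out$split <- split
  if (!is.null(disc_rows)) out$discordant <- disc_rows
  out
}

empty_informative <- function(min_clip) {
  structure(list(
    split = data.frame(read_id = character(0), anchor_ref = character(0),
                       anchor_class = character(0), clip_side = character(0),
                       clip_len = integer(0), clip_target = character(0),
                       clip_target_pos = integer(0), construct_pos = integer(0),
                       side = character(0), tail_seq = character(0),
                       tail_anchor = character(0), stringsAsFactors = FALSE),
    discordant = data.frame(read_id = character(0), mate_id = character(0),
                            ref = character(0), mate_ref = character(0),
                            side = character(0), stringsAsFactors = FALSE),
    min_clip = min_clip), class = "InformativeReadSet")
}

#' @export
print.InformativeReadSet <- function(x, ...) {
  cat(sprintf("InformativeReadSet: %d split read(s) (%d 5', %d 3'), %d discordant pair(s)\n",
              nrow(x$split), sum(x$split$side == "5prime"),
              sum(x$split$side == "3prime"), nrow(x$discordant)))
  invisible(x)
}

#' Junction-anchored flank consensus
#'
#' Builds the genomic flank adjacent to one construct junction by majority
#' vote over the junction-anchored genomic tails of split reads. Tails are
#' aligned at the junction (the construct boundary), so for the 5' side
#' every tail is right-anchored (its last base abuts the construct) and the
#' consensus grows leftward/outward; columns supported by fewer than
#' `min_support` reads are trimmed. Ties (e.g. 2 vs 2 bases) are broken
#' alphabetically and flagged in the `tie_columns` attribute.
#'
#' @param informative `InformativeReadSet`.
#' @param side `"5prime"` or `"3prime"`.
#' @param min_reads minimum supporting reads (default 3).
#' @param min_support minimum per-column support kept in the consensus.
#' @return consensus sequence (genome forward orientation; for the 5' side
#'   it ends with the TSD motif, for the 3' side it begins with it), with
#'   attributes `n_reads` and `tie_columns`.
#' @export
build_flank_consensus <- function(informative, side = c("5prime", "3prime"),
                                  min_reads = 3, min_support = 2) {
  side <- match.arg(side)
  # construct-anchored tails only: their clip boundary sits exactly at the
  # construct terminus, so the junction anchoring is structurally exact;
  # genome-anchored alignments can over-run the junction by chance matches.
  sp <- informative$split[informative$split$side == side &
                          informative$split$anchor_class == "construct", ,
                          drop = FALSE]
  if (nrow(sp) < min_reads)
    insertra_abort(sprintf(
      "only %d supporting read(s) on the %s side (need >= %d)",
      nrow(sp), side, min_reads), "insertra_evidence_error")
  anchor_right <- side == "5prime"
  tails <- sp$tail_seq
  # guard: tails must be anchored on the junction side
  keep <- sp$tail_anchor == (if (anchor_right) "right" else "left")
  tails <- tails[keep]
  if (length(tails) < min_reads)
    insertra_abort(sprintf(
      "only %d junction-anchored read(s) on the %s side (need >= %d)",
      length(tails), side, min_reads), "insertra_evidence_error")
  W <- max(nchar(tails))
  mat <- matrix(NA_character_, nrow = length(tails), ncol = W)
  for (i in seq_along(tails)) {
    ch <- strsplit(tails[i], "")[[1]]
    if (anchor_right) mat[i, (W - length(ch) + 1):W] <- ch
    else mat[i, 1:length(ch)] <- ch
  }
  cons <- character(W)
  support <- integer(W)
  ties <- integer(0)
  for (j in seq_len(W)) {
    col <- mat[, j]
    col <- col[!is.na(col)]
    support[j] <- length(col)
    if (length(col) == 0) { cons[j] <- NA; next }
    tb <- sort(table(col), decreasing = TRUE)
    if (length(tb) > 1 && tb[1] == tb[2]) {
      cons[j] <- sort(names(tb)[tb == tb[1]])[1]
      ties <- c(ties, j)
    } else cons[j] <- names(tb)[1]
  }
  ok <- support >= min_support
  # keep the maximal junction-anchored run of supported columns
  if (anchor_right) {
    bad <- which(!ok)
    from <- if (length(bad)) max(bad) + 1 else 1
    keep_idx <- seq(from, W)
  } else {
    bad <- which(!ok)
    to <- if (length(bad)) min(bad) - 1 else W
    keep_idx <- seq_len(max(to, 0))
  }
  if (length(keep_idx) == 0)
    insertra_abort("no consensus columns reach the support threshold",
                   "insertra_evidence_error")
  out <- paste(cons[keep_idx], collapse = "")
  attr(out, "n_reads") <- length(tails)
  attr(out, "tie_columns") <- ties[ties %in% keep_idx]
  attr(out, "side") <- side
  out
}

#' Call the target-site duplication from the two flank consensi
#'
#' For a genuine piggyBac-style insertion the TTAA motif is duplicated:
#' the 5' genomic flank must end with it and the 3' flank must begin with
#' it.
#'
#' @param flank5,flank3 flank consensus sequences (>= 4 bp each).
#' @param motif the duplicated motif, default `"TTAA"`.
#' @return object of class `TSDCall`: list(motif, present_5prime,
#'   present_3prime, flank5, flank3).
#' @export
detect_tsd <- function(flank5, flank3, motif = "TTAA") {
  if (is.null(motif) || is.na(motif) || !nzchar(motif))
    insertra_abort("empty motif", "insertra_parameter_error")
  if (nchar(flank5) < nchar(motif) || nchar(flank3) < nchar(motif))
    insertra_abort("flanks shorter than the motif", "insertra_parameter_error")
  structure(list(
    motif = motif,
    present_5prime = endsWith(as.character(flank5), motif),
    present_3prime = startsWith(as.character(flank3), motif),
    flank5 = as.character(flank5), flank3 = as.character(flank3)),
    class = "TSDCall")
}

#' @export
print.TSDCall <- function(x, ...) {
  cat(sprintf("TSDCall: motif %s, 5' %s, 3' %s\n", x$motif,
              ifelse(x$present_5prime, "present", "absent"),
              ifelse(x$present_3prime, "present", "absent")))
  invisible(x)
}
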