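#' Assemble a transgene construct from ordered features
#'
#' Features are given in order as a list of
#' `list(name=, class=, seq= | length= | from_host=, role=)` where `class` is
#' the expected copy class of the feature in a heterozygous transgenic
#' diploid: `"n"` (transgene-unique, e.g. the fluorescent marker or the
#' endonuclease payload), `"3n"` (present once in the construct plus two
#' endogenous alleles, e.g. a borrowed promoter/terminator) or `"spacer"`
#' (plumbing, treated as `n`). `from_host` copies the sequence verbatim from
#' a named annotation of the host genome — this is what makes a feature 3n.
#' The first feature must be the 5' inverted terminal repeat (`role =
#' "itr5"`) and the last the 3' ITR (`role = "itr3"`).
#'
#' @param features ordered feature list (see Details).
#' @param host optional `HostGenome`, required when any feature uses
#'   `from_host`.
#' @param seed integer seed for randomly generated feature sequences.
#' @param exclude_motifs motifs scrubbed from generated feature sequences.
#' @return object of class `TransgeneConstruct`: list with `full_sequence`,
#'   `features` (data.frame name/class/role/start/end, 0-based half-open in
#'   construct coordinates), `itr5`, `itr3`.
#' @export
build_construct <- function(features, host = NULL, seed = 1,
                            exclude_motifs = NULL) {
  if (length(features) < 2)
    insertra_abort("need at least the two ITR features", "insertra_config_error")
  set.seed(derive_seed(seed, "construct"))
  rows <- list()
  seqs <- character(0)
  pos <- 0
  for (f in features) {
    if (is.null(f$name)) insertra_abort("feature without name", "insertra_config_error")
    cls <- if (is.null(f$class)) "spacer" else f$class
    if (!cls %in% c("n", "3n", "spacer"))
      insertra_abort(sprintf("bad copy class '%s' for %s", cls, f$name),
                     "insertra_config_error")
    if (!is.null(f$from_host)) {
      if (is.null(host))
        insertra_abort("from_host feature needs a host genome", "insertra_config_error")
      a <- host$annotations[host$annotations$name == f$from_host, , drop = FALSE]
      if (nrow(a) != 1)
        insertra_abort(sprintf("host annotation '%s' not found once", f$from_host),
                       "insertra_config_error")
      sq <- genome_substring(host, a$chrom, a$start, a$end)
    } else if (!is.null(f$seq)) {
      sq <- f$seq
    } else if (!is.null(f$length)) {
      if (f$length == 0) sq <- "" else
        sq <- random_dna(f$length, exclude_motifs = c(exclude_motifs, f$exclude))
    } else insertra_abort(sprintf("feature %s has no sequence source", f$name),
                          "insertra_config_error")
    L <- nchar(sq)
    rows[[length(rows) + 1]] <- data.frame(
      name = f$name, class = cls,
      role = if (is.null(f$role)) NA_character_ else f$role,
      start = pos, end = pos + L, stringsAsFactors = FALSE)
    seqs <- c(seqs, sq)
    pos <- pos + L
  }
  ft <- do.call(rbind, rows)
  if (is.na(ft$role[1]) || ft$role[1] != "itr5" ||
      is.na(ft$role[nrow(ft)]) || ft$role[nrow(ft)] != "itr3")
    insertra_abort("construct must start with itr5 and end with itr3",
                   "insertra_config_error")
  if (!any(ft$class == "n"))
    insertra_abort("construct needs an n-class (transgene-unique) feature",
                   "insertra_config_error")
  structure(list(
    full_sequence = paste(seqs, collapse = ""),
    features = ft,
    itr5 = seqs[1],
    itr3 = seqs[length(seqs)]),
    class = "TransgeneConstruct")
}

#' @export
print.TransgeneConstruct <- function(x, ...) {
  cat("TransgeneConstruct:", nchar(x$full_sequence), "bp,",
      nrow(x$features), "features\n")
  print(x$features, row.names = FALSE)
  invisible(x)
}

#' Sequence of a named construct feature
#' @param construct `TransgeneConstruct`.
#' @param name feature name.
#' @export
construct_feature <- function(construct, name) {
  f <- construct$features[construct$features$name == name, , drop = FALSE]
  if (nrow(f) != 1)
    insertra_abort(sprintf("feature '%s' not found", name), "insertra_config_error")
  substr(construct$full_sequence, f$start + 1, f$end)
}
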