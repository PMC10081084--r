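#' Simulate a family of near-identical repeat copies
#'
#' Draws one random ancestor sequence and derives `n_copies` descendants by
#' independent substitutions at per-base rate `divergence`. Under this model
#' two copies differ at a site with probability
#' \eqn{2d(1-d) + \frac{2}{3}d^2} (both mutated to different bases), so the
#' expected pairwise identity is \eqn{1 - 2d(1-d) - \frac{2}{3}d^2}; for
#' `divergence = 0.04` that is about 0.922, i.e. the >= 90\% identity regime
#' typical of pericentromeric repeat clusters.
#'
#' @param ancestor_length ancestor length in bp (>= 50).
#' @param n_copies number of copies to derive (>= 1).
#' @param divergence per-base substitution rate in `[0, 0.3]`.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param ancestor optional explicit ancestor sequence (overrides
#'   `ancestor_length`).
#' @param protect optional integer `c(start, end)` 0-based half-open interval
#'   of the ancestor shielded from substitutions — used e.g. to keep a TTAA
#'   transposon target motif intact in every copy, as observed when all
#'   ambiguous insertion-site hits still carry the motif.
#' @param exclude_motifs motifs scrubbed from the random ancestor (e.g. a
#'   restriction site that must only occur where the genome layout plants it).
#' @return character vector of `n_copies` sequences, with the ancestor in
#'   attribute `"ancestor"`.
#' @export
make_repeat_family <- function(ancestor_length, n_copies, divergence, seed,
                               ancestor = NULL, protect = NULL,
                               exclude_motifs = NULL) {
  if (is.null(ancestor) && (!is.numeric(ancestor_length) || ancestor_length < 50))
    insertra_abort("ancestor_length must be >= 50", "insertra_parameter_error")
  if (!is.numeric(n_copies) || n_copies < 1)
    insertra_abort("n_copies must be >= 1", "insertra_parameter_error")
  if (!is.numeric(divergence) || divergence < 0 || divergence > 0.3)
    insertra_abort("divergence must be in [0, 0.3]", "insertra_parameter_error")

  set.seed(derive_seed(seed, "repeat_family"))
  if (is.null(ancestor))
    ancestor <- random_dna(ancestor_length, exclude_motifs = exclude_motifs)
  L <- nchar(ancestor)
  anc <- strsplit(ancestor, "")[[1]]
  protected <- rep(FALSE, L)
  if (!is.null(protect)) {
    if (length(protect) != 2 || protect[1] < 0 || protect[2] > L)
      insertra_abort("protect must be a 0-based [start, end) inside the ancestor",
                     "insertra_parameter_error")
    if (protect[2] > protect[1]) protected[(protect[1] + 1):protect[2]] <- TRUE
  }
  copies <- character(n_copies)
  for (i in seq_len(n_copies)) {
    ch <- anc
    mut <- which(runif(L) < divergence & !protected)
    if (length(mut) > 0) {
      for (p in mut) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
    }
    copies[i] <- paste(ch, collapse = "")
  }
  attr(copies, "ancestor") <- ancestor
  copies
}
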