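# End-to-end orchestration: simulate -> flank recovery -> candidate
# ranking -> long-read assembly -> resolution -> copy number -> assays,
# with a deterministic JSON report and artifact files.

default_pipeline_config <- function() {
  list(
    schema_version = 1L,
    scenario = "ambiguity",
    seed = 1L,
    insertion = list(enabled = TRUE, zygosity = "het"),
    long_reads = list(enabled = TRUE, n_reads = 300L, anchor_n = 12L,
                      error_rate = 0.08),
    copy_number = list(enabled = FALSE, depth = 30),
    southern = list(enabled = TRUE, enzyme = "DraI"),
    thresholds = list(t_identity = 0.90, t_length = 700L,
                      unique_flank_min = 500L, link_window = 25000L))
}

#' Validate and complete a pipeline configuration
#'
#' Unknown keys (at the top level or inside known sections) are errors —
#' a misspelled option must fail fast, not be silently ignored.
#'
#' @param config list or path to a YAML file.
#' @return completed config list.
#' @export
load_pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- default_pipeline_config()
  bad <- setdiff(names(config), names(def))
  if (length(bad))
    insertra_abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")),
                   "insertra_config_error")
  for (sec in names(config)) {
    if (is.list(def[[sec]]) && is.list(config[[sec]])) {
      badk <- setdiff(names(config[[sec]]), names(def[[sec]]))
      if (length(badk))
        insertra_abort(sprintf("unknown config key(s) in %s: %s", sec,
                               paste(badk, collapse = ", ")),
                       "insertra_config_error")
      def[[sec]][names(config[[sec]])] <- config[[sec]]
    } else def[[sec]] <- config[[sec]]
  }
  if (!def$scenario %in% c("ambiguity", "copy_number", "tsd"))
    insertra_abort(sprintf("unknown scenario '%s'", def$scenario),
                   "insertra_config_error")
  def
}

#' Run the full insertion-characterization pipeline on a simulated scenario
#'
#' Builds the configured scenario genome and (optionally) the insertion,
#' recovers junction flanks by in-silico inverse PCR, ranks candidate
#' loci, assembles anchored long reads and resolves the ambiguity,
#' optionally estimates copy number from 30x short reads and runs the
#' in-silico Southern. Rerunning with the same config gives a
#' byte-identical report.
#'
#' @param config list or YAML path (see [load_pipeline_config()]).
#' @param out_dir optional directory for artifact files (JSON report,
#'   candidate TSV, contig FASTA, truth files).
#' @return report list (invisibly written to `out_dir/report.json`).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- load_pipeline_config(config)
  seed <- cfg$seed
  builder <- switch(cfg$scenario, ambiguity = ambiguity_scenario,
                    copy_number = copy_number_scenario, tsd = tsd_scenario)
  sc <- builder(seed = seed, zygosity = cfg$insertion$zygosity)
  if (!isTRUE(cfg$insertion$enabled)) {
    # wild-type: both haplotypes are the unmodified genome
    sc$diploid$hapA <- sc$genome$chromosomes
    sc$diploid$hapB <- sc$genome$chromosomes
    sc$diploid$event <- NULL
  }
  report <- list(schema_version = cfg$schema_version,
                 scenario = cfg$scenario, seed = seed)
  gidx <- index_reference(sc$genome)

  # --- junction flank recovery (in-silico inverse PCR) ---
  flanks <- tryCatch(recover_flanks_ipcr(sc$diploid),
                     insertra_error = function(e) NULL)
  report$insertion_evidence <- !is.null(flanks)
  cand <- empty_candidates()
  if (!is.null(flanks)) {
    tsd <- detect_tsd(flanks$flank5, flanks$flank3)
    report$tsd_call <- list(motif = tsd$motif,
                            present_5prime = tsd$present_5prime,
                            present_3prime = tsd$present_3prime)
    hits <- local_search(gidx, flanks$query, min_score = 300, band = 150)
    cand <- rank_candidate_loci(hits, sc$genome,
                                t_identity = cfg$thresholds$t_identity,
                                t_length = cfg$thresholds$t_length,
                                junction_offset = flanks$junction_offset)
    report$n_candidates <- nrow(cand)
    report$ambiguous <- nrow(cand) >= 2
  } else {
    report$tsd_call <- NULL
    report$n_candidates <- 0L
    report$ambiguous <- FALSE
  }

  # --- long-read resolution ---
  resolution <- NULL
  contig <- NULL
  if (isTRUE(cfg$long_reads$enabled) && isTRUE(cfg$insertion$enabled) &&
      nrow(cand) > 0) {
    mk <- sc$construct$features[sc$construct$features$name == "marker", ]
    ai <- list(chrom = sc$event$chrom, start = sc$site + 4 + mk$start,
               end = sc$site + 4 + mk$end)
    lr <- simulate_long_reads(sc$diploid, n_reads = cfg$long_reads$n_reads,
                              error_rate = cfg$long_reads$error_rate,
                              seed = derive_seed(seed, "pipeline_long"),
                              anchor_n = cfg$long_reads$anchor_n,
                              anchor_interval = ai)
    marker <- construct_feature(sc$construct, "marker")
    asm <- tryCatch(assemble_long_reads(lr, c(marker = marker)),
                    insertra_error = function(e) NULL)
    if (!is.null(asm)) {
      contig <- asm$contig
      resolution <- integrate_long_read_evidence(
        cand, contig, gidx, sc$construct, anchors = c(marker = marker),
        unique_flank_min = cfg$thresholds$unique_flank_min,
        link_window = cfg$thresholds$link_window)
      report$ambiguous <- resolution$ambiguous
      if (!is.null(resolution$resolved_locus))
        report$resolved_locus <- list(
          chrom = resolution$resolved_locus$chrom,
          start = resolution$resolved_locus$start,
          end = resolution$resolved_locus$end,
          evidence_tier = resolution$resolved_locus$evidence_tier)
    }
  }

  # --- copy number ---
  if (isTRUE(cfg$copy_number$enabled) && isTRUE(cfg$insertion$enabled)) {
    dip <- sc$diploid
    Ldip <- sum(nchar(dip$hapA)) + sum(nchar(dip$hapB))
    n_pairs <- round(cfg$copy_number$depth * Ldip / 600)
    rs <- simulate_short_reads(dip, n_pairs,
                               seed = derive_seed(seed, "pipeline_short"))
    midx <- index_reference(reference_with_construct(dip))
    aln <- map_reads(midx, rs, band = 25, seed_step = 2)
    feats <- rbind(
      construct_class_features(sc$construct),
      select_reference_loci(sc$genome,
                            seed = derive_seed(seed, "pipeline_loci"))[,
        c("name", "ref", "start", "end", "class")])
    est <- estimate_copy_number(feature_coverage_table(aln, feats))
    report$copy_number <- list(
      reference_2n_depth = attr(est, "reference_2n_depth"),
      features = lapply(seq_len(nrow(est)), function(i) list(
        name = est$name[i], class = est$class[i],
        cn_estimate = round(est$cn_estimate[i], 3),
        consistent = est$consistent[i])))
  }

  # --- in-silico Southern ---
  if (isTRUE(cfg$southern$enabled)) {
    probe <- substr(construct_feature(sc$construct, "payload"), 1, 499)
    genome_like <- if (isTRUE(cfg$insertion$enabled)) sc$diploid$hapA else
      sc$genome$chromosomes
    sizes <- southern_blot(genome_like, enzyme_preset(cfg$southern$enzyme),
                           probe)
    report$southern <- list(enzyme = cfg$southern$enzyme,
                            n_positive_fragments = length(sizes),
                            fragment_sizes = as.integer(sizes))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    write_genome_fasta(sc$genome, file.path(out_dir, "genome.fa"))
    write_truth_bed(sc$genome, file.path(out_dir, "truth.bed"))
    if (isTRUE(cfg$insertion$enabled))
      write_truth_json(sc$event, file.path(out_dir, "truth_insertion.json"))
    if (nrow(cand) > 0)
      write.table(cand, file.path(out_dir, "candidates.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    if (!is.null(contig))
      write_contig_fasta(c(contig = contig), file.path(out_dir, "contig.fa"))
  }
  invisible(report)
}
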