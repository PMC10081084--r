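# Study-condition scenario builders.
#
# These encode, as defaults, the situation the pipeline is designed for: a
# heterozygous piggyBac-style insertion whose TTAA site lies inside one
# copy of a pericentromeric repeat family with ~12 near-identical copies
# (>= 90% identity over ~750 bp) spread over two chromosome arms, so that
# short flank evidence is ambiguous, while a ~563 bp unique island ~1.5 kb
# upstream of the junction lets a long-read contig resolve the true locus.

# repeat ancestor with a protected central TTAA (the transposon target
# motif every copy retains) and no DraI site that would truncate flanks
main_repeat_ancestor <- function(length = 750) {
  s <- random_dna(length, exclude_motifs = c("TTTAAA"))
  mid <- floor(length / 2) - 2
  # G..TTAA..C guard bases so the planted motif cannot create a DraI site
  substr(s, mid, mid + 5) <- "GTTAAC"
  list(seq = s, ttaa_at = mid, protect = c(mid - 1, mid + 5))
}

# filler repeat ancestor with a protected central DraI site: the cluster's
# internal restriction sites that inverse PCR cuts at
filler_repeat_ancestor <- function(length = 500) {
  s <- random_dna(length, exclude_motifs = c("TTTAAA"))
  mid <- floor(length / 2) - 3
  substr(s, mid + 1, mid + 6) <- "TTTAAA"
  list(seq = s, cut_at = mid, protect = c(mid - 1, mid + 7))
}

# cluster element list: filler / copy / filler / copy ... / filler
cluster_elements <- function(at, copies, fillers, family, filler_family,
                             copy_ids, filler_ids) {
  els <- list()
  pos <- at
  for (i in seq_along(copies)) {
    els[[length(els) + 1]] <- list(
      name = sprintf("%s:%d", filler_family, filler_ids[i]),
      seq = fillers[i], at = pos, family = filler_family,
      copy = filler_ids[i])
    pos <- pos + nchar(fillers[i])
    els[[length(els) + 1]] <- list(
      name = sprintf("%s:%d", family, copy_ids[i]),
      seq = copies[i], at = pos, family = family, copy = copy_ids[i])
    pos <- pos + nchar(copies[i])
  }
  i <- length(copies) + 1
  els[[length(els) + 1]] <- list(
    name = sprintf("%s:%d", filler_family, filler_ids[i]),
    seq = fillers[i], at = pos, family = filler_family, copy = filler_ids[i])
  els
}

#' Default transgene construct (~8.3 kb piggyBac-style cassette)
#'
#' ITRs at both termini, a 1.5 kb fluorescent-marker cassette (class n,
#' the long-read assembly anchor), a 4 kb effector payload (class n, used
#' as the Southern probe source and therefore free of DraI/ScaI sites),
#' and promoter/terminator sequences copied verbatim from the host
#' genome's endogenous gene (class 3n). Two spacers carry planted DraI
#' sites so inverse PCR can release junction fragments of amplifiable
#' size.
#'
#' @param host `HostGenome` with `beta2_promoter` / `beta2_terminator`
#'   annotations.
#' @param seed integer seed.
#' @return `TransgeneConstruct`.
#' @export
default_construct <- function(host, seed = 1) {
  set.seed(derive_seed(seed, "construct_parts"))
  sp_with_site <- function(n) {
    # spacer with one DraI site planted at its center
    h <- floor(n / 2)
    paste0(random_dna(h - 3, "TTTAAA"), "TTTAAA",
           random_dna(n - h - 3, "TTTAAA"))
  }
  feats <- list(
    list(name = "itr5", role = "itr5", class = "spacer", length = 300,
         exclude = "TTTAAA"),
    list(name = "spacer1", class = "spacer", seq = sp_with_site(200)),
    list(name = "marker", role = "marker", class = "n", length = 1500),
    list(name = "spacer2", class = "spacer", length = 150,
         exclude = "TTTAAA"),
    list(name = "promoter", class = "3n", from_host = "beta2_promoter"),
    list(name = "payload", class = "n", length = 4000,
         exclude = c("TTTAAA", "AGTACT")),
    list(name = "spacer3", class = "spacer", length = 150,
         exclude = "TTTAAA"),
    list(name = "terminator", class = "3n", from_host = "beta2_terminator"),
    list(name = "spacer4", class = "spacer", seq = sp_with_site(200)),
    list(name = "itr3", role = "itr3", class = "spacer", length = 250,
         exclude = "TTTAAA"))
  build_construct(feats, host = host, seed = seed)
}

# shared genome assembly machinery for the scenarios
scenario_genome <- function(seed, chrom_bg, cluster_plan, endo_chrom,
                            endo_at, ancestor_length = 750,
                            filler_length = 500, divergence = 0.035,
                            filler_divergence = divergence,
                            extra_fillers = list()) {
  main_anc <- local({
    set.seed(derive_seed(seed, "main_ancestor")); main_repeat_ancestor(ancestor_length)
  })
  fill_anc <- local({
    set.seed(derive_seed(seed, "filler_ancestor")); filler_repeat_ancestor(filler_length)
  })
  n_copies <- sum(vapply(cluster_plan, function(p) length(p$copies), integer(1)))
  n_fillers <- n_copies + length(cluster_plan) + length(extra_fillers)
  copies <- if (n_copies > 0) make_repeat_family(
    n_copies = n_copies, divergence = divergence,
    seed = derive_seed(seed, "main"),
    ancestor = main_anc$seq, protect = main_anc$protect) else character(0)
  fillers <- if (n_fillers > 0) make_repeat_family(
    n_copies = n_fillers, divergence = filler_divergence,
    seed = derive_seed(seed, "filler"),
    ancestor = fill_anc$seq, protect = fill_anc$protect) else character(0)

  set.seed(derive_seed(seed, "endogenous"))
  promoter <- random_dna(1200)
  terminator <- random_dna(800)

  chroms <- list()
  fi <- 1
  for (cn in names(chrom_bg)) {
    els <- list()
    for (p in cluster_plan) {
      if (p$chrom != cn) next
      nf <- length(p$copies) + 1
      els <- c(els, cluster_elements(
        p$at, copies[p$copies], fillers[fi:(fi + nf - 1)],
        "mainrep", "filler", p$copies, fi:(fi + nf - 1)))
      fi <- fi + nf
      if (!is.null(p$island_at))
        els[[length(els) + 1]] <- list(
          name = "island", seq = local({
            set.seed(derive_seed(seed, "island")); random_dna(p$island_len)
          }), at = p$island_at)
    }
    for (xf in extra_fillers) {
      if (xf$chrom != cn) next
      els[[length(els) + 1]] <- list(
        name = sprintf("filler:%d", fi), seq = fillers[fi],
        at = xf$at, family = "filler", copy = fi)
      fi <- fi + 1
    }
    if (cn == endo_chrom) {
      els[[length(els) + 1]] <- list(name = "beta2_promoter", seq = promoter,
                                     at = endo_at)
      els[[length(els) + 1]] <- list(name = "beta2_terminator",
                                     seq = terminator, at = endo_at + 2000)
    }
    chroms[[cn]] <- list(bg_length = chrom_bg[[cn]], elements = els)
  }
  genome <- build_host_genome(list(chromosomes = chroms,
                                   seed = derive_seed(seed, "background")))
  ttaa_off <- main_anc$ttaa_at  # 0-based offset of TTAA within each copy
  attr(genome, "ttaa_offset") <- ttaa_off
  genome
}

#' Ambiguity/resolution scenario: insertion inside a 12-copy repeat
#'
#' Builds a ~2 Mb two-chromosome haploid genome (so a ~4 Mb diploid)
#' carrying 12 copies of a 750 bp repeat family at ~92% pairwise identity,
#' each copy embedded in shorter "filler" repeats. The insertion lands at
#' the protected central TTAA of one chr2R copy whose upstream
#' neighbourhood contains a 563 bp unique island about 1.5 kb from the
#' junction — the only unique sequence within reach of a long-read contig
#' arm. The other 11 copies (5 more on chr2R, 6 on chr3R) are all at
#' least 30 kb from the island.
#'
#' @param seed integer seed.
#' @param zygosity insertion zygosity (default `"het"`).
#' @param island_length unique island length (default 563 bp).
#' @return list(genome, construct, diploid, event, site, island).
#' @export
ambiguity_scenario <- function(seed = 1, zygosity = "het",
                               island_length = 563) {
  island_at <- 600000
  # upstream geometry at the true site: [island 563][filler 500][filler 500]
  # [true copy 750, TTAA at its center][filler 500] — so the junction sits
  # ~1.4 kb from the nearest unique sequence, and only repeats in between.
  plan <- list(
    list(chrom = "chr2R", at = island_at + island_length + 500, copies = 1L,
         island_at = island_at, island_len = island_length),
    list(chrom = "chr2R", at = 700000, copies = 2L),
    list(chrom = "chr2R", at = 760000, copies = 3L),
    list(chrom = "chr2R", at = 820000, copies = 4L),
    list(chrom = "chr2R", at = 880000, copies = 5L),
    list(chrom = "chr2R", at = 940000, copies = 6L),
    list(chrom = "chr3R", at = 300000, copies = 7L),
    list(chrom = "chr3R", at = 360000, copies = 8L),
    list(chrom = "chr3R", at = 420000, copies = 9L),
    list(chrom = "chr3R", at = 480000, copies = 10L),
    list(chrom = "chr3R", at = 540000, copies = 11L),
    list(chrom = "chr3R", at = 600000, copies = 12L))
  genome <- scenario_genome(
    seed, chrom_bg = list(chr2R = 1200000, chr3R = 800000),
    cluster_plan = plan, endo_chrom = "chr3R", endo_at = 100000,
    extra_fillers = list(list(chrom = "chr2R",
                              at = island_at + island_length)))
  construct <- default_construct(genome, seed = seed)
  ann <- genome$annotations
  tgt <- ann[ann$name == "mainrep:1", ]
  site <- tgt$start + attr(genome, "ttaa_offset")
  ins <- insert_transgene(genome, construct, tgt$chrom, site, zygosity)
  island <- ann[ann$name == "island", ]
  list(genome = genome, construct = construct, diploid = ins$diploid,
       event = ins$event, site = site, island = island)
}

#' Copy-number scenario: small genome for 30x depth analysis
#'
#' A ~70 kb two-chromosome genome with a 12-copy repeat cluster split
#' across both chromosomes, the endogenous promoter/terminator donor on
#' chrB, and a heterozygous insertion planted inside a chrA repeat copy
#' (so the immediate transgene flanks are repetitive, reproducing the
#' multi-mapping coverage inflation next to the junction).
#'
#' @param seed integer seed.
#' @param zygosity `"het"` or `"hom"`.
#' @return list(genome, construct, diploid, event, site).
#' @export
copy_number_scenario <- function(seed = 1, zygosity = "het") {
  plan <- list(
    list(chrom = "chrA", at = 20000, copies = 1:8),
    list(chrom = "chrB", at = 5000, copies = 9:12))
  # near-identical (young) filler repeats flank each main copy: short
  # reads from them multi-map, reproducing the coverage inflation seen in
  # the immediate transgene-flanking sequence
  genome <- scenario_genome(
    seed, chrom_bg = list(chrA = 40000, chrB = 30000),
    cluster_plan = plan, endo_chrom = "chrB", endo_at = 22000,
    filler_divergence = 0.002)
  construct <- default_construct(genome, seed = seed)
  ann <- genome$annotations
  tgt <- ann[ann$name == "mainrep:4", ]
  site <- tgt$start + attr(genome, "ttaa_offset")
  ins <- insert_transgene(genome, construct, tgt$chrom, site, zygosity)
  list(genome = genome, construct = construct, diploid = ins$diploid,
       event = ins$event, site = site)
}

#' Simple unique-background scenario for junction/TSD analyses
#'
#' A 30 kb genome without repeats; the insertion goes into a randomly
#' chosen TTAA of chrA, so junction evidence is clean and flank recovery
#' can be compared byte-for-byte against the planted truth.
#'
#' @param seed integer seed.
#' @param zygosity insertion zygosity.
#' @return list(genome, construct, diploid, event, site).
#' @export
tsd_scenario <- function(seed = 1, zygosity = "het") {
  genome <- scenario_genome(
    seed, chrom_bg = list(chrA = 20000, chrB = 10000),
    cluster_plan = list(), endo_chrom = "chrB", endo_at = 4000)
  construct <- default_construct(genome, seed = seed)
  set.seed(derive_seed(seed, "site_choice"))
  sites <- Biostrings::start(Biostrings::matchPattern(
    "TTAA", Biostrings::DNAString(genome$chromosomes[["chrA"]]))) - 1L
  sites <- sites[sites > 2000 & sites < 18000]
  site <- sample(sites, 1)
  ins <- insert_transgene(genome, construct, "chrA", site, zygosity)
  list(genome = genome, construct = construct, diploid = ins$diploid,
       event = ins$event, site = site)
}

#' Crop a diploid genome to a window around the insertion junction
#'
#' Returns a mini-diploid whose haplotype A is the insertion-bearing
#' window (junction +/- `radius` plus the construct) and haplotype B the
#' matching wild-type window — the cheap way to simulate deep local
#' resequencing around a junction. Reads simulated from it are mapped
#' against the full reference as usual.
#'
#' @param diploid `DiploidGenome` with an insertion event.
#' @param radius flanking bp kept on each side (default 3000).
#' @return a `DiploidGenome`-shaped list with one chromosome `"win"`.
#' @export
junction_window_diploid <- function(diploid, radius = 3000) {
  ev <- diploid$event
  cl <- ev$construct_length
  a <- diploid$hapA[[ev$chrom]]
  b <- diploid$hapB[[ev$chrom]]
  a_from <- max(0, ev$site - radius)
  a_to <- min(nchar(a), ev$site + 8 + cl + radius)
  b_from <- max(0, ev$site - radius)
  b_to <- min(nchar(b), ev$site + 4 + radius)
  hapA <- c(win = substr(a, a_from + 1, a_to))
  hapB <- c(win = substr(b, b_from + 1, b_to))
  if (ev$zygosity == "hom") hapB <- hapA
  structure(list(hapA = hapA, hapB = hapB, construct = diploid$construct,
                 construct_name = diploid$construct_name, event = ev,
                 genome = diploid$genome), class = "DiploidGenome")
}

#' In-silico inverse PCR recovery of both junction flanks
#'
#' Runs the inverse-PCR emulation on the insertion-bearing haplotype with
#' outward-facing primer pairs taken from the construct ITRs, strips the
#' construct-derived portions (computable from the construct sequence and
#' the enzyme alone), and returns the genomic flanks plus the combined
#' flank query used for candidate-locus searching.
#'
#' @param diploid `DiploidGenome` with an insertion.
#' @param enzyme enzyme spec (default the DraI preset).
#' @param max_product maximum amplifiable product (bp).
#' @return list(flank5, flank3, query, junction_offset, amplicons).
#'   `flank5` ends with the TSD motif, `flank3` begins with it; `query`
#'   is `flank5 + flank3` with one TSD copy removed, and
#'   `junction_offset` is the query coordinate of the junction.
#' @export
recover_flanks_ipcr <- function(diploid, enzyme = enzyme_preset("DraI"),
                                max_product = 10000) {
  ev <- diploid$event
  if (is.null(ev))
    insertra_abort("diploid carries no insertion event",
                   "insertra_evidence_error")
  cons <- diploid$construct
  cseq <- cons$full_sequence
  clen <- nchar(cseq)
  hap <- diploid$hapA[[ev$chrom]]
  ccuts <- digest(cseq, enzyme)$cut_positions
  if (length(ccuts) == 0)
    insertra_abort("enzyme does not cut inside the construct",
                   "insertra_primer_error")
  itr3_start <- cons$features$start[which(cons$features$role %in% "itr3")]

  # 5' junction: primers inside the 5' ITR, facing outward on the circle
  fwd5 <- substr(cseq, 101, 121)
  rev5 <- revcomp(substr(cseq, 41, 61))
  amp5 <- inverse_pcr(hap, enzyme, fwd5, rev5, max_product = max_product)
  lead5 <- ccuts[1] - 100        # construct bases before the joint
  trail5 <- 61                   # construct bases after the junction
  flank5 <- substr(amp5$sequence, lead5 + 1,
                   nchar(amp5$sequence) - trail5)

  # 3' junction: primers inside the 3' ITR
  fwd3 <- substr(cseq, itr3_start + 151, itr3_start + 171)
  rev3 <- revcomp(substr(cseq, itr3_start + 41, itr3_start + 61))
  amp3 <- inverse_pcr(hap, enzyme, fwd3, rev3, max_product = max_product)
  lead3 <- clen - (itr3_start + 150)
  trail3 <- (itr3_start + 61) - ccuts[length(ccuts)]
  flank3 <- substr(amp3$sequence, lead3 + 1,
                   nchar(amp3$sequence) - trail3)

  query <- paste0(flank5, substr(flank3, 5, nchar(flank3)))
  list(flank5 = flank5, flank3 = flank3, query = query,
       junction_offset = nchar(flank5),
       amplicons = list(amp5 = amp5, amp3 = amp3))
}
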