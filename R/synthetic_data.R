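#' @title Seeded synthetic cohorts
#' @description Generates synthetic samples with the structural features the
#'   analysis assumes — BFB-amplified arms with fold-back junctions and
#'   stepped copy-number segments, planted tail-to-tail junctions inside the
#'   FGFR1-like gene or in its 400 kb upstream window, planted NSD3-like
#'   disruptions, non-centered amplification controls and per-sample
#'   responder labels — so every pipeline stage is testable with no external
#'   data. All randomness flows from one integer seed through a documented
#'   cohort -> sample -> event hierarchy, and the caller's RNG state is left
#'   untouched.
#' @name synthetic_data
NULL

.derive_seed <- function(seed, i) (abs(seed) * 7919 + i * 104729) %% 2147483647

#' Random multi-exon transcript model (property-test workhorse)
#'
#' @param seed integer seed
#' @param n_exons number of exons (default random 2-8)
#' @param strand `"+"`, `"-"` or NULL for random
#' @param with_cds attach a CDS (start mid exon 1 or 2, stop in the last exon)
#'   and a random coding sequence free of internal stops
#' @return a [transcript()]
#' @export
random_transcript <- function(seed, n_exons = NULL, strand = NULL,
                              with_cds = TRUE) {
  with_preserved_seed(seed, {
    if (is.null(n_exons)) n_exons <- sample(2:8, 1)
    if (is.null(strand)) strand <- sample(c("+", "-"), 1)
    utr5 <- sample(10:60, 1)
    utr3 <- sample(10:60, 1)
    coding <- 3 * sample(10:60, n_exons)       # codon-aligned per exon
    widths <- coding
    widths[1] <- widths[1] + utr5
    widths[n_exons] <- widths[n_exons] + utr3
    introns <- sample(50:500, max(n_exons - 1, 1))
    anchor <- sample(1000:100000, 1)
    starts <- integer(n_exons); ends <- integer(n_exons)
    pos <- anchor
    for (i in seq_len(n_exons)) {       # laid out in transcription order
      if (strand == "+") {
        starts[i] <- pos; ends[i] <- pos + widths[i]
        if (i < n_exons) pos <- ends[i] + introns[i]
      } else {
        ends[i] <- pos; starts[i] <- pos - widths[i]
        if (i < n_exons) pos <- starts[i] - introns[i]
      }
    }
    exons <- data.frame(start = starts, end = ends)
    n_codons <- sum(coding) / 3
    pool <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                      c("A", "C", "G", "T"),
                                      c("A", "C", "G", "T")), 1,
                          paste0, collapse = ""),
                    c("ATG", "TAA", "TAG", "TGA"))
    codons <- sample(pool, n_codons, replace = TRUE)
    codons[1] <- "ATG"
    extra <- which(stats::runif(n_codons) < 0.05)   # sprinkle internal ATGs
    codons[setdiff(extra, c(1, n_codons))] <- "ATG"
    codons[n_codons] <- "TAA"
    cds_seq <- paste0(codons, collapse = "")
    cds_len <- nchar(cds_seq)
    tx0 <- transcript("synth", "chrS", strand, exons)
    sc <- spliced_coords(tx0)
    cds_start <- sc[utr5 + 1]
    cds_end <- sc[utr5 + cds_len]
    transcript("synth", "chrS", strand, exons, cds_start, cds_end, cds_seq)
  })
}

# synthetic FGFR1-like gene: 18 exons, minus strand, exon 1 noncoding,
# in-frame ATG at the first codon of every exon 2..10 (so any 5' truncation
# upstream of the kinase exons finds a start), kinase in exons 11-17.
.synth_fgfr1 <- function(seed) {
  with_preserved_seed(seed, {
    coding <- c(0, 3 * sample(30:70, 17, replace = TRUE))
    widths <- coding
    widths[1] <- sample(200:400, 1)             # UTR-only exon 1
    widths[2] <- widths[2] + 100                # 5'UTR head of exon 2
    widths[18] <- widths[18] + 150              # 3'UTR tail of exon 18
    introns <- sample(2000:4000, 17, replace = TRUE)
    top <- 38326000 + sample(-2000:2000, 1)
    starts <- integer(18); ends <- integer(18)
    pos <- top
    for (i in 1:18) {
      ends[i] <- pos; starts[i] <- pos - widths[i]
      if (i < 18) pos <- starts[i] - introns[i]
    }
    n_codons <- sum(coding) / 3                 # includes the stop codon
    cum_aa <- cumsum(coding / 3)                # aa reached at each exon end
    pool <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                      c("A", "C", "G", "T"),
                                      c("A", "C", "G", "T")), 1,
                          paste0, collapse = ""),
                    c("ATG", "TAA", "TAG", "TGA"))
    codons <- sample(pool, n_codons, replace = TRUE)
    first_codon_of_exon <- c(NA, 1, cum_aa[2:17] + 1)  # exon i coding start
    codons[first_codon_of_exon[2:10]] <- "ATG"
    codons[n_codons] <- "TAA"
    cds_seq <- paste0(codons, collapse = "")
    exons <- data.frame(start = starts, end = ends)
    tx0 <- transcript("FGFR1S", "chrS", "-", exons)
    sc <- spliced_coords(tx0)
    utr5 <- widths[1] + 100
    cds_start <- sc[utr5 + 1]
    cds_end <- sc[utr5 + nchar(cds_seq)]
    tx <- transcript("FGFR1S", "chrS", "-", exons, cds_start, cds_end, cds_seq)
    dom <- protein_domains(data.frame(
      name = c("IG-I", "acid box", "IG-II", "IG-III", "TM", "kinase"),
      aa_start = c(5, cum_aa[3] + 2, cum_aa[4] + 2, cum_aa[6] + 2,
                   cum_aa[9] + 2, cum_aa[10] + 2),
      aa_end = c(cum_aa[3] - 1, cum_aa[4] - 1, cum_aa[6] - 1, cum_aa[8] - 1,
                 cum_aa[10] - 1, cum_aa[17] - 1)))
    gene_fixture(tx, dom, ends[1] - 1)
  })
}

# synthetic NSD3-like gene: 24 exons, plus strand, SET domain in exons 19-21
.synth_nsd3 <- function(seed) {
  with_preserved_seed(seed, {
    aa <- sample(40:70, 24, replace = TRUE)
    coding <- 3 * aa
    widths <- coding
    widths[1] <- widths[1] + 100
    widths[24] <- widths[24] + 3 + 150
    introns <- sample(2000:4500, 23, replace = TRUE)
    bottom <- 38135000 + sample(-2000:2000, 1)
    starts <- integer(24); ends <- integer(24)
    pos <- bottom
    for (i in 1:24) {
      starts[i] <- pos; ends[i] <- pos + widths[i]
      if (i < 24) pos <- ends[i] + introns[i]
    }
    cum_aa <- cumsum(aa)
    exons <- data.frame(start = starts, end = ends)
    tx0 <- transcript("NSD3S", "chrS", "+", exons)
    sc <- spliced_coords(tx0)
    cds_start <- sc[101]
    cds_end <- sc[100 + 3 * sum(aa) + 3]
    tx <- transcript("NSD3S", "chrS", "+", exons, cds_start, cds_end)
    dom <- protein_domains(data.frame(
      name = c("PWWP", "SET"),
      aa_start = c(cum_aa[4] + 2, cum_aa[18] + 2),
      aa_end = c(cum_aa[6] - 1, cum_aa[21] - 1)))
    gene_fixture(tx, dom, starts[1])
  })
}

#' Synthetic gene fixtures on a model chromosome arm
#'
#' Builds an FGFR1-like fixture (minus strand, 18 exons, ectodomain/TM/kinase
#' domain table) and an NSD3-like fixture (plus strand, 24 exons, 3' SET
#' domain) on a synthetic 45 Mb arm with the telomere at coordinate 0
#' (8p-like), plus a gene table for peak annotation. Deterministic per seed.
#'
#' @param seed integer seed
#' @return list: `fgfr1`, `nsd3` ([gene_fixture()]s), `genes` (data.frame)
#' @export
make_gene_models <- function(seed) {
  fg <- .synth_fgfr1(.derive_seed(seed, 1))
  ns <- .synth_nsd3(.derive_seed(seed, 2))
  fs <- gene_span(fg); nss <- gene_span(ns)
  genes <- data.frame(
    gene = c("FGFR1S", "NSD3S", "GENE_A", "GENE_B"),
    chrom = "chrS",
    start = c(fs$start, nss$start, 37600000, 39000000),
    end = c(fs$end, nss$end, 37680000, 39090000),
    strand = c("-", "+", "+", "-"))
  list(fgfr1 = fg, nsd3 = ns, genes = genes)
}

#' Scenario specification for the cohort simulator
#'
#' Defaults encode the stated world of the source analysis: BFB backgrounds
#' with enough cycles to produce multi-segment stepped profiles, focal gains
#' with amplitude drawn uniformly from 4-20 extra copies on top of a 1-copy
#' homolog baseline, a 0.5 probability of an accompanying NSD3 disruption for
#' FGFR1-centered samples (5 of 9 in the source), response-label rates of
#' 0.78 for predicted-dependent and 0.25 for other samples (7/9 and 3/12),
#' and no coordinate jitter (10 kb models breakpoint-calling uncertainty in
#' the robustness tests).
#'
#' @param scenario one of `deltaEC_FGFR1`, `FGFR1_centered`, `non_centered`,
#'   `FGFR1_inactivated`
#' @param n_samples samples to draw from this scenario
#' @param n_segments BFB segmentation size
#' @param cycles_range inclusive range of BFB cycle counts
#' @param amp_range inclusive range of focal-gain amplitudes (copies)
#' @param jitter_bp SD of Gaussian jitter added to junction breakends
#' @param p_nsd3 probability of an NSD3 disruption (FGFR1-centered samples)
#' @param p_responder_dep,p_responder_nondep response-label rule
#' @return a `ScenarioSpec` list
#' @export
scenario_spec <- function(scenario = c("deltaEC_FGFR1", "FGFR1_centered",
                                       "non_centered", "FGFR1_inactivated"),
                          n_samples = 10, n_segments = 12,
                          cycles_range = c(4, 6), amp_range = c(4, 20),
                          jitter_bp = 0, p_nsd3 = 0.5,
                          p_responder_dep = 0.78,
                          p_responder_nondep = 0.25) {
  scenario <- match.arg(scenario)
  stopifnot(n_samples >= 0, n_segments >= 1,
            p_nsd3 >= 0, p_nsd3 <= 1,
            p_responder_dep >= 0, p_responder_dep <= 1,
            p_responder_nondep >= 0, p_responder_nondep <= 1)
  structure(list(scenario = scenario, n_samples = n_samples,
                 n_segments = n_segments, cycles_range = cycles_range,
                 amp_range = amp_range, jitter_bp = jitter_bp,
                 p_nsd3 = p_nsd3, p_responder_dep = p_responder_dep,
                 p_responder_nondep = p_responder_nondep),
            class = "ScenarioSpec")
}

# segmentation boundaries of the simulated arm (centromere at high coords),
# chosen to avoid the FGFR1/NSD3 zone (38.0-38.8 Mb) so background fold-backs
# never land in the gene body or the upstream window
.arm_bounds <- c(44.0, 43.2, 42.4, 41.6, 40.8, 40.0, 39.2, 38.8,
                 38.0, 37.2, 36.4, 35.2, 34.0) * 1e6

#' Overlay an additional copy gain onto a segment list
#'
#' Splits segments at the interval boundaries and adds `add` copies inside.
#'
#' @param segments data.frame `chrom, start, end, cn`
#' @param interval [genomic_interval()]
#' @param add copies to add
#' @return modified segment data.frame
#' @export
overlay_gain <- function(segments, interval, add) {
  out <- list()
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    if (s$chrom != interval$chrom || s$end <= interval$start ||
        s$start >= interval$end) { out[[length(out) + 1]] <- s; next }
    cuts <- sort(unique(c(s$start, s$end,
                          max(interval$start, s$start),
                          min(interval$end, s$end))))
    for (j in seq_len(length(cuts) - 1)) {
      piece <- s
      piece$start <- cuts[j]; piece$end <- cuts[j + 1]
      inside <- cuts[j] >= interval$start && cuts[j + 1] <= interval$end
      if (inside) piece$cn <- piece$cn + add
      out[[length(out) + 1]] <- piece
    }
  }
  res <- do.call(rbind, out)
  res[res$end > res$start, , drop = FALSE]
}

#' Simulate one sample
#'
#' Runs [simulate_bfb()] on the arm segmentation to produce stepped copy
#' number and fold-back junctions, plants the scenario's defining junction
#' (intragenic tail-to-tail at a random intron of exons 1-5; upstream-window
#' tail-to-tail; kinase-deleting head-to-head; or none) plus an optional
#' NSD3 deletion, overlays the scenario's focal gain, and emits a truth
#' record.
#'
#' @param spec a [scenario_spec()]
#' @param fixtures result of [make_gene_models()]
#' @param seed integer seed
#' @return list: `segments` (`chrom, start, end, cn`), `junctions`, `truth`
#' @export
simulate_sample <- function(spec, fixtures, seed) {
  fg <- fixtures$fgfr1
  ns <- fixtures$nsd3
  span <- gene_span(fg)
  tss <- fg$tss
  with_preserved_seed(.derive_seed(seed, 3), {
    cycles <- sample(spec$cycles_range[1]:spec$cycles_range[2], 1)
    amp <- sample(spec$amp_range[1]:spec$amp_range[2], 1)
    k <- spec$n_segments
    bounds <- .arm_bounds[round(seq(1, length(.arm_bounds),
                                    length.out = k + 1))]
    smap <- segment_map("chrS", bounds)
    sim <- simulate_bfb(k, cycles, seed = .derive_seed(seed, 4), smap = smap)
    segments <- data.frame(chrom = "chrS", start = smap$start,
                           end = smap$end, cn = 1 + sim$counts)
    segments <- segments[order(segments$start), ]
    mid <- floor((span$start + span$end) / 2)
    scen <- spec$scenario
    focal <- switch(scen,
      deltaEC_FGFR1 = genomic_interval("chrS", mid - 250e3, mid + 250e3),
      FGFR1_centered = genomic_interval("chrS", mid - 250e3, mid + 250e3),
      FGFR1_inactivated = genomic_interval("chrS", mid - 100e3, mid + 1.7e6),
      non_centered = genomic_interval("chrS", mid + 200e3, mid + 2.0e6))
    segments <- overlay_gain(segments, focal, amp)
    if (scen %in% c("deltaEC_FGFR1", "FGFR1_centered") && amp > 0) {
      # amplicons step up toward the driver gene: a higher inner tier makes
      # the profile maximum sit over the gene body, not a flat plateau
      inner <- genomic_interval("chrS", mid - 80e3, mid + 80e3)
      segments <- overlay_gain(segments, inner, max(1, amp %/% 4))
    }
    jx <- sim$foldbacks
    jx$sample <- NULL
    planted <- NULL
    if (scen == "deltaEC_FGFR1") {
      intron <- sample(1:5, 1)
      ex <- fg$transcript$exons
      b <- floor((ex$start[intron] + ex$end[intron + 1]) / 2)
      planted <- data.frame(chrom1 = "chrS", pos1 = b - sample(300:900, 1),
                            side1 = "left", chrom2 = "chrS", pos2 = b,
                            side2 = "left", name = "planted_tt_intragenic",
                            support = sample(15:200, 1))
    } else if (scen == "FGFR1_centered") {
      d <- sample(20000:380000, 1)
      planted <- data.frame(chrom1 = "chrS", pos1 = tss + d, side1 = "left",
                            chrom2 = "chrS", pos2 = tss + d + sample(300:900, 1),
                            side2 = "left", name = "planted_tt_upstream",
                            support = sample(15:200, 1))
    } else if (scen == "FGFR1_inactivated") {
      ex <- fg$transcript$exons
      b <- floor((ex$start[5] + ex$end[6]) / 2)      # intron 5
      planted <- data.frame(chrom1 = "chrS", pos1 = b, side1 = "right",
                            chrom2 = "chrS", pos2 = b + sample(300:600, 1),
                            side2 = "right", name = "planted_hh_kinase_del",
                            support = sample(15:200, 1))
    }
    nsd3_planted <- FALSE
    if (scen == "FGFR1_centered" && stats::runif(1) < spec$p_nsd3) {
      nsd3_planted <- TRUE
      nex <- ns$transcript$exons
      m <- sample(5:15, 1)
      bn <- floor((nex$end[m] + nex$start[m + 1]) / 2)    # intron m
      planted <- rbind(planted, data.frame(
        chrom1 = "chrS", pos1 = bn, side1 = "left",
        chrom2 = "chrS", pos2 = max(nex$end) + sample(5000:20000, 1),
        side2 = "right", name = "planted_nsd3_del",
        support = sample(15:200, 1)))
    }
    base_cols <- c("chrom1", "pos1", "side1", "chrom2", "pos2", "side2",
                   "name", "support")
    all_jx <- rbind(jx[, base_cols],
                    if (!is.null(planted)) planted[, base_cols])
    if (spec$jitter_bp > 0) {
      all_jx$pos1 <- pmax(0, all_jx$pos1 +
                            round(stats::rnorm(nrow(all_jx), 0, spec$jitter_bp)))
      all_jx$pos2 <- pmax(0, all_jx$pos2 +
                            round(stats::rnorm(nrow(all_jx), 0, spec$jitter_bp)))
    }
    junctions <- junction_table(all_jx)
    predicted_dep <- scen %in% c("deltaEC_FGFR1", "FGFR1_centered")
    p_resp <- if (predicted_dep) spec$p_responder_dep
              else spec$p_responder_nondep
    response <- if (stats::runif(1) < p_resp) "responder" else "nonresponder"
    truth <- list(category = scen, nsd3_disrupted = nsd3_planted,
                  response = response,
                  planted = if (!is.null(planted)) planted else NULL,
                  bfb_string = sim$string$symbols, bfb_cycles = cycles,
                  telomeric_loss = sim$telomeric_loss)
    list(segments = segments, junctions = junctions, truth = truth)
  })
}

#' Simulate a cohort and write it to disk
#'
#' Writes `seg.tsv` (SEG-like, with a sample column), `junctions.bedpe`
#' (10-column, sample id in the name field), `labels.tsv` and `truth.json`
#' into `dir`. Byte-identical output for identical (specs, seed).
#'
#' @param specs list of [scenario_spec()]s
#' @param seed integer seed
#' @param dir output directory (created if missing)
#' @return list with file `paths`, the `samples` (in-memory results) and
#'   `fixtures`
#' @export
simulate_cohort <- function(specs, seed, dir) {
  if (inherits(specs, "ScenarioSpec")) specs <- list(specs)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fixtures <- make_gene_models(seed)
  samples <- list(); labels <- list(); idx <- 0
  for (spec in specs) {
    for (r in seq_len(spec$n_samples)) {
      idx <- idx + 1
      id <- sprintf("S%03d", idx)
      sm <- simulate_sample(spec, fixtures, .derive_seed(seed, 100 + idx))
      samples[[id]] <- sm
      labels[[id]] <- data.frame(sample = id, response = sm$truth$response,
                                 scenario = spec$scenario)
    }
  }
  seg <- do.call(rbind, lapply(names(samples), function(id) {
    s <- samples[[id]]$segments
    data.frame(sample = id, chrom = s$chrom, start = s$start, end = s$end,
               total_cn = s$cn)
  }))
  paths <- list(seg = file.path(dir, "seg.tsv"),
                bedpe = file.path(dir, "junctions.bedpe"),
                labels = file.path(dir, "labels.tsv"),
                truth = file.path(dir, "truth.json"))
  if (is.null(seg)) {
    seg <- data.frame(sample = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      total_cn = numeric(0))
  }
  write_seg(seg, paths$seg)
  jx <- do.call(rbind, lapply(names(samples), function(id) {
    j <- samples[[id]]$junctions
    if (nrow(j)) j$name <- id
    j
  }))
  if (is.null(jx))
    jx <- junction_table(data.frame(chrom1 = character(0), pos1 = numeric(0),
                                    side1 = character(0),
                                    chrom2 = character(0), pos2 = numeric(0),
                                    side2 = character(0)))
  write_bedpe(jx, paths$bedpe)
  lab <- do.call(rbind, labels)
  if (is.null(lab))
    lab <- data.frame(sample = character(0), response = character(0),
                      scenario = character(0))
  .write_table(lab, paths$labels, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(lapply(samples, `[[`, "truth"), paths$truth,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  list(paths = paths, samples = samples, fixtures = fixtures)
}
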