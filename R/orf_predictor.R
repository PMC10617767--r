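#' @title Truncated open-reading-frame prediction
#' @description Predicts the protein consequence of an intragenic
#'   rearrangement: which exons survive on the derivative, whether the
#'   canonical start codon survives, and otherwise the first in-frame ATG of
#'   the retained spliced coding sequence (the mechanism behind
#'   ectodomain-deficient FGFR1). Scanning considers in-frame ATGs only, with
#'   no Kozak-context scoring, and works on the mRNA-sense sequence; for a
#'   minus-strand gene this is the same operation as reading TAC motifs right
#'   to left on the genome strand. The fused partner sequence across the
#'   junction is never scanned (its identity is unknown in general).
#' @name orf_predictor
NULL

# retained reference flank of a breakend: "left" keeps coords <= pos,
# "right" keeps coords >= pos
.breakend_keeps <- function(pos, side, x) {
  if (side == "left") x <= pos else x >= pos
}

#' Exons retained on the rearranged derivative
#'
#' Uses the breakend(s) falling inside the transcript span. For an inverted
#' junction (tail-to-tail / head-to-head) the retained region is the common
#' retained flank (for two same-side intragenic breakends, the more
#' restrictive one); for a deletion-type junction with both breakends inside
#' the transcript the interval between them is removed. An exon cut by a
#' breakend is reported as retained but partial.
#'
#' @param tx a [transcript()]
#' @param j a one-row junction table (see [junction_table()])
#' @return list with `exons` (retained exon numbers, transcription order),
#'   `partial` (subset of `exons` only partially retained) and `keep`
#'   (predicate function over genomic positions, used downstream)
#' @export
retained_exons <- function(tx, j) {
  stopifnot(nrow(j) == 1)
  ex <- tx$exons
  lo <- min(ex$start); hi <- max(ex$end)
  b <- data.frame(chrom = c(j$chrom1, j$chrom2), pos = c(j$pos1, j$pos2),
                  side = c(j$side1, j$side2))
  b <- b[b$chrom == tx$chrom & b$pos >= lo & b$pos < hi, , drop = FALSE]
  if (nrow(b) == 0)
    stop("not intragenic: no breakend falls inside the transcript")
  keep <- if (nrow(b) == 1 || all(b$side == b$side[1])) {
    side <- b$side[1]
    posq <- if (side == "left") min(b$pos) else max(b$pos)
    function(x) .breakend_keeps(posq, side, x)
  } else if (j$side1 == "left" && j$side2 == "right") {
    # internal deletion of (pos1, pos2)
    function(x) x <= j$pos1 | x >= j$pos2
  } else {
    # duplication-type: all reference bases remain present
    function(x) rep(TRUE, length(x))
  }
  n <- nrow(ex)
  status <- vapply(seq_len(n), function(i) {
    bases_kept <- sum(keep(seq.int(ex$start[i], ex$end[i] - 1)))
    if (bases_kept == 0) "lost"
    else if (bases_kept == ex$end[i] - ex$start[i]) "full" else "partial"
  }, character(1))
  list(exons = which(status != "lost"),
       partial = which(status == "partial"),
       keep = keep)
}

#' First surviving in-frame start codon of the retained CDS
#'
#' If the canonical start codon survives it is returned (`canonical = TRUE`);
#' otherwise the retained spliced sequence is scanned 5' to 3' in transcript
#' orientation for the first ATG whose offset is congruent to the canonical
#' reading frame. A breakend inside an exon discards the 5' part of that exon
#' up to the breakpoint before scanning.
#'
#' @param tx a [transcript()] carrying `cds_sequence`
#' @param retained result of [retained_exons()] (or a keep predicate)
#' @return list with `found`, `canonical`, `exon`, `cds_offset` (0-based),
#'   `protein_start_aa` (1-based residue on the canonical protein); `found =
#'   FALSE` means no in-frame ATG survives ("no ORF")
#' @export
next_inframe_start <- function(tx, retained) {
  if (is.null(tx$cds_sequence)) stop("transcript lacks cds_sequence")
  keep <- if (is.function(retained)) retained else retained$keep
  cc <- cds_coords(tx)
  kp <- keep(cc)
  L <- min(length(cc), nchar(tx$cds_sequence))
  canonical <- all(kp[1:3])
  if (canonical) {
    loc <- exon_index_of(tx, cc[1])
    return(list(found = TRUE, canonical = TRUE, exon = loc$exon,
                cds_offset = 0L, protein_start_aa = 1L))
  }
  codon_starts <- seq.int(1, L - 2, by = 3)       # 1-based, in-frame
  for (s in codon_starts) {
    if (!all(kp[s:(s + 2)])) next
    if (substr(tx$cds_sequence, s, s + 2) == "ATG") {
      loc <- exon_index_of(tx, cc[s])
      return(list(found = TRUE, canonical = FALSE, exon = loc$exon,
                  cds_offset = s - 1L, protein_start_aa = (s - 1L) %/% 3L + 1L))
    }
  }
  list(found = FALSE, canonical = FALSE, exon = NA_integer_,
       cds_offset = NA_integer_, protein_start_aa = NA_integer_)
}

#' Predict the protein variant produced by an intragenic rearrangement
#'
#' Composes [retained_exons()] and [next_inframe_start()], then intersects the
#' translated span with the fixture's domain table: a domain is lost when it
#' ends before the predicted start (or starts after the retained 3' end for a
#' kinase-deleting rearrangement); a domain cut by either boundary is counted
#' lost and flagged partial. `kinase_retained` requires the kinase domain to
#' lie entirely inside the translated span.
#'
#' @param fixture a [gene_fixture()] (transcript with CDS sequence + domains)
#' @param j one-row junction table
#' @return a `TruncationCall` list
#' @export
predict_variant <- function(fixture, j) {
  tx <- fixture$transcript
  ret <- retained_exons(tx, j)
  start <- next_inframe_start(tx, ret)
  cc <- cds_coords(tx)
  kp <- ret$keep(cc)
  n_aa <- (min(length(cc), nchar(tx$cds_sequence))) %/% 3 - 1  # minus stop
  # last fully retained residue of the translated suffix
  last_aa <- 0L
  if (start$found) {
    off <- start$cds_offset
    run <- off
    while (run + 3 <= 3 * n_aa && all(kp[(run + 1):(run + 3)])) run <- run + 3
    last_aa <- run %/% 3            # residue number of last intact codon
  }
  dom <- fixture$domains
  if (start$found) {
    lost <- dom$aa_end < start$protein_start_aa | dom$aa_start > last_aa
    partial <- !lost & (dom$aa_start < start$protein_start_aa |
                          dom$aa_end > last_aa)
  } else {
    lost <- rep(TRUE, nrow(dom)); partial <- rep(FALSE, nrow(dom))
  }
  kin <- dom[dom$name == "kinase", , drop = FALSE]
  kinase_retained <- start$found && nrow(kin) == 1 &&
    kin$aa_start >= start$protein_start_aa && kin$aa_end <= last_aa
  structure(list(
    gene = tx$gene,
    breakend_pos = c(j$pos1, j$pos2),
    retained_exons = ret$exons,
    partial_exons = ret$partial,
    start_codon = start,
    lost_domains = dom$name[lost | partial],
    partial_domains = dom$name[partial],
    kinase_retained = kinase_retained,
    protein_start_aa = start$protein_start_aa,
    protein_end_aa = if (start$found) last_aa else NA_integer_),
    class = "TruncationCall")
}

#' Predicted protein sequence of a truncation call
#'
#' Translates the retained coding span; useful for reports and as the basis
#' of frame-correctness checks (the result is always a substring of the
#' canonical protein).
#'
#' @param fixture a [gene_fixture()]
#' @param call a `TruncationCall` from [predict_variant()]
#' @return amino-acid string (empty when no ORF survives)
#' @export
truncated_protein <- function(fixture, call) {
  tx <- fixture$transcript
  if (!call$start_codon$found) return("")
  s <- 3 * (call$protein_start_aa - 1) + 1
  e <- 3 * call$protein_end_aa
  aa <- Biostrings::translate(Biostrings::DNAString(
    substr(tx$cds_sequence, s, e)))
  as.character(aa)
}

#' JSON truncation report for a set of junctions
#'
#' @param fixture a [gene_fixture()]
#' @param junctions junction table (only rows intersecting the transcript are
#'   reported)
#' @param path output JSON path
#' @export
write_truncation_report <- function(fixture, junctions, path) {
  calls <- list()
  for (i in seq_len(nrow(junctions))) {
    ji <- junctions[i, , drop = FALSE]
    res <- tryCatch(predict_variant(fixture, ji), error = function(e) NULL)
    if (!is.null(res)) calls[[ji$name]] <- unclass(res)
  }
  jsonlite::write_json(calls, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
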