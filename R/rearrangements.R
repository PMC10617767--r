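#' @title Rearrangement junctions: I/O, orientation classes, fold-backs
#' @description A junction is a pair of oriented breakends. `retained_side`
#'   records which reference flank of a breakend is joined into the derivative
#'   chromosome: `"left"` keeps the lower-coordinate flank (BEDPE strand "+"),
#'   `"right"` the higher-coordinate flank (BEDPE strand "-"). Orientation
#'   nomenclature follows the field's usage: "tail" is the high-coordinate
#'   flank, so a tail-to-tail junction joins two left-retained breakends
#'   ("+/+") and a head-to-head junction two right-retained ones ("-/-").
#' @name rearrangements
NULL

.sides <- c("left", "right")
.orientations <- c("tail_to_tail", "head_to_head", "deletion_type",
                   "duplication_type", "interchromosomal")

#' Build a canonical junction table
#'
#' Breakends are canonically ordered (`a <= b` by chromosome, then position)
#' and each junction is classified by [classify_junction()]. Junctions with
#' support below `min_support` are flagged low-confidence but kept.
#'
#' @param df data.frame with columns `chrom1, pos1, side1, chrom2, pos2,
#'   side2` (0-based positions, sides in `"left"`/`"right"`) and optionally
#'   `support` and `name`
#' @param min_support support threshold below which a junction is flagged
#'   (default 2; no published cutoff exists, reported support values range
#'   from 15 to 192 reads)
#' @return data.frame with canonical breakend order, `orientation_class` and
#'   `low_confidence` columns
#' @export
junction_table <- function(df, min_support = 2) {
  need <- c("chrom1", "pos1", "side1", "chrom2", "pos2", "side2")
  if (!all(need %in% names(df)))
    stop("junction table needs columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0) {
    df$support <- integer(0)
    df$name <- character(0)
    df$orientation_class <- character(0)
    df$low_confidence <- logical(0)
    return(df[c(need, "support", "name", "orientation_class",
                "low_confidence")])
  }
  if (!"support" %in% names(df)) df$support <- NA_integer_
  if (!"name" %in% names(df)) df$name <- paste0("jx", seq_len(nrow(df)))
  if (any(df$pos1 < 0 | df$pos2 < 0)) stop("negative breakend coordinate")
  if (!all(df$side1 %in% .sides & df$side2 %in% .sides))
    stop("sides must be 'left' or 'right'")
  if (any(!is.na(df$support) & df$support < 0)) stop("support must be >= 0")
  swap <- df$chrom2 < df$chrom1 |
    (df$chrom2 == df$chrom1 & df$pos2 < df$pos1)
  if (any(swap)) {
    tmp <- df[swap, c("chrom1", "pos1", "side1")]
    df[swap, c("chrom1", "pos1", "side1")] <-
      df[swap, c("chrom2", "pos2", "side2")]
    df[swap, c("chrom2", "pos2", "side2")] <- tmp
  }
  df$orientation_class <- classify_junction(df)
  df$low_confidence <- !is.na(df$support) & df$support < min_support
  rownames(df) <- NULL
  df
}

#' Classify junctions by breakend orientation
#'
#' For same-chromosome junctions with canonically ordered breakends:
#' (left,left) is tail-to-tail, (right,right) head-to-head, (left,right)
#' deletion-type and (right,left) duplication-type; different chromosomes give
#' `interchromosomal` (the side pair stays available as metadata).
#'
#' @param j junction data.frame (see [junction_table()])
#' @return character vector of orientation classes
#' @export
classify_junction <- function(j) {
  ifelse(j$chrom1 != j$chrom2, "interchromosomal",
  ifelse(j$side1 == "left" & j$side2 == "left", "tail_to_tail",
  ifelse(j$side1 == "right" & j$side2 == "right", "head_to_head",
  ifelse(j$side1 == "left" & j$side2 == "right", "deletion_type",
         "duplication_type"))))
}

#' Read junctions from a 10-column BEDPE file
#'
#' Strand columns encode retained sides: `+` keeps the left flank, `-` the
#' right flank. Breakend positions are taken as the BEDPE `end` coordinate
#' minus one (the last base of each 0-based half-open breakend interval).
#'
#' @param path BEDPE path
#' @param ... passed to [junction_table()]
#' @return a canonical junction table
#' @export
read_bedpe <- function(path, ...) {
  if (length(readLines(path, n = 1)) == 0)
    return(junction_table(data.frame(chrom1 = character(0), pos1 = numeric(0),
                                     side1 = character(0),
                                     chrom2 = character(0), pos2 = numeric(0),
                                     side2 = character(0)), ...))
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 10)
    stop("BEDPE needs 10 columns, got ", ncol(tab))
  if (!all(tab[[9]] %in% c("+", "-")) || !all(tab[[10]] %in% c("+", "-")))
    stop("BEDPE strand columns must be '+' or '-'")
  if (any(tab[[2]] < 0 | tab[[5]] < 0)) stop("negative coordinates in BEDPE")
  df <- data.frame(chrom1 = tab[[1]], pos1 = tab[[3]] - 1,
                   side1 = ifelse(tab[[9]] == "+", "left", "right"),
                   chrom2 = tab[[4]], pos2 = tab[[6]] - 1,
                   side2 = ifelse(tab[[10]] == "+", "left", "right"),
                   name = as.character(tab[[7]]),
                   support = suppressWarnings(as.integer(tab[[8]])),
                   stringsAsFactors = FALSE)
  junction_table(df, ...)
}

#' Write a junction table to BEDPE
#' @param j junction table
#' @param path output path
#' @export
write_bedpe <- function(j, path) {
  tab <- data.frame(j$chrom1, j$pos1, j$pos1 + 1, j$chrom2, j$pos2,
                    j$pos2 + 1, j$name,
                    ifelse(is.na(j$support), ".", j$support),
                    ifelse(j$side1 == "left", "+", "-"),
                    ifelse(j$side2 == "left", "+", "-"))
  .write_table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Decode one VCF BND ALT string. Returns list(side, mate_chrom, mate_pos,
# mate_side) or NULL if the ALT is not bracket notation.
decode_bnd_alt <- function(alt) {
  m <- regmatches(alt, regexec(
    "^([ACGTNacgtn]*)([\\[\\]])([^\\[\\]:]+):([0-9]+)([\\[\\]])([ACGTNacgtn]*)$",
    alt, perl = TRUE))[[1]]
  if (length(m) == 0) return(NULL)
  t_first <- nzchar(m[2])          # replacement sequence precedes the bracket
  bracket <- m[3]
  if (bracket != m[6]) stop("malformed BND ALT: ", alt)
  list(side = if (t_first) "left" else "right",
       mate_chrom = m[4], mate_pos = as.integer(m[5]) - 1,
       mate_side = if (bracket == "]") "left" else "right")
}

#' Read breakend (BND) junctions from a VCF
#'
#' Bracket notation in ALT is decoded to retained sides and mate pairs are
#' merged into single junction records; unmated breakends are reported with a
#' warning and skipped.
#'
#' @param path VCF path (4.2, BND-style records)
#' @param ... passed to [junction_table()]
#' @return a canonical junction table
#' @export
read_vcf_bnd <- function(path, ...) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf_bnd requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alts <- vapply(as.list(VariantAnnotation::alt(vcf)),
                 function(a) as.character(a)[1], character(1))
  ids <- names(rr)
  info <- VariantAnnotation::info(vcf)
  mateid <- if ("MATEID" %in% names(info)) {
    vapply(as.list(info$MATEID), function(x)
      if (length(x)) as.character(x)[1] else NA_character_, character(1))
  } else rep(NA_character_, length(ids))
  dec <- lapply(alts, decode_bnd_alt)
  keep <- !vapply(dec, is.null, logical(1))
  rows <- list(); used <- character(0)
  for (i in which(keep)) {
    if (ids[i] %in% used) next
    j <- which(ids == mateid[i])
    if (is.na(mateid[i]) || length(j) != 1 || !keep[j]) {
      warning("unmated BND record skipped: ", ids[i])
      next
    }
    used <- c(used, ids[i], ids[j])
    d <- dec[[i]]
    sup <- NA_integer_
    if ("SUPPORT" %in% names(info)) sup <- as.integer(info$SUPPORT[i])
    rows[[length(rows) + 1]] <- data.frame(
      chrom1 = as.character(GenomeInfoDb::seqnames(rr))[i],
      pos1 = BiocGenerics::start(rr)[i] - 1, side1 = d$side,
      chrom2 = d$mate_chrom, pos2 = d$mate_pos, side2 = d$mate_side,
      name = sub("_[12]$", "", ids[i]), support = sup,
      stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(chrom1 = character(0), pos1 = numeric(0),
                        side1 = character(0), chrom2 = character(0),
                        pos2 = numeric(0), side2 = character(0))
  junction_table(df, ...)
}

#' Detect fold-back inversions
#'
#' Same-chromosome tail-to-tail or head-to-head junctions whose breakend span
#' does not exceed `proximity_bp` — the genomic signature of a
#' breakage-fusion-bridge fusion event. The published observation is "close
#' proximity" without a number (one validated example spans 720 bp); the
#' default threshold of 100 kb is a configurable package choice.
#'
#' @param junctions junction table
#' @param proximity_bp maximum breakend span in bp (default 1e5)
#' @return the qualifying junction rows with an added `span` column
#' @export
detect_foldbacks <- function(junctions, proximity_bp = 1e5) {
  stopifnot(proximity_bp > 0)
  span <- abs(junctions$pos2 - junctions$pos1)
  sel <- junctions$chrom1 == junctions$chrom2 &
    junctions$orientation_class %in% c("tail_to_tail", "head_to_head") &
    span <= proximity_bp
  out <- junctions[sel, , drop = FALSE]
  out$span <- span[sel]
  rownames(out) <- NULL
  out
}

#' Assign junctions to the FGFR1 gene-body / upstream-window partition
#'
#' A junction is `intragenic` when either breakend falls in the gene span;
#' otherwise `upstream_window` when either breakend falls in the strand-aware
#' upstream window (for the minus-strand FGFR1 the half-open genomic interval
#' `(TSS, TSS + window_bp]`); otherwise `outside`. Gene-body overlap takes
#' precedence over window membership. The 400 kb default is the window chosen
#' in the source analysis; it is anchored at the fixture TSS.
#'
#' @param junctions junction table
#' @param fixture FGFR1 [gene_fixture()]
#' @param window_bp upstream window size in bp (default 400,000)
#' @return character vector (`intragenic`, `upstream_window`, `outside`),
#'   one entry per junction
#' @export
assign_fgfr1_window <- function(junctions, fixture, window_bp = 400000) {
  span <- gene_span(fixture)
  tss <- fixture$tss
  strand <- fixture$transcript$strand
  in_gene <- function(chrom, pos)
    chrom == span$chrom & pos >= span$start & pos < span$end
  in_window <- function(chrom, pos) {
    if (strand == "-") chrom == span$chrom & pos > tss & pos <= tss + window_bp
    else chrom == span$chrom & pos >= tss - window_bp & pos < tss
  }
  gene_hit <- in_gene(junctions$chrom1, junctions$pos1) |
    in_gene(junctions$chrom2, junctions$pos2)
  win_hit <- in_window(junctions$chrom1, junctions$pos1) |
    in_window(junctions$chrom2, junctions$pos2)
  ifelse(gene_hit, "intragenic", ifelse(win_hit, "upstream_window", "outside"))
}

#' Call NSD3 disruption from junction breakends
#'
#' NSD3 is treated as disrupted when any junction breakend falls inside the
#' NSD3 ORF at or 5' of the SET-domain-encoding exons: such a break either
#' deletes the SET domain or separates it from the promoter-proximal exons
#' (out-of-frame fusions included). Breakends outside the ORF — including a
#' whole-gene deletion whose breakends flank the gene — do not trigger a call.
#'
#' @param junctions junction table
#' @param fixture NSD3 [gene_fixture()] with a SET domain in its domain table
#' @return list with `status` (`"disrupted"`/`"intact"`) and `evidence` (the
#'   triggering junction rows with breakend exon labels and the affected exon
#'   range)
#' @export
call_nsd3_disruption <- function(junctions, fixture) {
  tx <- fixture$transcript
  cc <- cds_coords(tx)
  dom <- fixture$domains
  set <- dom[dom$name == "SET", ]
  if (nrow(set) != 1) stop("fixture lacks a SET domain")
  # genomic position of the last SET-domain base
  set_last <- cc[3 * set$aa_end]
  orf_lo <- min(cc); orf_hi <- max(cc)
  # 5' of or within the SET exons, strand-aware
  hit1 <- function(chrom, pos) {
    ok <- chrom == tx$chrom & pos >= orf_lo & pos <= orf_hi
    if (tx$strand == "+") ok & pos <= set_last else ok & pos >= set_last
  }
  h <- hit1(junctions$chrom1, junctions$pos1) |
    hit1(junctions$chrom2, junctions$pos2)
  ev <- junctions[h, , drop = FALSE]
  if (nrow(ev) == 0) return(list(status = "intact", evidence = ev))
  lab <- function(chrom, pos) {
    if (chrom != tx$chrom) return(NA_character_)
    exon_index_of(tx, pos)$label
  }
  ev$breakend1_locus <- mapply(lab, ev$chrom1, ev$pos1)
  ev$breakend2_locus <- mapply(lab, ev$chrom2, ev$pos2)
  # affected exon range: from the first broken exon (an intronic break affects
  # the downstream exon) to the terminal exon
  broken <- function(chrom, pos) {
    if (!hit1(chrom, pos)) return(NA_integer_)
    loc <- exon_index_of(tx, pos)
    if (loc$status == "exon") loc$exon else max(loc$exon)
  }
  first_exon <- min(unlist(lapply(seq_len(nrow(ev)), function(i)
    c(broken(ev$chrom1[i], ev$pos1[i]), broken(ev$chrom2[i], ev$pos2[i])))),
    na.rm = TRUE)
  ev$affected_exons <- paste0(first_exon, "-", nrow(tx$exons))
  rownames(ev) <- NULL
  list(status = "disrupted", evidence = ev)
}

#' Write an annotated junction TSV
#'
#' @param junctions junction table
#' @param path output path
#' @param fgfr1 optional FGFR1 fixture: adds the window class column
#' @param nsd3 optional NSD3 fixture: adds a per-junction disruption flag
#' @param proximity_bp fold-back threshold (see [detect_foldbacks()])
#' @export
write_junction_tsv <- function(junctions, path, fgfr1 = NULL, nsd3 = NULL,
                               proximity_bp = 1e5) {
  out <- junctions
  fb <- detect_foldbacks(junctions, proximity_bp)
  out$foldback <- out$name %in% fb$name
  if (!is.null(fgfr1)) out$fgfr1_window <- assign_fgfr1_window(out, fgfr1)
  if (!is.null(nsd3)) {
    out$nsd3_disrupting <- vapply(seq_len(nrow(out)), function(i)
      call_nsd3_disruption(out[i, , drop = FALSE], nsd3)$status == "disrupted",
      logical(1))
  }
  .write_table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
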