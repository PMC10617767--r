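#' @title Gene, transcript and domain data model
#' @description Coordinate-bearing types every other module consumes. All
#'   internal coordinates are 0-based half-open; GTF (1-based inclusive) and
#'   the bundled fixture TSVs are converted at the I/O boundary. Exons are
#'   always numbered in transcription order, so for a minus-strand gene exon 1
#'   carries the highest genomic coordinates.
#' @name genome_model
NULL

# write.table without scientific notation (genomic coordinates must stay
# plain integers in BEDPE/SEG/GTF output)
.write_table <- function(...) {
  op <- options(scipen = 15)
  on.exit(options(op))
  utils::write.table(...)
}

#' Construct a genomic interval
#'
#' @param chrom chromosome name (nonempty string)
#' @param start 0-based inclusive start
#' @param end 0-based exclusive end (must exceed `start`)
#' @param strand one of `"+"`, `"-"`, `"*"` (unstranded)
#' @return a `GenomicInterval` list
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  stopifnot(is.character(chrom), nzchar(chrom), length(chrom) == 1)
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || start < 0) stop("start must be >= 0")
  if (is.na(end) || end <= start) stop("end must be > start")
  if (!strand %in% c("+", "-", "*")) stop("strand must be '+', '-' or '*'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "GenomicInterval")
}

#' Construct a transcript model
#'
#' @param gene gene name
#' @param chrom chromosome
#' @param strand `"+"` or `"-"`
#' @param exons data.frame with columns `start`, `end` (0-based half-open),
#'   rows in transcription order (exon 1 first; for minus-strand transcripts
#'   exon 1 must have the greatest coordinates)
#' @param cds_start 0-based genomic position of the base at CDS offset 0
#'   (the `A` of the canonical ATG), or `NA`
#' @param cds_end 0-based genomic position of the last CDS base (final stop
#'   codon base), or `NA`
#' @param cds_sequence spliced coding nucleotide string (optional; required by
#'   start-codon scanning)
#' @return a `Transcript` object
#' @export
transcript <- function(gene, chrom, strand, exons,
                       cds_start = NA, cds_end = NA, cds_sequence = NULL) {
  stopifnot(strand %in% c("+", "-"),
            is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  exons <- exons[, c("start", "end")]
  if (any(exons$end <= exons$start)) stop("exon end must exceed exon start")
  # non-overlap and transcription-order checks
  o <- order(exons$start)
  so <- exons[o, ]
  if (nrow(exons) > 1 && any(so$start[-1] < so$end[-nrow(so)]))
    stop("exons overlap")
  if (nrow(exons) > 1) {
    asc <- all(diff(exons$start) > 0)
    desc <- all(diff(exons$start) < 0)
    if (strand == "+" && !asc)
      stop("plus-strand exons must be in ascending genomic order")
    if (strand == "-" && !desc)
      stop("minus-strand exons must be in descending genomic order (exon 1 on top)")
  }
  tx <- structure(list(gene = gene, chrom = chrom, strand = strand,
                       exons = exons, cds_start = cds_start, cds_end = cds_end,
                       cds_sequence = cds_sequence),
                  class = "Transcript")
  if (!is.na(cds_start) && is.na(map_position_to_spliced(tx, cds_start)))
    stop("cds_start does not fall inside an exon")
  tx
}

#' Validate a protein-domain table
#'
#' @param df data.frame with columns `name`, `aa_start`, `aa_end`
#'   (1-based inclusive amino-acid coordinates on the canonical protein)
#' @return the validated data.frame, classed `ProteinDomainTable`
#' @export
protein_domains <- function(df) {
  stopifnot(all(c("name", "aa_start", "aa_end") %in% names(df)))
  if (any(df$aa_start < 1 | df$aa_end < df$aa_start))
    stop("require 1 <= aa_start <= aa_end")
  class(df) <- c("ProteinDomainTable", "data.frame")
  df
}

#' Bundle a transcript with its domain table and TSS
#'
#' @param transcript a [transcript()] object
#' @param domains a [protein_domains()] table
#' @param tss 0-based genomic position of the transcription start site; must
#'   equal the transcription-order first base of exon 1
#' @return a `GeneFixture`
#' @export
gene_fixture <- function(transcript, domains, tss) {
  first <- if (transcript$strand == "-") transcript$exons$end[1] - 1
           else transcript$exons$start[1]
  if (tss != first)
    stop("tss must equal the transcription-order first base of exon 1")
  structure(list(transcript = transcript, domains = domains, tss = tss),
            class = "GeneFixture")
}

#' Genomic span of a fixture's gene body
#' @param fixture a [gene_fixture()]
#' @return a [genomic_interval()] covering all exons
#' @export
gene_span <- function(fixture) {
  ex <- fixture$transcript$exons
  genomic_interval(fixture$transcript$chrom, min(ex$start), max(ex$end),
                   fixture$transcript$strand)
}

# positions of spliced transcript bases, 5'->3' in transcript orientation
spliced_coords <- function(tx) {
  pieces <- lapply(seq_len(nrow(tx$exons)), function(i) {
    s <- tx$exons$start[i]; e <- tx$exons$end[i]
    if (tx$strand == "-") seq.int(e - 1, s) else seq.int(s, e - 1)
  })
  unlist(pieces, use.names = FALSE)
}

# index (1-based) of a genomic position within the spliced transcript, or NA
map_position_to_spliced <- function(tx, pos) {
  match(pos, spliced_coords(tx))
}

# genomic positions of CDS bases, ordered by CDS offset (0-based offsets)
cds_coords <- function(tx) {
  if (is.na(tx$cds_start)) stop("transcript has no CDS annotation")
  sc <- spliced_coords(tx)
  i0 <- match(tx$cds_start, sc)
  i1 <- if (!is.na(tx$cds_end)) match(tx$cds_end, sc) else length(sc)
  if (is.na(i0) || is.na(i1) || i1 < i0) stop("invalid CDS bounds")
  sc[i0:i1]
}

#' Locate a genomic position relative to a transcript's exon structure
#'
#' Exons are numbered 1-based in transcription order; intronic positions are
#' reported between their flanking exons and positions beyond the transcript
#' span are reported `"outside"` with the transcript-orientation side.
#'
#' @param tx a [transcript()]
#' @param pos 0-based genomic position
#' @return list with `status` (`"exon"`, `"intron"`, `"outside"`), `exon`
#'   (exon number, or `c(k, k+1)` for introns, or `NA`), `side` (`"5'"`/`"3'"`
#'   for outside positions) and a human-readable `label`
#' @export
exon_index_of <- function(tx, pos) {
  ex <- tx$exons
  n <- nrow(ex)
  hit <- which(pos >= ex$start & pos < ex$end)
  if (length(hit) == 1)
    return(list(status = "exon", exon = hit, side = NA_character_,
                label = paste0("exon ", hit)))
  lo <- min(ex$start); hi <- max(ex$end)
  if (pos < lo || pos >= hi) {
    # genomic side -> transcript side
    genomic_left <- pos < lo
    side <- if (tx$strand == "+") {
      if (genomic_left) "5'" else "3'"
    } else {
      if (genomic_left) "3'" else "5'"
    }
    return(list(status = "outside", exon = NA_integer_, side = side,
                label = paste0("outside/", side)))
  }
  # intron: find flanking exons in transcription order
  if (tx$strand == "+") {
    k <- max(which(ex$end <= pos))
  } else {
    k <- max(which(ex$start > pos))
  }
  list(status = "intron", exon = c(k, k + 1L), side = NA_character_,
       label = paste0("intron ", k, "/", k + 1L))
}

#' Map a genomic position to its spliced-CDS offset
#'
#' @param tx a [transcript()] carrying `cds_start`
#' @param pos 0-based genomic position
#' @return 0-based offset into the spliced CDS, or `NA_integer_` when the
#'   position is intronic or in a UTR ("noncoding")
#' @export
map_genomic_to_cds <- function(tx, pos) {
  cc <- cds_coords(tx)
  i <- match(pos, cc)
  if (is.na(i)) NA_integer_ else i - 1L
}

## ------------------------------------------------------------- GTF I/O ----

#' Read transcripts of selected genes from a GTF file
#'
#' Standard 9-column GTF with 1-based inclusive coordinates; exon features are
#' grouped per transcript, converted to internal 0-based half-open coordinates
#' and sorted in transcription order. When `start_codon`/`stop_codon` or CDS
#' features are present the CDS bounds are attached.
#'
#' @param path GTF file path
#' @param gene_names character vector of gene names (matched against
#'   `gene_name`, falling back to `gene_id`)
#' @return named list of [transcript()] objects (one per requested gene; the
#'   first transcript encountered per gene is used)
#' @export
load_gtf <- function(path, gene_names) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9))
    stop("malformed GTF line ", body[which(nf != 9)[1]], ": expected 9 fields")
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  gname <- if ("gene_name" %in% names(md)) as.character(md$gene_name)
           else NA_character_
  gid <- if ("gene_id" %in% names(md)) as.character(md$gene_id)
         else NA_character_
  key <- ifelse(is.na(gname) | !nzchar(gname), gid, gname)
  out <- list()
  for (g in gene_names) {
    sel <- which(key == g | gid == g)
    if (length(sel) == 0) stop("gene not found in GTF: ", g)
    sub <- gr[sel]
    exi <- sub[as.character(sub$type) == "exon"]
    if (length(exi) == 0) stop("gene has no exon features: ", g)
    strand <- as.character(BiocGenerics::strand(exi))[1]
    ex <- data.frame(start = BiocGenerics::start(exi) - 1,
                     end = BiocGenerics::end(exi))
    ex <- ex[order(ex$start, decreasing = (strand == "-")), , drop = FALSE]
    rownames(ex) <- NULL
    cds <- sub[as.character(sub$type) %in% c("CDS", "start_codon", "stop_codon")]
    cds_start <- NA; cds_end <- NA
    if (length(cds) > 0) {
      lo <- min(BiocGenerics::start(cds)) - 1
      hi <- max(BiocGenerics::end(cds)) - 1
      if (strand == "+") { cds_start <- lo; cds_end <- hi }
      else { cds_start <- hi; cds_end <- lo }
    }
    out[[g]] <- transcript(g, as.character(GenomeInfoDb::seqnames(exi))[1],
                           strand, ex, cds_start, cds_end)
  }
  out
}

#' Write transcripts back to GTF (exon features only, plus CDS bounds)
#'
#' Inverse of [load_gtf()] up to attribute formatting: re-loading reproduces
#' identical internal coordinates.
#'
#' @param transcripts list of [transcript()] objects
#' @param path output path
#' @export
write_gtf <- function(transcripts, path) {
  rows <- lapply(transcripts, function(tx) {
    attr_str <- sprintf('gene_id "%s"; gene_name "%s"; transcript_id "%s.t1";',
                        tx$gene, tx$gene, tx$gene)
    ex <- data.frame(seqname = tx$chrom, source = "ampliconlens",
                     feature = "exon", start = tx$exons$start + 1,
                     end = tx$exons$end, score = ".", strand = tx$strand,
                     frame = ".", attribute = attr_str)
    if (!is.na(tx$cds_start)) {
      lo <- min(tx$cds_start, tx$cds_end); hi <- max(tx$cds_start, tx$cds_end)
      # one CDS row per overlapping exon piece
      cdsrows <- do.call(rbind, lapply(seq_len(nrow(tx$exons)), function(i) {
        s <- max(tx$exons$start[i], lo); e <- min(tx$exons$end[i] - 1, hi)
        if (s > e) return(NULL)
        data.frame(seqname = tx$chrom, source = "ampliconlens",
                   feature = "CDS", start = s + 1, end = e + 1, score = ".",
                   strand = tx$strand, frame = ".", attribute = attr_str)
      }))
      ex <- rbind(ex, cdsrows)
    }
    ex
  })
  tab <- do.call(rbind, rows)
  .write_table(tab, path, sep = "\t", quote = FALSE,
               row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ----------------------------------------------------- bundled fixtures ----

extdata <- function(name) {
  p <- system.file("extdata", name, package = "ampliconlens")
  if (!nzchar(p)) stop("bundled fixture not found: ", name)
  p
}

#' Load a gene model from the bundled fixture TSV format
#'
#' The fixture format is a TSV with columns
#' `gene, element_type, name, start, end, frame_or_aa` and 1-based inclusive
#' genomic coordinates; `element_type` is one of `gene` (frame_or_aa holds the
#' strand), `tss`, `exon`, `cds` (`start_codon`/`stop_codon` rows) and
#' `domain` (start/end are amino-acid coordinates).
#'
#' @param path fixture TSV path
#' @param cds_fasta optional FASTA with the spliced CDS sequence
#' @param chrom chromosome the model lives on
#' @return a [gene_fixture()]
#' @export
load_fixture_tsv <- function(path, cds_fasta = NULL, chrom = "chr8") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  gene <- tab$gene[1]
  strand <- tab$frame_or_aa[tab$element_type == "gene"][1]
  ex <- tab[tab$element_type == "exon", ]
  ex <- ex[order(as.integer(ex$frame_or_aa)), ]
  exons <- data.frame(start = ex$start - 1, end = ex$end)
  sc <- tab[tab$element_type == "cds" & tab$name == "start_codon", ]
  st <- tab[tab$element_type == "cds" & tab$name == "stop_codon", ]
  if (strand == "-") {
    cds_start <- sc$end - 1; cds_end <- st$start - 1
  } else {
    cds_start <- sc$start - 1; cds_end <- st$end - 1
  }
  cds_seq <- NULL
  if (!is.null(cds_fasta)) {
    seqs <- Biostrings::readDNAStringSet(cds_fasta)
    cds_seq <- as.character(seqs[[1]])
  }
  tx <- transcript(gene, chrom, strand, exons, cds_start, cds_end, cds_seq)
  dm <- tab[tab$element_type == "domain", ]
  domains <- protein_domains(data.frame(name = dm$name, aa_start = dm$start,
                                        aa_end = dm$end))
  tss <- tab$start[tab$element_type == "tss"][1] - 1
  gene_fixture(tx, domains, tss)
}

#' Bundled synthetic FGFR1 annotation snapshot
#'
#' 18 exons on the minus strand of chr8 (GRCh37-compatible span), canonical
#' ATG in exon 2, domain table for FGFR1-alpha (822 aa) and a synthetic CDS
#' whose in-frame ATGs sit at residues 1, 150, 250 and 365. See the package
#' vignette for what this snapshot does and does not emulate.
#'
#' @return a [gene_fixture()]
#' @export
fgfr1_fixture <- function() {
  load_fixture_tsv(extdata("fgfr1_model_synthetic.tsv"),
                   cds_fasta = extdata("fgfr1_cds_synthetic.fa"))
}

#' Bundled synthetic NSD3 (long isoform) annotation snapshot
#'
#' 24 exons on the plus strand of chr8, 1437 aa, SET domain (residues
#' 1152-1262) encoded by exons 19-21.
#'
#' @return a [gene_fixture()]
#' @export
nsd3_fixture <- function() {
  load_fixture_tsv(extdata("nsd3_model_synthetic.tsv"))
}

#' Gene spans on the 8p11-p12 amplicon used for peak annotation
#'
#' @return data.frame with columns `gene, chrom, start, end, strand`
#'   (0-based half-open)
#' @export
amplicon_genes <- function() {
  tab <- utils::read.delim(extdata("genes_8p_synthetic.tsv"),
                           stringsAsFactors = FALSE)
  tab$start <- tab$start - 1
  tab
}

#' Project a domain table onto exon numbers via CDS arithmetic
#'
#' @param fixture a [gene_fixture()] whose transcript has CDS bounds
#' @return the domain table with added `exon_start`, `exon_end` columns
#' @export
domains_to_exons <- function(fixture) {
  tx <- fixture$transcript
  cc <- cds_coords(tx)
  dom <- fixture$domains
  exon_of_aa <- function(aa) {
    pos <- cc[3 * (aa - 1) + 1]
    exon_index_of(tx, pos)$exon
  }
  dom$exon_start <- vapply(dom$aa_start, exon_of_aa, integer(1))
  dom$exon_end <- vapply(dom$aa_end, exon_of_aa, integer(1))
  dom
}
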