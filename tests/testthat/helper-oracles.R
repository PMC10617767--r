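# Shared toy builders and independent brute-force oracles. Oracles stay
# deliberately naive (per-base loops, exhaustive enumeration) and never share
# code with the implementation paths they check.

toy_transcript <- function(strand = "+", exon_starts, exon_ends,
                           cds_start = NA, cds_end = NA, cds_seq = NULL) {
  transcript("toy", "chrT", strand,
             data.frame(start = exon_starts, end = exon_ends),
             cds_start, cds_end, cds_seq)
}

# per-base exon/intron/outside table by direct scanning (independent of
# exon_index_of's arithmetic)
brute_locate <- function(tx, pos) {
  ex <- tx$exons
  for (i in seq_len(nrow(ex)))
    if (pos >= ex$start[i] && pos < ex$end[i]) return(paste0("exon ", i))
  if (pos < min(ex$start) || pos >= max(ex$end)) {
    left <- pos < min(ex$start)
    side <- if (tx$strand == "+") (if (left) "5'" else "3'")
            else (if (left) "3'" else "5'")
    return(paste0("outside/", side))
  }
  # intron: which consecutive exon pair flanks pos in transcription order
  for (i in seq_len(nrow(ex) - 1)) {
    lo <- min(ex$end[i], ex$end[i + 1], ex$start[i], ex$start[i + 1])
    a <- if (tx$strand == "+") ex$end[i] else ex$end[i + 1]
    b <- if (tx$strand == "+") ex$start[i + 1] else ex$start[i]
    if (pos >= a && pos < b) return(paste0("intron ", i, "/", i + 1))
  }
  stop("unlocatable position ", pos)
}

# spliced CDS offset by independent concatenation
brute_cds_offset <- function(tx, pos) {
  ex <- tx$exons
  ord <- order(ex$start, decreasing = (tx$strand == "-"))
  coords <- c()
  for (i in ord) {
    b <- ex$start[i]:(ex$end[i] - 1)
    if (tx$strand == "-") b <- rev(b)
    coords <- c(coords, b)
  }
  i0 <- which(coords == tx$cds_start)
  i1 <- which(coords == tx$cds_end)
  cds <- coords[i0:i1]
  hit <- which(cds == pos)
  if (length(hit)) hit - 1L else NA_integer_
}

# per-base binned means
naive_bins <- function(segments, window, n_bins, baseline = 2) {
  bw <- (window$end - window$start) / n_bins
  vals <- numeric(n_bins)
  for (i in seq_len(n_bins)) {
    lo <- window$start + (i - 1) * bw
    cns <- c()
    for (p in lo:(lo + bw - 1)) {
      hit <- which(segments$chrom == window$chrom & segments$start <= p &
                     segments$end > p)
      if (length(hit)) cns <- c(cns, segments$cn[hit[1]])
    }
    vals[i] <- if (length(cns)) mean(cns) else baseline
  }
  vals
}

# naive O(n*w) centered rolling mean with edge truncation
naive_rolling <- function(x, w) {
  n <- length(x)
  hl <- floor(w / 2); hr <- w - 1 - hl
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - hl):min(n, i + hr)]), numeric(1))
}

# Exhaustive closure of BFB strings under the simulation update rule,
# keeping every state whose per-segment counts stay within `cap`. Because
# any final string with counts <= cap admits a cycle chain whose
# intermediates also stay within cap, this closure is complete for count
# vectors bounded by cap.
bfb_oracle_closure <- function(k, cap) {
  key <- function(s) paste(s, collapse = ",")
  start <- seq_len(k)
  seen <- new.env(parent = emptyenv())
  assign(key(start), TRUE, envir = seen)
  queue <- list(start); head <- 1
  strings <- list(start)
  while (head <= length(queue)) {
    s <- queue[[head]]; head <- head + 1
    for (b in seq_along(s)) {
      child <- c(s[seq_len(b)], rev(-s[seq_len(b)]))
      if (any(tabulate(abs(child), k) > cap)) next
      ck <- key(child)
      if (is.null(seen[[ck]])) {
        assign(ck, TRUE, envir = seen)
        queue[[length(queue) + 1]] <- child
        strings[[length(strings) + 1]] <- child
      }
    }
  }
  counts <- unique(vapply(strings, function(s)
    paste(tabulate(abs(s), k), collapse = ","), character(1)))
  list(strings = strings, count_keys = counts)
}

# exhaustive two-sided Fisher by enumeration over tables with fixed margins
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || (N - c1) == 0) return(1)
  xs <- max(0, c1 - r2):min(c1, r1)
  p <- vapply(xs, function(x)
    choose(r1, x) * choose(r2, c1 - x) / choose(N, c1), numeric(1))
  p0 <- p[xs == a]
  sum(p[p <= p0 * (1 + 1e-7)])
}

write_toy_gtf <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtf_line <- function(chrom, feature, start, end, strand, gene,
                     tx_id = paste0(gene, ".t1")) {
  sprintf("%s\tsynthetic\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_name \"%s\"; transcript_id \"%s\";",
          chrom, feature, start, end, strand, gene, gene, tx_id)
}

rand_segments <- function(seed, chrom = "chrT", lo = 800, hi = 2200) {
  set.seed(seed)
  cuts <- sort(sample(lo:hi, sample(3:8, 1)))
  bounds <- c(lo, cuts, hi)
  data.frame(chrom = chrom, start = bounds[-length(bounds)],
             end = bounds[-1], cn = sample(0:12, length(bounds) - 1, TRUE))
}

make_test_junction <- function(p1, s1, p2, s2, chrom1 = "chr8",
                               chrom2 = chrom1, support = NA) {
  junction_table(data.frame(chrom1 = chrom1, pos1 = p1, side1 = s1,
                            chrom2 = chrom2, pos2 = p2, side2 = s2,
                            support = support))
}
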