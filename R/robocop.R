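#' @title ROBOCOP copy-number profiling
#' @description ROlling Binmeans Of COPy numbers: a fixed view window (by
#'   default 2 Mb around the FGFR1 locus) is split into equal bins (default
#'   10,000, i.e. 200 bp each), segmented copy number is mapped onto the bins
#'   per sample, per-condition per-bin means are taken and a rolling mean
#'   (window 10 for WGS-derived segments, 500 for CAGE-derived data) smooths
#'   the profile. Peak-centering and half-maximum focality metrics summarise
#'   where an amplicon is centered and how narrow it is.
#' @name robocop
NULL

#' Read a SEG-like copy-number TSV
#'
#' Expected columns: `sample, chrom, start, end, total_cn` (1-based inclusive
#' coordinates in the file, converted to 0-based half-open).
#'
#' @param path TSV path
#' @return data.frame of segments
#' @export
read_seg <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "total_cn")
  if (!all(need %in% names(tab)))
    stop("SEG file needs columns: ", paste(need, collapse = ", "))
  tab$start <- tab$start - 1
  if (any(tab$total_cn < 0)) stop("negative copy number in SEG file")
  tab
}

#' Write segments to a SEG-like TSV (inverse of [read_seg()])
#' @param segments data.frame with `sample, chrom, start, end, total_cn`
#'   (0-based half-open)
#' @param path output path
#' @export
write_seg <- function(segments, path) {
  out <- segments
  out$start <- out$start + 1
  .write_table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default 2 Mb view window centered on the FGFR1 gene body
#' @param fixture FGFR1 [gene_fixture()]
#' @param size window size in bp (default 2e6)
#' @return a [genomic_interval()]
#' @export
fgfr1_view_window <- function(fixture, size = 2e6) {
  span <- gene_span(fixture)
  center <- floor((span$start + span$end) / 2)
  genomic_interval(span$chrom, center - size / 2, center + size / 2)
}

#' Map copy-number segments onto fixed-width bins
#'
#' Each bin's value is the overlap-length-weighted mean of the overlapping
#' segments' copy numbers; bins with no overlapping segment take the diploid
#' baseline (default 2, switchable to `NA`).
#'
#' @param segments data.frame with `chrom, start, end, cn` (or `total_cn`),
#'   0-based half-open, non-overlapping within a sample
#' @param window [genomic_interval()] view window
#' @param n_bins number of equal bins (window length must be divisible)
#' @param baseline value for uncovered bins (default 2; `NA` to propagate
#'   missingness)
#' @return a `BinnedProfile` list: `window`, `n_bins`, `bin_width`, `values`,
#'   `roll_window`
#' @export
bin_segments <- function(segments, window, n_bins = 10000, baseline = 2) {
  stopifnot(n_bins >= 1)
  if (!"cn" %in% names(segments) && "total_cn" %in% names(segments))
    segments$cn <- segments$total_cn
  len <- window$end - window$start
  if (len %% n_bins != 0)
    stop("window length ", len, " not divisible into ", n_bins, " bins")
  bw <- len / n_bins
  seg <- segments[segments$chrom == window$chrom &
                  segments$end > window$start &
                  segments$start < window$end, , drop = FALSE]
  if (nrow(seg) > 1) {
    o <- order(seg$start)
    so <- seg[o, ]
    bad <- which(so$start[-1] < so$end[-nrow(so)])
    if (length(bad))
      stop(sprintf("overlapping segments: [%d,%d) and [%d,%d)",
                   so$start[bad[1]], so$end[bad[1]],
                   so$start[bad[1] + 1], so$end[bad[1] + 1]))
  }
  wsum <- numeric(n_bins)   # overlap-weighted cn sum per bin
  wlen <- numeric(n_bins)   # covered length per bin
  for (i in seq_len(nrow(seg))) {
    s <- max(seg$start[i], window$start)
    e <- min(seg$end[i], window$end)
    b0 <- floor((s - window$start) / bw) + 1     # first overlapped bin
    b1 <- ceiling((e - window$start) / bw)       # last overlapped bin
    idx <- b0:b1
    bin_lo <- window$start + (idx - 1) * bw
    ov <- pmin(bin_lo + bw, e) - pmax(bin_lo, s)
    wsum[idx] <- wsum[idx] + ov * seg$cn[i]
    wlen[idx] <- wlen[idx] + ov
  }
  vals <- ifelse(wlen > 0, wsum / pmax(wlen, .Machine$double.eps), baseline)
  structure(list(window = window, n_bins = n_bins, bin_width = bw,
                 values = vals, roll_window = 1L),
            class = "BinnedProfile")
}

#' Per-bin mean across profiles
#'
#' @param profiles list of `BinnedProfile`s sharing window and bin count
#' @return a `BinnedProfile` of per-bin arithmetic means
#' @export
group_mean_profile <- function(profiles) {
  if (length(profiles) == 0) stop("empty profile list")
  w <- profiles[[1]]$window
  nb <- profiles[[1]]$n_bins
  for (p in profiles) {
    if (p$n_bins != nb || p$window$chrom != w$chrom ||
        p$window$start != w$start || p$window$end != w$end)
      stop("profiles have mismatched windows")
  }
  vals <- rowMeans(vapply(profiles, function(p) p$values, numeric(nb)))
  structure(list(window = w, n_bins = nb, bin_width = profiles[[1]]$bin_width,
                 values = vals, roll_window = 1L),
            class = "BinnedProfile")
}

#' Centered rolling mean with edge shrinkage
#'
#' Window size `w` covers `floor(w/2)` bins to the left and `w - 1 -
#' floor(w/2)` to the right of each bin; at the profile edges the window is
#' truncated to the available bins, so the output length equals the input
#' length and constant profiles are unchanged for any `w`.
#'
#' @param profile a `BinnedProfile`
#' @param w rolling window size in bins (1 gives the identity)
#' @return smoothed `BinnedProfile` with `roll_window` set
#' @export
rolling_mean <- function(profile, w) {
  stopifnot(w >= 1)
  n <- profile$n_bins
  if (w > n) stop("rolling window ", w, " exceeds bin count ", n)
  x <- profile$values
  hl <- floor(w / 2); hr <- w - 1 - hl
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - hl, 1); hi <- pmin(i + hr, n)
  out <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  profile$values <- out
  profile$roll_window <- as.integer(w)
  profile
}

#' The ROBOCOP algorithm: per-condition binned rolling-mean profiles
#'
#' Composition of [bin_segments()] per sample, [group_mean_profile()] per
#' condition and [rolling_mean()] with a data-kind-specific window (WGS: 10,
#' CAGE: 500).
#'
#' @param samples named list of per-sample segment data.frames
#' @param labels character vector of condition labels, one per sample
#' @param window [genomic_interval()] view window
#' @param n_bins bins in the window (default 10,000)
#' @param data_kind `"wgs"` or `"cage"`; selects the rolling window
#' @param roll_window override for the rolling window size
#' @param baseline uncovered-bin value (see [bin_segments()])
#' @return named list of `BinnedProfile`s, one per condition
#' @export
robocop_profile <- function(samples, labels, window, n_bins = 10000,
                            data_kind = c("wgs", "cage"), roll_window = NULL,
                            baseline = 2) {
  data_kind <- match.arg(data_kind)
  if (length(samples) != length(labels))
    stop("one label per sample required")
  if (length(samples) == 0) stop("empty sample list")
  if (is.null(roll_window))
    roll_window <- if (data_kind == "wgs") 10 else 500
  out <- list()
  for (cond in unique(labels)) {
    idx <- which(labels == cond)
    if (length(idx) == 0) stop("empty condition group: ", cond)
    profs <- lapply(samples[idx], bin_segments, window = window,
                    n_bins = n_bins, baseline = baseline)
    out[[cond]] <- rolling_mean(group_mean_profile(profs), roll_window)
  }
  out
}

#' Genomic position of the profile maximum and its gene
#'
#' @param profile a `BinnedProfile`
#' @param genes data.frame with `gene, chrom, start, end` (0-based half-open),
#'   e.g. [amplicon_genes()]
#' @return list: `peak_pos` (genomic midpoint of the maximal bin, leftmost on
#'   ties), `peak_value`, `gene` (containing or nearest gene), `distinct`
#'   (FALSE for a flat profile)
#' @export
peak_center <- function(profile, genes) {
  v <- profile$values
  i <- which.max(v)                      # leftmost maximum on ties
  pos <- profile$window$start + (i - 0.5) * profile$bin_width
  distinct <- max(v) > min(v)
  g <- genes[genes$chrom == profile$window$chrom, , drop = FALSE]
  gene <- NA_character_
  if (nrow(g)) {
    inside <- which(pos >= g$start & pos < g$end)
    if (length(inside)) gene <- g$gene[inside[1]]
    else {
      d <- pmax(g$start - pos, pos - g$end, 0)
      gene <- g$gene[which.min(d)]
    }
  }
  list(peak_pos = pos, peak_value = v[i], gene = gene, distinct = distinct)
}

#' Half-maximum focality width of an amplicon profile
#'
#' Length (bp) of the maximal contiguous run of bins containing the peak with
#' value at or above `baseline + (peak - baseline)/2`. A profile that never
#' exceeds the baseline has width 0 and is flagged.
#'
#' @param profile a `BinnedProfile`
#' @param baseline diploid baseline (default 2)
#' @return list: `width_bp`, `flagged` (no amplification above baseline)
#' @export
focal_width <- function(profile, baseline = 2) {
  v <- profile$values
  peak <- max(v)
  if (peak <= baseline) return(list(width_bp = 0, flagged = TRUE))
  thr <- baseline + (peak - baseline) / 2
  i <- which.max(v)
  above <- v >= thr
  lo <- i; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- i; while (hi < length(v) && above[hi + 1]) hi <- hi + 1
  list(width_bp = (hi - lo + 1) * profile$bin_width, flagged = FALSE)
}

#' Write per-condition profiles to TSV
#' @param profiles named list of `BinnedProfile`s (same window)
#' @param path output path
#' @export
write_profile_tsv <- function(profiles, path) {
  p1 <- profiles[[1]]
  starts <- p1$window$start + (seq_len(p1$n_bins) - 1) * p1$bin_width
  tab <- data.frame(bin_start = starts + 1, bin_end = starts + p1$bin_width)
  for (nm in names(profiles)) tab[[nm]] <- profiles[[nm]]$values
  .write_table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
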