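win_small <- genomic_interval("chrT", 1000, 2000)   # 1 kb toy window

test_that("bin_segments: constants, steps, defaults and per-base oracle", {
  flat <- data.frame(chrom = "chrT", start = 0, end = 5000, cn = 2)
  p <- bin_segments(flat, win_small, n_bins = 10)
  expect_equal(p$values, rep(2, 10))
  expect_equal(p$bin_width, 100)

  step <- data.frame(chrom = "chrT", start = c(0, 1500), end = c(1500, 5000),
                     cn = c(2, 8))
  p <- bin_segments(step, win_small, n_bins = 10)
  expect_equal(p$values, c(rep(2, 5), rep(8, 5)))
  # straddling bin takes the overlap-weighted mix
  p2 <- bin_segments(data.frame(chrom = "chrT", start = c(0, 1550),
                                end = c(1550, 5000), cn = c(2, 8)),
                     win_small, n_bins = 10)
  expect_equal(p2$values[6], (50 * 2 + 50 * 8) / 100)

  for (seed in 1:10) {
    seg <- rand_segments(seed)
    p <- bin_segments(seg, win_small, n_bins = 20)
    expect_equal(p$values, naive_bins(seg, win_small, 20), tolerance = 1e-9,
                 info = paste("seed", seed))
  }
  # default parameters: 2 Mb over 10,000 bins gives 200 bp bins
  big <- bin_segments(data.frame(chrom = "chrT", start = 0, end = 4e6, cn = 3),
                      genomic_interval("chrT", 1e6, 3e6))
  expect_equal(big$bin_width, 200)
  expect_equal(big$n_bins, 10000)
})

test_that("bin_segments flags overlapping input and honours NA baseline", {
  ov <- data.frame(chrom = "chrT", start = c(1000, 1400), end = c(1500, 1900),
                   cn = c(2, 4))
  expect_error(bin_segments(ov, win_small, 10), "overlapping segments")
  gap <- data.frame(chrom = "chrT", start = 1000, end = 1500, cn = 4)
  p <- bin_segments(gap, win_small, 10, baseline = NA)
  expect_true(all(is.na(p$values[6:10])))
  expect_equal(p$values[1:5], rep(4, 5))
})

test_that("conservation: fully covered window preserves the weighted mean", {
  for (seed in 11:15) {
    seg <- rand_segments(seed)
    p <- bin_segments(seg, win_small, n_bins = 50)
    clipped <- seg
    clipped$start <- pmax(clipped$start, win_small$start)
    clipped$end <- pmin(clipped$end, win_small$end)
    clipped <- clipped[clipped$end > clipped$start, ]
    wmean <- sum(clipped$cn * (clipped$end - clipped$start)) /
      sum(clipped$end - clipped$start)
    expect_equal(mean(p$values), wmean, tolerance = 1e-9)
  }
})

test_that("group_mean_profile averages and is permutation invariant", {
  ps <- lapply(1:5, function(s) bin_segments(rand_segments(s), win_small, 20))
  g <- group_mean_profile(ps)
  mat <- sapply(ps, function(p) p$values)
  expect_equal(g$values, rowMeans(mat), tolerance = 1e-12)
  g2 <- group_mean_profile(ps[c(3, 5, 1, 4, 2)])
  expect_equal(g$values, g2$values)
  expect_equal(group_mean_profile(list(ps[[1]]))$values, ps[[1]]$values)
  two <- list(bin_segments(data.frame(chrom = "chrT", start = 0, end = 5000,
                                      cn = 2), win_small, 10),
              bin_segments(data.frame(chrom = "chrT", start = 0, end = 5000,
                                      cn = 4), win_small, 10))
  expect_equal(group_mean_profile(two)$values, rep(3, 10))
  shifted <- bin_segments(rand_segments(1), genomic_interval("chrT", 0, 1000),
                          20)
  expect_error(group_mean_profile(list(ps[[1]], shifted)), "mismatched")
})

test_that("rolling_mean: identity, idempotence, bounds, oracle", {
  p <- bin_segments(rand_segments(21), win_small, 50)
  expect_equal(rolling_mean(p, 1)$values, p$values)
  const <- p; const$values <- rep(3.5, 50)
  for (w in c(2, 7, 10, 49)) {
    expect_equal(rolling_mean(const, w)$values, rep(3.5, 50))
    sm <- rolling_mean(p, w)$values
    expect_equal(sm, naive_rolling(p$values, w), tolerance = 1e-12)
    expect_true(all(sm >= min(p$values) - 1e-12 &
                      sm <= max(p$values) + 1e-12))
  }
  expect_error(rolling_mean(p, 51), "exceeds")
})

test_that("robocop_profile composes per condition with kind-specific windows", {
  flat <- data.frame(chrom = "chrT", start = 0, end = 5000, cn = 2)
  prof <- robocop_profile(list(flat), "a", win_small, n_bins = 100)
  expect_equal(prof$a$values, rep(2, 100))
  expect_equal(prof$a$roll_window, 10)     # wgs default
  prof2 <- robocop_profile(list(flat), "a", win_small, n_bins = 1000,
                           data_kind = "cage")
  expect_equal(prof2$a$roll_window, 500)
  # planted peaks at different loci per condition
  peak1 <- rbind(flat, data.frame(chrom = "chrT", start = 1200, end = 1300,
                                  cn = 20))
  peak1 <- peak1[c(1), ]; # rebuild non-overlapping
  peak1 <- data.frame(chrom = "chrT", start = c(0, 1200, 1300),
                      end = c(1200, 1300, 5000), cn = c(2, 20, 2))
  peak2 <- data.frame(chrom = "chrT", start = c(0, 1700, 1800),
                      end = c(1700, 1800, 5000), cn = c(2, 18, 2))
  prof <- robocop_profile(list(peak1, peak2), c("c1", "c2"), win_small,
                          n_bins = 100, roll_window = 1)
  expect_equal(which.max(prof$c1$values), 21)   # bins 21-30 cover 1200-1300
  expect_true(all(prof$c1$values[21:30] == max(prof$c1$values)))
  expect_equal(which.max(prof$c2$values), 71)
  expect_error(robocop_profile(list(), character(0), win_small), "empty")
})

test_that("peak_center finds the argmax and annotates genes", {
  genes <- data.frame(gene = c("G1", "G2"), chrom = "chrT",
                      start = c(1200, 1700), end = c(1350, 1900))
  two_peaks <- data.frame(chrom = "chrT", start = c(0, 1200, 1300, 1700, 1800),
                          end = c(1200, 1300, 1700, 1800, 5000),
                          cn = c(2, 12, 2, 20, 2))
  p <- bin_segments(two_peaks, win_small, 100)
  pc <- peak_center(p, genes)
  expect_equal(pc$gene, "G2")              # taller peak wins
  expect_true(pc$peak_pos >= 1700 && pc$peak_pos < 1800)
  # exhaustive argmax oracle
  expect_equal(pc$peak_value, max(p$values))
  flat <- bin_segments(data.frame(chrom = "chrT", start = 0, end = 5000,
                                  cn = 2), win_small, 100)
  fc <- peak_center(flat, genes)
  expect_false(fc$distinct)
  expect_equal(fc$peak_pos, win_small$start + 0.5 * flat$bin_width)
})

test_that("focal_width: rectangle, flat flag, triangle oracle", {
  rect <- data.frame(chrom = "chrT", start = c(0, 1400, 1600),
                     end = c(1400, 1600, 5000), cn = c(2, 10, 2))
  p <- bin_segments(rect, win_small, 100)
  expect_equal(focal_width(p)$width_bp, 200)     # 20 bins x 10 bp
  flat <- bin_segments(data.frame(chrom = "chrT", start = 0, end = 5000,
                                  cn = 2), win_small, 100)
  fw <- focal_width(flat)
  expect_equal(fw$width_bp, 0)
  expect_true(fw$flagged)
  # triangular peak: compare against a direct threshold scan
  tri <- flat
  tri$values <- 2 + pmax(0, 10 - abs(seq_len(100) - 50)) / 2
  thr <- 2 + (max(tri$values) - 2) / 2
  i <- which.max(tri$values)
  lo <- i; while (lo > 1 && tri$values[lo - 1] >= thr) lo <- lo - 1
  hi <- i; while (hi < 100 && tri$values[hi + 1] >= thr) hi <- hi + 1
  expect_equal(focal_width(tri)$width_bp, (hi - lo + 1) * tri$bin_width)
})
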