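test_that("BEDPE strands map to retained sides and orientation classes", {
  path <- tempfile(fileext = ".bedpe")
  writeLines(c(
    "chr8\t99\t100\tchr8\t499\t500\tj1\t10\t+\t+",
    "chr8\t99\t100\tchr8\t499\t500\tj2\t10\t-\t-",
    "chr8\t99\t100\tchr8\t499\t500\tj3\t10\t+\t-",
    "chr8\t99\t100\tchr8\t499\t500\tj4\t10\t-\t+"), path)
  j <- read_bedpe(path)
  expect_equal(j$orientation_class,
               c("tail_to_tail", "head_to_head", "deletion_type",
                 "duplication_type"))
  expect_equal(j$pos1, rep(99, 4))
  bad <- tempfile(fileext = ".bedpe")
  writeLines("chr8\t1\t2\tchr8\t3\t4\tx\t1", bad)
  expect_error(read_bedpe(bad), "10 columns")
})

test_that("BEDPE round trip preserves junctions", {
  j <- make_test_junction(c(100, 5000), c("left", "right"),
                          c(900, 9000), c("left", "right"), support = c(5, 9))
  path <- tempfile(fileext = ".bedpe")
  write_bedpe(j, path)
  back <- read_bedpe(path)
  expect_equal(back[, c("chrom1", "pos1", "side1", "pos2", "side2",
                        "orientation_class")],
               j[, c("chrom1", "pos1", "side1", "pos2", "side2",
                     "orientation_class")])
})

test_that("VCF BND bracket notation decodes to junctions", {
  vcf <- c("##fileformat=VCFv4.2",
    "##contig=<ID=chr8>", "##contig=<ID=chr9>",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"m\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr8\t100\tbnd_a_1\tN\tN]chr8:500]\t.\tPASS\tSVTYPE=BND;MATEID=bnd_a_2",
    "chr8\t500\tbnd_a_2\tN\tN]chr8:100]\t.\tPASS\tSVTYPE=BND;MATEID=bnd_a_1",
    "chr8\t1000\tbnd_b_1\tN\t[chr8:2000[N\t.\tPASS\tSVTYPE=BND;MATEID=bnd_b_2",
    "chr8\t2000\tbnd_b_2\tN\t[chr8:1000[N\t.\tPASS\tSVTYPE=BND;MATEID=bnd_b_1",
    "chr8\t3000\tbnd_c_1\tN\tN[chr9:4000[\t.\tPASS\tSVTYPE=BND;MATEID=bnd_c_2",
    "chr9\t4000\tbnd_c_2\tN\t]chr8:3000]N\t.\tPASS\tSVTYPE=BND;MATEID=bnd_c_1")
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  j <- read_vcf_bnd(f)
  # hand-decoded expectations: t]p] -> both left; [p[t -> both right;
  # t[p[ / ]p]t -> left/right
  expect_equal(nrow(j), 3)
  expect_equal(j$orientation_class,
               c("tail_to_tail", "head_to_head", "interchromosomal"))
  expect_equal(j$pos1, c(99, 999, 2999))
  expect_equal(j$pos2, c(499, 1999, 3999))
  # unmated record warns and is skipped
  f2 <- tempfile(fileext = ".vcf")
  writeLines(vcf[c(1:6, 7)], f2)
  expect_warning(j2 <- read_vcf_bnd(f2), "unmated")
  expect_equal(nrow(j2), 0)
})

test_that("classification is invariant under breakend swap", {
  set.seed(5)
  for (i in 1:50) {
    p <- sort(sample(1e6, 2))
    s <- sample(c("left", "right"), 2, replace = TRUE)
    a <- make_test_junction(p[1], s[1], p[2], s[2])
    b <- make_test_junction(p[2], s[2], p[1], s[1])
    expect_equal(a$orientation_class, b$orientation_class)
    expect_equal(a$pos1, b$pos1)
  }
})

test_that("the validated fold-back pair classifies head-to-head", {
  # two breaks 720 bp apart, both right-retained (S00674)
  j <- make_test_junction(36417297, "right", 36418017, "right", support = 54)
  expect_equal(j$orientation_class, "head_to_head")
  fb <- detect_foldbacks(j)
  expect_equal(nrow(fb), 1)
  expect_equal(fb$span, 720)
})

test_that("detect_foldbacks equals a brute-force filter", {
  set.seed(11)
  n <- 120
  df <- data.frame(
    chrom1 = sample(c("chr8", "chr9"), n, TRUE),
    pos1 = sample(1e7, n), side1 = sample(c("left", "right"), n, TRUE),
    chrom2 = sample(c("chr8", "chr9"), n, TRUE),
    pos2 = sample(1e7, n), side2 = sample(c("left", "right"), n, TRUE))
  j <- junction_table(df)
  for (thr in c(1e3, 1e5, 5e6)) {
    got <- detect_foldbacks(j, thr)$name
    want <- j$name[sapply(seq_len(nrow(j)), function(i)
      j$chrom1[i] == j$chrom2[i] && j$side1[i] == j$side2[i] &&
        abs(j$pos2[i] - j$pos1[i]) <= thr)]
    expect_setequal(got, want)
  }
  # a 5 Mb tail-to-tail is not a fold-back at the default threshold
  far <- make_test_junction(1e6, "left", 6e6, "left")
  expect_equal(nrow(detect_foldbacks(far)), 0)
})

test_that("FGFR1 window assignment handles the published cases", {
  fx <- fgfr1_fixture()
  # H1581 upstream tail-to-tail (1-based chr8:38,595,657)
  h <- make_test_junction(38595656, "left", 38596261, "left")
  expect_equal(assign_fgfr1_window(h, fx), "upstream_window")
  # intragenic break beats window membership
  intra <- make_test_junction(38320000, "left", 38400000, "left")
  expect_equal(assign_fgfr1_window(intra, fx), "intragenic")
  # 1 Mb upstream is outside
  far <- make_test_junction(39326352, "left", 39327000, "left")
  expect_equal(assign_fgfr1_window(far, fx), "outside")
})

test_that("window partition is exclusive and exhaustive on chr8", {
  fx <- fgfr1_fixture()
  set.seed(3)
  pos <- sample(3.7e7:3.95e7, 300)
  j <- junction_table(data.frame(chrom1 = "chr8", pos1 = pos, side1 = "left",
                                 chrom2 = "chr8", pos2 = pos + 500,
                                 side2 = "left"))
  cls <- assign_fgfr1_window(j, fx)
  expect_true(all(cls %in% c("intragenic", "upstream_window", "outside")))
  # boundary behaviour: window is (TSS, TSS+400kb]
  tss <- fx$tss
  at_tss <- make_test_junction(tss, "left", tss + 100, "left")
  expect_equal(assign_fgfr1_window(at_tss, fx), "intragenic")
  edge <- make_test_junction(tss + 400000, "left", tss + 400600, "left")
  expect_equal(assign_fgfr1_window(edge, fx), "upstream_window")
  past <- make_test_junction(tss + 400001, "left", tss + 400601, "left")
  expect_equal(assign_fgfr1_window(past, fx), "outside")
})

test_that("NSD3 disruption calls match the described rearrangements", {
  ns <- nsd3_fixture()
  tx <- ns$transcript
  # deletion of exons 16-24: breakend in intron 15, partner past the gene end
  i15 <- floor((tx$exons$end[15] + tx$exons$start[16]) / 2)
  del <- make_test_junction(i15, "left", max(tx$exons$end) + 6000, "right")
  res <- call_nsd3_disruption(del, ns)
  expect_equal(res$status, "disrupted")
  expect_equal(res$evidence$affected_exons[1], "16-24")
  # out-of-frame fusion at exon 15
  e15 <- floor((tx$exons$start[15] + tx$exons$end[15]) / 2)
  fus <- make_test_junction(e15, "left", 41510000, "right")
  expect_equal(call_nsd3_disruption(fus, ns)$status, "disrupted")
  # 50 kb downstream: intact
  down <- make_test_junction(max(tx$exons$end) + 50000, "left",
                             max(tx$exons$end) + 51000, "left")
  expect_equal(call_nsd3_disruption(down, ns)$status, "intact")
  # whole-gene deletion with breakends flanking the gene: no ORF breakend
  flank <- make_test_junction(min(tx$exons$start) - 30000, "left",
                              max(tx$exons$end) + 30000, "right")
  expect_equal(call_nsd3_disruption(flank, ns)$status, "intact")
  # break 3' of the SET exons inside the ORF leaves SET attached
  e23 <- floor((tx$exons$start[23] + tx$exons$end[23]) / 2)
  late <- make_test_junction(e23, "left", max(tx$exons$end) + 6000, "right")
  expect_equal(call_nsd3_disruption(late, ns)$status, "intact")
})

test_that("low-support junctions are flagged, not dropped", {
  j <- make_test_junction(c(100, 200), "left", c(900, 1100), "left",
                          support = c(1, 20))
  expect_equal(nrow(j), 2)
  expect_equal(j$low_confidence, c(TRUE, FALSE))
})
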