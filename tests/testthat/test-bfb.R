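test_that("simulate_bfb executes the update rule and its contracts", {
  # zero cycles: reference string, unit counts, no fold-backs
  s0 <- simulate_bfb(4, 0)
  expect_equal(s0$string$symbols, 1:4)
  expect_equal(s0$counts, rep(1, 4))
  expect_equal(nrow(s0$foldbacks), 0)
  expect_false(s0$telomeric_loss)
  # one cycle breaking after segment 2 of k=3 (hand-executed)
  s1 <- simulate_bfb(3, 1, breaks = 2)
  expect_equal(s1$string$symbols, c(1, 2, -2, -1))
  expect_equal(s1$counts, c(2, 2, 0))
  expect_equal(nrow(s1$foldbacks), 1)
  expect_true(s1$telomeric_loss)
  # determinism: identical seeds give identical everything
  a <- simulate_bfb(5, 4, seed = 99)
  b <- simulate_bfb(5, 4, seed = 99)
  expect_identical(a$string$symbols, b$string$symbols)
  expect_identical(a$foldbacks, b$foldbacks)
  expect_error(simulate_bfb(3, 1, breaks = 9), "invalid break index")
  # simulation does not disturb the caller's RNG stream
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(simulate_bfb(4, 3, seed = 7)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("fold-back orientation tracks the local terminus orientation", {
  # telomere at low coordinates: +j termini give head-to-head fold-backs,
  # inverted termini give tail-to-tail
  s <- simulate_bfb(3, 2, breaks = c(2, 3))
  expect_equal(s$foldbacks$orientation_class[1], "head_to_head")
  expect_equal(s$foldbacks$orientation_class[2], "tail_to_tail")
  # all simulated fold-backs are detected at the default threshold
  for (seed in 1:10) {
    sim <- simulate_bfb(4, 3, seed = seed)
    expect_equal(nrow(detect_foldbacks(sim$foldbacks)), sim$string$cycles)
  }
})

test_that("check_bfb_string agrees with the simulation-rule closure", {
  for (k in 2:3) {
    oracle <- bfb_oracle_closure(k, cap = 4)
    keys <- vapply(oracle$strings, paste, character(1), collapse = ",")
    for (s in oracle$strings)
      expect_true(check_bfb_string(s, k), info = paste(s, collapse = ","))
    # perturbed strings not in the closure must be rejected
    set.seed(k)
    for (i in 1:40) {
      s <- oracle$strings[[sample(length(oracle$strings), 1)]]
      s[sample(length(s), 1)] <- sample(c(-k:-1, 1:k), 1)
      if (paste(s, collapse = ",") %in% keys) next
      expect_false(check_bfb_string(s, k), info = paste(s, collapse = ","))
    }
  }
  expect_true(check_bfb_string(1:5, 5))
  expect_true(check_bfb_string(c(1, 2, -2, -1), 3))
  expect_false(check_bfb_string(c(1, 2, 1), 2))     # non-palindromic tail
})

test_that("string/count conservation and palindromic structure", {
  for (seed in 1:20) {
    sim <- simulate_bfb(sample(2:5, 1), sample(0:4, 1), seed = seed)
    expect_equal(length(sim$string$symbols), sum(sim$counts))
    expect_true(check_bfb_string(sim$string))
  }
})

test_that("is_bfb_count_vector matches enumeration on small instances", {
  expect_true(isTRUE(is_bfb_count_vector(c(1, 1, 1, 1))))
  expect_true(isTRUE(is_bfb_count_vector(c(2, 2, 0))))
  expect_false(isTRUE(is_bfb_count_vector(c(1, 2))))
  oracle <- bfb_oracle_closure(3, cap = 4)
  grid <- expand.grid(a = 0:4, b = 0:4, c = 0:4)
  for (i in seq_len(nrow(grid))) {
    n <- as.integer(grid[i, ])
    want <- paste(n, collapse = ",") %in% oracle$count_keys
    got <- is_bfb_count_vector(n)
    expect_false(is.na(got), info = paste(n, collapse = ","))
    expect_equal(isTRUE(got), want, info = paste(n, collapse = ","))
  }
})

test_that("achievable vectors round-trip through their witness strings", {
  enum <- enumerate_bfb_vectors(3, max_count = 4)
  expect_true(enum$complete)
  for (i in seq_len(nrow(enum$vectors))) {
    s <- enum$strings[[i]]
    expect_true(check_bfb_string(s, 3))
    expect_equal(count_vector(s, 3), as.integer(enum$vectors[i, ]))
  }
})

test_that("nearest_bfb_poisson: exact mode, Poisson mode, baseline", {
  # already achievable: approximation equals the observation
  call <- nearest_bfb_poisson(c(2, 2, 0), baseline = 0)
  expect_equal(call$approximation, c(2, 2, 0))
  # real-valued observation snaps to the nearest achievable vector
  call <- nearest_bfb_poisson(c(2.1, 1.9, 0.2), baseline = 0)
  expect_equal(call$approximation, c(2, 2, 0))
  # Poisson search agrees with an exhaustive scan over achievable vectors
  obs <- c(3.9, 2.2, 1.8, 0.1)
  call <- nearest_bfb_poisson(obs, baseline = 0, max_error = Inf,
                              max_count = 6)
  enum <- enumerate_bfb_vectors(4, max_count = 6)
  ll <- apply(enum$vectors, 1, function(v)
    sum(ifelse(v == 0, ifelse(round(obs) == 0, 0, log(1e-10)),
               obs * log(v) - v - lgamma(obs + 1))))
  expect_equal(call$log_poisson_likelihood, max(ll), tolerance = 1e-9)
  # homolog baseline is subtracted before matching
  call <- nearest_bfb_poisson(c(3, 3, 1), baseline = 1)
  expect_equal(call$approximation, c(2, 2, 0))
  # infeasible at maxError 0: excluded
  call <- nearest_bfb_poisson(c(1, 2), baseline = 0)
  expect_null(call$approximation)
  expect_equal(call$confidence, "excluded")
  # degenerate all-zero observation is excluded (documented behaviour)
  expect_equal(nearest_bfb_poisson(rep(0, 3), baseline = 0)$confidence,
               "excluded")
})

test_that("bfb_confidence is a pure function of its three inputs", {
  mk <- function(nseg, fb, tel, approx = rep(2, nseg)) {
    structure(list(approximation = approx,
                   n_segments_in_approximation = nseg,
                   foldback_support = fb, telomeric_loss = tel),
              class = "BFBCall")
  }
  expect_equal(bfb_confidence(mk(9, TRUE, TRUE)), "high")
  expect_equal(bfb_confidence(mk(9, TRUE, FALSE)), "high")  # loss not gating
  expect_equal(bfb_confidence(mk(5, TRUE, TRUE)), "ambiguous")
  expect_equal(bfb_confidence(mk(9, FALSE, TRUE)), "ambiguous")
  expect_equal(bfb_confidence(structure(list(approximation = NULL),
                                        class = "BFBCall")), "excluded")
  expect_equal(bfb_confidence(structure(list(approximation = NULL,
                                             undecided = TRUE),
                                        class = "BFBCall")), "ambiguous")
})

test_that("reconstruct_amplicon recovers simulated strings", {
  for (seed in 1:15) {
    k <- 4
    sim <- simulate_bfb(k, 3, seed = seed)
    smap <- segment_map("chrS", seq(k * 1e6, 0, by = -1e6))
    segs <- data.frame(chrom = "chrS", start = smap$start, end = smap$end,
                       cn = sim$counts)
    rec <- reconstruct_amplicon(sim$foldbacks, segs)
    expect_gt(length(rec), 0)
    expect_identical(rec[[1]]$symbols, sim$string$symbols,
                     info = paste("seed", seed))
  }
  # single fold-back with counts (2,0): the one-cycle string (1,-1)
  sim1 <- simulate_bfb(2, 1, breaks = 1)
  segs1 <- data.frame(chrom = "chrS", start = c(1e6, 0), end = c(2e6, 1e6),
                      cn = c(2, 0))
  rec <- reconstruct_amplicon(sim1$foldbacks, segs1)
  expect_equal(rec[[1]]$symbols, c(1, -1))
  # contradictory input: fold-back but flat counts
  segs_flat <- segs1; segs_flat$cn <- c(1, 1)
  expect_length(reconstruct_amplicon(sim1$foldbacks, segs_flat), 0)
})
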