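#' @title Breakage-fusion-bridge simulation and inference
#' @description A BFB string is an ordered sequence of signed segment
#'   identifiers describing the derivative chromosome of an arm whose
#'   reference segmentation is `1..k` in centromere-to-telomere order. Each
#'   BFB cycle truncates the current string at a segment boundary and appends
#'   the inverted retained prefix, emitting one fold-back junction; the
#'   per-segment symbol counts form the count vector tested for BFB
#'   achievability. Observed (real-valued) copy-number vectors are matched to
#'   achievable integer vectors either exactly (maxError 0, after subtracting
#'   the unrearranged-homolog baseline and rounding) or by maximising a
#'   Poisson likelihood over the achievable set.
#' @name bfb
NULL

.neg_rev <- function(s) rev(-s)

# run `expr` under a fixed seed without disturbing the caller's RNG state
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

bfb_string <- function(symbols, k, cycles = NA_integer_, breaks = integer(0)) {
  structure(list(symbols = as.integer(symbols), k = as.integer(k),
                 cycles = as.integer(cycles), breaks = as.integer(breaks)),
            class = "BFBString")
}

#' Per-segment count vector of a BFB string
#' @param s a `BFBString` (or bare signed integer vector with attribute-free
#'   symbols, in which case `k` must be given)
#' @param k number of reference segments
#' @return integer vector of counts, centromere to telomere
#' @export
count_vector <- function(s, k = NULL) {
  if (inherits(s, "BFBString")) { k <- s$k; s <- s$symbols }
  if (is.null(k)) stop("k required for a bare symbol vector")
  tabulate(abs(s), nbins = k)
}

#' Map from segment index to genomic coordinates
#'
#' Rows must be ordered centromere to telomere; on the short arm of a
#' chromosome (telomere at coordinate 0, as for 8p) coordinates therefore
#' decrease along rows.
#'
#' @param chrom chromosome
#' @param bounds numeric vector of k+1 segment boundary coordinates, from the
#'   centromeric edge to the telomeric edge (monotone)
#' @return data.frame with `segment, chrom, start, end` plus an attribute
#'   `tel_side` (`"low"` or `"high"`)
#' @export
segment_map <- function(chrom, bounds) {
  k <- length(bounds) - 1
  if (k < 1) stop("need at least one segment")
  d <- diff(bounds)
  if (!(all(d > 0) || all(d < 0))) stop("boundaries must be monotone")
  tel_side <- if (d[1] < 0) "low" else "high"
  out <- data.frame(segment = seq_len(k),
                    chrom = chrom,
                    start = pmin(bounds[-(k + 1)], bounds[-1]),
                    end = pmax(bounds[-(k + 1)], bounds[-1]))
  attr(out, "tel_side") <- tel_side
  out
}

# fold-back junction emitted when the retained terminus is symbol `sym`
# (signed). Returns a one-row junction data.frame.
.foldback_junction <- function(sym, smap, cycle) {
  tel_low <- attr(smap, "tel_side") == "low"
  seg <- smap[abs(sym), ]
  # terminal base of the retained prefix: +j ends at the telomere-side end of
  # segment j, -j at its centromere-side end; the retained flank faces away
  # from the terminus.
  tel_end_low <- tel_low            # telomere-side end is the low coordinate?
  at_tel_end <- sym > 0
  boundary_low <- xor(!at_tel_end, tel_end_low)  # TRUE: boundary at seg start
  pos <- if (boundary_low) seg$start else seg$end - 1
  side <- if (boundary_low) "right" else "left"
  data.frame(chrom1 = seg$chrom, pos1 = pos, side1 = side,
             chrom2 = seg$chrom, pos2 = pos, side2 = side,
             name = paste0("foldback_c", cycle), support = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Simulate breakage-fusion-bridge cycles
#'
#' Starting from the reference string `1..k`, each cycle truncates the
#' current string after a boundary index (sampled uniformly unless explicit
#' positions are given) and appends the inverted retained prefix, emitting a
#' fold-back junction (tail-to-tail or head-to-head depending on the local
#' orientation of the terminus). Telomeric loss is recorded whenever a cycle
#' discards distal material.
#'
#' @param n_segments number of reference segments (k >= 1)
#' @param n_cycles number of BFB cycles (>= 0)
#' @param breaks optional explicit retained-prefix lengths, one per cycle
#'   (each in `1..length(current string)`)
#' @param seed integer seed for the break sampler (no global RNG state is
#'   touched)
#' @param smap optional [segment_map()]; defaults to unit segments on a
#'   synthetic arm with the telomere at low coordinates (8p-like)
#' @return list: `string` (`BFBString`), `counts` (count vector), `foldbacks`
#'   (junction table, one row per cycle), `telomeric_loss`
#' @export
simulate_bfb <- function(n_segments, n_cycles, breaks = NULL, seed = 1,
                         smap = NULL) {
  stopifnot(n_segments >= 1, n_cycles >= 0)
  if (is.null(smap))
    smap <- segment_map("chrS", seq(n_segments * 1e6, 0, by = -1e6))
  u <- NULL
  if (is.null(breaks) && n_cycles > 0) {
    u <- with_preserved_seed(seed, stats::runif(n_cycles))
  }
  s <- seq_len(n_segments)
  fb <- list(); used_breaks <- integer(0); tel_loss <- FALSE
  for (cyc in seq_len(n_cycles)) {
    b <- if (!is.null(breaks)) breaks[cyc]
         else max(1L, ceiling(u[cyc] * length(s)))
    if (is.na(b) || b < 1 || b > length(s))
      stop("invalid break index ", b, " for string length ", length(s))
    if (b < length(s)) tel_loss <- TRUE
    p <- s[seq_len(b)]
    fb[[cyc]] <- .foldback_junction(p[b], smap, cyc)
    s <- c(p, .neg_rev(p))
    used_breaks <- c(used_breaks, b)
  }
  foldbacks <- if (length(fb)) junction_table(do.call(rbind, fb))
               else junction_table(data.frame(chrom1 = character(0),
                                              pos1 = numeric(0),
                                              side1 = character(0),
                                              chrom2 = character(0),
                                              pos2 = numeric(0),
                                              side2 = character(0)))
  st <- bfb_string(s, n_segments, n_cycles, used_breaks)
  list(string = st, counts = count_vector(st), foldbacks = foldbacks,
       telomeric_loss = tel_loss)
}

# ok_prefix(t): is t a prefix of some reachable BFB string?
# t == 1..len(t) (len <= k), or t = p + q with q a nonempty prefix of
# rev(-p) and ok_prefix(p). Memoised per call via an environment.
.ok_prefix <- function(t, k, memo) {
  key <- paste(t, collapse = ",")
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  n <- length(t)
  res <- FALSE
  if (n <= k && identical(t, seq_len(n))) {
    res <- TRUE
  } else if (n >= 2) {
    for (b in seq.int(ceiling(n / 2), n - 1)) {
      p <- t[seq_len(b)]
      q <- t[(b + 1):n]
      if (identical(q, .neg_rev(p)[seq_len(n - b)]) &&
          .ok_prefix(p, k, memo)) { res <- TRUE; break }
    }
  }
  memo[[key]] <- res
  res
}

#' Is a signed-segment string reachable by BFB cycles?
#'
#' Structural check: a reachable string is either the reference `1..k` or
#' decomposes as `t + rev(-t)` where `t` is itself a prefix of a reachable
#' string (recursively). This is exact — no cycle bound is needed.
#'
#' @param s `BFBString` or signed integer vector
#' @param k number of reference segments (taken from the object if present)
#' @return TRUE/FALSE
#' @export
check_bfb_string <- function(s, k = NULL) {
  if (inherits(s, "BFBString")) { k <- s$k; s <- s$symbols }
  if (is.null(k)) k <- max(abs(s))
  s <- as.integer(s)
  n <- length(s)
  if (n == 0 || any(abs(s) < 1 | abs(s) > k)) return(FALSE)
  if (identical(s, seq_len(k))) return(TRUE)
  if (n %% 2 != 0) return(FALSE)
  t <- s[seq_len(n / 2)]
  if (!identical(s[(n / 2 + 1):n], .neg_rev(t))) return(FALSE)
  .ok_prefix(t, k, new.env(parent = emptyenv()))
}

# Breadth-first closure of ok-prefix strings with per-segment counts bounded
# by `cap`. Returns list(states = list of integer vectors, cycles = integer
# vector of minimal append counts, truncated = logical: TRUE when the state
# cap stopped the search).
.prefix_closure <- function(k, cap, max_cycles = 12, max_states = 2e5) {
  total_cap <- sum(cap)
  seeds <- lapply(seq_len(min(k, length(cap))), function(m) seq_len(m))
  seeds <- Filter(function(p) all(count_vector(p, k) <= cap), seeds)
  states <- list(); cycles <- integer(0)
  seen <- new.env(parent = emptyenv())
  queue <- seeds; qcyc <- rep(0L, length(seeds))
  head <- 1L
  truncated <- FALSE
  while (head <= length(queue)) {
    t <- queue[[head]]; cy <- qcyc[head]
    head <- head + 1L
    key <- paste(t, collapse = ",")
    prev <- seen[[key]]
    if (!is.null(prev) && prev <= cy) next
    seen[[key]] <- cy
    states[[length(states) + 1]] <- t
    cycles[length(states)] <- cy
    if (length(states) >= max_states) { truncated <- TRUE; break }
    if (cy + 1 > max_cycles) { truncated <- TRUE; next }
    inv <- .neg_rev(t)
    for (jlen in seq_len(length(t))) {
      child <- c(t, inv[seq_len(jlen)])
      if (length(child) > total_cap) break
      if (all(count_vector(child, k) <= cap)) {
        queue[[length(queue) + 1]] <- child
        qcyc[length(queue)] <- cy + 1L
      }
    }
  }
  list(states = states, cycles = cycles, truncated = truncated)
}

#' Decide whether a count vector is BFB-achievable
#'
#' A vector is achievable when some BFB string has exactly these per-segment
#' counts: either the zero-cycle reference (all counts 1) or a palindromic
#' string `t + rev(-t)`, so all counts even and `t` an ok-prefix string with
#' half the counts. Implemented as a pruned breadth-first search over
#' ok-prefix strings; on bound exhaustion without a witness the result is
#' `NA` ("undecided at bound"), never a silent `FALSE`.
#'
#' @param n integer count vector (centromere to telomere)
#' @param max_cycles search bound on BFB cycles (default 12)
#' @param max_states search bound on explored prefix states
#' @return TRUE, FALSE or NA (undecided at bound); a TRUE result carries the
#'   witness string as attribute `string` and its cycle count as `cycles`
#' @export
is_bfb_count_vector <- function(n, max_cycles = 12, max_states = 2e5) {
  if (any(n < 0) || any(n != floor(n))) stop("counts must be non-negative integers")
  n <- as.integer(n)
  k <- length(n)
  if (all(n == 1))
    return(structure(TRUE, string = seq_len(k), cycles = 0L))
  if (any(n %% 2 != 0)) return(FALSE)
  if (all(n == 0)) return(FALSE)      # nothing left: not a BFB product here
  m <- n %/% 2L
  cl <- .prefix_closure(k, m, max_cycles = max_cycles - 1,
                        max_states = max_states)
  for (i in seq_along(cl$states)) {
    t <- cl$states[[i]]
    if (identical(count_vector(t, k), m))
      return(structure(TRUE, string = c(t, .neg_rev(t)),
                       cycles = cl$cycles[i] + 1L))
  }
  if (cl$truncated) NA else FALSE
}

#' All BFB-achievable count vectors within bounds
#'
#' @param k number of segments
#' @param max_count per-segment count cap
#' @param max_cycles cycle bound
#' @param max_states state bound
#' @return list with `vectors` (matrix, one row per achievable vector),
#'   `cycles` (minimal cycles), `strings` (witness strings, fewest-cycle then
#'   lexicographically smallest) and `complete` (FALSE when a bound was hit)
#' @export
enumerate_bfb_vectors <- function(k, max_count, max_cycles = 12,
                                  max_states = 2e5) {
  cap <- rep(floor(max_count / 2), k)
  cl <- .prefix_closure(k, cap, max_cycles = max_cycles - 1,
                        max_states = max_states)
  best <- new.env(parent = emptyenv())
  put <- function(vec, cyc, s) {
    key <- paste(vec, collapse = ",")
    cur <- best[[key]]
    if (is.null(cur) || cyc < cur$cycles ||
        (cyc == cur$cycles && .lex_less(s, cur$string)))
      best[[key]] <- list(vec = vec, cycles = cyc, string = s)
  }
  put(rep(1L, k), 0L, seq_len(k))
  for (i in seq_along(cl$states)) {
    t <- cl$states[[i]]
    put(2L * count_vector(t, k), cl$cycles[i] + 1L, c(t, .neg_rev(t)))
  }
  items <- as.list(best)
  vecs <- do.call(rbind, lapply(items, `[[`, "vec"))
  o <- do.call(order, as.data.frame(vecs))
  list(vectors = vecs[o, , drop = FALSE],
       cycles = vapply(items, `[[`, integer(1), "cycles")[o],
       strings = lapply(items, `[[`, "string")[o],
       complete = !cl$truncated)
}

.lex_less <- function(a, b) {
  if (length(a) != length(b)) return(length(a) < length(b))
  d <- which(a != b)
  if (!length(d)) return(FALSE)
  a[d[1]] < b[d[1]]
}

# Poisson log-likelihood of observed (possibly real-valued) counts given an
# integer approximation; lambda = 0 contributes 0 when the observation rounds
# to 0 and log(zero_floor) otherwise.
.bfb_loglik <- function(obs, lam, zero_floor = 1e-10) {
  ll <- numeric(length(obs))
  z <- lam == 0
  ll[z] <- ifelse(round(obs[z]) == 0, 0, log(zero_floor))
  nz <- !z
  ll[nz] <- obs[nz] * log(lam[nz]) - lam[nz] - lgamma(obs[nz] + 1)
  sum(ll)
}

#' Nearest BFB-achievable approximation of an observed count vector
#'
#' The configurable homolog baseline (default 1 copy, for the unrearranged
#' homolog) is subtracted and clamped at zero first. With `max_error = 0` the
#' rounded vector must be exactly achievable, otherwise the call is
#' `excluded`; with `max_error = Inf` the achievable vector maximising the
#' Poisson likelihood within the search bounds is returned (ties: fewer
#' cycles, then lexicographically smallest witness string).
#'
#' @param observed numeric vector of total copy numbers per segment
#' @param baseline homolog copies subtracted first (0, 1 or 2; default 1)
#' @param max_error 0 for exact matching (default), `Inf` for the Poisson
#'   search
#' @param max_count per-segment cap of the search (default: observed max + 2)
#' @param max_cycles cycle bound (default 12)
#' @param foldback_support,telomeric_loss observed metadata carried into the
#'   confidence call
#' @param zero_floor likelihood floor for observations over zero-copy
#'   segments
#' @return a `BFBCall` list (observed, approximation, log likelihood, number
#'   of nonzero segments in the approximation, metadata, confidence)
#' @export
nearest_bfb_poisson <- function(observed, baseline = 1, max_error = 0,
                                max_count = NULL, max_cycles = 12,
                                max_states = 2e5,
                                foldback_support = FALSE,
                                telomeric_loss = FALSE, zero_floor = 1e-10) {
  if (any(observed < 0)) stop("observed counts must be >= 0")
  adj <- pmax(observed - baseline, 0)
  k <- length(adj)
  target <- as.integer(round(adj))
  approx <- NULL; cycles <- NA_integer_; string <- NULL
  undecided <- FALSE
  if (max_error == 0) {
    hit <- is_bfb_count_vector(target, max_cycles = max_cycles,
                               max_states = max_states)
    if (isTRUE(hit)) {
      approx <- target
      string <- attr(hit, "string")
      cycles <- attr(hit, "cycles")
    } else if (is.na(hit)) {
      undecided <- TRUE
    }
  } else {
    if (is.null(max_count)) max_count <- max(target) + 2
    enum <- enumerate_bfb_vectors(k, max_count, max_cycles = max_cycles,
                                  max_states = max_states)
    if (nrow(enum$vectors)) {
      ll <- apply(enum$vectors, 1, .bfb_loglik, obs = adj,
                  zero_floor = zero_floor)
      o <- order(-ll, enum$cycles)
      approx <- enum$vectors[o[1], ]
      cycles <- enum$cycles[o[1]]
      string <- enum$strings[[o[1]]]
    }
  }
  call <- structure(list(
    observed = observed, baseline = baseline, adjusted = adj,
    approximation = approx,
    log_poisson_likelihood =
      if (is.null(approx)) -Inf else .bfb_loglik(adj, approx, zero_floor),
    n_segments_in_approximation =
      if (is.null(approx)) 0L else sum(approx > 0),
    cycles = cycles, string = string, undecided = undecided,
    foldback_support = foldback_support, telomeric_loss = telomeric_loss,
    confidence = NA_character_), class = "BFBCall")
  call$confidence <- bfb_confidence(call)
  call
}

#' Confidence class of a BFB call
#'
#' `high` requires a BFB approximation of at least `min_segments` (default 8)
#' nonzero segments together with fold-back support; `ambiguous` covers
#' approximations with fewer segments and/or no fold-back support; `excluded`
#' means no BFB approximation exists within the configured error bound.
#' Telomeric loss is carried as supportive metadata, not a gate.
#'
#' @param call a `BFBCall`
#' @param min_segments segment threshold for high confidence (default 8)
#' @return `"high"`, `"ambiguous"` or `"excluded"`
#' @export
bfb_confidence <- function(call, min_segments = 8) {
  if (is.null(call$approximation)) {
    # an undecided search (bound hit without a witness) is not an exclusion
    return(if (isTRUE(call$undecided)) "ambiguous" else "excluded")
  }
  if (call$n_segments_in_approximation >= min_segments &&
      isTRUE(call$foldback_support)) "high" else "ambiguous"
}

#' Reconstruct BFB strings from observed fold-backs and copy numbers
#'
#' Depth-first search over cycle sequences whose emitted fold-back junctions
#' (position and orientation) exactly use up the observed fold-back set and
#' whose final count vector matches the observed per-segment counts (after
#' baseline subtraction and rounding). Consistent strings are ranked by
#' Poisson likelihood of the unrounded counts, then by fewest cycles, then
#' lexicographically; the list may be empty when the observations are
#' contradictory.
#'
#' @param foldbacks junction table of fold-back junctions (e.g. from
#'   [detect_foldbacks()] or [simulate_bfb()])
#' @param segments data.frame with `chrom, start, end, cn` — the segmentation
#'   implied by the fold-back boundaries, rows centromere to telomere
#' @param baseline homolog copies subtracted from `cn` (default 0: pass
#'   derivative-only counts)
#' @param max_results cap on returned strings
#' @return list of `BFBString`s, best first
#' @export
reconstruct_amplicon <- function(foldbacks, segments, baseline = 0,
                                 max_results = 20) {
  k <- nrow(segments)
  bounds <- if (nrow(segments) > 1 && segments$start[1] > segments$start[2])
    c(segments$end[1], segments$start)       # telomere at low coords
  else c(segments$start[1], segments$end)
  smap <- segment_map(segments$chrom[1], bounds)
  adj <- pmax(segments$cn - baseline, 0)
  target <- as.integer(round(adj))
  n_cycles <- nrow(foldbacks)
  fb_key <- function(j) paste0(j$side1, "@", j$pos1)
  remaining <- table(vapply(seq_len(n_cycles), function(i)
    fb_key(foldbacks[i, , drop = FALSE]), character(1)))
  results <- list()
  recurse <- function(s, rem, breaks, depth) {
    if (length(results) >= max_results) return()
    if (depth == n_cycles) {
      if (identical(count_vector(s, k), target) && all(rem == 0))
        results[[length(results) + 1]] <<-
          bfb_string(s, k, depth, breaks)
      return()
    }
    for (b in seq_along(s)) {
      key <- fb_key(.foldback_junction(s[b], smap, depth + 1))
      if (is.na(rem[key]) || rem[key] == 0) next
      p <- s[seq_len(b)]
      child <- c(p, .neg_rev(p))
      if (any(count_vector(child, k) > target)) {
        # counts can still shrink by later truncation, but never below the
        # per-segment counts of the retained prefix of length 1
        if (depth + 1 == n_cycles) next
      }
      rem2 <- rem; rem2[key] <- rem2[key] - 1
      recurse(child, rem2, c(breaks, b), depth + 1)
    }
  }
  rem0 <- stats::setNames(as.integer(remaining), names(remaining))
  recurse(seq_len(k), rem0, integer(0), 0)
  if (!length(results)) return(list())
  ll <- vapply(results, function(st) .bfb_loglik(adj, count_vector(st)),
               numeric(1))
  cyc <- vapply(results, function(st) st$cycles, integer(1))
  o <- order(-ll, cyc)
  results[o]
}

#' Format a BFB string as signed integers
#' @param x a `BFBString`
#' @param ... unused
#' @export
format.BFBString <- function(x, ...) paste(x$symbols, collapse = " ")

#' @export
print.BFBString <- function(x, ...) {
  cat("BFB string (k =", x$k, ", cycles =", x$cycles, "):",
      format(x), "\n")
  invisible(x)
}
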