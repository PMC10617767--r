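#' @title Per-sample dependency calls and cohort association
#' @description Integrates junction classification, ORF prediction, NSD3
#'   calls and BFB inference into one per-sample call, and tests the
#'   cohort-level association between rearrangement status and
#'   FGFR-inhibitor response with a two-tailed Fisher's exact test. Response
#'   labels (GI50 at the 1 uM cutoff, 30% tumor reduction, RECIST) are
#'   consumed as given metadata, never recomputed.
#' @name cohort
NULL

.categories <- c("deltaEC_FGFR1", "FGFR1_inactivated", "FGFR1_centered",
                 "non_centered")

#' Integrate one sample's evidence into a dependency call
#'
#' Precedence: (1) an intragenic tail-to-tail rearrangement with the kinase
#' domain retained gives `deltaEC_FGFR1`; (2) a kinase-deleting intragenic
#' rearrangement gives `FGFR1_inactivated`; (3) a tail-to-tail junction in
#' the upstream window gives `FGFR1_centered`; (4) otherwise `non_centered`.
#' Predicted FGFR dependency covers `deltaEC_FGFR1` and `FGFR1_centered`.
#' NSD3 disruption and BFB confidence are attached as annotations.
#'
#' @param junctions junction table for the sample
#' @param segments copy-number segments (`chrom, start, end, cn` or
#'   `total_cn`), or NULL; used for the BFB annotation and the no-amplicon
#'   flag
#' @param fgfr1,nsd3 gene fixtures (defaults: bundled snapshots)
#' @param sample_id sample name
#' @param response response label (`responder`/`nonresponder`/`unknown`)
#' @param window_bp upstream window (default 400 kb)
#' @param proximity_bp fold-back threshold (default 100 kb)
#' @param baseline homolog copies for the BFB call (default 1)
#' @return a `SampleCall` list
#' @export
call_sample <- function(junctions, segments = NULL,
                        fgfr1 = fgfr1_fixture(), nsd3 = nsd3_fixture(),
                        sample_id = "sample", response = "unknown",
                        window_bp = 400000, proximity_bp = 1e5,
                        baseline = 1) {
  win <- assign_fgfr1_window(junctions, fgfr1, window_bp)
  tt <- junctions$orientation_class == "tail_to_tail"
  has_intragenic_tt <- any(win == "intragenic" & tt)
  has_upstream_tt <- any(win == "upstream_window" & tt)
  # consequence of intragenic rearrangements
  kinase_deleted <- FALSE
  deltaec <- FALSE
  best_variant <- NULL
  for (i in which(win == "intragenic")) {
    v <- tryCatch(predict_variant(fgfr1, junctions[i, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(v)) next
    if (tt[i] && v$kinase_retained) {
      deltaec <- TRUE
      if (is.null(best_variant)) best_variant <- v
    }
    if (!v$kinase_retained) kinase_deleted <- TRUE
  }
  ns <- call_nsd3_disruption(junctions, nsd3)
  category <- if (deltaec) "deltaEC_FGFR1"
    else if (kinase_deleted) "FGFR1_inactivated"
    else if (has_upstream_tt) "FGFR1_centered"
    else "non_centered"
  # BFB annotation from segments + fold-backs
  bfb_conf <- NA_character_; no_amplicon <- FALSE
  if (!is.null(segments)) {
    chrom <- gene_span(fgfr1)$chrom
    seg <- segments[segments$chrom == chrom, , drop = FALSE]
    if (!"cn" %in% names(seg) && "total_cn" %in% names(seg))
      seg$cn <- seg$total_cn
    if (nrow(seg) == 0) no_amplicon <- TRUE
    else {
      fb <- detect_foldbacks(junctions, proximity_bp)
      # centromere -> telomere ordering for the short arm: descending coords
      seg <- seg[order(seg$start, decreasing = TRUE), , drop = FALSE]
      call <- nearest_bfb_poisson(seg$cn, baseline = baseline,
                                  max_states = 2e4,
                                  foldback_support = nrow(fb) > 0,
                                  telomeric_loss = NA)
      bfb_conf <- call$confidence
    }
  }
  flags <- list(has_intragenic_TT = has_intragenic_tt,
                has_upstream_TT = has_upstream_tt,
                nsd3_disrupted = ns$status == "disrupted",
                fgfr1_kinase_deleted = kinase_deleted)
  structure(list(sample = sample_id, response = response, flags = flags,
                 category = category,
                 predicted_dependency =
                   category %in% c("deltaEC_FGFR1", "FGFR1_centered"),
                 variant = best_variant, nsd3_evidence = ns$evidence,
                 bfb_confidence = bfb_conf, no_amplicon = no_amplicon,
                 no_evidence = nrow(junctions) == 0),
            class = "SampleCall")
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Minimum-likelihood convention: the p-value sums the hypergeometric
#' probabilities of all tables with the observed margins whose point
#' probability does not exceed (up to a 1e-7 relative tolerance) that of the
#' observed table. Degenerate margins give p = 1.
#'
#' @param a,b,c,d cell counts, rows = response groups, columns =
#'   rearrangement status
#' @return two-sided p-value
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("negative cell count")
  if (any(cells != floor(cells))) stop("cell counts must be integers")
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  p <- stats::dhyper(support, m, n, k)
  p0 <- stats::dhyper(a, m, n, k)
  min(sum(p[p <= p0 * (1 + 1e-7)]), 1)
}

#' Cohort-level association of a rearrangement flag with response
#'
#' Builds the 2x2 table of flag presence versus responder status over all
#' calls with known response labels and applies [fisher_exact_2x2()].
#'
#' @param calls list of `SampleCall`s
#' @param flag which logical flag to test (a name in `call$flags`, e.g.
#'   `"tt_in_or_near_fgfr1"` for the union of intragenic and upstream
#'   tail-to-tail, or `"nsd3_disrupted"`)
#' @return list: `table` (2x2 matrix), `p_value`, `fractions` (positive
#'   fraction per response group), `n_excluded` (unknown-label samples)
#' @export
cohort_association <- function(calls, flag = "tt_in_or_near_fgfr1") {
  resp <- vapply(calls, function(x) x$response, character(1))
  keep <- resp %in% c("responder", "nonresponder")
  n_excluded <- sum(!keep)
  calls <- calls[keep]; resp <- resp[keep]
  pos <- vapply(calls, function(x) {
    if (flag == "tt_in_or_near_fgfr1")
      isTRUE(x$flags$has_intragenic_TT) || isTRUE(x$flags$has_upstream_TT)
    else isTRUE(x$flags[[flag]])
  }, logical(1))
  tab <- matrix(c(sum(resp == "responder" & pos),
                  sum(resp == "responder" & !pos),
                  sum(resp == "nonresponder" & pos),
                  sum(resp == "nonresponder" & !pos)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("responder", "nonresponder"),
                                c("positive", "negative")))
  p <- if (any(rowSums(tab) < 2)) {
    warning("fewer than 2 samples in a response group; p undefined")
    NA_real_
  } else fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  list(table = tab, p_value = p,
       fractions = c(responder = tab[1, 1] / max(sum(tab[1, ]), 1),
                     nonresponder = tab[2, 1] / max(sum(tab[2, ]), 1)),
       n_excluded = n_excluded)
}

#' Load the bundled pooled-cohort fixture
#'
#' 21 models (9 responders, 12 nonresponders: cell lines, PDX models and
#' patient specimens) encoded as junction records. Published breakpoint
#' coordinates are used verbatim where available; records the source
#' describes only in words carry representative synthetic coordinates, with
#' per-record provenance in the `provenance` column.
#'
#' @return list: `junctions` (junction table with `sample` and `provenance`
#'   columns), `labels` (sample, model_type, response)
#' @export
pooled_cohort <- function() {
  jx <- utils::read.delim(extdata("pooled_cohort_junctions_synthetic.tsv"),
                          stringsAsFactors = FALSE)
  jx$pos1 <- jx$pos1 - 1
  jx$pos2 <- jx$pos2 - 1
  labels <- utils::read.delim(extdata("pooled_cohort_labels.tsv"),
                              stringsAsFactors = FALSE)
  list(junctions = junction_table(jx), labels = labels)
}

#' Per-sample calls for the bundled pooled cohort
#'
#' @param ... passed to [call_sample()]
#' @return named list of `SampleCall`s, one per model
#' @export
pooled_cohort_calls <- function(...) {
  cohort <- pooled_cohort()
  fg <- fgfr1_fixture(); ns <- nsd3_fixture()
  calls <- lapply(seq_len(nrow(cohort$labels)), function(i) {
    s <- cohort$labels$sample[i]
    jx <- cohort$junctions[cohort$junctions$sample == s, , drop = FALSE]
    call_sample(jx, fgfr1 = fg, nsd3 = ns, sample_id = s,
                response = cohort$labels$response[i], ...)
  })
  stats::setNames(calls, cohort$labels$sample)
}

#' Write sample calls and the cohort association to files
#'
#' @param calls list of `SampleCall`s
#' @param json_path per-sample JSON report path (NULL to skip)
#' @param tsv_path cohort summary TSV path (NULL to skip)
#' @param flags flags to test at cohort level
#' @return the association results, invisibly
#' @export
write_cohort_report <- function(calls, json_path = NULL, tsv_path = NULL,
                                flags = c("tt_in_or_near_fgfr1",
                                          "nsd3_disrupted")) {
  if (!is.null(json_path)) {
    out <- lapply(calls, function(x)
      list(sample = x$sample, response = x$response, flags = x$flags,
           category = x$category,
           predicted_dependency = x$predicted_dependency,
           bfb_confidence = x$bfb_confidence))
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  assoc <- lapply(flags, function(f) cohort_association(calls, f))
  names(assoc) <- flags
  if (!is.null(tsv_path)) {
    tab <- do.call(rbind, lapply(flags, function(f) {
      a <- assoc[[f]]
      data.frame(flag = f, resp_pos = a$table[1, 1], resp_n = sum(a$table[1, ]),
                 nonresp_pos = a$table[2, 1], nonresp_n = sum(a$table[2, ]),
                 frac_responder = a$fractions["responder"],
                 frac_nonresponder = a$fractions["nonresponder"],
                 p_value = a$p_value)
    }))
    .write_table(tab, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(assoc)
}
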