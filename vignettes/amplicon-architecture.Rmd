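---
title: "Amplicon architecture: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amplicon architecture: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliconlens)
```

`ampliconlens` analyses how a cancer gene amplicon was assembled: which
rearrangement junctions shaped it, whether a breakage-fusion-bridge (BFB)
process can explain its stepped copy-number profile, and whether its
structure predicts dependency on the amplified kinase. This vignette is the
package's own account of the underlying models, the tunable parameters and
the decisions taken where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Coordinate and orientation conventions

All internal coordinates are 0-based half-open; GTF and the fixture TSVs
(1-based inclusive) and VCF positions are converted at the I/O boundary, so
off-by-one arithmetic lives in exactly one place. Exons are numbered in
transcription order: for the minus-strand FGFR1, exon 1 sits at the highest
genomic coordinates and "upstream" means higher coordinates.

A breakend's `retained_side` says which reference flank survives on the
derivative chromosome: `left` keeps coordinates at or below the breakend
(BEDPE strand `+`), `right` keeps those at or above it (`-`). "Tail" denotes
the high-coordinate flank. The four same-chromosome orientation classes
follow mechanically: tail-to-tail (`left`/`left`), head-to-head
(`right`/`right`), deletion-type (`left`/`right`), duplication-type
(`right`/`left`). This nomenclature is defined explicitly here because usage
in the literature is informal; the choice is anchored to the copy-number
consequence that a tail-to-tail junction whose upper breakend lies inside
minus-strand FGFR1 deletes the gene's 5' exons (they sit above the break).

## FGFR1 window rule

`assign_fgfr1_window()` classifies a junction as `intragenic` when either
breakend falls in the FGFR1 gene span, else `upstream_window` when either
breakend falls in the half-open interval `(TSS, TSS + 400 kb]` on the
upstream (high-coordinate) side, else `outside`. Gene-body overlap takes
precedence, making the partition exclusive and exhaustive. The 400 kb width
is the source analysis's choice and is exposed as `window_bp`. Whether that
window was anchored at the TSS or the gene boundary is not documented in the
source; the TSS is used here and is part of the fixture, so the assumption
is visible and overridable.

## ΔEC-FGFR1 open-reading-frame prediction

For an intragenic junction, `retained_exons()` keeps the exons on the
retained flank of the breakend inside the transcript (for two same-side
intragenic breakends, the more restrictive one; a deletion-type junction
with both breakends inside removes the interval between them). An exon cut
by the breakend is retained but flagged partial, and its 5' portion up to
the breakpoint is discarded before scanning.

`next_inframe_start()` first checks whether the canonical start codon
survives. Otherwise it scans the retained spliced coding sequence 5'→3' for
the first ATG whose offset is congruent to the canonical frame. Design
choices, all deliberate:

* Only in-frame ATGs count; out-of-frame upstream ATGs are ignored and no
  Kozak-context scoring is applied (the source analysis gives none).
* Scanning runs on the mRNA-sense sequence; for minus-strand genes this is
  the same operation as reading TAC motifs right-to-left on the genome
  strand.
* The fused partner sequence across the junction is never scanned — the
  partner is unknown in general. This is a documented limitation: a start
  codon created by the junction itself would be missed.

`predict_variant()` intersects the translated span with the domain table: a
domain ending before the new start (or beginning after the retained 3' end)
is lost; a domain cut by either boundary is counted lost and flagged
partial. `kinase_retained` demands the complete kinase domain inside the
translated span. A junction deleting the kinase-coding exons (e.g. a
head-to-head fold-back between exons 5 and 6) therefore yields
`kinase_retained = FALSE` and, at the sample level, the
`FGFR1_inactivated` category.

## NSD3 disruption

NSD3 counts as disrupted when any breakend falls inside its ORF at or 5' of
the end of the SET-domain-encoding exons: such a break deletes the SET
domain or separates it from the promoter-proximal exons, regardless of the
partner. Two deliberate consequences: a whole-gene deletion whose breakends
flank the gene is *not* called (no breakend in the ORF — matching the
source's treatment of a fold-back that removes NSD3 entirely yet counts as
zero NSD3 rearrangements in the nonresponder group), and a break 3' of the
SET exons leaves SET attached to the promoter and is also not called.

## ROBOCOP

`bin_segments()` maps segmented copy number onto `n_bins` equal bins of a
fixed view window (defaults: 2 Mb centered on the FGFR1 gene-body midpoint,
10,000 bins, i.e. 200 bp bins). Each bin takes the overlap-length-weighted
mean of overlapping segments; the alternative midpoint rule (value of the
covering segment at the bin midpoint) would differ only in partially covered
bins and the weighted mean was chosen because it conserves the
length-weighted mean copy number exactly (tested at 1e-9). Uncovered bins
default to the diploid baseline 2 so that group means stay defined;
`baseline = NA` switches to missing-value propagation.

`rolling_mean()` is a centered rolling mean whose window is truncated at the
profile edges, keeping the output length stable and constant inputs
invariant; window size 10 is the WGS default and 500 the CAGE default, both
from the source's stated parameters. For even `w` the window covers
`floor(w/2)` bins left and `w-1-floor(w/2)` right of each bin — one of the
two standard centering conventions for even windows; the brute-force oracle
in the tests encodes the same convention independently.

`focal_width()` needs a threshold the source never states (it reports widths
such as 550 kb vs 1.7 Mb without a rule); the half-maximum convention —
the maximal contiguous run around the peak at or above
`baseline + (peak - baseline)/2` — was chosen as the standard peak-width
definition. `peak_center()` takes the leftmost maximal bin on ties and flags
flat profiles as having no distinct peak.

## BFB model

The reference arm is segmented `1..k` from centromere to telomere. One BFB
cycle truncates the current signed-symbol string after a chosen position and
appends the inverted retained prefix, emitting one fold-back junction whose
orientation follows the local orientation of the terminus: on an arm with
the telomere at low coordinates (like 8p), a reference-orientation terminus
gives a head-to-head fold-back and an inverted terminus a tail-to-tail one —
which is why both classes coexist on BFB-amplified arms. Telomeric loss is
recorded whenever a cycle discards distal material.

Reachability of a string is decided structurally: a reachable string is the
reference or decomposes as `t + rev(-t)` with `t` a prefix of a reachable
string, recursively. This check is exact and needs no cycle bound. It
implies every post-cycle count vector has all-even entries, so achievability
of a count vector reduces to finding an ok-prefix string with half the
counts; `is_bfb_count_vector()` performs that search breadth-first with
per-segment count caps. When a search bound (cycles or states) is hit
without a witness the result is `NA` — "undecided at bound", never a silent
`FALSE` — and downstream confidence calls treat undecided as ambiguous, not
excluded.

Matching observed copy numbers:

* A configurable homolog baseline (default 1 copy — the unrearranged
  homolog; the source is silent, and 0/2 are available) is subtracted and
  clamped at zero.
* `max_error = 0` (the default, mirroring the source's exact-matching
  invocation): the rounded adjusted vector must be exactly achievable,
  otherwise the call is `excluded`.
* `max_error = Inf`: Poisson-nearest search over all achievable vectors
  within bounds, maximising `sum(log Poisson(n_i | n'_i))` with the
  convention that a zero-copy prediction contributes probability 1 when the
  observation rounds to zero and a configurable floor (1e-10) otherwise.
  Ties break by fewer cycles, then the lexicographically smallest witness.
* The all-zero observed vector is treated as excluded (degenerate: complete
  loss carries no amplification evidence), a documented choice.

Confidence: `high` requires an approximation with at least 8 nonzero
segments *and* fold-back support; fewer segments and/or no fold-back support
give `ambiguous`; infeasibility at the configured error bound gives
`excluded`. The 8-segment rule is the source's stated criterion; which exact
rule separated its "excluded" from "uncertain" fractions is not fully
specified, so infeasibility-at-maxError-0 is this package's documented
interpretation. Telomeric loss is carried as supportive metadata, not a
gate, because the source lists it among the observed features but omits it
from the formal criterion.

`reconstruct_amplicon()` searches cycle sequences whose emitted fold-backs
(boundary position + orientation) exactly consume the observed fold-back
set and whose final counts match the observed segmentation; candidates are
ranked by Poisson likelihood, then fewest cycles. It expects fold-back
coordinates that lie on segment boundaries (as produced by the simulator);
snapping noisy real-world breakends to boundaries is left to the caller.

## Sample integration and cohort statistics

`call_sample()` applies a fixed precedence: intragenic tail-to-tail with
kinase retained → `deltaEC_FGFR1`; kinase-deleting intragenic rearrangement
→ `FGFR1_inactivated`; upstream-window tail-to-tail → `FGFR1_centered`;
otherwise `non_centered`. Predicted FGFR dependency covers the first and
third categories. NSD3 status and BFB confidence ride along as annotations;
junctions with support below `min_support = 2` are flagged low-confidence
but never dropped, because the source reports support counts (15–192)
without a cutoff.

`fisher_exact_2x2()` implements the two-sided Fisher's exact test in the
minimum-likelihood convention (summing hypergeometric probabilities of all
tables with the observed margins whose point probability does not exceed the
observed one). The convention matters: it reproduces the published headline
p = 0.03 for the pooled 7/9-vs-3/12 table. For the NSD3 table (5/9 vs 0/12)
the same convention — and exhaustive enumeration, and `stats::fisher.test` —
give p = 0.0062, while the source prints 0.007; the tests assert the
enumeration oracle, and the discrepancy is surfaced rather than matched. No
multiple-testing correction is applied, as none was in the source. Response
labels (GI50 ≤ 1 µM, ≥ 30% tumor reduction, RECIST) are consumed as given
and never recomputed.

## Bundled fixtures: what they are and are not

The real transcript annotation and sequence cannot be shipped (the study's
raw data are controlled-access), so the bundled FGFR1 and NSD3 models are
**synthetic snapshots**, generated once by `tools/make_fixtures.R` and
marked `synthetic` in their filenames:

* Genomic spans, strands and the TSS are GRCh37-compatible, so published
  breakpoint coordinates (H1581 chr8:38,595,657; DMS114 chr8:38,382,689;
  PDX003 chr8:38,371,080; PDX008 chr8:38,481,135) land in the correct
  window classes.
* FGFR1 has 18 exons with a UTR-only exon 1 and the canonical ATG in exon
  2; the coding sequence is generated with in-frame ATGs planted only at
  residues 1, 150, 250 and 365, which realises the reported start-codon
  choices (exon 5 after exons 1–3 are lost; the end of exon 6 after a break
  in exon 6; exon 9 after exons 1–8 are lost) with the documented domain
  table (IG-I 25–119, acid box 126–138, IG-II 158–246, IG-III 255–357, TM
  377–397, kinase 478–767 of 822 aa).
* NSD3-long has 24 exons with the SET domain (1152–1262 of 1437 aa) encoded
  by exons 19–21; the source does not state which isoform's exon numbering
  its "exons 16 to 24" refers to, so the long isoform is assumed and
  documented. Exon sizes and intron sizes are regular rather than real.

A green test on these fixtures therefore establishes that the *logic*
(window arithmetic, frame arithmetic, domain projection) reproduces the
reported calls — not that the real FGFR1 sequence was used.

The pooled-cohort fixture encodes the 21 pooled models as junction records:
verbatim coordinates where printed, representative synthetic coordinates
where the source gives only prose (notably the three tail-to-tail-positive
nonresponders, which the source counts but does not name), with per-record
provenance in the file.

## Synthetic cohorts

`simulate_cohort()` draws per-sample BFB backgrounds (12 segments over a
synthetic 8p-like arm with the telomere at coordinate 0; 4–6 cycles),
overlays a focal gain whose amplitude is uniform on 4–20 extra copies above
a 1-copy homolog baseline (no amplitude model is published; this range spans
reported amplicon levels), and plants the scenario-defining junction:
intragenic tail-to-tail in introns 1–5, upstream tail-to-tail uniform in
(20 kb, 380 kb] past the TSS, a kinase-deleting head-to-head in intron 5, or
none. FGFR1-centered samples additionally receive an NSD3-deleting junction
with probability 0.5 (5 of 9 in the source) and a higher inner gain tier
over the gene, mimicking amplicons that step up toward the driver. Response
labels follow P(responder | predicted dependent) = 0.78 and
P(responder | otherwise) = 0.25 — the source's observed fractions — and a
Monte-Carlo test checks convergence to the rule. Segment boundaries of the
background deliberately avoid the gene zone so that background fold-backs
never alias the planted signal; breakpoint-calling noise is modelled
separately as Gaussian jitter (0 by default; 10 kb in robustness tests).
All randomness derives from one integer seed through a cohort → sample →
event hierarchy, outputs are byte-identical per seed, and the caller's RNG
state is never disturbed.

What the generator does **not** emulate: read-level evidence, microhomology
at breakpoints, subclonal mixtures, real amplitude distributions, or
non-BFB amplification mechanisms. A green recovery test shows the decision
logic inverts the generator's stated world, nothing more.

## Numerical and degenerate-input choices

* Fisher p-values clamp at 1 and compare point probabilities with a 1e-7
  relative tolerance to absorb floating-point ties; degenerate margins give
  p = 1 exactly.
* Binned profiles use exact interval arithmetic (no per-base loops) and are
  tested against per-base brute force at 1e-9.
* Rolling-mean windows larger than the profile raise an error rather than
  shrink to nothing.
* `is_bfb_count_vector` distinguishes FALSE (search space exhausted) from
  NA (bound hit); `enumerate_bfb_vectors` reports `complete = FALSE` when
  truncated.
* Empty junction sets classify as `non_centered` with a no-evidence flag;
  samples with no segments on the amplicon chromosome carry a no-amplicon
  flag.

## Known limitations

* ORF prediction ignores junction-created codons and promoter/enhancer
  consequences; protein size is not estimated.
* BFB inference assumes a single derivative per arm and no interleaved
  non-BFB rearrangements; cohort-scale tallies from the source
  (11/25 high confidence) are not reproducible without the controlled-access
  data and are not claimed.
* `reconstruct_amplicon` requires fold-backs on exact segment boundaries.
* The Poisson search and the achievability search are exponential in the
  worst case; desk-scale bounds (counts ≤ 64, cycles ≤ 12, bounded states)
  are enforced and overruns reported as undecided.
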