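---
title: "Methods: mapping Ty elements and their meiotic DSB landscape"
author: "tymap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping Ty elements and their meiotic DSB landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tymap)
```

## Background

Ty elements are ~6-kb LTR retrotransposons of *S. cerevisiae* (families
Ty1–Ty5), each carrying ~330-bp long terminal repeats around a Gag/Pol-like
internal coding region. Integration duplicates a 5-bp target sequence
(the TSD), and Ty1–Ty4 integration is strongly biased toward the vicinity
of RNA pol III-transcribed genes such as tRNAs; Ty5 instead targets
subtelomeres. During meiosis, Spo11 makes programmed DNA double-strand
breaks (DSBs), preferentially in nucleosome-depleted RNA pol II
promoters. DSBs in or near dispersed repeats like Tys can seed
non-allelic homologous recombination, so two questions matter: where
exactly are the elements in a given strain, and how much DSB activity do
they and their flanks experience? `tymap` implements a complete,
testable computational treatment of both.

## Insertion detection

**Evidence chain.** A mate pair supports an insertion when one mate
matches Ty internal sequence and the other maps uniquely to the
reference. The chain is:

1. *Classification* (`classify_reads`): exact k-mer seeds (k = 21, at
   stride k/2 so any ≥(k + stride − 1)-bp exact overlap is guaranteed a
   seed) against an index of exemplar internal spans on both strands,
   followed by ungapped verification at the implied diagonal. A hit
   requires ≥ `min_match_len` (default 40 bp) of internal overlap at
   ≤ `max_mismatch_rate` (default 0.05). LTR sequence is excluded from
   the index, so LTR-only reads — which cannot distinguish a full
   element from a solo LTR — are never classified as Ty-matching.
2. *Anchoring* (`te_anchors`): the non-Ty mate is mapped by exact search
   on both strands (`map_reads_unique`); reads with two or more equally
   good locations are discarded outright. A genomic mate on the plus
   strand points rightward toward the insertion, minus strand leftward;
   the anchor coordinate is the mate's innermost base.
3. *Clustering* (`cluster_anchors`): single linkage per chromosome and
   direction with gap ≤ `max_gap`. Because anchor spread is bounded by
   the fragment length, `max_gap` defaults to the library's expected
   insert size (2.8 kb for the default library geometry; 4–5 kb for a
   long-insert library).
4. *Calling* (`call_insertions`): each right-pointing cluster pairs with
   the nearest unused downstream left-pointing cluster whose facing edge
   lies within `pairing_window` (same default as `max_gap`). A call is
   `confirmed` when both directions are represented and total support is
   ≥ `min_support` (default 2 — permissive, but it excludes
   singletons; typical per-site support in a 10× mate-pair library is an
   order of magnitude higher). The family vote is the majority family
   over member anchors, `ambiguous` on ties.
5. *Junction resolution* (`call_tsd_and_orientation`): reads containing
   an element edge (first/last 25 bp, either orientation) adjoined to
   ≥ 25 bp of genomic sequence are split at the edge; the genomic part
   beyond the 5 bases nearest the junction is mapped exactly. With both
   junctions resolved, the spacing between the two genomic attachment
   points distinguishes a 5-bp duplication (spacing 0 between inferred
   target starts, identical pentamers → TSD called, coordinates set to
   the third and fourth duplicated bases) from no duplication (spacing
   5 → `absent`). Any other spacing, disagreeing pentamers, or support
   for multiple orientations leaves the call `undetermined` with a
   conflict note. Orientation follows from which exemplar end abuts the
   left junction; `+` means the exemplar's coding strand matches the
   reference top strand.

**Coordinates.** Everything internal is 1-based inclusive. Where an
insertion shows a TSD beginning at position *t*, the insertion site is
reported as (*t* + 2, *t* + 3) — the third and fourth duplicated bases —
and `tsd_to_insert_coords()` / `insert_coords_to_tsd_start()` are the
single source of truth for that rule. BED exports convert to 0-based
half-open at the boundary.

**Presence/absence anomalies** (`detect_structural_anomalies`): mapped
pair spans exceeding mean + *z*·SD (default *z* = 3) mark sequence the
reference has and the sample lacks (`deletion_in_sample`); clustered
orphan reads (one mate unmapped/multi/discordant, innie orientation
expected) mark novel insertions in the sample. Candidate regions with
fewer than `min_pairs` (default 3) supporting pairs are reported
concordant with a low-coverage note rather than called.

## Completeness model

Supporting-read counts per insertion site are modeled as Poisson;
`fit_poisson` takes λ as the arithmetic mean (the maximum-likelihood
estimate). The per-site miss probability is P(X = 0) = e^−λ. Because
"missed" could also be read genome-wide, the fit reports both the
per-site value and 1 − (1 − e^−λ)^n for *n* sites, labeled distinctly.
At λ = 8.6 these are 1.8 × 10⁻⁴ and (for n = 28) 5.1 × 10⁻³. The
observed/expected table aggregates trailing bins with expected count
< 1 so both columns sum to the site count; no formal test statistic is
attached to it — the package reports the comparison and leaves
significance to the user, since small-sample Poisson goodness-of-fit
p-values depend heavily on binning.

## DSB landscape

**Normalization.** Tracks are per-position counts; `normalize_to_hpm`
scales by 10⁶ / total mapped oligos, making densities comparable across
libraries (and exactly invariant to uniform count rescaling).

**Regions.** Elements closer than `merge_dist` (default 2 kb) merge into
one analysis region, because their flanking windows would otherwise read
each other's element sequence. Ty5-family elements are excluded by
default: Ty5 targets subtelomeres, where DSBs are globally suppressed
for reasons unrelated to the element itself, so including them would
conflate two effects. When chromosome lengths are known, an explicit
distance-from-end rule (default 20 kb) and per-name exclusions are also
available; the packaged 30-element catalog reduces to 27 regions under
the defaults. Control sites come from reference-strain element
positions, minus any within 2 kb of a case region, merged the same way.

**Densities.** Flanking windows of 0.5, 1 and 2 kb abut the focal
interval's edges and exclude element-internal sequence — for an
insertion point (absent from reference coordinates) the windows meet at
the point; for a reference-annotated element they abut its boundaries.
This keeps flanking sequence comparable across site types. Windows
truncated by a chromosome end are flagged and averaged over the bases
actually covered. Element-internal density uses the same hpM/kb formula
over the element span.

**Statistics.** The rank-sum test enumerates all C(m+n, m) group
assignments exactly for combined n ≤ 12 — valid under ties via midranks,
where the textbook exact tables are not — and otherwise uses the normal
approximation with tie-corrected variance. No continuity correction is
applied, which keeps null p-values closely uniform (verified by a KS
check in the test suite); for the sample sizes where the approximation
is used the correction would change p-values by well under the decision
thresholds in play. Two-sided p-values double the smaller tail, capped
at 1. One-way ANOVA delegates to `stats::oneway.test` (equal-variance
form) with explicit degenerate handling: all-constant input returns
F = 0, p = 1. No multiple-testing correction is applied across the
three window widths, which are reported separately, not selected among.

**Burden arithmetic** (`burden_metrics`, `oligo_fraction_to_dsb_percent`):
fold suppression is genome-fraction over oligo-fraction; the ORF-relative
fold divides the per-base oligo rate of coding sequence by that of
elements; percent of DNA broken × 4 chromatids gives percent of cells
(valid while ≤ 25% of DNA, i.e. at most one DSB per four chromatids);
and an oligo fraction times the per-cell DSB count (default 160) gives
expected element DSBs per meiosis. The linear map from oligo counts to
percent DNA broken comes from external calibration against direct DSB
measurements and must be supplied by the user (`dsb_calibration`); only
the mapping strain's relative efficiency (default 0.8) and the rounding
convention (2 significant figures) are built in.

## The simulator

`sim_config` fixes every generator parameter under one seed. Defaults
describe the study system: ~6-kb elements (330-bp LTRs flanking a
5,340-bp internal span), 5-bp TSDs drawn from the packaged target-site
consensus frequencies, insertion sites tRNA-adjacent with probability
0.9, a Ty1-dominant family mix, and an innie mate-pair library with
150-bp reads and 2,800 ± 280-bp inserts (the short-insert library
geometry of the data the detection strategy was designed around; a
4–5-kb long-insert geometry is one configuration change away). Fragment
positions are uniform — no GC bias — because that is the simplest model
that exercises every downstream contract. Oligo tracks draw per-position
Poisson counts around a background rate, multiply promoter windows
(300 bp upstream of each gene) by long-tailed log-normal intensities so
flanking densities span roughly two orders of magnitude, divide
element-internal positions by a suppression factor (default 15), and
optionally enrich designated case flanks by a known factor for recovery
tests.

The Ty1 and Ty2 exemplars share a near-identical LTR differing at the
diagnostic residue (position 284 of the reference LTR; T in Ty1), with
the diagnostic T kept as a lone T so that a deletion is not absorbed
into a homopolymer during alignment — family typing from LTR alignments
(`classify_family_from_ltr`) is exactly the presence/absence of that
residue, and a fragment not covering the position is `ambiguous`.

What the simulator does *not* model: sequencing errors beyond uniform
substitutions, chimeric fragments, platform-specific artifacts, rDNA,
solo LTRs, and nested/truncated elements. Passing tests therefore show
the pipeline's contracts hold on clean evidence at realistic geometry;
they do not certify sensitivity on degraded real archives, which is why
detection thresholds (`min_match_len`, `max_mismatch_rate`,
`min_support`) are exposed rather than fixed.

## Worked pipeline run

A small end-to-end run (two chromosomes totalling 250 kb, six planted
insertions, 8× coverage — the same scale the test suite uses, small
enough to run in seconds-to-minutes yet deep enough that every planted
site is recovered):

```{r pipeline, eval = FALSE}
cfg <- sim_config(seed = 42, n_insertions = 6, coverage = 8,
                  chrom_lengths = c(chrA = 150000, chrB = 100000),
                  family_probs = c(Ty1 = 0.5, Ty2 = 0.3, Ty3 = 0.2))
ref <- make_reference_genome(cfg)
ex  <- make_te_exemplars(cfg)
smp <- plant_insertions(ref, cfg, ex)
prs <- simulate_mate_pairs(smp$genome, cfg)
det <- detect_insertions(prs, ref$genome, ex)
det$calls[, c("chrom", "breakpoint_start", "tsd", "family_vote",
              "orientation", "status")]
fit <- fit_poisson(support_histogram(det$support))
```

On this input every call is `confirmed`, coordinates equal the
third/fourth-base convention applied to the planted TSD starts, and
TSDs, families and orientations match the ground truth exactly (these
are assertions in the test suite, not just an illustration).

## Design choices that were genuinely open

- **Ty5/subtelomere exclusion:** implemented as a family default plus an
  optional distance rule rather than a hard-coded element name, since
  the biological rationale (subtelomeric DSB suppression) is a property
  of the zone and the family's targeting, not of one locus.
- **Windows at insertion points vs element boundaries:** flanks abut the
  breakpoint for case sites but element edges for reference-annotated
  controls, keeping the measured sequence genomic in both cases.
- **Per-site vs genome-wide miss probability:** both are reported under
  distinct names instead of guessing which reading a user intends.
- **Exact rank-sum under ties:** enumeration rather than the classical
  tables, because tied densities are common in sparse windows.
- **Breakpoint representation:** an interval between cluster-facing
  edges until junction evidence exists, collapsed to the two-coordinate
  TSD convention only when a duplication is actually resolved.

## Limitations

Exact-match unique mapping is deliberately simple: adequate for clean
simulated libraries and for the package's contracts, but not a
general-purpose aligner for real archives. Family typing uses only the
single diagnostic LTR residue, not whole-LTR phylogeny, and so inherits
that marker's blind spots. The completeness model assumes sites are
exchangeable Poisson draws; strongly heterogeneous mappability would
violate that. Solo-LTR discovery, hotspot calling, and Southern-blot
style DSB quantification are out of scope.
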