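# tymap

Mapping Ty retrotransposons and their meiotic DSB landscape in budding
yeast.

`tymap` is an R package for researchers studying transposable elements and
meiotic recombination in *Saccharomyces cerevisiae*. It covers the full
computational path from raw paired-end reads to a quantitative picture of
double-strand-break (DSB) potential around every Ty insertion:

1. **Insertion discovery from mate pairs.** Reads matching the internal
   (non-LTR) portion of Ty family exemplars are identified by k-mer
   seeding with ungapped verification; their mates are mapped uniquely to
   the reference (multi-mappers are discarded, never arbitrarily
   assigned). Anchors cluster by direction, and a right-pointing cluster
   converging on a downstream left-pointing cluster yields an insertion
   call. Junction-spanning reads then resolve the element's orientation
   and its 5-bp target-site duplication (TSD); when a TSD is found the
   insertion coordinates collapse to the third and fourth duplicated
   bases, the convention used throughout. Insert-size and orphan-read
   anomalies additionally flag elements present in the reference but
   absent from the sample, and vice versa.
2. **Catalog completeness.** Per-site supporting-read counts are modeled
   as Poisson with rate λ equal to the observed mean. The probability
   that a site was missed for lack of supporting reads is the zero-count
   probability *P*(X = 0) = e^−λ; at the observed mean of 8.6 reads per
   site this is 1.8 × 10⁻⁴, and the genome-wide chance that any of *n*
   comparable sites was missed is 1 − (1 − e^−λ)^n.
3. **DSB landscape.** Spo11-oligo count tracks are normalized to hits per
   million mapped reads (hpM) and summarized as hpM/kb densities in 0.5,
   1 and 2-kb windows abutting each insertion, against control sites
   where only the reference strain carries an element. Intergenic
   contexts (divergent / tandem / convergent) are classified from
   flanking gene strands; group comparisons use a Wilcoxon rank-sum test
   (exact enumeration with midrank ties for small samples) and one-way
   ANOVA. Burden arithmetic converts oligo fractions to fold-suppression
   values and per-cell DSB frequencies (e.g. percent of DNA broken × 4
   chromatids = percent of cells).
4. **Synthetic data with ground truth.** A seeded simulator emits
   annotated reference genomes, sample genomes with planted ~6-kb
   elements (330-bp LTRs, 5-bp TSDs, 90% tRNA-adjacent targeting), innie
   mate-pair libraries, and Spo11-oligo-like tracks with promoter
   hotspots and element-internal suppression, so every downstream claim
   is testable against known truth.

## Worked example

```r
library(tymap)

catalog <- sk1_ty_catalog()        # packaged 30-element SK1 catalog
summary(catalog)
#> Ty catalog summary: 30 elements (2 fragment(s))
#>   families:           Ty1=21, Ty2=5, Ty3=1, Ty5=1, ambiguous=2
#>   tRNA-adjacent:      26 of 29 non-Ty5 elements (90%)
#>   perfect TSD:        23 of 24 determined sites (95.8%)
#>   genome occupancy:   ~1.5% of genomic DNA

length(build_analysis_regions(catalog))
#> [1] 27

# completeness of a screen averaging ~8.6 supporting reads per site
fit_poisson(support_histogram(rep(c(8, 9), c(11, 17))))
#> Poisson fit to supporting-read counts at 28 sites
#>   lambda (mean support):     8.61
#>   per-site miss probability: 0.000183
#>   P(any of 28 sites missed): 0.00511

# burden arithmetic: elements occupy 1.5% of the genome but yield only
# 0.1% of Spo11 oligos; coding sequence yields 11.5% from 69.4% of bases
b <- burden_metrics(ty_genome_frac = 1.5, ty_oligo_frac = 0.1,
                    orf_oligo_frac = 11.5, orf_genome_frac = 69.4,
                    per_dna_frac = 0.3, oligo_frac = 0.28)
#> fold suppression vs genome: 15
#> fold colder than a typical ORF: 2.5
#> cells with a DSB in this element: 1.2%
#> one Ty/LTR DSB per 2.2 cells
```

The summary says: the catalog holds 30 elements, dominated by Ty1;
26 of the 29 non-Ty5 elements sit next to a tRNA gene (the hallmark of
Ty1–Ty4 targeting); all but one precisely mapped site shows a perfect
5-bp duplication; and after merging co-located neighbours and excluding
the subtelomeric Ty5, 27 regions remain for DSB analysis. The Poisson
fit says a screen that deep misses a given site with probability
~2 × 10⁻⁴. The burden numbers say DSBs inside elements are ~15-fold
rarer than the genome average, but only ~2.5-fold rarer than in a
typical ORF, and that a within-element DSB is a routine event at the
population scale.

A full simulated pipeline run (genome → planted insertions → reads →
detection) is shown in the methods vignette; the command-line front end
in `inst/cli/tymap` exposes `simulate`, `detect` and `landscape`
subcommands over the same functions.

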