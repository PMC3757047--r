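# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# One moderately sized end-to-end simulation reused by the detection,
# synthetic-data and acceptance tests: 250-kb two-chromosome genome,
# six planted elements across three families, 8x read coverage.
shared_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    cfg <- sim_config(seed = 42, n_insertions = 6, coverage = 8,
                      chrom_lengths = c(chrA = 150000, chrB = 100000),
                      family_probs = c(Ty1 = 0.5, Ty2 = 0.3, Ty3 = 0.2))
    ref <- make_reference_genome(cfg)
    ex <- make_te_exemplars(cfg)
    smp <- plant_insertions(ref, cfg, ex)
    prs <- simulate_mate_pairs(smp$genome, cfg)
    det <- detect_insertions(prs, ref$genome, ex)
    .fixture_cache$sim <- list(cfg = cfg, ref = ref, ex = ex, smp = smp,
                               prs = prs, det = det)
  }
  .fixture_cache$sim
}

# A tiny catalog for merge/control-site tests.
toy_catalog <- function(chrom, start, end, family = "Ty1", strand = "+",
                        name = NULL) {
  n <- length(start)
  ty_catalog(data.frame(
    chrom = rep_len(chrom, n),
    name = if (is.null(name)) sprintf("el%02d", seq_len(n)) else name,
    start = start, end = end,
    family = rep_len(family, n), strand = rep_len(strand, n),
    trna = rep_len("unknown", n), tsd = rep_len("undetermined", n),
    completeness = rep_len("full", n), note = rep_len("", n)))
}

# Expected sample-genome coordinate of each planted element's first base,
# from the ground truth (elements splice in left to right per chromosome).
truth_sample_coords <- function(truth, element_len = 6000L, tsd_len = 5L) {
  truth <- truth[order(truth$chrom, truth$tsd_start), , drop = FALSE]
  out <- integer(nrow(truth))
  for (ch in unique(truth$chrom)) {
    rows <- which(truth$chrom == ch)
    shift <- 0L
    for (i in rows) {
      has_tsd <- truth$tsd[i] != "absent"
      out[i] <- truth$tsd_start[i] + shift + if (has_tsd) tsd_len else 0L
      shift <- shift + element_len + if (has_tsd) tsd_len else 0L
    }
  }
  out
}
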