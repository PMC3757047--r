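test_that("hpM normalization scales by library size and is idempotent", {
  v <- numeric(1000); v[10] <- 5
  tr <- oligo_track(list(chr1 = v), total_mapped = 1e6)
  norm <- normalize_to_hpm(tr)
  expect_equal(norm$counts$chr1[10], 5)

  tr2 <- oligo_track(list(chr1 = v), total_mapped = 2e6)
  expect_equal(normalize_to_hpm(tr2)$counts$chr1[10], 2.5)

  # idempotent
  expect_equal(normalize_to_hpm(norm)$counts$chr1, norm$counts$chr1)
  # all-zero track stays all-zero (with explicit library size)
  z <- oligo_track(list(chr1 = numeric(100)), total_mapped = 10)
  expect_equal(sum(normalize_to_hpm(z)$counts$chr1), 0)
  expect_error(normalize_to_hpm(oligo_track(list(chr1 = numeric(10)))),
               "total mapped")

  # full raw track normalizes to a genome-wide hpM sum of 1e6
  set.seed(2)
  raw <- oligo_track(list(a = rpois(5000, 2), b = rpois(3000, 1)))
  expect_equal(sum(unlist(normalize_to_hpm(raw)$counts)), 1e6,
               tolerance = 1e-9)
})

test_that("bedGraph round-trip preserves per-position counts", {
  set.seed(3)
  counts <- list(chrA = as.numeric(rpois(400, 0.5)),
                 chrB = as.numeric(rpois(250, 2)))
  tr <- oligo_track(counts)
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_oligo_track(tr, path)
  back <- read_oligo_track(path, chrom_lengths = c(chrA = 400, chrB = 250))
  expect_equal(back$counts$chrA, counts$chrA)
  expect_equal(back$counts$chrB, counts$chrB)
  expect_equal(back$total_mapped, tr$total_mapped)
})

test_that("the packaged catalog yields 27 merged analysis regions", {
  cat30 <- sk1_ty_catalog()
  regions <- build_analysis_regions(cat30)
  expect_length(regions, 27)
  # 29 of 30 elements survive the Ty5 exclusion and fill the regions
  expect_identical(sum(regions$n_members), 29L)
  # the two co-located pairs merged into two-member regions
  expect_identical(sum(regions$n_members == 2L), 2L)
  merged <- regions[regions$n_members == 2L]
  expect_true(any(grepl("EXG2", merged$members)))
  expect_true(any(grepl("NCE103", merged$members)))

  # no merging when elements are isolated
  iso <- toy_catalog("I", c(1000, 50000), c(1010, 50010))
  expect_length(build_analysis_regions(iso), 2)
  # zero-gap neighbours merge into a single two-member region
  touching <- toy_catalog("I", c(1000, 1021), c(1020, 1040))
  reg <- build_analysis_regions(touching)
  expect_length(reg, 1)
  expect_identical(reg$n_members, 2L)
})

test_that("control sites are filtered by distance to cases, then merged", {
  cases <- build_analysis_regions(toy_catalog("I", 50000, 56000))
  ctrl_cat <- toy_catalog(
    "I", c(10000, 20000, 30000, 57500, 90000),
    c(16000, 26000, 36000, 63500, 96000))
  # one control sits 1.5 kb from the case edge -> removed at min_dist 2 kb
  kept <- select_control_sites(ctrl_cat, cases)
  expect_length(kept, 4)
  expect_false(any(grepl("el04", kept$members)))

  # empty reference list
  empty <- select_control_sites(toy_catalog("I", integer(0), integer(0)),
                                cases)
  expect_length(empty, 0)

  # two reference elements 500 bp apart, far from cases, merge
  near <- toy_catalog("II", c(10000, 16500), c(16000, 22500))
  merged <- select_control_sites(near, cases)
  expect_length(merged, 1)
  expect_identical(merged$n_members, 2L)
})

test_that("flanking windows abut the focal interval and use hpM per kb", {
  uniform <- oligo_track(list(chr1 = rep(0.1, 20000)), normalized = TRUE)
  region <- list(chrom = "chr1", start = 10000, end = 10001)
  for (w in c(500, 1000, 2000)) {
    for (s in c("left", "right")) {
      fd <- flanking_density(uniform, region, w, s)
      expect_equal(fd$density, 100)
      expect_false(fd$truncated)
    }
  }

  # 50 hpM concentrated inside a 0.5-kb window -> 100 hpM/kb
  v <- numeric(20000); v[9600] <- 50
  tr <- oligo_track(list(chr1 = v), normalized = TRUE)
  expect_equal(flanking_density(tr, region, 500, "left")$density, 100)
  # zero-count window
  expect_equal(flanking_density(tr, region, 500, "right")$density, 0)

  # two adjacent 0.5-kb windows average to the 1-kb density
  set.seed(4)
  rnd <- oligo_track(list(chr1 = as.numeric(rpois(20000, 1))),
                     normalized = TRUE)
  d500 <- flanking_density(rnd, region, 500, "left")$density
  inner <- list(chrom = "chr1", start = 9500, end = 10001)
  d500b <- flanking_density(rnd, inner, 500, "left")$density
  d1000 <- flanking_density(rnd, region, 1000, "left")$density
  expect_equal((d500 + d500b) / 2, d1000)

  # truncation at the chromosome end is flagged
  edge <- flanking_density(rnd, list(chrom = "chr1", start = 300, end = 301),
                           500, "left")
  expect_true(edge$truncated)
  expect_identical(edge$actual_width, 299L)
  expect_error(
    flanking_density(rnd, list(chrom = "chr1", start = 1, end = 2),
                     500, "left"),
    "off chromosome")
  expect_error(flanking_density(oligo_track(list(chr1 = v)), region, 500),
               "normalized")
})

test_that("internal density matches the flanking formula on the element span", {
  # uniform 0.0067 hpM/bp over a 6-kb element -> 6.7 hpM/kb
  tr <- oligo_track(list(chr1 = rep(0.0067, 10000)), normalized = TRUE)
  expect_equal(internal_density(tr, list(chrom = "chr1", start = 2001,
                                         end = 8000)), 6.7)
  z <- oligo_track(list(chr1 = numeric(10000)), normalized = TRUE)
  expect_equal(internal_density(z, list(chrom = "chr1", start = 2001,
                                        end = 8000)), 0)
})

test_that("densities are invariant to library-size rescaling of raw counts", {
  set.seed(8)
  counts <- as.numeric(rpois(20000, 1))
  region <- list(chrom = "chr1", start = 10000, end = 10001)
  t1 <- normalize_to_hpm(oligo_track(list(chr1 = counts)))
  t2 <- normalize_to_hpm(oligo_track(list(chr1 = counts * 7)))
  expect_equal(flanking_density(t1, region, 1000, "left")$density,
               flanking_density(t2, region, 1000, "left")$density)
})

test_that("rank-sum exact branch matches enumeration and reference code", {
  # frozen hand-enumerated case: 20 assignments, one per tail at the extreme
  res <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_two_sided, 0.1)
  expect_equal(res$statistic, 6)

  # identical multisets are maximally null
  expect_equal(rank_sum_test(c(1, 2, 2, 3), c(1, 2, 2, 3))$p_two_sided, 1)

  # tie-free exact branch reproduces wilcox.test's exact p
  set.seed(9)
  for (r in 1:25) {
    a <- sample(seq(1, 399, by = 2), 5)
    b <- sample(seq(2, 400, by = 2), 6)
    expect_equal(rank_sum_test(a, b)$p_two_sided,
                 wilcox.test(a, b, exact = TRUE)$p.value)
  }

  # independent brute-force enumeration, including ties
  brute <- function(a, b) {
    m <- length(a); N <- m + length(b)
    r <- rank(c(a, b))
    W <- sum(r[seq_len(m)])
    sums <- apply(utils::combn(N, m), 2, function(ix) sum(r[ix]))
    min(1, 2 * min(mean(sums <= W + 1e-9), mean(sums >= W - 1e-9)))
  }
  set.seed(10)
  for (r in 1:15) {
    a <- sample(1:6, 5, replace = TRUE)
    b <- sample(1:6, 6, replace = TRUE)
    expect_equal(rank_sum_test(a, b)$p_two_sided, brute(a, b))
  }
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum p-values are uniform under the null at n = 30 vs 37", {
  set.seed(5)
  ps <- replicate(200, rank_sum_test(rnorm(30), rnorm(37))$p_two_sided)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("intergenic context follows flanking gene strands", {
  mk_ann <- function(s1, s2) {
    GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(c(1000, 9000, 4500), c(3000, 11000, 4580)),
      strand = c(s1, s2, "+"),
      type = c("gene", "gene", "tRNA_gene"),
      ID = c("g1", "g2", "t1"))
  }
  region <- list(chrom = "chr1", start = 5500, end = 5501)
  expect_identical(classify_intergenic(region, mk_ann("-", "+"))$class,
                   "divergent")
  expect_identical(classify_intergenic(region, mk_ann("+", "+"))$class,
                   "tandem")
  expect_identical(classify_intergenic(region, mk_ann("-", "-"))$class,
                   "tandem")
  expect_identical(classify_intergenic(region, mk_ann("+", "-"))$class,
                   "convergent")
  expect_true(classify_intergenic(region, mk_ann("-", "+"))$contains_trna)

  # focal point inside a gene
  expect_identical(
    classify_intergenic(list(chrom = "chr1", start = 2000, end = 2001),
                        mk_ann("+", "-"))$class,
    "intragenic")
  # chromosome end: no flanking gene on one side
  expect_identical(
    classify_intergenic(list(chrom = "chr1", start = 500, end = 501),
                        mk_ann("+", "-"))$class,
    "undetermined")
})

test_that("one-way ANOVA matches its algebraic identities", {
  # two groups: F equals the square of the pooled-variance t statistic
  set.seed(6)
  a <- rnorm(9); b <- rnorm(12, 0.5)
  res <- one_way_anova(list(a, b))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)

  # hand-computed oracle: SSB = 6 (df 2), SSW = 6 (df 6) -> F = 3
  res3 <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(res3$F, 3)
  expect_identical(res3$df_between, 2)
  expect_identical(res3$df_within, 6)

  # identical constants carry no signal
  const <- one_way_anova(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(const$F, 0)
  expect_equal(const$p, 1)

  expect_error(one_way_anova(list(1:3)), "two groups")
  expect_error(one_way_anova(list(1, 2)), "exceed")
})

test_that("oligo fractions convert to efficiency-corrected DSB percentages", {
  # calibration chosen so the uncorrected estimates are 2.0% and 0.85%
  calib <- dsb_calibration(slope = 20, intercept = 0, efficiency = 0.8)
  dmc1 <- oligo_fraction_to_dsb_percent(0.1, calib)
  expect_equal(dmc1$uncorrected, 2.0)
  expect_equal(dmc1$corrected, 2.5)

  sae2 <- oligo_fraction_to_dsb_percent(0.0425, calib)
  expect_equal(sae2$uncorrected, 0.85)
  expect_equal(sae2$corrected, 1.1)  # 1.0625 to 2 s.f.

  ident <- oligo_fraction_to_dsb_percent(
    0.1, dsb_calibration(slope = 20, efficiency = 1))
  expect_equal(ident$corrected, ident$uncorrected)

  expect_error(dsb_calibration(efficiency = 0), "efficiency")
  expect_error(dsb_calibration(efficiency = 1.2), "efficiency")
  expect_error(oligo_fraction_to_dsb_percent(0.1, dsb_calibration()),
               "slope")
})

test_that("burden metrics reproduce the printed arithmetic", {
  b <- burden_metrics(ty_genome_frac = 1.5, ty_oligo_frac = 0.1,
                      orf_oligo_frac = 11.5, orf_genome_frac = 69.4,
                      per_dna_frac = 0.3, oligo_frac = 0.28)
  expect_equal(b$fold_suppression, 15)
  expect_equal(round(b$orf_relative_fold, 2), 2.49)
  expect_lte(b$orf_relative_fold, 3)
  expect_equal(b$cell_frac, 1.2)
  # ~0.28% of oligos at ~160 DSBs/cell -> one Ty DSB in every 2-3 cells
  expect_equal(b$expected_dsbs_per_cell, 0.448)
  expect_gt(b$one_in_n_cells, 2)
  expect_lt(b$one_in_n_cells, 3)

  # exact linear / multiplicative scaling in each argument
  b2 <- burden_metrics(2 * 1.5, 0.1)
  expect_equal(b2$fold_suppression, 2 * b$fold_suppression)
  b3 <- burden_metrics(1.5, 2 * 0.1)
  expect_equal(b3$fold_suppression, b$fold_suppression / 2)
  b4 <- burden_metrics(1.5, 0.1, per_dna_frac = 0.15)
  expect_equal(b4$cell_frac, b$cell_frac / 2)

  expect_error(burden_metrics(1.5, 0), "denominator")
  expect_error(burden_metrics(1.5, 0.1, per_dna_frac = 30), "25")
})
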