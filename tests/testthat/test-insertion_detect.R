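test_that("read classification hits internal sequence only", {
  ex <- make_te_exemplars(sim_config(seed = 3))
  index <- te_kmer_index(ex)
  ty1 <- ex$Ty1

  # exact 100-bp substring of the Ty1 internal span, known offset
  offset <- ty1$internal_span[1] + 500L
  read <- substr(ty1$sequence, offset, offset + 99L)
  hit <- classify_read(read, index)
  expect_identical(hit$family, "Ty1")
  expect_identical(hit$te_offset, offset)
  expect_identical(hit$te_strand, "+")

  # same read on the opposite strand
  hit_rc <- classify_read(revcomp(read), index)
  expect_identical(hit_rc$family, "Ty1")
  expect_identical(hit_rc$te_offset, offset)
  expect_identical(hit_rc$te_strand, "-")

  # a read drawn entirely from an LTR is never Ty-matching
  ltr_read <- substr(ty1$sequence, 101L, 200L)
  expect_null(classify_read(ltr_read, index))

  # junction read with insufficient internal overlap fails min_match_len
  junct39 <- substr(ty1$sequence, ty1$internal_span[1] - 61L,
                    ty1$internal_span[1] + 38L)
  expect_null(classify_read(junct39, index, min_match_len = 40L))
  junct60 <- substr(ty1$sequence, ty1$internal_span[1] - 40L,
                    ty1$internal_span[1] + 59L)
  hit_j <- classify_read(junct60, index, min_match_len = 40L)
  expect_identical(hit_j$family, "Ty1")
  expect_identical(hit_j$te_offset, ty1$internal_span[1])

  # random sequence sharing no k-mer with the exemplars
  set.seed(12)
  rnd <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
               collapse = "")
  expect_null(classify_read(rnd, index))

  expect_error(te_kmer_index(list()), "empty exemplar set")
})

test_that("unique mapping distinguishes unique, multi and unmapped reads", {
  set.seed(13)
  dup <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
  genome <- c(
    g1 = paste0(paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                      collapse = ""), dup),
    g2 = paste0(dup, paste(sample(c("A", "C", "G", "T"), 5000,
                                  replace = TRUE), collapse = "")))

  unique_read <- substr(genome[["g1"]], 1001, 1100)
  m <- map_read_unique(unique_read, genome)
  expect_identical(m$chrom, "g1")
  expect_identical(m$position, 1001L)
  expect_identical(m$strand, "+")

  # reverse-complemented copy maps to the same locus on the minus strand
  m_rc <- map_read_unique(revcomp(unique_read), genome)
  expect_identical(m_rc$chrom, "g1")
  expect_identical(m_rc$strand, "-")

  # sequence planted at two loci is discarded as multi
  expect_identical(map_read_unique(substr(dup, 1, 100), genome), "multi")
  # novel sequence is unmapped
  set.seed(14)
  expect_identical(
    map_read_unique(paste(sample(c("A", "C", "G", "T"), 100,
                                 replace = TRUE), collapse = ""), genome),
    "unmapped")
})

test_that("anchor clustering is single-linkage, complete and order-invariant", {
  mk <- function(pos, chrom = "c1", dir = "points_right") {
    n <- length(pos)
    data.frame(pair_id = sprintf("p%d", seq_len(n)),
               chrom = rep_len(chrom, n), position = pos,
               direction = rep_len(dir, n),
               te_family = rep_len("Ty1", n),
               te_offset = rep_len(1000L, n))
  }
  cl <- cluster_anchors(mk(c(100, 600, 1100)), max_gap = 5000)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$n, 3L)
  expect_identical(cl$span_start, 100)
  expect_identical(cl$span_end, 1100)

  cl2 <- cluster_anchors(mk(c(100, 20000)), max_gap = 5000)
  expect_identical(nrow(cl2), 2L)

  expect_identical(nrow(cluster_anchors(mk(numeric(0)), 5000)), 0L)

  # invariance to input order; every anchor lands in exactly one cluster
  set.seed(15)
  anchors <- rbind(mk(sample(1:100000, 40)),
                   mk(sample(1:100000, 30), dir = "points_left"),
                   mk(sample(1:50000, 20), chrom = "c2"))
  shuffled <- anchors[sample(nrow(anchors)), ]
  c_a <- cluster_anchors(anchors, max_gap = 3000)
  c_b <- cluster_anchors(shuffled, max_gap = 3000)
  expect_identical(c_a[setdiff(names(c_a), "cluster_id")],
                   c_b[setdiff(names(c_b), "cluster_id")])
  members <- attr(c_a, "anchors")
  expect_identical(nrow(members), nrow(anchors))
  expect_false(any(is.na(members$cluster_id)))
  # members lie within their cluster span and share chrom/direction
  for (cid in c_a$cluster_id) {
    a <- members[members$cluster_id == cid, ]
    row <- c_a[c_a$cluster_id == cid, ]
    expect_true(all(a$position >= row$span_start &
                      a$position <= row$span_end))
    expect_identical(unique(a$chrom), row$chrom)
    expect_identical(unique(a$direction), row$direction)
  }
})

test_that("converging clusters pair into calls with support bookkeeping", {
  clusters <- data.frame(
    cluster_id = 1:3,
    chrom = c("c1", "c1", "c2"),
    direction = c("points_right", "points_left", "points_right"),
    span_start = c(47000, 50100, 8000),
    span_end = c(49900, 52800, 9000),
    n = c(10L, 8L, 4L),
    families = c(paste(rep("Ty1", 10), collapse = ","),
                 paste(rep("Ty1", 8), collapse = ","),
                 paste(rep("Ty2", 4), collapse = ",")))
  calls <- call_insertions(clusters, pairing_window = 3000, min_support = 2)
  expect_identical(nrow(calls), 2L)
  paired <- calls[calls$chrom == "c1", ]
  expect_identical(paired$status, "confirmed")
  expect_identical(paired$left_support, 10L)
  expect_identical(paired$right_support, 8L)
  expect_identical(paired$family_vote, "Ty1")
  expect_identical(paired$breakpoint_start, 49900)
  expect_identical(paired$breakpoint_end, 50100)

  lone <- calls[calls$chrom == "c2", ]
  expect_identical(lone$status, "candidate")
  expect_identical(lone$right_support, 0L)

  empty <- call_insertions(clusters[0, ], 3000)
  expect_identical(nrow(empty), 0L)
})

test_that("end-to-end detection recovers every planted insertion exactly", {
  sim <- shared_sim()
  calls <- sim$det$calls
  truth <- sim$smp$truth[order(sim$smp$truth$chrom,
                               sim$smp$truth$tsd_start), ]

  # complete recovery, all confirmed, and zero false positives
  expect_identical(nrow(calls), nrow(truth))
  expect_true(all(calls$status == "confirmed"))
  expect_true(all(calls$left_support >= 2 & calls$right_support >= 2))

  ord <- order(calls$chrom, calls$breakpoint_start)
  calls <- calls[ord, ]
  expect_identical(calls$chrom, truth$chrom)
  # footnote-convention coordinates, exact TSDs, family and orientation
  expect_identical(as.integer(calls$breakpoint_start), truth$insert_start)
  expect_identical(as.integer(calls$breakpoint_end), truth$insert_end)
  expect_identical(calls$tsd, truth$tsd)
  expect_identical(calls$family_vote, truth$family)
  expect_identical(calls$orientation, truth$strand)

  # no confirmed call farther than the pairing window from a breakpoint
  for (i in seq_len(nrow(calls)))
    expect_lt(min(abs(calls$breakpoint_start[i] -
                        truth$tsd_start[truth$chrom == calls$chrom[i]])),
              sim$cfg$insert_mean)

  # per-site support is consistent with the library geometry:
  # fragments place one mate in the internal span and the other in
  # unique flanking sequence over ~(insert - read - LTR - min_match) bp
  # per junction
  lambda0 <- 2 * (sim$prs$n_pairs / sum(nchar(sim$smp$genome))) *
    (sim$cfg$insert_mean - sim$cfg$read_len - sim$cfg$ltr_len - 40 + 1)
  lam_hat <- fit_poisson(support_histogram(sim$det$support))$lambda
  expect_lt(abs(lam_hat - lambda0),
            3 * sqrt(lambda0 / nrow(calls)) + 0.05 * lambda0)
})

test_that("insertions planted without duplication are called TSD-absent", {
  cfg <- sim_config(seed = 51, chrom_lengths = c(cA = 80000),
                    trna_count = 4L, n_insertions = 2L, coverage = 8,
                    tsd_absent_prob = 1, min_separation = 15000L)
  ref <- make_reference_genome(cfg)
  ex <- make_te_exemplars(cfg)
  smp <- plant_insertions(ref, cfg, ex)
  expect_true(all(smp$truth$tsd == "absent"))
  expect_identical(sum(nchar(smp$genome)) - sum(nchar(ref$genome)),
                   2L * 6000L)
  prs <- simulate_mate_pairs(smp$genome, cfg)
  det <- detect_insertions(prs, ref$genome, ex)
  expect_identical(nrow(det$calls), 2L)
  expect_true(all(det$calls$tsd == "absent"))
  expect_equal(sort(det$calls$breakpoint_end),
               sort(as.numeric(smp$truth$tsd_start)))
})

test_that("calls without junction coverage stay undetermined", {
  sim <- shared_sim()
  fake <- data.frame(chrom = "chrA", breakpoint_start = 20L,
                     breakpoint_end = 21L, left_support = 2L,
                     right_support = 2L, family_vote = "Ty1",
                     orientation = "undetermined", tsd = "undetermined",
                     status = "confirmed")
  res <- call_tsd_and_orientation(fake, c(sim$prs$read1[1:50],
                                          sim$prs$read2[1:50]),
                                  sim$ref$genome, sim$ex, window = 1000)
  expect_identical(res$tsd, "undetermined")
})

test_that("structural anomalies flag missing and novel elements", {
  cfg <- sim_config(seed = 61, chrom_lengths = c(cA = 60000),
                    trna_count = 3L, n_insertions = 1L, coverage = 6)
  ref <- make_reference_genome(cfg)
  ex <- make_te_exemplars(cfg)
  smp <- plant_insertions(ref, cfg, ex)
  t0 <- smp$truth$tsd_start[1]

  # reads from a sample identical to the reference: concordant only
  prs_self <- simulate_mate_pairs(ref$genome, cfg)
  self <- detect_structural_anomalies(prs_self, ref$genome)
  expect_true(all(self$kind == "concordant"))

  # sample lacking a 6-kb element present in the reference: pairs span
  # the element with ~6-kb stretched inserts
  prs_ref <- simulate_mate_pairs(ref$genome, cfg)
  del <- detect_structural_anomalies(prs_ref, smp$genome)
  del_hits <- del[del$kind == "deletion_in_sample", ]
  expect_gte(nrow(del_hits), 1L)
  # flagged gap encloses the element position in sample coordinates
  el_start <- truth_sample_coords(smp$truth)[1]
  expect_true(any(del_hits$start < el_start &
                    del_hits$end > el_start + 6000))

  # sample carrying a novel insertion: orphan pileup at the breakpoint
  prs_smp <- simulate_mate_pairs(smp$genome, cfg)
  ins <- detect_structural_anomalies(prs_smp, ref$genome)
  ins_hits <- ins[ins$kind == "insertion_in_sample", ]
  expect_gte(nrow(ins_hits), 1L)
  expect_true(any(abs((ins_hits$start + ins_hits$end) / 2 - t0) <
                    2 * cfg$insert_mean))
})

test_that("calls and anomalies export to TSV and BED conventions", {
  sim <- shared_sim()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_insertion_calls(sim$det$calls, tsv, bed)
  tab <- utils::read.delim(tsv)
  expect_identical(nrow(tab), nrow(sim$det$calls))
  expect_identical(names(tab)[1:4], c("chrom", "name", "start", "end"))
  bedtab <- utils::read.delim(bed, header = FALSE)
  # BED is 0-based half-open: width of a two-base breakpoint is 2
  expect_true(all(bedtab$V3 - bedtab$V2 == 2))
  expect_identical(bedtab$V2, sim$det$calls$breakpoint_start - 1L)

  an <- data.frame(chrom = "cA", start = 100L, end = 200L,
                   kind = "deletion_in_sample", stretched_pairs = 5L,
                   orphan_reads = 0L, note = "")
  abed <- withr::local_tempfile(fileext = ".bed")
  write_anomalies_bed(an, abed)
  atab <- utils::read.delim(abed, header = FALSE)
  expect_identical(atab$V4, "deletion_in_sample")
  expect_identical(atab$V2, 99L)
})
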