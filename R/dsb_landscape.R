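# Spo11-oligo track handling and DSB-potential statistics: hpM
# normalization, analysis/control region construction, flanking-window and
# element-internal densities, intergenic-context classification, the
# rank-sum and ANOVA comparisons, and burden arithmetic.

#' Construct a per-position Spo11-oligo count track
#'
#' @param counts named list of per-position numeric vectors, one per
#'   chromosome (position i of vector = 1-based coordinate i).
#' @param total_mapped total mapped oligo count used for hpM
#'   normalization; defaults to the sum of `counts` (appropriate for raw
#'   tracks covering the whole genome).
#' @param normalized logical; `TRUE` when values are already hits per
#'   million mapped reads (hpM).
#' @return object of class `oligo_track`.
#' @export
oligo_track <- function(counts, total_mapped = NULL, normalized = FALSE) {
  stopifnot(is.list(counts), !is.null(names(counts)),
            all(nzchar(names(counts))))
  counts <- lapply(counts, as.numeric)
  if (any(vapply(counts, function(v) any(v < 0 | is.na(v)), logical(1L))))
    stop("track counts must be non-negative and non-missing")
  if (is.null(total_mapped)) total_mapped <- sum(vapply(counts, sum, 0))
  structure(list(counts = counts, total_mapped = total_mapped,
                 normalized = isTRUE(normalized)),
            class = "oligo_track")
}

#' @export
print.oligo_track <- function(x, ...) {
  cat(sprintf("Spo11-oligo track: %d chromosome(s), %s bp, %s\n",
              length(x$counts),
              format(sum(lengths(x$counts)), big.mark = ","),
              if (x$normalized) "normalized (hpM)" else
                sprintf("raw (%.4g mapped)", x$total_mapped)))
  invisible(x)
}

#' Normalize a track to hits per million mapped reads
#'
#' Scales every per-position value by `1e6 / total_mapped` so the
#' genome-wide sum of a full raw track becomes 1e6. Idempotent on already
#' normalized tracks.
#'
#' @param track an [oligo_track()].
#' @return normalized `oligo_track`.
#' @export
normalize_to_hpm <- function(track) {
  stopifnot(inherits(track, "oligo_track"))
  if (track$normalized) return(track)
  if (track$total_mapped <= 0)
    stop("cannot normalize: total mapped count is zero")
  track$counts <- lapply(track$counts, function(v) v * 1e6 / track$total_mapped)
  track$normalized <- TRUE
  track
}

#' Read / write a track as bedGraph
#'
#' bedGraph intervals are 0-based half-open on disk and converted to the
#' internal 1-based per-position representation; positions not covered by
#' any interval are zero.
#'
#' @param path bedGraph file.
#' @param chrom_lengths optional named lengths; defaults to the largest
#'   covered coordinate per chromosome.
#' @return an [oligo_track()] (raw; `total_mapped` = sum of values).
#' @export
read_oligo_track <- function(path, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  chroms <- as.character(unique(GenomicRanges::seqnames(gr)))
  if (is.null(chrom_lengths))
    chrom_lengths <- vapply(chroms, function(ch)
      max(GenomicRanges::end(gr[GenomicRanges::seqnames(gr) == ch])), 0)
  counts <- lapply(names(chrom_lengths), function(ch) {
    v <- numeric(chrom_lengths[[ch]])
    g <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
    if (length(g) > 0L)
      for (i in seq_along(g)) {
        sel <- GenomicRanges::start(g)[i]:GenomicRanges::end(g)[i]
        v[sel] <- v[sel] + g$score[i]
      }
    v
  })
  oligo_track(stats::setNames(counts, names(chrom_lengths)))
}

#' @rdname read_oligo_track
#' @param track an [oligo_track()].
#' @return for `write_oligo_track`, `path` invisibly.
#' @export
write_oligo_track <- function(track, path) {
  stopifnot(inherits(track, "oligo_track"))
  grs <- lapply(names(track$counts), function(ch) {
    r <- S4Vectors::Rle(track$counts[[ch]])
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r) + 1L
    keep <- S4Vectors::runValue(r) != 0
    GenomicRanges::GRanges(ch, IRanges::IRanges(starts[keep], ends[keep]),
                           score = S4Vectors::runValue(r)[keep])
  })
  gr <- suppressWarnings(do.call(c, grs))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

# catalog rows -> named GRanges of element spans
catalog_granges <- function(catalog) {
  stopifnot(inherits(catalog, "ty_catalog"))
  gr <- GenomicRanges::GRanges(
    seqnames = catalog$chrom,
    ranges = IRanges::IRanges(catalog$start, catalog$end),
    family = catalog$family, strand_tag = catalog$strand)
  names(gr) <- catalog$name
  gr
}

apply_exclusions <- function(gr, exclude_families, exclude_names,
                             chrom_lengths, subtelomere_dist) {
  drop <- rep(FALSE, length(gr))
  if (length(exclude_families) > 0L && !is.null(gr$family))
    drop <- drop | gr$family %in% exclude_families
  if (length(exclude_names) > 0L)
    drop <- drop | names(gr) %in% exclude_names
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[as.character(GenomicRanges::seqnames(gr))]
    drop <- drop | GenomicRanges::start(gr) <= subtelomere_dist |
      GenomicRanges::end(gr) > (len - subtelomere_dist)
  }
  gr[!drop]
}

merge_into_regions <- function(gr, merge_dist, id_prefix) {
  if (length(gr) == 0L) {
    out <- GenomicRanges::GRanges()
    out$id <- character(0); out$members <- character(0)
    out$n_members <- integer(0)
    return(out)
  }
  red <- GenomicRanges::reduce(gr, min.gapwidth = merge_dist + 1L,
                               ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(gr, red, ignore.strand = TRUE)
  members <- split(names(gr)[S4Vectors::queryHits(ov)],
                   S4Vectors::subjectHits(ov))
  red$id <- sprintf("%s%02d", id_prefix, seq_along(red))
  red$members <- vapply(seq_along(red), function(i)
    paste(unique(members[[as.character(i)]]), collapse = ","), "")
  red$n_members <- lengths(lapply(strsplit(red$members, ","), unique))
  red
}

#' Build Ty-bearing analysis regions from a catalog
#'
#' Closely neighbouring elements (within `merge_dist`) are merged into a
#' single region, since their flanking windows would otherwise overlap each
#' other's element sequence. Elements of excluded families (default Ty5,
#' the subtelomere-targeting family; DSBs are suppressed near telomeres),
#' explicitly named elements, and — when chromosome lengths are supplied —
#' elements within `subtelomere_dist` of a chromosome end are dropped.
#'
#' @param catalog a [ty_catalog()].
#' @param merge_dist merge distance in bp (default 2000).
#' @param exclude_families family tags to drop (default `"Ty5"`).
#' @param exclude_names element names to drop.
#' @param chrom_lengths optional named chromosome lengths enabling the
#'   distance-from-end exclusion.
#' @param subtelomere_dist distance from a chromosome end defining the
#'   subtelomeric zone (default 20000 bp).
#' @return a [GenomicRanges::GRanges] of regions with metadata columns
#'   `id`, `members` (comma-separated element names) and `n_members`.
#' @export
build_analysis_regions <- function(catalog, merge_dist = 2000,
                                   exclude_families = "Ty5",
                                   exclude_names = NULL,
                                   chrom_lengths = NULL,
                                   subtelomere_dist = 20000) {
  gr <- catalog_granges(catalog)
  gr <- apply_exclusions(gr, exclude_families, exclude_names,
                         chrom_lengths, subtelomere_dist)
  merge_into_regions(gr, merge_dist, "region")
}

#' Select control sites from reference-strain element positions
#'
#' Reference-strain element positions serve as controls for Ty-flanking
#' DSB density: loci where the reference carries an element but the mapped
#' strain does not. Reference positions within `min_dist` of any case
#' region are removed (their flanks would overlap case flanks), then the
#' same merging and exclusion rules as for cases are applied.
#'
#' @param reference_catalog a [ty_catalog()] of reference-strain elements.
#' @param case_regions regions from [build_analysis_regions()].
#' @param min_dist removal distance from case sites in bp (default 2000).
#' @inheritParams build_analysis_regions
#' @return a `GRanges` of control regions (same metadata as cases).
#' @export
select_control_sites <- function(reference_catalog, case_regions,
                                 min_dist = 2000, merge_dist = 2000,
                                 exclude_families = "Ty5",
                                 exclude_names = NULL,
                                 chrom_lengths = NULL,
                                 subtelomere_dist = 20000) {
  gr <- catalog_granges(reference_catalog)
  gr <- apply_exclusions(gr, exclude_families, exclude_names,
                         chrom_lengths, subtelomere_dist)
  if (length(gr) > 0L && length(case_regions) > 0L) {
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(gr, case_regions, maxgap = min_dist,
                                  ignore.strand = TRUE))
    if (length(hits) > 0L)
      gr <- gr[-unique(S4Vectors::queryHits(hits))]
  }
  merge_into_regions(gr, merge_dist, "control")
}

track_window_sum <- function(track, chrom, start, end) {
  v <- track$counts[[chrom]]
  if (is.null(v)) stop("track has no chromosome '", chrom, "'")
  sum(v[max(1L, start):min(length(v), end)])
}

#' Spo11-oligo density in a window flanking a region
#'
#' Windows abut the focal interval's edges and exclude element-internal
#' sequence: the left window is `[start - width, start - 1]`, the right
#' window `[end + 1, end + width]`. Windows truncated by a chromosome end
#' are flagged and their density computed over the bases actually covered.
#'
#' @param track a normalized [oligo_track()] (see [normalize_to_hpm()]).
#' @param region a length-1 `GRanges` (e.g. one row of
#'   [build_analysis_regions()] output) or a `list(chrom, start, end)`.
#' @param width window width in bp; conventionally 500, 1000 or 2000.
#' @param side `"left"` or `"right"` in reference coordinates.
#' @return one-row data frame: `region_id`, `chrom`, `side`, `width`,
#'   `actual_width`, `density` (hpM per kb), `truncated`.
#' @export
flanking_density <- function(track, region, width, side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(inherits(track, "oligo_track"))
  if (!track$normalized)
    stop("track must be normalized to hpM first (see normalize_to_hpm)")
  r <- as_region(region)
  v <- track$counts[[r$chrom]]
  if (is.null(v)) stop("track has no chromosome '", r$chrom, "'")
  if (side == "left") {
    w_start <- r$start - width; w_end <- r$start - 1L
  } else {
    w_start <- r$end + 1L; w_end <- r$end + width
  }
  if (w_end < 1L || w_start > length(v))
    stop(sprintf("window fully off chromosome for region %s (%s side)",
                 r$id, side))
  a_start <- max(1L, w_start); a_end <- min(length(v), w_end)
  actual <- as.integer(a_end - a_start + 1L)
  data.frame(region_id = r$id, chrom = r$chrom, side = side,
             width = width, actual_width = actual,
             density = sum(v[a_start:a_end]) / (actual / 1000),
             truncated = actual < width)
}

as_region <- function(region) {
  if (inherits(region, "GRanges")) {
    stopifnot(length(region) == 1L)
    id <- if (!is.null(region$id)) region$id else
      if (!is.null(names(region))) names(region) else "region"
    list(chrom = as.character(GenomicRanges::seqnames(region)),
         start = GenomicRanges::start(region),
         end = GenomicRanges::end(region), id = id)
  } else {
    if (is.null(region$id)) region$id <- "region"
    region[c("chrom", "start", "end", "id")]
  }
}

#' Flanking densities for a set of regions at several window widths
#'
#' @param track a normalized [oligo_track()].
#' @param regions `GRanges` from [build_analysis_regions()] /
#'   [select_control_sites()].
#' @param widths window widths in bp (default `c(500, 1000, 2000)`).
#' @param orientation optional per-region element orientation (`"+"`/`"-"`);
#'   when given, each window is annotated with which LTR end it abuts
#'   (`ltr_side`).
#' @return data frame, one row per region x width x side.
#' @export
flanking_densities <- function(track, regions, widths = c(500, 1000, 2000),
                               orientation = NULL) {
  rows <- list()
  for (i in seq_along(regions)) {
    for (w in widths) {
      for (s in c("left", "right")) {
        row <- flanking_density(track, regions[i], w, s)
        if (!is.null(orientation)) {
          o <- orientation[i]
          row$ltr_side <- if (is.na(o) || !o %in% c("+", "-")) NA_character_
          else if ((o == "+") == (s == "left")) "5'-LTR side" else "3'-LTR side"
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  do.call(rbind, rows)
}

#' Spo11-oligo density within an element span
#'
#' Same hpM-per-kb formula as [flanking_density()], computed over the
#' element's own (internal) span.
#'
#' @inheritParams flanking_density
#' @param region element span (`GRanges` length 1 or `list(chrom, start,
#'   end)`).
#' @return density in hpM per kb.
#' @export
internal_density <- function(track, region) {
  stopifnot(inherits(track, "oligo_track"))
  if (!track$normalized)
    stop("track must be normalized to hpM first (see normalize_to_hpm)")
  r <- as_region(region)
  len <- r$end - r$start + 1L
  if (len < 1L) stop("zero-length element span for region ", r$id)
  track_window_sum(track, r$chrom, r$start, r$end) / (len / 1000)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Rank-sum test with midrank handling of ties. For combined sample sizes
#' up to `exact_max_n` the null distribution of the rank sum is obtained by
#' exact enumeration of all group assignments (valid under ties); larger
#' samples use the normal approximation with tie-corrected variance (no
#' continuity correction, so null p-values are closely uniform).
#'
#' @param a,b numeric samples (non-empty).
#' @param exact_max_n largest combined n for the exact branch (default 12).
#' @return list with `statistic` (rank sum of `a`), `U` (Mann-Whitney U),
#'   `p_two_sided`, and `method`.
#' @export
rank_sum_test <- function(a, b, exact_max_n = 12L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty")
  m <- length(a); n <- length(b); N <- m + n
  r <- rank(c(a, b))
  W <- sum(r[seq_len(m)])
  if (N <= exact_max_n) {
    sums <- colSums(matrix(r[utils::combn(N, m)], nrow = m))
    p <- min(1, 2 * min(mean(sums <= W + 1e-9), mean(sums >= W - 1e-9)))
    method <- "exact enumeration"
  } else {
    mu <- m * (N + 1) / 2
    ties <- table(r)
    sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (W - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal approximation, tie-corrected"
  }
  list(statistic = W, U = W - m * (m + 1) / 2, p_two_sided = p,
       method = method)
}

#' Classify the intergenic context of a region
#'
#' The flanking protein-coding gene strands define the promoter content of
#' an intergenic region: `(-,+)` is divergent (two promoters), `(+,-)`
#' convergent (none), and equal strands tandem (one). A focal point inside
#' a gene is intragenic; a region with no flanking gene on one side
#' (chromosome end) is undetermined.
#'
#' @param region length-1 `GRanges` or `list(chrom, start, end)`.
#' @param annotation `GRanges` gene models with a `type` metadata column
#'   (`"gene"` for protein-coding, `"tRNA_gene"` for tRNA genes) and
#'   strand.
#' @return list with `region_id`, `class` (one of `divergent`, `tandem`,
#'   `convergent`, `intragenic`, `undetermined`) and `contains_trna`.
#' @export
classify_intergenic <- function(region, annotation) {
  r <- as_region(region)
  focal <- as.integer(floor((r$start + r$end) / 2))
  ann <- annotation[as.character(GenomicRanges::seqnames(annotation)) == r$chrom]
  genes <- ann[ann$type == "gene"]
  trnas <- ann[ann$type == "tRNA_gene"]
  gs <- GenomicRanges::start(genes); ge <- GenomicRanges::end(genes)
  inside <- which(gs <= focal & ge >= focal)
  if (length(inside) > 0L)
    return(list(region_id = r$id, class = "intragenic",
                contains_trna = FALSE))
  left <- which(ge < focal); right <- which(gs > focal)
  if (length(left) == 0L || length(right) == 0L)
    return(list(region_id = r$id, class = "undetermined",
                contains_trna = NA))
  li <- left[which.max(ge[left])]
  ri <- right[which.min(gs[right])]
  sl <- as.character(GenomicRanges::strand(genes))[li]
  sr <- as.character(GenomicRanges::strand(genes))[ri]
  cls <- if (sl == "-" && sr == "+") "divergent"
  else if (sl == "+" && sr == "-") "convergent"
  else "tandem"
  ig_start <- ge[li] + 1L; ig_end <- gs[ri] - 1L
  has_trna <- length(trnas) > 0L &&
    any(GenomicRanges::start(trnas) <= ig_end &
        GenomicRanges::end(trnas) >= ig_start)
  list(region_id = r$id, class = cls, contains_trna = has_trna)
}

#' @rdname classify_intergenic
#' @param regions `GRanges` of regions.
#' @return for `classify_intergenic_regions`, a data frame with one row
#'   per region.
#' @export
classify_intergenic_regions <- function(regions, annotation) {
  rows <- lapply(seq_along(regions), function(i) {
    as.data.frame(classify_intergenic(regions[i], annotation))
  })
  do.call(rbind, rows)
}

#' One-way fixed-effects ANOVA over density groups
#'
#' Thin wrapper around [stats::oneway.test()] (equal-variance form, i.e.
#' the classical F test), with explicit handling of degenerate inputs:
#' when both between- and within-group variance are zero the data carry no
#' signal and `F = 0`, `p = 1` is returned.
#'
#' @param groups list of two or more numeric vectors.
#' @return list with `F`, `df_between`, `df_within`, `p`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least two groups")
  sizes <- lengths(groups)
  if (any(sizes < 1L)) stop("every group needs at least one value")
  values <- unlist(groups, use.names = FALSE)
  k <- length(groups); n <- length(values)
  if (n <= k) stop("total observations must exceed the number of groups")
  g <- factor(rep(seq_len(k), sizes))
  means <- tapply(values, g, mean)
  ssb <- sum(sizes * (means - mean(values))^2)
  ssw <- sum((values - means[g])^2)
  if (ssw == 0) {
    if (ssb == 0) return(list(F = 0, df_between = k - 1L,
                              df_within = n - k, p = 1))
    return(list(F = Inf, df_between = k - 1L, df_within = n - k, p = 0))
  }
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic),
       df_between = unname(fit$parameter[1]),
       df_within = unname(fit$parameter[2]),
       p = fit$p.value)
}

#' DSB calibration parameters
#'
#' The linear map from a Spo11-oligo measure to percent of DNA broken is
#' established by external calibration against direct DSB measurements and
#' must be supplied by the user (`slope`, `intercept`). `efficiency` is
#' the relative DSB activity of the oligo-mapping strain versus wild type
#' (the epitope-tagged mapping strain breaks at ~80% of the untagged
#' level, hence the default 0.8). `chromatids_per_cell` (4 after meiotic
#' replication) and `dsbs_per_cell` (~160 in wild type) feed the per-cell
#' burden conversions.
#'
#' @param slope,intercept linear calibration coefficients (user-supplied).
#' @param efficiency relative DSB efficiency in `(0, 1]` (default 0.8).
#' @param chromatids_per_cell chromatids per meiotic cell (default 4).
#' @param dsbs_per_cell average DSBs per meiosis (default 160).
#' @return object of class `dsb_calibration`.
#' @export
dsb_calibration <- function(slope = NA_real_, intercept = 0,
                            efficiency = 0.8, chromatids_per_cell = 4,
                            dsbs_per_cell = 160) {
  if (is.na(efficiency) || efficiency <= 0 || efficiency > 1)
    stop("efficiency must lie in (0, 1]")
  structure(list(slope = slope, intercept = intercept,
                 efficiency = efficiency,
                 chromatids_per_cell = chromatids_per_cell,
                 dsbs_per_cell = dsbs_per_cell),
            class = "dsb_calibration")
}

#' Convert a Spo11-oligo fraction to a DSB frequency
#'
#' Applies the user-supplied linear calibration to obtain the percent of
#' DNA broken, then divides by the mapping strain's relative DSB
#' efficiency to express the estimate on the wild-type scale. Both values
#' are reported to 2 significant figures.
#'
#' @param oligo_fraction percent of mapped Spo11 oligos attributed to the
#'   feature of interest.
#' @param calib a [dsb_calibration()] with `slope`/`intercept` set.
#' @return list with `uncorrected` and `corrected` percent of DNA broken.
#' @export
oligo_fraction_to_dsb_percent <- function(oligo_fraction, calib) {
  stopifnot(inherits(calib, "dsb_calibration"))
  if (is.na(calib$slope))
    stop("calibration slope is unset; supply external calibration values")
  uncorrected <- calib$slope * oligo_fraction + calib$intercept
  list(uncorrected = signif(uncorrected, 2),
       corrected = signif(uncorrected / calib$efficiency, 2))
}

#' Genome-burden arithmetic for DSBs in repetitive elements
#'
#' Converts genome-occupancy and oligo-count fractions into the headline
#' burden numbers: how many fold DSBs inside elements are suppressed
#' relative to genome average; how elements compare to a typical open
#' reading frame once coding-sequence base rates are accounted for; what
#' percent of meiotic cells experience a within-element DSB given a
#' percent-of-DNA-broken estimate; and the expected DSBs per cell for a
#' given oligo fraction.
#'
#' @param ty_genome_frac percent of the genome occupied by elements.
#' @param ty_oligo_frac percent of mapped oligos from element-internal
#'   sequence.
#' @param orf_oligo_frac,orf_genome_frac percent of oligos from, and of
#'   the genome occupied by, coding sequence (optional).
#' @param per_dna_frac percent of DNA broken within an element (optional;
#'   must be <= 25 so the per-cell conversion stays <= 100%).
#' @param oligo_frac percent of mapped oligos from element-derived
#'   sequence including LTRs (optional; drives the per-cell expectation).
#' @param calib a [dsb_calibration()] (supplies `chromatids_per_cell` and
#'   `dsbs_per_cell`).
#' @return list with `fold_suppression`, `orf_relative_fold`, `cell_frac`,
#'   `expected_dsbs_per_cell`, `one_in_n_cells` (unused inputs yield
#'   `NA`).
#' @export
burden_metrics <- function(ty_genome_frac, ty_oligo_frac,
                           orf_oligo_frac = NA_real_,
                           orf_genome_frac = NA_real_,
                           per_dna_frac = NA_real_,
                           oligo_frac = NA_real_,
                           calib = dsb_calibration()) {
  stopifnot(inherits(calib, "dsb_calibration"))
  if (ty_oligo_frac == 0 || isTRUE(orf_genome_frac == 0) ||
      ty_genome_frac == 0)
    stop("zero denominator in burden ratios")
  fold_suppression <- ty_genome_frac / ty_oligo_frac
  orf_relative_fold <- if (is.na(orf_oligo_frac) || is.na(orf_genome_frac))
    NA_real_
  else (orf_oligo_frac / orf_genome_frac) / (ty_oligo_frac / ty_genome_frac)
  cell_frac <- if (is.na(per_dna_frac)) NA_real_ else {
    if (per_dna_frac > 25)
      stop("per_dna_frac > 25% would imply more than one DSB per chromatid set")
    calib$chromatids_per_cell * per_dna_frac
  }
  expected <- if (is.na(oligo_frac)) NA_real_
  else calib$dsbs_per_cell * oligo_frac / 100
  list(fold_suppression = fold_suppression,
       orf_relative_fold = orf_relative_fold,
       cell_frac = cell_frac,
       expected_dsbs_per_cell = expected,
       one_in_n_cells = if (is.na(expected) || expected == 0) NA_real_
       else 1 / expected)
}
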