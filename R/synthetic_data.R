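# Seeded simulator: reference genomes with gene/tRNA annotation, planted
# full-length elements with target-site duplications, innie mate-pair
# libraries, and Spo11-oligo-like count tracks with known structure.

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator. Defaults
#' emulate the study system: ~6-kb elements carrying 330-bp LTRs and 5-bp
#' TSDs, insertion sites biased 90% toward tRNA-adjacent intergenic
#' regions, an NKY291-like mate-pair library geometry (insert 2.8 kb), and
#' oligo tracks with long-tailed promoter hotspots and ~15-fold
#' element-internal suppression.
#'
#' @param seed integer; fixes all randomness of every generator.
#' @param chrom_lengths named chromosome lengths in bp.
#' @param gc genome G+C fraction.
#' @param gene_len_mean,gene_len_sd,gene_len_min gene-length model (bp).
#' @param intergenic_len_min,intergenic_len_max intergenic gap range (bp).
#' @param trna_count number of tRNA genes placed in intergenic regions.
#' @param n_insertions elements to plant.
#' @param trna_bias probability an insertion targets a tRNA-adjacent
#'   intergenic region (default 0.9).
#' @param tsd_len target-site duplication length (fixed at 5).
#' @param family_probs named planting proportions per family
#'   (Ty1-dominant by default).
#' @param ltr_len,internal_len LTR and internal span lengths (bp; element
#'   length = `2 * ltr_len + internal_len` = 6 kb by default).
#' @param tsd_source `"consensus"` draws planted TSD pentamers from the
#'   packaged SK1 target-site consensus frequencies; `"reference"` uses
#'   the native reference pentamer; `"uniform"` draws uniformly.
#' @param tsd_absent_prob probability an insertion is planted without a
#'   duplication.
#' @param min_separation minimum distance between planted sites (bp).
#' @param read_len,insert_mean,insert_sd,coverage,n_pairs library model;
#'   `n_pairs` defaults to `coverage * genome_len / (2 * read_len)`.
#' @param error_rate per-base substitution error rate for reads.
#' @param background_rate oligo-track background Poisson rate per bp.
#' @param promoter_width promoter hotspot window upstream of each gene
#'   (bp).
#' @param hotspot_meanlog,hotspot_sdlog log-normal per-promoter intensity
#'   multipliers (long-tailed, spanning ~100-fold).
#' @param internal_suppression factor by which element-internal rates are
#'   divided (default 15).
#' @param case_flank_enrichment multiplier applied to rates within
#'   `case_flank_width` of designated case sites (default 1 = none).
#' @param case_flank_width width of the enriched case flank (bp).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chrI = 150000, chrII = 100000),
                       gc = 0.38,
                       gene_len_mean = 1400, gene_len_sd = 400,
                       gene_len_min = 300,
                       intergenic_len_min = 400, intergenic_len_max = 900,
                       trna_count = 10L,
                       n_insertions = 8L,
                       trna_bias = 0.9,
                       tsd_len = 5L,
                       family_probs = c(Ty1 = 0.7, Ty2 = 0.2, Ty3 = 0.1),
                       ltr_len = 330L, internal_len = 5340L,
                       tsd_source = c("consensus", "reference", "uniform"),
                       tsd_absent_prob = 0,
                       min_separation = 8000L,
                       read_len = 150L, insert_mean = 2800, insert_sd = 280,
                       coverage = 10, n_pairs = NULL,
                       error_rate = 0,
                       background_rate = 0.02,
                       promoter_width = 300L,
                       hotspot_meanlog = log(20), hotspot_sdlog = 1.2,
                       internal_suppression = 15,
                       case_flank_enrichment = 1,
                       case_flank_width = 2000L) {
  tsd_source <- match.arg(tsd_source)
  stopifnot(tsd_len == 5L, trna_bias >= 0, trna_bias <= 1,
            tsd_absent_prob >= 0, tsd_absent_prob <= 1,
            all(chrom_lengths > 0), read_len < insert_mean,
            all(family_probs >= 0), sum(family_probs) > 0,
            internal_suppression >= 1, case_flank_enrichment > 0)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  cfg <- as.list(environment())
  cfg$family_probs <- family_probs / sum(family_probs)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "Simulation config (seed %d): %d chrom(s), %s bp total\n",
    "  %d insertions (tRNA bias %.2f), element %d bp (LTR %d bp)\n",
    "  library: read %d bp, insert %.0f +/- %.0f bp, coverage %.1fx\n"),
    x$seed, length(x$chrom_lengths),
    format(sum(x$chrom_lengths), big.mark = ","),
    x$n_insertions, x$trna_bias, 2L * x$ltr_len + x$internal_len, x$ltr_len,
    x$read_len, x$insert_mean, x$insert_sd, x$coverage))
  invisible(x)
}

random_dna <- function(n, gc = 0.38) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

#' Reverse-complement plain character sequences
#' @param x character vector of DNA strings.
#' @return character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate deterministic TE family exemplars
#'
#' Ty1 and Ty2 exemplars share a near-identical LTR differing at the
#' diagnostic position 284 (T in Ty1; substituted in Ty2, plus ~3% further
#' divergence), mirroring how those families are distinguished in real
#' data; other families get independent LTRs. Internal spans are
#' family-specific random sequence.
#'
#' @param config a [sim_config()].
#' @return named list of [te_exemplar()] objects, one per family in
#'   `config$family_probs`.
#' @export
make_te_exemplars <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 101L, {
    fams <- names(config$family_probs)
    ltr_len <- config$ltr_len
    base_ltr <- strsplit(random_dna(ltr_len, config$gc), "")[[1L]]
    if (ltr_len >= 285L) {
      # lone diagnostic T so Ty1/Ty2 typing is alignment-unambiguous
      base_ltr[284L] <- "T"
      base_ltr[c(283L, 285L)][base_ltr[c(283L, 285L)] == "T"] <- "A"
    }
    out <- lapply(fams, function(fam) {
      ltr <- if (fam == "Ty1") {
        base_ltr
      } else if (fam == "Ty2") {
        l <- base_ltr
        if (ltr_len >= 284L) l[284L] <- "C"
        mut <- sample(setdiff(seq_len(ltr_len), 284L),
                      max(1L, round(0.03 * ltr_len)))
        l[mut] <- vapply(l[mut], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
        l
      } else {
        strsplit(random_dna(ltr_len, config$gc), "")[[1L]]
      }
      ltr <- paste(ltr, collapse = "")
      internal <- random_dna(config$internal_len, config$gc)
      seqc <- paste0(ltr, internal, ltr)
      te_exemplar(fam, seqc,
                  ltr5 = c(1L, ltr_len),
                  ltr3 = c(ltr_len + config$internal_len + 1L,
                           nchar(seqc)))
    })
    stats::setNames(out, fams)
  })
}

#' Generate a random annotated reference genome
#'
#' Chromosome sequences are i.i.d. with the configured GC; genes of random
#' length and strand alternate with intergenic gaps, and tRNA genes are
#' placed inside randomly chosen intergenic regions. Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_reference` with `genome` (named character
#'   vector), `annotation` ([GenomicRanges::GRanges] with `type`
#'   `"gene"`/`"tRNA_gene"` and `ID`), and `config`.
#' @export
make_reference_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 202L, {
    genome <- vapply(config$chrom_lengths, random_dna, "",
                     gc = config$gc)
    names(genome) <- names(config$chrom_lengths)
    feats <- list()
    for (ch in names(genome)) {
      L <- config$chrom_lengths[[ch]]
      pos <- 1000L
      while (TRUE) {
        gap <- sample(config$intergenic_len_min:config$intergenic_len_max, 1L)
        glen <- max(config$gene_len_min,
                    round(stats::rnorm(1L, config$gene_len_mean,
                                       config$gene_len_sd)))
        g_start <- pos + gap
        g_end <- g_start + glen - 1L
        if (g_end > L - 1000L) break
        feats[[length(feats) + 1L]] <- data.frame(
          chrom = ch, start = g_start, end = g_end,
          strand = sample(c("+", "-"), 1L), type = "gene")
        pos <- g_end
      }
      if (pos == 1000L)
        stop("gene model infeasible for chromosome length ", L)
    }
    feats <- do.call(rbind, feats)
    feats$ID <- sprintf("gene%04d", seq_len(nrow(feats)))
    # tRNA genes inside randomly chosen intergenic gaps
    igs <- intergenic_gaps(feats)
    wide <- igs[igs$end - igs$start + 1L >= 240L, , drop = FALSE]
    if (nrow(wide) < config$trna_count)
      stop("gene model infeasible: not enough intergenic space for tRNAs")
    pick <- wide[sample(nrow(wide), config$trna_count), , drop = FALSE]
    trna <- data.frame(
      chrom = pick$chrom,
      start = floor((pick$start + pick$end) / 2) - 40L,
      end = floor((pick$start + pick$end) / 2) + 39L,
      strand = sample(c("+", "-"), nrow(pick), replace = TRUE),
      type = "tRNA_gene",
      ID = sprintf("trna%03d", seq_len(nrow(pick))))
    feats <- rbind(feats, trna)
    feats <- feats[order(feats$chrom, feats$start), ]
    ann <- GenomicRanges::GRanges(
      seqnames = feats$chrom,
      ranges = IRanges::IRanges(feats$start, feats$end),
      strand = feats$strand, type = feats$type, ID = feats$ID)
    structure(list(genome = genome, annotation = ann, config = config),
              class = "sim_reference")
  })
}

# gaps between consecutive protein-coding genes, per chromosome
intergenic_gaps <- function(feats) {
  genes <- feats[feats$type == "gene", , drop = FALSE]
  out <- list()
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) < 2L) next
    out[[ch]] <- data.frame(
      chrom = ch,
      start = g$end[-nrow(g)] + 1L,
      end = g$start[-1L] - 1L)
  }
  do.call(rbind, out)
}

#' Write / read simulator outputs in standard formats
#'
#' @param genome named character vector of chromosome sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' @rdname write_genome_fasta
#' @param annotation a `GRanges` with `type` and `ID` columns.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  rtracklayer::export(annotation, path, format = "gff3")
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_annotation_gff3 <- function(path) {
  rtracklayer::import(path, format = "gff3")
}

#' Plant full-length elements into a reference genome
#'
#' Each insertion chooses an intergenic target site (tRNA-adjacent with
#' probability `trna_bias`), draws a family and orientation, and splices
#' in the family exemplar flanked by a duplicated 5-bp target pentamer
#' (unless planted TSD-less with probability `tsd_absent_prob`). The
#' returned ground truth records `tsd_start`, so the expected insertion
#' call coordinates follow the third/fourth-base convention of
#' [tsd_to_insert_coords()].
#'
#' @param reference a `sim_reference` from [make_reference_genome()].
#' @param config a [sim_config()] (defaults to the reference's own).
#' @param exemplars exemplar list from [make_te_exemplars()].
#' @return list of class `sim_sample` with `genome` (sample chromosomes),
#'   `truth` (data frame: chrom, tsd_start, family, strand, tsd,
#'   insert_start, insert_end, element_len, trna_adjacent), `exemplars`,
#'   and `config`.
#' @export
plant_insertions <- function(reference, config = reference$config,
                             exemplars = make_te_exemplars(config)) {
  stopifnot(inherits(reference, "sim_reference"))
  withr::with_seed(config$seed + 303L, {
    feats <- as.data.frame(reference$annotation)
    feats <- data.frame(chrom = as.character(feats$seqnames),
                        start = feats$start, end = feats$end,
                        strand = as.character(feats$strand),
                        type = feats$type)
    igs <- intergenic_gaps(feats)
    trnas <- feats[feats$type == "tRNA_gene", , drop = FALSE]
    igs$has_trna <- vapply(seq_len(nrow(igs)), function(i) {
      any(trnas$chrom == igs$chrom[i] & trnas$start >= igs$start[i] &
            trnas$end <= igs$end[i])
    }, logical(1L))
    margin <- 100L
    tsd_freq <- NULL
    if (config$tsd_source == "consensus") {
      cat30 <- sk1_ty_catalog()
      perfect <- cat30$tsd[grepl("^[ACGT]{5}$", cat30$tsd)]
      tsd_freq <- tsd_consensus(perfect)$matrix
    }
    chosen <- data.frame()
    n_left <- config$n_insertions
    truth <- list()
    while (n_left > 0L) {
      want_trna <- stats::runif(1L) < config$trna_bias
      pool <- igs[igs$has_trna == want_trna, , drop = FALSE]
      if (nrow(pool) == 0L) pool <- igs
      placed <- FALSE
      for (j in sample(nrow(pool))) {
        ig <- pool[j, ]
        lo <- ig$start + margin
        hi <- ig$end - margin - config$tsd_len
        if (hi <= lo) next
        cand <- lo:hi
        tr <- trnas[trnas$chrom == ig$chrom &
                      trnas$start >= ig$start & trnas$end <= ig$end, ]
        if (nrow(tr) > 0L)
          cand <- cand[cand > max(tr$end) + 50L | cand < min(tr$start) - 50L -
                         config$tsd_len]
        if (nrow(chosen) > 0L) {
          near <- chosen[chosen$chrom == ig$chrom, "tsd_start"]
          if (length(near) > 0L)
            cand <- cand[vapply(cand, function(p)
              all(abs(p - near) >= config$min_separation), logical(1L))]
        }
        if (length(cand) == 0L) next
        t0 <- if (length(cand) == 1L) cand else sample(cand, 1L)
        fam <- sample(names(config$family_probs), 1L,
                      prob = config$family_probs)
        strand <- sample(c("+", "-"), 1L)
        absent <- stats::runif(1L) < config$tsd_absent_prob
        tsd <- if (absent) "absent" else switch(
          config$tsd_source,
          reference = substr(reference$genome[[ig$chrom]], t0,
                             t0 + config$tsd_len - 1L),
          consensus = paste(vapply(1:5, function(p)
            sample(rownames(tsd_freq), 1L, prob = tsd_freq[, p]), ""),
            collapse = ""),
          uniform = random_dna(config$tsd_len, 0.5))
        chosen <- rbind(chosen, data.frame(
          chrom = ig$chrom, tsd_start = t0, family = fam,
          strand = strand, tsd = tsd, trna_adjacent = ig$has_trna))
        placed <- TRUE
        break
      }
      if (!placed)
        stop("requested insertions exceed available intergenic sites")
      n_left <- n_left - 1L
    }
    if (nrow(chosen) > 0L)
      chosen <- chosen[order(chosen$chrom, chosen$tsd_start), ]
    # splice elements left-to-right, per chromosome
    sample_genome <- reference$genome
    for (ch in unique(chosen$chrom)) {
      rows <- chosen[chosen$chrom == ch, , drop = FALSE]
      ref <- reference$genome[[ch]]
      pieces <- character(0)
      cursor <- 1L
      for (i in seq_len(nrow(rows))) {
        t0 <- rows$tsd_start[i]
        ex <- exemplars[[rows$family[i]]]
        elem <- if (rows$strand[i] == "+") ex$sequence else
          revcomp(ex$sequence)
        if (rows$tsd[i] == "absent") {
          pieces <- c(pieces, substr(ref, cursor, t0 - 1L), elem)
          cursor <- t0
        } else {
          pieces <- c(pieces, substr(ref, cursor, t0 - 1L),
                      rows$tsd[i], elem, rows$tsd[i])
          cursor <- t0 + config$tsd_len
        }
      }
      pieces <- c(pieces, substr(ref, cursor, nchar(ref)))
      sample_genome[[ch]] <- paste(pieces, collapse = "")
    }
    if (nrow(chosen) == 0L) {
      chosen <- data.frame(chrom = character(0), tsd_start = integer(0),
                           family = character(0), strand = character(0),
                           tsd = character(0), trna_adjacent = logical(0))
    }
    ins_coords <- ifelse(chosen$tsd == "absent", NA_integer_,
                         chosen$tsd_start + 2L)
    truth <- cbind(chosen,
                   insert_start = as.integer(ins_coords),
                   insert_end = as.integer(ins_coords) + 1L,
                   element_len = rep(2L * config$ltr_len + config$internal_len,
                                     nrow(chosen)))
    rownames(truth) <- NULL
    structure(list(genome = sample_genome, truth = truth,
                   exemplars = exemplars, config = config),
              class = "sim_sample")
  })
}

#' Simulate an innie mate-pair library
#'
#' Fragment start positions are uniform over the genome, insert lengths
#' normal (truncated to at least the read length), orientation innie
#' (forward read at the left end, reverse-complemented read at the right
#' end). Deterministic given `config$seed`.
#'
#' @param genome named character vector (e.g. the sample genome of
#'   [plant_insertions()]).
#' @param config a [sim_config()].
#' @return list of class `mate_pairs`: `id`, `read1`, `read2` (character
#'   vectors), `read_len`, `insert_mean`, `insert_sd`, `n_pairs`.
#' @export
simulate_mate_pairs <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  G <- sum(nchar(genome))
  n_pairs <- if (!is.null(config$n_pairs)) config$n_pairs else
    round(config$coverage * G / (2 * config$read_len))
  rl <- config$read_len
  withr::with_seed(config$seed + 404L, {
    chroms <- sample(names(genome), n_pairs, replace = TRUE,
                     prob = nchar(genome))
    inserts <- pmax(rl, round(stats::rnorm(n_pairs, config$insert_mean,
                                           config$insert_sd)))
    lens <- nchar(genome)[chroms]
    inserts <- pmin(inserts, lens)
    starts <- floor(stats::runif(n_pairs) * (lens - inserts + 1)) + 1L
    frag_end <- starts + inserts - 1L
    read1 <- substr(genome[chroms], starts, starts + rl - 1L)
    read2 <- revcomp(substr(genome[chroms], frag_end - rl + 1L, frag_end))
    if (config$error_rate > 0) {
      read1 <- add_read_errors(read1, config$error_rate)
      read2 <- add_read_errors(read2, config$error_rate)
    }
    structure(list(id = sprintf("pair%06d", seq_len(n_pairs)),
                   read1 = unname(read1), read2 = unname(read2),
                   read_len = rl, insert_mean = config$insert_mean,
                   insert_sd = config$insert_sd, n_pairs = n_pairs,
                   inserts = inserts),
              class = "mate_pairs")
  })
}

add_read_errors <- function(reads, rate) {
  vapply(reads, function(r) {
    n <- nchar(r)
    hit <- which(stats::runif(n) < rate)
    if (length(hit) == 0L) return(r)
    chars <- strsplit(r, "")[[1L]]
    chars[hit] <- vapply(chars[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    paste(chars, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' @export
print.mate_pairs <- function(x, ...) {
  cat(sprintf("Mate-pair library: %d pairs, read %d bp, insert %.0f +/- %.0f bp\n",
              x$n_pairs, x$read_len, x$insert_mean, x$insert_sd))
  invisible(x)
}

#' @rdname write_genome_fasta
#' @param pairs a `mate_pairs` object.
#' @param prefix output prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` with `/1`/`/2` mate suffixes.
#' @export
write_mate_pairs <- function(pairs, prefix) {
  for (mate in 1:2) {
    reads <- pairs[[paste0("read", mate)]]
    s <- Biostrings::DNAStringSet(reads)
    names(s) <- paste0(pairs$id, "/", mate)
    q <- Biostrings::PhredQuality(
      vapply(nchar(reads), function(n) strrep("I", n), ""))
    Biostrings::writeXStringSet(
      s, sprintf("%s_%d.fastq", prefix, mate), format = "fastq",
      qualities = Biostrings::BStringSet(q))
  }
  invisible(prefix)
}

#' @rdname write_genome_fasta
#' @param path1,path2 FASTQ (or FASTA) mate files with `/1`/`/2` suffixes.
#' @export
read_mate_pairs <- function(path1, path2) {
  fmt <- function(p) if (grepl("\\.f(ast)?q$", p)) "fastq" else "fasta"
  r1 <- Biostrings::readDNAStringSet(path1, format = fmt(path1))
  r2 <- Biostrings::readDNAStringSet(path2, format = fmt(path2))
  stopifnot(length(r1) == length(r2))
  structure(list(id = sub("/1$", "", sub("\\s.*$", "", names(r1))),
                 read1 = unname(as.character(r1)),
                 read2 = unname(as.character(r2)),
                 read_len = as.integer(round(mean(Biostrings::width(r1)))),
                 insert_mean = NA_real_, insert_sd = NA_real_,
                 n_pairs = length(r1)),
            class = "mate_pairs")
}

#' Simulate a Spo11-oligo-like count track
#'
#' Per-position counts are Poisson draws around a background rate;
#' promoter windows upstream of each protein-coding gene are boosted by
#' per-promoter log-normal intensity multipliers (long-tailed, so
#' flanking densities span roughly two orders of magnitude); positions
#' inside supplied element spans are suppressed by
#' `config$internal_suppression`; and, optionally, flanks of designated
#' case sites are enriched by `config$case_flank_enrichment`.
#' Deterministic given `config$seed`.
#'
#' @param annotation `GRanges` gene models (types `gene` / `tRNA_gene`).
#' @param chrom_lengths named chromosome lengths the track should cover.
#' @param config a [sim_config()].
#' @param elements optional `GRanges` of element spans to suppress.
#' @param enriched_sites optional `GRanges` of case sites whose flanks
#'   (within `case_flank_width`, excluding the site span itself) are
#'   multiplied by `case_flank_enrichment`.
#' @return list with `track` (a raw [oligo_track()]), `rates` (the
#'   per-position expected counts), and `hotspots` (data frame of
#'   per-promoter intensities).
#' @export
simulate_oligo_track <- function(annotation, chrom_lengths, config,
                                 elements = NULL, enriched_sites = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 505L, {
    rates <- lapply(chrom_lengths, function(L)
      rep(config$background_rate, L))
    names(rates) <- names(chrom_lengths)
    genes <- annotation[annotation$type == "gene"]
    intens <- stats::rlnorm(length(genes), config$hotspot_meanlog,
                            config$hotspot_sdlog)
    hot <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(genes)),
      gene_start = GenomicRanges::start(genes),
      gene_end = GenomicRanges::end(genes),
      strand = as.character(GenomicRanges::strand(genes)),
      intensity = intens)
    for (i in seq_len(nrow(hot))) {
      ch <- hot$chrom[i]
      L <- length(rates[[ch]])
      win <- if (hot$strand[i] == "+")
        c(hot$gene_start[i] - config$promoter_width, hot$gene_start[i] - 1L)
      else c(hot$gene_end[i] + 1L, hot$gene_end[i] + config$promoter_width)
      a <- max(1L, win[1]); b <- min(L, win[2])
      if (b >= a)
        rates[[ch]][a:b] <- rates[[ch]][a:b] * hot$intensity[i]
    }
    if (!is.null(enriched_sites) && config$case_flank_enrichment != 1) {
      for (i in seq_along(enriched_sites)) {
        ch <- as.character(GenomicRanges::seqnames(enriched_sites))[i]
        L <- length(rates[[ch]])
        s <- GenomicRanges::start(enriched_sites)[i]
        e <- GenomicRanges::end(enriched_sites)[i]
        left <- c(max(1L, s - config$case_flank_width), max(0L, s - 1L))
        right <- c(min(L + 1L, e + 1L), min(L, e + config$case_flank_width))
        if (left[2] >= left[1])
          rates[[ch]][left[1]:left[2]] <-
            rates[[ch]][left[1]:left[2]] * config$case_flank_enrichment
        if (right[2] >= right[1])
          rates[[ch]][right[1]:right[2]] <-
            rates[[ch]][right[1]:right[2]] * config$case_flank_enrichment
      }
    }
    if (!is.null(elements)) {
      for (i in seq_along(elements)) {
        ch <- as.character(GenomicRanges::seqnames(elements))[i]
        L <- length(rates[[ch]])
        a <- max(1L, GenomicRanges::start(elements)[i])
        b <- min(L, GenomicRanges::end(elements)[i])
        if (b >= a)
          rates[[ch]][a:b] <- rates[[ch]][a:b] / config$internal_suppression
      }
    }
    counts <- lapply(rates, function(r) stats::rpois(length(r), r))
    list(track = oligo_track(counts), rates = rates, hotspots = hot)
  })
}
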