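# Insertion-site discovery from mate pairs: Ty-matching read
# classification (k-mer seed + ungapped extension over internal spans),
# unique mate anchoring, bidirectional single-linkage clustering,
# breakpoint/TSD/orientation calling at element-genome junctions, and
# insert-size / orphan anomaly detection.

#' Build a k-mer index over exemplar internal spans
#'
#' Indexes every k-mer of each exemplar's internal (non-LTR) span, on both
#' strands, keyed to its element coordinate. LTR sequence is deliberately
#' excluded so LTR-only reads are never classified as Ty-matching.
#'
#' @param exemplars named list of [te_exemplar()] objects.
#' @param k seed length (default 21).
#' @return object of class `te_kmer_index`.
#' @export
te_kmer_index <- function(exemplars, k = 21L) {
  if (length(exemplars) == 0L)
    stop("configuration error: empty exemplar set")
  rows <- lapply(exemplars, function(ex) {
    s <- internal_seq(ex)
    n <- nchar(s)
    if (n < k) return(NULL)
    int_start <- ex$internal_span[1]
    int_end <- ex$internal_span[2]
    fwd_pos <- seq_len(n - k + 1L)
    fwd <- substring(s, fwd_pos, fwd_pos + k - 1L)
    rc <- revcomp(s)
    rc_kmers <- substring(rc, fwd_pos, fwd_pos + k - 1L)
    data.frame(
      kmer = c(fwd, rc_kmers),
      family = ex$family,
      # element coordinate of the k-mer's leftmost base on the forward
      # element strand
      offset = c(int_start + fwd_pos - 1L,
                 int_end - (fwd_pos + k - 1L) + 1L),
      strand = rep(c("+", "-"), each = length(fwd_pos)))
  })
  tab <- do.call(rbind, rows)
  structure(list(k = k, table = tab, exemplars = exemplars),
            class = "te_kmer_index")
}

#' Classify reads as Ty-matching
#'
#' A read is a Ty hit when it matches an exemplar's internal (non-LTR)
#' sequence over at least `min_match_len` bases at a mismatch rate of at
#' most `max_mismatch_rate`, on either strand. Matching is exact-seed
#' (k-mers at stride `floor(k/2)`) followed by ungapped verification
#' against the exemplar at the implied diagonal.
#'
#' @param reads character vector of read sequences.
#' @param index a [te_kmer_index()] (or an exemplar list, which is
#'   indexed on the fly).
#' @param min_match_len minimum matched length within the internal span
#'   (bp, default 40).
#' @param max_mismatch_rate maximum mismatch fraction over the internal
#'   overlap (default 0.05).
#' @return data frame with one row per read: `family` (`NA` when no
#'   hit), `te_offset` (element coordinate where the internal match
#'   begins), `te_strand`.
#' @export
classify_reads <- function(reads, index, min_match_len = 40L,
                           max_mismatch_rate = 0.05) {
  if (!inherits(index, "te_kmer_index")) index <- te_kmer_index(index)
  k <- index$k
  n <- length(reads)
  out <- data.frame(family = rep(NA_character_, n),
                    te_offset = rep(NA_integer_, n),
                    te_strand = rep(NA_character_, n))
  if (n == 0L) return(out)
  lens <- nchar(reads)
  stride <- max(1L, k %/% 2L)
  seed_rows <- lapply(seq_len(n), function(i) {
    if (lens[i] < k) return(NULL)
    pos <- unique(c(seq(1L, lens[i] - k + 1L, by = stride), lens[i] - k + 1L))
    data.frame(read = i, pos = pos)
  })
  seeds <- do.call(rbind, seed_rows)
  if (is.null(seeds)) return(out)
  seeds$kmer <- substring(reads[seeds$read], seeds$pos, seeds$pos + k - 1L)
  hit <- match(seeds$kmer, index$table$kmer)
  cand <- seeds[!is.na(hit), , drop = FALSE]
  if (nrow(cand) == 0L) return(out)
  hit <- hit[!is.na(hit)]
  cand$family <- index$table$family[hit]
  cand$strand <- index$table$strand[hit]
  cand$offset <- index$table$offset[hit]
  # implied element coordinate of the (possibly reverse-complemented)
  # read's first base on the forward element strand
  cand$diag <- ifelse(
    cand$strand == "+",
    cand$offset - (cand$pos - 1L),
    cand$offset - (lens[cand$read] - (cand$pos + k - 1L)))
  cand <- cand[!duplicated(cand[c("read", "family", "strand", "diag")]), ,
               drop = FALSE]
  rc_cache <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(cand))) {
    i <- cand$read[r]
    if (!is.na(out$family[i])) next
    ex <- index$exemplars[[cand$family[r]]]
    seqc <- if (cand$strand[r] == "+") reads[i] else {
      key <- as.character(i)
      if (is.null(rc_cache[[key]])) rc_cache[[key]] <- revcomp(reads[i])
      rc_cache[[key]]
    }
    v <- verify_diagonal(seqc, cand$diag[r], ex, min_match_len,
                         max_mismatch_rate)
    if (!is.null(v)) {
      out$family[i] <- cand$family[r]
      out$te_offset[i] <- v
      out$te_strand[i] <- cand$strand[r]
    }
  }
  out
}

# Ungapped verification of seqc (already on the forward element strand)
# against exemplar `ex` with seqc position 1 at element coordinate `d`.
# Returns the element coordinate where the internal-span match begins, or
# NULL on failure.
verify_diagonal <- function(seqc, d, ex, min_match_len, max_mismatch_rate) {
  len <- nchar(seqc)
  ia <- max(d, ex$internal_span[1])
  ib <- min(d + len - 1L, ex$internal_span[2])
  ov <- ib - ia + 1L
  if (ov < min_match_len) return(NULL)
  x <- substr(seqc, ia - d + 1L, ib - d + 1L)
  y <- substr(ex$sequence, ia, ib)
  mism <- sum(charToRaw(x) != charToRaw(y))
  if (mism / ov > max_mismatch_rate) return(NULL)
  ia
}

#' @rdname classify_reads
#' @param read a single read sequence.
#' @return for `classify_read`, a list `(family, te_offset, te_strand)`
#'   or `NULL` when the read does not match internal Ty sequence.
#' @export
classify_read <- function(read, index, min_match_len = 40L,
                          max_mismatch_rate = 0.05) {
  res <- classify_reads(read, index, min_match_len, max_mismatch_rate)
  if (is.na(res$family[1])) return(NULL)
  list(family = res$family[1], te_offset = res$te_offset[1],
       te_strand = res$te_strand[1])
}

#' Map reads to unique genomic positions
#'
#' Exact matching on both strands. A read with one genome-wide match is
#' `unique`; two or more equally good matches give `multi` (such reads are
#' discarded downstream, never arbitrarily assigned); no match gives
#' `unmapped`.
#'
#' @param reads character vector of read sequences.
#' @param genome named character vector of chromosome sequences.
#' @return data frame per read: `status` (`unique`/`multi`/`unmapped`),
#'   `chrom`, `position` (1-based leftmost base of the match), `strand`.
#' @export
map_reads_unique <- function(reads, genome) {
  n <- length(reads)
  counts <- integer(n)
  chrom <- rep(NA_character_, n)
  pos <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n)
  if (n == 0L)
    return(data.frame(status = character(0), chrom = character(0),
                      position = integer(0), strand = character(0)))
  subj <- lapply(genome, Biostrings::DNAString)
  same_width <- length(unique(nchar(reads))) == 1L
  sets <- list(`+` = Biostrings::DNAStringSet(reads))
  sets[["-"]] <- Biostrings::reverseComplement(sets[["+"]])
  for (std in names(sets)) {
    if (same_width) {
      pd <- Biostrings::PDict(sets[[std]])
      for (ch in names(subj)) {
        m <- Biostrings::matchPDict(pd, subj[[ch]])
        nh <- S4Vectors::elementNROWS(m)
        hits <- which(nh > 0L)
        if (length(hits) == 0L) next
        starts <- Biostrings::startIndex(m)
        for (i in hits) {
          if (counts[i] == 0L) {
            chrom[i] <- ch; pos[i] <- starts[[i]][1L]; strand[i] <- std
          }
          counts[i] <- counts[i] + nh[i]
        }
      }
    } else {
      for (i in seq_len(n)) {
        for (ch in names(subj)) {
          m <- Biostrings::matchPattern(sets[[std]][[i]], subj[[ch]])
          if (length(m) > 0L) {
            if (counts[i] == 0L) {
              chrom[i] <- ch
              pos[i] <- Biostrings::start(m)[1L]
              strand[i] <- std
            }
            counts[i] <- counts[i] + length(m)
          }
        }
      }
    }
  }
  status <- ifelse(counts == 0L, "unmapped",
                   ifelse(counts == 1L, "unique", "multi"))
  chrom[status != "unique"] <- NA_character_
  pos[status != "unique"] <- NA_integer_
  strand[status != "unique"] <- NA_character_
  data.frame(status = status, chrom = chrom, position = pos, strand = strand)
}

#' @rdname map_reads_unique
#' @param read a single read sequence.
#' @return for `map_read_unique`, a list `(chrom, position, strand)` when
#'   unique, or the string `"multi"` / `"unmapped"`.
#' @export
map_read_unique <- function(read, genome) {
  res <- map_reads_unique(read, genome)
  if (res$status[1] != "unique") return(res$status[1])
  list(chrom = res$chrom[1], position = res$position[1],
       strand = res$strand[1])
}

#' Extract Ty anchors from a mate-pair library
#'
#' A Ty anchor is a pair in which exactly one mate matches exemplar
#' internal sequence and the other maps uniquely to the genome. The
#' anchor's direction points from the genomic mate toward the putative
#' insertion: a genomic mate on the `+` strand points right, on the `-`
#' strand points left. The anchor position is the mate's innermost base
#' (the one nearest the insertion).
#'
#' @param pairs a `mate_pairs` object.
#' @param genome named character vector of chromosome sequences.
#' @param index a [te_kmer_index()].
#' @inheritParams classify_reads
#' @return data frame of anchors: `pair_id`, `chrom`, `position`,
#'   `direction` (`points_right`/`points_left`), `te_family`,
#'   `te_offset`.
#' @export
te_anchors <- function(pairs, genome, index, min_match_len = 40L,
                       max_mismatch_rate = 0.05) {
  cls1 <- classify_reads(pairs$read1, index, min_match_len, max_mismatch_rate)
  cls2 <- classify_reads(pairs$read2, index, min_match_len, max_mismatch_rate)
  te1 <- !is.na(cls1$family)
  te2 <- !is.na(cls2$family)
  sel <- xor(te1, te2)
  if (!any(sel))
    return(data.frame(pair_id = character(0), chrom = character(0),
                      position = integer(0), direction = character(0),
                      te_family = character(0), te_offset = integer(0)))
  idx <- which(sel)
  genomic_reads <- ifelse(te1[idx], pairs$read2[idx], pairs$read1[idx])
  te_cls <- rbind(cls1, cls2)[ifelse(te1[idx], idx,
                                     idx + length(pairs$read1)), ,
                              drop = FALSE]
  mapped <- map_reads_unique(genomic_reads, genome)
  ok <- mapped$status == "unique"
  rl <- nchar(genomic_reads)
  data.frame(
    pair_id = pairs$id[idx[ok]],
    chrom = mapped$chrom[ok],
    position = ifelse(mapped$strand[ok] == "+",
                      mapped$position[ok] + rl[ok] - 1L,
                      mapped$position[ok]),
    direction = ifelse(mapped$strand[ok] == "+", "points_right",
                       "points_left"),
    te_family = te_cls$family[ok],
    te_offset = te_cls$te_offset[ok])
}

#' Cluster anchors by single linkage
#'
#' Anchors sharing a chromosome and direction whose consecutive positions
#' are at most `max_gap` apart join one cluster. Every anchor belongs to
#' exactly one cluster and the result is invariant to input order.
#'
#' @param anchors anchor data frame from [te_anchors()].
#' @param max_gap maximum gap between consecutive member positions (bp);
#'   sensibly the library's expected insert size.
#' @return data frame of clusters (`cluster_id`, `chrom`, `direction`,
#'   `span_start`, `span_end`, `n`, `families`) with the annotated anchor
#'   table attached as attribute `"anchors"` (column `cluster_id`).
#' @export
cluster_anchors <- function(anchors, max_gap) {
  empty <- data.frame(cluster_id = integer(0), chrom = character(0),
                      direction = character(0), span_start = integer(0),
                      span_end = integer(0), n = integer(0),
                      families = character(0))
  if (nrow(anchors) == 0L) {
    attr(empty, "anchors") <- cbind(anchors, cluster_id = integer(0))
    return(empty)
  }
  anchors <- anchors[order(anchors$chrom, anchors$direction,
                           anchors$position), , drop = FALSE]
  key <- paste(anchors$chrom, anchors$direction)
  new_group <- c(TRUE, key[-1] != key[-nrow(anchors)] |
                   diff(anchors$position) > max_gap)
  anchors$cluster_id <- cumsum(new_group)
  cl <- do.call(rbind, lapply(split(anchors, anchors$cluster_id), function(a) {
    data.frame(cluster_id = a$cluster_id[1], chrom = a$chrom[1],
               direction = a$direction[1],
               span_start = min(a$position), span_end = max(a$position),
               n = nrow(a),
               families = paste(a$te_family, collapse = ","))
  }))
  rownames(cl) <- NULL
  attr(cl, "anchors") <- anchors
  cl
}

majority_family <- function(fams) {
  tab <- sort(table(fams), decreasing = TRUE)
  if (length(tab) == 0L) return("ambiguous")
  if (length(tab) > 1L && tab[1] == tab[2]) return("ambiguous")
  names(tab)[1]
}

#' Call insertion sites from bidirectional anchor clusters
#'
#' An insertion appears as a right-pointing cluster just upstream of a
#' left-pointing cluster: each right-pointing cluster is paired with the
#' nearest unused downstream left-pointing cluster whose facing edge lies
#' within `pairing_window`, and the breakpoint interval spans the two
#' facing edges. A call is `confirmed` when both directions are supported
#' and total support reaches `min_support`; unpaired clusters emit
#' `candidate` calls. The family vote is the majority family over member
#' anchors (`ambiguous` on a tie).
#'
#' @param clusters output of [cluster_anchors()].
#' @param pairing_window maximum distance between converging cluster
#'   edges (bp); sensibly the library's expected insert size.
#' @param min_support minimum total supporting reads for `confirmed`
#'   status (default 2).
#' @return data frame of calls: `chrom`, `breakpoint_start`,
#'   `breakpoint_end`, `left_support`, `right_support`, `family_vote`,
#'   `orientation`, `tsd`, `status`.
#' @export
call_insertions <- function(clusters, pairing_window, min_support = 2L) {
  calls <- list()
  for (ch in unique(clusters$chrom)) {
    rights <- clusters[clusters$chrom == ch &
                         clusters$direction == "points_right", , drop = FALSE]
    lefts <- clusters[clusters$chrom == ch &
                        clusters$direction == "points_left", , drop = FALSE]
    rights <- rights[order(rights$span_end), , drop = FALSE]
    lefts <- lefts[order(lefts$span_start), , drop = FALSE]
    used_left <- rep(FALSE, nrow(lefts))
    for (i in seq_len(nrow(rights))) {
      gap <- lefts$span_start - rights$span_end[i]
      ok <- !used_left & gap <= pairing_window & gap >= -pairing_window / 2 &
        lefts$span_start >= rights$span_start[i]
      j <- which(ok)[which.min(abs(gap[ok]))]
      if (length(j) == 1L) {
        used_left[j] <- TRUE
        fams <- c(strsplit(rights$families[i], ",")[[1L]],
                  strsplit(lefts$families[j], ",")[[1L]])
        total <- rights$n[i] + lefts$n[j]
        calls[[length(calls) + 1L]] <- data.frame(
          chrom = ch,
          breakpoint_start = min(rights$span_end[i], lefts$span_start[j]),
          breakpoint_end = max(rights$span_end[i], lefts$span_start[j]),
          left_support = rights$n[i], right_support = lefts$n[j],
          family_vote = majority_family(fams),
          orientation = "undetermined", tsd = "undetermined",
          status = if (total >= min_support) "confirmed" else "candidate")
      } else {
        calls[[length(calls) + 1L]] <- data.frame(
          chrom = ch, breakpoint_start = rights$span_end[i],
          breakpoint_end = rights$span_end[i],
          left_support = rights$n[i], right_support = 0L,
          family_vote = majority_family(
            strsplit(rights$families[i], ",")[[1L]]),
          orientation = "undetermined", tsd = "undetermined",
          status = "candidate")
      }
    }
    for (j in which(!used_left)) {
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = ch, breakpoint_start = lefts$span_start[j],
        breakpoint_end = lefts$span_start[j],
        left_support = 0L, right_support = lefts$n[j],
        family_vote = majority_family(strsplit(lefts$families[j], ",")[[1L]]),
        orientation = "undetermined", tsd = "undetermined",
        status = "candidate")
    }
  }
  if (length(calls) == 0L)
    return(data.frame(chrom = character(0), breakpoint_start = integer(0),
                      breakpoint_end = integer(0), left_support = integer(0),
                      right_support = integer(0), family_vote = character(0),
                      orientation = character(0), tsd = character(0),
                      status = character(0)))
  out <- do.call(rbind, calls)
  out <- out[order(out$chrom, out$breakpoint_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve TSD and orientation at element-genome junctions
#'
#' Searches the read set for junction reads: reads containing an
#' element edge (first/last `edge_len` bases, in either orientation)
#' adjoined to genomic sequence. The genomic part beyond the 5 bases
#' nearest the junction is mapped exactly to the call's chromosome; when
#' both junctions resolve and the two flanking pentamers agree at the
#' spacing of a 5-bp duplication, the TSD is that pentamer and the
#' breakpoint collapses to the third/fourth-base coordinate convention
#' ([tsd_to_insert_coords()]). A spacing of zero duplicated bases yields
#' `tsd = "absent"`. Contradictory junction reads leave the call
#' undetermined with a conflict note.
#'
#' @param call one row of the [call_insertions()] data frame.
#' @param reads character vector of all read sequences in the library.
#' @param genome named character vector of chromosome sequences.
#' @param exemplars named exemplar list.
#' @param window maximum distance between a junction and the provisional
#'   breakpoint (bp).
#' @param edge_len element-edge seed length (default 25).
#' @param k_flank minimum mapped genomic anchor beyond the pentamer
#'   (default 20).
#' @return the call row, updated in place (`tsd`, `orientation`,
#'   `breakpoint_start`, `breakpoint_end`, `note`).
#' @export
call_tsd_and_orientation <- function(call, reads, genome, exemplars,
                                     window = 5000L, edge_len = 25L,
                                     k_flank = 20L) {
  fams <- if (call$family_vote %in% names(exemplars)) call$family_vote
  else names(exemplars)
  read_set <- Biostrings::DNAStringSet(c(reads, revcomp(reads)))
  chrom_seq <- Biostrings::DNAString(genome[[call$chrom]])
  call$note <- ""
  solutions <- list()
  for (fam in fams) {
    for (o in c("+", "-")) {
      elem <- exemplars[[fam]]$sequence
      if (o == "-") elem <- revcomp(elem)
      Ls <- substr(elem, 1L, edge_len)
      Rs <- substr(elem, nchar(elem) - edge_len + 1L, nchar(elem))
      left <- junction_hits(read_set, Ls, "left", chrom_seq, call, window,
                            edge_len, k_flank)
      right <- junction_hits(read_set, Rs, "right", chrom_seq, call, window,
                             edge_len, k_flank)
      if (is.null(left) || is.null(right)) next
      if (left$conflict || right$conflict) {
        call$tsd <- "undetermined"
        call$orientation <- "undetermined"
        call$note <- "conflicting junction reads"
        return(call)
      }
      solutions[[length(solutions) + 1L]] <-
        list(fam = fam, o = o, t_left = left$t, p_left = left$p,
             t_right = right$t, p_right = right$p)
    }
  }
  if (length(solutions) == 0L) {
    call$tsd <- "undetermined"
    return(call)
  }
  if (length(solutions) > 1L) {
    call$tsd <- "undetermined"
    call$orientation <- "undetermined"
    call$note <- "junctions consistent with multiple orientations"
    return(call)
  }
  sol <- solutions[[1L]]
  d <- sol$t_right - sol$t_left
  if (d == 0L && sol$p_left == sol$p_right) {
    coords <- tsd_to_insert_coords(sol$t_left)
    call$tsd <- sol$p_left
    call$orientation <- sol$o
    call$breakpoint_start <- coords$insert_start
    call$breakpoint_end <- coords$insert_end
  } else if (d == 5L) {
    call$tsd <- "absent"
    call$orientation <- sol$o
    call$breakpoint_start <- sol$t_right - 1L
    call$breakpoint_end <- sol$t_right
  } else {
    call$tsd <- "undetermined"
    call$orientation <- "undetermined"
    call$note <- "conflicting junction reads"
  }
  call
}

# Find and interpret junction reads for one element edge.
# side "left": reads look like  <genomic><P><element edge ...>
# side "right": reads look like <... element edge><P><genomic>
# Returns NULL (no junction reads), or list(t, p, conflict): t is the
# inferred reference coordinate of the first base whose reference copy
# follows the left genomic flank (left side) or starts the right genomic
# flank minus the 5-bp spacer (right side).
junction_hits <- function(read_set, edge_pattern, side, chrom_seq, call,
                          window, edge_len, k_flank) {
  m <- Biostrings::vmatchPattern(edge_pattern, read_set)
  nh <- S4Vectors::elementNROWS(m)
  hits <- which(nh > 0L)
  if (length(hits) == 0L) return(NULL)
  ts <- integer(0); ps <- character(0)
  for (i in hits) {
    w <- as.character(read_set[[i]])
    p0 <- Biostrings::start(m[[i]])[1L]
    if (side == "left") {
      if (p0 - 1L < 5L + k_flank) next
      pent <- substr(w, p0 - 5L, p0 - 1L)
      anchor <- substr(w, 1L, p0 - 6L)
    } else {
      qe <- p0 + edge_len - 1L
      if (nchar(w) - qe < 5L + k_flank) next
      pent <- substr(w, qe + 1L, qe + 5L)
      anchor <- substr(w, qe + 6L, nchar(w))
    }
    am <- Biostrings::matchPattern(Biostrings::DNAString(anchor), chrom_seq)
    if (length(am) != 1L) next
    t_cand <- if (side == "left") Biostrings::end(am)[1L] + 1L
    else Biostrings::start(am)[1L] - 5L
    if (abs(t_cand - call$breakpoint_start) > window) next
    ts <- c(ts, t_cand); ps <- c(ps, pent)
  }
  if (length(ts) == 0L) return(NULL)
  tab <- table(paste(ts, ps))
  if (length(tab) > 1L && sort(tab, decreasing = TRUE)[1] ==
      sort(tab, decreasing = TRUE)[2])
    return(list(t = ts[1], p = ps[1], conflict = TRUE))
  best <- names(sort(tab, decreasing = TRUE))[1]
  parts <- strsplit(best, " ")[[1L]]
  list(t = as.integer(parts[1]), p = parts[2], conflict = FALSE)
}

#' End-to-end insertion detection
#'
#' Runs the full evidence chain: classify both mates against the exemplar
#' internal spans, map the genomic mate of each Ty-matching pair
#' uniquely, cluster the resulting anchors per direction, pair converging
#' clusters into insertion calls, and (optionally) resolve TSD and
#' orientation from junction reads.
#'
#' @param pairs a `mate_pairs` object.
#' @param genome named character vector of chromosome sequences (the
#'   reference the sample is compared against).
#' @param exemplars named list of [te_exemplar()] objects.
#' @param min_support minimum total support for `confirmed` calls.
#' @param max_gap anchor clustering gap; defaults to the library's
#'   expected insert size.
#' @param pairing_window cluster pairing window; defaults to `max_gap`.
#' @param resolve_junctions logical; resolve TSD/orientation (default
#'   `TRUE`).
#' @inheritParams classify_reads
#' @param k seed length for the exemplar k-mer index.
#' @return object of class `ty_detection`: list with `calls`, `clusters`,
#'   `anchors`, and `support` (per-call total supporting reads, suitable
#'   for [fit_poisson()]).
#' @export
detect_insertions <- function(pairs, genome, exemplars, min_support = 2L,
                              max_gap = NULL, pairing_window = NULL,
                              resolve_junctions = TRUE, k = 21L,
                              min_match_len = 40L, max_mismatch_rate = 0.05) {
  if (is.null(max_gap))
    max_gap <- if (is.finite(pairs$insert_mean)) pairs$insert_mean else 3000
  if (is.null(pairing_window)) pairing_window <- max_gap
  index <- te_kmer_index(exemplars, k = k)
  anchors <- te_anchors(pairs, genome, index, min_match_len,
                        max_mismatch_rate)
  clusters <- cluster_anchors(anchors, max_gap)
  calls <- call_insertions(clusters, pairing_window, min_support)
  calls$note <- ""
  if (resolve_junctions && nrow(calls) > 0L) {
    all_reads <- c(pairs$read1, pairs$read2)
    resolved <- lapply(seq_len(nrow(calls)), function(i)
      call_tsd_and_orientation(calls[i, , drop = FALSE], all_reads, genome,
                               exemplars, window = pairing_window))
    calls <- do.call(rbind, resolved)
    rownames(calls) <- NULL
  }
  structure(list(calls = calls, clusters = clusters, anchors = anchors,
                 support = calls$left_support + calls$right_support),
            class = "ty_detection")
}

#' @export
print.ty_detection <- function(x, ...) {
  cat(sprintf("Ty insertion detection: %d call(s) (%d confirmed) from %d anchor(s)\n",
              nrow(x$calls), sum(x$calls$status == "confirmed"),
              nrow(x$anchors)))
  if (nrow(x$calls) > 0L)
    print(x$calls[c("chrom", "breakpoint_start", "breakpoint_end",
                    "left_support", "right_support", "family_vote",
                    "orientation", "tsd", "status")])
  invisible(x)
}

#' Detect insert-size and orphan anomalies against a reference
#'
#' Pairs whose mapped span is substantially larger than the library mean
#' indicate sequence present in the reference but absent from the sample
#' (e.g. a reference-only element): the gaps between such stretched mates
#' are reported as `deletion_in_sample` regions. Pileups of orphan reads
#' (one mate unmapped, multi-mapped, or discordantly mapped) indicate
#' novel insertions in the sample: `insertion_in_sample`. Candidate
#' regions supported by fewer than `min_pairs` pairs are reported as
#' concordant with a low-coverage note, and each chromosome additionally
#' reports a concordant baseline row.
#'
#' @param pairs a `mate_pairs` object.
#' @param genome named character vector of reference chromosomes.
#' @param library_stats list with `insert_mean` and `insert_sd`; defaults
#'   to the values carried by `pairs`.
#' @param z_threshold flag spans above `insert_mean + z_threshold *
#'   insert_sd` (default 3).
#' @param min_pairs minimum supporting pairs for an anomaly region
#'   (default 3).
#' @return data frame: `chrom`, `start`, `end`, `kind`,
#'   `stretched_pairs`, `orphan_reads`, `note`.
#' @export
detect_structural_anomalies <- function(pairs, genome, library_stats = NULL,
                                        z_threshold = 3, min_pairs = 3L) {
  if (is.null(library_stats))
    library_stats <- list(insert_mean = pairs$insert_mean,
                          insert_sd = pairs$insert_sd)
  rl <- pairs$read_len
  n <- pairs$n_pairs
  mapped <- map_reads_unique(c(pairs$read1, pairs$read2), genome)
  m1 <- mapped[seq_len(n), , drop = FALSE]
  m2 <- mapped[n + seq_len(n), , drop = FALSE]
  both <- m1$status == "unique" & m2$status == "unique"
  same <- both & m1$chrom == m2$chrom & m1$strand != m2$strand
  # innie span from the + strand mate's start to the - strand mate's end
  plus_start <- ifelse(m1$strand == "+", m1$position, m2$position)
  minus_end <- ifelse(m1$strand == "-", m1$position, m2$position) + rl - 1L
  proper <- same & !is.na(plus_start) & (minus_end > plus_start)
  span <- minus_end - plus_start + 1L
  cutoff <- library_stats$insert_mean + z_threshold * library_stats$insert_sd
  stretched <- which(proper & span > cutoff)
  # orphans: exactly one unique mate, or both unique but discordant
  one_side <- xor(m1$status == "unique", m2$status == "unique")
  discordant <- both & !proper
  orphan_idx <- which(one_side | discordant)
  orphan_chrom <- ifelse(m1$status[orphan_idx] == "unique",
                         m1$chrom[orphan_idx], m2$chrom[orphan_idx])
  orphan_pos <- ifelse(m1$status[orphan_idx] == "unique",
                       m1$position[orphan_idx], m2$position[orphan_idx])
  rows <- list()
  if (length(stretched) > 0L) {
    gaps <- GenomicRanges::GRanges(
      ifelse(m1$strand[stretched] == "+", m1$chrom[stretched],
             m2$chrom[stretched]),
      IRanges::IRanges(plus_start[stretched] + rl,
                       pmax(plus_start[stretched] + rl,
                            minus_end[stretched] - rl)))
    red <- GenomicRanges::reduce(gaps)
    ov <- GenomicRanges::countOverlaps(red, gaps)
    for (i in seq_along(red)) {
      low <- ov[i] < min_pairs
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(red))[i],
        start = GenomicRanges::start(red)[i],
        end = GenomicRanges::end(red)[i],
        kind = if (low) "concordant" else "deletion_in_sample",
        stretched_pairs = if (low) 0L else ov[i],
        orphan_reads = 0L,
        note = if (low) "low_coverage" else "")
    }
  }
  if (length(orphan_idx) > 0L) {
    keep <- !is.na(orphan_chrom)
    oc <- orphan_chrom[keep]; op <- orphan_pos[keep]
    if (length(op) > 0L) {
      o <- order(oc, op)
      oc <- oc[o]; op <- op[o]
      brk <- c(TRUE, oc[-1] != oc[-length(oc)] |
                 diff(op) > library_stats$insert_mean)
      grp <- cumsum(brk)
      for (g in unique(grp)) {
        sel <- grp == g
        low <- sum(sel) < min_pairs
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = oc[sel][1], start = min(op[sel]),
          end = max(op[sel]) + rl - 1L,
          kind = if (low) "concordant" else "insertion_in_sample",
          stretched_pairs = 0L,
          orphan_reads = if (low) 0L else sum(sel),
          note = if (low) "low_coverage" else "")
      }
    }
  }
  base <- data.frame(chrom = names(genome), start = 1L,
                     end = nchar(genome), kind = "concordant",
                     stretched_pairs = 0L, orphan_reads = 0L, note = "")
  out <- rbind(do.call(rbind, rows), base)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write insertion calls as TSV and BED
#'
#' The TSV mirrors the catalog columns (`chrom, name, start, end, family,
#' strand, trna, tsd, completeness, note`); coordinates stay 1-based
#' inclusive, with the TSD tokens of the catalog format. The BED is
#' 0-based half-open with the call name and total support as score.
#'
#' @param calls call data frame (from [detect_insertions()]'s `calls`).
#' @param tsv_path,bed_path output paths (`NULL` to skip either).
#' @return invisibly, a list of the written paths.
#' @export
write_insertion_calls <- function(calls, tsv_path = NULL, bed_path = NULL) {
  name <- sprintf("call%03d", seq_len(nrow(calls)))
  if (!is.null(tsv_path)) {
    tsd <- calls$tsd
    tsd[tsd == "undetermined"] <- "N.D."
    tsd[tsd == "absent"] <- "-"
    tsv <- data.frame(chrom = calls$chrom, name = name,
                      start = calls$breakpoint_start,
                      end = calls$breakpoint_end,
                      family = calls$family_vote,
                      strand = ifelse(calls$orientation %in% c("+", "-"),
                                      calls$orientation, "."),
                      trna = "unknown", tsd = tsd, completeness = "full",
                      note = paste0(calls$status, "; support=",
                                    calls$left_support + calls$right_support))
    utils::write.table(tsv, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = calls$chrom,
                      start = calls$breakpoint_start - 1L,
                      end = calls$breakpoint_end,
                      name = name,
                      score = calls$left_support + calls$right_support,
                      strand = ifelse(calls$orientation %in% c("+", "-"),
                                      calls$orientation, "."))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(list(tsv = tsv_path, bed = bed_path))
}

#' @rdname write_insertion_calls
#' @param anomalies data frame from [detect_structural_anomalies()].
#' @param path BED output path (anomaly kind in the name field).
#' @export
write_anomalies_bed <- function(anomalies, path) {
  bed <- data.frame(chrom = anomalies$chrom, start = anomalies$start - 1L,
                    end = anomalies$end, name = anomalies$kind,
                    score = anomalies$stretched_pairs + anomalies$orphan_reads,
                    strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
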