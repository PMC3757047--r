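# TE family exemplars: full-length element sequences partitioned into
# terminal repeats (LTRs) and the internal coding span.

#' Construct a TE family exemplar
#'
#' An exemplar is a full-length element sequence for one Ty family,
#' annotated with the spans of its two ~330-bp long terminal repeats; the
#' interval between them is the internal (Gag/Pol-like) span used for
#' Ty-matching read classification. The diagnostic LTR position is the
#' residue used to distinguish Ty1 from Ty2 (see
#' [classify_family_from_ltr()]).
#'
#' @param family family tag (one of [TY_FAMILIES] except `"ambiguous"`).
#' @param sequence full element sequence, 5' LTR first.
#' @param ltr5,ltr3 integer `c(start, end)` spans of the 5' and 3' LTRs,
#'   1-based inclusive on `sequence`.
#' @param diagnostic_ltr_position diagnostic residue coordinate on the LTR
#'   (default 284).
#' @return object of class `te_exemplar`.
#' @export
te_exemplar <- function(family, sequence, ltr5, ltr3,
                        diagnostic_ltr_position = 284L) {
  sequence <- as.character(sequence)
  stopifnot(family %in% setdiff(TY_FAMILIES, "ambiguous"),
            length(ltr5) == 2L, length(ltr3) == 2L)
  ltr5 <- as.integer(ltr5); ltr3 <- as.integer(ltr3)
  n <- nchar(sequence)
  if (ltr5[1] < 1L || ltr3[2] > n || ltr5[2] >= ltr3[1])
    stop("LTR spans must be ordered, disjoint and within the sequence")
  internal <- c(ltr5[2] + 1L, ltr3[1] - 1L)
  if (internal[2] < internal[1])
    stop("internal span is empty: LTRs are adjacent or overlapping")
  structure(list(family = family, sequence = sequence,
                 ltr5 = ltr5, ltr3 = ltr3, internal_span = internal,
                 diagnostic_ltr_position = as.integer(diagnostic_ltr_position)),
            class = "te_exemplar")
}

#' @export
print.te_exemplar <- function(x, ...) {
  cat(sprintf("%s exemplar: %d bp; LTRs %d-%d / %d-%d; internal %d-%d\n",
              x$family, nchar(x$sequence),
              x$ltr5[1], x$ltr5[2], x$ltr3[1], x$ltr3[2],
              x$internal_span[1], x$internal_span[2]))
  invisible(x)
}

#' Extract exemplar subsequences
#'
#' @param exemplar a [te_exemplar()].
#' @param which for `ltr_seq`, `"5"` or `"3"`.
#' @return character sequence of the requested span.
#' @export
ltr_seq <- function(exemplar, which = c("5", "3")) {
  which <- match.arg(which)
  span <- if (which == "5") exemplar$ltr5 else exemplar$ltr3
  substr(exemplar$sequence, span[1], span[2])
}

#' @rdname ltr_seq
#' @export
internal_seq <- function(exemplar) {
  substr(exemplar$sequence, exemplar$internal_span[1], exemplar$internal_span[2])
}

#' Write / read exemplars as FASTA plus GFF3 sidecar
#'
#' The FASTA holds one record per family (record name = family); the GFF3
#' sidecar annotates each record with two `long_terminal_repeat` features
#' and one `internal` feature in the record's own coordinates.
#'
#' @param exemplars list of [te_exemplar()] objects.
#' @param fasta_path,gff3_path output (or input) file paths.
#' @return `write_te_exemplars`: invisibly, the fasta path.
#'   `read_te_exemplars`: a named list of `te_exemplar` objects.
#' @export
write_te_exemplars <- function(exemplars, fasta_path, gff3_path) {
  seqs <- Biostrings::DNAStringSet(vapply(exemplars, `[[`, "", "sequence"))
  names(seqs) <- vapply(exemplars, `[[`, "", "family")
  Biostrings::writeXStringSet(seqs, fasta_path)
  feats <- suppressWarnings(do.call(c, unname(lapply(exemplars, function(ex) {
    GenomicRanges::GRanges(
      seqnames = ex$family,
      ranges = IRanges::IRanges(
        start = c(ex$ltr5[1], ex$internal_span[1], ex$ltr3[1]),
        end = c(ex$ltr5[2], ex$internal_span[2], ex$ltr3[2])),
      type = c("long_terminal_repeat", "internal", "long_terminal_repeat"),
      ID = paste0(ex$family, c("_LTR5", "_internal", "_LTR3")))
  }))))
  rtracklayer::export(feats, gff3_path, format = "gff3")
  invisible(fasta_path)
}

#' @rdname write_te_exemplars
#' @export
read_te_exemplars <- function(fasta_path, gff3_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  feats <- rtracklayer::import(gff3_path, format = "gff3")
  out <- lapply(names(seqs), function(fam) {
    f <- feats[as.character(GenomicRanges::seqnames(feats)) == fam]
    ltrs <- f[f$type == "long_terminal_repeat"]
    ltrs <- ltrs[order(GenomicRanges::start(ltrs))]
    if (length(ltrs) != 2L)
      stop("exemplar ", fam, ": expected exactly 2 LTR features")
    te_exemplar(fam, as.character(seqs[[fam]]),
                ltr5 = c(GenomicRanges::start(ltrs)[1], GenomicRanges::end(ltrs)[1]),
                ltr3 = c(GenomicRanges::start(ltrs)[2], GenomicRanges::end(ltrs)[2]))
  })
  stats::setNames(out, names(seqs))
}
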