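# Ty insertion catalog: data model, TSV I/O, coordinate conventions,
# LTR-based family typing, and summary statistics.

#' Recognised Ty families
#'
#' Family labels for budding-yeast LTR retrotransposons, plus `"ambiguous"`
#' for elements that cannot be typed from available sequence.
#' @export
TY_FAMILIES <- c("Ty1", "Ty2", "Ty3", "Ty4", "Ty5", "ambiguous")

.TSD_TOKENS <- c(absent = "-", undetermined = "N.D.")

#' Construct a Ty insertion catalog
#'
#' A `ty_catalog` is a data frame of Ty elements, one row per element, in
#' 1-based inclusive reference coordinates. When an insertion site shows a
#' 5-bp target-site duplication (TSD), the convention is that the third and
#' fourth duplicated bases give the start and end coordinates of the
#' insertion site (see [tsd_to_insert_coords()]).
#'
#' @param x data frame with columns `chrom`, `name`, `start`, `end`,
#'   `family`, `strand`, `trna`, `tsd`, `completeness`, `note`.
#'   `family` must be one of [TY_FAMILIES]; `strand` one of `"+"`/`"-"`;
#'   `trna` one of `"yes"`, `"no"`, `"unknown"`; `tsd` a 5-base A/C/G/T
#'   string, `"absent"` (no duplication observed) or `"undetermined"`;
#'   `completeness` one of `"full"`, `"fragment"`.
#' @return the validated data frame with class `ty_catalog` and attribute
#'   `coordinate_system = "1-based inclusive"`.
#' @export
ty_catalog <- function(x) {
  required <- c("chrom", "name", "start", "end", "family", "strand",
                "trna", "tsd", "completeness", "note")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L)
    stop("catalog is missing column(s): ", paste(missing_cols, collapse = ", "))
  x <- as.data.frame(x)[required]
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  validate_ty_catalog(x)
  class(x) <- c("ty_catalog", "data.frame")
  attr(x, "coordinate_system") <- "1-based inclusive"
  x
}

validate_ty_catalog <- function(x) {
  bad_row <- function(i, msg) {
    stop(sprintf("catalog row %d (%s): %s", i, as.character(x$name[i]), msg),
         call. = FALSE)
  }
  if (anyDuplicated(x$name))
    stop("element names must be unique; duplicated: ",
         paste(unique(x$name[duplicated(x$name)]), collapse = ", "))
  for (i in seq_len(nrow(x))) {
    if (is.na(x$start[i]) || is.na(x$end[i]))
      bad_row(i, "malformed coordinate")
    if (x$end[i] < x$start[i])
      bad_row(i, sprintf("end (%d) < start (%d)", x$end[i], x$start[i]))
    if (!x$family[i] %in% TY_FAMILIES)
      bad_row(i, sprintf("unknown family token '%s'", x$family[i]))
    if (!x$strand[i] %in% c("+", "-"))
      bad_row(i, sprintf("unknown strand token '%s'", x$strand[i]))
    if (!x$trna[i] %in% c("yes", "no", "unknown"))
      bad_row(i, sprintf("unknown tRNA-adjacency token '%s'", x$trna[i]))
    if (!x$completeness[i] %in% c("full", "fragment"))
      bad_row(i, sprintf("unknown completeness token '%s'", x$completeness[i]))
    tsd <- x$tsd[i]
    if (!tsd %in% c("absent", "undetermined") &&
        !grepl("^[ACGT]{5}$", tsd))
      bad_row(i, sprintf("tsd '%s' is not a 5-base ACGT string, 'absent' or 'undetermined'", tsd))
  }
  invisible(x)
}

#' Read a Ty catalog from a tab-separated file
#'
#' The file must carry a header row with the canonical column names. The
#' TSD column uses `N.D.` for "not determined" and `-` for "duplication not
#' observed"; these map to `"undetermined"` and `"absent"` internally.
#' Parsing preserves row order; a malformed row raises an error naming it.
#'
#' @param path path to a TSV file.
#' @return a [ty_catalog()].
#' @export
read_ty_catalog <- function(path) {
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character", fill = TRUE,
                         quote = "", na.strings = NULL)
  if (nrow(x) == 0L) {
    x <- data.frame(chrom = character(), name = character(),
                    start = integer(), end = integer(),
                    family = character(), strand = character(),
                    trna = character(), tsd = character(),
                    completeness = character(), note = character())
    return(ty_catalog(x))
  }
  if (is.null(x$note)) x$note <- ""
  x$note[is.na(x$note)] <- ""
  suppressWarnings({
    start <- as.integer(x$start)
    end <- as.integer(x$end)
  })
  if (anyNA(start) || anyNA(end)) {
    i <- which(is.na(start) | is.na(end))[1L]
    stop(sprintf("catalog row %d (%s): malformed coordinate", i, x$name[i]))
  }
  x$start <- start
  x$end <- end
  for (tok in names(.TSD_TOKENS))
    x$tsd[x$tsd == .TSD_TOKENS[[tok]]] <- tok
  ty_catalog(x)
}

#' Write a Ty catalog to a tab-separated file
#'
#' Inverse of [read_ty_catalog()]: `"undetermined"` is written back as
#' `N.D.` and `"absent"` as `-`, so write-then-read round-trips a catalog
#' unchanged.
#'
#' @param catalog a [ty_catalog()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ty_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "ty_catalog"))
  x <- as.data.frame(catalog)
  for (tok in names(.TSD_TOKENS))
    x$tsd[x$tsd == tok] <- .TSD_TOKENS[[tok]]
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @export
print.ty_catalog <- function(x, ...) {
  cat(sprintf("Ty insertion catalog: %d element(s), coordinates %s\n",
              nrow(x), attr(x, "coordinate_system")))
  if (nrow(x) > 0L) {
    fam <- table(factor(x$family, levels = TY_FAMILIES))
    fam <- fam[fam > 0L]
    cat("  families:", paste(sprintf("%s=%d", names(fam), fam), collapse = ", "), "\n")
    print(utils::head(as.data.frame(x)[c("chrom", "name", "start", "end",
                                         "family", "strand", "tsd")], 10L))
    if (nrow(x) > 10L) cat(sprintf("  ... and %d more rows\n", nrow(x) - 10L))
  }
  invisible(x)
}

#' Convert a TSD start position to insertion-site coordinates
#'
#' Integration of a Ty element duplicates a 5-bp target sequence. By
#' convention the insertion site is reported as the third and fourth bases
#' of the duplicated pentamer, so a TSD beginning at `tsd_start` maps to
#' the coordinate pair `(tsd_start + 2, tsd_start + 3)`.
#'
#' @param tsd_start 1-based position(s) of the first duplicated base.
#' @param tsd_len duplication length; only 5 is supported.
#' @return data frame with columns `insert_start`, `insert_end`.
#' @seealso [insert_coords_to_tsd_start()] for the inverse.
#' @export
tsd_to_insert_coords <- function(tsd_start, tsd_len = 5L) {
  if (any(tsd_len != 5L))
    stop("unsupported duplication length: only 5-bp TSDs are supported")
  tsd_start <- as.integer(tsd_start)
  if (anyNA(tsd_start) || any(tsd_start < 1L))
    stop("tsd_start must be a positive 1-based coordinate")
  data.frame(insert_start = tsd_start + 2L, insert_end = tsd_start + 3L)
}

#' @rdname tsd_to_insert_coords
#' @param insert_start insertion-site start coordinate(s) produced by
#'   [tsd_to_insert_coords()].
#' @return for `insert_coords_to_tsd_start`, the TSD start position(s).
#' @export
insert_coords_to_tsd_start <- function(insert_start) {
  insert_start <- as.integer(insert_start)
  if (anyNA(insert_start) || any(insert_start < 3L))
    stop("insert_start must be >= 3 for a 5-bp duplication")
  insert_start - 2L
}

#' Type a Ty1/Ty2 LTR from the diagnostic residue
#'
#' Ty1 and Ty2 long terminal repeats are nearly identical and are
#' distinguished by a single diagnostic T residue in the Ty1 reference LTR
#' (position 284 of the Ty1-H3 LTR). The query LTR is aligned to the Ty1
#' reference LTR; a T aligned at the diagnostic position types the element
#' Ty1, a gap or any other base types it Ty2, and an alignment that does
#' not cover the position (e.g. a short LTR fragment) is `"ambiguous"`.
#'
#' @param ltr query LTR sequence (character or [Biostrings::DNAString]).
#' @param reference_ltr Ty1 reference LTR sequence.
#' @param diagnostic_pos 1-based position of the diagnostic residue on the
#'   reference LTR (default 284).
#' @return one of `"Ty1"`, `"Ty2"`, `"ambiguous"`.
#' @export
classify_family_from_ltr <- function(ltr, reference_ltr, diagnostic_pos = 284L) {
  ltr <- as.character(ltr)
  reference_ltr <- as.character(reference_ltr)
  if (nchar(ltr) == 0L)
    stop("empty LTR sequence")
  if (diagnostic_pos > nchar(reference_ltr))
    stop("diagnostic position lies beyond the reference LTR")
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(ltr),
    subject = Biostrings::DNAString(reference_ltr),
    type = "local")
  sub_start <- Biostrings::start(Biostrings::subject(aln))
  sub_end <- Biostrings::end(Biostrings::subject(aln))
  if (diagnostic_pos < sub_start || diagnostic_pos > sub_end)
    return("ambiguous")
  sub_chars <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  pat_chars <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sub_pos <- sub_start - 1L + cumsum(sub_chars != "-")
  idx <- which(sub_pos == diagnostic_pos & sub_chars != "-")[1L]
  if (is.na(idx)) return("ambiguous")
  if (pat_chars[idx] == "T") "Ty1" else "Ty2"
}

#' Summarise a Ty catalog
#'
#' Computes the headline statistics of a catalog: element count, counts per
#' family, the fraction of non-Ty5 elements adjacent to a tRNA gene (Ty5
#' targets subtelomeres, not tRNA genes, so it is excluded from that
#' denominator), the fraction of determined insertion sites showing a
#' perfect target-site duplication, and the fraction of the genome occupied
#' by elements.
#'
#' @param catalog a [ty_catalog()].
#' @param element_len assumed full element length in bp (default 6000).
#' @param genome_len genome size in bp (default 12.1e6, the S. cerevisiae
#'   nuclear genome).
#' @return an object of class `ty_catalog_summary`: a list with
#'   `n_total`, `family_counts`, `n_fragments`, `n_non_ty5`,
#'   `n_trna_adjacent`, `trna_fraction`, `n_tsd_determined`,
#'   `n_tsd_perfect`, `tsd_perfect_fraction`, `genome_fraction` and
#'   `genome_percent` (both to 2 significant figures).
#' @export
catalog_summary <- function(catalog, element_len = 6000, genome_len = 12.1e6) {
  stopifnot(inherits(catalog, "ty_catalog"))
  n <- nrow(catalog)
  fam <- table(factor(catalog$family, levels = TY_FAMILIES))
  non_ty5 <- catalog[catalog$family != "Ty5", , drop = FALSE]
  known_trna <- non_ty5[non_ty5$trna != "unknown", , drop = FALSE]
  n_trna <- sum(known_trna$trna == "yes")
  determined <- catalog$tsd[catalog$tsd != "undetermined"]
  n_perfect <- sum(determined != "absent")
  frac_or_na <- function(num, den) if (den > 0L) num / den else NA_real_
  genome_fraction <- if (n > 0L) signif(n * element_len / genome_len, 2) else NA_real_
  structure(list(
    n_total = n,
    family_counts = as.integer(fam) |> stats::setNames(names(fam)),
    n_fragments = sum(catalog$completeness == "fragment"),
    n_non_ty5 = nrow(non_ty5),
    n_trna_adjacent = n_trna,
    trna_fraction = frac_or_na(n_trna, nrow(known_trna)),
    n_tsd_determined = length(determined),
    n_tsd_perfect = n_perfect,
    tsd_perfect_fraction = frac_or_na(n_perfect, length(determined)),
    genome_fraction = genome_fraction,
    genome_percent = if (n > 0L) signif(100 * n * element_len / genome_len, 2) else NA_real_
  ), class = "ty_catalog_summary")
}

#' @export
print.ty_catalog_summary <- function(x, ...) {
  cat(sprintf("Ty catalog summary: %d elements (%d fragment(s))\n",
              x$n_total, x$n_fragments))
  fam <- x$family_counts[x$family_counts > 0L]
  cat("  families:          ",
      paste(sprintf("%s=%d", names(fam), fam), collapse = ", "), "\n")
  cat(sprintf("  tRNA-adjacent:      %d of %d non-Ty5 elements (%.0f%%)\n",
              x$n_trna_adjacent, x$n_non_ty5, 100 * x$trna_fraction))
  cat(sprintf("  perfect TSD:        %d of %d determined sites (%.1f%%)\n",
              x$n_tsd_perfect, x$n_tsd_determined, 100 * x$tsd_perfect_fraction))
  cat(sprintf("  genome occupancy:   ~%g%% of genomic DNA\n", x$genome_percent))
  invisible(x)
}

#' @export
summary.ty_catalog <- function(object, ...) catalog_summary(object, ...)

#' Target-site duplication consensus
#'
#' Builds a position-frequency matrix from a set of 5-bp target-site
#' duplications and derives a consensus string, using IUPAC ambiguity codes
#' where bases tie for the per-position maximum.
#'
#' @param tsds character vector of 5-base A/C/G/T strings.
#' @return object of class `tsd_consensus`: list with `matrix` (4 bases x 5
#'   positions, column frequencies summing to 1), `n_observations`, and
#'   `consensus` (length-5 IUPAC string, `NA` when no observations).
#' @export
tsd_consensus <- function(tsds) {
  tsds <- as.character(tsds)
  if (length(tsds) > 0L && any(!grepl("^[ACGT]{5}$", tsds)))
    stop("all TSDs must be 5-base strings over {A,C,G,T}")
  bases <- c("A", "C", "G", "T")
  mat <- matrix(0, nrow = 4L, ncol = 5L, dimnames = list(bases, paste0("pos", 1:5)))
  n <- length(tsds)
  consensus <- NA_character_
  if (n > 0L) {
    chars <- do.call(rbind, strsplit(tsds, ""))
    for (j in 1:5) mat[, j] <- table(factor(chars[, j], levels = bases)) / n
    iupac <- Biostrings::IUPAC_CODE_MAP
    consensus <- paste(vapply(1:5, function(j) {
      top <- bases[mat[, j] == max(mat[, j])]
      key <- paste(top, collapse = "")
      names(iupac)[match(key, iupac)]
    }, character(1L)), collapse = "")
  }
  structure(list(matrix = mat, n_observations = n, consensus = consensus),
            class = "tsd_consensus")
}

#' @export
print.tsd_consensus <- function(x, ...) {
  cat(sprintf("TSD consensus from %d observation(s): %s\n",
              x$n_observations,
              if (is.na(x$consensus)) "(none)" else x$consensus))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Packaged SK1 Ty catalog fixture
#'
#' Convenience accessor for the packaged 30-element SK1 Ty insertion
#' catalog shipped under `extdata`.
#'
#' @return a [ty_catalog()] of 30 elements.
#' @export
sk1_ty_catalog <- function() {
  read_ty_catalog(system.file("extdata", "sk1_ty_catalog.tsv",
                              package = "tymap", mustWork = TRUE))
}
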