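# Poisson model of per-site supporting-read counts: how likely is it that
# an insertion site was missed because no supporting read pair was drawn?

#' Per-site supporting-read histogram
#'
#' @param counts non-negative integer vector, one entry per insertion site,
#'   giving the number of read pairs supporting that site.
#' @return object of class `support_histogram` with fields `counts` and
#'   `n_sites`.
#' @export
support_histogram <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L)
    stop("empty support histogram: at least one site is required")
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts)))
    stop("supporting-read counts must be non-negative integers")
  structure(list(counts = as.integer(counts), n_sites = length(counts)),
            class = "support_histogram")
}

#' Read a site/support TSV into a support histogram
#'
#' Expects columns `site` and `support` (as emitted by
#' [write_support_table()]).
#' @param path TSV path.
#' @return a [support_histogram()].
#' @export
read_support_table <- function(path) {
  x <- utils::read.delim(path)
  support_histogram(x$support)
}

#' @rdname read_support_table
#' @param hist a [support_histogram()] (site labels are generated).
#' @export
write_support_table <- function(hist, path) {
  stopifnot(inherits(hist, "support_histogram"))
  utils::write.table(
    data.frame(site = paste0("site", seq_len(hist$n_sites)),
               support = hist$counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fit a Poisson model to per-site supporting-read counts
#'
#' The method-of-moments (= maximum-likelihood) fit takes lambda as the
#' arithmetic mean count. The zero-count probability `exp(-lambda)`
#' estimates the per-site probability that an insertion received no
#' supporting reads and was therefore missed by the screen.
#'
#' @param hist a [support_histogram()] or a bare count vector.
#' @return object of class `poisson_fit`: list with `lambda`, `n_sites`,
#'   `miss_prob` (= `exp(-lambda)`), `genome_miss_prob`
#'   (= `1 - (1 - miss_prob)^n_sites`, the chance that at least one of
#'   `n_sites` comparable sites was missed) and `expected`, the expected
#'   site count per support bin with the tail aggregated (sums to
#'   `n_sites`).
#' @export
fit_poisson <- function(hist) {
  if (!inherits(hist, "support_histogram")) hist <- support_histogram(hist)
  lambda <- mean(hist$counts)
  expected <- expected_bins(lambda, hist$n_sites, max(hist$counts))
  structure(list(lambda = lambda,
                 n_sites = hist$n_sites,
                 counts = hist$counts,
                 miss_prob = exp(-lambda),
                 genome_miss_prob = 1 - (1 - exp(-lambda))^hist$n_sites,
                 expected = expected),
            class = "poisson_fit")
}

# Expected site counts per bin 0..K plus an aggregated ">=K+1" tail, with
# the cut chosen so trailing bins with expected count < 1 are pooled.
expected_bins <- function(lambda, n_sites, max_count) {
  k <- 0:max(max_count, 0L)
  exp_k <- n_sites * stats::dpois(k, lambda)
  keep <- max(1L, {
    big <- which(exp_k >= 1)
    if (length(big) == 0L) 1L else max(big)
  })
  bins <- k[seq_len(keep)]
  out <- exp_k[seq_len(keep)]
  tail_mass <- n_sites * stats::ppois(bins[keep], lambda, lower.tail = FALSE)
  labels <- as.character(bins)
  if (tail_mass > 0 || max_count > bins[keep]) {
    out <- c(out, tail_mass)
    labels <- c(labels, paste0(">=", bins[keep] + 1L))
  }
  stats::setNames(out, labels)
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat(sprintf("Poisson fit to supporting-read counts at %d sites\n", x$n_sites))
  cat(sprintf("  lambda (mean support):     %.3g\n", x$lambda))
  cat(sprintf("  per-site miss probability: %.3g\n", x$miss_prob))
  cat(sprintf("  P(any of %d sites missed): %.3g\n", x$n_sites, x$genome_miss_prob))
  invisible(x)
}

#' @export
summary.poisson_fit <- function(object, ...) {
  print(object)
  cat("\nObserved vs expected site counts per support bin:\n")
  print(poisson_goodness(support_histogram(object$counts), object))
  invisible(object)
}

#' Per-site miss probability under a Poisson support model
#'
#' The probability that a site drew zero supporting reads,
#' `P(X = 0) = exp(-lambda)`.
#'
#' @param lambda mean supporting reads per site (>= 0).
#' @return probability in `[0, 1]`.
#' @export
miss_probability <- function(lambda) {
  if (any(is.na(lambda)) || any(lambda < 0))
    stop("lambda must be non-negative")
  exp(-lambda)
}

#' @rdname miss_probability
#' @param n_sites number of comparable sites in the genome.
#' @return for `genome_miss_probability`, the probability that at least one
#'   of `n_sites` sites has zero support.
#' @export
genome_miss_probability <- function(lambda, n_sites) {
  1 - (1 - miss_probability(lambda))^n_sites
}

#' Observed vs expected support-bin table
#'
#' Pairs the observed number of sites per supporting-read bin with the
#' Poisson expectation from [fit_poisson()]. Tail bins whose expected count
#' falls below 1 are aggregated into a single `>=k` bin, so both columns
#' sum to `n_sites`.
#'
#' @param hist a [support_histogram()].
#' @param fit the [fit_poisson()] result for `hist`.
#' @return data frame with columns `bin`, `observed`, `expected`.
#' @export
poisson_goodness <- function(hist, fit) {
  if (!inherits(hist, "support_histogram")) hist <- support_histogram(hist)
  stopifnot(inherits(fit, "poisson_fit"))
  labels <- names(fit$expected)
  tail_lab <- grep("^>=", labels, value = TRUE)
  plain <- as.integer(labels[!grepl("^>=", labels)])
  observed <- vapply(plain, function(k) sum(hist$counts == k), integer(1L))
  if (length(tail_lab) == 1L) {
    cut <- as.integer(sub("^>=", "", tail_lab))
    observed <- c(observed, sum(hist$counts >= cut))
  }
  data.frame(bin = labels, observed = observed,
             expected = as.numeric(fit$expected))
}

#' @export
plot.poisson_fit <- function(x, ...) {
  tab <- poisson_goodness(support_histogram(x$counts), x)
  bp <- graphics::barplot(tab$observed, names.arg = tab$bin,
                          xlab = "supporting reads per site",
                          ylab = "number of sites",
                          main = sprintf("Support distribution (lambda = %.2g)", x$lambda),
                          ...)
  graphics::lines(bp, tab$expected, type = "b", pch = 19)
  graphics::legend("topright", legend = c("observed", "Poisson expected"),
                   pch = c(22, 19), bty = "n")
  invisible(x)
}
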