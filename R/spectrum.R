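#' Allele (or haplotype) frequency spectrum for one locus
#'
#' Holds the allele-label -> frequency map together with the number of
#' chromosomes the frequencies were estimated from. Frequencies are kept
#' verbatim: published tables are often rounded so that columns sum to
#' 0.9999--1.0001, and reproducing published forensic parameters requires
#' using the printed values as-is. Renormalization is opt-in.
#'
#' @param locus locus (or linkage-group) name.
#' @param freqs named numeric vector of strictly positive frequencies; names
#'   are allele labels (decimal microvariants such as "17.3" are fine).
#' @param n_chromosomes positive integer, at least the number of alleles.
#' @param sum_tol allowed deviation of `sum(freqs)` from 1 (default 0.01).
#' @param renormalize if `TRUE`, divide by `sum(freqs)` so frequencies sum
#'   to exactly 1.
#' @return An object of class `freq_spectrum`.
#' @examples
#' freq_spectrum("X029", c(`9` = 0.6, `10` = 0.4), n_chromosomes = 100)
#' @export
freq_spectrum <- function(locus, freqs, n_chromosomes,
                          sum_tol = 0.01, renormalize = FALSE) {
  if (length(freqs) == 0) stop("empty spectrum for locus ", locus)
  if (is.null(names(freqs)) || any(!nzchar(names(freqs))))
    stop("freqs must be named by allele label")
  if (anyDuplicated(names(freqs)))
    stop("duplicate allele label at locus ", locus)
  if (any(!is.finite(freqs)) || any(freqs <= 0))
    stop("frequencies must be finite and > 0 at locus ", locus)
  s <- sum(freqs)
  if (abs(s - 1) > sum_tol)
    stop(sprintf("frequencies at locus %s sum to %.6f (tolerance %g)",
                 locus, s, sum_tol))
  if (renormalize) freqs <- freqs / s
  n_chromosomes <- as.integer(n_chromosomes)
  if (is.na(n_chromosomes) || n_chromosomes < 1)
    stop("n_chromosomes must be a positive integer")
  if (n_chromosomes < length(freqs))
    stop("n_chromosomes smaller than the number of alleles at ", locus)
  freqs <- freqs[sort_alleles(names(freqs))]
  structure(list(locus = locus, freqs = freqs,
                 n_chromosomes = n_chromosomes),
            class = "freq_spectrum")
}

#' @export
print.freq_spectrum <- function(x, ...) {
  cat(sprintf("freq_spectrum %s: %d alleles, n = %d chromosomes, sum = %.4f\n",
              x$locus, length(x$freqs), x$n_chromosomes, sum(x$freqs)))
  print(x$freqs)
  invisible(x)
}

# Accept a freq_spectrum or a bare numeric vector of frequencies.
spec_freqs <- function(x) {
  if (inherits(x, "freq_spectrum")) return(x$freqs)
  if (is.numeric(x) && length(x) > 0) return(x)
  stop("expected a freq_spectrum or a numeric frequency vector")
}

#' Power sums of a frequency spectrum
#'
#' Computes \eqn{P_k = \sum_i p_i^k} for k = 1..5. Every forensic parameter
#' in this package is a polynomial in these moments, so they are exposed as
#' a unit.
#'
#' @param x a [freq_spectrum()] or numeric frequency vector.
#' @return Named numeric vector `c(P1, P2, P3, P4, P5)`.
#' @examples
#' power_sums(c(0.5, 0.5))
#' @export
power_sums <- function(x) {
  p <- spec_freqs(x)
  c(P1 = sum(p), P2 = sum(p^2), P3 = sum(p^3), P4 = sum(p^4), P5 = sum(p^5))
}

#' Read a per-locus allele frequency table
#'
#' Tab-separated with header `locus allele frequency` or `locus allele count`
#' (counts are converted to frequencies by the per-locus chromosome count).
#'
#' @param path file path.
#' @param n_chromosomes per-locus chromosome counts: a single number applied
#'   to all loci, or a named vector. Required when the table carries
#'   frequencies; with counts it defaults to the per-locus count sum.
#' @param renormalize,sum_tol passed to [freq_spectrum()].
#' @return Named list of [freq_spectrum()] objects, in file order.
#' @export
read_frequency_table <- function(path, n_chromosomes = NULL,
                                 renormalize = FALSE, sum_tol = 0.01) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                  colClasses = "character")
  if (!all(c("locus", "allele") %in% names(d)))
    stop("frequency table must have columns locus and allele")
  has_freq <- "frequency" %in% names(d)
  has_count <- "count" %in% names(d)
  if (!has_freq && !has_count)
    stop("frequency table needs a frequency or count column")
  if (anyDuplicated(d[c("locus", "allele")]))
    stop("duplicate (locus, allele) row in ", path)
  loci <- unique(d$locus)
  out <- lapply(loci, function(l) {
    rows <- d[d$locus == l, , drop = FALSE]
    if (has_count) {
      cnt <- as.numeric(rows$count)
      if (any(is.na(cnt) | cnt < 0)) stop("bad count at locus ", l)
      n <- if (is.null(n_chromosomes)) sum(cnt) else
        unname(if (length(n_chromosomes) > 1) n_chromosomes[[l]] else n_chromosomes)
      f <- cnt / n
    } else {
      f <- as.numeric(rows$frequency)
      if (any(is.na(f))) stop("bad frequency at locus ", l)
      if (any(f < 0)) stop("negative frequency at locus ", l)
      if (is.null(n_chromosomes))
        stop("n_chromosomes is required when the table carries frequencies")
      n <- unname(if (length(n_chromosomes) > 1) n_chromosomes[[l]] else n_chromosomes)
    }
    freq_spectrum(l, setNames(f, rows$allele), n,
                  sum_tol = sum_tol, renormalize = renormalize)
  })
  names(out) <- loci
  out
}

#' Write a per-locus allele frequency table
#'
#' Inverse of [read_frequency_table()]; emits `locus allele frequency`.
#'
#' @param specs list of [freq_spectrum()] objects.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(specs, path) {
  rows <- do.call(rbind, lapply(specs, function(s) {
    data.frame(locus = s$locus, allele = names(s$freqs),
               frequency = unname(s$freqs), stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
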