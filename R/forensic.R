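#' Estimate allele frequencies at one locus
#'
#' Gene counting on the X: every non-missing male call contributes one
#' chromosome, every female call two. Frequencies are counts divided by the
#' number of chromosomes observed at the locus.
#'
#' @param ds an [xstr_dataset()].
#' @param locus locus name.
#' @return A [freq_spectrum()].
#' @export
estimate_allele_frequencies <- function(ds, locus) {
  if (!locus %in% colnames(ds$a1)) stop("locus ", locus, " not in dataset")
  male <- ds$sex == "M"
  alleles <- c(ds$a1[male, locus], ds$a1[!male, locus], ds$a2[!male, locus])
  alleles <- alleles[!is.na(alleles)]
  if (!length(alleles)) stop("zero observations at locus ", locus)
  cnt <- table(alleles)
  freq_spectrum(locus, setNames(as.numeric(cnt) / sum(cnt), names(cnt)),
                n_chromosomes = sum(cnt))
}

#' Gene diversity (unbiased expected heterozygosity)
#'
#' \eqn{GD = \frac{n}{n-1}(1 - \sum_i p_i^2)} where n is the number of
#' chromosomes sampled (269 for 127 males + 71 females fully typed; the
#' number of typed males for haplotype spectra).
#'
#' @param x a [freq_spectrum()] or numeric frequency vector.
#' @param n_chromosomes chromosome count; taken from the spectrum when `x`
#'   is a [freq_spectrum()].
#' @return Gene diversity in `[0, n/(n-1)]`.
#' @export
gene_diversity <- function(x, n_chromosomes = NULL) {
  p <- spec_freqs(x)
  n <- if (inherits(x, "freq_spectrum")) x$n_chromosomes else n_chromosomes
  if (is.null(n)) stop("n_chromosomes required for a bare frequency vector")
  if (n < 2) stop("gene diversity needs at least 2 chromosomes")
  n / (n - 1) * (1 - sum(p^2))
}

#' Haplotype diversity
#'
#' Identical estimator to [gene_diversity()] applied to a haplotype
#' spectrum, where n is the number of typed males.
#'
#' @inheritParams gene_diversity
#' @return Haplotype diversity.
#' @export
haplotype_diversity <- function(x, n_chromosomes = NULL)
  gene_diversity(x, n_chromosomes)

#' Polymorphism information content
#'
#' \eqn{PIC = 1 - P_2 - P_2^2 + P_4} with \eqn{P_k = \sum_i p_i^k}.
#'
#' @inheritParams gene_diversity
#' @return PIC in `[0, 1]`.
#' @export
pic <- function(x) {
  P <- power_sums(x)
  unname(1 - P["P2"] - P["P2"]^2 + P["P4"])
}

#' Power of discrimination in males (haploid)
#'
#' Probability that two random male profiles differ: \eqn{1 - \sum p_i^2}.
#'
#' @inheritParams gene_diversity
#' @export
pd_male <- function(x) unname(1 - power_sums(x)["P2"])

#' Power of discrimination in females (diploid)
#'
#' \eqn{1 - 2 P_2^2 + P_4}.
#'
#' @inheritParams gene_diversity
#' @export
pd_female <- function(x) {
  P <- power_sums(x)
  unname(1 - 2 * P["P2"]^2 + P["P4"])
}

#' Mean exclusion chance, Krueger variant (deficiency cases)
#'
#' The classic trio exclusion probability used for X-linked markers in
#' deficiency casework. It is evaluated as the exclusion-probability sum
#' over allele configurations without assuming that the frequencies sum to
#' one, which matters for published tables rounded to four decimals:
#' \deqn{MEC = 1 - 2P_2 + P_3 + 2P_4 - 3P_5 - 2P_2^2 + 3P_2P_3
#'       + (P_1 - 1)(1 + P_2 - 2P_3 + P_4)}
#' The correction term vanishes when \eqn{P_1 = \sum p_i = 1}, recovering
#' the familiar moment polynomial.
#'
#' @inheritParams gene_diversity
#' @export
mec_kruger <- function(x) {
  P <- power_sums(x)
  base <- 1 - 2 * P["P2"] + P["P3"] + 2 * P["P4"] - 3 * P["P5"] -
    2 * P["P2"]^2 + 3 * P["P2"] * P["P3"]
  unname(base + (P["P1"] - 1) * (1 + P["P2"] - 2 * P["P3"] + P["P4"]))
}

#' Mean exclusion chance, Kishida variant (trios)
#'
#' Trio exclusion chance for X-linked markers, evaluated as the
#' allele-configuration sum
#' \deqn{\sum_i p_i(1-p_i)^2 + \sum_i p_i^3(1-p_i)
#'       + \sum_{i \ne j} p_i^2 p_j (1 - p_i - p_j)}
#' which equals \eqn{1 - P_2 - P_2^2 + P_4} (the Desmarais trio MEC and
#' PIC) exactly when frequencies sum to one, but differs on rounded
#' published tables whose columns sum to 0.9999 or 1.0001.
#'
#' @inheritParams gene_diversity
#' @export
mec_kishida <- function(x) {
  P <- power_sums(x)
  base <- 1 - P["P2"] - P["P2"]^2 + P["P4"]
  unname(base + (P["P1"] - 1) * (1 + P["P2"] - P["P3"]))
}

#' Mean exclusion chance, Desmarais variant (trios)
#'
#' \eqn{1 - P_2 - P_2^2 + P_4}; algebraically identical to [pic()].
#'
#' @inheritParams gene_diversity
#' @export
mec_desmarais <- function(x) pic(x)

#' Mean exclusion chance, Desmarais variant for duos
#'
#' Mother--child (or father--daughter) duo exclusion chance
#' \eqn{1 - 2P_2 + P_3}.
#'
#' @inheritParams gene_diversity
#' @export
mec_desmarais_duo <- function(x) {
  P <- power_sums(x)
  unname(1 - 2 * P["P2"] + P["P3"])
}

#' Full forensic parameter battery for one spectrum
#'
#' @inheritParams gene_diversity
#' @return Named numeric vector with `GD`, `PIC`, `PD_male`, `PD_female`,
#'   `MEC_Kruger`, `MEC_Kishida`, `MEC_Desmarais`, `MEC_Desmarais_duo`.
#' @export
forensic_params <- function(x, n_chromosomes = NULL) {
  c(GD = gene_diversity(x, n_chromosomes), PIC = pic(x),
    PD_male = pd_male(x), PD_female = pd_female(x),
    MEC_Kruger = mec_kruger(x), MEC_Kishida = mec_kishida(x),
    MEC_Desmarais = mec_desmarais(x), MEC_Desmarais_duo = mec_desmarais_duo(x))
}

#' Parameter table for a set of spectra
#'
#' One row per parameter, one column per spectrum, mirroring the layout of
#' published X-STR characterization tables.
#'
#' @param specs list of [freq_spectrum()] objects.
#' @param digits rounding applied to the frequencies before computing
#'   parameters (`NULL` for none). Published tables are reproduced from
#'   4-decimal frequencies without renormalization.
#' @return Data frame (parameters x loci).
#' @export
params_table <- function(specs, digits = NULL) {
  cols <- lapply(specs, function(s) {
    p <- s$freqs
    if (!is.null(digits)) p <- round(p, digits)
    forensic_params(p, s$n_chromosomes)
  })
  out <- as.data.frame(cols, check.names = FALSE)
  names(out) <- vapply(specs, function(s) s$locus, "")
  out
}

#' Estimate male haplotype frequencies for a linkage group
#'
#' Haplotypes are counted from hemizygous males only, where phase is
#' observed directly; unrelated females are excluded because their phase is
#' unknown. The chromosome count is the number of males fully typed at the
#' group's loci.
#'
#' @param ds an [xstr_dataset()].
#' @param panel an [xstr_panel()].
#' @param group linkage-group label in the panel.
#' @return A [freq_spectrum()] over haplotype labels (alleles joined by
#'   `-` in map order).
#' @export
estimate_haplotype_frequencies <- function(ds, panel, group) {
  loci <- panel$locus[panel$linkage_group == group]
  if (!length(loci)) stop("no loci in linkage group ", group)
  if (!all(loci %in% colnames(ds$a1)))
    stop("dataset lacks loci of group ", group)
  male <- ds$sex == "M"
  h <- ds$a1[male, loci, drop = FALSE]
  full <- rowSums(is.na(h)) == 0
  if (!any(full)) stop("no fully typed male for group ", group)
  lab <- apply(h[full, , drop = FALSE], 1, paste, collapse = "-")
  cnt <- table(lab)
  freq_spectrum(group, setNames(as.numeric(cnt) / sum(cnt), names(cnt)),
                n_chromosomes = sum(cnt))
}

#' Combine a parameter across independent linkage groups
#'
#' \eqn{1 - \prod_g (1 - v_g)}: the probability that at least one group
#' discriminates/excludes, assuming independence between groups.
#'
#' @param values numeric vector of per-group parameter values in `[0, 1]`.
#' @return Combined value, at least `max(values)`.
#' @examples
#' combine_across_groups(c(0.9, 0.9)) # 0.99
#' @export
combine_across_groups <- function(values) {
  if (!length(values)) stop("empty value list")
  if (any(values < 0 | values > 1)) stop("values must lie in [0, 1]")
  1 - prod(1 - values)
}
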