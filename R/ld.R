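# Pairwise linkage-disequilibrium exact tests. Male X chromosomes are
# haploid with known phase, so the male test is an exact test of allelic
# association on the two-locus contingency table (probability-ordered tail
# conditional on the margins). Female genotypes have unknown phase, so the
# female test fits two-locus haplotype frequencies by EM and permutes
# single-locus genotypes across individuals to build the null of its
# likelihood-ratio statistic.

# Enumerate r x c tables with fixed margins; visit(count_matrix) per table.
enumerate_margin_tables <- function(rows, cols, visit, max_tables = 2e6) {
  r <- length(rows); cc <- length(cols)
  M <- matrix(0L, r, cc)
  n_seen <- 0L
  rec <- function(i, j, rrem, crem) {
    if (i == r) {                       # last row forced by column margins
      if (all(crem >= 0) && sum(crem) == rrem[r]) {
        M[r, ] <<- crem
        n_seen <<- n_seen + 1L
        if (n_seen > max_tables)
          stop("enumeration cap exceeded; use method = 'monte_carlo'",
               call. = FALSE)
        visit(M)
      }
      return(invisible())
    }
    if (j == cc) {                      # last cell in row forced
      n <- rrem[i]
      if (n <= crem[cc]) {
        M[i, cc] <<- n
        cr <- crem; cr[cc] <- cr[cc] - n
        rr <- rrem; rr[i] <- 0L
        rec(i + 1L, 1L, rr, cr)
      }
      return(invisible())
    }
    for (n in 0:min(rrem[i], crem[j])) {
      M[i, j] <<- n
      rr <- rrem; rr[i] <- rr[i] - n
      cr <- crem; cr[j] <- cr[j] - n
      rec(i, j + 1L, rr, cr)
    }
  }
  rec(1L, 1L, as.integer(rows), as.integer(cols))
  n_seen
}

#' Exact LD test on male (haploid) two-locus data
#'
#' Probability-ordered exact test of independence on the contingency table
#' of male haplotypes, conditional on both margins (the multi-allelic
#' generalization of Fisher's exact test). Enumeration for small tables,
#' otherwise Monte Carlo over margin-preserving permutations of the second
#' locus.
#'
#' @param x,y allele labels of the two loci for the same males (equal
#'   length; pairs with a missing entry are dropped).
#' @param method `"auto"`, `"enumerate"` or `"monte_carlo"`.
#' @param permutations Monte Carlo sample size.
#' @param seed RNG seed.
#' @param max_tables enumeration cap.
#' @return An `xstr_test` (`statistic_kind = "ld_exact_haploid"`). A
#'   monomorphic locus yields p = 1 with a warning.
#' @export
ld_exact_test_haploid <- function(x, y, method = c("auto", "enumerate",
                                                   "monte_carlo"),
                                  permutations = 1e5, seed = 1L,
                                  max_tables = 2e6) {
  method <- match.arg(method)
  keep <- !is.na(x) & !is.na(y)
  x <- as.character(x[keep]); y <- as.character(y[keep])
  if (length(x) < 2) stop("need at least 2 males")
  ax <- sort_alleles(unique(x)); ay <- sort_alleles(unique(y))
  if (length(ax) < 2 || length(ay) < 2) {
    warning("degenerate table: monomorphic locus; p = 1")
    return(new_test_result("ld_exact_haploid", 1, NULL, 0L, seed,
                           "degenerate"))
  }
  ix <- match(x, ax); iy <- match(y, ay)
  r <- length(ax); cc <- length(ay)
  obs <- matrix(0L, r, cc)
  for (i in seq_along(ix)) obs[ix[i], iy[i]] <- obs[ix[i], iy[i]] + 1L
  obs_stat <- -sum(lfactorial(obs))
  tol <- 1e-9 * max(1, abs(obs_stat))

  # as in the HWE test, 'auto' only attempts the recursive enumeration when
  # the table space is plausibly small; otherwise permutation Monte Carlo
  try_enum <- method == "enumerate" ||
    (method == "auto" && r <= 3 && cc <= 3 && length(x) <= 30)
  if (try_enum) {
    logK <- sum(lfactorial(rowSums(obs))) + sum(lfactorial(colSums(obs))) -
      lfactorial(sum(obs))
    tail_p <- 0; total_p <- 0
    res <- tryCatch({
      enumerate_margin_tables(rowSums(obs), colSums(obs), function(M) {
        s <- -sum(lfactorial(M))
        p <- exp(logK + s)
        total_p <<- total_p + p
        if (s <= obs_stat + tol) tail_p <<- tail_p + p
      }, max_tables = max_tables)
      TRUE
    }, error = function(e) e)
    if (isTRUE(res)) {
      if (abs(total_p - 1) > 1e-6)
        warning("enumerated probabilities sum to ", format(total_p))
      return(new_test_result("ld_exact_haploid", min(tail_p / total_p, 1),
                             NULL, 0L, seed, "enumerate"))
    }
    if (method == "enumerate") stop(conditionMessage(res), call. = FALSE)
  }

  set.seed(seed)
  B <- as.integer(permutations)
  hits <- 0L
  base <- (ix - 1L) * cc
  nb <- r * cc
  for (b in seq_len(B)) {
    cnt <- tabulate(base + iy[sample.int(length(iy))], nbins = nb)
    if (-sum(lfactorial(cnt)) <= obs_stat + tol) hits <- hits + 1L
  }
  p <- (hits + 1) / (B + 1)
  new_test_result("ld_exact_haploid", p, sqrt(p * (1 - p) / B), B, seed,
                  "monte_carlo")
}

# EM fit of two-locus haplotype frequencies from unphased diploid data.
# ia1/ia2, ib1/ib2: integer allele indices per individual at locus A and B.
# Returns list(h, loglik).
em_haplotypes <- function(ia1, ia2, ib1, ib2, nA, nB,
                          max_iter = 60, tol = 1e-7) {
  n <- length(ia1)
  pa <- tabulate(c(ia1, ia2), nA) / (2 * n)
  pb <- tabulate(c(ib1, ib2), nB) / (2 * n)
  h <- outer(pa, pb)
  # two phase resolutions per individual; identical when either locus is hom
  hom <- ia1 == ia2 | ib1 == ib2
  idx1a <- cbind(ia1, ib1); idx1b <- cbind(ia2, ib2)
  idx2a <- cbind(ia1, ib2); idx2b <- cbind(ia2, ib1)
  mult <- function(i, j) ifelse(i[, 1] == j[, 1] & i[, 2] == j[, 2], 1, 2)
  m1 <- mult(idx1a, idx1b); m2 <- mult(idx2a, idx2b)
  # linear haplotype indices for the vectorized M-step
  lin <- function(idx) (idx[, 1] - 1L) * nB + idx[, 2]
  l1a <- lin(idx1a); l1b <- lin(idx1b); l2a <- lin(idx2a); l2b <- lin(idx2b)
  loglik <- function(h) {
    p1 <- m1 * h[idx1a] * h[idx1b]
    p2 <- ifelse(hom, 0, m2 * h[idx2a] * h[idx2b])
    sum(log(pmax(p1 + p2, 1e-300)))
  }
  ll0 <- loglik(h)
  for (it in seq_len(max_iter)) {
    p1 <- m1 * h[idx1a] * h[idx1b]
    p2 <- ifelse(hom, 0, m2 * h[idx2a] * h[idx2b])
    w1 <- p1 / pmax(p1 + p2, 1e-300)
    w1[hom] <- 1
    w2 <- 1 - w1
    acc <- rowsum(c(w1, w1, w2, w2), c(l1a, l1b, l2a, l2b))
    cnt <- numeric(nA * nB)
    cnt[as.integer(rownames(acc))] <- acc
    h <- matrix(cnt, nA, nB, byrow = TRUE) / (2 * n)
    ll <- loglik(h)
    if (ll - ll0 < tol) break
    ll0 <- ll
  }
  list(h = h, loglik = loglik(h))
}

#' Exact (permutation) LD test on female genotypic data
#'
#' Phase-unknown association test: two-locus haplotype frequencies are fit
#' by EM, the statistic is the likelihood ratio of the EM fit against
#' linkage equilibrium (the product of allele frequencies), and its null
#' distribution is built by permuting the second locus' genotypes across
#' individuals.
#'
#' @param g1,g2 n x 2 matrices of female allele labels at the two loci
#'   (rows are individuals; rows with missing entries dropped).
#' @param permutations permutation count.
#' @param seed RNG seed.
#' @return An `xstr_test` (`statistic_kind = "ld_exact_genotypic"`).
#' @export
ld_exact_test_genotypic <- function(g1, g2, permutations = 1e5, seed = 1L) {
  g1 <- as.matrix(g1); g2 <- as.matrix(g2)
  keep <- stats::complete.cases(g1) & stats::complete.cases(g2)
  g1 <- g1[keep, , drop = FALSE]; g2 <- g2[keep, , drop = FALSE]
  n <- nrow(g1)
  if (n < 1) stop("empty input: no female genotypes")
  aA <- sort_alleles(unique(c(g1))); aB <- sort_alleles(unique(c(g2)))
  if (n < 2 || length(aA) < 2 || length(aB) < 2) {
    if (length(aA) < 2 || length(aB) < 2)
      warning("degenerate table: monomorphic locus; p = 1")
    return(new_test_result("ld_exact_genotypic", 1, NULL, 0L, seed,
                           "degenerate"))
  }
  ia1 <- match(g1[, 1], aA); ia2 <- match(g1[, 2], aA)
  ib1 <- match(g2[, 1], aB); ib2 <- match(g2[, 2], aB)
  nA <- length(aA); nB <- length(aB)
  lr_stat <- function(ib1, ib2) {
    fit <- em_haplotypes(ia1, ia2, ib1, ib2, nA, nB)
    pa <- tabulate(c(ia1, ia2), nA) / (2 * n)
    pb <- tabulate(c(ib1, ib2), nB) / (2 * n)
    h0 <- outer(pa, pb)
    ll0 <- {
      hom <- ia1 == ia2 | ib1 == ib2
      i1a <- cbind(ia1, ib1); i1b <- cbind(ia2, ib2)
      i2a <- cbind(ia1, ib2); i2b <- cbind(ia2, ib1)
      m <- function(i, j) ifelse(i[, 1] == j[, 1] & i[, 2] == j[, 2], 1, 2)
      p1 <- m(i1a, i1b) * h0[i1a] * h0[i1b]
      p2 <- ifelse(hom, 0, m(i2a, i2b) * h0[i2a] * h0[i2b])
      sum(log(pmax(p1 + p2, 1e-300)))
    }
    2 * (fit$loglik - ll0)
  }
  obs <- lr_stat(ib1, ib2)
  set.seed(seed)
  B <- as.integer(permutations)
  hits <- 0L
  for (b in seq_len(B)) {
    perm <- sample.int(n)
    if (lr_stat(ib1[perm], ib2[perm]) >= obs - 1e-9) hits <- hits + 1L
  }
  p <- (hits + 1) / (B + 1)
  new_test_result("ld_exact_genotypic", p, sqrt(p * (1 - p) / B), B, seed,
                  "monte_carlo")
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param n_tests number of tests (36 for all pairs of nine loci).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 36) # 0.00138889
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Pairwise LD tests over a dataset
#'
#' Runs the haploid test on males and the genotypic test on females for
#' every locus pair, returning two p-value matrices.
#'
#' @param ds an [xstr_dataset()].
#' @param permutations Monte Carlo size per test.
#' @param seed base seed; each pair uses a deterministic sub-seed.
#' @return List with matrices `male` and `female` (upper triangle filled).
#' @export
ld_tests <- function(ds, permutations = 1e4, seed = 1L) {
  loci <- colnames(ds$a1)
  L <- length(loci)
  male <- ds$sex == "M"; fem <- !male
  pm <- matrix(NA_real_, L, L, dimnames = list(loci, loci))
  pf <- pm
  pair_i <- 0L
  for (i in seq_len(L - 1)) for (j in (i + 1):L) {
    pair_i <- pair_i + 1L
    s <- (seed * 1000L + pair_i) %% .Machine$integer.max
    tm <- suppressWarnings(
      ld_exact_test_haploid(ds$a1[male, loci[i]], ds$a1[male, loci[j]],
                            permutations = permutations, seed = s))
    tf <- suppressWarnings(
      ld_exact_test_genotypic(cbind(ds$a1[fem, loci[i]], ds$a2[fem, loci[i]]),
                              cbind(ds$a1[fem, loci[j]], ds$a2[fem, loci[j]]),
                              permutations = permutations, seed = s + 1L))
    pm[i, j] <- tm$p_value; pf[i, j] <- tf$p_value
  }
  list(male = pm, female = pf)
}
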