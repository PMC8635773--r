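# Exact HWE and LD tests.

# Independent oracle for the biallelic HWE exact test: loop over the number
# of heterozygotes directly (same parity as the minor allele count).
hwe_biallelic_oracle <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  cA <- 2 * nAA + nAB
  lp <- function(h) { # log P(h heterozygotes | allele counts)
    a <- (cA - h) / 2; b <- (2 * n - cA - h) / 2
    if (h < 0 || a < 0 || b < 0 || a != round(a)) return(-Inf)
    lfactorial(n) - lfactorial(a) - lfactorial(h) - lfactorial(b) +
      h * log(2) + lfactorial(cA) + lfactorial(2 * n - cA) -
      lfactorial(2 * n)
  }
  hs <- seq(cA %% 2, min(cA, 2 * n - cA), by = 2)
  probs <- vapply(hs, function(h) exp(lp(h)), 0)
  obs <- exp(lp(nAB))
  sum(probs[probs <= obs + 1e-12])
}

# Independent oracle by enumeration of all pairings of the 2n allele
# tokens (each pairing equally likely conditional on allele counts).
hwe_matching_oracle <- function(alleles) {
  pairings <- list()
  rec <- function(v, acc) {
    if (!length(v)) {
      pairings[[length(pairings) + 1]] <<- acc
      return(invisible())
    }
    for (j in 2:length(v)) {
      rec(v[-c(1, j)], c(acc, paste(sort(c(v[1], v[j])), collapse = "/")))
    }
  }
  rec(alleles, character(0))
  keys <- vapply(pairings, function(p) paste(sort(p), collapse = ";"), "")
  tab <- table(keys)
  probs <- as.numeric(tab) / length(keys)
  obs_key <- paste(sort(vapply(seq(1, length(alleles), 2), function(i)
    paste(sort(alleles[c(i, i + 1)]), collapse = "/"), "")), collapse = ";")
  obs_p <- probs[match(obs_key, names(tab))]
  sum(probs[probs <= obs_p + 1e-12])
}

test_that("HWE enumeration agrees with the biallelic tail oracle", {
  cases <- list(c(3, 4, 3), c(0, 10, 0), c(5, 0, 5), c(2, 7, 1), c(8, 2, 0))
  for (cs in cases) {
    g <- rbind(matrix("A", cs[1], 2),
               if (cs[2]) cbind(rep("A", cs[2]), rep("B", cs[2])),
               matrix("B", cs[3], 2))
    got <- hwe_exact_test(g, method = "enumerate")$p_value
    expect_equal(got, hwe_biallelic_oracle(cs[1], cs[2], cs[3]),
                 tolerance = 1e-10,
                 label = paste(cs, collapse = "/"))
  }
})

test_that("HWE enumeration agrees with brute-force pairing enumeration", {
  # 3 alleles, 4 females (8 allele tokens -> 105 pairings)
  g <- rbind(c("a", "b"), c("a", "c"), c("b", "b"), c("c", "a"))
  got <- hwe_exact_test(g, method = "enumerate")$p_value
  alleles <- c(t(g))
  expect_equal(got, hwe_matching_oracle(alleles), tolerance = 1e-10)
  # another configuration
  g2 <- rbind(c("a", "a"), c("b", "c"), c("b", "b"), c("c", "c"))
  expect_equal(hwe_exact_test(g2, method = "enumerate")$p_value,
               hwe_matching_oracle(c(t(g2))), tolerance = 1e-10)
})

test_that("HWE Monte Carlo converges to the enumerated tail", {
  set.seed(1)
  for (i in 1:6) {
    k <- sample(2:3, 1)
    n <- sample(5:20, 1)
    g <- matrix(sample(letters[1:k], 2 * n, replace = TRUE), n, 2)
    pe <- hwe_exact_test(g, method = "enumerate")$p_value
    mc <- hwe_exact_test(g, method = "monte_carlo", steps = 20000, seed = i)
    expect_lt(abs(mc$p_value - pe), 3 * mc$mc_stderr + 1e-4)
  }
})

test_that("HWE test edge cases and reproducibility", {
  # all females homozygous for the single observed allele: one table only
  g <- matrix("9", 5, 2)
  expect_equal(hwe_exact_test(g)$p_value, 1)
  expect_error(hwe_exact_test(matrix(character(0), 0, 2)), "empty")
  g2 <- matrix(sample(c("a", "b", "c"), 40, replace = TRUE), 20, 2)
  r1 <- hwe_exact_test(g2, method = "monte_carlo", steps = 3000, seed = 9)
  r2 <- hwe_exact_test(g2, method = "monte_carlo", steps = 3000, seed = 9)
  expect_identical(r1$p_value, r2$p_value)
  expect_equal(r1$n_permutations_or_steps, 3000L)
  expect_equal(r1$seed, 9)
  # enumeration cap error instructs the caller
  big <- matrix(sample(as.character(1:8), 160, replace = TRUE), 80, 2)
  expect_error(hwe_exact_test(big, method = "enumerate", max_tables = 100),
               "monte_carlo")
})

test_that("haploid LD exact test matches Fisher's exact test", {
  # diagonal 2x2 table: p = 2/choose(20,10)
  x <- rep(c("a", "b"), each = 10)
  y <- rep(c("c", "d"), each = 10)
  pe <- ld_exact_test_haploid(x, y, method = "enumerate")$p_value
  expect_equal(pe, 2 / choose(20, 10), tolerance = 1e-10)
  pm <- ld_exact_test_haploid(x, y, method = "monte_carlo",
                              permutations = 1e5, seed = 4)$p_value
  expect_lt(pm, 0.001)
  # random r x c tables against fisher.test (the reference implementation)
  set.seed(21)
  for (i in 1:5) {
    x <- sample(letters[1:3], 25, replace = TRUE)
    y <- sample(LETTERS[1:3], 25, replace = TRUE)
    pe <- ld_exact_test_haploid(x, y, method = "enumerate")$p_value
    pf <- stats::fisher.test(table(x, y))$p.value
    expect_equal(pe, pf, tolerance = 1e-7)
  }
})

test_that("haploid LD degenerate and error cases", {
  expect_warning(p <- ld_exact_test_haploid(rep("a", 10),
                                            sample(c("c", "d"), 10, TRUE)),
                 "monomorphic")
  expect_equal(p$p_value, 1)
  expect_error(ld_exact_test_haploid("a", "b"), "at least 2")
})

test_that("haploid LD test has correct type-I error under independence", {
  set.seed(33)
  n_rep <- 300
  rej <- 0
  for (i in 1:n_rep) {
    x <- sample(c("a", "b", "c"), 40, replace = TRUE,
                prob = c(0.5, 0.3, 0.2))
    y <- sample(c("d", "e"), 40, replace = TRUE, prob = c(0.6, 0.4))
    p <- ld_exact_test_haploid(x, y, method = "monte_carlo",
                               permutations = 400, seed = i)$p_value
    if (p < 0.05) rej <- rej + 1
  }
  # exact tests are conservative; allow [0, 0.07] at alpha = 0.05
  expect_lt(rej / n_rep, 0.07)
})

test_that("genotypic LD test discriminates and degrades gracefully", {
  set.seed(12)
  n <- 50
  a <- sample(c("9", "10"), 2 * n, replace = TRUE)
  b <- sample(c("7", "8"), 2 * n, replace = TRUE)
  g1 <- cbind(a[1:n], a[(n + 1):(2 * n)])
  g2_ind <- cbind(b[1:n], b[(n + 1):(2 * n)])
  p_ind <- ld_exact_test_genotypic(g1, g2_ind, permutations = 400,
                                   seed = 3)$p_value
  expect_gt(p_ind, 0.01)
  # perfectly correlated double heterozygotes: small p, smaller with more n
  link <- c(`9` = "7", `10` = "8")
  g2_cor <- cbind(link[g1[, 1]], link[g1[, 2]])
  p_cor <- ld_exact_test_genotypic(g1, g2_cor, permutations = 400,
                                   seed = 3)$p_value
  expect_lt(p_cor, 0.05)
  p_cor_small <- suppressWarnings(
    ld_exact_test_genotypic(g1[1:8, ], g2_cor[1:8, ],
                            permutations = 400, seed = 3)$p_value)
  expect_lte(p_cor, p_cor_small)
  # single female (monomorphic by construction: warned, p = 1)
  expect_equal(suppressWarnings(
    ld_exact_test_genotypic(g1[1, , drop = FALSE],
                            g2_cor[1, , drop = FALSE],
                            permutations = 100, seed = 1)$p_value), 1)
})

test_that("genotypic LD test holds its size under independence", {
  set.seed(44)
  n_rep <- 120
  rej <- 0
  for (i in 1:n_rep) {
    g1 <- matrix(sample(c("9", "10", "11"), 60, replace = TRUE), 30, 2)
    g2 <- matrix(sample(c("7", "8"), 60, replace = TRUE), 30, 2)
    p <- ld_exact_test_genotypic(g1, g2, permutations = 200,
                                 seed = i)$p_value
    if (p < 0.05) rej <- rej + 1
  }
  expect_lt(rej / n_rep, 0.10)
})

test_that("bonferroni threshold", {
  expect_equal(bonferroni_threshold(0.05, 36), 0.00138889,
               tolerance = 1e-6)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 10), 0.001)
  expect_error(bonferroni_threshold(1.2, 3), "alpha")
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
})
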