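# Exact test of Hardy-Weinberg equilibrium on female (diploid) genotypes,
# conditional on the observed allele counts. The tail is probability-ordered:
# p is the total conditional probability of genotype tables no more probable
# than the observed one. Small tables are enumerated exactly; otherwise the
# null is sampled by i.i.d. random pairings of the observed alleles (every
# pairing is equally likely conditional on allele counts, so no Markov chain
# or burn-in is needed and the estimate is unbiased with binomial SE).

# Build (k x k upper-triangular) genotype count matrix from input.
# Accepts an n x 2 matrix/data.frame of allele labels or a named count
# vector with names "a/b" (order within a pair irrelevant).
as_genotype_counts <- function(genotypes) {
  if (is.null(dim(genotypes)) && !is.null(names(genotypes))) {
    parts <- strsplit(names(genotypes), "/", fixed = TRUE)
    if (any(lengths(parts) != 2)) stop("genotype names must look like 'a/b'")
    g <- matrix(unlist(parts), ncol = 2, byrow = TRUE)
    g <- g[rep(seq_len(nrow(g)), times = as.integer(genotypes)), ,
           drop = FALSE]
  } else {
    g <- as.matrix(genotypes)
    if (ncol(g) != 2) stop("genotypes must have two allele columns")
    g <- g[stats::complete.cases(g), , drop = FALSE]
  }
  if (!nrow(g)) stop("empty input: no female genotypes")
  alleles <- sort_alleles(unique(c(g[, 1], g[, 2])))
  i <- match(g[, 1], alleles); j <- match(g[, 2], alleles)
  lo <- pmin(i, j); hi <- pmax(i, j)
  k <- length(alleles)
  N <- matrix(0L, k, k, dimnames = list(alleles, alleles))
  for (r in seq_along(lo)) N[lo[r], hi[r]] <- N[lo[r], hi[r]] + 1L
  N
}

# log "distinguishability" statistic of a genotype table: tables with equal
# allele counts have conditional probability proportional to exp(stat).
hwe_table_stat <- function(counts_vec, het_mask) {
  sum(het_mask * counts_vec) * log(2) - sum(lfactorial(counts_vec))
}

# Enumerate all genotype tables with the given allele counts. Calls
# `visit(counts_vec)` for each; aborts via error when more than max_tables.
enumerate_hwe_tables <- function(allele_counts, visit, max_tables = 2e6) {
  k <- length(allele_counts)
  pairs <- do.call(rbind, lapply(seq_len(k), function(i)
    cbind(i, i:k)))
  np <- nrow(pairs)
  counts <- integer(np)
  n_seen <- 0L
  rec <- function(idx, rem) {
    if (idx > np) {
      n_seen <<- n_seen + 1L
      if (n_seen > max_tables)
        stop("enumeration cap exceeded; use method = 'monte_carlo'",
             call. = FALSE)
      visit(counts)
      return(invisible())
    }
    i <- pairs[idx, 1]; j <- pairs[idx, 2]
    if (i == j) {
      if (j == k) {                      # final (k,k): forced
        if (rem[k] %% 2L == 0L) {
          counts[idx] <<- rem[k] %/% 2L
          rec(idx + 1L, rem - c(rep(0L, k - 1), rem[k]))
        }
      } else {
        for (n in 0:(rem[i] %/% 2L)) {
          counts[idx] <<- n
          r <- rem; r[i] <- r[i] - 2L * n
          rec(idx + 1L, r)
        }
      }
    } else if (j == k) {                 # last pair containing i: forced
      n <- rem[i]
      if (n <= rem[k]) {
        counts[idx] <<- n
        r <- rem; r[i] <- 0L; r[k] <- r[k] - n
        rec(idx + 1L, r)
      }
    } else {
      for (n in 0:min(rem[i], rem[j])) {
        counts[idx] <<- n
        r <- rem; r[i] <- r[i] - n; r[j] <- r[j] - n
        rec(idx + 1L, r)
      }
    }
  }
  rec(1L, as.integer(allele_counts))
  list(pairs = pairs, n_tables = n_seen)
}

new_test_result <- function(kind, p, stderr, n_steps, seed, method) {
  structure(list(statistic_kind = kind, p_value = p, mc_stderr = stderr,
                 n_permutations_or_steps = n_steps, seed = seed,
                 method = method),
            class = "xstr_test")
}

#' @export
print.xstr_test <- function(x, ...) {
  cat(sprintf("%s: p = %.6g (%s%s)\n", x$statistic_kind, x$p_value, x$method,
              if (!is.null(x$mc_stderr) && !is.na(x$mc_stderr))
                sprintf(", MC stderr %.2g, %d steps, seed %s",
                        x$mc_stderr, x$n_permutations_or_steps,
                        format(x$seed)) else ""))
  invisible(x)
}

#' Exact test of Hardy-Weinberg equilibrium (female data)
#'
#' Conditional exact test on diploid genotypes: under the null every pairing
#' of the observed 2n alleles into n genotypes is equally likely, and the
#' p-value is the probability of genotype tables no more probable than the
#' observed one (probability-ordered tail). `enumerate` sums the tail over
#' all tables with the observed allele counts; `monte_carlo` samples random
#' pairings i.i.d. and reports a standard error. `auto` enumerates when the
#' table count stays under `max_tables` and falls back to Monte Carlo.
#'
#' @param genotypes n x 2 matrix/data.frame of female allele labels, or a
#'   named count vector (`c("9/9" = 3, "9/10" = 4, ...)`).
#' @param method `"auto"`, `"enumerate"` or `"monte_carlo"`.
#' @param steps Monte Carlo sample size.
#' @param seed RNG seed (required for `monte_carlo`; stored in the result).
#' @param max_tables enumeration cap.
#' @return An `xstr_test` with fields `p_value`, `mc_stderr` (Monte Carlo
#'   only), `n_permutations_or_steps`, `seed`.
#' @examples
#' g <- rbind(matrix("a", 3, 2), cbind(rep("a", 4), rep("b", 4)),
#'            matrix("b", 3, 2))
#' hwe_exact_test(g, method = "enumerate")
#' @export
hwe_exact_test <- function(genotypes, method = c("auto", "enumerate",
                                                 "monte_carlo"),
                           steps = 1e5, seed = 1L, max_tables = 2e6) {
  method <- match.arg(method)
  N <- as_genotype_counts(genotypes)
  k <- nrow(N)
  allele_counts <- integer(k)
  for (i in seq_len(k)) {
    allele_counts[i] <- sum(N[i, ]) + sum(N[, i]) # diagonal counted twice
  }
  nf <- sum(N)
  het <- row(N) != col(N)
  obs_stat <- sum(N[het]) * log(2) - sum(lfactorial(N))
  tol <- 1e-9 * max(1, abs(obs_stat))

  if (k == 1L)
    return(new_test_result("hwe_exact", 1, NULL, 0L, seed, "degenerate"))

  run_enum <- function(cap) {
    # constant completing the conditional probability of a table
    logK <- lfactorial(nf) + sum(lfactorial(allele_counts)) -
      lfactorial(2 * nf)
    tail_p <- 0; total_p <- 0
    pairs <- do.call(rbind, lapply(seq_len(k), function(i) cbind(i, i:k)))
    het_mask <- as.numeric(pairs[, 1] != pairs[, 2])
    visit <- function(cv) {
      s <- hwe_table_stat(cv, het_mask)
      p <- exp(logK + s)
      total_p <<- total_p + p
      if (s <= obs_stat + tol) tail_p <<- tail_p + p
    }
    enumerate_hwe_tables(allele_counts, visit, max_tables = cap)
    if (abs(total_p - 1) > 1e-6)
      warning("enumerated probabilities sum to ", format(total_p))
    tail_p / total_p
  }

  # 'auto' only attempts enumeration when the table space is plausibly
  # small; the recursive sweep is pure R and the cap would otherwise be
  # reached slowly for every many-allele locus
  try_enum <- method == "enumerate" ||
    (method == "auto" && k <= 4 && nf <= 30)
  if (try_enum) {
    p <- tryCatch(run_enum(max_tables), error = function(e) e)
    if (!inherits(p, "error"))
      return(new_test_result("hwe_exact", min(p, 1), NULL, 0L, seed,
                             "enumerate"))
    if (method == "enumerate") stop(conditionMessage(p), call. = FALSE)
  }

  # Monte Carlo over i.i.d. random pairings of the observed alleles
  if (is.null(seed)) stop("monte_carlo requires a seed")
  set.seed(seed)
  v <- rep.int(seq_len(k), allele_counts)
  m <- length(v)
  steps <- as.integer(steps)
  hits <- 0L
  for (b in seq_len(steps)) {
    w <- v[sample.int(m)]
    x <- w[seq(1L, m, 2L)]; y <- w[seq(2L, m, 2L)]
    lo <- pmin(x, y); hi <- pmax(x, y)
    cnt <- tabulate((hi - 1L) * k + lo, nbins = k * k)
    s <- sum(x != y) * log(2) - sum(lfactorial(cnt))
    if (s <= obs_stat + tol) hits <- hits + 1L
  }
  p <- (hits + 1) / (steps + 1)
  se <- sqrt(p * (1 - p) / steps)
  new_test_result("hwe_exact", p, se, steps, seed, "monte_carlo")
}
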