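# Transmission classification, meiosis counting and two-point LOD.

test_that("maternal haplotypes are anchored by the grandfather", {
  res <- resolve_maternal_haplotypes(fam_three_gen(), demo_panel(), "LG1")
  expect_equal(res$provenance, "grandfather_anchored")
  expect_equal(res$hap1, "13-16-9")   # grandfather's X
  expect_equal(res$hap2, "15-18-10")
  expect_equal(res$child_maternal, "15-18-10")
})

test_that("homozygous mother loci are flagged uninformative", {
  res <- resolve_maternal_haplotypes(fam_recombination(), demo_panel(),
                                     "LG1")
  expect_true(all(res$uninformative_loci == "X008"))
  res2 <- resolve_maternal_haplotypes(fam_recombination_unresolved(),
                                      demo_panel(), "LG3")
  expect_true(all(res2$uninformative_loci == "X029"))
})

test_that("paternal and maternal one-step mutations are called", {
  c1 <- classify_transmission(fam_paternal_mutation(), demo_panel(), "LG1")
  d1 <- c1[c1$child_id == "D1", ]
  expect_equal(d1$verdict, "one_step_mutation")
  expect_equal(d1$locus, "X006")
  expect_equal(d1$parent, "paternal")
  expect_equal(c(d1$from_allele, d1$to_allele), c("16", "17"))
  expect_equal(c1[c1$child_id == "D2", "verdict"], "consistent")

  c2 <- classify_transmission(fam_maternal_mutation(), demo_panel(), "LG2")
  d2 <- c2[c2$child_id == "D1", ]
  expect_equal(d2$verdict, "one_step_mutation")
  expect_equal(d2$locus, "X018")
  expect_equal(d2$parent, "maternal")
  expect_equal(c(d2$from_allele, d2$to_allele), c("11", "12"))
  expect_equal(c2[c2$child_id == "S1", "verdict"], "consistent")
})

test_that("a clean haplotype switch is called as intragroup recombination", {
  calls <- classify_transmission(fam_recombination(), demo_panel(), "LG1")
  rec <- calls[calls$verdict == "intragroup_recombination", ]
  expect_equal(nrow(rec), 1)
  expect_equal(rec$interval_left, "X003")
  expect_equal(rec$interval_right, "X006")
  expect_false(rec$unresolved)
  expect_equal(sum(calls$verdict == "consistent"), 1)
})

test_that("breakpoint is widened across a homozygous mother locus", {
  calls <- classify_transmission(fam_recombination_unresolved(),
                                 demo_panel(), "LG3")
  rec <- calls[calls$verdict == "intragroup_recombination", ]
  expect_equal(nrow(rec), 1)
  expect_equal(rec$interval_left, "X028")
  expect_equal(rec$interval_right, "X033")
  expect_true(rec$unresolved)
})

test_that("equal-parsimony mutation vs recombination is ambiguous", {
  calls <- classify_transmission(fam_ambiguous(), demo_panel(), "LG1")
  expect_true("ambiguous" %in% calls$verdict)
  amb <- calls[calls$verdict == "ambiguous", ]
  expect_match(amb$detail, "recombination")
  expect_match(amb$detail, "mutation")
})

test_that("classification is invariant to child ordering and never invents
           a mutation when a consistent explanation exists", {
  fam <- fam_recombination()
  swap <- make_family("famRC", c("MO", "S2", "S1"),
                      c("0", "0", "0"), c("0", "MO", "MO"),
                      c("F", "M", "M"),
                      gmat(c("13/15", "11/17", "9/9",
                             "13",    "17",    "9",
                             "15",    "17",    "9"), LG1))
  c1 <- classify_transmission(fam, demo_panel(), "LG1")
  c2 <- classify_transmission(swap, demo_panel(), "LG1")
  o1 <- c1[order(c1$child_id), c("child_id", "verdict")]
  o2 <- c2[order(c2$child_id), c("child_id", "verdict")]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
  # consistent transmissions stay consistent under random panels
  set.seed(13)
  for (i in 1:10) {
    mo <- c(sample(10:14, 1), sample(10:14, 1))
    son <- sample(mo, 1)
    fam <- make_family("f", c("MO", "S1"), c("0", "0"), c("0", "MO"),
                       c("F", "M"),
                       gmat(c(paste(sort(mo), collapse = "/"), "11/12", "9/9",
                              as.character(son), "11", "9"), LG1))
    calls <- classify_transmission(fam, demo_panel(), "LG1")
    expect_equal(unique(calls$verdict), "consistent")
  }
})

test_that("incompatible transmissions are flagged, not silently dropped", {
  fam <- make_family("fBAD", c("MO", "S1"), c("0", "0"), c("0", "MO"),
                     c("F", "M"),
                     gmat(c("13/15", "11/17", "9/10",
                            "19",    "14",    "7"), LG1))
  calls <- classify_transmission(fam, demo_panel(), "LG1")
  expect_equal(calls$verdict, "incompatible")
})

test_that("count_meioses: anchored recombinant and nonrecombinant", {
  panel <- demo_panel()
  # son inherits grandfather's haplotype at both loci: nonrecombinant
  nr <- fam_three_gen(son = c("13", "16", "9"))
  cm <- count_meioses(list(nr), c("X003", "X006"), panel)
  expect_equal(cm$tally$R, 0L); expect_equal(cm$tally$N, 1L)
  # recombinant: X003 from grandfather side, X006 from grandmother side
  rc <- fam_three_gen(son = c("13", "18", "10"))
  cm2 <- count_meioses(list(rc), c("X003", "X006"), panel)
  expect_equal(cm2$tally$R, 1L); expect_equal(cm2$tally$N, 1L)
  # mother homozygous at a locus: meiosis not counted
  hom <- make_family("fH", c("GF", "MO", "S1"), c("0", "GF", "0"),
                     c("0", "0", "MO"), c("M", "F", "M"),
                     gmat(c("13",    "16",    "9",
                            "13/13", "16/18", "9/10",
                            "13",    "18",    "9"), LG1))
  cm3 <- count_meioses(list(hom), c("X003", "X006"), panel)
  expect_equal(cm3$tally$N, 0L)
  # mutation at a pair locus removes the meiosis from the tally
  cm4 <- count_meioses(list(fam_maternal_mutation()), c("X016", "X018"),
                       panel)
  expect_true(all(cm4$excluded$reason != "" &
                    grepl("mutation|ambiguous",
                          paste(cm4$excluded$reason, collapse = " "))))
  # ambiguous transmissions are excluded and reported
  cm5 <- count_meioses(list(fam_ambiguous()), c("X003", "X006"), panel)
  expect_false(is.null(cm5$excluded))
})

test_that("empirical recombination fraction and capping", {
  expect_equal(empirical_recombination_fraction(
    meiosis_tally(c("A", "B"), 0, 12)), 0)
  expect_equal(empirical_recombination_fraction(
    meiosis_tally(c("A", "B"), 1, 28)), 1 / 28)
  expect_warning(th <- empirical_recombination_fraction(
    meiosis_tally(c("A", "B"), 5, 5)), "capped")
  expect_equal(th, 0.5)
  expect_true(is.na(empirical_recombination_fraction(
    meiosis_tally(c("A", "B"), 0, 0))))
})

test_that("phase-known LOD maximization matches the closed form", {
  # closed form: theta = R/N, LOD = R log10(2 theta) + (N-R) log10(2(1-theta))
  cases <- rbind(c(0, 10), c(1, 28), c(1, 25), c(1, 23), c(5, 40), c(9, 20))
  for (i in seq_len(nrow(cases))) {
    R <- cases[i, 1]; N <- cases[i, 2]
    r <- two_point_lod(meiosis_tally(c("A", "B"), R, N))
    th <- R / N
    closed <- if (R == 0) N * log10(2) else
      R * log10(2 * th) + (N - R) * log10(2 * (1 - th))
    expect_equal(r$max_lod, closed, tolerance = 1e-6)
    expect_lt(abs(r$theta_hat - th), 1e-4) # grid resolution
    expect_equal(r$R, as.integer(R))
  }
  # LOD at free recombination is zero
  r <- two_point_lod(meiosis_tally(c("A", "B"), 10, 20))
  expect_equal(r$theta_hat, 0.5)
  expect_equal(r$max_lod, 0)
})

test_that("phase-unknown likelihood equals brute-force phase enumeration", {
  panel <- demo_panel()
  set.seed(17)
  cfg <- default_study_config(seed = 17)
  sim <- simulate_study(cfg)
  # up to 10 two-generation families
  fams <- Filter(function(f) f$family_type == "two_generation",
                 sim$families)[1:10]
  for (pair in list(c("X003", "X006"), c("X016", "X019"),
                    c("X003", "X029"))) {
    cm <- count_meioses(fams, pair, panel)
    r <- two_point_lod(fams, pair, panel)
    th <- seq(0, 0.5, by = 1e-4)
    xlog <- function(k, x) if (k == 0) rep(0, length(x)) else k * log(x)
    ll <- xlog(cm$tally$R, th) + xlog(cm$tally$N - cm$tally$R, 1 - th)
    n_tot <- cm$tally$N
    pu <- cm$phase_unknown
    if (length(pu)) {
      # enumerate all 2^m joint phase assignments
      flips <- as.matrix(expand.grid(rep(list(0:1), length(pu))))
      L <- matrix(0, length(th), nrow(flips))
      for (q in seq_len(nrow(flips))) {
        lf <- 0
        for (j in seq_along(pu)) {
          r1 <- if (flips[q, j] == 0) pu[[j]][["r"]] else
            pu[[j]][["n"]] - pu[[j]][["r"]]
          lf <- lf + xlog(r1, th) + xlog(pu[[j]][["n"]] - r1, 1 - th)
        }
        L[, q] <- lf
      }
      mx <- apply(L, 1, max)
      lsum <- ifelse(is.finite(mx),
                     mx + log(rowSums(exp(L - mx))), -Inf)
      ll <- ll + lsum - length(pu) * log(2)
      n_tot <- n_tot + sum(vapply(pu, function(u) u[["n"]], 0))
    }
    lod <- (ll - n_tot * log(0.5)) / log(10)
    expect_equal(r$max_lod, max(lod), tolerance = 1e-9,
                 label = paste(pair, collapse = "-"))
    expect_equal(r$theta_hat, th[which.max(lod)], tolerance = 1e-9)
  }
})

test_that("single-child phase-unknown families carry no linkage signal", {
  fam <- make_family("f1", c("MO", "S1"), c("0", "0"), c("0", "MO"),
                     c("F", "M"),
                     gmat(c("13/15", "11/17", "9/10",
                            "13",    "11",    "9"), LG1))
  r <- two_point_lod(list(fam), c("X003", "X006"), demo_panel())
  expect_equal(r$max_lod, 0, tolerance = 1e-9)
})

test_that("no informative meioses yields a missing result", {
  fam <- make_family("f1", c("MO", "S1"), c("0", "0"), c("0", "MO"),
                     c("F", "M"),
                     gmat(c("13/13", "11/11", "9/9",
                            "13",    "11",    "9"), LG1))
  r <- two_point_lod(list(fam), c("X003", "X006"), demo_panel())
  expect_true(is.na(r$max_lod))
  expect_equal(r$n_informative, 0L)
})

test_that("lod_matrix separates linked from unlinked pairs", {
  # tight intragroup linkage (theta 0.01) vs near-free intergroup
  # recombination (theta 0.4), 200 phase-unknown sibships: intragroup
  # pairs must exceed LOD 3, intergroup pairs must stay below 1
  panel <- demo_panel()
  theta <- rep(0.01, 8)
  theta[c(3, 6)] <- 0.4 # the two group gaps in map order
  cfg <- default_study_config(seed = 23, mu = 0, theta = theta,
                              n_three_gen = 0,
                              offspring_two_gen = rep(2, 200),
                              n_males = 2, n_females = 2)
  sim <- simulate_study(cfg)
  lm <- lod_matrix(sim$families, panel, theta_grid_step = 1e-3)
  intra <- cbind(c("X003", "X006"), c("X003", "X008"), c("X016", "X019"),
                 c("X028", "X033"))
  for (q in seq_len(ncol(intra)))
    expect_gt(lm$lod[intra[1, q], intra[2, q]], 3)
  inter <- cbind(c("X003", "X016"), c("X006", "X029"), c("X018", "X033"))
  for (q in seq_len(ncol(inter)))
    expect_lt(lm$lod[inter[1, q], inter[2, q]], 1)
  # single family: finite, no crash
  one <- lod_matrix(sim$families[1], panel, theta_grid_step = 1e-2)
  expect_true(all(is.finite(one$lod[upper.tri(one$lod)]) |
                    is.na(one$lod[upper.tri(one$lod)])))
})
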