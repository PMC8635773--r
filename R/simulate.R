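# Seeded simulator of the study design: unrelated sex-aware X genotypes and
# typed families of the two pedigree designs, with ground-truth records for
# every maternal meiosis. Founder haplotypes are i.i.d. draws (linkage
# equilibrium unless explicit haplotype spectra are given); maternal gametes
# walk the loci in map order switching haplotype between adjacent loci with
# the interval's recombination fraction (no interference), and each
# transmitted allele mutates by one repeat with probability mu.

#' Build a simulation configuration
#'
#' Defaults mirror the reference study design: 198 unrelated individuals
#' (127 males, 71 females) and 43 families totalling 86 maternal meioses
#' (10 three-generation grandfather--mother--son pedigrees, 23 families with
#' two offspring, 10 with three).
#'
#' @param panel an [xstr_panel()].
#' @param freqs named list (by locus) of named allele-frequency vectors, or
#'   a list of [freq_spectrum()] objects.
#' @param haplotype_freqs optional named list (by linkage group) of named
#'   haplotype-frequency vectors (labels `a-b-c` in map order); loci are
#'   otherwise drawn independently (linkage equilibrium).
#' @param theta optional numeric vector of per-interval recombination
#'   fractions between adjacent loci in map order (length `L - 1`); by
#'   default derived from map distances with [kosambi_theta()].
#' @param mu per-locus per-meiosis one-step mutation probability
#'   (default 0.0025, a typical STR rate; must be in `[0, 0.1]`).
#' @param n_males,n_females unrelated sample sizes.
#' @param n_three_gen number of three-generation families.
#' @param offspring_two_gen integer vector: offspring count of each
#'   two-generation family.
#' @param seed integer seed driving every draw.
#' @return A `sim_config` list.
#' @export
sim_config <- function(panel, freqs, haplotype_freqs = NULL, theta = NULL,
                       mu = 0.0025, n_males = 127, n_females = 71,
                       n_three_gen = 10,
                       offspring_two_gen = c(rep(2, 23), rep(3, 10)),
                       seed = 1L) {
  stopifnot(inherits(panel, "xstr_panel"))
  if (all(vapply(freqs, inherits, TRUE, "freq_spectrum")))
    freqs <- setNames(lapply(freqs, function(s) s$freqs),
                      vapply(freqs, function(s) s$locus, ""))
  missing_spec <- setdiff(panel$locus, names(freqs))
  if (length(missing_spec))
    stop("spectrum missing for loci: ", paste(missing_spec, collapse = ", "))
  if (is.null(theta)) theta <- kosambi_theta(diff(panel$position_cM))
  if (length(theta) != nrow(panel) - 1)
    stop("theta must have one entry per adjacent-locus interval")
  if (any(theta < 0 | theta > 0.5)) stop("theta must lie in [0, 0.5]")
  if (mu < 0 || mu > 0.1) stop("mu must lie in [0, 0.1]")
  if (n_males < 0 || n_females < 0 || any(offspring_two_gen < 1))
    stop("counts must be positive")
  structure(list(panel = panel, freqs = freqs,
                 haplotype_freqs = haplotype_freqs, theta = theta, mu = mu,
                 n_males = n_males, n_females = n_females,
                 n_three_gen = n_three_gen,
                 offspring_two_gen = as.integer(offspring_two_gen),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# n founder haplotypes as an n x L character matrix
draw_haplotypes <- function(config, n) {
  panel <- config$panel
  H <- matrix(NA_character_, n, nrow(panel),
              dimnames = list(NULL, panel$locus))
  for (g in panel_groups(panel)) {
    hf <- config$haplotype_freqs[[g$linkage_group[1]]]
    if (!is.null(hf)) {
      lab <- sample(names(hf), n, replace = TRUE, prob = hf)
      parts <- strsplit(lab, "-", fixed = TRUE)
      if (any(lengths(parts) != nrow(g)))
        stop("haplotype label length does not match group ",
             g$linkage_group[1])
      H[, g$locus] <- t(vapply(parts, identity, character(nrow(g))))
    } else {
      for (l in g$locus) {
        f <- config$freqs[[l]]
        H[, l] <- sample(names(f), n, replace = TRUE, prob = f)
      }
    }
  }
  H
}

# apply one-step mutations to a haplotype matrix; returns the mutated
# matrix and a record of events
mutate_haplotypes <- function(H, mu) {
  events <- NULL
  if (mu > 0) {
    hit <- which(matrix(runif(length(H)) < mu, nrow(H)))
    if (length(hit)) {
      from <- H[hit]
      d <- sample(c(-1, 1), length(hit), replace = TRUE)
      to <- formatC(allele_num(from) + d, format = "g")
      H[hit] <- to
      events <- data.frame(row = (hit - 1) %% nrow(H) + 1,
                           locus = colnames(H)[(hit - 1) %/% nrow(H) + 1],
                           from = from, to = to, stringsAsFactors = FALSE)
    }
  }
  list(H = H, events = events)
}

#' Simulate maternal gametes with recombination and mutation
#'
#' Low-level generator used by [simulate_family()] and directly useful for
#' property checks: forms `n` gametes from the two maternal haplotypes by
#' walking loci in map order and switching haplotype between adjacent loci
#' with the interval's recombination fraction, then applying one-step
#' mutations.
#'
#' @param h1,h2 character vectors: the mother's two haplotypes (map order).
#' @param n number of gametes.
#' @param theta per-interval recombination fractions (length `L - 1`).
#' @param mu one-step mutation probability per locus.
#' @return List: `alleles` (n x L matrix), `switches` (n x (L-1) logical),
#'   `start` (starting haplotype, 1 or 2), `mutations` (data frame or NULL).
#' @export
simulate_meioses <- function(h1, h2, n, theta, mu = 0) {
  L <- length(h1)
  stopifnot(length(h2) == L, length(theta) == L - 1 || L == 1)
  start <- sample(1:2, n, replace = TRUE)
  sw <- matrix(FALSE, n, max(L - 1, 0))
  if (L > 1)
    sw[] <- runif(n * (L - 1)) < rep(theta, each = n)
  state <- matrix(start, n, L)
  if (L > 1) for (i in 2:L)
    state[, i] <- ifelse(sw[, i - 1], 3L - state[, i - 1], state[, i - 1])
  A <- matrix(ifelse(state == 1L, rep(h1, each = n), rep(h2, each = n)),
              n, L)
  colnames(A) <- names(h1)
  mu_res <- mutate_haplotypes(A, mu)
  list(alleles = mu_res$H, switches = sw, start = start,
       mutations = mu_res$events)
}

#' Simulate unrelated individuals
#'
#' Males receive one founder haplotype, females two independent ones
#' (Hardy-Weinberg and, by default, linkage equilibrium).
#'
#' @param config a [sim_config()].
#' @return An [xstr_dataset()]. Deterministic given `config$seed`.
#' @export
simulate_unrelated <- function(config) {
  set.seed(config$seed)
  panel <- config$panel
  nm <- config$n_males; nf <- config$n_females
  Hm <- draw_haplotypes(config, nm)
  Hf1 <- draw_haplotypes(config, nf)
  Hf2 <- draw_haplotypes(config, nf)
  L <- nrow(panel)
  a1 <- rbind(Hm, matrix(NA_character_, nf, L))
  a2 <- rbind(matrix(NA_character_, nm, L), matrix(NA_character_, nf, L))
  for (i in seq_len(nf)) {
    pair <- rbind(Hf1[i, ], Hf2[i, ])
    for (j in seq_len(L)) {
      s <- sort_alleles(pair[, j])
      a1[nm + i, j] <- s[1]; a2[nm + i, j] <- s[2]
    }
  }
  colnames(a1) <- colnames(a2) <- panel$locus
  xstr_dataset(panel,
               c(sprintf("M%03d", seq_len(nm)), sprintf("F%03d", seq_len(nf))),
               c(rep("M", nm), rep("F", nf)), a1, a2)
}

# assemble an xstr_family from member specs (list of list(id, fa, mo, sex,
# hap1, hap2)); haplotypes are character vectors over panel loci or NULL.
build_family <- function(family_id, specs, loci) {
  members <- do.call(rbind, lapply(specs, function(s)
    data.frame(individual_id = s$id, father_id = s$fa, mother_id = s$mo,
               sex = s$sex, stringsAsFactors = FALSE)))
  n <- length(specs)
  a1 <- matrix(NA_character_, n, length(loci), dimnames = list(NULL, loci))
  a2 <- a1
  for (i in seq_len(n)) {
    s <- specs[[i]]
    if (s$sex == "M") {
      a1[i, ] <- s$hap1
    } else {
      for (j in seq_along(loci)) {
        p <- sort_alleles(c(s$hap1[j], s$hap2[j]))
        a1[i, j] <- p[1]; a2[i, j] <- p[2]
      }
    }
  }
  xstr_family(family_id, members, a1, a2)
}

#' Simulate one typed family
#'
#' `three_generation`: grandfather, his daughter (the mother, whose other X
#' is a fresh founder draw) and her son. `two_generation`: mother, father
#' (included only when a daughter is present; with all-male offspring the
#' father is left untyped) and `n_offspring` children of random sex. Sons
#' are hemizygous for the maternal gamete; daughters additionally receive
#' the paternal X unchanged (no male recombination), subject to one-step
#' mutation.
#'
#' @param config a [sim_config()].
#' @param family_type `"three_generation"` or `"two_generation"`.
#' @param family_id identifier for the emitted family.
#' @param n_offspring offspring count (two-generation only).
#' @return List with `family` (an [xstr_family()]) and `truth` (one row per
#'   maternal meiosis: start haplotype and per-interval switch indicators)
#'   plus `mutations` (all mutation events, any parent).
#' @export
simulate_family <- function(config, family_type = c("two_generation",
                                                    "three_generation"),
                            family_id = "F1", n_offspring = 2) {
  family_type <- match.arg(family_type)
  panel <- config$panel
  loci <- panel$locus
  L <- length(loci)
  theta <- config$theta; mu <- config$mu
  muts <- list()
  note_muts <- function(ev, who, parent) {
    if (!is.null(ev) && nrow(ev))
      muts[[length(muts) + 1]] <<- data.frame(
        family_id = family_id, child_id = who[ev$row],
        locus = ev$locus, parent = parent, from = ev$from, to = ev$to,
        stringsAsFactors = FALSE)
  }
  truth <- NULL
  if (family_type == "three_generation") {
    gf <- drop(draw_haplotypes(config, 1))
    gm_gamete <- drop(draw_haplotypes(config, 1)) # untyped grandmother
    gf_trans <- mutate_haplotypes(matrix(gf, 1, L,
                                         dimnames = list(NULL, loci)), mu)
    mother_pat <- drop(gf_trans$H)
    note_muts(gf_trans$events, "MO", "grandfather")
    son_g <- simulate_meioses(mother_pat, gm_gamete, 1, theta, mu)
    note_muts(son_g$mutations, "S1", "maternal")
    specs <- list(
      list(id = "GF", fa = "0", mo = "0", sex = "M", hap1 = gf, hap2 = NULL),
      list(id = "MO", fa = "GF", mo = "0", sex = "F", hap1 = mother_pat,
           hap2 = gm_gamete),
      list(id = "S1", fa = "0", mo = "MO", sex = "M",
           hap1 = drop(son_g$alleles), hap2 = NULL))
    kid_ids <- "S1"
    truth <- data.frame(family_id = family_id, child_id = "S1",
                        start = son_g$start, stringsAsFactors = FALSE)
    swm <- matrix(son_g$switches, nrow = 1)
  } else {
    mo1 <- drop(draw_haplotypes(config, 1))
    mo2 <- drop(draw_haplotypes(config, 1))
    fa <- drop(draw_haplotypes(config, 1))
    sexes <- sample(c("M", "F"), n_offspring, replace = TRUE)
    gam <- simulate_meioses(mo1, mo2, n_offspring, theta, mu)
    kid_ids <- sprintf("C%d", seq_len(n_offspring))
    note_muts(gam$mutations, kid_ids, "maternal")
    specs <- list(
      list(id = "MO", fa = "0", mo = "0", sex = "F", hap1 = mo1, hap2 = mo2))
    father_typed <- any(sexes == "F")
    if (father_typed)
      specs[[length(specs) + 1]] <- list(id = "FA", fa = "0", mo = "0",
                                         sex = "M", hap1 = fa, hap2 = NULL)
    for (i in seq_len(n_offspring)) {
      if (sexes[i] == "M") {
        specs[[length(specs) + 1]] <- list(id = kid_ids[i],
                                           fa = "0", mo = "MO", sex = "M",
                                           hap1 = gam$alleles[i, ],
                                           hap2 = NULL)
      } else {
        pat <- mutate_haplotypes(matrix(fa, 1, L,
                                        dimnames = list(NULL, loci)), mu)
        note_muts(pat$events, kid_ids[i], "paternal")
        specs[[length(specs) + 1]] <- list(id = kid_ids[i],
                                           fa = "FA", mo = "MO", sex = "F",
                                           hap1 = drop(pat$H),
                                           hap2 = gam$alleles[i, ])
      }
    }
    truth <- data.frame(family_id = family_id, child_id = kid_ids,
                        start = gam$start, stringsAsFactors = FALSE)
    swm <- gam$switches
  }
  if (L > 1) {
    colnames(swm) <- paste0("sw_", loci[-L], "_", loci[-1])
    truth <- cbind(truth, as.data.frame(swm))
  }
  list(family = build_family(family_id, specs, loci), truth = truth,
       mutations = if (length(muts)) do.call(rbind, muts) else NULL)
}

#' Simulate a full characterization study
#'
#' Composes [simulate_unrelated()] and [simulate_family()] under one seed:
#' the unrelated panel plus `n_three_gen` three-generation families and one
#' two-generation family per entry of `offspring_two_gen`. With the default
#' design this yields 43 families and 86 maternal meioses. Per-family RNG
#' substreams are derived deterministically from `(seed, family index)`.
#'
#' @param config a [sim_config()].
#' @return List with `dataset`, `families` (named list), `truth` (meiosis
#'   table with switch indicators) and `mutations`.
#' @export
simulate_study <- function(config) {
  ds <- simulate_unrelated(config)
  fams <- list(); truths <- list(); muts <- list()
  idx <- 0L
  add <- function(type, n_off) {
    idx <<- idx + 1L
    set.seed((config$seed * 1009L + idx) %% .Machine$integer.max)
    fid <- sprintf("FAM%02d", idx)
    sim <- simulate_family(config, type, family_id = fid,
                           n_offspring = n_off)
    fams[[fid]] <<- sim$family
    truths[[fid]] <<- sim$truth
    if (!is.null(sim$mutations)) muts[[fid]] <<- sim$mutations
  }
  for (i in seq_len(config$n_three_gen)) add("three_generation", 1L)
  for (n_off in config$offspring_two_gen) add("two_generation", n_off)
  list(dataset = ds, families = fams,
       truth = do.call(rbind, truths),
       mutations = if (length(muts)) do.call(rbind, muts) else NULL)
}

#' Write a simulated study to disk
#'
#' Emits `genotypes.tsv`, `families.ped`, `map.tsv`, `truth_meioses.tsv`
#' and `truth_mutations.tsv` in the formats read by the package parsers.
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @param panel the panel used for the simulation.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, panel) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotype_table(sim$dataset, file.path(dir, "genotypes.tsv"))
  write_pedigree_file(sim$families, file.path(dir, "families.ped"))
  write_map_table(panel, file.path(dir, "map.tsv"))
  write.table(sim$truth, file.path(dir, "truth_meioses.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(sim$mutations))
    write.table(sim$mutations, file.path(dir, "truth_mutations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
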