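# Maternal-transmission analysis in typed families.
#
# The engine explains each child's maternal alleles within one linkage group
# as a path through the mother's two haplotypes: switching haplotype between
# adjacent loci costs one event (an intragroup recombination), a one-repeat
# discordance costs one event (a one-step mutation), anything else is
# incompatible. Phase is fixed by the grandfather's hemizygous haplotype in
# three-generation families and otherwise chosen, jointly over the sibship,
# as the assignment minimising the total number of events. Equal-parsimony
# alternatives (mutation vs recombination) are reported as ambiguous rather
# than resolved, and are excluded from recombination counts.

BIG_COST <- 50

# mother units: one entry per mother with typed children
fam_mother_units <- function(fam) {
  m <- fam$members
  mothers <- unique(m$mother_id[m$mother_id != "0"])
  lapply(mothers, function(mo) {
    kids <- m$individual_id[m$mother_id == mo]
    gf <- m$father_id[match(mo, m$individual_id)]
    list(mother = mo, children = kids,
         grandfather = if (!is.na(gf) && gf != "0") gf else NA_character_)
  })
}

# candidate maternal alleles for one child at one locus.
# Returns list of options (mat, cost, pat_event) or NULL when undetermined.
maternal_options <- function(fam, child, locus) {
  m <- fam$members
  row <- match(child, m$individual_id)
  sex <- m$sex[row]
  g <- member_geno(fam, child, locus)
  if (is.null(g)) return(NULL)
  if (sex == "M") return(list(list(mat = g[1], cost = 0, pat = NULL)))
  fa <- m$father_id[row]
  f <- if (fa != "0") member_geno(fam, fa, locus) else NULL
  opts <- list()
  cand <- if (g[1] == g[2]) 1L else 1:2
  for (ix in cand) {
    pat <- g[ix]; mat <- g[-ix][1]
    if (g[1] == g[2]) mat <- g[1]
    if (is.null(f)) {
      opts[[length(opts) + 1]] <- list(mat = mat, cost = 0, pat = NULL)
    } else if (pat == f[1]) {
      opts[[length(opts) + 1]] <- list(mat = mat, cost = 0, pat = NULL)
    } else if (is_one_step(pat, f[1])) {
      opts[[length(opts) + 1]] <- list(
        mat = mat, cost = 1,
        pat = list(type = "mutation", locus = locus, parent = "paternal",
                   from = f[1], to = pat))
    }
  }
  if (!length(opts))
    opts <- list(list(mat = g[1], cost = BIG_COST, pat = NULL),
                 list(mat = g[2], cost = BIG_COST, pat = NULL))
  # drop duplicate options (hom daughters)
  keys <- vapply(opts, function(o) paste(o$mat, o$cost), "")
  opts[!duplicated(keys)]
}

# phase configurations of one mother over the LG loci.
# Each config is a 2 x L character matrix (row 1 / row 2 = the two
# haplotypes; for anchored configs row 1 is the grandfather's side).
mother_configs <- function(fam, unit, loci) {
  L <- length(loci)
  mg <- lapply(loci, function(l) member_geno(fam, unit$mother, l))
  het <- vapply(seq_len(L), function(i)
    !is.null(mg[[i]]) && mg[[i]][1] != mg[[i]][2], TRUE)
  gf_events <- list()
  if (!is.na(unit$grandfather)) {
    hap1 <- hap2 <- rep(NA_character_, L)
    ok <- TRUE
    for (i in seq_len(L)) {
      if (is.null(mg[[i]])) next
      if (!het[i]) { hap1[i] <- hap2[i] <- mg[[i]][1]; next }
      gfa <- member_geno(fam, unit$grandfather, loci[i])
      if (is.null(gfa)) { ok <- FALSE; break }
      if (gfa[1] %in% mg[[i]]) {
        hap1[i] <- gfa[1]
      } else if (any(is_one_step(mg[[i]], gfa[1]))) {
        hap1[i] <- mg[[i]][which(is_one_step(mg[[i]], gfa[1]))[1]]
        gf_events[[length(gf_events) + 1]] <-
          list(type = "mutation", locus = loci[i], parent = "grandfather",
               from = gfa[1], to = hap1[i])
      } else { ok <- FALSE; break }
      hap2[i] <- setdiff(mg[[i]], hap1[i])[1]
    }
    if (ok) {
      cfg <- rbind(hap1, hap2)
      colnames(cfg) <- loci
      return(list(configs = list(cfg), provenance = "grandfather_anchored",
                  het = het, gf_events = gf_events))
    }
  }
  hx <- which(het)
  if (!length(hx)) {
    hap <- vapply(seq_len(L), function(i)
      if (is.null(mg[[i]])) NA_character_ else mg[[i]][1], "")
    cfg <- rbind(hap, hap); colnames(cfg) <- loci
    return(list(configs = list(cfg), provenance = "offspring_inferred",
                het = het, gf_events = list()))
  }
  base1 <- base2 <- rep(NA_character_, L)
  for (i in seq_len(L)) if (!is.null(mg[[i]]) && !het[i])
    base1[i] <- base2[i] <- mg[[i]][1]
  flips <- if (length(hx) == 1) matrix(FALSE, 1, 1) else
    as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(hx) - 1)))
  configs <- lapply(seq_len(nrow(flips)), function(r) {
    h1 <- base1; h2 <- base2
    h1[hx[1]] <- mg[[hx[1]]][1]; h2[hx[1]] <- mg[[hx[1]]][2]
    if (length(hx) > 1) for (q in 2:length(hx)) {
      sel <- if (flips[r, q - 1]) 2:1 else 1:2
      h1[hx[q]] <- mg[[hx[q]]][sel[1]]
      h2[hx[q]] <- mg[[hx[q]]][sel[2]]
    }
    cfg <- rbind(h1, h2); colnames(cfg) <- loci
    cfg
  })
  # canonical deterministic order (independent of child ordering)
  keys <- vapply(configs, function(cfg) {
    a <- paste(cfg[1, ], collapse = "-"); b <- paste(cfg[2, ], collapse = "-")
    paste(sort(c(a, b)), collapse = "|")
  }, "")
  configs <- configs[order(keys)]
  list(configs = configs, provenance = "offspring_inferred", het = het,
       gf_events = list())
}

# minimal-cost explanations of one child's maternal vector under one config.
# options_by_locus: list over loci (each a list of options or NULL).
# Returns list(cost, explanations, mats): explanations deduped by event set;
# mats = maternal allele per locus of the first minimal explanation.
child_explanations <- function(options_by_locus, cfg) {
  L <- ncol(cfg)
  paths <- as.matrix(expand.grid(rep(list(1:2), L)))
  best_cost <- Inf
  expl <- list()
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    sw <- if (L > 1) which(s[-L] != s[-1]) else integer(0)
    cost <- length(sw)
    if (cost > best_cost) next
    per_locus <- vector("list", L)
    ok <- TRUE
    for (i in seq_len(L)) {
      opts <- options_by_locus[[i]]
      if (is.null(opts)) { per_locus[[i]] <- list(list(mat = NA, ev = NULL, c = 0)); next }
      hap <- cfg[s[i], i]
      evald <- lapply(opts, function(o) {
        if (is.na(hap)) {
          list(mat = o$mat, ev = if (is.null(o$pat)) NULL else list(o$pat),
               c = o$cost)
        } else if (o$mat == hap) {
          list(mat = o$mat, ev = if (is.null(o$pat)) NULL else list(o$pat),
               c = o$cost)
        } else if (is_one_step(o$mat, hap)) {
          mut <- list(type = "mutation", locus = colnames(cfg)[i],
                      parent = "maternal", from = hap, to = o$mat)
          list(mat = o$mat,
               ev = c(if (is.null(o$pat)) NULL else list(o$pat), list(mut)),
               c = o$cost + 1)
        } else {
          list(mat = o$mat, ev = if (is.null(o$pat)) NULL else list(o$pat),
               c = o$cost + BIG_COST)
        }
      })
      cs <- vapply(evald, function(e) e$c, 0)
      per_locus[[i]] <- evald[cs == min(cs)]
      cost <- cost + min(cs)
      if (cost > best_cost) { ok <- FALSE; break }
    }
    if (!ok) next
    if (cost < best_cost) { best_cost <- cost; expl <- list() }
    # cross product of per-locus minimal alternatives
    combo <- list(list(mats = character(0), evs = list()))
    for (i in seq_len(L)) {
      combo <- unlist(lapply(combo, function(cb)
        lapply(per_locus[[i]], function(e)
          list(mats = c(cb$mats, e$mat), evs = c(cb$evs, e$ev)))),
        recursive = FALSE)
    }
    for (cb in combo) {
      evs <- cb$evs
      for (iv in sw) evs <- c(evs, list(list(type = "recombination",
                                             interval = c(iv, iv + 1L))))
      expl[[length(expl) + 1]] <- list(mats = cb$mats, events = evs,
                                       path = s)
    }
  }
  sig <- vapply(expl, function(e)
    paste(sort(vapply(e$events, function(ev)
      paste(unlist(ev), collapse = ":"), "")), collapse = ";"), "")
  keep <- !duplicated(sig)
  list(cost = best_cost, explanations = expl[keep],
       mats = if (length(expl)) expl[[1]]$mats else rep(NA_character_, L))
}

# canonicalize a recombination interval: widen across loci where the child
# carries no phase information (mother homozygous/untyped or child untyped).
canonical_interval <- function(iv, informative, loci) {
  L <- length(loci)
  left <- iv[1]; while (left >= 1 && !informative[left]) left <- left - 1
  right <- iv[2]; while (right <= L && !informative[right]) right <- right + 1
  open <- left < 1 || right > L
  left <- max(left, 1); right <- min(right, L)
  list(left = loci[left], right = loci[right],
       unresolved = open || (right - left) > 1L)
}

verdict_from <- function(cost, explanations, informative, loci) {
  if (cost == 0)
    return(list(verdict = "consistent", detail = ""))
  if (cost >= BIG_COST || cost > 2)
    return(list(verdict = "incompatible",
                detail = sprintf("%d unexplained discordances", cost)))
  describe <- function(ev) {
    if (ev$type == "mutation")
      sprintf("%s one-step mutation %s->%s at %s", ev$parent, ev$from,
              ev$to, ev$locus)
    else {
      ci <- canonical_interval(ev$interval, informative, loci)
      sprintf("recombination in %s..%s%s", ci$left, ci$right,
              if (ci$unresolved) " (unresolved)" else "")
    }
  }
  alts <- vapply(explanations, function(e)
    paste(vapply(e$events, describe, ""), collapse = " + "), "")
  alts <- unique(alts)
  if (cost == 2)
    return(list(verdict = "ambiguous",
                detail = paste("two events required:",
                               paste(alts, collapse = " | "))))
  evs <- lapply(explanations, function(e) e$events[[1]])
  types <- vapply(evs, function(e) e$type, "")
  if (all(types == "mutation")) {
    key <- unique(vapply(evs, function(e) paste(e$locus, e$parent), ""))
    if (length(key) == 1)
      return(list(verdict = "one_step_mutation", detail = alts[1],
                  locus = evs[[1]]$locus, parent = evs[[1]]$parent,
                  from = evs[[1]]$from, to = evs[[1]]$to))
    return(list(verdict = "ambiguous",
                detail = paste(alts, collapse = " | ")))
  }
  if (all(types == "recombination")) {
    cis <- lapply(evs, function(e)
      canonical_interval(e$interval, informative, loci))
    lefts <- vapply(cis, `[[`, "", "left")
    rights <- vapply(cis, `[[`, "", "right")
    li <- min(match(lefts, loci)); ri <- max(match(rights, loci))
    return(list(verdict = "intragroup_recombination",
                detail = paste(unique(alts), collapse = " | "),
                interval_left = loci[li], interval_right = loci[ri],
                unresolved = any(vapply(cis, `[[`, TRUE, "unresolved")) ||
                  length(unique(paste(lefts, rights))) > 1))
  }
  list(verdict = "ambiguous", detail = paste(alts, collapse = " | "))
}

# full engine for one mother unit and one linkage group
analyze_mother_lg <- function(fam, unit, loci, group_id) {
  mc <- mother_configs(fam, unit, loci)
  opts <- lapply(unit$children, function(ch)
    lapply(loci, function(l) maternal_options(fam, ch, l)))
  names(opts) <- unit$children
  evals <- lapply(mc$configs, function(cfg)
    lapply(unit$children, function(ch) child_explanations(opts[[ch]], cfg)))
  totals <- vapply(evals, function(ev)
    sum(vapply(ev, function(e) min(e$cost, BIG_COST), 0)), 0)
  pick <- which.min(totals) # ties: first in canonical order
  cfg <- mc$configs[[pick]]
  ev <- evals[[pick]]
  names(ev) <- unit$children
  # a locus is phase-informative for a child when the mother is het there
  # and the child is typed
  informative <- function(ch) {
    vapply(seq_along(loci), function(i)
      mc$het[i] && !is.null(opts[[ch]][[i]]), TRUE)
  }
  calls <- do.call(rbind, lapply(unit$children, function(ch) {
    v <- verdict_from(ev[[ch]]$cost, ev[[ch]]$explanations,
                      informative(ch), loci)
    data.frame(family_id = fam$family_id, child_id = ch,
               linkage_group = group_id, verdict = v$verdict,
               locus = v$locus %||% NA_character_,
               parent = v$parent %||% NA_character_,
               from_allele = v$from %||% NA_character_,
               to_allele = v$to %||% NA_character_,
               interval_left = v$interval_left %||% NA_character_,
               interval_right = v$interval_right %||% NA_character_,
               unresolved = v$unresolved %||% NA,
               n_events = ev[[ch]]$cost,
               detail = v$detail,
               provenance = mc$provenance,
               stringsAsFactors = FALSE)
  }))
  list(calls = calls, config = cfg, provenance = mc$provenance,
       het = mc$het, evals = ev, gf_events = mc$gf_events,
       tied_configs = sum(totals == totals[pick]))
}

#' Classify X-STR transmissions within families
#'
#' For every child and linkage group, finds the minimal-event explanation of
#' the child's maternal alleles: `consistent`, `one_step_mutation` (with
#' locus and parent of origin), `intragroup_recombination` (with breakpoint
#' interval, widened to "unresolved" across loci where the mother is
#' homozygous), `ambiguous` (equal-parsimony alternatives, listed), or
#' `incompatible`. Paternal one-step mutations in father-daughter
#' transmissions are detected as part of resolving the daughter's maternal
#' allele.
#'
#' @param fam an [xstr_family()] or list of them.
#' @param panel an [xstr_panel()] assigning loci to linkage groups.
#' @param groups linkage groups to analyse (default: all groups with at
#'   least one typed locus in the family).
#' @return Data frame of transmission calls, one row per child x group.
#' @export
classify_transmission <- function(fam, panel, groups = NULL) {
  if (!inherits(fam, "xstr_family") && is.list(fam)) {
    return(do.call(rbind, lapply(fam, classify_transmission, panel = panel,
                                 groups = groups)))
  }
  pgs <- panel_groups(panel)
  if (is.null(groups)) groups <- names(pgs)
  units <- fam_mother_units(fam)
  out <- list()
  for (g in groups) {
    loci <- intersect(pgs[[g]]$locus, fam$loci)
    if (!length(loci)) next
    for (unit in units) {
      res <- analyze_mother_lg(fam, unit, loci, g)
      out[[length(out) + 1]] <- res$calls
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Resolve maternal haplotypes per linkage group
#'
#' Reconstructs each mother's two haplotypes and the maternal haplotype
#' transmitted to each child. In three-generation families the grandfather's
#' hemizygous X fixes the mother's phase (`grandfather_anchored`); otherwise
#' the most parsimonious assignment over the sibship is used
#' (`offspring_inferred`), or `ambiguous` when several assignments tie.
#'
#' @inheritParams classify_transmission
#' @return Data frame with one row per mother x group: the two maternal
#'   haplotypes, phase provenance, uninformative (homozygous) loci, and one
#'   row per child with the transmitted maternal haplotype.
#' @export
resolve_maternal_haplotypes <- function(fam, panel, groups = NULL) {
  stopifnot(inherits(fam, "xstr_family"))
  pgs <- panel_groups(panel)
  if (is.null(groups)) groups <- names(pgs)
  units <- fam_mother_units(fam)
  rows <- list()
  for (g in groups) {
    loci <- intersect(pgs[[g]]$locus, fam$loci)
    if (!length(loci)) next
    for (unit in units) {
      res <- analyze_mother_lg(fam, unit, loci, g)
      prov <- res$provenance
      if (prov == "offspring_inferred" && res$tied_configs > 1)
        prov <- "ambiguous"
      for (ch in unit$children) {
        rows[[length(rows) + 1]] <- data.frame(
          family_id = fam$family_id, mother_id = unit$mother,
          child_id = ch, linkage_group = g,
          hap1 = paste(res$config[1, ], collapse = "-"),
          hap2 = paste(res$config[2, ], collapse = "-"),
          child_maternal = paste(res$evals[[ch]]$mats, collapse = "-"),
          provenance = prov,
          uninformative_loci = paste(loci[!res$het], collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Tally of informative meioses for a locus pair
#'
#' @param loci character vector of the two locus names.
#' @param R recombinant count.
#' @param N informative meiosis count (`R <= N`).
#' @return Object of class `meiosis_tally`.
#' @export
meiosis_tally <- function(loci, R, N) {
  R <- as.integer(R); N <- as.integer(N)
  if (R < 0 || N < 0 || R > N) stop("need 0 <= R <= N")
  structure(list(loci = loci, R = R, N = N), class = "meiosis_tally")
}

#' @export
print.meiosis_tally <- function(x, ...) {
  cat(sprintf("meiosis_tally %s-%s: R = %d / N = %d\n",
              x$loci[1], x$loci[2], x$R, x$N))
  invisible(x)
}

#' Count informative meioses and recombinants for a locus pair
#'
#' A meiosis is informative when the mother is heterozygous at both loci and
#' the child's maternal allele is resolvable at both. With a
#' grandfather-anchored mother, recombinant status is absolute and enters
#' `tally`; without anchoring the family contributes its pattern (number of
#' children on each side of an arbitrary phase labelling) to
#' `phase_unknown`, which the LOD likelihood averages over both phases.
#' Meioses involving a one-step mutation at either locus, or an ambiguous
#' transmission in either locus' linkage group, are excluded and reported.
#'
#' @param families list of [xstr_family()] objects.
#' @param pair character vector of two locus names.
#' @param panel an [xstr_panel()].
#' @param verdicts optional precomputed [classify_transmission()] result for
#'   `families` (computed on the fly otherwise); passing it avoids
#'   re-classifying every family for every pair.
#' @return List with `tally` (a [meiosis_tally()] of phase-known meioses),
#'   `phase_unknown` (per-family `c(n, r)` patterns) and `excluded`
#'   (data frame of skipped meioses with reasons).
#' @export
count_meioses <- function(families, pair, panel, verdicts = NULL) {
  if (inherits(families, "xstr_family")) families <- list(families)
  stopifnot(length(pair) == 2)
  pos <- panel$position_cM[match(pair, panel$locus)]
  pair <- pair[order(pos)]
  lgs <- panel$linkage_group[match(pair, panel$locus)]
  if (is.null(verdicts))
    verdicts <- classify_transmission(families, panel, groups = unique(lgs))
  R <- 0L; N <- 0L
  unknown <- list()
  excl <- list()
  note <- function(fid, ch, why)
    excl[[length(excl) + 1]] <<- data.frame(family_id = fid, child_id = ch,
                                            reason = why,
                                            stringsAsFactors = FALSE)
  for (fam in families) {
    if (!all(pair %in% fam$loci)) next
    units <- fam_mother_units(fam)
    for (unit in units) {
      mg <- lapply(pair, function(l) member_geno(fam, unit$mother, l))
      if (any(vapply(mg, is.null, TRUE))) next
      het <- vapply(mg, function(g) g[1] != g[2], TRUE)
      if (!all(het)) next
      anchored <- FALSE
      hapside <- NULL
      if (!is.na(unit$grandfather)) {
        cfgs <- mother_configs(fam, unit, pair)
        if (cfgs$provenance == "grandfather_anchored") {
          anchored <- TRUE
          hapside <- cfgs$configs[[1]]
        }
      }
      n_u <- 0L; r_u <- 0L
      for (ch in unit$children) {
        bad <- FALSE
        if (!is.null(verdicts)) {
          vch <- verdicts[verdicts$child_id == ch &
                            verdicts$family_id == fam$family_id, ]
          for (q in 1:2) {
            vlg <- vch[vch$linkage_group == lgs[q], ]
            if (!nrow(vlg)) next
            if (vlg$verdict[1] %in% c("ambiguous", "incompatible")) {
              note(fam$family_id, ch, paste0(vlg$verdict[1], " in ", lgs[q]))
              bad <- TRUE; break
            }
            if (vlg$verdict[1] == "one_step_mutation" &&
                !is.na(vlg$locus[1]) && vlg$locus[1] %in% pair &&
                vlg$parent[1] != "paternal") {
              note(fam$family_id, ch, paste0("mutation at ", vlg$locus[1]))
              bad <- TRUE; break
            }
          }
        }
        if (bad) next
        mats <- character(2)
        for (q in 1:2) {
          o <- maternal_options(fam, ch, pair[q])
          if (is.null(o)) { bad <- TRUE; break }
          if (length(o) > 1) {
            hit <- vapply(o, function(oo) oo$mat %in% mg[[q]], TRUE)
            if (sum(hit) != 1) {
              note(fam$family_id, ch, paste0("ambiguous maternal allele at ",
                                             pair[q]))
              bad <- TRUE; break
            }
            o <- o[hit]
          }
          if (o[[1]]$cost >= BIG_COST) {
            note(fam$family_id, ch, paste0("incompatible at ", pair[q]))
            bad <- TRUE; break
          }
          if (!(o[[1]]$mat %in% mg[[q]])) {
            why <- if (any(is_one_step(mg[[q]], o[[1]]$mat)))
              "maternal mutation" else "incompatible maternal allele"
            note(fam$family_id, ch, paste0(why, " at ", pair[q]))
            bad <- TRUE; break
          }
          mats[q] <- o[[1]]$mat
        }
        if (bad) next
        if (anchored) {
          side <- vapply(1:2, function(q)
            which(hapside[, pair[q]] == mats[q])[1], 0L)
          N <- N + 1L
          if (side[1] != side[2]) R <- R + 1L
        } else {
          first <- vapply(1:2, function(q)
            mats[q] == sort_alleles(mg[[q]])[1], TRUE)
          n_u <- n_u + 1L
          if (first[1] != first[2]) r_u <- r_u + 1L
        }
      }
      if (n_u > 0) unknown[[length(unknown) + 1]] <- c(n = n_u, r = r_u)
    }
  }
  list(tally = meiosis_tally(pair, R, N), phase_unknown = unknown,
       excluded = if (length(excl)) do.call(rbind, excl) else NULL)
}

#' Empirical recombination fraction from a tally
#'
#' \eqn{\hat\theta = R/N}. Fractions above 0.5 are truncated to 0.5 with a
#' warning when `cap = TRUE` (the reporting convention), since a
#' recombination fraction cannot exceed free recombination.
#'
#' @param tally a [meiosis_tally()].
#' @param cap truncate at 0.5?
#' @return Recombination fraction estimate, `NA` when `N = 0`.
#' @export
empirical_recombination_fraction <- function(tally, cap = TRUE) {
  stopifnot(inherits(tally, "meiosis_tally"))
  if (tally$N == 0) return(NA_real_)
  th <- tally$R / tally$N
  if (cap && th > 0.5) {
    warning(sprintf("R/N = %.3f exceeds 0.5; capped", th))
    th <- 0.5
  }
  th
}

# LOD(theta) over a grid given phase-known counts and phase-unknown
# family patterns; returns the lod_result object.
lod_from_counts <- function(pair, R, N, unknown = list(),
                            theta_grid_step = 1e-4) {
  n_unknown <- sum(vapply(unknown, function(u) u[["n"]], 0))
  if (N + n_unknown == 0) {
    return(structure(list(loci = pair, theta_hat = NA_real_,
                          max_lod = NA_real_, R = NA_integer_,
                          N = NA_integer_, n_informative = 0L,
                          n_phase_unknown = 0L,
                          grid_step = theta_grid_step),
                     class = "lod_result"))
  }
  th <- seq(0, 0.5, by = theta_grid_step)
  # k * log(x) with the 0 * log(0) := 0 convention
  xlog <- function(k, x) if (k == 0) rep(0, length(x)) else k * log(x)
  ll <- xlog(R, th) + xlog(N - R, 1 - th)
  ll0 <- N * log(0.5)
  for (u in unknown) {
    a <- exp(xlog(u[["r"]], th) + xlog(u[["n"]] - u[["r"]], 1 - th))
    b <- exp(xlog(u[["n"]] - u[["r"]], th) + xlog(u[["r"]], 1 - th))
    ll <- ll + log(0.5 * (a + b))
    ll0 <- ll0 + u[["n"]] * log(0.5)
  }
  lod <- (ll - ll0) / log(10)
  i <- which.max(lod)
  structure(list(loci = pair, theta_hat = th[i], max_lod = max(lod[i], 0),
                 R = if (!length(unknown)) as.integer(R) else NA_integer_,
                 N = if (!length(unknown)) as.integer(N) else NA_integer_,
                 n_informative = as.integer(N + n_unknown),
                 n_phase_unknown = as.integer(n_unknown),
                 grid_step = theta_grid_step),
            class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf("two-point LOD %s-%s: max LOD %.2f at theta = %.3f (%d informative meioses)\n",
              x$loci[1], x$loci[2], x$max_lod, x$theta_hat, x$n_informative))
  invisible(x)
}

#' Two-point LOD score for a locus pair
#'
#' Likelihood-ratio test of linkage: \eqn{LOD(\theta) = \log_{10}
#' L(\theta)/L(1/2)} with \eqn{L(\theta) = \theta^R(1-\theta)^{N-R}} over
#' phase-known meioses; a phase-unknown mother contributes
#' \eqn{\frac12[\theta^r(1-\theta)^{n-r} + \theta^{n-r}(1-\theta)^r]} for
#' her sibship. The score is maximised over a theta grid on `[0, 0.5]`.
#'
#' @param x a [meiosis_tally()] (phase-known counts) or a list of
#'   [xstr_family()] objects.
#' @param pair locus pair (for the family method).
#' @param panel an [xstr_panel()] (for the family method).
#' @param theta_grid_step grid resolution (default 1e-4).
#' @param ... unused.
#' @return A `lod_result` with `theta_hat`, `max_lod`, and `R`, `N`
#'   populated when all contributing meioses are phase-known.
#' @examples
#' two_point_lod(meiosis_tally(c("A", "B"), R = 0, N = 10)) # LOD 10*log10(2)
#' @export
two_point_lod <- function(x, ...) UseMethod("two_point_lod")

#' @rdname two_point_lod
#' @export
two_point_lod.meiosis_tally <- function(x, theta_grid_step = 1e-4, ...) {
  lod_from_counts(x$loci, x$R, x$N, list(), theta_grid_step)
}

#' @rdname two_point_lod
#' @param verdicts optional precomputed classification (see
#'   [count_meioses()]).
#' @export
two_point_lod.list <- function(x, pair, panel, theta_grid_step = 1e-4,
                               verdicts = NULL, ...) {
  cm <- count_meioses(x, pair, panel, verdicts = verdicts)
  lod_from_counts(cm$tally$loci, cm$tally$R, cm$tally$N, cm$phase_unknown,
                  theta_grid_step)
}

#' LOD and recombination-fraction matrices over all locus pairs
#'
#' @param families list of [xstr_family()] objects.
#' @param panel an [xstr_panel()].
#' @param theta_grid_step grid resolution.
#' @param lod_threshold LOD above which a pair is flagged linked
#'   (conventionally 3).
#' @return List with upper-triangular matrices `lod` and `theta`, logical
#'   `linked`, and `n_informative`.
#' @export
lod_matrix <- function(families, panel, theta_grid_step = 1e-4,
                       lod_threshold = 3) {
  loci <- panel$locus
  L <- length(loci)
  lod <- theta <- matrix(NA_real_, L, L, dimnames = list(loci, loci))
  ninf <- matrix(NA_integer_, L, L, dimnames = list(loci, loci))
  verdicts <- classify_transmission(families, panel)
  for (i in seq_len(L - 1)) for (j in (i + 1):L) {
    r <- two_point_lod(families, c(loci[i], loci[j]), panel,
                       theta_grid_step = theta_grid_step,
                       verdicts = verdicts)
    lod[i, j] <- r$max_lod
    theta[i, j] <- r$theta_hat
    ninf[i, j] <- r$n_informative
  }
  list(lod = lod, theta = theta, linked = lod > lod_threshold,
       n_informative = ninf)
}
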