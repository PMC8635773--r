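#' Bundled reference inputs for the nine-locus panel
#'
#' Convenience accessors for the package's bundled published allele
#' frequencies (Shanghai Han, n = 269 chromosomes) and the constructed
#' female-X genetic map of the nine-locus panel.
#'
#' @return `reference_panel()` returns an [xstr_panel()];
#'   `reference_frequencies()` a named list of [freq_spectrum()] objects.
#' @export
reference_panel <- function() {
  read_map_table(system.file("extdata", "panel_map.tsv", package = "xstrkit",
                             mustWork = TRUE))
}

#' @rdname reference_panel
#' @export
reference_frequencies <- function() {
  read_frequency_table(
    system.file("extdata", "panel_allele_freqs.tsv", package = "xstrkit",
                mustWork = TRUE),
    n_chromosomes = 269)
}

#' Default simulation configuration mirroring the reference study
#'
#' Bundled panel and frequencies, 127 + 71 unrelated individuals, 43
#' families with 86 maternal meioses.
#'
#' @param seed integer seed.
#' @param freqs frequency spectra (defaults to the bundled published table).
#' @param ... overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
default_study_config <- function(seed = 1L, freqs = reference_frequencies(),
                                 ...) {
  sim_config(reference_panel(), freqs, seed = seed, ...)
}

#' Run the full characterization pipeline
#'
#' Frequencies -> forensic parameters -> HWE and LD exact tests ->
#' map-predicted recombination fractions -> family-based transmission
#' classification, recombination fractions and two-point LOD scores.
#' All stochastic stages are seeded; rerunning with the same inputs and
#' configuration reproduces the outputs byte for byte.
#'
#' @param genotypes path to a genotype table ([read_genotype_table()]).
#' @param pedigree path to a pedigree file ([read_pedigree_file()]),
#'   or `NULL` to skip the family stage.
#' @param map path to a genetic map table ([read_map_table()]).
#' @param out_dir output directory.
#' @param seed seed for the Monte Carlo tests.
#' @param mc_steps steps for the HWE Monte Carlo fallback.
#' @param permutations permutations per LD test.
#' @param theta_grid_step LOD grid resolution.
#' @param alpha,n_tests Bonferroni correction parameters (`n_tests = NULL`
#'   uses the number of locus pairs).
#' @param table3_compat round frequencies to 4 decimals before computing
#'   parameters (reproduces published tables).
#' @return Invisibly, a list with every computed object; files are written
#'   to `out_dir` (`params.tsv`, `hwe.tsv`, `ld_male.tsv`, `ld_female.tsv`,
#'   `theta_map.tsv`, `transmissions.tsv`, `lod.tsv`, `theta_family.tsv`,
#'   `run.log`).
#' @export
run_characterization <- function(genotypes, pedigree = NULL, map,
                                 out_dir = ".", seed = 1L, mc_steps = 1e5,
                                 permutations = 1e4, theta_grid_step = 1e-4,
                                 alpha = 0.05, n_tests = NULL,
                                 table3_compat = FALSE) {
  for (p in c(genotypes, pedigree, map))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- read_map_table(map)
  ds <- read_genotype_table(genotypes, panel)
  loci <- colnames(ds$a1)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  specs <- stage("frequencies", lapply(loci, function(l)
    estimate_allele_frequencies(ds, l)))
  names(specs) <- loci

  par_tab <- stage("parameters",
                   params_table(specs, digits = if (table3_compat) 4 else NULL))
  groups <- panel_groups(panel)
  hap_specs <- stage("haplotypes", lapply(names(groups), function(g)
    estimate_haplotype_frequencies(ds, panel, g)))
  names(hap_specs) <- names(groups)
  hap_tab <- params_table(hap_specs)
  combined <- apply(hap_tab, 1, combine_across_groups)
  par_out <- cbind(parameter = rownames(par_tab), par_tab,
                   setNames(hap_tab, paste0(names(hap_tab), "_haplotype")),
                   Combined = combined)

  fem <- ds$sex == "F"
  hwe <- stage("hwe", do.call(rbind, lapply(loci, function(l) {
    g <- cbind(ds$a1[fem, l], ds$a2[fem, l])
    t <- hwe_exact_test(g[stats::complete.cases(g), , drop = FALSE],
                        method = "auto", steps = mc_steps,
                        seed = seed)
    data.frame(locus = l, p_value = t$p_value,
               mc_stderr = t$mc_stderr %||% NA_real_, method = t$method,
               stringsAsFactors = FALSE)
  })))

  ld <- stage("ld", ld_tests(ds, permutations = permutations, seed = seed))
  if (is.null(n_tests)) n_tests <- sum(!is.na(ld$male))
  threshold <- bonferroni_threshold(alpha, max(n_tests, 1))

  mt <- stage("map_theta", pairwise_map_theta(panel))

  out <- list(dataset = ds, params = par_out, hwe = hwe, ld = ld,
              map_theta = mt, bonferroni = threshold)

  wt <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wtm <- function(m, f) write.table(data.frame(locus = rownames(m),
                                               round(m, 6),
                                               check.names = FALSE),
                                    file.path(out_dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  num_fmt <- function(d) {
    d[] <- lapply(d, function(col)
      if (is.numeric(col)) formatC(col, digits = 8, format = "f") else col)
    d
  }
  wt(num_fmt(par_out), "params.tsv")
  wt(hwe, "hwe.tsv")
  wtm(ld$male, "ld_male.tsv")
  wtm(ld$female, "ld_female.tsv")
  wtm(mt$locus_theta, "theta_map.tsv")

  if (!is.null(pedigree)) {
    fams <- stage("pedigree", read_pedigree_file(pedigree, panel))
    calls <- stage("classification", classify_transmission(fams, panel))
    lm <- stage("lod", lod_matrix(fams, panel,
                                  theta_grid_step = theta_grid_step))
    wt(calls, "transmissions.tsv")
    wtm(round(lm$lod, 2), "lod.tsv")
    wtm(round(lm$theta, 3), "theta_family.tsv")
    out$families <- fams; out$transmissions <- calls; out$lod <- lm
  }

  log_lines <- c(
    paste("xstrkit version:", as.character(packageVersion("xstrkit"))),
    paste("seed:", seed),
    paste("mc_steps:", mc_steps),
    paste("permutations:", permutations),
    paste("theta_grid_step:", theta_grid_step),
    paste("alpha:", alpha), paste("n_tests:", n_tests),
    paste("bonferroni_threshold:", format(threshold, digits = 6)),
    paste("table3_compat:", table3_compat),
    paste("inputs:", genotypes, pedigree %||% "(no pedigree)", map))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out)
}
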