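# Shared fixtures: the bundled nine-locus panel, its published frequencies
# and parameter values, and the characteristic family patterns (mutation,
# recombination, ambiguous) used across the pedigree tests.

`%||%` <- function(x, y) if (is.null(x)) y else x

demo_panel <- function() reference_panel()
demo_freqs <- function() reference_frequencies()

LG1 <- c("X003", "X006", "X008")
LG2 <- c("X016", "X018", "X019")
LG3 <- c("X028", "X029", "X033")

# Published forensic parameter values for the nine loci (n = 269
# chromosomes, frequencies as printed to 4 decimals, no renormalization).
published_params <- function() {
  matrix(c(
    # GD, PIC, PD_male, PD_female, MEC_Kruger, MEC_Kishida, MEC_Desmarais, MEC_Desmarais_duo
    0.68903553, 0.62802294, 0.68647406, 0.84325037, 0.42292542, 0.62802294, 0.62802294, 0.48218233,  # X003
    0.87163153, 0.85562055, 0.86839126, 0.96990843, 0.73972107, 0.85562055, 0.85562055, 0.75936208,  # X006
    0.62397225, 0.57101025, 0.62165265, 0.80621088, 0.37614525, 0.57113018, 0.57101025, 0.42239785,  # X008
    0.70485797, 0.65607784, 0.70223768, 0.86517776, 0.46116225, 0.65607784, 0.65607784, 0.51142369,  # X016
    0.70771122, 0.65474895, 0.70508032, 0.86269101, 0.45643172, 0.65474895, 0.65474895, 0.51038631,  # X018
    0.72971167, 0.69756273, 0.72699899, 0.89603419, 0.52479063, 0.69744589, 0.69756273, 0.55866141,  # X019
    0.81819275, 0.79076049, 0.81515114, 0.94144025, 0.63774334, 0.79076049, 0.79076049, 0.67120101,  # X028
    0.55270647, 0.49208521, 0.55065180, 0.73951960, 0.30538169, 0.49208521, 0.49208521, 0.34750737,  # X029
    0.79071099, 0.75944837, 0.78777155, 0.92663591, 0.59645406, 0.75956392, 0.75944837, 0.63231176), # X033
    nrow = 8,
    dimnames = list(c("GD", "PIC", "PD_male", "PD_female", "MEC_Kruger",
                      "MEC_Kishida", "MEC_Desmarais", "MEC_Desmarais_duo"),
                    c("X003", "X006", "X008", "X016", "X018", "X019",
                      "X028", "X029", "X033")))
}

# loci whose published 4-decimal frequencies sum to exactly 1
loci_sum_one <- function() c("X003", "X006", "X016", "X018", "X028", "X029")

# Published linkage-group level parameter values used by the combined checks
published_group_params <- function() {
  list(PD_male = c(LG1 = 0.97813006, LG2 = 0.95889816, LG3 = 0.97749811),
       MEC_Kruger = c(LG1 = 0.95649244, LG2 = 0.91831739, LG3 = 0.95554094),
       combined_PD_male = 0.99997977,
       combined_MEC_Kruger = 0.99984200)
}

# Compact family constructor: geno is a character matrix with cells
# "a" (male), "a/b" (female) or "." (missing).
make_family <- function(fid, ids, fathers, mothers, sexes, geno) {
  loci <- colnames(geno)
  a1 <- a2 <- matrix(NA_character_, length(ids), length(loci),
                     dimnames = list(NULL, loci))
  for (i in seq_along(ids)) for (j in seq_along(loci)) {
    g <- geno[i, j]
    if (is.na(g) || g == ".") next
    p <- strsplit(g, "/", fixed = TRUE)[[1]]
    a1[i, j] <- p[1]
    if (length(p) > 1) a2[i, j] <- p[2]
  }
  xstr_family(fid, data.frame(individual_id = ids, father_id = fathers,
                              mother_id = mothers, sex = sexes,
                              stringsAsFactors = FALSE), a1, a2)
}

gmat <- function(cells, loci) {
  matrix(cells, ncol = length(loci), byrow = TRUE,
         dimnames = list(NULL, loci))
}

# family with a paternal one-step mutation (16 -> 17 at X006, daughter 1)
fam_paternal_mutation <- function() {
  make_family("famPM", c("FA", "MO", "D1", "D2"),
              c("0", "0", "FA", "FA"), c("0", "0", "MO", "MO"),
              c("M", "F", "F", "F"),
              gmat(c("15",    "16",    "10",
                     "15/17", "12/18", "9/9",
                     "15/17", "12/17", "9/10",
                     "15/15", "16/18", "9/10"), LG1))
}

# family with a maternal one-step mutation (11 -> 12 at X018, daughter)
fam_maternal_mutation <- function() {
  make_family("famMM", c("FA", "MO", "D1", "S1"),
              c("0", "0", "FA", "0"), c("0", "0", "MO", "MO"),
              c("M", "F", "F", "M"),
              gmat(c("14",    "10",    "8",
                     "12/12", "9/11",  "6/8",
                     "12/14", "10/12", "8/8",
                     "12",    "11",    "8"), LG2))
}

# sibship proving one intragroup recombination between X003 and X006
fam_recombination <- function() {
  make_family("famRC", c("MO", "S1", "S2"),
              c("0", "0", "0"), c("0", "MO", "MO"), c("F", "M", "M"),
              gmat(c("13/15", "11/17", "9/9",
                     "15",    "17",    "9",
                     "13",    "17",    "9"), LG1))
}

# recombination within LG3 with unresolved breakpoint (mother hom at X029)
fam_recombination_unresolved <- function() {
  make_family("famRU", c("FA", "MO", "D1", "D2"),
              c("0", "0", "FA", "FA"), c("0", "0", "MO", "MO"),
              c("M", "F", "F", "F"),
              gmat(c("21",    "10",   "12",
                     "12/17", "8/8",  "12/16",
                     "12/21", "8/10", "12/16",
                     "12/21", "8/10", "12/12"), LG3))
}

# equal-parsimony mutation-vs-recombination sibship (ambiguous)
fam_ambiguous <- function() {
  make_family("famAM", c("MO", "S1", "S2"),
              c("0", "0", "0"), c("0", "MO", "MO"), c("F", "M", "M"),
              gmat(c("13/14", "11/18", "9/10",
                     "13",    "11",    "9",
                     "13",    "18",    "10"), LG1))
}

# three-generation family: grandfather anchors the mother's phase
fam_three_gen <- function(son = c("15", "18", "10")) {
  make_family("fam3G", c("GF", "MO", "S1"),
              c("0", "GF", "0"), c("0", "0", "MO"), c("M", "F", "M"),
              gmat(c("13",    "16",    "9",
                     "13/15", "16/18", "9/10",
                     son), LG1))
}
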