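Package: xstrkit
Title: Forensic and Linkage Characterization of X-Chromosomal STR Panels
Version: 1.0.0
Authors@R:
    person("xstrkit", "contributors", email = "xstrkit@example.org",
           role = c("aut", "cre"))
Description: Statistical characterization of X-chromosomal short tandem
    repeat (X-STR) marker panels for forensic genetics. Estimates allele
    and male-haplotype frequencies from sex-aware genotype tables, computes
    the standard battery of forensic efficiency parameters (gene diversity,
    polymorphism information content, male/female power of discrimination,
    and the Krueger, Kishida and Desmarais mean exclusion chances, with
    multi-group combination), runs exact Hardy-Weinberg and linkage
    disequilibrium tests on female and hemizygous male data, converts
    genetic map distances to recombination fractions with the Kosambi
    mapping function, classifies allele transmissions in two- and
    three-generation pedigrees (one-step mutations, intragroup
    recombinations, ambiguous cases), estimates recombination fractions
    from informative meioses and computes two-point LOD scores with
    phase-unknown mothers handled by likelihood. A seeded study simulator
    generates unrelated samples and typed families with per-meiosis ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
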