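---
title: "Statistical characterization of X-STR panels with xstrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical characterization of X-STR panels with xstrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xstrkit)
```

## The problem

X-chromosomal short tandem repeats (X-STRs) occupy a special place in
kinship testing: males are hemizygous (one allele, phase known), females
diploid, and tightly linked loci travel together as linkage-group (LG)
haplotypes. Characterizing a new X-STR panel therefore needs more than
allele frequencies — it needs sex-aware efficiency parameters, exact tests
of Hardy–Weinberg and linkage equilibrium run separately on female and male
data, map-based predictions of recombination, and a family study that
classifies each observed transmission and measures linkage directly.
`xstrkit` implements that pipeline end to end for panels of loci grouped
into LGs, together with a seeded simulator of the whole study design.

The bundled reference inputs describe a nine-locus panel in three linkage
groups (LG1 on Xp21.1, LG2 on Xq21.31, LG3 on Xq23), typed in 198 unrelated
Shanghai Han individuals (127 males, 71 females; 269 chromosomes per locus)
and in 43 families contributing 86 maternal meioses.

## Forensic efficiency parameters

All parameters are polynomials in the power sums $P_k = \sum_i p_i^k$ of an
allele (or haplotype) spectrum:

* gene/haplotype diversity $GD = \frac{n}{n-1}(1 - P_2)$, with $n$ the
  number of chromosomes sampled (269 for loci; the number of typed males
  for haplotypes);
* $PIC = 1 - P_2 - P_2^2 + P_4$;
* power of discrimination $PD_{male} = 1 - P_2$ (haploid) and
  $PD_{female} = 1 - 2P_2^2 + P_4$ (diploid);
* mean exclusion chances: Krüger (deficiency cases)
  $1 - 2P_2 + P_3 + 2P_4 - 3P_5 - 2P_2^2 + 3P_2P_3$, Kishida and Desmarais
  (trios, both algebraically equal to PIC), and Desmarais-duo
  $1 - 2P_2 + P_3$;
* combination across independent LGs: $1 - \prod_g (1 - v_g)$.

### Reproducing printed tables: the $\sum p \ne 1$ subtlety

Published frequency tables are rounded to four decimals, so columns sum to
0.9999–1.0001. The package deliberately does **not** renormalize (an option
exists), because published parameter values are computed from the printed
numbers. Two of the MEC variants turn out to be sensitive to
$S_1 = \sum_i p_i \ne 1$: evaluating the exclusion-probability sums without
assuming $S_1 = 1$ gives

$$MEC_{Kishida} = (1 - P_2 - P_2^2 + P_4) + (S_1 - 1)(1 + P_2 - P_3),$$
$$MEC_{Krüger} = \text{poly} + (S_1 - 1)(1 + P_2 - 2P_3 + P_4),$$

both of which collapse to the familiar polynomials when frequencies sum to
one, and which reproduce reference software output on rounded tables to
$<10^{-7}$. `params_table(..., digits = 4)` is the "published-table
compatibility" mode; the default uses full-precision estimated frequencies.

Haplotype frequencies are estimated from hemizygous males only: male phase
is observed, while unrelated female phase is not. Haplotype diversity uses
the same unbiased estimator with $n$ = number of typed males.

```{r}
freqs <- reference_frequencies()
round(forensic_params(freqs$X029), 6)
```

## Exact association tests

**HWE (female data).** Conditional on the observed allele counts, every
pairing of the $2n$ alleles into $n$ genotypes is equally likely under
Hardy–Weinberg equilibrium. The p-value is the probability-ordered tail:
the total conditional probability of genotype tables no more probable than
the observed one. Small tables are enumerated exactly (recursively, with a
cap); larger ones are sampled by i.i.d. random pairings. We chose i.i.d.
resampling over the traditional Markov-chain walk because each draw is an
exact, independent sample from the null — no burn-in, no autocorrelation,
and an exactly binomial standard error. The estimator
$(1 + \#\{\text{as or more extreme}\})/(B + 1)$ never reports zero.

**LD, male data.** Male X haplotypes are phase-known, so allelic
association is tested on the two-locus contingency table with the
margin-conditional probability-ordered exact test (the multi-allelic
generalization of Fisher's test), enumerated when feasible and otherwise
permuted.

**LD, female data.** Phase is unknown, so two-locus haplotype frequencies
are fit by EM, the statistic is the likelihood ratio of the fitted
haplotype frequencies against linkage equilibrium, and the null
distribution comes from permuting one locus' genotypes across individuals.
The reference study does not state which variant its software used on
females; both tests are implemented and labelled, and results are reported
separately for the sexes with a Bonferroni threshold $\alpha/m$
($m = 36$ pairs for nine loci).

Ties in the probability ordering are compared with a relative tolerance of
$10^{-9}$; all Monte Carlo procedures are bit-reproducible given
`(seed, steps)`.

## Map-based recombination prediction

The Kosambi mapping function $\theta = \frac{1}{2}\tanh(2d)$ (with $d$ in
Morgans; inverse $d = \frac{1}{4}\ln\frac{1+2\theta}{1-2\theta}$) converts
genetic distances into recombination fractions, allowing for crossover
interference at short range. Internally distances are Morgans, all I/O is
cM. Intragroup predictions use a group's full span; intergroup predictions
use group midpoints by default (`intergroup = "edge"` switches to nearest
edges) — the choice matters because published intergroup distances are
usually quoted without stating their endpoints, and midpoint separations
are not additive across three groups. The bundled map reproduces the
reference spans (0.763, 0.417, 1.906 cM) and the LG1–LG2 / LG2–LG3
midpoint separations (37.60, 25.67 cM) exactly; locus offsets inside each
group are constructed, not measured.

```{r}
round(pairwise_map_theta(reference_panel())$group_theta, 3)
```

## Family study

**Phase.** In a three-generation family the grandfather's hemizygous X
fixes his daughter's phase (`grandfather_anchored`). In two-generation
families the engine enumerates the mother's $2^{h-1}$ phase assignments
over her $h$ heterozygous loci and picks the assignment minimizing the
total number of events across the sibship (`offspring_inferred`); exact
ties are broken deterministically (lexicographically smallest haplotype
pair) and flagged.

**Classification.** A child's maternal alleles within one LG are explained
by a path through the mother's two haplotypes: a haplotype switch between
adjacent loci costs one event (intragroup recombination), a one-repeat
discordance costs one event (one-step mutation), anything else is
incompatible. Daughters' maternal alleles are resolved against the father
first, which is where paternal one-step mutations surface. Verdicts:

* 0 events — `consistent`;
* a unique single-event explanation — `one_step_mutation` (with locus,
  parent of origin and direction) or `intragroup_recombination` (with a
  breakpoint interval, widened to "unresolved" across loci where the mother
  is homozygous);
* several equal-parsimony explanations, or two events — `ambiguous`, with
  every alternative listed; the package never resolves a
  mutation-vs-recombination tie by fiat, mirroring how such transmissions
  are reported in practice;
* more than two events — `incompatible`, flagged for manual review.

**Counting and LOD.** An informative meiosis has the mother heterozygous at
both loci of a pair with resolvable maternal origin. Phase-known meioses
give $\hat\theta = R/N$; meioses involving a mutation at a pair locus or an
ambiguous verdict are excluded from $R/N$ (and reported), which is
conservative. The two-point LOD is
$\log_{10} L(\theta)/L(\tfrac12)$ with
$L(\theta) = \theta^R(1-\theta)^{N-R}$ over phase-known meioses; a
phase-unknown mother contributes
$\frac12[\theta^r(1-\theta)^{n-r} + \theta^{n-r}(1-\theta)^r]$ for her
sibship (the unbiased likelihood, rather than majority-rule phasing).
The score is maximized on a $\theta$ grid (default step $10^{-4}$); LOD
> 3 conventionally declares linkage. With no informative meioses the
result is reported missing, and $R/N$ fractions above 0.5 are truncated to
0.5 with a warning at the reporting level.

```{r}
two_point_lod(meiosis_tally(c("X018", "X019"), R = 1, N = 28))
```

## The simulator: what it emulates, and what it does not

`simulate_study()` reproduces the reference design: 127 + 71 unrelated
samples and 43 families. The family composition behind the published "86
meioses" is not itself published; the package fixes it once as 10
three-generation families plus 23 two-child and 10 three-child
two-generation families ($10 + 46 + 30 = 86$ maternal meioses), exposed
through `sim_config()`. Other stated-world choices:

* founders are i.i.d. draws from the bundled allele spectra in linkage
  equilibrium (explicit haplotype spectra can be supplied); founder LD is
  out of scope;
* maternal gametes walk loci in map order, switching haplotype between
  adjacent loci with the interval's $\theta$ (map-derived via Kosambi by
  default, overridable); interference is **not** modelled — Kosambi is used
  only for map$\leftrightarrow\theta$ conversion, not gamete generation;
* each transmitted allele mutates $\pm 1$ repeat with probability
  $\mu = 0.0025$ per locus per meiosis (a typical STR rate, consistent with
  observing ~2 mutations among the study's $86 \times 9$ maternal
  locus-transmissions); direction equiprobable;
* fathers transmit their X to daughters unchanged (no male recombination),
  subject to the same mutation rate; in all-male two-generation sibships
  the father is left untyped, as in the reference sampling design;
* per-family RNG substreams derive deterministically from
  `(seed, family index)`, so the full bundle is reproducible.

Every meiosis carries a ground-truth record (starting haplotype,
per-interval switch indicators, mutation events), which the test suite uses
as an oracle: at $\mu = 0$ the pipeline's $R/N$ tally must equal the truth
tally exactly on the informative subset.

A green simulation test therefore establishes that the pipeline recovers
the generative parameters of this idealized world — it does not establish
robustness to genotyping error, null alleles, population structure,
crossover interference, or founder LD, none of which are generated.

## Numerical and design notes

* Tolerances: published-table reproduction is asserted at $5\cdot10^{-7}$;
  exact-vs-Monte-Carlo agreement at 3 reported standard errors; the
  exact-test tie tolerance is $10^{-9}$ relative.
* The $\theta$-recovery property is simulated with allele ladders spaced
  two repeats apart. With adjacent ladders a true recombinant is often
  exactly explainable as a one-step mutation; the verdict is then
  `ambiguous` and the meiosis is excluded from $R/N$ by design, which
  biases $\hat\theta$ downward at large $\theta$. Spacing the ladders
  isolates the estimator property; ambiguity handling is tested on its own
  fixtures.
* The LOD "separation" property (intragroup pairs > 3, intergroup pairs
  < 1) holds for the two-generation sibship design: phase-unknown sib
  pairs carry almost no information near $\theta = 0.4$ (the observable
  concordance rate $2\theta(1-\theta)$ approaches its null value 0.5),
  while a few hundred *phase-known* meioses at $\theta \approx 0.3$ would
  genuinely push intergroup LOD above 1.
* Enumerating "all" small HWE tables is infeasible (the space is
  astronomically large even for 3 alleles and 20 females); the
  Monte-Carlo-vs-enumeration property is checked on a seeded random sample
  of such tables plus fixed edge cases.
* The exact-test enumeration caps at a configurable table count and
  instructs the caller to switch to Monte Carlo rather than running
  unbounded.
* Missing calls are excluded locus-wise; a half-missing female call is a
  parse error, not a missing value.

## Limitations

Mutation-rate estimation, multipoint linkage, kinship likelihood ratios and
locus discovery are out of scope. The transmission classifier assumes at
most moderate event counts per LG (more than two events in one linkage
group is flagged rather than explained), single-step mutations only, and
typed mothers throughout — all consistent with its intended use on small
forensic pedigrees.
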