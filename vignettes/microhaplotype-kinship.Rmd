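---
title: "Statistical methods for microhaplotype kinship panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for microhaplotype kinship panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microkin)
```

# Scope

`microkin` evaluates panels of short microhaplotype loci for forensic
kinship testing. This vignette documents the statistical models behind
each stage, the tunable parameters and their defaults, what the
synthetic-data engine does and does not emulate, and the numerical and
design decisions that were genuinely open.

# Panel screening

A candidate locus is retained when it has at least two SNPs, an extent
(inclusive span from first to last SNP, in bp) strictly below 100, an
effective number of alleles strictly above 3.00, an expected
heterozygosity strictly above 0.65, and a distance strictly above 5 Mb
to the nearest retained locus on the same chromosome. All four numeric
criteria are deliberately strict inequalities, so boundary values
(extent exactly 100 bp, Ae exactly 3.00) are excluded. Two choices here
were open and are fixed as follows:

* **Spacing conflicts.** When two passing loci are within 5 Mb of each
  other the filter keeps the one with the higher Ae. This is
  deterministic, maximizes panel information, and makes the filter
  idempotent (`filter_candidates(filter_candidates(x))` equals
  `filter_candidates(x)`), which the tests assert.
* **Distance convention.** Inter-locus distance is measured between
  first-SNP coordinates in bp on GRCh37; coordinates are 1-based
  inclusive throughout, and the extent convention `last − first + 1`
  is validated against all 36 packaged loci by `panel_extent_check()`
  rather than silently assumed.
* **Per-SNP frequency distinctness.** The requirement that member SNPs
  have different allele frequencies comes with no published tolerance;
  `snp_maf_distinct()` exposes it as an optional predicate with a
  default tolerance of 0.01 on the absolute difference.

# Forensic parameters

For a locus with allele frequencies $p_i$ and observed heterozygosity
$h$ (fraction of typed individuals with two distinct alleles):

* $A_e = 1/\sum_i p_i^2$, the number of equally frequent alleles with
  the same expected homozygosity; $1 \le A_e \le A$.
* $PD = 1 - \sum_j g_j^2$ over genotype frequencies $g_j$. Two modes
  are provided because the provenance of published values is ambiguous:
  `observed` tabulates genotypes from data (the usual worksheet
  behaviour on real samples), `hwe_expected` derives $g_j$ from allele
  frequencies under Hardy–Weinberg proportions, for which the closed
  form $1 - 2(\sum p^2)^2 + \sum p^4$ is used and cross-checked against
  explicit genotype enumeration in the tests. The mode is always
  recorded in reports.
* $PE = h^2 (1 - 2 h H^2)$ with $H = 1 - h$: the heterozygosity-based
  trio exclusion power. This convention was fixed only after verifying
  that it reproduces all 29 published per-locus PE values from the
  published Ho values within the 2-dp rounding (0.79 → 0.58 and
  0.58 → 0.27 at the extremes).
* Combined powers $1 - \prod_i (1 - v_i)$ accumulate the complement as
  $\exp \sum_i \log(1 - v_i)$; magnitudes like $10^{-26}$ are far below
  double-precision resolution of $1 - x$, so reports carry the
  complement explicitly (`1-3.76E-27` style).

**Frequency renormalization.** Published frequency tables are rounded
to 2 dp and rarely sum to exactly 1 per locus (the packaged fixture's
raw sums range 0.99–1.03). The loader renormalizes each locus by its
column sum and records the adjustment; every downstream consumer —
forensic parameters, the simulator and the LR evaluator — uses the same
renormalized object, so simulation and evaluation can never disagree
about the frequency model. This renormalization is also why recomputed
Ae values differ from published ones by up to ±0.2 at heavily rounded
multi-allelic loci.

# Equilibrium testing

**Hardy–Weinberg.** The exact test conditions on the observed allele
counts. Under Hardy–Weinberg sampling every assignment of the $2n$
allele copies to the $2n$ ordered genotype slots is equally likely, so
a Markov chain that repeatedly swaps the contents of two random slots
(accepting every move) has exactly the conditional distribution of
genotype tables as its stationary law; table probabilities satisfy
$P \propto 2^H / \prod_{i \le j} n_{ij}!$ with $H$ the heterozygote
count. The p-value is the post-burn-in fraction of visited tables whose
conditional probability does not exceed the observed table's
(tolerance $10^{-9}$ on the log scale for ties). Defaults are
1,000,000 steps after 100,000 burn-in, mirroring the defaults of the
standard population-genetics packages for this test; the tests
themselves use much shorter chains validated against full table
enumeration on small margins. Monomorphic loci return $p = 1$ with a
warning, since no alternative table exists.

**Linkage disequilibrium.** With gametic phase unknown, two-locus
haplotype frequencies are estimated by EM starting from the uniform
distribution over all haplotypes compatible with the data; the
log-likelihood is non-decreasing and iteration stops at a gain below
`tol` (default 1e-8) or `max_iter` (1000). The test statistic is
$2(\log L_{EM} - \log L_{LE})$, where the linkage-equilibrium
likelihood constrains each haplotype frequency to the product of its
single-locus allele frequencies. Because the asymptotic distribution is
unreliable for sparse multi-allelic tables, the null is built by
permuting one locus' genotypes across samples and re-running EM;
p-values use the add-one estimator $(1 + \#\{T_{perm} \ge T_{obs}\}) /
(1 + B)$, which can never report exactly zero. The default $B$ is
10,000; the type-I error of the whole procedure is verified at
$\alpha = 0.05$ over 200 null replicates in the test suite. When
double heterozygotes make the likelihood surface symmetric the EM
solution is the one reached from the deterministic uniform start and
the result is flagged (`ambiguous_phase`).

**Correction and workflow.** `equilibrium_scan()` reproduces the
two-stage workflow: HWE on all loci at $\alpha/m$, then LD on all
pairs of HWE-passing loci at $\alpha/\binom{k}{2}$ (for 36 loci and 29
survivors: 0.05/36 ≈ 0.0014 and 0.05/406 ≈ 0.0001). Per-test seeds are
spawned from the root seed by a fixed Lehmer step
($s_{i} = (48271 s + i) \bmod (2^{31}-1)$) so individual results are
reproducible independently of execution order.

# Pair simulation

The synthetic-data engine is the package's data source for power
evaluation; it emulates frequency-based kinship simulation of the
Families-3 kind. Founders are drawn under Hardy–Weinberg proportions
from the (renormalized) allele frequencies; related pairs are built
structurally — parent-child: founder parent plus child receiving one
transmitted allele and one population allele; full siblings: two
founder parents, each child receiving one transmitted allele from
each; half siblings: one shared founder parent; first cousins:
full-sibling parents married to independent founders. Mutation is
applied independently on *every* simulated transmission edge
(pedigree-faithful), not as a post-hoc perturbation: one mutable
meiosis separates parent and child, four meioses lie on the path
connecting full siblings (two per child), two for half siblings, and
six transmissions are simulated for first cousins.

Mutation models and defaults:

* `equal_probability` (microhaplotypes), rate $10^{-8}$ per meiosis
  per locus: a mutating allele becomes any of the other $A - 1$
  alleles with equal probability. A single-allele universe with a
  positive rate is an error (no target exists).
* `extended_stepwise` (STRs), rate $10^{-3}$: the repeat number moves
  by $s \ge 1$ steps with $s$ geometric (default
  `step_geometric_p = 0.9`, i.e. mostly single steps), direction
  up/down equally likely, reflected off the ends of the observed
  allele ladder. The exact multi-step law of the classical simulators
  is unpublished, so this parameterization is a documented stand-in;
  at rate $10^{-3}$ and 100,000 pairs the difference between
  `step_geometric_p` values is numerically invisible, and the
  single-step setting `step_geometric_p = 1` is available. Reflection
  can return a multi-step mutation to its origin allele, so the
  diagonal of the transmission matrix slightly exceeds $1 - \mu$ away
  from the ladder ends; simulator and LR matrix share this behaviour
  exactly.
* First-cousin studies default to zero mutation, matching how that
  comparison is conventionally simplified.

Loci are simulated independently (the linkage-equilibrium assumption);
the engine does not model linked loci, allele dropout, degradation or
genotyping error. Power estimates therefore describe the idealized
marker model, not assay-level robustness — passing tests show the
statistical pipeline is correct under its stated model, not that a wet
laboratory will reach the same numbers.

# Likelihood ratios

For an unordered pair $(g_1, g_2)$ and IBD coefficients
$(k_0, k_1, k_2)$:

$$P(g_2 \mid g_1, k) = k_0 P(g_2) + k_1 P(g_2 \mid \text{1 IBD}, g_1)
  + k_2 \,[g_2 = g_1],$$

with $P(\cdot)$ the Hardy–Weinberg genotype probability
($2pq$ for heterozygotes) and the one-IBD term transmitting one of
$g_1$'s alleles (probability $\tfrac12$ each) plus a population allele.
PI, FSI, HSI and FCI divide the Hp-conditional pair probability by the
unrelated one; FHSI divides full-sibling by half-sibling, so
$\log_{10} FHSI = \log_{10} FSI - \log_{10} HSI$ exactly (asserted in
the tests). The paternity index numerator replaces Mendelian
transmission with $T(a \to b) = 1 - \mu$ for $a = b$ and
$\mu\, m(a, b)$ otherwise, $m$ being the mutation model's target law.
Design decisions:

* Mutation enters only the parent-child numerator. At $10^{-8}$ its
  effect on sibling likelihoods is below floating-point visibility,
  and pairwise $k$-coefficient likelihoods have no natural
  single-meiosis factorization; whether the classical simulators
  mutation-adjust sibling indices is not documented, so this
  interpretation is stated rather than hidden.
* With $\mu = 0$, incompatible parent-child pairs give
  $\log_{10} LR = -\infty$; these are retained unclamped and support
  Hd at any threshold.
* Alleles absent from the frequency table raise an error; simulation
  and evaluation share one frequency object, so the error path cannot
  trigger in an internally consistent study. A minimum-frequency floor
  for casework data is deliberately not applied silently.
* Panel LRs add per-locus $\log_{10}$ values (independent loci).
* The first pair member is treated as the parent in PI; with the
  symmetric equal-probability transmission matrix the direction is
  immaterial.

Cohort evaluation precomputes, per locus, the $G \times G$ table of
log10 LRs over all ordered genotype pairs ($G = A(A+1)/2 \le 91$ for
$A \le 13$) and indexes it with the simulated integer genotypes, which
is what makes 100,000-pair studies take seconds. The lookup path is
asserted identical to the scalar per-pair path in the tests.

# System power

Classification at a threshold pair $(t_1, t_2)$, $t_1 \ge t_2$, uses
strict inequalities: $\log_{10} LR > t_1$ supports Hp,
$< t_2$ supports Hd, and everything between — including values exactly
on a threshold — is uncertain. From the six resulting tallies:
sensitivity and specificity are the correctly supported fractions of
each cohort; PPV and NPV condition on the verdict and are reported as
missing (`NA`) when no verdict of that kind was issued, rather than
fabricating 0 or 1; error rate and effectiveness are the misclassified
and correctly classified fractions of all pairs, so effectiveness +
error rate + uncertain fraction ≡ 1 (asserted exactly). Widening the
uncertain zone can only shrink the error rate (asserted over the
default grid $t = 1/-1 \dots 4/-4$).

The uncovered rates are the fraction of Hp samples strictly above the
Hd maximum and the fraction of Hd samples strictly below the Hp
minimum. Because they depend on the single most extreme simulated pair
per cohort they are irreproducible beyond order of magnitude between
runs; they are reported as descriptive outputs and deliberately not
used as correctness checks.

# Problem sizes and reproducibility

Default study size is 100,000 pairs per cohort, which reproduces
published effectiveness values to within a few tenths of a percentage
point; tests and examples use smaller cohorts where only structural
properties are at stake, and the equilibrium tests are validated
against full enumeration on tables of up to 6 alleles and 10
individuals, where enumeration is exact and fast. Every stochastic
entry point takes an integer seed; study-level functions spawn
per-cohort and per-test child seeds deterministically, so identical
seeds give byte-identical machine outputs.

# Known limitations

* PD for published tables can be computed under either observed or
  HWE-expected genotype frequencies; for one locus of the packaged
  fixture the two modes differ visibly (0.85 vs 0.83 at
  mh05zha004a), and which one the original worksheet used is not
  documented. Both are provided and labelled.
* The HWE p-value is a Monte-Carlo estimate with autocorrelated draws;
  its standard error is larger than the binomial formula suggests.
  Enumeration remains the reference for small tables.
* No subpopulation correction ($\theta$/F_ST), trio indices, mixture
  likelihoods or linked-locus models are implemented; they are outside
  the package's scope.
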