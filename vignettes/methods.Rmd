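---
title: "Models and methods behind lactsnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lactsnp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

lactsnp implements the statistical machinery of a candidate-gene association
study of milk production traits in a paternal half-sib dairy cattle design:
marker descriptive statistics, pedigree-aware mixed-model association for
single SNPs and haplotype combinations, haplotype-block construction, genetic
effect decomposition, and allele-differential scanning of transcription
factor binding sites (TFBS). This vignette explains the models, the defaults,
and the design choices, in that order.

## The animal model

Every association test is run under the animal model

$$y = \mu + \mathrm{HYS} + b\,M + G + u + e,$$

where $y$ is a trait record (305-day milk yield, fat yield, fat percentage,
protein yield, or protein percentage, one lactation at a time), HYS is the
fixed crossed herd(farm)–year–season class, $M$ is the calving age in months
with regression coefficient $b$, $G$ is the genotype or
haplotype-combination fixed factor, $u \sim N(0, A\sigma_a^2)$ is the random
additive genetic effect with $A$ the pedigree numerator relationship matrix,
and $e \sim N(0, I\sigma_e^2)$. The model assumes one record per animal per
fit, no genotype-by-environment interaction, and known pedigree.

`build_A()` uses the tabular method ($a_{ii} = 1 + a_{sd}/2$,
$a_{ij} = (a_{j,s} + a_{j,d})/2$), with unknown parents treated as unrelated,
non-inbred founders. `build_A_inverse()` assembles the sparse inverse
directly by Henderson's rules with the inbreeding-adjusted
Mendelian-sampling variances $d_i = \tfrac12 - \tfrac14(F_s + F_d)$
(three-quarter rule for one known parent). Both are verified against each
other and against a Monte-Carlo gene-dropping estimate of kinship in the test
suite.

### REML through Henderson's equations

`fit_animal_model()` estimates $(\sigma_a^2, \sigma_e^2)$ by REML, profiled
down to the single variance ratio $\lambda = \sigma_e^2/\sigma_a^2$. For a
given $\lambda$ the mixed-model equations

$$\begin{pmatrix} X'X & X'Z \\ Z'X & Z'Z + \lambda A^{-1} \end{pmatrix}
\begin{pmatrix} \hat b \\ \hat u \end{pmatrix} =
\begin{pmatrix} X'y \\ Z'y \end{pmatrix}$$

are solved by sparse Cholesky factorisation, $\hat\sigma_e^2$ has the closed
form $(y'y - \hat\theta'W'y)/(n - p)$, and the restricted likelihood reduces
(up to a constant) to
$(n-p)\log\hat\sigma_e^2 - q\log\lambda + \log|C(\lambda)|$ with $C$ the
coefficient matrix. The profile is minimised over $\log\lambda \in
[\log 10^{-3}, \log 10^3]$ with `stats::optimize()` (golden-section search
with parabolic refinement) at tolerance $10^{-6}$; an estimate at either
bound (heritability numerically 0 or 1) triggers a warning rather than an
error, because small fixtures legitimately land there. Fixed effects are
identified by treatment contrasts (first level set to zero); a rank-deficient
design is an error that names the confounded columns, since silently dropping
them would change the hypothesis being tested.

The Wald chi-square for the tested factor uses the fixed-effect covariance
$\sigma_e^2 [C^{-1}]_{bb}$ with $df = (\text{levels} - 1)$. Degrees-of-freedom
adjustments (Kenward–Roger, containment) are deliberately not implemented:
at cohort sizes of several hundred records per genotype class the chi-square
reference is adequate, and the package reports the statistic in that form.

Least-squares means are computed at equal HYS weights and the grand covariate
mean, $\hat\mu + \hat G_\ell + \overline{\mathrm{HYS}} + \hat b\,\bar M$, with
standard errors from the same covariance; they are invariant to the
identifiability constraint. Pairwise significance letters use all pairwise
Wald z-tests and the insert-and-absorb compact-letter algorithm, written here
because no compact-letter utility is available among the package's
dependencies; lowercase letters encode differences at 0.05, uppercase at
0.01. Variance components are re-estimated for every trait × lactation ×
marker model — the simplest faithful reading of a per-model mixed analysis —
and a fit reuses nothing across markers except $A^{-1}$.

Bonferroni correction is a bare multiplication `raw p × m`, uncapped, so
corrected values above 1 are reported as such. The family is per-gene for
single-SNP scans (each gene's SNP count) and the number of blocks for
haplotype scans; a global mode is available.

## Marker statistics

Genotype frequencies are counts over typed animals (missing calls excluded
listwise per SNP); allele frequencies are $p = f_{11} + f_{12}/2$. The
Hardy–Weinberg test compares observed genotype counts with
$n(p^2, 2pq, q^2)$ by a chi-square on 1 degree of freedom (three classes,
one estimated allele frequency), without continuity correction — the
convention of the Haploview era of candidate-gene work. The pass flag uses
$\alpha = 0.05$. A monomorphic SNP yields an expected zero cell; it is
reported as $\chi^2 = 0$, passing, with a warning, and flagged out of
downstream analyses.

## Linkage disequilibrium and haplotype blocks

Pairwise LD uses the standard two-locus EM over the double-heterozygote
ambiguity, initialised at linkage-equilibrium product frequencies (a single
start: the two-locus likelihood is well behaved at these dimensions),
iterated to a log-likelihood change below $10^{-8}$ with a hard cap of 1000
iterations and a monotonicity assertion. From the haplotype frequencies,
$D = p_{AB} - p_A p_B$, $D' = |D|/D_{\max}$ with the usual sign-dependent
$D_{\max}$, and $r^2$.

The $D'$ confidence interval is computed from the normalised likelihood of
$D'$ on a 101-point grid over $[0,1]$, holding allele frequencies at their
estimates and the sign of $D$ at its point estimate — the construction behind
the Gabriel block definition. Block detection then classifies pairs as strong
LD (CI $[\ge 0.70, \ge 0.98]$), strong recombination (upper bound < 0.90), or
uninformative, and accepts a contiguous span when at least 95% of its
informative pairs are strong LD, choosing maximal non-overlapping spans
greedily longest-first. The thresholds are the Haploview defaults, exposed as
arguments; blocks never span chromosomes.

Multi-locus phasing of a block (`em_block_phase()`) runs EM over all
haplotype pairs consistent with each multilocus genotype, capped at 12 SNPs
($2^{12}$ haplotype space); frequencies below $10^{-4}$ are pruned between
iterations. Haplotypes above the retention threshold (default 0.05) are
labelled H1…Hk by descending frequency. Each animal receives its
maximum-posterior consistent pair, with ties broken toward the pair
containing the globally more frequent haplotype, so reported combinations
are stable across runs. Haplotype combinations carried by fewer than 30
animals (configurable) are excluded from association, matching the practice
of analysing only well-populated combinations.

## Genetic effect decomposition

From genotype least-squares means and cohort allele frequencies,

$$a = \frac{\overline{AA} - \overline{BB}}{2},\qquad
  d = \overline{AB} - \frac{\overline{AA} + \overline{BB}}{2},\qquad
  \alpha = a + (q - p)\,d,$$

computed from model-adjusted means rather than raw means so the decomposition
inherits the HYS and covariate adjustment. The allele whose homozygote is
$\overline{AA}$ is the first-listed (usually major) allele, and the reported
orientation is recorded alongside the values; swapping labels negates $a$ and
$\alpha$ and leaves $d$ unchanged.

## TFBS scanning

JASPAR position frequency matrices are parsed from the common dialects (with
or without row labels and brackets). Log-odds weights follow the JASPAR
pseudocount convention: $w_{bk} = \log_2\frac{(c_{bk} + 0.8\,g_b)}{(N_k +
0.8)\,g_b}$ with background $g$ (uniform 0.25 by default, configurable) and a
total pseudocount of 0.8. The relative score of a window is
$(S - S_{\min})/(S_{\max} - S_{\min})$, scaled between the worst and best
achievable match; an `N` contributes its position's worst-case weight. A
matrix whose columns are all uniform has $S_{\min} = S_{\max}$ and is
rejected as degenerate.

`scan_alleles()` scores every window overlapping the SNP, on both strands,
for the reference- and alternate-allele sequence, and classifies each
transcription factor by its best hit against the threshold (default 0.8):
gained, lost, retained, or absent. Only this single relative-score criterion
is implemented; the intersection with a proprietary "conservative core"
criterion used alongside it in some published workflows is not reproducible
from open data and is therefore out of scope, which the output metadata
records. Reproducing specific published hits additionally requires the
original JASPAR matrix versions and the bovine flanking sequences, which the
user must supply.

## The synthetic cohort generator

`default_cohort_config()` encodes the study design the package targets:
44 paternal half-sib families totalling 924 daughters (family sizes 6–62),
each daughter with a unique unrelated dam; 10 biallelic SNPs in two candidate
genes, 7 of which form two haplotype blocks — a 5-SNP block with founder
haplotype frequencies 0.580/0.172/0.094/0.066/0.066/0.022 and a 2-SNP block
at 0.874/0.124 plus a rare 0.002 third haplotype carrying the residual mass
(the published frequencies leave 0.2% unaccounted, most plausibly a rare
third haplotype, and the generator models it as such); and five traits over
two lactations, the second covering 635/924 of the cohort, since the two
lactation cohorts need not coincide.

Family sizes are drawn uniformly from the configured range; because a
uniform 6–62 draw cannot also average 21 daughters per sire, the
configuration additionally fixes the cohort total and rebalances the draws
by random within-range ±1 moves. Genotypes are gene-dropped: founders draw
whole block haplotypes i.i.d. and loose SNP alleles per locus; offspring
receive one gamete per parent with no recombination within a block and free
recombination between blocks — a deliberate idealisation of tight intra-gene
LD that avoids needing a genetic map. Phenotypes are generated from the
analysis model itself, with HYS effects i.i.d. normal per class, calving age
uniform on 22–34 months (+12 for the second lactation), genotype values
coded $(+a, d, -a)$, polygenic effects dropped through the pedigree with
Mendelian-sampling variance $(\tfrac12 - \tfrac14(F_s+F_d))\sigma_a^2$, and
i.i.d. residuals.

Default trait scales are realistic for Holstein-type yields: milk
$\mu = 10{,}250$ kg with $\sigma_a^2 = 4\times10^5$,
$\sigma_e^2 = 8\times10^5$ (heritability $1/3$); fat yield 360 kg with an
embedded SNP effect of $a = 20$, $d = 15$ kg; analogous choices for protein
yield and the percentages. The HYS structure defaults to 10 farms × 3 years
× 4 seasons, coarser than a real multi-farm recording scheme, so that
classes stay populated at $n = 924$ and the fixed-effect design remains
well-conditioned; the counts are configurable.

What the generator does *not* emulate: genotyping error, missingness,
selection and assortative mating, dam relatedness, genetic correlations
between traits (polygenic effects are drawn independently per trait),
lactation-curve dynamics, and real bovine genome coordinates. Passing
recovery tests therefore demonstrates the estimators' correctness under the
stated model, not robustness to real-data pathologies.

## Verification protocols and problem sizes

The test suite pins every nontrivial computation to an independent oracle:
the A matrix to a $10^6$-replicate gene-dropping kinship simulation
(±0.005), the A-inverse to `A %*% Ainv = I` at $10^{-8}$, two-locus EM to
direct haplotype counting on phase-unambiguous data ($10^{-6}$), the
confidence-interval grid to a $10^4$-point refinement, the MME solution to a
dense GLS with explicit $V = ZAZ'\sigma_a^2 + I\sigma_e^2$ on small
instances ($10^{-6}$ relative), and the REML optimum to a $10^4$-point
dense-likelihood grid on a 12-animal fixture (the profile there is nearly
flat, so the comparison is on attained likelihood, not on the argmin).

Stochastic protocols use fixed problem sizes chosen to keep Monte-Carlo
error well inside the asserted margins: variance-component and effect
recovery use medians over 20 cohort replicates at $n = 924$; the Wald test
size uses 400 null replicates at 400 records each on a fixed design
(pedigree held constant, genotypes and phenotypes redrawn), for a binomial
standard error of about 1.1% around the nominal 5%; block recovery uses 20
genotype replicates. Because 924 paternal gametes descend from only 44
sires, a haplotype frequency carries a sampling standard deviation of about
0.03 per replicate — medians across replicates recover the configured truth
closely, while the 0.05 retention filter can misclassify a 0.066 or 0.022
haplotype in a minority of individual replicates; the tests assert the
per-replicate majorities and the median behaviour accordingly.

## Known limitations

Single-trait, single-record analyses only: no repeatability model across
lactations, no multi-trait REML, no genomic relationship matrices. The Wald
chi-square is asymptotic; exact small-sample df corrections are out of
scope. The Gabriel implementation uses the informative-pair rule with the
default thresholds and does not implement the four-gamete or solid-spine
alternatives. Phasing ignores pedigree information (population EM only),
which is slightly less efficient than family-aware phasing for half-sib
data.
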