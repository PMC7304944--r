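---
title: "Models and methods for pseudo-haploid population-genetic inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for pseudo-haploid population-genetic inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoflow)
```

paleoflow implements the statistical core of the ancient-DNA population
workflow: allele-frequency moment statistics (f2, f3, f4) with weighted
block-jackknife errors, matrix rank tests and admixture-proportion
estimation against outgroup panels, admixture-graph fitting with greedy
topology growth, admixture dating from the decay of weighted allele
covariance, and the genotype-level plumbing (EIGENSTRAT triples,
authenticity gating, grouping, kinship screening) those analyses sit on.
This vignette records the models, the numerical choices, and what the
bundled simulator does and does not emulate.

## Data model

Genotypes are alternative-allele dosages (0/1/2, `NA` missing) on a SNP x
sample matrix. Ancient samples are *pseudo-haploid*: a single sequencing
read is drawn at each covered site, so the stored call is a homozygous
dosage carrying one allele of information. We keep one matrix code path
for both ploidies and record the mode per sample; frequency pooling
(`group_freqs()`) exposes an `inbreed` mode in which a pseudo-haploid
sample contributes one allele copy, so the finite-sample bias corrections
(below) see the true number of independent draws.

Jackknife blocks are contiguous 5-Mb windows per chromosome, assigned when
a dataset is constructed. All standard errors in the package are weighted
delete-one-block jackknives over these windows (weights = per-block usable
SNP counts), which is robust to linkage at the scale of typical SNP
panels.

## f-statistics

For groups with observed frequencies $\hat p$ and allele-copy counts $m$:

* $f_2(A,B) = \overline{(\hat p_A - \hat p_B)^2 - h_A/m_A - h_B/m_B}$,
  with $h = \hat p(1-\hat p)\,m/(m-1)$ the unbiased heterozygosity;
  the corrections remove the sampling part of the squared difference.
  Sites with $m = 1$ carry no heterozygosity information and their
  correction is skipped.
* $f_3(C;A,B) = \overline{(\hat p_C - \hat p_A)(\hat p_C - \hat p_B) -
  h_C/m_C}$; significantly negative values demonstrate admixture in $C$.
* $f_4(A,B;X,Y) = \overline{(\hat p_A - \hat p_B)(\hat p_X - \hat p_Y)}$,
  needing no correction.

Identities tie them together: $f_3(C;A,B) = \tfrac12\{f_2(C,A) +
f_2(C,B) - f_2(A,B)\}$ and $f_4(A,B;X,Y) = \tfrac12\{f_2(A,Y) + f_2(B,X)
- f_2(A,X) - f_2(B,Y)\}$. Internally every derived statistic over a fixed
group set is a linear combination of per-block corrected $f_2$ sums on
the shared SNP intersection, which gives exact consistency between the
statistics and a cheap jackknife covariance for any collection of them.
SNP usability is intersection mode by default; `allsnps` mode (each
statistic on its own maximal SNP set) is available where matrices of f4
values are built, and the mode is recorded in every result.

A significance convention of $|Z| > 3$ is used by the homogeneity helper
and is configurable.

## Rank tests and admixture weights

`build_f4_matrix()` assembles $X_{ij} = f_4(l_i, l_0;\; r_j, r_0)$ for a
left and a right population set, with the jackknife covariance of
$\mathrm{vec}(X)$. The number of independent ancestry streams relating
left to right is the rank of $E[X]$: `rank_test()` fits the best rank-$k$
approximation by alternating generalized least squares under that
covariance (deterministic initialization from the unweighted SVD;
relative objective change $< 10^{-10}$ or 1000 iterations) and refers the
residual quadratic form to $\chi^2$ with $(|L|-1-k)(|R|-1-k)$ degrees of
freedom. The classical small-sample form of this test is a Hotelling
$T^2$; with the ~hundreds of genomic blocks used here the scaling factor
is within a percent of 1, so the $\chi^2$ form is used and its
calibration is verified by simulation (null rejection at the nominal 5%
level stays within [0.02, 0.10] in the validation suite). Covariances
with condition number above $10^{12}$ are ridge-regularized by
$10^{-6}\cdot\overline{\mathrm{diag}}$ with a warning.

`qpadm_weights()` estimates mixture proportions for a target from $N$
sources against a disjoint right set: the f4 matrix with left set
$(\text{target}, \text{sources})$ must have rank $N-1$ under the model,
and the weight vector is the left null vector of the fitted rank-deficient
matrix, normalized to sum to one. Standard errors re-run the entire solve
with one block deleted at a time; the model-fit p-value is the rank test
at $k = N - 1$, which makes the internal-consistency identity between the
two exact by construction. Weights are not constrained to $[0,1]$ — as in
standard practice, negative estimates signal a poor model. The weights
are only estimable when the right set relates *differentially* to the
sources; with rights that are clean outgroups to the sources' join the
expected matrix is identically zero and no information about the
proportions exists.

The base populations $l_0, r_0$ are the first listed; the tests verify
invariance of p-values and weights to that bookkeeping choice.

## Admixture graphs

A graph is a rooted DAG of drift edges (f2-scale lengths) and two-parent
admixture nodes with weight $\alpha$. Expected statistics come from edge
lineage probabilities: for each leaf, the probability its ancestry passes
each drift edge is the sum of admixture-weight products over root paths,
and $E\,f_2(i,j) = \sum_e (w_e(i)-w_e(j))^2\,\ell_e$. In the bundled
simulator this expression is exact, not a small-drift approximation,
because drift increments are anchored to the ancestral heterozygosity
(below).

Fitting minimizes the inverse-variance weighted squared deviation of
observed from expected basis statistics $f_3(\text{base}; i, j)$ over all
$i \le j$ — the diagonal terms $f_3(\text{base};i,i) = f_2(\text{base},
i)$ are required, otherwise leaf-specific drift is unconstrained. The
weight matrix is the diagonal of the jackknife covariance (the full
inverse is ill-conditioned for more than a few leaves); the residual
scoring absorbs the difference. Optimization is bounded L-BFGS-B from one
deterministic and several seeded random starts. Fit quality is
`worst_abs_z`, the largest $|Z|$ between observed and expected values over
*all* f2, f3 and f4 of the fitted leaves (a basis-only view is available
through the residual table).

Parameter uncertainty: the default sandwich estimator (Gauss–Newton
curvature with the observed covariance) is fast but understates the
uncertainty of admixture weights when they trade off against attachment
positions along a flat profile; `se_method = "jackknife"` re-optimizes
with each block deleted and is used wherever weight coverage matters.
Mixing weights are well identified only when the unobserved mixing
ancestors are close (in drift) to sampled relatives; the recovery fixtures
are built in that regime, which is also the regime proportion estimation
assumes.

The greedy search attaches each new population to every drift edge
(unadmixed) and to every unordered pair of drift edges (one two-way
admixture), refits every candidate, and keeps the lowest `worst_abs_z`.
Because an admixed attachment nests every unadmixed one, it scores
nominally lower even when the admixture is spurious; candidates within
`tie_margin` (default 0.5, a meaningful |Z| difference) of the best are
treated as tied and resolved toward fewer admixture events, then
lexicographically. Admixed attachments are refused once a global cap
(default 3) is reached. Every candidate's score is retained in a ledger
table.

## Admixture dating

For an admixed target and two source panels, each SNP gets weight
$w = \hat p_A - \hat p_B$ and each target sample the residual of its call
(on the frequency scale) from the pooled least-squares mixture of the
source frequencies. Admixture $g$ generations ago leaves ancestry tracts
of exponential length $1/g$ Morgans, so the covariance of weighted
residuals between linked SNPs decays as $a\,e^{-g d} + c$ in genetic
distance $d$. The curve accumulates per-sample pair products (summed over
samples by a single cross-product per chromosome) in 0.1-cM bins;
accumulating per sample rather than on the sample-averaged frequency
preserves each sample's tract realization as an independent draw, which
is what makes $g$ estimable from modest panels. The affine term $c$
absorbs assortative/background covariance and is reported.

The fit profiles the exponential rate (amplitude and offset solved in
closed form at each candidate rate), then polishes all three parameters
with L-BFGS-B; this inverts noiseless curves to ~$10^{-7}$ and is robust
to poor initialization on noisy ones. The fit range defaults to
0.45–50 cM: the simulator generates no background LD, but in real data
distances below ~0.45 cM are dominated by it, and the convention is kept
so defaults transfer. Standard errors on $g$ are delete-one-chromosome
jackknives; dates in years use a generation time of 28.5 years. If the
fitted rate or amplitude is not positive the result is flagged as having
no admixture-date signal rather than quoting a date.

## The simulator

`simulate_frequencies()` draws ancestral frequencies $p_0$ from
Uniform(0.1, 0.9) by default, then evolves them down the graph with
Beta (Balding–Nichols parameterization) increments of mean equal to the
parent frequency and variance $\ell_e\,p_0(1-p_0)$, mixing linearly at
admixture nodes. Anchoring the variance to the *ancestral*
heterozygosity makes expected f-statistics exactly linear in branch
lengths, with the single proportionality constant
$E[p_0(1-p_0)]$ (`ancestral_het()`), so simulation and path-based
expectation can be compared without approximation error. The Beta law
avoids boundary atoms at 0/1; where the target variance is infeasible for
a Beta it is capped at 95% of the maximum, a guard that matters only for
extreme drift.

`sample_dataset()` lays SNPs evenly over chromosomes with a constant
recombination map and draws Binomial(2, p) dosages for diploids, a single
Bernoulli(p) allele for pseudo-haploids, and independent missingness.
`simulate_admixture_tracts()` generates haplotypes as mosaics of
exponential ancestry segments with per-segment source choice, recording
the generating truth. The defaults used in the validation suites are the
regime the corresponding methods are used in: an 8-leaf graph with drift
lengths of 0.01–0.08 for structure statistics; for dating, source panels
separated by $f_2$ drift 0.25 on each side (a continental-scale
contrast), a 50/50 pulse, and 1,000 SNPs per 1-Morgan chromosome.

What the simulator does *not* emulate: background linkage disequilibrium
within source populations, ancient-DNA damage and contamination (QC
metrics are consumed as a table, not generated from reads), reference
bias, SNP ascertainment, and mutation. Passing tests therefore validate
the estimators under their own model assumptions — unbiasedness,
calibration, parameter recovery, and internal consistency — not
robustness to those real-data artifacts.

## Problem sizes in the validation suites

The test and acceptance runs use 4,000–50,000 SNPs, 4–16 samples per
group, 200 genomic blocks, 200 null replicates for calibration, 20
replicates for greedy-search recovery, and 200 haplotypes over ten
1-Morgan chromosomes for dating — sizes chosen so each estimator's
uncertainty is small relative to the effect being validated while the
whole suite remains quick on a single CPU.

## Known limitations

* qpAdm here implements the single fixed left/right protocol of the
  classical workflow, not rotating model competition.
* The greedy search explores single-leaf additions with at most one
  admixture per addition, as in the published procedure; it does not
  revisit earlier attachments.
* Rank tests use the $\chi^2$ residual form; with very few blocks a
  small-sample correction would be needed.
* Graph mixing weights are reported with honest (jackknife) errors, but
  remain weakly identified in geometries where the mixing ancestors carry
  substantial private drift; the ledger of candidate fits should be
  inspected rather than trusting a single winner when scores are close.
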