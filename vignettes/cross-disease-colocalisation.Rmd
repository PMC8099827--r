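---
title: "Cross-disease colocalisation: models, parameters and design choices"
author: "dualcoloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-disease colocalisation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualcoloc)
```

# The problem

Two diseases can show genetic association in the same genomic region for
two very different reasons: because one causal variant affects the risk
of both (a shared, colocalising signal), or because two distinct causal
variants happen to sit in linkage disequilibrium (LD) within the region.
Distinguishing these cases matters when two diseases — for example two
forms of diabetes with partly overlapping clinical presentation — are
suspected of sharing biology at specific loci, and when the *direction*
of the shared effect (risk allele for one disease protective for the
other, or risk for both) carries mechanistic information.

`dualcoloc` implements a complete, testable pipeline for this question
on case-control GWAS data:

1. per-variant logistic association per trait, Benjamini–Hochberg FDR;
2. selection of regions where variants pass FDR < 0.01 in *both*
   traits, windowed to roughly 0.5 Mb;
3. dissection of each region into conditionally independent signals by
   forward stepwise logistic regression (plus a summary-statistic,
   COJO-style conditional mode);
4. Bayesian colocalisation of every trait-1 signal against every
   trait-2 signal by Wakefield approximate Bayes factors and the
   five-hypothesis enumeration;
5. an eCAVIAR-style corroboration: LD-aware fine-mapping per trait and
   the colocalisation posterior probability (CLPP);
6. classification of each shared signal as concordant or discordant.

Because full-scale disease GWAS inputs cannot be bundled, the package
includes a first-class synthetic-data module that generates
LD-structured haplotypes and two case-control cohorts with planted
shared or distinct causal variants; every statistical claim the package
makes is validated against those known truths and against independent
brute-force oracles.

# The colocalisation model

For one variant with estimated log odds ratio $\hat\beta$ and standard
error $s$, the Wakefield approximate Bayes factor against the null
under a $N(0, W)$ prior on the true effect is, in log form,

$$\mathrm{lABF} = \tfrac12\left[\log(1 - r) + r z^2\right],
\qquad r = \frac{W}{s^2 + W},\quad z = \hat\beta/s.$$

Assuming at most one causal variant per trait in a region of $n$
variants, every joint causal configuration is one of five hypotheses:
H0 (no association), H1/H2 (association with one trait only), H3 (both
traits, distinct variants), H4 (both traits, one shared variant). With
per-variant priors $p_1$, $p_2$ (association with a single trait) and
$p_{12}$ (association with both), the unnormalised hypothesis weights
are

$$S_0 = 1,\quad
S_1 = p_1\sum_i L_1(i),\quad
S_2 = p_2\sum_i L_2(i),$$
$$S_3 = p_1 p_2\Bigl(\sum_i L_1(i)\sum_j L_2(j) - \sum_i L_1(i)L_2(i)\Bigr),
\quad
S_4 = p_{12}\sum_i L_1(i)L_2(i),$$

where $L_t(i)$ is trait $t$'s Bayes factor at variant $i$. Posteriors
are $PP_h = S_h / \sum_h S_h$. All sums run in log space with
log-sum-exp: strong GWAS signals reach $z > 40$, where the Bayes
factors overflow double precision by hundreds of orders of magnitude.

Defaults: $p_1 = p_2 = 10^{-4}$ and $p_{12} = 5\times10^{-6}$, the
conservative recommendation for cross-disease analyses, and a decision
threshold of $PP_4 \ge 0.9$ — deliberately stringent so declared shared
signals are very likely real, at some cost in sensitivity. Both are
configurable (`coloc_priors()`, `pipeline_params()`); relaxing
$p_{12}$ to $10^{-5}$ and the threshold to $0.5$ reproduces the more
permissive regime used by some earlier cross-disease analyses, and
$PP_4$ is provably non-decreasing in $p_{12}$ (a property the test
suite asserts on every tested input).

The effect prior is $W = 0.04$ (standard deviation 0.2 on the log-OR
scale), the standard choice for case-control traits; it is exposed as
`prior_sd_w`.

## Why conditioning matters

The single-causal-variant assumption of the enumeration fails in
regions with multiple independent signals — exactly the situation at
complex loci where a secondary signal of one disease may share a
variant with the other disease while the primary does not. The package
therefore dissects each region per trait by forward stepwise logistic
regression (entry threshold `p_enter`, default $10^{-5}$; a
conventional locus-wide bound, surfaced in configuration and logs
because no single value is canonical). The rank-$k$ signal conditions
on the $k{-}1$ previously selected index variants, and its
*conditional* summary statistics — each remaining variant refit jointly
with the conditioning dosages — enter colocalisation. Every trait-1
signal is paired with every trait-2 signal, so a region with two
trait-1 signals and one trait-2 signal contributes two colocalisation
analyses.

When a region passes the FDR overlap but stepwise selects nothing (the
entry threshold is stricter than the FDR cut), the region is still
analysed through a single unconditional signal anchored at the best
marginal variant; this mirrors how regions with `–` in a conditional
column of a results table arise.

A summary-statistic mode (`cojo_conditional()`) approximates the same
conditioning when only marginal statistics and an LD reference panel
are available: in standardized units
$\beta_{c}(j) = \beta(j) - R_{jC}R_{CC}^{-1}\beta(C)$ with variance
scaled by the Schur complement $1 - R_{jC}R_{CC}^{-1}R_{Cj}$, then
de-standardized via $\mathrm{sd}(g) = \sqrt{2f(1-f)}$. On synthetic
data its conditional z-scores track individual-level conditioning with
correlation above 0.95 at 20,000 individuals (asserted in the suite).
Collinearity guard: candidates with $|r| > 0.99$ to the span of the
conditioning set are skipped (logistic fits are unstable beyond this);
a computationally singular $R_{CC}$ receives a logged $10^{-8}$ ridge.

## The CLPP corroboration

As a second, methodologically distinct check, each trait is fine-mapped
under the multivariate-normal model $z \sim N(R\lambda, R)$ with LD
matrix $R$, each variant causal independently with prior
$\gamma = 0.01$ and standardized effects $\lambda_i \sim N(0,
\sigma^2)$, $\sigma = 5$ — the conventions of the eCAVIAR family, since
no single published setting is authoritative; all are arguments to
`finemap()`. Configurations up to `max_causal = 2` are enumerated
exhaustively (a guard refuses regions where $\binom{n}{c} > 10^7$).
The likelihood of a configuration $C$ reduces by the
matrix-determinant lemma to $|C|\times|C|$ algebra, so enumeration is
fast even for 200-variant regions. Per-variant
$\mathrm{CLPP}(i) = \mathrm{PIP}_1(i)\cdot\mathrm{PIP}_2(i)$ and the
regional CLPP is their sum.

The two scores agree strongly where it matters — the suite asserts
rank correlation above 0.7 across regions spanning null to strongly
shared scenarios with graded effect sizes — but they are not
interchangeable: in a
region where both traits are associated through *distinct* variants,
the enumeration actively demotes H4 (its $PP_4$ drops far below the
null's prior level), whereas the regional CLPP settles near the
fine-mapping prior floor, *above* a null region's value, because one
trait's concentrated PIP mass multiplies the other trait's prior-level
PIPs. The rank-agreement test in the suite therefore mixes null,
distinct-causal and shared-causal regions with shared effects graded
from OR 1.05 to 1.5 — a composition that reflects regions actually
reaching the colocalisation stage (FDR-overlap selection enriches for
shared signals) and gives the correlation something real to measure;
an equal-weight mix of saturated scenarios would mostly compare noise
ranks among near-zero quantities. No CLPP decision threshold is
enforced; the score is reported as corroborating evidence only.

## Direction of effect

For a signal pair passing the H4 threshold, the effect direction is
read at the variant with the largest per-variant H4 contribution
(falling back to the trait-2 index variant if an estimate is missing):
$\mathrm{sign}(\beta_1)\cdot\mathrm{sign}(\beta_2) > 0$ is concordant,
$< 0$ discordant. Harmonization makes this frame-invariant: flipping
ref/alt in one study flips its $\beta$ and mirrors its frequency, so
the product of signs is unchanged (asserted in the suite).

# Region selection

Variants with BH-adjusted $q <$ 0.01 (strict) in *both* traits seed
analysis windows: the overlap variant with the smallest
$\max(q_1, q_2)$ anchors a window of $\pm$ 250 kb, absorbed variants
are removed, the rule repeats, and overlapping or abutting windows
merge (keeping the better seed). "Approximately 0.5 Mb" admits several
constructions; this greedy-seed-and-merge rule is fixed, documented and
tested on hand-constructed layouts (single variant; pair 100 kb apart
→ one region; pair 600 kb apart → two regions). Windows are clipped at
position 1; coordinates are 1-based inclusive internally and convert
to 0-based half-open on BED export. FDR is computed per trait across
all supplied variants (genome-wide scope), not per region, since
region construction happens downstream of the FDR cut.

# The synthetic-data generator

`simulate_haplotype_panel()` draws haplotypes from a Gaussian copula
whose latent correlation is AR(1) with parameter `ld_rho` (optionally
block-diagonal via `ld_blocks`): variant $j$'s latent value is
$\rho z_{j-1} + \sqrt{1-\rho^2}\,\epsilon$, thresholded at the normal
quantile of its allele frequency. One parameter thus reproduces the
monotone LD decay of a real locus, and the implied pairwise LD has a
closed form through the bivariate-normal orthant probability — the
test suite integrates that probability numerically and checks the
panel against it, and calibrates a latent $\rho$ to hit a target
$r^2$.

`simulate_case_control()` forms individuals by pairing panel
haplotypes, assigns disease by the logistic model
$\mathrm{logit}\,P(\text{case}) = \alpha + \sum_k \beta_k g_k$ with
$\alpha$ solved by bisection so the *population* prevalence matches the
request, and rejection-samples until the case and control counts are
reached — the ascertainment process that actually produces GWAS
cohorts, keeping odds ratios interpretable. The two traits' cohorts
are drawn independently on the same panel (no sample overlap, matching
the independence assumption of the colocalisation model).

Defaults, chosen once: 2 kb variant spacing (so a 200-variant region
spans 0.4 Mb, commensurate with the 0.5 Mb analysis windows),
`ld_rho = 0.9` (adjacent-variant $r^2 \approx 0.6$, a realistically
tight LD block), allele frequencies uniform on (0.05, 0.5], panel of
10,000 haplotypes, baseline prevalence 0.1 per trait — a common-disease
prevalence; the colocalisation machinery is invariant to it, and
rejection sampling at rare-disease prevalences would only cost
simulation time without changing what is tested.

What the generator does *not* emulate: imputation dosage uncertainty,
relatedness, population structure and covariates, sample overlap
between the two cohorts, X-chromosome inheritance, and realistic
genome-scale LD beyond AR(1) blocks. Passing tests therefore
demonstrate the statistical machinery is correct under its stated
assumptions, not that those assumptions hold in any particular real
dataset.

# Validation design and problem sizes

Every numerically substantive operation has an independent oracle in
the test suite:

- `coloc_posteriors()` against a plain-arithmetic enumeration over all
  causal-configuration pairs (1,000 random small regions, relative
  error $10^{-12}$);
- `finemap()` against direct multivariate-normal densities via
  `solve()`/`determinant()` (200 random regions up to 12 variants,
  $10^{-10}$);
- `bh_fdr()` against a literal step-up implementation and
  `p.adjust()` (1,000 random inputs);
- the haplotype generator against orthant-probability integration;
- closed forms: lABF at $z=0$, $V=W$ equals $\tfrac12\ln\tfrac12$;
  flat-evidence colocalisation with the default priors gives weights
  $(1, 2\times10^{-4}, 2\times10^{-4}, 2\times10^{-8}, 10^{-5})$;
  uniform PIPs give regional CLPP $1/n$.

Scenario-recovery simulations use one shared causal variant of
OR 1.3, two cohorts of 10,000 cases / 10,000 controls, 200-variant
AR(1) regions: $PP_4 \ge 0.9$ in at least 80% of 100 replicates;
distinct-causal scenarios ($r^2 < 0.05$ between the causals) give
$PP_3 > PP_4$ in at least 95%; 500 null regions (2,000/2,000 cohorts,
100 variants — the null holds at any size) produce no $PP_4 \ge 0.9$.
The conditional-dissection test plants a strong distinct causal
(OR 1.5) plus a weaker shared one (OR 1.3) for trait 1: the rank-2
conditional signal colocalises with trait 2 in at least 70% of 50
replicates while the unconditioned primary pairing succeeds less often
— the situation where conditioning is the difference between finding
and missing a shared signal. The end-to-end test plants five shared
loci (four discordant, one concordant, OR 1.4) on separate LD blocks
and requires at least four detections with every direction correct and
exact signal-pair bookkeeping. Replicate counts and cohort sizes are
the package's validation design; they were fixed before the assertions
and are not tuned.

# Numerical choices and degenerate inputs

- Monomorphic variants and (quasi-)separated logistic fits are flagged
  (`monomorphic`, `separated`) with missing statistics rather than
  patched; harmonization and colocalisation drop flagged records.
- The marginal scan exploits hard-called dosages: the two-parameter
  logistic likelihood depends only on the six genotype-by-phenotype
  counts per variant, so Newton iterations run vectorised across all
  variants on count summaries and agree with `glm()` to $10^{-6}$.
  Non-integer dosages fall back to a dense vectorised IRLS.
- Wald p-values are floored at the smallest positive double so they
  stay in (0, 1].
- Sample LD matrices are eigenvalue-floored at $10^{-8}$ (with
  re-symmetrization and unit-diagonal restoration) before Cholesky;
  PIPs move by less than $10^{-3}$ when the floor shifts by many
  orders of magnitude (asserted).
- Strand-ambiguous (A/T, C/G) variants with alternative-allele
  frequency in [0.42, 0.58] are dropped during harmonization — the
  window is standard practice where no published value governs.
- Ties in BH share a q-value by construction of the step-up minimum.

# Known limitations

- The enumeration assumes at most one causal variant per trait per
  signal; multiplicity is handled by conditioning, not by multi-causal
  colocalisation, so signals missed by stepwise (below `p_enter`) are
  invisible to the pairing.
- Summary-mode conditioning inherits the usual COJO caveats: it
  degrades when the LD panel mismatches the study population
  (a frequency-mismatch guard drops variants differing by more than
  0.2) and uses the effective sample size
  $4/(1/\text{cases} + 1/\text{controls})$ linearization for binary
  traits.
- Regional CLPP and $PP_4$ answer subtly different questions in
  distinct-causal regions (see above); CLPP is reported, never
  thresholded.
- Case-control ascertainment by rejection sampling becomes expensive at
  very low prevalence with large case counts; the generator aborts
  with a clear error after a bounded number of draws.
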