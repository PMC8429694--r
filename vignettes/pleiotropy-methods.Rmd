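---
title: "Statistical methods for genic and allelic pleiotropy of de novo variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for genic and allelic pleiotropy of de novo variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnmpleio)
```

## The scientific question

Trio sequencing studies of severe neurodevelopmental disorders (NDDs) and
of schizophrenia each implicate rare coding de novo variants. Two distinct
forms of shared aetiology can be asked about:

* **genic pleiotropy** — do the *genes* enriched for de novo variants in
  NDDs also accumulate de novo variants in schizophrenia, and if so, in
  the *same mutation class* (protein-truncating vs missense)?
* **allelic pleiotropy** — are the *identical alleles* observed de novo in
  NDD probands seen again, de novo, in schizophrenia probands more often
  than mutation rates predict?

`dnmpleio` implements the full statistical machinery for both questions,
plus a case-control burden replication, and a seeded synthetic-cohort
generator so that every claim the statistics make can be checked as
parameter recovery against a known ground truth.

## The null model

Every test rests on the same null: de novo events at a set of units
(alleles or genes) arise as a Poisson process with mean

$$\lambda = \sum_{u} O(\mathrm{chrom}_u)\, \mu_u,$$

where $\mu_u$ is the per-generation per-haploid-genome mutation rate of
the unit and $O$ is the number of transmissible parental haplotypes the
cohort offers: $2N$ trios on autosomes and $N_{male} + 2N_{female}$ on X
(one transmissible maternal X meiosis for male probands, two for female
probands). The X correction is a package decision — the source data for
per-gene expectations do not pin it down — and `x_as_autosome = TRUE`
switches to the flat $2N$ convention everywhere.

Allele-level rates come from a trinucleotide context model: 64 reference
3-mers $\times$ 3 alternate bases, strand-collapsed to 96 canonical
entries (the canonical representative is the lexicographically smaller of
a context and its reverse complement; no 3-mer is its own reverse
complement, so the map is well defined and involutive). Gene-level rates
are per-gene class rates ($\mu_{PTV}, \mu_{mis}, \mu_{syn}$), optionally
multiplied by a per-gene sequencing-coverage factor in $(0,1]$ supplied as
input, never computed. Indel rates are not modelled; indel records are
excluded from every expectation-based de novo test and retained only for
the case-control burden analysis.

## Variant classification and strata

PTVs are stop-gain, frameshift and canonical splice donor/acceptor
variants. The **primary** pathogenicity stratum contains PTVs in
loss-of-function-intolerant genes (pLI $\ge$ 0.9) and missense variants
with MPC $\ge$ 2; everything else is the **comparator** stratum. Both
thresholds are exposed as configuration. The MPC boundary is implemented
as $\ge 2$ (inclusive): published descriptions of this design vary
between "MPC > 2" and "MPC $\ge$ 2", and the inclusive rule is the one
consistent with the variant lists (a shared risk allele with MPC exactly
2.16 near the boundary motivates caring); the strict rule is one config
switch away. Missing MPC is treated as below threshold and missing pLI as
0, so incomplete annotation can only demote a variant into the comparator
set — conservative for the primary-set test. Records on Y or MT are
rejected at ingest; X records are retained.

Gene strata use gene-level NDD association P values at exome-wide
significance ($P < 2.5\times10^{-6}$): PTV-specific, missense-specific,
and independently-both, pairwise disjoint by construction.

## The tests

**One-sample exact Poisson test** (`poisson_exact_test`): observed count
$x$ against $\mathrm{Poisson}(\lambda)$. The two-tailed P value uses the
point-probability rule — the sum of all outcome probabilities not
exceeding the observed outcome's probability, with relative tie tolerance
$1+10^{-7}$ — matching the de facto reference behaviour of exact Poisson
tests; `two_sided_rule = "doubled"` gives $\min(1, 2\min(\text{tails}))$
instead. The 95% CI on the rate ratio $x/\lambda$ is the exact
chi-square (garwood) interval $[\tfrac12\chi^2_{\alpha/2}(2x),
\tfrac12\chi^2_{1-\alpha/2}(2x+2)]/\lambda$, with lower bound 0 at
$x = 0$. P values are computed by direct summation over the Poisson
support (the expectations in this problem are small), and chi-square tail
probabilities use the survival function, never $1 - \mathrm{CDF}$.

**Two-sample exact rate-ratio test** (`two_sample_poisson_test`):
conditioning on the total, $X_1 \mid X_1{+}X_2 \sim
\mathrm{Binomial}(x_1{+}x_2, \lambda_1/(\lambda_1{+}\lambda_2))$ under the
null of equal observed/expected ratios. This is how the gene-set analyses
control for the modest cohort-wide elevation of the de novo rate: the
background arm is "all genes outside the set". The reported rate ratio
$(x_1/\lambda_1)/(x_2/\lambda_2)$ and its Clopper–Pearson-derived CI are
invariant to rescaling both expectations by any common factor.

**Class-congruence test** (`class_congruence_test`): is the gene-set rate
ratio larger for PTVs than for missense variants? Per class, a two-cell
offset-Poisson regression of (in-set, out-of-set) counts on set
membership is saturated, so its ML solution is closed form: $\beta_c =
\log\frac{x_{in}/\lambda_{in}}{x_{out}/\lambda_{out}}$ with
$\mathrm{var}_c = 1/x_{in} + 1/x_{out}$. The statistic
$(\beta_1-\beta_2)^2/(\mathrm{var}_1+\mathrm{var}_2)$ is referred to
$\chi^2_1$; $\exp(\beta_1-\beta_2)$ is the ratio of rate ratios. Because
each class has its own out-of-set cell, the background enrichment is
allowed to differ between classes. With a zero cell the ML estimate is
not finite; the package then uses the Firth-penalised saturated fit,
which in closed form is the $+\tfrac12$ adjustment to every count (hat
values are 1 in a saturated model), and flags the result.

**Genome-wide pleiotropy regression**
(`genomewide_pleiotropy_regression`): per-gene counts
$y_g \sim \mathrm{Poisson}$ with
$\log \mathbb{E}[y_g] = \log\lambda_g + \beta_0 + \beta_1(-\log P^{PTV}_g)
+ \beta_2(-\log P^{mis}_g) + \ldots$, dropping genes without both P
values (mirroring the source tables, where about a third of genes lack a
missense statistic). $-\log$ is the natural log by default
(`log_base` configurable). The fit is IRLS (`stats::glm`) at relative
tolerance $10^{-10}$, capped at 100 iterations with an explicit
non-convergence error. Brain expression and observed/expected constraint
enter as optional appended covariates.

**Firth burden test** (`firth_burden_test`): one-tailed case-control
burden replication, adjusting for 10 ancestry principal components,
exome-wide synonymous burden, sequencing platform and sex. The penalised
likelihood $l^*(\beta) = l(\beta) + \tfrac12\log\det X^{\top}WX$
(Jeffreys prior) is maximised by Newton iteration with step-halving;
estimates are finite even under complete separation. The burden P value
is the penalised likelihood-ratio test of the burden coefficient, halved
in the direction of excess risk; confidence limits are
profile-penalised-likelihood bounds. `penalty_weight = 0` recovers
ordinary maximum likelihood, which the test suite uses to cross-check
against `glm`. The implementation is self-contained Newton–Raphson
because the profile machinery needs fits with pinned coefficients.

Case-control variant lists are restricted to ultra-rare alleles by the
reference-database filter (`gnomad_ac_filter`, allele count $\le 5$;
absent means kept); indels are included here.

## The synthetic world

`make_world` builds the generative ground truth: genes on autosomes and X
(default 4% X-linked), each with `sites_per_gene` mutable-site bins of 3
alternate alleles, class annotations, an MPC landscape for missense
alleles (a configurable fraction above 2), a pLI mixture (a configurable
fraction above 0.9), and gene-level NDD P values that are uniform for
null genes and spiked below $2.5\times10^{-6}$ for the named risk sets
(default sizes 127 / 103 / 53, matching the strata sizes the gene-set
analyses are designed around). Per-gene class rates are *defined* as the
sum of their site-allele rates — `validate_world` checks this exactly —
so the simulator and the expectation engine cannot drift apart.

Site bins are aggregated mutational opportunity, not single base pairs: a
default of 40 bins per gene with `rate_scale = 25` on the trinucleotide
table yields realistic per-gene class rates (PTV rates around
$10^{-6}$, cohort totals of a few hundred events at trio counts in the
thousands) while keeping worlds of up to ~13,000 genes comfortably in
memory. The trade-off is deliberate and only affects how many distinct
alleles carry the rate mass, not any expectation or test statistic.

`simulate_trios` draws each site-allele's event count as
$\mathrm{Poisson}(O(\mathrm{chrom})\,\mu\,\gamma)$ — valid because
per-site rates are far below 1 — and expands counts into variant records,
so recurrent alleles (the same allele in two probands) occur naturally
and are collapsed downstream by `deduplicate_variants`. Enrichment is
injected through `enrichment_spec`: multiplicative factors $\gamma$ per
(gene set, class), per gene (a named vector, used for continuous
alternatives such as $\gamma_g = e^{0.15(-\log P_g)}$), or per allele
set; $\gamma \equiv 1$ is exactly the null.

`simulate_case_control` assigns primary-set carrier status from a
logistic model in which case status shifts the log-odds by
$\log(\mathrm{OR})$ on top of small covariate effects, so the true
covariate-adjusted odds ratio is the injected one. Defaults mirror a
realistic replication cohort: 4070 cases, 5712 controls, a control-arm
carrier rate of 0.0023. The NDD cohort builder uses a 50/50 proband sex
split for the developmental-disorder cohort and 80/20 male for the
autism cohort — field-typical values, chosen once, not fitted.

What the generator does **not** emulate: real sequence context (3-mers
are drawn, not read from a genome), linkage between sites, indels,
annotation error, relatedness and ancestry structure in the trio cohorts,
and case-control genotype-level data (burdens are generated directly).
Passing recovery tests therefore demonstrates that the statistics are
correct and calibrated under the stated model, not that the model
captures every failure mode of real cohort data.

## Numerical and design choices

* Exact-test P values by direct summation over a support window of
  $\lambda + 20\sqrt{\lambda} + 100$; error far below $10^{-12}$ for the
  $\lambda$ this problem produces.
* Two-tailed rule: point-probability by default, doubled-tail by config;
  both are exposed because published exact tests differ silently.
* A printed expectation of 1.20 with 9 observed gives $P =
  4.9\times10^{-6}$; the unrounded expectation $\approx 1.203$ gives
  $5.0\times10^{-6}$ and reproduces the printed rate ratio 7.48 and CI
  (3.42, 14.20). The package always reports full precision and leaves
  rounding to the display layer.
* With only a total per-gene missense rate available, the one-sample
  expectation for the MPC-filtered missense class is not identifiable;
  the two-sample in-set vs out-of-set contrast is unaffected because the
  MPC-qualifying fraction of the rate cancels between arms (exactly, in
  expectation, in the synthetic world). The gene-set analyses therefore
  use only the two-sample form, and the allelic analysis — where rates
  are per-allele — uses the one-sample form.
* The allelic pipeline's secondary contrast (risk-allele enrichment vs
  the cohort-wide constrained de novo background) needs an expectation
  for "all constrained sites". Synthetic worlds provide it exactly via
  `expected_constrained_background`; for gene-table-only runs a
  configurable `mpc_rate_fraction` (default 0.07) scales the missense
  rate, and the result should be read as approximate.
* Duplicate records with conflicting annotations resolve first-seen-wins
  with a warning; conflicting strand-equivalent rate-table rows are an
  error.
* All simulations take explicit integer seeds; identical seeds give
  byte-identical outputs end to end. Cohorts that should be independent
  must use distinct seeds: two cohorts simulated from the same world
  with the same seed share an RNG stream and will hit strongly
  overlapping site sets (`make_ndd_variant_lists` consumes `seed` and
  `seed + 1` for its two cohorts, so keep other cohort seeds away from
  that pair).

## Problem sizes used in the checks

The packaged checks run at desk scale, chosen to keep the full suite in
minutes while leaving every comparison statistically informative: a
2,500-gene world with 500 replicates for gene-set recovery ($\gamma = 5$
in a 127-gene set; exact CI coverage $\ge 93\%$), a 13,000-gene world for
the genome-wide regression (injected $\beta = 0.15$ recovered within 3
standard errors, with the standard error itself required to be small),
200 replicates of the Firth replication at the published arm sizes
(median fitted OR within [1.7, 2.1] of a true 1.9), 2,000 null cohorts
for calibration (rejection $\le 6\%$ at $\alpha = 0.05$; the exact test
is conservative), 1,000-table sweeps for the congruence closed form
(agreement to $10^{-8}$), and full enumeration grids for the exact tests
(agreement to $10^{-10}$).

## Known limitations

* Consequence annotation, MPC, per-gene rates and NDD gene-level P
  values are inputs; the package neither re-annotates variants nor
  re-derives gene-level statistics.
* No liftover: all inputs in one run must share a genome build, by
  declaration.
* Single-gene implication is out of scope by design; the statistics
  quantify set-level and genome-wide sharing.
* The Poisson site-level simulator slightly overdisperses relative to a
  per-trio Bernoulli model only when per-site $O\mu\gamma$ approaches 1,
  far outside the regime used anywhere in the package.
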