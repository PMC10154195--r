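---
title: "PTV-burden survival analysis: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PTV-burden survival analysis: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptvsurv)
```

## The problem

Loss-of-function alleles of individual genes can shorten human lifespan, but
each allele is rare: no single protein-truncating variant (PTV) has enough
carriers for a variant-level survival test in a biobank-scale cohort.
`ptvsurv` implements the standard remedy — *burden collapsing*: all
qualifying PTVs in a gene (or pathway, or the whole exome) are collapsed
into one per-sample predictor, which is then tested against censored
survival with a Cox proportional-hazards model, against a phenome of binary
and quantitative traits with logistic and linear models, and screened for a
somatic (clonal-hematopoiesis) origin from read-level evidence.

The hazard model is

$$h(x_i) = h_0(x_i)\, \exp(\beta g_i + \gamma' Z_i),$$

where $x$ is attained age, $g_i$ the burden predictor (carrier indicator
for genes and gene sets, PTV count for exome-wide tests, minor-allele count
for single-variant tests) and $Z_i$ the covariates: baseline age, sex and
ten genotype principal components. $h_0$ is eliminated by partial
likelihood; $\exp(\beta)$ is the reported hazard ratio.

Because a proband's own follow-up covers only part of the lifespan, the
pipeline also builds *proxy* outcomes from reported parental lifespans:
father's and mother's age (censored at the reported age if alive), and a
combined outcome whose time is the sum of both parents' ages with an event
only when both have died. Six outcomes are analysed in total: all probands,
male and female probands, fathers, mothers and combined parents.

## PTV qualification

A variant qualifies for collapsing when it is

1. annotated on the gene's canonical transcript (variants with no canonical
   annotation are dropped and counted, never silently lost);
2. a high-confidence truncation: `stop_gained`, `frameshift`,
   `splice_acceptor` or `splice_donor`, *and* at least
   `end_trunc_distance` base pairs from the transcript end. Truncations in
   the terminal window tend to escape nonsense-mediated decay and are
   demoted to `low_confidence`. The default window is 50 bp, the
   convention of the annotation tools this classifier emulates; the window
   is a plain parameter, so a 50 kb convention is one argument away —
   the right value is genuinely ambiguous in the literature this package
   follows, and we refuse to hard-code a guess;
3. rare: minor allele frequency below `maf_threshold` (default 1%)
   computed **within the designated ancestry subset** with a complete-case
   denominator (missing genotypes leave the denominator; nothing is
   imputed).

Multi-allelic sites are split into biallelic records first
(`split_multiallelic()`); genotype codes for other alternative alleles
become reference, and allelic depths are reassigned per extracted allele.
No left-normalisation of positions is attempted.

## Sample filters and outcome construction

Exclusions are applied in a fixed, logged order: ancestry (both the
genetically inferred flag and self-report must be set), then relatedness
(one member of every pair of second-degree-or-closer relatives removed
uniformly at random under a seed), then outcome-specific rules (adopted
probands, "do not know" parental answers, parental death before age 40,
implausible ages beyond 120 years). Every builder returns an exclusion log,
and `included + excluded = input` is asserted in the test suite for every
path — silent sample loss is treated as a bug.

Parental answers are taken from the most recent assessment visit that
answered them; a repeat visit that left the question blank falls back to
the earlier answer. Ages of living parents are used as censoring times as
reported, without projection to the censoring date, because no defensible
projection rule exists for questionnaire data.

Two deliberate literalisms deserve a note. First, the model uses attained
age as the time axis *and* keeps baseline age as a covariate, without
delayed-entry correction; this mirrors the analysis convention the package
reproduces. The covariate absorbs the cohort's age-structure trend, and a
left-truncation option would change the risk sets — it is off by default
and the interaction is documented rather than silently "fixed". Second,
the per-gene eligibility rule "at least 10 PTVs among noncensored
individuals" is implemented as *carriers with events*, matching the
carrier-indicator burden; an allele-count reading is available via the
same function's inputs.

## The Cox fitter

`fit_cox()` maximises the log partial likelihood by damped Newton
iteration, entirely in R on time-sorted arrays with reverse cumulative sums
over risk sets. Ties use the Efron correction by default (Breslow
selectable); the two agree exactly when no event times are tied, which the
tests assert. Numerical choices:

* step-halving up to 10 times whenever a Newton step would decrease the
  likelihood;
* convergence when the gradient max-norm falls below 1e-6 or the relative
  log-likelihood change below 1e-9, capped at 25 iterations;
* the linear predictor is max-shifted before exponentiation, so large
  coefficients cannot overflow;
* monotone-likelihood escape (the infinite-MLE case, e.g. every carrier
  dying before every non-carrier) is flagged when a coefficient passes 15
  on the log scale, or when the likelihood plateaus while the gradient on
  an escaping coefficient stays large. Flagged fits carry
  `converged = FALSE` and are excluded from scans;
* a constant burden predictor yields a `degenerate` fit object rather than
  an error, so exome scans skip rather than abort;
* p-values are two-sided Wald. The reference implementation in the
  `survival` package is used in the test suite as an independent
  cross-check (agreement to 1e-6 on random fixtures) and never at runtime.

Proportional hazards are checked per coefficient by regressing Schoenfeld
residuals on event time (`schoenfeld_ph_test()`); under
proportional-hazards simulations the 5%-level rejection rate stays below
7%. Genomic inflation uses the printed convention
$\lambda = \mathrm{median}(\chi^2)/0.456$; the analytic $\chi^2_1$ median
0.4549 is available as `constant = "exact"`, and both conventions are
recorded in the output.

The exome-wide significance threshold is fixed by convention at
$0.05 / 20{,}000 / 6 = 4.17\times10^{-7}$ regardless of the realized gene
count — `significance_threshold()` takes the realized count when the
convention is not wanted.

## PheWAS

Binary traits are ICD-style code unions: a sample is a case if the code
appears in any source column (primary, secondary, cause of death; family
history questions union the same way). Traits with fewer than 100 cases
are dropped; quantitative traits need 500 observations, and values
strictly beyond 5 standard deviations of the mean (computed once, from the
original values — a single pass, not iterated) are masked. Quantitative
traits are tested on the raw scale and after an inverse rank-normal
transform $\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$ (Blom offset; ties
share average ranks; missing values propagate).

Binary fits use maximum-likelihood logistic regression; whenever the
burden p-value falls below 0.05 (or separation is detected) the fit is
repeated with Firth's Jeffreys-prior penalty, implemented from scratch:
Newton iteration with step-halving on the penalized likelihood, hat-value
adjusted scores, and a penalized likelihood-ratio p-value obtained by
refitting without the burden column. The penalized LRT, not Wald, is the
default because it remains usable exactly where Firth is needed — under
separation. Sex-stratified scans drop the sex covariate and re-apply the
case-count filter within the stratum. The phenome-wide threshold divides
0.05 by the *configured* phenome size (e.g. 4,130), matching the printed
derivation rather than the post-filter count.

## Somatic origin from read evidence

The variant allele fraction of a germline heterozygote centres on 0.5;
clonal somatic variants sit below it. VAF is reported descriptively and
never used alone as a classifier — the deciding evidence is phasing
against a nearby common SNP (MAF > 1%) heterozygous in the carrier. Four
fragment patterns are counted: (1) PTV-ref/SNP-ref, (2) PTV-ref/SNP-alt,
(3) PTV-alt/SNP-ref, (4) PTV-alt/SNP-alt; mate pairs count once, and
fragments whose mates disagree are discarded. A germline PTV occupies one
haplotype — patterns (3)+(2) or (4)+(1) only. A somatic PTV arose in a
cell subpopulation, so PTV-ref fragments appear on *both* haplotypes:
observing (3) with (1), or (4) with (2), calls the variant somatic.

`min_support` (default 2 fragments) guards each required pattern. With a
known flat error rate, the *presence* floor is raised to just above the
99.9% binomial quantile of the fragments that errors alone would
contribute, because one or two miscalled bases can otherwise fake the
complementary pattern; with `error_rate = 0` the classifier is exactly the
count rule. Evidence from several SNPs for one PTV is combined by voting,
somatic calls winning — somatic phasing is positive evidence, a clean
pattern at another SNP is merely absence of it.

## The synthetic cohort generator

No individual-level biobank data can ship with a package, so every
statistical claim is exercised on seeded synthetic cohorts with recorded
ground truth (`sim_config()`, `simulate_cohort()`). The generator emulates:

* **Mortality**: Gompertz baseline $h_0(t) = b\,e^{at}$ with defaults
  $a = 0.09/\mathrm{yr}$, $b = 4.5\times10^{-5}/\mathrm{yr}$, putting the
  median death age near 80 years, plus a male excess log-hazard of 0.45.
  Carrier effects enter as proportional hazards, so the generated data
  satisfy the fitted model's assumption by construction (Schoenfeld
  calibration is tested).
* **Censoring** emerges from dates: recruitment at ages 40-69 around 2008,
  censoring in June 2020, so attained censor ages span roughly 52-82.
* **Parental proxies**: parental genotypes are simulated explicitly — a
  germline heterozygous proband has exactly one carrier parent, chosen at
  random — so the power loss of proxy phenotypes arises from transmission,
  not from an ad hoc attenuation factor. Somatic carriers' parents are
  non-carriers. Configured rates add adoption, "do not know" answers and
  parental deaths before 40.
* **Variants**: per-gene carrier frequencies in (0, 1%]; read depths
  Poisson (mean 30) with alt counts binomial at the true VAF — 0.5 for
  germline carriers, Uniform(0.05, 0.40) for somatic ones. Every filter
  rule gets decoys on both sides: missense/synonymous variants, a
  near-transcript-end truncation, a common (MAF ≥ 1%) PTV,
  a non-canonical-only annotation and a shared-position pair that becomes
  a multi-allelic VCF record.
* **Phenome**: binary traits across the prevalence range including one
  with exactly 99 cases, a planted odds-ratio trait, quantitative traits
  with heavy-tailed (t, 4 df) noise, planted >5-s.d. outliers, a
  499-observation trait, and a coded-events table for aggregation tests.
* **Reproducibility**: one global seed; each component derives its own
  substream by integer hashing of a text label, so outputs are
  byte-identical for a fixed seed and adding a generator never perturbs
  the draws of another.

What the generator does *not* emulate — and therefore what green tests do
not establish about real data: linkage disequilibrium, sequencing-error
structure beyond a flat substitution rate, genuine population
stratification (the PC columns are pure noise), informative censoring,
shared household environment, and reporting biases in parental ages beyond
simple non-response. A default of note: with shape fixed at 0.09/yr, the
Gompertz rate constant 4.5e-5/yr was chosen by inverting
$t_{med} = \ln(1 + a\ln 2/b)/a$ for a median death age of 80; a commonly
quoted rate near 2e-5 would push the median to ~89.

## Study sizes

The packaged simulation studies use: 10,000 null genes in a cohort of
6,000 for type-I error and genomic inflation — the scan size is set by the
inflation factor, whose median-based estimate has standard deviation
~0.074 at 1,000 genes but ~0.023 at 10,000, and each gene retains
~15-25 carrier events so the per-gene Wald test stays calibrated; 200 replicates of a
20,000-sample cohort (carrier frequency 0.003, HR 2.5, ~30% events) for
Cox coverage; 200 replicates of 50,000 samples (prevalence 1%, OR 5,
carrier frequency 0.005) for logistic coverage; 50 random fixtures
(n ≤ 200) for oracle agreement; 8,000 samples at depth 30 for the VAF
contrast; and 40 carriers × 40 fragments for phasing. These sizes make the
Monte-Carlo error comfortably smaller than each pass band while keeping a
full run in minutes on a laptop.

## Known limitations

* Wald inference only for the Cox model (no likelihood-ratio or score
  intervals); penalized Cox regression is out of scope.
* No frailty, stratified baselines, time-varying covariates or competing
  risks.
* The relatedness filter removes one member per pair greedily; it does not
  attempt a maximum independent set.
* The VCF writer emits a minimal GT:AD representation sufficient for this
  pipeline, not a general-purpose VCF library.
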