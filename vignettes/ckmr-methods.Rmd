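---
title: "Close-kin mark-recapture for lethally sampled populations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Close-kin mark-recapture for lethally sampled populations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckmrseal)
```

## The estimation problem

Close-kin mark-recapture (CKMR) estimates abundance and demographic
parameters from the kin relationships found among sampled animals. Each
animal's genotype "marks" its parents: observing a parent-offspring pair
(POP) is a direct recapture of a parent, and observing a half-sibling pair
(HSP) is an indirect recapture of a shared mother or father. For a given
sample size, small populations yield more kin pairs than large ones; the
kinship probability formulae make that intuition quantitative and
attribute the right information to survival, fecundity and breeding
behaviour. `ckmrseal` implements the variant of CKMR developed for
harvested bearded seals: all samples are lethal (the sampling year is the
death year), ages come from tooth annuli and are treated as exact, and the
second-order kin class pools half-siblings with grandparent-grandchild
pairs (GGPs), which are genetically indistinguishable from HSPs.

## Demographic model

An age-structured, two-sex model with age classes $a = 0,\dots,39$ (pups
to a 40-year lifespan) underlies every kinship probability. Annual
survival follows the reduced additive Weibull (RAW) hazard, whose
cumulative survivorship is

$$S(a) = \exp\!\left[-\big((\eta_1 a)^{\eta_2} + (\eta_1 a)^{1/\eta_2}
 + \eta_3 a\big)\right],\qquad
\varphi_a = S(a+1)/S(a),$$

a "bathtub": high pup mortality, low young-adult mortality, senescent
increase. The defaults $\eta = (0.055, 2.80, 0.076)$ are the prior means
from a hierarchical meta-analysis of phocid mortality. We interpret the
RAW expression as cumulative survivorship rather than annual survival:
the annual-survival reading gives implausible values (pup survival below
one half of the adult level and adult survival far from the 0.85-0.9
range that the bathtub description implies), while the survivorship
reading produces exactly the described curve.

The census is post-breeding, with a 50/50 birth sex ratio and equal
female and male survival, so $N^F_{t,a} = N^M_{t,a}$ throughout. Cohorts
age as $N^F_{t,a} = N^F_{t-1,a-1}\varphi_{a-1}$ and recruitment is

$$N^F_{t,0} = N^M_{t,0} = \tfrac12 \sum_{a} N^F_{t,a} f_a,$$

i.e. every female alive at the census whelps a single pup with
probability equal to her fecundity at her age *in the pupping year*. One
indexing choice deserves a note: the recruitment sum can equivalently be
written over the pre-survival ages with fecundity indexed one year
earlier. We align fecundity with the mother's age in the birth year
because the kinship kernels, the Leslie matrix (fertilities
$\tfrac12\varphi_a f_{a+1}$) and the pedigree simulator must all weight
mothers identically — otherwise the kernels would be biased against the
simulator by one year of the fecundity ogive. With the fecundity ogives
flat above age 6 the numerical difference is small, but the internal
consistency is what the validation tests rely on.

Fecundity-at-age and male maturity-at-age are fixed inputs, not
estimated. Their exact values come from external harvest-based analyses
whose age tables are not reproduced here, so the package ships
configurable schedules with documented defaults: a logistic fecundity
ogive with midpoint age 5 and asymptote 0.95 (females begin pupping
around the age of first parturition; at most 95% of adult females pup in
a year) and a logistic male maturity ogive with midpoint age 6. Knife-edge
schedules (`list(type = "knife_edge", age = 4)`) reproduce the simpler
design of the power analysis. Users can supply any age table through
`build_schedules()` or a 4-column CSV. The finite growth rate $\lambda$
is the dominant eigenvalue of the female Leslie matrix; with the default
ogives and the prior RAW parameters it is close to 1, and the published
value of 1.04 is only reproducible with the external fecundity table.

Trajectories start from the stable age distribution one maximum lifespan
before data collection and are anchored so that total abundance in a
reference year equals the abundance parameter $N$.

## Kinship probability kernels

All kernels condition on the demographic trajectory and the covariates of
both animals (sex, birth year, death year, mtDNA haplotype where
relevant), and are exposed through `kin_context()`.

**Parent-offspring.** A female aged $a$ and alive in the offspring's
birth year $b$ is the mother with probability
$f_a / \sum_{a'} N^F_{b,a'} f_{a'}$; the paternal version replaces
fecundity with male maturity. The male breeding fraction $\pi$ cancels
here: a random mature male is a breeder with probability $\pi$, but each
breeder's expected paternity share is $1/\pi$ times larger.

**Maternal half-siblings.** The unobserved shared mother is drawn from
the fecundity-weighted female age distribution at the older sibling's
birth, must survive the birth gap $\delta$, and must whelp again:
$$p_{\mathrm{MHSP}} = \sum_a
 \frac{N^F_{b_i,a} f_a}{\sum N^F_{b_i} f}
 \Big(\prod_{t=0}^{\delta-1}\varphi_{a+t}\Big)
 \frac{f_{a+\delta}}{\sum_{a'} N^F_{b_j,a'} f_{a'}}.$$
A gap of zero is impossible — one pup per female per year.

**Paternal half-siblings.** The mirror with maturity in place of
fecundity, two differences: same-cohort pairs are possible (a male breeds
with several females in one season), and conditioning on the first
offspring identifies the father as a breeder, shrinking the competing
pool to the breeding fraction — $p_{\mathrm{PHSP}} \propto 1/\pi$. This
is the sole channel through which $\pi$ is identified: it inflates
paternal relative to maternal half-sibling counts.

**Grandparent-grandchild.** Chains run grandparent → unobserved
intermediate parent (sex $s$, birth year $c$) → grandchild, summing the
grandparent's expected offspring in each year it was alive (aliveness is
known exactly under lethal sampling), the intermediate's survivorship to
its reproductive age, and the intermediate's relative reproductive output
in the grandchild's birth year. Written in full, every male link carries
the breeder probability $\pi$ times the breeder-pool share
$1/(\pi \sum N^M m)$; because the grandparent and the intermediate each
breed once in the chain, $\pi$ cancels and $p_{\mathrm{GGP}}$ is free of
it — unlike the PHSP kernel, where the same male must breed twice.
Feasibility demands a birth gap of at least twice the minimum breeding
age (default 5 years) and an older member that reached breeding age, so
most observed pairs are unambiguous HSPs; `rel_prob_hsp()` reports
$p_{\mathrm{HSP}}/(p_{\mathrm{HSP}}+p_{\mathrm{GGP}})$ per pair.

**mtDNA conditioning.** Maternal half-siblings always share a haplotype
and paternal ones never do (chance identity is neglected, as the small
haplotype-sharing probability of the real control-region spectrum
justifies; the simulator can nonetheless generate chance sharing so tests
can bound the induced bias). GGPs share only along the all-female chain,
so a male older animal has zero probability in the sharing stratum and a
female older animal roughly a 50% chance of sharing. Because haplotype
sharing is informative about kinship, it cannot be treated as an ordinary
conditioning covariate of every pair: each second-order comparison is
instead a trinomial outcome — not observed as kin, kin sharing mtDNA
(probability $(1-\mathrm{fn})(p_{\mathrm{MHSP}} +
p_{\mathrm{GGP,shared}})$), or kin not sharing — which reproduces exactly
the study situation where mtDNA was sequenced only for identified kin.
The false-negative rate $\mathrm{fn}$ thins the whole mixture, matching a
threshold applied to the pooled second-order PLOD class.

## Pseudo-likelihood, penalties and fitting

Comparisons are grouped by the covariates the kernels depend on (grouping
leaves the likelihood unchanged; the grouped and ungrouped forms agree to
$10^{-10}$ in the tests). The negative log pseudo-likelihood is the
product-Bernoulli kin likelihood plus two penalties:

$$-\log L = -\sum_g \big[k_g \log p_g + (n_g-k_g)\log(1-p_g)\big]
 + \sum_{i=1}^3 \frac{(\eta_i-\mu_i)^2}{2\sigma_i^2}
 + w\,(\lambda(\eta) - \lambda_0)^2 .$$

The Gaussian penalty plays the role of the survival prior; its SDs are
not published, so the defaults $\sigma = (0.01, 0.3, 0.02)$ are set to
the order of magnitude suggested by the meta-analytic context — tight
enough that survival stays biologically plausible, loose enough that the
growth-rate constraint can bend the curve. The $\lambda$ penalty weight
defaults to $10^4$ per unit$^2$, holding $\lambda$ within about 0.01 of
the analyst-chosen $\lambda_0$ (1 for the stationary base models). AIC
uses the kin-pair likelihood only, with the count of freely estimated
parameters: the penalties act as priors and the growth-rate scenarios are
compared on the kin likelihood alone.

Optimisation is quasi-Newton (`nlminb`) with box constraints over
log-abundance, optionally the RAW parameters, and optionally
$\mathrm{logit}\,\pi$, restarted from three dispersed abundance values
around a moment-matched start; standard errors come from the central
finite-difference Hessian at the optimum, with the abundance CV by the
delta method on the log scale. When survival is fixed, every kernel
scales as $1/N$ (and the PHSP part as $1/(N\pi)$), so the kernels are
evaluated once and rescaled analytically — the fit then costs almost
nothing, which is what makes replicated power analysis and coverage
experiments affordable. The reported abundance is the reference-year
total (all ages, both sexes) for stationary models and the average over
the reporting window (default, the 31 years ending at the reference
year) for trend scenarios; the published abundance never states its
reference class more precisely, and this convention is recorded in every
fit object.

## Kin identification from null-allele SNP panels

The genotyping chemistry produces heritable null alleles: mutations at
primer sites that make an allele consistently invisible, inflating
apparent homozygotes. Observed classes are `AA*` (true `AA` or
`A-null`), `AB`, `BB*`, and `FAIL` (`null/null` or a technical failure).
Under Hardy-Weinberg with a null,
$P = (p^2+2p\nu,\; 2pq,\; q^2+2q\nu,\; \nu^2)$; `estimate_locus_model()`
fits $(p,q,\nu)$ by EM, with a separable known technical-failure rate.

PLOD (pseudo-log-odds) scores sum, over jointly called loci, the log
likelihood-ratio of the observed class pair under a kinship hypothesis
versus unrelated. Hypotheses enter through Cotterman coefficients
$\kappa$ — the probabilities of sharing 0/1/2 alleles identical by
descent: POP $(0,1,0)$, full siblings $(\tfrac14,\tfrac12,\tfrac14)$,
HSP/GGP $(\tfrac12,\tfrac12,0)$. The pair tables are computed on true
three-allele genotypes (nulls inherited like any allele — which is why
moderate-null loci carry extra kin-finding power) and marginalised to
observed classes. Failed loci are skipped; the score is a raw sum.
Classification gates pairs on the second-order threshold first, then
adjudicates the first-order contrasts with thresholds placed halfway
between the expected scores of the competing true relationships, ties
breaking toward POP. At panel sizes like the study's 2,569 loci the
classes separate by many standard deviations; the practical risks are
third-order kin (half-thiatic pairs) crossing a low second-order
threshold from above, and true second-order kin falling below it — the
false-negative rate estimated by `false_negative_rate()` from the
theoretical HSP mean and a variance taken from the upper half of the
observed kin-score distribution (folded about the mean, robust to the
threshold truncating the lower tail, flagged as wide-uncertainty below
five exceedances).

Panel QC (`qc_panel()`) iterates to a fixed point: minor-allele-frequency
and null-frequency filters (defaults 0.05 and 0.45), a per-locus
chi-square goodness-of-fit to Hardy-Weinberg-with-nulls at $\alpha=0.05$
(one degree of freedom; plain per-test threshold by default, FDR
optionally — the study reports only that about 600 loci were removed,
without naming a correction), a per-sample heterozygosity z-score screen,
and duplicate removal by genotype concordance, re-admitting previously
rejected loci and samples each round so good samples are not lost to bad
loci or vice versa. Genetic sex is a majority vote over male-specific
presence markers (the simulator's convention; real-data encodings can be
remapped).

## The pedigree and genotype simulator

`simulate_pedigree()` generates the exact process the kernels assume:
survival draws by $\varphi_a$, whelping draws by $f_a$ (at most one pup
per female-year), fathers drawn from living breeder males weighted by
maturity, Bernoulli(0.5) offspring sex, lifelong breeder status assigned
with probability $\pi$ (an annual-reassignment switch exists only for
sensitivity analysis), and strictly maternal mtDNA inheritance from a
founder spectrum of 40 symmetric-Dirichlet haplotypes — enough that
chance sharing is rare but present, so the kernels' neglect of it can be
quantified rather than assumed away.

Harvest sampling treats the harvest as a small component of total
mortality: samples are drawn without replacement from the animals dying
in each design year, stratified to the target age distribution (46%
pups, 65% at ages 0-3, geometrically decaying adult ages, following the
published composition of the monitoring series). This automatically
makes sampling lethal and consistent — no sampled animal reproduces
after its death year — without feeding back on the population dynamics,
which is appropriate while harvest rates are a few percent of abundance.
The default year profile ramps from a handful of samples per year in the
late 1990s to just under 100 per year from 2009.

`simulate_genotypes()` drops founder alleles $(p, q, \nu)$ down the
pedigree with Mendelian transmission, projects to observed classes, adds
technical failures and sex-linked presence markers, and reports the true
design frequencies for validation. `true_kin_pairs()` labels every
sampled pair from the realised pedigree (POP, FSP, MHSP, PHSP, GGP by
chain, half-thiatic), which provides the oracle classification used by
the power analysis.

What the simulator deliberately does not emulate: aging error (ages are
exact, as the analysis assumes), spatial structure and village-level
sampling heterogeneity, environmental stochasticity in vital rates,
density dependence, and harvest feedback on dynamics. Tests passing
against the simulator therefore validate the internal consistency of
kernels, likelihood and estimator under the stated model — not robustness
to these real-data complications.

## Numerical choices and conventions

* Ages are integer years; the birth year is the calendar year of the
  spring pupping season; `a = 0` are pups; the terminal age class (39)
  dies after its final season.
* Individuals' ids in the simulator are integer row numbers; the
  configuration coerces the founding abundance to an integer.
* Kernel evaluations use precomputed year-by-age lookup tables; the GGP
  chain sum deduplicates identical covariate keys.
* Convergence: `nlminb` relative tolerance $10^{-10}$, three restarts,
  best kept; Hessian by `optimHess`; a non-positive-definite Hessian
  flags the fit instead of reporting silent standard errors.
* A kin-positive comparison with zero model probability returns an
  infinite negative log-likelihood carrying a diagnostic naming the
  offending group — such conflicts are data errors (typically aging
  errors) to be repaired by `repair_covariates()`, whose two
  minimal-edit rules (posthumous-parent and same-cohort-MHSP) mirror the
  documented covariate repairs, log every edit, and exclude pairs
  needing more than a configurable two years of adjustment.
* Same-sampling-year parent-offspring comparisons are omitted as
  dependent captures (mother-pup harvests).
* Displayed p-values round to two decimals; raw values are always kept
  in the returned objects.

## Scale of the validation experiments

The routine test suite works at reduced population sizes so the full
suite runs in minutes on one CPU: kernel-versus-pedigree agreement uses
abundance 5,000 with 200 replicates (checked cell-by-cell within three
Monte-Carlo standard errors of the replicate mean), parameter recovery
uses abundance 20,000 with 100 replicates (Wald 95% intervals for $N$
and $\pi$ are expected to cover the truth in roughly 90% of replicates
or more — slight undercoverage is the known small-sample behaviour of
Wald intervals with a few dozen kin pairs), and the full 300,000
scenario is reserved for the power-analysis reproduction, where expected
kin counts are computed analytically and a handful of simulation
replicates provide the CV. Kin-pair counts between replicates are
strongly overdispersed relative to Poisson — one prolific breeder male
sampled together with several of his offspring contributes many pairs at
once — so all simulation checks use replicate-level standard errors, not
binomial ones.

## Reconstructing the published analysis

The archived individual-level covariates and genotypes are not packaged.
`reconstruct_study_samples()` rebuilds a synthetic stand-in from
published summaries alone: 1,484 samples with the reported year ramp, age
profile and sex balance, the 22 published second-order pairs with their
exact covariates and mtDNA strata, and two parent-offspring pairs
synthesised to match their published description. Fits of this
reconstruction exercise the full machinery at the real scale and land in
the published range for the equal-breeding model, but they approximate
rather than reproduce the published numbers: the individual covariates of
the 1,460 background animals, the study's exact fecundity/maturity
tables, and its full kernel derivations are not recoverable from the
published text. The acceptance script reports the reconstruction
values under their own names for exactly this reason.

## Known limitations

Aging error is ignored (a stated assumption of the analysis); the
fecundity and maturity defaults are plausible ogives, not the study's
tables, so absolute reconstruction fits shift with them; the
heterogeneity model treats breeder status as lifelong with a single
fraction $\pi$; chance mtDNA haplotype sharing is neglected in the
kernels; and the pseudo-likelihood treats pairs as independent, so the
reported CVs inherit the usual CKMR optimism when kin pairs cluster on
few parents.
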