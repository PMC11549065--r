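# ckmrseal

Close-kin mark-recapture (CKMR) estimation of abundance and demographic
parameters from harvested (lethally sampled) animals, built around the
Alaska bearded seal monitoring problem — the setting in which every
sample comes from the subsistence harvest, ages come from tooth annuli,
and the kin pairs found among ~1,500 genotyped seals must carry all the
information about a population of a few hundred thousand.

## What it does

CKMR treats each kin relationship among sampled animals as a recapture
of a shared parent. `ckmrseal` provides the full pipeline:

* **Demography** — an age-structured model over ages 0–39 with reduced
  additive Weibull ("bathtub") survival
  `S(a) = exp(-[(η₁a)^η₂ + (η₁a)^(1/η₂) + η₃a])`, fixed fecundity and
  male-maturity ogives, Leslie-matrix growth rate λ, and stable-age
  trajectories anchored to a reference abundance.
* **Kinship probability kernels** — parent–offspring
  (`p = f_a / Σ N^F_{b,a'} f_{a'}` for mothers, maturity-weighted for
  fathers), maternal and paternal half-siblings, and
  grandparent–grandchild chains with mitochondrial-haplotype
  conditioning. Persistent heterogeneity in male breeding success enters
  through the breeding fraction π: only paternal half-sibling
  probabilities scale as 1/π, which is what lets the paternal:maternal
  ratio among identified kin estimate π.
* **Pseudo-likelihood fitting** — grouped product-Bernoulli kin
  likelihood with Gaussian penalties on the survival parameters and a
  quadratic penalty holding λ at an analyst-chosen λ₀; quasi-Newton
  optimisation, finite-difference Hessian standard errors, AIC on the
  kin-only likelihood, and growth-rate profiles.
* **Kin identification** — pseudo-log-odds (PLOD) scores for POP, full-
  sibling and HSP/GGP hypotheses from SNP panels with heritable null
  alleles (Cotterman-coefficient mixtures over a three-allele system),
  iterative panel QC (MAF/null-frequency/Hardy-Weinberg-with-nulls
  filters, heterozygosity screens, duplicate detection), genetic sexing,
  threshold false-negative estimation, GGP feasibility screening and
  covariate repair.
* **Synthetic data** — an individual-based pedigree, harvest-sampling
  and genotype simulator with exactly the statistical structure the
  analysis assumes, used for the power analysis and for validating every
  kernel against realised kin frequencies.
* **Reported statistics** — the binomial mtDNA sharing test, the
  sex-ratio chi-square, birth-gap summaries and the packaged table of
  the 22 published second-order kin pairs.

## A worked example

Simulate a population with strong male reproductive skew, harvest it,
and refit:

```r
library(ckmrseal)

sch <- build_schedules()                      # RAW prior + default ogives
cfg <- sim_config(N0 = 20000, years = 60, schedules = sch,
                  pi = 0.4, seed = 77, start_year = 1950)
ped <- simulate_pedigree(cfg)
sam <- sample_harvest(ped, harvest_design(1999:2010, 70))
kin <- true_kin_pairs(ped, sam$id)            # oracle kin labels
kin <- kin[kin$class %in% c("POP", "MHSP", "PHSP", "GGP"), ]
kin2 <- data.frame(id1 = kin$id1, id2 = kin$id2,
                   class = ifelse(kin$class == "POP", "POP", "HSP-GGP"),
                   stratum = ifelse(kin$class == "MHSP" |
                                    kin$chain %in% "GGP-FF", "M", "P"))
cmp <- build_comparisons(sam, kin = kin2)
fit <- fit_ckmr(cmp, ckmr_config(fix_eta = TRUE, pi_free = TRUE,
                                 fn_rate = 0, eta_prior = sch$params))
fit
```

```
2 identified POP(s) fall in omitted same-year comparisons (dependent captures)
CKMR pseudo-likelihood fit
  N_hat = 3.38e+04 (CV 0.19)
  pi_hat = 0.35 (SE 0.08)
  eta = (0.0550, 2.800, 0.0760), lambda = 1.0049
  kin -logL = 857.512, AIC = 1719.02 (2 free parameters)
  expected kin: POP 5.57, MHSP-GGP 18.18, PHSP-GGP 66.25
```

The generating truth in this run is an abundance of about 26,900 in the
final sampling year with π = 0.4: the estimate lands within its CV, and
the paternal excess among the simulated half-siblings (66 expected
paternal versus 18 maternal second-order pairs) is what identifies the
breeding fraction. Coverage of the reported intervals is checked over
100 such replicates in the test suite.

On the genotype side, a simulated 2,500-locus null-allele panel
separates the kin classes cleanly — every true POP and half-sibling
recovered, no POP/HSP confusion, and third-order kin rejected — which is
the regime the published panel operates in.

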