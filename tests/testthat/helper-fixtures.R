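# shared fixture builders; everything is generated in code at test time

# schedules with a single reproducing age class k for closed-form checks
single_age_schedules <- function(k = 3, s = 0.8, max_age = 9) {
  f <- numeric(max_age + 1); f[k + 1] <- 1
  sch <- build_schedules(raw_params(0, 1, -log(s)),
                         fecundity = f, maturity = f, max_age = max_age)
  sch
}

# hand-built stationary trajectory with a chosen female age composition
toy_trajectory <- function(NF_row, years = 2000:2020,
                           schedules = build_schedules()) {
  NF <- matrix(rep(NF_row, each = length(years)), length(years),
               length(NF_row))
  structure(list(years = years, NF = NF, lambda = 1, schedules = schedules),
            class = "pop_trajectory")
}

quiet_comparisons <- function(...) suppressMessages(build_comparisons(...))

# small simulated dataset for likelihood tests
sim_dataset <- function(seed, N0 = 5000, years = 50, pi = 0.5,
                        sample_years = 1999:2008, per_year = 60,
                        schedules = build_schedules()) {
  cfg <- sim_config(N0 = N0, years = years, schedules = schedules, pi = pi,
                    seed = seed, start_year = min(sample_years) - years + 9)
  ped <- simulate_pedigree(cfg)
  sam <- sample_harvest(ped, harvest_design(sample_years, per_year))
  kin <- ckmrseal:::oracle_kin(ped, sam)
  list(ped = ped, sam = sam, kin = kin, cfg = cfg)
}

# independent biallelic (no null allele) kinship pair-probability oracle:
# explicit 9-state enumeration over ordered genotypes with IBD mixtures,
# written without reference to the package implementation
biallelic_pair_oracle <- function(p, q, kappa) {
  stopifnot(abs(p + q - 1) < 1e-12)
  fr <- c(p, q)
  geno <- rbind(c(1, 1), c(1, 2), c(2, 2))   # AA, AB, BB
  gprob <- c(p^2, 2 * p * q, q^2)
  J <- matrix(0, 3, 3)
  for (g1 in 1:3) for (g2 in 1:3) {
    # P(g2 | g1, one shared allele): average over which allele is shared
    p1 <- 0
    for (sh in 1:2) {
      x <- geno[g1, sh]
      for (z in 1:2) {
        gg <- sort(c(x, z))
        if (all(gg == geno[g2, ])) p1 <- p1 + 0.5 * fr[z]
      }
    }
    J[g1, g2] <- kappa[1] * gprob[g2] + kappa[2] * p1 +
      kappa[3] * (g1 == g2)
  }
  J * gprob
}
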