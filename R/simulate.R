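#' Configuration for the individual-based simulator
#'
#' Defines the generative model the CKMR analysis assumes: an age-structured
#' population with the given life-history schedules, a 50/50 birth sex
#' ratio, at most one pup per female per year, fathers drawn from the pool
#' of living breeder males weighted by maturity-at-age, lifelong breeder
#' status assigned to a fraction `pi` of males, and strictly maternal mtDNA
#' inheritance from a founder haplotype spectrum.
#'
#' @param N0 Initial total abundance (both sexes), seeded at the stable age
#'   distribution.
#' @param years Number of years to simulate beyond the founding year.
#' @param schedules A [build_schedules()] object.
#' @param pi Fraction of males that are (lifelong) breeders.
#' @param n_haplotypes Number of founder mtDNA haplotypes; founder
#'   frequencies are symmetric-Dirichlet(1) draws, making chance sharing
#'   rare but present.
#' @param start_year Calendar year of the founding census.
#' @param seed Mandatory random seed.
#' @param breeder_reassign If `TRUE`, breeder status is redrawn every year
#'   (sensitivity switch; default off, persistent status).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(N0 = 10000, years = 60, schedules = build_schedules(),
                       pi = 1, n_haplotypes = 40, start_year = 1958,
                       seed, breeder_reassign = FALSE) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  stopifnot(pi > 0, pi <= 1, N0 >= 2, years >= 1)
  N0 <- as.integer(round(N0))
  structure(list(N0 = N0, years = years, schedules = schedules, pi = pi,
                 n_haplotypes = n_haplotypes, start_year = start_year,
                 seed = as.integer(seed), breeder_reassign = breeder_reassign),
            class = "sim_config")
}

#' Simulate an individual-based pedigree
#'
#' Runs the yearly cycle implied by the demographic model: survival draws
#' by age-specific `phi_a`, whelping draws by fecundity `f_a` for each
#' surviving female, father assignment among living breeder males weighted
#' by maturity `m_a`, Bernoulli(0.5) offspring sex, breeder status assigned
#' with probability `pi`, and maternal mtDNA copying. Founders have no
#' recorded parents, so analyses should leave a burn-in of one or two
#' generations before sampling.
#'
#' @param config A [sim_config()].
#' @return A `data.table` of class `pedigree` with one row per individual
#'   ever alive: `id`, `sex`, `birth`, `death` (last year alive; `NA` if
#'   alive at the end), `mother`, `father` (`NA` for founders), `breeder`,
#'   `hap` (mtDNA haplotype label). Attribute `years` holds the simulated
#'   calendar span; attribute `extinct` flags early extinction.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sch <- config$schedules
  A <- sch$max_age
  phi <- sch$phi; f <- sch$fecundity; m <- sch$maturity
  hap_freq <- stats::rgamma(config$n_haplotypes, 1)
  hap_freq <- hap_freq / sum(hap_freq)

  n0 <- config$N0
  w <- stable_age(sch)
  cap <- as.integer(n0 * 2 + n0 * 0.15 * (config$years + 1) * 1.6 + 1000)
  sex <- integer(cap)      # 1 = F, 2 = M
  birth <- integer(cap); death <- rep(NA_integer_, cap)
  mother <- rep(NA_integer_, cap); father <- rep(NA_integer_, cap)
  breeder <- logical(cap); hap <- integer(cap)

  ages0 <- sample.int(A + 1, n0, replace = TRUE, prob = w) - 1L
  y0 <- config$start_year
  sex[1:n0] <- sample(1:2, n0, replace = TRUE)
  birth[1:n0] <- y0 - ages0
  breeder[1:n0] <- sex[1:n0] == 2L & stats::runif(n0) < config$pi
  hap[1:n0] <- sample.int(config$n_haplotypes, n0, replace = TRUE,
                          prob = hap_freq)
  n_tot <- n0
  alive <- 1:n0
  extinct <- FALSE

  grow <- function(need) {
    while (n_tot + need > length(sex)) {
      extra <- length(sex)
      sex <<- c(sex, integer(extra)); birth <<- c(birth, integer(extra))
      death <<- c(death, rep(NA_integer_, extra))
      mother <<- c(mother, rep(NA_integer_, extra))
      father <<- c(father, rep(NA_integer_, extra))
      breeder <<- c(breeder, logical(extra)); hap <<- c(hap, integer(extra))
    }
  }

  for (t in (y0 + 1):(y0 + config$years)) {
    a <- t - 1L - birth[alive]                 # age at the previous census
    p_surv <- ifelse(a >= A, 0, phi[pmin(a, A) + 1])
    surv <- stats::runif(length(alive)) < p_surv
    death[alive[!surv]] <- t - 1L
    alive <- alive[surv]
    if (length(alive) < 2) { extinct <- TRUE; break }
    if (config$breeder_reassign) {
      males <- alive[sex[alive] == 2L]
      breeder[males] <- stats::runif(length(males)) < config$pi
    }
    a <- t - birth[alive]
    fem <- alive[sex[alive] == 1L]
    fa <- t - birth[fem]
    whelp <- stats::runif(length(fem)) < f[fa + 1]
    moms <- fem[whelp]
    nb <- length(moms)
    if (nb > 0) {
      cand <- alive[sex[alive] == 2L & breeder[alive]]
      wts <- m[t - birth[cand] + 1]
      cand <- cand[wts > 0]; wts <- wts[wts > 0]
      if (length(cand) == 0) next                # no mature breeder males
      dads <- cand[sample.int(length(cand), nb, replace = TRUE, prob = wts)]
      grow(nb)
      idx <- (n_tot + 1L):(n_tot + nb)
      sex[idx] <- sample(1:2, nb, replace = TRUE)
      birth[idx] <- t
      mother[idx] <- moms; father[idx] <- dads
      hap[idx] <- hap[moms]
      breeder[idx] <- sex[idx] == 2L & stats::runif(nb) < config$pi
      n_tot <- n_tot + nb
      alive <- c(alive, idx)
    }
  }

  ped <- data.table::data.table(
    id = seq_len(n_tot),
    sex = c("F", "M")[sex[1:n_tot]],
    birth = birth[1:n_tot], death = death[1:n_tot],
    mother = mother[1:n_tot], father = father[1:n_tot],
    breeder = breeder[1:n_tot],
    hap = sprintf("H%02d", hap[1:n_tot]))
  data.table::setattr(ped, "class", c("pedigree", class(ped)))
  data.table::setattr(ped, "years", c(y0, y0 + config$years))
  data.table::setattr(ped, "extinct", extinct)
  data.table::setattr(ped, "config", config)
  ped
}

#' Harvest sampling design
#'
#' @param years Sampling (calendar) years.
#' @param n_per_year Samples per year (recycled to `length(years)`).
#' @param age_probs Target age distribution of the samples (length 40;
#'   default: the harvest profile of the bearded seal monitoring data, 46%
#'   pups, 65% at ages 0-3, geometrically decaying adult ages).
#' @return A list of class `harvest_design`.
#' @export
harvest_design <- function(years, n_per_year, age_probs = harvest_age_profile()) {
  stopifnot(all(n_per_year >= 0), abs(sum(age_probs) - 1) < 1e-8)
  structure(list(years = as.integer(years),
                 n_per_year = rep_len(n_per_year, length(years)),
                 age_probs = age_probs),
            class = "harvest_design")
}

#' Harvest age profile of the monitoring data
#'
#' Age distribution used for simulated harvest sampling: 46% pups, ages 1-3
#' at 6.43% each (pups plus juveniles 65.3%), and the remaining mass spread
#' over ages 4-34 with a geometric decay (ratio 0.85), matching a harvest
#' that strongly favours young seals with occasional animals into their
#' thirties.
#'
#' @param max_age Oldest age class.
#' @return Probability vector over ages `0..max_age`.
#' @export
harvest_age_profile <- function(max_age = 39) {
  p <- numeric(max_age + 1)
  p[1] <- 0.46
  p[2:4] <- (0.653 - 0.46) / 3
  adult <- 0.85^(0:30)            # ages 4..34
  p[5:35] <- (1 - 0.653) * adult / sum(adult)
  p
}

#' Draw harvest samples from a simulated pedigree
#'
#' Lethal sampling: harvest is a small fraction of total mortality, so
#' samples are drawn without replacement from the animals dying in each
#' design year, stratified to match the target age distribution (shortfalls
#' in an age class are logged and redistributed to the classes that still
#' have animals). The sampling year equals the death year by construction.
#'
#' @param pedigree A [simulate_pedigree()] result.
#' @param design A [harvest_design()].
#' @return A `data.table` of sample records (`id`, `sex`, `birth_year`,
#'   `death_year`, `age`, `mtdna`) with attribute `shortfall` (total
#'   unfilled demand).
#' @export
sample_harvest <- function(pedigree, design) {
  stopifnot(inherits(pedigree, "pedigree"), inherits(design, "harvest_design"))
  yrs <- attr(pedigree, "years")
  if (min(design$years) <= yrs[1] || max(design$years) > yrs[2])
    stop("design years must lie inside the simulated span")
  picks <- integer(0)
  shortfall <- 0L
  for (k in seq_along(design$years)) {
    t <- design$years[k]
    n_t <- design$n_per_year[k]
    if (n_t == 0) next
    pool <- which(!is.na(pedigree$death) & pedigree$death == t)
    page <- t - pedigree$birth[pool]
    want <- round_counts(n_t, design$age_probs)
    got <- integer(0)
    for (a in order(-want)) {
      if (want[a] == 0) next
      avail <- pool[page == a - 1L]
      take <- min(length(avail), want[a])
      if (take > 0)
        got <- c(got, if (length(avail) == 1) avail else
          sample(avail, take))
    }
    deficit <- n_t - length(got)
    if (deficit > 0) {
      rest <- setdiff(pool, got)
      extra <- min(deficit, length(rest))
      if (extra > 0) got <- c(got, if (length(rest) == 1) rest else
        sample(rest, extra))
      shortfall <- shortfall + (deficit - extra)
    }
    picks <- c(picks, got)
  }
  out <- data.table::data.table(
    id = as.character(pedigree$id[picks]),
    sex = pedigree$sex[picks],
    birth_year = pedigree$birth[picks],
    death_year = pedigree$death[picks],
    age = pedigree$death[picks] - pedigree$birth[picks],
    mtdna = pedigree$hap[picks])
  data.table::setattr(out, "shortfall", shortfall)
  out
}

round_counts <- function(n, probs) {
  raw <- n * probs
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' True kin relationships among sampled individuals
#'
#' Classifies every unordered pair of the given individuals using the
#' realised pedigree: `POP`, `FSP`, `MHSP`, `PHSP`, `GGP` (with the chain
#' recorded as grandparent sex + intermediate sex, e.g. `"GGP-FM"`), and
#' `HTP` (half-thiatic: one animal is a half-sibling of the other's
#' parent). When a pair satisfies several definitions the most related
#' class wins (POP > FSP > HSP > GGP > HTP). Pairs involving founders are
#' classified from the recorded links only.
#'
#' @param pedigree A [simulate_pedigree()] result.
#' @param ids Individual ids (integer rows of the pedigree or the character
#'   ids of a [sample_harvest()] table).
#' @return A `data.table` with `id1`, `id2` (older first by birth year),
#'   `class`, `chain` and `shares_mtdna`.
#' @export
true_kin_pairs <- function(pedigree, ids) {
  ids <- as.integer(ids)
  n <- length(ids)
  if (n < 2) return(data.table::data.table(
    id1 = character(0), id2 = character(0), class = character(0),
    chain = character(0), shares_mtdna = logical(0)))
  mo <- pedigree$mother; fa <- pedigree$father
  gm_m <- mo[mo[ids]]; gf_m <- fa[mo[ids]]   # maternal grandparents
  gm_f <- mo[fa[ids]]; gf_f <- fa[fa[ids]]   # paternal grandparents
  b <- pedigree$birth[ids]
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  swap <- b[j] < b[i]
  oi <- ifelse(swap, j, i); oj <- ifelse(swap, i, j)
  I <- ids[oi]; J <- ids[oj]

  same <- function(x, y) !is.na(x) & !is.na(y) & x == y
  pop <- same(mo[J], I) | same(fa[J], I) | same(mo[I], J) | same(fa[I], J)
  sm <- same(mo[I], mo[J]); sf <- same(fa[I], fa[J])
  fsp <- sm & sf
  mhsp <- sm & !sf
  phsp <- sf & !sm
  # grandparent chains: older is grandparent of younger
  ggFF <- same(gm_m[oj], I); ggFM <- same(gm_f[oj], I)
  ggMF <- same(gf_m[oj], I); ggMM <- same(gf_f[oj], I)
  ggp <- ggFF | ggFM | ggMF | ggMM
  # half-thiatic: I half-sib of a parent of J, or J half-sib of a parent of I
  hs_with <- function(x, y) {
    (same(mo[x], mo[y]) & !same(fa[x], fa[y])) |
      (same(fa[x], fa[y]) & !same(mo[x], mo[y]))
  }
  htp <- hs_with(I, mo[J]) | hs_with(I, fa[J]) |
    hs_with(J, mo[I]) | hs_with(J, fa[I])

  cls <- rep(NA_character_, length(I))
  chain <- rep(NA_character_, length(I))
  cls[htp] <- "HTP"
  cls[ggp] <- "GGP"
  chain[ggp] <- paste0("GGP-",
                       ifelse(ggFF[ggp], "FF", ifelse(ggFM[ggp], "FM",
                              ifelse(ggMF[ggp], "MF", "MM"))))
  cls[phsp] <- "PHSP"; cls[mhsp] <- "MHSP"; cls[fsp] <- "FSP"
  cls[pop] <- "POP"
  keep <- !is.na(cls)
  data.table::data.table(
    id1 = as.character(I[keep]), id2 = as.character(J[keep]),
    class = cls[keep], chain = chain[keep],
    shares_mtdna = pedigree$hap[I[keep]] == pedigree$hap[J[keep]])
}
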