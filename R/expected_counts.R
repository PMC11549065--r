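#' Sampling design of the bearded seal harvest monitoring series
#'
#' Per-year sample totals ramping from a handful per year in the late
#' 1990s to just under 100 per year from 2009 on (about 1,600 samples over
#' 1998-2020), with the harvest age profile of [harvest_age_profile()]
#' (46% pups). This is the design used by the power analysis.
#'
#' @return A [harvest_design()].
#' @export
study_sampling_design <- function() {
  years <- 1998:2020
  n <- c(5, 8, 12, 18, 28, 40, 55, 70, 80, 90, rep(97, 13))
  harvest_design(years, n)
}

#' Analytic expected kin-pair counts for a design
#'
#' Sums the kinship probability kernels over the expected covariate
#' composition of the sample -- no pedigree realisation is needed. The
#' sample composition is the design's year totals spread over its age
#' profile (sexes 50/50); parent-offspring comparisons exclude same-year
#' pairs, as in the likelihood.
#'
#' @param schedules A [build_schedules()] object.
#' @param N Total abundance in the final design year.
#' @param design A [harvest_design()].
#' @param pi Male breeding fraction.
#' @param fn_rate False-negative rate applied to second-order counts.
#' @return Named list: `POP`, `MHSP`, `PHSP`, `HSP`, `GGP_shared`,
#'   `GGP_unshared`, `GGP`, `second_order`.
#' @export
expected_kin_counts_analytic <- function(schedules, N, design, pi = 1,
                                         fn_rate = 0) {
  stopifnot(inherits(design, "harvest_design"))
  ref <- max(design$years)
  ages <- which(design$age_probs > 0) - 1L
  y0 <- min(design$years) - max(ages) - schedules$max_age - 2L
  traj <- make_trajectory(schedules, N, ref_year = ref, year0 = y0)
  ctx <- kin_context(traj, schedules, pi = pi, fn_rate = fn_rate)

  # expected sample counts per (death year, age) stratum
  strata <- data.table::CJ(y = design$years, a = ages)
  strata$n <- design$n_per_year[match(strata$y, design$years)] *
    design$age_probs[strata$a + 1]
  strata$b <- strata$y - strata$a
  ns <- nrow(strata)

  # --- POP: ordered stratum pairs (parent stratum x offspring stratum)
  pg <- data.table::CJ(ip = seq_len(ns), io = seq_len(ns))
  pg <- pg[strata$y[ip] != strata$y[io]]           # same-year exclusion
  pop_groups <- data.table::data.table(
    b_p = strata$b[pg$ip], d_p = strata$y[pg$ip], b_o = strata$b[pg$io],
    w = strata$n[pg$ip] * strata$n[pg$io])
  pf <- cbind(pop_groups, sex_p = "F")
  pm <- cbind(pop_groups, sex_p = "M")
  e_pop <- 0.5 * sum(pop_group_probs(pf, ctx) * pf$w) +
    0.5 * sum(pop_group_probs(pm, ctx) * pm$w)

  # --- second order: unordered stratum pairs, older first
  sg <- data.table::CJ(i = seq_len(ns), j = seq_len(ns))
  sg <- sg[strata$b[i] < strata$b[j] |
             (strata$b[i] == strata$b[j] & i <= j)]
  w <- strata$n[sg$i] * strata$n[sg$j]
  same <- strata$b[sg$i] == strata$b[sg$j]
  w[same & sg$i == sg$j] <- strata$n[sg$i][same & sg$i == sg$j]^2 / 2
  w[same & sg$i != sg$j] <- w[same & sg$i != sg$j] / 2
  groupsF <- data.table::data.table(
    sex_i = "F", b_i = strata$b[sg$i], d_i = strata$y[sg$i],
    b_j = strata$b[sg$j])
  groupsM <- data.table::data.table(
    sex_i = "M", b_i = strata$b[sg$i], d_i = strata$y[sg$i],
    b_j = strata$b[sg$j])
  sF <- second_order_group_probs(groupsF, ctx)
  sM <- second_order_group_probs(groupsM, ctx)
  half <- function(x, y) sum(0.5 * (x + y) * w)
  thin <- 1 - fn_rate
  e_mhsp <- thin * half(sF$mhsp, sM$mhsp)
  e_phsp <- thin * half(sF$phsp, sM$phsp)
  e_ggs <- thin * half(sF$ggp_shared, sM$ggp_shared)
  e_ggu <- thin * half(sF$ggp_unshared, sM$ggp_unshared)
  list(POP = e_pop, MHSP = e_mhsp, PHSP = e_phsp, HSP = e_mhsp + e_phsp,
       GGP_shared = e_ggs, GGP_unshared = e_ggu, GGP = e_ggs + e_ggu,
       second_order = e_mhsp + e_phsp + e_ggs + e_ggu)
}

#' Simulation-based power analysis
#'
#' For each replicate: simulate a pedigree under the configuration, draw
#' the harvest sample, classify kin from the pedigree truth (oracle
#' labels), build comparisons and fit the CKMR model; report the abundance
#' estimate and its CV. Replicate seeds derive from `config$seed`.
#'
#' @param config A [sim_config()].
#' @param design A [harvest_design()].
#' @param reps Number of replicates (`>= 1`).
#' @param fit_config A [ckmr_config()]; the default fixes survival at the
#'   generating values and, when `pi_free = FALSE`, fixes `pi` at the
#'   generating value.
#' @param min_kin Replicates with fewer observed kin are flagged
#'   non-estimable and skipped.
#' @return A `data.table` with one row per replicate: `rep`, `n_samples`,
#'   `n_kin`, `N_hat`, `cv`, `pi_hat`, `estimable`, `converged`.
#' @export
power_analysis <- function(config, design, reps = 10,
                           fit_config = NULL, min_kin = 1) {
  stopifnot(inherits(config, "sim_config"), reps >= 1)
  if (is.null(fit_config))
    fit_config <- ckmr_config(fix_eta = TRUE, pi_fixed = config$pi,
                              eta_prior = config$schedules$params,
                              fecundity = config$schedules$fecundity,
                              maturity = config$schedules$maturity,
                              fn_rate = 0)
  rows <- lapply(seq_len(reps), function(r) {
    cfg <- config; cfg$seed <- (config$seed + 7919L * r) %% .Machine$integer.max
    ped <- simulate_pedigree(cfg)
    sam <- sample_harvest(ped, design)
    kin <- oracle_kin(ped, sam)
    n_kin <- nrow(kin)
    out <- data.table::data.table(rep = r, n_samples = nrow(sam),
                                  n_kin = n_kin, N_hat = NA_real_,
                                  cv = NA_real_, pi_hat = NA_real_,
                                  estimable = n_kin >= min_kin,
                                  converged = FALSE)
    if (n_kin < min_kin) return(out)
    cmp <- build_comparisons(sam, kin = kin)
    fit <- tryCatch(fit_ckmr(cmp, fit_config), error = function(e) NULL)
    if (!is.null(fit)) {
      out$N_hat <- fit$estimates$N_report
      out$cv <- fit$cv_N
      out$pi_hat <- fit$estimates$pi
      out$converged <- fit$convergence == 0
    }
    out
  })
  data.table::rbindlist(rows)
}

# oracle kin classification: pedigree-truth labels in the form expected by
# build_comparisons(); second-order strata from the true chain, so chance
# haplotype sharing does not contaminate the strata
oracle_kin <- function(pedigree, samples) {
  tk <- true_kin_pairs(pedigree, samples$id)
  tk <- tk[tk$class %in% c("POP", "MHSP", "PHSP", "GGP"), ]
  if (!nrow(tk))
    return(data.frame(id1 = character(0), id2 = character(0),
                      class = character(0), stratum = character(0)))
  data.frame(
    id1 = tk$id1, id2 = tk$id2,
    class = ifelse(tk$class == "POP", "POP", "HSP-GGP"),
    stratum = ifelse(tk$class == "MHSP" |
                       (!is.na(tk$chain) & tk$chain == "GGP-FF"), "M", "P"))
}
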