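test_that("comparison building counts pairs and applies exclusions", {
  s <- data.frame(id = c("a", "b", "c"), sex = c("F", "M", "F"),
                  birth_year = c(1990, 2000, 2005),
                  death_year = c(2005, 2005, 2006))
  cmp <- quiet_comparisons(s)
  expect_equal(cmp$n_pairs, 3)
  # pair a-b shares the sampling year 2005: no POP comparison either way
  expect_equal(sum(cmp$pop$n), 4)          # 6 ordered minus the 2 same-year
  expect_equal(sum(cmp$second$n), 3)       # all pairs stay second-order
  # n samples -> choose(n, 2) pairs
  n <- 120
  s2 <- data.frame(id = sprintf("s%03d", 1:n), sex = "F",
                   birth_year = rep(1990:2009, 6),
                   death_year = rep(2010:2015, 20))
  s2$death_year <- pmax(s2$death_year, s2$birth_year)
  cmp2 <- quiet_comparisons(s2)
  expect_equal(cmp2$n_pairs, choose(n, 2))
  expect_equal(sum(cmp2$second$n), choose(n, 2))
})

test_that("records with missing or inconsistent covariates are rejected", {
  s <- data.frame(id = c("a", "b", "c", "d"), sex = c("F", "M", "x", "F"),
                  birth_year = c(2000, NA, 2001, 2002),
                  death_year = c(2005, 2006, 2004, 2003),
                  age = c(5, NA, 3, 2))   # d: age disagrees with the years
  expect_warning(out <- sample_records(s), "dropping 3")
  expect_equal(out$id, "a")
  expect_error(sample_records(data.frame(id = c("a", "a"), sex = "F",
                                         death_year = 1, age = 0)),
               "duplicate")
})

test_that("grouped and ungrouped likelihoods agree to 1e-10", {
  d <- sim_dataset(seed = 301, N0 = 3000, years = 45, pi = 0.5,
                   sample_years = 2000:2004, per_year = 40)
  par <- list(log_N = log(4000), eta = c(0.055, 2.8, 0.076), pi = 0.5)
  cfg <- ckmr_config(fn_rate = 0.01)
  g <- negative_lpl(par, quiet_comparisons(d$sam, kin = d$kin), cfg)
  u <- negative_lpl(par, quiet_comparisons(d$sam, kin = d$kin,
                                           group = FALSE), cfg)
  expect_equal(as.numeric(g), as.numeric(u), tolerance = 1e-10)
  # invariance to sample ordering and id relabelling
  perm <- sample(nrow(d$sam))
  sam2 <- d$sam[perm, ]
  sam2$id <- paste0("X", sam2$id)
  kin2 <- d$kin; kin2$id1 <- paste0("X", kin2$id1)
  kin2$id2 <- paste0("X", kin2$id2)
  g2 <- negative_lpl(par, quiet_comparisons(sam2, kin = kin2), cfg)
  expect_equal(as.numeric(g), as.numeric(g2), tolerance = 1e-10)
})

test_that("penalties vanish at the prior means with lambda at its target", {
  d <- sim_dataset(seed = 302, N0 = 2000, years = 40, pi = 1,
                   sample_years = 2000:2003, per_year = 30)
  cmp <- quiet_comparisons(d$sam, kin = d$kin)
  sch <- build_schedules()
  cfg <- ckmr_config(lambda0 = as.numeric(growth_rate(sch)))
  comps <- negative_lpl(list(log_N = log(3000), eta = c(0.055, 2.8, 0.076),
                             pi = 1), cmp, cfg, components = TRUE)
  expect_equal(comps$pen_eta, 0)
  expect_lt(comps$pen_lambda, 1e-12)
  expect_equal(comps$total, comps$kin_nll + comps$pen_eta + comps$pen_lambda)
})

test_that("tiny probabilities give the Poisson limit of the kin likelihood", {
  s <- data.frame(id = sprintf("s%02d", 1:30), sex = rep(c("F", "M"), 15),
                  birth_year = rep(1996:2005, 3),
                  death_year = rep(2006:2008, each = 10))
  cmp <- quiet_comparisons(s)                     # no kin observed
  par <- list(log_N = log(1e7), eta = c(0.055, 2.8, 0.076), pi = 1)
  cfg <- ckmr_config()
  comps <- negative_lpl(par, cmp, cfg, components = TRUE)
  ctx <- ckmrseal:::build_ckmr_context(par, cmp, cfg)
  exp_kin <- sum(ckmrseal:::pop_group_probs(cmp$pop, ctx) * cmp$pop$n) +
    sum(ckmrseal:::second_order_group_probs(cmp$second, ctx)$p_tot *
          cmp$second$n)
  expect_equal(comps$kin_nll, exp_kin, tolerance = 1e-4)
})

test_that("an observed kin pair with probability zero is diagnosed", {
  s <- data.frame(id = c("par", "off", "x"), sex = c("F", "F", "M"),
                  birth_year = c(1990, 2005, 2000),
                  death_year = c(2000, 2006, 2007))   # parent dead in 2000
  kin <- data.frame(id1 = "par", id2 = "off", class = "POP")
  cmp <- quiet_comparisons(s, kin = kin)
  v <- negative_lpl(list(log_N = log(1e4), eta = c(0.055, 2.8, 0.076),
                         pi = 1), cmp, ckmr_config())
  expect_true(is.infinite(as.numeric(v)))
  expect_match(attr(v, "diagnostic"), "POP group")
})

test_that("the likelihood prefers the generating abundance over double", {
  hits <- 0
  reps <- 30
  for (r in seq_len(reps)) {
    d <- sim_dataset(seed = 500 + r, N0 = 4000, years = 45, pi = 0.5,
                     sample_years = 2000:2005, per_year = 45)
    cmp <- quiet_comparisons(d$sam, kin = d$kin)
    lam <- as.numeric(growth_rate(d$cfg$schedules))
    N_true <- 4000 * lam^(max(d$sam$death_year) - d$cfg$start_year)
    cfg <- ckmr_config(fn_rate = 0)
    at <- function(N) as.numeric(negative_lpl(
      list(log_N = log(N), eta = c(0.055, 2.8, 0.076), pi = 0.5), cmp, cfg))
    if (at(N_true) < at(2 * N_true)) hits <- hits + 1
  }
  expect_gte(hits, 25)
})

test_that("fitting recovers scale and reports coherent summaries", {
  d <- sim_dataset(seed = 303, N0 = 8000, years = 55, pi = 0.5,
                   sample_years = 1999:2008, per_year = 70)
  cmp <- quiet_comparisons(d$sam, kin = d$kin)
  sch <- d$cfg$schedules
  cfg <- ckmr_config(fix_eta = TRUE, pi_free = TRUE, fn_rate = 0,
                     eta_prior = sch$params)
  fit <- fit_ckmr(cmp, cfg)
  lam <- as.numeric(growth_rate(sch))
  N_true <- 8000 * lam^(max(d$sam$death_year) - d$cfg$start_year)
  expect_equal(fit$convergence, 0)
  # estimate within a factor of 2 of the generating abundance
  expect_lt(abs(log(fit$estimates$N_hat / N_true)), log(2))
  expect_true(fit$cv_N > 0)
  expect_equal(fit$n_free, 2)
  ec <- expected_kin_counts(fit)
  expect_true(all(unlist(ec) >= 0))
  # expected counts at the optimum track the observed totals
  expect_lt(abs(ec$POP - fit$comparison_totals["k_pop"]),
            4 * sqrt(max(ec$POP, 1)))
  # fixed-survival fast path equals the general evaluator at the optimum
  pars <- list(log_N = log(fit$estimates$N_hat), eta = fit$estimates$eta,
               pi = fit$estimates$pi)
  comps <- negative_lpl(pars, cmp, cfg, components = TRUE)
  expect_equal(comps$kin_nll + comps$pen_lambda + comps$pen_eta,
               unname(fit$nll$total), tolerance = 1e-8)
  expect_error(fit_ckmr(quiet_comparisons(d$sam), cfg), "no kin")
})

test_that("AIC comparison and the trend profile behave", {
  d <- sim_dataset(seed = 304, N0 = 8000, years = 55, pi = 0.4,
                   sample_years = 1999:2008, per_year = 70)
  cmp <- quiet_comparisons(d$sam, kin = d$kin)
  sch <- d$cfg$schedules
  base <- ckmr_config(fix_eta = TRUE, fn_rate = 0, eta_prior = sch$params,
                      pi_fixed = 1)
  free <- ckmr_config(fix_eta = TRUE, pi_free = TRUE, fn_rate = 0,
                      eta_prior = sch$params)
  f_fix <- fit_ckmr(cmp, base)
  f_free <- fit_ckmr(cmp, free)
  expect_equal(compare_aic(f_free, f_free), 0)
  # with strong simulated heterogeneity the free-pi model wins
  expect_gt(compare_aic(f_free, f_fix), 0)
  d2 <- sim_dataset(seed = 305, N0 = 3000, years = 45, pi = 1,
                    sample_years = 2000:2004, per_year = 40)
  cmp2 <- quiet_comparisons(d2$sam, kin = d2$kin)
  expect_error(compare_aic(f_free, fit_ckmr(cmp2, base)), "identical")
  # single-point profile reproduces the base fit
  tp <- trend_profile(cmp, lambda_grid = 1.0, config = base)
  expect_equal(tp$kin_loglik, -f_fix$kin_nll, tolerance = 1e-6)
  expect_equal(tp$N_report, f_fix$estimates$N_report, tolerance = 1e-4)
})
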