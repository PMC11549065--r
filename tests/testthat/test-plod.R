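test_that("pair probabilities are proper distributions", {
  for (h in c("UP", "POP", "FSP", "HSP")) {
    J <- genotype_pair_probs(0.5, 0.3, 0.2, ckmrseal:::kappa_for(h),
                             eps = 0.02)
    expect_equal(sum(J), 1, tolerance = 1e-12)
    expect_true(all(J >= 0))
    expect_equal(J, t(J), tolerance = 1e-12)    # exchangeable pair
  }
  # POP with a null allele: opposite apparent homozygotes are possible
  # only through nulls, so their joint probability shrinks with nu -> 0
  J0 <- genotype_pair_probs(0.6, 0.4, 0, ckmrseal:::kappa_for("POP"))
  expect_equal(J0["AA", "BB"], 0)
  J1 <- genotype_pair_probs(0.55, 0.35, 0.10, ckmrseal:::kappa_for("POP"))
  expect_gt(J1["AA", "BB"], 0)
})

test_that("with no nulls the tables equal the 9-state biallelic oracle", {
  for (h in c("UP", "POP", "FSP", "HSP")) {
    for (p in c(0.5, 0.7, 0.9)) {
      kap <- ckmrseal:::kappa_for(h)
      J <- genotype_pair_probs(p, 1 - p, 0, kap)
      expect_equal(unname(J[1:3, 1:3]),
                   unname(biallelic_pair_oracle(p, 1 - p, kap)),
                   tolerance = 1e-12)
      expect_equal(sum(J[4, ]) + sum(J[, 4]), 0)
    }
  }
})

test_that("PLOD scores favour kinship for concordant genotypes", {
  models <- data.frame(p = rep(0.6, 50), q = rep(0.3, 50),
                       nu = rep(0.1, 50))
  g <- rep(c(0L, 1L, 2L), length.out = 50)
  s <- plod(g, g, "POP", models)
  expect_gt(as.numeric(s), 0)
  expect_equal(attr(s, "n_loci"), 50)
  # failed loci are skipped
  g2 <- g; g2[1:10] <- 9L
  expect_equal(attr(plod(g, g2, "POP", models), "n_loci"), 40)
  expect_error(plod(g, rep(9L, 50), "POP", models, min_loci = 5), "called")
  expect_error(plod(c(g[-1], 7L), g, "POP", models), "invalid")
})

test_that("expected PLOD moments match simulated score distributions", {
  set.seed(21)
  L <- 300
  models <- data.frame(p = runif(L, 0.4, 0.7))
  models$nu <- ifelse(seq_len(L) <= 90, runif(90, 0.05, 0.3), 0)
  models$q <- 1 - models$p - models$nu
  tabs <- ckmrseal:::plod_tables(models, "HSP")
  sim_scores <- function(truth, n) {
    s <- numeric(n)
    for (l in seq_len(L)) {
      J <- genotype_pair_probs(models$p[l], models$q[l], models$nu[l],
                               ckmrseal:::kappa_for(truth))
      cells <- sample.int(16, n, replace = TRUE, prob = as.vector(J))
      s <- s + tabs[[l]]$HSP[cells]
    }
    s
  }
  up <- sim_scores("UP", 120)
  hs <- sim_scores("HSP", 120)
  th <- expected_plod(models, "HSP", "HSP")
  tu <- expected_plod(models, "HSP", "UP")
  expect_lt(mean(up), 0)
  expect_gt(mean(hs), 0)
  expect_lt(abs(mean(hs) - th$mean), 3 * sqrt(th$var / 120))
  expect_lt(abs(mean(up) - tu$mean), 3 * sqrt(tu$var / 120))
})

test_that("classification separates kin classes on simulated panels", {
  sch <- build_schedules()
  cfg <- sim_config(N0 = 2500, years = 45, schedules = sch, pi = 0.5,
                    seed = 31, start_year = 1970)
  ped <- simulate_pedigree(cfg)
  sam <- sample_harvest(ped, harvest_design(2006:2013, 25))
  gd <- genotype_design(n_loci = 1200, eps = 0.01, seed = 32)
  pan <- estimate_panel_models(simulate_genotypes(ped, sam$id, gd, seed = 33))
  mu <- expected_plod(pan$models[!pan$sex_linked, ], "HSP", "HSP",
                      eps = 0.01)$mean
  calls <- classify_pairs(pan, threshold = mu / 2)
  tk <- true_kin_pairs(ped, sam$id)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  calls$truth <- tk$class[match(key(calls$id1, calls$id2),
                                key(tk$id1, tk$id2))]
  calls$truth[is.na(calls$truth)] <- "UP"
  # every true POP called POP; no half-sibling called POP or missed
  expect_true(all(calls$call[calls$truth == "POP"] == "POP"))
  hs <- calls[calls$truth %in% c("MHSP", "PHSP"), ]
  expect_true(all(hs$call == "HSP-GGP"))
  # third-order pairs are never promoted to first order
  expect_true(all(calls$call[calls$truth == "HTP"] != "POP"))
  # a threshold above the maximum score calls nothing
  none <- classify_pairs(pan, threshold = max(calls$plod_hsp) + 1)
  expect_equal(sum(none$call != "UP" & none$call != "ambiguous"), 0)
})

test_that("false-negative rates match the threshold tail construction", {
  set.seed(41)
  L <- 600
  models <- data.frame(p = runif(L, 0.4, 0.7))
  models$nu <- ifelse(seq_len(L) <= 180, runif(180, 0.05, 0.3), 0)
  models$q <- 1 - models$p - models$nu
  th <- expected_plod(models, "HSP", "HSP")
  thr <- th$mean - 1.5 * sqrt(th$var)
  truth <- pnorm(thr, th$mean, sqrt(th$var))
  # median over replicate score sets of 50 kin pairs: within 2x of truth
  ratios <- sapply(1:9, function(i) {
    scores <- rnorm(50, th$mean, sqrt(th$var))
    false_negative_rate(scores, models, thr)$fn / truth
  })
  expect_lt(median(ratios), 2)
  expect_gt(median(ratios), 0.5)
  est <- false_negative_rate(rnorm(50, th$mean, sqrt(th$var)), models, thr)
  expect_equal(est$flag, "")
  # far-away threshold: no false negatives
  expect_lt(false_negative_rate(rnorm(50, th$mean, sqrt(th$var)), models,
                                th$mean - 20 * sqrt(th$var))$fn, 1e-12)
  # too few scores above the mean triggers the wide-uncertainty flag
  low <- false_negative_rate(rep(th$mean - 1, 10), models, thr)
  expect_equal(low$flag, "wide-uncertainty")
})
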