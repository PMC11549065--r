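test_that("pedigrees satisfy every structural constraint", {
  sch <- build_schedules()
  cfg <- sim_config(N0 = 4000, years = 50, schedules = sch, pi = 0.34,
                    seed = 61, start_year = 1960)
  ped <- simulate_pedigree(cfg)
  kids <- ped[!is.na(ped$mother), ]
  mo <- kids$mother; fa <- kids$father
  # mothers female, alive at the birth, born before it
  expect_true(all(ped$sex[mo] == "F"))
  expect_true(all(ped$birth[mo] < kids$birth))
  expect_true(all(is.na(ped$death[mo]) | ped$death[mo] >= kids$birth))
  # fathers male, breeder-flagged, alive in the birth year
  expect_true(all(ped$sex[fa] == "M"))
  expect_true(all(ped$breeder[fa]))
  expect_true(all(is.na(ped$death[fa]) | ped$death[fa] >= kids$birth))
  # mtDNA strictly maternal
  expect_true(all(ped$hap[mo] == kids$hap))
  # no animal lives past the maximum age
  done <- ped[!is.na(ped$death), ]
  expect_true(all(done$death - done$birth <= sch$max_age))
})

test_that("identical seeds give identical pedigrees and samples", {
  sch <- build_schedules()
  cfg <- sim_config(N0 = 1500, years = 30, schedules = sch, pi = 0.5,
                    seed = 62, start_year = 1980)
  p1 <- simulate_pedigree(cfg)
  p2 <- simulate_pedigree(cfg)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  s1 <- sample_harvest(p1, harvest_design(2001:2005, 30))
  cfg2 <- cfg
  p3 <- simulate_pedigree(cfg2)
  s3 <- sample_harvest(p3, harvest_design(2001:2005, 30))
  expect_identical(as.data.frame(s1), as.data.frame(s3))
  expect_error(sim_config(N0 = 100, years = 10), "seed")
})

test_that("no births occur without fecundity", {
  sch <- build_schedules(fecundity = rep(0, 40))
  cfg <- sim_config(N0 = 800, years = 10, schedules = sch, pi = 1,
                    seed = 63, start_year = 2000)
  ped <- suppressWarnings(simulate_pedigree(cfg))
  expect_equal(sum(ped$birth > 2000), 0)
})

test_that("equal breeding gives balanced half-sibling sexes; skew does not", {
  sch <- build_schedules()
  counts <- function(pi, seeds) {
    mh <- ph <- 0
    for (s in seeds) {
      cfg <- sim_config(N0 = 4000, years = 45, schedules = sch, pi = pi,
                        seed = s, start_year = 1965)
      ped <- simulate_pedigree(cfg)
      sam <- sample_harvest(ped, harvest_design(2000:2007, 60))
      tk <- true_kin_pairs(ped, sam$id)
      mh <- mh + sum(tk$class == "MHSP")
      ph <- ph + sum(tk$class == "PHSP")
    }
    c(mh = mh, ph = ph)
  }
  eq <- counts(1, 64:66)
  expect_gt(stats::chisq.test(eq)$p.value, 1e-3)
  sk <- counts(0.34, 67:69)
  expect_lt(stats::chisq.test(sk)$p.value, 1e-6)
  # the skewed ratio approximates 1/pi
  expect_lt(abs(sk["ph"] / sk["mh"] - 1 / 0.34), 1.2)
})

test_that("harvest sampling hits the target age profile", {
  sch <- build_schedules()
  cfg <- sim_config(N0 = 30000, years = 55, schedules = sch, pi = 1,
                    seed = 70, start_year = 1960)
  ped <- simulate_pedigree(cfg)
  sam <- sample_harvest(ped, harvest_design(2005:2014, 100))
  expect_equal(nrow(sam), 1000)
  expect_lt(abs(mean(sam$age == 0) - 0.46), 0.02)
  expect_true(all(sam$death_year %in% 2005:2014))
  # zero samples -> empty output
  s0 <- sample_harvest(ped, harvest_design(2005, 0))
  expect_equal(nrow(s0), 0)
  expect_error(sample_harvest(ped, harvest_design(1900, 10)), "span")
})

test_that("whelping-year mother-pup pairs appear as same-year POPs", {
  sch <- build_schedules()
  cfg <- sim_config(N0 = 8000, years = 50, schedules = sch, pi = 1,
                    seed = 71, start_year = 1960)
  ped <- simulate_pedigree(cfg)
  # find a mother and pup that both died in the pup's birth year
  kids <- which(!is.na(ped$mother) & !is.na(ped$death) &
                  ped$death == ped$birth & ped$birth >= 2000)
  mo <- ped$mother[kids]
  both <- which(!is.na(ped$death[mo]) & ped$death[mo] == ped$birth[kids])
  expect_gt(length(both), 0)
  k <- kids[both[1]]; m <- mo[both[1]]
  tk <- true_kin_pairs(ped, c(k, m))
  expect_equal(tk$class, "POP")
  s <- data.frame(id = c(m, k), sex = ped$sex[c(m, k)],
                  birth_year = ped$birth[c(m, k)],
                  death_year = ped$death[c(m, k)])
  kin <- data.frame(id1 = as.character(m), id2 = as.character(k),
                    class = "POP")
  expect_message(cmp <- build_comparisons(rbind(s, data.frame(
    id = "pad", sex = "F", birth_year = 1990, death_year = 2010)),
    kin = kin), "same-year")
  expect_equal(sum(cmp$pop$k), 0)          # excluded as a dependent capture
})

test_that("true kin labels agree with direct pedigree lookups", {
  sch <- build_schedules()
  cfg <- sim_config(N0 = 2000, years = 40, schedules = sch, pi = 0.5,
                    seed = 72, start_year = 1975)
  ped <- simulate_pedigree(cfg)
  ids <- ped$id[ped$birth >= 1995][1:150]
  tk <- true_kin_pairs(ped, ids)
  for (r in seq_len(min(nrow(tk), 200))) {
    i <- as.integer(tk$id1[r]); j <- as.integer(tk$id2[r])
    ok <- switch(tk$class[r],
      POP = identical(ped$mother[j], i) || identical(ped$father[j], i) ||
        identical(ped$mother[i], j) || identical(ped$father[i], j),
      MHSP = ped$mother[i] == ped$mother[j] &&
        !identical(ped$father[i], ped$father[j]),
      PHSP = ped$father[i] == ped$father[j] &&
        !identical(ped$mother[i], ped$mother[j]),
      FSP = ped$mother[i] == ped$mother[j] &&
        ped$father[i] == ped$father[j],
      TRUE)
    expect_true(ok)
  }
  # GGP chains point at a real grandparent
  gg <- tk[tk$class == "GGP", ]
  if (nrow(gg)) {
    j <- as.integer(gg$id2[1]); i <- as.integer(gg$id1[1])
    gps <- c(ped$mother[ped$mother[j]], ped$father[ped$mother[j]],
             ped$mother[ped$father[j]], ped$father[ped$father[j]])
    expect_true(i %in% gps)
  }
})

test_that("simulated genotype panels match their design", {
  sch <- build_schedules()
  cfg <- sim_config(N0 = 10000, years = 12, schedules = sch, pi = 1,
                    seed = 73, start_year = 2000)
  ped <- simulate_pedigree(cfg)
  founders <- ped$id[is.na(ped$mother)][1:5000]
  gd <- genotype_design(n_loci = 40, n_null_loci = 20, eps = 0, seed = 74)
  pan <- simulate_genotypes(ped, founders, gd, seed = 75)
  # founder class frequencies match HWE-with-nulls within 3 SEs
  tf <- attr(pan, "true_freqs")
  for (l in c(1, 10, 25, 40)) {
    cp <- locus_class_probs(tf$p[l], tf$q[l], tf$nu[l])
    obs <- tabulate(ckmrseal:::class_to_index(pan$classes[l, ]), 4) / 5000
    se <- sqrt(cp * (1 - cp) / 5000)
    expect_true(all(abs(obs - cp) < 3.5 * se + 1e-9))
  }
  # no failures at null-free loci when eps = 0
  expect_equal(sum(pan$classes[21:40, ] == 9L), 0)
  # parent and offspring never opposite homozygotes at null-free loci
  kids <- ped$id[!is.na(ped$mother)][1:300]
  pan2 <- simulate_genotypes(ped, kids, gd, seed = 76)
  for (k in seq_along(kids)) {
    moid <- as.character(ped$mother[kids[k]])
    pan3 <- simulate_genotypes(ped, c(kids[k], ped$mother[kids[k]]), gd,
                               seed = 76)
    g <- pan3$classes[21:40, ]
    expect_false(any(g[, 1] == 0L & g[, 2] == 2L))
    expect_false(any(g[, 1] == 2L & g[, 2] == 0L))
    if (k >= 20) break
  }
})
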