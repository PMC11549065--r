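test_that("maternal POP probability is 1/K in a single-age toy population", {
  k <- 3; K <- 250
  sch <- single_age_schedules(k = k, s = 0.9)
  NF <- numeric(10); NF[k + 1] <- K        # K reproducing females
  NF[1] <- K                               # some pups, irrelevant to weights
  ctx <- kin_context(toy_trajectory(NF, schedules = sch), sch)
  mom <- list(sex = "F", birth_year = 2005 - k, death_year = 2010)
  kid <- list(sex = "F", birth_year = 2005, death_year = 2006)
  expect_equal(p_pop(mom, kid, ctx), 1 / K)
  # dead before the offspring's birth
  expect_equal(p_pop(list(sex = "F", birth_year = 2002, death_year = 2004),
                     kid, ctx), 0)
  # zero fecundity at the parent's age
  expect_equal(p_pop(list(sex = "F", birth_year = 2003, death_year = 2010),
                     kid, ctx), 0)
  expect_error(p_pop(list(birth_year = 1, death_year = 2), kid, ctx), "sex")
})

test_that("motherhood is conserved over an enumerated closed population", {
  sch <- build_schedules()
  tr <- make_trajectory(sch, 5e4, ref_year = 2020, year0 = 1960)
  ctx <- kin_context(tr, sch)
  b <- 2000
  kid <- list(sex = "F", birth_year = b, death_year = 2001)
  probs <- sapply(0:39, function(a)
    p_pop(list(sex = "F", birth_year = b - a, death_year = 2020), kid, ctx))
  it <- match(b, tr$years)
  expect_equal(sum(tr$NF[it, ] * probs), 1, tolerance = 1e-12)
})

test_that("half-sibling kernels respect structural zeros and pi scaling", {
  sch <- build_schedules()
  tr <- make_trajectory(sch, 1e5, ref_year = 2020, year0 = 1960)
  ctx1 <- kin_context(tr, sch, pi = 1)
  ctx2 <- kin_context(tr, sch, pi = 0.5)
  o <- list(sex = "F", birth_year = 2000, death_year = 2006)
  y <- list(sex = "M", birth_year = 2004, death_year = 2010)
  same <- list(sex = "M", birth_year = 2000, death_year = 2003)
  # same-cohort maternal siblings are impossible; paternal are not
  expect_equal(p_mhsp(o, same, ctx1), 0)
  expect_gt(p_phsp(o, same, ctx1), 0)
  # halving pi doubles the paternal probability only
  expect_equal(p_phsp(o, y, ctx2) / p_phsp(o, y, ctx1), 2)
  expect_equal(p_mhsp(o, y, ctx2), p_mhsp(o, y, ctx1))
  expect_error(p_mhsp(y, o, ctx1), "ordered")
  expect_error(kin_context(tr, sch, pi = 0), "pi")
  # dead adult survival: no shared mother can survive a gap if adult
  # survival is zero
  sch0 <- build_schedules()
  sch0$phi[2:40] <- 0
  ctx0 <- kin_context(toy_trajectory(rep(10, 40), schedules = sch0), sch0)
  expect_equal(p_mhsp(list(sex = "F", birth_year = 2005, death_year = 2005),
                      list(sex = "F", birth_year = 2008, death_year = 2008),
                      ctx0), 0)
})

test_that("pi = 1 reduces the paternal kernel to the maternal mirror", {
  # identical fecundity and maturity schedules: with pi = 1 and a shared
  # trajectory, p_phsp must equal p_mhsp for every positive gap
  f <- logistic_ogive(0:39, 5, 1, 0.9)
  sch <- build_schedules(fecundity = f, maturity = f)
  tr <- make_trajectory(sch, 8e4, ref_year = 2020, year0 = 1960)
  ctx <- kin_context(tr, sch, pi = 1)
  for (d in c(1, 3, 7)) {
    o <- list(sex = "F", birth_year = 2000, death_year = 2001)
    y <- list(sex = "F", birth_year = 2000 + d, death_year = 2001 + d)
    expect_equal(p_phsp(o, y, ctx), p_mhsp(o, y, ctx), tolerance = 1e-12)
  }
})

test_that("grandparent chains obey mtDNA and maturity constraints", {
  sch <- build_schedules(fecundity = list(type = "knife_edge", age = 5),
                         maturity = list(type = "knife_edge", age = 5))
  tr <- make_trajectory(sch, 1e5, ref_year = 2020, year0 = 1950)
  ctx <- kin_context(tr, sch)
  male <- list(sex = "M", birth_year = 1995, death_year = 2007)
  kid <- list(sex = "F", birth_year = 2008, death_year = 2010)
  # a male grandparent never shares mtDNA with the grandchild
  expect_equal(p_ggp(male, kid, TRUE, ctx), 0)
  expect_gt(p_ggp(male, kid, FALSE, ctx), 0)
  # birth gap below twice the breeding age cannot be a GGP
  fem <- list(sex = "F", birth_year = 2000, death_year = 2012)
  near <- list(sex = "F", birth_year = 2009, death_year = 2010)
  expect_equal(p_ggp(fem, near, NA, ctx), 0)
})

test_that("grandparent kernel equals a hand-enumerated chain product", {
  # deterministic toy: knife-edge reproduction at age k, constant survival
  k <- 4; s <- 0.85
  f <- numeric(21); f[(k + 1):21] <- 1
  sch <- build_schedules(raw_params(0, 1, -log(s)), fecundity = f,
                         maturity = f, max_age = 20)
  NF <- rep(50, 21)
  ctx <- kin_context(toy_trajectory(NF, years = 1980:2020, schedules = sch),
                     sch)
  gp <- list(sex = "F", birth_year = 1990, death_year = 2001)
  gc <- list(sex = "M", birth_year = 2003, death_year = 2004)
  # independent enumeration over intermediate birth years and sexes
  FF <- sum(NF * f); MM <- sum(NF * f)
  hand <- function(sexes) {
    tot <- 0
    for (cc in 1991:2001) {                 # grandparent alive through 2001
      a_g <- cc - 1990
      E <- if (a_g <= 20) f[a_g + 1] else 0
      a_i <- 2003 - cc
      if (a_i < 1 || a_i > 20) next
      for (s_int in sexes)
        tot <- tot + E * 0.5 * s^a_i * f[a_i + 1] / FF
    }
    tot
  }
  expect_equal(p_ggp(gp, gc, TRUE, ctx), hand("F"), tolerance = 1e-12)
  expect_equal(p_ggp(gp, gc, FALSE, ctx), hand("M"), tolerance = 1e-12)
  expect_equal(p_ggp(gp, gc, NA, ctx), hand(c("F", "M")), tolerance = 1e-12)
})

test_that("kernels scale as 1/N and stay within [0, 1]", {
  sch <- build_schedules()
  tr1 <- make_trajectory(sch, 5e4, ref_year = 2020, year0 = 1960)
  tr2 <- tr1; tr2$NF <- 2 * tr1$NF
  c1 <- kin_context(tr1, sch, pi = 0.4)
  c2 <- kin_context(tr2, sch, pi = 0.4)
  o <- list(sex = "F", birth_year = 1995, death_year = 2008)
  y <- list(sex = "M", birth_year = 2006, death_year = 2010)
  for (fn in list(p_mhsp, p_phsp)) {
    expect_equal(fn(o, y, c1) / fn(o, y, c2), 2, tolerance = 1e-10)
    expect_true(fn(o, y, c1) >= 0 && fn(o, y, c1) <= 1)
  }
  expect_equal(p_ggp(o, y, NA, c1) / p_ggp(o, y, NA, c2), 2,
               tolerance = 1e-10)
  expect_equal(p_pop(o, y, c1) / p_pop(o, y, c2), 2, tolerance = 1e-10)
})

test_that("second-order mixture composes HSP and GGP with thinning", {
  sch <- build_schedules()
  tr <- make_trajectory(sch, 1e5, ref_year = 2020, year0 = 1950)
  o <- list(sex = "F", birth_year = 1994, death_year = 2006)
  y <- list(sex = "F", birth_year = 2006, death_year = 2008)
  ctx0 <- kin_context(tr, sch, pi = 0.4, fn_rate = 0)
  ctx3 <- kin_context(tr, sch, pi = 0.4, fn_rate = 0.3)
  expect_equal(p_second_order(o, y, TRUE, ctx0),
               p_mhsp(o, y, ctx0) + p_ggp(o, y, TRUE, ctx0))
  expect_equal(p_second_order(o, y, TRUE, ctx3),
               0.7 * p_second_order(o, y, TRUE, ctx0))
  expect_error(kin_context(tr, sch, fn_rate = 1), "fn_rate")
  # relative HSP probability: identity, infeasible-GGP limit, undefined case
  rel <- rel_prob_hsp(o, y, TRUE, ctx0)
  expect_equal(rel, p_mhsp(o, y, ctx0) /
                 (p_mhsp(o, y, ctx0) + p_ggp(o, y, TRUE, ctx0)))
  near <- list(sex = "F", birth_year = 2003, death_year = 2004)
  sch_k <- build_schedules(fecundity = list(type = "knife_edge", age = 5),
                           maturity = list(type = "knife_edge", age = 5))
  ctx_k <- kin_context(make_trajectory(sch_k, 1e5, 2020, 1950), sch_k)
  expect_equal(rel_prob_hsp(list(sex = "F", birth_year = 2000,
                                 death_year = 2010), near, NA, ctx_k), 1)
  expect_warning(
    out <- rel_prob_hsp(list(sex = "F", birth_year = 2003,
                             death_year = 2003),
                        list(sex = "F", birth_year = 2003,
                             death_year = 2003), TRUE, ctx_k),
    "undefined")
  expect_true(is.na(out))
})
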