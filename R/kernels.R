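#' Kinship kernel context
#'
#' Bundles everything the pairwise kinship probability kernels condition on:
#' the demographic trajectory, the life-history schedules, the fraction
#' `pi` of sexually mature males that persistently breed, and the
#' false-negative probability for second-order kin identification.
#' Pre-computes the year-indexed reproductive-output denominators and the
#' half-sibling lookup tables so repeated kernel evaluation is cheap.
#'
#' @param trajectory A [project()] / [make_trajectory()] result.
#' @param schedules Life-history schedules (default: those of `trajectory`).
#' @param pi Breeding fraction of mature males, in `(0, 1]`. Values below 1
#'   concentrate paternity on fewer males, inflating paternal half-sibling
#'   probabilities by `1/pi` while parent-offspring probabilities are
#'   unaffected.
#' @param fn_rate False-negative probability for the pooled second-order
#'   (HSP + GGP) kin class, in `[0, 1)`.
#' @return An object of class `kin_context`.
#' @export
kin_context <- function(trajectory, schedules = trajectory$schedules,
                        pi = 1, fn_rate = 0) {
  stopifnot(inherits(trajectory, "pop_trajectory"),
            inherits(schedules, "life_schedules"))
  if (pi <= 0 || pi > 1) stop("pi must lie in (0, 1]")
  if (fn_rate < 0 || fn_rate >= 1) stop("fn_rate must lie in [0, 1)")
  A <- schedules$max_age
  f <- schedules$fecundity
  m <- schedules$maturity
  phi <- schedules$phi
  NF <- trajectory$NF
  years <- trajectory$years
  # survivorship from birth: S[a + 1] = prod(phi[0..a-1])
  S <- c(1, cumprod(phi))
  FF <- as.vector(NF %*% f)   # expected total births in each year
  MM <- as.vector(NF %*% m)   # male reproductive-output denominator
  WF <- NF * rep(f, each = nrow(NF))
  WF <- WF / ifelse(FF > 0, FF, 1)      # age distribution of mothers by year
  WM <- NF * rep(m, each = nrow(NF))
  WM <- WM / ifelse(MM > 0, MM, 1)      # age distribution of fathers by year
  # Rf[a + 1, d + 1]: P(parent aged a at first birth survives d more years) *
  #                   her fecundity at age a + d (zero beyond the last class)
  idx <- outer(0:A, 0:A, `+`)           # parent age at the second birth
  ok <- idx <= A
  surv <- matrix(0, A + 1, A + 1)
  surv[ok] <- (S[idx[ok] + 1] / S[rep(0:A, A + 1)[as.vector(ok)] + 1])
  surv[!is.finite(surv)] <- 0     # 0/0 when survivorship already hit zero
  Rf <- Rm <- matrix(0, A + 1, A + 1)
  Rf[ok] <- surv[ok] * f[idx[ok] + 1]
  Rm[ok] <- surv[ok] * m[idx[ok] + 1]
  # Pm[t, d + 1] = sum_a WF[t, a] * surv(a, d) * f_{a+d}; likewise Pp for males
  Pm <- WF %*% Rf
  Pp <- WM %*% Rm
  structure(list(trajectory = trajectory, schedules = schedules,
                 pi = pi, fn_rate = fn_rate,
                 A = A, f = f, m = m, phi = phi, S = S,
                 years = years, y0 = years[1], NF = NF,
                 FF = FF, MM = MM, WF = WF, WM = WM, Pm = Pm, Pp = Pp),
            class = "kin_context")
}

year_index <- function(ctx, year, what = "year") {
  idx <- year - ctx$y0 + 1L
  if (any(idx < 1L | idx > length(ctx$years)))
    stop(sprintf("trajectory does not cover %s %s", what,
                 paste(year[idx < 1L | idx > length(ctx$years)], collapse = ", ")))
  idx
}

as_record <- function(x) {
  x <- as.list(x)
  stopifnot(!is.null(x$birth_year), !is.null(x$death_year))
  if (is.null(x$age)) x$age <- x$death_year - x$birth_year
  if (x$death_year < x$birth_year) stop("death_year precedes birth_year")
  x
}

#' Parent-offspring pair probability
#'
#' Probability that `parent` is the mother (if female) or father (if male)
#' of `offspring`, conditional on both animals' covariates and the
#' demographic trajectory. Maternal:
#' `P = f_a / sum_a' N^F_{b,a'} f_a'` for a mother aged `a` and alive in the
#' offspring's birth year `b`; paternal replaces fecundity with male
#' maturity and the female abundances with male abundances. Under lethal
#' sampling a parent dead before the offspring's birth (mothers) or before
#' the mating/birth year (fathers) has probability zero. The male breeding
#' fraction `pi` cancels for parent-offspring pairs: a randomly chosen
#' mature male is a breeder with probability `pi`, but each breeder's
#' expected paternity share is inflated by `1/pi`.
#'
#' @param parent,offspring Sample records: lists or one-row data frames with
#'   `sex` (`"F"`/`"M"`, parent only), `birth_year` and `death_year`.
#' @param ctx A [kin_context()].
#' @return A probability.
#' @export
p_pop <- function(parent, offspring, ctx) {
  stopifnot(inherits(ctx, "kin_context"))
  parent <- as_record(parent); offspring <- as_record(offspring)
  if (is.null(parent$sex) || !parent$sex %in% c("F", "M"))
    stop("parent sex must be 'F' or 'M'")
  b <- offspring$birth_year
  it <- year_index(ctx, b, "birth year")
  a <- b - parent$birth_year
  if (a < 0 || a > ctx$A) return(0)
  if (parent$death_year < b) return(0)  # dead before the offspring's birth
  if (parent$sex == "F") {
    if (ctx$FF[it] <= 0) return(0)
    ctx$f[a + 1] / ctx$FF[it]
  } else {
    if (ctx$MM[it] <= 0) return(0)
    ctx$m[a + 1] / ctx$MM[it]
  }
}

#' Maternal half-sibling pair probability
#'
#' Probability that the two animals share a mother. The shared (unobserved)
#' mother's age distribution at the older sibling's birth is the
#' fecundity-weighted female age distribution; she must survive the birth
#' gap and whelp again in the younger sibling's birth year:
#' `P = sum_a [N^F_{bi,a} f_a / sum N^F_{bi} f] * prod_t phi_{a+t} *
#' f_{a+gap} / sum_a' N^F_{bj,a'} f_a'`.
#' A gap of zero is impossible (one pup per female per year).
#'
#' @param older,younger Sample records (see [p_pop()]); `older` must have
#'   the earlier (or equal) birth year.
#' @param ctx A [kin_context()].
#' @return A probability.
#' @export
p_mhsp <- function(older, younger, ctx) {
  stopifnot(inherits(ctx, "kin_context"))
  older <- as_record(older); younger <- as_record(younger)
  d <- younger$birth_year - older$birth_year
  if (d < 0) stop("pair must be ordered by birth year (older first)")
  if (d == 0 || d > ctx$A) return(0)
  ii <- year_index(ctx, older$birth_year, "birth year")
  ij <- year_index(ctx, younger$birth_year, "birth year")
  if (ctx$FF[ij] <= 0) return(0)
  ctx$Pm[ii, d + 1] / ctx$FF[ij]
}

#' Paternal half-sibling pair probability
#'
#' Probability that the two animals share a father. Mirrors [p_mhsp()] with
#' male maturity in place of fecundity, except that (i) a birth gap of zero
#' is possible (a male can breed with several females in one season) and
#' (ii) conditioning on the first offspring identifies the father as a
#' breeder, so the competing-father pool shrinks by the breeding fraction:
#' the probability is proportional to `1/pi`.
#'
#' @inheritParams p_mhsp
#' @return A probability.
#' @export
p_phsp <- function(older, younger, ctx) {
  stopifnot(inherits(ctx, "kin_context"))
  older <- as_record(older); younger <- as_record(younger)
  d <- younger$birth_year - older$birth_year
  if (d < 0) stop("pair must be ordered by birth year (older first)")
  if (d > ctx$A) return(0)
  ii <- year_index(ctx, older$birth_year, "birth year")
  ij <- year_index(ctx, younger$birth_year, "birth year")
  if (ctx$MM[ij] <= 0) return(0)
  ctx$Pp[ii, d + 1] / (ctx$pi * ctx$MM[ij])
}

# Grandparent-grandchild chain sums for a set of (sex_i, b_i, d_i, b_j) rows.
# Chains run grandparent -> intermediate parent (born c, sex s) -> grandchild.
# For a male intermediate the breeder probability pi and the breeder-pool
# denominator pi * sum(N^M m) cancel, as they do for the male grandparent's
# own expected offspring, so the chain probabilities are free of pi.
# Returns ggp_shared (mtDNA-sharing chain: female grandparent via a female
# intermediate) and ggp_unshared (all remaining chains).
ggp_components <- function(sex_i, b_i, d_i, b_j, ctx) {
  n <- length(b_i)
  shared <- unshared <- numeric(n)
  year_index(ctx, b_j, "birth year")
  b_i <- as.integer(b_i); d_i <- as.integer(d_i); b_j <- as.integer(b_j)
  # expand every row over its candidate intermediate birth years c
  c_lo <- b_i + 1L
  c_hi <- pmin(d_i, b_j - 1L, b_i + ctx$A)
  len <- pmax(c_hi - c_lo + 1L, 0L)
  if (!any(len > 0)) return(list(shared = shared, unshared = unshared))
  row <- rep.int(seq_len(n), len)
  cs <- sequence(len) - 1L + c_lo[row]
  k <- b_j[row] - cs                       # intermediate's age at b_j
  keep <- k >= 1L & k <= ctx$A
  row <- row[keep]; cs <- cs[keep]; k <- k[keep]
  if (!length(row)) return(list(shared = shared, unshared = unshared))
  ic <- year_index(ctx, cs, "year")
  ij <- year_index(ctx, b_j[row], "birth year")
  ai <- cs - b_i[row]                      # grandparent's age at c
  isF <- sex_i[row] == "F"
  E <- numeric(length(row))
  E[isF] <- ctx$f[ai[isF] + 1]             # expected pups of a female
  # expected offspring of a male: relative share of all births that year
  mm <- ctx$MM[ic]
  E[!isF] <- ctx$m[ai[!isF] + 1] *
    ifelse(mm[!isF] > 0, ctx$FF[ic][!isF] / mm[!isF], 0)
  Sjuv <- ctx$S[k + 1]                     # intermediate survives 0 -> k
  shareF <- ctx$f[k + 1] / ifelse(ctx$FF[ij] > 0, ctx$FF[ij], Inf)
  shareM <- ctx$m[k + 1] / ifelse(ctx$MM[ij] > 0, ctx$MM[ij], Inf)
  viaF <- E * 0.5 * Sjuv * shareF          # intermediate is a daughter/son:
  viaM <- E * 0.5 * Sjuv * shareM          # 0.5 is the birth sex ratio
  sh_c <- ifelse(isF, viaF, 0)             # only the all-female chain
  un_c <- ifelse(isF, viaM, viaF + viaM)   # shares the grandparent's mtDNA
  agg <- rowsum(cbind(sh_c, un_c), row)
  at <- as.integer(rownames(agg))
  shared[at] <- agg[, 1]; unshared[at] <- agg[, 2]
  list(shared = shared, unshared = unshared)
}

#' Grandparent-grandchild pair probability
#'
#' Probability that the older animal is a grandparent of the younger,
#' summing over the sex and birth year of the unobserved intermediate
#' parent. Each chain multiplies (i) the older animal's expected offspring
#' of the intermediate sex in each candidate year it was alive (lethal
#' sampling makes aliveness known exactly), (ii) the intermediate's
#' survivorship from birth to its age at the younger animal's birth, and
#' (iii) the intermediate's relative reproductive output in that year.
#' Mitochondrial DNA is shared only along the all-female chain, so a male
#' older animal has zero probability in the shared stratum; with
#' `shares_mtdna = NA` both strata are summed.
#'
#' @inheritParams p_mhsp
#' @param shares_mtdna `TRUE` for the mtDNA-sharing stratum, `FALSE` for the
#'   non-sharing stratum, `NA` for both.
#' @return A probability.
#' @export
p_ggp <- function(older, younger, shares_mtdna, ctx) {
  stopifnot(inherits(ctx, "kin_context"))
  older <- as_record(older); younger <- as_record(younger)
  if (is.null(older$sex) || !older$sex %in% c("F", "M"))
    stop("the candidate grandparent's sex must be 'F' or 'M'")
  if (younger$birth_year < older$birth_year)
    stop("pair must be ordered by birth year (older first)")
  year_index(ctx, c(older$birth_year, younger$birth_year), "birth year")
  g <- ggp_components(older$sex, older$birth_year, older$death_year,
                      younger$birth_year, ctx)
  if (is.na(shares_mtdna)) g$shared + g$unshared
  else if (shares_mtdna) g$shared
  else g$unshared
}

#' Pooled second-order kin probability
#'
#' Probability that a pair is observed as second-order kin (HSP or GGP),
#' conditional on its mtDNA stratum. Maternal half-siblings always share
#' mtDNA and paternal half-siblings never do (chance haplotype identity is
#' neglected), so the sharing stratum pools MHSP with the all-female GGP
#' chain and the non-sharing stratum pools PHSP with the remaining chains.
#' The whole mixture is thinned by `1 - fn_rate`, the probability that a
#' true second-order pair survives the PLOD calling threshold.
#'
#' @inheritParams p_ggp
#' @return A probability.
#' @export
p_second_order <- function(older, younger, shares_mtdna, ctx) {
  stopifnot(inherits(ctx, "kin_context"))
  o <- as_record(older); y <- as_record(younger)
  d <- y$birth_year - o$birth_year
  if (d < 0) stop("pair must be ordered by birth year (older first)")
  ggp <- p_ggp(older, younger, shares_mtdna, ctx)
  hsp <- if (is.na(shares_mtdna)) {
    p_mhsp(older, younger, ctx) + p_phsp(older, younger, ctx)
  } else if (shares_mtdna) {
    p_mhsp(older, younger, ctx)
  } else {
    p_phsp(older, younger, ctx)
  }
  (1 - ctx$fn_rate) * (hsp + ggp)
}

#' Relative probability that a second-order pair is an HSP rather than a GGP
#'
#' `P(HSP) / (P(HSP) + P(GGP))` for an observed second-order pair in its
#' mtDNA stratum. Pairs whose covariates make grandparenthood infeasible
#' (short birth gap, juvenile older member) have value 1.
#'
#' @inheritParams p_ggp
#' @return A ratio in `[0, 1]`, or `NA` (with a warning) when both
#'   component probabilities are zero.
#' @export
rel_prob_hsp <- function(older, younger, shares_mtdna, ctx) {
  hsp <- if (isTRUE(shares_mtdna)) p_mhsp(older, younger, ctx)
         else if (isFALSE(shares_mtdna)) p_phsp(older, younger, ctx)
         else p_mhsp(older, younger, ctx) + p_phsp(older, younger, ctx)
  ggp <- p_ggp(older, younger, shares_mtdna, ctx)
  if (hsp + ggp <= 0) {
    warning("both HSP and GGP probabilities are zero; ratio undefined")
    return(NA_real_)
  }
  hsp / (hsp + ggp)
}

# Vectorised kernels over grouped covariate tables -------------------------

# groups: data.table with sex_p, b_p, d_p, b_o -> probability vector
pop_group_probs <- function(groups, ctx) {
  it <- year_index(ctx, groups$b_o, "birth year")
  a <- groups$b_o - groups$b_p
  ok <- a >= 0 & a <= ctx$A & groups$d_p >= groups$b_o
  p <- numeric(nrow(groups))
  fem <- ok & groups$sex_p == "F"
  mal <- ok & groups$sex_p == "M"
  p[fem] <- ctx$f[a[fem] + 1] / ctx$FF[it[fem]]
  p[mal] <- ctx$m[a[mal] + 1] / ctx$MM[it[mal]]
  p[!is.finite(p)] <- 0
  p
}

# groups: data.table with sex_i, b_i, d_i, b_j.
# Returns per-row detection probabilities split by mtDNA stratum:
#   p_m = P(pair observed as second-order kin and shares mtDNA)
#   p_p = P(observed as kin, not sharing)     p_tot = p_m + p_p
# Maternal half-siblings always share mtDNA and paternal ones never do
# (chance sharing neglected), so the split is exact given the chains.
second_order_group_probs <- function(groups, ctx) {
  ii <- year_index(ctx, groups$b_i, "birth year")
  ij <- year_index(ctx, groups$b_j, "birth year")
  d <- groups$b_j - groups$b_i
  if (any(d < 0)) stop("second-order groups must be ordered by birth year")
  mh <- ifelse(d >= 1 & d <= ctx$A,
               ctx$Pm[cbind(ii, pmin(d, ctx$A) + 1)] / ctx$FF[ij], 0)
  ph <- ifelse(d <= ctx$A,
               ctx$Pp[cbind(ii, pmin(d, ctx$A) + 1)] / (ctx$pi * ctx$MM[ij]), 0)
  mh[!is.finite(mh)] <- 0
  ph[!is.finite(ph)] <- 0
  key <- paste(groups$sex_i, groups$b_i, groups$d_i, groups$b_j)
  u <- which(!duplicated(key))
  gg_u <- ggp_components(groups$sex_i[u], groups$b_i[u], groups$d_i[u],
                         groups$b_j[u], ctx)
  mi <- match(key, key[u])
  gg <- list(shared = gg_u$shared[mi], unshared = gg_u$unshared[mi])
  thin <- 1 - ctx$fn_rate
  p_m <- thin * (mh + gg$shared)
  p_p <- thin * (ph + gg$unshared)
  list(p_m = p_m, p_p = p_p, p_tot = p_m + p_p,
       mhsp = mh, phsp = ph, ggp_shared = gg$shared,
       ggp_unshared = gg$unshared)
}
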