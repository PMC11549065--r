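#' Female Leslie matrix implied by the schedules
#'
#' Post-breeding census, female-only projection matrix over age classes
#' `0..max_age`. A female aged `b` at the census survives with probability
#' `phi_b`, is aged `b + 1` at the next census, and whelps a female pup with
#' probability `0.5 * f_{b+1}` (50/50 sex ratio at birth). Fertility
#' coefficients are therefore `0.5 * phi_b * f_{b+1}` and the sub-diagonal
#' carries the survival probabilities; the terminal age class dies after its
#' final breeding season.
#'
#' @param schedules A [build_schedules()] object.
#' @return A `(max_age + 1)` square matrix.
#' @export
leslie_matrix <- function(schedules) {
  stopifnot(inherits(schedules, "life_schedules"))
  A <- schedules$max_age
  L <- matrix(0, A + 1, A + 1)
  # column a+1 holds age class a at time t-1
  L[1, 1:A] <- 0.5 * schedules$phi[1:A] * schedules$fecundity[2:(A + 1)]
  L[cbind(2:(A + 1), 1:A)] <- schedules$phi[1:A]
  L
}

#' Finite annual population growth rate
#'
#' Dominant eigenvalue `lambda` of the female Leslie matrix. A value of 1
#' is a stationary population; 1.04 is 4% annual growth.
#'
#' @param schedules A [build_schedules()] object.
#' @return A numeric scalar with attribute `stable_age` (the normalised
#'   dominant right eigenvector) and attribute `degenerate` set to `TRUE`
#'   when no strictly positive eigenvector exists (reducible matrix, e.g.
#'   zero fecundity everywhere).
#' @export
growth_rate <- function(schedules) {
  L <- leslie_matrix(schedules)
  e <- eigen(L)
  # an imprimitive Leslie matrix (isolated reproducing ages) has several
  # eigenvalues of maximal modulus; the growth rate is the real positive one
  mx <- max(Mod(e$values))
  i <- which(Mod(e$values) > mx - 1e-9 * max(mx, 1) &
               abs(Im(e$values)) < 1e-9 & Re(e$values) > 0)
  i <- if (length(i)) i[1] else which.max(Mod(e$values))
  lambda <- Re(e$values[i])
  v <- Re(e$vectors[, i])
  if (sum(v) < 0) v <- -v
  degenerate <- any(abs(Im(e$values[i])) > 1e-8) || any(v < -1e-10) ||
    all(v[1] <= 0)
  v[v < 0] <- 0
  if (sum(v) > 0) v <- v / sum(v)
  structure(lambda, stable_age = v, degenerate = degenerate)
}

#' Stable age distribution
#'
#' @param schedules A [build_schedules()] object.
#' @return Normalised stable age proportions (length `max_age + 1`).
#' @export
stable_age <- function(schedules) {
  attr(growth_rate(schedules), "stable_age")
}

#' Project an age-structured population
#'
#' Deterministic projection under a post-breeding census. Each year, age
#' classes advance with survival `phi_{a-1}`
#' (`N_{t,a} = N_{t-1,a-1} * phi_{a-1}`), and recruitment is
#' `N_{t,0}^F = N_{t,0}^M = 0.5 * sum_a N_{t,a}^F * f_a`: every surviving
#' female whelps a single pup with probability equal to her
#' fecundity-at-age in the pupping year. Female and male numbers are equal
#' at every age (50/50 birth sex ratio, identical survival).
#'
#' @param schedules A [build_schedules()] object.
#' @param N0_total Total abundance (both sexes, all ages) in the first year.
#' @param T Number of years to project (`T >= 1`).
#' @param start_year Calendar year of the initial state (default 0).
#' @param init_ages Initial female age proportions; defaults to the stable
#'   age distribution, in which case every projection step multiplies the
#'   population by `lambda`.
#'
#' @return An object of class `pop_trajectory`: a list with `years`
#'   (length `T + 1`), `NF` (a `(T + 1) x (max_age + 1)` matrix of expected
#'   female counts; male counts are identical), `lambda`, and `schedules`.
#' @export
project <- function(schedules, N0_total, T, start_year = 0, init_ages = NULL) {
  stopifnot(inherits(schedules, "life_schedules"))
  if (T <= 0) stop("T must be a positive number of years")
  A <- schedules$max_age
  gr <- growth_rate(schedules)
  if (is.null(init_ages)) init_ages <- attr(gr, "stable_age")
  stopifnot(length(init_ages) == A + 1)
  NF <- matrix(0, T + 1, A + 1)
  NF[1, ] <- 0.5 * N0_total * init_ages / sum(init_ages)
  phi <- schedules$phi
  f <- schedules$fecundity
  for (t in 2:(T + 1)) {
    NF[t, 2:(A + 1)] <- NF[t - 1, 1:A] * phi[1:A]
    NF[t, 1] <- 0.5 * sum(NF[t, 2:(A + 1)] * f[2:(A + 1)])
  }
  structure(list(years = start_year + 0:T, NF = NF,
                 lambda = as.numeric(gr), schedules = schedules),
            class = "pop_trajectory")
}

#' @export
print.pop_trajectory <- function(x, ...) {
  n <- nrow(x$NF)
  cat(sprintf("Population trajectory %d..%d (lambda = %.4f)\n",
              min(x$years), max(x$years), x$lambda))
  cat(sprintf("  total abundance: %.0f (first year) -> %.0f (last year)\n",
              2 * sum(x$NF[1, ]), 2 * sum(x$NF[n, ])))
  invisible(x)
}

#' Total abundance by year from a trajectory
#'
#' @param trajectory A [project()] or [make_trajectory()] result.
#' @param years Calendar years (default: all).
#' @return Named numeric vector of total (both-sex, all-age) abundance.
#' @export
total_abundance <- function(trajectory, years = trajectory$years) {
  idx <- match(years, trajectory$years)
  if (anyNA(idx)) stop("trajectory does not cover the requested years")
  stats::setNames(2 * rowSums(trajectory$NF[idx, , drop = FALSE]), years)
}

#' Build a stable-age trajectory anchored to a reference abundance
#'
#' Convenience wrapper around [project()]: the population starts at the
#' stable age distribution in `year0` and is scaled so that total abundance
#' in `ref_year` equals `N_ref`. Under the stable start the trajectory grows
#' (or shrinks) geometrically at `lambda`.
#'
#' @param schedules A [build_schedules()] object.
#' @param N_ref Total abundance (both sexes, all ages) in `ref_year`.
#' @param ref_year Reference calendar year.
#' @param year0 First calendar year of the trajectory (`year0 <= ref_year`);
#'   default one maximum lifespan before `ref_year`.
#' @param end_year Last year (default `ref_year`).
#' @return A `pop_trajectory` object.
#' @export
make_trajectory <- function(schedules, N_ref, ref_year,
                            year0 = ref_year - schedules$max_age - 1,
                            end_year = ref_year) {
  stopifnot(year0 <= ref_year, end_year >= ref_year || end_year >= year0 + 1)
  gr <- growth_rate(schedules)
  lambda <- as.numeric(gr)
  N0 <- N_ref / lambda^(ref_year - year0)
  project(schedules, N0, T = end_year - year0, start_year = year0,
          init_ages = attr(gr, "stable_age"))
}
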