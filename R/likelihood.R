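#' Configuration for CKMR model fitting
#'
#' Collects every model switch and threshold of the pseudo-likelihood so
#' that a fit is fully reproducible from its configuration echo.
#'
#' @param pi_free Estimate the male breeding fraction `pi` (TRUE) or fix it
#'   (FALSE, the equal-breeding model).
#' @param pi_fixed Value of `pi` when not estimated.
#' @param lambda0 Growth rate imposed through the penalty (1 = stationary).
#' @param fn_rate False-negative probability for second-order kin calls
#'   (default 0.003, appropriate for a mid-range PLOD threshold).
#' @param eta_prior Prior means of the RAW survival parameters
#'   ([raw_params()]).
#' @param eta_sd Gaussian penalty SDs for `eta1, eta2, eta3`. Defaults keep
#'   survival close to the meta-analysis prior while letting the growth
#'   constraint bend the curve.
#' @param lambda_weight Weight of the quadratic penalty on
#'   `(lambda - lambda0)^2`; the default `1e4` holds `lambda` within about
#'   0.01 of `lambda0`.
#' @param fix_eta Hold survival parameters at `eta_prior` instead of
#'   estimating them.
#' @param fecundity,maturity Schedules passed to [build_schedules()]; fixed
#'   during estimation.
#' @param max_age Oldest age class.
#' @param ref_year Calendar year whose total abundance is the `N`
#'   parameter; default: the last sampling year.
#' @param report_years Years averaged for the reported abundance when
#'   `lambda0 != 1`; default: the 31 years ending at `ref_year`.
#' @param restarts Dispersion factors for the abundance starting value.
#' @return A list of class `ckmr_config`.
#' @export
ckmr_config <- function(pi_free = FALSE, pi_fixed = 1.0, lambda0 = 1.0,
                        fn_rate = 0.003,
                        eta_prior = raw_params(),
                        eta_sd = c(0.01, 0.3, 0.02),
                        lambda_weight = 1e4,
                        fix_eta = FALSE,
                        fecundity = fecundity_spec(),
                        maturity = maturity_spec(),
                        max_age = 39,
                        ref_year = NULL,
                        report_years = NULL,
                        restarts = c(0.3, 1, 3)) {
  stopifnot(lambda0 > 0, pi_fixed > 0, pi_fixed <= 1, length(eta_sd) == 3)
  structure(list(pi_free = pi_free, pi_fixed = pi_fixed, lambda0 = lambda0,
                 fn_rate = fn_rate, eta_prior = eta_prior, eta_sd = eta_sd,
                 lambda_weight = lambda_weight, fix_eta = fix_eta,
                 fecundity = fecundity, maturity = maturity,
                 max_age = max_age, ref_year = ref_year,
                 report_years = report_years, restarts = restarts),
            class = "ckmr_config")
}

bern_nll <- function(n, k, p) {
  p <- pmin(p, 1 - 1e-12)
  bad <- p <= 0 & k > 0
  if (any(bad)) return(structure(Inf, offending = which(bad)))
  -sum(ifelse(k > 0, k * log(pmax(p, 1e-300)), 0) + (n - k) * log1p(-p))
}

# trinomial outcome per second-order comparison:
#   not kin (n - k), kin sharing mtDNA (k_m), kin not sharing (k_p),
#   kin with unknown haplotypes (k_u, uses the pooled probability)
second_nll <- function(groups, s2) {
  k <- groups$k_m + groups$k_p + groups$k_u
  p_tot <- pmin(s2$p_tot, 1 - 1e-12)
  bad <- (s2$p_m <= 0 & groups$k_m > 0) | (s2$p_p <= 0 & groups$k_p > 0) |
    (p_tot <= 0 & groups$k_u > 0)
  if (any(bad)) return(structure(Inf, offending = which(bad)))
  -sum((groups$n - k) * log1p(-p_tot) +
         ifelse(groups$k_m > 0, groups$k_m * log(pmax(s2$p_m, 1e-300)), 0) +
         ifelse(groups$k_p > 0, groups$k_p * log(pmax(s2$p_p, 1e-300)), 0) +
         ifelse(groups$k_u > 0, groups$k_u * log(pmax(p_tot, 1e-300)), 0))
}

ckmr_years <- function(comparisons, config) {
  s <- comparisons$samples
  ref_year <- config$ref_year %||% max(s$death_year)
  year0 <- min(s$birth_year, ref_year - config$max_age - 1)
  list(year0 = year0, ref_year = ref_year,
       report_years = config$report_years %||% ((ref_year - 30):ref_year))
}

build_ckmr_context <- function(params, comparisons, config) {
  sch <- build_schedules(raw_params(params$eta[1], params$eta[2], params$eta[3]),
                         fecundity = config$fecundity,
                         maturity = config$maturity,
                         max_age = config$max_age)
  yrs <- ckmr_years(comparisons, config)
  traj <- make_trajectory(sch, N_ref = exp(params$log_N),
                          ref_year = yrs$ref_year, year0 = yrs$year0,
                          end_year = max(yrs$ref_year,
                                         max(comparisons$samples$death_year)))
  kin_context(traj, sch, pi = params$pi, fn_rate = config$fn_rate)
}

#' Negative log pseudo-likelihood of a CKMR model
#'
#' Product-Bernoulli kin likelihood over the grouped POP and second-order
#' comparisons, plus a Gaussian log-penalty holding the RAW survival
#' parameters near their prior means and a quadratic penalty on the
#' deviation of the implied growth rate from `lambda0`:
#' `-sum_g [k log p + (n - k) log(1 - p)] + sum_i (eta_i - mu_i)^2 /
#' (2 sd_i^2) + w (lambda - lambda0)^2`.
#'
#' @param params List with `log_N` (log total abundance in the reference
#'   year), `eta` (length-3 RAW vector) and `pi`.
#' @param comparisons A [build_comparisons()] object.
#' @param config A [ckmr_config()].
#' @param components Return the individual terms instead of the total.
#' @return The scalar negative LPL, or (with `components = TRUE`) a list
#'   with `kin_nll`, `pop_nll`, `second_nll`, `pen_eta`, `pen_lambda`,
#'   `lambda` and `total`. A kin-positive group with probability zero gives
#'   `+Inf` and a diagnostic attribute naming the group.
#' @export
negative_lpl <- function(params, comparisons, config = ckmr_config(),
                         components = FALSE) {
  stopifnot(inherits(comparisons, "ckmr_comparisons"))
  ctx <- build_ckmr_context(params, comparisons, config)
  p1 <- pop_group_probs(comparisons$pop, ctx)
  s2 <- second_order_group_probs(comparisons$second, ctx)
  pop_nll <- bern_nll(comparisons$pop$n, comparisons$pop$k, p1)
  sec_nll <- second_nll(comparisons$second, s2)
  if (is.infinite(pop_nll) || is.infinite(sec_nll)) {
    which_set <- if (is.infinite(pop_nll)) "POP" else "HSP-GGP"
    off <- attr(if (is.infinite(pop_nll)) pop_nll else sec_nll, "offending")
    out <- structure(Inf, diagnostic = sprintf(
      "zero kinship probability with observed kin in %s group(s) %s",
      which_set, paste(off, collapse = ", ")))
    if (!components) return(out)
    return(list(kin_nll = Inf, pop_nll = pop_nll, second_nll = sec_nll,
                pen_eta = NA, pen_lambda = NA, lambda = ctx$trajectory$lambda,
                total = out))
  }
  mu <- unlist(config$eta_prior, use.names = FALSE)
  pen_eta <- sum((params$eta - mu)^2 / (2 * config$eta_sd^2))
  lambda <- ctx$trajectory$lambda
  pen_lambda <- config$lambda_weight * (lambda - config$lambda0)^2
  total <- pop_nll + sec_nll + pen_eta + pen_lambda
  if (!components) return(total)
  list(kin_nll = pop_nll + sec_nll, pop_nll = pop_nll, second_nll = sec_nll,
       pen_eta = pen_eta, pen_lambda = pen_lambda, lambda = lambda,
       total = total)
}

params_from_working <- function(x, config) {
  out <- list(log_N = x[["log_N"]],
              eta = unlist(config$eta_prior, use.names = FALSE),
              pi = config$pi_fixed)
  if (!config$fix_eta) out$eta <- c(x[["eta1"]], x[["eta2"]], x[["eta3"]])
  if (config$pi_free) out$pi <- stats::plogis(x[["logit_pi"]])
  out
}

#' Fit a CKMR model by penalised maximum pseudo-likelihood
#'
#' Minimises [negative_lpl()] over log-abundance, optionally the RAW
#' survival parameters, and optionally the logit of the male breeding
#' fraction, using quasi-Newton optimisation (`nlminb`) with box
#' constraints and several dispersed abundance starting values. Standard
#' errors come from the inverse finite-difference Hessian at the optimum;
#' the abundance CV uses the delta method on the log scale.
#'
#' For the common fixed-survival case the kinship kernels are evaluated
#' once at a reference scale and rescaled analytically (`p` is proportional
#' to `1/N`, and the paternal half-sibling component to `1/(N pi)`), which
#' makes each likelihood evaluation essentially free.
#'
#' @param comparisons A [build_comparisons()] object with observed kin
#'   counts attached.
#' @param config A [ckmr_config()].
#' @return An object of class `ckmr_fit` with elements `estimates`
#'   (`N_hat`, `eta`, `pi`), `se`, `cv_N`, `vcov`, `nll` (component list),
#'   `kin_nll`, `aic`, `n_free`, `expected_counts`, `convergence`,
#'   `flags`, `config`, and the reported abundance `N_report` (reference
#'   year, or the `report_years` average when `lambda0 != 1`).
#' @export
fit_ckmr <- function(comparisons, config = ckmr_config()) {
  stopifnot(inherits(comparisons, "ckmr_comparisons"))
  k2 <- comparisons$second$k_m + comparisons$second$k_p + comparisons$second$k_u
  k_tot <- sum(comparisons$pop$k) + sum(k2)
  if (k_tot == 0) stop("no kin pairs observed; abundance is not estimable")

  fast <- config$fix_eta
  if (fast) {
    # with survival fixed the trajectory shape is fixed: every kernel scales
    # as 1/N and the paternal half-sibling component additionally as 1/pi
    base <- local({
      par0 <- list(log_N = log(1e5),
                   eta = unlist(config$eta_prior, use.names = FALSE), pi = 1)
      ctx <- build_ckmr_context(par0, comparisons, config)
      s2 <- second_order_group_probs(comparisons$second, ctx)
      list(N0 = 1e5, p1 = pop_group_probs(comparisons$pop, ctx),
           m_base = s2$mhsp + s2$ggp_shared, p_base_pi = s2$phsp,
           p_base_fix = s2$ggp_unshared, lambda = ctx$trajectory$lambda)
    })
    pen_lambda <- config$lambda_weight * (base$lambda - config$lambda0)^2
    thin <- 1 - config$fn_rate
    objective <- function(x) {
      p <- params_from_working(x, config)
      sc <- base$N0 / exp(p$log_N)
      p1 <- base$p1 * sc
      s2 <- list(p_m = thin * base$m_base * sc,
                 p_p = thin * (base$p_base_pi / p$pi + base$p_base_fix) * sc)
      s2$p_tot <- s2$p_m + s2$p_p
      v <- bern_nll(comparisons$pop$n, comparisons$pop$k, p1) +
        second_nll(comparisons$second, s2) + pen_lambda
      as.numeric(v)
    }
  } else {
    objective <- function(x) {
      v <- negative_lpl(params_from_working(x, config), comparisons, config)
      as.numeric(v)
    }
  }

  # crude moment start for N: expected kin scale ~ 1/N
  par0 <- list(log_N = log(1e5),
               eta = unlist(config$eta_prior, use.names = FALSE),
               pi = if (config$pi_free) 0.5 else config$pi_fixed)
  ctx0 <- build_ckmr_context(par0, comparisons, config)
  e0 <- sum(pop_group_probs(comparisons$pop, ctx0) * comparisons$pop$n) +
    sum(second_order_group_probs(comparisons$second, ctx0)$p_tot *
          comparisons$second$n)
  N_start <- 1e5 * e0 / k_tot

  lower <- c(log_N = log(50)); upper <- c(log_N = log(1e9))
  start <- c(log_N = log(N_start))
  if (!config$fix_eta) {
    mu <- unlist(config$eta_prior, use.names = FALSE)
    start <- c(start, eta1 = mu[1], eta2 = mu[2], eta3 = mu[3])
    lower <- c(lower, eta1 = 1e-8, eta2 = 0.5, eta3 = 0)
    upper <- c(upper, eta1 = 0.5, eta2 = 8, eta3 = 0.5)
  }
  if (config$pi_free) {
    start <- c(start, logit_pi = 0)
    lower <- c(lower, logit_pi = -7); upper <- c(upper, logit_pi = 7)
  }

  best <- NULL
  for (fac in config$restarts) {
    st <- start; st[["log_N"]] <- log(N_start * fac)
    opt <- tryCatch(
      stats::nlminb(st, objective, lower = lower, upper = upper,
                    control = list(rel.tol = 1e-10, eval.max = 2000,
                                   iter.max = 1000)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$objective < best$objective))
      best <- opt
  }
  if (is.null(best)) stop("optimisation failed from every starting value")
  flags <- character(0)
  if (best$convergence != 0)
    flags <- c(flags, paste0("nlminb: ", best$message))

  hess <- tryCatch(stats::optimHess(best$par, objective),
                   error = function(e) NULL)
  vcov <- if (!is.null(hess))
    tryCatch(solve(hess), error = function(e) NULL) else NULL
  if (is.null(vcov) || any(!is.finite(diag(vcov))) || any(diag(vcov) < 0)) {
    flags <- c(flags, "Hessian not positive definite; SEs unavailable")
    vcov <- NULL
  }
  se <- if (!is.null(vcov)) sqrt(diag(vcov)) else
    stats::setNames(rep(NA_real_, length(best$par)), names(best$par))

  pars <- params_from_working(best$par, config)
  ctx <- build_ckmr_context(pars, comparisons, config)
  comps <- negative_lpl(pars, comparisons, config, components = TRUE)
  n_free <- length(best$par)
  aic <- 2 * n_free + 2 * comps$kin_nll

  yrs <- ckmr_years(comparisons, config)
  N_hat <- exp(pars$log_N)
  N_report <- if (config$lambda0 == 1) N_hat else
    mean(total_abundance(ctx$trajectory,
                         intersect(yrs$report_years, ctx$trajectory$years)))
  cv_N <- unname(se["log_N"])
  se_pi <- if (config$pi_free && !is.null(vcov))
    unname(se["logit_pi"]) * pars$pi * (1 - pars$pi) else NA_real_

  ec <- second_order_group_probs(comparisons$second, ctx)
  expected <- list(
    POP = sum(pop_group_probs(comparisons$pop, ctx) * comparisons$pop$n),
    MHSP_GGP = sum(ec$p_m * comparisons$second$n),
    PHSP_GGP = sum(ec$p_p * comparisons$second$n))

  structure(list(
    estimates = list(N_hat = N_hat, N_report = N_report, eta = pars$eta,
                     pi = pars$pi),
    se = se, cv_N = cv_N, se_pi = se_pi, vcov = vcov,
    nll = comps, kin_nll = comps$kin_nll, aic = aic, n_free = n_free,
    lambda = comps$lambda, expected_counts = expected,
    convergence = best$convergence, flags = flags,
    par = best$par, config = config,
    comparison_totals = c(pop = sum(comparisons$pop$n),
                          second = sum(comparisons$second$n),
                          k_pop = sum(comparisons$pop$k),
                          k_second = sum(k2))),
    class = "ckmr_fit")
}

#' @export
print.ckmr_fit <- function(x, ...) {
  cat("CKMR pseudo-likelihood fit\n")
  cat(sprintf("  N_hat = %.3g (CV %.2f)%s\n", x$estimates$N_report,
              x$cv_N,
              if (x$config$lambda0 != 1)
                sprintf(" [average over report years, lambda0 = %.2f]",
                        x$config$lambda0) else ""))
  if (x$config$pi_free)
    cat(sprintf("  pi_hat = %.2f (SE %.2f)\n", x$estimates$pi, x$se_pi))
  else cat(sprintf("  pi fixed at %.2f\n", x$estimates$pi))
  cat(sprintf("  eta = (%.4f, %.3f, %.4f), lambda = %.4f\n",
              x$estimates$eta[1], x$estimates$eta[2], x$estimates$eta[3],
              x$lambda))
  cat(sprintf("  kin -logL = %.3f, AIC = %.2f (%d free parameters)\n",
              x$kin_nll, x$aic, x$n_free))
  cat(sprintf("  expected kin: POP %.2f, MHSP-GGP %.2f, PHSP-GGP %.2f\n",
              x$expected_counts$POP, x$expected_counts$MHSP_GGP,
              x$expected_counts$PHSP_GGP))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Compare equal-breeding and heterogeneous-breeding fits by AIC
#'
#' AIC uses the kin-pair likelihood only (penalties act as priors and are
#' excluded) with the number of freely estimated parameters. Returns
#' `AIC(fixed) - AIC(free)`: positive values favour the model with `pi`
#' estimated.
#'
#' @param fit_free_pi,fit_fixed_pi Converged [fit_ckmr()] results on the
#'   identical comparison set.
#' @return The AIC difference (numeric scalar).
#' @export
compare_aic <- function(fit_free_pi, fit_fixed_pi) {
  stopifnot(inherits(fit_free_pi, "ckmr_fit"), inherits(fit_fixed_pi, "ckmr_fit"))
  if (!identical(fit_free_pi$comparison_totals, fit_fixed_pi$comparison_totals))
    stop("fits were not run on identical comparison sets")
  fit_fixed_pi$aic - fit_free_pi$aic
}

#' Profile the kin-pair likelihood over imposed growth rates
#'
#' Refits the model for each value of `lambda0` and reports the kin-only
#' log-likelihood (penalty contributions omitted, so different growth-rate
#' scenarios are comparable) together with the reported abundance.
#'
#' @param comparisons A [build_comparisons()] object.
#' @param lambda_grid Growth-rate values to profile over.
#' @param config Base configuration; its `lambda0` is replaced per point.
#' @return A `data.table` with `lambda0`, `kin_loglik`, `N_report`, `pi`,
#'   `converged`, and `error` (message for failed points, which do not stop
#'   the grid).
#' @export
trend_profile <- function(comparisons, lambda_grid, config = ckmr_config()) {
  rows <- lapply(lambda_grid, function(l0) {
    cfg <- config; cfg$lambda0 <- l0
    res <- tryCatch(fit_ckmr(comparisons, cfg), error = function(e) e)
    if (inherits(res, "error"))
      return(data.table::data.table(lambda0 = l0, kin_loglik = NA_real_,
                                    N_report = NA_real_, pi = NA_real_,
                                    converged = FALSE,
                                    error = conditionMessage(res)))
    data.table::data.table(lambda0 = l0, kin_loglik = -res$kin_nll,
                           N_report = res$estimates$N_report,
                           pi = res$estimates$pi,
                           converged = res$convergence == 0, error = "")
  })
  data.table::rbindlist(rows)
}

#' Expected kin-pair counts from a converged fit
#'
#' Sums the fitted kinship probabilities over all comparisons, by kin class
#' and mtDNA stratum.
#'
#' @param fit A [fit_ckmr()] result.
#' @return Named list: `POP`, `MHSP_GGP`, `PHSP_GGP`.
#' @export
expected_kin_counts <- function(fit) {
  stopifnot(inherits(fit, "ckmr_fit"))
  fit$expected_counts
}
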