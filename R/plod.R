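#' Joint observed-class pair probabilities for a locus under a kinship
#' hypothesis
#'
#' Enumerates all ordered pairs of true genotypes over the three-allele
#' system (major `A`, minor `B`, null) under the identity-by-descent
#' mixture defined by Cotterman coefficients `kappa = (k0, k1, k2)` --
#' the probabilities of sharing 0, 1 or 2 alleles IBD -- then collapses
#' true genotypes to the observed classes (`AA*`, `AB`, `BB*`, `FAIL`).
#' Null alleles are inherited like any other allele, which is what gives
#' loci with moderate null frequencies extra power for kin finding.
#'
#' @param p,q,nu Allele frequencies.
#' @param kappa Length-3 Cotterman vector; `UP = (1,0,0)`,
#'   `POP = (0,1,0)`, `FSP = (1/4,1/2,1/4)`, `HSP/GGP = (1/2,1/2,0)`.
#' @param eps Technical failure rate (applied independently to each
#'   member of the pair).
#' @return A 4x4 matrix of joint probabilities over classes
#'   `(AA, AB, BB, FAIL)` for (animal i, animal j); sums to 1.
#' @export
genotype_pair_probs <- function(p, q, nu, kappa, eps = 0) {
  stopifnot(length(kappa) == 3, abs(sum(kappa) - 1) < 1e-8,
            abs(p + q + nu - 1) < 1e-8)
  fr <- c(p, q, nu)
  # unordered true genotypes indexed 1..6: AA AB AN BB BN NN
  gidx <- matrix(0L, 3, 3)
  gidx[1, 1] <- 1L; gidx[1, 2] <- gidx[2, 1] <- 2L
  gidx[1, 3] <- gidx[3, 1] <- 3L; gidx[2, 2] <- 4L
  gidx[2, 3] <- gidx[3, 2] <- 5L; gidx[3, 3] <- 6L
  Pg <- numeric(6)
  J1 <- matrix(0, 6, 6)
  for (x in 1:3) for (y in 1:3) {
    g1 <- gidx[x, y]
    pr1 <- fr[x] * fr[y]
    Pg[g1] <- Pg[g1] + pr1
    # one shared allele: pick x or y with prob 1/2, partner allele from freqs
    for (z in 1:3) {
      J1[g1, gidx[x, z]] <- J1[g1, gidx[x, z]] + pr1 * 0.5 * fr[z]
      J1[g1, gidx[y, z]] <- J1[g1, gidx[y, z]] + pr1 * 0.5 * fr[z]
    }
  }
  J <- kappa[1] * outer(Pg, Pg) + kappa[2] * J1 + kappa[3] * diag(Pg)
  # collapse to observed classes: AA,AN -> AA*; BB,BN -> BB*; NN -> FAIL
  collapse <- matrix(0, 6, 4)
  collapse[cbind(1:6, c(1, 2, 1, 3, 3, 4))] <- 1
  obs <- t(collapse) %*% J %*% collapse
  if (eps > 0) {
    Tm <- rbind(cbind(diag(3) * (1 - eps), rep(eps, 3)), c(0, 0, 0, 1))
    obs <- t(Tm) %*% obs %*% Tm
  }
  dimnames(obs) <- list(c("AA", "AB", "BB", "FAIL"),
                        c("AA", "AB", "BB", "FAIL"))
  obs
}

kappa_for <- function(hypothesis) {
  switch(hypothesis,
         UP = c(1, 0, 0),
         POP = c(0, 1, 0),
         FSP = c(0.25, 0.5, 0.25),
         HSP = c(0.5, 0.5, 0),
         GGP = c(0.5, 0.5, 0),
         stop("unknown kinship hypothesis: ", hypothesis))
}

# per-locus PLOD lookup tables: log P(classes | K) - log P(classes | UP),
# zero whenever either member is FAIL (failed loci are skipped, and the
# joint probability of the called classes is used without renormalisation,
# so differential failure rates under K vs UP carry no weight)
plod_tables <- function(models, hypotheses = c("POP", "FSP", "HSP"),
                        eps = 0) {
  lapply(seq_len(nrow(models)), function(l) {
    p <- models$p[l]; q <- models$q[l]; nu <- models$nu[l]
    up <- genotype_pair_probs(p, q, nu, kappa_for("UP"), eps)
    out <- lapply(hypotheses, function(h) {
      k <- genotype_pair_probs(p, q, nu, kappa_for(h), eps)
      lut <- log(pmax(k, 1e-300)) - log(pmax(up, 1e-300))
      lut[4, ] <- 0; lut[, 4] <- 0
      lut
    })
    names(out) <- hypotheses
    out
  })
}

class_to_index <- function(code) {
  # 0 -> 1, 1 -> 2, 2 -> 3, 9 -> 4
  i <- match(code, c(0L, 1L, 2L, 9L))
  if (anyNA(i)) stop("invalid genotype class code(s): ",
                     paste(unique(code[is.na(i)]), collapse = ", "))
  i
}

#' Pseudo-log-odds (PLOD) score for one pair of multilocus genotypes
#'
#' Sum over loci of the log likelihood-ratio of the observed genotype
#' class pair under kinship hypothesis `K` versus unrelated. Loci where
#' either animal failed are skipped; the score is the raw sum (no
#' per-locus scaling).
#'
#' @param g_i,g_j Integer class-code vectors (one entry per locus, codes
#'   0/1/2/9).
#' @param hypothesis `"POP"`, `"FSP"` or `"HSP"` (GGPs share the HSP
#'   statistic).
#' @param panel A [genotype_panel()] with estimated locus models, or a
#'   models data frame with columns `p`, `q`, `nu`.
#' @param min_loci Minimum number of jointly called loci; fewer is an
#'   error.
#' @return The PLOD score (numeric scalar) with attribute `n_loci`.
#' @export
plod <- function(g_i, g_j, hypothesis, panel, min_loci = 1) {
  if (inherits(panel, "genotype_panel")) {
    models <- panel$models[!panel$sex_linked, ]
    eps <- panel$eps
    if (length(g_i) == length(panel$loci)) {
      g_i <- g_i[!panel$sex_linked]; g_j <- g_j[!panel$sex_linked]
    }
  } else {
    models <- panel; eps <- 0
  }
  stopifnot(length(g_i) == nrow(models), length(g_j) == nrow(models))
  tabs <- plod_tables(models, hypotheses = hypothesis, eps = eps)
  ci <- class_to_index(g_i); cj <- class_to_index(g_j)
  called <- ci != 4L & cj != 4L
  if (sum(called) < min_loci)
    stop(sprintf("only %d jointly called loci (minimum %d)",
                 sum(called), min_loci))
  sc <- sum(vapply(which(called), function(l)
    tabs[[l]][[hypothesis]][ci[l], cj[l]], numeric(1)))
  structure(sc, n_loci = sum(called))
}

#' Expected PLOD mean and variance under a true relationship
#'
#' Moments of the PLOD statistic for hypothesis `stat` when the pair's
#' true relationship is `truth`, computed exactly from the locus models
#' (loci are independent). Used for threshold placement and
#' false-negative estimation.
#'
#' @param models Data frame of locus models (`p`, `q`, `nu`).
#' @param stat Hypothesis whose PLOD statistic is evaluated.
#' @param truth True relationship generating the genotypes.
#' @param eps Technical failure rate.
#' @return List with `mean` and `var`.
#' @export
expected_plod <- function(models, stat = "HSP", truth = stat, eps = 0) {
  mu <- 0; v <- 0
  for (l in seq_len(nrow(models))) {
    p <- models$p[l]; q <- models$q[l]; nu <- models$nu[l]
    up <- genotype_pair_probs(p, q, nu, kappa_for("UP"), eps)
    kk <- genotype_pair_probs(p, q, nu, kappa_for(stat), eps)
    tw <- genotype_pair_probs(p, q, nu, kappa_for(truth), eps)
    lut <- log(pmax(kk, 1e-300)) - log(pmax(up, 1e-300))
    lut[4, ] <- 0; lut[, 4] <- 0
    m1 <- sum(tw * lut); m2 <- sum(tw * lut^2)
    mu <- mu + m1; v <- v + (m2 - m1^2)
  }
  list(mean = mu, var = v)
}

#' PLOD scores and kin classification for all pairs of a panel
#'
#' Computes POP/UP, FSP/UP and HSP/UP PLOD scores for every pair of
#' samples (or a supplied subset of pairs) and calls kin classes:
#' first-order contrasts are adjudicated first (POP and FSP are reliably
#' separated from lower orders at realistic panel sizes), then pairs
#' exceeding the second-order threshold are called `HSP-GGP`; ties between
#' POP and FSP break toward POP. Pairs with too few jointly called loci
#' are labelled `ambiguous`.
#'
#' @param panel A [genotype_panel()] with estimated models.
#' @param threshold HSP/UP PLOD threshold for second-order calls.
#' @param first_order_threshold POP/UP threshold for first-order calls;
#'   default halfway between the expected POP/UP score of a true HSP and
#'   of a true POP.
#' @param pairs Optional 2-column matrix of sample indices to score
#'   (default: all pairs).
#' @param min_loci Minimum jointly called loci for a usable score.
#' @return A `data.table` with ids, the three scores, `n_loci` and `call`
#'   (`UP`, `POP`, `FSP`, `HSP-GGP`, `ambiguous`).
#' @export
classify_pairs <- function(panel, threshold,
                           first_order_threshold = NULL,
                           pairs = NULL, min_loci = 50) {
  stopifnot(inherits(panel, "genotype_panel"))
  models <- panel$models[!panel$sex_linked, ]
  auto <- panel$classes[!panel$sex_linked, , drop = FALSE]
  n <- ncol(auto)
  if (is.null(pairs)) {
    i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
    pairs <- cbind(i, sequence((n - 1L):1L) + i)
  }
  tabs <- plod_tables(models, eps = panel$eps)
  idx <- matrix(class_to_index(auto), nrow(auto), n)
  np <- nrow(pairs)
  s_pop <- s_fsp <- s_hsp <- numeric(np)
  nloc <- integer(np)
  p1 <- pairs[, 1]; p2 <- pairs[, 2]
  for (l in seq_len(nrow(models))) {
    ci <- idx[l, p1]; cj <- idx[l, p2]
    cell <- (cj - 1L) * 4L + ci
    s_pop <- s_pop + tabs[[l]]$POP[cell]
    s_fsp <- s_fsp + tabs[[l]]$FSP[cell]
    s_hsp <- s_hsp + tabs[[l]]$HSP[cell]
    nloc <- nloc + (ci != 4L & cj != 4L)
  }
  # default first-order thresholds: halfway between the expected score of
  # a true first-order pair and of a true half-sibling on each contrast
  if (is.null(first_order_threshold)) {
    t_pop <- (expected_plod(models, "POP", "POP", panel$eps)$mean +
                expected_plod(models, "POP", "HSP", panel$eps)$mean) / 2
    t_fsp <- (expected_plod(models, "FSP", "FSP", panel$eps)$mean +
                expected_plod(models, "FSP", "HSP", panel$eps)$mean) / 2
  } else {
    t_pop <- t_fsp <- first_order_threshold
  }
  # pairs must clear the second-order threshold to be kin at all; among
  # those, the first-order contrasts are adjudicated first, with ties
  # broken toward the more related POP hypothesis
  call <- rep("UP", np)
  kin <- s_hsp >= threshold
  call[kin] <- "HSP-GGP"
  call[kin & s_fsp >= t_fsp & s_fsp > s_pop] <- "FSP"
  call[kin & s_pop >= t_pop & s_pop >= s_fsp] <- "POP"
  call[nloc < min_loci] <- "ambiguous"
  data.table::data.table(
    id1 = panel$samples[pairs[, 1]], id2 = panel$samples[pairs[, 2]],
    plod_pop = s_pop, plod_fsp = s_fsp, plod_hsp = s_hsp,
    n_loci = nloc, call = call)
}

#' False-negative rate of the second-order PLOD threshold
#'
#' The HSP/UP PLOD of a true second-order pair has a theoretical mean
#' `mu_HSP` computable from the locus models. Its variance is estimated
#' from the upper half of the observed kin-score distribution (scores
#' above `mu_HSP`, folded about the mean), which is robust to the
#' truncation of the lower tail by the calling threshold. The
#' false-negative rate is the normal tail mass below the threshold.
#'
#' @param scores Observed HSP/UP PLOD scores of accepted second-order kin.
#' @param models Locus models (data frame with `p`, `q`, `nu`) or a
#'   [genotype_panel()].
#' @param threshold The calling threshold.
#' @param eps Technical failure rate (taken from the panel if supplied).
#' @return List with `fn`, `mu`, `sigma`, `n_upper` and `flag`
#'   (`"wide-uncertainty"` when fewer than 5 scores exceed the mean, in
#'   which case `sigma` is likely underestimated).
#' @export
false_negative_rate <- function(scores, models, threshold, eps = NULL) {
  if (inherits(models, "genotype_panel")) {
    if (is.null(eps)) eps <- models$eps
    models <- models$models[!models$sex_linked, ]
  }
  if (is.null(eps)) eps <- 0
  mu <- expected_plod(models, "HSP", "HSP", eps)$mean
  upper <- scores[scores > mu]
  flag <- if (length(upper) < 5) "wide-uncertainty" else ""
  sigma <- if (length(upper) >= 1) sqrt(mean((upper - mu)^2))
  else sqrt(expected_plod(models, "HSP", "HSP", eps)$var)
  list(fn = stats::pnorm(threshold, mu, sigma), mu = mu, sigma = sigma,
       n_upper = length(upper), flag = flag)
}
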