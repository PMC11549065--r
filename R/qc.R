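#' QC configuration for a null-allele SNP panel
#'
#' @param malf_min Minimum minor allele frequency (among non-null alleles);
#'   loci below are removed.
#' @param nalf_max Null-allele frequency at or above which a locus is
#'   removed.
#' @param hwe_alpha Per-locus significance level for the
#'   Hardy-Weinberg-with-nulls goodness-of-fit test.
#' @param hwe_adjust Multiplicity handling for HWE p-values: `"none"`
#'   (plain per-test threshold) or `"fdr"` (Benjamini-Hochberg).
#' @param het_z Absolute per-sample heterozygosity z-score beyond which a
#'   sample is removed (contamination shows as excess, degraded DNA as
#'   deficient heterozygosity).
#' @param dup_concordance Genotype concordance above which a pair of
#'   samples is considered a duplicate; the member with more failures is
#'   removed.
#' @param max_iter Maximum filter iterations.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(malf_min = 0.05, nalf_max = 0.45, hwe_alpha = 0.05,
                      hwe_adjust = c("none", "fdr"), het_z = 4,
                      dup_concordance = 0.95, max_iter = 20) {
  structure(list(malf_min = malf_min, nalf_max = nalf_max,
                 hwe_alpha = hwe_alpha,
                 hwe_adjust = match.arg(hwe_adjust), het_z = het_z,
                 dup_concordance = dup_concordance, max_iter = max_iter),
            class = "qc_config")
}

#' Iterative quality control of a genotype panel
#'
#' Runs the filter loop to a fixed point: estimate per-locus allele and
#' null frequencies from the currently retained samples; drop loci with
#' low minor allele frequency, high null frequency, or lack of fit to
#' Hardy-Weinberg-with-nulls; drop samples with outlying heterozygosity;
#' drop one member of each near-duplicate pair. Previously rejected loci
#' and samples are re-evaluated in every round against the current
#' estimates, so a locus rejected because of bad samples (or vice versa)
#' can return. Deterministic given the configuration.
#'
#' @param panel A [genotype_panel()].
#' @param config A [qc_config()].
#' @return A list with `panel` (filtered, models estimated), and `report`
#'   (data.table of removals with reasons, iteration count, and per-round
#'   history).
#' @export
qc_panel <- function(panel, config = qc_config()) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "qc_config"))
  auto <- which(!panel$sex_linked)
  if (!length(auto)) stop("panel has no autosomal loci")
  keep_l <- rep(TRUE, length(panel$loci)); keep_l[-auto] <- FALSE
  keep_s <- rep(TRUE, length(panel$samples))
  history <- list()
  removed <- data.table::data.table(item = character(0), kind = character(0),
                                    reason = character(0), round = integer(0))
  for (it in seq_len(config$max_iter)) {
    prev_l <- keep_l; prev_s <- keep_s
    # (re-)estimate models for ALL autosomal loci from retained samples
    cls_s <- panel$classes[, keep_s, drop = FALSE]
    L <- length(panel$loci)
    stats_l <- data.table::data.table(idx = auto, malf = NA_real_,
                                      nalf = NA_real_, hwe_p = NA_real_)
    for (r in seq_along(auto)) {
      l <- auto[r]
      cnt <- tabulate(class_to_index(cls_s[l, ]), 4)
      ht <- hwe_null_test(cnt, eps = panel$eps)
      stats_l$malf[r] <- min(ht$model$p, ht$model$q) /
        max(ht$model$p + ht$model$q, 1e-12)
      stats_l$nalf[r] <- ht$model$nu
      stats_l$hwe_p[r] <- ht$p_value
    }
    hp <- stats_l$hwe_p
    if (config$hwe_adjust == "fdr") hp <- stats::p.adjust(hp, "BH")
    ok_l <- stats_l$malf >= config$malf_min &
      stats_l$nalf < config$nalf_max & hp >= config$hwe_alpha
    keep_l[auto] <- ok_l

    # per-sample heterozygosity screen against expected P(AB) per locus,
    # evaluated for ALL samples over currently retained loci
    la <- which(keep_l)
    if (length(la) >= 10) {
      mods <- t(vapply(la, function(l) {
        cnt <- tabulate(class_to_index(cls_s[l, ]), 4)
        m <- estimate_locus_model(cnt, eps = panel$eps)
        locus_class_probs(m$p, m$q, m$nu, panel$eps)
      }, numeric(4)))
      pAB <- mods[, 2] / pmax(1 - mods[, 4], 1e-12)  # P(AB | called)
      cl <- panel$classes[la, , drop = FALSE]
      called <- cl != 9L
      het <- cl == 1L
      E <- as.vector(pAB %*% called)
      V <- as.vector((pAB * (1 - pAB)) %*% called)
      z <- (colSums(het) - E) / sqrt(pmax(V, 1e-12))
      keep_s <- abs(z) <= config$het_z
    }

    # duplicate detection among retained samples over retained loci
    cl <- panel$classes[keep_l, keep_s, drop = FALSE]
    ns <- ncol(cl)
    if (ns >= 2) {
      called <- cl != 9L
      eq <- matrix(0L, nrow(cl), ns)
      drop_dup <- rep(FALSE, ns)
      sids <- which(keep_s)
      fails <- colSums(!called)
      for (a in seq_len(ns - 1)) {
        if (drop_dup[a]) next
        ca <- called[, a]
        for (b in (a + 1):ns) {
          if (drop_dup[b]) next
          shared <- ca & called[, b]
          nsh <- sum(shared)
          if (nsh < 20) next
          conc <- sum(cl[shared, a] == cl[shared, b]) / nsh
          if (conc > config$dup_concordance) {
            victim <- if (fails[a] > fails[b]) a else if (fails[b] > fails[a])
              b else max(a, b)
            drop_dup[victim] <- TRUE
          }
        }
      }
      if (any(drop_dup)) keep_s[sids[drop_dup]] <- FALSE
    }

    history[[it]] <- c(loci = sum(keep_l), samples = sum(keep_s))
    newly_l <- which(prev_l & !keep_l)
    newly_s <- which(prev_s & !keep_s)
    if (length(newly_l))
      removed <- rbind(removed, data.table::data.table(
        item = panel$loci[newly_l], kind = "locus",
        reason = "MALF/NALF/HWE filter", round = it))
    if (length(newly_s))
      removed <- rbind(removed, data.table::data.table(
        item = panel$samples[newly_s], kind = "sample",
        reason = "heterozygosity/duplicate", round = it))
    if (identical(prev_l, keep_l) && identical(prev_s, keep_s)) break
  }
  if (!any(keep_l))
    stop("quality control removed every locus; see the filter report")
  out <- subset_panel(panel,
                      loci = panel$loci[keep_l | panel$sex_linked],
                      samples = panel$samples[keep_s])
  out <- estimate_panel_models(out)
  list(panel = out,
       report = list(removed = removed, n_iter = it,
                     history = do.call(rbind, history)))
}

#' Genetic sex assignment from sex-linked markers
#'
#' Majority vote over the panel's sex-linked loci, which use a
#' male-specific presence convention: code `2` = marker present (male
#' vote), `0` = absent (female vote), `9` = no call. Users with a
#' different encoding can supply their own code sets.
#'
#' @param panel A [genotype_panel()] with sex-linked loci.
#' @param sample Optional sample id(s); default all.
#' @param present_codes,absent_codes Class codes counting as
#'   presence/absence.
#' @return A `data.table` with `id`, `sex` (`"F"`, `"M"` or `"U"` when no
#'   marker was called), vote counts, and `flagged` (`TRUE` when the vote
#'   was not unanimous over called markers).
#' @export
assign_sex <- function(panel, sample = NULL, present_codes = 2L,
                       absent_codes = 0L) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!any(panel$sex_linked)) stop("panel has no sex-linked loci")
  cls <- panel$classes[panel$sex_linked, , drop = FALSE]
  if (!is.null(sample)) cls <- cls[, panel$samples %in% sample, drop = FALSE]
  pres <- colSums(matrix(cls %in% present_codes, nrow(cls)))
  abs_ <- colSums(matrix(cls %in% absent_codes, nrow(cls)))
  ncall <- pres + abs_
  sex <- ifelse(ncall == 0, "U", ifelse(pres > abs_, "M", "F"))
  data.table::data.table(
    id = colnames(cls), sex = sex, n_present = pres, n_absent = abs_,
    n_missing = nrow(cls) - ncall,
    flagged = ncall > 0 & pres > 0 & abs_ > 0 | (ncall > 0 & ncall < nrow(cls)))
}
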