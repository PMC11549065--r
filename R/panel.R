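#' Genotype panel container
#'
#' Observed genotype classes for a set of loci and samples, with per-locus
#' allele/null frequency models and a flag for sex-linked loci.
#'
#' @param classes Integer matrix (loci x samples) of class codes 0/1/2/9.
#' @param loci Locus ids (default `L001...`).
#' @param samples Sample ids (default column names of `classes`).
#' @param sex_linked Logical vector marking sex-linked rows (default all
#'   `FALSE`). Sex-linked loci use presence/absence coding: `2` = marker
#'   present (male), `0` = absent (female), `9` = no call.
#' @param eps Technical failure rate assumed for the panel.
#' @param models Optional pre-computed locus models (data frame with
#'   `p, q, nu`); otherwise call [estimate_panel_models()].
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(classes, loci = NULL, samples = NULL,
                           sex_linked = NULL, eps = 0, models = NULL) {
  classes <- as.matrix(classes)
  storage.mode(classes) <- "integer"
  if (!all(classes %in% c(0L, 1L, 2L, 9L)))
    stop("genotype classes must be coded 0 (AA*), 1 (AB), 2 (BB*), 9 (FAIL)")
  loci <- loci %||% rownames(classes) %||%
    sprintf("L%04d", seq_len(nrow(classes)))
  samples <- samples %||% colnames(classes) %||%
    sprintf("S%04d", seq_len(ncol(classes)))
  sex_linked <- sex_linked %||% rep(FALSE, nrow(classes))
  stopifnot(length(loci) == nrow(classes), length(samples) == ncol(classes),
            length(sex_linked) == nrow(classes))
  if (all(sex_linked)) stop("panel needs at least one autosomal locus")
  dimnames(classes) <- list(loci, samples)
  structure(list(classes = classes, loci = loci, samples = samples,
                 sex_linked = sex_linked, eps = eps, models = models),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype panel: %d loci (%d sex-linked) x %d samples, eps = %g%s\n",
              length(x$loci), sum(x$sex_linked), length(x$samples), x$eps,
              if (is.null(x$models)) ", models not estimated" else ""))
  invisible(x)
}

#' Estimate locus models for every autosomal locus of a panel
#'
#' @param panel A [genotype_panel()].
#' @param samples Optional subset of sample ids to estimate from.
#' @return The panel with `models` filled in (rows aligned with loci;
#'   sex-linked rows are `NA`).
#' @export
estimate_panel_models <- function(panel, samples = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  cls <- panel$classes
  if (!is.null(samples)) cls <- cls[, panel$samples %in% samples, drop = FALSE]
  L <- nrow(cls)
  p <- q <- nu <- rep(NA_real_, L)
  hwe_p <- rep(NA_real_, L)
  for (l in which(!panel$sex_linked)) {
    cnt <- tabulate(class_to_index(cls[l, ]), 4)
    names(cnt) <- c("AA", "AB", "BB", "FAIL")
    ht <- hwe_null_test(cnt, eps = panel$eps)
    p[l] <- ht$model$p; q[l] <- ht$model$q; nu[l] <- ht$model$nu
    hwe_p[l] <- ht$p_value
  }
  panel$models <- data.table::data.table(locus = panel$loci, p = p, q = q,
                                         nu = nu, hwe_p = hwe_p)
  panel
}

subset_panel <- function(panel, loci = panel$loci, samples = panel$samples) {
  keep_l <- panel$loci %in% loci
  keep_s <- panel$samples %in% samples
  genotype_panel(panel$classes[keep_l, keep_s, drop = FALSE],
                 loci = panel$loci[keep_l], samples = panel$samples[keep_s],
                 sex_linked = panel$sex_linked[keep_l], eps = panel$eps,
                 models = if (!is.null(panel$models))
                   panel$models[keep_l, ] else NULL)
}
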