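#' Write/read a genotype panel as a TSV matrix
#'
#' One row per locus: columns `locus`, `sex_linked`, `p`, `q`, `nu`
#' (estimated frequencies, `NA` when not estimated), then one column per
#' sample holding the class codes `0` (AA*), `1` (AB), `2` (BB*),
#' `9` (FAIL). Round-trips losslessly.
#'
#' @param panel A [genotype_panel()].
#' @param path TSV path.
#' @return `write_genotypes()` returns `path` invisibly; `read_genotypes()`
#'   returns a [genotype_panel()].
#' @export
write_genotypes <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  m <- panel$models
  d <- data.frame(locus = panel$loci, sex_linked = panel$sex_linked,
                  p = if (is.null(m)) NA_real_ else m$p,
                  q = if (is.null(m)) NA_real_ else m$q,
                  nu = if (is.null(m)) NA_real_ else m$nu)
  d <- cbind(d, as.data.frame(panel$classes))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @param eps Technical failure rate to record on the panel.
#' @export
read_genotypes <- function(path, eps = 0) {
  d <- utils::read.delim(path, check.names = FALSE)
  meta <- c("locus", "sex_linked", "p", "q", "nu")
  if (!all(meta %in% names(d)) || ncol(d) <= length(meta))
    stop("genotype TSV needs columns locus, sex_linked, p, q, nu and >= 1 sample")
  cls <- as.matrix(d[, setdiff(names(d), meta), drop = FALSE])
  bad <- matrix(!cls %in% c(0, 1, 2, 9), nrow(cls))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid class code %s at locus %s, sample %s",
                 cls[bad][1], d$locus[w[1]],
                 colnames(cls)[w[2]]))
  }
  models <- if (!all(is.na(d$p)))
    data.table::data.table(locus = d$locus, p = d$p, q = d$q, nu = d$nu)
  else NULL
  genotype_panel(cls, loci = d$locus, samples = colnames(cls),
                 sex_linked = as.logical(d$sex_linked), eps = eps,
                 models = models)
}

#' Read mtDNA haplotypes
#'
#' Either a 2-column CSV (`id,haplotype`) or a FASTA of aligned
#' control-region sequences with sample ids as headers (requires the
#' Biostrings package).
#'
#' @param path File path; format inferred from the extension (`.csv` vs
#'   `.fa`/`.fasta`).
#' @return Named character vector: haplotype label or sequence per sample.
#' @export
read_mtdna <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (ncol(d) < 2) stop("mtDNA CSV needs columns id, haplotype")
    stats::setNames(as.character(d[[2]]), d[[1]])
  } else {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("reading FASTA haplotypes requires the Biostrings package")
    seqs <- Biostrings::readDNAStringSet(path)
    stats::setNames(as.character(seqs), names(seqs))
  }
}

#' Write identified kin pairs to CSV
#'
#' Columns: ids, the three PLOD scores, call, mtDNA stratum, and the GGP
#' feasibility flag when covariates are supplied.
#'
#' @param kin A [classify_pairs()] result (rows with calls of interest).
#' @param path CSV path.
#' @param samples Optional [sample_records()] table to add strata and
#'   feasibility flags.
#' @param min_breeding_age Passed to [ggp_feasible()].
#' @return `path`, invisibly.
#' @export
write_kin_pairs <- function(kin, path, samples = NULL,
                            min_breeding_age = 5) {
  out <- as.data.frame(kin)
  if (!is.null(samples)) {
    s <- sample_records(samples)
    i1 <- match(out$id1, s$id); i2 <- match(out$id2, s$id)
    sw <- !is.na(i1) & !is.na(i2) & s$birth_year[i2] < s$birth_year[i1]
    tmp <- i1[sw]; i1[sw] <- i2[sw]; i2[sw] <- tmp
    out$stratum <- ifelse(is.na(s$mtdna[i1]) | is.na(s$mtdna[i2]), "U",
                          ifelse(s$mtdna[i1] == s$mtdna[i2], "M", "P"))
    out$ggp_feasible <- ggp_feasible(
      list(birth_year = s$birth_year[i1], death_year = s$death_year[i1]),
      list(birth_year = s$birth_year[i2], death_year = s$death_year[i2]),
      min_breeding_age)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export a fit as JSON
#'
#' Serialises estimates, standard errors, expected kin counts, likelihood
#' components and the full configuration echo (with a content hash) so a
#' fit is auditable from its output alone.
#'
#' @param fit A [fit_ckmr()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "ckmr_fit"))
  cfg <- unclass(fit$config)
  cfg$eta_prior <- unlist(unclass(cfg$eta_prior))
  payload <- list(
    estimates = list(N_hat = fit$estimates$N_hat,
                     N_report = fit$estimates$N_report,
                     eta = fit$estimates$eta, pi = fit$estimates$pi,
                     lambda = fit$lambda),
    se = as.list(fit$se), cv_N = fit$cv_N, se_pi = fit$se_pi,
    kin_nll = fit$kin_nll, aic = fit$aic, n_free = fit$n_free,
    nll = fit$nll[c("pop_nll", "second_nll", "pen_eta", "pen_lambda")],
    expected_counts = fit$expected_counts,
    comparison_totals = as.list(fit$comparison_totals),
    convergence = fit$convergence, flags = fit$flags,
    config = cfg)
  payload$config_hash <- substr(paste(
    sum(utils::head(unlist(lapply(cfg, function(x)
      sum(as.numeric(utf8ToInt(paste(format(x), collapse = ""))))), 50))),
    collapse = ""), 1, 16)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
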