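#' Genotype panel design for the simulator
#'
#' @param n_loci Number of autosomal SNP loci.
#' @param n_null_loci Number of loci carrying a heritable null allele
#'   (default 30% of loci).
#' @param maf_range Founder minor-allele frequencies are drawn uniformly
#'   from this range.
#' @param nu_range Founder null-allele frequencies (for null loci).
#' @param eps Technical failure rate.
#' @param n_sex_loci Number of male-specific presence markers.
#' @param sex_dropout No-call rate of the sex-linked markers.
#' @param seed Mandatory seed for drawing the founder frequencies.
#' @return A list of class `genotype_design` with per-locus `p`, `q`, `nu`.
#' @export
genotype_design <- function(n_loci = 300, n_null_loci = round(0.3 * n_loci),
                            maf_range = c(0.1, 0.5), nu_range = c(0.05, 0.3),
                            eps = 0.01, n_sex_loci = 7, sex_dropout = 0.05,
                            seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  set.seed(as.integer(seed))
  maf <- stats::runif(n_loci, maf_range[1], maf_range[2])
  nu <- numeric(n_loci)
  if (n_null_loci > 0)
    nu[seq_len(n_null_loci)] <- stats::runif(n_null_loci, nu_range[1],
                                             nu_range[2])
  q <- maf * (1 - nu)
  p <- 1 - q - nu
  structure(list(n_loci = n_loci, p = p, q = q, nu = nu, eps = eps,
                 n_sex_loci = n_sex_loci, sex_dropout = sex_dropout,
                 seed = as.integer(seed)),
            class = "genotype_design")
}

#' Simulate a genotype panel down a pedigree
#'
#' Founders draw two alleles per locus from the design frequencies
#' (major / minor / null); descendants receive one random allele from each
#' parent, so null alleles are heritable and consistently invisible.
#' Observed classes project `AA, A-null -> AA*`, `BB, B-null -> BB*`,
#' `null/null -> FAIL`, plus independent technical failures. Sex-linked
#' presence markers are added for genetic sexing (code 2 in males, 0 in
#' females, 9 on dropout).
#'
#' @param pedigree A [simulate_pedigree()] result.
#' @param ids Individuals to genotype (e.g. the harvest sample); their
#'   ancestors are simulated internally but not reported.
#' @param design A [genotype_design()].
#' @param seed Seed for the transmission and failure draws.
#' @return A [genotype_panel()] for the requested individuals, with
#'   attribute `true_freqs` (the design frequencies).
#' @export
simulate_genotypes <- function(pedigree, ids, design, seed) {
  stopifnot(inherits(pedigree, "pedigree"), inherits(design, "genotype_design"))
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  set.seed(as.integer(seed))
  ids <- as.integer(ids)
  # ancestor closure, oldest first
  need <- unique(ids)
  frontier <- need
  repeat {
    par <- unique(stats::na.omit(c(pedigree$mother[frontier],
                                   pedigree$father[frontier])))
    new <- setdiff(par, need)
    if (!length(new)) break
    need <- c(need, new); frontier <- new
  }
  need <- need[order(pedigree$birth[need], need)]
  row_of <- integer(nrow(pedigree)); row_of[need] <- seq_along(need)
  L <- design$n_loci
  n <- length(need)
  A1 <- matrix(0L, n, L); A2 <- matrix(0L, n, L)
  founder <- is.na(pedigree$mother[need])
  fr <- rbind(design$p, design$q, design$nu)
  nf <- sum(founder)
  if (nf > 0) {
    for (l in seq_len(L)) {
      A1[founder, l] <- sample.int(3L, nf, replace = TRUE, prob = fr[, l])
      A2[founder, l] <- sample.int(3L, nf, replace = TRUE, prob = fr[, l])
    }
  }
  for (r in which(!founder)) {
    mo <- row_of[pedigree$mother[need[r]]]
    fa <- row_of[pedigree$father[need[r]]]
    pickm <- stats::runif(L) < 0.5
    pickf <- stats::runif(L) < 0.5
    A1[r, ] <- ifelse(pickm, A1[mo, ], A2[mo, ])
    A2[r, ] <- ifelse(pickf, A1[fa, ], A2[fa, ])
  }
  rows <- row_of[ids]
  a1 <- A1[rows, , drop = FALSE]; a2 <- A2[rows, , drop = FALSE]
  cls <- matrix(9L, length(ids), L)
  cls[(a1 == 1L & a2 == 1L) | (a1 == 1L & a2 == 3L) |
        (a1 == 3L & a2 == 1L)] <- 0L
  cls[(a1 == 1L & a2 == 2L) | (a1 == 2L & a2 == 1L)] <- 1L
  cls[(a1 == 2L & a2 == 2L) | (a1 == 2L & a2 == 3L) |
        (a1 == 3L & a2 == 2L)] <- 2L
  if (design$eps > 0)
    cls[matrix(stats::runif(length(cls)) < design$eps, nrow(cls))] <- 9L
  cls <- t(cls)                                   # loci x samples
  # sex-linked presence markers
  if (design$n_sex_loci > 0) {
    male <- pedigree$sex[ids] == "M"
    sl <- matrix(rep(ifelse(male, 2L, 0L), each = design$n_sex_loci),
                 design$n_sex_loci, length(ids))
    sl[matrix(stats::runif(length(sl)) < design$sex_dropout, nrow(sl))] <- 9L
    cls <- rbind(cls, sl)
  }
  panel <- genotype_panel(
    cls,
    loci = c(sprintf("L%04d", seq_len(L)),
             if (design$n_sex_loci > 0) sprintf("SEX%02d",
                                                seq_len(design$n_sex_loci))),
    samples = as.character(ids),
    sex_linked = c(rep(FALSE, L), rep(TRUE, design$n_sex_loci)),
    eps = design$eps)
  attr(panel, "true_freqs") <- data.table::data.table(
    locus = sprintf("L%04d", seq_len(L)),
    p = design$p, q = design$q, nu = design$nu)
  panel
}

#' Simulate mtDNA control-region sequences for haplotype labels
#'
#' Generates one synthetic control-region sequence per haplotype label
#' (fixed length, mutations from a random reference), so that
#' sequence-based and label-based mtDNA sharing can be exercised
#' interchangeably. Sequences are synthetic stand-ins, not real seal
#' haplotypes.
#'
#' @param haplotypes Character vector of haplotype labels.
#' @param length Sequence length.
#' @param seed Mandatory seed.
#' @return Named character vector of sequences.
#' @export
simulate_mtdna_sequences <- function(haplotypes, length = 200, seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, length, replace = TRUE)
  haps <- unique(haplotypes)
  out <- vapply(seq_along(haps), function(i) {
    s <- ref
    nmut <- 2 + (i - 1) %% 6
    pos <- sample.int(length, nmut)
    s[pos] <- vapply(s[pos], function(b) sample(setdiff(bases, b), 1), "")
    paste(s, collapse = "")
  }, "")
  names(out) <- haps
  out
}
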