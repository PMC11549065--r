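#' Observed genotype class codes
#'
#' SNP genotypes with a possible heritable null allele are observed as four
#' classes: `0` = apparent major homozygote (`AA` or `A-null`), `1` =
#' heterozygote `AB`, `2` = apparent minor homozygote (`BB` or `B-null`),
#' `9` = failure (`null/null`, or a technical failure). The null allele is
#' consistently invisible to the assay, so it inflates apparent homozygote
#' frequencies rather than producing random errors.
#'
#' @name genotype-classes
#' @keywords internal
NULL

CLASS_CODES <- c(AA = 0L, AB = 1L, BB = 2L, FAIL = 9L)

#' Expected observed-class probabilities for a locus
#'
#' Hardy-Weinberg with a null allele: with major/minor/null frequencies
#' `(p, q, nu)`, `P(AA*) = p^2 + 2 p nu`, `P(AB) = 2 p q`,
#' `P(BB*) = q^2 + 2 q nu`, `P(FAIL) = nu^2`, plus an independent technical
#' failure converting any class to `FAIL` with probability `eps`.
#'
#' @param p,q,nu Allele frequencies summing to 1.
#' @param eps Technical failure rate.
#' @return Named probability vector over classes `AA, AB, BB, FAIL`.
#' @export
locus_class_probs <- function(p, q, nu, eps = 0) {
  stopifnot(abs(p + q + nu - 1) < 1e-8, eps >= 0, eps < 1)
  base <- c(AA = p^2 + 2 * p * nu, AB = 2 * p * q,
            BB = q^2 + 2 * q * nu, FAIL = nu^2)
  out <- (1 - eps) * base
  out["FAIL"] <- out["FAIL"] + eps
  out
}

#' Maximum-likelihood locus model from observed class counts
#'
#' EM estimation of `(p, q, nu)` under Hardy-Weinberg with a null allele
#' (see [locus_class_probs()]). Apparent homozygotes are fractionally
#' allocated between true homozygotes and null carriers at each step;
#' failures are split between `null/null` and technical failure (rate
#' `eps`, assumed known).
#'
#' @param counts Named counts over `AA, AB, BB, FAIL` (order respected if
#'   unnamed).
#' @param eps Known technical failure rate.
#' @param tol,max_iter EM convergence controls.
#' @return An object of class `locus_model`: list with `p`, `q`, `nu`,
#'   `class_probs`, `loglik`, `n`, `monomorphic` (flag), `iterations`.
#' @export
estimate_locus_model <- function(counts, eps = 0, tol = 1e-10,
                                 max_iter = 500) {
  if (!is.null(names(counts))) counts <- counts[c("AA", "AB", "BB", "FAIL")]
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 4, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("no genotype calls at locus")
  fr <- c(p = 0.5, q = 0.3, nu = 0.2)
  it <- 0
  repeat {
    it <- it + 1
    p <- fr["p"]; q <- fr["q"]; nu <- fr["nu"]
    # expected allele counts given observed classes
    wAA <- if (p^2 + 2 * p * nu > 0) p^2 / (p^2 + 2 * p * nu) else 1
    wBB <- if (q^2 + 2 * q * nu > 0) q^2 / (q^2 + 2 * q * nu) else 1
    pf <- eps + (1 - eps) * nu^2
    wNN <- if (pf > 0) (1 - eps) * nu^2 / pf else 0
    A <- counts[1] * (2 * wAA + (1 - wAA)) + counts[2]
    B <- counts[3] * (2 * wBB + (1 - wBB)) + counts[2]
    Nl <- counts[1] * (1 - wAA) + counts[3] * (1 - wBB) + counts[4] * wNN * 2
    # technical failures carry no allele information: current frequencies
    tech <- counts[4] * (1 - wNN) * 2
    new <- c(A, B, Nl) + tech * fr          # allocate tech mass at current freqs
    new <- new / sum(new)
    names(new) <- c("p", "q", "nu")
    if (max(abs(new - fr)) < tol || it >= max_iter) { fr <- new; break }
    fr <- new
  }
  cp <- locus_class_probs(unname(fr["p"]), unname(fr["q"]),
                          unname(fr["nu"]), eps)
  ll <- sum(counts * log(pmax(cp, 1e-300)))
  structure(list(p = unname(fr["p"]), q = unname(fr["q"]),
                 nu = unname(fr["nu"]),
                 class_probs = cp, loglik = ll, n = n,
                 monomorphic = fr["q"] < 1e-6 || fr["p"] < 1e-6,
                 iterations = it),
            class = "locus_model")
}

#' @export
print.locus_model <- function(x, ...) {
  cat(sprintf("locus model: p = %.4f, q = %.4f, nu = %.4f (n = %d%s)\n",
              x$p, x$q, x$nu, x$n,
              if (x$monomorphic) ", monomorphic" else ""))
  invisible(x)
}

#' Hardy-Weinberg (with nulls) goodness-of-fit test for one locus
#'
#' Pearson chi-square of observed class counts against the fitted
#' null-allele model; two frequencies are estimated from four classes, so
#' the statistic has one degree of freedom.
#'
#' @param counts Counts over `AA, AB, BB, FAIL`.
#' @param eps Technical failure rate.
#' @return List with `statistic`, `df`, `p_value`, `model`.
#' @export
hwe_null_test <- function(counts, eps = 0) {
  if (!is.null(names(counts))) counts <- counts[c("AA", "AB", "BB", "FAIL")]
  counts <- as.numeric(counts)
  mod <- estimate_locus_model(counts, eps = eps)
  n <- sum(counts)
  expd <- n * mod$class_probs
  keep <- expd > 0
  stat <- sum((counts[keep] - expd[keep])^2 / expd[keep])
  df <- 1
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE), model = mod)
}
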