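#' Assemble grouped pairwise kinship comparisons
#'
#' Expands a sample table into the two comparison sets of the CKMR
#' pseudo-likelihood and groups them by the covariates the kinship kernels
#' actually depend on, which makes likelihood evaluation cheap without
#' changing its value.
#'
#' * Parent-offspring: every ordered pair of samples is a candidate
#'   (parent, offspring) comparison, keyed by parent sex, parent birth and
#'   death year, and offspring birth year. Pairs sampled in the same year
#'   are omitted (mother/pup harvests are dependent captures).
#' * Second order (HSP + GGP): every unordered pair, ordered within pair by
#'   birth year, keyed by the older animal's sex, both birth years, and the
#'   older animal's death year. Each pair has a trinomial outcome -- not
#'   observed as kin, observed kin sharing mtDNA (`k_m`), or observed kin
#'   not sharing (`k_p`; `k_u` for kin with unknown haplotypes) -- because
#'   haplotype sharing is informative about kinship and is therefore part
#'   of the kin observation, not a conditioning covariate of the pair.
#'   Pairs already identified as POPs are excluded from this set.
#'
#' @param samples A data frame accepted by [sample_records()].
#' @param kin Optional data frame of identified kin pairs with columns
#'   `id1`, `id2`, `class` (`"POP"` or `"HSP-GGP"`); an optional `stratum`
#'   column (`"M"`/`"P"`/`"U"`) overrides the stratum inferred from the
#'   samples' haplotype labels. Matched pairs set the kin-positive counts
#'   of their groups.
#' @param group If `FALSE`, return one row per pairwise comparison
#'   (`n = 1`); the grouped and ungrouped forms give identical likelihoods.
#' @return An object of class `ckmr_comparisons`: a list with data.tables
#'   `pop` (`sex_p, b_p, d_p, b_o, n, k`) and `second`
#'   (`sex_i, b_i, d_i, b_j, n, k_m, k_p, k_u`), plus the validated samples.
#' @export
build_comparisons <- function(samples, kin = NULL, group = TRUE) {
  s <- sample_records(samples)
  n <- nrow(s)
  if (n < 2) stop("need at least two samples")
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i

  # order within pair: older (earlier birth; tie-break death year then id)
  swap <- (s$birth_year[j] < s$birth_year[i]) |
    (s$birth_year[j] == s$birth_year[i] & s$death_year[j] < s$death_year[i]) |
    (s$birth_year[j] == s$birth_year[i] & s$death_year[j] == s$death_year[i] &
       s$id[j] < s$id[i])
  oi <- ifelse(swap, j, i)
  oj <- ifelse(swap, i, j)

  pairkey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  pop_kin <- character(0)
  second_kin <- data.frame(key = character(0), stratum = character(0))
  if (!is.null(kin) && nrow(kin)) {
    kin <- as.data.frame(kin)
    stopifnot(all(c("id1", "id2", "class") %in% names(kin)))
    known <- kin$id1 %in% s$id & kin$id2 %in% s$id
    if (any(!known))
      warning("dropping kin pairs whose members are not in the sample table")
    kin <- kin[known, , drop = FALSE]
    kk <- pairkey(kin$id1, kin$id2)
    pop_kin <- kk[kin$class == "POP"]
    str <- if (!is.null(kin$stratum)) as.character(kin$stratum) else {
      h1 <- s$mtdna[match(kin$id1, s$id)]
      h2 <- s$mtdna[match(kin$id2, s$id)]
      ifelse(is.na(h1) | is.na(h2), "U", ifelse(h1 == h2, "M", "P"))
    }
    second_kin <- data.frame(key = kk, stratum = str)[kin$class != "POP", ]
  }
  keys <- pairkey(s$id[oi], s$id[oj])

  # --- parent-offspring comparisons (both directions, same-year excluded)
  pd <- data.table::data.table(
    sex_p = c(s$sex[oi], s$sex[oj]),
    b_p = c(s$birth_year[oi], s$birth_year[oj]),
    d_p = c(s$death_year[oi], s$death_year[oj]),
    b_o = c(s$birth_year[oj], s$birth_year[oi]),
    d_o = c(s$death_year[oj], s$death_year[oi]),
    k = 0L)
  # an observed POP's parent is the earlier-born member (direction 1)
  pd$k[seq_along(keys)] <- as.integer(keys %in% pop_kin)
  pd <- pd[pd$d_p != pd$d_o]
  if (length(pop_kin) && sum(pd$k) < length(unique(pop_kin)))
    message(sprintf(
      "%d identified POP(s) fall in omitted same-year comparisons (dependent captures)",
      length(unique(pop_kin)) - sum(pd$k)))
  pd$d_o <- NULL

  # --- second-order comparisons (POP pairs excluded)
  mstr <- second_kin$stratum[match(keys, second_kin$key)]
  sd <- data.table::data.table(
    sex_i = s$sex[oi], b_i = s$birth_year[oi], d_i = s$death_year[oi],
    b_j = s$birth_year[oj],
    k_m = as.integer(!is.na(mstr) & mstr == "M"),
    k_p = as.integer(!is.na(mstr) & mstr == "P"),
    k_u = as.integer(!is.na(mstr) & mstr == "U"))
  sd <- sd[!(keys %in% pop_kin)]

  if (group) {
    pop <- pd[, list(n = .N, k = sum(k)), by = c("sex_p", "b_p", "d_p", "b_o")]
    second <- sd[, list(n = .N, k_m = sum(k_m), k_p = sum(k_p),
                        k_u = sum(k_u)),
                 by = c("sex_i", "b_i", "d_i", "b_j")]
  } else {
    pd$n <- 1L; sd$n <- 1L
    pop <- pd[, c("sex_p", "b_p", "d_p", "b_o", "n", "k"), with = FALSE]
    second <- sd[, c("sex_i", "b_i", "d_i", "b_j", "n", "k_m", "k_p", "k_u"),
                 with = FALSE]
  }
  structure(list(pop = pop, second = second, samples = s,
                 n_pairs = length(keys)),
            class = "ckmr_comparisons")
}

#' @export
print.ckmr_comparisons <- function(x, ...) {
  cat(sprintf("CKMR comparisons: %d samples, %d unordered pairs\n",
              nrow(x$samples), x$n_pairs))
  cat(sprintf("  POP: %d comparisons in %d groups, %d kin\n",
              sum(x$pop$n), nrow(x$pop), sum(x$pop$k)))
  cat(sprintf("  HSP-GGP: %d comparisons in %d groups, %d kin (%d P / %d M / %d U)\n",
              sum(x$second$n), nrow(x$second),
              sum(x$second$k_m + x$second$k_p + x$second$k_u),
              sum(x$second$k_p), sum(x$second$k_m), sum(x$second$k_u)))
  invisible(x)
}
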