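#' Do two animals share an mtDNA haplotype?
#'
#' Exact label match, or sequence identity after masking positions where
#' either sequence has an ambiguous base (anything outside `ACGT`,
#' case-insensitive). Sequences of unequal length are never shared.
#'
#' @param hap_i,hap_j Haplotype labels or aligned control-region sequences.
#' @param sequences Treat inputs as sequences (default: auto-detect, a
#'   string longer than 20 characters consisting of IUPAC letters).
#' @return `TRUE`, `FALSE`, or `NA` when either haplotype is missing (such
#'   pairs are analysed without mtDNA conditioning).
#' @export
mtdna_shared <- function(hap_i, hap_j, sequences = NULL) {
  if (length(hap_i) != 1 || length(hap_j) != 1) {
    return(mapply(mtdna_shared, hap_i, hap_j,
                  MoreArgs = list(sequences = sequences), USE.NAMES = FALSE))
  }
  if (is.na(hap_i) || is.na(hap_j)) return(NA)
  hap_i <- toupper(hap_i); hap_j <- toupper(hap_j)
  if (is.null(sequences))
    sequences <- nchar(hap_i) > 20 && grepl("^[A-Z-]+$", hap_i)
  if (!sequences) return(hap_i == hap_j)
  if (nchar(hap_i) != nchar(hap_j)) return(FALSE)
  si <- strsplit(hap_i, "")[[1]]; sj <- strsplit(hap_j, "")[[1]]
  keep <- si %in% c("A", "C", "G", "T") & sj %in% c("A", "C", "G", "T")
  all(si[keep] == sj[keep])
}

#' Could the older animal be a grandparent of the younger?
#'
#' Under lethal sampling a grandparent-grandchild pair needs (i) a birth
#' gap of at least twice the minimum breeding age (two generations) and
#' (ii) an older member that reached breeding age before it died.
#'
#' @param older,younger Sample records (lists/rows with `birth_year`,
#'   `death_year`), or vectors via `b_i`, `d_i`, `b_j`.
#' @param min_breeding_age Minimum breeding age in years (default 5,
#'   around the age of first parturition).
#' @return Logical.
#' @export
ggp_feasible <- function(older, younger, min_breeding_age = 5) {
  o <- as.list(older); y <- as.list(younger)
  gap <- y$birth_year - o$birth_year
  gap >= 2 * min_breeding_age &
    (o$death_year - o$birth_year) >= min_breeding_age
}

#' Repair aging errors revealed by identified kin pairs
#'
#' Two deterministic minimal-edit rules resolve impossible kin
#' configurations caused by underestimated tooth ages:
#' * a parent-offspring pair whose parent was harvested before the
#'   offspring's nominal birth year: the offspring's age is incremented
#'   (birth year decremented) until the birth is no later than the
#'   parent's death;
#' * a same-cohort maternal half-sibling pair (impossible with one pup
#'   per female per year): the older (non-pup) member's age is
#'   incremented by one to create a birth gap.
#'
#' Every edit is logged; a pair needing more than `max_edit` years is
#' flagged and excluded rather than repaired.
#'
#' @param kin Data frame of identified kin with `id1`, `id2`, `class`
#'   (`"POP"` or `"HSP-GGP"`/`"MHSP"`); for second-order pairs an
#'   optional `stratum` column (`"M"`/`"P"`) identifies maternal pairs.
#' @param samples A [sample_records()] table.
#' @param max_edit Maximum permitted age edit in years.
#' @return List with `samples` (edited), `log` (data.table of edits) and
#'   `excluded` (irreconcilable pairs).
#' @export
repair_covariates <- function(kin, samples, max_edit = 2) {
  s <- sample_records(samples)
  kin <- as.data.frame(kin)
  log <- data.table::data.table(id = character(0), field = character(0),
                                from = integer(0), to = integer(0),
                                reason = character(0))
  excluded <- kin[0, ]
  for (r in seq_len(nrow(kin))) {
    i1 <- match(kin$id1[r], s$id); i2 <- match(kin$id2[r], s$id)
    if (is.na(i1) || is.na(i2)) next
    # order: older (parent candidate) first
    if (s$birth_year[i2] < s$birth_year[i1]) { tmp <- i1; i1 <- i2; i2 <- tmp }
    if (kin$class[r] == "POP") {
      need <- s$birth_year[i2] - s$death_year[i1]
      if (need > 0) {
        if (need > max_edit) { excluded <- rbind(excluded, kin[r, ]); next }
        old <- s$birth_year[i2]
        s$birth_year[i2] <- s$death_year[i1]
        s$age[i2] <- s$death_year[i2] - s$birth_year[i2]
        log <- rbind(log, data.table::data.table(
          id = s$id[i2], field = "birth_year", from = old,
          to = s$birth_year[i2],
          reason = "parent harvested before nominal birth"))
      }
    } else {
      maternal <- (!is.null(kin$stratum) && !is.na(kin$stratum[r]) &&
                     kin$stratum[r] == "M") || kin$class[r] == "MHSP"
      if (maternal && s$birth_year[i1] == s$birth_year[i2]) {
        # the older member is the non-pup; a pup's age is considered exact
        older <- if (s$age[i1] >= s$age[i2]) i1 else i2
        if (max_edit < 1) { excluded <- rbind(excluded, kin[r, ]); next }
        old <- s$birth_year[older]
        s$birth_year[older] <- old - 1L
        s$age[older] <- s$age[older] + 1L
        log <- rbind(log, data.table::data.table(
          id = s$id[older], field = "age", from = s$age[older] - 1L,
          to = s$age[older],
          reason = "same-cohort maternal half-siblings impossible"))
      }
    }
  }
  list(samples = s, log = log, excluded = excluded)
}
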