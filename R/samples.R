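#' Validate and normalise a table of sampled animals
#'
#' One row per (lethally) sampled animal. Requires `id`, `sex` and
#' `death_year` (the sampling year), and at least one of `age` /
#' `birth_year`; whichever is missing is derived from
#' `age = death_year - birth_year`. Optional columns `mtdna` (haplotype
#' label) and `village` are carried through. Records with missing or
#' inconsistent covariates are dropped with a warning naming the rows.
#'
#' @param x A data frame.
#' @return A `data.table` with columns `id`, `sex`, `birth_year`,
#'   `death_year`, `age`, `mtdna`.
#' @export
sample_records <- function(x) {
  x <- as.data.frame(x)
  if (!all(c("id", "sex", "death_year") %in% names(x)))
    stop("samples need columns id, sex, death_year")
  if (is.null(x$age) && is.null(x$birth_year))
    stop("samples need an age or birth_year column")
  if (anyDuplicated(x$id)) stop("duplicate sample ids: ",
                                paste(unique(x$id[duplicated(x$id)]), collapse = ", "))
  n <- nrow(x)
  age <- if (!is.null(x$age)) suppressWarnings(as.numeric(x$age)) else rep(NA_real_, n)
  by <- if (!is.null(x$birth_year)) suppressWarnings(as.numeric(x$birth_year)) else rep(NA_real_, n)
  dy <- suppressWarnings(as.numeric(x$death_year))
  age[is.na(age)] <- dy[is.na(age)] - by[is.na(age)]
  by[is.na(by)] <- dy[is.na(by)] - age[is.na(by)]
  bad <- is.na(age) | is.na(by) | is.na(dy) | !x$sex %in% c("F", "M") |
    age != round(age) | age < 0 | age > 40 | (dy - by) != age
  if (any(bad)) {
    warning(sprintf("dropping %d record(s) with missing/inconsistent covariates: %s",
                    sum(bad), paste(utils::head(x$id[bad], 10), collapse = ", ")))
    x <- x[!bad, , drop = FALSE]; age <- age[!bad]; by <- by[!bad]; dy <- dy[!bad]
  }
  data.table::data.table(
    id = as.character(x$id), sex = as.character(x$sex),
    birth_year = as.integer(by), death_year = as.integer(dy),
    age = as.integer(age),
    mtdna = if (!is.null(x$mtdna)) as.character(x$mtdna) else NA_character_,
    village = if (!is.null(x$village)) as.character(x$village) else NA_character_)
}

#' Read a sample covariate CSV
#'
#' Thin wrapper around [sample_records()] for a CSV with header
#' `id,sex,birth_year,death_year,age,mtdna,village` (either of
#' `age`/`birth_year` may be absent and is derived from the other).
#'
#' @param path CSV path.
#' @return A validated `data.table` of sample records.
#' @export
read_samples <- function(path) {
  sample_records(utils::read.csv(path, stringsAsFactors = FALSE))
}
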