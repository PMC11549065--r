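#' Logistic ogive over age
#'
#' @param ages Integer ages.
#' @param midpoint Age at which the ogive reaches half its asymptote.
#' @param slope Scale of the logistic (years); smaller is steeper.
#' @param asymptote Upper asymptote in `[0, 1]`.
#' @return Numeric vector, monotone nondecreasing in age.
#' @export
logistic_ogive <- function(ages, midpoint, slope = 1, asymptote = 1) {
  stopifnot(slope > 0, asymptote >= 0, asymptote <= 1)
  asymptote * stats::plogis((ages - midpoint) / slope)
}

#' Knife-edge maturity schedule
#'
#' Zero below `age_at_maturity`, one at and above it.
#'
#' @param ages Integer ages.
#' @param age_at_maturity First reproductive age.
#' @return 0/1 numeric vector.
#' @export
knife_edge <- function(ages, age_at_maturity = 4) {
  as.numeric(ages >= age_at_maturity)
}

resolve_schedule <- function(spec, ages, what) {
  if (is.numeric(spec)) {
    if (length(spec) < length(ages))
      stop(sprintf("%s table has %d entries but %d age classes are required",
                   what, length(spec), length(ages)))
    out <- spec[seq_along(ages)]
  } else if (is.list(spec)) {
    out <- switch(spec$type %||% "logistic",
      logistic = logistic_ogive(ages,
                                midpoint = spec$midpoint,
                                slope = spec$slope %||% 1,
                                asymptote = spec$asymptote %||% 1),
      knife_edge = knife_edge(ages, spec$age %||% 4),
      stop("unknown schedule type: ", spec$type)
    )
  } else {
    stop(what, " spec must be a numeric age table or a list(type = ...)")
  }
  if (any(out < 0 | out > 1))
    stop(what, " values must lie in [0, 1]")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default female fecundity specification
#'
#' Logistic ogive with midpoint age 5 and asymptote 0.95: females begin
#' pupping around their first parturition age and at most 95% of adult
#' females produce a (single) pup in a given year.
#' @param midpoint,slope,asymptote Logistic parameters.
#' @return A schedule specification list.
#' @export
fecundity_spec <- function(midpoint = 5, slope = 1, asymptote = 0.95) {
  list(type = "logistic", midpoint = midpoint, slope = slope, asymptote = asymptote)
}

#' Default male maturity specification
#'
#' Logistic ogive with midpoint age 6: male reproductive output rises with
#' age slightly later than female fecundity.
#' @param midpoint,slope,asymptote Logistic parameters.
#' @return A schedule specification list.
#' @export
maturity_spec <- function(midpoint = 6, slope = 1, asymptote = 1) {
  list(type = "logistic", midpoint = midpoint, slope = slope, asymptote = asymptote)
}

#' Build aligned life-history schedules
#'
#' Combines RAW annual survival with fecundity-at-age (`f_a`, expected pups
#' per female per year; at most one) and male maturity-at-age (`m_a`,
#' relative male reproductive output) into a single object covering age
#' classes `0..max_age`. All kinship probability kernels read vital rates
#' only through this object.
#'
#' @param params A [raw_params()] object.
#' @param fecundity Age-indexed numeric table (length `>= max_age + 1`) or a
#'   specification list such as [fecundity_spec()] or
#'   `list(type = "knife_edge", age = 4)`.
#' @param maturity Same forms as `fecundity`; see [maturity_spec()].
#' @param max_age Oldest age class (default 39, a 40-year lifespan with
#'   `a = 0` denoting pups).
#'
#' @return An object of class `life_schedules` with elements `ages`, `phi`,
#'   `fecundity`, `maturity`, `max_age` and `params`.
#' @examples
#' sch <- build_schedules()
#' plot(sch$ages, sch$phi, type = "l")
#' @export
build_schedules <- function(params = raw_params(),
                            fecundity = fecundity_spec(),
                            maturity = maturity_spec(),
                            max_age = 39) {
  stopifnot(inherits(params, "raw_params"), max_age >= 1)
  ages <- 0:max_age
  phi <- raw_annual_survival(params, ages)
  f <- resolve_schedule(fecundity, ages, "fecundity")
  m <- resolve_schedule(maturity, ages, "maturity")
  if (any(phi < 0 | phi > 1)) stop("survival values must lie in [0, 1]")
  structure(list(ages = ages, phi = phi, fecundity = f, maturity = m,
                 max_age = max_age, params = params),
            class = "life_schedules")
}

#' @export
print.life_schedules <- function(x, ...) {
  cat(sprintf("Life-history schedules over ages 0..%d\n", x$max_age))
  cat(sprintf("  survival: %.3f (pup) .. %.3f (max adult) .. %.3f (age %d)\n",
              x$phi[1], max(x$phi), x$phi[x$max_age + 1], x$max_age))
  cat(sprintf("  fecundity asymptote %.2f, male maturity asymptote %.2f\n",
              max(x$fecundity), max(x$maturity)))
  invisible(x)
}

#' Read/write schedules as a 4-column CSV
#'
#' Columns: `age, survival, fecundity, male_maturity`.
#'
#' @param path File path.
#' @param schedules A `life_schedules` object (for writing).
#' @return `read_schedules()` returns a `life_schedules` object (with
#'   `params` unset); `write_schedules()` returns `path` invisibly.
#' @export
write_schedules <- function(schedules, path) {
  stopifnot(inherits(schedules, "life_schedules"))
  utils::write.csv(data.frame(age = schedules$ages,
                              survival = schedules$phi,
                              fecundity = schedules$fecundity,
                              male_maturity = schedules$maturity),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedules
#' @export
read_schedules <- function(path) {
  d <- utils::read.csv(path)
  need <- c("age", "survival", "fecundity", "male_maturity")
  if (!all(need %in% names(d)))
    stop("schedule CSV must have columns: ", paste(need, collapse = ", "))
  d <- d[order(d$age), ]
  if (!identical(as.integer(d$age), seq(0L, nrow(d) - 1L)))
    stop("schedule CSV ages must be consecutive integers starting at 0")
  if (any(d$survival < 0 | d$survival > 1) || any(d$fecundity < 0 | d$fecundity > 1) ||
      any(d$male_maturity < 0 | d$male_maturity > 1))
    stop("schedule values must lie in [0, 1]")
  structure(list(ages = d$age, phi = d$survival, fecundity = d$fecundity,
                 maturity = d$male_maturity, max_age = max(d$age), params = NULL),
            class = "life_schedules")
}
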