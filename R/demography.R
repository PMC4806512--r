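#' Construct an age pyramid
#'
#' The population state: counts by single year of age (0 to the open-ended
#' top group) and sex. Counts are non-negative reals (the model is
#' deterministic; fractional persons are allowed).
#'
#' @param counts numeric matrix, ages in rows (0 .. `max_age`, the last row an
#'   open-ended accumulator), columns `"female"` and `"male"`.
#' @param year calendar year the counts refer to.
#' @param max_age top (open-ended) age group; used when `counts` is missing to
#'   build an empty pyramid.
#' @return an object of class `age_pyramid`.
#' @examples
#' p <- age_pyramid(year = 2010)
#' p$counts["65", "female"] <- 1000
#' @export
age_pyramid <- function(counts = NULL, year = 2010, max_age = 100) {
  if (is.null(counts)) {
    counts <- matrix(0, nrow = max_age + 1, ncol = 2,
                     dimnames = list(0:max_age, c("female", "male")))
  }
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) colnames(counts) <- c("female", "male")
  if (is.null(rownames(counts))) rownames(counts) <- seq_len(nrow(counts)) - 1
  if (!identical(colnames(counts), c("female", "male")))
    counts <- counts[, c("female", "male"), drop = FALSE]
  if (any(counts < 0))
    stop("age_pyramid: counts must be non-negative")
  structure(list(counts = counts, year = year), class = "age_pyramid")
}

#' @export
print.age_pyramid <- function(x, ...) {
  cat("<age_pyramid> year", x$year,
      "| total", format(round(sum(x$counts)), big.mark = ","),
      "| ages 0-", nrow(x$counts) - 1L, "+\n", sep = " ")
  invisible(x)
}

#' Total population in an age range
#'
#' @param pyramid an [age_pyramid()].
#' @param ages integer vector of ages to include (default: all).
#' @param sex `"female"`, `"male"` or both (default).
#' @return total count (numeric scalar).
#' @export
pyramid_total <- function(pyramid, ages = NULL, sex = c("female", "male")) {
  m <- pyramid$counts
  if (!is.null(ages)) {
    keep <- as.integer(rownames(m)) %in% ages
    m <- m[keep, , drop = FALSE]
  }
  sum(m[, sex, drop = FALSE])
}

#' Construct a set of vital rates
#'
#' Annual demographic rates driving [step_population()]. Mortality is a
#' per-(age, sex) probability of death within the year; immigration and
#' emigration are absolute annual counts per (age, sex). A single aggregate
#' fertility rate applies to women of reproductive age (15-44); births split
#' by sex at `sex_ratio_at_birth`.
#'
#' @param fertility_rate annual births per woman aged 15-44 (>= 0).
#' @param mortality matrix (age x sex) of annual death probabilities in
#'   \[0, 1\], or a scalar recycled over all cells.
#' @param immigration,emigration matrices (age x sex) of annual counts, or
#'   scalars recycled; default 0.
#' @param sex_ratio_at_birth fraction of births that are female (default
#'   0.487).
#' @param max_age top age group, used to shape scalar inputs.
#' @return an object of class `vital_rates`.
#' @export
vital_rates <- function(fertility_rate = 0, mortality = 0,
                        immigration = 0, emigration = 0,
                        sex_ratio_at_birth = 0.487, max_age = 100) {
  expand <- function(x) {
    if (is.matrix(x)) {
      x
    } else {
      matrix(x, nrow = max_age + 1, ncol = 2,
             dimnames = list(0:max_age, c("female", "male")))
    }
  }
  mortality <- expand(mortality)
  if (fertility_rate < 0)
    stop("vital_rates: fertility_rate must be non-negative")
  if (any(mortality < 0 | mortality > 1))
    stop("vital_rates: mortality probabilities must lie in [0, 1]")
  if (sex_ratio_at_birth < 0 || sex_ratio_at_birth > 1)
    stop("vital_rates: sex_ratio_at_birth must lie in [0, 1]")
  structure(list(fertility_rate = fertility_rate,
                 mortality = mortality,
                 immigration = expand(immigration),
                 emigration = expand(emigration),
                 sex_ratio_at_birth = sex_ratio_at_birth),
            class = "vital_rates")
}

#' Annual births implied by a pyramid and vital rates
#'
#' Births are the aggregate fertility rate times the female population of
#' reproductive age (15-44).
#'
#' @inheritParams pyramid_total
#' @param rates a [vital_rates()].
#' @return number of births (numeric scalar).
#' @examples
#' p <- age_pyramid(year = 2010)
#' p$counts[as.character(15:44), "female"] <- 10000 / 30
#' births(p, vital_rates(fertility_rate = 0.05))  # 500
#' @export
births <- function(pyramid, rates) {
  if (rates$fertility_rate < 0)
    stop("births: fertility rate must be non-negative")
  rates$fertility_rate * pyramid_total(pyramid, ages = 15:44, sex = "female")
}

#' Advance the population one year
#'
#' One annual step of the cohort-component projection: each cohort loses
#' deaths (mortality x count), gains net migration, and survivors move up one
#' age; births enter age 0; the top cohort is an open-ended accumulator. A
#' cohort driven negative by net outflow is clipped at zero with a warning.
#'
#' @inheritParams births
#' @param time_step step length in years; the default 1 gives the annual
#'   difference-equation formulation in which survivors shift one whole age
#'   group. `time_step < 1` gives an Euler step of the underlying aging chain
#'   (each cohort passes a fraction `time_step` of its survivors to the next
#'   age), with all flows scaled by `time_step`.
#' @return an `age_pyramid` for `year + time_step`.
#' @export
step_population <- function(pyramid, rates, time_step = 1) {
  cn <- pyramid$counts
  if (!identical(dim(cn), dim(rates$mortality)))
    stop("step_population: pyramid and mortality age grids differ")
  if (time_step <= 0 || time_step > 1)
    stop("step_population: time_step must lie in (0, 1]")
  dt <- time_step
  deaths <- rates$mortality * cn * dt
  net <- cn - deaths + (rates$immigration - rates$emigration) * dt
  if (any(net < 0)) {
    warning("step_population: net outflow exceeded stock in ",
            sum(net < 0), " cohort(s); clipped at zero")
    net[net < 0] <- 0
  }
  n <- nrow(cn)
  out <- matrix(0, nrow = n, ncol = 2, dimnames = dimnames(cn))
  # aging chain: every cohort but the top passes dt of survivors up one age
  out[1:(n - 1), ] <- net[1:(n - 1), ] * (1 - dt)
  out[2:n, ] <- out[2:n, ] + net[1:(n - 1), ] * dt
  out[n, ] <- out[n, ] + net[n, ]          # top group accumulates
  b <- births(pyramid, rates) * dt
  out[1, "female"] <- out[1, "female"] + b * rates$sex_ratio_at_birth
  out[1, "male"] <- out[1, "male"] + b * (1 - rates$sex_ratio_at_birth)
  age_pyramid(out, year = pyramid$year + dt)
}

#' Project the population over a span of years
#'
#' Iterates [step_population()] with rates held constant; element 1 of the
#' result is the input pyramid.
#'
#' @inheritParams step_population
#' @param start_year,end_year projection window (inclusive).
#' @return a list of `age_pyramid`s of length `end_year - start_year + 1`,
#'   named by year.
#' @export
project_population <- function(pyramid0, rates, start_year, end_year) {
  if (start_year > end_year)
    stop("project_population: start_year must not exceed end_year")
  years <- start_year:end_year
  out <- vector("list", length(years))
  names(out) <- years
  p <- pyramid0
  p$year <- start_year
  out[[1]] <- p
  for (i in seq_along(years)[-1]) {
    p <- step_population(p, rates)
    out[[i]] <- p
  }
  out
}

#' Read / write pyramids and vital-rate tables as CSV
#'
#' `read_pyramid_csv()` expects columns `age, sex, count` (and optionally
#' `year`); `write_pyramid_csv()` writes the same tidy layout.
#' `read_vital_rates_csv()` expects columns
#' `age, sex, mortality, immigration, emigration`.
#'
#' @param path file path.
#' @param pyramid an [age_pyramid()].
#' @param fertility_rate,sex_ratio_at_birth scalars not representable in the
#'   per-age table, supplied alongside the CSV.
#' @return the parsed object, or (for the writer) `path` invisibly.
#' @name pyramid_io
NULL

#' @rdname pyramid_io
#' @export
read_pyramid_csv <- function(path) {
  d <- read.csv(path)
  ages <- sort(unique(d$age))
  m <- matrix(0, nrow = length(ages), ncol = 2,
              dimnames = list(ages, c("female", "male")))
  for (s in c("female", "male")) {
    di <- d[d$sex == s, ]
    m[as.character(di$age), s] <- di$count
  }
  yr <- if ("year" %in% names(d)) d$year[1] else NA_integer_
  age_pyramid(m, year = yr)
}

#' @rdname pyramid_io
#' @export
write_pyramid_csv <- function(pyramid, path) {
  d <- data.frame(
    age = rep(as.integer(rownames(pyramid$counts)), 2),
    sex = rep(c("female", "male"), each = nrow(pyramid$counts)),
    count = c(pyramid$counts[, "female"], pyramid$counts[, "male"]),
    year = pyramid$year)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pyramid_io
#' @export
read_vital_rates_csv <- function(path, fertility_rate = 0,
                                 sex_ratio_at_birth = 0.487) {
  d <- read.csv(path)
  ages <- sort(unique(d$age))
  grab <- function(col) {
    m <- matrix(0, nrow = length(ages), ncol = 2,
                dimnames = list(ages, c("female", "male")))
    for (s in c("female", "male")) {
      di <- d[d$sex == s, ]
      m[as.character(di$age), s] <- di[[col]]
    }
    m
  }
  vital_rates(fertility_rate = fertility_rate,
              mortality = grab("mortality"),
              immigration = grab("immigration"),
              emigration = grab("emigration"),
              sex_ratio_at_birth = sex_ratio_at_birth,
              max_age = max(ages))
}
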