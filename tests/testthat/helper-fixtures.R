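# shared builders for small, fully specified test inputs

# pyramid with given counts placed at given ages (both sexes split 50/50
# unless female_only)
toy_pyramid <- function(ages, counts, year = 2010, max_age = 100,
                        female_only = FALSE) {
  p <- age_pyramid(year = year, max_age = max_age)
  if (female_only) {
    p$counts[as.character(ages), "female"] <- counts
  } else {
    p$counts[as.character(ages), "female"] <- counts / 2
    p$counts[as.character(ages), "male"] <- counts / 2
  }
  p
}

# deterministic "random" rates for property tests
random_rates <- function(seed, max_age = 100, migration = TRUE) {
  set.seed(seed)
  n <- max_age + 1
  mk <- function(x) matrix(x, n, 2, dimnames = list(0:max_age,
                                                    c("female", "male")))
  vital_rates(
    fertility_rate = runif(1, 0, 0.1),
    mortality = mk(runif(2 * n, 0, 0.2)),
    immigration = if (migration) mk(runif(2 * n, 0, 50)) else 0,
    emigration = if (migration) mk(runif(2 * n, 0, 10)) else 0,
    max_age = max_age)
}

random_pyramid <- function(seed, max_age = 100, scale = 1000) {
  set.seed(seed)
  n <- max_age + 1
  counts <- matrix(runif(2 * n, 0, scale), n, 2,
                   dimnames = list(0:max_age, c("female", "male")))
  age_pyramid(counts, year = 2010)
}

# a care mix with a single populated cell
single_cell_mix <- function(severity, arrangement, count) {
  m <- matrix(0, 3, 5, dimnames = list(c("low", "medium", "high"),
                                       c("nursing_home", "home_services",
                                         "home_fdw", "home_services_fdw",
                                         "home_unpaid")))
  m[severity, arrangement] <- count
  structure(m, year = 2020, class = c("care_mix", class(m)))
}
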