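test_that("births follow the fertility rate times reproductive-age women", {
  p <- toy_pyramid(15:44, rep(10000 / 30, 30), female_only = TRUE)
  expect_equal(births(p, vital_rates(fertility_rate = 0.05)), 500)
  expect_equal(births(p, vital_rates(fertility_rate = 0)), 0)
  expect_equal(births(age_pyramid(), vital_rates(fertility_rate = 0.1)), 0)
  # men and women outside 15-44 do not contribute
  p2 <- toy_pyramid(c(10, 50), c(5000, 5000))
  expect_equal(births(p2, vital_rates(fertility_rate = 0.05)), 0)
  expect_error(vital_rates(fertility_rate = -0.1), "non-negative")
})

test_that("pure aging shifts every cohort and conserves the total", {
  p <- random_pyramid(11)
  p2 <- step_population(p, vital_rates())
  expect_equal(sum(p2$counts), sum(p$counts))
  expect_equal(unname(p2$counts[as.character(1:99), ]),
               unname(p$counts[as.character(0:98), ]))
  # top group accumulates 99 year olds plus previous top
  expect_equal(p2$counts["100", ],
               p$counts["99", ] + p$counts["100", ])
  expect_equal(p2$year, p$year + 1)
})

test_that("constant mortality gives closed-form survivorship", {
  # mass far from the top accumulator, no migration or births
  p <- toy_pyramid(30:34, rep(1000, 5))
  rates <- vital_rates(mortality = 0.1)
  for (k in 1:3) p <- step_population(p, rates)
  expect_equal(sum(p$counts), 5000 * 0.9^3, tolerance = 1e-12)
})

test_that("the top age group is an open-ended accumulator", {
  p <- toy_pyramid(100, 800)
  p2 <- step_population(p, vital_rates(mortality = 0.5))
  expect_equal(sum(p2$counts), 400)
  expect_equal(unname(p2$counts["100", "female"]), 200)
})

test_that("each step balances births, deaths and net migration", {
  for (seed in 1:5) {
    p <- random_pyramid(seed)
    rates <- random_rates(seed + 100)
    deaths <- sum(rates$mortality * p$counts)
    net_mig <- sum(rates$immigration) - sum(rates$emigration)
    b <- births(p, rates)
    p2 <- step_population(p, rates)
    expect_equal(sum(p2$counts) - sum(p$counts), b - deaths + net_mig,
                 tolerance = 1e-9)
  }
})

test_that("raising mortality never increases any future cohort", {
  p <- random_pyramid(21)
  lo <- random_rates(22, migration = TRUE)
  hi <- lo
  hi$mortality <- pmin(lo$mortality + 0.05, 1)
  pl <- p; ph <- p
  for (k in 1:4) {
    pl <- step_population(pl, lo)
    ph <- step_population(ph, hi)
    expect_true(all(ph$counts <= pl$counts + 1e-9))
  }
})

test_that("matrix step matches a scalar-loop oracle on a tiny grid", {
  max_age <- 3
  counts <- matrix(c(10, 20, 30, 40, 5, 15, 25, 35), ncol = 2,
                   dimnames = list(0:3, c("female", "male")))
  p <- age_pyramid(counts, year = 2000)
  rates <- random_rates(33, max_age = max_age)
  # hand-rolled scalar loop over ages and sexes
  oracle <- function(cn, r) {
    out <- cn * 0
    for (s in 1:2) {
      for (a in 1:4) {
        surv <- cn[a, s] - r$mortality[a, s] * cn[a, s] +
          r$immigration[a, s] - r$emigration[a, s]
        dest <- min(a + 1, 4)
        out[dest, s] <- out[dest, s] + surv
      }
    }
    # no women aged 15-44 on this grid: no births
    out
  }
  got <- p
  expect_cn <- p$counts
  for (k in 1:3) {
    got <- step_population(got, rates)
    expect_cn <- oracle(expect_cn, rates)
    expect_equal(got$counts, expect_cn)
  }
})

test_that("net outflow beyond the stock is clipped with a warning", {
  p <- toy_pyramid(50, 100)
  rates <- vital_rates(emigration = 2)  # 2 emigrants from every cohort
  expect_warning(p2 <- step_population(p, rates), "clipped")
  expect_true(all(p2$counts >= 0))
})

test_that("sub-annual Euler steps conserve people under pure aging", {
  p <- random_pyramid(44)
  p2 <- step_population(p, vital_rates(), time_step = 0.25)
  expect_equal(sum(p2$counts), sum(p$counts))
  expect_equal(p2$year, p$year + 0.25)
  expect_error(step_population(p, vital_rates(), time_step = 0), "time_step")
})

test_that("step rejects mismatched age grids", {
  p <- age_pyramid(max_age = 90)
  expect_error(step_population(p, vital_rates(max_age = 100)), "grids")
})

test_that("project_population returns the stated trajectory", {
  p <- random_pyramid(55)
  rates <- random_rates(56, migration = FALSE)
  expect_error(project_population(p, rates, 2020, 2010), "start_year")
  traj1 <- project_population(p, rates, 2010, 2010)
  expect_length(traj1, 1)
  expect_equal(traj1[[1]]$counts, p$counts)
  # composition: two-year trajectory equals stepping twice
  traj <- project_population(p, rates, 2010, 2012)
  manual <- step_population(step_population(traj[[1]], rates), rates)
  expect_equal(traj[[3]]$counts, manual$counts)
})

test_that("the synthetic fixture projects finite non-negative counts", {
  cfg <- make_fixture_config()
  demo <- make_demography(cfg$synthetic_demography)
  rates <- demo$rates
  rates$fertility_rate <- cfg$demography$fertility_rate
  traj <- project_population(demo$pyramid, rates, 2010, 2030)
  for (p in traj) {
    expect_true(all(is.finite(p$counts)))
    expect_true(all(p$counts >= 0))
  }
})

test_that("pyramids and vital rates round-trip through CSV", {
  p <- random_pyramid(66)
  f <- withr::local_tempfile(fileext = ".csv")
  write_pyramid_csv(p, f)
  p2 <- read_pyramid_csv(f)
  expect_equal(p2$counts, p$counts)
  rates <- random_rates(67)
  f2 <- withr::local_tempfile(fileext = ".csv")
  d <- data.frame(age = rep(0:100, 2),
                  sex = rep(c("female", "male"), each = 101),
                  mortality = c(rates$mortality),
                  immigration = c(rates$immigration),
                  emigration = c(rates$emigration))
  write.csv(d, f2, row.names = FALSE)
  r2 <- read_vital_rates_csv(f2, fertility_rate = rates$fertility_rate)
  expect_equal(r2$mortality, rates$mortality)
  expect_equal(r2$emigration, rates$emigration)
})
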