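test_that("ramps interpolate linearly and clamp outside their knots", {
  cfg <- make_fixture_config()
  cur <- build_scenario("current", cfg)
  expect_equal(eval_ramp(cur$nh_beds, 2030), 22400)
  expect_equal(eval_ramp(cur$nh_beds, 2020), 14900)
  expect_equal(eval_ramp(cur$nh_beds, 2005), 9750)    # clamped before 2012
  expect_equal(eval_ramp(cur$hcbs_uptake, 2021.5), 0.25)
  expect_equal(eval_ramp(cur$hcbs_uptake, 2050), 0.30)
  expect_error(ramp(c(2010, 2010), c(1, 2)), "increasing")
  expect_error(ramp(2010, Inf), "finite")
})

test_that("the six policy scenarios carry the published lever settings", {
  cfg <- make_fixture_config()
  no <- build_scenario("no_ltc", cfg)
  expect_equal(eval_ramp(no$nh_beds, 2030), 0)
  expect_equal(eval_ramp(no$hcbs_uptake, 2030), 0)
  expect_equal(eval_ramp(no$fdw_proportion, 2030), 0)
  cur <- build_scenario("current", cfg)
  expect_equal(eval_ramp(cur$fdw_proportion, 2013), 0.49)
  expect_equal(eval_ramp(cur$fdw_proportion, 2030), 0.60)
  expect_equal(eval_ramp(cur$hcbs_uptake, 2013), 0.20)
  expect_equal(eval_ramp(cur$hcbs_uptake, 2030), 0.30)
  hc <- build_scenario("pro_hcbs", cfg)
  expect_equal(eval_ramp(hc$hcbs_uptake, 2030), 0.80)
  expect_equal(eval_ramp(hc$fdw_proportion, 2030), 0.60)
  fd <- build_scenario("pro_fdw", cfg)
  expect_equal(eval_ramp(fd$fdw_proportion, 2030), 0.80)
  expect_equal(eval_ramp(fd$hcbs_uptake, 2030), 0.30)
  nh <- build_scenario("pro_nh", cfg)
  expect_identical(nh$nh_beds, "all_high_severity_in_nh")
  expect_equal(eval_ramp(nh$hcbs_uptake, 2030), 0.30)
  ai <- build_scenario("all_in", cfg)
  expect_identical(ai$nh_beds, "all_high_severity_in_nh")
  expect_equal(eval_ramp(ai$hcbs_uptake, 2030), 0.80)
  expect_equal(eval_ramp(ai$fdw_proportion, 2030), 0.80)
  expect_error(build_scenario("laissez_faire"), "unknown scenario")
})

test_that("the opening bed count can be overridden to the scenario text", {
  cfg <- make_fixture_config()
  cfg$scenario$bed_start_override <- 9300
  cur <- build_scenario("current", cfg)
  expect_equal(eval_ramp(cur$nh_beds, 2013), 9300)
  expect_equal(eval_ramp(cur$nh_beds, 2030), 22400)
})

test_that("the counterfactual run needs no paid labor and reports dashes", {
  oc <- run_scenario("no_ltc")
  expect_true(all(oc$paid_labor == 0))
  expect_true(all(oc$nh_occupancy == 0))
  expect_true(all(is.na(oc$labor_requirement_ratio)))
  expect_true(all(is.na(oc$increase_in_caregivers_working)))
})

test_that("every policy keeps more caregivers in the labor market", {
  runs <- run_scenarios()
  base <- runs$no_ltc$caregivers_in_market
  for (nm in setdiff(names(runs), "no_ltc"))
    expect_true(all(runs[[nm]]$caregivers_in_market >= base - 1e-9),
                label = paste(nm, "dominates no_ltc"))
  # the combined policy weakly beats each single-lever option, every year
  for (nm in c("current", "pro_hcbs", "pro_fdw", "pro_nh"))
    expect_true(all(runs$all_in$percent_dropping_out <=
                      runs[[nm]]$percent_dropping_out + 1e-9),
                label = paste("all_in dominates", nm))
})

test_that("identical inputs give bit-identical outcomes", {
  a <- run_scenario("current")
  b <- run_scenario("current")
  expect_identical(a, b)
  # a scenario rebuilt with the same ramps matches, whatever its label
  cfg <- make_fixture_config()
  clone <- build_scenario("current", cfg)
  clone$name <- "current_clone"
  cc <- run_scenario(clone, cfg)
  expect_equal(cc[, -1], a[, -1])
})

test_that("reported ratios equal new paid labor over caregiver increase", {
  oc <- run_scenario("pro_fdw")
  keep <- !is.na(oc$labor_requirement_ratio)
  expect_equal(oc$labor_requirement_ratio[keep],
               (oc$new_paid_labor / oc$increase_in_caregivers_working)[keep])
})

test_that("summaries use the published rounding conventions", {
  runs <- run_scenarios(c("no_ltc", "current"))
  tab <- summarize_outcomes(runs)
  expect_setequal(names(tab), c("scenario", "metric", "y2020", "y2030"))
  counts <- tab[tab$metric == "caregivers_in_market", c("y2020", "y2030")]
  expect_true(all(unlist(counts) %% 100 == 0))
  rat <- tab$y2030[tab$scenario == "current" &
                     tab$metric == "labor_requirement_ratio"]
  raw <- run_scenario("current")
  expect_equal(rat,
               round(raw$labor_requirement_ratio[raw$year == 2030], 1))
  # rounding helpers behave like the published cells
  expect_equal(round(1.6986, 1), 1.7)
  expect_equal(round(35512 / 100) * 100, 35500)
  # single scenario, single year
  one <- summarize_outcomes(run_scenario("current"), years = 2030)
  expect_setequal(names(one), c("scenario", "metric", "y2030"))
  expect_error(summarize_outcomes(runs, years = 2050), "lacks year")
})

test_that("the pro-nursing-home rule places all high-severity elderly", {
  oc <- run_scenario("pro_nh", keep_caremix = TRUE)
  stocks <- attr(oc, "stocks")
  mixes <- attr(oc, "caremix")
  for (y in as.character(2013:2030)) {
    expect_equal(unname(mixes[[y]]["high", "nursing_home"]),
                 unname(stocks[[y]][["high"]]), tolerance = 1e-9)
  }
})
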