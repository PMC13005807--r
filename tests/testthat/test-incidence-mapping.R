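test_that("unit case counts are conserved and errors name unmapped cells", {
  map <- data.frame(cell_id = 1:6, unit_id = c(1, 1, 2, 2, 3, 3))
  a <- data.frame(case_id = 1:5, window = "first5",
                  cell_id = c(1, 2, 1, 3, 5), n_years_used = 1)
  counts <- count_cases_by_unit(a, map, "first5")
  expect_equal(unname(counts), c(3L, 1L, 1L))
  expect_equal(sum(counts), nrow(a))

  # degenerate: all in one unit / empty input
  a1 <- a; a1$cell_id <- 2
  expect_equal(unname(count_cases_by_unit(a1, map, "first5")), c(5L, 0L, 0L))
  expect_equal(sum(count_cases_by_unit(a[0, ], map, "first5")), 0L)

  a_bad <- a; a_bad$cell_id[2] <- 99
  expect_error(count_cases_by_unit(a_bad, map, "first5"), "cell 99")
})

test_that("crude incidence arithmetic", {
  expect_equal(crude_incidence(10, 5000, 18), 11.11111, tolerance = 1e-6)
  expect_equal(crude_incidence(648, 100000, 18), 36.0)
  expect_equal(crude_incidence(0, 123, 18), 0)
  expect_error(crude_incidence(1, 0, 18), "undefined rate")
})

test_that("expected cases and observed-vs-expected percentages", {
  ed <- expected_and_difference(972, 100000, 36 / 1e5, 18)
  expect_equal(ed$expected, 648)
  expect_equal(ed$obs_vs_exp_pct, 50)
  expect_equal(expected_and_difference(324, 100000, 36 / 1e5, 18)$obs_vs_exp_pct,
               -50)
  expect_equal(expected_and_difference(648, 100000, 36 / 1e5, 18)$obs_vs_exp_pct,
               0)
  expect_error(expected_and_difference(5, 100, 0, 18), "undefined difference")
})

test_that("quintile and top-2% display classification", {
  cls <- classify_display(1:100)
  expect_equal(unname(table(cls$quintile)), rep(20L, 5), ignore_attr = TRUE)
  expect_equal(sum(cls$top2pct), 2L)

  # 290 units: 98th percentile = 284.22, so 285..290 flagged (6 units)
  cls290 <- classify_display(1:290)
  expect_equal(sum(cls290$top2pct), 6L)
  expect_true(all(which(cls290$top2pct) >= 285))

  # degenerate all-equal input: single quintile, closed >= flags everything
  same <- classify_display(rep(3.5, 10))
  expect_true(all(same$quintile == 1L))
  expect_true(all(same$top2pct))

  expect_error(classify_display(1:4), "classification error")
})

test_that("direct standardisation", {
  expect_equal(standardised_incidence(c(18, 18), c(100000, 100000),
                                      c(0.5, 0.5), 1), 18)
  # stratum rates 10 and 30 per 100k py with equal weights -> 20
  expect_equal(standardised_incidence(c(10, 30), c(100000, 100000),
                                      c(0.5, 0.5), 1), 20)
  # zero-weight stratum ignored regardless of its rate
  expect_equal(standardised_incidence(c(10, 5000), c(100000, 100000),
                                      c(1, 0), 1), 10)
  expect_error(standardised_incidence(c(1, 1), c(100, 0), c(0.5, 0.5), 1),
               "zero population")
  expect_error(standardised_incidence(c(1, 1), c(100, 100), c(0.7, 0.7), 1),
               "sum to 1")
})

test_that("nativity stratification partitions the cohort at the expected share", {
  cfg <- scenario_config(grid_nx = 15, grid_ny = 15, total_population = 80000,
                         n_units = 4, seed = 19)
  g <- generate_grid(cfg)
  cs <- case_summary(generate_case_histories(g, cfg))
  s <- stratify_native(cs)
  n <- nrow(cs)
  expect_equal(nrow(s$native) + nrow(s$non_native), n)
  share <- nrow(s$native) / n
  se <- sqrt(0.762 * 0.238 / n)
  expect_lt(abs(share - 0.762), 3 * se)

  all_native <- cs; all_native$native <- TRUE
  expect_equal(nrow(stratify_native(all_native)$non_native), 0L)
  bad <- cs; bad$native[1] <- NA
  expect_error(stratify_native(bad), "missing nativity")
})

test_that("unit incidence table satisfies its conservation invariants", {
  cfg <- scenario_config(grid_nx = 15, grid_ny = 15, total_population = 80000,
                         n_units = 9, seed = 23)
  g <- generate_grid(cfg)
  ch <- generate_case_histories(g, cfg)
  a <- assign_windows(ch)
  nyears <- length(cfg$years)
  for (w in exposure_windows()) {
    ui <- unit_incidence(a, g, w, nyears)
    expect_equal(sum(ui$cases), length(unique(ch$case_id)))
    # national crude rate = population-weighted mean of unit crude rates
    national <- sum(ui$cases) / sum(ui$person_years) * 1e5
    expect_equal(sum(ui$crude_incidence * ui$population) / sum(ui$population),
                 national)
    # self-consistent expectation: sum E = sum O, weighted mean O-E% = 0
    expect_equal(sum(ui$expected), sum(ui$cases))
    expect_equal(sum(ui$obs_vs_exp_pct * ui$expected) / sum(ui$expected), 0,
                 tolerance = 1e-9)
    expect_true(all(ui$quintile %in% 1:5))
  }
})

test_that("standardised rate equals crude rate under homogeneous stratum rates", {
  pops <- c(40000, 25000, 10000)
  cases <- pops * 36 / 1e5 * 18        # identical stratum rates
  w <- pops / sum(pops)
  std <- standardised_incidence(cases, pops, w, 18)
  crude <- crude_incidence(sum(cases), sum(pops), 18)
  expect_equal(std, crude)
})
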