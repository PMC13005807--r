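test_that("window enumeration respects population and radius caps", {
  # 3 collinear cells 1 km apart, any pair exceeds a 0.34 population cap
  cells <- data.frame(cell_id = 1:3, x = c(0, 1000, 2000), y = 0,
                      population = 100, unit_id = 1)
  w <- enumerate_windows(cells, scan_config(max_pop_fraction = 0.34))
  expect_equal(nrow(w), 3L)
  expect_true(all(w$n_cells == 1L))

  # two cells 150 km apart are never co-members under a 100 km radius cap
  far <- data.frame(cell_id = 1:2, x = c(0, 150000), y = 0,
                    population = 100, unit_id = 1)
  wf <- enumerate_windows(far, scan_config(max_pop_fraction = 0.5))
  expect_true(all(wf$n_cells == 1L))

  # two equal cells with cap 0.5: the pair has fraction 1.0 -> excluded
  near <- data.frame(cell_id = 1:2, x = c(0, 1000), y = 0,
                     population = 100, unit_id = 1)
  wn <- enumerate_windows(near, scan_config(max_pop_fraction = 0.5))
  expect_equal(nrow(wn), 2L)

  # duplicate member sets are deduplicated
  expect_equal(anyDuplicated(vapply(wn$members, paste, "", collapse = ",")), 0L)

  expect_error(enumerate_windows(cells[0, ], scan_config()), "empty cell")
})

test_that("poisson_llr matches its closed form and direction conditions", {
  expect_equal(poisson_llr(10, 10, 100, "high"), 0)
  expect_equal(poisson_llr(20, 10, 100, "high"), 4.44028, tolerance = 1e-5)
  expect_equal(poisson_llr(20, 10, 100, "low"), 0)
  expect_gt(poisson_llr(2, 10, 100, "low"), 0)
  expect_equal(poisson_llr(0, 10, 100, "low"),
               100 * log(100 / 90), tolerance = 1e-12)  # 0*log0 convention
  expect_error(poisson_llr(5, 0, 100, "high"), "invalid expectation")
  expect_error(poisson_llr(5, 100, 100, "high"), "invalid expectation")
})

test_that("LLR is strictly increasing in c beyond E (fixed E, C)", {
  llrs <- vapply(11:99, function(c) poisson_llr(c, 10, 100, "high"), 0)
  expect_true(all(diff(llrs) > 0))
})

test_that("relative risk arithmetic", {
  expect_equal(relative_risk(10, 10, 100), 1)
  expect_equal(relative_risk(20, 10, 100), 2.25)
  expect_equal(relative_risk(0, 10, 100), 0)
  expect_identical(relative_risk(100, 10, 100), Inf)
})

test_that("scan finds a concentrated cluster and reports the MC rank p-value", {
  g <- make_lattice(7, 7)
  counts <- rep(0, 49); counts[25] <- 60; counts[-25] <- 1
  cl <- scan_poisson(g, counts, scan_config(n_replications = 99, seed = 4))
  expect_gte(nrow(cl), 1L)
  expect_equal(cl$centre_cell[1], g$cell_id[25])
  expect_equal(cl$n_cells[1], 1L)
  # observed max exceeded every replication maximum -> p = 1/(R+1)
  expect_true(all(attr(cl, "mc_max_llr") < cl$llr[1]))
  expect_equal(cl$p_value[1], 1 / 100)
  expect_gt(cl$rr[1], 1)
})

test_that("cases proportional to population yield a null scan", {
  g <- make_lattice(10, 10)
  counts <- rep(5, 100)                 # exactly proportional
  cl <- scan_poisson(g, counts, scan_config(n_replications = 99, seed = 8))
  expect_equal(nrow(cl), 0L)
  expect_equal(attr(cl, "best")$llr, 0)
})

test_that("scan best cluster is invariant to cell relabelling and population scaling", {
  g <- random_small_grid(15, seed = 101)
  set.seed(3)
  counts <- as.numeric(rmultinom(1, 80, g$population))
  cfg <- scan_config(n_replications = 19, seed = 5)
  ref <- attr(scan_poisson(g, counts, cfg), "best")

  perm <- sample(nrow(g))
  g2 <- g[perm, ]; counts2 <- counts[perm]
  got <- attr(scan_poisson(g2, counts2, cfg), "best")
  expect_equal(got$llr, ref$llr, tolerance = 1e-12)
  expect_equal(got$centre_cell, ref$centre_cell)

  g3 <- g; g3$population <- g$population * 10
  got3 <- attr(scan_poisson(g3, counts, cfg), "best")
  expect_equal(got3$llr, ref$llr, tolerance = 1e-12)
  expect_equal(got3$E, ref$E, tolerance = 1e-12)
})

test_that("scan agrees with the brute-force oracle on small random grids", {
  for (s in 1:6) {
    g <- random_small_grid(sample(8:20, 1), seed = 300 + s)
    set.seed(600 + s)
    counts <- as.numeric(rmultinom(1, 60, g$population))
    for (dir in c("high", "low")) {
      cfg <- scan_config(n_replications = 9, direction = dir, seed = 1,
                         max_pop_fraction = 0.3, max_radius_m = 12000)
      best <- attr(scan_poisson(g, counts, cfg), "best")
      oracle <- brute_force_best(g, counts, cfg)
      expect_equal(best$llr, oracle$llr, tolerance = 1e-9)
      if (oracle$llr > 0) expect_equal(best$centre_cell, oracle$centre)
    }
  }
})

test_that("reported clusters never overlap and p-values sit on the MC grid", {
  g <- make_lattice(8, 8)
  counts <- rep(1, 64); counts[c(1, 64)] <- 30    # two separated hotspots
  cl <- scan_poisson(g, counts, scan_config(n_replications = 99, seed = 11))
  expect_gte(nrow(cl), 2L)
  all_members <- unlist(cl$members)
  expect_equal(anyDuplicated(all_members), 0L)
  expect_true(all(abs(cl$p_value * 100 - round(cl$p_value * 100)) < 1e-12))
})

test_that("run_all_windows produces eight scan sets and flags errors", {
  cfg <- scenario_config(grid_nx = 10, grid_ny = 10, total_population = 30000,
                         n_units = 4, seed = 15)
  g <- generate_grid(cfg)
  ch <- generate_case_histories(g, cfg)
  a <- assign_windows(ch)
  res <- run_all_windows(a, g, scan_config(n_replications = 19, seed = 2))
  expect_named(res, as.vector(outer(exposure_windows(), c("high", "low"),
                                    paste, sep = "_")), ignore.order = TRUE)
  a_bad <- a; a_bad$cell_id[1] <- 99999
  expect_error(run_all_windows(a_bad, g, scan_config(n_replications = 19)),
               "missing from the grid")
  expect_error(scan_poisson(g, rep(0, nrow(g)), scan_config()), "no cases")
})
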