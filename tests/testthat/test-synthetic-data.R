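test_that("grid is a regular lattice with stable ids and exclusion of empty cells", {
  cfg <- scenario_config(grid_nx = 2, grid_ny = 2, total_population = 4000,
                         n_units = 1, seed = 1)
  g <- generate_grid(cfg)
  expect_setequal(g$x, c(500, 1500))
  expect_setequal(g$y, c(500, 1500))
  dmin <- min(dist(cbind(g$x, g$y)))
  expect_equal(dmin, 1000)

  # all-zero population mass -> every cell excluded
  empty_cfg <- scenario_config(grid_nx = 5, grid_ny = 5,
                               total_population = 0, urban_fraction = 0,
                               seed = 1)
  expect_equal(nrow(generate_grid(empty_cfg)), 0L)

  expect_error(scenario_config(grid_nx = 0), "configuration error")
})

test_that("grid and case generation are deterministic under a fixed seed", {
  cfg <- scenario_config(grid_nx = 15, grid_ny = 15, total_population = 20000,
                         n_units = 4, seed = 77)
  g1 <- generate_grid(cfg); g2 <- generate_grid(cfg)
  expect_identical(g1, g2)
  c1 <- generate_case_histories(g1, cfg)
  c2 <- generate_case_histories(g2, cfg)
  expect_identical(c1, c2)
})

test_that("case histories satisfy their structural invariants", {
  cfg <- scenario_config(grid_nx = 15, grid_ny = 15, total_population = 40000,
                         n_units = 4, seed = 5)
  g <- generate_grid(cfg)
  ch <- generate_case_histories(g, cfg)
  cs <- case_summary(ch)
  expect_gt(nrow(cs), 0)
  expect_true(all(cs$birth_year <= cs$diagnosis_year))
  expect_true(all(cs$diagnosis_year - cs$birth_year <= cfg$age_range[2]))
  expect_true(all(cs$diagnosis_year %in% cfg$years))
  # residence covers every year from birth to diagnosis, no gaps, no duplicates
  for (id in cs$case_id) {
    rows <- ch[ch$case_id == id, ]
    expect_identical(sort(rows$year),
                     seq(rows$birth_year[1], rows$diagnosis_year[1]))
  }
  expect_true(all(ch$cell_id %in% g$cell_id))
})

test_that("zero relocation freezes every case in a single cell", {
  cfg <- scenario_config(grid_nx = 10, grid_ny = 10, total_population = 30000,
                         n_units = 4, relocation_prob = 0, seed = 9)
  g <- generate_grid(cfg)
  ch <- generate_case_histories(g, cfg)
  per_case_cells <- tapply(ch$cell_id, ch$case_id, function(z) length(unique(z)))
  expect_true(all(per_case_cells == 1L))
})

test_that("null incidence matches the baseline within 3 binomial standard errors", {
  cfg <- scenario_config(grid_nx = 20, grid_ny = 20, total_population = 60000,
                         n_units = 4, seed = 21)
  g <- generate_grid(cfg)
  ch <- generate_case_histories(g, cfg)
  n <- attr(ch, "n_cases"); py <- attr(ch, "person_years")
  emp <- n / py * 1e5
  se <- sqrt(n) / py * 1e5
  expect_lt(abs(emp - cfg$baseline_incidence), 3 * se)
})

test_that("unit-relocation fraction increases with relocation_prob", {
  frac <- function(p) {
    cfg <- scenario_config(grid_nx = 15, grid_ny = 15,
                           total_population = 60000, n_units = 9,
                           relocation_prob = p, seed = 31)
    g <- generate_grid(cfg)
    ch <- generate_case_histories(g, cfg)
    u <- setNames(g$unit_id, g$cell_id)
    first <- ch[!duplicated(ch$case_id), ]
    last <- ch[!duplicated(ch$case_id, fromLast = TRUE), ]
    mean(u[as.character(first$cell_id)] != u[as.character(last$cell_id)])
  }
  f <- vapply(c(0, 0.02, 0.1), frac, 0)
  expect_identical(f[1], 0)
  expect_true(all(diff(f) > 0))
})

test_that("a planted first5 cluster triples in-circle incidence (simulation oracle)", {
  pc <- planted_cluster(3000, 12000, 2500, 3, "first5")
  cfg <- scenario_config(grid_nx = 15, grid_ny = 15, total_population = 150000,
                         n_units = 9, planted_clusters = list(pc), seed = 13)
  g <- generate_grid(cfg)
  ch <- generate_case_histories(g, cfg)
  a <- assign_windows(ch)
  f5 <- a[a$window == "first5", ]
  inside_cells <- g$cell_id[(g$x - 3000)^2 + (g$y - 12000)^2 <= 2500^2]
  n_in <- sum(f5$cell_id %in% inside_cells)
  n_out <- nrow(f5) - n_in
  pop_in <- sum(g$population[g$cell_id %in% inside_cells])
  ratio <- (n_in / pop_in) / (n_out / (sum(g$population) - pop_in))
  se_log <- sqrt(1 / n_in + 1 / n_out)
  expect_lt(abs(log(ratio / 3)), 3 * se_log)
})

test_that("a planted circle over empty space warns and has no effect", {
  pc <- planted_cluster(-50000, -50000, 500, 5, "lifetime")
  cfg <- scenario_config(grid_nx = 5, grid_ny = 5, total_population = 5000,
                         n_units = 1, planted_clusters = list(pc), seed = 3)
  g <- generate_grid(cfg)
  expect_warning(ch <- generate_case_histories(g, cfg), "no populated cell")
  cfg0 <- cfg; cfg0$planted_clusters <- list()
  ch0 <- generate_case_histories(g, cfg0)
  expect_equal(attr(ch, "n_cases"), attr(ch0, "n_cases"))
})
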