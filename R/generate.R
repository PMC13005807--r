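#' Generate the synthetic population grid
#'
#' Builds a regular lattice of cell centroids spaced `cell_size_m` apart,
#' assigns each cell to a contiguous rectangular administrative unit, and
#' draws cell populations from a two-component mixture: a small set of
#' high-density "urban" units receiving `urban_fraction` of the total
#' population, and a sparse background elsewhere. Cells whose drawn
#' population is zero are excluded, mirroring the exclusion of uninhabited
#' cells in registry grids.
#'
#' @param config A [scenario_config()].
#' @return A data.frame with columns `cell_id`, `x`, `y`, `population`,
#'   `unit_id`. `cell_id` is the (stable) row-major lattice index, so ids are
#'   not renumbered when empty cells are dropped.
#' @export
generate_grid <- function(config) {
  validate_scenario_config(config)
  nx <- config$grid_nx; ny <- config$grid_ny; cs <- config$cell_size_m
  i <- rep(seq_len(nx), times = ny)
  j <- rep(seq_len(ny), each = nx)
  cell_id <- (j - 1L) * nx + i
  x <- (i - 0.5) * cs
  y <- (j - 0.5) * cs

  # contiguous rectangular unit blocks tiling the lattice
  kx <- max(1L, floor(sqrt(config$n_units)))
  ky <- ceiling(config$n_units / kx)
  ti <- pmin(ceiling(i / (nx / kx)), kx)
  tj <- pmin(ceiling(j / (ny / ky)), ky)
  unit_id <- pmin((tj - 1L) * kx + ti, config$n_units)

  set.seed(stage_seed(config$seed, "grid"))
  n_urban <- max(1L, round(0.1 * config$n_units))
  urban_units <- sort(sample.int(config$n_units, n_urban))
  is_urban <- unit_id %in% urban_units

  n_urb_cells <- sum(is_urban)
  n_bg_cells <- sum(!is_urban)
  lambda <- numeric(length(cell_id))
  if (n_urb_cells > 0L)
    lambda[is_urban] <- config$urban_fraction * config$total_population / n_urb_cells
  if (n_bg_cells > 0L)
    lambda[!is_urban] <- (1 - config$urban_fraction) * config$total_population / n_bg_cells
  population <- rpois(length(cell_id), lambda)

  keep <- population > 0L
  data.frame(cell_id = cell_id[keep], x = x[keep], y = y[keep],
             population = population[keep], unit_id = unit_id[keep])
}

# cells of `grid` whose centroid lies inside a planted circle
.cells_in_circle <- function(grid, centre_x, centre_y, radius_m) {
  (grid$x - centre_x)^2 + (grid$y - centre_y)^2 <= radius_m^2
}

#' Generate synthetic case residential histories
#'
#' Simulates one person per unit of grid population. Each person has a birth
#' year drawn uniformly so that ages at the start of the study period are
#' uniform over `age_range`, a yearly residential relocation process (with
#' probability `relocation_prob` the cell changes, the destination drawn
#' population-weighted over all cells), and a constant per-person-year onset
#' hazard of `baseline_incidence` per 100,000, multiplied by the
#' `risk_multiplier` of every planted cluster whose circle contains the
#' person's dominant residence during the cluster's active exposure window
#' (windows evaluated relative to the candidate onset year). Persons whose
#' first onset falls inside the study period and age range become cases.
#'
#' @param grid Output of [generate_grid()].
#' @param config The [scenario_config()] used to build `grid`.
#' @return A long-format data.frame of class `case_histories` with one row
#'   per case-year: `case_id`, `sex`, `birth_year`, `diagnosis_year`,
#'   `native`, `year`, `cell_id`, covering every year from birth to diagnosis
#'   inclusive. Attribute `person_years` holds the exact number of at-risk
#'   person-years simulated (onset years count fully; post-onset years do
#'   not), for use as an incidence denominator in calibration checks.
#' @export
generate_case_histories <- function(grid, config) {
  validate_scenario_config(config)
  if (nrow(grid) == 0L) stop("non-empty grid required", call. = FALSE)
  set.seed(stage_seed(config$seed, "cases"))

  y0 <- config$years[1]; y1 <- config$years[length(config$years)]
  amin <- config$age_range[1]; amax <- config$age_range[2]
  base_rate <- config$baseline_incidence / 1e5

  N <- sum(grid$population)
  home <- rep.int(grid$cell_id, grid$population)
  birth <- sample.int(amax + 1L, N, replace = TRUE) - 1L
  birth <- y0 - birth                      # ages uniform over 0..amax at y0

  sim_years <- (y0 - amax):y1
  nyr <- length(sim_years)
  res <- matrix(0L, nrow = N, ncol = nyr)
  cur <- home
  w <- grid$population / sum(grid$population)
  for (k in seq_len(nyr)) {
    yr <- sim_years[k]
    can_move <- birth < yr
    movers <- can_move & (runif(N) < config$relocation_prob)
    nm <- sum(movers)
    if (nm > 0L)
      cur[movers] <- sample(grid$cell_id, nm, replace = TRUE, prob = w)
    res[, k] <- cur
  }

  # hazard multipliers from planted clusters
  study_cols <- match(config$years, sim_years)
  nsy <- length(study_cols)
  mult <- NULL
  clusters <- config$planted_clusters
  if (length(clusters) > 0L) {
    circle_cells <- lapply(clusters, function(pc) {
      inside <- .cells_in_circle(grid, pc$centre_x, pc$centre_y, pc$radius_m)
      if (!any(inside))
        warning("planted cluster circle contains no populated cell; it has no effect",
                call. = FALSE)
      grid$cell_id[inside]
    })
    any_circle <- unique(unlist(circle_cells))
    flagged <- which(.rows_with_any(res, any_circle))
    if (length(flagged) > 0L) {
      mult <- matrix(1, nrow = N, ncol = nsy)
      for (idx in flagged) {
        b <- birth[idx]
        hist_years <- sim_years
        hist_cells <- res[idx, ]
        for (k in seq_len(nsy)) {
          yr <- config$years[k]
          age <- yr - b
          if (age < amin || age > amax) next
          m <- 1
          for (ci in seq_along(clusters)) {
            pc <- clusters[[ci]]
            bnds <- window_bounds(b, yr, pc$active_window)
            sel <- hist_years >= bnds[1] & hist_years <= bnds[2]
            dom <- .dominant_cell(hist_years[sel], hist_cells[sel])
            if (dom %in% circle_cells[[ci]]) m <- m * pc$risk_multiplier
          }
          mult[idx, k] <- m
        }
      }
    }
  }

  # per-person-year onset draws over the study period
  ages <- outer(-birth, config$years, `+`)     # N x nsy matrix of ages
  at_risk <- ages >= amin & ages <= amax
  U <- matrix(runif(N * nsy), nrow = N)
  hazard <- base_rate * (if (is.null(mult)) 1 else mult)
  onset <- at_risk & (U < hazard)
  first_onset <- apply(onset, 1L, function(z) {
    k <- which(z)
    if (length(k) == 0L) NA_integer_ else k[1]
  })
  is_case <- !is.na(first_onset)

  # exact at-risk person-years: cases stop contributing after the onset year
  py <- sum(at_risk)
  if (any(is_case)) {
    for (idx in which(is_case)) {
      k <- first_onset[idx]
      if (k < nsy) py <- py - sum(at_risk[idx, (k + 1L):nsy])
    }
  }

  case_idx <- which(is_case)
  n_cases <- length(case_idx)
  sex <- ifelse(runif(n_cases) < config$male_fraction, "male", "female")
  native <- runif(n_cases) < config$native_fraction

  rows <- vector("list", n_cases)
  for (q in seq_len(n_cases)) {
    idx <- case_idx[q]
    dx <- config$years[first_onset[idx]]
    yrs <- birth[idx]:dx
    cols <- match(yrs, sim_years)
    rows[[q]] <- data.frame(
      case_id = q, sex = sex[q], birth_year = birth[idx],
      diagnosis_year = dx, native = native[q],
      year = yrs, cell_id = res[idx, cols]
    )
  }
  out <- if (n_cases > 0L) do.call(rbind, rows) else
    data.frame(case_id = integer(), sex = character(), birth_year = integer(),
               diagnosis_year = integer(), native = logical(),
               year = integer(), cell_id = integer())
  class(out) <- c("case_histories", "data.frame")
  attr(out, "person_years") <- py
  attr(out, "n_cases") <- n_cases
  out
}

# TRUE per row of integer matrix m if any entry is in `values`
.rows_with_any <- function(m, values) {
  hits <- matrix(m %in% values, nrow = nrow(m))
  rowSums(hits) > 0L
}

#' Summarise case histories to one row per case
#'
#' @param cases A `case_histories` long-format data.frame.
#' @return A data.frame with one row per case: `case_id`, `sex`,
#'   `birth_year`, `diagnosis_year`, `native`.
#' @export
case_summary <- function(cases) {
  first <- !duplicated(cases$case_id)
  out <- cases[first, c("case_id", "sex", "birth_year", "diagnosis_year", "native")]
  rownames(out) <- NULL
  out
}
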