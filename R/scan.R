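#' Spatial scan configuration
#'
#' @param max_pop_fraction Maximum share of the total population a scanning
#'   window may contain (default 0.05).
#' @param max_radius_m Maximum window radius in metres (default 100 km).
#' @param n_replications Monte Carlo replications for the null distribution
#'   (default 999).
#' @param alpha Significance level for reported clusters (default 0.05,
#'   closed comparison `p <= alpha`).
#' @param direction `"high"` scans for elevated risk, `"low"` for reduced
#'   risk; each is a separate one-sided analysis.
#' @param seed Seed for the Monte Carlo stream.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(max_pop_fraction = 0.05, max_radius_m = 1e5,
                        n_replications = 999L, alpha = 0.05,
                        direction = c("high", "low"), seed = 1L) {
  direction <- match.arg(direction)
  if (max_pop_fraction <= 0 || max_pop_fraction > 0.5)
    stop("max_pop_fraction must be in (0, 0.5]", call. = FALSE)
  if (max_radius_m <= 0) stop("max_radius_m must be > 0", call. = FALSE)
  if (n_replications < 9L) stop("n_replications must be >= 9", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  structure(list(max_pop_fraction = max_pop_fraction,
                 max_radius_m = max_radius_m,
                 n_replications = as.integer(n_replications),
                 alpha = alpha, direction = direction,
                 seed = as.integer(seed)),
            class = "scan_config")
}

#' One-sided discrete-Poisson log-likelihood ratio
#'
#' `LLR = c log(c/E) + (C - c) log((C - c)/(C - E))` when the one-sided
#' condition holds (`c > E` for the high direction, `c < E` for low), and 0
#' otherwise; terms with `c = 0` or `c = C` use the `0 log 0 = 0` convention.
#'
#' @param c Observed cases inside the window.
#' @param E Expected cases inside the window under homogeneity.
#' @param C Total cases in the study region.
#' @param direction `"high"` or `"low"`.
#' @return Non-negative log-likelihood ratio.
#' @export
poisson_llr <- function(c, E, C, direction = c("high", "low")) {
  direction <- match.arg(direction)
  if (E <= 0 || E >= C)
    stop("invalid expectation: need 0 < E < C", call. = FALSE)
  if (c < 0 || c > C) stop("need 0 <= c <= C", call. = FALSE)
  if (direction == "high" && c <= E) return(0)
  if (direction == "low" && c >= E) return(0)
  t1 <- if (c > 0) c * log(c / E) else 0
  t2 <- if (C - c > 0) (C - c) * log((C - c) / (C - E)) else 0
  max(t1 + t2, 0)
}

#' Relative risk of a scanning window
#'
#' Rate inside the window relative to the rate in the population outside it:
#' `RR = (c/E) / ((C - c)/(C - E))`. When all cases fall inside the window
#' (`c = C`) the RR is infinite and returned as `Inf`.
#'
#' @inheritParams poisson_llr
#' @return Relative risk (0 for an empty window, `Inf` when `c = C`).
#' @export
relative_risk <- function(c, E, C) {
  if (E <= 0 || E >= C)
    stop("invalid expectation: need 0 < E < C", call. = FALSE)
  if (c == C) return(Inf)
  (c / E) / ((C - c) / (C - E))
}

# Candidate window index: for each centre cell, neighbours sorted by
# Euclidean distance (ties by cell_id), truncated where the next addition
# would exceed the population cap or the radius cap. Every singleton is kept.
# Encodes windows as prefixes: offsets/nbr/cumpop/dist flat arrays (C++ layout).
.window_index <- function(cells, config) {
  n <- nrow(cells)
  if (n == 0L) stop("empty cell list", call. = FALSE)
  P <- sum(cells$population)
  capP <- config$max_pop_fraction * P
  offs <- integer(n + 1L)
  nbr <- vector("list", n)
  cpop <- vector("list", n)
  dst <- vector("list", n)
  for (i in seq_len(n)) {
    d <- sqrt((cells$x - cells$x[i])^2 + (cells$y - cells$y[i])^2)
    o <- order(d, cells$cell_id)
    within <- d[o] <= config$max_radius_m
    cum <- cumsum(cells$population[o])
    ok <- within & cum <= capP
    K <- if (ok[1]) {
      bad <- which(!ok)
      if (length(bad)) bad[1] - 1L else n
    } else 1L                         # singleton windows are always candidates
    nbr[[i]] <- o[seq_len(K)]
    cpop[[i]] <- cum[seq_len(K)]
    dst[[i]] <- d[o][seq_len(K)]
    offs[i + 1L] <- offs[i] + K
  }
  list(offsets = offs, nbr = unlist(nbr) - 1L, cumpop = unlist(cpop),
       dist = unlist(dst), P = P)
}

#' Enumerate candidate scanning windows
#'
#' Materialises the candidate window set used by [scan_poisson()]: for each
#' centre cell, windows grow one neighbour at a time in order of Euclidean
#' distance (ties by cell id) and stop before any addition that would exceed
#' the population cap or the radius cap. Duplicate member sets are removed.
#'
#' @param cells Grid data.frame (`cell_id`, `x`, `y`, `population`).
#' @param config A [scan_config()].
#' @return Data.frame with `centre_cell`, `radius_m`, `n_cells`,
#'   `population`, and a list-column `members` of cell ids.
#' @export
enumerate_windows <- function(cells, config) {
  idx <- .window_index(cells, config)
  n <- nrow(cells)
  out <- list(); keys <- character(0)
  w <- 0L
  for (i in seq_len(n)) {
    lo <- idx$offsets[i] + 1L; hi <- idx$offsets[i + 1L]
    rows <- idx$nbr[lo:hi] + 1L
    for (k in seq_along(rows)) {
      members <- sort(cells$cell_id[rows[seq_len(k)]])
      key <- paste(members, collapse = ",")
      if (key %in% keys) next
      keys <- c(keys, key)
      w <- w + 1L
      out[[w]] <- data.frame(centre_cell = cells$cell_id[i],
                             radius_m = idx$dist[lo + k - 1L],
                             n_cells = k,
                             population = idx$cumpop[lo + k - 1L])
      out[[w]]$members <- list(members)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Discrete-Poisson spatial scan over grid-cell centroids
#'
#' Finds the most anomalous circular windows under a discrete Poisson model:
#' expected counts are proportional to window population, the one-sided LLR
#' is maximised over all candidate windows, and significance is assessed by
#' Monte Carlo replication (cases redistributed multinomially with
#' probability proportional to population). Reported clusters are selected
#' greedily in decreasing LLR order (ties: smaller window, then lower centre
#' cell id) subject to sharing no cell with an already-reported cluster and
#' `p <= alpha`.
#'
#' @param cells Grid data.frame (`cell_id`, `x`, `y`, `population`).
#' @param case_counts Cases per cell: either an unnamed vector aligned with
#'   the rows of `cells`, or a named vector keyed by `cell_id` (cells absent
#'   from the names count zero).
#' @param config A [scan_config()].
#' @return Data.frame of reported clusters (`rank`, `centre_cell`,
#'   `radius_m`, `n_cells`, `population`, `c`, `E`, `llr`, `rr`, `p_value`,
#'   list-column `members`) with attributes `mc_max_llr` (the replication
#'   maxima), `best` (the most likely window before the significance filter)
#'   and `C` (total cases).
#' @export
scan_poisson <- function(cells, case_counts, config = scan_config()) {
  counts <- .align_counts(cells, case_counts)
  C <- sum(counts)
  if (C < 1) stop("no cases to scan", call. = FALSE)
  idx <- .window_index(cells, config)
  st <- scan_windows_cpp(idx$offsets, idx$nbr, idx$cumpop, counts,
                         C, idx$P, if (config$direction == "high") 1L else -1L)
  set.seed(config$seed)
  maxima <- scan_mc_max_llr_cpp(idx$offsets, idx$nbr, idx$cumpop,
                                as.integer(C), idx$P,
                                cells$population / idx$P,
                                config$n_replications,
                                if (config$direction == "high") 1L else -1L)

  ord <- order(-st$llr, st$k, cells$cell_id[st$centre])
  used <- logical(nrow(cells))
  picked <- list(); r <- 0L
  for (w in ord) {
    if (st$llr[w] <= 0) break
    p <- (1 + sum(maxima >= st$llr[w])) / (config$n_replications + 1)
    if (p > config$alpha) break       # p is monotone in llr along this order
    i <- st$centre[w]; k <- st$k[w]
    lo <- idx$offsets[i] + 1L
    rows <- idx$nbr[lo:(lo + k - 1L)] + 1L
    if (any(used[rows])) next
    used[rows] <- TRUE
    r <- r + 1L
    cl <- data.frame(rank = r, centre_cell = cells$cell_id[i],
                     radius_m = idx$dist[lo + k - 1L], n_cells = k,
                     population = idx$cumpop[lo + k - 1L],
                     c = st$c[w], E = st$E[w], llr = st$llr[w],
                     rr = relative_risk(st$c[w], st$E[w], C), p_value = p)
    cl$members <- list(sort(cells$cell_id[rows]))
    picked[[r]] <- cl
  }
  out <- if (r > 0L) do.call(rbind, picked) else {
    z <- data.frame(rank = integer(), centre_cell = integer(),
                    radius_m = numeric(), n_cells = integer(),
                    population = numeric(), c = numeric(), E = numeric(),
                    llr = numeric(), rr = numeric(), p_value = numeric())
    z$members <- list()
    z
  }
  rownames(out) <- NULL
  wb <- ord[1]
  attr(out, "best") <- list(centre_cell = cells$cell_id[st$centre[wb]],
                            n_cells = st$k[wb], c = st$c[wb], E = st$E[wb],
                            llr = st$llr[wb])
  attr(out, "mc_max_llr") <- maxima
  attr(out, "C") <- C
  out
}

.align_counts <- function(cells, case_counts) {
  if (!is.null(names(case_counts))) {
    counts <- rep(0, nrow(cells))
    m <- match(names(case_counts), as.character(cells$cell_id))
    if (anyNA(m))
      stop("data integrity: case counts reference cells absent from the grid",
           call. = FALSE)
    counts[m] <- as.numeric(case_counts)
    counts
  } else {
    if (length(case_counts) != nrow(cells))
      stop("case_counts must align with the cell table", call. = FALSE)
    as.numeric(case_counts)
  }
}

#' Run high- and low-risk scans for every exposure window
#'
#' @param assignments Exposure assignments ([assign_windows()]).
#' @param cells Grid data.frame.
#' @param config Base [scan_config()]; direction is overridden per run and
#'   each of the eight runs draws its Monte Carlo null from its own
#'   deterministic sub-seed of `config$seed`.
#' @return Named list of eight cluster tables, `<window>_<direction>`.
#' @export
run_all_windows <- function(assignments, cells, config = scan_config()) {
  out <- list()
  for (win in exposure_windows()) {
    a <- assignments[assignments$window == win, , drop = FALSE]
    counts <- table(factor(as.character(a$cell_id),
                           levels = as.character(cells$cell_id)))
    counts <- as.numeric(counts)
    if (sum(counts) != nrow(a))
      stop(sprintf("data integrity: %s assignment cells missing from the grid",
                   win), call. = FALSE)
    for (dir in c("high", "low")) {
      cfg <- config
      cfg$direction <- dir
      cfg$seed <- stage_seed(config$seed, paste0("scan_", win, "_", dir))
      out[[paste0(win, "_", dir)]] <- scan_poisson(cells, counts, cfg)
    }
  }
  out
}
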