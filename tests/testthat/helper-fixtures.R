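# Shared fixtures and the independent brute-force scan oracle.

# small uniform lattice grid, optionally with custom populations
make_lattice <- function(nx, ny, pop = 100, cell_size = 1000) {
  i <- rep(seq_len(nx), times = ny)
  j <- rep(seq_len(ny), each = nx)
  data.frame(cell_id = (j - 1L) * nx + i,
             x = (i - 0.5) * cell_size, y = (j - 0.5) * cell_size,
             population = pop, unit_id = 1L)
}

# random small grid for oracle-equivalence checks
random_small_grid <- function(n_cells, seed) {
  set.seed(seed)
  data.frame(cell_id = sample.int(1000, n_cells),
             x = runif(n_cells, 0, 20000), y = runif(n_cells, 0, 20000),
             population = sample(20:200, n_cells, replace = TRUE),
             unit_id = 1L)
}

# Independent LLR evaluation (separate code path from the package's C++/R)
oracle_llr <- function(c, E, C, direction) {
  if (direction == "high" && c <= E) return(0)
  if (direction == "low" && c >= E) return(0)
  t1 <- if (c > 0) c * (log(c) - log(E)) else 0
  t2 <- if (C - c > 0) (C - c) * (log(C - c) - log(C - E)) else 0
  max(t1 + t2, 0)
}

# Brute-force most-likely-cluster search: enumerates, for every centre and
# every prefix of the (distance, cell_id)-sorted neighbour list, the window
# statistics by direct summation, applies the population and radius caps, and
# maximises the LLR with the package's tie-break (smaller window, then lower
# centre cell id). Independent of the package's scan internals.
brute_force_best <- function(cells, counts, config) {
  n <- nrow(cells)
  P <- sum(cells$population)
  C <- sum(counts)
  best <- list(llr = -1, k = Inf, centre = Inf, members = NULL)
  for (i in seq_len(n)) {
    d <- sqrt((cells$x - cells$x[i])^2 + (cells$y - cells$y[i])^2)
    o <- order(d, cells$cell_id)
    for (k in seq_len(n)) {
      members <- o[seq_len(k)]
      if (d[o[k]] > config$max_radius_m) break
      pop <- sum(cells$population[members])
      if (k > 1 && pop > config$max_pop_fraction * P) break
      c_in <- sum(counts[members])
      E <- C * pop / P
      if (E <= 0 || E >= C) next
      llr <- oracle_llr(c_in, E, C, config$direction)
      better <- llr > best$llr + 1e-12 ||
        (abs(llr - best$llr) <= 1e-12 &&
           (k < best$k || (k == best$k && cells$cell_id[i] < best$centre)))
      if (better) {
        best <- list(llr = llr, k = k, centre = cells$cell_id[i],
                     members = sort(cells$cell_id[members]),
                     c = c_in, E = E)
      }
    }
  }
  best
}
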