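#' Dorling cartogram layout
#'
#' Replaces each administrative unit by a circle whose area is proportional
#' to its population (radius `k * sqrt(population)` with one global `k`),
#' then iteratively relaxes the layout: overlapping pairs repel along their
#' centre line proportionally to the overlap depth, and non-overlapping
#' circles are pulled gently back toward their seed (centroid) positions.
#' Iteration order is fixed by unit id, so the layout is deterministic.
#'
#' @param units Data.frame with `unit_id`, `x`, `y` (unit centroids) and
#'   `population` (> 0).
#' @param k Radius scale (metres per sqrt-person). Default: chosen so total
#'   circle area is about 60% of the seed bounding-box area.
#' @param max_iter Maximum relaxation sweeps.
#' @param tolerance Maximum tolerated pairwise overlap depth, metres.
#' @param attraction Seed-attraction step fraction per sweep.
#' @return Data.frame with `unit_id`, `seed_x`, `seed_y`, `x`, `y`,
#'   `radius`, `value`; attribute `overlap_trace` logs the maximum overlap
#'   per sweep (a convergence diagnostic).
#' @export
dorling_layout <- function(units, k = NULL, max_iter = 500L,
                           tolerance = 1, attraction = 0.05) {
  if (any(units$population <= 0))
    stop("input error: populations must be > 0", call. = FALSE)
  if (any(!is.finite(units$x)) || any(!is.finite(units$y)))
    stop("input error: centroids must be finite", call. = FALSE)
  o <- order(units$unit_id)
  units <- units[o, , drop = FALSE]
  n <- nrow(units)
  if (is.null(k)) {
    if (n == 1L) {
      k <- 1
    } else {
      box <- (diff(range(units$x)) + 1) * (diff(range(units$y)) + 1)
      k <- sqrt(0.6 * box / (pi * sum(units$population)))
    }
  }
  r <- k * sqrt(units$population)
  x <- units$x; y <- units$y
  trace <- numeric(0)
  if (n > 1L) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    for (iter in seq_len(max_iter)) {
      dx <- x[pairs[, 2]] - x[pairs[, 1]]
      dy <- y[pairs[, 2]] - y[pairs[, 1]]
      d <- sqrt(dx^2 + dy^2)
      need <- r[pairs[, 1]] + r[pairs[, 2]]
      overlap <- need - d
      trace <- c(trace, max(overlap, 0))
      if (all(overlap <= tolerance)) break
      fx <- numeric(n); fy <- numeric(n)
      hit <- logical(n)
      ov <- which(overlap > 0)
      for (q in ov) {
        i <- pairs[q, 1]; j <- pairs[q, 2]
        if (d[q] > 0) {
          ux <- dx[q] / d[q]; uy <- dy[q] / d[q]
        } else {
          ux <- 1; uy <- 0        # coincident centres: split along fixed axis
        }
        push <- overlap[q] / 2 * 0.5          # damped half-depth per circle
        fx[i] <- fx[i] - ux * push; fy[i] <- fy[i] - uy * push
        fx[j] <- fx[j] + ux * push; fy[j] <- fy[j] + uy * push
        hit[i] <- TRUE; hit[j] <- TRUE
      }
      free <- !hit
      fx[free] <- fx[free] + attraction * (units$x[free] - x[free])
      fy[free] <- fy[free] + attraction * (units$y[free] - y[free])
      x <- x + fx; y <- y + fy
    }
  }
  out <- data.frame(unit_id = units$unit_id, seed_x = units$x,
                    seed_y = units$y, x = x, y = y, radius = r,
                    value = units$population)
  attr(out, "overlap_trace") <- trace
  out
}

#' Maximum pairwise overlap depth of a circle layout
#'
#' @param layout Output of [dorling_layout()].
#' @return Largest `r_i + r_j - dist(i, j)` over all pairs (<= 0 means no
#'   circles overlap).
#' @export
max_overlap <- function(layout) {
  n <- nrow(layout)
  if (n < 2L) return(-Inf)
  worst <- -Inf
  for (i in seq_len(n - 1L)) {
    d <- sqrt((layout$x[(i + 1):n] - layout$x[i])^2 +
              (layout$y[(i + 1):n] - layout$y[i])^2)
    worst <- max(worst, max(layout$radius[i] + layout$radius[(i + 1):n] - d))
  }
  worst
}
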