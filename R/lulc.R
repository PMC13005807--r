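#' The five aggregate land-cover classes
#' @return Character vector of class labels.
#' @export
lulc_classes <- function() {
  c("Urban", "Agriculture", "Forest", "Open land", "Lakes and streams")
}

#' Default 17-class land-cover legend
#'
#' A synthetic legend with the named classes of a national land-cover
#' product, mapped onto the five aggregate classes: built-up categories to
#' Urban, agricultural categories to Agriculture, all forest categories to
#' Forest, wetlands and other open land to Open land, and water bodies to
#' Lakes and streams. The legend is configurable: any data.frame with
#' columns `code`, `name`, `class5` works wherever a legend is accepted.
#'
#' @return Data.frame with columns `code` (1-17), `name`, `class5`.
#' @export
lulc_legend_default <- function() {
  data.frame(
    code = 1:17,
    name = c("buildings", "other built-up land", "roads and railways",
             "arable land", "pasture", "other agricultural land",
             "coniferous forest", "deciduous forest", "mixed forest",
             "clear-cut forest", "young forest",
             "wetlands", "open land with vegetation",
             "open land without vegetation", "bare rock",
             "lakes", "streams"),
    class5 = c("Urban", "Urban", "Urban",
               "Agriculture", "Agriculture", "Agriculture",
               "Forest", "Forest", "Forest", "Forest", "Forest",
               "Open land", "Open land", "Open land", "Open land",
               "Lakes and streams", "Lakes and streams")
  )
}

#' Reclassify 17-class codes to the five aggregate classes
#'
#' @param codes Integer vector of legend codes.
#' @param legend Legend data.frame (`code`, `class5`); defaults to
#'   [lulc_legend_default()].
#' @return Character vector of aggregate class labels.
#' @export
reclassify_lulc <- function(codes, legend = lulc_legend_default()) {
  m <- match(codes, legend$code)
  if (anyNA(m)) {
    bad <- codes[is.na(m)][1]
    stop(sprintf("legend error: unknown land-cover code %s", bad), call. = FALSE)
  }
  legend$class5[m]
}

#' Categorical raster in planar coordinates
#'
#' A minimal in-memory raster: an integer matrix of class codes with row 1
#' at the top (north), plus an origin and square cell size, matching the
#' ESRI ASCII grid layout used for on-disk storage.
#'
#' @param codes Integer matrix of legend codes (row 1 = top row).
#' @param xmin,ymin Coordinates of the lower-left corner, metres.
#' @param cellsize Cell edge length, metres.
#' @return Object of class `lulc_raster`.
#' @export
lulc_raster <- function(codes, xmin = 0, ymin = 0, cellsize = 1000) {
  stopifnot(is.matrix(codes), cellsize > 0)
  structure(list(codes = codes, xmin = xmin, ymin = ymin,
                 cellsize = cellsize), class = "lulc_raster")
}

# centre coordinates of every raster cell, row-major over the code matrix
.raster_centres <- function(r) {
  nr <- nrow(r$codes); nc <- ncol(r$codes)
  col <- rep(seq_len(nc), each = nr)
  row <- rep(seq_len(nr), times = nc)
  list(x = r$xmin + (col - 0.5) * r$cellsize,
       y = r$ymin + (nr - row + 0.5) * r$cellsize)
}

#' Write / read a categorical raster as an ESRI ASCII grid
#'
#' Plain-text raster exchange format (`ncols/nrows/xllcorner/yllcorner/`
#' `cellsize/NODATA_value` header followed by rows of codes, north first).
#'
#' @param r An [lulc_raster()].
#' @param path File path.
#' @return `read_asc` returns an `lulc_raster`; `write_asc` returns `path`
#'   invisibly.
#' @export
write_asc <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(r$codes)),
               sprintf("nrows %d", nrow(r$codes)),
               sprintf("xllcorner %.6f", r$xmin),
               sprintf("yllcorner %.6f", r$ymin),
               sprintf("cellsize %.6f", r$cellsize),
               "NODATA_value -9999"), con)
  for (i in seq_len(nrow(r$codes)))
    writeLines(paste(r$codes[i, ], collapse = " "), con)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  vals <- setNames(vapply(hdr, function(h) as.numeric(h[2]), 0),
                   tolower(vapply(hdr, `[`, "", 1)))
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  body <- lines[7:(6 + nr)]
  codes <- do.call(rbind, lapply(body, function(l)
    as.integer(strsplit(trimws(l), "\\s+")[[1]])))
  if (!all(dim(codes) == c(nr, nc)))
    stop(sprintf("malformed raster: expected %d x %d codes", nr, nc),
         call. = FALSE)
  lulc_raster(codes, vals[["xllcorner"]], vals[["yllcorner"]],
              vals[["cellsize"]])
}

#' Zonal histogram of land-cover classes inside a circle
#'
#' Counts raster cells whose centre lies inside the circle, by aggregate
#' class. A degenerate circle containing no cell centre falls back to the
#' single cell containing the circle centre (cell-centre rule).
#'
#' @param r An [lulc_raster()].
#' @param centre_x,centre_y,radius_m Circle in the raster's planar system.
#' @param legend Legend data.frame.
#' @return Named integer vector of counts over [lulc_classes()].
#' @export
zonal_histogram <- function(r, centre_x, centre_y, radius_m,
                            legend = lulc_legend_default()) {
  cc <- .raster_centres(r)
  inside <- (cc$x - centre_x)^2 + (cc$y - centre_y)^2 <= radius_m^2
  if (!any(inside)) {
    # degenerate zone: the cell containing (or nearest to) the circle centre
    d2 <- (cc$x - centre_x)^2 + (cc$y - centre_y)^2
    xmax <- r$xmin + ncol(r$codes) * r$cellsize
    ymax <- r$ymin + nrow(r$codes) * r$cellsize
    if (centre_x < r$xmin || centre_x > xmax ||
        centre_y < r$ymin || centre_y > ymax)
      stop("empty zone: circle lies entirely outside the raster", call. = FALSE)
    inside <- seq_along(d2) == which.min(d2)
  }
  cls <- reclassify_lulc(as.vector(r$codes)[inside], legend)
  counts <- table(factor(cls, levels = lulc_classes()))
  setNames(as.integer(counts), lulc_classes())
}

#' Land-cover shares of one cluster circle
#'
#' @inheritParams zonal_histogram
#' @return Named numeric vector of proportions over [lulc_classes()],
#'   summing to 1.
#' @export
lulc_shares <- function(r, centre_x, centre_y, radius_m,
                        legend = lulc_legend_default()) {
  counts <- zonal_histogram(r, centre_x, centre_y, radius_m, legend)
  counts / sum(counts)
}

#' Mean land-cover shares per cluster group
#'
#' Unweighted arithmetic mean of per-cluster shares within each group
#' (typically exposure window x scan direction); each group's mean shares
#' sum to 1. Empty groups are dropped with a warning.
#'
#' @param profiles Data.frame with a `group` column and one numeric column
#'   per class in [lulc_classes()].
#' @return Data.frame with one row per group.
#' @export
group_mean_shares <- function(profiles) {
  cls <- lulc_classes()
  groups <- unique(profiles$group)
  out <- lapply(groups, function(g) {
    sub <- profiles[profiles$group == g, cls, drop = FALSE]
    if (nrow(sub) == 0L) {
      warning(sprintf("group %s has no profiles; omitted", g), call. = FALSE)
      return(NULL)
    }
    cbind(data.frame(group = g), as.data.frame(t(colMeans(sub))))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  names(res) <- c("group", cls)
  res
}

#' Generate a synthetic land-cover raster for a scenario
#'
#' Emulates a national land-cover product over the scenario lattice: cells in
#' urban (high-density) units draw mostly built-up codes, rural cells mostly
#' forest with agricultural and open-land admixture and a small share of
#' water. The output is deterministic given the scenario seed.
#'
#' @param grid Population grid ([generate_grid()]).
#' @param config The matching [scenario_config()].
#' @param resolution_factor Integer: raster cells per grid-cell edge
#'   (default 2, i.e. four raster cells per population cell).
#' @return An [lulc_raster()] covering the full lattice extent.
#' @export
generate_lulc_raster <- function(grid, config, resolution_factor = 2L) {
  set.seed(stage_seed(config$seed, "lulc"))
  cs <- config$cell_size_m / resolution_factor
  nr <- config$grid_ny * resolution_factor
  nc <- config$grid_nx * resolution_factor
  # population density of the parent grid cell, row 1 = top
  popmap <- matrix(0, nrow = config$grid_ny, ncol = config$grid_nx)
  gi <- ceiling(grid$x / config$cell_size_m)
  gj <- ceiling(grid$y / config$cell_size_m)
  popmap[cbind(gj, gi)] <- grid$population
  urban_cell <- popmap > quantile(popmap[popmap > 0], 0.8)
  codes <- matrix(0L, nrow = nr, ncol = nc)
  p_urban <- c(0.35, 0.2, 0.15, 0.1, 0.05, 0.02, 0.04, 0.02, 0.01, 0.005,
               0.005, 0.01, 0.02, 0.01, 0.005, 0.03, 0.015)
  p_rural <- c(0.01, 0.01, 0.02, 0.1, 0.06, 0.02, 0.3, 0.12, 0.12, 0.05,
               0.05, 0.04, 0.03, 0.02, 0.01, 0.03, 0.01)
  for (i in seq_len(nr)) {
    gj_row <- config$grid_ny - ceiling(i / resolution_factor) + 1L
    urb <- urban_cell[gj_row, ceiling(seq_len(nc) / resolution_factor)]
    codes[i, ] <- ifelse(urb,
                         sample(1:17, nc, replace = TRUE, prob = p_urban),
                         sample(1:17, nc, replace = TRUE, prob = p_rural))
  }
  lulc_raster(codes, xmin = 0, ymin = 0, cellsize = cs)
}
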