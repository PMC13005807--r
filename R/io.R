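#' Read and write pipeline tables
#'
#' Plain-CSV readers/writers for the pipeline schemas. Readers validate the
#' required columns and report the offending file; writers round-trip the
#' data model exactly.
#'
#' @param x Table to write.
#' @param path File path.
#' @name table_io
NULL

.check_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  df[, cols, drop = FALSE]
}

#' @rdname table_io
#' @export
write_cases_csv <- function(x, path) {
  write.csv(x[, c("case_id", "sex", "birth_year", "diagnosis_year",
                  "native", "year", "cell_id")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_cases_csv <- function(path) {
  df <- .check_cols(read.csv(path), c("case_id", "sex", "birth_year",
                                      "diagnosis_year", "native", "year",
                                      "cell_id"), path)
  class(df) <- c("case_histories", "data.frame")
  df
}

#' @rdname table_io
#' @export
write_grid_csv <- function(x, path) {
  write.csv(x[, c("cell_id", "x", "y", "population", "unit_id")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_grid_csv <- function(path) {
  .check_cols(read.csv(path), c("cell_id", "x", "y", "population", "unit_id"),
              path)
}

#' @rdname table_io
#' @export
write_assignments_csv <- function(x, path) {
  write.csv(x[, c("case_id", "window", "cell_id", "n_years_used")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_assignments_csv <- function(path) {
  .check_cols(read.csv(path), c("case_id", "window", "cell_id",
                                "n_years_used"), path)
}

# rectangle polygon ring (closed, counter-clockwise) as a GeoJSON coord array
.rect_ring <- function(x0, y0, x1, y1) {
  list(list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0)))
}

#' Write administrative-unit polygons as GeoJSON
#'
#' Units are rectangular blocks of grid cells; each feature carries the unit
#' id and population.
#'
#' @param grid Population grid ([generate_grid()]).
#' @param config Matching [scenario_config()] (for the cell size).
#' @param path Output path.
#' @export
write_units_geojson <- function(grid, config, path) {
  cs <- config$cell_size_m
  feats <- lapply(sort(unique(grid$unit_id)), function(u) {
    g <- grid[grid$unit_id == u, ]
    list(type = "Feature",
         properties = list(unit_id = u, population = sum(g$population)),
         geometry = list(type = "Polygon",
                         coordinates = .rect_ring(min(g$x) - cs / 2,
                                                  min(g$y) - cs / 2,
                                                  max(g$x) + cs / 2,
                                                  max(g$y) + cs / 2)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write per-unit incidence results joined to unit polygons as GeoJSON
#'
#' One layer (file) per exposure window; each feature carries the full
#' unit-incidence record as properties.
#'
#' @param inc Output of [unit_incidence()] for one window.
#' @param grid Population grid ([generate_grid()]).
#' @param config Matching [scenario_config()].
#' @param path Output path.
#' @export
write_unit_incidence_geojson <- function(inc, grid, config, path) {
  cs <- config$cell_size_m
  feats <- lapply(seq_len(nrow(inc)), function(i) {
    g <- grid[grid$unit_id == inc$unit_id[i], ]
    list(type = "Feature",
         properties = as.list(inc[i, ]),
         geometry = list(type = "Polygon",
                         coordinates = .rect_ring(min(g$x) - cs / 2,
                                                  min(g$y) - cs / 2,
                                                  max(g$x) + cs / 2,
                                                  max(g$y) + cs / 2)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# circle polygon ring approximated with `n` vertices
.circle_ring <- function(cx, cy, r, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)
  list(lapply(seq_len(n + 1L), function(i)
    c(cx + r * cos(th[i]), cy + r * sin(th[i]))))
}

#' Write scan clusters as GeoJSON circle polygons
#'
#' @param clusters Cluster table from [scan_poisson()].
#' @param cells Grid data.frame (for centre coordinates).
#' @param path Output path.
#' @export
write_clusters_geojson <- function(clusters, cells, path) {
  feats <- lapply(seq_len(nrow(clusters)), function(i) {
    ctr <- cells[cells$cell_id == clusters$centre_cell[i], ]
    list(type = "Feature",
         properties = list(rank = clusters$rank[i],
                           centre_cell = clusters$centre_cell[i],
                           radius_m = clusters$radius_m[i],
                           c = clusters$c[i], E = clusters$E[i],
                           llr = clusters$llr[i], rr = clusters$rr[i],
                           p_value = clusters$p_value[i]),
         geometry = list(type = "Polygon",
                         coordinates = .circle_ring(ctr$x, ctr$y,
                                                    max(clusters$radius_m[i],
                                                        1))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a Dorling layout as GeoJSON points with radius attributes
#'
#' @param layout Output of [dorling_layout()].
#' @param path Output path.
#' @export
write_dorling_geojson <- function(layout, path) {
  feats <- lapply(seq_len(nrow(layout)), function(i) {
    list(type = "Feature",
         properties = list(unit_id = layout$unit_id[i],
                           radius = layout$radius[i],
                           value = layout$value[i]),
         geometry = list(type = "Point",
                         coordinates = c(layout$x[i], layout$y[i])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' JSON key-value configuration; recognised keys mirror the arguments of
#' [scenario_config()] and [scan_config()] (`scan.` prefix), plus
#' `planted_clusters` as an array of objects.
#'
#' @param path Path to a JSON configuration file.
#' @return List with elements `scenario` and `scan`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pcs <- list()
  if (!is.null(raw$planted_clusters) && length(raw$planted_clusters)) {
    pc_df <- as.data.frame(raw$planted_clusters)
    pcs <- lapply(seq_len(nrow(pc_df)), function(i)
      planted_cluster(pc_df$centre_x[i], pc_df$centre_y[i],
                      pc_df$radius_m[i], pc_df$risk_multiplier[i],
                      pc_df$active_window[i]))
  }
  sc_keys <- setdiff(names(formals(scenario_config)), "planted_clusters")
  sc_args <- raw[intersect(names(raw), sc_keys)]
  sc_args$planted_clusters <- pcs
  scan_keys <- names(formals(scan_config))
  scan_raw <- raw[startsWith(names(raw), "scan_")]
  names(scan_raw) <- sub("^scan_", "", names(scan_raw))
  scan_args <- scan_raw[intersect(names(scan_raw), scan_keys)]
  list(scenario = do.call(scenario_config, sc_args),
       scan = do.call(scan_config, scan_args))
}
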