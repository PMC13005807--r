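#' Year bounds of a life-stage exposure window
#'
#' `at_diagnosis` is the diagnosis year alone; `first5` covers the five
#' calendar years starting at birth (truncated at diagnosis for cases
#' diagnosed before age five); `last5` covers the five calendar years ending
#' at diagnosis (truncated at birth); `lifetime` covers birth to diagnosis.
#' All bounds are inclusive.
#'
#' @param birth_year,diagnosis_year Integers, `birth_year <= diagnosis_year`.
#' @param window One of [exposure_windows()].
#' @return Integer vector `c(first_year, last_year)`.
#' @export
window_bounds <- function(birth_year, diagnosis_year, window) {
  if (birth_year > diagnosis_year)
    stop("invalid case: birth_year > diagnosis_year", call. = FALSE)
  window <- match.arg(window, exposure_windows())
  switch(window,
    at_diagnosis = c(diagnosis_year, diagnosis_year),
    first5 = c(birth_year, min(birth_year + 4L, diagnosis_year)),
    last5 = c(max(diagnosis_year - 4L, birth_year), diagnosis_year),
    lifetime = c(birth_year, diagnosis_year)
  )
}

# core rule shared by dominant_location() and the generator: cell occupied
# the most years; ties broken by the cell occupied earliest
.dominant_cell <- function(years, cells) {
  o <- order(years)
  cells <- cells[o]
  u <- unique(cells)                       # unique() preserves first-seen order
  counts <- tabulate(match(cells, u), nbins = length(u))
  u[which.max(counts)]                     # which.max takes the earliest tie
}

#' Dominant residential location within a window
#'
#' Returns the cell occupied for the largest number of years inside the
#' bounds; ties are broken in favour of the cell occupied earliest within the
#' window, making the result deterministic and invariant to the ordering of
#' the input rows.
#'
#' @param years,cells Parallel vectors giving the residence (year, cell) pairs.
#' @param bounds Inclusive year range, as returned by [window_bounds()].
#' @return The dominant `cell_id`, with attribute `n_years` giving the number
#'   of in-window years it was occupied.
#' @export
dominant_location <- function(years, cells, bounds) {
  sel <- years >= bounds[1] & years <= bounds[2]
  if (!any(sel))
    stop("missing data: no residence years inside window bounds", call. = FALSE)
  cell <- .dominant_cell(years[sel], cells[sel])
  structure(cell, n_years = sum(cells[sel] == cell))
}

#' Assign all four exposure windows for every case
#'
#' @param cases A `case_histories` long-format data.frame
#'   (see [generate_case_histories()]).
#' @return A data.frame of exposure assignments with exactly four rows per
#'   case: `case_id`, `window`, `cell_id`, `n_years_used`.
#' @export
assign_windows <- function(cases) {
  ids <- unique(cases$case_id)
  wins <- exposure_windows()
  split_idx <- split(seq_len(nrow(cases)), cases$case_id)
  out <- vector("list", length(ids))
  for (q in seq_along(ids)) {
    rows <- split_idx[[as.character(ids[q])]]
    yrs <- cases$year[rows]
    cls <- cases$cell_id[rows]
    b <- cases$birth_year[rows[1]]
    d <- cases$diagnosis_year[rows[1]]
    cell <- integer(length(wins)); nyu <- integer(length(wins))
    for (k in seq_along(wins)) {
      bnds <- window_bounds(b, d, wins[k])
      dom <- tryCatch(dominant_location(yrs, cls, bnds), error = function(e)
        stop(sprintf("case %s: %s", ids[q], conditionMessage(e)), call. = FALSE))
      cell[k] <- dom
      nyu[k] <- attr(dom, "n_years")
    }
    out[[q]] <- data.frame(case_id = ids[q], window = wins,
                           cell_id = cell, n_years_used = nyu)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(case_id = integer(), window = character(),
               cell_id = integer(), n_years_used = integer())
  rownames(res) <- NULL
  res
}
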