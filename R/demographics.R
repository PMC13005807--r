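#' Cohort demographics reference table
#'
#' Loads the published cohort demographic counts shipped with the package
#' (total cohort size, counts by sex, age group at diagnosis, age-under-18
#' and nativity) together with the period incidence rates. These are the
#' printed registry totals used by the worked-example arithmetic checks; the
#' package never has access to the underlying individual-level data.
#'
#' @return List with `counts` (data.frame: `item`, `group`, `n`) and
#'   `rates` (data.frame: `item`, `value`).
#' @export
cohort_reference <- function() {
  path <- system.file("extdata", "cohort_reference.csv", package = "t1dscan")
  df <- read.csv(path, stringsAsFactors = FALSE)
  rates <- df[df$kind == "rate", c("item", "n")]
  names(rates)[2] <- "value"
  rownames(rates) <- NULL
  list(counts = df[df$kind == "count", c("item", "group", "n")],
       rates = rates)
}

#' Percentage of a total
#'
#' @param count,total Counts, `total > 0`.
#' @return `count / total * 100`.
#' @export
proportion_pct <- function(count, total) {
  if (any(total <= 0)) stop("total must be > 0", call. = FALSE)
  count / total * 100
}
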