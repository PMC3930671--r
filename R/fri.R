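#' Composite fire chronology (all fires)
#'
#' Builds the composite fire record over an analysis period: fire years are
#' the union of all scar years across samples; each year also carries the
#' number of samples scarred and the number of samples recording (samples
#' whose recording spans cover the year).  Period endpoints are closed.
#'
#' @param records A [fire_scar_records()] object.
#' @param period Length-2 vector `c(start, end)`; default the full span of
#'   the recording intervals.
#' @return A `composite_series`: tibble with `year`, `n_scarred`,
#'   `n_recording`, plus `filter` attribute `"all"`.
#' @export
build_composite <- function(records, period = NULL) {
  rec <- records$recording
  if (is.null(period))
    period <- if (nrow(rec)) c(min(rec$start), max(rec$end)) else c(NA, NA)
  sc <- records$scars
  sc <- sc[sc$year >= period[1] & sc$year <= period[2], ]
  years <- sort(unique(sc$year))
  out <- tibble(
    year = years,
    n_scarred = vapply(years, function(y)
      length(unique(sc$sample_id[sc$year == y])), integer(1)),
    n_recording = vapply(years, function(y)
      length(unique(rec$sample_id[rec$start <= y & rec$end >= y])),
      integer(1)))
  new_tibble(out, period = period, filter = "all", class = "composite_series")
}

#' Scar-count / percentage filter for composite fire years
#'
#' The widely used "25% filter": keep a fire year iff at least `min_samples`
#' samples were scarred AND the scarred fraction of recording samples exceeds
#' `min_fraction`.  The fraction comparison is strict (`> 25\%`) by default,
#' with `strict = FALSE` switching to `>=` ("at least 25%") -- both
#' conventions are in circulation.
#'
#' @param series A [build_composite()] series.
#' @param min_samples Minimum scarred samples, default 3.
#' @param min_fraction Minimum scarred fraction of recording samples,
#'   default 0.25.
#' @param strict Use `>` (default) rather than `>=` for the fraction.
#' @return The filtered `composite_series`.
#' @export
apply_filter <- function(series, min_samples = 3, min_fraction = 0.25,
                         strict = TRUE) {
  if (any(series$n_recording == 0 & series$n_scarred > 0))
    abort("scarred year with zero recording samples: inconsistent records")
  frac <- series$n_scarred / series$n_recording
  keep <- series$n_scarred >= min_samples &
    (if (strict) frac > min_fraction else frac >= min_fraction)
  out <- series[keep, ]
  new_tibble(out, period = attr(series, "period"),
             filter = sprintf("min %d samples, %s%g%% of recording",
                              min_samples, if (strict) ">" else ">=",
                              100 * min_fraction),
             class = "composite_series")
}

#' Fire-return-interval summary
#'
#' Intervals are successive differences of composite fire years; reported as
#' mean, sample standard deviation and median over the analysis period.
#'
#' @param series A `composite_series`.
#' @return A `fri_summary` tibble (one row): `n_fires`, `n_intervals`,
#'   `mean`, `sd`, `median`, `min`, `max`, `period_start`, `period_end`,
#'   `filter`.
#' @export
fri_summary <- function(series) {
  if (nrow(series) < 2)
    abort("no intervals: need at least 2 composite fire years")
  iv <- diff(series$year)
  period <- attr(series, "period")
  new_tibble(
    tibble(n_fires = nrow(series), n_intervals = length(iv),
           mean = mean(iv),
           sd = if (length(iv) > 1) sd(iv) else NA_real_,
           median = median(iv), min = min(iv), max = max(iv),
           period_start = period[1], period_end = period[2],
           filter = attr(series, "filter")),
    class = "fri_summary")
}
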