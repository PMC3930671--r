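#' Site geography
#'
#' Elevation, latitude and longitude of a site, feeding the Hopkins
#' bioclimatic index used as a geographic covariate in crown-width models.
#'
#' @param elevation Elevation (m above sea level).
#' @param latitude,longitude Decimal degrees (longitude negative west).
#' @return A `site_geography`.
#' @export
site_geography <- function(elevation, latitude, longitude) {
  if (latitude < -90 || latitude > 90) abort("latitude must be in [-90, 90]")
  if (longitude < -180 || longitude > 180) abort("longitude must be in [-180, 180]")
  structure(list(elevation = elevation, latitude = latitude,
                 longitude = longitude), class = "site_geography")
}

#' Hopkins bioclimatic index
#'
#' Affine function of elevation, latitude and longitude expressing
#' bioclimatic position.  The default coefficients follow Hopkins'
#' bioclimatic-law scaling -- one unit per 100 ft (30.48 m) of elevation,
#' four units per degree of latitude, 1.25 units per degree of longitude --
#' about a reference point at which the index is zero.  Both the coefficients
#' and the reference point are user-replaceable data, not fitted here.
#'
#' @param geo A [site_geography()].
#' @param coef Named vector `c(elev, lat, lon)`: index units per metre of
#'   elevation, per degree latitude, per degree longitude.
#' @param ref Named vector `c(elev, lat, lon)`: the zero-index reference
#'   point (m, degrees, degrees).
#' @return The index value (affine in all three inputs).
#' @examples
#' hopkins_index(site_geography(2440, 31.62, -115.98))
#' @export
hopkins_index <- function(geo,
                          coef = c(elev = 1 / 30.48, lat = 4, lon = 1.25),
                          ref = c(elev = 1661, lat = 42.16, lon = -116.39)) {
  coef[["elev"]] * (geo$elevation - ref[["elev"]]) +
    coef[["lat"]] * (geo$latitude - ref[["lat"]]) +
    coef[["lon"]] * (geo$longitude - ref[["lon"]])
}

#' Crown-width coefficient table
#'
#' Loads a per-species coefficient table for the crown-width model
#' `CW = b0 + b1 DBH + b2 DBH^2 + b3 CR + b4 BA + b5 HI` (CW in m, DBH in cm,
#' CR the live-crown ratio in (0, 1], BA plot basal area in m^2 ha^-1, HI the
#' Hopkins index), with 0/1 inclusion flags per predictor -- a predictor
#' enters a species' prediction only when its flag is set.  The table shipped
#' with the package (`crown_coefficients_default.csv`) contains documented
#' package-default coefficients producing realistic crown widths for the
#' species codes of Jeffrey pine-mixed conifer forests (JP, WF, IC, SP, LP,
#' SJ, QA, QU, PE) plus `CONIFER` and `DEFAULT` fallback rows; it is data,
#' not code, and should be replaced with locally fitted coefficients where
#' available.
#'
#' @param path CSV path; `NULL` loads the packaged default table.
#' @return A `crown_model` tibble.
#' @export
load_crown_model <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "crown_coefficients_default.csv",
                        package = "stemmosaic")
  tab <- as_tibble(read.csv(path, colClasses = c(species = "character")))
  need <- c("species", paste0("b", 0:5), "use_dbh2", "use_cr", "use_ba", "use_hi")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    abort(paste0("crown coefficient table missing column(s): ",
                 paste(miss, collapse = ", ")))
  structure(tab, class = c("crown_model", class(tab)))
}

#' Predict crown width
#'
#' Evaluates the species' crown-width equation.  Predictors whose inclusion
#' flag is unset are ignored; a flagged predictor that is missing raises an
#' error naming the species and predictor.  Negative extrapolations are
#' clamped to `floor` metres with a warning.
#'
#' @param model A [load_crown_model()] table.
#' @param species Species code(s).
#' @param dbh DBH (cm), `> 5`.
#' @param cr Live-crown ratio in (0, 1] (required only by species whose
#'   `use_cr` flag is set).
#' @param ba Plot basal area (m^2 ha^-1).
#' @param hi Hopkins index (or a [site_geography()], converted internally).
#' @param fallback Substitute the `CONIFER`/`DEFAULT` rows for unknown
#'   species codes (with a warning) instead of erroring.
#' @param floor Minimum crown width (m) for clamping, default 0.5.
#' @return Crown width (m); the crown radius is `CW / 2`.
#' @export
crown_width <- function(model, species, dbh, cr = NA_real_, ba = 0, hi = 0,
                        fallback = TRUE, floor = 0.5) {
  if (inherits(hi, "site_geography")) hi <- hopkins_index(hi)
  n <- length(dbh)
  species <- rep_len(species, n)
  cr <- rep_len(cr, n); ba <- rep_len(ba, n); hi <- rep_len(hi, n)
  idx <- match(species, model$species)
  if (anyNA(idx)) {
    unknown <- unique(species[is.na(idx)])
    if (!fallback)
      abort(paste0("no crown coefficients for species: ",
                   paste(unknown, collapse = ", ")))
    warn(paste0("using fallback crown coefficients for species: ",
                paste(unknown, collapse = ", ")))
    fb <- match("CONIFER", model$species)
    if (is.na(fb)) fb <- match("DEFAULT", model$species)
    if (is.na(fb)) abort("coefficient table has no CONIFER/DEFAULT fallback row")
    idx[is.na(idx)] <- fb
  }
  m <- model[idx, ]
  needs_cr <- m$use_cr == 1
  if (any(needs_cr & is.na(cr)))
    abort(paste0("crown ratio (CR) required but missing for species: ",
                 paste(unique(species[needs_cr & is.na(cr)]), collapse = ", ")))
  cw <- m$b0 + m$b1 * dbh +
    ifelse(m$use_dbh2 == 1, m$b2 * dbh^2, 0) +
    ifelse(needs_cr, m$b3 * cr, 0) +
    ifelse(m$use_ba == 1, m$b4 * ba, 0) +
    ifelse(m$use_hi == 1, m$b5 * hi, 0)
  if (any(cw < floor)) {
    warn(sprintf("%d crown width(s) below %.2g m clamped (extrapolation guard)",
                 sum(cw < floor), floor))
    cw <- pmax(cw, floor)
  }
  cw
}

#' Assign crown radii to a stem map
#'
#' Fills `crown_radius` (m) for every live tree from the species crown-width
#' model.  The crown ratio is derived as `(height - crown_base) / height`
#' where both are present, otherwise `cr_default`; the basal-area covariate
#' is the plot-level live basal area (m^2 ha^-1); the Hopkins index comes
#' from the site geography (0 when no geography is given).  Snags take no
#' part in canopy geometry and keep `crown_radius = NA`.
#'
#' @param sm A [stem_map()].
#' @param model A [load_crown_model()] table (default: packaged table).
#' @param geo Optional [site_geography()].
#' @param cr_default Crown ratio used when height data are absent.
#' @inheritParams crown_width
#' @return `sm` with `crown_radius` filled for live trees.
#' @export
assign_crowns <- function(sm, model = load_crown_model(), geo = NULL,
                          cr_default = 0.6, fallback = TRUE, floor = 0.5) {
  live <- sm$status == "live"
  if (!any(live)) return(sm)
  hi <- if (is.null(geo)) 0 else hopkins_index(geo)
  ba <- plot_basal_area(sm)
  cr <- ifelse(!is.na(sm$height) & !is.na(sm$crown_base) & sm$height > 0,
               (sm$height - sm$crown_base) / sm$height, cr_default)
  cw <- crown_width(model, sm$species[live], sm$dbh[live], cr = cr[live],
                    ba = ba, hi = hi, fallback = fallback, floor = floor)
  sm$crown_radius[live] <- cw / 2
  sm$crown_radius[!live] <- NA_real_
  validate_stem_map(sm)
}

#' @rdname assign_crowns
#' @export
plot_basal_area <- function(sm) {
  # live basal area in m^2 per ha
  live <- sm$status == "live"
  sum(pi * (sm$dbh[live] / 200)^2) / (window_area(sm_window(sm)) / 1e4)
}
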