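#' @useDynLib stemmosaic, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import tibble
#' @importFrom rlang abort warn .data
#' @importFrom stats sd median quantile rnorm runif rpois rbinom qnorm pnorm
#' @importFrom utils read.csv write.csv head tail
NULL

#' Rectangular plot window
#'
#' Defines the survey extent, in plot-local metres (origin at the lower-left
#' corner), together with the interior edge buffer used by the patch, single
#' tree and gap summaries.
#'
#' @param x_max,y_max Upper coordinate limits (m).
#' @param x_min,y_min Lower coordinate limits (m), default 0.
#' @param buffer_width Width of the interior edge buffer (m), default 5.
#' @return An object of class `plot_window`.
#' @examples
#' w <- plot_window(200, 200)   # a 4 ha plot
#' window_area(w)
#' @export
plot_window <- function(x_max, y_max, x_min = 0, y_min = 0, buffer_width = 5) {
  if (!(x_max > x_min) || !(y_max > y_min))
    abort("plot window must have positive extent (x_max > x_min, y_max > y_min)")
  side <- min(x_max - x_min, y_max - y_min)
  if (buffer_width < 0 || buffer_width >= side / 2)
    abort("buffer_width must satisfy 0 <= buffer_width < min(width, height)/2")
  structure(
    list(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
         buffer_width = buffer_width),
    class = "plot_window")
}

#' @rdname plot_window
#' @param window A `plot_window`.
#' @export
window_area <- function(window) {
  (window$x_max - window$x_min) * (window$y_max - window$y_min)
}

#' @export
print.plot_window <- function(x, ...) {
  cat(sprintf("<plot_window> [%g, %g] x [%g, %g] m (%.4g ha), buffer %g m\n",
              x$x_min, x$x_max, x$y_min, x$y_max,
              window_area(x) / 1e4, x$buffer_width))
  invisible(x)
}

in_window <- function(window, x, y) {
  # closed window: stems exactly on the boundary are members
  x >= window$x_min & x <= window$x_max & y >= window$y_min & y <= window$y_max
}

#' Build a stem map
#'
#' A stem map is a tibble with one row per stem (columns `id`, `x`, `y`,
#' `species`, `dbh`, `height`, `crown_base`, `status`, `crown_radius`) plus a
#' `plot_window` and a site label carried as attributes.  All positions are
#' plot-local metres; `dbh` is in cm and must exceed 5 (the mapping threshold
#' for these surveys); `status` is `"live"` or `"snag"`.
#'
#' @param trees A data frame with at least `x`, `y`, `species`, `dbh`.
#'   `id` defaults to the row number; `status` defaults to `"live"`.
#' @param window A [plot_window()].
#' @param site_label Free-text site name.
#' @return A `stem_map` (tibble subclass).
#' @examples
#' sm <- stem_map(
#'   data.frame(x = c(10, 50), y = c(10, 60), species = "JP", dbh = c(20, 40)),
#'   plot_window(200, 200), site_label = "demo")
#' @export
stem_map <- function(trees, window, site_label = "") {
  stopifnot(inherits(window, "plot_window"))
  trees <- as_tibble(trees)
  need <- c("x", "y", "species", "dbh")
  miss <- setdiff(need, names(trees))
  if (length(miss))
    abort(paste0("stem map is missing mandatory column(s): ",
                 paste(miss, collapse = ", ")))
  if (!"id" %in% names(trees)) trees$id <- as.character(seq_len(nrow(trees)))
  trees$id <- as.character(trees$id)
  if (!"status" %in% names(trees)) trees$status <- "live"
  for (opt in c("height", "crown_base", "crown_radius"))
    if (!opt %in% names(trees)) trees[[opt]] <- NA_real_
  for (num in c("x", "y", "dbh", "height", "crown_base", "crown_radius"))
    trees[[num]] <- as.numeric(trees[[num]])
  trees <- trees[, c("id", "x", "y", "species", "dbh", "height",
                     "crown_base", "status", "crown_radius")]
  out <- new_tibble(trees, window = window, site_label = site_label,
                    class = "stem_map")
  validate_stem_map(out)
}

#' @rdname stem_map
#' @param sm A `stem_map`.
#' @export
sm_window <- function(sm) attr(sm, "window")

#' @rdname stem_map
#' @export
sm_site <- function(sm) attr(sm, "site_label")

#' Validate a stem map against its invariants
#'
#' Checks id uniqueness, window membership, the 5 cm dbh threshold, status
#' tokens, and crown geometry sanity.  Violations raise an error naming the
#' offending tree ids.
#'
#' @param sm A `stem_map`.
#' @return `sm`, invisibly unchanged, if valid.
#' @export
validate_stem_map <- function(sm) {
  w <- sm_window(sm)
  if (anyDuplicated(sm$id))
    abort(paste0("duplicate tree ids: ",
                 paste(unique(sm$id[duplicated(sm$id)]), collapse = ", ")))
  bad <- !in_window(w, sm$x, sm$y)
  if (any(bad))
    abort(paste0("trees outside the plot window: ",
                 paste(sm$id[bad], collapse = ", ")))
  bad <- !(sm$dbh > 5)
  if (any(bad))
    abort(paste0("dbh must exceed 5 cm (mapping threshold); offending ids: ",
                 paste(sm$id[bad], collapse = ", ")))
  if (!all(sm$status %in% c("live", "snag")))
    abort("status must be 'live' or 'snag'")
  both <- !is.na(sm$height) & !is.na(sm$crown_base)
  bad <- both & sm$crown_base >= sm$height
  if (any(bad))
    abort(paste0("crown_base must be below height; offending ids: ",
                 paste(sm$id[bad], collapse = ", ")))
  if (any(!is.na(sm$crown_radius) & sm$crown_radius <= 0))
    abort("crown_radius must be positive where present")
  sm
}

#' @export
print.stem_map <- function(x, ...) {
  w <- sm_window(x)
  cat(sprintf("Stem map '%s': %d stems (%d live, %d snag) on %.4g ha\n",
              sm_site(x), nrow(x), sum(x$status == "live"),
              sum(x$status == "snag"), window_area(w) / 1e4))
  NextMethod()
}

#' Read / write stem maps
#'
#' Stem maps are stored as comma-separated tables with a key-value header
#' block (lines starting `#!`) carrying the window extent, buffer width and
#' site label, so a file is self-describing and `write_stem_map()` followed by
#' [read_stem_map()] is the identity.
#'
#' @param path File path.
#' @return `read_stem_map()` returns a validated [stem_map()];
#'   `write_stem_map()` returns `path` invisibly.
#' @examples
#' sm <- stem_map(data.frame(x = 1:3 * 10, y = 1:3 * 10, species = "JP",
#'                           dbh = c(12, 30, 80)), plot_window(100, 100))
#' f <- tempfile(fileext = ".csv")
#' write_stem_map(sm, f)
#' identical(dim(read_stem_map(f)), dim(sm))
#' @export
read_stem_map <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#!", lines)
  kv <- list()
  for (ln in lines[hdr]) {
    m <- regmatches(ln, regexec("^#!\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) kv[[trimws(m[2])]] <- trimws(m[3])
  }
  need <- c("x_min", "y_min", "x_max", "y_max")
  if (!all(need %in% names(kv)))
    abort("stem-map header must define x_min, y_min, x_max, y_max (#! key: value lines)")
  w <- plot_window(as.numeric(kv$x_max), as.numeric(kv$y_max),
                   as.numeric(kv$x_min), as.numeric(kv$y_min),
                   buffer_width = if (is.null(kv$buffer_width)) 5
                                  else as.numeric(kv$buffer_width))
  body <- lines[-hdr]
  trees <- read.csv(text = paste(body, collapse = "\n"),
                    colClasses = c(id = "character", species = "character",
                                   status = "character"))
  stem_map(trees, w, site_label = if (is.null(kv$site_label)) "" else kv$site_label)
}

#' @rdname read_stem_map
#' @param sm A `stem_map`.
#' @export
write_stem_map <- function(sm, path) {
  w <- sm_window(sm)
  hdr <- c(
    sprintf("#! x_min: %.10g", w$x_min), sprintf("#! y_min: %.10g", w$y_min),
    sprintf("#! x_max: %.10g", w$x_max), sprintf("#! y_max: %.10g", w$y_max),
    sprintf("#! buffer_width: %.10g", w$buffer_width),
    paste0("#! site_label: ", sm_site(sm)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(as.data.frame(sm), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Label stems as interior or edge-buffer
#'
#' A stem is in the buffer iff it lies within `buffer_width` of any window
#' edge.  Buffer trees still contribute crown geometry to patch and gap
#' delineation but are excluded from the patch/single-tree summary tables.
#'
#' @param sm A `stem_map`.
#' @return `sm` with an added `zone` column (`"interior"` or `"buffer"`).
#' @export
partition_by_buffer <- function(sm) {
  w <- sm_window(sm)
  b <- w$buffer_width
  buf <- (sm$x - w$x_min) < b | (w$x_max - sm$x) < b |
         (sm$y - w$y_min) < b | (w$y_max - sm$y) < b
  sm$zone <- ifelse(buf, "buffer", "interior")
  sm
}

#' Diameter size classes
#'
#' The default scheme follows the standard small/medium/large convention for
#' these forests: small `[5, 25)` cm, medium `[25, 75)` cm, large `[75, Inf)`
#' cm DBH.  Classes partition `(5, Inf)` so every mapped stem gets exactly one
#' class.
#'
#' @param breaks Ascending class boundaries starting at 5 and ending at `Inf`.
#' @param labels One label per class.
#' @return A `size_class_scheme`.
#' @export
size_class_scheme <- function(breaks = c(5, 25, 75, Inf),
                              labels = c("small", "medium", "large")) {
  stopifnot(length(labels) == length(breaks) - 1, !is.unsorted(breaks),
            breaks[1] == 5, is.infinite(breaks[length(breaks)]))
  structure(list(breaks = breaks, labels = labels), class = "size_class_scheme")
}

#' @rdname size_class_scheme
#' @param sm A `stem_map` (or any data frame with a `dbh` column).
#' @param scheme A `size_class_scheme`.
#' @export
assign_size_class <- function(sm, scheme = size_class_scheme()) {
  sm$size_class <- cut(sm$dbh, breaks = scheme$breaks, labels = scheme$labels,
                       right = FALSE, include.lowest = FALSE)
  sm
}

#' Fire-scar record set
#'
#' Per-sample fire-scar years plus the spans during which each sample is
#' capable of recording fire.  Scar years must fall inside their sample's
#' recording intervals; intervals must be ascending and non-overlapping.
#'
#' @param scars Tibble with columns `sample_id`, `year` (one row per scar).
#' @param recording Tibble with columns `sample_id`, `start`, `end`
#'   (one row per recording interval; closed years).
#' @return A `fire_scar_records` object.
#' @export
fire_scar_records <- function(scars, recording) {
  scars <- as_tibble(scars)[c("sample_id", "year")]
  recording <- as_tibble(recording)[c("sample_id", "start", "end")]
  scars$sample_id <- as.character(scars$sample_id)
  recording$sample_id <- as.character(recording$sample_id)
  if (any(recording$end < recording$start))
    abort("recording intervals must have end >= start")
  for (sid in unique(recording$sample_id)) {
    iv <- recording[recording$sample_id == sid, ]
    iv <- iv[order(iv$start), ]
    if (nrow(iv) > 1 && any(iv$start[-1] <= iv$end[-nrow(iv)]))
      abort(paste0("overlapping recording intervals for sample ", sid))
  }
  if (nrow(scars)) {
    ok <- vapply(seq_len(nrow(scars)), function(i) {
      iv <- recording[recording$sample_id == scars$sample_id[i], ]
      any(scars$year[i] >= iv$start & scars$year[i] <= iv$end)
    }, logical(1))
    if (!all(ok))
      abort(paste0("scar years outside recording spans for sample(s): ",
                   paste(unique(scars$sample_id[!ok]), collapse = ", ")))
  }
  structure(list(scars = scars, recording = recording),
            class = "fire_scar_records")
}

#' @export
print.fire_scar_records <- function(x, ...) {
  cat(sprintf("<fire_scar_records> %d samples, %d scars, span %s-%s\n",
              length(unique(x$recording$sample_id)), nrow(x$scars),
              if (nrow(x$recording)) min(x$recording$start) else NA,
              if (nrow(x$recording)) max(x$recording$end) else NA))
  invisible(x)
}

#' Read / write fire-scar chronologies
#'
#' The on-disk format is one CSV row per sample recording interval with the
#' sample's scar years as a semicolon-separated list (repeated rows for a
#' sample may carry additional intervals; scar years are pooled).
#'
#' @param path File path.
#' @return `read_fire_scars()` returns a [fire_scar_records()] object.
#' @export
read_fire_scars <- function(path) {
  df <- read.csv(path, colClasses = c(sample_id = "character",
                                      scar_years = "character"))
  recording <- tibble(sample_id = df$sample_id,
                      start = df$record_start, end = df$record_end)
  scars <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    ys <- df$scar_years[i]
    if (is.na(ys) || !nzchar(ys)) return(NULL)
    data.frame(sample_id = df$sample_id[i],
               year = as.integer(strsplit(ys, ";")[[1]]))
  }))
  if (is.null(scars)) scars <- tibble(sample_id = character(), year = integer())
  fire_scar_records(unique(as_tibble(scars)), recording)
}

#' @rdname read_fire_scars
#' @param records A [fire_scar_records()] object.
#' @export
write_fire_scars <- function(records, path) {
  rec <- records$recording
  rows <- lapply(seq_len(nrow(rec)), function(i) {
    sid <- rec$sample_id[i]
    first <- !duplicated(rec$sample_id)[i]
    ys <- sort(records$scars$year[records$scars$sample_id == sid])
    data.frame(sample_id = sid, record_start = rec$start[i],
               record_end = rec$end[i],
               scar_years = if (first) paste(ys, collapse = ";") else "")
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Minimal FHX-style chronology importer
#'
#' Reads the event matrix of an FHX2 file: one column per sample, one row per
#' year; uppercase letters and `|`/`U` mark scars and recording years,
#' lowercase/`.` non-recording.  Only scar years and recording spans are
#' extracted (season codes are ignored).  This is a convenience importer, not
#' a full FHX parser.
#'
#' @param path File path to an FHX-format text file.
#' @return A [fire_scar_records()] object.
#' @export
read_fhx <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^FHX2 FORMAT|^FIRE2 FORMAT", lines)
  if (!length(hdr)) abort("not an FHX-format file (missing FHX2 FORMAT line)")
  meta <- as.integer(strsplit(trimws(lines[hdr + 1]), "\\s+")[[1]])
  first_year <- meta[1]; n_samp <- meta[2]; id_len <- meta[3]
  id_rows <- lines[(hdr + 2):(hdr + 1 + id_len)]
  ids <- vapply(seq_len(n_samp), function(j)
    trimws(paste0(vapply(id_rows, function(r) substr(r, j, j), ""),
                  collapse = "")), "")
  data_rows <- lines[(hdr + 2 + id_len):length(lines)]
  data_rows <- data_rows[nzchar(trimws(data_rows))]
  scars <- list(); recording <- list()
  for (j in seq_len(n_samp)) {
    col <- vapply(data_rows, function(r) substr(r, j, j), "")
    yrs <- first_year + seq_along(col) - 1
    rec <- col %in% c("|", "U", "u") | grepl("[A-Z]", col)
    scar <- grepl("[A-Z]", col) & !(col %in% c("U"))
    if (any(scar))
      scars[[j]] <- data.frame(sample_id = ids[j], year = yrs[scar])
    if (any(rec)) {
      rr <- rle(rec)
      ends <- cumsum(rr$lengths); starts <- ends - rr$lengths + 1
      keep <- which(rr$values)
      recording[[j]] <- data.frame(sample_id = ids[j],
                                   start = yrs[starts[keep]],
                                   end = yrs[ends[keep]])
    }
  }
  fire_scar_records(do.call(rbind, scars), do.call(rbind, recording))
}
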