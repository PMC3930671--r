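#' @importFrom dplyr bind_rows group_by summarise mutate arrange n
#' @importFrom grDevices contourLines
NULL

# --- angular interval utilities (radians) -----------------------------------

# normalise intervals to [0, 2pi), splitting any that cross zero
normalise_intervals <- function(iv) {
  if (!nrow(iv)) return(iv)
  two_pi <- 2 * pi
  out <- list()
  for (k in seq_len(nrow(iv))) {
    lo <- iv[k, 1] %% two_pi
    hi <- lo + (iv[k, 2] - iv[k, 1])
    if (hi <= two_pi) out[[length(out) + 1]] <- c(lo, hi)
    else {
      out[[length(out) + 1]] <- c(lo, two_pi)
      out[[length(out) + 1]] <- c(0, hi - two_pi)
    }
  }
  do.call(rbind, out)
}

merge_intervals <- function(iv) {
  if (!nrow(iv)) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (k in seq_len(nrow(iv))[-1]) {
    last <- nrow(out)
    if (iv[k, 1] <= out[last, 2] + 1e-12)
      out[last, 2] <- max(out[last, 2], iv[k, 2])
    else out <- rbind(out, iv[k, ])
  }
  out
}

complement_intervals <- function(iv) {
  two_pi <- 2 * pi
  if (!nrow(iv)) return(matrix(c(0, two_pi), 1))
  iv <- merge_intervals(normalise_intervals(iv))
  gaps <- list()
  if (iv[1, 1] > 0) gaps[[1]] <- c(0, iv[1, 1])
  for (k in seq_len(nrow(iv) - 1))
    if (iv[k + 1, 1] > iv[k, 2])
      gaps[[length(gaps) + 1]] <- c(iv[k, 2], iv[k + 1, 1])
  if (iv[nrow(iv), 2] < two_pi)
    gaps[[length(gaps) + 1]] <- c(iv[nrow(iv), 2], two_pi)
  if (!length(gaps)) return(matrix(numeric(), 0, 2))
  do.call(rbind, gaps)
}

# merged 1-D interval union, clipped to [lo, hi]; returns matrix + total length
union_1d <- function(iv, lo, hi) {
  if (!nrow(iv)) return(matrix(numeric(), 0, 2))
  iv[, 1] <- pmax(iv[, 1], lo); iv[, 2] <- pmin(iv[, 2], hi)
  iv <- iv[iv[, 2] > iv[, 1], , drop = FALSE]
  if (!nrow(iv)) return(iv)
  merge_intervals(iv)
}

# --- exact union-of-disks geometry ------------------------------------------

#' Area and perimeter of a union of disks, clipped to a window
#'
#' Exact circular-arc computation: the boundary of a union of disks consists
#' of arcs; each disk's covered angular intervals (from overlapping disks and
#' from the parts of the circle outside the clipping window) are removed, and
#' the remaining arcs are integrated by Green's theorem, together with the
#' window-edge segments lying inside the union.  Handles holes automatically
#' (their boundary arcs carry the correct orientation).
#'
#' @param x,y Disk centres (m).
#' @param r Disk radii (m), positive.
#' @param window Optional [plot_window()] for clipping; `NULL` = no clipping.
#' @return A list with `area` (m^2) and `perimeter` (m; window-edge portions
#'   of a clipped boundary are included).
#' @examples
#' # two radius-3 disks 2 m apart: area = 2 pi 9 - lens
#' disk_union_geometry(c(0, 2), c(0, 0), c(3, 3))$area
#' @export
disk_union_geometry <- function(x, y, r, window = NULL) {
  stopifnot(length(x) == length(y), length(x) == length(r), all(r > 0))
  # drop exact duplicates, then disks contained in another disk
  key <- paste(signif(x, 12), signif(y, 12), signif(r, 12))
  keep <- !duplicated(key)
  x <- x[keep]; y <- y[keep]; r <- r[keep]
  n <- length(x)
  if (n == 0) return(list(area = 0, perimeter = 0))
  if (n > 1) {
    contained <- logical(n)
    for (i in seq_len(n)) {
      d <- sqrt((x - x[i])^2 + (y - y[i])^2)
      contained[i] <- any(!contained & seq_len(n) != i &
                            d + r[i] <= r + 1e-12 &
                            (d + r[i] < r - 1e-12 | r[i] < r | seq_len(n) < i))
    }
    x <- x[!contained]; y <- y[!contained]; r <- r[!contained]
    n <- length(x)
  }
  area <- 0; perim <- 0
  for (i in seq_len(n)) {
    iv <- list()
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    nb <- which(seq_len(n) != i & d < r + r[i])
    for (j in nb) {
      alpha <- acos(pmin(1, pmax(-1, (d[j]^2 + r[i]^2 - r[j]^2) /
                                       (2 * d[j] * r[i]))))
      theta <- atan2(y[j] - y[i], x[j] - x[i])
      iv[[length(iv) + 1]] <- c(theta - alpha, theta + alpha)
    }
    if (!is.null(window)) {
      # parts of the circle outside the window are not boundary
      w <- window
      if (x[i] + r[i] > w$x_max) {
        phi <- acos(pmin(1, (w$x_max - x[i]) / r[i]))
        iv[[length(iv) + 1]] <- c(-phi, phi)
      }
      if (x[i] - r[i] < w$x_min) {
        phi <- acos(pmin(1, (x[i] - w$x_min) / r[i]))
        iv[[length(iv) + 1]] <- c(pi - phi, pi + phi)
      }
      if (y[i] + r[i] > w$y_max) {
        phi <- acos(pmin(1, (w$y_max - y[i]) / r[i]))
        iv[[length(iv) + 1]] <- c(pi / 2 - phi, pi / 2 + phi)
      }
      if (y[i] - r[i] < w$y_min) {
        phi <- acos(pmin(1, (y[i] - w$y_min) / r[i]))
        iv[[length(iv) + 1]] <- c(3 * pi / 2 - phi, 3 * pi / 2 + phi)
      }
    }
    covered <- if (length(iv)) do.call(rbind, iv) else matrix(numeric(), 0, 2)
    arcs <- complement_intervals(covered)
    for (k in seq_len(nrow(arcs))) {
      t1 <- arcs[k, 1]; t2 <- arcs[k, 2]
      area <- area + 0.5 * (r[i]^2 * (t2 - t1) +
                              x[i] * r[i] * (sin(t2) - sin(t1)) -
                              y[i] * r[i] * (cos(t2) - cos(t1)))
      perim <- perim + r[i] * (t2 - t1)
    }
  }
  if (!is.null(window)) {
    w <- window
    edge_cover <- function(fixed, axis) {
      # intervals of the edge (along the other axis) covered by a disk
      dd <- if (axis == "x") abs(y - fixed) else abs(x - fixed)
      ctr <- if (axis == "x") x else y
      hit <- which(dd < r)
      if (!length(hit)) return(matrix(numeric(), 0, 2))
      s <- sqrt(r[hit]^2 - dd[hit]^2)
      cbind(ctr[hit] - s, ctr[hit] + s)
    }
    # bottom (y = y_min, +x), right (x = x_max, +y), top (-x), left (-y)
    segs <- union_1d(edge_cover(w$y_min, "x"), w$x_min, w$x_max)
    for (k in seq_len(nrow(segs))) {
      area <- area + 0.5 * w$y_min * (segs[k, 1] - segs[k, 2])
      perim <- perim + segs[k, 2] - segs[k, 1]
    }
    segs <- union_1d(edge_cover(w$x_max, "y"), w$y_min, w$y_max)
    for (k in seq_len(nrow(segs))) {
      area <- area + 0.5 * w$x_max * (segs[k, 2] - segs[k, 1])
      perim <- perim + segs[k, 2] - segs[k, 1]
    }
    segs <- union_1d(edge_cover(w$y_max, "x"), w$x_min, w$x_max)
    for (k in seq_len(nrow(segs))) {
      area <- area + 0.5 * w$y_max * (segs[k, 2] - segs[k, 1])
      perim <- perim + segs[k, 2] - segs[k, 1]
    }
    segs <- union_1d(edge_cover(w$x_min, "y"), w$y_min, w$y_max)
    for (k in seq_len(nrow(segs))) {
      area <- area + 0.5 * w$x_min * (segs[k, 1] - segs[k, 2])
      perim <- perim + segs[k, 2] - segs[k, 1]
    }
  }
  list(area = area, perimeter = perim)
}

# --- patch delineation -------------------------------------------------------

#' Delineate crown-overlap tree patches and single trees
#'
#' Two or more live trees with strictly overlapping crown disks (centre
#' distance < r_i + r_j; tangency does not connect) constitute a patch;
#' patches are the connected components of the crown-overlap graph.  Trees in
#' the edge buffer contribute crown geometry (so patch shapes are correct
#' near edges) but are excluded from the membership counts and the
#' single-tree table; conservation holds over interior live trees.
#'
#' @param sm A [stem_map()] with crown radii assigned ([assign_crowns()]).
#' @param clip Clip patch geometry to the plot window (default `TRUE`).
#' @return A `mosaic_partition`: list with `patches` (tibble: `patch_id`,
#'   `n_trees` total members, `n_interior`, `area` m^2, `perimeter` m,
#'   `density_ha` stems per ha of crown-union area, `basal_area_m2`,
#'   `ba_ha`, `dbh_mean`, `dbh_max`, `dbh_sd`, `category`), `singles`
#'   (interior live single trees), `members` (tree id to patch id map),
#'   `window`, and counts.
#' @export
delineate_patches <- function(sm, clip = TRUE) {
  w <- sm_window(sm)
  sm <- partition_by_buffer(sm)
  crowned <- sm[sm$status == "live" & !is.na(sm$crown_radius), ]
  if (!nrow(crowned))
    return(structure(list(patches = empty_patch_table(),
                          singles = crowned, members = tibble(
                            id = character(), patch_id = integer()),
                          window = w, n_interior_live = 0L),
                     class = "mosaic_partition"))
  n <- nrow(crowned)
  # strict crown overlap graph -> connected components
  comp <- if (n == 1) 1L else {
    d <- as.matrix(stats::dist(cbind(crowned$x, crowned$y)))
    rs <- outer(crowned$crown_radius, crowned$crown_radius, "+")
    adj <- d < rs & upper.tri(d)
    ee <- which(adj, arr.ind = TRUE)
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (nrow(ee)) g <- igraph::add_edges(g, t(ee))
    igraph::components(g)$membership
  }
  crowned$comp <- comp
  sizes <- table(comp)
  patch_comps <- as.integer(names(sizes)[sizes >= 2])
  singles <- crowned[comp %in% as.integer(names(sizes)[sizes == 1]) &
                       crowned$zone == "interior", ]
  patches <- lapply(seq_along(patch_comps), function(k) {
    mem <- crowned[crowned$comp == patch_comps[k], ]
    geo <- disk_union_geometry(mem$x, mem$y, mem$crown_radius,
                               window = if (clip) w else NULL)
    tibble(patch_id = k,
           n_trees = nrow(mem),
           n_interior = sum(mem$zone == "interior"),
           area = geo$area, perimeter = geo$perimeter,
           density_ha = nrow(mem) / (geo$area / 1e4),
           basal_area_m2 = sum(pi * (mem$dbh / 200)^2),
           ba_ha = sum(pi * (mem$dbh / 200)^2) / (geo$area / 1e4),
           dbh_mean = mean(mem$dbh), dbh_max = max(mem$dbh),
           dbh_sd = sd(mem$dbh))
  })
  patches <- if (length(patches)) bind_rows(patches) else empty_patch_table()
  patches$category <- patch_category(patches$n_trees)
  members <- tibble(id = crowned$id,
                    patch_id = match(crowned$comp, patch_comps),
                    zone = crowned$zone)
  structure(list(patches = patches, singles = singles, members = members,
                 window = w,
                 n_interior_live = sum(sm$status == "live" &
                                         sm$zone == "interior")),
            class = "mosaic_partition")
}

empty_patch_table <- function() {
  tibble(patch_id = integer(), n_trees = integer(), n_interior = integer(),
         area = numeric(), perimeter = numeric(), density_ha = numeric(),
         basal_area_m2 = numeric(), ba_ha = numeric(), dbh_mean = numeric(),
         dbh_max = numeric(), dbh_sd = numeric(),
         category = factor(levels = c("2-4", "5-9", "10+")))
}

patch_category <- function(n_trees) {
  cut(n_trees, breaks = c(2, 5, 10, Inf), labels = c("2-4", "5-9", "10+"),
      right = FALSE, include.lowest = TRUE)
}

#' @export
print.mosaic_partition <- function(x, ...) {
  cat(sprintf("<mosaic_partition> %d patches, %d interior single trees, %d interior live trees\n",
              nrow(x$patches), nrow(x$singles), x$n_interior_live))
  invisible(x)
}

#' Patch / single-tree summary tables
#'
#' Attribute tables in the standard trees-per-patch categories 2-4 (with the
#' 2-tree subcategory), 5-9 and 10+: number of patches, proportion of
#' interior live trees, and mean (SE) per-patch tree density, basal area and
#' area; plus the single-tree block (count, proportion, mean (SE) DBH, basal
#' area per ha) and stand totals (patch density per ha, % of the plot in
#' patches).
#'
#' @param partition A [delineate_patches()] result.
#' @return A list of tibbles: `categories`, `singles`, `stand`.
#' @export
summarize_mosaic <- function(partition) {
  p <- partition$patches
  n_int <- partition$n_interior_live
  se <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  cat_rows <- function(sub, label) {
    tibble(category = label, n = nrow(sub),
           prop_trees = if (n_int > 0) sum(sub$n_interior) / n_int else NA_real_,
           density_mean = mean(sub$density_ha), density_se = se(sub$density_ha),
           ba_ha_mean = mean(sub$ba_ha), ba_ha_se = se(sub$ba_ha),
           area_mean = mean(sub$area), area_se = se(sub$area))
  }
  categories <- bind_rows(
    cat_rows(p[p$n_trees == 2, ], "2"),
    cat_rows(p[p$category == "2-4", ], "2-4"),
    cat_rows(p[p$category == "5-9", ], "5-9"),
    cat_rows(p[p$category == "10+", ], "10+"))
  s <- partition$singles
  singles <- tibble(
    n = nrow(s),
    prop_trees = if (n_int > 0) nrow(s) / n_int else NA_real_,
    dbh_mean = if (nrow(s)) mean(s$dbh) else NA_real_,
    dbh_se = se(s$dbh),
    ba_ha = sum(pi * (s$dbh / 200)^2) / (window_area(partition$window) / 1e4))
  stand <- tibble(
    patches_per_ha = nrow(p) / (window_area(partition$window) / 1e4),
    pct_area_in_patches = 100 * sum(p$area) / window_area(partition$window),
    mean_trees_per_patch = if (nrow(p)) mean(p$n_trees) else NA_real_,
    trees_per_patch_se = se(p$n_trees))
  list(categories = categories, singles = singles, stand = stand)
}

# --- gap delineation ---------------------------------------------------------

#' Delineate canopy gaps by raster morphology
#'
#' The crown union is rasterised over the full window; open space (the
#' complement) is cleaned by a morphological closing with a disc of radius
#' `gap_threshold / 2` (absorbing canopy slivers -- e.g. isolated crowns --
#' thinner than the gap threshold) followed by an opening with a disc of
#' radius `spur_threshold / 2` (removing open corridors thinner than the spur
#' threshold).  The surviving connected open components are the gaps.  The
#' region outside the plot is treated as open, so gaps may extend to the
#' window edge; [filter_edge_gaps()] implements the with/without edge-gap
#' bookkeeping.
#'
#' @param sm A crowned [stem_map()].
#' @param cell Raster cell size (m), `<= 0.5` (default 0.25) so 2 m features
#'   are resolved.
#' @param gap_threshold Maximum absorbable canopy thickness (m), default 2.
#' @param spur_threshold Minimum open-area thickness (m), default 12.
#' @param min_gap_area Open components smaller than this (m^2) are discarded
#'   as raster artifacts (default 1; the closing step inevitably rounds
#'   convex canopy corners by a fraction of a cell, and a genuine gap
#'   surviving the opening contains a full spur-radius disc, orders of
#'   magnitude larger).
#' @return A `gap_set`: tibble with `gap_id`, `area` (m^2), `perimeter` (m),
#'   `frac_perimeter_buffer`, `frac_area_buffer`; the label raster is kept in
#'   `attr(, "labels")`.
#' @export
delineate_gaps <- function(sm, cell = 0.25, gap_threshold = 2,
                           spur_threshold = 12, min_gap_area = 1) {
  if (cell > 0.5) abort("cell size must be <= 0.5 m to resolve 2 m features")
  w <- sm_window(sm)
  nx <- round((w$x_max - w$x_min) / cell)
  ny <- round((w$y_max - w$y_min) / cell)
  xc <- w$x_min + (seq_len(nx) - 0.5) * cell
  yc <- w$y_min + (seq_len(ny) - 0.5) * cell
  canopy <- matrix(FALSE, nx, ny)
  crowned <- sm[sm$status == "live" & !is.na(sm$crown_radius), ]
  for (i in seq_len(nrow(crowned))) {
    cx <- crowned$x[i]; cy <- crowned$y[i]; cr <- crowned$crown_radius[i]
    ix <- which(abs(xc - cx) <= cr)
    iy <- which(abs(yc - cy) <= cr)
    if (!length(ix) || !length(iy)) next
    sub <- outer((xc[ix] - cx)^2, (yc[iy] - cy)^2, "+") <= cr^2
    canopy[ix, iy] <- canopy[ix, iy] | sub
  }
  open <- 1 - canopy
  # pad with open space so morphology does not erode the window edge; the
  # pad must exceed twice the spur radius so image-border erosion cannot
  # reach back into the window after dilation
  pad <- 2 * ceiling(spur_threshold / 2 / cell) +
    ceiling(gap_threshold / 2 / cell) + 2
  big <- matrix(1, nx + 2 * pad, ny + 2 * pad)
  big[pad + seq_len(nx), pad + seq_len(ny)] <- open
  disc <- function(radius_m) {
    px <- floor(radius_m / cell)
    EBImage::makeBrush(2 * px + 1, shape = "disc")
  }
  big <- EBImage::closing(big, disc(gap_threshold / 2))
  big <- EBImage::opening(big, disc(spur_threshold / 2))
  open2 <- big[pad + seq_len(nx), pad + seq_len(ny)]
  labels <- EBImage::bwlabel(open2)
  ids <- setdiff(sort(unique(as.vector(labels))), 0)
  sizes <- tabulate(as.vector(labels) + 1L)[-1]  # cells per label
  drop <- ids[sizes[ids] * cell^2 < min_gap_area]
  if (length(drop)) {
    labels[labels %in% drop] <- 0
    ids <- setdiff(ids, drop)
  }
  # renumber labels consecutively so gap_id indexes the stored raster
  labels <- array(match(labels, ids, nomatch = 0L), dim = dim(labels))
  ids <- seq_along(ids)
  buffer_cell <- outer(pmin(xc - w$x_min, w$x_max - xc) < w$buffer_width,
                       rep(TRUE, ny)) |
                 outer(rep(TRUE, nx),
                       pmin(yc - w$y_min, w$y_max - yc) < w$buffer_width)
  gaps <- lapply(seq_along(ids), function(k) {
    m <- labels == ids[k]
    # perimeter = exposed cell faces (raster polygon; window edge included)
    faces <- boundary_faces(m)
    n_cells <- sum(m)
    tibble(gap_id = k, area = n_cells * cell^2,
           perimeter = faces$n_faces * cell,
           frac_perimeter_buffer = if (faces$n_faces > 0)
             faces$n_faces_buffer(buffer_cell) / faces$n_faces else 0,
           frac_area_buffer = sum(m & buffer_cell) / n_cells)
  })
  gaps <- if (length(gaps)) bind_rows(gaps)
          else tibble(gap_id = integer(), area = numeric(),
                      perimeter = numeric(), frac_perimeter_buffer = numeric(),
                      frac_area_buffer = numeric())
  new_tibble(gaps, labels = labels, cell = cell, window = w,
             gap_threshold = gap_threshold, spur_threshold = spur_threshold,
             class = "gap_set")
}

# exposed faces of a logical raster mask; faces on the image border count
boundary_faces <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  pad <- matrix(FALSE, nx + 2, ny + 2)
  pad[1 + seq_len(nx), 1 + seq_len(ny)] <- m
  core <- pad[1 + seq_len(nx), 1 + seq_len(ny)]
  nb_open <- (!pad[seq_len(nx), 1 + seq_len(ny)]) +
             (!pad[2 + seq_len(nx), 1 + seq_len(ny)]) +
             (!pad[1 + seq_len(nx), seq_len(ny)]) +
             (!pad[1 + seq_len(nx), 2 + seq_len(ny)])
  faces <- ifelse(core, nb_open, 0)
  list(n_faces = sum(faces),
       cells = core & faces > 0,
       n_faces_buffer = function(buffer_cell) sum(faces[buffer_cell]))
}

#' Partition gaps into kept and edge gaps
#'
#' A gap is an edge gap when more than `overlap_limit` of its perimeter
#' (default mode) -- or of its area, under `mode = "area"` -- lies inside the
#' window's edge buffer.  Summaries are conventionally reported both with and
#' without edge gaps.
#'
#' @param gaps A [delineate_gaps()] result.
#' @param overlap_limit Fraction above which a gap is flagged, default 0.10.
#' @param mode `"perimeter"` or `"area"`.
#' @return `gaps` with an added logical `edge` column.
#' @export
filter_edge_gaps <- function(gaps, overlap_limit = 0.10,
                             mode = c("perimeter", "area")) {
  mode <- match.arg(mode)
  frac <- if (mode == "perimeter") gaps$frac_perimeter_buffer
          else gaps$frac_area_buffer
  gaps$edge <- frac > overlap_limit
  gaps
}

#' Gap summary (with and without edge gaps)
#'
#' @param gaps A [filter_edge_gaps()] result (must carry the `edge` column;
#'   it is added with defaults when absent).
#' @return Tibble with rows `with` / `without` edge gaps: gap count, % of the
#'   plot area in gaps, mean gap size and its SE.
#' @export
summarize_gaps <- function(gaps) {
  if (is.null(gaps$edge)) gaps <- filter_edge_gaps(gaps)
  w <- attr(gaps, "window")
  A <- window_area(w)
  se <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  row <- function(sub, label) {
    tibble(edge_gaps = label, n = nrow(sub),
           pct_area = 100 * sum(sub$area) / A,
           mean_size = if (nrow(sub)) mean(sub$area) else NA_real_,
           size_se = se(sub$area))
  }
  bind_rows(row(gaps, "with"), row(gaps[!gaps$edge, ], "without"))
}

#' Export patch and gap outlines as GeoJSON
#'
#' Plot-local coordinates; geometries are raster-contour approximations
#' intended for display and GIS hand-off, not exact areas (use the attribute
#' tables for areas).
#'
#' @param sm The crowned [stem_map()].
#' @param partition A [delineate_patches()] result.
#' @param gaps A [delineate_gaps()] result.
#' @param path Output file.
#' @param cell Contouring cell size (m).
#' @return `path`, invisibly.
#' @export
mosaic_geojson <- function(sm, partition, gaps, path, cell = 0.5) {
  w <- sm_window(sm)
  feats <- list()
  crowned <- sm[sm$status == "live" & !is.na(sm$crown_radius), ]
  members <- partition$members
  for (k in partition$patches$patch_id) {
    mem <- crowned[crowned$id %in% members$id[!is.na(members$patch_id) &
                                                members$patch_id == k], ]
    rings <- disk_union_contours(mem$x, mem$y, mem$crown_radius, cell)
    feats[[length(feats) + 1]] <- list(
      type = "Feature",
      properties = list(kind = "patch", patch_id = k,
                        area_m2 = partition$patches$area[k]),
      geometry = list(type = "MultiPolygon",
                      coordinates = lapply(rings, function(rg) list(rg))))
  }
  labels <- attr(gaps, "labels"); gc <- attr(gaps, "cell")
  for (k in gaps$gap_id) {
    m <- (labels == k) * 1
    cl <- grDevices::contourLines(
      x = w$x_min + (seq_len(nrow(m)) - 0.5) * gc,
      y = w$y_min + (seq_len(ncol(m)) - 0.5) * gc, z = m, levels = 0.5)
    rings <- lapply(cl, function(c0) {
      xy <- cbind(c0$x, c0$y)
      rbind(xy, xy[1, , drop = FALSE])
    })
    feats[[length(feats) + 1]] <- list(
      type = "Feature",
      properties = list(kind = "gap", gap_id = k, area_m2 = gaps$area[k]),
      geometry = list(type = "MultiPolygon",
                      coordinates = lapply(rings, function(rg) list(rg))))
  }
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 6)
  invisible(path)
}

disk_union_contours <- function(x, y, r, cell) {
  x0 <- min(x - r) - 2 * cell; x1 <- max(x + r) + 2 * cell
  y0 <- min(y - r) - 2 * cell; y1 <- max(y + r) + 2 * cell
  xg <- seq(x0, x1, by = cell); yg <- seq(y0, y1, by = cell)
  z <- matrix(0, length(xg), length(yg))
  for (i in seq_along(x))
    z <- z + (outer((xg - x[i])^2, (yg - y[i])^2, "+") <= r[i]^2)
  cl <- grDevices::contourLines(xg, yg, pmin(z, 1), levels = 0.5)
  lapply(cl, function(c0) {
    xy <- cbind(c0$x, c0$y)
    rbind(xy, xy[1, , drop = FALSE])
  })
}
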