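test_that("crown-overlap thresholds and transitivity define patches", {
  w <- plot_window(50, 50, buffer_width = 0)
  toy <- stem_map(data.frame(x = c(10, 16), y = c(25, 25), species = "JP",
                             dbh = 30), w)
  toy$crown_radius <- c(3, 2)
  # 6 m apart with radii 3 + 2: tangent, strict overlap fails -> two singles
  part <- delineate_patches(toy)
  expect_equal(nrow(part$patches), 0)
  expect_equal(nrow(part$singles), 2)
  # 4.9 m apart: one 2-tree patch
  toy$x <- c(10, 14.9)
  part2 <- delineate_patches(toy)
  expect_equal(part2$patches$n_trees, 2)
  expect_equal(nrow(part2$singles), 0)
  # chain A-B, B-C overlap, A-C disjoint: one 3-tree patch
  chain <- stem_map(data.frame(x = c(10, 14, 18), y = 25, species = "JP",
                               dbh = 30), w)
  chain$crown_radius <- c(2.5, 2.5, 2.5)
  part3 <- delineate_patches(chain)
  expect_equal(part3$patches$n_trees, 3)
})

test_that("partition equals the brute-force union-find oracle", {
  for (seed in c(101, 102, 103)) {
    sm <- make_crowned_map(300, wside = 100, buffer = 0, seed = seed)
    part <- delineate_patches(sm)
    roots <- oracle_union_find(sm$x, sm$y, sm$crown_radius)
    sizes <- table(roots)
    expect_equal(sort(part$patches$n_trees),
                 sort(as.integer(sizes[sizes >= 2])))
    expect_equal(nrow(part$singles), sum(sizes == 1))
    # memberships agree up to component relabelling
    mem <- part$members
    pkg_lab <- ifelse(is.na(mem$patch_id), -seq_along(mem$patch_id),
                      mem$patch_id)
    expect_equal(length(unique(paste(pkg_lab, roots))),
                 length(unique(roots)))
  }
})

test_that("disk-union geometry matches analytic and Monte Carlo oracles", {
  # two radius-3 disks, centres 2 m apart: analytic lens formula
  g <- disk_union_geometry(c(0, 2), c(0, 0), c(3, 3))
  expect_equal(g$area, oracle_two_circle_union(2, 3, 3), tolerance = 1e-12)
  # coincident disks collapse to one
  expect_equal(disk_union_geometry(c(1, 1), c(2, 2), c(3, 3))$area, pi * 9)
  # contained disk is absorbed
  expect_equal(disk_union_geometry(c(0, 0.5), c(0, 0), c(5, 1))$area, pi * 25)
  # n-disk union against a dart oracle, unclipped and clipped
  set.seed(104)
  x <- runif(12, 0, 20); y <- runif(12, 0, 20); rr <- runif(12, 1, 4)
  g2 <- disk_union_geometry(x, y, rr)
  nd <- 4e5
  bx <- range(c(x - rr, x + rr)); by <- range(c(y - rr, y + rr))
  dx <- runif(nd, bx[1], bx[2]); dy <- runif(nd, by[1], by[2])
  inside <- rep(FALSE, nd)
  for (i in seq_along(x))
    inside <- inside | ((dx - x[i])^2 + (dy - y[i])^2 <= rr[i]^2)
  mc <- mean(inside) * diff(bx) * diff(by)
  expect_equal(g2$area, mc, tolerance = 0.005)
  w <- plot_window(20, 20)
  g3 <- disk_union_geometry(x, y, rr, window = w)
  mc3 <- mean(inside & dx >= 0 & dx <= 20 & dy >= 0 & dy <= 20) *
    diff(bx) * diff(by)
  expect_equal(g3$area, mc3, tolerance = 0.005)
  expect_lt(g3$area, g2$area)
  # area never exceeds the sum of disk areas
  expect_lt(g2$area, sum(pi * rr^2))
})

test_that("interior live trees are conserved across patches and singles", {
  for (seed in 105:109) {
    sm <- make_crowned_map(150, wside = 80, buffer = 5, seed = seed)
    sm$status[seq(1, 150, 7)] <- "snag"
    part <- delineate_patches(sm)
    expect_equal(sum(part$patches$n_interior) + nrow(part$singles),
                 part$n_interior_live)
  }
})

test_that("mosaic summaries count categories and proportions correctly", {
  # hand-built map: patches of sizes {2, 3, 5, 10} plus 2 singles, buffer 0
  w <- plot_window(200, 200, buffer_width = 0)
  place_patch <- function(x0, n) data.frame(
    x = x0 + (seq_len(n) - 1) * 3, y = 100, species = "JP", dbh = 20)
  df <- rbind(place_patch(5, 2), place_patch(30, 3), place_patch(60, 5),
              place_patch(100, 10), data.frame(x = c(150, 170), y = 100,
                                               species = "JP", dbh = 20))
  sm <- stem_map(df, w)
  sm$crown_radius <- 2  # 3 m spacing < 4 -> chains; isolated trees singles
  part <- delineate_patches(sm)
  expect_equal(sort(part$patches$n_trees), c(2, 3, 5, 10))
  summ <- summarize_mosaic(part)
  expect_equal(summ$categories$n[summ$categories$category == "2"], 1)
  expect_equal(summ$categories$n[summ$categories$category == "2-4"], 2)
  expect_equal(summ$categories$n[summ$categories$category == "5-9"], 1)
  expect_equal(summ$categories$n[summ$categories$category == "10+"], 1)
  expect_equal(summ$singles$n, 2)
  # proportions over interior live trees sum to 1
  expect_equal(sum(summ$categories$prop_trees[-1]) + summ$singles$prop_trees, 1)
  # per-patch density uses the crown-union area
  p2 <- part$patches[part$patches$n_trees == 2, ]
  expect_equal(p2$density_ha, 2 / (p2$area / 1e4))
  # category sizes {2,3,5,10,12} -> {2-4: 2, 5-9: 1, 10+: 2}
  expect_equal(as.character(stemmosaic:::patch_category(c(2, 3, 5, 10, 12))),
               c("2-4", "2-4", "5-9", "10+", "10+"))
})

test_that("gap morphology honours the 2 m gap and 12 m spur thresholds", {
  w <- plot_window(100, 100)
  mk <- function(df, r) { sm <- stem_map(df, w); sm$crown_radius <- r; sm }
  # empty canopy: exactly one gap covering the window
  sm0 <- stem_map(data.frame(x = 50, y = 50, species = "JP", dbh = 20), w)
  g0 <- delineate_gaps(sm0, cell = 0.5)
  expect_equal(nrow(g0), 1)
  expect_equal(g0$area, 1e4)
  # full canopy: zero gaps
  xy <- expand.grid(x = seq(5, 95, 10), y = seq(5, 95, 10))
  gF <- delineate_gaps(mk(data.frame(x = xy$x, y = xy$y, species = "JP",
                                     dbh = 50), 8), cell = 0.5)
  expect_equal(nrow(gF), 0)
  # an isolated 1 m crown is absorbed into the surrounding gap
  g1 <- delineate_gaps(mk(data.frame(x = 50, y = 50, species = "JP",
                                     dbh = 10), 1), cell = 0.5)
  expect_equal(nrow(g1), 1)
  expect_equal(g1$area, 1e4)
  # an enclosed 10 m x 40 m slot is thinner than the 12 m spur: no gap;
  # a 16 m slot survives (tree grid at 2 m so crown edges sit at the slot)
  slot_map <- function(half_gap) {
    xs <- seq(1, 99, 2)
    grid <- expand.grid(x = xs, y = xs)
    keep <- !(abs(grid$x - 50) < half_gap + 4 & abs(grid$y - 50) < 20 + 4)
    mk(data.frame(x = grid$x[keep], y = grid$y[keep], species = "JP",
                  dbh = 50), 4)
  }
  g10 <- delineate_gaps(slot_map(5), cell = 0.25)
  expect_equal(nrow(g10), 0)
  g16 <- delineate_gaps(slot_map(8), cell = 0.25)
  expect_equal(nrow(g16), 1)
  expect_error(delineate_gaps(sm0, cell = 1), "cell size")
})

test_that("gap area is monotone in canopy and stable under refinement", {
  sm <- make_crowned_map(60, wside = 100, buffer = 5, rmin = 2, rmax = 6,
                         seed = 110)
  g1 <- delineate_gaps(sm, cell = 0.5)
  # adding a crown never increases total gap area
  sm2 <- rbind(as.data.frame(sm),
               data.frame(id = "extra", x = 50, y = 50, species = "JP",
                          dbh = 40, height = NA, crown_base = NA,
                          status = "live", crown_radius = 6))
  sm2 <- stem_map(sm2[, -1], sm_window(sm))
  sm2$crown_radius <- c(sm$crown_radius, 6)
  g2 <- delineate_gaps(sm2, cell = 0.5)
  expect_lte(sum(g2$area), sum(g1$area) + 1)
  # refinement: 0.5 m vs 0.25 m cells agree within 1%
  g3 <- delineate_gaps(sm, cell = 0.25)
  expect_equal(sum(g3$area), sum(g1$area), tolerance = 0.01)
})

test_that("edge-gap filtering distinguishes perimeter and area modes", {
  # semantics on constructed fractions: the mode picks its column
  gaps <- tibble::new_tibble(
    tibble::tibble(gap_id = 1:3, area = c(200, 300, 400),
                   perimeter = c(60, 70, 80),
                   frac_perimeter_buffer = c(0, 0.05, 0.5),
                   frac_area_buffer = c(0, 0.15, 0.5)),
    window = plot_window(100, 100), cell = 0.5, class = "gap_set")
  per <- filter_edge_gaps(gaps, mode = "perimeter")
  are <- filter_edge_gaps(gaps, mode = "area")
  expect_equal(per$edge, c(FALSE, FALSE, TRUE))  # 5% perimeter kept
  expect_equal(are$edge, c(FALSE, TRUE, TRUE))   # 15% area excluded
  # measured fractions: interior gap has zero overlap, edge gap positive
  sm <- make_crowned_map(80, wside = 100, buffer = 5, rmin = 2, rmax = 5,
                         seed = 111)
  g <- delineate_gaps(sm, cell = 0.5)
  expect_true(all(g$frac_perimeter_buffer >= 0 & g$frac_perimeter_buffer <= 1))
  expect_true(all(g$frac_area_buffer >= 0 & g$frac_area_buffer <= 1))
  summ <- summarize_gaps(filter_edge_gaps(g))
  expect_equal(summ$edge_gaps, c("with", "without"))
  expect_gte(summ$n[1], summ$n[2])
})
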