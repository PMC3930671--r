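test_that("isotropic edge weights match an angle-sampling oracle", {
  set.seed(4)
  px <- runif(15, 0, 100); py <- runif(15, 0, 100); d <- runif(15, 0.5, 49)
  frac <- stemmosaic:::cpp_ripley_frac(px, py, d, 0, 100, 0, 100)
  th <- seq(0, 2 * pi, length.out = 40001)[-1]
  num <- vapply(seq_along(px), function(i)
    mean(px[i] + d[i] * cos(th) >= 0 & px[i] + d[i] * cos(th) <= 100 &
         py[i] + d[i] * sin(th) >= 0 & py[i] + d[i] * sin(th) <= 100),
    numeric(1))
  expect_equal(frac, num, tolerance = 1e-3)
  # a point exactly in a corner sees a quarter circle
  expect_equal(stemmosaic:::cpp_ripley_frac(0, 0, 10, 0, 100, 0, 100), 0.25)
})

test_that("vectorized estimator equals the naive double-loop oracle", {
  w <- plot_window(100, 100)
  set.seed(42)
  p <- data.frame(x = runif(100, 0, 100), y = runif(100, 0, 100))
  r <- r_grid(50, 0.5)
  for (divisor in c("d", "r")) for (zc in c(TRUE, FALSE)) {
    est <- pcf(p, window = w, r = r, divisor = divisor, zerocor = zc)
    ora <- oracle_pcf(p, w, r, attr(est, "delta"), divisor, zc)
    expect_lt(max(abs(est$ghat - ora)), 1e-8)
  }
  # known-intensity normaliser
  est <- pcf(p, window = w, r = r, lambda = 0.011)
  ora <- oracle_pcf(p, w, r, attr(est, "delta"), lambda = 0.011)
  expect_lt(max(abs(est$ghat - ora)), 1e-8)
})

test_that("bivariate estimator matches its oracle and is symmetric", {
  w <- plot_window(100, 100)
  set.seed(43)
  p1 <- data.frame(x = runif(40, 0, 100), y = runif(40, 0, 100))
  p2 <- data.frame(x = runif(60, 0, 100), y = runif(60, 0, 100))
  r <- r_grid(40, 0.5)
  est <- pcf(p1, p2, window = w, r = r)
  ora <- oracle_pcf_cross(p1, p2, w, r, attr(est, "delta"))
  expect_lt(max(abs(est$ghat - ora)), 1e-8)
  # symmetrised edge weights: g12 = g21 exactly
  est21 <- pcf(p2, p1, window = w, r = r, bandwidth = attr(est, "bandwidth"))
  expect_lt(max(abs(est$ghat - est21$ghat)), 1e-10)
  expect_equal(attr(est, "pair"), "bivariate")
})

test_that("L function matches the naive K oracle and flags aggregation", {
  w <- plot_window(100, 100)
  set.seed(44)
  p <- data.frame(x = runif(50, 0, 100), y = runif(50, 0, 100))
  r <- r_grid(40, 1)
  est <- l_function(p, window = w, r = r)
  expect_equal(est$khat, oracle_kest(p, w, r), tolerance = 1e-10)
  expect_equal(est$lhat, sqrt(est$khat / pi))
  # clustered pattern: L(r) - r > 0 at short range
  set.seed(45)
  pc <- simulate_points(w, point_process_spec("thomas", kappa = 2e-3,
                                              mu = 10, sigma = 3))
  lc <- l_function(pc, window = w, r = r)
  expect_true(all((lc$lhat - lc$r)[lc$r <= 10] > 0))
})

test_that("estimator contracts: errors, warnings, reliability flags", {
  w <- plot_window(100, 100)
  expect_error(pcf(data.frame(x = 1, y = 1), window = w), "at least 2")
  # two far-apart points beyond r_max: all-zero ghat with a warning
  expect_warning(
    g <- pcf(data.frame(x = c(1, 99), y = c(1, 99)), window = w,
             r = r_grid(20), bandwidth = 0.5),
    "exceed")
  expect_true(all(g$ghat == 0))
  # small-r estimates below one kernel half-width flagged unreliable
  set.seed(46)
  p <- data.frame(x = runif(80, 0, 100), y = runif(80, 0, 100))
  g2 <- pcf(p, window = w)
  expect_true(all(!g2$reliable[g2$r < attr(g2, "delta")]))
  expect_true(all(g2$reliable[g2$r >= attr(g2, "delta")]))
  expect_true(all(g2$ghat >= 0))
})

test_that("intensity surface integrates to n, is flat under CSR, tracks trends", {
  w <- plot_window(200, 200)
  set.seed(47)
  p <- simulate_points(w, point_process_spec("csr", lambda = 0.02))
  surf <- estimate_intensity(p, w)
  expect_equal(intensity_integral(surf), nrow(p), tolerance = 0.02)
  # flat within +/-15% over the deep interior at the default bandwidth
  grid <- expand.grid(x = seq(40, 160, 24), y = seq(40, 160, 24))
  vals <- surf$lambda_at(grid$x, grid$y)
  expect_true(all(abs(vals / (nrow(p) / 4e4) - 1) < 0.15))
  # log-linear trend: increasing in x, rank correlation with truth > 0.9
  spec <- point_process_spec("inhom", lambda = 0.02, trend_ratio = 3)
  set.seed(48)
  pt <- simulate_points(w, spec)
  st <- estimate_intensity(pt, w)
  truth <- stemmosaic:::inhom_intensity_fun(w, spec)
  xs <- runif(300, 5, 195); ys <- runif(300, 5, 195)
  expect_gt(cor(st$lambda_at(xs, ys), truth(xs, ys), method = "spearman"), 0.9)
  xs_line <- seq(10, 190, 20)
  expect_true(all(diff(st$lambda_at(xs_line, rep(100, length(xs_line)))) > 0))
  expect_error(estimate_intensity(p, w, bandwidth = -1), "positive")
  expect_error(estimate_intensity(p[1:5, ], w), "at least 10")
})

test_that("inhomogeneous pcf with the true intensity recovers g = 1", {
  w <- plot_window(200, 200)
  spec <- point_process_spec("inhom", lambda = 0.015, trend_ratio = 3)
  truth <- stemmosaic:::inhom_intensity_fun(w, spec)
  set.seed(49)
  g <- rowMeans(sapply(1:60, function(i) {
    p <- simulate_points(w, spec)
    pcf(p, window = w, mode = "inhomogeneous",
        lambda = function(x, y) truth(x, y))$ghat
  }))
  r <- r_grid()
  expect_lt(max(abs(g[r >= 5 & r <= 45] - 1)), 0.07)
})
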