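test_that("generators are exactly reproducible under a seed", {
  w <- plot_window(200, 200)
  for (model in c("csr", "thomas", "inhom")) {
    spec <- point_process_spec(model, lambda = 0.01)
    p1 <- simulate_points(w, spec, seed = 11)
    p2 <- simulate_points(w, spec, seed = 11)
    expect_identical(p1, p2)
  }
  sm1 <- simulate_stem_map(w, seed = 3)
  sm2 <- simulate_stem_map(w, seed = 3)
  expect_identical(as.data.frame(sm1), as.data.frame(sm2))
})

test_that("CSR counts are Poisson(lambda |W|)", {
  # chi-square goodness of fit of simulated counts against the Poisson law
  w <- plot_window(100, 100)
  lambda <- 0.01
  set.seed(501)
  counts <- replicate(500, nrow(simulate_points(w, point_process_spec("csr",
                                                lambda = lambda))))
  mu <- lambda * 1e4
  breaks <- c(-Inf, qpois(seq(0.1, 0.9, 0.1), mu), Inf)
  obs <- table(cut(counts, breaks))
  pr <- diff(ppois(breaks, mu))
  chi <- suppressWarnings(chisq.test(obs, p = pr, rescale.p = TRUE))
  expect_gt(chi$p.value, 0.01)
  expect_equal(mean(counts), mu, tolerance = 0.05)
})

test_that("the 4 ha defaults land in the 1000-1500 stem range", {
  w <- plot_window(200, 200)
  set.seed(77)
  counts <- replicate(20, nrow(simulate_points(w, point_process_spec("csr"))))
  expect_equal(mean(counts), 1300, tolerance = 0.05)
  # individual counts within generous Poisson bounds
  expect_true(all(counts > qpois(0.005, 1300) & counts < qpois(0.995, 1300)))
})

test_that("Thomas closed-form pair correlation has the stated properties", {
  # direct evaluation at r = 0
  expect_equal(thomas_pcf(0, kappa = 5e-4, sigma = 5),
               1 + 1 / (4 * pi * 25 * 5e-4), tolerance = 1e-12)
  expect_equal(thomas_pcf(0, kappa = 5e-4, sigma = 5), 7.366, tolerance = 1e-3)
  # long-range independence and monotone decay
  expect_equal(thomas_pcf(1e6, 5e-4, 5), 1)
  r <- seq(0, 60, 0.5)
  expect_true(all(diff(thomas_pcf(r, 5e-4, 5)) < 0))
})

test_that("Thomas patterns are aggregated at short range", {
  w <- plot_window(200, 200)
  set.seed(21)
  g <- rowMeans(sapply(1:40, function(i)
    pcf(simulate_points(w, point_process_spec("thomas", kappa = 5e-4,
                                              mu = 8, sigma = 5)),
        window = w)$ghat))
  r <- r_grid()
  expect_true(all(g[r < 10] > 1.5))
})

test_that("mark attachment reproduces mixtures, snag fractions, size shares", {
  w <- plot_window(200, 200)
  pts <- data.frame(x = runif(2000, 0, 200), y = runif(2000, 0, 200))
  spec <- mark_model_spec(species_probs = c(JP = 0.995, QU = 0.004, WF = 0.001),
                          snag_fraction = 0.1, p_small = 0.6)
  sm <- attach_marks(pts, spec, w, seed = 9)
  prop <- prop.table(table(sm$species))
  # binomial 99% bounds at n = 2000
  expect_equal(unname(prop[["JP"]]), 0.995,
               tolerance = 3 * sqrt(0.995 * 0.005 / 2000) / 0.995)
  expect_equal(mean(sm$status == "snag"), 0.1, tolerance = 0.01)
  # configured small-class share
  expect_equal(mean(sm$dbh < 25), 0.6,
               tolerance = 3 * sqrt(0.6 * 0.4 / 2000) / 0.6)
  expect_true(all(sm$dbh > 5))
  # snag fraction 0 -> all live; empty inputs -> empty stem map
  sm0 <- attach_marks(pts, mark_model_spec(snag_fraction = 0), w, seed = 1)
  expect_true(all(sm0$status == "live"))
  expect_equal(nrow(attach_marks(data.frame(x = numeric(), y = numeric()),
                                 spec, w)), 0)
})

test_that("clustered snag placement concentrates snags in dense neighbourhoods", {
  w <- plot_window(200, 200)
  set.seed(31)
  pts <- simulate_points(w, point_process_spec("thomas", kappa = 5e-4,
                                               mu = 20, sigma = 4))
  nb <- stemmosaic:::count_neighbours(pts$x, pts$y, 10)
  sm_cl <- attach_marks(pts, mark_model_spec(snag_fraction = 0.2,
                                             snag_mode = "clustered"), w,
                        seed = 5)
  sm_rl <- attach_marks(pts, mark_model_spec(snag_fraction = 0.2,
                                             snag_mode = "random_label"), w,
                        seed = 5)
  expect_gt(mean(nb[sm_cl$status == "snag"]), mean(nb[sm_rl$status == "snag"]))
})

test_that("simulated fire histories honour the scar probability", {
  fy <- seq(1800, 1890, 10)
  # probability 1: every recording sample scarred at every fire year
  fr1 <- simulate_fire_history(5, fy, c(1750, 1950), scar_prob = 1, seed = 2)
  expect_equal(nrow(fr1$scars), 5 * length(fy))
  # probability 0: empty scar set, recording spans retained
  fr0 <- simulate_fire_history(5, fy, c(1750, 1950), scar_prob = 0, seed = 2)
  expect_equal(nrow(fr0$scars), 0)
  expect_equal(nrow(fr0$recording), 5)
  # binomial expectation: about 3 scars per fire at p = 0.3 with 10 samples
  set.seed(8)
  scars_per_fire <- replicate(60, {
    fr <- simulate_fire_history(10, fy, c(1750, 1950), scar_prob = 0.3)
    nrow(fr$scars) / length(fy)
  })
  expect_equal(mean(scars_per_fire), 3, tolerance = 0.1)
})

test_that("rejected parameters raise errors", {
  expect_error(point_process_spec("csr", lambda = -1), "positive")
  expect_error(point_process_spec("thomas", sigma = 0), "positive")
  expect_error(mark_model_spec(species_probs = c(a = 0.5, b = 0.4)), "sum to 1")
  expect_error(mark_model_spec(snag_fraction = 1), "snag_fraction")
})
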