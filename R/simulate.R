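#' Point-process specification for synthetic stem maps
#'
#' Three generating models cover the situations the estimators must handle:
#' `"csr"` (homogeneous Poisson; the null model of complete spatial
#' randomness), `"thomas"` (Poisson cluster process with Poisson(`mu`)
#' offspring displaced by an isotropic Gaussian of sd `sigma` around
#' Poisson(`kappa`) parents -- a true aggregated pattern with a closed-form
#' pair correlation function, see [thomas_pcf()]), and `"inhom"`
#' (inhomogeneous Poisson with a log-linear intensity trend in x, emulating
#' large-scale environmental heterogeneity).
#'
#' @param model `"csr"`, `"thomas"` or `"inhom"`.
#' @param lambda Intensity (stems m^-2) for `"csr"`, and the *mean* intensity
#'   for `"inhom"`.
#' @param kappa,mu,sigma Thomas parent intensity (m^-2), mean offspring count,
#'   and offspring dispersal sd (m).
#' @param trend_ratio For `"inhom"`: ratio of maximum to minimum intensity
#'   across the window (log-linear in x); default 3.
#' @return A `point_process_spec`.
#' @export
point_process_spec <- function(model = c("csr", "thomas", "inhom"),
                               lambda = 0.0325, kappa = 5e-4, mu = 8,
                               sigma = 5, trend_ratio = 3) {
  model <- match.arg(model)
  if (lambda <= 0 || kappa <= 0 || mu <= 0 || sigma <= 0 || trend_ratio <= 0)
    abort("all point-process rates and scales must be positive")
  structure(list(model = model, lambda = lambda, kappa = kappa, mu = mu,
                 sigma = sigma, trend_ratio = trend_ratio),
            class = "point_process_spec")
}

#' Simulate point locations in a window
#'
#' @param window A [plot_window()].
#' @param spec A [point_process_spec()].
#' @param seed Optional integer; when given the output is reproducible.
#' @return A tibble with columns `x`, `y`.
#' @examples
#' pts <- simulate_points(plot_window(200, 200),
#'                        point_process_spec("csr", lambda = 0.0325), seed = 1)
#' @export
simulate_points <- function(window, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- window
  wx <- w$x_max - w$x_min; wy <- w$y_max - w$y_min
  switch(spec$model,
    csr = {
      n <- rpois(1, spec$lambda * wx * wy)
      tibble(x = runif(n, w$x_min, w$x_max), y = runif(n, w$y_min, w$y_max))
    },
    thomas = {
      # parents in a 4*sigma-dilated window (stationarity inside W);
      # offspring outside W are discarded, not wrapped
      ex <- 4 * spec$sigma
      n_par <- rpois(1, spec$kappa * (wx + 2 * ex) * (wy + 2 * ex))
      if (n_par == 0) return(tibble(x = numeric(), y = numeric()))
      px <- runif(n_par, w$x_min - ex, w$x_max + ex)
      py <- runif(n_par, w$y_min - ex, w$y_max + ex)
      n_off <- rpois(n_par, spec$mu)
      x <- rnorm(sum(n_off), rep(px, n_off), spec$sigma)
      y <- rnorm(sum(n_off), rep(py, n_off), spec$sigma)
      keep <- in_window(w, x, y)  # offspring outside the window are discarded
      tibble(x = x[keep], y = y[keep])
    },
    inhom = {
      # log-linear trend in x with max/min = trend_ratio, mean = lambda
      lam_fun <- inhom_intensity_fun(w, spec)
      lam_max <- lam_fun(w$x_max, 0)
      n <- rpois(1, lam_max * wx * wy)
      x <- runif(n, w$x_min, w$x_max); y <- runif(n, w$y_min, w$y_max)
      keep <- runif(n) < lam_fun(x, y) / lam_max
      tibble(x = x[keep], y = y[keep])
    })
}

# intensity function lambda(x, y) for the "inhom" generator model
inhom_intensity_fun <- function(window, spec) {
  wx <- window$x_max - window$x_min
  beta <- log(spec$trend_ratio) / wx
  # normalise so the window mean equals spec$lambda
  z <- (exp(beta * wx) - 1) / (beta * wx)
  lam0 <- spec$lambda / z
  function(x, y) lam0 * exp(beta * (x - window$x_min))
}

#' Closed-form Thomas-process pair correlation function
#'
#' For a (modified) Thomas process with parent intensity `kappa` and Gaussian
#' offspring dispersal sd `sigma`,
#' `g(r) = 1 + exp(-r^2 / (4 sigma^2)) / (4 pi sigma^2 kappa)`.
#' Used as the analytic oracle when validating the kernel estimator.
#'
#' @param r Distances (m), `r >= 0`.
#' @param kappa Parent intensity (m^-2).
#' @param sigma Offspring dispersal sd (m).
#' @return `g(r)` values.
#' @export
thomas_pcf <- function(r, kappa, sigma) {
  stopifnot(all(r >= 0), kappa > 0, sigma > 0)
  1 + exp(-r^2 / (4 * sigma^2)) / (4 * pi * sigma^2 * kappa)
}

#' Mark-model specification for synthetic stem maps
#'
#' Diameters follow a Weibull distribution left-truncated at the 5 cm mapping
#' threshold; by default the scale is solved so that the small size class
#' (`dbh < 25` cm) holds `p_small` of the stems, matching the right-skewed
#' size distributions of these forests.  Species are drawn from a fixed
#' mixture; snags are labelled either completely at random
#' (`snag_mode = "random_label"` -- the random-mortality null is then true) or
#' preferentially in dense neighbourhoods (`"clustered"`, selection weight
#' `(1 + n_neighbours_within_10m)^2`, giving random-labeling tests a true
#' positive).
#'
#' @param species_probs Named numeric vector of species mixture proportions
#'   (summing to 1).
#' @param snag_fraction Fraction of stems that are snags, in `[0, 1)`.
#' @param snag_mode `"random_label"` or `"clustered"`.
#' @param dbh_shape Weibull shape for the diameter distribution.
#' @param p_small Target probability of `dbh < 25` cm after truncation at 5 cm
#'   (ignored when `dbh_scale` is given).
#' @param dbh_scale Optional explicit Weibull scale (cm).
#' @return A `mark_model_spec`.
#' @export
mark_model_spec <- function(species_probs = c(JP = 0.995, QU = 0.004, WF = 0.001),
                            snag_fraction = 0.03,
                            snag_mode = c("random_label", "clustered"),
                            dbh_shape = 1.2, p_small = 0.6, dbh_scale = NULL) {
  snag_mode <- match.arg(snag_mode)
  if (abs(sum(species_probs) - 1) > 1e-8)
    abort("species mixture proportions must sum to 1")
  if (snag_fraction < 0 || snag_fraction >= 1)
    abort("snag_fraction must be in [0, 1)")
  if (is.null(dbh_scale))
    dbh_scale <- solve_dbh_scale(dbh_shape, p_small)
  structure(list(species_probs = species_probs, snag_fraction = snag_fraction,
                 snag_mode = snag_mode, dbh_shape = dbh_shape,
                 dbh_scale = dbh_scale),
            class = "mark_model_spec")
}

# scale of the 5cm-truncated Weibull such that P(dbh < 25 | dbh > 5) = p_small
solve_dbh_scale <- function(shape, p_small) {
  f <- function(s) {
    F5 <- stats::pweibull(5, shape, s); F25 <- stats::pweibull(25, shape, s)
    (F25 - F5) / (1 - F5) - p_small
  }
  stats::uniroot(f, c(1, 500))$root
}

# truncated-Weibull diameter sampler
rdbh <- function(n, spec) {
  F5 <- stats::pweibull(5, spec$dbh_shape, spec$dbh_scale)
  stats::qweibull(F5 + runif(n) * (1 - F5), spec$dbh_shape, spec$dbh_scale)
}

#' Attach marks (species, dbh, status) to point locations
#'
#' @param points Tibble with `x`, `y` (e.g. from [simulate_points()]).
#' @param spec A [mark_model_spec()].
#' @param window A [plot_window()].
#' @param site_label Site label for the resulting stem map.
#' @param seed Optional integer seed.
#' @return A [stem_map()].  Heights and crown-base heights are filled with a
#'   simple monotone-in-dbh default so crown-ratio-based allometry is
#'   exercised.
#' @export
attach_marks <- function(points, spec, window, site_label = "synthetic",
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(points)
  if (n == 0)
    return(stem_map(tibble(x = numeric(), y = numeric(),
                           species = character(), dbh = numeric()),
                    window, site_label))
  dbh <- rdbh(n, spec)
  species <- sample(names(spec$species_probs), n, replace = TRUE,
                    prob = spec$species_probs)
  status <- rep("live", n)
  n_snag <- round(spec$snag_fraction * n)
  if (n_snag > 0) {
    idx <- if (spec$snag_mode == "random_label") {
      sample.int(n, n_snag)
    } else {
      # clustered mortality: weight by local crowding within 10 m
      nb <- count_neighbours(points$x, points$y, 10)
      sample.int(n, n_snag, prob = (1 + nb)^2)
    }
    status[idx] <- "snag"
  }
  # monotone height/crown-base defaults (height in m from a simple
  # diameter-height curve; live-crown base at 40% of height)
  height <- 1.37 + 28 * (1 - exp(-0.025 * dbh)) * (0.9 + 0.2 * runif(n))
  crown_base <- 0.4 * height
  stem_map(tibble(x = points$x, y = points$y, species = species, dbh = dbh,
                  height = height, crown_base = crown_base, status = status),
           window, site_label)
}

count_neighbours <- function(x, y, radius) {
  n <- length(x)
  if (n == 0) return(integer())
  d <- as.matrix(stats::dist(cbind(x, y)))
  as.integer(rowSums(d > 0 & d <= radius))
}

#' Simulate a complete synthetic stem map
#'
#' Convenience wrapper: [simulate_points()] then [attach_marks()], with
#' independent seeded streams per stage so each stage can be re-run alone.
#'
#' @inheritParams simulate_points
#' @param marks A [mark_model_spec()].
#' @param site_label Site label.
#' @return A [stem_map()].
#' @examples
#' sm <- simulate_stem_map(plot_window(200, 200), seed = 1)
#' nrow(sm)  # about 1300 stems on 4 ha
#' @export
simulate_stem_map <- function(window, spec = point_process_spec(),
                              marks = mark_model_spec(),
                              site_label = "synthetic", seed = NULL) {
  pts <- simulate_points(window, spec,
                         seed = if (is.null(seed)) NULL else seed)
  attach_marks(pts, marks, window, site_label,
               seed = if (is.null(seed)) NULL else seed + 1L)
}

#' Simulate a fire-scar chronology with known ground truth
#'
#' Each sample records each true fire year falling inside its recording span
#' independently with probability `scar_prob`.  With `scar_prob = 1` and full
#' recording, the composite exactly recovers `fire_years`, which anchors the
#' filter-validation tests.
#'
#' @param n_samples Number of fire-scar samples.
#' @param fire_years Integer vector of true fire years.
#' @param recording Either a length-2 vector `c(start, end)` applied to all
#'   samples, or a tibble with `sample_id`, `start`, `end`.
#' @param scar_prob Per-fire, per-recording-sample scar probability.
#' @param seed Optional integer seed.
#' @return A [fire_scar_records()] object (samples with no scars still carry
#'   their recording spans).
#' @export
simulate_fire_history <- function(n_samples, fire_years, recording,
                                  scar_prob = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(scar_prob >= 0, scar_prob <= 1)
  if (!is.data.frame(recording))
    recording <- tibble(sample_id = as.character(seq_len(n_samples)),
                        start = recording[1], end = recording[2])
  scars <- list()
  for (i in seq_len(nrow(recording))) {
    yrs <- fire_years[fire_years >= recording$start[i] &
                      fire_years <= recording$end[i]]
    hit <- yrs[runif(length(yrs)) < scar_prob]
    if (length(hit))
      scars[[length(scars) + 1]] <-
        tibble(sample_id = recording$sample_id[i], year = hit)
  }
  scars <- if (length(scars)) dplyr::bind_rows(scars)
           else tibble(sample_id = character(), year = integer())
  fire_scar_records(scars, recording)
}
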