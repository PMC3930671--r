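#' Distance grid for second-order statistics
#'
#' All second-order summaries are evaluated up to 50 m, the standard range
#' for 4 ha stem maps.
#'
#' @param r_max Maximum distance (m), default 50.
#' @param dr Grid spacing (m), default 0.25.
#' @return Strictly ascending distances from `dr` to `r_max`.
#' @export
r_grid <- function(r_max = 50, dr = 0.25) {
  seq(dr, r_max, by = dr)
}

# Stoyan rule-of-thumb Epanechnikov bandwidth: half-width c/sqrt(lambda)
# (equivalently kernel sd c/sqrt(5 lambda), the bw.stoyan convention)
stoyan_delta <- function(lambda_bar, stoyan = 0.15) {
  stoyan / sqrt(lambda_bar)
}

as_points <- function(x) {
  stopifnot(is.data.frame(x), all(c("x", "y") %in% names(x)))
  x
}

#' Pair correlation function with isotropic edge correction
#'
#' Kernel (Epanechnikov) estimate of the pair correlation function g(r) --
#' the non-cumulative density of point pairs at distance r relative to a
#' Poisson process -- with Ripley's isotropic edge-correction weights.  With
#' one point set the univariate g(r) is returned; with two sets the bivariate
#' g12(r) (symmetrised edge weights, so g12 = g21 by construction).  In
#' inhomogeneous mode the pair normaliser is lambda(x_i) lambda(x_j) from a
#' supplied or estimated intensity instead of a constant density.
#'
#' Numerical conventions: each pair's kernel contribution is divided by its
#' own distance (`divisor = "d"`) and the kernel is reflected at r = 0
#' (`zerocor`), both of which remove most of the small-r bias of the naive
#' estimator; values of r below one kernel half-width are still flagged
#' (`reliable == FALSE`).  The bandwidth follows Stoyan's rule of thumb:
#' Epanechnikov half-width `stoyan / sqrt(lambda_bar)` (kernel sd
#' `stoyan / sqrt(5 lambda_bar)`).
#'
#' @param x Point set: a `stem_map` or data frame with `x`, `y`.
#' @param y Optional second point set for the bivariate estimate.
#' @param window A [plot_window()] (defaults to the stem map's window).
#' @param r Distance grid, default [r_grid()].
#' @param mode `"homogeneous"` or `"inhomogeneous"`.
#' @param lambda,lambda2 Intensities (per set): an [estimate_intensity()]
#'   surface, a `function(x, y)`, or a numeric vector for inhomogeneous mode
#'   (a surface is estimated from the data when omitted).  In homogeneous
#'   mode a scalar `lambda` replaces the plug-in `n / |W|` -- useful when the
#'   generating intensity is known, as in estimator validation.
#' @param stoyan Stoyan bandwidth coefficient, default 0.15.
#' @param bandwidth Optional explicit kernel sd (m), overriding the rule.
#' @param divisor `"d"` (default) or `"r"`.
#' @param zerocor Reflect the kernel at r = 0 (default `TRUE`).
#' @return A `pcf_estimate`: tibble with columns `r`, `ghat`, `reliable`, and
#'   attributes (`mode`, `pair`, `bandwidth`, `delta`, `kernel`,
#'   `correction`).
#' @examples
#' sm <- simulate_stem_map(plot_window(200, 200), seed = 7)
#' g <- pcf(sm)
#' head(tidy(g))
#' @export
pcf <- function(x, y = NULL, window = NULL, r = r_grid(),
                mode = c("homogeneous", "inhomogeneous"),
                lambda = NULL, lambda2 = NULL,
                stoyan = 0.15, bandwidth = NULL,
                divisor = c("d", "r"), zerocor = TRUE) {
  mode <- match.arg(mode)
  divisor <- match.arg(divisor)
  if (is.null(window)) window <- sm_window(x)
  stopifnot(inherits(window, "plot_window"), !is.unsorted(r), all(r > 0))
  p1 <- as_points(x)
  p2 <- if (is.null(y)) NULL else as_points(y)
  n1 <- nrow(p1); n2 <- if (is.null(p2)) n1 else nrow(p2)
  if (n1 < 2 || n2 < 2) abort("pcf needs at least 2 points per set")
  A <- window_area(window)

  lam1_bar <- n1 / A
  lam2_bar <- n2 / A
  lam_bar <- if (is.null(p2)) lam1_bar else sqrt(lam1_bar * lam2_bar)
  delta <- if (is.null(bandwidth)) stoyan_delta(lam_bar, stoyan)
           else bandwidth * sqrt(5)

  if (mode == "inhomogeneous") {
    if (is.null(lambda)) lambda <- estimate_intensity(p1, window)
    rl1 <- 1 / lambda_values(lambda, p1)
    rl2 <- if (is.null(p2)) rl1
           else 1 / lambda_values(if (is.null(lambda2)) lambda else lambda2, p2)
  } else {
    # known constant intensities may be supplied (e.g. validating against a
    # generating model); default is the usual plug-in n / |W|
    if (!is.null(lambda) && is.numeric(lambda) && length(lambda) == 1)
      lam1_bar <- lambda
    if (!is.null(lambda2) && is.numeric(lambda2) && length(lambda2) == 1)
      lam2_bar <- lambda2
    else if (!is.null(lambda) && is.null(y)) lam2_bar <- lam1_bar
    rl1 <- rep(1 / lam1_bar, n1)
    rl2 <- rep(1 / lam2_bar, n2)
  }

  cross <- !is.null(p2)
  xs2 <- if (cross) p2 else p1
  rl2u <- if (cross) rl2 else rl1
  ghat <- cpp_pcf_engine(p1$x, p1$y, rl1, xs2$x, xs2$y, rl2u, cross,
                         window$x_min, window$x_max,
                         window$y_min, window$y_max,
                         r, delta, divisor == "d", zerocor) / A
  if (all(ghat == 0))
    warn("all pairwise distances exceed r_max + bandwidth; ghat is all zero")
  new_tibble(
    tibble(r = r, ghat = ghat, reliable = r >= delta),
    mode = mode, pair = if (cross) "bivariate" else "univariate",
    bandwidth = delta / sqrt(5), delta = delta,
    kernel = "epanechnikov", correction = "isotropic",
    n = c(n1, n2), window = window,
    class = "pcf_estimate")
}

#' Ripley's K and its L transform
#'
#' Isotropic-corrected cumulative second-order statistic
#' `K(r) = sum w_ij 1(d_ij <= r) / (lambda^2 |W|)` and
#' `L(r) = sqrt(K(r) / pi)`; under complete spatial randomness `L(r) = r`.
#' Used for the large-scale homogeneity screen.
#'
#' @inheritParams pcf
#' @return An `l_estimate`: tibble with columns `r`, `khat`, `lhat`.
#' @export
l_function <- function(x, window = NULL, r = r_grid()) {
  if (is.null(window)) window <- sm_window(x)
  p <- as_points(x)
  n <- nrow(p)
  if (n < 2) abort("l_function needs at least 2 points")
  A <- window_area(window)
  sums <- cpp_kest_engine(p$x, p$y, window$x_min, window$x_max,
                          window$y_min, window$y_max, r)
  khat <- sums * A / (n^2)
  new_tibble(tibble(r = r, khat = khat, lhat = sqrt(khat / pi)),
             n = n, window = window, correction = "isotropic",
             class = "l_estimate")
}
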