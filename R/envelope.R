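#' Toroidal shift of a point set
#'
#' Translates a pattern by `(dx, dy)` on the window treated as a torus,
#' preserving the pattern's internal geometry while randomising its position
#' relative to a second, fixed pattern -- the null model of independence for
#' bivariate analyses.
#'
#' @param points Data frame with `x`, `y`.
#' @param window A [plot_window()].
#' @param dx,dy Translation (m); defaults are uniform over the window.
#' @return The shifted points (same columns).
#' @export
torus_shift <- function(points, window,
                        dx = runif(1, 0, window$x_max - window$x_min),
                        dy = runif(1, 0, window$y_max - window$y_min)) {
  wx <- window$x_max - window$x_min
  wy <- window$y_max - window$y_min
  out <- points
  out$x <- window$x_min + (points$x - window$x_min + dx) %% wx
  out$y <- window$y_min + (points$y - window$y_min + dy) %% wy
  out
}

#' Monte Carlo simulation envelopes for second-order statistics
#'
#' Simulates `n_sim` patterns under a null model, computes the chosen summary
#' statistic for each, and returns the pointwise band formed by the `rank`-th
#' smallest and largest simulated values at every distance (the default
#' 5th-of-199 gives a pointwise two-sided exceedance probability of
#' 2 x 5 / 200 = 0.05).  The band is pointwise, not familywise; pair it with
#' [gof()] for a global statement of departure.
#'
#' Null models:
#' \describe{
#'   \item{`csr`}{homogeneous Poisson with the estimated intensity
#'     (unconditional count by default; `fixed_n = TRUE` conditions on n).}
#'   \item{`inhom_poisson`}{inhomogeneous Poisson simulated by thinning from
#'     the estimated (or supplied) intensity surface; the observed and
#'     simulated statistics are both normalised by that same surface.}
#'   \item{`toroidal_independence`}{for two sets: set 1 held fixed, set 2
#'     wrapped by a uniform toroidal translation.}
#'   \item{`random_labeling`}{marks permuted over fixed locations (the random
#'     mortality null); `x` must carry the mark column named by `split_by`.}
#' }
#'
#' @param x Point set (`stem_map` or data frame); for `random_labeling` the
#'   full marked pattern.
#' @param y Second point set (bivariate nulls).
#' @param null_model One of `"csr"`, `"inhom_poisson"`,
#'   `"toroidal_independence"`, `"random_labeling"`.
#' @param statistic `"pcf"` or `"l"`.
#' @param n_sim Number of simulations (default 199).
#' @param rank Envelope rank (default 5).
#' @param r Distance grid.
#' @param window A [plot_window()].
#' @param lambda Intensity surface for `inhom_poisson` (estimated from `x`
#'   when omitted).
#' @param fixed_n Condition CSR simulations on the observed count.
#' @param split_by,type1,type2 Random labeling: mark column and the two mark
#'   values; `target = "cross"` tracks g12(type1, type2), `target = "group2"`
#'   the univariate statistic of the `type2` subset.
#' @param target See `split_by`.
#' @param stoyan,bandwidth,divisor,zerocor Passed to [pcf()]; the bandwidth is
#'   frozen at the observed pattern's value so all curves share a kernel.
#' @param seed Optional integer seed.
#' @return An `envelope_result`: tibble with columns `r`, `obs`, `lo`, `hi`
#'   and the simulated curves in `attr(, "sims")`.
#' @examples
#' sm <- simulate_stem_map(plot_window(100, 100),
#'                         point_process_spec("csr", lambda = 0.02), seed = 2)
#' env <- envelope(sm, null_model = "csr", n_sim = 39, seed = 3)
#' gof(env)
#' @export
envelope <- function(x, y = NULL,
                     null_model = c("csr", "inhom_poisson",
                                    "toroidal_independence", "random_labeling"),
                     statistic = c("pcf", "l"),
                     n_sim = 199, rank = 5, r = r_grid(), window = NULL,
                     lambda = NULL, fixed_n = FALSE,
                     split_by = "status", type1 = "live", type2 = "snag",
                     target = c("cross", "group2"),
                     stoyan = 0.15, bandwidth = NULL,
                     divisor = "d", zerocor = TRUE, seed = NULL) {
  null_model <- match.arg(null_model)
  statistic <- match.arg(statistic)
  target <- match.arg(target)
  if (n_sim < 2 * rank)
    abort("n_sim must be at least 2 * rank")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(window)) window <- sm_window(x)
  A <- window_area(window)

  # freeze the kernel bandwidth at the observed pattern's value
  if (statistic == "pcf" && is.null(bandwidth)) {
    nb1 <- nrow(x); nb2 <- if (is.null(y)) NULL else nrow(y)
    if (null_model == "random_labeling") {
      g1 <- x[x[[split_by]] == type1, ]; g2 <- x[x[[split_by]] == type2, ]
      nb1 <- nrow(g1); nb2 <- nrow(g2)
      if (target == "group2") { nb1 <- nrow(g2); nb2 <- NULL }
    }
    lam_bar <- if (is.null(nb2)) nb1 / A else sqrt(nb1 * nb2) / A
    bandwidth <- stoyan_delta(lam_bar, stoyan) / sqrt(5)  # kernel sd
  }

  surf <- NULL
  if (null_model == "inhom_poisson") {
    surf <- if (is.null(lambda)) estimate_intensity(x, window) else lambda
  }

  delta <- if (statistic == "pcf") bandwidth * sqrt(5) else NULL
  stat_fun <- function(p1, p2 = NULL) {
    if (statistic == "l") {
      n <- nrow(p1)
      sums <- cpp_kest_engine(p1$x, p1$y, window$x_min, window$x_max,
                              window$y_min, window$y_max, r)
      return(sqrt(sums * A / n^2 / pi))
    }
    cross <- !is.null(p2)
    if (is.null(surf)) {
      rl1 <- rep(A / nrow(p1), nrow(p1))
      rl2 <- if (cross) rep(A / nrow(p2), nrow(p2)) else rl1
    } else {
      rl1 <- 1 / lambda_values(surf, p1)
      rl2 <- if (cross) 1 / lambda_values(surf, p2) else rl1
    }
    p2u <- if (cross) p2 else p1
    cpp_pcf_engine(p1$x, p1$y, rl1, p2u$x, p2u$y, rl2, cross,
                   window$x_min, window$x_max, window$y_min, window$y_max,
                   r, delta, divisor == "d", zerocor) / A
  }

  sim_inhom_poisson <- function() {
    lam_max <- max(surf$raster) * 1.05
    n <- rpois(1, lam_max * A)
    px <- runif(n, window$x_min, window$x_max)
    py <- runif(n, window$y_min, window$y_max)
    keep <- runif(n) < surf$lambda_at(px, py) / lam_max
    tibble(x = px[keep], y = py[keep])
  }

  obs <- switch(null_model,
    csr = ,
    inhom_poisson = stat_fun(x),
    toroidal_independence = {
      if (is.null(y)) abort("toroidal_independence needs two point sets")
      stat_fun(x, y)
    },
    random_labeling = {
      g1 <- x[x[[split_by]] == type1, ]
      g2 <- x[x[[split_by]] == type2, ]
      if (target == "cross") stat_fun(g1, g2) else stat_fun(g2)
    })

  n_obs <- nrow(x)
  sims <- matrix(NA_real_, length(r), n_sim)
  for (s in seq_len(n_sim)) {
    sims[, s] <- switch(null_model,
      csr = {
        n <- if (fixed_n) n_obs else rpois(1, n_obs)
        while (n < 2) n <- if (fixed_n) n_obs else rpois(1, n_obs)
        stat_fun(tibble(x = runif(n, window$x_min, window$x_max),
                        y = runif(n, window$y_min, window$y_max)))
      },
      inhom_poisson = stat_fun(sim_inhom_poisson()),
      toroidal_independence = stat_fun(x, torus_shift(y, window)),
      random_labeling = {
        lab <- sample(x[[split_by]])
        g1 <- x[lab == type1, ]
        g2 <- x[lab == type2, ]
        if (target == "cross") stat_fun(g1, g2) else stat_fun(g2)
      })
  }
  lo <- apply(sims, 1, function(v) sort(v)[rank])
  hi <- apply(sims, 1, function(v) sort(v, decreasing = TRUE)[rank])
  new_tibble(tibble(r = r, obs = obs, lo = lo, hi = hi),
             sims = sims, n_sim = n_sim, rank = rank,
             null_model = null_model, statistic = statistic,
             window = window, class = "envelope_result")
}

#' Goodness-of-fit test for global departure from a null model
#'
#' Loosemore-Ford rank test: for the observed curve and each simulated curve,
#' the departure statistic is the integrated squared deviation from the mean
#' of all *other* curves, `u_i = sum_r (stat_i(r) - mean_{-i}(r))^2 dr`.  The
#' p value is the rank of the observed `u` among all curves (observed
#' included), `p = #\{u_i >= u_obs\} / (n_sim + 1)`, with ties counted as
#' `>=` (conservative).
#'
#' @param env An [envelope()] result (simulated curves retained).
#' @param range Integration range in r (m), default the full 0-50 m.
#' @return A `gof_result` list: `u` (observed statistic), `p`, `range`,
#'   `n_sim`.
#' @export
gof <- function(env, range = c(0, 50)) {
  stopifnot(inherits(env, "envelope_result"))
  sims <- attr(env, "sims")
  keep <- env$r >= range[1] & env$r <= range[2]
  if (!any(keep)) abort("integration range contains no grid points")
  r <- env$r[keep]
  dr <- c(diff(r), diff(r)[length(r) - 1])
  curves <- cbind(env$obs[keep], sims[keep, , drop = FALSE])
  m <- ncol(curves)
  tot <- rowSums(curves)
  u <- vapply(seq_len(m), function(i) {
    mean_others <- (tot - curves[, i]) / (m - 1)
    sum((curves[, i] - mean_others)^2 * dr)
  }, numeric(1))
  p <- sum(u >= u[1]) / m
  structure(list(u = u[1], p = p, range = range, n_sim = m - 1,
                 u_sims = u[-1]),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("Goodness-of-fit (Loosemore-Ford): u = %.5g, p = %.4g (%d simulations, %g-%g m)\n",
              x$u, x$p, x$n_sim, x$range[1], x$range[2]))
  invisible(x)
}
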