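# Independent oracles used across the suite.  These deliberately re-derive
# every quantity with plain R loops / closed forms, sharing no code with the
# package internals they check.

# closed-form fraction of a circle (centre p, radius d) inside a rectangle,
# re-derived independently of the C++ implementation
oracle_circle_frac <- function(px, py, d, x0, x1, y0, y1) {
  ang <- function(a) if (a < d) acos(max(-1, min(1, a / d))) else 0
  a1 <- ang(px - x0); a2 <- ang(x1 - px)
  b1 <- ang(py - y0); b2 <- ang(y1 - py)
  ext <- 2 * (a1 + a2 + b1 + b2) -
    max(0, a1 + b1 - pi / 2) - max(0, a1 + b2 - pi / 2) -
    max(0, a2 + b1 - pi / 2) - max(0, a2 + b2 - pi / 2)
  1 - ext / (2 * pi)
}

# naive O(n^2) pair-correlation estimator (double loop over ordered pairs)
oracle_pcf <- function(p, w, r, delta, divisor = "d", zerocor = TRUE,
                       lambda = NULL) {
  n <- nrow(p)
  A <- (w$x_max - w$x_min) * (w$y_max - w$y_min)
  lam <- if (is.null(lambda)) n / A else lambda
  epa <- function(t) ifelse(abs(t / delta) <= 1,
                            0.75 * (1 - (t / delta)^2) / delta, 0)
  out <- numeric(length(r))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt((p$x[i] - p$x[j])^2 + (p$y[i] - p$y[j])^2)
    wi <- 1 / oracle_circle_frac(p$x[i], p$y[i], d,
                                 w$x_min, w$x_max, w$y_min, w$y_max)
    k <- epa(d - r) + if (zerocor) epa(d + r) else 0
    div <- if (divisor == "d") d else r
    out <- out + k * wi / (2 * pi * div)
  }
  out / (lam^2 * A)
}

# naive bivariate estimator with symmetrised edge weights
oracle_pcf_cross <- function(p1, p2, w, r, delta, divisor = "d",
                             zerocor = TRUE) {
  A <- (w$x_max - w$x_min) * (w$y_max - w$y_min)
  lam1 <- nrow(p1) / A; lam2 <- nrow(p2) / A
  epa <- function(t) ifelse(abs(t / delta) <= 1,
                            0.75 * (1 - (t / delta)^2) / delta, 0)
  out <- numeric(length(r))
  for (i in seq_len(nrow(p1))) for (j in seq_len(nrow(p2))) {
    d <- sqrt((p1$x[i] - p2$x[j])^2 + (p1$y[i] - p2$y[j])^2)
    if (d == 0) next
    wi <- 1 / oracle_circle_frac(p1$x[i], p1$y[i], d,
                                 w$x_min, w$x_max, w$y_min, w$y_max)
    wj <- 1 / oracle_circle_frac(p2$x[j], p2$y[j], d,
                                 w$x_min, w$x_max, w$y_min, w$y_max)
    k <- epa(d - r) + if (zerocor) epa(d + r) else 0
    div <- if (divisor == "d") d else r
    out <- out + k * (wi + wj) / 2 / (2 * pi * div)
  }
  out / (lam1 * lam2 * A)
}

# naive isotropic-corrected K function
oracle_kest <- function(p, w, r) {
  n <- nrow(p)
  A <- (w$x_max - w$x_min) * (w$y_max - w$y_min)
  out <- numeric(length(r))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt((p$x[i] - p$x[j])^2 + (p$y[i] - p$y[j])^2)
    if (d > max(r)) next
    wi <- 1 / oracle_circle_frac(p$x[i], p$y[i], d,
                                 w$x_min, w$x_max, w$y_min, w$y_max)
    out <- out + wi * (r >= d)
  }
  out * A / n^2
}

# brute-force union-find partition over the strict crown-overlap relation
oracle_union_find <- function(x, y, r) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    if (d < r[i] + r[j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# exhaustive Ward agglomeration: at each step merge the pair minimising
# sqrt(2 |A||B| / (|A|+|B|)) * ||centroid_A - centroid_B||
oracle_ward_heights <- function(X) {
  cl <- lapply(seq_len(nrow(X)), function(i) i)
  heights <- numeric(0)
  while (length(cl) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_len(length(cl) - 1)) for (j in (i + 1):length(cl)) {
      na <- length(cl[[i]]); nb <- length(cl[[j]])
      ca <- colMeans(X[cl[[i]], , drop = FALSE])
      cb <- colMeans(X[cl[[j]], , drop = FALSE])
      d <- sqrt(2 * na * nb / (na + nb)) * sqrt(sum((ca - cb)^2))
      if (d < bd) { bd <- d; best <- c(i, j) }
    }
    heights <- c(heights, bd)
    cl[[best[1]]] <- c(cl[[best[1]]], cl[[best[2]]])
    cl[[best[2]]] <- NULL
  }
  heights
}

# analytic area of the union of two overlapping circles
oracle_two_circle_union <- function(d, r1, r2) {
  lens <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1)) +
    r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2)) -
    0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
  pi * r1^2 + pi * r2^2 - lens
}

# quick crowned synthetic map for mosaic tests
make_crowned_map <- function(n, wside = 100, buffer = 5, rmin = 1, rmax = 4,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- plot_window(wside, wside, buffer_width = buffer)
  sm <- stem_map(data.frame(x = runif(n, 0, wside), y = runif(n, 0, wside),
                            species = "JP", dbh = runif(n, 6, 80)), w)
  sm$crown_radius <- runif(n, rmin, rmax)
  sm
}
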