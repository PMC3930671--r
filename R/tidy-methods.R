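#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_ribbon geom_point
#'   geom_hline labs theme_minimal scale_size_area coord_equal
#' @export
ggplot2::autoplot

#' @export
tidy.pcf_estimate <- function(x, ...) {
  tibble(r = x$r, ghat = x$ghat, reliable = x$reliable)
}

#' @export
glance.pcf_estimate <- function(x, ...) {
  tibble(mode = attr(x, "mode"), pair = attr(x, "pair"),
         kernel = attr(x, "kernel"), correction = attr(x, "correction"),
         bandwidth = attr(x, "bandwidth"), delta = attr(x, "delta"))
}

#' @export
tidy.envelope_result <- function(x, ...) {
  tibble(r = x$r, obs = x$obs, lo = x$lo, hi = x$hi)
}

#' @export
glance.envelope_result <- function(x, ...) {
  tibble(null_model = attr(x, "null_model"), statistic = attr(x, "statistic"),
         n_sim = attr(x, "n_sim"), rank = attr(x, "rank"),
         pointwise_alpha = 2 * attr(x, "rank") / (attr(x, "n_sim") + 1))
}

#' @export
glance.gof_result <- function(x, ...) {
  tibble(u = x$u, p = x$p, n_sim = x$n_sim,
         r_min = x$range[1], r_max = x$range[2])
}

#' @export
tidy.group_anova <- function(x, ...) x$letters

#' @export
glance.group_anova <- function(x, ...) {
  tibble(f = x$f, df1 = x$df[1], df2 = x$df[2], p = x$p, log10 = x$log10,
         shapiro_p = x$shapiro_p, levene_p = x$levene_p)
}

#' @export
tidy.kruskal_nemenyi <- function(x, ...) {
  if (is.null(x$pairwise))
    tibble(group1 = character(), group2 = character(),
           statistic = numeric(), p = numeric())
  else x$pairwise
}

#' @export
glance.kruskal_nemenyi <- function(x, ...) {
  tibble(h = x$h, df = x$df, p = x$p)
}

#' @export
tidy.patch_pca <- function(x, matrix = c("eigenvalues", "loadings"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "eigenvalues")
    return(tibble(component = seq_along(x$var_explained),
                  variance = x$fit$sdev^2,
                  prop_variance = x$var_explained,
                  cum_variance = cumsum(x$var_explained)))
  as_tibble(as.data.frame(x$loadings), rownames = "variable") |>
    tidyr::pivot_longer(-"variable", names_to = "component",
                        values_to = "loading")
}

#' @export
tidy.patch_grouping <- function(x, ...) {
  tibble(patch = seq_along(x$labels), group = x$labels)
}

#' @export
glance.patch_grouping <- function(x, ...) {
  tibble(k = x$k, n = length(x$labels),
         max_height = max(x$hclust$height))
}

#' Envelope diagnostic plot
#'
#' Observed summary curve over the Monte Carlo null band; departures above
#' the band indicate aggregation (positive association), below it regularity
#' (negative association).
#'
#' @param object An [envelope()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.envelope_result <- function(object, ...) {
  ref <- if (attr(object, "statistic") == "pcf") 1 else NA
  p <- ggplot(tidy(object), aes(x = .data$r)) +
    geom_ribbon(aes(ymin = .data$lo, ymax = .data$hi), fill = "grey75") +
    geom_line(aes(y = .data$obs), linewidth = 0.7) +
    labs(x = "r (m)",
         y = if (attr(object, "statistic") == "pcf") "g(r)" else "L(r)",
         title = sprintf("%s vs %s null (rank %d of %d simulations)",
                         attr(object, "statistic"), attr(object, "null_model"),
                         attr(object, "rank"), attr(object, "n_sim"))) +
    theme_minimal()
  if (!is.na(ref)) p <- p + geom_hline(yintercept = ref, linetype = 2)
  p
}

#' @export
autoplot.pcf_estimate <- function(object, ...) {
  ggplot(tidy(object), aes(.data$r, .data$ghat)) +
    geom_line() + geom_hline(yintercept = 1, linetype = 2) +
    labs(x = "r (m)", y = "g(r)") + theme_minimal()
}

#' Stem-map plot
#'
#' Live trees as open circles scaled by DBH, snags as red points; optional
#' crown disks when radii are assigned.
#'
#' @param sm A [stem_map()].
#' @param crowns Draw crown circles when available.
#' @return A ggplot.
#' @export
plot_stem_map <- function(sm, crowns = TRUE) {
  w <- sm_window(sm)
  p <- ggplot(as_tibble(sm), aes(.data$x, .data$y)) +
    geom_point(aes(size = .data$dbh, colour = .data$status), shape = 1) +
    ggplot2::scale_colour_manual(values = c(live = "black", snag = "red")) +
    scale_size_area(max_size = 4) +
    coord_equal(xlim = c(w$x_min, w$x_max), ylim = c(w$y_min, w$y_max)) +
    labs(x = "x (m)", y = "y (m)", title = sm_site(sm)) +
    theme_minimal()
  if (crowns && any(!is.na(sm$crown_radius))) {
    cr <- sm[!is.na(sm$crown_radius), ]
    ang <- seq(0, 2 * pi, length.out = 33)
    circ <- bind_rows(lapply(seq_len(nrow(cr)), function(i)
      tibble(id = cr$id[i], x = cr$x[i] + cr$crown_radius[i] * cos(ang),
             y = cr$y[i] + cr$crown_radius[i] * sin(ang))))
    p <- p + ggplot2::geom_path(data = circ,
                                aes(.data$x, .data$y, group = .data$id),
                                colour = "forestgreen", alpha = 0.4,
                                inherit.aes = FALSE)
  }
  p
}

#' Gap mosaic plot
#'
#' Raster view of the delineated gaps (labelled regions) within the plot.
#'
#' @param gaps A [delineate_gaps()] result.
#' @return A ggplot.
#' @export
plot_gaps <- function(gaps) {
  labels <- attr(gaps, "labels"); cell <- attr(gaps, "cell")
  w <- attr(gaps, "window")
  df <- tidyr::expand_grid(
    ix = seq_len(nrow(labels)), iy = seq_len(ncol(labels)))
  df$gap <- labels[cbind(df$ix, df$iy)]
  df <- df[df$gap > 0, ]
  df$x <- w$x_min + (df$ix - 0.5) * cell
  df$y <- w$y_min + (df$iy - 0.5) * cell
  ggplot(df, aes(.data$x, .data$y, fill = factor(.data$gap))) +
    ggplot2::geom_raster(show.legend = FALSE) +
    coord_equal(xlim = c(w$x_min, w$x_max), ylim = c(w$y_min, w$y_max)) +
    labs(x = "x (m)", y = "y (m)") + theme_minimal()
}
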