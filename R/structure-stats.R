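#' Standardized patch feature matrix
#'
#' Assembles the seven patch-structure variables used for typology -- mean,
#' maximum and standard deviation of tree diameters, trees per patch, tree
#' density, patch area and patch perimeter -- and standardizes each column to
#' zero mean and unit variance.  Standardization is essential here: the raw
#' variables mix cm, m^2 and stems per ha, so unscaled Euclidean distances
#' would be dominated by whichever unit happens to be largest.
#'
#' @param partition A [delineate_patches()] result (or a data frame already
#'   holding the seven feature columns).
#' @return A `patch_features` tibble with attributes `center` and `scale`.
#' @export
patch_features <- function(partition) {
  p <- if (inherits(partition, "mosaic_partition")) partition$patches
       else as_tibble(partition)
  cols <- c("dbh_mean", "dbh_max", "dbh_sd", "n_trees", "density_ha",
            "area", "perimeter")
  miss <- setdiff(cols, names(p))
  if (length(miss))
    abort(paste0("missing patch feature column(s): ", paste(miss, collapse = ", ")))
  x <- as.matrix(p[cols])
  if (anyNA(x)) abort("patch feature matrix must have no missing cells")
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    abort(paste0("constant feature column(s): ",
                 paste(cols[sds == 0], collapse = ", ")))
  ctr <- colMeans(x)
  xs <- scale(x, center = ctr, scale = sds)
  out <- as_tibble(as.data.frame(xs))
  if (!is.null(p$patch_id)) out <- mutate(out, patch_id = p$patch_id,
                                          .before = 1)
  new_tibble(out, center = ctr, scale = sds, features = cols,
             class = "patch_features")
}

feature_matrix <- function(features) {
  as.matrix(features[attr(features, "features")])
}

#' Principal components of patch structure
#'
#' PCA of the standardized patch feature matrix (equivalently, of the feature
#' correlation matrix), identifying which structural variables distinguish
#' patch types.
#'
#' @param features A [patch_features()] matrix.
#' @return A `patch_pca`: list with `loadings`, `var_explained` (fractions
#'   summing to 1), `scores`, and the underlying `prcomp` fit.
#' @export
pca_patch_structure <- function(features) {
  x <- feature_matrix(features)
  if (nrow(x) < 3) abort("PCA needs at least 3 patches")
  fit <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(loadings = fit$rotation, var_explained = ve,
                 scores = fit$x, fit = fit),
            class = "patch_pca")
}

#' @export
print.patch_pca <- function(x, ...) {
  cat("<patch_pca> variance explained:",
      paste0(sprintf("PC%d %.1f%%", seq_along(x$var_explained),
                     100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' Ward clustering of patch types
#'
#' Agglomerative hierarchical clustering of patches on Euclidean distances of
#' the standardized features with Ward's linkage (each merge minimizes the
#' increase in within-group variance).  The number of groups is either given
#' or chosen automatically over candidate cuts k in 3..6 by the branch
#' elongation criterion: the cut whose next merge height is largest relative
#' to the current one (stable groups sit below a long branch).
#'
#' @param features A [patch_features()] matrix.
#' @param k Number of groups, or `NULL` for automatic selection in 3..6.
#' @param k_range Candidate range for automatic selection.
#' @return A `patch_grouping`: list with `labels` (1..k per patch), `k`,
#'   `hclust` (merge sequence + heights), and the `elongation` table when
#'   automatic selection was used.
#' @export
cluster_patch_types <- function(features, k = NULL, k_range = 3:6) {
  x <- feature_matrix(features)
  n <- nrow(x)
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  elong <- NULL
  if (is.null(k)) {
    k_range <- k_range[k_range < n]
    if (!length(k_range)) abort("too few patches for automatic k selection")
    # cutting between merges n-k and n-k+1 leaves k groups; the branch
    # elongation of a cut is the ratio of the enclosing merge heights
    elong <- tibble(
      k = k_range,
      elongation = vapply(k_range, function(kk)
        hc$height[n - kk + 1] / hc$height[n - kk], numeric(1)))
    k <- elong$k[which.max(elong$elongation)]
  }
  if (k > n) abort("k cannot exceed the number of patches")
  labels <- stats::cutree(hc, k = k)
  structure(list(labels = labels, k = k, hclust = hc, elongation = elong),
            class = "patch_grouping")
}

#' @export
print.patch_grouping <- function(x, ...) {
  cat(sprintf("<patch_grouping> %d patches in %d groups (sizes: %s)\n",
              length(x$labels), x$k,
              paste(table(x$labels), collapse = ", ")))
  invisible(x)
}

# --- one-way ANOVA with assumption screens and Bonferroni letters -----------

# Brown-Forsythe variance screen: one-way ANOVA on |x - group median|
levene_p <- function(values, groups) {
  z <- abs(values - stats::ave(values, groups, FUN = median))
  stats::anova(stats::lm(z ~ groups))[["Pr(>F)"]][1]
}

#' One-way ANOVA with post hoc Bonferroni letters
#'
#' One-way analysis of variance across groups, with assumption screens
#' (Shapiro-Wilk on residuals; Brown-Forsythe on absolute deviations from
#' group medians, both at `alpha_screen`); when either screen fails and all
#' values are positive, the analysis is recomputed on log10 values and
#' flagged.  Pairwise Bonferroni-adjusted t comparisons (pooled SD) are
#' summarized as a compact letter display: groups sharing a letter are not
#' significantly different.
#'
#' @param data Data frame.
#' @param value,group Column names (strings) of the response and grouping
#'   variable.
#' @param alpha Pairwise significance level, default 0.05.
#' @param alpha_screen Screen level, default 0.05.
#' @param transform `"auto"` (screens decide), `"none"`, or `"log10"`.
#' @return A `group_anova`: list with `f`, `df`, `p`, `log10` flag, screen p
#'   values, the pairwise p matrix and a `letters` tibble (group, n, mean,
#'   se, letters on the analysis scale).
#' @export
compare_groups_anova <- function(data, value, group, alpha = 0.05,
                                 alpha_screen = 0.05,
                                 transform = c("auto", "none", "log10")) {
  transform <- match.arg(transform)
  v <- data[[value]]; g <- factor(data[[group]])
  if (nlevels(g) < 2) abort("need at least 2 groups")
  if (any(table(g) < 2)) abort("every group needs at least 2 values")
  fit <- stats::lm(v ~ g)
  shapiro <- tryCatch(stats::shapiro.test(stats::residuals(fit))$p.value,
                      error = function(e) NA_real_)
  lev <- levene_p(v, g)
  use_log <- switch(transform,
    auto = (isTRUE(shapiro < alpha_screen) || isTRUE(lev < alpha_screen)) &&
      all(v > 0),
    none = FALSE,
    log10 = TRUE)
  if (use_log && any(v <= 0))
    abort("log10 transform requires positive values")
  vv <- if (use_log) log10(v) else v
  fit <- stats::lm(vv ~ g)
  a <- stats::anova(fit)
  pw <- stats::pairwise.t.test(vv, g, p.adjust.method = "bonferroni",
                               pool.sd = TRUE)$p.value
  letters <- letter_display(pw, levels(g), alpha,
                            order_by = tapply(vv, g, mean))
  means <- tapply(vv, g, mean)
  ses <- tapply(vv, g, function(z) sd(z) / sqrt(length(z)))
  structure(list(
    f = a[["F value"]][1], df = a[["Df"]], p = a[["Pr(>F)"]][1],
    log10 = use_log, shapiro_p = shapiro, levene_p = lev,
    pairwise_p = pw,
    letters = tibble(group = levels(g), n = as.integer(table(g)),
                     mean = as.numeric(means), se = as.numeric(ses),
                     letters = letters[levels(g)])),
    class = "group_anova")
}

# compact letter display from a pairwise p matrix (as from pairwise.t.test):
# letters = maximal cliques of the "not significantly different" graph
letter_display <- function(pw, lev, alpha, order_by = NULL) {
  k <- length(lev)
  adj <- matrix(TRUE, k, k, dimnames = list(lev, lev))
  for (i in rownames(pw)) for (j in colnames(pw)) {
    if (!is.na(pw[i, j]) && pw[i, j] < alpha) {
      adj[i, j] <- FALSE; adj[j, i] <- FALSE
    }
  }
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cl <- igraph::max_cliques(g)
  # order cliques by the mean of their groups so 'a' is the lowest block
  if (!is.null(order_by)) {
    ord <- order(vapply(cl, function(c0) min(order_by[lev[as.integer(c0)]]),
                        numeric(1)))
    cl <- cl[ord]
  }
  lets <- stats::setNames(rep("", k), lev)
  for (m in seq_along(cl)) {
    members <- lev[as.integer(cl[[m]])]
    lets[members] <- paste0(lets[members], letters[m])
  }
  lets
}

#' @export
print.group_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA%s: F(%d, %d) = %.4g, p = %.4g\n",
              if (x$log10) " (log10 scale)" else "",
              x$df[1], x$df[2], x$f, x$p))
  print(x$letters)
  invisible(x)
}

# --- Kruskal-Wallis with Nemenyi post hoc -----------------------------------

#' Kruskal-Wallis test with Nemenyi pairwise comparisons
#'
#' Rank-based comparison of two or more sites with the standard tie
#' correction.  When the overall test is significant at `alpha`, pairwise
#' sites are compared with the Nemenyi test (the non-parametric analogue of
#' Tukey's studentized-range comparisons, on rank sums); otherwise the
#' pairwise stage is suppressed.
#'
#' @param data Data frame.
#' @param value,group Column names (strings).
#' @param alpha Gating level for the pairwise stage, default 0.05.
#' @return A `kruskal_nemenyi`: list with `h`, `df`, `p`, and `pairwise`
#'   (tibble of pairwise Nemenyi p values, or `NULL` when gated off).
#' @export
kruskal_nemenyi <- function(data, value, group, alpha = 0.05) {
  v <- data[[value]]; g <- factor(data[[group]])
  k <- nlevels(g); N <- length(v)
  if (k < 2) abort("need at least 2 sites")
  rk <- rank(v)
  Ri <- tapply(rk, g, sum); ni <- as.integer(table(g))
  if (length(unique(v)) == 1) {
    h <- 0; p <- 1
  } else {
    h <- 12 / (N * (N + 1)) * sum(Ri^2 / ni) - 3 * (N + 1)
    ties <- table(v)
    C <- 1 - sum(ties^3 - ties) / (N^3 - N)
    h <- h / C
    p <- stats::pchisq(h, k - 1, lower.tail = FALSE)
  }
  pairwise <- NULL
  if (p < alpha) {
    rbar <- Ri / ni
    combs <- utils::combn(levels(g), 2)
    pairwise <- bind_rows(lapply(seq_len(ncol(combs)), function(m) {
      a <- combs[1, m]; b <- combs[2, m]
      ia <- match(a, levels(g)); ib <- match(b, levels(g))
      stat <- abs(rbar[ia] - rbar[ib]) /
        sqrt(N * (N + 1) / 12 * (1 / ni[ia] + 1 / ni[ib]))
      tibble(group1 = a, group2 = b, statistic = as.numeric(stat),
             p = stats::ptukey(as.numeric(stat) * sqrt(2), k, Inf,
                               lower.tail = FALSE))
    }))
  }
  structure(list(h = h, df = k - 1, p = p, pairwise = pairwise,
                 alpha = alpha),
            class = "kruskal_nemenyi")
}

#' @export
print.kruskal_nemenyi <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g (df = %d), p = %.4g\n",
              x$h, x$df, x$p))
  if (is.null(x$pairwise))
    cat("Pairwise Nemenyi comparisons suppressed (overall test not significant)\n")
  else print(x$pairwise)
  invisible(x)
}
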