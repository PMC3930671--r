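fake_patch_table <- function(f) {
  tibble::tibble(patch_id = seq_len(nrow(f)),
                 dbh_mean = f[, 1], dbh_max = f[, 2], dbh_sd = f[, 3],
                 n_trees = f[, 4], density_ha = f[, 5], area = f[, 6],
                 perimeter = f[, 7])
}

test_that("feature matrix standardizes and guards against bad columns", {
  set.seed(201)
  f <- matrix(rnorm(70, 10, 3), 10, 7)
  feats <- patch_features(fake_patch_table(f))
  X <- stemmosaic:::feature_matrix(feats)
  expect_equal(unname(colMeans(X)), rep(0, 7), tolerance = 1e-12)
  expect_equal(unname(apply(X, 2, sd)), rep(1, 7), tolerance = 1e-12)
  f2 <- f; f2[, 3] <- 5
  expect_error(patch_features(fake_patch_table(f2)), "dbh_sd")
  f3 <- f; f3[2, 2] <- NA
  expect_error(patch_features(fake_patch_table(f3)), "missing")
})

test_that("PCA satisfies its decomposition identities", {
  set.seed(202)
  f <- matrix(rnorm(210, 20, 4), 30, 7)
  pca <- pca_patch_structure(patch_features(fake_patch_table(f)))
  expect_equal(sum(pca$var_explained), 1, tolerance = 1e-10)
  # scores' covariance is diagonal with the eigenvalues
  expect_equal(cov(pca$scores) * (30 - 1) / (30 - 1),
               diag(pca$fit$sdev^2), tolerance = 1e-10,
               ignore_attr = TRUE)
  # eigenvalues match the correlation-matrix spectrum, itself verified
  # against an independent characteristic-polynomial hand solution
  # (5 observations x 3 variables)
  h <- matrix(c(1, 2, 3, 4, 5,
                2, 1, 4, 3, 6,
                5, 3, 1, 2, 4), 5, 3)
  C <- cor(h)
  # det(C - lambda I) coefficients assembled by cofactor expansion
  cp <- c(det(C),
          -(C[1, 1] * C[2, 2] - C[1, 2] * C[2, 1] +
              C[1, 1] * C[3, 3] - C[1, 3] * C[3, 1] +
              C[2, 2] * C[3, 3] - C[2, 3] * C[3, 2]),
          sum(diag(C)),
          -1)
  lam <- sort(Re(polyroot(cp)), decreasing = TRUE)
  fit <- stats::prcomp(scale(h), center = FALSE, scale. = FALSE)
  expect_equal(fit$sdev^2, lam, tolerance = 1e-8)
  # rank-1 case: two perfectly correlated variables -> PC1 explains all
  z <- rnorm(12)
  f1 <- cbind(z, 2 * z)
  p1 <- stats::prcomp(scale(f1))
  expect_equal(p1$sdev[1]^2 / sum(p1$sdev^2), 1, tolerance = 1e-10)
})

test_that("Ward merges equal the exhaustive-agglomeration oracle", {
  for (seed in c(203, 204)) {
    set.seed(seed)
    X <- matrix(rnorm(16), 8, 2)
    hc <- stats::hclust(stats::dist(X), method = "ward.D2")
    expect_equal(hc$height, oracle_ward_heights(X), tolerance = 1e-10)
    expect_true(all(diff(hc$height) >= -1e-12))
  }
})

test_that("clustering recovers separated blobs and is permutation invariant", {
  set.seed(205)
  shift <- rep(c(0, 10), each = 15)
  f <- matrix(rnorm(30 * 7), 30, 7) + shift
  tab <- fake_patch_table(f)
  gr <- cluster_patch_types(patch_features(tab), k = 2)
  truth <- rep(1:2, each = 15)
  agree <- max(mean(gr$labels == truth), mean(gr$labels == 3 - truth))
  expect_equal(agree, 1)
  # permuting rows relabels but does not regroup
  perm <- sample(30)
  gr2 <- cluster_patch_types(patch_features(tab[perm, ]), k = 2)
  expect_equal(length(unique(paste(gr$labels[perm], gr2$labels))), 2)
  # automatic k lands in the candidate range and reports elongations
  gra <- cluster_patch_types(patch_features(tab))
  expect_true(gra$k %in% 3:6)
  expect_equal(nrow(gra$elongation), 4)
  expect_error(cluster_patch_types(patch_features(tab), k = 31), "exceed")
})

test_that("one-way ANOVA matches hand sums of squares and F = t^2", {
  df <- data.frame(v = c(5, 6, 7, 9, 10, 11, 1, 2, 3),
                   g = rep(c("a", "b", "c"), each = 3))
  gm <- mean(df$v)
  ssb <- sum(tapply(df$v, df$g, function(x) length(x) * (mean(x) - gm)^2))
  ssw <- sum(tapply(df$v, df$g, function(x) sum((x - mean(x))^2)))
  Fh <- (ssb / 2) / (ssw / 6)
  a <- compare_groups_anova(df, "v", "g", transform = "none")
  expect_equal(a$f, Fh, tolerance = 1e-8)
  expect_equal(a$p, pf(Fh, 2, 6, lower.tail = FALSE), tolerance = 1e-8)
  # two-group F equals the pooled t statistic squared
  set.seed(206)
  df2 <- data.frame(v = rnorm(24), g = rep(c("x", "y"), each = 12))
  a2 <- compare_groups_anova(df2, "v", "g", transform = "none")
  tt <- t.test(v ~ g, data = df2, var.equal = TRUE)
  expect_equal(a2$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_error(compare_groups_anova(
    data.frame(v = c(1, 2, 3), g = c("a", "a", "b")), "v", "g"),
    "at least 2")
})

test_that("letters and the log10 fallback behave as designed", {
  # identical groups: F ~ 0 and a single shared letter
  df <- data.frame(v = rep(c(1, 2, 3, 4), 3),
                   g = rep(c("a", "b", "c"), each = 4))
  a <- compare_groups_anova(df, "v", "g", transform = "none")
  expect_lt(a$f, 1e-20)
  expect_true(all(a$letters$letters == "a"))
  # clearly separated groups get distinct letters
  set.seed(207)
  df2 <- data.frame(v = c(rnorm(10, 0, 0.1), rnorm(10, 5, 0.1),
                          rnorm(10, 10, 0.1)),
                    g = rep(c("a", "b", "c"), each = 10))
  a2 <- compare_groups_anova(df2, "v", "g", transform = "none")
  expect_equal(length(unique(a2$letters$letters)), 3)
  # multiplicative-error data trigger the log10 screen path
  set.seed(208)
  mu <- rep(c(2, 8, 32), each = 12)
  df3 <- data.frame(v = mu * exp(rnorm(36, 0, 0.8)),
                    g = rep(c("a", "b", "c"), each = 12))
  a3 <- compare_groups_anova(df3, "v", "g")
  expect_true(a3$log10)
  # letters computed on the transformed scale match an explicit log fit
  a3b <- compare_groups_anova(transform(df3, v = log10(v)), "v", "g",
                              transform = "none")
  expect_equal(a3$f, a3b$f, tolerance = 1e-10)
})

test_that("the variance screen agrees with the reference Levene implementation", {
  skip_if_not_installed("car")
  set.seed(210)
  df <- data.frame(v = c(rnorm(12, 0, 1), rnorm(12, 0, 4), rnorm(12, 0, 2)),
                   g = factor(rep(c("a", "b", "c"), each = 12)))
  p_pkg <- stemmosaic:::levene_p(df$v, df$g)
  p_car <- car::leveneTest(v ~ g, data = df, center = median)[["Pr(>F)"]][1]
  expect_equal(p_pkg, p_car, tolerance = 1e-10)
})

test_that("Kruskal-Wallis matches the tie-corrected hand computation", {
  df <- data.frame(v = c(7, 7, 3, 9, 12, 12, 12, 1, 5, 5),
                   g = rep(c("a", "b"), each = 5))
  rk <- rank(df$v)
  Ri <- tapply(rk, df$g, sum); ni <- c(5, 5); N <- 10
  h <- 12 / (N * (N + 1)) * sum(Ri^2 / ni) - 3 * (N + 1)
  ties <- table(df$v)
  h <- h / (1 - sum(ties^3 - ties) / (N^3 - N))
  k <- kruskal_nemenyi(df, "v", "g")
  expect_equal(k$h, unname(h), tolerance = 1e-8)
  kw <- stats::kruskal.test(df$v, factor(df$g))
  expect_equal(k$h, unname(kw$statistic), tolerance = 1e-10)
  expect_equal(k$p, kw$p.value, tolerance = 1e-10)
})

test_that("Nemenyi comparisons are gated on the overall test", {
  set.seed(209)
  # clear differences: pairwise table present, extreme pair most significant
  df <- data.frame(v = c(rnorm(10, 0), rnorm(10, 3), rnorm(10, 9)),
                   g = rep(c("a", "b", "c"), each = 10))
  k <- kruskal_nemenyi(df, "v", "g")
  expect_false(is.null(k$pairwise))
  pw <- k$pairwise
  expect_lt(pw$p[pw$group1 == "a" & pw$group2 == "c"],
            pw$p[pw$group1 == "a" & pw$group2 == "b"] + 1e-12)
  # overall non-significant: suppressed
  df2 <- data.frame(v = rep(c(1, 2, 3, 4), 3),
                    g = rep(c("a", "b", "c"), each = 4))
  expect_null(kruskal_nemenyi(df2, "v", "g")$pairwise)
  # degenerate all-tied input
  kt <- kruskal_nemenyi(data.frame(v = rep(5, 12),
                                   g = rep(c("a", "b", "c"), 4)), "v", "g")
  expect_equal(kt$h, 0)
  expect_equal(kt$p, 1)
})
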