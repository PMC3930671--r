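#' Analysis configuration
#'
#' Bundles every tunable of the per-site analysis suite with the standard
#' defaults: 199 simulations with rank-5 envelopes, 0-50 m distances, 5 m
#' edge buffer (on the window), 2 m / 12 m gap and spur thresholds,
#' perimeter-mode edge gaps, automatic group count in 3..6, strict 25% FRI
#' filter.
#'
#' @param geo Optional [site_geography()].
#' @param scheme A [size_class_scheme()].
#' @param r Distance grid.
#' @param n_sim,rank Envelope simulations and rank.
#' @param cell,gap_threshold,spur_threshold Gap-delineation parameters (m).
#' @param edge_gap_mode `"perimeter"` or `"area"`.
#' @param k Patch group count (`NULL` = automatic in 3..6).
#' @param crown_model Coefficient table ([load_crown_model()] default).
#' @param homogeneity_alpha Significance level of the homogeneity screen.
#' @param mode `"auto"` (screen decides), `"homogeneous"`, or
#'   `"inhomogeneous"`.
#' @param fri_period Optional `c(start, end)` years for FRI summaries.
#' @param fri_strict Strict (`>`) 25% filter.
#' @param seed Master seed for the Monte Carlo stages.
#' @return An `analysis_config` list.
#' @export
site_config <- function(geo = NULL, scheme = size_class_scheme(),
                        r = r_grid(), n_sim = 199, rank = 5,
                        cell = 0.25, gap_threshold = 2, spur_threshold = 12,
                        edge_gap_mode = "perimeter", k = NULL,
                        crown_model = NULL, homogeneity_alpha = 0.05,
                        mode = c("auto", "homogeneous", "inhomogeneous"),
                        fri_period = NULL, fri_strict = TRUE, seed = 1L) {
  stopifnot(n_sim >= 2 * rank, cell > 0, gap_threshold > 0, spur_threshold > 0)
  structure(list(geo = geo, scheme = scheme, r = r, n_sim = n_sim,
                 rank = rank, cell = cell, gap_threshold = gap_threshold,
                 spur_threshold = spur_threshold,
                 edge_gap_mode = edge_gap_mode, k = k,
                 crown_model = crown_model,
                 homogeneity_alpha = homogeneity_alpha,
                 mode = match.arg(mode),
                 fri_period = fri_period, fri_strict = fri_strict,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Run the full per-site analysis suite
#'
#' Orchestrates the analysis stages end to end on one stem map:
#' \enumerate{
#'   \item homogeneity screen -- univariate g(r) of established trees
#'     (DBH > 25 cm) against CSR with a goodness-of-fit test; significant
#'     large-scale aggregation switches all subsequent second-order analyses
#'     to inhomogeneous mode (manual override via `config$mode`);
#'   \item univariate pair correlation by size class with CSR (or
#'     inhomogeneous Poisson) envelopes and GoF tests;
#'   \item bivariate size-class independence (toroidal shifts) and live/snag
#'     random-labeling analyses;
#'   \item crown assignment, patch / single-tree delineation and summaries,
#'     gap delineation with edge-gap bookkeeping;
#'   \item patch typology (PCA + Ward grouping);
#'   \item composite fire-return-interval summaries when fire-scar records
#'     are supplied.
#' }
#'
#' @param sm A [stem_map()].
#' @param config An [site_config()].
#' @param fire_records Optional [fire_scar_records()].
#' @param out_dir Optional directory; when given, tidy CSV/JSON artifacts and
#'   a manifest are written there.
#' @return A `site_analysis` list with components `screen`, `mode`,
#'   `univariate`, `bivariate`, `snags`, `mosaic`, `gaps`, `typology`, `fri`.
#' @export
run_site_analysis <- function(sm, config = site_config(),
                              fire_records = NULL, out_dir = NULL) {
  set.seed(config$seed)
  w <- sm_window(sm)
  live <- sm[sm$status == "live", ]
  res <- list(site = sm_site(sm), config = config)

  # 1. homogeneity screen on established live trees
  established <- live[live$dbh > 25, ]
  res$screen <- NULL
  mode <- config$mode
  if (nrow(established) >= 10) {
    env_g <- envelope(established, null_model = "csr", statistic = "pcf",
                      n_sim = config$n_sim, rank = config$rank,
                      r = config$r, window = w)
    env_l <- envelope(established, null_model = "csr", statistic = "l",
                      n_sim = config$n_sim, rank = config$rank,
                      r = config$r, window = w)
    gof_g <- gof(env_g, range = range(config$r))
    gof_l <- gof(env_l, range = range(config$r))
    res$screen <- list(pcf_envelope = env_g, l_envelope = env_l,
                       gof = gof_l, gof_pcf = gof_g)
    # the cumulative L statistic drives the mode decision: it accumulates
    # the large-scale departures that indicate environmental trend, which
    # the non-cumulative g(r) dilutes across distances
    if (mode == "auto")
      mode <- if (gof_l$p < config$homogeneity_alpha) "inhomogeneous"
              else "homogeneous"
  } else if (mode == "auto") mode <- "homogeneous"
  res$mode <- mode

  surf <- if (mode == "inhomogeneous") estimate_intensity(live, w) else NULL

  # 2. univariate size-class analyses
  live_cls <- assign_size_class(live, config$scheme)
  res$univariate <- list()
  for (cls in levels(live_cls$size_class)) {
    sub <- live_cls[live_cls$size_class == cls, ]
    if (nrow(sub) < 10) next
    env <- if (mode == "inhomogeneous")
      envelope(sub, null_model = "inhom_poisson", n_sim = config$n_sim,
               rank = config$rank, r = config$r, window = w,
               lambda = estimate_intensity(sub, w))
    else
      envelope(sub, null_model = "csr", n_sim = config$n_sim,
               rank = config$rank, r = config$r, window = w)
    res$univariate[[cls]] <- list(envelope = env,
                                  gof = gof(env, range = range(config$r)))
  }

  # 3. bivariate size-class independence (toroidal shifts)
  res$bivariate <- list()
  cls_lv <- levels(live_cls$size_class)
  for (a in seq_along(cls_lv)) for (b in seq_along(cls_lv)) {
    if (a >= b) next
    s1 <- live_cls[live_cls$size_class == cls_lv[a], ]
    s2 <- live_cls[live_cls$size_class == cls_lv[b], ]
    if (nrow(s1) < 10 || nrow(s2) < 10) next
    env <- envelope(s1, s2, null_model = "toroidal_independence",
                    n_sim = config$n_sim, rank = config$rank,
                    r = config$r, window = w)
    res$bivariate[[paste(cls_lv[a], cls_lv[b], sep = "-")]] <-
      list(envelope = env, gof = gof(env, range = range(config$r)))
  }

  # snags: univariate under random mortality, and live/snag random labeling
  res$snags <- list()
  if (sum(sm$status == "snag") >= 10) {
    env_u <- envelope(sm, null_model = "random_labeling", target = "group2",
                      n_sim = config$n_sim, rank = config$rank,
                      r = config$r, window = w)
    env_b <- envelope(sm, null_model = "random_labeling", target = "cross",
                      n_sim = config$n_sim, rank = config$rank,
                      r = config$r, window = w)
    res$snags <- list(
      univariate = list(envelope = env_u, gof = gof(env_u, range(config$r))),
      live_snag = list(envelope = env_b, gof = gof(env_b, range(config$r))))
  }

  # 4. crowns, patches, gaps
  model <- if (is.null(config$crown_model)) load_crown_model()
           else config$crown_model
  sm_cr <- assign_crowns(sm, model, geo = config$geo)
  partition <- delineate_patches(sm_cr)
  gaps <- delineate_gaps(sm_cr, cell = config$cell,
                         gap_threshold = config$gap_threshold,
                         spur_threshold = config$spur_threshold)
  gaps <- filter_edge_gaps(gaps, mode = config$edge_gap_mode)
  res$stem_map <- sm_cr
  res$mosaic <- list(partition = partition,
                     summary = summarize_mosaic(partition))
  res$gaps <- list(gaps = gaps, summary = summarize_gaps(gaps))

  # 5. patch typology
  res$typology <- NULL
  if (nrow(partition$patches) >= 10) {
    feats <- patch_features(partition)
    pca <- pca_patch_structure(feats)
    grouping <- cluster_patch_types(feats, k = config$k)
    res$typology <- list(features = feats, pca = pca, grouping = grouping)
  }

  # 6. fire history
  res$fri <- NULL
  if (!is.null(fire_records)) {
    all_series <- build_composite(fire_records, period = config$fri_period)
    filt <- apply_filter(all_series, strict = config$fri_strict)
    res$fri <- list(
      all = all_series, filtered = filt,
      summary_all = if (nrow(all_series) >= 2) fri_summary(all_series) else NULL,
      summary_filtered = if (nrow(filt) >= 2) fri_summary(filt) else NULL)
  }

  res <- structure(res, class = "site_analysis")
  if (!is.null(out_dir)) write_site_analysis(res, out_dir)
  res
}

#' @export
print.site_analysis <- function(x, ...) {
  cat(sprintf("<site_analysis> '%s': mode = %s\n", x$site, x$mode))
  if (!is.null(x$screen))
    cat(sprintf("  homogeneity screen GoF p = %.4g\n", x$screen$gof$p))
  for (cls in names(x$univariate))
    cat(sprintf("  univariate %s: GoF p = %.4g\n", cls,
                x$univariate[[cls]]$gof$p))
  for (pr in names(x$bivariate))
    cat(sprintf("  bivariate %s: GoF p = %.4g\n", pr, x$bivariate[[pr]]$gof$p))
  s <- x$mosaic$summary$stand
  cat(sprintf("  %d patches (%.1f%% of plot), %d single trees, %d gaps\n",
              nrow(x$mosaic$partition$patches), s$pct_area_in_patches,
              nrow(x$mosaic$partition$singles), nrow(x$gaps$gaps)))
  if (!is.null(x$typology))
    cat(sprintf("  patch typology: k = %d groups\n", x$typology$grouping$k))
  if (!is.null(x$fri) && !is.null(x$fri$summary_all))
    cat(sprintf("  FRI all fires: mean %.1f yr; filtered: %s\n",
                x$fri$summary_all$mean,
                if (is.null(x$fri$summary_filtered)) "n/a"
                else sprintf("mean %.1f yr", x$fri$summary_filtered$mean)))
  invisible(x)
}

# tidy CSV/JSON artifacts with a manifest naming seed and parameters
write_site_analysis <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(as.data.frame(df), p, row.names = FALSE)
    name
  }
  files <- character()
  for (cls in names(res$univariate))
    files <- c(files, wr(tidy(res$univariate[[cls]]$envelope),
                         paste0("univariate_", cls, ".csv")))
  for (pr in names(res$bivariate))
    files <- c(files, wr(tidy(res$bivariate[[pr]]$envelope),
                         paste0("bivariate_", pr, ".csv")))
  files <- c(files,
             wr(res$mosaic$summary$categories, "patch_categories.csv"),
             wr(res$mosaic$summary$singles, "single_trees.csv"),
             wr(res$mosaic$summary$stand, "stand_summary.csv"),
             wr(tibble::as_tibble(res$gaps$summary), "gap_summary.csv"))
  if (!is.null(res$fri) && !is.null(res$fri$summary_all))
    files <- c(files, wr(res$fri$summary_all, "fri_all.csv"))
  if (!is.null(res$fri) && !is.null(res$fri$summary_filtered))
    files <- c(files, wr(res$fri$summary_filtered, "fri_filtered.csv"))
  gof_tab <- dplyr::bind_rows(
    lapply(names(res$univariate), function(cls)
      tibble(analysis = paste0("univariate_", cls),
             u = res$univariate[[cls]]$gof$u, p = res$univariate[[cls]]$gof$p)),
    lapply(names(res$bivariate), function(pr)
      tibble(analysis = paste0("bivariate_", pr),
             u = res$bivariate[[pr]]$gof$u, p = res$bivariate[[pr]]$gof$p)))
  files <- c(files, wr(gof_tab, "gof_tests.csv"))
  manifest <- list(site = res$site, mode = res$mode,
                   seed = res$config$seed, n_sim = res$config$n_sim,
                   rank = res$config$rank,
                   gap_threshold = res$config$gap_threshold,
                   spur_threshold = res$config$spur_threshold,
                   files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
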