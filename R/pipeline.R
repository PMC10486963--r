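#' Default pipeline configuration
#'
#' All parameters of [run_pipeline()] with their defaults: weight style and
#' band, per-stage permutation counts, significance level, GLM pools and
#' averaging threshold, and the master seed from which each stage's seed is
#' derived deterministically (so stages are individually reproducible and
#' mutually independent).
#'
#' @param weights_style `"binary"` or `"inverse"` (see [build_weights()]).
#' @param band_km neighbourhood band in km (default 20).
#' @param n_iter_roap D* relabelling iterations (default 999).
#' @param n_perm_moran global Moran permutations (default 999).
#' @param n_perm_lisa LISA conditional permutations (default 999).
#' @param alpha significance level used throughout (default 0.05).
#' @param lag_edges_km correlogram bin edges (default 0-100 by 10).
#' @param covariate_pool GLM covariate pool; `NULL` (default) means the
#'   variables that pass the High/Low screen.
#' @param temporal_years years used as temporal terms (default: all years
#'   before the response year).
#' @param max_spatial_terms cap on trend-surface terms (default 4).
#' @param delta_threshold AICc averaging window (default 2).
#' @param seed master seed (default 1).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(weights_style = "binary", band_km = 20,
                            n_iter_roap = 999, n_perm_moran = 999,
                            n_perm_lisa = 999, alpha = 0.05,
                            lag_edges_km = seq(0, 100, by = 10),
                            covariate_pool = NULL,
                            temporal_years = NULL,
                            max_spatial_terms = 4, delta_threshold = 2,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

# deterministic per-stage seed derived from the master seed and stage name
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h) %% .Machine$integer.max)
}

#' Run the full census analysis pipeline
#'
#' Orchestrates the complete analysis of a multi-year gridded census:
#' ever-present filtering, D* temporal-stability tests for every year
#' pair, global Moran's I with Monte-Carlo inference and a distance-lag
#' correlogram, LISA classification into High/Low aggregation cells (for
#' the last census year), the Kruskal-Wallis High-vs-Low covariate screen
#' with Bonferroni correction, and one negative-binomial model-selection
#' run per temporal term. If `out_dir` is given, per-stage artifacts are
#' written there (CSV tables, a LISA GeoJSON map layer, and a JSON
#' manifest echoing every effective parameter and stage seed).
#'
#' @param census a [census_table()] or path to a census CSV.
#' @param covariates covariate data.frame or path to a covariate CSV.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if missing).
#' @return list of class `pipeline_report` with elements `stability`
#'   (D* table), `moran`, `correlogram`, `lisa`, `classes`,
#'   `class_summary`, `kw`, `models` (one `model_selection` per temporal
#'   term), `changes`, `config`, `seeds`.
#' @export
run_pipeline <- function(census, covariates, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(census)) census <- read_census_csv(census)
  if (is.character(covariates)) covariates <- read_covariates_csv(covariates)
  census <- filter_ever_present(census)
  seeds <- vapply(c("roap", "moran", "correlogram", "lisa"),
                  function(s) stage_seed(config$seed, s), integer(1))
  yrs <- census$years
  resp_year <- max(yrs)

  # temporal stability: D* for every year pair
  pairs <- utils::combn(yrs, 2, simplify = FALSE)
  chg <- change_table(census)
  stability <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    dt <- dstar_permutation_test(census, p[2L], p[1L],
                                 n_iter = config$n_iter_roap,
                                 alpha = config$alpha,
                                 seed = seeds[["roap"]] + i)
    row <- chg[chg$year_a == p[2L] & chg$year_b == p[1L], ]
    data.frame(year_a = p[2L], year_b = p[1L],
               d_star = dt$d_star_observed, p_value = dt$p_value,
               stable = dt$stable,
               abundance_change = row$abundance_change,
               occupancy_change = row$occupancy_change)
  }))

  # spatial aggregation on the most recent census
  x <- as.numeric(census$counts[, as.character(resp_year)])
  w <- build_weights(census$cells, style = config$weights_style,
                     band_km = config$band_km)
  mor <- moran_montecarlo(x, w, n_perm = config$n_perm_moran,
                          seed = seeds[["moran"]])
  corr <- correlogram(x, census$cells, lag_edges_km = config$lag_edges_km,
                      n_perm = max(99L, config$n_perm_moran %/% 5L),
                      seed = seeds[["correlogram"]], alpha = config$alpha)
  lisa <- local_moran(x, w, n_perm = config$n_perm_lisa,
                      alpha = config$alpha, seed = seeds[["lisa"]])
  classes <- classify_high_low(lisa)
  cls_sum <- lisa_class_summary(x, classes)

  # covariate screen between High and Low cells
  kw <- compare_high_low(covariates, classes, alpha = config$alpha)

  # abundance models, one family per temporal term
  pool <- config$covariate_pool
  if (is.null(pool)) pool <- kw$variable[kw$significant]
  tyears <- config$temporal_years
  if (is.null(tyears)) tyears <- setdiff(yrs, resp_year)
  models <- list()
  if (length(pool) >= 1L) {
    for (ty in tyears) {
      fr <- design_frame(census, covariates, response_year = resp_year,
                         temporal_year = ty)
      np <- attr(fr, "temporal_term")
      specs <- enumerate_models(covariate_pool = pool, temporal_term = np,
                                max_spatial_terms = config$max_spatial_terms)
      fits <- fit_candidates(specs, fr)
      models[[np]] <- select_and_average(fits,
                                         delta_threshold =
                                           config$delta_threshold)
    }
  }

  report <- structure(list(stability = stability, moran = mor,
                           correlogram = corr, lisa = lisa,
                           classes = classes, class_summary = cls_sum,
                           kw = kw, models = models, changes = chg,
                           config = config, seeds = seeds),
                      class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, census, out_dir)
  report
}

write_report <- function(report, census, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  utils::write.csv(report$stability, p("stability.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$correlogram), p("correlogram.csv"),
                   row.names = FALSE)
  lisa_df <- as.data.frame(report$lisa)
  lisa_df$class <- unname(report$classes)
  utils::write.csv(lisa_df, p("lisa.csv"), row.names = FALSE)
  write_geojson(census$cells,
                data.frame(cell_id = names(report$classes),
                           class = unname(report$classes)),
                p("lisa.geojson"))
  utils::write.csv(as.data.frame(report$kw), p("kruskal_wallis.csv"),
                   row.names = FALSE)
  utils::write.csv(report$class_summary, p("class_summary.csv"),
                   row.names = FALSE)
  for (np in names(report$models)) {
    utils::write.csv(report$models[[np]]$table,
                     p(paste0("models_", np, ".csv")), row.names = FALSE)
    utils::write.csv(data.frame(
      term = names(report$models[[np]]$coef_full),
      coef_full = report$models[[np]]$coef_full,
      coef_conditional =
        report$models[[np]]$coef_conditional[
          names(report$models[[np]]$coef_full)]),
      p(paste0("averaged_", np, ".csv")), row.names = FALSE)
  }
  cfg <- report$config
  manifest <- list(
    moran = list(I = report$moran$I, p = report$moran$p_value),
    seeds = as.list(report$seeds),
    config = cfg[setdiff(names(cfg), "lag_edges_km")],
    lag_edges_km = cfg$lag_edges_km,
    class_counts = as.list(table(report$classes)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== Gridded census analysis report ==\n\nTemporal stability (D*):\n")
  st <- x$stability
  st$d_star <- round(st$d_star, 3); st$p_value <- round(st$p_value, 3)
  print(st, row.names = FALSE)
  cat("\nGlobal Moran's I:\n"); print(x$moran)
  cat("\nLISA classes:\n")
  print(x$class_summary, row.names = FALSE)
  cat("\nHigh vs Low covariate screen:\n"); print(x$kw)
  for (np in names(x$models)) {
    cat("\nAbundance models (temporal term ", np, "):\n", sep = "")
    print(x$models[[np]])
  }
  invisible(x)
}
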