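# End-to-end orchestration: synthesize/ingest -> thin -> partition ->
# fit all variable-subset models -> rank -> threshold -> categorize ->
# Koppen overlay -> summary tables.

#' Pipeline configuration
#'
#' All seeds are explicit so a run is reproducible from its manifest.
#'
#' @param scenario A [synthetic_scenario()] (synthetic input mode), or
#'   NULL when `stack_paths`/`points_path` are given.
#' @param stack_paths Named layer -> `.asc` path map (file input mode).
#' @param points_path Occurrence CSV path (file input mode).
#' @param thin_km Minimum thinning distance, km (default 1).
#' @param thin_reps Thinning repetitions (default 100).
#' @param schemes Partition schemes to run (default all four).
#' @param n_background Background sample size (default 10000).
#' @param buffer_km Background buffer radius around thinned training
#'   points, km (default 400).
#' @param vars Candidate model variables.
#' @param settings Maxent settings, see [fit_subset_model()].
#' @param retention Category retention fractions, see [categorize()].
#' @param transform Suitability transform for thresholding/categorization
#'   (`"cloglog"` default).
#' @param seeds Named list: `thin`, `partition`, `background` (defaults
#'   derived from `base_seed`).
#' @param base_seed Single integer from which unset seeds are derived.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = synthetic_scenario(),
                            stack_paths = NULL, points_path = NULL,
                            thin_km = 1, thin_reps = 100,
                            schemes = c("random", "elevation",
                                        "longitude", "latitude"),
                            n_background = 10000, buffer_km = 400,
                            vars = c("MAT", "MAP", "P_cold", "P_warm"),
                            settings = list(),
                            retention = c(0.30, 0.70, 0.90),
                            transform = "cloglog",
                            seeds = list(), base_seed = 1) {
  stopifnot(thin_km > 0, buffer_km > 0, n_background >= 1)
  seeds <- utils::modifyList(
    list(thin = base_seed * 1000L + 1L,
         partition = base_seed * 1000L + 2L,
         background = base_seed * 1000L + 3L), seeds)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: load or synthesize the climate stack and occurrences; spatially
#' thin; partition per scheme; sample one shared background within a
#' buffer of the thinned points; fit and rank all variable-subset models
#' (AICc, train/test AUC); find the maximum-TSS threshold and categorize
#' the suitability surfaces of the two named representative models --
#' cold desert {MAT, MAP, P_cold} and cold steppe {MAT, MAP, P_warm} --
#' plus the AICc top model; tabulate categories and Koppen-Geiger classes
#' at the occurrence points. Any stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return List of class `pipeline_result`: `stack`, `occurrences`,
#'   `thinned`, `partitions`, `background`, `rankings` (one table per
#'   scheme), `thresholds`, `category_maps`, `category_tables`,
#'   `koppen_thinned`, `koppen_all`, `variable_summary`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cf <- config
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say("[%s] done in %.1fs", name,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }

  inp <- stage("input", {
    if (!is.null(cf$stack_paths)) {
      list(stack = read_stack(cf$stack_paths),
           occ = read_points(cf$points_path))
    } else {
      stk <- make_stack(cf$scenario)
      suit <- true_suitability(stk, cf$scenario$coef)
      occ <- sample_presences(stk, suit, cf$scenario$n_occurrences,
                              cf$scenario$seed + 10L)
      list(stack = stk, occ = occ)
    }
  })
  stack <- inp$stack

  thinned <- stage("thin",
    thin(inp$occ, cf$thin_km, reps = cf$thin_reps, seed = cf$seeds$thin))

  parts <- stage("partition", {
    out <- lapply(cf$schemes, function(s)
      partition(thinned$retained, s, seed = cf$seeds$partition))
    stats::setNames(out, cf$schemes)
  })

  background <- stage("background", {
    region <- buffer_region(stack, thinned$retained, cf$buffer_km)
    sample_background(stack, region, cf$n_background, cf$seeds$background)
  })

  rankings <- stage("rank", {
    lapply(parts, function(p)
      rank_models(stack, thinned$retained, p, background,
                  vars = cf$vars, settings = cf$settings))
  })

  # representative models: cold desert, cold steppe, and the AICc top model
  ranking_main <- rankings[[1]]
  models <- attr(ranking_main, "models")
  rep_names <- unique(c(
    intersect(c("MAT+MAP+P_cold", "MAT+MAP+P_warm"), names(models)),
    ranking_main$model[1]))

  ex_all <- extract_at_points(stack, inp$occ)
  thr_cat <- stage("categorize", {
    thresholds <- list(); maps <- list(); tables <- list()
    bg_tab <- background$points
    for (nm in rep_names) {
      mdl <- models[[nm]]
      if (is.null(mdl)) next
      fs <- mdl$features
      score_fun <- if (cf$transform == "cloglog") predict_cloglog else
        function(m, X) predict_raw(m, X)
      occ_tab <- ex_all[ex_all$valid, , drop = FALSE]
      sc_pres <- score_fun(mdl, feature_matrix(fs, occ_tab))
      sc_bg <- score_fun(mdl, feature_matrix(fs, bg_tab))
      thr <- tss_threshold(sc_pres, sc_bg)
      surf <- predict_stack(mdl, stack, transform = cf$transform)
      cmap <- categorize(surf, thr$threshold, retention = cf$retention)
      thresholds[[nm]] <- thr
      maps[[nm]] <- cmap
      tables[[nm]] <- category_counts_at_points(cmap, stack, inp$occ)
    }
    list(thresholds = thresholds, maps = maps, tables = tables)
  })

  koppen <- stage("koppen", {
    list(thinned = classify_points(stack, thinned$retained),
         all = classify_points(stack, inp$occ))
  })

  var_summary <- stage("summarize", {
    ex <- extract_at_points(stack, thinned$retained)
    ex <- ex[ex$valid, , drop = FALSE]
    do.call(rbind, lapply(
      c("MAP", "MAT", "P_cold", "P_warm", "P_winter", "P_summer"),
      function(v) cbind(data.frame(variable = v),
                        as.data.frame(summarize_variable(ex[[v]])))))
  })

  manifest <- list(
    input_mode = if (is.null(cf$stack_paths)) "synthetic" else "files",
    scenario_seed = if (is.null(cf$stack_paths)) cf$scenario$seed else NA,
    thin_km = cf$thin_km, thin_reps = cf$thin_reps,
    n_background = cf$n_background, buffer_km = cf$buffer_km,
    schemes = cf$schemes, vars = cf$vars, transform = cf$transform,
    retention = cf$retention, seeds = cf$seeds,
    representative_models = rep_names)

  structure(list(stack = stack, occurrences = inp$occ, thinned = thinned,
                 partitions = parts, background = background,
                 rankings = rankings, thresholds = thr_cat$thresholds,
                 category_maps = thr_cat$maps,
                 category_tables = thr_cat$tables,
                 koppen_thinned = koppen$thinned, koppen_all = koppen$all,
                 variable_summary = var_summary, manifest = manifest),
            class = "pipeline_result")
}
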