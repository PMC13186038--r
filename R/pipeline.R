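#' Pipeline configuration
#'
#' Bundles every stage's parameters behind one object: the synthetic scene
#' (or optional user-supplied input paths), sampling sizes, the SPXY
#' fraction, variable-selection and model settings, pool parameters, the
#' reference epoch, change threshold, and driver-detection settings. All
#' randomness derives from `seed`.
#'
#' @param scene a [scene_config()].
#' @param inputs optional named list of file paths to user-supplied rasters
#'   or tables; validated to exist before any stage runs.
#' @param n_agb_samples,n_soc_samples field sample sizes; defaults 162, 96.
#' @param train_fraction SPXY training fraction; default 0.7.
#' @param alpha Pearson screening level; default 0.05.
#' @param cars_runs,iriv_models selector settings (see [cars_select()],
#'   [iriv_select()]).
#' @param methods regression methods to compare.
#' @param reference_epoch epoch whose densities are estimated directly.
#' @param pool_params a [pool_parameters()].
#' @param rel_threshold change-classification threshold; default 0.05.
#' @param opgd_k_range,opgd_permutations,opgd_stride driver-detection grid.
#' @param seed master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(scene = scene_config(), inputs = NULL,
                            n_agb_samples = 162L, n_soc_samples = 96L,
                            train_fraction = 0.7, alpha = 0.05,
                            cars_runs = 50L, iriv_models = 500L,
                            methods = c("RFR", "SVMR"),
                            reference_epoch = "2019",
                            pool_params = pool_parameters(),
                            rel_threshold = 0.05,
                            opgd_k_range = 3:8,
                            opgd_permutations = 199L,
                            opgd_stride = 1L,
                            seed = 42L) {
  stopifnot(inherits(scene, "scene_config"),
            inherits(pool_params, "pool_parameters"))
  if (!reference_epoch %in% scene$years)
    stop("reference epoch ", reference_epoch, " not among scene years")
  if (anyDuplicated(scene$years)) stop("epochs must be unique")
  structure(list(scene = scene, inputs = inputs,
                 n_agb_samples = as.integer(n_agb_samples),
                 n_soc_samples = as.integer(n_soc_samples),
                 train_fraction = train_fraction, alpha = alpha,
                 cars_runs = as.integer(cars_runs),
                 iriv_models = as.integer(iriv_models),
                 methods = methods, reference_epoch = reference_epoch,
                 pool_params = pool_params, rel_threshold = rel_threshold,
                 opgd_k_range = opgd_k_range,
                 opgd_permutations = as.integer(opgd_permutations),
                 opgd_stride = as.integer(opgd_stride),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

object_checksum <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  # strip environments that would make serialization unstable
  saveRDS(x, f, compress = FALSE, version = 3L)
  unname(tools::md5sum(f))
}

#' Run the full assessment pipeline
#'
#' Executes synthesis → sample draw → SPXY split → variable selection →
#' model comparison → raster inversion → pool assembly → per-class density
#' tables → climate correction → stock accounting, change classification and
#' transition decomposition for every epoch pair → driver (factor and
#' interaction) detection, and returns all stage results plus a run manifest
#' whose checksums reproduce bit-identically for an identical config and
#' seed.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional directory; when given, stage outputs are written
#'   (rasters as `.asc`, tables as `.csv`, manifest as `.json`).
#' @return List of class `pipeline_result` with elements `scene`, `agb`,
#'   `soc` (per-response sampling/selection/model stages), `pools`,
#'   `density_tables`, `stocks`, `changes`, `transitions`, `shares`,
#'   `drivers`, `interactions`, and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$inputs)) {
    missing_files <- unlist(config$inputs)[!file.exists(unlist(config$inputs))]
    if (length(missing_files))
      stop("validation failed before run: missing input path(s): ",
           paste(missing_files, collapse = ", "))
  }
  n_warn <- 0L
  timings <- c()
  checksums <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)),
      warning = function(w) {
        n_warn <<- n_warn + 1L
        invokeRestart("muffleWarning")
      })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  seed <- config$seed

  scene <- stage("synth", generate_scene(config$scene))
  checksums[["synth"]] <- object_checksum(lapply(scene$lu_maps, unclass))

  fit_response <- function(resp, n_samples, sub_seed) {
    pts <- sample_points(scene, n_samples, seed = sub_seed)
    X <- predictor_matrix(scene, pts)
    ps <- paired_samples(X, pts[[resp]])
    split <- spxy_split(ps, config$train_fraction)
    train <- subset_samples(ps, split$train_idx)
    val <- subset_samples(ps, split$val_idx)
    combos <- variable_combinations(train, seed = sub_seed,
                                    alpha = config$alpha,
                                    cars_runs = config$cars_runs,
                                    iriv_models = config$iriv_models)
    cmp <- compare_models(train, val, combos, methods = config$methods,
                          seed = sub_seed)
    list(points = pts, samples = ps, split = split, selections = combos,
         comparison = cmp, best_model = cmp$models[[cmp$best]])
  }
  agb <- stage("select_fit_agb",
               fit_response("agb", config$n_agb_samples, seed + 101L))
  soc <- stage("select_fit_soc",
               fit_response("soc", config$n_soc_samples, seed + 202L))
  checksums[["fit"]] <- object_checksum(list(agb$comparison$table,
                                             soc$comparison$table))

  agb_raster <- stage("invert_agb",
                      invert_raster(agb$best_model, scene$predictors))
  soc_raster <- stage("invert_soc",
                      invert_raster(soc$best_model, scene$predictors))
  checksums[["invert"]] <- object_checksum(list(unclass(agb_raster),
                                                unclass(soc_raster)))

  ref <- config$reference_epoch
  lu_ref <- scene$lu_maps[[ref]]
  pools <- stage("density",
                 assemble_pools(agb_raster, soc_raster, lu_ref,
                                config$pool_params))
  ref_table <- stage("zonal", zonal_density_table(pools, lu_ref, epoch = ref))

  climate <- scene$climate
  ref_row <- climate[climate$epoch == ref, ]
  ref_state <- climate_state(ref, ref_row$temperature_c,
                             ref_row$precipitation_mm)
  tables <- stage("correct", {
    out <- list()
    for (ep in names(scene$lu_maps)) {
      row <- climate[climate$epoch == ep, ]
      if (nrow(row) == 0L) stop("no climate for epoch ", ep)
      st <- climate_state(ep, row$temperature_c, row$precipitation_mm,
                          row$scenario)
      out[[ep]] <- correct_table(ref_table,
                                 correction_coefficients(ref_state, st))
    }
    out[[ref]] <- ref_table
    out
  })
  checksums[["density"]] <- object_checksum(lapply(tables, as.data.frame))

  stocks <- stage("stock", lapply(names(scene$lu_maps), function(ep)
    total_carbon(scene$lu_maps[[ep]], tables[[ep]])))
  names(stocks) <- names(scene$lu_maps)

  hist_eps <- config$scene$years
  pairs <- if (length(hist_eps) > 1L)
    Map(c, hist_eps[-length(hist_eps)], hist_eps[-1L]) else list()
  last <- hist_eps[length(hist_eps)]
  for (sc in names(config$scene$scenarios))
    pairs[[length(pairs) + 1L]] <-
      c(last, paste0(config$scene$scenarios[[sc]], "_", sc))
  changes <- stage("change", lapply(pairs, function(pr) {
    cs1 <- stock_raster(scene$lu_maps[[pr[1L]]], tables[[pr[1L]]])
    cs2 <- stock_raster(scene$lu_maps[[pr[2L]]], tables[[pr[2L]]])
    change_classify(cs1, cs2, config$rel_threshold)
  }))
  names(changes) <- vapply(pairs, paste, character(1), collapse = "_to_")
  transitions <- stage("transition", lapply(pairs, function(pr)
    transition_analysis(scene$lu_maps[[pr[1L]]], scene$lu_maps[[pr[2L]]],
                        tables[[pr[1L]]], tables[[pr[2L]]])))
  names(transitions) <- names(changes)
  shares <- share_comparison(stocks[[ref]])
  checksums[["stock"]] <- object_checksum(
    list(lapply(stocks, function(s) s$table),
         lapply(transitions, function(t) t$matrix_dcs_t)))

  cs_ref <- oc_raster(unclass(pools$above) + unclass(pools$below) +
                        unclass(pools$soil) + unclass(pools$dead),
                      cell_size = cell_size(lu_ref))
  detection <- stage("drivers",
                     factor_detect(cs_ref, scene$drivers, categorical = "ST",
                                   k_range = config$opgd_k_range,
                                   permutations = config$opgd_permutations,
                                   seed = seed + 303L,
                                   stride = config$opgd_stride))
  interactions <- stage("interactions", interaction_matrix(detection))
  checksums[["drivers"]] <- object_checksum(list(detection$table,
                                                 interactions))

  cfg_hash <- object_checksum(config)
  manifest <- structure(list(config_hash = cfg_hash, seed = seed,
                             checksums = checksums, timings = timings,
                             n_warnings = n_warn),
                        class = "run_manifest")
  result <- structure(list(scene = scene, agb = agb, soc = soc,
                           agb_raster = agb_raster, soc_raster = soc_raster,
                           pools = pools, density_tables = tables,
                           stocks = stocks, changes = changes,
                           transitions = transitions, shares = shares,
                           drivers = detection, interactions = interactions,
                           manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  result
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> seed %d, config %s, %d warning(s)\n",
              x$seed, substr(x$config_hash, 1, 8), x$n_warnings))
  for (nm in names(x$checksums))
    cat(sprintf("  %-12s %s\n", nm, x$checksums[[nm]]))
  cat("  stage timings (s):",
      paste(names(x$timings), unlist(x$timings), sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  best AGB model:", x$agb$comparison$best,
      sprintf("(validation R2 %.3f)\n",
              x$agb$comparison$table[x$agb$comparison$best, "val_r2"]))
  cat("  best SOC model:", x$soc$comparison$best,
      sprintf("(validation R2 %.3f)\n",
              x$soc$comparison$table[x$soc$comparison$best, "val_r2"]))
  tot <- vapply(x$stocks, function(s) s$total_t, numeric(1))
  cat("  total stock (t):\n")
  print(round(tot, 1))
  cat("  top driver:", x$drivers$table$name[1L],
      sprintf("(q=%.3f, %s influence)\n", x$drivers$table$q[1L],
              x$drivers$table$band[1L]))
  print(x$manifest)
  invisible(x)
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (ep in names(result$scene$lu_maps))
    write_raster(result$scene$lu_maps[[ep]],
                 file.path(outdir, paste0("lu_", ep, ".asc")))
  write_raster(result$agb_raster, file.path(outdir, "agb_inversion.asc"))
  write_raster(result$soc_raster, file.path(outdir, "soc_inversion.asc"))
  for (ep in names(result$density_tables))
    write_table(as.data.frame(result$density_tables[[ep]]),
                file.path(outdir, paste0("density_", ep, ".csv")))
  stock_tab <- do.call(rbind, lapply(names(result$stocks), function(ep)
    cbind(epoch = ep, result$stocks[[ep]]$table)))
  write_table(stock_tab, file.path(outdir, "stocks.csv"))
  write_table(result$drivers$table, file.path(outdir, "factor_detection.csv"))
  write_table(result$interactions, file.path(outdir, "interactions.csv"))
  man <- result$manifest
  jsonlite::write_json(
    list(config_hash = man$config_hash, seed = man$seed,
         checksums = as.list(man$checksums),
         timings = as.list(man$timings), n_warnings = man$n_warnings),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
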