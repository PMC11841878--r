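# End-to-end orchestration: simulate -> render -> extract TAOs ->
# covariates -> balanced sample -> fit -> P/E classification -> patch
# delineation -> evaluation, with every stage's artifact and parameters
# written to disk and hashed into a run manifest.

#' Pipeline configuration
#'
#' All stage parameters in one structured object.  Every default that the
#' analysis design fixes is visible here: 5-m analysis grid, 20-m
#' used-point exclusion, RM 2.0, P/E bins of width 0.02 every 0.002 from
#' 0.02, 80.25-m patch buffer, concavity 0.8, 60/55-m smoothing.
#'
#' @param scenario a [forest_scenario()] (or NULL to read inputs from
#'   files via `dsm_path` / `used_path`).
#' @param dsm_path,used_path optional input files (ESRI ASCII DSM,
#'   GeoJSON used polygons) used when no scenario is given.
#' @param dsm_resolution synthetic DSM resolution (m).
#' @param tao_window local-maxima window radius (m).
#' @param tao_min_height minimum TAO height at extraction (m).
#' @param grid_res analysis grid resolution (m).
#' @param ha_per_point sampling density (ha per BAS point).
#' @param exclusion used-point inner-boundary exclusion (m).
#' @param feature_classes,n_knots model feature construction.
#' @param rm regularization multiplier.
#' @param replicates bootstrap replicates for evaluation statistics.
#' @param pe_width,pe_step,pe_start P/E binning.
#' @param pe_span smoother span.
#' @param k_breaks interior breakpoints (3 gives the standard five-class
#'   scheme directly).
#' @param min_class patch threshold class.
#' @param buffer,concavity,length_threshold,smooth_out,smooth_in patch
#'   delineation parameters.
#' @param smooth_resolution perimeter-smoothing grid (m).
#' @param seed root seed; stage seeds are derived deterministically.
#' @export
pipeline_config <- function(scenario = NULL, dsm_path = NULL, used_path = NULL,
                            dsm_resolution = 1, tao_window = 2,
                            tao_min_height = 0, grid_res = 5,
                            ha_per_point = 0.04, exclusion = 20,
                            feature_classes = c("linear", "quadratic",
                                                "product", "hinge"),
                            n_knots = 50, rm = 2.0, replicates = 10,
                            pe_width = 0.02, pe_step = 0.002, pe_start = 0.02,
                            pe_span = 0.2, k_breaks = 3,
                            min_class = "low", buffer = 80.25,
                            concavity = 0.8, length_threshold = 0,
                            smooth_out = 60, smooth_in = 55,
                            smooth_resolution = 2, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Demonstration scenario
#'
#' A 120-ha second-growth landscape (lognormal heights around 28 m,
#' 150 stems/ha) holding one rectangular 6.6-ha old-growth patch with
#' 20 tall stems/ha drawn uniformly on 60-105 m -- a deliberately
#' separable configuration for exercising the full pipeline.
#'
#' @param seed scenario seed.
#' @param tall_density tall stems per hectare in the patch (default 20).
#' @export
demo_scenario <- function(seed = 1L, tall_density = 20) {
  forest_scenario(
    extent = c(0, 0, 1200, 1000),
    matrix_height_dist = height_dist("lognormal", meanlog = log(28), sdlog = 0.22),
    matrix_stem_density = 150,
    patches = list(list(
      polygon = rect_polygon(450, 390, 750, 610),
      tall_tree_density = tall_density,
      tall_height_dist = height_dist("uniform", min = 60, max = 105))),
    crown_radius_coeff = 0.1,
    seed = seed)
}

#' Run the full pipeline
#'
#' Executes every stage in order, writes each intermediate artifact under
#' `out_dir`, and returns (and writes) a manifest of files, MD5 hashes and
#' echoed parameters.  All randomness derives from `config$seed`, so a
#' rerun with the same config reproduces every artifact hash.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @param quiet suppress stage logging.
#' @return invisibly, a list with all stage results plus the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(scenario = demo_scenario()),
                         out_dir = tempfile("hsmrun"), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  res <- list(config = config, out_dir = out_dir)

  # -- stage 1: forest / inputs
  if (!is.null(config$scenario)) {
    say("[simulate] scenario seed %d", config$scenario$seed)
    stems <- generate_stem_map(config$scenario)
    write_stem_map(stems, file.path(out_dir, "stems.csv"))
    dsm <- render_dsm(stems, resolution = config$dsm_resolution)
    used_polys <- used_polygons_from_scenario(config$scenario)
    res$stems <- stems
  } else {
    say("[inputs] reading DSM %s", config$dsm_path)
    dsm <- read_asc(config$dsm_path)
    used_polys <- read_polygons_geojson(config$used_path)
  }
  write_asc(dsm, file.path(out_dir, "dsm.asc"))
  write_polygons_geojson(used_polys, file.path(out_dir, "used_polygons.geojson"))
  res$dsm <- dsm; res$used_polygons <- used_polys

  # -- stage 2: TAO extraction
  say("[taos] window %g m, min height %g m", config$tao_window, config$tao_min_height)
  taos <- extract_taos(dsm, config$tao_window, config$tao_min_height)
  write_taos(taos, file.path(out_dir, "taos.csv"))
  say("[taos] %d TAOs (%d >= 50 m)", nrow(taos), sum(taos$height_m >= 50))
  res$taos <- taos

  # -- stage 3: covariates
  grid <- grid_spec_from_raster(dsm, res = config$grid_res)
  say("[covariates] final trio on %d x %d @ %g m grid", grid$nrow, grid$ncol,
      grid$res)
  stack <- final3_stack(taos, grid)
  write_stack(stack, file.path(out_dir, "covariates"))
  res$stack <- stack

  # -- stage 4: balanced sample
  ext <- raster_extent(dsm)
  region <- rect_polygon(ext["xmin"], ext["ymin"], ext["xmax"], ext["ymax"])
  area_ha <- polygon_area(region) / 1e4
  n <- target_n_for_density(area_ha, config$ha_per_point)
  say("[sample] %d BAS points (1 per %g ha), %g m exclusion", n,
      config$ha_per_point, config$exclusion)
  pts <- bas_points(region, n, seed = derive_seed(config$seed, "bas"))
  sample <- label_samples(pts, used_polys, exclusion = config$exclusion)
  design <- extract_design(sample, stack)
  write_sample(design, file.path(out_dir, "sample.csv"))
  say("[sample] %d used / %d available", nrow(design$used), nrow(design$available))
  res$design <- design

  # -- stage 5: model fit
  spec <- feature_spec(config$feature_classes, config$n_knots)
  cfg <- fit_config(rm = config$rm, replicates = config$replicates,
                    seed = derive_seed(config$seed, "fit"))
  say("[fit] RM %.2g, classes %s, %d knots", config$rm,
      paste(config$feature_classes, collapse = "+"), config$n_knots)
  model <- maxent_hsm(design$used, design$available, spec, cfg)
  say("[fit] %d/%d nonzero features, gain %.3f", sum(model$beta != 0),
      length(model$beta), gain(model, design$used))
  write_model(model, file.path(out_dir, "model.json"))
  res$model <- model

  # -- stage 6: HSI prediction + P/E classification
  hsi_raster <- predict_stack(model, stack)
  write_asc(hsi_raster, file.path(out_dir, "hsi.asc"))
  used_hsi <- predict_logistic(model, design$used)
  avail_hsi <- predict_logistic(model, design$available)
  curve <- pe_curve(used_hsi, avail_hsi, config$pe_width, config$pe_step,
                    config$pe_start)
  curve <- smooth_pe(curve, config$pe_span)
  fb <- forced_unsuitable_break(curve)
  bp <- fit_breakpoints(curve, k = config$k_breaks, forced_break = fb)
  classes <- build_classes(fb, bp, max_hsi = max(curve$center))
  say("[classify] forced break %.3f, interior {%s}", fb,
      paste(sprintf("%.3f", bp$breaks), collapse = ", "))
  class_raster <- classify_grid(hsi_raster, classes)
  write_asc(class_raster, file.path(out_dir, "classes.asc"))
  write_pe_curve(curve, file.path(out_dir, "pe_curve.csv"))
  jsonlite::write_json(list(boundaries = classes$boundaries,
                            labels = classes$labels),
                       file.path(out_dir, "classes.json"),
                       auto_unbox = TRUE, digits = NA)
  res$curve <- curve; res$classes <- classes
  res$hsi_raster <- hsi_raster; res$class_raster <- class_raster

  # -- stage 7: patch delineation
  say("[patches] buffer %.2f m, concavity %.2g, smoothing %g/%g m",
      config$buffer, config$concavity, config$smooth_out, config$smooth_in)
  patches <- delineate_patches(class_raster, taos,
                               min_class = config$min_class,
                               buffer = config$buffer,
                               concavity = config$concavity,
                               length_threshold = config$length_threshold,
                               smooth_out = config$smooth_out,
                               smooth_in = config$smooth_in,
                               resolution = config$smooth_resolution)
  pset <- summarize_patches(patches, hsi_raster, class_raster, used_polys)
  if (nrow(pset)) write_patches(pset, file.path(out_dir, "patches.geojson"))
  say("[patches] %d patch(es)", nrow(pset))
  res$patches <- patches; res$patch_set <- pset

  # -- stage 8: evaluation at the low-class threshold
  low_idx <- match(config$min_class, classes$labels)
  threshold <- if (!is.na(low_idx) && low_idx >= 2L) {
    classes$boundaries[low_idx - 1L]
  } else classes$boundaries[1L]
  metrics <- evaluate_model(used_hsi, avail_hsi, threshold,
                            used_included = TRUE)
  say("[evaluate] AUC %.3f, sensitivity %.3f, PPV %.3f, kappa %.3f @ %.3f",
      metrics$auc, metrics$sensitivity, metrics$ppv, metrics$kappa, threshold)
  jsonlite::write_json(list(auc = metrics$auc,
                            sensitivity = metrics$sensitivity,
                            ppv = metrics$ppv, kappa = metrics$kappa,
                            threshold = threshold,
                            confusion = metrics$cm[c("tp", "fp", "fn", "tn")]),
                       file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  res$metrics <- metrics

  # -- manifest
  files <- sort(list.files(out_dir, recursive = TRUE))
  files <- setdiff(files, "manifest.json")
  hashes <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(files = as.list(stats::setNames(unname(hashes), files)),
                   parameters = config_echo(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

config_echo <- function(config) {
  keep <- !vapply(config, function(x) is.null(x) ||
                    inherits(x, "forest_scenario"), TRUE)
  echo <- unclass(config)[keep]
  if (!is.null(config$scenario)) {
    echo$scenario_seed <- config$scenario$seed
    echo$scenario_extent <- config$scenario$extent
    echo$scenario_patches <- length(config$scenario$patches)
  }
  echo
}

#' Predict HSI over a covariate stack
#'
#' @param model a fitted `maxent_model` with feature definition.
#' @param stack a `covariate_stack` holding the model's covariates.
#' @return a [grid_raster()] of logistic HSI.
#' @export
predict_stack <- function(model, stack) {
  covs <- model$def$covariates
  X <- vapply(covs, function(nm) as.numeric(stack$layers[[nm]]$values),
              numeric(stack$grid$nrow * stack$grid$ncol))
  colnames(X) <- covs
  hsi <- predict_logistic(model, X)
  out <- stack$layers[[1L]]
  out$values <- matrix(hsi, stack$grid$nrow, stack$grid$ncol)
  out$name <- "hsi"
  out
}

#' Serialise / restore a fitted model as JSON
#' @param model a `maxent_model`.
#' @param path JSON file.
#' @export
write_model <- function(model, path) {
  obj <- list(beta = as.list(model$beta), logZ = model$logZ, H = model$H,
              rm = model$rm, tau = model$tau,
              lambda = model$lambda,
              parents = model$parents,
              feature_classes = model$feature_classes,
              n_used = model$n_used, n_available = model$n_available,
              iterations = model$iterations, converged = model$converged,
              objective = model$objective,
              def = if (!is.null(model$def)) {
                list(classes = model$def$spec$classes,
                     n_knots = model$def$spec$n_knots,
                     covariates = model$def$covariates,
                     mu = as.list(model$def$mu), sd = as.list(model$def$sd),
                     knots = model$def$knots)
              })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  def <- if (!is.null(obj$def)) {
    structure(list(spec = feature_spec(obj$def$classes, obj$def$n_knots),
                   covariates = obj$def$covariates,
                   mu = unlist(obj$def$mu), sd = unlist(obj$def$sd),
                   knots = lapply(obj$def$knots, unlist)),
              class = "feature_def")
  }
  structure(list(beta = unlist(obj$beta), logZ = obj$logZ, H = obj$H,
                 rm = obj$rm, tau = obj$tau, lambda = obj$lambda,
                 parents = obj$parents, feature_classes = obj$feature_classes,
                 def = def, n_used = obj$n_used,
                 n_available = obj$n_available,
                 iterations = obj$iterations, converged = obj$converged,
                 objective = obj$objective, contrib = NULL),
            class = "maxent_model")
}
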