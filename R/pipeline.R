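#' Configuration for an end-to-end synthetic pipeline run
#'
#' Bundles every stage's settings.  The master `seed` deterministically
#' derives a seed per stage (see [stage_seed()]), so stages are individually
#' reproducible and a rerun with the same config produces byte-identical
#' tabular outputs.
#'
#' @param outdir output directory, or `NULL` to skip writing files.
#' @param landscape a [landscape_config()].
#' @param species a [virtual_species()].
#' @param n_per_month occurrence records sampled per month per year.
#' @param methods pseudo-absence methods to run.
#' @param sampler a [sampler_config()] (its seed is overridden per stage).
#' @param screen a [screen_config()].
#' @param k cross-validation folds.
#' @param map_months months mapped (default June-September).
#' @param map_method method whose models are mapped.
#' @param niche_periods two named month sets compared in niche space.
#' @param occupancy_quantile binarization quantile for niche indices.
#' @param seed master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir = NULL,
                            landscape = landscape_config(),
                            species = virtual_species(),
                            n_per_month = 50,
                            methods = c("RS", "RSEP"),
                            sampler = sampler_config(),
                            screen = screen_config(),
                            k = 5,
                            map_months = 6:9,
                            map_method = "RSEP",
                            niche_periods = list(non_outbreak = c(1:5, 10:12),
                                                 outbreak = 6:9),
                            occupancy_quantile = 0.05,
                            seed = 1L) {
  structure(list(outdir = outdir, landscape = landscape, species = species,
                 n_per_month = n_per_month, methods = methods,
                 sampler = sampler, screen = screen, k = k,
                 map_months = map_months, map_method = map_method,
                 niche_periods = niche_periods,
                 occupancy_quantile = occupancy_quantile,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full seasonal SDM pipeline on a synthetic landscape
#'
#' Executes, in order: landscape + virtual-species simulation; occurrence
#' thinning; seasonal Pearson collinearity screen (on the RS model
#' datasets, all variables); the full pseudo-absence x replicate-set x
#' season-bin modelling design with AIC selection and cross-validation;
#' monthly suitability maps (averaged across years and replicate
#' sub-models) with 10-interval classification and monthly presence convex
#' polygons; the response-optima summary; and the PCA niche-dynamics
#' comparison between the two configured periods.  Writes CSV/JSON outputs
#' under `outdir` and a manifest listing every file, stage seed and model
#' count.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the `manifest` plus the in-memory stage
#'   results (`stack`, `presences`, `screen`, `design`, `maps`, `optima`,
#'   `niche`).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  out <- config$outdir
  files <- character(0)
  emit_csv <- function(obj, name) {
    if (is.null(out)) return(invisible(NULL))
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    p <- file.path(out, name)
    write.csv(obj, p, row.names = FALSE)
    files <<- c(files, name)
  }
  emit_json <- function(obj, name) {
    if (is.null(out)) return(invisible(NULL))
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(obj, file.path(out, name), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    files <<- c(files, name)
  }
  seeds <- list(simulate = stage_seed(config$seed, "simulate"),
                occurrences = stage_seed(config$seed, "occurrences"),
                screen = stage_seed(config$seed, "screen"),
                design = stage_seed(config$seed, "design"),
                niche = stage_seed(config$seed, "niche"))

  say("stage simulate: generating landscape and occurrences")
  lc <- config$landscape
  lc$seed <- seeds$simulate
  stack <- generate_env_stack(lc)
  raw <- sample_occurrences(config$species, stack, config$n_per_month,
                            seed = seeds$occurrences)
  presences <- thin_occurrences(raw, stack)
  emit_csv(presences, "occurrences.csv")

  say("stage screen: seasonal Pearson collinearity screen")
  bins <- config$screen$season_bins
  scr_cfg <- config$sampler
  screen_sets <- list()
  for (bin in names(bins)) {
    pres_bin <- presences[presences$month %in% bins[[bin]], , drop = FALSE]
    scr_cfg$seed <- stage_seed(seeds$screen, bin)
    pa <- sample_rs(pres_bin, stack, scr_cfg, stack$variables)
    screen_sets[[bin]] <- lapply(seq_len(scr_cfg$n_sets), function(s)
      make_model_dataset(pres_bin, pa, stack, stack$variables, s, bin))
  }
  screen <- pearson_screen(screen_sets, config$screen)
  for (bin in names(screen$matrices))
    emit_csv(as.data.frame(screen$matrices[[bin]]),
             sprintf("pearson_%s.csv", bin))
  emit_json(list(retained = screen$retained,
                 dropped = screen$dropped$variable), "screen.json")
  say("  retained: %s", paste(screen$retained, collapse = ", "))

  say("stage design: %s x %d sets x %d bins",
      paste(config$methods, collapse = "+"), config$sampler$n_sets,
      length(bins))
  design <- run_design(presences, stack, screen$retained,
                       methods = config$methods, season_bins = bins,
                       config = config$sampler, cv = TRUE, k = config$k,
                       seed = seeds$design)
  emit_csv(design$frequency, "variable_frequency.csv")
  if (!is.null(design$cv)) emit_csv(design$cv, "cv_report.csv")
  emit_json(lapply(design$models, function(m) list(
    method = m$method, subset = m$subset, set_id = m$set_id,
    terms = as.list(m$fit$terms), coef = as.list(m$fit$coef_std),
    coef_data_scale = as.list(m$fit$coef_data),
    ranef_var = m$fit$ranef_var, aic = m$fit$aic,
    loglik = m$fit$loglik, engine = m$fit$engine,
    fallback = m$fit$fallback)), "models.json")

  say("stage mapper: monthly suitability maps and optima")
  map_method <- if (config$map_method %in% config$methods)
    config$map_method else config$methods[1]
  maps <- list()
  for (mo in config$map_months) {
    bin <- names(bins)[vapply(bins, function(m) mo %in% m, logical(1))][1]
    fits <- Filter(function(x)
      x$method == map_method && x$subset == bin, design$models)
    per <- list()
    for (f in fits) for (yr in stack$years)
      per[[length(per) + 1]] <- predict_map(f$fit, stack, mo, yr)
    avg <- average_maps(per)
    maps[[as.character(mo)]] <- avg
    emit_csv(as.data.frame(avg$values),
             sprintf("suitability_%s_%02d.csv", map_method, mo))
    emit_csv(as.data.frame(classify_map(avg)$bins),
             sprintf("bins_%s_%02d.csv", map_method, mo))
    hull <- tryCatch(min_convex_polygon(presences, mo), error = function(e) NULL)
    if (!is.null(hull))
      emit_csv(as.data.frame(unclass(hull)), sprintf("mcp_%02d.csv", mo))
  }
  optima <- optima_summary(design, stack, presences, method = map_method)
  emit_csv(optima, "optima_summary.csv")

  say("stage niche: PCA niche dynamics")
  background <- buffer_background(presences, stack,
                                  config$sampler$radius_km,
                                  screen$retained)
  space <- fit_niche_space(background, screen$retained)
  pres_env <- extract_env(stack, presences, screen$retained)
  bg_scores <- niche_scores(space, background)
  lims <- c(range(bg_scores[, 1]), range(bg_scores[, 2]))
  periods <- config$niche_periods
  grids <- lapply(periods, function(months) {
    occ <- niche_scores(space, pres_env[pres_env$month %in% months, ,
                                        drop = FALSE])
    bgp <- bg_scores[background$month %in% months, , drop = FALSE]
    density_grid(occ, bgp, lims = lims)
  })
  dyn <- niche_dynamics(grids[[1]], grids[[2]],
                        occupancy_quantile = config$occupancy_quantile)
  emit_json(list(reference = names(periods)[1],
                 comparison = names(periods)[2],
                 stability = dyn$stability, expansion = dyn$expansion,
                 unfilled = dyn$unfilled), "niche_indices.json")
  curves <- do.call(rbind, lapply(screen$retained, function(v)
    variable_occupancy(pres_env, background, v, periods)))
  emit_csv(curves, "niche_occupancy_curves.csv")

  manifest <- list(
    n_models = design$n_models,
    methods = config$methods,
    n_sets = config$sampler$n_sets,
    season_bins = lapply(bins, as.integer),
    variables_screened = stack$variables,
    variables_retained = screen$retained,
    master_seed = config$seed, stage_seeds = seeds,
    niche_indices = list(stability = dyn$stability,
                         expansion = dyn$expansion,
                         unfilled = dyn$unfilled),
    files = sort(files),
    versions = list(
      r = R.version.string,
      seasonsdm = as.character(utils::packageVersion("seasonsdm")),
      lme4 = as.character(utils::packageVersion("lme4")),
      e1071 = as.character(utils::packageVersion("e1071"))))
  emit_json(manifest, "manifest.json")
  say("done: %d models", design$n_models)
  invisible(list(manifest = manifest, stack = stack, presences = presences,
                 screen = screen, design = design, maps = maps,
                 optima = optima,
                 niche = list(space = space, grids = grids, dynamics = dyn,
                              curves = curves)))
}
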