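#' Assemble a labeled presence / pseudo-absence model dataset
#'
#' Merges one replicate pseudo-absence set (label 0) with the presences
#' (label 1) and extracts the covariates of each row from the layers
#' matching its own (year, month).  Balanced by construction.
#'
#' @param presences occurrence data.frame for one season/month subset.
#' @param pabs a `pseudo_absences` data.frame (see [sample_rs()]).
#' @param stack an [env_stack()].
#' @param variables covariates to extract.
#' @param set_id which replicate set of `pabs` to use.
#' @param subset subset tag (e.g. `"winter"`, `"July"`).
#' @return data.frame `label, lon, lat, year, month, cell_id, <vars>` with
#'   attributes `subset`, `set_id`, `method`.
#' @export
make_model_dataset <- function(presences, pabs, stack, variables,
                               set_id = 1L, subset = NA_character_) {
  ab <- pabs[pabs$set_id == set_id, , drop = FALSE]
  if (!nrow(ab)) stop(sprintf("pseudo-absence set %d is empty", set_id))
  base_cols <- c("lon", "lat", "year", "month", "cell_id")
  pres <- presences[, base_cols, drop = FALSE]
  absn <- ab[, base_cols, drop = FALSE]
  out <- rbind(cbind(label = 1L, pres), cbind(label = 0L, absn))
  out <- extract_env(stack, out, variables)
  if (anyNA(out[, variables]))
    stop("extracted covariates contain missing values")
  rownames(out) <- NULL
  attr(out, "subset") <- subset
  attr(out, "set_id") <- set_id
  attr(out, "method") <- unique(ab$method)[1]
  out
}

#' Run the full seasonal modelling design
#'
#' For every pseudo-absence method and season bin, draws `n_sets` replicate
#' pseudo-absence sets, builds the balanced model datasets, performs
#' backward AIC selection from the full linear+quadratic term set, and
#' (optionally) evaluates each selected model by stratified k-fold
#' cross-validation.  With 2 methods, 5 replicate sets and the 8 default
#' season bins this yields 80 fitted models.  Also tabulates, per method and
#' bin, how often each variable survives selection across the replicate
#' sub-models and which variables are common to all of them.
#'
#' @param presences full-year thinned occurrence table.
#' @param stack an [env_stack()].
#' @param variables covariates to model (post-screen).
#' @param methods subset of `c("RS", "RSEP")`.
#' @param season_bins named list of month vectors.
#' @param config a [sampler_config()]; its seed is overridden per
#'   (method, bin) by seeds derived from `seed`.
#' @param cv logical: run cross-validation.
#' @param k CV folds.
#' @param seed master seed for the design.
#' @param use_mixed passed to [fit_sdm()].
#' @return An `sdm_design` object: `models` (list with `method`, `subset`,
#'   `set_id`, `fit`, `cv`), `frequency` (long data.frame), `cv` (combined
#'   per-fold report), `n_models`.
#' @export
run_design <- function(presences, stack, variables,
                       methods = c("RS", "RSEP"),
                       season_bins = default_season_bins(),
                       config = sampler_config(), cv = TRUE, k = 5,
                       seed = 1L, use_mixed = "auto") {
  stopifnot(all(methods %in% c("RS", "RSEP")))
  models <- list()
  cv_rows <- list()
  for (method in methods) for (bin in names(season_bins)) {
    pres_bin <- presences[presences$month %in% season_bins[[bin]], ,
                          drop = FALSE]
    if (!nrow(pres_bin))
      stop(sprintf("no presences in season bin %s", bin))
    cfg <- config
    cfg$seed <- stage_seed(seed, paste("pabs", method, bin))
    pabs <- if (method == "RS")
      sample_rs(pres_bin, stack, cfg, variables)
    else
      sample_rsep(pres_bin, stack, variables, cfg)
    for (s in seq_len(cfg$n_sets)) {
      ds <- make_model_dataset(pres_bin, pabs, stack, variables,
                               set_id = s, subset = bin)
      fit <- stepwise_aic(ds, full_quadratic_terms(variables), use_mixed)
      cvr <- NULL
      if (cv) {
        cvr <- cross_validate(ds, fit$terms, k = k,
                              seed = stage_seed(seed,
                                                paste("cv", method, bin, s)),
                              use_mixed = use_mixed)
        cv_rows[[length(cv_rows) + 1]] <-
          cbind(subset = bin, method = method, set_id = s,
                as.data.frame(cvr))
      }
      models[[length(models) + 1]] <- list(method = method, subset = bin,
                                           set_id = s, fit = fit, cv = cvr)
    }
  }
  freq <- do.call(rbind, lapply(methods, function(m)
    do.call(rbind, lapply(names(season_bins), function(bin) {
      fits <- Filter(function(x) x$method == m && x$subset == bin, models)
      data.frame(method = m, subset = bin, variable = variables,
                 frequency = vapply(variables, function(v)
                   sum(vapply(fits, function(x)
                     v %in% names(x$fit$terms), logical(1))), numeric(1)),
                 n_sets = length(fits))
    }))))
  rownames(freq) <- NULL
  freq$common <- freq$frequency == freq$n_sets
  structure(list(models = models, frequency = freq,
                 cv = if (length(cv_rows)) do.call(rbind, cv_rows) else NULL,
                 n_models = length(models), variables = variables,
                 methods = methods, season_bins = season_bins, seed = seed),
            class = "sdm_design")
}

#' @exportS3Method base::print
print.sdm_design <- function(x, ...) {
  cat(sprintf("sdm_design: %d models (%s x %d sets x %d bins)\n",
              x$n_models, paste(x$methods, collapse = "+"),
              max(vapply(x$models, `[[`, numeric(1), "set_id")),
              length(x$season_bins)))
  invisible(x)
}

#' Variable-retention summary for one pseudo-absence method
#'
#' One row per season bin: retention frequency of each variable across the
#' replicate sub-models (0..n_sets) and the comma-separated set of variables
#' common to all of them.
#'
#' @param design an `sdm_design` from [run_design()].
#' @param method `"RS"` or `"RSEP"`.
#' @return Wide data.frame `subset, <one column per variable>, common`.
#' @export
variable_frequency <- function(design, method = "RSEP") {
  f <- design$frequency[design$frequency$method == method, , drop = FALSE]
  bins <- names(design$season_bins)
  out <- data.frame(subset = bins)
  for (v in design$variables)
    out[[v]] <- vapply(bins, function(b)
      f$frequency[f$subset == b & f$variable == v], numeric(1))
  out$common <- vapply(bins, function(b) {
    fb <- f[f$subset == b, ]
    paste(fb$variable[fb$common], collapse = ", ")
  }, character(1))
  rownames(out) <- NULL
  out
}
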