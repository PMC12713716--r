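#' Configuration for pseudo-absence sampling
#'
#' Defaults follow the standard design for a strong-flying migratory pest:
#' candidate cells lie within 500 km of a presence (roughly the maximum
#' single-generation flight range), five replicate pseudo-absence sets are
#' drawn to average out sampling noise, and the environmentally profiled
#' sampler screens 30 candidate background points per presence with a
#' one-class support vector machine (RBF kernel, `nu = 0.1`,
#' `gamma = 1/p` on z-standardized covariates).
#'
#' @param radius_km positive buffer radius around each presence (closed
#'   ball: a point at exactly `radius_km` is eligible).
#' @param n_sets number of replicate pseudo-absence sets (>= 1).
#' @param candidates_per_presence background candidates screened per
#'   presence by the profiled sampler (>= 1).
#' @param kernel,nu,gamma one-class SVM settings (`gamma = NULL` means
#'   `1/p`).
#' @param max_resample_attempts candidate redraw rounds before giving up on
#'   a presence with no environmentally dissimilar neighbourhood.
#' @param seed integer seed; identical seeds reproduce sets bit-for-bit.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(radius_km = 500, n_sets = 5,
                           candidates_per_presence = 30,
                           kernel = "radial", nu = 0.1, gamma = NULL,
                           max_resample_attempts = 10, seed = 1L) {
  stopifnot(radius_km > 0, n_sets >= 1, candidates_per_presence >= 1,
            max_resample_attempts >= 1)
  structure(list(radius_km = radius_km, n_sets = as.integer(n_sets),
                 candidates_per_presence = as.integer(candidates_per_presence),
                 kernel = kernel, nu = nu, gamma = gamma,
                 max_resample_attempts = as.integer(max_resample_attempts),
                 seed = as.integer(seed)),
            class = "sampler_config")
}

## integer cell ids within the closed ball of radius_km around (x, y),
## excluding `exclude` cells
cells_in_buffer <- function(stack, x, y, radius_km, exclude = integer(0)) {
  cc <- cell_centers(stack)
  d <- point_distance_km(stack$grid$crs, x, y, cc$x, cc$y)
  cid <- cc$cell_id[d <= radius_km]
  setdiff(cid, exclude)
}

## lazily computed per-(year, month) mask of cells with complete data
valid_cells_fun <- function(stack, variables) {
  cache <- new.env(parent = emptyenv())
  function(year, month) {
    key <- paste(year, month)
    if (!is.null(cache[[key]])) return(cache[[key]])
    ok <- rep(TRUE, stack$grid$n_rows * stack$grid$n_cols)
    for (v in variables) {
      lay <- get_layer(stack, v, year, month)
      ok <- ok & !is.na(as.vector(t(lay)))   # row-major = cell_id order
    }
    cache[[key]] <- which(ok)
    cache[[key]]
  }
}

new_pseudo_absence <- function(rows, method) {
  out <- do.call(rbind, rows)
  out$method <- method
  rownames(out) <- NULL
  class(out) <- c("pseudo_absences", "data.frame")
  out
}

#' Random-sampling (RS) pseudo-absences
#'
#' For each presence, one pseudo-absence cell is drawn uniformly from the
#' cells within `radius_km` of that presence, excluding every presence cell
#' of the supplied table and any cell already used for the same (year,
#' month) within the set.  Each pseudo-absence inherits the (year, month) of
#' its presence so covariates come from matching layers.  `n_sets`
#' independent replicate sets are produced; cells may recur across sets.
#'
#' @param presences occurrence data.frame with `lon,lat,year,month,cell_id`
#'   (one model subset's presences).
#' @param stack an [env_stack()].
#' @param config a [sampler_config()].
#' @param variables variables whose no-data cells are excluded (default:
#'   all stack variables).
#' @return A `pseudo_absences` data.frame with columns
#'   `lon,lat,year,month,cell_id,set_id,method`; `nrow = n_sets *
#'   nrow(presences)`.
#' @export
sample_rs <- function(presences, stack, config = sampler_config(),
                      variables = NULL) {
  prep <- prepare_sampler(presences, stack, config, variables)
  set.seed(config$seed)
  sets <- list()
  for (s in seq_len(config$n_sets)) {
    used <- new.env(parent = emptyenv())
    rows <- vector("list", nrow(presences))
    for (i in seq_len(nrow(presences))) {
      ym <- paste(presences$year[i], presences$month[i])
      cand <- intersect(prep$elig[[i]], prep$valid(presences$year[i],
                                                   presences$month[i]))
      if (length(cand))
        cand <- cand[!vapply(paste0(cand, "_", ym), function(k)
          isTRUE(used[[k]]), logical(1))]
      if (!length(cand))
        stop(sprintf("presence %d: no eligible pseudo-absence cell (degenerate buffer?)", i))
      cid <- if (length(cand) == 1) cand else sample(cand, 1)
      used[[paste0(cid, "_", ym)]] <- TRUE
      rows[[i]] <- data.frame(
        lon = prep$cc$x[cid], lat = prep$cc$y[cid],
        year = presences$year[i], month = presences$month[i],
        cell_id = cid, set_id = s)
    }
    sets[[s]] <- do.call(rbind, rows)
  }
  new_pseudo_absence(sets, "RS")
}

prepare_sampler <- function(presences, stack, config, variables) {
  stop_if_missing_cols(presences, c("lon", "lat", "year", "month"),
                       "presences")
  if (!nrow(presences)) stop("no presences supplied")
  if (is.null(presences$cell_id))
    presences$cell_id <- cell_from_xy(stack, presences$lon, presences$lat)
  variables <- variables %||% stack$variables
  pres_cells <- unique(presences$cell_id)
  elig <- lapply(seq_len(nrow(presences)), function(i)
    cells_in_buffer(stack, presences$lon[i], presences$lat[i],
                    config$radius_km, exclude = pres_cells))
  pool <- unique(unlist(elig))
  if (length(pool) < 2 * nrow(presences))
    stop(sprintf("buffer union holds %d non-presence cells; need >= %d",
                 length(pool), 2 * nrow(presences)))
  list(presences = presences, elig = elig, pool = pool,
       valid = valid_cells_fun(stack, variables), cc = cell_centers(stack))
}

#' One-class environmental profile of presence points
#'
#' Trains a one-class SVM on the z-standardized presence covariates.  The
#' classifier's binary similarity follows the sign of the decision function:
#' similarity 1 for predicted inliers (presence-like environments),
#' similarity 0 for outliers (environmentally dissimilar).
#'
#' @param presence_covariates data.frame holding the covariate columns.
#' @param variables covariate names to use.
#' @inheritParams sampler_config
#' @return A `profile_classifier` object.
#' @export
profile_classifier <- function(presence_covariates, variables,
                               kernel = "radial", nu = 0.1, gamma = NULL) {
  x <- as.matrix(presence_covariates[, variables, drop = FALSE])
  if (anyNA(x)) stop("presence covariates contain missing values")
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  ## a degenerate (single-point) presence environment admits no boundary:
  ## everything is then presence-like and no candidate is ever dissimilar
  degenerate <- nrow(unique(z)) == 1
  fit <- if (!degenerate)
    e1071::svm(z, y = NULL, type = "one-classification",
               kernel = kernel, nu = nu,
               gamma = gamma %||% (1 / ncol(z)), scale = FALSE)
  structure(list(fit = fit, center = ctr, scale = scl,
                 variables = variables, degenerate = degenerate),
            class = "profile_classifier")
}

#' @rdname profile_classifier
#' @param object a `profile_classifier`.
#' @param newdata data.frame with the classifier's covariate columns.
#' @param ... unused.
#' @return `predict()`: data.frame with `inlier` (logical), `decision`
#'   (signed decision value) and `similarity` (1 for inliers, 0 for
#'   outliers).
#' @export
predict.profile_classifier <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$variables, drop = FALSE])
  z <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  if (isTRUE(object$degenerate))
    return(data.frame(inlier = TRUE, decision = 0,
                      similarity = 1)[rep(1, nrow(z)), , drop = FALSE])
  p <- predict(object$fit, z, decision.values = TRUE)
  dec <- as.numeric(attr(p, "decision.values"))
  data.frame(inlier = as.logical(p), decision = dec,
             similarity = as.numeric(as.logical(p)))
}

#' Environmentally profiled (RSEP) pseudo-absences
#'
#' For each presence, `candidates_per_presence` candidate cells are drawn
#' uniformly within `radius_km`; candidates are scored by a one-class SVM
#' trained on the presence environments and only candidates with similarity
#' 0 (classifier outliers) are kept.  One such candidate is selected per
#' presence; when none of a draw is dissimilar the candidates are redrawn up
#' to `max_resample_attempts` times before erroring, which signals a
#' landscape with no environmental contrast around that presence.
#'
#' @inheritParams sample_rs
#' @param variables covariates used for profiling (default: all stack
#'   variables).
#' @return A `pseudo_absences` data.frame (as [sample_rs()]), with the
#'   trained [profile_classifier()] attached as attribute `"classifier"`.
#' @export
sample_rsep <- function(presences, stack, variables = NULL,
                        config = sampler_config()) {
  variables <- variables %||% stack$variables
  prep <- prepare_sampler(presences, stack, config, variables)
  presences <- prep$presences
  pres_env <- extract_env(stack, presences, variables)
  clf <- profile_classifier(pres_env, variables,
                            kernel = config$kernel, nu = config$nu,
                            gamma = config$gamma)
  set.seed(config$seed)
  K <- config$candidates_per_presence
  sets <- list()
  for (s in seq_len(config$n_sets)) {
    used <- new.env(parent = emptyenv())
    rows <- vector("list", nrow(presences))
    for (i in seq_len(nrow(presences))) {
      yr <- presences$year[i]; mo <- presences$month[i]
      ym <- paste(yr, mo)
      base_cand <- intersect(prep$elig[[i]], prep$valid(yr, mo))
      picked <- NA_integer_
      for (att in seq_len(config$max_resample_attempts)) {
        cand <- if (length(base_cand) <= K) base_cand
                else sample(base_cand, K)
        if (!length(cand)) break
        cdf <- data.frame(lon = prep$cc$x[cand], lat = prep$cc$y[cand],
                          year = yr, month = mo, cell_id = cand)
        sc <- predict(clf, extract_env(stack, cdf, variables))
        ok <- cand[sc$similarity == 0]
        if (length(ok))
          ok <- ok[!vapply(paste0(ok, "_", ym), function(k)
            isTRUE(used[[k]]), logical(1))]
        if (length(ok)) {
          picked <- if (length(ok) == 1) ok else sample(ok, 1)
          break
        }
        if (length(base_cand) <= K) break  # candidates exhausted; retries identical
      }
      if (is.na(picked))
        stop(sprintf(
          "presence %d (year %d, month %d): no environmentally dissimilar candidate after %d round(s)",
          i, yr, mo, config$max_resample_attempts))
      used[[paste0(picked, "_", ym)]] <- TRUE
      rows[[i]] <- data.frame(
        lon = prep$cc$x[picked], lat = prep$cc$y[picked],
        year = yr, month = mo, cell_id = picked, set_id = s)
    }
    sets[[s]] <- do.call(rbind, rows)
  }
  out <- new_pseudo_absence(sets, "RSEP")
  attr(out, "classifier") <- clf
  out
}
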