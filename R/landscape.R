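#' Configuration for a synthetic monthly landscape
#'
#' Defines a planar-km grid with smooth seasonal climate fields.  Each
#' continuous variable is a sinusoid of month (peaking at `peak_month`) plus
#' a latitudinal (south-north) gradient, a variable-specific smooth spatial
#' field and i.i.d. noise.  Derived variables listed in
#' `collinearity_targets` are linear functions of their source layer plus
#' calibrated noise, so that the per-month sample correlation matches the
#' requested `target_r` (this engineers the collinear pairs a screening step
#' must detect, e.g. maximum vs minimum temperature and vapour-pressure
#' deficit vs evapotranspiration).  The host-crop cultivation layer `RFD` is
#' non-negative, strictly zero in months outside `crop_season`, and stored
#' for a single reference year.
#'
#' Defaults emulate a temperate study region roughly 600 km on a side at
#' monthly resolution over three years: minimum temperature peaking at
#' ~23 degC in the warm south in July and dipping below zero in the north in
#' winter, a 11 degC seasonal amplitude, and a May-October growing season.
#'
#' @param n_rows,n_cols grid dimensions (>= 10).
#' @param cell_size_km positive cell edge, km.
#' @param years integer vector of years (non-empty).
#' @param peak_month month (1-12) at which the seasonal sinusoid peaks.
#' @param var_params named list per base variable with entries `base`,
#'   `amplitude` (seasonal), `lat_gradient` (units per km, applied to the
#'   centred y coordinate), `field_amp` (amplitude of the variable-specific
#'   smooth spatial field) and `noise_sd`.
#' @param collinearity_targets list of lists with entries `derived`,
#'   `source`, `target_r` (in (0,1]), `offset`, `slope`.
#' @param crop_season integer months (subset of 1..12) with nonzero `RFD`.
#' @param rfd_base peak cultivation area per cell (arbitrary area units).
#' @param seed integer seed; identical configs give bit-identical stacks.
#' @return A `landscape_config` list.
#' @export
landscape_config <- function(n_rows = 60, n_cols = 60, cell_size_km = 10,
                             years = 2015:2017, peak_month = 7,
                             var_params = default_var_params(),
                             collinearity_targets = default_collinearity_targets(),
                             crop_season = 5:10,
                             rfd_base = 10,
                             seed = 1L) {
  stopifnot(n_rows >= 10, n_cols >= 10, cell_size_km > 0, length(years) >= 1,
            peak_month %in% 1:12, all(crop_season %in% 1:12))
  for (ct in collinearity_targets)
    stopifnot(ct$target_r > 0, ct$target_r <= 1)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size_km = cell_size_km, years = as.integer(years),
                 peak_month = peak_month, var_params = var_params,
                 collinearity_targets = collinearity_targets,
                 crop_season = as.integer(crop_season), rfd_base = rfd_base,
                 seed = as.integer(seed)),
            class = "landscape_config")
}

#' @rdname landscape_config
#' @export
default_var_params <- function() {
  list(
    MINTEMP = list(base = 12,  amplitude = 11, lat_gradient = -0.020,
                   field_amp = 5,  noise_sd = 0.8),
    PRECIPI = list(base = 80,  amplitude = 35, lat_gradient = 0.030,
                   field_amp = 40, noise_sd = 12),
    EVAPO   = list(base = 90,  amplitude = 45, lat_gradient = -0.050,
                   field_amp = 25, noise_sd = 8),
    NDVI    = list(base = 0.55, amplitude = 0.25, lat_gradient = -3e-4,
                   field_amp = 0.15, noise_sd = 0.04)
  )
}

#' @rdname landscape_config
#' @export
default_collinearity_targets <- function() {
  list(
    list(derived = "MAXTEMP", source = "MINTEMP", target_r = 0.9,
         offset = 8, slope = 1),
    list(derived = "VAPOR", source = "EVAPO", target_r = 0.9,
         offset = 200, slope = 8)
  )
}

#' Virtual species with a known seasonal niche
#'
#' Monthly occurrence probability is `plogis(eta)` with
#' `eta = intercept + sum_v beta2_v (x_v - opt_v)^2` for quadratic
#' (bell-shaped) responses, `beta2_v < 0` and optimum
#' `opt_v = -beta1_v / (2 beta2_v)`, plus `beta1_v x_v` for pure linear
#' terms.  `intercept` is therefore the log-odds of occurrence at the joint
#' optimum, and suitability falls off quadratically away from each
#' optimum.  An optional seasonal niche shift moves the optimum of selected
#' variables by `shift_delta` during `shift_months`, emulating phenotypic
#' plasticity between outbreak and non-outbreak periods.
#'
#' @param intercept real; `plogis(intercept)` is the suitability at the
#'   joint optimum.
#' @param coefs named list per variable of `c(linear, quadratic)` with
#'   quadratic < 0 (or a pure linear term as `c(linear, 0)`).
#' @param detection_rate in (0, 1]; multiplies suitability when sampling
#'   occurrences.
#' @param shift_months integer months in which the optima are shifted.
#' @param shift_delta named numeric: additive shift of the optimum of each
#'   named variable during `shift_months`.
#' @return A `virtual_species` object; `known_optima` holds the per-variable
#'   response optima (unshifted).
#' @export
virtual_species <- function(intercept = 2.5,
                            coefs = default_species_coefs(),
                            detection_rate = 1,
                            shift_months = integer(0),
                            shift_delta = numeric(0)) {
  stopifnot(detection_rate > 0, detection_rate <= 1)
  opt <- vapply(coefs, function(b) {
    if (b[2] < 0) -b[1] / (2 * b[2]) else NA_real_
  }, numeric(1))
  structure(list(intercept = intercept, coefs = coefs,
                 known_optima = opt, detection_rate = detection_rate,
                 shift_months = as.integer(shift_months),
                 shift_delta = shift_delta),
            class = "virtual_species")
}

#' @rdname virtual_species
#' @export
default_species_coefs <- function() {
  ## optima: MINTEMP 18 degC (sd 3.5), NDVI 0.75 (sd 0.18)
  list(
    MINTEMP = c(2 * 18 / (2 * 3.5^2), -1 / (2 * 3.5^2)),
    NDVI    = c(2 * 0.75 / (2 * 0.18^2), -1 / (2 * 0.18^2))
  )
}

## smooth unit-amplitude spatial field, deterministic given phases/freqs
smooth_field <- function(xn, yn, fx, fy, px, py) {
  outer(sin(2 * pi * fy * yn + py), sin(2 * pi * fx * xn + px))
}

#' Generate a synthetic monthly environmental stack
#'
#' @param config a [landscape_config()].
#' @return An [env_stack()] with one layer per (variable, year, month);
#'   base variables, derived collinear variables and a single-year `RFD`
#'   cultivation layer.  Identical configs (including seed) give
#'   bit-identical stacks.
#' @export
generate_env_stack <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  if (!length(config$years)) stop("empty years list")
  set.seed(config$seed)
  nr <- config$n_rows; nc <- config$n_cols
  xn <- (seq_len(nc) - 0.5) / nc           # normalized coords for fields
  yn <- (seq_len(nr) - 0.5) / nr
  ycen <- ((seq_len(nr) - 0.5) - nr / 2) * config$cell_size_km
  vars <- names(config$var_params)
  ## per-variable field geometry, fixed across months/years
  geo <- lapply(vars, function(v)
    list(fx = sample(1:2, 1), fy = sample(1:2, 1),
         px = runif(1, 0, 2 * pi), py = runif(1, 0, 2 * pi)))
  names(geo) <- vars
  layers <- list()
  for (yr in config$years) for (mo in 1:12) {
    seas <- cos(2 * pi * (mo - config$peak_month) / 12)
    for (v in vars) {
      p <- config$var_params[[v]]
      m <- p$base + p$amplitude * seas +
        matrix(p$lat_gradient * ycen, nr, nc) +
        p$field_amp * smooth_field(xn, yn, geo[[v]]$fx, geo[[v]]$fy,
                                   geo[[v]]$px, geo[[v]]$py) +
        matrix(rnorm(nr * nc, 0, p$noise_sd), nr, nc)
      if (v == "NDVI") m <- matrix(pmin(1, pmax(0, m)), nr, nc)
      layers[[layer_key(v, yr, mo)]] <- m
    }
    for (ct in config$collinearity_targets) {
      src <- layers[[layer_key(ct$source, yr, mo)]]
      sde <- abs(ct$slope) * sd(src) * sqrt(1 / ct$target_r^2 - 1)
      layers[[layer_key(ct$derived, yr, mo)]] <-
        ct$offset + ct$slope * src + matrix(rnorm(nr * nc, 0, sde), nr, nc)
    }
  }
  ## RFD: single reference year, zero outside the growing season
  rfd_year <- config$years[1]
  crop_pattern <- matrix(pmax(0, smooth_field(xn, yn, 1, 1, runif(1, 0, 2 * pi),
                                              runif(1, 0, 2 * pi)) +
                                matrix(rnorm(nr * nc, 0.3, 0.2), nr, nc)),
                         nr, nc)
  cs <- sort(config$crop_season)
  for (mo in 1:12) {
    w <- if (mo %in% cs)
      sin(pi * (match(mo, cs)) / (length(cs) + 1)) else 0
    layers[[layer_key("RFD", rfd_year, mo)]] <-
      config$rfd_base * w * crop_pattern
  }
  env_stack(layers, nr, nc, config$cell_size_km, crs = "planar_km",
            rfd_year = rfd_year)
}

#' Suitability of a virtual species over one monthly layer set
#'
#' @param species a [virtual_species()].
#' @param stack an [env_stack()].
#' @param year,month layer keys.
#' @return Matrix of occurrence probabilities in `[0, 1]`.
#' @export
species_suitability <- function(species, stack, year, month) {
  eta <- matrix(species$intercept, stack$grid$n_rows, stack$grid$n_cols)
  for (v in names(species$coefs)) {
    b <- species$coefs[[v]]
    x <- get_layer(stack, v, year, month)
    if (b[2] < 0) {
      opt <- -b[1] / (2 * b[2])
      if (month %in% species$shift_months &&
          v %in% names(species$shift_delta))
        opt <- opt + species$shift_delta[[v]]
      eta <- eta + b[2] * (x - opt)^2    # 0 at the optimum by construction
    } else {
      eta <- eta + b[1] * x
    }
  }
  plogis(eta)
}

#' Sample virtual-species occurrences from a stack
#'
#' For every (year, month), cells are drawn without replacement with
#' probability proportional to suitability times the detection rate, so at
#' most one record exists per (cell, month, year) by construction and
#' presences concentrate where the species' suitability is high.
#'
#' @param species a [virtual_species()].
#' @param stack an [env_stack()].
#' @param n_per_month single count or named vector / list keyed `"1"`..`"12"`
#'   giving the number of records per month for each year.
#' @param seed integer seed.
#' @param months months to sample (default 1..12).
#' @return Occurrence data.frame `lon, lat, year, month, cell_id` (cell
#'   centre coordinates).
#' @export
sample_occurrences <- function(species, stack, n_per_month, seed = 1L,
                               months = 1:12) {
  set.seed(seed)
  cc <- cell_centers(stack)
  out <- list()
  for (yr in stack$years) for (mo in months) {
    n <- if (length(n_per_month) == 1) n_per_month
         else (n_per_month[[as.character(mo)]] %||% 0)
    if (n == 0) next
    w <- as.vector(t(species_suitability(species, stack, yr, mo))) *
      species$detection_rate        # t(): row-major to match cell_id order
    w[is.na(w)] <- 0
    if (sum(w > 0) < n)
      stop(sprintf("month %d year %d: %d cells with nonzero suitability < %d requested",
                   mo, yr, sum(w > 0), n))
    cid <- sample(cc$cell_id, n, replace = FALSE, prob = w)
    out[[length(out) + 1]] <- data.frame(
      lon = cc$x[cid], lat = cc$y[cid], year = yr, month = mo, cell_id = cid)
  }
  if (!length(out))
    return(data.frame(lon = numeric(0), lat = numeric(0),
                      year = integer(0), month = integer(0),
                      cell_id = integer(0)))
  do.call(rbind, out)
}
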