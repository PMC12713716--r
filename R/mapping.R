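#' Predict a monthly habitat-suitability map
#'
#' Applies a fitted seasonal model cellwise to the layers of one
#' (month, year): inverse-logit of the linear predictor with the year
#' random intercept at zero.  No-data cells propagate as `NA`.
#'
#' @param model a `fitted_sdm`.
#' @param stack an [env_stack()].
#' @param month,year layer keys.
#' @return A `suitability_map`: list with `values` (matrix in `[0,1]`),
#'   `grid`, `month`, `provenance`.
#' @export
predict_map <- function(model, stack, month, year) {
  g <- stack$grid
  nd <- data.frame(row.names = seq_len(g$n_rows * g$n_cols))
  for (v in names(model$terms))
    nd[[v]] <- as.vector(get_layer(stack, v, year, month))
  eta <- if (length(model$terms)) predict(model, nd, type = "link")
         else rep(unname(model$coef_std["(Intercept)"]), nrow(nd))
  structure(list(values = matrix(plogis(eta), g$n_rows, g$n_cols),
                 grid = g, month = month,
                 provenance = list(years = year, n_models = 1)),
            class = "suitability_map")
}

#' Average suitability maps cellwise
#'
#' Arithmetic mean ignoring no-data; used to average monthly predictions
#' across years and across replicate sub-models.
#'
#' @param maps non-empty list of `suitability_map`s sharing grid and month.
#' @return A `suitability_map` whose provenance pools the inputs'.
#' @export
average_maps <- function(maps) {
  if (!length(maps)) stop("empty map list")
  mo <- unique(vapply(maps, `[[`, numeric(1), "month"))
  if (length(mo) > 1) stop("cannot average maps of different months")
  dims <- vapply(maps, function(m) dim(m$values), numeric(2))
  if (any(dims != dims[, 1])) stop("maps do not share a grid")
  vals <- lapply(maps, `[[`, "values")
  tot <- Reduce(`+`, lapply(vals, function(v) ifelse(is.na(v), 0, v)))
  cnt <- Reduce(`+`, lapply(vals, function(v) !is.na(v)))
  avg <- tot / cnt
  avg[cnt == 0] <- NA
  structure(list(values = avg, grid = maps[[1]]$grid, month = mo,
                 provenance = list(
                   years = sort(unique(unlist(lapply(maps, function(m)
                     m$provenance$years)))),
                   n_models = sum(vapply(maps, function(m)
                     m$provenance$n_models, numeric(1))))),
            class = "suitability_map")
}

#' Bin a suitability map into equal intervals
#'
#' Bin `i` (0-based) covers `[i/n, (i+1)/n)`; the top bin is closed at 1,
#' so `floor(n * v)` capped at `n - 1`.  Idempotent under re-binning of the
#' bin midpoints.
#'
#' @param map a `suitability_map`.
#' @param n_bins number of equal intervals spanning 0..1 (default 10).
#' @return List with integer matrix `bins` (`NA` passthrough), `n_bins`,
#'   `month`.
#' @export
classify_map <- function(map, n_bins = 10) {
  b <- pmin(floor(map$values * n_bins), n_bins - 1)
  structure(list(bins = b, n_bins = n_bins, month = map$month,
                 grid = map$grid),
            class = "classified_map")
}

#' Minimum convex polygon of monthly presences
#'
#' @param points occurrence data.frame with `lon`, `lat` (and `month` when
#'   `month` is given).
#' @param month optional month filter.
#' @return Matrix of hull vertices (columns `lon`, `lat`) in
#'   counter-clockwise order, class `mcp`.  Errors for fewer than 3
#'   distinct points or a collinear point set.
#' @export
min_convex_polygon <- function(points, month = NULL) {
  if (!is.null(month)) points <- points[points$month %in% month, ,
                                        drop = FALSE]
  xy <- unique(cbind(points$lon, points$lat))
  if (nrow(xy) < 3) stop("need at least 3 distinct points")
  h <- chull(xy[, 1], xy[, 2])   # clockwise
  v <- xy[rev(h), , drop = FALSE]
  area2 <- sum(v[, 1] * v[c(2:nrow(v), 1), 2] -
                 v[c(2:nrow(v), 1), 1] * v[, 2])
  if (abs(area2) < 1e-12) stop("points are collinear; hull is degenerate")
  colnames(v) <- c("lon", "lat")
  structure(v, class = c("mcp", class(v)))
}

#' Response-curve optimum of one variable
#'
#' Partial-dependence peak with the other covariates fixed at their
#' training means.  For a concave quadratic the peak is the parabola vertex
#' `-b1 / (2 b2)` back-transformed to the data scale; otherwise (linear-only
#' term, convex quadratic, or vertex outside `value_range`) the maximizing
#' endpoint of the range is returned with the boundary flag set.
#'
#' @param model a `fitted_sdm`.
#' @param variable a variable retained in the model.
#' @param value_range numeric length-2 evaluation range (default: the
#'   variable's training range).
#' @return List with `optimum`, `boundary` (logical), `variable`.
#' @export
response_optimum <- function(model, variable, value_range = NULL) {
  if (!variable %in% names(model$terms))
    stop(sprintf("variable %s not retained in model", variable))
  value_range <- sort(value_range %||% model$ranges[[variable]])
  m <- model$scaling$center[[variable]]
  s <- model$scaling$scale[[variable]]
  b1 <- unname(model$coef_std[variable])
  b2 <- if (model$terms[[variable]] == "quadratic")
    unname(model$coef_std[paste0(variable, "^2")]) else 0
  if (b2 < 0) {
    x_star <- m + s * (-b1 / (2 * b2))
    if (x_star >= value_range[1] && x_star <= value_range[2])
      return(list(optimum = x_star, boundary = FALSE, variable = variable))
  }
  ## maximizing endpoint of the (possibly monotone) curve
  eta_end <- vapply(value_range, function(x) {
    z <- (x - m) / s
    b1 * z + b2 * z^2
  }, numeric(1))
  list(optimum = value_range[which.max(eta_end)], boundary = TRUE,
       variable = variable)
}

#' OEA / TEA / PEA optima summary
#'
#' For each variable and season bin compares three quantities: OEA, the
#' mean of per-model response-curve optima over the sub-models retaining
#' the variable (`NA` when no model retains it); TEA, the regional mean of
#' the variable over all no-data-free cells of the bin's months across
#' years; and PEA, the mean value extracted at that bin's presence points.
#' Boundary optima are flagged and still averaged into OEA.
#'
#' @param design an `sdm_design` from [run_design()].
#' @param stack an [env_stack()].
#' @param presences full-year occurrence table.
#' @param method which pseudo-absence method's models to summarize.
#' @param variables variables to summarize (default: the design's).
#' @return data.frame `variable, period, OEA, TEA, PEA, n_models,
#'   boundary_fraction`.
#' @export
optima_summary <- function(design, stack, presences, method = "RSEP",
                           variables = NULL) {
  variables <- variables %||% design$variables
  bins <- design$season_bins
  rows <- list()
  for (bin in names(bins)) {
    months <- bins[[bin]]
    fits <- Filter(function(x) x$method == method && x$subset == bin,
                   design$models)
    pres_bin <- presences[presences$month %in% months, , drop = FALSE]
    pres_env <- if (nrow(pres_bin))
      extract_env(stack, pres_bin, variables) else NULL
    for (v in variables) {
      ## landscape range and regional mean over the bin's layers
      vals <- unlist(lapply(stack$years, function(yr)
        lapply(months, function(mo)
          as.vector(get_layer(stack, v, yr, mo)))))
      vrange <- range(vals, na.rm = TRUE)
      keep <- Filter(function(x) v %in% names(x$fit$terms), fits)
      opts <- lapply(keep, function(x)
        response_optimum(x$fit, v, value_range = vrange))
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, period = bin,
        OEA = if (length(opts)) mean(vapply(opts, `[[`, numeric(1),
                                            "optimum")) else NA_real_,
        TEA = mean(vals, na.rm = TRUE),
        PEA = if (!is.null(pres_env)) mean(pres_env[[v]]) else NA_real_,
        n_models = length(opts),
        boundary_fraction = if (length(opts))
          mean(vapply(opts, `[[`, logical(1), "boundary")) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a suitability or classified map as a CSV matrix
#'
#' @param map a `suitability_map` or `classified_map`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_map_csv <- function(map, path) {
  m <- if (inherits(map, "classified_map")) map$bins else map$values
  write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
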