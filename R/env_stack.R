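#' Gridded monthly environmental stack
#'
#' An `env_stack` holds one 2-D layer per (variable, year, month) on a shared
#' regular grid.  Coordinates are planar kilometres (`crs = "planar_km"`,
#' synthetic landscapes) or geographic degrees (`crs = "geographic"`); the
#' choice only switches the distance function used by buffer operations.
#' Host-crop cultivation layers (`RFD`) may be stored for a single reference
#' year and are transparently reused for every other year, mirroring
#' cultivation datasets that provide a single multi-year average.
#'
#' Grid convention: cell (row r, col c) has centre
#' `x = origin[1] + (c - 0.5) * cell_size`, `y = origin[2] + (r - 0.5) *
#' cell_size`; `cell_id = (r - 1) * n_cols + c`.  Cells are half-open: a
#' point on a boundary belongs to the cell to its lower-left.
#' `NA` cells are no-data (sea, out-of-region) and are excluded from
#' screening, prediction and regional averages.
#'
#' @param layers named list of numeric matrices (`n_rows x n_cols`), named
#'   `"{VAR}_{YYYY}_{MM}"` (see [layer_key()]).
#' @param n_rows,n_cols grid dimensions (each >= 1).
#' @param cell_size cell edge length (km in planar mode, degrees in
#'   geographic mode).
#' @param origin numeric length-2, coordinates of the grid's lower-left
#'   corner.
#' @param crs `"planar_km"` or `"geographic"`.
#' @param rfd_year optional integer: the single year for which `RFD` layers
#'   are stored; lookups for other years fall back to it.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(layers, n_rows, n_cols, cell_size, origin = c(0, 0),
                      crs = c("planar_km", "geographic"), rfd_year = NULL) {
  crs <- match.arg(crs)
  stopifnot(is.list(layers), length(layers) > 0, n_rows >= 1, n_cols >= 1,
            cell_size > 0, length(origin) == 2)
  for (nm in names(layers)) {
    m <- layers[[nm]]
    if (!is.matrix(m) || nrow(m) != n_rows || ncol(m) != n_cols)
      stop(sprintf("layer %s does not match the %dx%d grid", nm, n_rows, n_cols))
  }
  keys <- do.call(rbind, lapply(names(layers), parse_layer_key))
  structure(list(
    layers = layers,
    grid = list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                cell_size = cell_size, origin = as.numeric(origin), crs = crs),
    variables = sort(unique(keys$variable)),
    years = sort(unique(keys$year)),
    months = sort(unique(keys$month)),
    rfd_year = rfd_year
  ), class = "env_stack")
}

#' @exportS3Method base::print
print.env_stack <- function(x, ...) {
  g <- x$grid
  cat(sprintf("env_stack: %d x %d cells (%g %s), %d layers\n",
              g$n_rows, g$n_cols, g$cell_size,
              if (g$crs == "planar_km") "km" else "deg", length(x$layers)))
  cat("  variables:", paste(x$variables, collapse = ", "), "\n")
  cat("  years:", paste(x$years, collapse = ", "),
      " months:", paste(x$months, collapse = ","), "\n")
  invisible(x)
}

#' Layer naming for (variable, year, month) keys
#'
#' @param variable character variable name.
#' @param year,month integers.
#' @return `"{VAR}_{YYYY}_{MM}"` key string.
#' @export
layer_key <- function(variable, year, month) {
  sprintf("%s_%04d_%02d", variable, as.integer(year), as.integer(month))
}

parse_layer_key <- function(key) {
  parts <- strsplit(key, "_")[[1]]
  n <- length(parts)
  data.frame(variable = paste(parts[seq_len(n - 2)], collapse = "_"),
             year = as.integer(parts[n - 1]), month = as.integer(parts[n]))
}

#' Fetch one layer, with RFD single-year fallback
#'
#' @param stack an [env_stack()].
#' @inheritParams layer_key
#' @return The layer matrix.
#' @export
get_layer <- function(stack, variable, year, month) {
  key <- layer_key(variable, year, month)
  m <- stack$layers[[key]]
  if (is.null(m) && identical(variable, "RFD") && !is.null(stack$rfd_year))
    m <- stack$layers[[layer_key(variable, stack$rfd_year, month)]]
  if (is.null(m))
    stop(sprintf("missing layer: variable %s, year %d, month %d",
                 variable, year, month), call. = FALSE)
  m
}

#' Cell centres of the stack grid
#'
#' @param stack an [env_stack()] (or its `$grid`).
#' @return data.frame with `cell_id`, `x`, `y` for all cells, row-major by
#'   cell_id.
#' @export
cell_centers <- function(stack) {
  g <- if (inherits(stack, "env_stack")) stack$grid else stack
  r <- rep(seq_len(g$n_rows), each = g$n_cols)
  c <- rep(seq_len(g$n_cols), times = g$n_rows)
  data.frame(cell_id = (r - 1L) * g$n_cols + c,
             x = g$origin[1] + (c - 0.5) * g$cell_size,
             y = g$origin[2] + (r - 0.5) * g$cell_size)
}

#' Locate the cell containing each point
#'
#' Cells are half-open; boundary points belong to the lower-left cell.
#' Points outside the grid extent get `NA`.
#'
#' @param stack an [env_stack()] (or its `$grid`).
#' @param x,y point coordinates (same units as the grid).
#' @return Integer vector of cell ids (`NA` outside the extent).
#' @export
cell_from_xy <- function(stack, x, y) {
  g <- if (inherits(stack, "env_stack")) stack$grid else stack
  cc <- floor((x - g$origin[1]) / g$cell_size) + 1L
  rr <- floor((y - g$origin[2]) / g$cell_size) + 1L
  ok <- cc >= 1L & cc <= g$n_cols & rr >= 1L & rr <= g$n_rows
  out <- rep(NA_integer_, length(x))
  out[ok] <- (rr[ok] - 1L) * g$n_cols + cc[ok]
  out
}

cell_rc <- function(g, cell_id) {
  r <- (cell_id - 1L) %/% g$n_cols + 1L
  c <- (cell_id - 1L) %% g$n_cols + 1L
  cbind(r, c)
}

#' Pairwise point-to-point distance in km
#'
#' Euclidean in planar mode, haversine great-circle in geographic mode
#' (coordinates then interpreted as lon/lat degrees).
#'
#' @param crs `"planar_km"` or `"geographic"`.
#' @param x1,y1 coordinates of the reference point (scalars).
#' @param x2,y2 coordinate vectors.
#' @return Numeric vector of distances in km.
#' @export
point_distance_km <- function(crs, x1, y1, x2, y2) {
  if (crs == "planar_km") {
    sqrt((x2 - x1)^2 + (y2 - y1)^2)
  } else {
    geosphere::distHaversine(c(x1, y1), cbind(x2, y2)) / 1000
  }
}

#' Rescale all layers of a stack to a new cell size
#'
#' Integer aggregation uses block means (block sums for `RFD` when
#' `rfd_rule = "sum"`, conserving areal totals).  Non-integer ratios and
#' disaggregation use bilinear interpolation at the new cell centres for
#' continuous variables; `RFD` is then interpolated like the others under
#' `rfd_rule = "mean"` and refused under `"sum"` (a non-integer block sum is
#' not area-conserving).
#'
#' @param stack an [env_stack()].
#' @param target_cell_size new cell edge length (same units as the grid).
#' @param rfd_rule `"mean"` or `"sum"`: aggregation rule for `RFD` layers.
#' @return A new [env_stack()] on the target grid.
#' @export
rescale_stack <- function(stack, target_cell_size, rfd_rule = c("mean", "sum")) {
  rfd_rule <- match.arg(rfd_rule)
  g <- stack$grid
  if (!length(stack$layers)) stop("empty stack")
  if (target_cell_size == g$cell_size) return(stack)
  f <- target_cell_size / g$cell_size
  int_agg <- f > 1 && abs(f - round(f)) < 1e-9 &&
    g$n_rows %% round(f) == 0 && g$n_cols %% round(f) == 0
  if (!int_agg && rfd_rule == "sum" && any(grepl("^RFD_", names(stack$layers))))
    stop("rfd_rule = \"sum\" requires an integer aggregation factor")
  new_layers <- lapply(stack$layers, function(m) NULL)
  if (int_agg) {
    f <- as.integer(round(f))
    nr <- g$n_rows %/% f; nc <- g$n_cols %/% f
    block <- function(m, fun) {
      rgrp <- (seq_len(g$n_rows) - 1L) %/% f + 1L
      cgrp <- (seq_len(g$n_cols) - 1L) %/% f + 1L
      t(rowsum(t(rowsum(m, rgrp, na.rm = FALSE)), cgrp, na.rm = FALSE)) /
        if (fun == "mean") f^2 else 1
    }
    for (nm in names(stack$layers)) {
      is_rfd <- grepl("^RFD_", nm)
      fun <- if (is_rfd && rfd_rule == "sum") "sum" else "mean"
      m <- block(stack$layers[[nm]], fun)
      dimnames(m) <- NULL
      new_layers[[nm]] <- m
    }
  } else {
    nr <- max(1L, floor(g$n_rows * g$cell_size / target_cell_size))
    nc <- max(1L, floor(g$n_cols * g$cell_size / target_cell_size))
    newc <- g$origin[1] + (seq_len(nc) - 0.5) * target_cell_size
    newr <- g$origin[2] + (seq_len(nr) - 0.5) * target_cell_size
    oldc <- g$origin[1] + (seq_len(g$n_cols) - 0.5) * g$cell_size
    oldr <- g$origin[2] + (seq_len(g$n_rows) - 0.5) * g$cell_size
    for (nm in names(stack$layers))
      new_layers[[nm]] <- bilinear_resample(stack$layers[[nm]], oldr, oldc,
                                            newr, newc)
  }
  env_stack(new_layers, nr, nc, target_cell_size, g$origin, g$crs,
            rfd_year = stack$rfd_year)
}

## bilinear interpolation of matrix m (rows indexed by ys, cols by xs)
## at the outer grid (new_ys x new_xs); clamped at the edges
bilinear_resample <- function(m, ys, xs, new_ys, new_xs) {
  ix <- findInterval(new_xs, xs, all.inside = TRUE)
  iy <- findInterval(new_ys, ys, all.inside = TRUE)
  wx <- pmin(1, pmax(0, (new_xs - xs[ix]) / (xs[ix + 1] - xs[ix])))
  wy <- pmin(1, pmax(0, (new_ys - ys[iy]) / (ys[iy + 1] - ys[iy])))
  a <- m[iy, ix, drop = FALSE] * outer(1 - wy, 1 - wx) +
    m[iy + 1, ix, drop = FALSE] * outer(wy, 1 - wx) +
    m[iy, ix + 1, drop = FALSE] * outer(1 - wy, wx) +
    m[iy + 1, ix + 1, drop = FALSE] * outer(wy, wx)
  a
}

#' Extract environmental values at occurrence points
#'
#' Each point takes the value of the cell containing it, from the layer
#' matching its own `(year, month)`; `RFD` falls back to the stack's single
#' replicated cultivation year.
#'
#' @param stack an [env_stack()].
#' @param points data.frame with `lon`, `lat`, `year`, `month`.
#' @param variables character vector of variables to extract (default: all
#'   stack variables).
#' @return `points` with one extra numeric column per variable.
#' @export
extract_env <- function(stack, points, variables = NULL) {
  variables <- variables %||% stack$variables
  stop_if_missing_cols(points, c("lon", "lat", "year", "month"), "points")
  cid <- points$cell_id %||% cell_from_xy(stack, points$lon, points$lat)
  if (anyNA(cid)) stop("point(s) outside the grid extent")
  out <- points
  g <- stack$grid
  rc <- cell_rc(g, cid)
  idx <- cbind(rc[, 1], rc[, 2])
  for (v in variables) out[[v]] <- NA_real_
  for (grp in split(seq_len(nrow(points)),
                    paste(points$year, points$month))) {
    yr <- points$year[grp[1]]; mo <- points$month[grp[1]]
    for (v in variables) {
      lay <- get_layer(stack, v, yr, mo)
      out[[v]][grp] <- lay[idx[grp, , drop = FALSE]]
    }
  }
  out
}

#' Write / read an environmental stack as plain text
#'
#' One CSV matrix per layer (`{VAR}_{YYYY}_{MM}.csv`, no headers) plus a
#' `grid.json` header describing the grid, under `dir`.
#'
#' @param stack an [env_stack()].
#' @param dir directory (created if needed).
#' @return `write_env_stack`: invisibly, the vector of files written;
#'   `read_env_stack`: an [env_stack()].
#' @export
write_env_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- stack$grid
  jsonlite::write_json(
    list(n_rows = g$n_rows, n_cols = g$n_cols, cell_size = g$cell_size,
         origin = g$origin, crs = g$crs, rfd_year = stack$rfd_year),
    file.path(dir, "grid.json"), auto_unbox = TRUE, digits = NA)
  files <- "grid.json"
  for (nm in names(stack$layers)) {
    f <- paste0(nm, ".csv")
    write.table(stack$layers[[nm]], file.path(dir, f), sep = ",",
                row.names = FALSE, col.names = FALSE)
    files <- c(files, f)
  }
  invisible(file.path(dir, files))
}

#' @rdname write_env_stack
#' @export
read_env_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "grid.json"), simplifyVector = TRUE)
  files <- setdiff(list.files(dir, pattern = "\\.csv$"), "grid.json")
  layers <- lapply(files, function(f)
    as.matrix(read.csv(file.path(dir, f), header = FALSE)))
  names(layers) <- sub("\\.csv$", "", files)
  layers <- lapply(layers, function(m) { dimnames(m) <- NULL; m })
  env_stack(layers, meta$n_rows, meta$n_cols, meta$cell_size, meta$origin,
            meta$crs, rfd_year = meta$rfd_year)
}
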