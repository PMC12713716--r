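#' Pooled background environment within presence buffers
#'
#' For every presence a closed buffer of `radius_km` is drawn; the
#' environmental values of all buffer cells are taken from the layers
#' matching that presence's own (year, month) and pooled across all years.
#' Cells reached by several presences of the same (year, month) are counted
#' once; the same cell may recur under different (year, month) keys, which
#' is what "pooling across years" means for monthly layers.
#'
#' @param presences occurrence table (`lon,lat,year,month`).
#' @param stack an [env_stack()].
#' @param radius_km buffer radius (closed ball), default 500.
#' @param variables covariates to extract.
#' @return data.frame `cell_id, year, month, lon, lat, <vars>`.
#' @export
buffer_background <- function(presences, stack, radius_km = 500,
                              variables = NULL) {
  variables <- variables %||% stack$variables
  if (!nrow(presences)) stop("presences are empty")
  cc <- cell_centers(stack)
  out <- list()
  for (grp in split(seq_len(nrow(presences)),
                    paste(presences$year, presences$month))) {
    yr <- presences$year[grp[1]]; mo <- presences$month[grp[1]]
    in_union <- rep(FALSE, nrow(cc))
    for (i in grp) {
      d <- point_distance_km(stack$grid$crs, presences$lon[i],
                             presences$lat[i], cc$x, cc$y)
      in_union <- in_union | d <= radius_km
    }
    cid <- cc$cell_id[in_union]
    if (!length(cid)) stop("empty buffer")
    df <- data.frame(cell_id = cid, year = yr, month = mo,
                     lon = cc$x[cid], lat = cc$y[cid])
    df <- extract_env(stack, df, variables)
    df <- df[complete.cases(df[, variables, drop = FALSE]), , drop = FALSE]
    out[[length(out) + 1]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-axis PCA environment space
#'
#' Principal component analysis of the pooled (all periods) background
#' covariates on the correlation scale; the first two axes define the
#' niche-analysis plane.  Constant variables are dropped with a warning.
#'
#' @param background covariate data.frame (see [buffer_background()]).
#' @param variables covariates to use (default: all covariate columns).
#' @return A `niche_space`: `rotation` (p x 2), `center`, `scale`,
#'   `explained` (variance fractions, all axes), `variables`.
#' @export
fit_niche_space <- function(background, variables = NULL) {
  variables <- variables %||% covariate_names(background)
  x <- as.matrix(background[, variables, drop = FALSE])
  if (nrow(x) < 3) stop("need >= 3 background rows")
  const <- apply(x, 2, function(v) sd(v) == 0)
  if (any(const)) {
    warning(sprintf("dropping constant variable(s): %s",
                    paste(variables[const], collapse = ", ")))
    variables <- variables[!const]
    x <- x[, !const, drop = FALSE]
  }
  if (ncol(x) < 2) stop("need >= 2 non-constant variables")
  p <- prcomp(x, center = TRUE, scale. = TRUE)
  structure(list(rotation = p$rotation[, 1:2, drop = FALSE],
                 center = p$center, scale = p$scale,
                 sdev = p$sdev,
                 explained = p$sdev^2 / sum(p$sdev^2),
                 variables = variables),
            class = "niche_space")
}

#' Project covariate rows onto the niche space
#'
#' @param space a `niche_space`.
#' @param data data.frame with the space's covariate columns.
#' @return n x 2 matrix of scores (axes PC1, PC2).
#' @export
niche_scores <- function(space, data) {
  x <- as.matrix(data[, space$variables, drop = FALSE])
  z <- sweep(sweep(x, 2, space$center), 2, space$scale, "/")
  z %*% space$rotation
}

#' Kernel density grid of occurrences and background in niche space
#'
#' Gaussian kernel densities of the occurrence scores and of the background
#' scores on an `R x R` grid spanning the pooled background score ranges.
#' The occurrence density is normalized to integrate to 1 over the window.
#' Bandwidths default to the normal-reference (Silverman-type) rule on the
#' background scores.  Scores outside the window are clipped onto it with a
#' warning.
#'
#' @param scores occurrence scores (n x 2, see [niche_scores()]), n >= 2.
#' @param background_scores background scores defining the window and the
#'   availability density.
#' @param R grid resolution per axis (default 100).
#' @param h optional bandwidth pair (passed to [MASS::kde2d()]).
#' @param lims optional window `c(xmin, xmax, ymin, ymax)`.
#' @return A `niche_grid`: `x`, `y` (axis node vectors), `z` (occurrence
#'   density, integrates to 1), `zbg` (background density), `h`, `n_occ`.
#' @export
density_grid <- function(scores, background_scores, R = 100, h = NULL,
                         lims = NULL) {
  if (nrow(scores) < 2) stop("need >= 2 occurrence points")
  lims <- lims %||% c(range(background_scores[, 1]),
                      range(background_scores[, 2]))
  if (any(scores[, 1] < lims[1] - 1e-12) || any(scores[, 1] > lims[2] + 1e-12) ||
      any(scores[, 2] < lims[3] - 1e-12) || any(scores[, 2] > lims[4] + 1e-12)) {
    warning("occurrence scores outside the background window were clipped")
    scores[, 1] <- pmin(pmax(scores[, 1], lims[1]), lims[2])
    scores[, 2] <- pmin(pmax(scores[, 2], lims[3]), lims[4])
  }
  nrd_safe <- function(v) {
    b <- MASS::bandwidth.nrd(v)
    if (!is.finite(b) || b <= 0) b <- diff(range(v)) / 10 + 1e-8
    b
  }
  h <- h %||% c(nrd_safe(background_scores[, 1]),
                nrd_safe(background_scores[, 2]))
  kz <- MASS::kde2d(scores[, 1], scores[, 2], h = h, n = R, lims = lims)
  kb <- MASS::kde2d(background_scores[, 1], background_scores[, 2], h = h,
                    n = R, lims = lims)
  cell_area <- diff(kz$x[1:2]) * diff(kz$y[1:2])
  z <- kz$z / (sum(kz$z) * cell_area)
  structure(list(x = kz$x, y = kz$y, z = z, zbg = kb$z, h = h,
                 n_occ = nrow(scores)),
            class = "niche_grid")
}

grid_density <- function(g) if (inherits(g, "niche_grid")) g$z else g
grid_background <- function(g) {
  if (inherits(g, "niche_grid")) g$zbg
  else matrix(1, nrow(g), ncol(g))   # plain matrix: analog everywhere
}

## binarize occupied niche: smallest density threshold keeping
## (1 - quantile) of the density mass inside the mask
occupied_cells <- function(z, mask, quantile) {
  zm <- z
  zm[!mask] <- 0
  if (quantile <= 0) return(zm > 0 & mask)
  o <- sort(zm[zm > 0], decreasing = TRUE)
  if (!length(o)) return(matrix(FALSE, nrow(z), ncol(z)))
  cs <- cumsum(o)
  t <- o[which(cs >= (1 - quantile) * cs[length(o)])[1]]
  zm >= t & mask
}

#' Niche stability / expansion / unfilling indices
#'
#' Within the analog environment (cells where both periods' background
#' densities are positive), each period's occupied niche is binarized by
#' dropping the thinnest `occupancy_quantile` of its occurrence-density
#' mass.  With the reference period's occupied cell set A (by convention
#' the non-outbreak months) and the comparison period's set B (outbreak
#' months):
#' `stability = |A n B| / |A|`, `expansion = |A \ B| / |A|` (so stability +
#' expansion = 1 exactly), and `unfilled = |B \ A| / |B|`.
#'
#' @param grid_ref,grid_comp `niche_grid`s on a shared space (or plain
#'   density matrices, then taken as analog everywhere).
#' @param occupancy_quantile density-mass fraction dropped when binarizing
#'   (default 0.05; 0 keeps every positive-density cell).
#' @param analog_threshold background density, as a fraction of each grid's
#'   maximum, below which a cell is non-analog (default 1e-3).
#' @return List with `stability`, `expansion`, `unfilled` (all in `[0,1]`)
#'   and the logical matrices `occupied_ref`, `occupied_comp`, `mask`.
#' @export
niche_dynamics <- function(grid_ref, grid_comp, occupancy_quantile = 0.05,
                           analog_threshold = 1e-3) {
  z1 <- grid_density(grid_ref); z2 <- grid_density(grid_comp)
  if (!all(dim(z1) == dim(z2))) stop("grids do not share a resolution")
  b1 <- grid_background(grid_ref); b2 <- grid_background(grid_comp)
  mask <- (b1 > analog_threshold * max(b1)) &
    (b2 > analog_threshold * max(b2))
  occ1 <- occupied_cells(z1, mask, occupancy_quantile)
  occ2 <- occupied_cells(z2, mask, occupancy_quantile)
  n1 <- sum(occ1); n2 <- sum(occ2)
  if (n1 == 0 || n2 == 0) stop("a period's occupied niche is empty")
  overlap <- sum(occ1 & occ2)
  list(stability = overlap / n1,
       expansion = (n1 - overlap) / n1,
       unfilled = (n2 - overlap) / n2,
       occupied_ref = occ1, occupied_comp = occ2, mask = mask)
}

#' Availability and occupancy curves along one variable
#'
#' One-dimensional Gaussian kernel densities of the background
#' (availability) and of the presences (occupancy) along a single
#' environmental axis, per period, each rescaled to a maximum of 1 on a
#' common evaluation grid; plus the occupied segments unique to each period
#' and shared.
#'
#' @param presence_tab presence covariate table with `month` and the
#'   variable column.
#' @param background_tab background covariate table (same columns).
#' @param variable variable name.
#' @param periods named list of month vectors (default: outbreak = June to
#'   September vs non-outbreak = remaining months).
#' @param n_grid evaluation points.
#' @param occupancy_cut fraction of the occupancy maximum above which a
#'   grid node counts as occupied when classifying segments (default 0.05).
#' @return data.frame `variable, period, x, availability, occupancy` with a
#'   `segments` attribute (`x`, `status` in shared / reference-only /
#'   comparison-only / none; the first listed period is the reference).
#' @export
variable_occupancy <- function(presence_tab, background_tab, variable,
                               periods = list(non_outbreak = c(1:5, 10:12),
                                              outbreak = 6:9),
                               n_grid = 512, occupancy_cut = 0.05) {
  stopifnot(length(periods) == 2)
  all_bg <- background_tab[[variable]]
  xr <- range(all_bg, presence_tab[[variable]])
  if (diff(xr) == 0) stop("degenerate density: constant variable values")
  rows <- list(); occ_curves <- list()
  for (p in names(periods)) {
    pv <- presence_tab[[variable]][presence_tab$month %in% periods[[p]]]
    bv <- background_tab[[variable]][background_tab$month %in% periods[[p]]]
    if (length(pv) < 2 || length(bv) < 2)
      stop(sprintf("period %s has < 2 values", p))
    if (sd(pv) == 0 || sd(bv) == 0)
      stop("degenerate density: constant variable values")
    da <- density(bv, from = xr[1], to = xr[2], n = n_grid)
    do <- density(pv, from = xr[1], to = xr[2], n = n_grid)
    rows[[p]] <- data.frame(variable = variable, period = p, x = da$x,
                            availability = da$y / max(da$y),
                            occupancy = do$y / max(do$y))
    occ_curves[[p]] <- rows[[p]]$occupancy
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  o1 <- occ_curves[[1]] >= occupancy_cut
  o2 <- occ_curves[[2]] >= occupancy_cut
  attr(out, "segments") <- data.frame(
    x = rows[[1]]$x,
    status = ifelse(o1 & o2, "shared",
                    ifelse(o1, paste0(names(periods)[1], "_only"),
                           ifelse(o2, paste0(names(periods)[2], "_only"),
                                  "none"))))
  out
}
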