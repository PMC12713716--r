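#' Season bins used for per-season models
#'
#' Data-poor months are merged: December-February form a winter bin and
#' March-May a spring bin; June through November are modelled individually,
#' giving eight bins in total.
#'
#' @return Named list of integer month vectors.
#' @export
default_season_bins <- function() {
  list(winter = c(12L, 1L, 2L), spring = 3:5,
       June = 6L, July = 7L, August = 8L, September = 9L,
       October = 10L, November = 11L)
}

#' Configuration for the seasonal collinearity screen
#'
#' @param r_threshold absolute Pearson correlation above which a pair is
#'   considered collinear (default 0.8).
#' @param drop_priority ordered character vector of variables preferred for
#'   removal when a pair exceeds the threshold.  The default drops the
#'   vapour-pressure and maximum-temperature layers first, reflecting which
#'   covariates are less established in armyworm distribution modelling;
#'   the rule is not algorithmic, so it is an explicit, user-editable list.
#' @param season_bins named list of month vectors (see
#'   [default_season_bins()]); bins must be disjoint.
#' @return A `screen_config` list.
#' @export
screen_config <- function(r_threshold = 0.8,
                          drop_priority = c("VAPOR", "MAXTEMP"),
                          season_bins = default_season_bins()) {
  stopifnot(r_threshold > 0, r_threshold <= 1)
  all_months <- unlist(season_bins)
  if (anyDuplicated(all_months)) stop("season bins must be disjoint")
  structure(list(r_threshold = r_threshold, drop_priority = drop_priority,
                 season_bins = season_bins),
            class = "screen_config")
}

## Pearson matrix of the covariate columns of one dataset;
## constant columns yield r = 0 with a warning
cor_matrix_safe <- function(df, variables) {
  x <- as.matrix(df[, variables, drop = FALSE])
  const <- apply(x, 2, function(v) sd(v, na.rm = TRUE) == 0 || all(is.na(v)))
  if (any(const))
    warning(sprintf("constant column(s) %s: correlation treated as 0",
                    paste(variables[const], collapse = ", ")), call. = FALSE)
  r <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  diag(r) <- 1
  r
}

#' Seasonal Pearson collinearity screen
#'
#' Computes a Pearson correlation matrix for every replicate covariate
#' dataset, averages the matrices within each season bin (arithmetic mean of
#' coefficients), and iteratively removes variables until no pair has an
#' averaged `|r| >= r_threshold` in any bin.  From each offending pair the
#' variable earlier in `drop_priority` is removed; if neither is listed, the
#' variable with the larger mean absolute correlation against all others is
#' removed (alphabetical tie-break), so the outcome does not depend on the
#' input column order.
#'
#' @param datasets named list keyed by season bin; each element is one
#'   covariate data.frame or a list of replicate covariate data.frames.
#' @param config a [screen_config()].
#' @param variables variables to screen (default: all covariate columns of
#'   the first dataset).
#' @return List with `retained` (character), `dropped` (data.frame of
#'   variable, partner, r, bin), and `matrices` (one averaged Pearson matrix
#'   per season bin, full variable set).
#' @export
pearson_screen <- function(datasets, config = screen_config(),
                           variables = NULL) {
  stopifnot(inherits(config, "screen_config"), length(datasets) >= 1)
  datasets <- lapply(datasets, function(d) if (is.data.frame(d)) list(d) else d)
  variables <- sort(variables %||% covariate_names(datasets[[1]][[1]]))
  for (bin in names(datasets)) for (d in datasets[[bin]]) {
    stop_if_missing_cols(d, variables, sprintf("dataset in bin %s", bin))
    if (nrow(d) < 2) stop(sprintf("bin %s: dataset has < 2 rows", bin))
  }
  matrices <- lapply(datasets, function(reps) {
    ms <- lapply(reps, cor_matrix_safe, variables = variables)
    Reduce(`+`, ms) / length(ms)
  })
  retained <- variables
  dropped <- data.frame(variable = character(0), partner = character(0),
                        r = numeric(0), bin = character(0))
  repeat {
    worst <- NULL
    for (bin in names(matrices)) {
      m <- abs(matrices[[bin]][retained, retained, drop = FALSE])
      diag(m) <- 0
      if (!length(m) || max(m) < config$r_threshold) next
      ij <- which(m == max(m), arr.ind = TRUE)[1, ]
      if (is.null(worst) || m[ij[1], ij[2]] > worst$r)
        worst <- list(pair = c(rownames(m)[ij[1]], colnames(m)[ij[2]]),
                      r = m[ij[1], ij[2]], bin = bin)
    }
    if (is.null(worst)) break
    pr <- match(worst$pair, config$drop_priority)
    drop_var <- if (all(is.na(pr))) {
      msum <- vapply(worst$pair, function(v) {
        mm <- abs(matrices[[worst$bin]][v, retained])
        mean(mm[names(mm) != v])
      }, numeric(1))
      sorted <- worst$pair[order(-msum, worst$pair)]
      sorted[1]
    } else {
      worst$pair[which.min(replace(pr, is.na(pr), Inf))]
    }
    dropped <- rbind(dropped, data.frame(
      variable = drop_var, partner = setdiff(worst$pair, drop_var)[1],
      r = worst$r, bin = worst$bin))
    retained <- setdiff(retained, drop_var)
  }
  list(retained = retained, dropped = dropped, matrices = matrices)
}
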