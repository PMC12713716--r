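`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage random seed from a master seed
#'
#' Stage seeds are a deterministic function of the master seed and the stage
#' name, so individual pipeline stages can be rerun in isolation while the
#' whole run remains reproducible from a single integer.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return An integer seed in `[0, 2^31)`.
#' @export
stage_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(master) * 7919 + h * 131) %% .Machine$integer.max)
}

## meta columns never treated as environmental covariates
.meta_cols <- c("lon", "lat", "year", "month", "cell_id", "label",
                "set_id", "method")

covariate_names <- function(df) setdiff(names(df), .meta_cols)

stop_if_missing_cols <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}
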