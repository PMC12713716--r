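#' Thin occurrence records to one per cell, month and year
#'
#' Mirrors the standard SDM thinning rule for gridded monthly data: at most
#' one record is kept per (grid cell, month, year) key; the first record is
#' retained on ties.  Records outside the grid extent are dropped with a
#' message stating how many.
#'
#' @param raw data.frame with `lon`, `lat`, `year`, `month`.
#' @param stack an [env_stack()] (or its `$grid`) defining the cells.
#' @return Thinned occurrence data.frame with a `cell_id` column.
#' @export
thin_occurrences <- function(raw, stack) {
  stop_if_missing_cols(raw, c("lon", "lat", "year", "month"), "occurrences")
  cid <- cell_from_xy(stack, raw$lon, raw$lat)
  n_out <- sum(is.na(cid))
  if (n_out > 0)
    message(sprintf("thin_occurrences: dropped %d record(s) outside the grid extent",
                    n_out))
  keep <- !is.na(cid)
  out <- raw[keep, , drop = FALSE]
  out$cell_id <- cid[keep]
  key <- paste(out$cell_id, out$year, out$month)
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write occurrence tables as CSV
#'
#' CSV with header `lon,lat,year,month` (plus any extra columns present).
#'
#' @param path file path.
#' @param occ occurrence data.frame.
#' @return `read_occurrences`: the data.frame; `write_occurrences`:
#'   invisibly, `path`.
#' @export
read_occurrences <- function(path) {
  occ <- read.csv(path)
  stop_if_missing_cols(occ, c("lon", "lat", "year", "month"), path)
  occ
}

#' @rdname read_occurrences
#' @export
write_occurrences <- function(occ, path) {
  write.csv(occ, path, row.names = FALSE)
  invisible(path)
}
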