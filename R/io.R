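# Plain-text interchange: observation and fertilization logs.

obs_csv_columns <- c(date = "date", clipping_yield = "clipping_gm2_d",
                     ndre = "ndre", soil_moisture = "soil_moisture_pct",
                     traffic = "traffic_rounds_wk", quality = "quality")

#' Read or write an observation CSV
#'
#' Columns: `date,clipping_gm2_d,ndre,soil_moisture_pct,traffic_rounds_wk,quality`
#' (ISO dates, header required). Internally the columns are named
#' `date, clipping_yield, ndre, soil_moisture, traffic, quality`.
#'
#' @param path file path.
#' @param observations observation data.frame (for writing).
#' @return `read_observations_csv` returns a data.frame;
#'   `write_observations_csv` returns `path` invisibly.
#' @export
read_observations_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(unname(obs_csv_columns), names(x))
  if (length(missing))
    stop("observation CSV is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- x[unname(obs_csv_columns)]
  names(out) <- names(obs_csv_columns)
  out$date <- as.Date(out$date)
  out
}

#' @rdname read_observations_csv
#' @export
write_observations_csv <- function(observations, path) {
  out <- observations[names(obs_csv_columns)]
  names(out) <- unname(obs_csv_columns)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read or write a fertilization log CSV
#'
#' Columns: `date,dose_kg_ha,strategy,branch` plus the branch's diagnostic
#' input (`input_value`: mean GP, window-mean NDRE or predicted yield).
#'
#' @param path file path.
#' @param fert_log fertilization data.frame (for writing).
#' @return `read_fert_csv` returns a data.frame; `write_fert_csv` returns
#'   `path` invisibly.
#' @export
read_fert_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "dose_kg_ha", "strategy", "branch")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("fertilization CSV is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  x$date <- as.Date(x$date)
  x
}

#' @rdname read_fert_csv
#' @export
write_fert_csv <- function(fert_log, path) {
  utils::write.csv(fert_log, path, row.names = FALSE)
  invisible(path)
}
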