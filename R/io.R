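#' Read and write plate-reader kinetic tables
#'
#' The plate CSV dialect has columns `time_s`, `temperature_C`,
#' `substrate_mM`, `replicate`, `absorbance_mOD`, `is_blank`; one row per
#' reading.
#'
#' @param path file path.
#' @return `read_plate_csv()` returns a tibble of traces.
#' @export
read_plate_csv <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE,
                         show_col_types = FALSE)
  required <- c("time_s", "temperature_C", "substrate_mM", "replicate",
                "absorbance_mOD", "is_blank")
  missing <- setdiff(required, names(out))
  if (length(missing) > 0) {
    abort(sprintf("Plate CSV is missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "dopatherm_schema_error")
  }
  for (col in setdiff(required, c("replicate", "is_blank"))) {
    out[[col]] <- as.numeric(out[[col]])
  }
  out$replicate <- as.integer(out$replicate)
  out$is_blank <- as.logical(out$is_blank)
  out
}

#' @param traces a tibble of absorbance traces.
#' @rdname read_plate_csv
#' @export
write_plate_csv <- function(traces, path) {
  readr::write_csv(traces, path)
  invisible(path)
}

#' Write a docking-run table as TSV
#'
#' @param runs a docking-run tibble (see [simulate_docking_table()]).
#' @param path file path.
#' @export
write_docking_tsv <- function(runs, path) {
  readr::write_tsv(runs, path)
  invisible(path)
}
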