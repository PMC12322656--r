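# Delimited-text I/O for the package's two table dialects, with key-value
# sidecar metadata for provenance (preset, seed, noise).

curve_cols <- c("time_min", "UMP_mM", "Ura_mM", "Rib5P_mM", "PsiMP_mM")

#' Write a progress curve as CSV
#'
#' Header `time_min,UMP_mM,Ura_mM,Rib5P_mM,PsiMP_mM`. A key-value sidecar
#' (`<path>.meta.txt`) records provenance when `metadata` is given.
#'
#' @param curve A [progress_curve()] or compatible data frame.
#' @param path Output CSV path.
#' @param metadata Optional named list written as `key: value` lines.
#' @return `path`, invisibly.
#' @export
write_progress_curve <- function(curve, path, metadata = NULL) {
  df <- as_tibble(curve)[, intersect(curve_cols, names(curve))]
  readr::write_csv(df, path)
  write_metadata(metadata, path)
  invisible(path)
}

#' Read a progress curve CSV
#'
#' Missing species columns are permitted and filled with `NA`.
#'
#' @param path CSV path.
#' @return A [progress_curve()]; `ump0` is taken from the first `UMP_mM`
#'   value.
#' @export
read_progress_curve <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"time_min" %in% names(df)) abort("missing `time_min` column")
  for (col in setdiff(curve_cols, names(df))) df[[col]] <- NA_real_
  progress_curve(df$time_min, df$UMP_mM, df$Ura_mM, df$Rib5P_mM, df$PsiMP_mM,
                 ump0 = df$UMP_mM[1],
                 kind = if (any(df$PsiMP_mM > 0, na.rm = TRUE)) "cascade"
                        else "hydrolysis")
}

#' Write an initial-rate dataset as CSV
#'
#' Header `S_mM,I_mM,rate_mM_per_min`, plus an optional key-value sidecar.
#'
#' @param data A tibble as produced by [gen_initial_rates()].
#' @inheritParams write_progress_curve
#' @return `path`, invisibly.
#' @export
write_initial_rates <- function(data, path, metadata = NULL) {
  readr::write_csv(as_tibble(data)[, c("S_mM", "I_mM", "rate_mM_per_min")],
                   path)
  write_metadata(metadata, path)
  invisible(path)
}

#' Read an initial-rate CSV
#'
#' @param path CSV path with columns `S_mM`, `I_mM` (optional),
#'   `rate_mM_per_min`.
#' @return A validated tibble ready for the fitters.
#' @export
read_initial_rates <- function(path) {
  check_rate_data(readr::read_csv(path, show_col_types = FALSE))
}

write_metadata <- function(metadata, data_path) {
  if (is.null(metadata)) return(invisible(NULL))
  lines <- vapply(names(metadata),
                  function(k) paste0(k, ": ", format(metadata[[k]])),
                  character(1))
  writeLines(lines, paste0(data_path, ".meta.txt"))
  invisible(NULL)
}
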