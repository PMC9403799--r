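#' Read a tri-axial sensor trace from CSV
#'
#' Reads `time` plus three channel columns, with configurable column names
#' (e.g. vendor exports naming the dorsoventral channel "heave"). Timestamps
#' must be strictly increasing; violations are reported with their row
#' number.
#'
#' @param path CSV file path.
#' @param columns Named character vector mapping the canonical names
#'   `time`, `x`, `y`, `z` to the column names in the file.
#' @param nominal_rate Optional nominal sampling rate (Hz) to attach.
#' @param units Unit label to attach ("g" for acceleration).
#' @return A `triax_trace` data frame.
#' @export
read_trace <- function(path,
                       columns = c(time = "time", x = "x", y = "y", z = "z"),
                       nominal_rate = NA_real_, units = "") {
  stopifnot(all(c("time", "x", "y", "z") %in% names(columns)))
  raw <- read.csv(path, check.names = FALSE)
  missing <- setdiff(unname(columns), names(raw))
  if (length(missing)) {
    stop("missing columns in ", path, ": ", paste(missing, collapse = ", "))
  }
  vals <- lapply(columns, function(cn) raw[[cn]])
  bad <- which(!vapply(vals, is.numeric, logical(1)))
  if (length(bad)) {
    stop("non-numeric column(s) in ", path, ": ",
         paste(columns[bad], collapse = ", "))
  }
  t <- vals$time
  nonmono <- which(diff(t) <= 0)
  if (length(nonmono)) {
    stop("timestamps not strictly increasing in ", path, " at row ",
         nonmono[1] + 1L, " (time ", t[nonmono[1] + 1L], ")")
  }
  new_trace(t, vals$x, vals$y, vals$z, nominal_rate, units,
            c(x = "surge", y = "sway", z = "heave"))
}

#' Write a tri-axial trace to CSV
#'
#' @param trace A `triax_trace` (or data frame with `time`, `x`, `y`, `z`).
#' @param path Output CSV path.
#' @param columns Column names to write, in the order time, x, y, z.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path,
                        columns = c("time", "x", "y", "z")) {
  out <- data.frame(trace$time, trace$x, trace$y, trace$z)
  names(out) <- columns
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file path.
#' @return A list suitable for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = FALSE)
}
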