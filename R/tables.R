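# Plain-text tabular input: two-column (T, rho) density tables and
# multi-column time series. Comment lines starting with #, @ or ; are
# tolerated (covers the GROMACS xvg dialect); fields may be whitespace- or
# comma-separated.

.read_numeric_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^\\s*[#@;]", lines)]
  if (!length(lines)) .stopf("no data rows in '%s'", path)
  rows <- strsplit(trimws(lines), "[,[:space:]]+")
  ncol <- length(rows[[1]])
  bad <- which(vapply(rows, length, 0L) != ncol)
  if (length(bad)) .stopf("ragged table in '%s' (row %d has %d fields, expected %d)",
                          path, bad[1], length(rows[[bad[1]]]), ncol)
  m <- matrix(as.numeric(unlist(rows)), ncol = ncol, byrow = TRUE)
  if (any(is.na(m))) .stopf("non-numeric field in '%s'", path)
  m
}

#' Read a density-temperature table
#'
#' Two or three columns: temperature (K), density (kg/m^3) and optionally
#' a density uncertainty. Comment lines (#, @, ;) and commas are accepted.
#'
#' @param path Input file.
#' @return `data.frame` with columns `T`, `rho` (and `sigma` if present).
#' @export
read_density_series <- function(path) {
  m <- .read_numeric_table(path)
  if (ncol(m) < 2L) .stopf("density series needs at least 2 columns (T, rho)")
  out <- data.frame(T = m[, 1], rho = m[, 2])
  if (ncol(m) >= 3L) out$sigma <- m[, 3]
  out
}

#' Read a multi-column time series table
#'
#' First column is time; remaining columns keep their order, named from
#' `col_names` when supplied.
#'
#' @param path Input file.
#' @param col_names Optional names for the value columns.
#' @return `data.frame` with a `time` column plus value columns.
#' @export
read_time_series <- function(path, col_names = NULL) {
  m <- .read_numeric_table(path)
  if (ncol(m) < 2L) .stopf("time series needs at least 2 columns")
  out <- as.data.frame(m)
  nm <- c("time", if (is.null(col_names)) paste0("V", seq_len(ncol(m) - 1L)) else col_names)
  if (length(nm) != ncol(m)) .stopf("col_names length does not match the table")
  names(out) <- nm
  out
}
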