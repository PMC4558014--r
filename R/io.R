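#' Write a grid as an ESRI ASCII raster
#'
#' Plain-text single-band format: a 6-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of
#' values top row first. Matrix row 1 is the southernmost row, so rows
#' are written in reverse order.
#'
#' @param grid `ny x nx` numeric matrix.
#' @param file Output path.
#' @param cell_size Cell size (km, written as-is).
#' @param xll,yll Lower-left corner coordinates.
#' @param nodata NODATA sentinel written for `NA` cells.
#' @export
write_ascii_grid <- function(grid, file, cell_size = 10, xll = 0, yll = 0,
                             nodata = -9999) {
  stopifnot(is.matrix(grid))
  g <- grid
  g[is.na(g)] <- nodata
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(g)),
               sprintf("nrows %d", nrow(g)),
               sprintf("xllcorner %g", xll),
               sprintf("yllcorner %g", yll),
               sprintf("cellsize %g", cell_size),
               sprintf("NODATA_value %g", nodata)), con)
  for (i in rev(seq_len(nrow(g))))
    writeLines(paste(format(g[i, ], trim = TRUE, digits = 10),
                     collapse = " "), con)
  invisible(file)
}

#' Read an ESRI ASCII raster
#'
#' @param file Path written by [write_ascii_grid()] (or any conforming
#'   ASCII grid).
#' @return `ny x nx` matrix (row 1 southernmost) with attributes
#'   `cell_size`, `xll`, `yll`; NODATA cells are `NA`.
#' @export
read_ascii_grid <- function(file) {
  lines <- readLines(file)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows")
  if (!all(need %in% names(hdr)))
    stop_climsens("malformed ASCII grid header in %s", file)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = " "),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # back to row 1 = south
  nodata <- hdr[["nodata_value"]]
  if (!is.null(nodata)) m[m == nodata] <- NA
  attr(m, "cell_size") <- hdr[["cellsize"]]
  attr(m, "xll") <- hdr[["xllcorner"]]
  attr(m, "yll") <- hdr[["yllcorner"]]
  m
}

#' Write and read occurrence tables
#'
#' CSV with the canonical columns `site_id, x, y, year, season,
#' species_id, presence, effort_hours, ordinal_date` (the inapplicable
#' survey covariate is empty).
#'
#' @param occurrences Occurrence data.frame.
#' @param file Path.
#' @export
write_occurrences <- function(occurrences, file) {
  cols <- c("site_id", "x", "y", "year", "season", "species_id", "presence",
            "effort_hours", "ordinal_date")
  missing <- setdiff(cols, names(occurrences))
  if (length(missing))
    stop_climsens("occurrence table lacks column(s): %s",
                  paste(missing, collapse = ", "))
  utils::write.csv(occurrences[, cols], file, row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname write_occurrences
#' @return `read_occurrences` returns the occurrence data.frame.
#' @export
read_occurrences <- function(file) {
  occ <- utils::read.csv(file, stringsAsFactors = FALSE)
  cols <- c("site_id", "x", "y", "year", "season", "species_id", "presence",
            "effort_hours", "ordinal_date")
  missing <- setdiff(cols, names(occ))
  if (length(missing))
    stop_climsens("occurrence file lacks column(s): %s",
                  paste(missing, collapse = ", "))
  occ
}
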