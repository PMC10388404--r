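#' Read and write rasters as Esri ASCII grids
#'
#' Single-layer grids round-trip through the plain-text Esri ASCII grid
#' format (`ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header
#' followed by rows from the top). Values are written with full double
#' precision so a write/read cycle preserves them exactly. Multi-layer
#' stacks are written as one file per layer with a `_b<i>` suffix.
#'
#' @param path File path (`.asc`).
#' @return `read_grid` returns a single-layer [grid()]; `write_grid`
#'   invisibly returns the path(s) written.
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("cannot read grid: no such file: ", path)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an Esri ASCII grid (missing header fields): ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  n_hdr <- 5L + !is.null(hdr$nodata_value)
  vals <- scan(path, skip = n_hdr, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("grid body does not match header dimensions: ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  grid(m, pixel_size = hdr$cellsize, xll = hdr$xllcorner, yll = hdr$yllcorner)
}

#' @rdname read_grid
#' @param g A [grid()] to write.
#' @param nodata Sentinel written for `NA` cells.
#' @export
write_grid <- function(g, path, nodata = -9999) {
  stopifnot(is_grid(g))
  if (n_layers(g) > 1L) {
    stem <- sub("\\.asc$", "", path)
    paths <- character(n_layers(g))
    for (i in seq_len(n_layers(g))) {
      li <- grid(g$values[, , i], g$pixel_size, g$xll, g$yll)
      paths[i] <- write_grid(li, sprintf("%s_b%d.asc", stem, i), nodata)
    }
    return(invisible(paths))
  }
  m <- g$values
  if (any(m == nodata, na.rm = TRUE))
    stop("grid contains the nodata sentinel ", nodata, " as a real value")
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)), paste("nrows", nrow(m)),
    paste("xllcorner", format(g$xll, digits = 17)),
    paste("yllcorner", format(g$yll, digits = 17)),
    paste("cellsize", format(g$pixel_size, digits = 17)),
    paste("NODATA_value", nodata)), con)
  for (r in seq_len(nrow(m)))
    writeLines(paste(format(m[r, ], digits = 17, trim = TRUE,
                            scientific = FALSE), collapse = " "), con)
  invisible(path)
}

#' Read and write class maps
#'
#' A class map is stored as an ASCII grid of integer codes plus a legend
#' CSV (`<stem>_legend.csv`, columns `code,name`) alongside it.
#'
#' @param path `.asc` path for the code raster.
#' @export
read_classmap <- function(path) {
  g <- read_grid(path)
  leg_path <- paste0(sub("\\.asc$", "", path), "_legend.csv")
  if (!file.exists(leg_path)) stop("missing legend file: ", leg_path)
  legend <- utils::read.csv(leg_path, stringsAsFactors = FALSE)
  codes <- g$values
  storage.mode(codes) <- "integer"
  classmap(codes, legend, g$pixel_size, g$xll, g$yll)
}

#' @rdname read_classmap
#' @param cm A [classmap()] to write.
#' @export
write_classmap <- function(cm, path) {
  stopifnot(is_classmap(cm))
  write_grid(grid(cm$codes + 0, cm$pixel_size, cm$xll, cm$yll), path)
  utils::write.csv(cm$legend,
                   paste0(sub("\\.asc$", "", path), "_legend.csv"),
                   row.names = FALSE)
  invisible(path)
}
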