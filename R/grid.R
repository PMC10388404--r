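#' Numeric raster grid
#'
#' A `grid` is the package's raster container: a numeric matrix (rows from the
#' top, columns from the left) with a pixel size in metres and a lower-left
#' origin. Missing cells are `NA` (nodata). Multi-layer stacks are 3-D arrays
#' (`row x col x layer`); see [grid_stack()].
#'
#' @param values Numeric matrix (single layer) or 3-D array (stack).
#' @param pixel_size Edge length of a square pixel in metres; must be > 0.
#' @param xll,yll Coordinates of the lower-left corner of the extent (metres).
#' @return An object of class `grid`.
#' @examples
#' g <- grid(matrix(1:12, 3, 4), pixel_size = 25)
#' g
#' @export
grid <- function(values, pixel_size = 1, xll = 0, yll = 0) {
  if (!is.numeric(values) && !is.logical(values))
    stop("grid values must be numeric")
  if (is.logical(values)) values <- values + 0
  if (!(length(dim(values)) %in% c(2L, 3L)))
    stop("grid values must be a matrix or a 3-D array")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number")
  structure(
    list(values = values, pixel_size = as.numeric(pixel_size),
         xll = as.numeric(xll), yll = as.numeric(yll)),
    class = "grid")
}

#' @export
print.grid <- function(x, ...) {
  d <- dim(x$values)
  nl <- if (length(d) == 3L) d[3L] else 1L
  v <- x$values
  cat(sprintf("<grid> %d x %d px, %d layer%s, pixel %g m\n",
              d[1L], d[2L], nl, if (nl > 1L) "s" else "", x$pixel_size))
  cat(sprintf("  values: [%g, %g], nodata: %d px\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' @rdname grid
#' @param g Object to test.
#' @export
is_grid <- function(g) inherits(g, "grid")

#' Stack single-layer grids into a multi-layer grid
#'
#' @param ... Single-layer `grid` objects sharing shape, pixel size and origin.
#' @return A `grid` whose values form a `row x col x layer` array.
#' @export
grid_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1L]]) && !is_grid(layers[[1L]]))
    layers <- layers[[1L]]
  stopifnot(length(layers) >= 1L, all(vapply(layers, is_grid, TRUE)))
  ref <- layers[[1L]]
  for (l in layers) check_aligned(ref, l)
  arr <- array(NA_real_, c(dim(ref$values)[1:2], length(layers)))
  for (i in seq_along(layers)) arr[, , i] <- layers[[i]]$values
  grid(arr, ref$pixel_size, ref$xll, ref$yll)
}

#' Number of layers in a grid
#' @param g A `grid`.
#' @export
n_layers <- function(g) {
  stopifnot(is_grid(g))
  d <- dim(g$values)
  if (length(d) == 3L) d[3L] else 1L
}

# aligned = same 2-D shape, pixel size and origin; layer counts may differ
check_aligned <- function(a, b) {
  stopifnot(is_grid(a), is_grid(b))
  if (!identical(dim(a$values)[1:2], dim(b$values)[1:2]))
    stop("grids are misaligned: shapes differ (",
         paste(dim(a$values)[1:2], collapse = "x"), " vs ",
         paste(dim(b$values)[1:2], collapse = "x"), ")")
  if (a$pixel_size != b$pixel_size)
    stop("grids are misaligned: pixel sizes differ")
  if (a$xll != b$xll || a$yll != b$yll)
    stop("grids are misaligned: origins differ")
  invisible(TRUE)
}

#' Categorical land-cover map
#'
#' A `classmap` holds integer class codes on a raster lattice plus a legend
#' mapping codes to class names. `NA` codes are nodata.
#'
#' @param codes Integer matrix of class codes (`NA` = nodata).
#' @param legend Data frame with columns `code` (integer) and `name`
#'   (character); every non-`NA` code must appear in it.
#' @param pixel_size Pixel edge length in metres.
#' @param xll,yll Lower-left corner of the extent.
#' @return An object of class `classmap`.
#' @examples
#' leg <- data.frame(code = 1:2, name = c("water", "mangrove"))
#' cm <- classmap(matrix(c(1L, 2L, 2L, 1L), 2), leg, pixel_size = 25)
#' @export
classmap <- function(codes, legend, pixel_size = 1, xll = 0, yll = 0) {
  if (!is.matrix(codes)) stop("codes must be a matrix")
  storage.mode(codes) <- "integer"
  if (!is.data.frame(legend) || !all(c("code", "name") %in% names(legend)))
    stop("legend must be a data frame with columns 'code' and 'name'")
  legend$code <- as.integer(legend$code)
  legend$name <- as.character(legend$name)
  if (anyDuplicated(legend$code)) stop("legend codes must be unique")
  seen <- unique(codes[!is.na(codes)])
  bad <- setdiff(seen, legend$code)
  if (length(bad))
    stop("class codes not in legend: ", paste(bad, collapse = ", "))
  structure(
    list(codes = codes, legend = legend[, c("code", "name")],
         pixel_size = as.numeric(pixel_size),
         xll = as.numeric(xll), yll = as.numeric(yll)),
    class = "classmap")
}

#' @rdname classmap
#' @param x Object to test.
#' @export
is_classmap <- function(x) inherits(x, "classmap")

#' @export
print.classmap <- function(x, ...) {
  d <- dim(x$codes)
  cat(sprintf("<classmap> %d x %d px, pixel %g m\n", d[1L], d[2L],
              x$pixel_size))
  tab <- table(factor(x$codes, levels = x$legend$code))
  for (i in seq_len(nrow(x$legend)))
    cat(sprintf("  %d %-18s %d px\n", x$legend$code[i], x$legend$name[i],
                tab[[i]]))
  invisible(x)
}

# classmap -> binary grid (1 where codes == code, 0 elsewhere, NA preserved)
class_mask <- function(cm, code) {
  stopifnot(is_classmap(cm))
  m <- (cm$codes == code) + 0
  grid(m, cm$pixel_size, cm$xll, cm$yll)
}
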