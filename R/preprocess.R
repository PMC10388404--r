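#' Calibrate SAR digital numbers to backscatter in decibels
#'
#' Converts digital numbers to the gamma-naught backscatter coefficient,
#' `gamma0 = 10 * log10(DN^2) + CF`, the standard calibration for L-band
#' PALSAR amplitude products. Zero digital numbers have no defined
#' backscatter and become nodata. The calibration factor defaults to
#' -83 dB, the usual PALSAR convention; it is configurable because product
#' generations differ.
#'
#' @param dn A [grid()] of nonnegative digital numbers.
#' @param cf Calibration factor in dB (signed, finite).
#' @return A [grid()] of backscatter in dB.
#' @examples
#' g <- grid(matrix(c(1, 1000, 0), 1))
#' dn_to_gamma0(g, cf = -83)$values   # -83, -23, NA
#' @export
dn_to_gamma0 <- function(dn, cf = -83) {
  stopifnot(is_grid(dn))
  if (!is.finite(cf)) stop("calibration factor must be finite")
  v <- dn$values
  n_neg <- sum(v < 0, na.rm = TRUE)
  if (n_neg > 0)
    stop("digital numbers must be nonnegative (", n_neg, " negative pixels)")
  out <- 10 * log10(v^2) + cf
  out[!is.na(v) & v == 0] <- NA_real_
  grid(out, dn$pixel_size, dn$xll, dn$yll)
}

#' Normalized difference vegetation index
#'
#' `NDVI = (NIR - Red) / (NIR + Red)`, bounded in \[-1, 1\] for nonnegative
#' reflectances. Pixels where both bands are zero are nodata.
#'
#' @param nir,red Same-shape [grid()]s of reflectance.
#' @return A [grid()] of NDVI values.
#' @export
ndvi <- function(nir, red) {
  check_aligned(nir, red)
  s <- nir$values + red$values
  out <- (nir$values - red$values) / s
  out[!is.na(s) & s == 0] <- NA_real_
  grid(out, nir$pixel_size, nir$xll, nir$yll)
}

#' Focal-median speckle filter
#'
#' Replaces each pixel by the median of the odd-sized window centred on it,
#' the robust choice for multiplicative SAR speckle: it removes isolated
#' impulses, is idempotent on constant fields and preserves edges better
#' than a mean filter. Nodata cells are ignored in each window; a pixel
#' whose window is entirely nodata stays nodata.
#'
#' @param g A [grid()] (single layer).
#' @param window Odd window edge length in pixels, at least 3.
#' @return A filtered [grid()] with the same shape.
#' @export
speckle_filter <- function(g, window = 3) {
  stopifnot(is_grid(g), n_layers(g) == 1L)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3")
  r <- (window - 1L) %/% 2L
  v <- g$values
  nr <- nrow(v); nc <- ncol(v)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    ri <- max(1L, i - r):min(nr, i + r)
    for (j in seq_len(nc)) {
      w <- v[ri, max(1L, j - r):min(nc, j + r)]
      out[i, j] <- stats::median(w, na.rm = TRUE)
    }
  }
  out[is.nan(out)] <- NA_real_
  grid(out, g$pixel_size, g$xll, g$yll)
}

#' Mask a grid
#'
#' Keeps values where the mask is 1 and sets nodata elsewhere — the generic
#' form of cloud-shadow or extent masking.
#'
#' @param g A [grid()].
#' @param mask A same-shape binary [grid()] (values 0/1; `NA` treated as 0).
#' @return A [grid()] with masked-out pixels set to nodata.
#' @export
apply_mask <- function(g, mask) {
  check_aligned(g, mask)
  mv <- mask$values
  if (!all(mv %in% c(0, 1) | is.na(mv)))
    stop("mask must be binary (0/1)")
  keep <- !is.na(mv) & mv == 1
  v <- g$values
  if (length(dim(v)) == 3L) {
    for (b in seq_len(dim(v)[3L])) {
      layer <- v[, , b]
      layer[!keep] <- NA_real_
      v[, , b] <- layer
    }
  } else {
    v[!keep] <- NA_real_
  }
  grid(v, g$pixel_size, g$xll, g$yll)
}
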