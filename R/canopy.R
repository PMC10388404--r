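#' Height and biomass model parameters
#'
#' Parameters of the DEM-based mangrove structure model. Over a closed
#' canopy an SRTM-class DEM reads a height between the ground and the
#' canopy top (near Lorey's height); maximum canopy height is recovered by
#' the empirical factor 1.697, and the basal-area-weighted height entering
#' the biomass allometry is about 1.08 times the DEM value. Aboveground
#' biomass density follows the height power law `B = 3.25 * Hba^1.53`
#' (Mg/ha), fitted to pantropical field plots.
#'
#' @param hmax_factor DEM-to-maximum-height factor (unitless, > 0).
#' @param hba_factor DEM-to-basal-area-weighted-height factor (> 0).
#' @param agb_scale Biomass scale coefficient in Mg/ha (> 0).
#' @param agb_exponent Biomass height exponent (> 0).
#' @param height_floor Heights below this (m) are clamped to 0 before the
#'   power law.
#' @return A list of class `height_model_params`.
#' @export
height_model_params <- function(hmax_factor = 1.697, hba_factor = 1.08,
                                agb_scale = 3.25, agb_exponent = 1.53,
                                height_floor = 0) {
  p <- list(hmax_factor = hmax_factor, hba_factor = hba_factor,
            agb_scale = agb_scale, agb_exponent = agb_exponent,
            height_floor = height_floor)
  if (any(unlist(p[1:4]) <= 0)) stop("model factors must be positive")
  structure(p, class = "height_model_params")
}

#' Maximum canopy height from a DEM
#'
#' `Hmax = hmax_factor * H_dem` inside the mangrove extent, nodata outside.
#'
#' @param dem A [grid()] of DEM heights (m).
#' @param mask Binary [grid()] of the mangrove extent, aligned with `dem`.
#' @param p A [height_model_params()].
#' @return A [grid()] of maximum canopy height in metres.
#' @examples
#' dem <- grid(matrix(10, 2, 2)); msk <- grid(matrix(1, 2, 2))
#' canopy_height_max(dem, msk)$values[1]   # 16.97
#' @export
canopy_height_max <- function(dem, mask, p = height_model_params()) {
  check_aligned(dem, mask)
  masked <- apply_mask(dem, mask)
  grid(p$hmax_factor * masked$values, dem$pixel_size, dem$xll, dem$yll)
}

#' Basal-area-weighted height from a DEM
#'
#' `Hba = hba_factor * H_dem` (applied to the original DEM reading, the
#' height scale the biomass allometry was fitted on), masked to the
#' mangrove extent.
#'
#' @inheritParams canopy_height_max
#' @return A [grid()] of basal-area-weighted height in metres.
#' @export
basal_area_weighted_height <- function(dem, mask, p = height_model_params()) {
  check_aligned(dem, mask)
  masked <- apply_mask(dem, mask)
  grid(p$hba_factor * masked$values, dem$pixel_size, dem$xll, dem$yll)
}

#' Aboveground biomass density from canopy height
#'
#' `B = agb_scale * Hba^agb_exponent` per pixel, in Mg/ha. Heights below
#' the configured floor are clamped to zero before exponentiation; negative
#' heights are an error.
#'
#' @param hba A [grid()] of basal-area-weighted height (m).
#' @param p A [height_model_params()].
#' @return A [grid()] of biomass density in Mg/ha.
#' @examples
#' agb_from_height(grid(matrix(1)))$values   # 3.25
#' @export
agb_from_height <- function(hba, p = height_model_params()) {
  stopifnot(is_grid(hba))
  v <- hba$values
  if (any(v < 0, na.rm = TRUE))
    stop("negative canopy heights (", sum(v < 0, na.rm = TRUE), " pixels)")
  v[!is.na(v) & v < p$height_floor] <- 0
  grid(p$agb_scale * v^p$agb_exponent, hba$pixel_size, hba$xll, hba$yll)
}

#' Zonal summary of a grid within a mask
#'
#' Minimum, maximum, mean and total of the non-nodata pixels inside the
#' mask. For per-area quantities such as biomass density the `total_mg`
#' field converts the per-hectare values to an absolute stock using the
#' pixel area.
#'
#' @param g A single-layer [grid()].
#' @param mask Binary [grid()]; if `NULL` the whole grid is summarised.
#' @return A list with `n`, `min`, `max`, `mean`, `total`, `total_mg`
#'   (total x pixel area in ha) and `area_ha`.
#' @export
zonal_summary <- function(g, mask = NULL) {
  stopifnot(is_grid(g), n_layers(g) == 1L)
  if (!is.null(mask)) g <- apply_mask(g, mask)
  v <- g$values[!is.na(g$values)]
  if (length(v) == 0L) stop("empty mask: no valid pixels to summarise")
  px_ha <- g$pixel_size^2 / 1e4
  list(n = length(v), min = min(v), max = max(v), mean = mean(v),
       total = sum(v), total_mg = sum(v) * px_ha,
       area_ha = length(v) * px_ha)
}
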