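#' Class areas in hectares
#'
#' Counts pixels per class and converts to hectares:
#' `area = count * pixel_size^2 / 10000`. Nodata pixels contribute to no
#' class.
#'
#' @param cm A [classmap()] with a known pixel size.
#' @param epoch Optional label attached to the result.
#' @return Data frame with columns `class`, `code`, `area_ha`.
#' @examples
#' leg <- data.frame(code = 1, name = "mangrove")
#' m <- classmap(matrix(1L, 10, 10), leg, pixel_size = 25)
#' class_areas(m)   # 100 px * 625 m2 = 6.25 ha
#' @export
class_areas <- function(cm, epoch = NULL) {
  stopifnot(is_classmap(cm))
  if (is.null(cm$pixel_size) || !is.finite(cm$pixel_size))
    stop("pixel size is missing")
  px_ha <- cm$pixel_size^2 / 1e4
  counts <- table(factor(cm$codes, levels = cm$legend$code))
  out <- data.frame(class = cm$legend$name, code = cm$legend$code,
                    area_ha = as.numeric(counts) * px_ha,
                    stringsAsFactors = FALSE)
  attr(out, "epoch") <- epoch
  attr(out, "pixel_size") <- cm$pixel_size
  out
}

#' Signed percent change between two epochs
#'
#' `100 * (a2 - a1) / a1` per class; classes absent in the first epoch
#' (zero area) get `NA` since relative change is undefined there.
#'
#' @param a1,a2 Area tables from [class_areas()] sharing the same legend.
#' @return Data frame with `class`, `area_ha_t1`, `area_ha_t2`,
#'   `percent_change`.
#' @examples
#' a1 <- data.frame(class = "mangrove", code = 1, area_ha = 1613)
#' a2 <- data.frame(class = "mangrove", code = 1, area_ha = 1340)
#' percent_change(a1, a2)$percent_change   # -16.9
#' @export
percent_change <- function(a1, a2) {
  if (!identical(a1$class, a2$class) || !identical(a1$code, a2$code))
    stop("area tables have mismatched legends")
  pc <- ifelse(a1$area_ha > 0, 100 * (a2$area_ha - a1$area_ha) / a1$area_ha,
               NA_real_)
  data.frame(class = a1$class, code = a1$code,
             area_ha_t1 = a1$area_ha, area_ha_t2 = a2$area_ha,
             percent_change = pc, stringsAsFactors = FALSE)
}

#' Class-transition cross-tabulation in hectares
#'
#' Cell (i, j) is the area classed i in the first epoch and j in the
#' second. Pixels that are nodata in either epoch are excluded entirely, so
#' row sums reproduce the epoch-1 areas and column sums the epoch-2 areas
#' over the jointly valid extent.
#'
#' @param t1,t2 Same-shape [classmap()]s sharing a legend.
#' @return k x k numeric matrix of hectares (rows = epoch 1).
#' @export
transition_table <- function(t1, t2) {
  stopifnot(is_classmap(t1), is_classmap(t2))
  if (!identical(dim(t1$codes), dim(t2$codes)))
    stop("class maps have different shapes")
  if (!identical(t1$legend, t2$legend))
    stop("class maps have different legends")
  px_ha <- t1$pixel_size^2 / 1e4
  keep <- !is.na(t1$codes) & !is.na(t2$codes)
  tab <- table(factor(t1$codes[keep], levels = t1$legend$code),
               factor(t2$codes[keep], levels = t1$legend$code))
  m <- unclass(tab) * px_ha
  dimnames(m) <- list(epoch1 = t1$legend$name, epoch2 = t1$legend$name)
  m
}
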