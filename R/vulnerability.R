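#' Sample points along a shoreline
#'
#' Places points at arc-length 0, `spacing`, `2 * spacing`, ... along a
#' polyline, starting at its first vertex, so a line of length L yields
#' `floor(L / spacing) + 1` points.
#'
#' @param line Two-column matrix (or data frame) of x, y vertices in
#'   metres.
#' @param spacing Point spacing in metres (> 0).
#' @return Data frame with `id`, `x`, `y`, `arc_length`.
#' @examples
#' nrow(sample_shoreline(cbind(c(0, 1000), c(0, 0)), 250))   # 5
#' @export
sample_shoreline <- function(line, spacing = 250) {
  line <- as.matrix(line)
  if (spacing <= 0) stop("spacing must be positive")
  if (nrow(line) < 2L) stop("degenerate shoreline: need at least 2 vertices")
  seg <- sqrt(rowSums(diff(line)^2))
  L <- sum(seg)
  if (L <= 0) stop("degenerate shoreline: zero length")
  s <- seq(0, L, by = spacing)
  cum <- c(0, cumsum(seg))
  idx <- pmin(findInterval(s, cum, rightmost.closed = TRUE), nrow(line) - 1L)
  frac <- (s - cum[idx]) / seg[idx]
  pts <- line[idx, , drop = FALSE] +
    (line[idx + 1L, , drop = FALSE] - line[idx, , drop = FALSE]) * frac
  data.frame(id = seq_along(s), x = pts[, 1L], y = pts[, 2L],
             arc_length = s)
}

#' Rank a hazard variable on the 1-5 exposure scale
#'
#' Bins values at their own 20/40/60/80th percentiles into ranks 1
#' (lowest exposure) to 5 (highest). `direction = "lower_is_riskier"`
#' reverses the scale (e.g. relief: low-lying shoreline is more exposed).
#' A variable with no variation gets the neutral rank 3 everywhere.
#' Already-ranked categorical variables (integers in 1-5, such as a
#' geomorphology erodibility score) can be passed straight through via
#' [rank_passthrough()].
#'
#' @param values Numeric vector; `NA`s keep `NA` ranks.
#' @param direction `"higher_is_riskier"` (default) or
#'   `"lower_is_riskier"`.
#' @return Integer ranks in 1-5.
#' @examples
#' rank_variable(c(10, 50, 95), direction = "higher_is_riskier")
#' @export
rank_variable <- function(values, direction = c("higher_is_riskier",
                                                "lower_is_riskier")) {
  direction <- match.arg(direction)
  ok <- is.finite(values)
  if (!any(ok)) stop("cannot rank: no finite values")
  v <- values[ok]
  r <- rep(NA_integer_, length(values))
  if (max(v) == min(v)) {
    r[ok] <- 3L
    return(r)
  }
  breaks <- stats::quantile(v, c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  r[ok] <- 1L + findInterval(v, breaks)
  if (direction == "lower_is_riskier") r[ok] <- 6L - r[ok]
  r
}

#' @rdname rank_variable
#' @export
rank_passthrough <- function(values) {
  if (!all(values %in% 1:5 | is.na(values)))
    stop("pass-through ranks must already be integers in 1..5")
  as.integer(values)
}

#' Coastal exposure index
#'
#' The geometric mean of the six ranked hazard variables at a shoreline
#' point: `EI = (R_geomorphology * R_relief * R_habitats * R_wind * R_wave
#' * R_surge)^(1/6)`, bounded in \[1, 5\] since every rank is.
#'
#' @param ranks Named list/vector or data frame of integer ranks for
#'   `geomorphology`, `relief`, `habitats`, `wind`, `wave`, `surge` (extra
#'   names ignored; a data frame gives one EI per row).
#' @return Numeric exposure index (vectorised over data-frame rows).
#' @examples
#' exposure_index(c(geomorphology = 1, relief = 2, habitats = 3,
#'                  wind = 4, wave = 5, surge = 5))   # 600^(1/6)
#' @export
exposure_index <- function(ranks) {
  vars <- c("geomorphology", "relief", "habitats", "wind", "wave", "surge")
  if (is.data.frame(ranks)) {
    missing <- setdiff(vars, names(ranks))
    if (length(missing))
      stop("missing rank for variable: ", paste(missing, collapse = ", "))
    m <- as.matrix(ranks[, vars])
  } else {
    ranks <- unlist(ranks)
    missing <- setdiff(vars, names(ranks))
    if (length(missing))
      stop("missing rank for variable: ", paste(missing, collapse = ", "))
    m <- matrix(ranks[vars], 1)
  }
  if (any(m < 1 | m > 5, na.rm = TRUE)) stop("ranks must lie in 1..5")
  out <- exp(rowMeans(log(m)))
  unname(out)
}

#' Exposure risk class
#'
#' Equal-width bins of the \[1, 5\] exposure index: very low \[1, 1.8),
#' low \[1.8, 2.6), moderate \[2.6, 3.4), high \[3.4, 4.2), very high
#' \[4.2, 5].
#'
#' @param ei Exposure index values in \[1, 5\].
#' @return Factor with levels very low < low < moderate < high < very high.
#' @export
risk_class <- function(ei) {
  if (any(ei < 1 | ei > 5, na.rm = TRUE))
    stop("exposure index out of range [1, 5]")
  labs <- c("very low", "low", "moderate", "high", "very high")
  i <- pmin(findInterval(ei, c(1, 1.8, 2.6, 3.4, 4.2, 5),
                         rightmost.closed = TRUE), 5L)
  factor(labs[i], levels = labs, ordered = TRUE)
}

#' Rank all hazard variables at shoreline points
#'
#' Applies the 1-5 ranking to each of the six variables of a shore-point
#' table. Geomorphology is treated as an already-scored 1-5 variable when
#' its values all lie in 1..5, otherwise it is percentile-ranked; relief is
#' ranked with `lower_is_riskier` (low-lying coast floods first); habitat
#' presence maps to a protective rank where mangrove fronts the point
#' (`habitat_rank_with`) and an exposed rank where it does not
#' (`habitat_rank_without`); wind, wave and surge are percentile-ranked
#' with higher values riskier.
#'
#' @param points Data frame with columns `geomorphology`, `relief`,
#'   `habitats` (0/1 presence or pre-assigned ranks 1-5), `wind`, `wave`,
#'   `surge`.
#' @param habitat_rank_with,habitat_rank_without Ranks used where habitat
#'   is present / absent (defaults 1 and 5).
#' @return The input with the six columns replaced by integer ranks.
#' @export
rank_shore_points <- function(points, habitat_rank_with = 1,
                              habitat_rank_without = 5) {
  p <- points
  p$geomorphology <- if (all(points$geomorphology %in% 1:5))
    rank_passthrough(points$geomorphology)
  else rank_variable(points$geomorphology)
  p$relief <- rank_variable(points$relief, "lower_is_riskier")
  p$habitats <- if (all(points$habitats %in% 0:1))
    ifelse(points$habitats == 1, habitat_rank_with, habitat_rank_without)
  else rank_passthrough(points$habitats)
  p$wind <- rank_variable(points$wind)
  p$wave <- rank_variable(points$wave)
  p$surge <- rank_variable(points$surge)
  p
}

#' Habitat present/absent exposure scenarios
#'
#' Computes the exposure index for every point twice: once with the
#' habitat variable at its protective rank (mangrove present) and once at
#' the rank it takes in the habitat's absence, all other ranks held fixed.
#' The summary gives the percentage of points in each risk class under
#' both scenarios — the habitat's defensive value is the shift of that
#' distribution.
#'
#' @param ranked_points Data frame of ranked points (see
#'   [rank_shore_points()]); the `habitats` column is overridden per
#'   scenario.
#' @param habitat_rank_with Habitat rank when the mangrove is present
#'   (1-5).
#' @param habitat_rank_without Habitat rank in its absence; must be >=
#'   `habitat_rank_with`.
#' @return A list with `points` (per-point EI and risk class under both
#'   scenarios) and `summary` (percent of points per risk class per
#'   scenario).
#' @export
scenario_compare <- function(ranked_points, habitat_rank_with = 1,
                             habitat_rank_without = 5) {
  if (habitat_rank_without < habitat_rank_with)
    stop("habitat_rank_without must be >= habitat_rank_with")
  with_p <- ranked_points
  with_p$habitats <- as.integer(habitat_rank_with)
  without_p <- ranked_points
  without_p$habitats <- as.integer(habitat_rank_without)
  ei_with <- exposure_index(with_p)
  ei_without <- exposure_index(without_p)
  pts <- data.frame(
    id = if (!is.null(ranked_points$id)) ranked_points$id
         else seq_len(nrow(ranked_points)),
    ei_with_habitat = ei_with, ei_without_habitat = ei_without,
    risk_with_habitat = risk_class(ei_with),
    risk_without_habitat = risk_class(ei_without))
  levs <- levels(pts$risk_with_habitat)
  pct <- function(f) 100 * as.numeric(table(f)) / length(f)
  summary <- data.frame(risk_class = factor(levs, levels = levs,
                                            ordered = TRUE),
                        with_habitat_pct = pct(pts$risk_with_habitat),
                        without_habitat_pct = pct(pts$risk_without_habitat))
  list(points = pts, summary = summary)
}
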