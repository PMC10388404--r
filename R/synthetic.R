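#' Specification of a synthetic mangrove scene
#'
#' Bundles every parameter the scene generator needs: grid geometry, the
#' four-class land-cover composition, the epoch-1 to epoch-2 transition
#' structure, per-class spectral/backscatter signatures, the canopy-height
#' range the DEM carries inside the mangrove extent, and a seed.
#'
#' Defaults emulate the study system: class fractions follow the 2009 area
#' shares of an estuarine mangrove complex (water 1770 ha, mangrove 1613 ha,
#' bare/built-up 370 ha, other vegetation 2617 ha), the transition matrix
#' reproduces a decade of mangrove loss to water, bare land and other
#' vegetation, pixels are 25 m (L-band SAR resolution class), and the DEM
#' height range of 3.71-7.48 m spans the canopy envelope that scales to
#' roughly 6.3-12.7 m maximum height under the 1.697 allometric factor.
#'
#' @param width,height Grid dimensions in pixels.
#' @param pixel_size Pixel edge in metres.
#' @param class_legend Data frame `code,name` for the four classes.
#' @param class_fractions Named per-class proportions summing to 1.
#' @param transition_matrix k x k row-stochastic matrix: row i gives the
#'   probability distribution of the epoch-2 class for a pixel of epoch-1
#'   class i (rows/columns in legend order).
#' @param band_means k x b matrix of per-class per-band signature means
#'   (defaults: two SAR backscatter layers in dB, an NDVI layer, one optical
#'   reflectance layer).
#' @param band_sds k x b matrix of signature standard deviations; if `NULL`,
#'   `noise_sd` is used for the SAR layers and `noise_sd/12` for the index /
#'   reflectance layers.
#' @param dem_height_range `c(min, max)` canopy height in metres inside the
#'   mangrove extent.
#' @param noise_sd Baseline signature noise (dB for SAR layers).
#' @param smooth_radius Box-filter radius (pixels) applied to the latent
#'   field so classes form patches rather than salt-and-pepper noise.
#' @param seed Integer seed; the whole scene is deterministic given it.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width = 120, height = 120, pixel_size = 25,
                       class_legend = default_legend(),
                       class_fractions = c(water = 0.2779, mangrove = 0.2532,
                                           bare_builtup = 0.0581,
                                           other_vegetation = 0.4108),
                       transition_matrix = default_transitions(),
                       band_means = default_band_means(),
                       band_sds = NULL,
                       dem_height_range = c(3.71, 7.48),
                       noise_sd = 1, smooth_radius = 2, seed = 1L) {
  k <- nrow(class_legend)
  if (length(class_fractions) != k)
    stop("class_fractions must have one entry per legend class")
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("class_fractions must sum to 1 (got ", sum(class_fractions), ")")
  if (any(class_fractions < 0)) stop("class_fractions must be nonnegative")
  transition_matrix <- as.matrix(transition_matrix)
  if (!all(dim(transition_matrix) == k))
    stop("transition_matrix must be ", k, " x ", k)
  rs <- rowSums(transition_matrix)
  bad <- which(abs(rs - 1) > 1e-9)
  if (length(bad))
    stop("transition_matrix row ", bad[1L], " (", class_legend$name[bad[1L]],
         ") sums to ", rs[bad[1L]], ", not 1")
  if (any(transition_matrix < 0)) stop("transition probabilities must be >= 0")
  if (width <= 0 || height <= 0 || pixel_size <= 0)
    stop("width, height and pixel_size must be positive")
  band_means <- as.matrix(band_means)
  if (nrow(band_means) != k) stop("band_means needs one row per class")
  if (is.null(band_sds)) {
    band_sds <- matrix(noise_sd, k, ncol(band_means))
    idx <- seq_len(ncol(band_means)) > 2
    band_sds[, idx] <- noise_sd / 12
  }
  band_sds <- as.matrix(band_sds)
  if (!all(dim(band_sds) == dim(band_means)))
    stop("band_sds must match band_means in shape")
  if (length(dem_height_range) != 2L ||
      dem_height_range[1L] > dem_height_range[2L])
    stop("dem_height_range must be c(min, max) with min <= max")
  structure(list(
    width = as.integer(width), height = as.integer(height),
    pixel_size = pixel_size, class_legend = class_legend,
    class_fractions = class_fractions, transition_matrix = transition_matrix,
    band_means = band_means, band_sds = band_sds,
    dem_height_range = dem_height_range, noise_sd = noise_sd,
    smooth_radius = as.integer(smooth_radius), seed = as.integer(seed)),
    class = "scene_spec")
}

#' @rdname scene_spec
#' @export
default_legend <- function() {
  data.frame(code = 1:4,
             name = c("water", "mangrove", "bare_builtup", "other_vegetation"),
             stringsAsFactors = FALSE)
}

#' @rdname scene_spec
#' @export
default_transitions <- function() {
  m <- rbind(water            = c(0.97, 0.00, 0.01, 0.02),
             mangrove         = c(0.07, 0.83, 0.05, 0.05),
             bare_builtup     = c(0.02, 0.00, 0.93, 0.05),
             other_vegetation = c(0.05, 0.01, 0.06, 0.88))
  colnames(m) <- rownames(m)
  m
}

#' @rdname scene_spec
#' @export
default_band_means <- function() {
  # columns: SAR VH (dB), SAR VV (dB), NDVI, red reflectance
  m <- rbind(water            = c(-24, -18, 0.02, 0.05),
             mangrove         = c(-14, -8, 0.80, 0.04),
             bare_builtup     = c(-9, -3, 0.12, 0.35),
             other_vegetation = c(-18, -12, 0.55, 0.10))
  colnames(m) <- c("sar_vh", "sar_vv", "ndvi", "red")
  m
}

# latent Gaussian field smoothed with a box filter so thresholding yields
# spatially coherent patches
smooth_field <- function(nr, nc, radius) {
  f <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (radius < 1L) return(f)
  w <- 2L * radius + 1L
  # separable box filter with edge replication
  pad_idx <- function(n) pmin(pmax(seq(1L - radius, n + radius), 1L), n)
  for (pass in 1:2) {
    f <- apply(f[pad_idx(nr), ], 2, function(col)
      stats::filter(col, rep(1 / w, w), sides = 2)[(radius + 1):(radius + nr)])
    f <- t(apply(f[, pad_idx(nc)], 1, function(row)
      stats::filter(row, rep(1 / w, w), sides = 2)[(radius + 1):(radius + nc)]))
  }
  f
}

#' Generate a complete synthetic scene
#'
#' Produces every input the downstream pipeline consumes: two-epoch land-cover
#' maps with a prescribed class-transition structure, per-epoch band stacks
#' drawn from class signatures, a DEM carrying canopy-top heights inside the
#' mangrove extent, the mangrove mask, a stratified labelled sample set, a
#' plot inventory on a shoreline transect, and shoreline hazard points.
#'
#' Epoch-1 classes are obtained by thresholding a smoothed Gaussian latent
#' field at the quantiles of the class fractions, so classes form contiguous
#' patches and empirical fractions match the specification closely. Each
#' epoch-2 class is drawn per pixel from the transition-matrix row of its
#' epoch-1 class. Bit-identical output is guaranteed for a fixed seed.
#'
#' @param spec A [scene_spec()].
#' @return An object of class `synthetic_scene` with elements `lulc_t1`,
#'   `lulc_t2` ([classmap()]), `bands_t1`, `bands_t2`, `dem`, `mangrove_mask`
#'   ([grid()]), `samples` (data frame), `inventory` (data frame of trees),
#'   `shore_points` (data frame), and the originating `spec`.
#' @examples
#' sc <- generate_scene(scene_spec(width = 40, height = 40, seed = 7))
#' table(sc$lulc_t1$codes)
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  nr <- spec$height; nc <- spec$width
  k <- nrow(spec$class_legend)
  codes <- spec$class_legend$code

  f <- smooth_field(nr, nc, spec$smooth_radius)
  cuts <- stats::quantile(f, cumsum(spec$class_fractions)[-k], names = FALSE)
  t1 <- matrix(codes[findInterval(f, cuts) + 1L], nr, nc)

  idx1 <- match(t1, codes)
  t2 <- matrix(NA_integer_, nr, nc)
  u <- stats::runif(nr * nc)
  for (i in seq_len(k)) {
    sel <- idx1 == i
    cum <- cumsum(spec$transition_matrix[i, ])
    t2[sel] <- codes[findInterval(u[sel], cum[-k]) + 1L]
  }

  lulc_t1 <- classmap(t1, spec$class_legend, spec$pixel_size)
  lulc_t2 <- classmap(t2, spec$class_legend, spec$pixel_size)

  draw_bands <- function(idx) {
    nb <- ncol(spec$band_means)
    arr <- array(NA_real_, c(nr, nc, nb))
    for (b in seq_len(nb))
      arr[, , b] <- spec$band_means[idx, b] +
        stats::rnorm(nr * nc, sd = spec$band_sds[idx, b])
    grid(arr, spec$pixel_size)
  }
  bands_t1 <- draw_bands(idx1)
  bands_t2 <- draw_bands(match(t2, codes))

  mang_code <- spec$class_legend$code[spec$class_legend$name == "mangrove"]
  mask <- (t1 == mang_code) + 0
  dem_vals <- matrix(0, nr, nc)
  inside <- mask == 1
  dem_vals[inside] <- stats::runif(sum(inside), spec$dem_height_range[1L],
                                   spec$dem_height_range[2L])
  dem <- grid(dem_vals, spec$pixel_size)
  mangrove_mask <- grid(mask, spec$pixel_size)

  samples <- sample_points(lulc_t1, n_total = min(2131L, nr * nc),
                           train_fraction = 0.8,
                           seed = spec$seed + 1L)
  inventory <- simulate_inventory(seed = spec$seed + 2L)
  shore_points <- simulate_shore_points(
    shoreline_length = nc * spec$pixel_size, spacing = 250,
    seed = spec$seed + 3L)

  structure(list(lulc_t1 = lulc_t1, lulc_t2 = lulc_t2,
                 bands_t1 = bands_t1, bands_t2 = bands_t2,
                 dem = dem, mangrove_mask = mangrove_mask,
                 samples = samples, inventory = inventory,
                 shore_points = shore_points, spec = spec),
            class = "synthetic_scene")
}

#' Draw stratified labelled sample points from a class map
#'
#' Samples pixels stratified by class (allocation proportional to class
#' pixel counts, largest-remainder rounding) and splits them into training
#' and validation sets. The training count is `floor(n_total *
#' train_fraction)`; the remainder goes to validation. The split is itself
#' stratified so each class contributes proportionally to both sets.
#'
#' @param cm A [classmap()] (or a `synthetic_scene`, whose epoch-1 map is
#'   used).
#' @param n_total Total number of points; at most the number of valid pixels.
#' @param train_fraction Fraction assigned to the training split, in (0, 1).
#' @param seed Integer seed.
#' @return Data frame with columns `row`, `col`, `class_code`, `class_name`,
#'   `split` (`"train"`/`"validation"`); attribute `split_counts` records the
#'   realised totals.
#' @examples
#' leg <- data.frame(code = 1:2, name = c("a", "b"))
#' cm <- classmap(matrix(rep(1:2, each = 50), 10), leg)
#' s <- sample_points(cm, 40, 0.8, seed = 1)
#' table(s$split)
#' @export
sample_points <- function(cm, n_total = 2131, train_fraction = 0.8,
                          seed = 1L) {
  if (inherits(cm, "synthetic_scene")) cm <- cm$lulc_t1
  stopifnot(is_classmap(cm))
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must be strictly between 0 and 1")
  valid <- which(!is.na(cm$codes))
  if (n_total > length(valid))
    stop("n_total exceeds the number of valid pixels")
  set.seed(seed)

  counts <- table(factor(cm$codes[valid], levels = cm$legend$code))
  present <- counts > 0
  if (any(!present))
    warning("classes with zero pixels skipped in stratification: ",
            paste(cm$legend$name[!present], collapse = ", "))
  alloc <- largest_remainder(n_total * counts[present] / sum(counts[present]))

  rows <- integer(0); cols <- integer(0); cls <- integer(0)
  split <- character(0)
  pres_codes <- cm$legend$code[present]
  n_train_target <- floor(n_total * train_fraction)
  tr_alloc <- largest_remainder(alloc * train_fraction, total = n_train_target)
  for (i in seq_along(pres_codes)) {
    cells <- valid[cm$codes[valid] == pres_codes[i]]
    take <- sample(cells, alloc[i])
    rc <- arrayInd(take, dim(cm$codes))
    rows <- c(rows, rc[, 1L]); cols <- c(cols, rc[, 2L])
    cls <- c(cls, rep(pres_codes[i], alloc[i]))
    sp <- rep("validation", alloc[i])
    sp[seq_len(tr_alloc[i])] <- "train"
    split <- c(split, sample(sp))
  }
  out <- data.frame(row = rows, col = cols, class_code = cls,
                    class_name = cm$legend$name[match(cls, cm$legend$code)],
                    split = split, stringsAsFactors = FALSE)
  attr(out, "split_counts") <- c(train = sum(split == "train"),
                                 validation = sum(split == "validation"))
  out
}

# integer allocation preserving a fixed total
largest_remainder <- function(x, total = round(sum(x))) {
  fl <- floor(x)
  rem <- total - sum(fl)
  if (rem > 0) {
    extra <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
  }
  as.integer(fl)
}

#' Simulate a mangrove field inventory
#'
#' Emulates the field protocol: square plots laid out at fixed intervals
#' along a transect perpendicular to the shoreline, every tree recorded with
#' species, diameter at breast height (cm) and height (m). Stem density
#' declines with distance from the shoreline (the landward plots may be
#' empty), diameters are log-normal, and height scales with diameter plus
#' noise. Some stems fall below the 2-m measurement threshold so the
#' downstream filter is exercised.
#'
#' @param n_plots Number of plots on the transect.
#' @param plot_area Plot area in square metres (5 m x 5 m by default).
#' @param spacing Distance between plot centres along the transect (m).
#' @param mean_stems Expected stems in the most seaward plot.
#' @param species Species pool to draw from.
#' @param seed Integer seed.
#' @return Data frame with columns `plot_id`, `transect_position_m`,
#'   `species`, `dbh_cm`, `height_m`; attributes `plot_area` and `spacing`.
#' @export
simulate_inventory <- function(n_plots = 4, plot_area = 25, spacing = 25,
                               mean_stems = 9,
                               species = wood_density_table()$species,
                               seed = 1L) {
  set.seed(seed)
  out <- list()
  for (p in seq_len(n_plots)) {
    # density decays landward; the far plot is often bare
    lambda <- mean_stems * exp(-0.9 * (p - 1))
    n <- stats::rpois(1, lambda)
    if (n == 0) next
    dbh <- stats::rlnorm(n, meanlog = log(3.2), sdlog = 0.45)
    dbh <- pmin(pmax(dbh, 0.5), 9)
    h <- pmax(0.8 + 0.85 * dbh + stats::rnorm(n, sd = 0.5), 0.5)
    out[[length(out) + 1L]] <- data.frame(
      plot_id = p, transect_position_m = (p - 1) * spacing,
      species = sample(species, n, replace = TRUE),
      dbh_cm = round(dbh, 2), height_m = round(h, 2),
      stringsAsFactors = FALSE)
  }
  inv <- if (length(out)) do.call(rbind, out) else
    data.frame(plot_id = integer(0), transect_position_m = numeric(0),
               species = character(0), dbh_cm = numeric(0),
               height_m = numeric(0))
  attr(inv, "plot_area") <- plot_area
  attr(inv, "spacing") <- spacing
  attr(inv, "n_plots") <- n_plots
  inv
}

#' Simulate shoreline hazard points
#'
#' Places points at a fixed spacing along a straight shoreline and attaches
#' the six hazard variables the exposure index consumes: a geomorphology
#' erodibility score, relief (m), habitat presence (1 = mangrove fronting
#' the point, 0 = none), and wind, wave and surge intensities. Values are
#' drawn from right-skewed distributions typical of met-ocean summaries.
#'
#' @param shoreline_length Shoreline length in metres.
#' @param spacing Point spacing in metres (250 m by default).
#' @param habitat_fraction Fraction of points fronted by mangrove.
#' @param seed Integer seed.
#' @return Data frame with columns `id`, `x`, `y` and the six variables.
#' @export
simulate_shore_points <- function(shoreline_length = 3000, spacing = 250,
                                  habitat_fraction = 0.6, seed = 1L) {
  set.seed(seed)
  x <- seq(0, shoreline_length, by = spacing)
  n <- length(x)
  data.frame(
    id = seq_len(n), x = x, y = 0,
    geomorphology = sample(1:5, n, replace = TRUE,
                           prob = c(0.1, 0.2, 0.3, 0.25, 0.15)),
    relief = stats::rlnorm(n, log(4), 0.6),
    habitats = as.integer(stats::runif(n) < habitat_fraction),
    wind = stats::rlnorm(n, log(6), 0.4),
    wave = stats::rlnorm(n, log(1.2), 0.5),
    surge = stats::rlnorm(n, log(0.8), 0.5))
}
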