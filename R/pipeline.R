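#' Default end-to-end run configuration
#'
#' Assembles and validates the parameters of every stage: the synthetic
#' scene, SAR calibration, speckle filtering, the classifier, the wood
#' density policy, the height/biomass model and the habitat scenario
#' ranks. Any field can be overridden; overrides are validated against the
#' owning stage's preconditions before a run starts.
#'
#' @param ... Named overrides of the defaults (see the returned list for
#'   field names). `scene` takes a [scene_spec()].
#' @param seed Master seed; stage seeds derive from it.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(..., seed = 1L) {
  cfg <- list(
    scene = scene_spec(seed = as.integer(seed)),
    cf = -83,
    speckle_window = 3,
    n_samples = 2131, train_fraction = 0.8,
    classifier = classifier_config(seed = as.integer(seed) + 10L),
    density_policy = "global_default",
    allometric_model = "komiyama",
    height_model = height_model_params(),
    habitat_rank_with = 1, habitat_rank_without = 5,
    shore_spacing = 250,
    seed = as.integer(seed))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (!is.finite(cfg$cf)) stop("cf must be finite")
  if (cfg$speckle_window < 3 || cfg$speckle_window %% 2 == 0)
    stop("speckle_window must be odd and >= 3")
  if (!(cfg$train_fraction > 0 && cfg$train_fraction < 1))
    stop("train_fraction must be in (0, 1)")
  if (cfg$habitat_rank_without < cfg$habitat_rank_with)
    stop("habitat_rank_without must be >= habitat_rank_with")
  if (cfg$shore_spacing <= 0) stop("shore_spacing must be positive")
  stopifnot(inherits(cfg$scene, "scene_spec"),
            inherits(cfg$classifier, "classifier_config"),
            inherits(cfg$height_model, "height_model_params"))
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Flat YAML keys map onto [run_config()] fields; nested `scene`,
#' `classifier` and `height_model` mappings are passed to their
#' constructors.
#'
#' @param path YAML file path.
#' @param seed Master seed overriding the file's, if given.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(seed)) y$seed <- as.integer(seed)
  if (!is.null(y$scene)) y$scene <- do.call(scene_spec, y$scene)
  if (!is.null(y$classifier))
    y$classifier <- do.call(classifier_config, y$classifier)
  if (!is.null(y$height_model))
    y$height_model <- do.call(height_model_params, y$height_model)
  do.call(run_config, y)
}

#' Run the full assessment pipeline
#'
#' Chains every stage on a synthetic scene: scene generation, speckle
#' filtering of the SAR layers, per-epoch classification and accuracy
#' assessment (overall accuracy, QADI), two-epoch change accounting,
#' canopy-height and biomass mapping inside the mangrove extent,
#' field-inventory allometry, and the habitat present/absent exposure
#' scenarios. Results are returned as a list; if `out_dir` is given, grids
#' and tables are also written there along with a JSON manifest recording
#' the seed and per-stage summary numbers. Identical configuration and
#' seed give identical manifests.
#'
#' @param cfg A [run_config()].
#' @param out_dir Optional output directory (created if missing).
#' @param quiet Suppress per-stage progress messages.
#' @return A list with `scene`, per-epoch `maps` and `accuracy`, `areas`,
#'   `change`, `transitions`, `height`, `agb`, `field_agb`, `exposure`
#'   and the `manifest`.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (!quiet) message(...)
  stage <- "simulate"
  res <- tryCatch({
    say("simulate: generating scene")
    scene <- generate_scene(cfg$scene)

    stage <- "preprocess"
    say("preprocess: speckle-filtering SAR layers")
    prep_stack <- function(bands) {
      layers <- lapply(seq_len(n_layers(bands)), function(b)
        grid(bands$values[, , b], bands$pixel_size, bands$xll, bands$yll))
      for (b in 1:2)   # SAR layers carry speckle; index layers do not
        layers[[b]] <- speckle_filter(layers[[b]], cfg$speckle_window)
      grid_stack(layers)
    }
    stack_t1 <- prep_stack(scene$bands_t1)
    stack_t2 <- prep_stack(scene$bands_t2)

    stage <- "classify"
    say("classify: training and predicting both epochs")
    legend <- cfg$scene$class_legend
    samples_t1 <- sample_points(scene$lulc_t1, cfg$n_samples,
                                cfg$train_fraction, seed = cfg$seed + 1L)
    samples_t2 <- sample_points(scene$lulc_t2, cfg$n_samples,
                                cfg$train_fraction, seed = cfg$seed + 2L)
    m1 <- train_classifier(stack_t1, samples_t1, cfg$classifier, legend)
    m2 <- train_classifier(stack_t2, samples_t2, cfg$classifier, legend)
    map_t1 <- predict_map(m1, stack_t1)
    map_t2 <- predict_map(m2, stack_t2)

    stage <- "assess"
    say("assess: accuracy against validation points")
    acc_t1 <- validate_map(map_t1, samples_t1)
    acc_t2 <- validate_map(map_t2, samples_t2)

    stage <- "change"
    say("change: area and transition accounting")
    a1 <- class_areas(map_t1, epoch = "t1")
    a2 <- class_areas(map_t2, epoch = "t2")
    chg <- percent_change(a1, a2)
    trans <- transition_table(map_t1, map_t2)

    stage <- "canopy"
    say("canopy: height and biomass inside the mangrove extent")
    hmax <- canopy_height_max(scene$dem, scene$mangrove_mask,
                              cfg$height_model)
    hba <- basal_area_weighted_height(scene$dem, scene$mangrove_mask,
                                      cfg$height_model)
    agb <- agb_from_height(hba, cfg$height_model)
    h_sum <- zonal_summary(hmax)
    agb_sum <- zonal_summary(agb)

    stage <- "allometry"
    say("allometry: field-inventory biomass")
    field <- lapply(c("komiyama", "chave", "njana"), function(m)
      aggregate_plots(scene$inventory, m,
                      density_policy = cfg$density_policy))
    names(field) <- c("komiyama", "chave", "njana")

    stage <- "vulnerability"
    say("vulnerability: habitat present/absent exposure scenarios")
    ranked <- rank_shore_points(scene$shore_points,
                                cfg$habitat_rank_with,
                                cfg$habitat_rank_without)
    expo <- scenario_compare(ranked, cfg$habitat_rank_with,
                             cfg$habitat_rank_without)

    manifest <- list(
      package_version = as.character(utils::packageVersion("mangresil")),
      seed = cfg$seed,
      scene = list(width = cfg$scene$width, height = cfg$scene$height,
                   pixel_size = cfg$scene$pixel_size),
      accuracy = list(
        t1 = list(overall = acc_t1$overall_accuracy, qadi = acc_t1$qadi,
                  confidence = acc_t1$confidence),
        t2 = list(overall = acc_t2$overall_accuracy, qadi = acc_t2$qadi,
                  confidence = acc_t2$confidence)),
      areas_ha = list(t1 = stats::setNames(a1$area_ha, a1$class),
                      t2 = stats::setNames(a2$area_ha, a2$class)),
      percent_change = stats::setNames(chg$percent_change, chg$class),
      height_m = h_sum[c("min", "max", "mean")],
      agb_mg_ha = agb_sum[c("min", "max", "mean")],
      field_agb_kg = lapply(field, function(f)
        stats::setNames(f$agb_kg, paste0("plot", f$plot_id))),
      exposure = list(
        mean_ei_with = mean(expo$points$ei_with_habitat),
        mean_ei_without = mean(expo$points$ei_without_habitat),
        summary_pct = expo$summary))

    out <- list(scene = scene,
                maps = list(t1 = map_t1, t2 = map_t2),
                models = list(t1 = m1, t2 = m2),
                accuracy = list(t1 = acc_t1, t2 = acc_t2),
                areas = list(t1 = a1, t2 = a2), change = chg,
                transitions = trans,
                height = hmax, agb = agb,
                field_agb = field, exposure = expo,
                manifest = manifest)
    if (!is.null(out_dir)) write_outputs(out, out_dir)
    out
  }, error = function(e)
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE))
  res
}

write_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_classmap(res$maps$t1, p("lulc_t1.asc"))
  write_classmap(res$maps$t2, p("lulc_t2.asc"))
  write_grid(res$height, p("canopy_height_max.asc"))
  write_grid(res$agb, p("agb.asc"))
  utils::write.csv(res$change, p("change.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(res$transitions), p("transitions.csv"))
  for (m in names(res$field_agb))
    utils::write.csv(res$field_agb[[m]],
                     p(sprintf("field_agb_%s.csv", m)), row.names = FALSE)
  utils::write.csv(res$exposure$points, p("exposure_points.csv"),
                   row.names = FALSE)
  utils::write.csv(res$exposure$summary, p("exposure_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Read a tree inventory from CSV
#'
#' Expects columns `plot_id`, `species`, `dbh_cm`, `height_m`.
#'
#' @param path CSV path.
#' @param plot_area Plot area in m2 recorded on the result.
#' @return Data frame usable by [aggregate_plots()].
#' @export
read_inventory <- function(path, plot_area = 25) {
  inv <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "species", "dbh_cm", "height_m")
  miss <- setdiff(need, names(inv))
  if (length(miss))
    stop("inventory is missing columns: ", paste(miss, collapse = ", "))
  attr(inv, "plot_area") <- plot_area
  inv
}

#' Read shoreline hazard points from CSV
#'
#' Expects columns `id`, `x`, `y` plus the six hazard variables
#' (`geomorphology`, `relief`, `habitats`, `wind`, `wave`, `surge`).
#'
#' @param path CSV path.
#' @return Data frame usable by [rank_shore_points()].
#' @export
read_shore_points <- function(path) {
  pts <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("geomorphology", "relief", "habitats", "wind", "wave", "surge")
  miss <- setdiff(need, names(pts))
  if (length(miss))
    stop("shore points are missing variables: ",
         paste(miss, collapse = ", "))
  pts
}
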