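test_that("scene spec validation names the offending component", {
  expect_error(scene_spec(class_fractions = c(0.5, 0.2, 0.2, 0.2)),
               "sum to 1")
  bad_tm <- default_transitions(); bad_tm[2, 1] <- 0.5
  expect_error(scene_spec(transition_matrix = bad_tm), "row 2")
  expect_error(scene_spec(width = 0), "positive")
})

test_that("identity transitions reproduce the first epoch exactly", {
  sp <- tiny_scene_spec(transition_matrix = diag(4))
  sc <- generate_scene(sp)
  expect_identical(sc$lulc_t2$codes, sc$lulc_t1$codes)
})

test_that("the same seed gives a bit-identical scene", {
  a <- generate_scene(tiny_scene_spec(seed = 7L))
  b <- generate_scene(tiny_scene_spec(seed = 7L))
  expect_identical(a$lulc_t1$codes, b$lulc_t1$codes)
  expect_identical(a$bands_t1$values, b$bands_t1$values)
  expect_identical(a$dem$values, b$dem$values)
  expect_identical(a$samples, b$samples)
  expect_identical(a$inventory, b$inventory)
  expect_identical(a$shore_points, b$shore_points)
  c <- generate_scene(tiny_scene_spec(seed = 8L))
  expect_false(identical(a$lulc_t1$codes, c$lulc_t1$codes))
})

test_that("scene grids share geometry and the mask tracks the mangrove class", {
  sc <- generate_scene(tiny_scene_spec())
  expect_equal(dim(sc$dem$values), dim(sc$lulc_t1$codes))
  expect_equal(dim(sc$bands_t1$values)[1:2], dim(sc$lulc_t1$codes))
  expect_equal(sc$dem$pixel_size, sc$lulc_t1$pixel_size)
  mang <- sc$lulc_t1$legend$code[sc$lulc_t1$legend$name == "mangrove"]
  expect_identical(sc$mangrove_mask$values == 1, sc$lulc_t1$codes == mang)
  # DEM inside the mask spans the configured range, zero outside
  inside <- sc$mangrove_mask$values == 1
  expect_true(all(sc$dem$values[inside] >= 3.71 &
                  sc$dem$values[inside] <= 7.48))
  expect_true(all(sc$dem$values[!inside] == 0))
})

test_that("epoch-2 counts follow the transition row within binomial bounds", {
  # mangrove fraction 0.25 on a 100x100 grid, survival probability 0.8
  tm <- matrix(0, 4, 4); diag(tm) <- 1
  tm[2, ] <- c(0.1, 0.8, 0.05, 0.05)
  sp <- scene_spec(width = 100, height = 100,
                   class_fractions = c(0.25, 0.25, 0.25, 0.25),
                   transition_matrix = tm, seed = 21L)
  sc <- generate_scene(sp)
  parents <- sc$lulc_t1$codes == 2
  n_parents <- sum(parents)
  expect_equal(n_parents, 2500, tolerance = 0.02)
  kept <- sum(sc$lulc_t2$codes[parents] == 2)
  sigma <- sqrt(n_parents * 0.8 * 0.2)
  expect_lt(abs(kept - n_parents * 0.8), 3 * sigma)
})

test_that("empirical class fractions approach the specification", {
  sp <- scene_spec(width = 150, height = 150, seed = 5L)
  sc <- generate_scene(sp)
  frac <- as.numeric(table(factor(sc$lulc_t1$codes, levels = 1:4))) / 150^2
  # quantile thresholding of the latent field pins fractions tightly
  expect_equal(frac, unname(sp$class_fractions), tolerance = 0.02)
})

test_that("stratified sampling hits the floor-rule split and partitions", {
  sp <- scene_spec(width = 60, height = 60, seed = 13L)
  sc <- generate_scene(sp)
  s <- sample_points(sc$lulc_t1, n_total = 2131, train_fraction = 0.8,
                     seed = 1)
  expect_equal(nrow(s), 2131)
  expect_equal(sum(s$split == "train"), 1704)       # floor(2131 * 0.8)
  expect_equal(sum(s$split == "validation"), 427)
  expect_false(any(duplicated(s[, c("row", "col")])))
  # labels equal the underlying map
  expect_equal(s$class_code, sc$lulc_t1$codes[cbind(s$row, s$col)])
  # stratification: per-class shares mirror the map within rounding
  map_frac <- as.numeric(table(factor(sc$lulc_t1$codes, levels = 1:4))) /
    3600
  samp_frac <- as.numeric(table(factor(s$class_code, levels = 1:4))) / 2131
  expect_equal(samp_frac, map_frac, tolerance = 0.01)
})

test_that("sampling a single-class map labels everything with that class", {
  leg <- small_legend(2)
  cm <- classmap(matrix(1L, 10, 10), leg)
  expect_warning(s <- sample_points(cm, 20, 0.8, seed = 2), "skipped")
  expect_true(all(s$class_code == 1))
  expect_equal(nrow(s), 20)
  expect_error(sample_points(cm, 1e6, 0.8), "exceeds")
  expect_error(sample_points(cm, 10, 1.2), "between 0 and 1")
})

test_that("simulated inventories and shore points carry the field structure", {
  inv <- simulate_inventory(seed = 3L)
  expect_true(all(c("plot_id", "species", "dbh_cm", "height_m") %in%
                  names(inv)))
  expect_equal(attr(inv, "plot_area"), 25)
  expect_true(all(inv$dbh_cm > 0))
  expect_true(all(inv$transect_position_m %in% c(0, 25, 50, 75)))

  pts <- simulate_shore_points(shoreline_length = 1000, spacing = 250,
                               seed = 3L)
  expect_equal(nrow(pts), 5)    # floor(1000/250) + 1
  expect_true(all(c("geomorphology", "relief", "habitats", "wind", "wave",
                    "surge") %in% names(pts)))
  expect_true(all(pts$habitats %in% 0:1))
})
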