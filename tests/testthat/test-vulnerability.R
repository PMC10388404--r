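test_that("shoreline sampling places floor(L/spacing)+1 points", {
  line <- cbind(c(0, 1000), c(0, 0))
  pts <- sample_shoreline(line, 250)
  expect_equal(nrow(pts), 5)
  expect_equal(pts$x, c(0, 250, 500, 750, 1000))
  # spacing beyond the length leaves just the start point
  expect_equal(nrow(sample_shoreline(line, 2000)), 1)
  # a 148-km shoreline at 250 m, the study's coastal segment scale
  long <- cbind(c(0, 148e3), c(0, 0))
  expect_equal(nrow(sample_shoreline(long, 250)), 593)
  expect_error(sample_shoreline(cbind(0, 0), 250), "degenerate")
  expect_error(sample_shoreline(cbind(c(0, 0), c(0, 0)), 250), "degenerate")
})

test_that("shoreline sampling follows multi-segment polylines", {
  line <- cbind(c(0, 300, 300), c(0, 0, 400))
  pts <- sample_shoreline(line, 100)
  expect_equal(nrow(pts), 8)               # L = 700
  expect_equal(pts$x[4], 300)              # turns the corner at s = 300
  expect_equal(pts$y[5], 100)
})

test_that("percentile ranking maps values onto the 1-5 scale", {
  r <- rank_variable(c(10, 50, 95, 1:100))
  expect_equal(r[1:3], c(1L, 3L, 5L))
  expect_true(all(rank_variable(rep(4, 10)) == 3L))   # no variation
  lo <- rank_variable(1:100, "lower_is_riskier")
  expect_equal(lo[which.min(1:100)], 5L)
  expect_equal(lo, 6L - rank_variable(1:100))
  expect_error(rank_variable(c(NA, NA)), "no finite")
  expect_error(rank_passthrough(c(1, 6)), "1..5")
})

test_that("the exposure index is the geometric mean of six ranks", {
  all_one <- c(geomorphology = 1, relief = 1, habitats = 1, wind = 1,
               wave = 1, surge = 1)
  expect_equal(exposure_index(all_one), 1)
  expect_equal(exposure_index(all_one * 5), 5)
  mixed <- c(geomorphology = 1, relief = 2, habitats = 3, wind = 4,
             wave = 5, surge = 5)
  expect_equal(exposure_index(mixed), 600^(1 / 6), tolerance = 1e-12)
  expect_error(exposure_index(all_one[-2]), "relief")
})

test_that("the index is symmetric, monotone and bounded", {
  vars <- c("geomorphology", "relief", "habitats", "wind", "wave", "surge")
  set.seed(12)
  for (i in 1:20) {
    r <- sample(1:5, 6, TRUE)
    names(r) <- vars
    ei <- exposure_index(r)
    expect_gte(ei, 1); expect_lte(ei, 5)
    # permutation of variables leaves EI unchanged
    p <- r[sample(vars)]
    names(p) <- vars
    expect_equal(exposure_index(p), ei)
    # raising any one rank raises EI
    j <- sample(which(r < 5), 1)
    up <- r; up[j] <- up[j] + 1
    expect_gt(exposure_index(up), ei)
  }
})

test_that("risk classes bin the index on equal widths of [1, 5]", {
  expect_equal(as.character(risk_class(c(1, 5, 2.904, 1.79, 1.8, 4.2))),
               c("very low", "very high", "moderate", "very low", "low",
                 "very high"))
  expect_error(risk_class(0.5), "out of range")
  expect_error(risk_class(5.1), "out of range")
})

test_that("ranking a shore-point table respects each variable's semantics", {
  pts <- simulate_shore_points(shoreline_length = 5000, spacing = 250,
                               seed = 23L)
  ranked <- rank_shore_points(pts)
  vars <- c("geomorphology", "relief", "habitats", "wind", "wave", "surge")
  for (v in vars) expect_true(all(ranked[[v]] %in% 1:5))
  # habitat presence is protective
  expect_true(all(ranked$habitats[pts$habitats == 1] == 1))
  expect_true(all(ranked$habitats[pts$habitats == 0] == 5))
  # low relief ranks as more exposed
  expect_equal(ranked$relief[which.min(pts$relief)], 5L)
})

test_that("removing habitat never lowers exposure at any point", {
  pts <- simulate_shore_points(shoreline_length = 10000, spacing = 250,
                               seed = 29L)
  ranked <- rank_shore_points(pts)
  sc <- scenario_compare(ranked, 1, 5)
  expect_true(all(sc$points$ei_without_habitat >=
                  sc$points$ei_with_habitat))
  # high + very-high share is non-decreasing without the habitat
  high <- c("high", "very high")
  share <- function(col) sum(sc$summary[[col]][
    sc$summary$risk_class %in% high])
  expect_gte(share("without_habitat_pct"), share("with_habitat_pct"))
  # class percentages partition each scenario
  expect_equal(sum(sc$summary$with_habitat_pct), 100)
  expect_equal(sum(sc$summary$without_habitat_pct), 100)
})

test_that("equal habitat ranks collapse the two scenarios", {
  pts <- simulate_shore_points(seed = 31L)
  ranked <- rank_shore_points(pts)
  sc <- scenario_compare(ranked, 3, 3)
  expect_equal(sc$points$ei_with_habitat, sc$points$ei_without_habitat)
  expect_error(scenario_compare(ranked, 4, 2), ">=")
})

test_that("the closed-form habitat shift matches the derivation", {
  # all other ranks 3: EI rises from (3^5)^(1/6) to (3^5 * 5)^(1/6)
  base <- data.frame(geomorphology = 3, relief = 3, habitats = 1,
                     wind = 3, wave = 3, surge = 3)
  sc <- scenario_compare(base, 1, 5)
  expect_equal(sc$points$ei_with_habitat, 243^(1 / 6), tolerance = 1e-9)
  expect_equal(sc$points$ei_without_habitat, 1215^(1 / 6),
               tolerance = 1e-9)
})
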