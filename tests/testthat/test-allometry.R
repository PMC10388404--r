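test_that("the three models reproduce the published plot-4 tree", {
  # single tree: D = 4.48 cm, H = 6.10 m, rho = 0.87 g/cm3
  expect_equal(agb_komiyama(4.48, 0.87), 8.75, tolerance = 0.005)
  expect_equal(agb_chave(4.48, 6.10, 0.87), 5.43, tolerance = 0.005)
  expect_equal(agb_njana(4.48, 6.10, 0.87), 11.54, tolerance = 0.005)
})

test_that("unit and zero inputs give the model coefficients and zero", {
  expect_equal(agb_komiyama(1, 1), 0.251)
  expect_equal(agb_chave(1, 1, 1), 0.0509)
  expect_equal(agb_njana(1, 1, 1), 0.353)
  expect_equal(agb_komiyama(0, 0.87), 0)
  expect_equal(agb_chave(5, 0, 0.87), 0)
  expect_equal(agb_njana(0, 5, 0.87), 0)
  expect_error(agb_komiyama(-1, 0.87), "negative dbh")
  expect_error(agb_chave(1, -2, 0.87), "negative height")
})

test_that("models are strictly increasing in every argument", {
  d <- seq(0.5, 10, by = 0.5)
  expect_true(all(diff(agb_komiyama(d, 0.87)) > 0))
  expect_true(all(diff(agb_chave(d, 5, 0.87)) > 0))
  expect_true(all(diff(agb_chave(5, d, 0.87)) > 0))
  expect_true(all(diff(agb_njana(d, 5, 0.87)) > 0))
  expect_true(all(diff(agb_njana(5, d, 0.87)) > 0))
  rho <- seq(0.6, 1.2, by = 0.1)
  expect_true(all(diff(agb_komiyama(5, rho)) > 0))
  expect_true(all(diff(agb_njana(5, 5, rho)) > 0))
})

test_that("model ordering on the plot-4 tree is Chave < Komiyama < Njana", {
  ch <- agb_chave(4.48, 6.10, 0.87)
  ko <- agb_komiyama(4.48, 0.87)
  nj <- agb_njana(4.48, 6.10, 0.87)
  expect_lt(ch, ko)
  expect_lt(ko, nj)
})

test_that("wood density resolution follows the policy", {
  expect_equal(resolve_density("anything"), 0.87)
  expect_equal(resolve_density("Rhizophora mucronata",
                               policy = "species_middle"), 1.02)
  expect_warning(
    d <- resolve_density(c("Rhizophora mucronata", "Unknown sp."),
                         policy = "species_middle"),
    "Unknown sp.")
  expect_equal(d, c(1.02, 0.87))
  # the table's middle-column mean is close to, but not exactly, the default
  expect_equal(mean(wood_density_table()$middle), 0.8725)
})

test_that("plot aggregation sums trees and converts to Mg/ha", {
  inv <- data.frame(plot_id = c(1, 1, 2), species = "x",
                    dbh_cm = c(4.48, 4.48, 4.48),
                    height_m = c(6.1, 6.1, 6.1))
  out <- aggregate_plots(inv, "komiyama", n_plots = 3)
  one_tree <- agb_komiyama(4.48, 0.87)
  expect_equal(out$agb_kg, c(2 * one_tree, one_tree, 0))
  expect_equal(out$n_trees, c(2L, 1L, 0L))
  # one ~8.74-kg tree on 25 m2 is ~3.50 Mg/ha; conversion is exact
  expect_equal(out$agb_mg_ha[2], out$agb_kg[2] / 1000 / (25 / 1e4))
  expect_equal(out$agb_mg_ha[2], 3.50, tolerance = 0.005)
  # empty plot reports zero, mirroring the bare landward plot
  expect_equal(out$agb_kg[3], 0)
})

test_that("aggregation is additive over a plot partition", {
  inv <- simulate_inventory(seed = 17L)
  all_plots <- aggregate_plots(inv, "njana")
  by_plot <- vapply(seq_len(attr(inv, "n_plots")), function(p) {
    sub <- inv[inv$plot_id == p, , drop = FALSE]
    attr(sub, "plot_area") <- attr(inv, "plot_area")
    sum(aggregate_plots(sub, "njana", n_plots = p)$agb_kg)
  }, 0)
  expect_equal(all_plots$agb_kg, by_plot)
})

test_that("the 2-m height threshold filters stems by default", {
  inv <- data.frame(plot_id = 1, species = "x",
                    dbh_cm = c(3, 3), height_m = c(1.5, 4))
  filtered <- aggregate_plots(inv, "chave", n_plots = 1)
  expect_equal(filtered$n_trees, 1L)
  unfiltered <- aggregate_plots(inv, "chave", n_plots = 1,
                                min_height_m = NULL)
  expect_equal(unfiltered$n_trees, 2L)
  expect_gt(unfiltered$agb_kg, filtered$agb_kg)
})
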