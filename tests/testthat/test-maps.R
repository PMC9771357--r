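# Optogenetic map analysis: detection-probability filtering, island
# removal, footprints, convergence.

planted_block <- function(r0, c0, h, w) {
  tidyr::expand_grid(row = r0:(r0 + h - 1), col = c0:(c0 + w - 1))
}

test_that("detection-probability rule keeps pixels at p >= 0.5", {
  planted <- planted_block(10, 10, 3, 3)
  grid <- gen_map_trials(planted, repeats = 3, response_prob = 1, seed = 1)
  # make one planted pixel respond in 2 of 3 repeats (p = 0.67): retained
  grid$amplitude_pA[grid$row == 10 & grid$col == 10 & grid$rep == 1] <- 0
  fld <- build_input_map(grid)
  expect_true(any(fld$pixels$row == 10 & fld$pixels$col == 10))
  expect_equal(nrow(fld$pixels), 9)
  expect_equal(fld$area_um2, 9 * 256)
  expect_equal(fld$n_clusters, 1)
})

test_that("response probability below the filter rejects the field", {
  planted <- planted_block(5, 5, 3, 3)
  grid <- gen_map_trials(planted, repeats = 3, response_prob = 0.4, seed = 3)
  fld <- build_input_map(grid)
  expect_lt(nrow(fld$pixels), 9)
})

test_that("isolated single pixels are excluded as spontaneous events", {
  planted <- dplyr::bind_rows(planted_block(8, 8, 3, 3),
                              tibble::tibble(row = 25, col = 25))
  grid <- gen_map_trials(planted, repeats = 2, response_prob = 1, seed = 2)
  fld <- build_input_map(grid)
  expect_false(any(fld$pixels$row == 25))
  expect_equal(nrow(fld$pixels), 9)
})

test_that("planted fields are recovered exactly under contamination", {
  planted <- planted_block(12, 6, 3, 4)
  hits <- 0
  for (s in 1:40) {
    grid <- gen_map_trials(planted, repeats = 3, response_prob = 1,
                           spont_prob = 0.004, seed = s)
    fld <- build_input_map(grid)
    got <- paste(fld$pixels$row, fld$pixels$col)
    want <- paste(planted$row, planted$col)
    hits <- hits + setequal(got, want)
  }
  expect_gte(hits / 40, 0.9)
})

test_that("two disjoint planted fields give two clusters and ratio 2", {
  planted <- dplyr::bind_rows(planted_block(5, 5, 3, 3),
                              planted_block(20, 20, 3, 3))
  grid <- gen_map_trials(planted, repeats = 3, response_prob = 1, seed = 4)
  fld <- build_input_map(grid)
  expect_equal(fld$n_clusters, 2)
  conv <- convergence_estimate(fld, footprint_areas = 9 * 256)
  expect_equal(conv$ratio, 2)
  # map area additivity: union area equals the sum over clusters
  by_cluster <- table(fld$pixels$cluster)
  expect_equal(sum(by_cluster) * 256, fld$area_um2)
})

test_that("footprints require consistent spiking across all repeats", {
  planted <- planted_block(15, 15, 4, 4)
  grid <- gen_map_trials(planted, repeats = 2, response_prob = 1,
                         spike = TRUE, seed = 6)
  # remove one pixel's spike in one repeat: 1/2 consistency -> excluded
  grid$spike[grid$row == 15 & grid$col == 15 & grid$rep == 2] <- FALSE
  fp <- build_footprint(grid)
  expect_false(any(fp$pixels$row == 15 & fp$pixels$col == 15))
  expect_equal(nrow(fp$pixels), 15)
  # empty grid: empty footprint
  empty <- gen_map_trials(planted[0, ], repeats = 2, spike = TRUE, seed = 7)
  expect_equal(build_footprint(empty)$area_um2, 0)
})

test_that("footprint recovery tolerates spontaneous spiking", {
  planted <- planted_block(10, 18, 4, 3)
  hits <- 0
  for (s in 1:30) {
    grid <- gen_map_trials(planted, repeats = 3, response_prob = 1,
                           spont_prob = 0.03, spike = TRUE, seed = 50 + s)
    fp <- build_footprint(grid)
    got <- paste(fp$pixels$row, fp$pixels$col)
    hits <- hits + setequal(got, paste(planted$row, planted$col))
  }
  expect_gte(hits / 30, 0.85)
})

test_that("convergence interpretation follows the area ratio", {
  expect_match(convergence_estimate(1.5 * 2560, 2560)$interpretation,
               "one to two")
  expect_equal(convergence_estimate(2560, 2560)$ratio, 1)
  expect_error(convergence_estimate(2560, 0), "positive")
})
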