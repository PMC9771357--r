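# Wiring generator: determinism, convergence ratios, feedback toggle,
# non-reciprocity, eligibility spans.

test_that("network build is deterministic and respects convergence ratios", {
  cfg <- tiny_config(seed = 3)
  net1 <- build_network(cfg)
  net2 <- build_network(cfg)
  expect_identical(network_edges(net1), network_edges(net2))
  # every granule cell has exactly 4 mossy-fiber sources
  expect_true(all(tabulate(net1$projections$mf_grc$tgt,
                           net1$pops[["grc"]]) == 4L))
  # one parallel-fiber synapse per granule cell
  expect_length(net1$projections$grc_pc$src, net1$pops[["grc"]])
  expect_identical(sort(unique(net1$projections$grc_pc$src)),
                   seq_len(net1$pops[["grc"]]))
  expect_invisible(validate_network(net1))
})

test_that("feedback toggle removes only the PC->PC-MLI projection", {
  on <- build_network(tiny_config(seed = 5, feedback = TRUE))
  off <- build_network(tiny_config(seed = 5, feedback = FALSE))
  expect_length(off$projections$pc_bc$src, 0)
  expect_gt(length(on$projections$pc_bc$src), 0)
  for (nm in setdiff(names(on$projections), "pc_bc")) {
    expect_identical(on$projections[[nm]][c("src", "tgt", "weight")],
                     off$projections[[nm]][c("src", "tgt", "weight")],
                     info = nm)
  }
})

test_that("PC/basket wiring is non-reciprocal and feedback hits only PC-MLIs", {
  for (seed in 1:5) {
    net <- build_network(tiny_config(seed = seed))
    p <- net$projections
    expect_true(all(p$pc_bc$tgt %in% net$pcmli_idx))
    fwd <- paste(p$pc_bc$src, p$pc_bc$tgt)
    rev <- paste(p$bc_pc$tgt, p$bc_pc$src)
    expect_length(intersect(fwd, rev), 0)
    # every PC-MLI receives one or two converging PCs
    conv <- tabulate(p$pc_bc$tgt, net$pops[["bc"]])[net$pcmli_idx]
    expect_true(all(conv %in% 1:2))
  }
})

test_that("scaled build keeps granule count and convergence exact", {
  cfg <- sim_config(seed = 1, scale_factor = 1 / 6)
  expect_identical(cfg$n_grc, 2000L)
  net <- build_network(cfg)
  # exhaustive edge count over the adjacency
  counts <- tabulate(net$projections$mf_grc$tgt, 2000)
  expect_identical(unique(counts), 4L)
  expect_length(net$projections$grc_pc$src, 2000)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_pc = 0), "positive")
  expect_error(sim_config(n_pcmli = 200, n_bc = 96), "n_pcmli")
  expect_error(sim_config(scale_factor = 0), "scale_factor")
  expect_error(sim_config(dt = 0.5), "dt")
})

test_that("granule axon contact areas are narrow transverse rectangles", {
  net <- build_network(tiny_config(seed = 2))
  for (nm in c("grc_goc", "grc_bc", "grc_sc")) {
    sp <- net$projections[[nm]]$span
    expect_gt(sp[["hx"]], sp[["hy"]])
  }
})

test_that("edge list round-trips through CSV with 0-based indices", {
  net <- build_network(tiny_config(seed = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_network_edges(net, path)
  edges <- utils::read.csv(path)
  expect_identical(min(edges$source_idx), 0L)
  expect_identical(nrow(edges), nrow(network_edges(net)))
})

test_that("config JSON round-trips and rejects unknown keys", {
  cfg <- sim_config(seed = 9, n_pc = 12)
  path <- withr::local_tempfile(fileext = ".json")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_identical(back$n_pc, 12L)
  expect_identical(back$seed, 9L)
  bad <- jsonlite::read_json(path)
  bad$bogus_key <- 1
  jsonlite::write_json(bad, path, auto_unbox = TRUE)
  expect_error(read_sim_config(path), "unknown config keys")
})
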