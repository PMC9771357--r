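# Wiring generator: realizes the circuit's cell counts, geometric eligibility
# spans on the 2-D cell sheet, fixed convergence ratios, and the non-reciprocal
# PC -> PC-MLI feedback projection.

.grid_positions <- function(n, aspect = 1) {
  nx <- max(1L, as.integer(ceiling(sqrt(n * aspect))))
  ny <- as.integer(ceiling(n / nx))
  ix <- ((seq_len(n) - 1L) %% nx) + 1L
  iy <- ((seq_len(n) - 1L) %/% nx) + 1L
  cbind(x = (ix - 0.5) / nx, y = (iy - 0.5) / ny)
}

# sample k sources whose sheet position lies inside a rectangular eligibility
# span centred on `center`; the span is widened (geometrically) if it holds
# fewer than k candidates, and the widest span actually used is reported so
# span-membership stays a checkable invariant.
.sample_in_span <- function(pos, center, hx, hy, k, exclude = integer()) {
  hx0 <- hx; hy0 <- hy
  repeat {
    ok <- which(abs(pos[, 1] - center[1]) <= hx &
                abs(pos[, 2] - center[2]) <= hy)
    ok <- setdiff(ok, exclude)
    if (length(ok) >= k || (hx >= 1 && hy >= 1)) break
    hx <- min(1, hx * 1.5); hy <- min(1, hy * 1.5)
  }
  if (length(ok) < k) {
    stop("wiring error: not enough eligible sources (need ", k, ", have ",
         length(ok), ")", call. = FALSE)
  }
  idx <- if (length(ok) == 1) ok else sample(ok, k)
  list(idx = idx, hx = hx, hy = hy)
}

.projection <- function(src_pop, tgt_pop, slot, src, tgt, weight, span = NULL) {
  list(src_pop = src_pop, tgt_pop = tgt_pop, slot = slot,
       src = as.integer(src), tgt = as.integer(tgt),
       weight = rep_len(as.numeric(weight), length(src)), span = span)
}

#' Build the wired cerebellar network
#'
#' Places granule cells, Golgi cells and mossy-fiber glomeruli on a 2-D sheet,
#' draws every projection randomly inside its geometric eligibility span while
#' enforcing the circuit's convergence ratios (each granule cell receives
#' exactly four mossy-fiber inputs; each granule cell places one parallel-fiber
#' synapse on one Purkinje cell, so the granule-to-PC synapse count equals the
#' granule count), and wires the feedback circuit: each designated PC-MLI
#' (a subset of basket cells) receives input from one or two nearby Purkinje
#' cells, and basket-to-PC edges exclude any pair that would be reciprocal.
#'
#' Granule-cell axons (parallel fibers) run transversely, so granule output
#' spans are narrow transverse rectangles; mossy-fiber and Golgi input spans
#' are squares centred on the target.
#'
#' @param config A [sim_config()] object.
#' @return A `pcmli_network`: list with `config`, `pops` (named counts),
#'   `params`, `placement`, `pcmli_idx` (basket-cell indices designated
#'   PC-MLI), `pc_of_grc` (the PC index each granule cell synapses on) and
#'   `projections` (named list of edge lists).
#' @export
#' @examples
#' net <- build_network(sim_config(seed = 1, scale_factor = 1 / 24))
#' table(tabulate(net$projections$mf_grc$tgt)) # every granule cell: 4 inputs
build_network <- function(config) {
  stopifnot(inherits(config, "pcmli_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  pops <- c(mf = config$n_mf, grc = config$n_grc, goc = config$n_goc,
            pc = config$n_pc, bc = config$n_bc, sc = config$n_sc,
            dcn = config$n_dcn, cf = config$n_cf)
  pos <- list(
    mf  = .grid_positions(pops[["mf"]]),
    grc = .grid_positions(pops[["grc"]], aspect = 4),
    goc = .grid_positions(pops[["goc"]]),
    pc  = cbind(x = rep(0.5, pops[["pc"]]),
                y = (seq_len(pops[["pc"]]) - 0.5) / pops[["pc"]]),
    bc  = cbind(x = rep(0.5, pops[["bc"]]),
                y = (seq_len(pops[["bc"]]) - 0.5) / pops[["bc"]]),
    sc  = cbind(x = rep(0.5, pops[["sc"]]),
                y = (seq_len(pops[["sc"]]) - 0.5) / pops[["sc"]])
  )
  pcmli_idx <- sort(sample(pops[["bc"]], config$n_pcmli))

  if (pops[["mf"]] < 4) {
    stop("configuration error: at least 4 mossy fibers required",
         call. = FALSE)
  }
  conv <- list(mf_grc = 4L, goc_grc = min(4L, pops[["goc"]]),
               mf_goc = min(12L, pops[["mf"]]),
               grc_goc = min(50L, pops[["grc"]]),
               grc_bc = min(80L, pops[["grc"]]),
               grc_sc = min(80L, pops[["grc"]]),
               bc_pc = max(1L, min(6L, pops[["bc"]] - config$n_pcmli)),
               sc_pc = min(10L, pops[["sc"]]),
               mf_dcn = min(60L, pops[["mf"]]))

  draw_many <- function(src_pos, tgt_pos, k, hx, hy) {
    n_tgt <- nrow(tgt_pos)
    src <- integer(n_tgt * k); hx_max <- hx; hy_max <- hy
    for (j in seq_len(n_tgt)) {
      s <- .sample_in_span(src_pos, tgt_pos[j, ], hx, hy, k)
      src[((j - 1) * k + 1):(j * k)] <- s$idx
      hx_max <- max(hx_max, s$hx); hy_max <- max(hy_max, s$hy)
    }
    list(src = src, tgt = rep(seq_len(n_tgt), each = k),
         span = c(hx = hx_max, hy = hy_max))
  }

  proj <- list()
  e <- draw_many(pos$mf, pos$grc, conv$mf_grc, 0.25, 0.25)
  proj$mf_grc <- .projection("mf", "grc", "mf", e$src, e$tgt, 1, e$span)
  e <- draw_many(pos$goc, pos$grc, conv$goc_grc, 0.15, 0.15)
  proj$goc_grc <- .projection("goc", "grc", "goc", e$src, e$tgt, 1, e$span)
  e <- draw_many(pos$mf, pos$goc, conv$mf_goc, 0.25, 0.25)
  proj$mf_goc <- .projection("mf", "goc", "mf", e$src, e$tgt, 1, e$span)
  e <- draw_many(pos$grc, pos$goc, conv$grc_goc, 0.5, 0.08)
  proj$grc_goc <- .projection("grc", "goc", "grc", e$src, e$tgt, 1, e$span)

  # parallel fibers: each granule cell contacts the PC whose sagittal band
  # contains its beam (one synapse per granule cell; plastic weights)
  band <- floor(pos$grc[, 2] * pops[["pc"]]) + 1L
  pc_of_grc <- pmin(pops[["pc"]], pmax(1L, as.integer(band)))
  proj$grc_pc <- .projection("grc", "pc", "pf", seq_len(pops[["grc"]]),
                             pc_of_grc, 1.0, c(hx = 0.5, hy = 1 / pops[["pc"]]))

  e <- draw_many(pos$grc, pos$bc, conv$grc_bc, 0.5, 0.08)
  # inner-molecular-layer basket cells designated PC-MLI carry denser
  # parallel-fiber input, poising them near threshold so that feedback
  # disinhibition can drive them; calibration choice
  w_bc <- ifelse(e$tgt %in% pcmli_idx, 1.0, 0.5)
  proj$grc_bc <- .projection("grc", "bc", "pf", e$src, e$tgt, w_bc, e$span)
  e <- draw_many(pos$grc, pos$sc, conv$grc_sc, 0.5, 0.08)
  proj$grc_sc <- .projection("grc", "sc", "pf", e$src, e$tgt, 0.5, e$span)

  # PC -> PC-MLI feedback: one or two converging PCs per designated PC-MLI.
  # Each converging PC carries an equal share of the strong perisomatic
  # inhibition, so total feedback conductance is convergence-invariant.
  fb_src <- integer(0); fb_tgt <- integer(0); fb_w <- numeric(0)
  fb_span <- c(hx = 1, hy = 0.35)
  for (j in pcmli_idx) {
    k <- sample(1:2, 1)
    s <- .sample_in_span(pos$pc, pos$bc[j, ], 1, 0.35, k)
    fb_src <- c(fb_src, s$idx); fb_tgt <- c(fb_tgt, rep(j, k))
    fb_w <- c(fb_w, rep(1 / k, k))
    fb_span["hy"] <- max(fb_span[["hy"]], s$hy)
  }
  if (config$feedback_enabled) {
    proj$pc_bc <- .projection("pc", "bc", "pc", fb_src, fb_tgt, fb_w, fb_span)
  } else {
    proj$pc_bc <- .projection("pc", "bc", "pc", integer(0), integer(0),
                              numeric(0), fb_span)
  }

  # basket -> PC, excluding reciprocal pairs with the feedback projection
  # (exclusion uses the designated wiring whether or not feedback is enabled,
  # so the two builds differ only in the pc_bc projection itself)
  bc_src <- integer(0); bc_tgt <- integer(0)
  bc_span <- c(hx = 1, hy = 0.35)
  for (i in seq_len(pops[["pc"]])) {
    excl <- fb_tgt[fb_src == i]
    s <- .sample_in_span(pos$bc, pos$pc[i, ], 1, 0.35, conv$bc_pc,
                         exclude = excl)
    bc_src <- c(bc_src, s$idx); bc_tgt <- c(bc_tgt, rep(i, conv$bc_pc))
    bc_span["hy"] <- max(bc_span[["hy"]], s$hy)
  }
  # basket (perisomatic/pinceau) synapses are stronger than stellate ones;
  # PC-MLIs additionally contact every non-partner PC with strong synapses,
  # closing the disinhibition loop (PC pause -> PC-MLI burst -> deeper pause
  # in neighboring PCs)
  bc_w <- rep(3, length(bc_src))
  for (j in pcmli_idx) {
    partners <- fb_src[fb_tgt == j]
    tgts <- setdiff(seq_len(pops[["pc"]]), partners)
    bc_src <- c(bc_src, rep(j, length(tgts)))
    bc_tgt <- c(bc_tgt, tgts)
    bc_w <- c(bc_w, rep(6, length(tgts)))
  }
  proj$bc_pc <- .projection("bc", "pc", "inh", bc_src, bc_tgt, bc_w, bc_span)
  e <- draw_many(pos$sc, pos$pc, conv$sc_pc, 1, 0.35)
  proj$sc_pc <- .projection("sc", "pc", "inh", e$src, e$tgt, 1, e$span)

  # climbing fibers: contiguous sagittal blocks of PCs per fiber
  cf_of_pc <- as.integer(ceiling(seq_len(pops[["pc"]]) * pops[["cf"]] /
                                   pops[["pc"]]))
  proj$cf_pc <- .projection("cf", "pc", "cf", cf_of_pc, seq_len(pops[["pc"]]), 1)

  # PC -> DCN (all-to-all) and mossy-fiber -> DCN (plastic)
  proj$pc_dcn <- .projection(
    "pc", "dcn", "pc",
    rep(seq_len(pops[["pc"]]), times = pops[["dcn"]]),
    rep(seq_len(pops[["dcn"]]), each = pops[["pc"]]), 1)
  mfd_src <- unlist(lapply(seq_len(pops[["dcn"]]), function(j)
    sample(pops[["mf"]], conv$mf_dcn)))
  proj$mf_dcn <- .projection("mf", "dcn", "mf", mfd_src,
                             rep(seq_len(pops[["dcn"]]), each = conv$mf_dcn),
                             0.5)

  structure(
    list(config = config, pops = pops, params = config$neuron_params,
         placement = pos, pcmli_idx = pcmli_idx, pc_of_grc = pc_of_grc,
         cf_of_pc = cf_of_pc, projections = proj),
    class = "pcmli_network")
}

#' @export
print.pcmli_network <- function(x, ...) {
  cat("<pcmli_network>\n  populations:",
      paste(names(x$pops), x$pops, sep = "=", collapse = " "), "\n",
      " feedback:", if (x$config$feedback_enabled) "on" else "off",
      sprintf("(%d PC-MLIs)", x$config$n_pcmli), "\n",
      " edges:", sum(vapply(x$projections, function(p) length(p$src), 1L)),
      "\n")
  invisible(x)
}

#' Network adjacency as a tidy edge table
#'
#' @param network A `pcmli_network`.
#' @return A tibble with columns `projection`, `source_pop`, `source_idx`,
#'   `target_pop`, `target_idx`, `weight`; indices are 0-based to match the
#'   on-disk edge-list format.
#' @export
network_edges <- function(network) {
  stopifnot(inherits(network, "pcmli_network"))
  purrr::map_dfr(names(network$projections), function(nm) {
    p <- network$projections[[nm]]
    tibble::tibble(projection = nm, source_pop = p$src_pop,
                   source_idx = p$src - 1L, target_pop = p$tgt_pop,
                   target_idx = p$tgt - 1L, weight = p$weight)
  })
}

#' Write the adjacency edge list as CSV
#'
#' @param network A `pcmli_network`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_network_edges <- function(network, path) {
  utils::write.csv(
    network_edges(network)[, c("source_pop", "source_idx", "target_pop",
                               "target_idx", "weight")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check the structural invariants of a built network
#'
#' Verifies population sizes, the four-mossy-fibers-per-granule-cell
#' convergence, that PC->basket edges terminate only on designated PC-MLIs,
#' non-reciprocity of the PC/basket wiring, and span membership of every edge.
#'
#' @param network A `pcmli_network`.
#' @return `TRUE` invisibly; stops with an informative message on violation.
#' @export
validate_network <- function(network) {
  p <- network$projections
  if (any(tabulate(p$mf_grc$tgt, network$pops[["grc"]]) != 4L))
    stop("granule cells must have exactly 4 mossy-fiber sources")
  if (length(p$pc_bc$tgt) && !all(p$pc_bc$tgt %in% network$pcmli_idx))
    stop("PC->basket edges must terminate on designated PC-MLIs")
  fwd <- paste(p$pc_bc$src, p$pc_bc$tgt)
  rev <- paste(p$bc_pc$tgt, p$bc_pc$src)
  if (length(intersect(fwd, rev)))
    stop("reciprocal PC/basket pair found")
  for (nm in c("mf_grc", "goc_grc", "mf_goc", "grc_goc", "grc_bc", "grc_sc")) {
    pr <- p[[nm]]
    sp <- network$placement[[pr$src_pop]][pr$src, , drop = FALSE]
    tp <- network$placement[[pr$tgt_pop]][pr$tgt, , drop = FALSE]
    if (any(abs(sp[, 1] - tp[, 1]) > pr$span[["hx"]] + 1e-12) ||
        any(abs(sp[, 2] - tp[, 2]) > pr$span[["hy"]] + 1e-12))
      stop("edge outside eligibility span in projection ", nm)
  }
  invisible(TRUE)
}
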