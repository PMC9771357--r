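# Optogenetic photostimulation-map analysis: input fields from IPSC
# detection probability across repeats, optical footprints from consistent
# spiking, and the convergence estimate from their area ratio.

.GRID_DIM <- 32L
.PIXEL_AREA_UM2 <- 16^2

# 4-connectivity connected components on a logical pixel set
.components <- function(pixels) {
  if (!nrow(pixels)) return(integer(0))
  key <- paste(pixels$row, pixels$col)
  idx <- stats::setNames(seq_len(nrow(pixels)), key)
  comp <- integer(nrow(pixels))
  cur <- 0L
  for (s in seq_len(nrow(pixels))) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      nb <- c(paste(pixels$row[i] + 1, pixels$col[i]),
              paste(pixels$row[i] - 1, pixels$col[i]),
              paste(pixels$row[i], pixels$col[i] + 1),
              paste(pixels$row[i], pixels$col[i] - 1))
      for (k in nb) {
        j <- idx[k]
        if (!is.na(j) && !comp[j]) {
          comp[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

#' Build a synaptic input map from repeated photostimulation grids
#'
#' Computes, for each pixel of the 32 x 32 scanning grid (16-um spacing),
#' the probability across repeats that an IPSC was detected; pixels with
#' probability >= 0.5 are considered to arise from photostimulation of
#' presynaptic PCs rather than spontaneous activity. Isolated single pixels
#' (4-connectivity islands of size 1) are excluded as spontaneous
#' contamination. The input-field area is the retained pixel count times
#' 256 um^2.
#'
#' @param grid Tibble with columns `row`, `col`, `rep` and either logical
#'   `detected` or numeric `amplitude_pA` (thresholded at
#'   `threshold_pA`).
#' @param threshold_pA IPSC detection threshold when amplitudes are given.
#' @param min_prob Detection-probability cutoff.
#' @return A `pcmli_field`: list with `pixels` (tibble `row`, `col`,
#'   `prob`, `cluster`), `area_um2`, `n_clusters`, `n_repeats`.
#' @export
build_input_map <- function(grid, threshold_pA = 15, min_prob = 0.5) {
  det <- if ("detected" %in% names(grid)) grid$detected else
    grid$amplitude_pA >= threshold_pA
  n_rep <- length(unique(grid$rep))
  if (n_rep < 2) {
    warning("single repeat: no detection-probability filtering possible")
  }
  prob <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(row = grid$row, col = grid$col, det = det),
                    .data$row, .data$col),
    prob = mean(.data$det), .groups = "drop")
  keep <- prob[prob$prob >= min_prob, ]
  comp <- .components(keep)
  if (length(comp)) {
    sizes <- tabulate(comp)
    keep <- keep[sizes[comp] > 1, , drop = FALSE]
    comp <- comp[sizes[comp] > 1]
    comp <- as.integer(factor(comp))
  }
  keep$cluster <- comp
  structure(list(pixels = keep, area_um2 = nrow(keep) * .PIXEL_AREA_UM2,
                 n_clusters = length(unique(comp)), n_repeats = n_rep),
            class = "pcmli_field")
}

#' Build an optical footprint from repeated spike maps
#'
#' A pixel belongs to a PC's optical footprint when photostimulation there
#' evoked an action potential within 0-14 ms of the light pulse in *every*
#' repeat.
#'
#' @param grid Tibble with columns `row`, `col`, `rep`, logical `spike`.
#' @return A `pcmli_field` (clusters computed as for input maps but single
#'   pixels retained, since consistency across repeats already filters
#'   spontaneous spikes).
#' @export
build_footprint <- function(grid) {
  n_rep <- length(unique(grid$rep))
  if (n_rep < 2) {
    warning("single repeat: consistency filtering not possible")
  }
  agg <- dplyr::summarise(
    dplyr::group_by(grid, .data$row, .data$col),
    all_reps = all(.data$spike) & dplyr::n() == n_rep, .groups = "drop")
  keep <- agg[agg$all_reps, c("row", "col")]
  keep$prob <- 1
  comp <- .components(keep)
  keep$cluster <- comp
  structure(list(pixels = keep, area_um2 = nrow(keep) * .PIXEL_AREA_UM2,
                 n_clusters = length(unique(comp)), n_repeats = n_rep),
            class = "pcmli_field")
}

#' @export
print.pcmli_field <- function(x, ...) {
  cat("<pcmli_field>", nrow(x$pixels), "pixels,", x$area_um2, "um^2,",
      x$n_clusters, "cluster(s)\n")
  invisible(x)
}

#' Estimate the number of converging presynaptic PCs
#'
#' The ratio of a PC-MLI's input-field area to the mean optical-footprint
#' area of single PCs estimates how many PCs converge on it; the observed
#' mean ratio of about 1.5 corresponds to one or two converging PCs.
#'
#' @param field A `pcmli_field` (input map) or its area in um^2.
#' @param footprint_areas Footprint areas (um^2) of reference PCs.
#' @return One-row tibble: `ratio`, `interpretation`, `n_clusters`.
#' @export
convergence_estimate <- function(field, footprint_areas) {
  area <- if (inherits(field, "pcmli_field")) field$area_um2 else
    as.numeric(field)
  ncl <- if (inherits(field, "pcmli_field")) field$n_clusters else NA_integer_
  fp <- mean(as.numeric(footprint_areas))
  if (!is.finite(fp) || fp <= 0) {
    stop("input error: footprint area must be positive", call. = FALSE)
  }
  ratio <- area / fp
  interp <- if (ratio >= 1 && ratio <= 2) "one to two converging PCs" else
    sprintf("about %d converging PCs", max(1L, round(ratio)))
  tibble::tibble(ratio = ratio, interpretation = interp, n_clusters = ncl)
}
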