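## quantification: summary tables, densities, depth-penetration QC.

#' Co-label percentage
#'
#' `100 * colabeled / total`, rounded half-up to one decimal — the
#' convention used in printed specificity tables, so published means
#' reproduce bit-exactly. Inputs may be raw counts or per-group means.
#'
#' @param total_spots total spot count (or mean count); must be > 0.
#' @param colabeled_spots spots also carrying the second label.
#' @return Percentage, one decimal.
#' @export
colabel_percentage <- function(total_spots, colabeled_spots) {
  sl_assert(is.numeric(total_spots) && total_spots > 0, "ZeroDenominator",
            "total_spots must be > 0")
  sl_assert(is.numeric(colabeled_spots) && colabeled_spots >= 0,
            "InvalidParams", "colabeled_spots must be >= 0")
  round_half_up(100 * colabeled_spots / total_spots, 1)
}

#' Percent change between two counts
#'
#' `100 * (new - old) / old`, rounded half-up to the nearest integer (e.g.
#' comparing SIM against confocal counts of the same field).
#'
#' @param new_count,old_count numeric; `old_count` must be > 0.
#' @return Integer percent change (negative for decreases).
#' @export
percent_change <- function(new_count, old_count) {
  sl_assert(is.numeric(old_count) && old_count > 0, "ZeroDenominator",
            "old_count must be > 0")
  round_half_up(100 * (new_count - old_count) / old_count, 0)
}

#' Synapse density and comparison to a reference density
#'
#' Converts a synapse count within a reference volume to synapses per
#' cubic millimetre (`count / volume_um3 * 1e9`) and, when a reference
#' density is supplied (e.g. an electron-microscopy estimate), the ratio of
#' the measured to the reference density.
#'
#' @param count synapse count (non-negative).
#' @param volume_um3 reference volume in cubic micrometres; must be > 0.
#' @param reference_density_per_mm3 optional reference density (per mm^3).
#' @return A `density_report`: `count`, `reference_volume_um3`,
#'   `density_per_mm3`, and optionally `reference_density_per_mm3`,
#'   `ratio_to_reference`.
#' @export
synapse_density <- function(count, volume_um3,
                            reference_density_per_mm3 = NULL) {
  sl_assert(is.numeric(volume_um3) && volume_um3 > 0, "ZeroDenominator",
            "volume_um3 must be > 0")
  sl_assert(is.numeric(count) && count >= 0, "InvalidParams",
            "count must be >= 0")
  dens <- count / volume_um3 * 1e9
  out <- list(count = count, reference_volume_um3 = volume_um3,
              density_per_mm3 = dens)
  if (!is.null(reference_density_per_mm3)) {
    sl_assert(reference_density_per_mm3 > 0, "ZeroDenominator",
              "reference density must be > 0")
    out$reference_density_per_mm3 <- reference_density_per_mm3
    out$ratio_to_reference <- dens / reference_density_per_mm3
  }
  structure(out, class = "density_report")
}

#' @export
print.density_report <- function(x, ...) {
  cat(sprintf("density_report: %g synapses in %g um^3 = %.4g per mm^3\n",
              x$count, x$reference_volume_um3, x$density_per_mm3))
  if (!is.null(x$ratio_to_reference))
    cat(sprintf("  ratio to reference (%.4g per mm^3): %.3f\n",
                x$reference_density_per_mm3, x$ratio_to_reference))
  invisible(x)
}

#' Antibody-penetration depth QC histogram
#'
#' Bins spot depths (um, measured from the top optical slice) into
#' fixed-width bins, computes the cumulative fraction per bin, and reports
#' the cutoff depth: the upper edge of the first bin whose cumulative
#' fraction reaches `cutoff_fraction`. Analysis deeper than the cutoff is
#' unreliable because label penetration falls off. Conventional bin widths
#' are 5 um for soma/proximal stacks and 3 um for distal-dendrite stacks.
#'
#' @param spots a non-empty `spot_set`.
#' @param bin_size_um positive bin width in micrometres.
#' @param cutoff_fraction cumulative-fraction cutoff in (0, 1]; default
#'   0.85.
#' @return A `depth_histogram`: `bin_size_um`, `bin_edges_um`, `counts`,
#'   `cumulative_fraction`, `cutoff_fraction`, `cutoff_depth_um`.
#' @export
depth_qc <- function(spots, bin_size_um = 5, cutoff_fraction = 0.85) {
  sl_assert(n_spots(spots) > 0, "EmptySpotSet", "spot set is empty")
  sl_assert(bin_size_um > 0, "InvalidParams", "bin_size_um must be > 0")
  sl_assert(cutoff_fraction > 0 && cutoff_fraction <= 1, "InvalidParams",
            "cutoff_fraction must be in (0, 1]")
  depth <- spots$spots$depth_um
  nb <- max(1L, ceiling((max(depth) + .Machine$double.eps) / bin_size_um))
  edges <- seq(0, by = bin_size_um, length.out = nb + 1L)
  bin <- pmin(nb, floor(depth / bin_size_um) + 1L)
  counts <- tabulate(bin, nbins = nb)
  cum <- cumsum(counts) / sum(counts)
  cut_bin <- which(cum >= cutoff_fraction)[1]
  structure(list(bin_size_um = bin_size_um, bin_edges_um = edges,
                 counts = counts, cumulative_fraction = cum,
                 cutoff_fraction = cutoff_fraction,
                 cutoff_depth_um = edges[cut_bin + 1L]),
            class = "depth_histogram")
}

#' @export
print.depth_histogram <- function(x, ...) {
  cat(sprintf(
    "depth_histogram: %d bin(s) of %g um; %.0f%% cutoff at %g um\n",
    length(x$counts), x$bin_size_um, 100 * x$cutoff_fraction,
    x$cutoff_depth_um))
  invisible(x)
}

#' Filter paired spot sets to a common usable depth
#'
#' For a pre/post label pair the usable depth is set by the
#' worst-penetrating label: take the minimum cutoff across the pair's
#' depth histograms and drop all spots deeper than it from every set, so
#' the two labels are compared over the same depth range.
#'
#' @param spot_sets list of `spot_set`s.
#' @param cutoff_depth_um maximum retained depth (um); typically
#'   `min(vapply(histograms, function(h) h$cutoff_depth_um, 1.0))`.
#' @return List of filtered `spot_set`s in input order.
#' @export
apply_depth_cutoff <- function(spot_sets, cutoff_depth_um) {
  sl_assert(is.numeric(cutoff_depth_um) && is.finite(cutoff_depth_um),
            "InvalidParams", "cutoff_depth_um must be finite")
  lapply(spot_sets, function(s)
    subset_spots(s, s$spots$depth_um <= cutoff_depth_um))
}

#' Per-compartment count summary table
#'
#' Aggregates per-cell spot counts into mean ± SEM for every
#' (compartment, marker) group, mirroring compartment tables that report
#' soma + proximal dendrites and distal dendrites separately.
#' SEM = sample SD / sqrt(n); single-cell groups report SEM 0 and are
#' flagged.
#'
#' @param per_cell_results data.frame with columns `cell`, `compartment`
#'   (`"soma_proximal"` or `"distal_dendrite"`), `marker`, `count`.
#' @return data.frame of class `quant_table` with columns `marker`,
#'   `compartment`, `n_cells`, `mean_count`, `sem`, `single_cell`.
#' @export
build_compartment_table <- function(per_cell_results) {
  need <- c("cell", "compartment", "marker", "count")
  sl_assert(all(need %in% names(per_cell_results)), "InvalidParams",
            "per_cell_results must have columns %s",
            paste(need, collapse = ", "))
  sl_assert(all(per_cell_results$compartment %in%
                  c("soma_proximal", "distal_dendrite")), "InvalidParams",
            "compartment must be 'soma_proximal' or 'distal_dendrite'")
  groups <- unique(per_cell_results[, c("marker", "compartment")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- per_cell_results[
      per_cell_results$marker == groups$marker[i] &
        per_cell_results$compartment == groups$compartment[i], ]
    n <- nrow(g)
    data.frame(marker = groups$marker[i],
               compartment = groups$compartment[i],
               n_cells = n,
               mean_count = mean(g$count),
               sem = if (n > 1) sd(g$count) / sqrt(n) else 0,
               single_cell = n == 1)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("quant_table", "data.frame")
  out
}
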