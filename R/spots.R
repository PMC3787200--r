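## spot_detection: punctate immunolabels as discrete quantitative spots.

#' Spot detection parameters
#'
#' @param diameter_um nominal punctum diameter in micrometres. Typical
#'   values: 0.3 for pre-synaptic terminals (VGLUT2, VGAT), 0.6 for
#'   post-synaptic scaffolds/receptors (PSD-95, GABA-A alpha-1).
#' @param quality_threshold minimum spot quality. Quality is the
#'   scale-normalized Laplacian-of-Gaussian response at the spot centre
#'   (filtered-intensity units); pick it from [quality_histogram()] at the
#'   inflection/valley between dim candidates and genuine puncta. Imaris
#'   "arbitrary units" do not transfer to this scale.
#' @param background_subtraction subtract the per-slice depth background
#'   (see [estimate_depth_background()]) before filtering (default `TRUE`);
#'   compensates the rise in background with imaging depth.
#' @param min_z_slices candidates whose supra-threshold support spans fewer
#'   than this many contiguous optical slices are rejected (default 2,
#'   suppressing single-slice artifacts).
#' @return A list of class `spot_params`.
#' @export
spot_params <- function(diameter_um, quality_threshold,
                        background_subtraction = TRUE, min_z_slices = 2L) {
  sl_assert(is.numeric(diameter_um) && diameter_um > 0, "NonPositiveDiameter",
            "diameter_um must be > 0")
  sl_assert(is.numeric(quality_threshold) && is.finite(quality_threshold),
            "InvalidParams", "quality_threshold must be finite")
  sl_assert(min_z_slices >= 1, "InvalidParams", "min_z_slices must be >= 1")
  structure(list(diameter_um = diameter_um,
                 quality_threshold = quality_threshold,
                 background_subtraction = isTRUE(background_subtraction),
                 min_z_slices = as.integer(min_z_slices)),
            class = "spot_params")
}

new_spot_set <- function(spots, params, channel_role, source = list()) {
  structure(list(spots = spots, params = params,
                 channel_role = channel_role, source = source),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("spot_set: %d %s spot(s), diameter %.2f um\n",
              nrow(x$spots), x$channel_role, x$params$diameter_um))
  invisible(x)
}

#' Number of spots in a spot set
#' @param spots a `spot_set`.
#' @return integer count.
#' @export
n_spots <- function(spots) nrow(spots$spots)

#' Subset a spot set by row index
#' @param spots a `spot_set`.
#' @param i integer or logical index into the spot table.
#' @return a `spot_set` with the selected spots.
#' @export
subset_spots <- function(spots, i) {
  new_spot_set(spots$spots[i, , drop = FALSE], spots$params,
               spots$channel_role, spots$source)
}

#' Per-slice depth background profile
#'
#' Estimates, for every optical slice, the mean intensity of its
#' low-contrast voxels — those at or below the slice median of a
#' local-contrast image (absolute residual from a small Gaussian blur).
#' Bright puncta are high-contrast and therefore excluded, so the profile
#' tracks the diffuse background that grows with imaging depth.
#'
#' @param channel 3-D (z, y, x) numeric array.
#' @param contrast_sigma_vox per-axis blur sigmas (voxels) for the
#'   local-contrast filter (default `c(1, 2, 2)`).
#' @return Numeric vector, one background level per z-slice.
#' @export
estimate_depth_background <- function(channel,
                                      contrast_sigma_vox = c(1, 2, 2)) {
  sl_assert(is.array(channel) && length(dim(channel)) == 3L, "InvalidParams",
            "channel must be a 3-D array")
  contrast <- abs(channel - gauss_blur3(channel, contrast_sigma_vox))
  nz <- dim(channel)[1]
  vapply(seq_len(nz), function(z) {
    cs <- contrast[z, , ]
    low <- cs <= median(cs)
    mean(channel[z, , ][low])
  }, 1.0)
}

subtract_depth_background <- function(channel, profile) {
  out <- channel
  for (z in seq_len(dim(channel)[1])) out[z, , ] <- out[z, , ] - profile[z]
  pmax(out, 0)
}

# Scale-normalized blob filter: Gaussian smoothing at sigma matched to the
# punctum diameter (sigma_um = d / (2*sqrt(3)), the LoG optimum for a blob
# of diameter d), then -sigma^2 * Laplacian with physical spacings, so
# bright blobs become positive peaks and responses are comparable across
# diameters and voxel sizes.
log_filter <- function(channel, voxel_size, diameter_um) {
  sigma_um <- diameter_um / (2 * sqrt(3))
  sm <- gauss_blur3(channel, sigma_um / voxel_size)
  d <- dim(sm)
  lap <- array(0, d)
  for (ax in 1:3) {
    h <- voxel_size[ax]
    n <- d[ax]
    if (n < 3) next
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(sm, perm)
    m <- matrix(ap, nrow = n)
    dd <- m
    dd[2:(n - 1), ] <- (m[1:(n - 2), ] - 2 * m[2:(n - 1), ] + m[3:n, ]) / h^2
    dd[1, ] <- dd[2, ]; dd[n, ] <- dd[n - 1, ]   # replicate at borders
    dim(dd) <- dim(ap)
    lap <- lap + aperm(dd, order(perm))
  }
  -sigma_um^2 * lap
}

# Local maxima of a 3-D response over the 26-neighbourhood.  Plateaus are
# broken deterministically: a voxel loses to an equal-valued neighbour with
# a smaller (z, y, x) lexicographic key.
local_maxima3 <- function(resp, threshold) {
  d <- dim(resp)
  key <- array(seq_len(prod(d)), d)  # column-major order is (z fastest)
  # lexicographic (z,y,x): build explicit key with z most significant
  zi <- slice.index(resp, 1); yi <- slice.index(resp, 2)
  xi <- slice.index(resp, 3)
  lex <- (zi * 1.0 * d[2] + yi) * d[3] + xi
  cand <- resp >= threshold
  offs <- rbind(.offsets26_forward, -.offsets26_forward)
  for (k in seq_len(nrow(offs))) {
    if (!any(cand)) break
    o <- offs[k, ]
    dst_z <- max(1, 1 + o[1]):min(d[1], d[1] + o[1])
    dst_y <- max(1, 1 + o[2]):min(d[2], d[2] + o[2])
    dst_x <- max(1, 1 + o[3]):min(d[3], d[3] + o[3])
    src_z <- dst_z - o[1]; src_y <- dst_y - o[2]; src_x <- dst_x - o[3]
    rv <- resp[dst_z, dst_y, dst_x]
    nv <- resp[src_z, src_y, src_x]
    beat <- nv > rv | (nv == rv & lex[src_z, src_y, src_x] <
                         lex[dst_z, dst_y, dst_x])
    sub <- cand[dst_z, dst_y, dst_x]
    sub[beat] <- FALSE
    cand[dst_z, dst_y, dst_x] <- sub
  }
  which(cand)
}

# Quadratic sub-voxel peak interpolation along one axis; offset clamped to
# half a voxel, zero at array borders.
subvoxel_offset <- function(resp, ind, axis) {
  d <- dim(resp)
  n <- nrow(ind)
  off <- numeric(n)
  ok <- ind[, axis] > 1 & ind[, axis] < d[axis]
  if (!any(ok)) return(off)
  lo <- ind; lo[, axis] <- lo[, axis] - 1L
  hi <- ind; hi[, axis] <- hi[, axis] + 1L
  f0 <- resp[ind[ok, , drop = FALSE]]
  fm <- resp[lo[ok, , drop = FALSE]]
  fp <- resp[hi[ok, , drop = FALSE]]
  den <- fm - 2 * f0 + fp
  o <- ifelse(abs(den) > .Machine$double.eps, 0.5 * (fm - fp) / den, 0)
  off[ok] <- pmin(0.5, pmax(-0.5, o))
  off
}

# Shared candidate machinery for detect_spots / quality_histogram.
spot_candidates <- function(channel, voxel_size, params) {
  work <- channel
  if (params$background_subtraction) {
    prof <- estimate_depth_background(work)
    work <- subtract_depth_background(work, prof)
  }
  resp <- log_filter(work, voxel_size, params$diameter_um)
  list(resp = resp, work = work)
}

#' Detect punctate spots in a 3-D channel
#'
#' Applies depth-background subtraction (optional), a scale-matched
#' Laplacian-of-Gaussian blob filter at the nominal punctum diameter, and
#' keeps local response maxima at or above the quality threshold. A
#' candidate is rejected when its supra-threshold support spans fewer than
#' `min_z_slices` optical slices (single-slice artifacts). Centres are
#' refined to sub-voxel precision by per-axis quadratic interpolation and
#' reported in micrometres (voxel-centre convention).
#'
#' @param channel 3-D (z, y, x) array; pre-mask it with the surface
#'   operations if a neuron-restricted analysis is intended.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @param params a [spot_params()].
#' @param depth_origin_um added to the z-coordinate to form `depth_um`
#'   (default 0).
#' @param channel_role role tag recorded on the result.
#' @return A `spot_set` whose `spots` data.frame has columns
#'   `z_um, y_um, x_um, diameter_um, quality, depth_um`.
#' @export
detect_spots <- function(channel, voxel_size, params, depth_origin_um = 0,
                         channel_role = "other") {
  sl_assert(inherits(params, "spot_params"), "InvalidParams",
            "params must be created with spot_params()")
  voxel_size <- check_voxel_size(voxel_size)
  cd <- spot_candidates(channel, voxel_size, params)
  resp <- cd$resp
  peaks <- local_maxima3(resp, params$quality_threshold)
  d <- dim(resp)
  empty <- data.frame(z_um = numeric(0), y_um = numeric(0),
                      x_um = numeric(0), diameter_um = numeric(0),
                      quality = numeric(0), depth_um = numeric(0))
  src <- list(voxel_size = as.numeric(voxel_size),
              dim = as.integer(d), depth_origin_um = depth_origin_um)
  if (length(peaks) == 0L)
    return(new_spot_set(empty, params, channel_role, src))
  if (params$min_z_slices > 1L) {
    supra <- resp >= params$quality_threshold
    lab <- label_components3(supra)
    zi <- slice.index(supra, 1)
    zr_min <- tapply(zi[supra], lab[supra], min)
    zr_max <- tapply(zi[supra], lab[supra], max)
    span <- zr_max - zr_min + 1L
    keep <- span[as.character(lab[peaks])] >= params$min_z_slices
    peaks <- peaks[keep]
  }
  if (length(peaks) == 0L)
    return(new_spot_set(empty, params, channel_role, src))
  ind <- arrayInd(peaks, d)
  offs <- vapply(1:3, function(ax) subvoxel_offset(resp, ind, ax),
                 numeric(length(peaks)))
  if (length(peaks) == 1L) offs <- matrix(offs, 1)
  pos <- sweep(ind - 1 + offs, 2, voxel_size, "*")
  spots <- data.frame(z_um = pos[, 1], y_um = pos[, 2], x_um = pos[, 3],
                      diameter_um = params$diameter_um,
                      quality = resp[ind],
                      depth_um = pos[, 1] + depth_origin_um)
  o <- order(spots$z_um, spots$y_um, spots$x_um)
  new_spot_set(spots[o, , drop = FALSE], params, channel_role, src)
}

#' Candidate-quality distribution for threshold selection
#'
#' Returns the qualities of all candidate peaks (local blob-filter maxima
#' with positive response) prior to thresholding, plus a precomputed
#' histogram, so the user can pick the quality threshold at the point of
#' inflection between the noise/dim-candidate bulk and genuine puncta.
#' Purely advisory: nothing is applied automatically.
#'
#' @inheritParams detect_spots
#' @param breaks histogram breaks (passed to [graphics::hist()]).
#' @return List with `qualities` (numeric vector) and `histogram`
#'   (a `histogram` object, `NULL` when there are no candidates).
#' @export
quality_histogram <- function(channel, voxel_size, params, breaks = 50) {
  sl_assert(inherits(params, "spot_params"), "InvalidParams",
            "params must be created with spot_params()")
  voxel_size <- check_voxel_size(voxel_size)
  cd <- spot_candidates(channel, voxel_size, params)
  # candidates need a genuinely positive response: the floor screens out
  # float-level ripple on structure-free images
  floor_q <- 1e-9 * max(abs(channel)) + .Machine$double.xmin
  peaks <- local_maxima3(cd$resp, floor_q)
  q <- cd$resp[peaks]
  list(qualities = q,
       histogram = if (length(q)) graphics::hist(q, breaks = breaks,
                                                 plot = FALSE) else NULL)
}
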