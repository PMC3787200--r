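## surface_segmentation: neuron occupancy mask from the fill channel, and
## the generalized-cylinder filament alternative.

#' Surface segmentation parameters
#'
#' @param intensity_threshold threshold in fill-channel intensity units;
#'   voxels at or above it enter the surface. Chosen by the user from the
#'   fill-channel histogram (see [intensity_histogram()]); there is no
#'   automatic default.
#' @param min_dendrite_diameter_um diameter of the smallest dendrite to
#'   preserve, in micrometres; sets the spatial scale of the background
#'   estimate when `background_subtraction` is on.
#' @param min_object_volume_um3 connected components (26-connectivity)
#'   smaller than this physical volume are discarded as blebs/debris.
#' @param smoothing_enabled morphological smoothing of the binary mask
#'   (Gaussian at half the minimum dendrite diameter, re-thresholded at
#'   0.5). Off by default: smoothing erodes thin dendrites.
#' @param background_subtraction subtract a Gaussian low-pass background
#'   estimate before thresholding (default `TRUE`).
#' @return A list of class `surface_params`.
#' @export
surface_params <- function(intensity_threshold,
                           min_dendrite_diameter_um = 0.4,
                           min_object_volume_um3 = 0,
                           smoothing_enabled = FALSE,
                           background_subtraction = TRUE) {
  sl_assert(is.numeric(intensity_threshold) && is.finite(intensity_threshold),
            "InvalidParams", "intensity_threshold must be finite")
  sl_assert(min_dendrite_diameter_um > 0, "NonPositiveScale",
            "min_dendrite_diameter_um must be > 0")
  sl_assert(min_object_volume_um3 >= 0, "InvalidParams",
            "min_object_volume_um3 must be >= 0")
  structure(list(intensity_threshold = intensity_threshold,
                 min_dendrite_diameter_um = min_dendrite_diameter_um,
                 min_object_volume_um3 = min_object_volume_um3,
                 smoothing_enabled = isTRUE(smoothing_enabled),
                 background_subtraction = isTRUE(background_subtraction)),
            class = "surface_params")
}

new_neuron_surface <- function(mask, voxel_size) {
  voxvol <- prod(voxel_size)
  lab <- label_components3(mask)
  structure(list(mask = mask, voxel_size = voxel_size,
                 volume_um3 = sum(mask) * voxvol,
                 component_count = max(lab)),
            class = "neuron_surface")
}

#' @export
print.neuron_surface <- function(x, ...) {
  cat(sprintf(
    "neuron_surface: %d voxels, volume %.2f um^3, %d component(s)\n",
    sum(x$mask), x$volume_um3, x$component_count))
  invisible(x)
}

#' Subtract a smooth low-frequency background from a channel
#'
#' The background is estimated as a Gaussian low-pass of the channel at the
#' stated object scale (per-axis sigmas in voxel units derived from the
#' physical voxel size) and subtracted, clipping at zero. A constant image
#' maps to all zeros; structure smaller than `object_scale_um` is preserved.
#'
#' @param channel 3-D (z, y, x) numeric array.
#' @param object_scale_um physical scale (um) of the largest objects to
#'   preserve; the background varies more slowly than this.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @return 3-D array, same shape, non-negative.
#' @export
subtract_background <- function(channel, object_scale_um, voxel_size) {
  sl_assert(is.numeric(object_scale_um) && object_scale_um > 0,
            "NonPositiveScale", "object_scale_um must be > 0")
  voxel_size <- check_voxel_size(voxel_size)
  sigma_vox <- object_scale_um / voxel_size
  bg <- gauss_blur3(channel, sigma_vox)
  pmax(channel - bg, 0)
}

#' Fill-channel intensity histogram for threshold selection
#'
#' Advisory helper mirroring interactive threshold picking: returns the
#' intensity distribution of the (optionally background-subtracted) fill
#' channel so the user can choose `intensity_threshold`. Never applied
#' automatically.
#'
#' @param stack a [volumetric_stack()] with a fill channel.
#' @param background_subtraction subtract background first (default `TRUE`).
#' @param object_scale_um background scale if subtracting (default 0.4 um).
#' @param breaks passed to [graphics::hist()] (computed, not plotted).
#' @return A `histogram` object.
#' @export
intensity_histogram <- function(stack, background_subtraction = TRUE,
                                object_scale_um = 0.4, breaks = 100) {
  ch <- get_channel(stack, "fill")
  if (isTRUE(background_subtraction))
    ch <- subtract_background(ch, object_scale_um, stack$voxel_size)
  graphics::hist(as.numeric(ch), breaks = breaks, plot = FALSE)
}

#' Segment the neuron surface from the fill channel
#'
#' Thresholds the (optionally background-subtracted) fill channel, labels
#' 26-connected components, removes components smaller than the minimum
#' object volume, and returns the resulting occupancy mask with its derived
#' physical volume. The surface is a voxel mask, not a mesh: every
#' downstream "distance to surface" is distance to the nearest mask voxel
#' centre.
#'
#' @param stack a [volumetric_stack()] with exactly one fill channel.
#' @param params a [surface_params()].
#' @return A `neuron_surface`: `mask` (3-D logical), `voxel_size`,
#'   `volume_um3`, `component_count`.
#' @export
create_surface <- function(stack, params) {
  sl_assert(inherits(params, "surface_params"), "InvalidParams",
            "params must be created with surface_params()")
  ch <- get_channel(stack, "fill")
  vs <- stack$voxel_size
  if (params$background_subtraction)
    ch <- subtract_background(ch, params$min_dendrite_diameter_um, vs)
  mask <- ch >= params$intensity_threshold
  if (params$smoothing_enabled) {
    sm <- gauss_blur3(mask * 1, (params$min_dendrite_diameter_um / 2) / vs)
    mask <- sm >= 0.5
  }
  sl_assert(any(mask), "EmptySurface",
            "no voxel reaches the intensity threshold (threshold too high?)")
  if (params$min_object_volume_um3 > 0) {
    voxvol <- prod(vs)
    min_vox <- round_half_up(params$min_object_volume_um3 / voxvol)
    lab <- label_components3(mask)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_vox)
    mask <- array(lab %in% keep, dim(mask))
    sl_assert(any(mask), "EmptySurface",
              "all components are below min_object_volume_um3")
  }
  new_neuron_surface(mask, vs)
}

## ---- filament tracing -----------------------------------------------------

# Anisotropic distance (um) from every mask voxel to the nearest
# non-mask voxel centre, exact, via the background shell.
interior_depth_um <- function(mask, voxel_size, idx = which(mask)) {
  d <- dim(mask)
  bg_shell <- mask_shell(!mask)
  # voxels on the array border are treated as adjacent to background
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE; border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  targ <- which(bg_shell | (border & !mask))
  qi <- arrayInd(idx, d)
  if (length(targ) == 0L) {
    # mask fills the array; depth relative to the border planes
    q_um <- index_to_um(qi, voxel_size)
    lim <- (d - 1) * voxel_size
    return(pmin(q_um[, 1], lim[1] - q_um[, 1], q_um[, 2], lim[2] - q_um[, 2],
                q_um[, 3], lim[3] - q_um[, 3]) + min(voxel_size))
  }
  ti <- arrayInd(targ, d)
  min_dist_to_points(index_to_um(qi, voxel_size),
                     index_to_um(ti, voxel_size))
}

#' Trace the neuron as a generalized-cylinder filament
#'
#' Alternative to [create_surface()] that models dendrites as chains of
#' circular-cross-section cylinders: the thresholded fill mask is reduced to
#' a geodesic centreline (farthest-point paths through the voxel adjacency
#' graph, weighted to ride the ridge of the interior distance transform),
#' the local radius at each centreline node is the anisotropic distance to
#' the mask boundary (a local-contrast proxy), side branches are added until
#' every mask voxel is covered, and branches shorter than the minimum
#' diameter are pruned.
#'
#' @param stack a [volumetric_stack()] with a fill channel.
#' @param intensity_threshold fill-channel threshold defining the traced
#'   mask (same meaning as in [surface_params()]).
#' @param min_diameter_um minimal dendrite diameter in micrometres (default
#'   0.4); node radii are floored at half this value.
#' @param background_subtraction subtract background before thresholding
#'   (default `TRUE`).
#' @param node_spacing_um approximate centreline node spacing (default:
#'   half the minimum diameter).
#' @return A `filament_trace`: `nodes` (data.frame `z_um, y_um, x_um,
#'   radius_um`), `edges` (2-column index matrix), `min_diameter_um`.
#' @export
trace_filament <- function(stack, intensity_threshold, min_diameter_um = 0.4,
                           background_subtraction = TRUE,
                           node_spacing_um = min_diameter_um / 2) {
  sl_assert(min_diameter_um > 0, "NonPositiveScale",
            "min_diameter_um must be > 0")
  ch <- get_channel(stack, "fill")
  vs <- stack$voxel_size
  if (background_subtraction) {
    # scale chosen well above the minimum dendrite so tubes survive
    ch <- subtract_background(ch, 4 * min_diameter_um, vs)
  }
  mask <- ch >= intensity_threshold
  sl_assert(any(mask), "EmptySurface",
            "no voxel reaches the intensity threshold")
  d <- dim(mask)
  idx <- which(mask)
  depth <- interior_depth_um(mask, vs, idx)
  pos <- array(0L, d); pos[idx] <- seq_along(idx)
  ai <- arrayInd(idx, d)
  # weighted voxel adjacency graph; low-depth voxels are expensive so
  # shortest paths follow the medial axis
  maxdep <- max(depth)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (k in seq_len(nrow(.offsets26_forward))) {
    o <- .offsets26_forward[k, ]
    nb <- sweep(ai, 2, o, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nbl <- pos[nb[ok, , drop = FALSE]]
    keep <- nbl > 0L
    src <- which(ok)[keep]; dst <- nbl[keep]
    step <- sqrt(sum((o * vs)^2))
    penal <- 1 + 16 * (1 - (depth[src] + depth[dst]) / (2 * maxdep))^2
    from <- c(from, src); to <- c(to, dst); w <- c(w, step * penal)
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  if (igraph::gorder(g) < length(idx))
    g <- igraph::add_vertices(g, length(idx) - igraph::gorder(g))
  igraph::E(g)$weight <- w

  paths <- list()           # list of voxel-id vectors (indices into idx)
  covered <- rep(FALSE, length(idx))
  comp <- igraph::components(g)$membership
  for (ci in seq_len(max(comp))) {
    verts <- which(comp == ci)
    if (length(verts) == 1L) {
      paths[[length(paths) + 1L]] <- verts
      covered[verts] <- TRUE
      next
    }
    # farthest-point heuristic: seed at the deepest voxel of the component
    seed <- verts[which.max(depth[verts])]
    d1 <- igraph::distances(g, v = seed)[1, ]
    e1 <- which.max(ifelse(is.finite(d1), d1, -Inf))
    d2 <- igraph::distances(g, v = e1)[1, ]
    e2 <- which.max(ifelse(is.finite(d2), d2, -Inf))
    main <- as.integer(igraph::shortest_paths(g, from = e1, to = e2,
                                              output = "vpath")$vpath[[1]])
    paths[[length(paths) + 1L]] <- main
    covered[main] <- TRUE
    # cover side branches: every mask voxel should lie within the local
    # tube radius of some skeleton node; repeatedly attach a geodesic path
    # from the farthest uncovered voxel to the nearest skeleton node
    vert_um <- index_to_um(ai[verts, , drop = FALSE], vs)
    # a voxel is covered when it lies inside the swept tube of ANY
    # skeleton node (ball of 1.25 x node radius, plus one voxel of slack);
    # only tube-like voxels (interior depth above half the minimum
    # diameter) can seed a side branch — shallow wall/cap slivers cannot
    uncovered_excess <- function(sk) {
      sk_um <- index_to_um(ai[sk, , drop = FALSE], vs)
      reach <- pmax(1.25 * depth[sk] + max(vs), min_diameter_um)
      nv <- nrow(vert_um)
      exc <- numeric(nv)
      for (s in seq(1L, nv, by = 256L)) {
        e <- min(nv, s + 255L)
        dz <- outer(vert_um[s:e, 1], sk_um[, 1], "-")
        dy <- outer(vert_um[s:e, 2], sk_um[, 2], "-")
        dx <- outer(vert_um[s:e, 3], sk_um[, 3], "-")
        dd <- sqrt(dz * dz + dy * dy + dx * dx)
        exc[s:e] <- apply(sweep(dd, 2, reach, "-"), 1, min)
      }
      exc
    }
    for (iter in seq_len(64L)) {
      sk <- which(covered)
      exc <- uncovered_excess(sk)
      uncov <- which(exc > 0 & depth[verts] >= min_diameter_um / 2)
      if (length(uncov) == 0L) break
      far <- verts[uncov[which.max(exc[uncov])]]
      far_um <- as.numeric(index_to_um(ai[far, , drop = FALSE], vs))
      sk_um <- index_to_um(ai[sk, , drop = FALSE], vs)
      anchor <- sk[which.min(sqrt(colSums((t(sk_um) - far_um)^2)))]
      br <- as.integer(igraph::shortest_paths(
        g, from = far, to = anchor, output = "vpath")$vpath[[1]])
      if (length(br) == 0L) break
      paths[[length(paths) + 1L]] <- br
      covered[br] <- TRUE
    }
  }
  # prune branches (non-primary paths) whose physical length is below the
  # minimum diameter
  path_len_um <- function(p) {
    if (length(p) < 2) return(0)
    pu <- index_to_um(ai[p, , drop = FALSE], vs)
    sum(sqrt(rowSums(diff(pu)^2)))
  }
  if (length(paths) > 1) {
    keep <- c(TRUE, vapply(paths[-1], path_len_um, 1.0) >= min_diameter_um)
    paths <- paths[keep]
  }
  # resample each path at ~node_spacing_um and build the node table
  nodes <- NULL; edges <- NULL
  for (p in paths) {
    pu <- index_to_um(ai[p, , drop = FALSE], vs)
    if (length(p) >= 2) {
      s <- c(0, cumsum(sqrt(rowSums(diff(pu)^2))))
      n_out <- max(2L, ceiling(s[length(s)] / node_spacing_um) + 1L)
      pick <- unique(vapply(seq(0, s[length(s)], length.out = n_out),
                            function(t) which.min(abs(s - t)), 1L))
    } else pick <- 1L
    sel <- p[pick]
    start <- if (is.null(nodes)) 0L else nrow(nodes)
    # interior depth measures to the nearest background voxel centre;
    # adding half the mean spacing recentres it on the mask boundary
    nd <- data.frame(z_um = index_to_um(ai[sel, , drop = FALSE], vs)[, 1],
                     y_um = index_to_um(ai[sel, , drop = FALSE], vs)[, 2],
                     x_um = index_to_um(ai[sel, , drop = FALSE], vs)[, 3],
                     radius_um = pmax(depth[sel] + mean(vs) / 2,
                                      min_diameter_um / 2))
    nodes <- rbind(nodes, nd)
    if (length(sel) >= 2)
      edges <- rbind(edges, cbind(start + seq_len(length(sel) - 1L),
                                  start + 2:length(sel)))
  }
  structure(list(nodes = nodes,
                 edges = if (is.null(edges)) matrix(0L, 0, 2) else edges,
                 min_diameter_um = min_diameter_um),
            class = "filament_trace")
}

#' @export
print.filament_trace <- function(x, ...) {
  cat(sprintf("filament_trace: %d nodes, %d edges, min diameter %.2f um\n",
              nrow(x$nodes), nrow(x$edges), x$min_diameter_um))
  invisible(x)
}

#' Voxelize a filament trace into a neuron surface mask
#'
#' Sweeps a sphere along every edge (a capsule with linearly interpolated
#' radius) and marks all voxels whose centres fall inside the union. The
#' result is a `neuron_surface` interchangeable with [create_surface()]
#' output in every downstream masking and distance operation.
#'
#' @param trace a `filament_trace`.
#' @param dim 3-vector, target grid size `(nz, ny, nx)`.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @return A `neuron_surface`.
#' @export
filament_to_mask <- function(trace, dim, voxel_size) {
  sl_assert(nrow(trace$nodes) >= 1, "EmptySurface", "trace has no nodes")
  voxel_size <- check_voxel_size(voxel_size)
  d <- as.integer(dim)
  mask <- array(FALSE, d)
  nd <- trace$nodes
  segs <- trace$edges
  if (nrow(segs) == 0L)  # isolated nodes render as spheres
    segs <- cbind(seq_len(nrow(nd)), seq_len(nrow(nd)))
  iso <- setdiff(seq_len(nrow(nd)), unique(as.integer(trace$edges)))
  if (nrow(trace$edges) > 0L && length(iso) > 0L)
    segs <- rbind(segs, cbind(iso, iso))
  for (k in seq_len(nrow(segs))) {
    a <- as.numeric(nd[segs[k, 1], c("z_um", "y_um", "x_um")])
    b <- as.numeric(nd[segs[k, 2], c("z_um", "y_um", "x_um")])
    ra <- nd$radius_um[segs[k, 1]]; rb <- nd$radius_um[segs[k, 2]]
    rmax <- max(ra, rb)
    lo <- pmax(1L, floor(pmin(a, b) / voxel_size - rmax / voxel_size) + 1L)
    hi <- pmin(d, ceiling(pmax(a, b) / voxel_size + rmax / voxel_size) + 1L)
    if (any(lo > hi)) next
    gz <- (lo[1]:hi[1] - 1) * voxel_size[1]
    gy <- (lo[2]:hi[2] - 1) * voxel_size[2]
    gx <- (lo[3]:hi[3] - 1) * voxel_size[3]
    pts <- as.matrix(expand.grid(z = gz, y = gy, x = gx))
    ab <- b - a
    L2 <- sum(ab^2)
    if (L2 == 0) {
      dist <- sqrt(colSums((t(pts) - a)^2))
      inside <- dist <= rmax
    } else {
      t_par <- pmin(1, pmax(0, ((pts[, 1] - a[1]) * ab[1] +
                                  (pts[, 2] - a[2]) * ab[2] +
                                  (pts[, 3] - a[3]) * ab[3]) / L2))
      proj <- cbind(a[1] + t_par * ab[1], a[2] + t_par * ab[2],
                    a[3] + t_par * ab[3])
      dist <- sqrt(rowSums((pts - proj)^2))
      inside <- dist <= ra + t_par * (rb - ra)
    }
    sub <- array(FALSE, hi - lo + 1L)
    sub[inside] <- TRUE
    mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] | sub
  }
  sl_assert(any(mask), "EmptySurface", "trace voxelizes to an empty mask")
  new_neuron_surface(mask, voxel_size)
}

#' Write a filament trace as SWC
#'
#' Standard neuron-morphology format: one node per line
#' (`id type x y z radius parent`), coordinates in micrometres, type 3
#' (dendrite). Root nodes have parent −1.
#'
#' @param trace a `filament_trace`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(trace, path) {
  n <- nrow(trace$nodes)
  parent <- rep(-1L, n)
  if (nrow(trace$edges) > 0)
    parent[trace$edges[, 2]] <- trace$edges[, 1]
  lines <- sprintf("%d 3 %.4f %.4f %.4f %.4f %d",
                   seq_len(n), trace$nodes$x_um, trace$nodes$y_um,
                   trace$nodes$z_um, trace$nodes$radius_um, parent)
  ok <- tryCatch({ writeLines(c("# SWC export", lines), path); TRUE },
                 error = function(e) FALSE)
  sl_assert(ok, "IOFailure", "cannot write SWC to '%s'", path)
  invisible(path)
}
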