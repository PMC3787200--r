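# Shared analytic fixtures, all built in code.

# Physical coordinate grids for a (z, y, x) array.
grid_um <- function(dim, voxel_size) {
  gz <- (seq_len(dim[1]) - 1) * voxel_size[1]
  gy <- (seq_len(dim[2]) - 1) * voxel_size[2]
  gx <- (seq_len(dim[3]) - 1) * voxel_size[3]
  list(
    Z = array(gz, dim),
    Y = aperm(array(gy, dim[c(2, 1, 3)]), c(2, 1, 3)),
    X = aperm(array(gx, dim[c(3, 2, 1)]), c(3, 2, 1))
  )
}

# Solid sphere fill channel as a one-channel stack.
sphere_stack <- function(center, radius, dim = c(60, 140, 140),
                         voxel_size = c(0.3, 0.1, 0.1), intensity = 100) {
  g <- grid_um(dim, voxel_size)
  fill <- intensity * (((g$Z - center[1])^2 + (g$Y - center[2])^2 +
                          (g$X - center[3])^2) <= radius^2)
  volumetric_stack(array(fill, c(1, dim)), voxel_size, "fill")
}

# Solid cylinder along y (axis at z = axis[1], x = axis[2]).
cylinder_fill <- function(axis, radius, y_range, dim = c(24, 100, 30),
                          voxel_size = c(0.3, 0.1, 0.1), intensity = 100) {
  g <- grid_um(dim, voxel_size)
  intensity * (((g$Z - axis[1])^2 + (g$X - axis[2])^2) <= radius^2 &
                 g$Y >= y_range[1] & g$Y <= y_range[2])
}

# Isotropic Gaussian blob of given peak and sigma (um) added in place.
add_gauss_blob <- function(channel, center, sigma, peak, voxel_size) {
  d <- dim(channel)
  gz <- (seq_len(d[1]) - 1) * voxel_size[1]
  gy <- (seq_len(d[2]) - 1) * voxel_size[2]
  gx <- (seq_len(d[3]) - 1) * voxel_size[3]
  channel + peak * (exp(-(gz - center[1])^2 / (2 * sigma^2)) %o%
                      exp(-(gy - center[2])^2 / (2 * sigma^2)) %o%
                      exp(-(gx - center[3])^2 / (2 * sigma^2)))
}

# Minimal spot_set from a matrix/data.frame of (z, y, x) um centres.
make_spot_set <- function(centers_um, diameter_um = 0.3, role = "other",
                          voxel_size = NULL, depth_origin_um = 0) {
  centers_um <- matrix(as.numeric(as.matrix(centers_um)), ncol = 3)
  n <- nrow(centers_um)
  sp <- data.frame(z_um = centers_um[, 1], y_um = centers_um[, 2],
                   x_um = centers_um[, 3],
                   diameter_um = rep(diameter_um, n),
                   quality = rep(1, n),
                   depth_um = centers_um[, 1] + depth_origin_um)
  structure(list(spots = sp, params = list(diameter_um = diameter_um),
                 channel_role = role,
                 source = if (is.null(voxel_size)) list()
                          else list(voxel_size = voxel_size)),
            class = "spot_set")
}

# Brute-force all-pairs colocalization oracle.
brute_force_pairs <- function(a_um, b_um, max_dist) {
  out <- NULL
  for (i in seq_len(nrow(a_um))) {
    for (j in seq_len(nrow(b_um))) {
      dd <- sqrt(sum((a_um[i, ] - b_um[j, ])^2))
      if (dd <= max_dist) out <- rbind(out, c(i, j, dd))
    }
  }
  out
}

# Brute-force two-sample KS statistic from the ECDF definition.
brute_force_ks_D <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  max(abs(vapply(xs, function(x) mean(a <= x) - mean(b <= x), 1.0)))
}

# Run the standard phantom analysis used by the recovery tests and match
# detections to ground truth. Thresholds suit the default generator
# contrast (puncta amplitude 150 over base-20 background).
analyze_phantom <- function(sim, coloc_um, pre_quality = 8,
                            post_quality = 15, surface_threshold = 50) {
  st <- sim$stack
  tru <- sim$truth
  vs <- st$voxel_size
  surf <- create_surface(st, surface_params(
    surface_threshold, background_subtraction = FALSE,
    min_object_volume_um3 = 2))
  masked <- mask_channels_by_role(st, surf)
  pre <- detect_spots(get_channel(masked, "presynaptic"), vs,
                      spot_params(0.3, pre_quality),
                      channel_role = "presynaptic")
  post <- detect_spots(get_channel(masked, "postsynaptic"), vs,
                       spot_params(0.6, post_quality),
                       channel_role = "postsynaptic")
  near <- spots_near_surface(pre, surf, coloc_params(coloc_um))
  cl <- colocalize_spots(near$near, post, coloc_params(coloc_um))
  match_truth <- function(det, truth_df) {
    if (n_spots(det) == 0) return(integer(0))
    np <- synaptoloc:::nearest_point(
      as.matrix(det$spots[, c("z_um", "y_um", "x_um")]),
      as.matrix(truth_df[, c("z_um", "y_um", "x_um")]))
    ifelse(np$dist < 0.35, np$index, NA_integer_)
  }
  pre_id <- match_truth(near$near, tru$pre_spots)
  post_id <- match_truth(post, tru$post_spots)
  ids <- cbind(pre_id[cl$pairs$a], post_id[cl$pairs$b])
  n_true_pairs <- nrow(tru$pairs)
  is_true <- !is.na(ids[, 1]) & !is.na(ids[, 2]) & ids[, 1] == ids[, 2] &
    ids[, 1] <= n_true_pairs
  list(surface = surf, pre = pre, post = post, near = near, coloc = cl,
       recovered = length(unique(ids[is_true, 1])),
       spurious = sum(!is_true),
       n_true = n_true_pairs,
       n_pre_near = n_spots(near$near),
       n_pre_paired = length(cl$near_a))
}
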