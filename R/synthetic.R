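## synthetic_data: phantom stacks with known geometry and ground-truth
## synapse pairings, and synthetic current traces with known event trains.

#' Phantom specification
#'
#' Describes a soma + dendrite neuron phantom with paired pre/post
#' synaptic puncta straddling the membrane, distractor puncta, a
#' depth-increasing diffuse background, anisotropic optical blur and
#' noise. Defaults emulate a confocal acquisition of a dye-filled neuron:
#' 0.3/0.1/0.1 um voxels, 0.3 um pre- and 0.6 um post-synaptic puncta,
#' blur FWHM 0.56 um axially and 0.15 um laterally (SIM mode: 0.30 and
#' 0.12 um).
#'
#' @param dim grid size `(nz, ny, nx)` in voxels.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @param soma_center_um,soma_radii_um ellipsoid soma centre and radii
#'   (z, y, x) in micrometres.
#' @param dendrites list of capsule chains; each chain is a list with
#'   `points` (n x 3 matrix of z, y, x um) and `radii_um` (length n,
#'   tapering allowed). `NULL` gives one straight tapering dendrite
#'   leaving the soma along +y.
#' @param n_synapses number of true pre/post pairs placed on the membrane.
#' @param pair_separation_max_um maximum centre separation of a true pair
#'   (default 0.8; keep below the colocalization threshold).
#' @param min_site_spacing_um minimum membrane distance between synapse
#'   sites (default 2.2 um) so neighbouring synapses do not cross-pair at
#'   a 1 um threshold.
#' @param n_distractor_pre,n_distractor_post unpaired puncta scattered
#'   uniformly through the volume (pre outside the neuron).
#' @param pre_diameter_um,post_diameter_um punctum diameters.
#' @param punctum_amplitude peak intensity of rendered puncta.
#' @param fill_amplitude fill-channel intensity inside the neuron.
#' @param background_base,background_slope_per_um diffuse label-channel
#'   background: `base + slope * depth_um`.
#' @param mode `"confocal"` or `"sim"`; sets the default blur FWHM.
#' @param blur_fwhm_um optional explicit blur FWHM `(z, y, x)` um.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed mandatory RNG seed; generation is fully reproducible.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(50, 192, 192),
                         voxel_size = c(0.3, 0.1, 0.1),
                         soma_center_um = NULL,
                         soma_radii_um = c(4, 5, 5),
                         dendrites = NULL,
                         n_synapses = 40,
                         pair_separation_max_um = 0.8,
                         min_site_spacing_um = 2.0,
                         n_distractor_pre = 100,
                         n_distractor_post = 100,
                         pre_diameter_um = 0.3,
                         post_diameter_um = 0.6,
                         punctum_amplitude = 150,
                         fill_amplitude = 100,
                         background_base = 20,
                         background_slope_per_um = 1.0,
                         mode = c("confocal", "sim"),
                         blur_fwhm_um = NULL,
                         noise_sd = 4,
                         seed) {
  mode <- match.arg(mode)
  sl_assert(!missing(seed) && is.numeric(seed), "InvalidParams",
            "seed is mandatory")
  sl_assert(pair_separation_max_um > 0, "InvalidParams",
            "pair_separation_max_um must be > 0")
  voxel_size <- check_voxel_size(voxel_size)
  dim <- as.integer(dim)
  extent <- (dim - 1) * voxel_size
  if (is.null(soma_center_um))
    soma_center_um <- c(0.5 * extent[1],
                        max(soma_radii_um[2] + 0.6, 0.3 * extent[2]),
                        0.5 * extent[3])
  if (is.null(blur_fwhm_um))
    blur_fwhm_um <- if (mode == "confocal") c(0.56, 0.15, 0.15)
                    else c(0.30, 0.12, 0.12)
  if (is.null(dendrites)) {
    y0 <- soma_center_um[2] + soma_radii_um[2] - 0.5
    dendrites <- list(list(
      points = rbind(c(soma_center_um[1], y0, soma_center_um[3]),
                     c(soma_center_um[1], extent[2] - 1.5,
                       soma_center_um[3])),
      radii_um = c(1.2, 0.6)))
  }
  spec <- structure(
    list(dim = dim, voxel_size = voxel_size,
         soma_center_um = soma_center_um, soma_radii_um = soma_radii_um,
         dendrites = dendrites, n_synapses = n_synapses,
         pair_separation_max_um = pair_separation_max_um,
         min_site_spacing_um = min_site_spacing_um,
         n_distractor_pre = n_distractor_pre,
         n_distractor_post = n_distractor_post,
         pre_diameter_um = pre_diameter_um,
         post_diameter_um = post_diameter_um,
         punctum_amplitude = punctum_amplitude,
         fill_amplitude = fill_amplitude,
         background_base = background_base,
         background_slope_per_um = background_slope_per_um,
         mode = mode, blur_fwhm_um = blur_fwhm_um, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "phantom_spec")
  # geometry must stay inside the grid
  hi <- soma_center_um + soma_radii_um; lo <- soma_center_um - soma_radii_um
  inb <- all(lo >= 0) && all(hi <= extent)
  for (dch in dendrites) {
    p <- dch$points
    inb <- inb && all(sweep(p, 2, dch$radii_um[1], "-") >= -1e-9) &&
      all(sweep(p, 2, extent, "-") <= 1e-9)
  }
  sl_assert(inb, "GeometryOutOfBounds",
            "phantom geometry extends beyond the stack bounds")
  spec
}

# Clean (pre-blur) neuron occupancy mask of the spec's geometry.
render_neuron_mask <- function(spec) {
  d <- spec$dim; vs <- spec$voxel_size
  gz <- (seq_len(d[1]) - 1) * vs[1]
  gy <- (seq_len(d[2]) - 1) * vs[2]
  gx <- (seq_len(d[3]) - 1) * vs[3]
  Z <- array(gz, d)
  Y <- aperm(array(gy, d[c(2, 1, 3)]), c(2, 1, 3))
  X <- aperm(array(gx, d[c(3, 2, 1)]), c(3, 2, 1))
  cz <- spec$soma_center_um[1]; cy <- spec$soma_center_um[2]
  cx <- spec$soma_center_um[3]
  r <- spec$soma_radii_um
  mask <- ((Z - cz) / r[1])^2 + ((Y - cy) / r[2])^2 +
    ((X - cx) / r[3])^2 <= 1
  for (dch in spec$dendrites) {
    p <- dch$points; rr <- dch$radii_um
    for (k in seq_len(nrow(p) - 1)) {
      a <- p[k, ]; b <- p[k + 1, ]; ab <- b - a; L2 <- sum(ab^2)
      t_par <- ((Z - a[1]) * ab[1] + (Y - a[2]) * ab[2] +
                  (X - a[3]) * ab[3]) / L2
      t_par <- pmin(1, pmax(0, t_par))
      dist2 <- (Z - a[1] - t_par * ab[1])^2 +
        (Y - a[2] - t_par * ab[2])^2 + (X - a[3] - t_par * ab[3])^2
      rad <- rr[k] + t_par * (rr[k + 1] - rr[k])
      mask <- mask | (dist2 <= rad^2)
    }
  }
  mask
}

# Signed distance helper: anisotropic distance (um) from points to the
# neuron membrane, positive outside, negative inside, via the mask shell.
signed_membrane_distance <- function(pts_um, mask, voxel_size) {
  d <- dim(mask)
  shell_um <- index_to_um(arrayInd(which(mask_shell(mask)), d), voxel_size)
  dist <- min_dist_to_points(pts_um, shell_um)
  ind <- um_to_index(pts_um, voxel_size)
  ind[, 1] <- pmin(pmax(ind[, 1], 1L), d[1])
  ind[, 2] <- pmin(pmax(ind[, 2], 1L), d[2])
  ind[, 3] <- pmin(pmax(ind[, 3], 1L), d[3])
  ifelse(mask[ind], -dist, dist)
}

# Add a Gaussian punctum of given diameter at a physical position.
render_puncta <- function(channel, pts_um, diameter_um, amplitude,
                          voxel_size) {
  if (nrow(pts_um) == 0) return(channel)
  d <- dim(channel)
  sigma <- rep(diameter_um / 2.355, 3)   # FWHM = diameter
  rad <- 3 * sigma
  for (i in seq_len(nrow(pts_um))) {
    p <- pts_um[i, ]
    lo <- pmax(1L, floor((p - rad) / voxel_size) + 1L)
    hi <- pmin(d, ceiling((p + rad) / voxel_size) + 1L)
    gz <- ((lo[1]:hi[1]) - 1) * voxel_size[1]
    gy <- ((lo[2]:hi[2]) - 1) * voxel_size[2]
    gx <- ((lo[3]:hi[3]) - 1) * voxel_size[3]
    bz <- exp(-((gz - p[1])^2) / (2 * sigma[1]^2))
    by <- exp(-((gy - p[2])^2) / (2 * sigma[2]^2))
    bx <- exp(-((gx - p[3])^2) / (2 * sigma[3]^2))
    blob <- amplitude * (bz %o% by %o% bx)
    channel[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      channel[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + blob
  }
  channel
}

#' Generate a multichannel neuron phantom with ground truth
#'
#' Renders the neuron geometry on the voxel grid, places paired pre/post
#' puncta straddling the membrane (post just inside, pre outside, centre
#' separation at most `pair_separation_max_um`), scatters distractor
#' puncta, adds a depth-linear background to the label channels, convolves
#' everything with the anisotropic optical blur, adds Gaussian noise, and
#' returns the stack (channels: fill, presynaptic, postsynaptic) together
#' with the complete ground truth. Fully reproducible from `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return List with `stack` (a [volumetric_stack()]) and `truth`
#'   (class `synthetic_ground_truth`): clean `neuron_mask`, `pre_spots` /
#'   `post_spots` tables (`z_um, y_um, x_um, diameter_um, is_distractor`),
#'   `pairs` (`pre, post, separation_um`), and the spec echo.
#' @export
generate_neuron_stack <- function(spec) {
  sl_assert(inherits(spec, "phantom_spec"), "InvalidParams",
            "spec must be created with phantom_spec()")
  set.seed(spec$seed)
  d <- spec$dim; vs <- spec$voxel_size
  extent <- (d - 1) * vs
  mask <- render_neuron_mask(spec)
  shell_idx <- which(mask_shell(mask))
  shell_um <- index_to_um(arrayInd(shell_idx, dim(mask)), vs)
  # outward unit normals: direction away from the nearest point of a
  # slightly eroded reference (the soma centre / dendrite axis is a good
  # enough proxy: use gradient of the blurred mask)
  sm <- gauss_blur3(mask * 1, 2 / vs * min(vs))
  grad_at <- function(ind) {
    g <- matrix(0, nrow(ind), 3)
    for (ax in 1:3) {
      up <- ind; up[, ax] <- pmin(d[ax], ind[, ax] + 1L)
      dn <- ind; dn[, ax] <- pmax(1L, ind[, ax] - 1L)
      g[, ax] <- (sm[up] - sm[dn]) / (2 * vs[ax])
    }
    -g / pmax(sqrt(rowSums(g^2)), 1e-9)   # outward = down-gradient
  }
  ## choose synapse sites with minimum spacing (dart throwing)
  sites <- matrix(numeric(0), 0, 3)
  if (spec$n_synapses > 0) {
    cand_order <- sample(nrow(shell_um))
    margin <- 1.2  # keep sites away from the stack faces
    for (ci in cand_order) {
      p <- shell_um[ci, ]
      if (any(p < margin) || any(extent - p < margin)) next
      if (nrow(sites) == 0 ||
          min(sqrt(rowSums(sweep(sites, 2, p, "-")^2))) >=
            spec$min_site_spacing_um) {
        sites <- rbind(sites, p)
        if (nrow(sites) == spec$n_synapses) break
      }
    }
  }
  sl_assert(nrow(sites) == spec$n_synapses, "GeometryOutOfBounds",
            "membrane too small for %d synapses at %.2f um spacing",
            spec$n_synapses, spec$min_site_spacing_um)
  nrm <- grad_at(um_to_index(sites, vs))
  n_syn <- nrow(sites)
  # post punctum just inside the membrane, pre punctum outside; offsets
  # scale with the admissible pair separation (defaults: 0.05-0.20 um in,
  # 0.30-0.55 um out at the 0.8 um default)
  post_in <- runif(n_syn, 0.0625, 0.25) * spec$pair_separation_max_um
  pre_out <- runif(n_syn, 0.375, 0.6875) * spec$pair_separation_max_um
  post_pts <- sites - nrm * post_in
  pre_pts <- sites + nrm * pre_out
  sep <- sqrt(rowSums((pre_pts - post_pts)^2))
  stopifnot(all(sep <= spec$pair_separation_max_um + 1e-9))
  ## distractors: uniform in the volume; pre-distractors outside the neuron
  draw_uniform <- function(n) {
    cbind(runif(n, 0.5, extent[1] - 0.5), runif(n, 0.5, extent[2] - 0.5),
          runif(n, 0.5, extent[3] - 0.5))
  }
  pre_dis <- matrix(numeric(0), 0, 3)
  while (nrow(pre_dis) < spec$n_distractor_pre) {
    cand <- draw_uniform(2 * spec$n_distractor_pre)
    sd_mem <- signed_membrane_distance(cand, mask, vs)
    cand <- cand[sd_mem > 0.2, , drop = FALSE]
    pre_dis <- rbind(pre_dis, cand)
  }
  pre_dis <- pre_dis[seq_len(spec$n_distractor_pre), , drop = FALSE]
  post_dis <- draw_uniform(spec$n_distractor_post)
  ## render channels
  depth_bg <- function() {
    gz <- (seq_len(d[1]) - 1) * vs[1]
    array(spec$background_base + spec$background_slope_per_um * gz, d)
  }
  fill <- mask * spec$fill_amplitude
  pre_ch <- render_puncta(array(0, d), rbind(pre_pts, pre_dis),
                          spec$pre_diameter_um, spec$punctum_amplitude, vs)
  post_ch <- render_puncta(array(0, d), rbind(post_pts, post_dis),
                           spec$post_diameter_um, spec$punctum_amplitude, vs)
  pre_ch <- pre_ch + depth_bg()
  post_ch <- post_ch + depth_bg()
  sigma_blur <- spec$blur_fwhm_um / 2.355 / vs
  fill <- gauss_blur3(fill, sigma_blur)
  pre_ch <- gauss_blur3(pre_ch, sigma_blur)
  post_ch <- gauss_blur3(post_ch, sigma_blur)
  noise <- function(a) pmax(a + rnorm(length(a), sd = spec$noise_sd), 0)
  a <- array(0, c(3, d))
  a[1, , , ] <- noise(fill)
  a[2, , , ] <- noise(pre_ch)
  a[3, , , ] <- noise(post_ch)
  stack <- volumetric_stack(a, vs, c("fill", "presynaptic", "postsynaptic"))
  spot_table <- function(pts, diam, n_true) {
    data.frame(z_um = pts[, 1], y_um = pts[, 2], x_um = pts[, 3],
               diameter_um = rep(diam, nrow(pts)),
               is_distractor = seq_len(nrow(pts)) > n_true)
  }
  truth <- structure(
    list(neuron_mask = mask,
         pre_spots = spot_table(rbind(pre_pts, pre_dis),
                                spec$pre_diameter_um, n_syn),
         post_spots = spot_table(rbind(post_pts, post_dis),
                                 spec$post_diameter_um, n_syn),
         pairs = data.frame(pre = seq_len(n_syn), post = seq_len(n_syn),
                            separation_um = sep),
         spec = spec),
    class = "synthetic_ground_truth")
  list(stack = stack, truth = truth)
}

#' Generate a synthetic synaptic-current trace with known events
#'
#' Superimposes Poisson trains of inward and outward difference-of-
#' exponential events on Gaussian baseline noise. The returned truth table
#' lists every injected event.
#'
#' @param duration_s trace duration in seconds.
#' @param rate_inward_hz,rate_outward_hz Poisson event rates.
#' @param amp_mean_pa,amp_sd_pa event amplitude distribution (pA, positive
#'   magnitudes; amplitudes are truncated below at 20% of the mean).
#' @param kinetics_inward,kinetics_outward `c(rise_ms, decay_ms)` of the
#'   difference-of-exponential kernels.
#' @param noise_sd_pa Gaussian noise SD.
#' @param sampling_rate_hz sampling frequency.
#' @param seed mandatory RNG seed.
#' @return List with `trace` (a [current_trace()]) and `events`
#'   (data.frame `onset_s, amplitude_pa, polarity`).
#' @export
generate_current_trace <- function(duration_s, rate_inward_hz = 10,
                                   rate_outward_hz = 0,
                                   amp_mean_pa = 30, amp_sd_pa = 8,
                                   kinetics_inward = c(1, 10),
                                   kinetics_outward = c(2.5, 25),
                                   noise_sd_pa = 2,
                                   sampling_rate_hz = 10000, seed) {
  sl_assert(!missing(seed) && is.numeric(seed), "InvalidParams",
            "seed is mandatory")
  sl_assert(duration_s > 0, "InvalidParams", "duration_s must be > 0")
  sl_assert(rate_inward_hz >= 0 && rate_outward_hz >= 0, "InvalidParams",
            "rates must be >= 0")
  set.seed(as.integer(seed))
  n <- round(duration_s * sampling_rate_hz)
  y <- rnorm(n, sd = noise_sd_pa)
  events <- data.frame(onset_s = numeric(0), amplitude_pa = numeric(0),
                       polarity = character(0))
  add_train <- function(rate, kin, sign, pol) {
    k <- stats::rpois(1, rate * duration_s)
    if (k == 0) return(invisible(NULL))
    onset <- sort(runif(k, 0, duration_s * (n - 1) / n))
    amp <- pmax(stats::rnorm(k, amp_mean_pa, amp_sd_pa), 0.2 * amp_mean_pa)
    kern <- event_template(kin[1], kin[2], sampling_rate_hz = sampling_rate_hz)
    for (i in seq_len(k)) {
      s <- floor(onset[i] * sampling_rate_hz) + 1L
      e <- min(n, s + length(kern) - 1L)
      y[s:e] <<- y[s:e] + sign * amp[i] * kern[seq_len(e - s + 1L)]
    }
    events <<- rbind(events,
                     data.frame(onset_s = (s_idx <- floor(onset *
                                  sampling_rate_hz)) / sampling_rate_hz,
                                amplitude_pa = sign * amp, polarity = pol))
    invisible(NULL)
  }
  add_train(rate_inward_hz, kinetics_inward, -1, "inward")
  add_train(rate_outward_hz, kinetics_outward, +1, "outward")
  events <- events[order(events$onset_s), , drop = FALSE]
  rownames(events) <- NULL
  list(trace = current_trace(y, sampling_rate_hz), events = events)
}
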