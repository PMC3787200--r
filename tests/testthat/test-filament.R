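vs_conf <- c(0.3, 0.1, 0.1)

cyl_stack <- function() {
  fill <- cylinder_fill(c(3.45, 1.45), 1, c(0.5, 9.4))
  volumetric_stack(array(fill, c(1, dim(fill))), vs_conf, "fill")
}

test_that("cylinder phantom traces to an on-axis centreline of true radius", {
  st <- cyl_stack()
  tr <- trace_filament(st, 50, background_subtraction = FALSE)
  inner <- tr$nodes$y_um > 1.5 & tr$nodes$y_um < 8.4  # away from end caps
  expect_gt(sum(inner), 10)
  expect_lt(abs(mean(tr$nodes$radius_um[inner]) - 1.0), 0.25)
  offsets <- sqrt((tr$nodes$z_um[inner] - 3.45)^2 +
                    (tr$nodes$x_um[inner] - 1.45)^2)
  expect_lt(max(offsets), sqrt(sum(vs_conf^2)))  # within one voxel of axis
  expect_true(all(tr$nodes$radius_um >= tr$min_diameter_um / 2))
})

test_that("tracing defaults to the 0.4 um minimal dendrite diameter", {
  expect_equal(formals(trace_filament)$min_diameter_um, 0.4)
  st <- volumetric_stack(array(0, c(1, 6, 10, 10)), vs_conf, "fill")
  expect_error(trace_filament(st, 10), class = "EmptySurface")
})

test_that("capsule voxelization reproduces closed-form volumes", {
  # single edge: cylinder + two hemispherical caps
  tr <- structure(list(
    nodes = data.frame(z_um = c(2, 2), y_um = c(1, 6), x_um = c(1.5, 1.5),
                       radius_um = c(0.8, 0.8)),
    edges = matrix(c(1L, 2L), 1), min_diameter_um = 0.4),
    class = "filament_trace")
  m <- filament_to_mask(tr, c(20, 80, 30), vs_conf)
  expect_equal(m$volume_um3, pi * 0.8^2 * 5 + 4 / 3 * pi * 0.8^3,
               tolerance = 0.10)

  # zero-length edge renders a sphere
  tr0 <- structure(list(
    nodes = data.frame(z_um = c(2, 2), y_um = c(2, 2), x_um = c(1.5, 1.5),
                       radius_um = c(1, 1)),
    edges = matrix(c(1L, 2L), 1), min_diameter_um = 0.4),
    class = "filament_trace")
  m0 <- filament_to_mask(tr0, c(20, 40, 30), vs_conf)
  expect_equal(m0$volume_um3, 4 / 3 * pi, tolerance = 0.10)
})

test_that("filament and surface reconstructions agree on the phantom", {
  st <- cyl_stack()
  surf <- create_surface(st, surface_params(50,
                                            background_subtraction = FALSE))
  tr <- trace_filament(st, 50, background_subtraction = FALSE)
  fil <- filament_to_mask(tr, dim(surf$mask), vs_conf)
  expect_equal(fil$volume_um3 / surf$volume_um3, 1, tolerance = 0.15)
})

test_that("surface and filament filtering give identical synapse counts", {
  # noiseless dendrite phantom: 2 internal post-synaptic puncta, 3
  # external pre-synaptic puncta, 2 genuine pre/post appositions
  d <- c(24, 100, 30); axis <- c(3.45, 1.45)
  fill <- cylinder_fill(axis, 1, c(0.5, 9.4), dim = d)
  st <- volumetric_stack(array(fill, c(1, d)), vs_conf, "fill")
  post_um <- rbind(c(3.45, 3.0, 1.0),    # inside, paired
                   c(3.45, 6.0, 1.9))    # inside, paired
  pre_um <- rbind(c(3.45, 3.0, 0.2),     # outside, 0.8 um from post 1
                  c(3.45, 6.0, 2.7),     # outside, 0.8 um from post 2
                  c(3.45, 8.5, 2.9))     # outside, unpaired distractor
  mk_channel <- function(pts, diam) {
    ch <- array(0, d)
    for (i in seq_len(nrow(pts)))
      ch <- add_gauss_blob(ch, pts[i, ], diam / 2.355, 150, vs_conf)
    ch
  }
  pre_ch <- mk_channel(pre_um, 0.45)
  post_ch <- mk_channel(post_um, 0.6)
  count_synapses <- function(surface) {
    pre_m <- mask_inside_to_zero(pre_ch, surface)
    post_m <- mask_outside_to_zero(post_ch, surface)
    pre <- detect_spots(pre_m, vs_conf,
                        spot_params(0.45, 5, background_subtraction = FALSE),
                        channel_role = "presynaptic")
    post <- detect_spots(post_m, vs_conf,
                         spot_params(0.6, 5, background_subtraction = FALSE),
                         channel_role = "postsynaptic")
    near <- spots_near_surface(pre, surface, coloc_params(1))
    cl <- colocalize_spots(near$near, post, coloc_params(1))
    c(post = n_spots(post), pre_near = n_spots(near$near),
      synapses = length(cl$near_b))
  }
  surf <- create_surface(st, surface_params(50,
                                            background_subtraction = FALSE))
  fil <- filament_to_mask(trace_filament(st, 50,
                                         background_subtraction = FALSE),
                          d, vs_conf)
  cs <- count_synapses(surf)
  cf <- count_synapses(fil)
  expect_equal(unname(cs["post"]), 2)
  expect_equal(unname(cs["synapses"]), 2)
  expect_equal(unname(cf["synapses"]), 2)
  expect_identical(unname(cs["synapses"]), unname(cf["synapses"]))
})
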