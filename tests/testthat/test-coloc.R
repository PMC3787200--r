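vs_conf <- c(0.3, 0.1, 0.1)

planar_surface <- function() {
  m <- array(FALSE, c(10, 30, 30))
  m[, 1, ] <- TRUE   # plane of voxel centres at y = 0
  synaptoloc:::new_neuron_surface(m, vs_conf)
}

test_that("spot-to-plane distances partition near and far as expected", {
  surf <- planar_surface()
  # centres aligned with voxel-centre planes so distances are exact
  spots <- make_spot_set(rbind(c(0.9, 0.5, 1.0), c(0.9, 0.9, 1.0),
                               c(0.9, 1.5, 1.0)), voxel_size = vs_conf)
  res <- spots_near_surface(spots, surf, coloc_params(1))
  expect_equal(res$distances_um, c(0.5, 0.9, 1.5))
  expect_equal(n_spots(res$near), 2)
  expect_equal(n_spots(res$far), 1)
  expect_equal(n_spots(res$near) + n_spots(res$far), 3)
  # a spot on a surface voxel has distance 0
  on_surf <- make_spot_set(rbind(c(0.9, 0, 1.0)), voxel_size = vs_conf)
  expect_equal(spots_near_surface(on_surf, surf,
                                  coloc_params(1))$distances_um, 0)
})

test_that("surface distances respect z anisotropy", {
  m <- array(FALSE, c(12, 10, 10)); m[5, , ] <- TRUE
  for (dz in c(0.3, 0.6)) {
    surf <- synaptoloc:::new_neuron_surface(m, c(dz, 0.1, 0.1))
    # spot 2 voxels above the plane, in-plane aligned
    spots <- make_spot_set(rbind(c((4 + 2) * dz, 0.5, 0.5)),
                           voxel_size = c(dz, 0.1, 0.1))
    res <- spots_near_surface(spots, surf, coloc_params(1))
    expect_equal(res$distances_um, 2 * dz)
    expect_equal(n_spots(res$near), if (dz == 0.3) 1 else 0)
  }
})

test_that("self-colocalization pairs every spot at distance zero", {
  set.seed(41)
  pts <- cbind(runif(20, 0, 3), runif(20, 0, 3), runif(20, 0, 3))
  s <- make_spot_set(pts)
  cl <- colocalize_spots(s, s, coloc_params(1))
  expect_equal(cl$near_a, 1:20)
  expect_equal(cl$near_b, 1:20)
  expect_true(all(cl$pairs$distance_um[cl$pairs$a == cl$pairs$b] == 0))
})

test_that("many-to-many semantics give asymmetric near counts", {
  a <- make_spot_set(rbind(c(1, 1.0, 1), c(1, 1.8, 1)))
  b <- make_spot_set(rbind(c(1, 1.4, 1)))
  cl <- colocalize_spots(a, b, coloc_params(1))
  expect_equal(length(cl$near_a), 2)
  expect_equal(length(cl$near_b), 1)
  expect_equal(nrow(cl$pairs), 2)
})

test_that("colocalization equals the brute-force all-pairs computation", {
  set.seed(42)
  for (rep in 1:3) {
    a_um <- cbind(runif(200, 0, 12), runif(200, 0, 12), runif(200, 0, 12))
    b_um <- cbind(runif(200, 0, 12), runif(200, 0, 12), runif(200, 0, 12))
    cl <- colocalize_spots(make_spot_set(a_um), make_spot_set(b_um),
                           coloc_params(1))
    oracle <- brute_force_pairs(a_um, b_um, 1)
    oracle <- oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE]
    expect_equal(cl$pairs$a, oracle[, 1])
    expect_equal(cl$pairs$b, oracle[, 2])
    expect_equal(cl$pairs$distance_um, oracle[, 3])
    expect_equal(cl$near_a, sort(unique(oracle[, 1])))
    expect_equal(cl$near_b, sort(unique(oracle[, 2])))
  }
})

test_that("enlarging the distance threshold never removes a pair", {
  set.seed(43)
  a <- make_spot_set(cbind(runif(60, 0, 8), runif(60, 0, 8),
                           runif(60, 0, 8)))
  b <- make_spot_set(cbind(runif(60, 0, 8), runif(60, 0, 8),
                           runif(60, 0, 8)))
  prev <- NULL
  for (th in c(0.5, 1, 1.5, 2.5)) {
    keys <- with(colocalize_spots(a, b, coloc_params(th))$pairs,
                 paste(a, b))
    if (!is.null(prev)) expect_true(all(prev %in% keys))
    prev <- keys
  }
})

test_that("scaling all voxel sizes scales every reported distance", {
  # same voxel geometry, voxel size scaled by k: physical distances and
  # the near/far split at a scaled threshold follow exactly
  m <- array(FALSE, c(10, 20, 20)); m[, 1, ] <- TRUE
  k <- 2.5
  for (scale in c(1, k)) {
    vs <- vs_conf * scale
    surf <- synaptoloc:::new_neuron_surface(m, vs)
    spots <- make_spot_set(rbind(c(3 * vs[1], 4 * vs[2], 5 * vs[3])),
                           voxel_size = vs)
    res <- spots_near_surface(spots, surf, coloc_params(1 * scale))
    if (scale == 1) d1 <- res$distances_um else dk <- res$distances_um
  }
  expect_equal(dk, k * d1)
})

test_that("colocalization is symmetric under swapping the two sets", {
  set.seed(44)
  a <- make_spot_set(cbind(runif(40, 0, 6), runif(40, 0, 6),
                           runif(40, 0, 6)))
  b <- make_spot_set(cbind(runif(50, 0, 6), runif(50, 0, 6),
                           runif(50, 0, 6)))
  ab <- colocalize_spots(a, b, coloc_params(1))
  ba <- colocalize_spots(b, a, coloc_params(1))
  ab_keys <- with(ab$pairs, sort(paste(a, b)))
  ba_keys <- with(ba$pairs, sort(paste(b, a)))
  expect_identical(ab_keys, ba_keys)
  expect_identical(ab$near_a, ba$near_b)
  expect_identical(ab$near_b, ba$near_a)
})

test_that("mismatched physical frames are rejected", {
  a <- make_spot_set(rbind(c(1, 1, 1)), voxel_size = c(0.3, 0.1, 0.1))
  b <- make_spot_set(rbind(c(1, 1, 1)), voxel_size = c(0.6, 0.1, 0.1))
  expect_error(colocalize_spots(a, b, coloc_params(1)),
               class = "FrameMismatch")
})
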