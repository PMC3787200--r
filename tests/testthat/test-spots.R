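vs_iso <- c(0.1, 0.1, 0.1)

test_that("a single noiseless blob yields one spot at its centre", {
  d <- c(40, 40, 40)
  ctr <- c(2.03, 2.05, 1.95)
  ch <- add_gauss_blob(array(0, d), ctr, 0.3 / 2.355, 100, vs_iso)
  sp <- detect_spots(ch, vs_iso,
                     spot_params(0.3, 5, background_subtraction = FALSE))
  expect_equal(n_spots(sp), 1)
  err <- abs(c(sp$spots$z_um, sp$spots$y_um, sp$spots$x_um) - ctr)
  expect_true(all(err < 0.05))  # within half a voxel
})

test_that("a uniform image contains no spots", {
  sp <- detect_spots(array(13, c(10, 12, 12)), vs_iso,
                     spot_params(0.3, 1, background_subtraction = FALSE))
  expect_equal(n_spots(sp), 0)
  qh <- quality_histogram(array(13, c(10, 12, 12)), vs_iso,
                          spot_params(0.3, 1,
                                      background_subtraction = FALSE))
  expect_length(qh$qualities, 0)
})

test_that("blobs confined to one optical slice fail the two-slice rule", {
  d <- c(12, 30, 30)
  ch <- array(0, d)
  ch[6, 15, 15] <- 100   # single-slice punctum (z artifact)
  two <- detect_spots(ch, c(0.3, 0.1, 0.1),
                      spot_params(0.3, 5, background_subtraction = FALSE,
                                  min_z_slices = 2))
  one <- detect_spots(ch, c(0.3, 0.1, 0.1),
                      spot_params(0.3, 5, background_subtraction = FALSE,
                                  min_z_slices = 1))
  expect_equal(n_spots(two), 0)
  expect_equal(n_spots(one), 1)
})

test_that("noiseless separated blob grids are recovered exactly", {
  # precision = recall = 1 with separation > 2x diameter
  d <- c(50, 50, 50)
  centers <- as.matrix(expand.grid(z = c(1.2, 2.4, 3.6),
                                   y = c(1.2, 2.4, 3.6),
                                   x = c(1.3, 2.6, 3.9)))
  ch <- array(0, d)
  for (i in seq_len(nrow(centers)))
    ch <- add_gauss_blob(ch, centers[i, ], 0.3 / 2.355, 100, vs_iso)
  sp <- detect_spots(ch, vs_iso,
                     spot_params(0.3, 5, background_subtraction = FALSE))
  expect_equal(n_spots(sp), nrow(centers))   # precision: no extras
  np <- synaptoloc:::nearest_point(
    as.matrix(sp$spots[, c("z_um", "y_um", "x_um")]), centers)
  expect_true(all(np$dist < 0.05))           # recall: every blob found
  expect_equal(sort(unique(np$index)), seq_len(nrow(centers)))
})

test_that("detection count is monotone non-increasing in the threshold", {
  set.seed(31)
  d <- c(30, 30, 30)
  ch <- array(0, d)
  for (i in 1:12)
    ch <- add_gauss_blob(ch, runif(3, 0.5, 2.4), 0.13,
                         runif(1, 20, 120), vs_iso)
  counts <- vapply(c(1, 3, 6, 12, 24), function(th)
    n_spots(detect_spots(ch, vs_iso,
                         spot_params(0.3, th,
                                     background_subtraction = FALSE))), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("spot centres are equivariant under integer-voxel translation", {
  d <- c(30, 30, 30)
  ch <- add_gauss_blob(array(0, d), c(1.52, 1.48, 1.5), 0.13, 100, vs_iso)
  shifted <- array(0, d)
  shifted[4:30, 2:30, 1:30] <- ch[1:27, 1:29, 1:30]
  p0 <- detect_spots(ch, vs_iso,
                     spot_params(0.3, 5, background_subtraction = FALSE))
  p1 <- detect_spots(shifted, vs_iso,
                     spot_params(0.3, 5, background_subtraction = FALSE))
  expect_equal(p1$spots$z_um, p0$spots$z_um + 3 * 0.1, tolerance = 1e-8)
  expect_equal(p1$spots$y_um, p0$spots$y_um + 1 * 0.1, tolerance = 1e-8)
  expect_equal(p1$spots$x_um, p0$spots$x_um, tolerance = 1e-8)
})

test_that("depth background profile tracks the per-slice background", {
  d <- c(20, 24, 24)
  ramp <- array(rep((seq_len(d[1]) - 1) * 1.0, prod(d[2:3])), d)
  prof <- estimate_depth_background(ramp)
  expect_equal(prof, (seq_len(d[1]) - 1) * 1.0, tolerance = 1e-8)
  expect_equal(estimate_depth_background(array(4, d)), rep(4, d[1]))
  # sparse bright blobs are excluded as high-contrast
  withblobs <- ramp
  set.seed(8)
  for (i in 1:6)
    withblobs <- add_gauss_blob(withblobs,
                                c(runif(1, 0.3, 1.7), runif(2, 0.3, 2.0)),
                                0.15, 200, vs_iso)
  prof2 <- estimate_depth_background(withblobs)
  expect_equal(prof2, prof, tolerance = 0.10)
})

test_that("quality histogram separates dim and bright blob populations", {
  set.seed(12)
  d <- c(40, 60, 60)
  dim_ctr <- as.matrix(expand.grid(z = c(1, 2, 3), y = c(1, 2.5, 4),
                                   x = c(1.2, 3.2)))
  bright_ctr <- as.matrix(expand.grid(z = c(1.5, 2.5), y = c(1.6, 3.4),
                                      x = c(2.2, 4.4)))
  ch <- array(0, d)
  for (i in seq_len(nrow(dim_ctr)))
    ch <- add_gauss_blob(ch, dim_ctr[i, ], 0.13, 10, vs_iso)
  for (i in seq_len(nrow(bright_ctr)))
    ch <- add_gauss_blob(ch, bright_ctr[i, ], 0.13, 100, vs_iso)
  qh <- quality_histogram(ch, vs_iso,
                          spot_params(0.3, 1, background_subtraction = FALSE))
  q <- qh$qualities
  ref <- detect_spots(ch, vs_iso,
                      spot_params(0.3, 2, background_subtraction = FALSE))
  bright_q <- min(q[q > max(q) / 2])
  dim_q <- max(q[q < max(q) / 2])
  expect_gt(bright_q / dim_q, 3)   # clear valley between the modes
  # thresholding at the valley recovers exactly the bright population
  valley <- (bright_q + dim_q) / 2
  got <- detect_spots(ch, vs_iso,
                      spot_params(0.3, valley,
                                  background_subtraction = FALSE))
  expect_equal(n_spots(got), nrow(bright_ctr))
  np <- synaptoloc:::nearest_point(
    as.matrix(got$spots[, c("z_um", "y_um", "x_um")]), bright_ctr)
  expect_true(all(np$dist < 0.05))
})

test_that("depth-dependent background does not bias detection counts", {
  # uniform-truth phantom: same blob layout with and without a depth ramp;
  # per-depth-bin counts agree within 10%
  set.seed(13)
  d <- c(40, 50, 50)
  vs <- c(0.3, 0.1, 0.1)
  # rejection-sample centres at least 1.5 um apart so no two blobs merge
  centers <- matrix(numeric(0), 0, 3)
  while (nrow(centers) < 30) {
    p <- c(runif(1, 0.6, 11.4), runif(1, 0.6, 4.4), runif(1, 0.6, 4.4))
    if (nrow(centers) == 0 ||
        min(sqrt(rowSums(sweep(centers, 2, p, "-")^2))) > 1.5)
      centers <- rbind(centers, p)
  }
  base <- array(0, d)
  for (i in seq_len(nrow(centers)))
    base <- add_gauss_blob(base, centers[i, ], 0.25, 100, vs)
  ramp <- array(rep((seq_len(d[1]) - 1) * vs[1] * 3, prod(d[2:3])), d)
  count_per_bin <- function(ch) {
    sp <- detect_spots(ch, vs, spot_params(0.6, 5))
    tabulate(floor(sp$spots$depth_um / 4) + 1, nbins = 3)
  }
  c0 <- count_per_bin(base)
  c1 <- count_per_bin(base + ramp)
  expect_equal(sum(c0), nrow(centers))
  expect_true(all(abs(c1 - c0) <= pmax(0.1 * c0, 0)))
})
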