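## Internal helpers shared across modules.

#' @importFrom stats median sd lm vcov coef qt ks.test nls predict
#' @importFrom utils read.csv write.csv head
NULL

# Classed error so callers can condition on failure mode, e.g.
# tryCatch(..., MissingVoxelSize = function(e) ...).
sl_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "synaptoloc_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

sl_assert <- function(cond, class, msg, ...) {
  if (!isTRUE(cond)) sl_stop(class, msg, ...)
  invisible(TRUE)
}

# Round half away from zero (printed tables use this, not banker's rounding).
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

check_voxel_size <- function(voxel_size) {
  sl_assert(is.numeric(voxel_size) && length(voxel_size) == 3 &&
              all(is.finite(voxel_size)) && all(voxel_size > 0),
            "InvalidVoxelSize",
            "voxel_size must be three positive finite numbers (dz, dy, dx)")
  vs <- as.numeric(voxel_size)
  names(vs) <- c("dz", "dy", "dx")
  vs
}

# 1-D Gaussian kernel, truncated at 4 sigma, unit sum.
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(((-r):r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Convolve a 3-D array along one axis with a 1-D kernel.  Edges use kernel
# renormalization (each output is a weighted mean of in-bounds samples), so a
# constant array is exactly invariant — required for the background
# subtraction contract (constant image -> all-zero residual).
conv_axis <- function(a, kernel, axis) {
  if (length(kernel) == 1L) return(a)
  d <- dim(a)
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    lo <- max(1L, j - r); hi <- min(n, j + r)
    w <- kernel[(lo - j + r + 1L):(hi - j + r + 1L)]
    K[j, lo:hi] <- w / sum(w)
  }
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  res <- K %*% matrix(ap, nrow = n)
  dim(res) <- dp
  aperm(res, order(perm))
}

# Separable anisotropic Gaussian blur; sigma_vox = (z, y, x) in voxel units.
gauss_blur3 <- function(a, sigma_vox) {
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0) a <- conv_axis(a, gauss_kernel(sigma_vox[ax]), ax)
  }
  a
}

# Forward half of the 26-neighbourhood (13 offsets), for edge construction.
.offsets26_forward <- local({
  o <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  o[o[, 3] > 0 | (o[, 3] == 0 & o[, 2] > 0) |
      (o[, 3] == 0 & o[, 2] == 0 & o[, 1] > 0), , drop = FALSE]
})

.offsets6 <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                   c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))

# Label connected components of a 3-D logical mask (26-connectivity).
# Returns integer array: 0 = background, 1..k = component id.
# The voxel adjacency graph is built vectorized and handed to igraph.
label_components3 <- function(mask, offsets = .offsets26_forward) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (length(idx) == 0L) return(lab)
  pos <- array(0L, d)
  pos[idx] <- seq_along(idx)
  ai <- arrayInd(idx, d)
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offsets))) {
    nb <- sweep(ai, 2, offsets[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nbl <- pos[nb[ok, , drop = FALSE]]
    keep <- nbl > 0L
    from <- c(from, which(ok)[keep])
    to <- c(to, nbl[keep])
  }
  if (length(from) == 0L) {
    lab[idx] <- seq_along(idx)
    return(lab)
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  extra <- length(idx) - igraph::gorder(g)
  if (extra > 0) g <- igraph::add_vertices(g, extra)
  lab[idx] <- igraph::components(g)$membership
  lab
}

# Voxels of `mask` with at least one 6-neighbour outside the mask (or on the
# array border).  The nearest mask voxel to any point whose own voxel is not
# in the mask is always one of these, which makes exact anisotropic
# point-to-mask distances cheap.
mask_shell <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, d)
  for (k in seq_len(nrow(.offsets6))) {
    o <- .offsets6[k, ]
    shifted <- array(FALSE, d)
    src_z <- seq_len(d[1]) - o[1]; src_y <- seq_len(d[2]) - o[2]
    src_x <- seq_len(d[3]) - o[3]
    okz <- src_z >= 1 & src_z <= d[1]; oky <- src_y >= 1 & src_y <= d[2]
    okx <- src_x >= 1 & src_x <= d[3]
    shifted[okz, oky, okx] <- mask[src_z[okz], src_y[oky], src_x[okx]]
    interior <- interior & shifted
  }
  mask & !interior
}

# Physical coordinates (um) of voxel array indices, voxel-centre convention:
# index i (1-based) -> (i - 1) * spacing.
index_to_um <- function(ind, voxel_size) {
  sweep(ind - 1, 2, voxel_size, "*")
}

# Voxel index containing a physical point (nearest voxel centre).
um_to_index <- function(um, voxel_size) {
  ind <- round(sweep(um, 2, voxel_size, "/")) + 1
  storage.mode(ind) <- "integer"
  ind
}

# Minimum anisotropic Euclidean distance from each query point (um, n x 3
# z/y/x) to any of the target points (um).  Chunked brute force.
min_dist_to_points <- function(query_um, target_um, chunk = 256L) {
  nearest_point(query_um, target_um, chunk)$dist
}

# As min_dist_to_points, but also reports which target point is nearest.
nearest_point <- function(query_um, target_um, chunk = 256L) {
  nq <- nrow(query_um)
  if (nq == 0L) return(list(dist = numeric(0), index = integer(0)))
  if (nrow(target_um) == 0L)
    return(list(dist = rep(Inf, nq), index = rep(NA_integer_, nq)))
  dist <- numeric(nq); index <- integer(nq)
  tz <- target_um[, 1]; ty <- target_um[, 2]; tx <- target_um[, 3]
  for (s in seq(1L, nq, by = chunk)) {
    e <- min(nq, s + chunk - 1L)
    dz <- outer(query_um[s:e, 1], tz, "-")
    dy <- outer(query_um[s:e, 2], ty, "-")
    dx <- outer(query_um[s:e, 3], tx, "-")
    d2 <- dz * dz + dy * dy + dx * dx
    wm <- max.col(-d2, ties.method = "first")
    index[s:e] <- wm
    dist[s:e] <- sqrt(d2[cbind(seq_len(e - s + 1L), wm)])
  }
  list(dist = dist, index = index)
}
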