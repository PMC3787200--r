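## stack_io: multichannel volumetric stacks with physical voxel metadata.

VALID_ROLES <- c("fill", "presynaptic", "postsynaptic", "other")

#' Construct a multichannel volumetric stack
#'
#' A `volumetric_stack` bundles a 4-D intensity array with the physical voxel
#' spacing and the biological role of each channel. The axis order is fixed
#' as (channel, z, y, x) and is enforced at construction; all physical
#' positions reported downstream are voxel-centre coordinates, computed as
#' `(index - 1) * spacing` in micrometres, so array indices are never
#' interpreted as distances.
#'
#' @param intensities 4-D numeric array ordered (channel, z, y, x); all
#'   values must be finite and non-negative.
#' @param voxel_size numeric length-3, physical voxel spacing `(dz, dy, dx)`
#'   in micrometres. Anisotropy (dz > dy = dx) is typical for confocal
#'   stacks (e.g. 0.3 um z-steps over ~0.1 um pixels).
#' @param channel_roles character vector, one role per channel, each one of
#'   `"fill"` (the dye-filled neuron), `"presynaptic"`, `"postsynaptic"`,
#'   or `"other"`.
#' @param depth_origin_um depth of the top optical slice relative to the
#'   analysis origin, in micrometres (default 0: depth is measured from the
#'   top of the stack, not the tissue surface).
#' @return An object of class `volumetric_stack`.
#' @export
volumetric_stack <- function(intensities, voxel_size, channel_roles,
                             depth_origin_um = 0) {
  sl_assert(is.array(intensities) && length(dim(intensities)) == 4L,
            "InvalidStack", "intensities must be a 4-D (channel, z, y, x) array")
  sl_assert(all(is.finite(intensities)) && all(intensities >= 0),
            "InvalidStack", "intensities must be finite and non-negative")
  voxel_size <- check_voxel_size(voxel_size)
  nc <- dim(intensities)[1]
  channel_roles <- as.character(channel_roles)
  sl_assert(length(channel_roles) == nc, "ChannelCountMismatch",
            "channel_roles names %d channels but the stack has %d",
            length(channel_roles), nc)
  bad <- setdiff(channel_roles, VALID_ROLES)
  sl_assert(length(bad) == 0, "InvalidChannelRole",
            "unknown channel role(s): %s", paste(bad, collapse = ", "))
  structure(list(intensities = intensities, voxel_size = voxel_size,
                 channel_roles = channel_roles,
                 depth_origin_um = as.numeric(depth_origin_um)),
            class = "volumetric_stack")
}

#' @export
print.volumetric_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("volumetric_stack: %d channel(s), %d x %d x %d (z,y,x) voxels\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size (um): dz=%.4g dy=%.4g dx=%.4g\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat("  roles:", paste(sprintf("%d=%s", seq_len(d[1]), x$channel_roles),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Extract one channel of a stack as a 3-D array
#'
#' @param stack a [volumetric_stack()].
#' @param role a channel role name, or an integer channel index.
#' @return 3-D numeric array (z, y, x).
#' @export
get_channel <- function(stack, role) {
  if (is.numeric(role)) {
    sl_assert(role >= 1 && role <= length(stack$channel_roles),
              "ChannelCountMismatch", "channel index %d out of range", role)
    i <- as.integer(role)
  } else {
    i <- which(stack$channel_roles == role)
    sl_assert(length(i) >= 1, "ChannelCountMismatch",
              "no channel with role '%s'", role)
    if (role == "fill")
      sl_assert(length(i) == 1, "InvalidChannelRole",
                "exactly one fill channel is required, found %d", length(i))
    i <- i[1]
  }
  a <- stack$intensities[i, , , , drop = FALSE]
  dim(a) <- dim(stack$intensities)[2:4]
  a
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a stack to a multi-page TIFF with a JSON metadata sidecar
#'
#' Pages are written channel-major (all z-slices of channel 1, then channel
#' 2, ...) as 32-bit float, scaled into `[0, 1]` by a global factor recorded
#' in the sidecar. The sidecar (`<path>.json`) carries the voxel size in
#' micrometres, the channel roles, the page layout and the intensity scale,
#' so a written stack always re-reads with full physical metadata.
#'
#' @param stack a [volumetric_stack()].
#' @param path output TIFF path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$intensities)
  scale <- max(stack$intensities)
  if (scale <= 0) scale <- 1
  pages <- vector("list", d[1] * d[2])
  p <- 0L
  for (ch in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      p <- p + 1L
      pages[[p]] <- matrix(stack$intensities[ch, z, , ] / scale, d[3], d[4])
    }
  }
  ok <- tryCatch({
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE,
                    compression = "deflate")
    meta <- list(format = "synaptoloc-stack-1",
                 axes = "czyx",
                 n_channels = d[1], n_z = d[2], n_y = d[3], n_x = d[4],
                 voxel_size_um = as.numeric(stack$voxel_size),
                 channel_roles = stack$channel_roles,
                 depth_origin_um = stack$depth_origin_um,
                 intensity_scale = scale)
    jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
    TRUE
  }, error = function(e) e)
  sl_assert(isTRUE(ok), "IOFailure", "cannot write stack to '%s': %s", path,
            if (isTRUE(ok)) "" else conditionMessage(ok))
  invisible(path)
}

# Extract PhysicalSizeZ/Y/X (um) from an OME-XML image description, if any.
parse_ome_voxel_size <- function(desc) {
  if (is.null(desc) || !nzchar(desc) || !grepl("<", desc, fixed = TRUE))
    return(NULL)
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  px <- xml2::xml_find_first(doc, "//*[local-name()='Pixels']")
  if (inherits(px, "xml_missing")) return(NULL)
  gz <- xml2::xml_attr(px, "PhysicalSizeZ")
  gy <- xml2::xml_attr(px, "PhysicalSizeY")
  gx <- xml2::xml_attr(px, "PhysicalSizeX")
  if (any(is.na(c(gz, gy, gx)))) return(NULL)
  as.numeric(c(gz, gy, gx))
}

#' Read a multichannel stack from a multi-page TIFF
#'
#' Physical voxel sizes are taken, in order of precedence, from the explicit
#' `voxel_size` argument, from a `synaptoloc` JSON sidecar next to the file,
#' or from `PhysicalSizeX/Y/Z` in an OME-XML image description embedded in
#' the TIFF. A plain TIFF with no physical metadata and no explicit
#' `voxel_size` is an error (`MissingVoxelSize`): defaulting silently to
#' 1 um would corrupt every downstream distance.
#'
#' @param path TIFF file path.
#' @param channel_roles character vector of roles, one per channel. May be
#'   omitted when a sidecar provides them.
#' @param voxel_size optional explicit `(dz, dy, dx)` in micrometres;
#'   overrides file metadata.
#' @param n_channels number of channels for plain TIFFs without a sidecar
#'   (defaults to `length(channel_roles)`); pages must be channel-major.
#' @param depth_origin_um optional override of the depth origin.
#' @return A [volumetric_stack()].
#' @export
read_stack <- function(path, channel_roles = NULL, voxel_size = NULL,
                       n_channels = NULL, depth_origin_um = NULL) {
  sl_assert(file.exists(path), "IOFailure", "file not found: '%s'", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e) e)
  sl_assert(!inherits(pages, "error"), "IOFailure",
            "cannot read TIFF '%s'", path)
  if (!is.list(pages)) pages <- list(pages)
  meta <- NULL
  if (file.exists(sidecar_path(path)))
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  if (is.null(voxel_size)) {
    if (!is.null(meta$voxel_size_um)) {
      voxel_size <- meta$voxel_size_um
    } else {
      voxel_size <- parse_ome_voxel_size(attr(pages[[1]], "description"))
    }
  }
  sl_assert(!is.null(voxel_size), "MissingVoxelSize",
            "'%s' carries no physical voxel size; pass voxel_size explicitly",
            path)
  voxel_size <- check_voxel_size(voxel_size)
  if (is.null(channel_roles)) channel_roles <- meta$channel_roles
  sl_assert(!is.null(channel_roles), "InvalidChannelRole",
            "channel_roles not given and not recorded in a sidecar")
  if (is.null(n_channels))
    n_channels <- if (!is.null(meta$n_channels)) meta$n_channels
                  else length(channel_roles)
  np <- length(pages)
  sl_assert(n_channels >= 1 && np %% n_channels == 0, "ChannelCountMismatch",
            "%d pages cannot be split into %d channels", np, n_channels)
  sl_assert(length(channel_roles) == n_channels, "ChannelCountMismatch",
            "roles name %d channels but the file has %d",
            length(channel_roles), n_channels)
  nz <- np %/% n_channels
  d1 <- dim(pages[[1]])
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  a <- array(0, c(n_channels, nz, d1[1], d1[2]))
  p <- 0L
  for (ch in seq_len(n_channels)) {
    for (z in seq_len(nz)) {
      p <- p + 1L
      pg <- pages[[p]]
      if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # collapse grey-as-RGB
      a[ch, z, , ] <- pg * scale
    }
  }
  if (is.null(depth_origin_um))
    depth_origin_um <- if (!is.null(meta$depth_origin_um)) meta$depth_origin_um
                       else 0
  volumetric_stack(a, voxel_size, channel_roles, depth_origin_um)
}

#' Write a detected spot set to CSV
#'
#' Columns: `x_um, y_um, z_um, diameter_um, quality, channel_role,
#' depth_um`. Detection parameters go to a JSON sidecar (`<path>.json`).
#'
#' @param spots a [spot_set].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spots_csv <- function(spots, path) {
  df <- spots$spots[, c("x_um", "y_um", "z_um", "diameter_um", "quality",
                        "depth_um")]
  df$channel_role <- spots$channel_role
  ok <- tryCatch({
    write.csv(df, path, row.names = FALSE)
    jsonlite::write_json(list(params = unclass(spots$params),
                              source = spots$source),
                         sidecar_path(path), auto_unbox = TRUE, digits = NA)
    TRUE
  }, error = function(e) FALSE)
  sl_assert(ok, "IOFailure", "cannot write spots to '%s'", path)
  invisible(path)
}

#' Write colocalization pairs to CSV with a JSON summary sidecar
#'
#' @param coloc a [coloc_result].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_coloc_csv <- function(coloc, path) {
  ok <- tryCatch({
    write.csv(coloc$pairs, path, row.names = FALSE)
    jsonlite::write_json(
      list(max_distance_um = coloc$params$max_distance_um,
           n_pairs = nrow(coloc$pairs),
           n_near_a = length(coloc$near_a), n_near_b = length(coloc$near_b)),
      sidecar_path(path), auto_unbox = TRUE, digits = NA)
    TRUE
  }, error = function(e) FALSE)
  sl_assert(ok, "IOFailure", "cannot write pairs to '%s'", path)
  invisible(path)
}
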