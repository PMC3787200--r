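## channel_masking: restrict label channels relative to the neuron surface.
## Post-synaptic labels live inside the filled neuron, pre-synaptic
## terminals outside; masking enforces that before spot detection.

check_mask_shape <- function(channel, surface) {
  sl_assert(inherits(surface, "neuron_surface"), "InvalidParams",
            "surface must be a neuron_surface")
  sl_assert(identical(dim(channel), dim(surface$mask)), "ShapeMismatch",
            "channel %s and surface mask %s differ in shape",
            paste(dim(channel), collapse = "x"),
            paste(dim(surface$mask), collapse = "x"))
}

#' Zero all voxels inside the neuron surface
#'
#' Used on pre-synaptic channels: terminals apposed to the neuron lie
#' outside its membrane, so fluorescence inside the fill is suppressed.
#' Always returns a new array; the input is never modified.
#'
#' @param channel 3-D (z, y, x) numeric array.
#' @param surface a `neuron_surface` on the same grid.
#' @return 3-D array with `channel[surface] == 0`, elsewhere unchanged.
#' @export
mask_inside_to_zero <- function(channel, surface) {
  check_mask_shape(channel, surface)
  out <- channel
  out[surface$mask] <- 0
  out
}

#' Zero all voxels outside the neuron surface
#'
#' Used on post-synaptic channels: receptor/scaffold puncta belonging to
#' the filled neuron lie within its membrane.
#'
#' @inheritParams mask_inside_to_zero
#' @return 3-D array with `channel[!surface] == 0`, elsewhere unchanged.
#' @export
mask_outside_to_zero <- function(channel, surface) {
  check_mask_shape(channel, surface)
  out <- channel
  out[!surface$mask] <- 0
  out
}

#' Mask every label channel of a stack by its role
#'
#' Convenience wrapper that applies [mask_inside_to_zero()] to every
#' presynaptic channel and [mask_outside_to_zero()] to every postsynaptic
#' channel, so the two conventions cannot be swapped by accident. Fill and
#' other channels pass through untouched.
#'
#' @param stack a [volumetric_stack()].
#' @param surface a `neuron_surface` on the stack grid.
#' @return A new [volumetric_stack()] with masked label channels.
#' @export
mask_channels_by_role <- function(stack, surface) {
  a <- stack$intensities
  for (i in seq_along(stack$channel_roles)) {
    ch <- get_channel(stack, i)
    ch <- switch(stack$channel_roles[i],
                 presynaptic = mask_inside_to_zero(ch, surface),
                 postsynaptic = mask_outside_to_zero(ch, surface),
                 ch)
    a[i, , , ] <- ch
  }
  volumetric_stack(a, stack$voxel_size, stack$channel_roles,
                   stack$depth_origin_um)
}
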