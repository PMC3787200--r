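## cli_orchestration: declarative config -> segment -> mask -> detect ->
## coloc -> quantify, with provenance.

cfg_get <- function(config, field, required = TRUE, default = NULL) {
  parts <- strsplit(field, ".", fixed = TRUE)[[1]]
  x <- config
  for (p in parts) {
    if (is.null(x[[p]])) {
      if (required)
        sl_stop("ConfigInvalid", "config is missing required field '%s'",
                field)
      return(default)
    }
    x <- x[[p]]
  }
  x
}

#' Read a pipeline configuration file
#'
#' The config is plain hierarchical YAML. Required fields: `input` (stack
#' TIFF path) or `simulate: true`, `channel_roles`, `surface.threshold`,
#' `spots.presynaptic.diameter_um` / `.quality_threshold` (same for
#' `postsynaptic`), `coloc.max_distance_um`, and `output_dir`. Optional:
#' `voxel_size`, `surface.min_dendrite_diameter_um`,
#' `surface.min_object_volume_um3`, `depth_qc.bin_size_um`,
#' `depth_qc.cutoff_fraction`, `seed`.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  sl_assert(file.exists(path), "ConfigInvalid", "config file not found: '%s'",
            path)
  yaml::read_yaml(path)
}

#' Run the full synapse-counting pipeline
#'
#' Executes segment -> mask -> detect -> colocalize -> quantify on one
#' stack (or on a freshly generated phantom when `simulate` is set), and
#' writes every intermediate product — surface mask, per-channel spot
#' CSVs, pair CSV, depth-QC histograms, a summary table and a JSON
#' provenance record with all parameters — into `output_dir`. Outputs are
#' a pure function of config + inputs; identical configs give identical
#' files.
#'
#' @param config a config list (see [read_pipeline_config()]) or the path
#'   to a YAML config file.
#' @return Invisibly, a result bundle: `surface`, `pre_spots`,
#'   `post_spots`, `pre_near`, `coloc`, `depth`, `summary` (named list of
#'   headline counts), `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  sl_assert(is.list(config), "ConfigInvalid", "config must be a list")
  # validate required fields before any stage runs
  required <- c("output_dir", "surface.threshold",
                "spots.presynaptic.diameter_um",
                "spots.presynaptic.quality_threshold",
                "spots.postsynaptic.diameter_um",
                "spots.postsynaptic.quality_threshold",
                "coloc.max_distance_um")
  for (f in required) cfg_get(config, f)
  if (isTRUE(config$simulate)) cfg_get(config, "seed") else
    cfg_get(config, "input")
  out_dir <- cfg_get(config, "output_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(fmt, ...) {
    message(sprintf("[synaptoloc %s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }

  truth <- NULL
  if (isTRUE(cfg_get(config, "simulate", required = FALSE, default = FALSE))) {
    seed <- cfg_get(config, "seed")
    log_stage("simulate: phantom seed %d", seed)
    sim_args <- cfg_get(config, "phantom", required = FALSE, default = list())
    sim_args$seed <- seed
    sim <- generate_neuron_stack(do.call(phantom_spec, sim_args))
    stack <- sim$stack
    truth <- sim$truth
  } else {
    input <- cfg_get(config, "input")
    stack <- read_stack(input,
                        channel_roles = cfg_get(config, "channel_roles",
                                                required = FALSE),
                        voxel_size = cfg_get(config, "voxel_size",
                                             required = FALSE))
    log_stage("read %s", input)
  }

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      sl_stop("PipelineStageError", "stage '%s' failed: %s", name,
              conditionMessage(e))
    })
  }

  surf <- run_stage("segment", {
    sp <- surface_params(
      intensity_threshold = cfg_get(config, "surface.threshold"),
      min_dendrite_diameter_um =
        cfg_get(config, "surface.min_dendrite_diameter_um",
                required = FALSE, default = 0.4),
      min_object_volume_um3 =
        cfg_get(config, "surface.min_object_volume_um3",
                required = FALSE, default = 0),
      smoothing_enabled = cfg_get(config, "surface.smoothing",
                                  required = FALSE, default = FALSE),
      background_subtraction =
        cfg_get(config, "surface.background_subtraction",
                required = FALSE, default = TRUE))
    create_surface(stack, sp)
  })
  log_stage("segment: volume %.1f um^3, %d component(s)",
            surf$volume_um3, surf$component_count)

  masked <- run_stage("mask", mask_channels_by_role(stack, surf))

  detect_role <- function(role) {
    pcfg <- cfg_get(config, paste0("spots.", role))
    pars <- spot_params(
      diameter_um = cfg_get(pcfg, "diameter_um"),
      quality_threshold = cfg_get(pcfg, "quality_threshold"),
      background_subtraction = cfg_get(pcfg, "background_subtraction",
                                       required = FALSE, default = TRUE),
      min_z_slices = cfg_get(pcfg, "min_z_slices", required = FALSE,
                             default = 2L))
    detect_spots(get_channel(masked, role), stack$voxel_size, pars,
                 depth_origin_um = stack$depth_origin_um,
                 channel_role = role)
  }
  pre <- run_stage("spots", detect_role("presynaptic"))
  post <- run_stage("spots", detect_role("postsynaptic"))
  log_stage("spots: %d presynaptic, %d postsynaptic", n_spots(pre),
            n_spots(post))

  cpar <- coloc_params(cfg_get(config, "coloc.max_distance_um"))
  near <- run_stage("coloc", spots_near_surface(pre, surf, cpar))
  pairs <- run_stage("coloc", colocalize_spots(near$near, post, cpar))
  log_stage("coloc: %d near-surface presynaptic, %d pairs",
            n_spots(near$near), nrow(pairs$pairs))

  dq_bin <- cfg_get(config, "depth_qc.bin_size_um", required = FALSE,
                    default = 5)
  dq_cut <- cfg_get(config, "depth_qc.cutoff_fraction", required = FALSE,
                    default = 0.85)
  depth <- run_stage("depth-qc", {
    hs <- list()
    if (n_spots(pre) > 0) hs$presynaptic <- depth_qc(pre, dq_bin, dq_cut)
    if (n_spots(post) > 0) hs$postsynaptic <- depth_qc(post, dq_bin, dq_cut)
    hs
  })

  paths <- list(
    surface = file.path(out_dir, "surface_mask.tif"),
    pre_spots = file.path(out_dir, "spots_presynaptic.csv"),
    post_spots = file.path(out_dir, "spots_postsynaptic.csv"),
    pairs = file.path(out_dir, "coloc_pairs.csv"),
    summary = file.path(out_dir, "summary.csv"),
    provenance = file.path(out_dir, "provenance.json"))
  mask_stack <- volumetric_stack(
    array(surf$mask * 1, c(1, dim(surf$mask))), stack$voxel_size, "other")
  write_stack(mask_stack, paths$surface)
  write_spots_csv(pre, paths$pre_spots)
  write_spots_csv(post, paths$post_spots)
  write_coloc_csv(pairs, paths$pairs)

  summary <- list(
    surface_volume_um3 = surf$volume_um3,
    n_presynaptic = n_spots(pre),
    n_postsynaptic = n_spots(post),
    n_pre_near_surface = n_spots(near$near),
    n_pairs = nrow(pairs$pairs),
    n_pre_paired = length(pairs$near_a),
    n_post_paired = length(pairs$near_b))
  write.csv(data.frame(quantity = names(summary),
                       value = unlist(summary)),
            paths$summary, row.names = FALSE)
  prov <- list(package = "synaptoloc",
               version = as.character(utils::packageVersion("synaptoloc")),
               config = config,
               depth_cutoff_um = lapply(depth, function(h) h$cutoff_depth_um))
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_stage("done: %d putative synapses", summary$n_pairs)

  invisible(list(surface = surf, pre_spots = pre, post_spots = post,
                 pre_near = near, coloc = pairs, depth = depth,
                 truth = truth, summary = summary, paths = paths))
}
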