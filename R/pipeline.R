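#' Pipeline configuration
#'
#' One object governs every stage; there are no hidden defaults outside
#' it. Unknown keys are rejected so silent typos cannot change an
#' analysis, and [run_pipeline()] writes the fully resolved configuration
#' next to its outputs for provenance.
#'
#' @param spacing A [voxel_spacing()] (or list with dx/dy/dz) used when
#'   input files carry no spacing metadata, and by the scene generator.
#' @param preprocess A [preprocess_params()] or plain list of overrides.
#' @param segment A [segmentation_params()] or plain list of overrides.
#' @param penetration List with `bin_width_um`, `min_depth_um`,
#'   `min_records`.
#' @param seed Integer seed for any stochastic stage.
#' @param out_dir Optional output directory for reports.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(spacing = voxel_spacing(),
                            preprocess = preprocess_params(),
                            segment = segmentation_params(),
                            penetration = list(bin_width_um = 0.2,
                                               min_depth_um = 0.4,
                                               min_records = 20L),
                            seed = 1L,
                            out_dir = NULL) {
  if (!inherits(spacing, "voxel_spacing")) {
    check_known_keys(spacing, c("dx", "dy", "dz"), "spacing")
    spacing <- do.call(voxel_spacing, as.list(spacing))
  }
  if (!inherits(preprocess, "preprocess_params")) {
    check_known_keys(preprocess, names(formals(preprocess_params)), "preprocess")
    preprocess <- do.call(preprocess_params, as.list(preprocess))
  }
  if (!inherits(segment, "segmentation_params")) {
    check_known_keys(segment, names(formals(segmentation_params)), "segment")
    segment <- do.call(segmentation_params, as.list(segment))
  }
  pen_defaults <- list(bin_width_um = 0.2, min_depth_um = 0.4, min_records = 20L)
  check_known_keys(penetration, names(pen_defaults), "penetration")
  penetration <- utils::modifyList(pen_defaults, as.list(penetration))
  structure(list(spacing = spacing, preprocess = preprocess,
                 segment = segment, penetration = penetration,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

check_known_keys <- function(x, known, where) {
  extra <- setdiff(names(x), known)
  if (length(extra))
    stop("unknown ", where, " key(s): ", paste(extra, collapse = ", "))
  invisible(x)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with any subset of the [pipeline_config()]
#'   sections; unknown keys are rejected.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  check_known_keys(y, c("spacing", "preprocess", "segment", "penetration",
                        "seed", "out_dir"), "config")
  do.call(pipeline_config, y)
}

#' Write a pipeline configuration to YAML
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  y <- list(
    spacing = list(dx = config$spacing$dx, dy = config$spacing$dy,
                   dz = config$spacing$dz),
    preprocess = unclass(config$preprocess),
    segment = unclass(config$segment),
    penetration = config$penetration,
    seed = config$seed)
  if (!is.null(config$out_dir)) y$out_dir <- config$out_dir
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

load_input <- function(input, config) {
  if (is.character(input)) {
    membrane <- tryCatch(read_stack(input, channel = 1L),
                         error = function(e) read_stack(input, channel = 1L,
                                                        spacing = config$spacing))
    particles <- tryCatch(read_stack(input, channel = 2L),
                          error = function(e) read_stack(input, channel = 2L,
                                                         spacing = config$spacing))
    list(membrane = membrane, particles = particles, id = basename(input))
  } else if (is.list(input) && all(c("membrane", "particles") %in% names(input))) {
    list(membrane = input$membrane, particles = input$particles,
         id = input$id %||% NA_character_)
  } else stop("inputs must be file paths or lists with membrane/particles stacks")
}

#' Analyze one two-channel stack
#'
#' The per-stack stage of [run_pipeline()]: preprocess both channels
#' (optional deconvolution; lateral smoothing of 2 px for particles and
#' 30 px for the membrane; axial thinning of the membrane by 2 px), Otsu
#' thresholds per channel, membrane selection and surface extraction,
#' watershed splitting and filtering of particle objects, and one distance
#' record per surviving particle.
#'
#' @param membrane,particles [voxel_stack()]s of the two channels.
#' @param config A [pipeline_config()].
#' @param stack_id Provenance label for the records.
#' @return List with `records` (data frame), `membrane_ref`, `objects`
#'   (surviving particle objects), `thresholds`, and object counts.
#' @export
analyze_stack <- function(membrane, particles, config = pipeline_config(),
                          stack_id = NA_character_) {
  pp <- config$preprocess
  sg <- config$segment
  if (pp$deconvolve) {
    membrane <- deconvolve_ml(membrane, pp$psf_sigma_um, pp$deconv_iterations)
    particles <- deconvolve_ml(particles, pp$psf_sigma_um, pp$deconv_iterations)
  }
  mem <- smooth_lateral(membrane, pp$membrane_smooth_sigma_px)
  mem <- thin_membrane_axially(mem, pp$membrane_shift_px)
  t_mem <- otsu_threshold(mem)
  mem_objects <- label_objects(mem, t_mem)
  membrane_ref <- filter_membrane(mem_objects, sg)

  par <- smooth_lateral(particles, pp$qd_smooth_sigma_px)
  t_par <- otsu_threshold(par)
  pdat <- stack_data(par)
  mask <- pdat >= t_par
  records <- NULL
  kept <- list()
  if (any(mask)) {
    objects <- watershed_split(par, mask, sg$watershed_sigma_um, sg)
    kept <- filter_particles(objects, t_par, max(pdat), sg)
    if (length(kept)) {
      rows <- lapply(kept, measure_distance, membrane = membrane_ref,
                     stack_id = stack_id)
      records <- do.call(rbind, rows)
    }
  }
  if (is.null(records))
    records <- data.frame(stack_id = character(0), object_id = integer(0),
                          axial_distance_um = numeric(0), volume_voxels = numeric(0),
                          com_z_um = numeric(0), nearest_z_um = numeric(0),
                          nearest_y_um = numeric(0), nearest_x_um = numeric(0),
                          com_y_um = numeric(0), com_x_um = numeric(0),
                          stringsAsFactors = FALSE)
  list(records = records, membrane_ref = membrane_ref, objects = kept,
       thresholds = c(membrane = t_mem, particles = t_par),
       n_membrane_objects = length(mem_objects),
       n_particle_objects = length(kept))
}

#' Run the full penetration-depth pipeline
#'
#' For each input stack: preprocess, segment, extract the apical membrane
#' surface, split and filter particle objects, and measure signed axial
#' distances; then pool distances across stacks, fit the depth Gaussian
#' and classify the population. Deterministic given the configuration. If
#' `config$out_dir` is set, writes `records.csv`, `histogram.csv`,
#' `fit.json`, the resolved `config.yaml` and a parameter log next to the
#' results.
#'
#' @param config A [pipeline_config()].
#' @param inputs Non-empty list of inputs: two-channel TIFF paths
#'   (membrane = channel 1, particles = channel 2) or lists with
#'   `membrane` / `particles` [voxel_stack()]s.
#' @return An object of class `penetration_report`: `fit` (a
#'   [pool_and_fit()] result), `verdict`, `records`, per-stack summaries
#'   and the resolved config.
#' @export
run_pipeline <- function(config, inputs) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(inputs) == 0) stop("no input stacks given")
  if (is.character(inputs)) inputs <- as.list(inputs)
  all_records <- list()
  per_stack <- list()
  for (i in seq_along(inputs)) {
    loaded <- load_input(inputs[[i]], config)
    id <- if (!is.na(loaded$id)) loaded$id else sprintf("stack%03d", i)
    res <- tryCatch(
      analyze_stack(loaded$membrane, loaded$particles, config, stack_id = id),
      error = function(e) stop("stack '", id, "': ", conditionMessage(e), call. = FALSE))
    all_records[[i]] <- res$records
    per_stack[[id]] <- list(thresholds = res$thresholds,
                            n_particles = res$n_particle_objects)
  }
  records <- do.call(rbind, all_records)
  fit <- pool_and_fit(records, bin_width_um = config$penetration$bin_width_um,
                      min_records = config$penetration$min_records)
  verdict <- if (isTRUE(fit$fit_ok))
    classify_penetration(fit, config$penetration$min_depth_um)
  else NA_character_
  report <- structure(list(fit = fit, verdict = verdict, records = records,
                           per_stack = per_stack, config = config),
                      class = "penetration_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_records(report$records, file.path(dir, "records.csv"))
  fit <- report$fit
  utils::write.csv(data.frame(mid_um = fit$mids, count = fit$counts),
                   file.path(dir, "histogram.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(x_c_um = fit$x_c, x_c_se_um = fit$x_c_se,
         sigma_um = fit$sigma_fit, sigma_se_um = fit$sigma_se,
         fit_ok = fit$fit_ok, method = fit$method, normal_p = fit$normal_p,
         n_stacks = fit$n_stacks, n_objects = fit$n_objects,
         verdict = report$verdict),
    file.path(dir, "fit.json"), auto_unbox = TRUE, digits = NA)
  write_pipeline_config(report$config, file.path(dir, "config.yaml"))
  log <- c(sprintf("qdepth run: %d stack(s), %d record(s)",
                   length(report$per_stack), nrow(report$records)),
           vapply(names(report$per_stack), function(id) {
             ps <- report$per_stack[[id]]
             sprintf("  %s: t_mem=%.6g t_par=%.6g particles=%d",
                     id, ps$thresholds["membrane"], ps$thresholds["particles"],
                     ps$n_particles)
           }, ""))
  writeLines(log, file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.penetration_report <- function(x, ...) {
  cat(sprintf("penetration_report: %d stack(s), %d particle record(s)\n",
              length(x$per_stack), nrow(x$records)))
  print(x$fit)
  cat(sprintf("  verdict: %s\n", x$verdict))
  invisible(x)
}

#' Write the canonical fixture scenes
#'
#' Renders the four canonical test scenes — flat or rough (0.5 um
#' undulation) membrane crossed with surface-associated (0 um) or deeply
#' penetrated (-1.3 um) particles — and writes each as a multi-channel
#' TIFF with its ground truth. The same seed always produces
#' byte-identical files.
#'
#' @param seed Integer seed.
#' @param out Output directory.
#' @param shape Stack shape for the fixtures.
#' @param n_spots Spots per scene.
#' @return Named character vector of the four stack paths.
#' @export
make_fixture_suite <- function(seed, out, shape = c(48L, 96L, 96L),
                               n_spots = 6L) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  sp <- voxel_spacing()
  cases <- expand.grid(surface = c("flat", "rough"),
                       depth = c("surface", "deep"),
                       stringsAsFactors = FALSE)
  paths <- character(0)
  for (i in seq_len(nrow(cases))) {
    offset <- if (cases$depth[i] == "deep") -1.3 else 0.0
    rough <- if (cases$surface[i] == "rough") 0.5 else 0.0
    name <- paste0(cases$surface[i], "_", cases$depth[i])
    spec <- scene_spec(
      shape = shape, spacing = sp,
      membrane_depth_um = 3, membrane_roughness_um = rough,
      spots = spot_grid(n_spots, offset, shape, sp),
      seed = seed + i, geometry_seed = seed)
    paths[name] <- write_scene(render_scene(spec), out, name)
  }
  paths
}
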