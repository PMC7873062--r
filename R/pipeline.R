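# End-to-end orchestration: phantom generation, preprocessing, fitting,
# scalar maps, tracking and ROI report, driven by a single config whose
# defaults mirror every module-level default. One global seed is fanned out
# per stage by a stable derivation so each stage is individually
# reproducible.

#' Default pipeline configuration
#'
#' @param ... Overrides of any default (e.g. `sigma = 0`,
#'   `small = TRUE`, `fa_threshold = 0.2`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # phantom
    small = TRUE, sigma = 0.05, s0 = 1000, gibbs_keep = 1,
    misalign_mm = 0, misalign_deg = 0,
    # acquisition
    delta = 3.1e-3, Delta = 8.502e-3, gamma = GAMMA_1H,
    b0_threshold = 50, shell_tolerance = 50,
    # preprocessing
    denoise = TRUE, unring = TRUE, eddy = TRUE,
    patch_radius = 1, search_radius = 3, h_factor = 1,
    # fitting / maps
    n_dir = 724, k_max = K_APP_MAX_DEFAULT,
    # tracking
    fa_threshold = 0.15, angle_threshold_deg = 45, step_mm = 0.05,
    min_length_mm = 0.31, max_length_mm = 50, n_tracts_target = 5000,
    interpolation = "cubic", max_seed_factor = 100,
    # provenance
    seed = 42L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    abort(paste("unknown config keys:", paste(unknown, collapse = ", ")),
          class = "microdki_config")
  }
  structure(modifyList(cfg, over), class = "pipeline_config")
}

#' Serialize / restore a pipeline config (round-trips losslessly)
#' @param config A `pipeline_config`.
#' @param path File path (plain `key: value` YAML subset).
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   `pipeline_config`.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    vs <- if (is.character(v)) v else format(v, digits = 17, scientific = NA)
    sprintf("%s: %s", k, vs)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, ":\\s*")
  cfg <- pipeline_config()
  over <- list()
  for (p in kv) {
    k <- p[1]; v <- paste(p[-1], collapse = ":")
    proto <- cfg[[k]]
    over[[k]] <- if (is.character(proto)) v
                 else if (is.logical(proto)) as.logical(v)
                 else if (is.integer(proto)) as.integer(round(as.numeric(v)))
                 else as.numeric(v)
  }
  do.call(pipeline_config, over)
}

config_hash <- function(config) {
  rlang::hash(config[order(names(config))])
}

#' Run the full pipeline on a phantom
#'
#' Generates the configured phantom, runs the preprocessing chain (denoise,
#' unring, eddy — stages individually disableable), fits the kurtosis
#' tensor, derives the six scalar maps, tracks streamlines and extracts the
#' ROI-median report. With `out_dir` set, all artefacts are written to disk
#' together with a provenance log (config hash, per-stage seeds, clamp and
#' mask counts).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return A list: `phantom`, `preprocessed`, `fit`, `maps`, `tract`,
#'   `report`, `config`, `log` (character vector).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  logln <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    message(msg)
    logln <<- c(logln, msg)
  }
  say("config hash: %s (seed %d)", config_hash(config), config$seed)

  spec <- phantom_spec(small = config$small, s0 = config$s0,
                       sigma = config$sigma, gibbs_keep = config$gibbs_keep,
                       misalign_mm = config$misalign_mm,
                       misalign_deg = config$misalign_deg,
                       seed = derive_seed(config$seed, "phantom"))
  scheme <- locust_scheme(delta = config$delta, Delta = config$Delta,
                          gamma = config$gamma)
  phantom <- make_phantom(spec, scheme)
  say("phantom: %s grid, %d volumes",
      paste(spec$grid_shape, collapse = "x"), dim(phantom$dwi)[4])

  pp <- preprocess_dwi(phantom$dwi, scheme, denoise = config$denoise,
                       unring = config$unring, eddy = config$eddy,
                       sigma = if (config$sigma > 0) NULL else 0,
                       patch_radius = config$patch_radius,
                       search_radius = config$search_radius,
                       h_factor = config$h_factor)
  say("preprocess: denoise=%s unring=%s eddy=%s sigma=%.4g",
      config$denoise, config$unring, config$eddy, pp$sigma %||% 0)

  fit <- fit_dki_volume(pp$dwi, pp$scheme)
  g <- glance(fit)
  say("fit: %d/%d voxels (%d masked, %d negative-eigenvalue)",
      g$n_fitted, g$n_voxels, g$n_masked, g$n_negative_eigenvalues)

  maps <- compute_scalar_maps(fit, n_dir = config$n_dir)
  say("maps: %d eigenvalue clamps", maps$clamp_count)

  params <- tracking_params(fa_threshold = config$fa_threshold,
                            angle_threshold_deg = config$angle_threshold_deg,
                            step_mm = config$step_mm,
                            min_length_mm = config$min_length_mm,
                            max_length_mm = config$max_length_mm,
                            n_tracts_target = config$n_tracts_target,
                            interpolation = config$interpolation,
                            seed = derive_seed(config$seed, "track"),
                            max_seed_factor = config$max_seed_factor)
  tract <- track(maps, params, voxel_mm = spec$voxel_mm)
  say("track: %d streamlines kept", length(tract$streamlines))

  report <- extract_medians(maps, phantom$truth$roi_masks,
                            sample_id = "phantom")
  say("report: %d cells", nrow(report))

  out <- list(phantom = phantom, preprocessed = pp, fit = fit, maps = maps,
              tract = tract, report = report, config = config, log = logln)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_phantom(phantom, file.path(out_dir, "phantom"))
    write_scalar_maps(maps, file.path(out_dir, "maps"),
                      voxel_mm = spec$voxel_mm)
    write_trk(tract, file.path(out_dir, "tracts.trk"))
    writeLines(render_report(report, "tsv"),
               file.path(out_dir, "roi_report.tsv"))
    writeLines(render_report(report, "markdown"),
               file.path(out_dir, "roi_report.md"))
    if (!is.null(pp$transforms)) {
      write_transforms(pp$transforms, file.path(out_dir, "eddy_transforms.txt"))
    }
    write_config(config, file.path(out_dir, "config.txt"))
    writeLines(c(sprintf("config_hash: %s", config_hash(config)), logln),
               file.path(out_dir, "run_log.txt"))
    say("artifacts written to %s", out_dir)
  }
  invisible(out)
}
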