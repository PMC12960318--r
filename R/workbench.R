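#' Default run configuration
#'
#' Assembles the configuration used by the pipeline entry points:
#' channel geometry, laser plane, motion model, frame rate, noise
#' levels and seed. Any element can be overridden; the resolved
#' configuration is written next to every pipeline output so runs are
#' reproducible from their own artifacts.
#'
#' @param ... named overrides of the default elements.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  fx <- fixture_centrimag_motion()
  cfg <- list(model = fx$model, geom = fx$geom, plane = fx$plane,
              fps = fx$fps, n_frames = 255,
              noise_marker_mm = 0, seed = 20250)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

# Serializable summary of a config (for the resolved-config copy).
config_as_list <- function(cfg) {
  list(model = unclass(cfg$model), fps = cfg$fps, n_frames = cfg$n_frames,
       noise_marker_mm = cfg$noise_marker_mm, seed = cfg$seed,
       plane = unclass(cfg$plane),
       geom = as.list(as.data.frame(unclass(cfg$geom))))
}

#' Simulate a synthetic fixture bundle
#'
#' Generates the ground-truth trajectory and the labeled marker track
#' from the configured motion model; optionally writes them (plus a
#' resolved-config copy) to a directory.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory; created if missing.
#' @return list: `poses` (ground-truth pose list), `tracks` (marker
#'   observation data.frame), `config`.
#' @export
rig_simulate <- function(config = run_config(), out_dir = NULL) {
  bundle <- synth_marker_tracks(config$model, config$geom, config$plane,
                                config$n_frames, config$fps,
                                noise_marker_mm = config$noise_marker_mm,
                                seed = config$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pose_csv(pose_table(bundle$poses),
                   file.path(out_dir, "poses_truth.csv"))
    utils::write.csv(bundle$tracks, file.path(out_dir, "marker_tracks.csv"),
                     row.names = FALSE)
    yaml::write_yaml(config_as_list(config),
                     file.path(out_dir, "config_resolved.yaml"))
  }
  c(bundle, list(config = config))
}

#' Reconstruct and decompose a marker track
#'
#' Chains the per-frame pose solver and the three-mode motion fit:
#' the end-to-end inverse of [rig_simulate()].
#'
#' @param tracks marker observation data.frame (labeled or not), or a
#'   path to a marker-track CSV.
#' @param config a [run_config()].
#' @param out_dir optional output directory for the pose CSV, per-frame
#'   diagnostics and motion summary YAML.
#' @return list: `fit` (a [rotor_motion()] object), `pose_table`,
#'   `diagnostics`.
#' @export
rig_reconstruct <- function(tracks, config = run_config(), out_dir = NULL) {
  if (is.character(tracks)) tracks <- utils::read.csv(tracks)
  dalpha <- 360 * config$model$rpm / (60 * config$fps)
  rec <- reconstruct_track(tracks, config$geom, config$plane,
                           dalpha_hint_deg = dalpha)
  fit <- rotor_motion(rec$table, geom = config$geom, rpm = config$model$rpm)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pose_csv(rec$table, file.path(out_dir, "poses_reconstructed.csv"))
    utils::write.csv(rec$diagnostics, file.path(out_dir, "diagnostics.csv"),
                     row.names = FALSE)
    yaml::write_yaml(lapply(fit$summary, function(x)
      if (length(x) > 1) as.list(x) else x),
      file.path(out_dir, "motion_summary.yaml"))
    yaml::write_yaml(config_as_list(config),
                     file.path(out_dir, "config_resolved.yaml"))
  }
  list(fit = fit, pose_table = rec$table, diagnostics = rec$diagnostics)
}

#' Compare two phase-averaged fields
#'
#' Computes the normalized relative-error map, its RMS (percent), the
#' error PDF and -- when pressure is available -- the inlet-referenced
#' pressure error statistics.
#'
#' @param field,reference `phase_avg_field` objects on congruent grids.
#' @param inlet_p,inlet_p_ref inlet reference pressures in Pa (only
#'   needed for the pressure comparison).
#' @param out_dir optional directory for a YAML report.
#' @return list: `E_rel` (matrix), `rms_pct`, `pdf` (data.frame),
#'   `pressure` (list or `NULL`).
#' @export
rig_compare <- function(field, reference, inlet_p = NULL,
                        inlet_p_ref = NULL, out_dir = NULL) {
  E <- relative_error(field, reference)
  rms <- rms_error(E)
  pdf <- if (sum(is.finite(E)) >= 100) error_pdf(E) else NULL
  pressure <- NULL
  if (!is.null(field$p) && !is.null(reference$p) &&
      !is.null(inlet_p) && !is.null(inlet_p_ref)) {
    pressure <- abs_pressure_error(field$p, reference$p, inlet_p, inlet_p_ref)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(list(
      rms_pct = rms,
      n_valid = sum(is.finite(E)),
      denominator = attr(E, "denominator"),
      pressure_mean_mmHg = if (!is.null(pressure)) pressure$mean_mmHg,
      pressure_rms_mmHg = if (!is.null(pressure)) pressure$rms_mmHg),
      file.path(out_dir, "comparison_report.yaml"))
  }
  list(E_rel = E, rms_pct = rms, pdf = pdf, pressure = pressure)
}
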