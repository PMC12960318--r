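#' Locate the motion center along the rotor axis
#'
#' The reconstructed per-frame center OR lives on the blade-root
#' reference plane and wanders when the axis tilts and precesses. The
#' motion center is found by sliding a probe point along the
#' instantaneous axis, `C(s, t) = OR(t) + s * z(t)`, and picking the
#' projection distance `s` that minimizes the summed X/Y variance of
#' the probe cloud (golden-section search, 1 um tolerance).
#'
#' @param pose_df pose table (>= 10 rows) as from [reconstruct_track()].
#' @param s_range search interval for `s`, mm.
#' @return list: `s_mm`, `center_mean` (X/Y, mm), `center_sd` (X/Y,
#'   mm), `flat` (`TRUE` when the objective is flat -- ideal rotation --
#'   in which case `s = 0` is returned by convention).
#' @export
find_motion_center <- function(pose_df, s_range = c(-20, 20)) {
  stopifnot(nrow(pose_df) >= 10)
  ax <- t(vapply(seq_len(nrow(pose_df)), function(i)
    axis_from_angles(pose_df$phi_deg[i], pose_df$theta_deg[i]), numeric(3)))
  OR <- cbind(pose_df$X_mm, pose_df$Y_mm)
  objective <- function(s) {
    x <- OR[, 1] + s * ax[, 1]
    y <- OR[, 2] + s * ax[, 2]
    stats::var(x) + stats::var(y)
  }
  probe <- vapply(seq(s_range[1], s_range[2], length.out = 21),
                  objective, numeric(1))
  flat <- diff(range(probe)) < 1e-18
  s_star <- if (flat) 0 else
    stats::optimize(objective, s_range, tol = 1e-3)$minimum
  x <- OR[, 1] + s_star * ax[, 1]
  y <- OR[, 2] + s_star * ax[, 2]
  list(s_mm = s_star,
       center_mean = c(X = mean(x), Y = mean(y)),
       center_sd = c(X = stats::sd(x), Y = stats::sd(y)),
       flat = flat)
}

#' Mean rotor axis of a pose track
#'
#' Normalized arithmetic mean of the unit axis vectors, reported as
#' spherical angles.
#'
#' @param pose_df pose table (>= 2 rows).
#' @return list: `axis` (unit 3-vector), `theta_deg`, `phi_deg`.
#' @export
mean_axis <- function(pose_df) {
  stopifnot(nrow(pose_df) >= 2)
  ax <- t(vapply(seq_len(nrow(pose_df)), function(i)
    axis_from_angles(pose_df$phi_deg[i], pose_df$theta_deg[i]), numeric(3)))
  m <- colMeans(ax)
  if (sqrt(sum(m^2)) < 0.5)
    stop("mean axis ill-defined: axis directions nearly cancel")
  m <- m / sqrt(sum(m^2))
  ang <- angles_from_axis(m)
  list(axis = m, theta_deg = ang$theta_deg, phi_deg = ang$phi_deg)
}

#' Deviating azimuth of an instantaneous axis
#'
#' Azimuth of the axis after removing the mean tilt: the axis is
#' rotated by the inverse mean-tilt rotation (which carries the mean
#' axis onto global Z) and its azimuth is read off. Near-vertical
#' de-tilted axes (within ~1e-6 degrees of Z) have no defined azimuth
#' and return `NA`.
#'
#' @param axis unit 3-vector (or matrix of row vectors).
#' @param mean_spec result of [mean_axis()] (or list with `phi_deg`,
#'   `theta_deg`).
#' @return deviating azimuth(s) in degrees, `NA` where undefined.
#' @export
deviating_azimuth <- function(axis, mean_spec) {
  R <- rotation_matrix(tilt_axis(mean_spec$phi_deg), -mean_spec$theta_deg)
  one <- function(v) {
    d <- as.numeric(R %*% v)
    if (angle_between(d, c(0, 0, 1)) < 1e-6) return(NA_real_)
    wrap_angle(rad2deg(atan2(d[2], d[1])))
  }
  if (is.matrix(axis)) apply(axis, 1, one) else one(axis)
}

#' Fit the synchronous-precession mode
#'
#' The precession inclination is the mean angle between the
#' instantaneous and mean axes; the phase offset is the circular mean
#' of (deviating azimuth - blade angle). A linear regression of the
#' unwrapped deviating azimuth on the blade angle is reported as a
#' synchrony diagnostic (the motion model itself fixes the slope at 1).
#' Samples where the instantaneous tilt from the mean axis is below
#' 0.05 degrees are down-weighted, since a near-aligned axis makes the
#' azimuth ill-conditioned.
#'
#' @param pose_df pose table covering >= 1 revolution (unwrapped
#'   `alpha_deg` preferred).
#' @param mean_spec result of [mean_axis()]; computed if missing.
#' @return list: `theta_prec_deg`, `phi_prec_deg`, `sync_slope`,
#'   `low_confidence` (TRUE when angular coverage < 180 degrees).
#' @export
fit_precession <- function(pose_df, mean_spec = NULL) {
  if (is.null(mean_spec)) mean_spec <- mean_axis(pose_df)
  ax <- t(vapply(seq_len(nrow(pose_df)), function(i)
    axis_from_angles(pose_df$phi_deg[i], pose_df$theta_deg[i]), numeric(3)))
  incl <- apply(ax, 1, angle_between, b = mean_spec$axis)
  phi_dev <- deviating_azimuth(ax, mean_spec)
  alpha <- pose_df$alpha_deg
  coverage <- diff(range(alpha))
  w <- ifelse(incl < 0.05, incl / 0.05, 1)
  if (sum(w) == 0) w <- rep(1, length(incl))  # no precession at all
  ok <- !is.na(phi_dev)
  offset <- circular_mean(phi_dev[ok] - alpha[ok], w = w[ok])
  theta_prec <- sum(w * incl) / sum(w)
  # synchrony diagnostic: slope of unwrapped phi_dev against alpha
  sync_slope <- NA_real_
  if (sum(ok) > 3 && theta_prec > 1e-6) {
    y <- phi_dev[ok]; x <- alpha[ok]
    y <- y[1] + unwrap_deg(y - y[1])
    if (x[1] != 0 || min(x) < 0) x <- x - x[1]
    sync_slope <- unname(stats::coef(stats::lm(y ~ x, weights = w[ok]))[2])
  }
  list(theta_prec_deg = theta_prec,
       phi_prec_deg = offset,
       sync_slope = sync_slope,
       low_confidence = coverage < 180)
}

# Unwrap a sequence of angle increments (degrees).
unwrap_deg <- function(x) {
  d <- c(0, diff(x))
  d <- ((d + 180) %% 360) - 180
  cumsum(d)
}

#' Predict blade reference-point heights from a motion model
#'
#' Applies the three-step motion transform to each blade's reference
#' point (the inner-channel intercept with the reference plane) and
#' reports its global Z as a function of the blade angle. For tilt-only
#' motion the curve is a sinusoid with amplitude `r_n sin(theta_mean)`,
#' `r_n` the base-point radius.
#'
#' @param model a [motion_model()].
#' @param geom a [channel_geometry()].
#' @param alpha_deg vector of blade angles, degrees.
#' @return data.frame: `alpha_deg, blade, Z_mm`.
#' @export
predict_blade_z <- function(model, geom, alpha_deg) {
  inner <- geom[geom$channel == "in", ]
  rows <- list()
  for (k in seq_along(alpha_deg)) {
    a <- alpha_deg[k]
    ax <- model_axis(model, a)
    ang <- angles_from_axis(ax)
    pose <- rotor_pose(center = c(model$shift_mm, model$rotor_plane_Z_mm),
                       phi_deg = ang$phi_deg, theta_deg = ang$theta_deg,
                       alpha_deg = a)
    for (i in seq_len(nrow(inner))) {
      P <- local_to_global(pose, c(inner$x0[i], inner$y0[i], 0))
      rows[[length(rows) + 1]] <- data.frame(alpha_deg = a,
                                             blade = inner$blade[i],
                                             Z_mm = P[3])
    }
  }
  do.call(rbind, rows)
}

# The rotor_motion model object -----------------------------------------

#' Fit the three-mode motion model to a pose track
#'
#' The package's central estimator: decomposes a reconstructed pose
#' time series into the three non-ideal rotation modes of a levitated
#' impeller -- center shift, mean-axis tilt, and synchronous precession
#' -- and returns them as a fitted model object with the usual `coef`,
#' `predict`, `plot`, `simulate` and `residuals` methods.
#'
#' @param pose_df pose table (data.frame with columns `X_mm, Y_mm,
#'   Z_mm, phi_deg, theta_deg, alpha_deg`; `alpha_deg` ideally
#'   unwrapped), e.g. the output of [reconstruct_track()].
#' @param geom the [channel_geometry()] used in the reconstruction
#'   (needed by the blade-height prediction; optional).
#' @param rpm rotation rate of the track, rpm (metadata; optional).
#' @return object of class `rotor_motion` with elements `summary`
#'   (the motion parameters), `mean_axis`, `motion_center`,
#'   `precession`, `pose_df`, `geom`.
#' @examples
#' fx <- fixture_centrimag_motion()
#' poses <- synth_trajectory(fx$model, 64, fx$fps)
#' fit <- rotor_motion(pose_table(poses), geom = fx$geom, rpm = fx$model$rpm)
#' coef(fit)
#' @export
rotor_motion <- function(pose_df, geom = NULL, rpm = NA_real_) {
  mc <- find_motion_center(pose_df)
  ma <- mean_axis(pose_df)
  pr <- fit_precession(pose_df, ma)
  rz <- stats::median(pose_df$Z_mm)
  pred_range <- NA_real_
  if (!is.null(geom)) {
    r1 <- sqrt(sum(geom[geom$blade == 1 & geom$channel == "in",
                        c("x0", "y0")]^2))
    pred_range <- 2 * r1 * sin(deg2rad(ma$theta_deg))
  }
  summary <- list(
    center_X_mm = unname(mc$center_mean["X"]),
    center_Y_mm = unname(mc$center_mean["Y"]),
    center_sd_mm = unname(mc$center_sd),
    s_star_mm = mc$s_mm,
    theta_mean_deg = ma$theta_deg,
    phi_mean_deg = ma$phi_deg,
    theta_prec_deg = pr$theta_prec_deg,
    phi_prec_deg = pr$phi_prec_deg,
    sync_slope = pr$sync_slope,
    blade_z_range_mm = pred_range,
    rotor_plane_Z_mm = rz,
    rpm = rpm)
  structure(list(summary = summary, mean_axis = ma, motion_center = mc,
                 precession = pr, pose_df = pose_df, geom = geom),
            class = "rotor_motion")
}

#' @export
coef.rotor_motion <- function(object, ...) {
  s <- object$summary
  c(center_X_mm = s$center_X_mm, center_Y_mm = s$center_Y_mm,
    theta_mean_deg = s$theta_mean_deg, phi_mean_deg = s$phi_mean_deg,
    theta_prec_deg = s$theta_prec_deg, phi_prec_deg = s$phi_prec_deg)
}

#' @export
print.rotor_motion <- function(x, ...) {
  s <- x$summary
  cat("Three-mode impeller motion fit\n")
  cat(sprintf("  1) center shift : (%+.3f, %+.3f) mm  [sd %.3f / %.3f mm, s* = %+.2f mm]\n",
              s$center_X_mm, s$center_Y_mm, s$center_sd_mm[1],
              s$center_sd_mm[2], s$s_star_mm))
  cat(sprintf("  2) mean tilt    : theta = %.3f deg at azimuth %.1f deg\n",
              s$theta_mean_deg, s$phi_mean_deg))
  cat(sprintf("  3) precession   : theta = %.3f deg at offset %.1f deg from blade 1 (sync slope %s)\n",
              s$theta_prec_deg,
              ifelse(is.na(s$phi_prec_deg), NaN, s$phi_prec_deg),
              ifelse(is.na(s$sync_slope), "n/a", sprintf("%.3f", s$sync_slope))))
  invisible(x)
}

#' @export
summary.rotor_motion <- function(object, ...) {
  print(object)
  cat(sprintf("  poses: %d, blade-Z peak-to-peak from mean tilt: %s mm\n",
              nrow(object$pose_df),
              ifelse(is.na(object$summary$blade_z_range_mm), "n/a",
                     sprintf("%.4f", object$summary$blade_z_range_mm))))
  invisible(object$summary)
}

#' Rebuild the motion model from a fit
#'
#' @param object a `rotor_motion` fit.
#' @return a [motion_model()] with the fitted parameters.
#' @export
as_motion_model <- function(object) {
  s <- object$summary
  motion_model(shift_mm = c(s$center_X_mm, s$center_Y_mm),
               rotor_plane_Z_mm = s$rotor_plane_Z_mm,
               theta_mean_deg = s$theta_mean_deg,
               phi_mean_deg = s$phi_mean_deg,
               theta_prec_deg = ifelse(is.na(s$theta_prec_deg), 0,
                                       s$theta_prec_deg),
               phi_prec_deg = ifelse(is.na(s$phi_prec_deg), 0,
                                     s$phi_prec_deg),
               rpm = ifelse(is.na(s$rpm), 2350, s$rpm))
}

#' @export
#' @param object a `rotor_motion` fit.
#' @param newdata optional vector of blade angles (degrees) at which to
#'   predict blade reference-point heights; defaults to a 1-degree grid.
#' @rdname rotor_motion
predict.rotor_motion <- function(object, newdata = NULL, ...) {
  if (is.null(object$geom))
    stop("prediction needs the channel geometry used in the fit")
  alpha <- if (is.null(newdata)) seq(0, 359, by = 1) else newdata
  predict_blade_z(as_motion_model(object), object$geom, alpha)
}

#' @export
simulate.rotor_motion <- function(object, nsim = 1, seed = NULL, ...,
                                  n_frames = 255, fps = 10000) {
  if (!is.null(seed)) set.seed(seed)
  model <- as_motion_model(object)
  lapply(seq_len(nsim), function(i)
    pose_table(synth_trajectory(model, n_frames, fps)))
}

#' @export
residuals.rotor_motion <- function(object, ...) {
  # residual axis direction after removing mean tilt + synchronous
  # precession: angle between measured and modeled instantaneous axis
  model <- as_motion_model(object)
  df <- object$pose_df
  vapply(seq_len(nrow(df)), function(i) {
    meas <- axis_from_angles(df$phi_deg[i], df$theta_deg[i])
    mod <- model_axis(model, df$alpha_deg[i])
    angle_between(meas, mod)
  }, numeric(1))
}

#' @export
plot.rotor_motion <- function(x, which = 1:4, ...) {
  df <- x$pose_df
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  if (1 %in% which) {
    graphics::plot(df$X_mm, df$Y_mm, pch = 16, cex = 0.4, asp = 1,
                   xlab = "X [mm]", ylab = "Y [mm]",
                   main = "center OR positions")
    graphics::points(x$summary$center_X_mm, x$summary$center_Y_mm,
                     col = 2, pch = 3, cex = 2)
  }
  if (2 %in% which) {
    ax <- t(vapply(seq_len(nrow(df)), function(i)
      axis_from_angles(df$phi_deg[i], df$theta_deg[i]), numeric(3)))
    graphics::plot(ax[, 1], ax[, 2], pch = 16, cex = 0.4, asp = 1,
                   xlab = "axis X", ylab = "axis Y",
                   main = "axis directions (top view)")
    m <- x$mean_axis$axis
    graphics::points(m[1], m[2], col = 2, pch = 3, cex = 2)
  }
  if (3 %in% which) {
    phi_dev <- deviating_azimuth(t(vapply(seq_len(nrow(df)), function(i)
      axis_from_angles(df$phi_deg[i], df$theta_deg[i]), numeric(3))),
      x$mean_axis)
    graphics::plot(wrap_angle(df$alpha_deg), phi_dev, pch = 16, cex = 0.4,
                   xlab = "blade angle [deg]",
                   ylab = "deviating azimuth [deg]",
                   main = "precession synchrony")
    graphics::abline(0, 1, col = 2, lty = 2)
  }
  if (4 %in% which && !is.null(x$geom)) {
    pred <- predict(x)
    graphics::plot(pred$alpha_deg, pred$Z_mm, col = pred$blade, pch = 16,
                   cex = 0.3, xlab = "blade angle [deg]",
                   ylab = "blade reference Z [mm]",
                   main = "modeled blade heights")
  }
  invisible(x)
}
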