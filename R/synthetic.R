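#' Three-mode motion model of a levitated impeller
#'
#' The measured deviation of a MagLev impeller from an ideal rotation is
#' described by transforming the ideal rotation in three steps:
#' (1) a static shift of the motion center in the X/Y plane,
#' (2) a constant tilt of the mean rotation axis (polar angle
#' `theta_mean` at azimuth `phi_mean`), and
#' (3) a synchronous precession: the instantaneous axis is inclined by
#' `theta_prec` relative to the mean axis, at an azimuth that rotates
#' with the impeller itself, offset by `phi_prec` from the first main
#' blade.
#'
#' @param shift_mm numeric length-2, center shift `(dX, dY)` in mm.
#' @param rotor_plane_Z_mm global Z of the blade-root reference plane, mm.
#' @param theta_mean_deg,phi_mean_deg mean-axis tilt: polar angle and
#'   azimuth in degrees.
#' @param theta_prec_deg precession inclination relative to the mean
#'   axis, degrees.
#' @param phi_prec_deg azimuth of the precession tilt relative to the
#'   first main blade, degrees.
#' @param rpm rotation rate, revolutions per minute.
#' @return list of class `motion_model`.
#' @export
motion_model <- function(shift_mm = c(0, 0), rotor_plane_Z_mm = -5.15,
                         theta_mean_deg = 0, phi_mean_deg = 0,
                         theta_prec_deg = 0, phi_prec_deg = 0,
                         rpm = 2350) {
  stopifnot(rpm > 0, theta_mean_deg >= 0, theta_mean_deg <= 5,
            theta_prec_deg >= 0, theta_prec_deg <= 5)
  structure(list(shift_mm = shift_mm, rotor_plane_Z_mm = rotor_plane_Z_mm,
                 theta_mean_deg = theta_mean_deg, phi_mean_deg = phi_mean_deg,
                 theta_prec_deg = theta_prec_deg, phi_prec_deg = phi_prec_deg,
                 rpm = rpm),
            class = "motion_model")
}

#' Reference synthetic study conditions
#'
#' The default test rig: the motion-mode magnitudes, rotor plane height,
#' rotation rate, laser-sheet placement and frame rate of the reference
#' measurement campaign on the CentriMag-type pump, combined with the
#' package's synthetic channel geometry (the true channel parameters of
#' the physical impeller are proprietary CAD data; the geometry here is
#' synthetic and merely shares the structure).
#'
#' @return list with elements `model` ([motion_model()]), `geom`
#'   ([channel_geometry()]), `plane` ([laser_plane()]) and `fps`.
#' @export
fixture_centrimag_motion <- function() {
  list(model = motion_model(shift_mm = c(-0.13, 0.04),
                            rotor_plane_Z_mm = -5.15,
                            theta_mean_deg = 0.65, phi_mean_deg = 273,
                            theta_prec_deg = 0.45, phi_prec_deg = 275,
                            rpm = 2350),
       geom = channel_geometry(),
       plane = laser_plane(Z_mm = -2.25, thickness_mm = 0.5),
       fps = 10000)
}

# Instantaneous axis of the three-mode model at blade angle alpha:
# tilt the precession axis (azimuth alpha + phi_prec, polar theta_prec)
# by the mean tilt. De-tilting with R_psi_mean(-theta_mean) recovers a
# deviating azimuth of exactly alpha + phi_prec.
model_axis <- function(model, alpha_deg) {
  base <- axis_from_angles(alpha_deg + model$phi_prec_deg,
                           model$theta_prec_deg)
  R <- rotation_matrix(tilt_axis(model$phi_mean_deg), model$theta_mean_deg)
  as.numeric(R %*% base)
}

#' Generate a synthetic pose trajectory
#'
#' Samples the three-mode motion model at the camera frame rate. The
#' blade angle advances by `360 * rpm / (60 * fps)` degrees per frame;
#' the axis follows the mean tilt plus synchronous precession; the
#' center stays at the configured shift apart from optional Gaussian
#' noise.
#'
#' @param model a [motion_model()].
#' @param n_frames number of frames (>= 1).
#' @param fps frame rate in Hz.
#' @param noise_center_mm s.d. of i.i.d. Gaussian noise added to the
#'   center X/Y, mm (0 = noiseless).
#' @param seed RNG seed used when noise is requested.
#' @return list of [rotor_pose()] objects, plus attribute `alpha_deg`
#'   with the unwrapped (non-modular) blade angle per frame.
#' @export
synth_trajectory <- function(model, n_frames, fps,
                             noise_center_mm = 0, seed = 20250) {
  stopifnot(n_frames >= 1, fps > 0)
  dalpha <- 360 * model$rpm / (60 * fps)
  alpha <- (seq_len(n_frames) - 1) * dalpha
  noise <- matrix(0, n_frames, 2)
  if (noise_center_mm > 0) {
    rng <- local_rng(seed)
    noise <- matrix(rng$rnorm(2 * n_frames, sd = noise_center_mm),
                    n_frames, 2)
  }
  poses <- lapply(seq_len(n_frames), function(k) {
    ax <- model_axis(model, alpha[k])
    ang <- angles_from_axis(ax)
    rotor_pose(center = c(model$shift_mm[1] + noise[k, 1],
                          model$shift_mm[2] + noise[k, 2],
                          model$rotor_plane_Z_mm),
               phi_deg = ang$phi_deg, theta_deg = ang$theta_deg,
               alpha_deg = alpha[k],
               frame = k, time_s = (k - 1) / fps)
  })
  attr(poses, "alpha_deg") <- alpha
  poses
}

# Self-contained RNG so generator seeds never disturb the caller's
# random stream.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  draw <- function(fn) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    out
  }
  list(rnorm = draw(stats::rnorm), runif = draw(stats::runif))
}

#' Project the marker channels onto the laser sheet
#'
#' Computes, for one pose, the exact intersection of every channel
#' centerline (a straight line in rotor-local coordinates, mapped to the
#' global frame by the pose transform) with the laser plane `Z = Z_L`.
#' No small-tilt approximation is made here: this is the forward truth
#' that the approximate inverse solver is tested against.
#'
#' @param pose a [rotor_pose()].
#' @param geom a [channel_geometry()].
#' @param plane a [laser_plane()].
#' @param noise_mm optional Gaussian noise s.d. added to the in-plane
#'   marker coordinates, mm (default 0 = exact).
#' @param rng optional RNG (from `local_rng`) used when `noise_mm > 0`.
#' @return data.frame with one row per visible marker: `frame, blade,
#'   channel, X_mm, Y_mm, Z_mm, z_local_mm`. Channels whose intersection
#'   falls outside the physical height range are dropped with a warning.
#' @export
project_channels <- function(pose, geom, plane, noise_mm = 0, rng = NULL) {
  M <- pose_rotation(pose)
  hr <- attr(geom, "height_range")
  out <- vector("list", nrow(geom))
  for (i in seq_len(nrow(geom))) {
    g <- geom[i, ]
    # Z-component of the transformed line is affine in z:
    num <- plane$Z_mm - pose$center[3] - (M[3, 1] * g$x0 + M[3, 2] * g$y0)
    den <- M[3, 1] * g$a + M[3, 2] * g$b + M[3, 3]
    if (abs(den) < 1e-9)
      stop(sprintf("channel %s of blade %d is parallel to the laser plane",
                   g$channel, g$blade))
    z <- num / den
    if (z < hr[1] || z > hr[2]) {
      warning(sprintf(
        "blade %d %s channel: laser-plane intersection at z = %.2f mm is outside the bore (dropped)",
        g$blade, g$channel, z))
      next
    }
    P <- local_to_global(pose, c(g$x0 + g$a * z, g$y0 + g$b * z, z))
    out[[i]] <- data.frame(frame = pose$frame, blade = g$blade,
                           channel = g$channel,
                           X_mm = P[1], Y_mm = P[2], Z_mm = P[3],
                           z_local_mm = z)
  }
  obs <- do.call(rbind, out)
  if (!is.null(obs) && noise_mm > 0) {
    if (is.null(rng)) rng <- local_rng(20250)
    obs$X_mm <- obs$X_mm + rng$rnorm(nrow(obs), sd = noise_mm)
    obs$Y_mm <- obs$Y_mm + rng$rnorm(nrow(obs), sd = noise_mm)
  }
  obs
}

#' Generate a labeled synthetic marker track
#'
#' Convenience wrapper: trajectory plus per-frame channel projection.
#'
#' @inheritParams synth_trajectory
#' @param geom a [channel_geometry()].
#' @param plane a [laser_plane()].
#' @param noise_marker_mm Gaussian noise s.d. on marker positions, mm.
#' @return list with `poses` (ground truth) and `tracks` (data.frame of
#'   marker observations across frames).
#' @export
synth_marker_tracks <- function(model, geom, plane, n_frames, fps,
                                noise_marker_mm = 0, seed = 20250) {
  poses <- synth_trajectory(model, n_frames, fps)
  rng <- if (noise_marker_mm > 0) local_rng(seed) else NULL
  tracks <- do.call(rbind, lapply(poses, project_channels,
                                  geom = geom, plane = plane,
                                  noise_mm = noise_marker_mm, rng = rng))
  list(poses = poses, tracks = tracks)
}

#' Camera/image specification for frame rendering
#'
#' Defaults emulate the reference high-speed camera: 896 x 848 px at
#' about 60 um/px, with the global origin at the image center.
#'
#' @param width_px,height_px image size in pixels.
#' @param scale_um_px image scale, micrometres per pixel.
#' @param sigma_px Gaussian blob s.d. in pixels (length 1 or 2 for an
#'   anisotropic blob).
#' @param intensity peak blob intensity (arbitrary units in `[0, 1]`).
#' @param background mean background level.
#' @param noise_sd background Gaussian noise s.d. (0 = clean).
#' @return list of class `image_spec`.
#' @export
image_spec <- function(width_px = 896, height_px = 848, scale_um_px = 60,
                       sigma_px = 2, intensity = 0.8,
                       background = 0.05, noise_sd = 0) {
  structure(list(width_px = width_px, height_px = height_px,
                 scale_um_px = scale_um_px,
                 sigma_px = rep(sigma_px, length.out = 2),
                 intensity = intensity, background = background,
                 noise_sd = noise_sd),
            class = "image_spec")
}

# mm (global X/Y) -> pixel coordinates (x right, y down is NOT used:
# both axes increase with mm; origin at image center).
mm_to_px <- function(spec, X_mm, Y_mm) {
  s <- spec$scale_um_px / 1000  # mm per px
  cbind(x_px = X_mm / s + (spec$width_px + 1) / 2,
        y_px = Y_mm / s + (spec$height_px + 1) / 2)
}

px_to_mm <- function(spec, x_px, y_px) {
  s <- spec$scale_um_px / 1000
  cbind(X_mm = (x_px - (spec$width_px + 1) / 2) * s,
        Y_mm = (y_px - (spec$height_px + 1) / 2) * s)
}

#' Render marker observations into a synthetic grayscale frame
#'
#' Each marker becomes an (optionally anisotropic) Gaussian blob; the
#' noiseless intensity-weighted centroid of a rendered blob reproduces
#' the projected position to well below 0.05 px.
#'
#' @param observations data.frame with columns `X_mm`, `Y_mm` (as from
#'   [project_channels()]).
#' @param spec an [image_spec()].
#' @param seed RNG seed for background noise.
#' @return numeric matrix `height_px x width_px` with values in
#'   `[0, ~1]`; attribute `log` records skipped/overlapping markers.
#' @export
render_frame <- function(observations, spec = image_spec(), seed = 20250) {
  img <- matrix(spec$background, spec$height_px, spec$width_px)
  log <- character()
  if (!is.null(observations) && nrow(observations) > 0) {
    px <- mm_to_px(spec, observations$X_mm, observations$Y_mm)
    # overlap warning for near-coincident markers
    if (nrow(px) > 1) {
      dmat <- as.matrix(stats::dist(px))
      close <- which(dmat < 4 & upper.tri(dmat), arr.ind = TRUE)
      for (k in seq_len(nrow(close)))
        log <- c(log, sprintf("markers %d and %d overlap (%.1f px apart)",
                              close[k, 1], close[k, 2],
                              dmat[close[k, 1], close[k, 2]]))
    }
    half <- ceiling(5 * max(spec$sigma_px))
    for (i in seq_len(nrow(px))) {
      x0 <- px[i, 1]; y0 <- px[i, 2]
      if (x0 < 1 || x0 > spec$width_px || y0 < 1 || y0 > spec$height_px) {
        log <- c(log, sprintf("marker %d out of frame (%.1f, %.1f)", i, x0, y0))
        next
      }
      xs <- max(1, floor(x0 - half)):min(spec$width_px, ceiling(x0 + half))
      ys <- max(1, floor(y0 - half)):min(spec$height_px, ceiling(y0 + half))
      gx <- exp(-(xs - x0)^2 / (2 * spec$sigma_px[1]^2))
      gy <- exp(-(ys - y0)^2 / (2 * spec$sigma_px[2]^2))
      img[ys, xs] <- img[ys, xs] + spec$intensity * outer(gy, gx)
    }
  }
  if (spec$noise_sd > 0) {
    rng <- local_rng(seed)
    img <- img + matrix(rng$rnorm(length(img), sd = spec$noise_sd),
                        nrow(img), ncol(img))
  }
  attr(img, "log") <- log
  attr(img, "spec") <- spec
  img
}

#' Write / read a rendered frame as 16-bit grayscale PNG
#'
#' @param img numeric matrix in `[0, 1]` (values are clipped).
#' @param path file path.
#' @export
write_frame_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG frame output")
  png::writePNG(pmin(pmax(unclass(img), 0), 1), path)
  invisible(path)
}

#' @rdname write_frame_png
#' @export
read_frame_png <- function(path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG frame input")
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Synthetic swirling velocity snapshot with blade-locked wakes
#'
#' Produces a planar velocity (and pressure) snapshot with the structure
#' the phase-averaging statistics expect: a deterministic solid-body /
#' free-vortex swirl (Rankine profile) decaying outward, four Gaussian
#' wake bumps locked to the blade phase, and i.i.d. Gaussian noise.
#' Repeated snapshots at the same phase differ only in noise, so the
#' phase average converges to the deterministic field.
#'
#' @param grid list with numeric vectors `x`, `y` (mm node coordinates).
#' @param alpha_deg blade phase of the snapshot, degrees.
#' @param swirl list: `U0` peak tangential speed (m/s), `r_core` solid
#'   body core radius (mm).
#' @param wake list: `amplitude` (m/s), `radius` (mm, radial location),
#'   `width` (mm), `sigma_ratio` (multiplier on the noise s.d. inside
#'   the wake bumps).
#' @param noise_sd i.i.d. noise s.d. on each velocity component, m/s.
#' @param seed RNG seed.
#' @return list of class `field_snapshot`: `x`, `y`, matrices `u`, `v`,
#'   `w`, `p`, scalar `alpha_deg`, and `wake_mask` (logical matrix).
#' @export
synth_field <- function(grid = list(x = seq(-20, 20, by = 0.5),
                                    y = seq(-20, 20, by = 0.5)),
                        alpha_deg = 0,
                        swirl = list(U0 = 2, r_core = 10),
                        wake = list(amplitude = 1, radius = 14,
                                    width = 2, sigma_ratio = 3),
                        noise_sd = 0, seed = 20250) {
  stopifnot(length(grid$x) > 0, length(grid$y) > 0)
  X <- matrix(grid$x, length(grid$y), length(grid$x), byrow = TRUE)
  Y <- matrix(grid$y, length(grid$y), length(grid$x))
  r <- sqrt(X^2 + Y^2)
  # Rankine vortex tangential speed
  ut <- ifelse(r <= swirl$r_core, swirl$U0 * r / swirl$r_core,
               swirl$U0 * swirl$r_core / pmax(r, 1e-9))
  th <- atan2(Y, X)
  u <- -ut * sin(th); v <- ut * cos(th)
  # four blade-locked wake bumps at azimuths alpha + k*90
  wake_mask <- matrix(FALSE, nrow(X), ncol(X))
  for (k in 0:3) {
    az <- deg2rad(alpha_deg + 90 * k)
    cx <- wake$radius * cos(az); cy <- wake$radius * sin(az)
    g <- exp(-((X - cx)^2 + (Y - cy)^2) / (2 * wake$width^2))
    u <- u - wake$amplitude * g * sin(az)
    v <- v + wake$amplitude * g * cos(az)
    wake_mask <- wake_mask | (g > exp(-0.5))
  }
  w <- 0.1 * ut                        # mild out-of-plane component
  p <- -500 * (swirl$U0^2 - ut^2)      # swirl-consistent pressure, Pa
  if (noise_sd > 0) {
    rng <- local_rng(seed)
    sd_field <- noise_sd * (1 + (wake$sigma_ratio - 1) * wake_mask)
    u <- u + matrix(rng$rnorm(length(u)), nrow(u)) * sd_field
    v <- v + matrix(rng$rnorm(length(v)), nrow(v)) * sd_field
  }
  structure(list(x = grid$x, y = grid$y, u = u, v = v, w = w, p = p,
                 alpha_deg = wrap_angle(alpha_deg), wake_mask = wake_mask),
            class = "field_snapshot")
}

#' Synthetic integral pump signals (pressure head, rotor moment)
#'
#' Sum of sinusoids at integer multiples of the rotation frequency plus
#' white noise -- the structure of blade-passage dominated pump signals.
#' An ideal fourfold-symmetric rotation puts energy only at multiples of
#' 4; a precessing rotor adds the rotational frequency itself.
#'
#' @param f_rot rotation frequency, Hz.
#' @param harmonics named numeric vector: amplitudes indexed by the
#'   harmonic number k (names), e.g. `c("4" = 1, "8" = 0.5)`.
#' @param duration_s signal length in seconds.
#' @param fs sampling rate, Hz; must exceed twice the highest harmonic.
#' @param noise_sd white-noise s.d.
#' @param seed RNG seed.
#' @return data.frame of class `integral_signal`, columns `t_s`,
#'   `value`; attributes `fs`, `f_rot`.
#' @export
synth_signals <- function(f_rot, harmonics, duration_s, fs,
                          noise_sd = 0, seed = 20250) {
  ks <- as.numeric(names(harmonics))
  stopifnot(length(ks) > 0, !any(is.na(ks)))
  if (fs <= 2 * max(ks) * f_rot)
    stop("sampling rate must exceed twice the highest harmonic frequency")
  t <- seq(0, duration_s, by = 1 / fs)
  x <- rep(0, length(t))
  for (i in seq_along(ks))
    x <- x + harmonics[i] * sin(2 * pi * ks[i] * f_rot * t)
  if (noise_sd > 0) {
    rng <- local_rng(seed)
    x <- x + rng$rnorm(length(x), sd = noise_sd)
  }
  out <- data.frame(t_s = t, value = x)
  attr(out, "fs") <- fs
  attr(out, "f_rot") <- f_rot
  class(out) <- c("integral_signal", "data.frame")
  out
}
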