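#' Solve the channel cut height from the marker-pair distance
#'
#' The planar distance between a blade's inner and outer marker dots
#' encodes the local height at which the laser sheet cuts the channels.
#' Neglecting the (small) height difference between the two channel
#' intersections, the distance obeys the quadratic
#' `d^2 = (da*z + dx0)^2 + (db*z + dy0)^2`, whose physically relevant
#' root is
#' `z = (-B + sqrt(delta)) / (da^2 + db^2)` with
#' `B = dx0*da + dy0*db` and
#' `delta = B^2 + (da^2 + db^2) * (d^2 - d0^2)`,
#' `d0` being the dot distance at the reference plane.
#'
#' @param d_mm measured planar marker-pair distance, mm (> 0).
#' @param deltas list with `dx0, dy0, da, db` (outer-minus-inner channel
#'   parameter differences, see [channel_geometry()]); obtainable from a
#'   geometry via the `blade` argument.
#' @param geom optional [channel_geometry()]; with `blade`, used to look
#'   up `deltas`.
#' @param blade blade index 1-4 (with `geom`).
#' @param tol_delta negative-discriminant tolerance; discriminants in
#'   `[-tol, 0)` are clamped to zero with a warning, below `-tol` the
#'   observation is rejected. Default propagates a 30 um marker noise
#'   through the quadratic.
#' @param z_range physical height range, mm; roots outside are rejected.
#' @return list of class `height_solution`: `z_mm`, `delta`,
#'   `root_used`, `rejected` (logical), `reason`.
#' @export
solve_channel_height <- function(d_mm, deltas = NULL, geom = NULL,
                                 blade = NULL, tol_delta = NULL,
                                 z_range = NULL) {
  if (is.null(deltas)) {
    stopifnot(!is.null(geom), !is.null(blade))
    deltas <- channel_deltas(geom, blade)
  }
  if (is.null(z_range))
    z_range <- if (!is.null(geom)) attr(geom, "height_range") else c(0, Inf)
  A <- deltas$da^2 + deltas$db^2
  stopifnot(A > 0, d_mm > 0)
  B <- deltas$dx0 * deltas$da + deltas$dy0 * deltas$db
  d0 <- sqrt(deltas$dx0^2 + deltas$dy0^2)
  if (is.null(tol_delta)) tol_delta <- 2 * 0.030 * d_mm * A
  delta <- B^2 + A * (d_mm^2 - d0^2)
  rejected <- FALSE; reason <- NA_character_
  if (delta < -tol_delta) {
    return(structure(list(z_mm = NA_real_, delta = delta, root_used = NA,
                          rejected = TRUE,
                          reason = "negative discriminant (inconsistent distance)"),
                     class = "height_solution"))
  }
  if (delta < 0) {
    warning("small negative discriminant clamped to zero")
    delta <- 0
  }
  z_plus <- (-B + sqrt(delta)) / A
  z_minus <- (-B - sqrt(delta)) / A
  in_range <- function(z) z >= z_range[1] - 1e-9 & z <= z_range[2] + 1e-9
  # The principal root is the one the closed form designates; when the
  # channel pair converges with height both roots can be positive and
  # the physical bore extent disambiguates.
  if (in_range(z_plus)) {
    z <- z_plus; root <- "+"
  } else if (in_range(z_minus)) {
    z <- z_minus; root <- "-"
  } else {
    rejected <- TRUE
    reason <- sprintf("no root inside physical range (roots %.3f / %.3f mm)",
                      z_plus, z_minus)
    z <- NA_real_; root <- NA_character_
  }
  structure(list(z_mm = z, delta = delta, root_used = root,
                 rejected = rejected, reason = reason),
            class = "height_solution")
}

#' Blade reference point from an inner marker
#'
#' Projects an inner-channel marker down the channel to its intercept
#' with the rotor reference plane:
#' `P_n = I_in - R_Z(alpha) . (a_in z, b_in z, z)` (the small-tilt
#' simplified form). With `exact = TRUE` and a tilt estimate, the full
#' pose rotation is used instead.
#'
#' @param I_in numeric length-3, global inner-marker position, mm.
#' @param z_mm solved channel height, mm.
#' @param alpha_deg blade angle estimate, degrees.
#' @param geom a [channel_geometry()].
#' @param blade blade index.
#' @param exact use the full (tilt-aware) transform.
#' @param phi_deg,theta_deg axis angles for the exact form.
#' @return numeric length-3, the reference point `P_n` in global mm.
#' @export
blade_reference_point <- function(I_in, z_mm, alpha_deg, geom, blade,
                                  exact = FALSE, phi_deg = 0, theta_deg = 0) {
  g <- geom[geom$blade == blade & geom$channel == "in", ]
  v <- c(g$a * z_mm, g$b * z_mm, z_mm)
  R <- if (exact) {
    pose_rotation(rotor_pose(c(0, 0, 0), phi_deg, theta_deg, alpha_deg))
  } else {
    rotation_matrix(c(0, 0, 1), alpha_deg)
  }
  as.numeric(I_in - R %*% v)
}

#' Fit the rotor axis and center from blade reference points
#'
#' With exactly three points the axis is the normalized cross product
#' of the two spanned edges; with four, the total-least-squares plane
#' normal (SVD of the centered points). The sign is chosen so the axis
#' has a positive global-Z component. The center is the mean of the
#' midpoints of available opposing blade pairs (1,3) and (2,4).
#'
#' @param P matrix with one row per blade reference point (>= 3 rows),
#'   global mm.
#' @param blades integer blade indices matching the rows of `P`.
#' @param force_three_point use the three-point cross-product path even
#'   with four points (for parity checks).
#' @return list: `axis` (unit 3-vector), `phi_deg`, `theta_deg`,
#'   `center` (length 3), `residual_mm` (RMS plane distance; `NA` for
#'   the exactly-determined 3-point case).
#' @export
fit_axis_and_center <- function(P, blades, force_three_point = FALSE) {
  P <- as.matrix(P)
  stopifnot(nrow(P) == length(blades))
  if (nrow(P) < 3) stop("at least three blade reference points are required")
  use3 <- nrow(P) == 3 || force_three_point
  if (use3) {
    Q <- P[1:3, , drop = FALSE]
    nvec <- pracma::cross(Q[2, ] - Q[1, ], Q[3, ] - Q[1, ])
    if (sqrt(sum(nvec^2)) < 1e-12) stop("blade reference points are collinear")
    residual <- if (nrow(P) == 3) NA_real_ else {
      n1 <- nvec / sqrt(sum(nvec^2))
      sqrt(mean((sweep(P, 2, Q[1, ]) %*% n1)^2))
    }
  } else {
    ctr <- colMeans(P)
    sv <- svd(sweep(P, 2, ctr))
    if (sv$d[2] < 1e-12) stop("blade reference points are collinear")
    nvec <- sv$v[, 3]
    residual <- sqrt(mean((sweep(P, 2, ctr) %*% nvec)^2))
  }
  if (nvec[3] < 0) nvec <- -nvec
  nvec <- nvec / sqrt(sum(nvec^2))
  mids <- list()
  for (pair in list(c(1, 3), c(2, 4))) {
    i <- match(pair[1], blades); j <- match(pair[2], blades)
    if (!is.na(i) && !is.na(j))
      mids[[length(mids) + 1]] <- (P[i, ] + P[j, ]) / 2
  }
  if (length(mids) == 0)
    stop("no opposing blade pair available to locate the center")
  center <- colMeans(do.call(rbind, mids))
  ang <- angles_from_axis(nvec)
  list(axis = nvec, phi_deg = ang$phi_deg, theta_deg = ang$theta_deg,
       center = as.numeric(center), residual_mm = residual)
}

#' Reconstruct the full rotor pose for one frame
#'
#' Orchestrates the inverse chain: blade-angle estimate about the
#' current center, quadratic height solve per blade, reference-point
#' projection, and axis/center fit -- iterated until the center moves
#' by less than 1 um and the blade angle by less than 0.01 degrees
#' (at most `max_iter` passes).
#'
#' With `solver = "exact"` (the default) the closed-form result seeds a
#' nonlinear least-squares refinement that fits all measured marker
#' positions -- inner and outer, the pair spacing being the depth cue
#' -- against the exact channel/laser-plane intersection forward model
#' over the six pose parameters (tilt parametrised as
#' `theta * (cos phi, sin phi)`, smooth through zero tilt). On
#' noiseless data the reprojection residual, and with it the pose
#' error, collapses to numerical zero. `solver = "closed_form"` stops
#' after the quadratic-height stage and carries the height-compromise
#' error of the `z_in ~ z_out` neglect, which the test suite
#' quantifies.
#'
#' @param pairing a [pair_and_assign()] result with >= 3 blades.
#' @param geom a [channel_geometry()].
#' @param plane a [laser_plane()].
#' @param alpha0_deg starting blade angle (e.g. previous frame).
#' @param center0 starting center `(X, Y)` mm; defaults to the marker
#'   centroid.
#' @param solver `"exact"` (default: full line-plane inversion) or
#'   `"closed_form"` (quadratic height solver only).
#' @param exact_eq12 in the closed-form stage, use the tilt-aware
#'   reference-point projection once a tilt estimate is available
#'   (default `FALSE`: the small-tilt closed form).
#' @param max_iter iteration cap for the closed-form stage.
#' @return list of class `pose_fit`: `pose` ([rotor_pose()]),
#'   `diagnostics` (data.frame: `n_blades, residual_mm, delta_min,
#'   iterations, converged`), `heights` (per-blade solutions).
#' @export
reconstruct_pose <- function(pairing, geom, plane, alpha0_deg = 0,
                             center0 = NULL,
                             solver = c("exact", "closed_form"),
                             exact_eq12 = FALSE, max_iter = 10) {
  solver <- match.arg(solver)
  if (nrow(pairing) < 3)
    stop("pose reconstruction needs markers of at least three blades")
  if (is.null(center0))
    center0 <- c(mean(c(pairing$X_in, pairing$X_out)),
                 mean(c(pairing$Y_in, pairing$Y_out)))
  center <- c(center0[1], center0[2], NA)
  alpha <- alpha0_deg
  phi <- 0; theta <- 0
  converged <- FALSE; it <- 0
  heights <- NULL; fit <- NULL; delta_min <- Inf
  kept <- pairing
  while (it < max_iter) {
    it <- it + 1
    # 1. per-blade heights from pair distances
    sols <- lapply(seq_len(nrow(kept)), function(i)
      solve_channel_height(kept$d_mm[i], geom = geom, blade = kept$blade[i]))
    ok <- !vapply(sols, `[[`, logical(1), "rejected")
    if (sum(ok) < 3) stop("fewer than three usable blade height solutions")
    kept <- kept[ok, , drop = FALSE]
    sols <- sols[ok]
    z <- vapply(sols, `[[`, numeric(1), "z_mm")
    delta_min <- min(delta_min, vapply(sols, `[[`, numeric(1), "delta"))
    # 2. blade angle about current center at solved heights
    alpha_new <- estimate_alpha(kept, center[1:2], geom, z_mm = z)
    # 3. reference points
    P <- t(vapply(seq_len(nrow(kept)), function(i)
      blade_reference_point(c(kept$X_in[i], kept$Y_in[i], plane$Z_mm),
                            z[i], alpha_new, geom, kept$blade[i],
                            exact = exact_eq12, phi_deg = phi,
                            theta_deg = theta),
      numeric(3)))
    # 4. axis and center
    fit <- fit_axis_and_center(P, kept$blade)
    phi <- fit$phi_deg; theta <- fit$theta_deg
    dc <- if (is.na(center[3])) Inf else
      sqrt(sum((fit$center[1:2] - center[1:2])^2))
    dal <- abs(((alpha_new - alpha + 180) %% 360) - 180)
    center <- fit$center
    conv_alpha <- if (it == 1) FALSE else dal < 0.01
    alpha <- alpha_new
    heights <- sols
    if (dc < 1e-3 && conv_alpha) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("pose iteration did not converge in %d passes", max_iter))
  if (solver == "exact") {
    ref <- refine_pose_exact(kept, geom, plane, alpha, fit)
    fit <- ref$fit; alpha <- ref$alpha
    it <- it + ref$iterations
    converged <- ref$converged
    if (!converged) warning("exact pose refinement did not converge")
  }
  pose <- rotor_pose(center = fit$center, phi_deg = fit$phi_deg,
                     theta_deg = fit$theta_deg, alpha_deg = alpha)
  structure(list(
    pose = pose,
    diagnostics = data.frame(n_blades = nrow(kept),
                             residual_mm = fit$residual_mm,
                             delta_min = delta_min,
                             iterations = it, converged = converged),
    heights = heights),
    class = "pose_fit")
}

#' Reconstruct a pose track from labeled marker observations
#'
#' Runs [reconstruct_pose()] frame by frame. Marker observations may be
#' blade-labeled (as produced by [project_channels()]) or unlabeled, in
#' which case blades are assigned by azimuthal sector with the previous
#' frame's pose as hint and the blade angle is unwrapped across frames
#' using the known rotation sense.
#'
#' @param tracks data.frame of marker observations: columns `frame,
#'   X_mm, Y_mm` plus either `blade`/`channel` labels or nothing.
#' @param geom a [channel_geometry()].
#' @param plane a [laser_plane()].
#' @param dalpha_hint_deg expected per-frame blade-angle advance
#'   (`360 rpm / (60 fps)`), used to propagate the sector hint for
#'   unlabeled input; sign encodes the rotation sense.
#' @param solver,exact_eq12 see [reconstruct_pose()].
#' @return list: `table` (pose table with unwrapped `alpha_deg`),
#'   `diagnostics` (per-frame data.frame).
#' @export
reconstruct_track <- function(tracks, geom, plane, dalpha_hint_deg = NULL,
                              solver = c("exact", "closed_form"),
                              exact_eq12 = FALSE) {
  solver <- match.arg(solver)
  frames <- sort(unique(tracks$frame))
  labeled <- all(c("blade", "channel") %in% names(tracks))
  alpha_prev <- 0; center_prev <- NULL
  rows <- list(); diags <- list()
  unwrap_offset <- 0; alpha_prev_wrapped <- NA
  for (f in frames) {
    sub <- tracks[tracks$frame == f, ]
    if (labeled) {
      pairing <- pairing_from_labels(sub)
    } else {
      ctr <- if (is.null(center_prev)) c(mean(sub$X_mm), mean(sub$Y_mm)) else center_prev
      pairing <- pair_and_assign(sub, ctr, geom, alpha_hint_deg = alpha_prev)
    }
    fitted <- reconstruct_pose(pairing, geom, plane, alpha0_deg = alpha_prev,
                               center0 = center_prev, solver = solver,
                               exact_eq12 = exact_eq12)
    a <- fitted$pose$alpha_deg
    if (!is.na(alpha_prev_wrapped) && a < alpha_prev_wrapped - 180)
      unwrap_offset <- unwrap_offset + 360
    alpha_unwrapped <- a + unwrap_offset
    alpha_prev_wrapped <- a
    alpha_prev <- if (is.null(dalpha_hint_deg)) a else
      wrap_angle(a + dalpha_hint_deg)
    center_prev <- fitted$pose$center[1:2]
    rows[[length(rows) + 1]] <- data.frame(
      frame = f, time_s = NA_real_,
      X_mm = fitted$pose$center[1], Y_mm = fitted$pose$center[2],
      Z_mm = fitted$pose$center[3],
      phi_deg = fitted$pose$phi_deg, theta_deg = fitted$pose$theta_deg,
      alpha_deg = alpha_unwrapped)
    diags[[length(diags) + 1]] <- cbind(frame = f, fitted$diagnostics)
  }
  list(table = do.call(rbind, rows), diagnostics = do.call(rbind, diags))
}

# Exact in-plane marker prediction for a pose parameter vector
# par = (cx, cy, cz, tx, ty, alpha) with the tilt encoded as
# (tx, ty) = theta * (cos phi, sin phi) -- smooth through theta = 0.
# Returns the 2n-vector of predicted (X, Y) per requested channel.
predict_marker_xy <- function(par, gsub, Z_L) {
  theta <- sqrt(par[4]^2 + par[5]^2)
  phi <- if (theta == 0) 0 else rad2deg(atan2(par[5], par[4]))
  pose <- rotor_pose(par[1:3], phi_deg = phi, theta_deg = theta,
                     alpha_deg = par[6])
  M <- pose_rotation(pose)
  num <- Z_L - par[3] - (M[3, 1] * gsub$x0 + M[3, 2] * gsub$y0)
  den <- M[3, 1] * gsub$a + M[3, 2] * gsub$b + M[3, 3]
  z <- num / den
  X <- par[1] + M[1, 1] * (gsub$x0 + gsub$a * z) +
    M[1, 2] * (gsub$y0 + gsub$b * z) + M[1, 3] * z
  Y <- par[2] + M[2, 1] * (gsub$x0 + gsub$a * z) +
    M[2, 2] * (gsub$y0 + gsub$b * z) + M[2, 3] * z
  c(X, Y)
}

# Exact pose refinement: nonlinear least squares of all measured marker
# positions (inner AND outer -- the pair distance is the depth cue)
# against the exact channel/laser-plane intersection forward model.
# Noiseless observations drive the reprojection residual, and hence the
# pose error, to numerical zero.
refine_pose_exact <- function(kept, geom, plane, alpha, fit) {
  gin <- geom[geom$channel == "in", ]
  gout <- geom[geom$channel == "out", ]
  gsub <- rbind(gin[match(kept$blade, gin$blade), ],
                gout[match(kept$blade, gout$blade), ])
  # predict_marker_xy returns (X..., Y...) over the rows of gsub
  obs <- c(kept$X_in, kept$X_out, kept$Y_in, kept$Y_out)
  par0 <- c(fit$center,
            fit$theta_deg * cos(deg2rad(fit$phi_deg)),
            fit$theta_deg * sin(deg2rad(fit$phi_deg)),
            alpha)
  objective <- function(par) {
    pred <- predict_marker_xy(par, gsub, plane$Z_mm)
    sum((pred - obs)^2)
  }
  opt <- stats::nlminb(par0, objective,
                       control = list(abs.tol = 0, rel.tol = 1e-15,
                                      x.tol = 1e-15, iter.max = 200))
  # under noise the minimum sits on a flat residual plateau and nlminb
  # labels the stop "singular convergence"; that is a converged fit
  ok_msg <- grepl("relative convergence|X-convergence|singular convergence|absolute function convergence",
                  opt$message %||% "")
  par <- opt$par
  theta <- sqrt(par[4]^2 + par[5]^2)
  phi <- if (theta == 0) 0 else wrap_angle(rad2deg(atan2(par[5], par[4])))
  ang <- angles_from_axis(axis_from_angles(phi, theta))
  fit_new <- list(axis = axis_from_angles(phi, theta),
                  phi_deg = ang$phi_deg, theta_deg = ang$theta_deg,
                  center = par[1:3],
                  residual_mm = sqrt(opt$objective / length(obs)))
  list(fit = fit_new, alpha = wrap_angle(par[6]),
       iterations = opt$iterations,
       converged = opt$convergence == 0 || ok_msg ||
         fit_new$residual_mm < 1e-6)
}

# Build a blade_pairing directly from labeled observations.
pairing_from_labels <- function(obs) {
  blades <- sort(unique(obs$blade))
  rows <- list()
  for (n in blades) {
    bi <- obs[obs$blade == n & obs$channel == "in", ]
    bo <- obs[obs$blade == n & obs$channel == "out", ]
    if (nrow(bi) != 1 || nrow(bo) != 1) next
    rows[[length(rows) + 1]] <- data.frame(
      blade = n, X_in = bi$X_mm, Y_in = bi$Y_mm,
      X_out = bo$X_mm, Y_out = bo$Y_mm,
      d_mm = sqrt((bo$X_mm - bi$X_mm)^2 + (bo$Y_mm - bi$Y_mm)^2))
  }
  out <- do.call(rbind, rows)
  attr(out, "unassigned") <- setdiff(1:4, out$blade)
  class(out) <- c("blade_pairing", "data.frame")
  out
}
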