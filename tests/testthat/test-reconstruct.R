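test_that("solve_channel_height inverts the distance quadratic", {
  # orthogonal configuration (B = 0): forward-evaluate the quadratic at
  # z = 2.9 mm and recover it
  deltas <- list(dx0 = 0, dy0 = 3, da = 0.2, db = 0)
  d <- sqrt((0.2 * 2.9 + 0)^2 + (0 + 3)^2)   # sqrt(9 + 0.3364)
  sol <- solve_channel_height(d, deltas = deltas)
  expect_equal(sol$z_mm, 2.9, tolerance = 1e-12)
  expect_false(sol$rejected)

  # d = d0 with B >= 0: the rotor reference plane itself
  deltas2 <- list(dx0 = 3, dy0 = 0, da = 0.2, db = 0)
  sol2 <- solve_channel_height(3, deltas = deltas2)
  expect_equal(sol2$z_mm, 0, tolerance = 1e-12)

  # forward substitution reproduces the measured distance
  for (blade in 1:4) {
    dl <- rotorpose:::channel_deltas(fx$geom, blade)
    z <- 2.37
    d <- sqrt((dl$da * z + dl$dx0)^2 + (dl$db * z + dl$dy0)^2)
    sol <- solve_channel_height(d, geom = fx$geom, blade = blade)
    expect_equal(sol$z_mm, z, tolerance = 1e-10)
    d_back <- sqrt((dl$da * sol$z_mm + dl$dx0)^2 + (dl$db * sol$z_mm + dl$dy0)^2)
    expect_equal(d_back, d, tolerance = 1e-10)
  }

  # inconsistent distance: discriminant below tolerance is rejected
  dl <- rotorpose:::channel_deltas(fx$geom, 1)
  d_min <- sqrt(max(0, dl$d0^2 - (dl$dx0 * dl$da + dl$dy0 * dl$db)^2 /
                      (dl$da^2 + dl$db^2)))
  bad <- solve_channel_height(d_min - 0.2, geom = fx$geom, blade = 1)
  expect_true(bad$rejected)
})

test_that("height-solver error from the equal-heights neglect scales with tilt", {
  # the quadratic returns a compromise between the two channels' cut
  # heights; against the exact forward model the error grows linearly
  # with tilt (values measured on this geometry and frozen)
  worst_z <- function(tilt) {
    w <- 0
    for (a in seq(0, 350, by = 36)) {
      pose <- rotor_pose(c(0, 0, -5.15), 273, tilt, a)
      obs <- project_channels(pose, fx$geom, fx$plane)
      pairing <- rotorpose:::pairing_from_labels(obs)
      for (i in 1:4) {
        sol <- solve_channel_height(pairing$d_mm[i], geom = fx$geom,
                                    blade = pairing$blade[i])
        zin <- obs$z_local_mm[obs$blade == pairing$blade[i] &
                                obs$channel == "in"]
        w <- max(w, abs(sol$z_mm - zin))
      }
    }
    w
  }
  e03 <- worst_z(0.3); e10 <- worst_z(1.0)
  expect_lt(e03, 0.010)          # < 10 um at 0.3 deg
  expect_lt(e10, 0.030)          # < 30 um at 1.0 deg
  expect_equal(e10 / e03, 1 / 0.3, tolerance = 0.15)  # ~linear in tilt
})

test_that("blade_reference_point projects markers to the reference plane", {
  vg <- vertical_geom()
  # vertical inner channel: plain vertical drop by z
  P <- blade_reference_point(c(11.5, 0, -2.25), 2.9, 0, vg, 1)
  expect_equal(P, c(11.5, 0, -5.15), tolerance = 1e-12)
  # alpha = 0: subtraction without rotation
  P2 <- blade_reference_point(c(12.08, 0.145, -2.25), 2.9, 0, fx$geom, 1)
  expect_equal(P2, c(12.08 - 0.2 * 2.9, 0.145 - 0.05 * 2.9, -5.15),
               tolerance = 1e-12)
  # Z coordinate is always Z_L - z
  expect_equal(P2[3], -2.25 - 2.9)

  # fixture round trip against the exact forward intercept: ~linear
  # growth with tilt (frozen measured bounds for this geometry)
  worst_P <- function(tilt) {
    w <- 0
    for (a in seq(0, 350, by = 72)) {
      pose <- rotor_pose(c(0, 0, -5.15), 273, tilt, a)
      obs <- project_channels(pose, fx$geom, fx$plane)
      pairing <- rotorpose:::pairing_from_labels(obs)
      for (i in 1:4) {
        sol <- solve_channel_height(pairing$d_mm[i], geom = fx$geom,
                                    blade = pairing$blade[i])
        g <- fx$geom[fx$geom$blade == pairing$blade[i] &
                       fx$geom$channel == "in", ]
        Ptrue <- local_to_global(pose, c(g$x0, g$y0, 0))
        P <- blade_reference_point(
          c(pairing$X_in[i], pairing$Y_in[i], fx$plane$Z_mm),
          sol$z_mm, a, fx$geom, pairing$blade[i])
        w <- max(w, sqrt(sum((P - Ptrue)^2)))
      }
    }
    w
  }
  expect_lt(worst_P(0.2), 0.015)   # 15 um at 0.2 deg tilt
  expect_lt(worst_P(1.0), 0.070)   # 70 um at 1.0 deg tilt
})

test_that("fit_axis_and_center recovers planes, centers and residuals", {
  # three points at equal Z: vertical axis, zero-residual plane
  P <- rbind(c(10, 0, -5), c(0, 10, -5), c(-10, 0, -5))
  f <- fit_axis_and_center(P, blades = c(1, 2, 3))
  expect_equal(f$axis, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(f$center, c(0, 0, -5), tolerance = 1e-12)

  # four points on a plane tilted by 0.65 deg: polar angle recovered
  pose <- rotor_pose(c(0.3, -0.1, -5.15), phi_deg = 273, theta_deg = 0.65)
  base <- rbind(c(11.5, 0, 0), c(0, 11.5, 0), c(-11.5, 0, 0), c(0, -11.5, 0))
  P4 <- local_to_global(pose, base)
  f4 <- fit_axis_and_center(P4, blades = 1:4)
  expect_equal(f4$theta_deg, 0.65, tolerance = 1e-9)
  expect_equal(f4$phi_deg, 273, tolerance = 1e-6)
  expect_equal(f4$center, c(0.3, -0.1, -5.15), tolerance = 1e-10)
  expect_equal(f4$residual_mm, 0, tolerance = 1e-12)

  # three-point parity: the cross-product path agrees on coplanar data
  f3 <- fit_axis_and_center(P4, blades = 1:4, force_three_point = TRUE)
  expect_equal(f3$axis, f4$axis, tolerance = 1e-9)

  # 10 um marker noise: median axis error over 1000 trials < 0.05 deg
  set.seed(77)
  errs <- replicate(1000, {
    Pn <- P4 + matrix(stats::rnorm(12, sd = 0.010), 4, 3)
    fn <- fit_axis_and_center(Pn, blades = 1:4)
    acos(pmin(1, sum(fn$axis * f4$axis))) * 180 / pi
  })
  expect_lt(stats::median(errs), 0.05)

  expect_error(fit_axis_and_center(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
                                   1:3), "collinear")
  expect_error(fit_axis_and_center(P[1:2, ], 1:2), "three")
})

test_that("reconstruct_pose round-trips single frames", {
  # ideal rotation: exact to numerical noise for both solvers
  pose <- rotor_pose(c(0, 0, -5.15), alpha_deg = 33)
  obs <- project_channels(pose, fx$geom, fx$plane)
  pairing <- rotorpose:::pairing_from_labels(obs)
  for (sv in c("closed_form", "exact")) {
    rec <- reconstruct_pose(pairing, fx$geom, fx$plane, alpha0_deg = 30,
                            solver = sv)
    expect_lt(max(abs(rec$pose$center[1:2])), 1e-3)
    expect_lt(rec$pose$theta_deg, 0.01)
    expect_equal(rec$pose$alpha_deg, 33, tolerance = 0.01)
    expect_true(rec$diagnostics$converged)
  }

  # tilted fixture frame, exact solver: machine precision
  ax <- rotorpose:::model_axis(fx$model, 40)
  ang <- angles_from_axis(ax)
  pose <- rotor_pose(c(-0.13, 0.04, -5.15), ang$phi_deg, ang$theta_deg, 40)
  obs <- project_channels(pose, fx$geom, fx$plane)
  pairing <- rotorpose:::pairing_from_labels(obs)
  rec <- reconstruct_pose(pairing, fx$geom, fx$plane, alpha0_deg = 40)
  expect_lt(max(abs(rec$pose$center - pose$center)), 1e-9)
  expect_lt(abs(rec$pose$theta_deg - pose$theta_deg), 1e-9)
  expect_lt(abs(wrap180(rec$pose$alpha_deg - 40)), 1e-9)

  # three blades only (one occluded): still a valid pose
  p3 <- pairing[pairing$blade != 3, ]
  rec3 <- reconstruct_pose(p3, fx$geom, fx$plane, alpha0_deg = 40)
  expect_lt(abs(rec3$pose$theta_deg - pose$theta_deg), 1e-6)
  expect_equal(rec3$diagnostics$n_blades, 3)
  # the closed-form path has no plane-fit residual with an exactly
  # determined three-point plane
  rec3cf <- reconstruct_pose(p3, fx$geom, fx$plane, alpha0_deg = 40,
                             solver = "closed_form")
  expect_true(is.na(rec3cf$diagnostics$residual_mm))
})

test_that("exact and closed-form solvers bracket the approximation error", {
  # over a (sub-sampled) revolution of the reference fixture: the exact
  # reprojection solver reaches numerical zero; the closed form carries
  # the documented height-compromise bias
  frames <- seq(1, 255, by = 16)
  poses <- synth_trajectory(fx$model, 255, fx$fps)[frames]
  worst <- list(exact = c(c = 0, th = 0, al = 0),
                closed_form = c(c = 0, th = 0, al = 0))
  for (p in poses) {
    obs <- project_channels(p, fx$geom, fx$plane)
    pairing <- rotorpose:::pairing_from_labels(obs)
    for (sv in names(worst)) {
      rec <- reconstruct_pose(pairing, fx$geom, fx$plane,
                              alpha0_deg = p$alpha_deg, solver = sv)
      worst[[sv]] <- pmax(worst[[sv]], c(
        c = max(abs(rec$pose$center - p$center)),
        th = abs(rec$pose$theta_deg - p$theta_deg),
        al = abs(wrap180(rec$pose$alpha_deg - p$alpha_deg))))
    }
  }
  expect_lt(worst$exact["c"], 1e-9)
  expect_lt(worst$exact["th"], 1e-9)
  expect_lt(worst$exact["al"], 1e-9)
  # closed form at the fixture's up-to-1.1 deg instantaneous tilt
  # (frozen measured bounds; see the methods vignette)
  expect_lt(worst$closed_form["c"], 0.060)
  expect_lt(worst$closed_form["th"], 0.200)
  expect_lt(worst$closed_form["al"], 0.002)
  # and the bias is real: the exact solver is at least 1000x tighter
  expect_gt(worst$closed_form["th"], 1e3 * worst$exact["th"])
})

test_that("height rejections grow monotonically with marker noise", {
  # count discriminant/range rejections of the quadratic over noisy
  # replicates of one frame, at increasing noise
  pose <- rotor_pose(c(0, 0, -5.15), 273, 0.65, 15)
  obs0 <- project_channels(pose, fx$geom, fx$plane)
  pairing0 <- rotorpose:::pairing_from_labels(obs0)
  count_rejects <- function(noise_mm, seeds = 1:40) {
    n <- 0
    for (s in seeds) {
      set.seed(s)
      d <- pairing0$d_mm + stats::rnorm(4, sd = noise_mm * sqrt(2))
      for (i in 1:4) {
        sol <- suppressWarnings(solve_channel_height(
          max(d[i], 1e-6), geom = fx$geom, blade = pairing0$blade[i]))
        n <- n + sol$rejected
      }
    }
    n
  }
  counts <- vapply(c(0, 0.1, 0.4), count_rejects, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[1], 0)
  expect_gt(counts[3], 0)
})

test_that("reconstruct_track handles labeled and unlabeled input alike", {
  n <- 24
  bundle <- synth_marker_tracks(fx$model, fx$geom, fx$plane, n, fx$fps)
  truth <- pose_table(bundle$poses)
  dal <- 360 * fx$model$rpm / (60 * fx$fps)

  lab <- reconstruct_track(bundle$tracks, fx$geom, fx$plane,
                           dalpha_hint_deg = dal)
  unlab <- reconstruct_track(bundle$tracks[, c("frame", "X_mm", "Y_mm")],
                             fx$geom, fx$plane, dalpha_hint_deg = dal)
  for (rec in list(lab, unlab)) {
    expect_equal(nrow(rec$table), n)
    expect_lt(max(abs(rec$table$theta_deg - truth$theta_deg)), 1e-9)
    expect_lt(max(abs(rec$table$X_mm - truth$X_mm)), 1e-9)
    expect_true(all(rec$diagnostics$converged))
    # blade angle agrees modulo 360 (unlabeled tracks may carry a
    # whole-turn offset from near-zero wrap at the first frame)
    expect_lt(max(abs(wrap180(rec$table$alpha_deg - truth$alpha_deg))), 1e-9)
  }
})
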