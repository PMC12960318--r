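test_that("bin_phases folds blade angles into 1-degree quarter-turn bins", {
  expect_equal(bin_phases(91.4), 2L)    # mod 90 -> 1.4
  expect_equal(bin_phases(0), 1L)
  expect_equal(bin_phases(89.999), 90L)
  expect_equal(bin_phases(270), 1L)
  # counting oracle: every angle lands in exactly one bin and a
  # uniform sweep fills the bins evenly
  a <- seq(0, 359.9, by = 0.1)
  b <- bin_phases(a)
  expect_equal(length(b), length(a))
  expect_true(all(tabulate(b, 90) == 40))
})

test_that("regrid interpolates exactly where exactness is guaranteed", {
  grid <- list(x = seq(-10, 10, by = 1), y = seq(-10, 10, by = 1))
  snap <- synth_field(grid, alpha_deg = 0, noise_sd = 0)
  # identity: same grid in, same values out
  out <- regrid(snap, grid)
  expect_equal(out$u, snap$u, tolerance = 1e-12)
  expect_true(all(out$mask))

  # affine fields are reproduced exactly by bilinear interpolation
  X <- matrix(grid$x, 21, 21, byrow = TRUE)
  Y <- matrix(grid$y, 21, 21)
  aff <- structure(list(x = grid$x, y = grid$y, u = 2 * X - 3 * Y + 1,
                        v = 0 * X, alpha_deg = 0),
                   class = "field_snapshot")
  fine <- list(x = seq(-9.5, 9.5, by = 0.25), y = seq(-9.5, 9.5, by = 0.25))
  outf <- regrid(aff, fine)
  Xf <- matrix(fine$x, length(fine$y), length(fine$x), byrow = TRUE)
  Yf <- matrix(fine$y, length(fine$y), length(fine$x))
  expect_equal(outf$u, 2 * Xf - 3 * Yf + 1, tolerance = 1e-12)

  # smooth swirl: refinement error bounded by the curvature estimate
  coarse <- list(x = seq(-10, 10, by = 1), y = seq(-10, 10, by = 1))
  h <- 1
  sw <- synth_field(coarse, alpha_deg = 0,
                    wake = list(amplitude = 0, radius = 14, width = 2,
                                sigma_ratio = 1))
  mid <- list(x = seq(-9.5, 9.5, by = 1), y = seq(-9.5, 9.5, by = 1))
  est <- regrid(sw, mid)
  truth <- synth_field(mid, alpha_deg = 0,
                       wake = list(amplitude = 0, radius = 14, width = 2,
                                   sigma_ratio = 1))
  # |interp - truth| <= h^2 * max|second difference|/something O(1);
  # use the measured curvature bound of the Rankine profile
  curv <- max(abs(diff(t(sw$u), differences = 2)),
              abs(diff(sw$u, differences = 2))) / h^2
  expect_lt(max(abs(est$u - truth$u), na.rm = TRUE), h^2 * curv)

  # nodes outside the source domain are masked
  wide <- regrid(sw, list(x = seq(-15, 15, by = 1), y = coarse$y))
  expect_true(any(!wide$mask))
})

test_that("phase_average takes the magnitude of the mean, not vice versa", {
  grid <- list(x = seq(-5, 5, by = 1), y = seq(-5, 5, by = 1))
  s1 <- synth_field(grid, alpha_deg = 10, noise_sd = 0)
  expect_equal(phase_average(list(s1))$U, sqrt(s1$u^2 + s1$v^2))

  # opposite instantaneous vectors cancel exactly
  s2 <- s1; s2$u <- -s1$u; s2$v <- -s1$v
  avg <- phase_average(list(s1, s2))
  expect_true(all(avg$U == 0))

  # triangle inequality: the mean-of-magnitudes never lies below it
  s3 <- synth_field(grid, alpha_deg = 40, noise_sd = 0)
  avg2 <- phase_average(list(s1, s3))
  mom <- (sqrt(s1$u^2 + s1$v^2) + sqrt(s3$u^2 + s3$v^2)) / 2
  expect_true(all(avg2$U <= mom + 1e-12))
  expect_gt(max(mom - avg2$U), 0)
})

test_that("relative_error and rms_error match brute-force summation", {
  set.seed(5)
  U_ref <- matrix(stats::runif(400, 0.2, 3), 20, 20)
  U <- U_ref + matrix(stats::rnorm(400, sd = 0.2), 20, 20)
  E <- relative_error(U, U_ref)
  # brute force, node by node
  mx <- max(U_ref)
  for (idx in sample(400, 25))
    expect_identical(E[idx], (U[idx] - U_ref[idx]) / mx)
  # RMS against direct summation, in percent
  direct <- 100 * sqrt(sum(((U - U_ref) / mx)^2) / 400)
  expect_equal(rms_error(E), direct, tolerance = 1e-12)

  expect_equal(unique(as.numeric(relative_error(U_ref, U_ref))), 0)
  # constant offset of 10% of the reference maximum
  E10 <- relative_error(U_ref + 0.1 * mx, U_ref)
  expect_equal(unique(round(as.numeric(E10), 12)), 0.1)
  expect_equal(rms_error(E10), 10, tolerance = 1e-9)
  expect_equal(rms_error(matrix(0.05, 5, 5)), 5, tolerance = 1e-12)
  expect_equal(rms_error(matrix(0, 5, 5)), 0)
  expect_error(relative_error(U_ref, matrix(0, 20, 20)), "maximum")

  # permutation invariance and monotonicity in a single node
  p <- sample(400)
  expect_equal(rms_error(matrix(E[p], 20, 20)), rms_error(E))
  E2 <- E; E2[7] <- E2[7] + sign(E2[7]) * 0.05
  expect_gt(rms_error(E2), rms_error(E))
})

test_that("abs_pressure_error works on inlet-referenced fields in mmHg", {
  p_ref <- matrix(1000, 10, 10)
  expect_equal(abs_pressure_error(p_ref, p_ref, 0, 0)$rms_mmHg, 0)
  # +4 mmHg constant offset
  off <- p_ref + 4 * 133.322
  res <- abs_pressure_error(off, p_ref, 0, 0)
  expect_equal(res$mean_mmHg, 4, tolerance = 1e-12)
  expect_equal(res$rms_mmHg, 4, tolerance = 1e-12)
  # differing inlet references cancel out
  res2 <- abs_pressure_error(off + 500, p_ref, 500, 0)
  expect_equal(res2$mean_mmHg, 4, tolerance = 1e-12)
  expect_error(abs_pressure_error(off, p_ref), "inlet")

  # two-population offset: bimodal error histogram
  mixed <- p_ref
  mixed[1:5, ] <- mixed[1:5, ] - 4 * 133.322
  res3 <- abs_pressure_error(mixed, p_ref, 0, 0)
  h <- hist(res3$E_abs_mmHg, breaks = seq(-5.25, 1.25, by = 0.5), plot = FALSE)
  modes <- h$mids[h$counts > 0]
  expect_equal(length(modes), 2)
  expect_equal(sort(modes), c(-4, 0))
})

test_that("field_std implements the printed mean-squared-deviation form", {
  # offset grid: keeps the vortex center (zero magnitude) off the nodes
  grid <- list(x = seq(-4.5, 4.5, by = 1), y = seq(-4.5, 4.5, by = 1))
  s1 <- synth_field(grid, alpha_deg = 10, noise_sd = 0)
  expect_true(all(field_std(list(s1, s1)) == 0))

  # magnitudes U +/- c in a common direction (c below the smallest
  # magnitude so no vector flips): printed form gives c^2
  c_ <- 0.1
  U1 <- sqrt(s1$u^2 + s1$v^2)
  scale_up <- (U1 + c_) / U1; scale_dn <- (U1 - c_) / U1
  sp <- s1; sp$u <- s1$u * scale_up; sp$v <- s1$v * scale_up
  sm <- s1; sm$u <- s1$u * scale_dn; sm$v <- s1$v * scale_dn
  sig <- field_std(list(sp, sm))
  expect_equal(as.numeric(sig), rep(c_^2, length(sig)), tolerance = 1e-10)
  # the square-root companion reports c
  both <- field_std(list(sp, sm), sqrt = TRUE)
  expect_equal(as.numeric(both$sigma_U_sqrt), rep(c_, length(sig)),
               tolerance = 1e-10)

  # direct-summation oracle on random snapshots
  set.seed(9)
  snaps <- lapply(1:5, function(i)
    synth_field(grid, alpha_deg = 10, noise_sd = 0.3, seed = 100 + i))
  avg <- phase_average(snaps)
  sig <- field_std(snaps, avg)
  mags <- lapply(snaps, function(s) sqrt(s$u^2 + s$v^2))
  direct <- Reduce(`+`, lapply(mags, function(U) (U - avg$U)^2)) / 5
  expect_equal(sig, direct, tolerance = 1e-14, ignore_attr = TRUE)

  # single snapshot: zero with a flag
  s0 <- field_std(list(s1))
  expect_true(all(s0 == 0))
  expect_true(attr(s0, "flagged_single"))
})

test_that("error_pdf yields a normalized density", {
  E0 <- matrix(0, 20, 20)
  pdf0 <- error_pdf(E0)
  expect_equal(sum(pdf0$density * 0.005), 1, tolerance = 1e-9)
  expect_equal(sum(pdf0$count > 0), 1)

  set.seed(3)
  E <- matrix(stats::rnorm(4000, sd = 0.02), 40, 100)
  pdf <- error_pdf(E)
  expect_equal(sum(pdf$density * 0.005), 1, tolerance = 1e-9)
  ks <- suppressWarnings(stats::ks.test(as.numeric(E), "pnorm", 0, 0.02))
  expect_gt(ks$p.value, 0.01)

  # positive-mean construction: the mode sits right of zero
  pdfp <- error_pdf(E + 0.03)
  expect_gt(pdfp$mid[which.max(pdfp$density)], 0)
})

test_that("out_of_plane_check applies the sheet-fraction threshold", {
  expect_equal(out_of_plane_check(matrix(0, 5, 5))$fraction, 0)
  # 1.3 m/s over 0.1 ms -> 0.13 mm > 25% of a 0.5 mm sheet
  expect_equal(out_of_plane_check(matrix(1.3, 2, 2), 1e-4, 0.5, 0.25)$fraction, 1)
  # 1.2 m/s -> 0.12 mm, inside the threshold
  expect_equal(out_of_plane_check(matrix(1.2, 2, 2), 1e-4, 0.5, 0.25)$fraction, 0)
  mix <- matrix(c(1.3, 1.2, 0, 2), 2, 2)
  expect_equal(out_of_plane_check(mix, 1e-4)$fraction, 0.5)
})

test_that("field snapshots survive the CSV round trip", {
  grid <- list(x = seq(-3, 3, by = 1), y = seq(-2, 2, by = 1))
  snap <- synth_field(grid, alpha_deg = 42, noise_sd = 0)
  path <- tempfile(fileext = ".csv")
  write_field_csv(snap, path)
  back <- read_field_csv(path)
  expect_equal(back$x, snap$x)
  expect_equal(back$u, snap$u, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$p, snap$p, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back$alpha_deg, 42)
  unlink(path)
})
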