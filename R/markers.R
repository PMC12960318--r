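#' Detect marker blobs in a grayscale frame
#'
#' Thresholded connected-component detection with intensity-weighted
#' sub-pixel centroids. The default threshold is the background mean
#' plus five background standard deviations (estimated robustly from
#' the image median/MAD).
#'
#' @param img numeric matrix (rows = y, columns = x), e.g. from
#'   [render_frame()].
#' @param threshold absolute intensity threshold; `NULL` for automatic.
#' @param min_area_px,max_area_px component area limits in pixels.
#' @return data.frame with columns `x_px, y_px, area_px, intensity`;
#'   zero rows (with a warning) when nothing is found.
#' @export
detect_markers <- function(img, threshold = NULL,
                           min_area_px = 4, max_area_px = Inf) {
  stopifnot(is.matrix(img))
  if (is.null(threshold)) {
    bg <- stats::median(img)
    bg_sd <- stats::mad(img)
    if (bg_sd == 0) bg_sd <- max(stats::sd(img), 1e-6) / 5
    threshold <- bg + 5 * bg_sd
  }
  mask <- img > threshold
  if (!any(mask)) {
    warning("no markers detected above threshold")
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      area_px = numeric(0), intensity = numeric(0)))
  }
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  bg_level <- stats::median(img[!mask])
  ids <- sort(unique(lab[lab > 0]))
  rows <- lapply(ids, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)  # (row = y, col = x)
    area <- nrow(idx)
    if (area < min_area_px || area > max_area_px) return(NULL)
    w <- pmax(img[idx] - bg_level, 0)
    if (sum(w) == 0) w <- rep(1, area)
    data.frame(x_px = sum(idx[, 2] * w) / sum(w),
               y_px = sum(idx[, 1] * w) / sum(w),
               area_px = area, intensity = max(img[idx]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      area_px = numeric(0), intensity = numeric(0))
  out
}

#' Fit an affine pixel-to-mm calibration
#'
#' Least-squares affine map `mm = A . px + t` from reference-grid
#' correspondences (e.g. drill holes machined into the housing at
#' surveyed positions).
#'
#' @param px two-column matrix of pixel coordinates.
#' @param mm two-column matrix of the matching physical coordinates, mm.
#' @return list of class `calibration`: `A` (2x2), `offset` (length 2),
#'   `residual_rms_mm`, `scale_um_px` (geometric mean singular-value
#'   scale, for reporting).
#' @export
fit_calibration <- function(px, mm) {
  px <- as.matrix(px); mm <- as.matrix(mm)
  stopifnot(ncol(px) == 2, ncol(mm) == 2, nrow(px) == nrow(mm),
            nrow(px) >= 3)
  X <- cbind(1, px)
  if (qr(X)$rank < 3) stop("calibration points are collinear")
  beta <- qr.solve(X, mm)             # 3 x 2: offset row + A^T rows
  fit <- X %*% beta
  res <- sqrt(mean(rowSums((mm - fit)^2)))
  A <- t(beta[2:3, ])
  sv <- svd(A)$d
  structure(list(A = A, offset = as.numeric(beta[1, ]),
                 residual_rms_mm = res,
                 scale_um_px = 1000 * sqrt(prod(sv))),
            class = "calibration")
}

#' Apply (or invert) a calibration
#'
#' @param cal a [fit_calibration()] result.
#' @param xy two-column matrix of coordinates.
#' @param inverse if `TRUE`, map mm back to pixels.
#' @return two-column matrix of mapped coordinates.
#' @export
apply_calibration <- function(cal, xy, inverse = FALSE) {
  xy <- as.matrix(xy)
  if (inverse) {
    t(solve(cal$A, t(xy) - cal$offset))
  } else {
    t(cal$A %*% t(xy) + cal$offset)
  }
}

# Expected in-plane azimuth (deg, local frame at alpha = 0) of a
# blade's channel point at height z.
channel_azimuth <- function(geom, blade, channel, z) {
  g <- geom[geom$blade == blade & geom$channel == channel, ]
  rad2deg(atan2(g$y0 + g$b * z, g$x0 + g$a * z))
}

#' Group detected markers into blade inner/outer pairs
#'
#' Centers are assigned to blades by azimuthal sector (+/- 45 degrees
#' about each blade's expected azimuth at the hinted blade angle), and
#' within a sector inner/outer are ranked by radial distance from the
#' provisional center. Sectors that do not contain exactly two centers
#' leave that blade unassigned.
#'
#' @param centers data.frame/matrix with columns `X_mm`, `Y_mm`.
#' @param center provisional rotor center `(X, Y)` in mm.
#' @param geom a [channel_geometry()].
#' @param alpha_hint_deg approximate blade angle used to place the
#'   sectors (previous frame's estimate; 0 for a first frame, in which
#'   case the assignment fixes the blade labelling modulo 90 degrees).
#' @param z_nominal_mm nominal channel height of the laser cut, used
#'   for the expected azimuths.
#' @return data.frame of class `blade_pairing`, one row per assigned
#'   blade: `blade, X_in, Y_in, X_out, Y_out, d_mm`; attribute
#'   `unassigned` lists blades without a clean pair.
#' @export
pair_and_assign <- function(centers, center, geom, alpha_hint_deg = 0,
                            z_nominal_mm = NULL) {
  centers <- as.data.frame(centers)
  stopifnot(nrow(centers) >= 2)
  if (is.null(z_nominal_mm)) {
    hr <- attr(geom, "height_range")
    z_nominal_mm <- mean(hr)
  }
  az <- wrap_angle(rad2deg(atan2(centers$Y_mm - center[2],
                                 centers$X_mm - center[1])))
  rad <- sqrt((centers$X_mm - center[1])^2 + (centers$Y_mm - center[2])^2)
  rows <- list(); unassigned <- integer(0)
  for (n in 1:4) {
    exp_az <- wrap_angle(alpha_hint_deg +
                           mean(c(channel_azimuth(geom, n, "in", z_nominal_mm),
                                  channel_azimuth(geom, n, "out", z_nominal_mm))))
    dist_az <- abs(((az - exp_az + 180) %% 360) - 180)
    in_sector <- which(dist_az <= 45)
    if (length(in_sector) != 2) {
      unassigned <- c(unassigned, n)
      next
    }
    ord <- in_sector[order(rad[in_sector])]
    rows[[length(rows) + 1]] <- data.frame(
      blade = n,
      X_in = centers$X_mm[ord[1]], Y_in = centers$Y_mm[ord[1]],
      X_out = centers$X_mm[ord[2]], Y_out = centers$Y_mm[ord[2]],
      d_mm = sqrt((centers$X_mm[ord[2]] - centers$X_mm[ord[1]])^2 +
                    (centers$Y_mm[ord[2]] - centers$Y_mm[ord[1]])^2))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(blade = integer(0), X_in = numeric(0),
                                      Y_in = numeric(0), X_out = numeric(0),
                                      Y_out = numeric(0), d_mm = numeric(0))
  attr(out, "unassigned") <- unassigned
  class(out) <- c("blade_pairing", "data.frame")
  out
}

#' Estimate the blade angle from inner-marker azimuths
#'
#' For each assigned blade, the apparent blade angle is the observed
#' azimuth of its inner marker about the (provisional) center minus the
#' channel's own local azimuth at the cut height. With blade labels the
#' estimates agree modulo 360 and are combined by a circular mean; for
#' unlabeled markers the estimate is only defined modulo 90 (fourfold
#' symmetry).
#'
#' @param pairing a [pair_and_assign()] result (or any data.frame with
#'   `blade`, `X_in`, `Y_in`).
#' @param center provisional rotor center `(X, Y)` mm.
#' @param geom a [channel_geometry()].
#' @param z_mm channel cut height(s): a single nominal value or a vector
#'   matching `pairing$blade` (refined heights from the quadratic
#'   solver).
#' @param modulo 360 (labeled blades) or 90 (unlabeled).
#' @return blade angle estimate in degrees (in `[0, modulo)`).
#' @export
estimate_alpha <- function(pairing, center, geom, z_mm = NULL, modulo = 360) {
  if (nrow(pairing) < 1) stop("no assigned markers: cannot estimate blade angle")
  if (is.null(z_mm)) z_mm <- mean(attr(geom, "height_range"))
  z_mm <- rep(z_mm, length.out = nrow(pairing))
  obs_az <- rad2deg(atan2(pairing$Y_in - center[2], pairing$X_in - center[1]))
  ref_az <- vapply(seq_len(nrow(pairing)), function(i)
    channel_azimuth(geom, pairing$blade[i], "in", z_mm[i]), numeric(1))
  est <- wrap_angle(obs_az - ref_az)
  circular_mean(est, period = modulo)
}
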