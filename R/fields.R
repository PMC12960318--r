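#' Phase bins modulo the fourfold blade symmetry
#'
#' Blade angles are sorted into 1-degree bins 1..90 after reduction
#' modulo 90 degrees (an impeller with four identical main blades
#' repeats its flow field every quarter turn). Bin `k` holds angles
#' with `alpha mod 90` in `[k-1, k)`.
#'
#' @param alpha_deg blade angles in degrees.
#' @return integer bin indices in 1..90.
#' @export
bin_phases <- function(alpha_deg) {
  stopifnot(is.finite(alpha_deg))
  as.integer(floor(wrap_angle(alpha_deg, 90))) + 1L
}

#' Resample a snapshot onto a uniform Eulerian grid
#'
#' Bilinear in-plane interpolation of each field component onto the
#' target grid; snapshots supplied as a list of Z slices are first
#' averaged (unweighted) over the slices falling inside `z_range`
#' (the region illuminated by the laser sheet). Target nodes outside
#' the source domain are masked.
#'
#' @param snapshot a `field_snapshot` (see [synth_field()]), or a list
#'   of them at different `z_mm` (each carrying a `z_mm` element).
#' @param grid list with target node vectors `x`, `y` (mm).
#' @param z_range Z interval in mm over which slices are averaged
#'   (default `c(-2.5, -2.0)`); only used for slice lists.
#' @return a `field_snapshot` on the target grid with a logical `mask`
#'   of valid nodes.
#' @export
regrid <- function(snapshot, grid, z_range = c(-2.5, -2.0)) {
  if (!inherits(snapshot, "field_snapshot") && is.list(snapshot) &&
      all(vapply(snapshot, inherits, logical(1), "field_snapshot"))) {
    zs <- vapply(snapshot, function(s) s$z_mm %||% NA_real_, numeric(1))
    keep <- which(zs >= z_range[1] & zs <= z_range[2])
    if (length(keep) == 0) stop("no slices fall inside the Z range")
    slices <- lapply(snapshot[keep], regrid, grid = grid, z_range = z_range)
    out <- slices[[1]]
    for (comp in c("u", "v", "w", "p")) {
      if (is.null(out[[comp]])) next
      acc <- Reduce(`+`, lapply(slices, `[[`, comp)) / length(slices)
      out[[comp]] <- acc
    }
    out$mask <- Reduce(`&`, lapply(slices, `[[`, "mask"))
    return(out)
  }
  interp_comp <- function(Zc) {
    if (is.null(Zc)) return(NULL)
    out <- matrix(NA_real_, length(grid$y), length(grid$x))
    inx <- grid$x >= min(snapshot$x) & grid$x <= max(snapshot$x)
    iny <- grid$y >= min(snapshot$y) & grid$y <= max(snapshot$y)
    if (any(inx) && any(iny)) {
      sub <- pracma::interp2(snapshot$x, snapshot$y, Zc,
                             rep(grid$x[inx], each = sum(iny)),
                             rep(grid$y[iny], times = sum(inx)),
                             method = "linear")
      out[iny, inx] <- matrix(sub, sum(iny), sum(inx))
    }
    out
  }
  u <- interp_comp(snapshot$u)
  structure(list(x = grid$x, y = grid$y,
                 u = u, v = interp_comp(snapshot$v),
                 w = interp_comp(snapshot$w), p = interp_comp(snapshot$p),
                 alpha_deg = snapshot$alpha_deg,
                 mask = !is.na(u)),
            class = "field_snapshot")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Phase-averaged field and in-plane velocity magnitude
#'
#' Averages the velocity components over all snapshots of a phase bin
#' and takes the magnitude of the averaged components:
#' `U-bar = sqrt(mean(u)^2 + mean(v)^2)`. The magnitude of the mean is
#' NOT the mean of magnitudes -- opposite instantaneous vectors cancel.
#'
#' @param snapshots list of congruent `field_snapshot`s (same grid).
#' @return list of class `phase_avg_field`: `x`, `y`, `u`, `v` (mean
#'   components), `U` (magnitude of the mean), `p` (mean pressure if
#'   present), `n` (snapshot count), `mask`.
#' @export
phase_average <- function(snapshots) {
  stopifnot(length(snapshots) >= 1)
  n <- length(snapshots)
  u <- Reduce(`+`, lapply(snapshots, `[[`, "u")) / n
  v <- Reduce(`+`, lapply(snapshots, `[[`, "v")) / n
  ps <- lapply(snapshots, `[[`, "p")
  p <- if (all(!vapply(ps, is.null, logical(1)))) Reduce(`+`, ps) / n else NULL
  masks <- lapply(snapshots, function(s) s$mask %||% !is.na(s$u))
  structure(list(x = snapshots[[1]]$x, y = snapshots[[1]]$y,
                 u = u, v = v, U = sqrt(u^2 + v^2), p = p, n = n,
                 mask = Reduce(`&`, masks)),
            class = "phase_avg_field")
}

#' Normalized relative error between two fields
#'
#' Nodewise difference normalized by a single scalar: the maximum of
#' the reference field over the valid (jointly unmasked) nodes.
#'
#' @param U field being assessed (matrix, or `phase_avg_field`).
#' @param U_ref reference field (congruent).
#' @param mask optional logical matrix of valid nodes; defaults to the
#'   intersection of both fields' masks (or all finite nodes).
#' @return matrix of relative errors (dimensionless; `NA` outside the
#'   mask), with the normalization stored in attribute `denominator`.
#' @export
relative_error <- function(U, U_ref, mask = NULL) {
  gm <- function(f) if (inherits(f, "phase_avg_field")) f$U else f
  gmask <- function(f) if (inherits(f, "phase_avg_field")) f$mask else NULL
  m1 <- gmask(U); m2 <- gmask(U_ref)
  U <- gm(U); U_ref <- gm(U_ref)
  if (is.null(mask)) {
    mask <- is.finite(U) & is.finite(U_ref)
    if (!is.null(m1)) mask <- mask & m1
    if (!is.null(m2)) mask <- mask & m2
  }
  denom <- max(U_ref[mask])
  if (!is.finite(denom) || denom == 0)
    stop("reference field has no positive maximum: normalization undefined")
  out <- (U - U_ref) / denom
  out[!mask] <- NA_real_
  attr(out, "denominator") <- denom
  attr(out, "mask") <- mask
  out
}

#' RMS of a normalized error field, in percent
#'
#' `RMS = 100 * sqrt(mean(E^2))` over the valid nodes only.
#'
#' @param E_rel relative-error matrix (from [relative_error()]).
#' @param mask optional logical matrix; defaults to the matrix's own
#'   mask attribute, else all finite entries.
#' @return RMS in percent.
#' @export
rms_error <- function(E_rel, mask = NULL) {
  if (is.null(mask)) mask <- attr(E_rel, "mask") %||% is.finite(E_rel)
  vals <- E_rel[mask]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) stop("no valid nodes for RMS")
  100 * sqrt(mean(vals^2))
}

#' Absolute pressure error relative to the inlet
#'
#' Both fields are first referenced to their own inlet pressure, then
#' differenced nodewise; summaries are reported in mmHg
#' (1 mmHg = 133.322 Pa).
#'
#' @param p,p_ref pressure matrices in Pa.
#' @param inlet_p,inlet_p_ref scalar inlet reference pressures, Pa.
#' @param mask optional logical matrix of valid nodes.
#' @return list: `E_abs_mmHg` (matrix), `mean_mmHg`, `rms_mmHg`.
#' @export
abs_pressure_error <- function(p, p_ref, inlet_p, inlet_p_ref, mask = NULL) {
  if (missing(inlet_p) || missing(inlet_p_ref))
    stop("both fields need an inlet reference pressure")
  mmHg <- 133.322
  E <- ((p - inlet_p) - (p_ref - inlet_p_ref)) / mmHg
  if (is.null(mask)) mask <- is.finite(E)
  vals <- E[mask]
  list(E_abs_mmHg = E, mean_mmHg = mean(vals),
       rms_mmHg = sqrt(mean(vals^2)))
}

#' Phase-bin velocity-magnitude variability
#'
#' Mean squared deviation of the instantaneous in-plane velocity
#' magnitudes about the phase-averaged magnitude:
#' `sigma_U = (1/N) * sum_n (U_n - U-bar)^2`.
#' This mean-of-squared-deviations form (units m^2/s^2) is the printed
#' convention of the field; set `sqrt = TRUE` to also obtain its square
#' root (units m/s).
#'
#' @param snapshots list of congruent `field_snapshot`s (N >= 2 for a
#'   meaningful value; N = 1 returns zero with a flag).
#' @param avg optional precomputed [phase_average()] of the snapshots.
#' @param sqrt also return the square-root form.
#' @return matrix `sigma_U` (attribute `flagged_single` when N = 1);
#'   with `sqrt = TRUE`, a list `(sigma_U, sigma_U_sqrt)`.
#' @export
field_std <- function(snapshots, avg = NULL, sqrt = FALSE) {
  if (is.null(avg)) avg <- phase_average(snapshots)
  N <- length(snapshots)
  acc <- 0
  for (s in snapshots) {
    Un <- base::sqrt(s$u^2 + s$v^2)
    acc <- acc + (Un - avg$U)^2
  }
  sig <- acc / N
  if (N == 1) attr(sig, "flagged_single") <- TRUE
  if (sqrt) list(sigma_U = sig, sigma_U_sqrt = base::sqrt(sig)) else sig
}

#' Density histogram of a normalized error field
#'
#' @param E_rel relative-error matrix.
#' @param bin_width histogram bin width on the normalized-error axis.
#' @return data.frame `mid, density, count`; densities integrate to 1.
#' @export
error_pdf <- function(E_rel, bin_width = 0.005) {
  vals <- E_rel[is.finite(E_rel)]
  stopifnot(length(vals) >= 100)
  lo <- floor(min(vals) / bin_width) * bin_width
  hi <- ceiling(max(vals) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  brk <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(vals, breaks = brk, plot = FALSE)
  data.frame(mid = h$mids, density = h$density, count = h$counts)
}

#' Out-of-plane displacement check
#'
#' Particles leaving the light sheet between the two frames of a PIV
#' image pair degrade the correlation; the accepted rule of thumb flags
#' displacements beyond 25% of the sheet thickness. A node is flagged
#' when `|w| * dt` exceeds `threshold * thickness`.
#'
#' @param w out-of-plane velocity matrix, m/s.
#' @param dt_s inter-frame time, s (default 1e-4, i.e. 10 kHz).
#' @param thickness_mm laser-sheet thickness, mm.
#' @param threshold displacement threshold as a fraction of thickness.
#' @return list: `fraction` of flagged nodes, `flagged` logical matrix.
#' @export
out_of_plane_check <- function(w, dt_s = 1e-4, thickness_mm = 0.5,
                               threshold = 0.25) {
  stopifnot(dt_s > 0)
  disp_mm <- abs(w) * dt_s * 1000
  flagged <- disp_mm > threshold * thickness_mm
  list(fraction = mean(flagged, na.rm = TRUE), flagged = flagged)
}

#' Write / read a field snapshot as long-format CSV
#'
#' Columns `X_mm, Y_mm, u, v[, w][, p], alpha_deg`; one row per node.
#'
#' @param snapshot a `field_snapshot`.
#' @param path file path.
#' @export
write_field_csv <- function(snapshot, path) {
  X <- rep(snapshot$x, each = length(snapshot$y))
  Y <- rep(snapshot$y, times = length(snapshot$x))
  df <- data.frame(X_mm = X, Y_mm = Y,
                   u = as.vector(snapshot$u), v = as.vector(snapshot$v))
  if (!is.null(snapshot$w)) df$w <- as.vector(snapshot$w)
  if (!is.null(snapshot$p)) df$p <- as.vector(snapshot$p)
  df$alpha_deg <- snapshot$alpha_deg
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  df <- utils::read.csv(path)
  x <- sort(unique(df$X_mm)); y <- sort(unique(df$Y_mm))
  df <- df[order(df$X_mm, df$Y_mm), ]
  shape <- function(col) if (col %in% names(df))
    matrix(df[[col]], length(y), length(x)) else NULL
  structure(list(x = x, y = y, u = shape("u"), v = shape("v"),
                 w = shape("w"), p = shape("p"),
                 alpha_deg = df$alpha_deg[1]),
            class = "field_snapshot")
}
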