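#' Blood-analog viscosity from the linear temperature model
#'
#' `mu(T) = mu0 + C_T * T`, the rheometer-fitted model of the
#' water/glycerol/ammonium-thiocyanate blood analog. The fit is valid
#' over the calibrated 24-31 degC range; evaluation outside it warns.
#'
#' @param T_degC fluid temperature in degrees Celsius.
#' @param mu0 intercept, Pa.s.
#' @param C_T temperature coefficient, Pa.s per degC.
#' @return dynamic viscosity in Pa.s.
#' @examples
#' viscosity(24.3)  # ~0.0039 Pa.s
#' @export
viscosity <- function(T_degC, mu0 = 5.975e-3, C_T = -8.55e-5) {
  if (any(T_degC < 24 | T_degC > 31))
    warning("temperature outside the 24-31 degC calibration range")
  mu <- mu0 + C_T * T_degC
  if (any(mu <= 0)) stop("viscosity model yields a non-positive value")
  mu
}

#' Turbulence boundary-condition estimates for developed pipe flow
#'
#' `I_turb = 0.16 Re^(-1/8)` and `l_turb = 0.07 D_h`, the standard
#' inlet estimates for fully developed turbulent pipe flow.
#'
#' @param Re Reynolds number (> 0).
#' @param D_h hydraulic diameter (any length unit; `l_turb` inherits it).
#' @return list: `I_turb` (dimensionless), `l_turb`.
#' @export
turbulence_bc <- function(Re, D_h) {
  stopifnot(Re > 0, D_h > 0)
  list(I_turb = 0.16 * Re^(-1 / 8), l_turb = 0.07 * D_h)
}

#' Inlet-pipe Reynolds number
#'
#' `Re = rho u D / mu` with the mean pipe velocity `u = Q / (pi D^2/4)`.
#'
#' @param rho density, kg/m^3.
#' @param mu dynamic viscosity, Pa.s.
#' @param Q_Lmin volume flow rate, litres per minute.
#' @param D_mm inner pipe diameter, mm.
#' @return dimensionless Reynolds number.
#' @export
reynolds_inlet <- function(rho, mu, Q_Lmin, D_mm) {
  stopifnot(rho > 0, mu > 0, Q_Lmin > 0, D_mm > 0)
  D <- D_mm / 1000
  Q <- Q_Lmin / 1000 / 60
  u <- Q / (pi * D^2 / 4)
  rho * u * D / mu
}

#' Rotary-pump Reynolds number
#'
#' `Re_pump = rho omega D_rotor^2 / mu` with the angular velocity in
#' rad/s (rpm is converted internally).
#'
#' @param rho density, kg/m^3.
#' @param mu dynamic viscosity, Pa.s.
#' @param rpm rotor speed, revolutions per minute.
#' @param D_rotor_mm rotor diameter, mm.
#' @return dimensionless pump Reynolds number.
#' @export
reynolds_pump <- function(rho, mu, rpm, D_rotor_mm) {
  stopifnot(rho > 0, mu > 0, rpm > 0, D_rotor_mm > 0)
  omega <- rpm * 2 * pi / 60
  rho * omega * (D_rotor_mm / 1000)^2 / mu
}

#' Relative deviation between two scalar readings, in percent
#'
#' `100 * (x - reference) / reference`; the convention used to compare
#' predicted and measured pressure heads.
#'
#' @param x value under assessment.
#' @param reference reference value.
#' @return signed percent deviation.
#' @examples
#' relative_deviation(123.9, 122.4)  # LES head vs measured head: 1.2%
#' @export
relative_deviation <- function(x, reference) {
  stopifnot(reference != 0)
  100 * (x - reference) / reference
}

#' Welch power spectral density of an integral signal
#'
#' Welch's averaged-periodogram estimate with a Hann window, segments
#' of an integer number of rotations (default 4) and 50% overlap. The
#' frequency axis is normalized by the rotation frequency, so
#' blade-passage harmonics sit at integer abscissae. The estimate is
#' scaled so that `sum(psd) * df` equals the signal variance
#' (one-sided, Parseval-consistent).
#'
#' @param signal an `integral_signal` (see [synth_signals()]) or a
#'   numeric vector.
#' @param fs sampling rate in Hz (taken from the signal attribute when
#'   available).
#' @param f_rot rotation frequency in Hz (idem).
#' @param segment_rotations segment length in rotations.
#' @param overlap fractional segment overlap.
#' @return data.frame of class `psd_estimate`: `f_Hz, f_norm, psd`;
#'   attributes `fs`, `f_rot`, `df_Hz`, `n_segments`.
#' @export
psd_welch <- function(signal, fs = NULL, f_rot = NULL,
                      segment_rotations = 4, overlap = 0.5) {
  x <- if (is.data.frame(signal)) signal$value else as.numeric(signal)
  fs <- fs %||% attr(signal, "fs")
  f_rot <- f_rot %||% attr(signal, "f_rot")
  stopifnot(!is.null(fs), !is.null(f_rot), f_rot > 0)
  nseg <- round(segment_rotations * fs / f_rot)
  if (length(x) < nseg)
    stop("signal too short: need at least ", segment_rotations, " rotations")
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq(0, nseg - 1) / (nseg - 1)))  # Hann
  U <- sum(win^2)
  nf <- floor(nseg / 2) + 1
  acc <- rep(0, nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1)]
    seg <- (seg - mean(seg)) * win
    X <- stats::fft(seg)[1:nf]
    acc <- acc + Mod(X)^2
  }
  psd <- acc / (length(starts) * U * fs)
  # one-sided: double all bins except DC (and Nyquist for even nseg)
  psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)]
  if (nseg %% 2 == 1) psd[nf] <- 2 * psd[nf]
  f <- (0:(nf - 1)) * fs / nseg
  out <- data.frame(f_Hz = f, f_norm = f / f_rot, psd = psd)
  attr(out, "fs") <- fs; attr(out, "f_rot") <- f_rot
  attr(out, "df_Hz") <- fs / nseg
  attr(out, "n_segments") <- length(starts)
  class(out) <- c("psd_estimate", "data.frame")
  out
}

#' Detect and classify spectral modes of a pump signal
#'
#' Peaks are local maxima exceeding the local spectral median by a
#' configurable margin (default 10 dB) and are matched to the nearest
#' integer multiple of the rotation frequency (within 2%). Multiples
#' of four are blade-passage harmonics (four main blades, eight with
#' the secondary blades); other integer multiples are rotational
#' harmonics -- the signature of a non-ideal (tilted / precessing)
#' rotation; unmatched peaks are non-harmonic.
#'
#' @param spectrum a [psd_welch()] result.
#' @param f_rot rotation frequency, Hz (from the spectrum attribute by
#'   default).
#' @param margin_dB required prominence over the local median.
#' @param match_tol relative tolerance for harmonic matching.
#' @return data.frame `f_norm, psd, harmonic, class` (one row per
#'   peak; zero rows for a featureless spectrum) with attribute
#'   `non_ideal` -- `TRUE` when any rotational harmonic is present.
#' @export
detect_modes <- function(spectrum, f_rot = NULL, margin_dB = 10,
                         match_tol = 0.02) {
  f_rot <- f_rot %||% attr(spectrum, "f_rot")
  p <- spectrum$psd
  n <- length(p)
  is_peak <- c(FALSE, p[2:(n - 1)] > p[1:(n - 2)] & p[2:(n - 1)] >= p[3:n],
               FALSE)
  # local background: median over a window around the candidate with
  # the candidate's own leakage skirt (+/- 2 bins) excluded
  half_w <- max(8, floor(n / 20))
  local_bg <- function(i) {
    win <- max(1, i - half_w):min(n, i + half_w)
    win <- setdiff(win, (i - 2):(i + 2))
    stats::median(p[win])
  }
  cand <- which(is_peak & spectrum$f_norm > 0.5)
  strong <- vapply(cand, function(i)
    10 * log10(p[i] / max(local_bg(i), .Machine$double.xmin)) > margin_dB,
    logical(1))
  idx <- cand[strong]
  rows <- lapply(idx, function(i) {
    fn <- spectrum$f_norm[i]
    h <- round(fn)
    matched <- h >= 1 && abs(fn - h) <= match_tol * max(h, 1)
    cls <- if (!matched) "non-harmonic"
    else if (h %% 4 == 0) "blade-passage" else "rotational"
    data.frame(f_norm = fn, psd = spectrum$psd[i],
               harmonic = if (matched) h else NA_integer_, class = cls)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(f_norm = numeric(0), psd = numeric(0),
               harmonic = integer(0), class = character(0))
  # merge duplicate detections of the same harmonic (keep strongest)
  if (nrow(out) > 1) {
    keyed <- !is.na(out$harmonic)
    keep <- rep(TRUE, nrow(out))
    for (h in unique(out$harmonic[keyed])) {
      ids <- which(keyed & out$harmonic == h)
      if (length(ids) > 1) keep[ids[-which.max(out$psd[ids])]] <- FALSE
    }
    out <- out[keep, ]
  }
  attr(out, "non_ideal") <- any(out$class == "rotational")
  out
}
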