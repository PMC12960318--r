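# Shared fixtures for the test suite. Everything is generated in code;
# the reference study conditions come from fixture_centrimag_motion().

fx <- fixture_centrimag_motion()

# A channel geometry with strictly vertical bores: markers sit exactly
# above the base points, so many quantities have closed forms.
vertical_geom <- function() {
  channel_geometry(inner_base = c(11.5, 0), inner_slope = c(0, 0),
                   outer_base = c(16.0, 0.8), outer_slope = c(0.001, 0))
}

# Independent rotation-matrix oracle: matrix exponential of the scaled
# skew generator, summed as a plain Taylor series (no Rodrigues form).
expm_rotation <- function(axis, angle_deg) {
  n <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, n[3], -n[2],
                -n[3], 0, n[1],
                n[2], -n[1], 0), 3, 3) * (angle_deg * pi / 180)
  acc <- diag(3); term <- diag(3)
  for (k in 1:40) {
    term <- term %*% K / k
    acc <- acc + term
  }
  acc
}

wrap180 <- function(x) ((x + 180) %% 360) - 180
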