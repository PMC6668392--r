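# Synthetic event-probability curve with hand-computable transitions: the
# shrinkage and loss columns are linear on the segments where they cross
# (piecewise-linear interpolation is exact there) and the splitting column
# is an exact parabola (the three-point quadratic fit recovers its vertex).
synthetic_curve <- function() {
  q <- seq(0.05, 0.95, by = 0.05)
  p_shrink <- c(0.999, 0.998, 0.997, 0.995, 0.992, 0.960, 0.92, 0.86, 0.78,
                0.70, 0.62, 0.56, 0.52, 0.50, 0.49, 0.48, 0.46, 0.44, 0.30)
  p_split <- pmax(0, 0.25 - 2 * (q - 0.57)^2)
  p_loss <- c(0.001, 0.001, 0.002, 0.003, 0.005, 0.01, 0.02, 0.03, 0.05,
              0.08, 0.12, 0.17, 0.23, 0.28, 0.33, 0.37, 0.40, 0.52, 0.75)
  data.frame(q = q, p_loss = p_loss, p_shrink = p_shrink, p_split = p_split)
}
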