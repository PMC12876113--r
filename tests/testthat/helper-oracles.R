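# Independent closed-form least-squares oracle (normal equations), kept free
# of lm() so regression fits can be cross-checked against it.
ols_oracle <- function(x, y, w = rep(1, length(x))) {
  sw <- sum(w)
  xbar <- sum(w * x) / sw
  ybar <- sum(w * y) / sw
  slope <- sum(w * (x - xbar) * (y - ybar)) / sum(w * (x - xbar)^2)
  c(intercept = ybar - slope * xbar, slope = slope)
}

# Brute-force grid search over (intercept, slope) minimising the residual sum
# of squares; used to confirm the analytic fit on tiny instances.
grid_search_fit <- function(x, y, center, half_width, n_grid = 201) {
  slopes <- seq(center[2] - half_width[2], center[2] + half_width[2],
                length.out = n_grid)
  intercepts <- seq(center[1] - half_width[1], center[1] + half_width[1],
                    length.out = n_grid)
  best <- c(NA, NA); best_sse <- Inf
  for (b in intercepts) {
    for (a in slopes) {
      sse <- sum((y - (b + a * x))^2)
      if (sse < best_sse) {
        best_sse <- sse
        best <- c(b, a)
      }
    }
  }
  list(intercept = best[1], slope = best[2],
       res_intercept = diff(intercepts[1:2]), res_slope = diff(slopes[1:2]))
}
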