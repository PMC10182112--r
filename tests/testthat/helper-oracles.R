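# Independent oracles, deliberately naive: used to cross-check the package's
# analytic implementations, never to compute results.

# IoU by rasterization: count cells of a fine grid whose centers fall inside
# each box. Exact for integer-coordinate boxes when step divides 1.
rasterized_iou <- function(a, b, step = 0.5) {
  xs <- seq(min(a$x_min, b$x_min) + step / 2, max(a$x_max, b$x_max), by = step)
  ys <- seq(min(a$y_min, b$y_min) + step / 2, max(a$y_max, b$y_max), by = step)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  in_a <- gx > a$x_min & gx < a$x_max & gy > a$y_min & gy < a$y_max
  in_b <- gx > b$x_min & gx < b$x_max & gy > b$y_min & gy < b$y_max
  sum(in_a & in_b) / sum(in_a | in_b)
}

# Between-class variance by direct two-class statistics at one cut.
brute_between_var <- function(values, t) {
  lo <- values[values <= t]; hi <- values[values > t]
  if (length(lo) == 0 || length(hi) == 0) return(0)
  w0 <- length(lo) / length(values)
  w0 * (1 - w0) * (mean(lo) - mean(hi))^2
}

# Exhaustive-search Otsu threshold over the midpoint candidate set.
brute_otsu <- function(values) {
  u <- sort(unique(values))
  cands <- (u[-1] + u[-length(u)]) / 2
  sb <- vapply(cands, function(t) brute_between_var(values, t), numeric(1))
  cands[which.max(sb)]
}
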