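# Independent oracles used by the tests. These deliberately re-derive the
# quantities by brute force rather than calling the implementation paths
# they check.

# exhaustive between-class-variance scan over all 255 candidate thresholds
brute_otsu <- function(h) {
  levels <- 0:255
  n <- sum(h)
  best_t <- NA_integer_
  best_v <- -Inf
  for (t in 1:255) {
    i0 <- which(levels < t & h > 0)
    i1 <- which(levels >= t & h > 0)
    if (length(i0) == 0L || length(i1) == 0L) next
    w0 <- sum(h[i0]) / n
    w1 <- sum(h[i1]) / n
    mu0 <- sum(h[i0] * levels[i0]) / sum(h[i0])
    mu1 <- sum(h[i1] * levels[i1]) / sum(h[i1])
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best_v) {             # strict: keeps the lowest tied level
      best_v <- v
      best_t <- t
    }
  }
  best_t
}

# random integer histogram with at least two non-empty bins
random_histogram <- function() {
  repeat {
    k <- sample(2:40, 1)
    h <- numeric(256)
    bins <- sample(0:255, k)
    h[bins + 1] <- rpois(k, lambda = sample(1:200, k, replace = TRUE))
    if (sum(h > 0) >= 2) return(h)
  }
}

# brute-force grid scan of the band-intersection criterion for MDC/RDL:
# first concentration on a dense log grid where the curve (or upper band)
# drops to the critical response
grid_scan_limits <- function(fit, level = 0.95, n_grid = 1e6) {
  y_crit <- confidence_band(fit, 0, level = level)$lower
  xs <- 10^seq(log10(1e-3), log10(1e5), length.out = n_grid)
  b <- confidence_band(fit, xs, level = level)
  list(
    MDC = xs[which(b$fit <= y_crit)[1]],
    RDL = xs[which(b$upper <= y_crit)[1]]
  )
}

# wrap a bare RGB array as a strip_image
list2strip <- function(px, id = "test") {
  structure(list(pixels = px, metadata = list(source_id = id)),
            class = "strip_image")
}

# measured (pixel-path) normalized ratio series over the configured
# concentration grid
pixel_ratio_series <- function(cfg, lay, seed_base = cfg$seed) {
  ratios <- vapply(seq_along(cfg$concentrations), function(i) {
    rs <- render_strip(cfg, lay, cfg$concentrations[i],
                       seed = seed_base + i)
    strip_signals(rs$image, lay)$mean
  }, 0)
  normalize_signals(data.frame(concentration = cfg$concentrations,
                               signal = ratios))
}
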