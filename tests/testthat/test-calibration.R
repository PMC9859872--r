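paper_concs <- c(0, 1, 10, 30, 100, 300, 1000, 10000)

noiseless_points <- function(A1 = 1, A2 = 0.1, x0 = 50, p = 1.2,
                             x = paper_concs) {
  data.frame(concentration = x, normalized = fourpl(x, A1, A2, x0, p))
}

test_that("blank normalization divides by the zero-concentration mean", {
  d <- data.frame(concentration = c(0, 0, 10), signal = c(1.8, 2.2, 1.0))
  n <- normalize_signals(d)
  expect_equal(mean(n$normalized[n$concentration == 0]), 1)
  expect_equal(n$normalized[3], 0.5)
  expect_error(normalize_signals(data.frame(concentration = 1, signal = 1)),
               "zero-concentration")
  expect_error(normalize_signals(data.frame(concentration = 0, signal = 0)),
               "degenerate blank")
})

test_that("4PL fit recovers noiseless parameters to high precision", {
  fit <- fit_4pl(noiseless_points())
  truth <- c(A1 = 1, A2 = 0.1, x0 = 50, p = 1.2)
  expect_lt(max(abs(coef(fit) - truth) / truth), 1e-6)
  expect_lt(fit$sigma2, 1e-20)
})

test_that("4PL midpoint identity and monotonicity hold for any parameters", {
  set.seed(21)
  for (i in 1:50) {
    A1 <- runif(1, 0.5, 2); A2 <- runif(1, 0, 0.4)
    x0 <- 10^runif(1, 0, 3); p <- runif(1, 0.5, 3)
    expect_equal(fourpl(x0, A1, A2, x0, p), (A1 + A2) / 2)
    xs <- 10^seq(-2, 5, length.out = 100)
    expect_true(all(diff(fourpl(xs, A1, A2, x0, p)) < 0))
  }
})

test_that("noisy fits centre on the true EC50", {
  set.seed(31)
  truth_x0 <- 50
  x0s <- replicate(200, {
    y <- fourpl(paper_concs, 1, 0.1, truth_x0, 1.2) + rnorm(8, 0, 0.03)
    fit <- try(fit_4pl(data.frame(concentration = paper_concs,
                                  normalized = y)), silent = TRUE)
    if (inherits(fit, "try-error")) NA_real_ else coef(fit)[["x0"]]
  })
  x0s <- x0s[is.finite(x0s)]
  se <- sd(x0s) / sqrt(length(x0s))
  expect_lt(abs(mean(x0s) - truth_x0), 2 * se + 0.02 * truth_x0)
})

test_that("delta-method band collapses without residual scatter", {
  fit <- fit_4pl(noiseless_points())
  b <- confidence_band(fit, c(0, 1, 50, 1000))
  expect_equal(b$lower, b$fit, tolerance = 1e-8)
  expect_equal(b$upper, b$fit, tolerance = 1e-8)

  # level 0 collapses the band regardless of scatter
  set.seed(41)
  noisy <- noiseless_points()
  noisy$normalized <- noisy$normalized + rnorm(8, 0, 0.03)
  fn <- fit_4pl(noisy)
  b0 <- confidence_band(fn, c(0, 50, 500), level = 0)
  expect_equal(b0$lower, b0$fit)
  expect_equal(b0$upper, b0$fit)
})

test_that("delta-method band agrees with a parametric bootstrap", {
  set.seed(51)
  x <- rep(paper_concs, each = 6)
  y <- fourpl(x, 1, 0.1, 50, 1.2) + rnorm(length(x), 0, 0.03)
  fit <- fit_4pl(data.frame(concentration = x, normalized = y))
  grid <- 10^seq(-1, 4, length.out = 25)
  bd <- confidence_band(fit, grid, method = "delta")
  bb <- confidence_band(fit, grid, method = "bootstrap", n_boot = 2000,
                        seed = 52)
  hw <- (bd$upper - bd$lower) / 2
  disagreement <- pmax(abs(bd$upper - bb$upper), abs(bd$lower - bb$lower))
  expect_lt(median(disagreement / hw), 0.10)
})

test_that("detection limits are ordered, solver matches the grid oracle", {
  set.seed(61)
  x <- rep(paper_concs, each = 3)
  y <- fourpl(x, 1, 0.1, 50, 1.2) + rnorm(length(x), 0, 0.03)
  fit <- fit_4pl(data.frame(concentration = x, normalized = y))
  dl <- detection_limits(fit)
  expect_true(dl$MDC <= dl$RDL)
  expect_equal(dl$EC50, unname(coef(fit)[["x0"]]))

  oracle <- grid_scan_limits(fit, n_grid = 1e6)
  expect_lt(abs(dl$MDC - oracle$MDC) / oracle$MDC, 1e-3)
  expect_lt(abs(dl$RDL - oracle$RDL) / oracle$RDL, 1e-3)

  # alternative reading: MDC located on the lower band; the lower band
  # lies below the curve, so it reaches the critical value no later
  dl2 <- detection_limits(fit, rule = "lower-upper")
  expect_lte(dl2$MDC, dl$MDC)
  expect_gt(dl2$MDC, 0)
  expect_equal(dl2$RDL, dl$RDL)
})

test_that("detection limits vanish as residual scatter vanishes", {
  fit <- fit_4pl(noiseless_points())
  dl <- detection_limits(fit)
  expect_lt(dl$MDC, 2e-3)
  expect_lt(dl$RDL, 2e-3)
})

test_that("conjugate comparison aggregates triplicates and ranks noise", {
  mk <- function(x0, sd = 0, seed = 1) {
    set.seed(seed)
    x <- rep(paper_concs, each = 3)
    y <- fourpl(x, 1, 0.1, x0, 1.2) + rnorm(length(x), 0, max(sd, 0))
    fit_4pl(data.frame(concentration = x, normalized = y))
  }
  # identical triplicates: zero SE; known x0 spread: mean 50
  fits <- list(mk(40), mk(50), mk(60), mk(50), mk(50), mk(50))
  lims <- lapply(fits, detection_limits)
  labels <- c("varied", "varied", "varied", "same", "same", "same")
  tab <- compare_conjugates(fits, lims, labels)
  expect_equal(tab$EC50[tab$label == "varied"], 50)
  expect_equal(tab$EC50_se[tab$label == "same"], 0)

  # weak (noisier) conjugate gets the larger MDC
  good <- mk(50, sd = 0.02, seed = 7)
  weak <- mk(50, sd = 0.10, seed = 7)
  lim_g <- detection_limits(good); lim_w <- detection_limits(weak)
  expect_gt(lim_w$MDC, lim_g$MDC)

  expect_error(compare_conjugates(fits[1], lims[1], "a"), ">= 2")
  # mismatched concentration grids draw a comparability warning
  other <- fit_4pl(data.frame(concentration = c(0, 2, 20, 200, 2000),
                              normalized = fourpl(c(0, 2, 20, 200, 2000),
                                                  1, 0.1, 50, 1.2)))
  expect_warning(compare_conjugates(list(fits[[1]], other),
                                    list(lims[[1]], lims[[1]]),
                                    c("a", "b")),
                 "comparability")
})
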