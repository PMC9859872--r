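test_that("green plane extraction validates its input", {
  px <- array(0, dim = c(2, 2, 3))
  px[1, 1, ] <- c(10, 200, 30)
  expect_equal(green_plane(px)[1, 1], 200)
  allg <- array(rep(c(0, 120, 0), each = 4), dim = c(2, 2, 3))
  expect_equal(green_plane(allg), matrix(120, 2, 2))
  expect_error(green_plane(matrix(1, 4, 4)), "format error")
})

test_that("Otsu threshold matches the contract on bimodal and degenerate input", {
  h <- numeric(256)
  h[10 + 1] <- 50
  h[200 + 1] <- 50
  expect_identical(otsu_threshold(h), 11L)   # lowest level on the tie plateau
  h1 <- numeric(256); h1[100] <- 10
  expect_error(otsu_threshold(h1), "degenerate")
})

test_that("Otsu threshold equals the exhaustive brute-force scan", {
  set.seed(11)
  for (i in 1:1000) {
    h <- random_histogram()
    expect_identical(otsu_threshold(h), brute_otsu(h))
  }
})

test_that("illumination correction removes planar gradients and is idempotent", {
  lay <- strip_layout()
  flat <- matrix(150, lay$height, lay$width)
  expect_equal(correct_illumination(flat, lay$reference_points), flat)

  # injected multiplicative planar gradient of known slope
  H <- lay$height; W <- lay$width
  grad <- 1 + 0.1 * outer((seq_len(H) - H / 2) / H,
                          (seq_len(W) - W / 2) / W, `+`)
  corr <- correct_illumination(flat * grad, lay$reference_points)
  # residual slope across the image < 1% of the injected slope
  injected_range <- diff(range(150 * grad))
  expect_lt(diff(range(corr)), 0.01 * injected_range)

  # idempotence on its own output
  corr2 <- correct_illumination(corr, lay$reference_points)
  expect_equal(corr2, corr, tolerance = 1e-10)

  expect_error(correct_illumination(flat, lay$reference_points[1:2, ]),
               ">= 3 reference points")
  coll <- cbind(c(10, 20, 30), c(10, 20, 30))
  expect_error(correct_illumination(flat, coll), "collinear")
})

test_that("gradient-corrupted strips quantify like gradient-free ones", {
  lay <- strip_layout()
  cfg0 <- simulation_config(noise_sd = 0, gradient_amplitude = 0)
  cfg1 <- simulation_config(noise_sd = 0, gradient_amplitude = 0.15)
  s0 <- strip_signals(render_strip(cfg0, lay, 30)$image, lay)
  s1 <- strip_signals(render_strip(cfg1, lay, 30)$image, lay)
  expect_equal(s1$channels$signal, s0$channels$signal, tolerance = 0.02)
})

test_that("zone quantification recovers exact means and flags blanks", {
  plane <- matrix(150, 60, 60)
  plane[20:30, 20:30] <- 100                  # spot block
  zone <- c(15, 35, 15, 35)
  ref <- c(40, 55, 15, 35)
  q <- quantify_zone(plane, zone, ref)
  expect_equal(q$spot_mean, 100)
  expect_equal(q$reference_mean, 150)
  expect_equal(q$signal, 50)
  expect_false(q$negative)

  # signal is a difference: invariant under a constant offset
  q2 <- quantify_zone(plane + 25, zone, ref)
  expect_equal(q2$signal, q$signal)

  blank <- matrix(150, 60, 60)
  expect_error(quantify_zone(blank, zone, ref), "no spot")
  qb <- quantify_zone(blank, zone, ref, on_blank = "zero")
  expect_true(qb$blank)
  expect_equal(qb$signal, 0)
})

test_that("fiducial matching recovers the global offset deterministically", {
  cfg <- simulation_config(noise_sd = 0)
  lay <- strip_layout()
  img <- render_strip(cfg, lay, 0)$image

  d0 <- detect_zones(img, lay)
  expect_equal(attr(d0, "offset"), c(0, 0))
  expect_identical(d0$zones, lay$zones)

  # translate the content by (+5, -3) px and recover the shift
  px <- img$pixels
  H <- dim(px)[1]; W <- dim(px)[2]
  shifted <- array(cfg$background_green, dim = dim(px))
  shifted[, , 1] <- 205; shifted[, , 3] <- 160
  shifted[(1 + 5):H, 1:(W - 3), ] <- px[1:(H - 5), (1 + 3):W, ]
  dd <- detect_zones(list2strip(shifted), lay)
  expect_equal(attr(dd, "offset"), c(5, -3))

  # masked fiducials: detection must fail loudly
  masked <- px
  for (k in 1:3) {
    pl <- masked[, , k]
    pl[lay$barrier_idx] <- c(205, cfg$background_green, 160)[k]
    masked[, , k] <- pl
  }
  expect_error(detect_zones(list2strip(masked), lay), "fiducial")
})

test_that("whole-strip evaluation reproduces ground truth within 0.5 units", {
  lay <- strip_layout()
  cfg <- simulation_config(noise_sd = 0)
  for (conc in c(0, 30, 1000)) {
    rs <- render_strip(cfg, lay, conc)
    ss <- strip_signals(rs$image, lay)
    tr <- rs$truth
    want <- tr$signal[match(paste(ss$channels$channel, ss$channels$role),
                            paste(tr$channel, tr$role))]
    expect_lt(max(abs(ss$channels$signal - want)), 0.5)
    # four identical noiseless channels: zero spread in the ratios
    expect_equal(ss$sd, 0)
    expect_equal(ss$mean, tr$ratio[1], tolerance = 1e-6)
  }
})

test_that("noisy strip ratios stay within sampling error of the truth", {
  lay <- strip_layout()
  cfg <- simulation_config(noise_sd = 2)
  rs <- lapply(1:10, function(i)
    render_strip(cfg, lay, 30, seed = 400L + i))
  means <- vapply(rs, function(r) strip_signals(r$image, lay)$mean, 0)
  truth <- rs[[1]]$truth$ratio[1]
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - truth), 3 * se + 0.005)
})
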