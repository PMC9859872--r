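#' Simulation configuration for synthetic strip images
#'
#' Collects the ground-truth dose-response and imaging conditions for the
#' synthetic strip generator. The true response is a four-parameter
#' logistic on the test/control signal ratio, decreasing with analyte
#' concentration as expected for a competitive (binding-inhibition) assay.
#'
#' Defaults are the study conditions emulated throughout the package:
#' eight calibrator concentrations 0, 1, 10, 30, 100, 300, 1000 and
#' 10000 ug/l, triplicate strips, a normalized response running from
#' A1 = 1 down to A2 = 0.1 with inflection x0 = 50 ug/l and slope
#' p = 1.2, and 2 intensity units of additive Gaussian pixel noise
#' (a plausible shot/readout level for an 8-bit consumer camera frame).
#'
#' @param A1,A2,x0,p true four-parameter-logistic parameters of the
#'   test/control ratio (upper asymptote, lower asymptote, inflection in
#'   ug/l, slope exponent); `p` must be > 0 and `x0` > 0.
#' @param concentrations calibrator concentrations, ug/l; must be >= 0 and
#'   include 0 (the blank used for normalization).
#' @param n_strips strips (replicates) per concentration.
#' @param noise_sd additive Gaussian pixel noise SD, 8-bit intensity units.
#' @param gradient_amplitude peak-to-centre relative amplitude of a planar
#'   multiplicative illumination gradient (0 = flat illumination).
#' @param background_green green-channel background intensity of the bare
#'   membrane (8-bit units).
#' @param control_amplitude green-channel depletion at the control-spot
#'   core for a fully developed spot (8-bit units).
#' @param control_mode `"constant"` (control signal independent of analyte)
#'   or `"increasing"` (control signal rises mildly with concentration, as
#'   unbound conjugate carries through to the control line).
#' @param edge_sigma Gaussian edge-softening scale of rendered spots, px.
#' @param seed integer seed; all generators are bit-reproducible under it.
#'
#' @return Object of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(noise_sd = 0)
#' cfg$concentrations
#' @export
simulation_config <- function(A1 = 1, A2 = 0.1, x0 = 50, p = 1.2,
                              concentrations = c(0, 1, 10, 30, 100, 300,
                                                 1000, 10000),
                              n_strips = 3L,
                              noise_sd = 2,
                              gradient_amplitude = 0,
                              background_green = 175,
                              control_amplitude = 60,
                              control_mode = c("constant", "increasing"),
                              edge_sigma = 0.3,
                              seed = 0L) {
  control_mode <- match.arg(control_mode)
  if (!is.numeric(p) || p <= 0) stop("'p' must be > 0")
  if (!is.numeric(x0) || x0 <= 0) stop("'x0' must be > 0")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (!any(concentrations == 0))
    stop("concentrations must include 0 (the normalization blank)")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  structure(list(
    A1 = A1, A2 = A2, x0 = x0, p = p,
    concentrations = sort(unique(concentrations)),
    n_strips = as.integer(n_strips),
    noise_sd = noise_sd,
    gradient_amplitude = gradient_amplitude,
    background_green = background_green,
    control_amplitude = control_amplitude,
    control_mode = control_mode,
    edge_sigma = edge_sigma,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# run code with the global RNG state saved/restored, seeded deterministically
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# true control/test green-channel depletion amplitudes at a concentration
true_amplitudes <- function(config, concentration) {
  y <- fourpl(concentration, config$A1, config$A2, config$x0, config$p)
  amp_control <- switch(config$control_mode,
    constant   = config$control_amplitude,
    increasing = config$control_amplitude *
      (1 + 0.08 * log10(1 + concentration / config$x0))
  )
  list(test = amp_control * y, control = amp_control, ratio = y)
}

#' Render a synthetic strip image with ground truth
#'
#' Draws an 8-bit-range RGB raster of a multi-channel LFA strip at one
#' analyte concentration: ablated barrier fiducials, a red control spot
#' per channel, a red test spot whose green-channel depletion follows the
#' configured four-parameter logistic, an optional planar multiplicative
#' illumination gradient, and additive Gaussian pixel noise. Red colorant
#' absorbs green light, so spots are rendered as green-channel depletion;
#' spot edges are softened with a Gaussian profile.
#'
#' Pixel values are kept as floating point within `[0, 255]`; they are
#' quantized to 8 bits only when written with [write_strip_png()].
#'
#' @param config a [simulation_config()].
#' @param layout a [strip_layout()].
#' @param concentration analyte concentration, ug/l.
#' @param strip_id identifier stored in the image metadata.
#' @param seed seed for this render (default derived from `config$seed`).
#'
#' @return A list with class `strip_render`: `image` (a `strip_image`),
#'   `truth` (data frame of noise-free, gradient-free zone means and
#'   signals per channel and role, plus the true test/control ratio) and
#'   `concentration`.
#' @examples
#' rs <- render_strip(simulation_config(noise_sd = 0), strip_layout(), 30)
#' subset(rs$truth, role == "test")
#' @export
render_strip <- function(config, layout, concentration,
                         strip_id = "strip", seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(layout, "strip_layout"))
  if (concentration < 0) stop("'concentration' must be >= 0")
  for (z in layout$zones)
    for (b in z[c("reference", "test", "control")])
      if (!box_in_bounds(b, layout$height, layout$width))
        stop("layout error: zone box exceeds image bounds")

  H <- layout$height; W <- layout$width
  base <- c(205, config$background_green, 160)  # membrane white-ish, R>G>B
  img <- array(rep(base, each = H * W), dim = c(H, W, 3L))

  # fiducials: dark ablated barriers
  dark <- c(70, 60, 55)
  for (k in 1:3) {
    plane <- img[, , k]
    plane[layout$barrier_idx] <- dark[k]
    img[, , k] <- plane
  }

  amps <- true_amplitudes(config, concentration)
  truth <- data.frame()
  for (ch in seq_len(layout$n_channels)) {
    z <- layout$zones[[ch]]
    img <- draw_spot(img, z$test, layout$spot_radius, config$edge_sigma,
                     amps$test)
    img <- draw_spot(img, z$control, layout$spot_radius, config$edge_sigma,
                     amps$control)
    g0 <- config$background_green
    truth <- rbind(truth, data.frame(
      channel = ch,
      role = c("reference", "test", "control"),
      spot_mean = c(g0, g0 - amps$test, g0 - amps$control),
      reference_mean = g0,
      signal = c(0, amps$test, amps$control),
      ratio = amps$test / amps$control
    ))
  }

  # planar multiplicative illumination gradient, unit mean at image centre
  if (config$gradient_amplitude != 0) {
    a <- config$gradient_amplitude
    rr <- (seq_len(H) - (H + 1) / 2) / H
    cc <- (seq_len(W) - (W + 1) / 2) / W
    plane <- 1 + a * outer(rr, cc, function(r, c) r + c)
    for (k in 1:3) img[, , k] <- img[, , k] * plane
  }

  if (config$noise_sd > 0) {
    img <- with_seed(seed, img + array(stats::rnorm(length(img), 0,
                                                    config$noise_sd),
                                       dim = dim(img)))
  }
  img[img < 0] <- 0; img[img > 255] <- 255

  image <- structure(list(
    pixels = img,
    metadata = list(source_id = strip_id, concentration = concentration,
                    seed = seed)
  ), class = "strip_image")
  structure(list(image = image, truth = truth, concentration = concentration),
            class = "strip_render")
}

# subtract a softened circular depletion of given amplitude from the green
# plane (and a 20% echo from blue) centred in a zone box
draw_spot <- function(img, box, radius, edge_sigma, amplitude) {
  if (amplitude <= 0) return(img)
  rows <- box_rows(box); cols <- box_cols(box)
  rc <- (box[1L] + box[2L]) / 2; cc <- (box[3L] + box[4L]) / 2
  d <- sqrt(outer((rows - rc)^2, (cols - cc)^2, `+`))
  g <- ifelse(d <= radius, 1,
              if (edge_sigma > 0) exp(-(d - radius)^2 / (2 * edge_sigma^2))
              else 0)
  img[rows, cols, 2L] <- img[rows, cols, 2L] - amplitude * g
  img[rows, cols, 3L] <- img[rows, cols, 3L] - 0.2 * amplitude * g
  img
}

#' @export
print.strip_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("strip_image %d x %d px RGB (id: %s)\n", d[1L], d[2L],
              x$metadata$source_id))
  invisible(x)
}

#' Synthetic localized-surface-plasmon-resonance spectrum
#'
#' Generates a Lorentzian absorbance profile on the 1-nm acquisition grid
#' (450-700 nm), emulating the plasmon band of gold nanoparticles (~522 nm
#' for bare 20-nm particles; red-shifted and broadened after protein
#' coating).
#'
#' @param peak_nm peak wavelength, nm; must lie in the 450-700 nm window.
#' @param width_nm full width at half maximum, nm; must be > 0.
#' @param od_peak absorbance at the maximum, OD units; must be >= 0
#'   (0 yields the all-zero spectrum).
#'
#' @return Data frame with columns `wavelength_nm` (450:700) and
#'   `absorbance`, class `lfa_spectrum`.
#' @examples
#' sp <- synth_spectrum(522, 60, 1.0)
#' lambda_max(sp)
#' @export
synth_spectrum <- function(peak_nm, width_nm, od_peak) {
  if (peak_nm < 450 || peak_nm > 700)
    stop("'peak_nm' must lie within the 450-700 nm acquisition window")
  if (!is.numeric(width_nm) || width_nm <= 0) stop("'width_nm' must be > 0")
  if (!is.numeric(od_peak) || od_peak < 0) stop("'od_peak' must be >= 0")
  wl <- 450:700
  gamma <- width_nm / 2
  ab <- od_peak * gamma^2 / ((wl - peak_nm)^2 + gamma^2)
  structure(data.frame(wavelength_nm = wl, absorbance = ab),
            class = c("lfa_spectrum", "data.frame"))
}

#' Synthetic number-weighted particle size distribution
#'
#' Draws a lognormal number-weighted sample of hydrodynamic diameters with
#' the requested mean and spread and bins it into a monomodal size
#' distribution, emulating a DLS number distribution.
#'
#' @param mean_nm number-mean diameter, nm; must be > 0.
#' @param sd_nm spread (SD) of the diameters, nm; must be >= 0. `0` puts
#'   all mass into the single bin containing `mean_nm`.
#' @param n number of draws.
#' @param seed integer seed (bit-reproducible output).
#' @param bin_width histogram bin width, nm.
#'
#' @return Data frame with columns `diameter_nm` (bin centres) and
#'   `weight` (number fractions summing to 1), class `size_distribution`.
#' @examples
#' d <- synth_size_distribution(22, 3, n = 1e4, seed = 1)
#' number_mean_diameter(d)
#' @export
synth_size_distribution <- function(mean_nm, sd_nm, n = 1e5L, seed = 0L,
                                    bin_width = 0.5) {
  if (!is.numeric(mean_nm) || mean_nm <= 0) stop("'mean_nm' must be > 0")
  if (!is.numeric(sd_nm) || sd_nm < 0) stop("'sd_nm' must be >= 0")
  if (sd_nm == 0) {
    centre <- (floor(mean_nm / bin_width) + 0.5) * bin_width
    out <- data.frame(diameter_nm = centre, weight = 1)
    return(structure(out, class = c("size_distribution", "data.frame")))
  }
  sdlog <- sqrt(log1p((sd_nm / mean_nm)^2))
  meanlog <- log(mean_nm) - sdlog^2 / 2
  draws <- with_seed(seed, stats::rlnorm(n, meanlog, sdlog))
  breaks <- seq(floor(min(draws) / bin_width) * bin_width,
                ceiling(max(draws) / bin_width) * bin_width, by = bin_width)
  counts <- graphics::hist(draws, breaks = breaks, plot = FALSE)
  out <- data.frame(diameter_nm = counts$mids, weight = counts$counts / n)
  structure(out, class = c("size_distribution", "data.frame"))
}

#' Simulate normalized calibration signals at the signal level
#'
#' Bypasses the raster pipeline and draws normalized test/control ratios
#' directly: true four-parameter-logistic response plus i.i.d. Gaussian
#' noise on the normalized-signal scale. Used for Monte-Carlo studies of
#' the calibration stage (coverage, detection-limit behaviour vs noise).
#'
#' @param config a [simulation_config()]; supplies the true curve and the
#'   concentration grid.
#' @param sd noise SD on the normalized-signal scale.
#' @param n_rep replicates per concentration.
#' @param seed integer seed.
#' @param noise optional pre-drawn standard-normal matrix
#'   (`length(concentrations) x n_rep`) scaled by `sd`; lets a noise
#'   ladder share common random numbers.
#'
#' @return Data frame with columns `concentration` and `signal`.
#' @export
simulate_normalized_signals <- function(config, sd = 0.03, n_rep = 1L,
                                        seed = config$seed, noise = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  x <- config$concentrations
  mu <- fourpl(x, config$A1, config$A2, config$x0, config$p)
  if (is.null(noise)) {
    noise <- with_seed(seed,
      matrix(stats::rnorm(length(x) * n_rep), length(x), n_rep))
  }
  stopifnot(nrow(noise) == length(x))
  data.frame(
    concentration = rep(x, times = ncol(noise)),
    signal = as.vector(mu + sd * noise)
  )
}
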