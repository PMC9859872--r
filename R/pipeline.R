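#' Run the simulate - quantify - calibrate pipeline end to end
#'
#' Renders strips for every batch and calibrator concentration, extracts
#' per-channel test/control signals from the rasters, fits one 4PL
#' calibration per batch on the blank-normalized strip-mean ratios, and
#' derives detection limits. All randomness is controlled by the single
#' seed in the configuration (each strip uses a seed derived from it), so
#' a fixed configuration reproduces its outputs bit-identically.
#'
#' @param config a list (or path to a YAML file) with elements
#'   `simulation` (a [simulation_config()] or argument list for one),
#'   `layout` (a [strip_layout()], argument list, or path to a layout
#'   JSON), `batches` (number of calibration batches, default 3),
#'   `level` (confidence level, default 0.95), `mode` (`"ratio"`,
#'   the test/control evaluation, or `"test"`, plain test-signal mode)
#'   and optional `out_dir` to write artifacts (signals.csv, fit JSON,
#'   curve CSV, manifest.json).
#' @param seed overrides `config$simulation$seed` when given.
#' @return List of class `lfa_run`: `signals` (per strip/channel data
#'   frame), `calibrations` (per batch: `fit`, `limits`, `points`),
#'   `manifest`.
#' @export
run_pipeline <- function(config, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  sim <- config$simulation
  if (is.null(sim)) sim <- simulation_config()
  if (!inherits(sim, "simulation_config"))
    sim <- do.call(simulation_config, sim)
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  lay <- config$layout
  if (is.null(lay)) lay <- strip_layout()
  if (is.character(lay)) {
    if (!file.exists(lay)) stop("layout file not found: ", lay)
    lay <- do.call(strip_layout, jsonlite::read_json(lay, simplifyVector = TRUE))
  }
  if (!inherits(lay, "strip_layout")) lay <- do.call(strip_layout, lay)
  batches <- if (is.null(config$batches)) 3L else as.integer(config$batches)
  level <- if (is.null(config$level)) 0.95 else config$level
  mode <- if (is.null(config$mode)) "ratio" else
    match.arg(config$mode, c("ratio", "test"))

  # stage 1+2: simulate and quantify
  signals <- data.frame()
  k <- 0L
  for (b in seq_len(batches)) {
    for (conc in sim$concentrations) {
      k <- k + 1L
      sid <- sprintf("b%02d_c%g", b, conc)
      rs <- render_strip(sim, lay, conc, strip_id = sid,
                         seed = (sim$seed + k) %% .Machine$integer.max)
      ss <- tryCatch(strip_signals(rs$image, lay),
                     error = function(e)
                       stop("stage 'quantify' failed on strip ", sid, ": ",
                            conditionMessage(e)))
      ch <- ss$channels[ss$channels$role == "test", ]
      ctrl <- ss$channels[ss$channels$role == "control", ]
      signals <- rbind(signals, data.frame(
        strip_id = sid, batch = b, concentration = conc,
        channel = ch$channel,
        test_signal = ch$signal,
        control_signal = ctrl$signal[match(ch$channel, ctrl$channel)],
        ratio = ch$ratio
      ))
    }
  }

  # stage 3: per batch, strip-level mean -> normalize -> fit -> limits
  calibrations <- lapply(seq_len(batches), function(b) {
    sb <- signals[signals$batch == b, ]
    value <- if (mode == "ratio") "ratio" else "test_signal"
    per_strip <- stats::aggregate(sb[[value]],
                                  by = list(concentration = sb$concentration),
                                  FUN = mean)
    names(per_strip)[2L] <- "signal"
    pts <- normalize_signals(per_strip, value = "signal")
    fit <- fit_4pl(pts, value = "normalized")
    limits <- detection_limits(fit, level = level)
    list(batch = b, points = pts, fit = fit, limits = limits)
  })

  manifest <- list(
    package = "lfaquant",
    version = as.character(utils::packageVersion("lfaquant")),
    seed = sim$seed, batches = batches, level = level, mode = mode,
    concentrations = sim$concentrations,
    truth = list(A1 = sim$A1, A2 = sim$A2, x0 = sim$x0, p = sim$p),
    noise_sd = sim$noise_sd
  )

  out <- structure(list(signals = signals, calibrations = calibrations,
                        manifest = manifest), class = "lfa_run")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    sig_path <- file.path(config$out_dir, "signals.csv")
    utils::write.csv(signals, sig_path, row.names = FALSE)
    for (cal in calibrations) {
      jsonlite::write_json(list(
        batch = cal$batch, par = as.list(cal$fit$par),
        cov = cal$fit$cov, sigma2 = cal$fit$sigma2,
        EC50 = cal$limits$EC50, MDC = cal$limits$MDC, RDL = cal$limits$RDL
      ), file.path(config$out_dir, sprintf("fit_batch%02d.json", cal$batch)),
      auto_unbox = TRUE, digits = NA)
      grid <- 10^seq(-1, 4.5, length.out = 200)
      band <- confidence_band(cal$fit, grid, level = level)
      utils::write.csv(band,
        file.path(config$out_dir, sprintf("curve_batch%02d.csv", cal$batch)),
        row.names = FALSE)
    }
    manifest$checksums <- as.list(tools::md5sum(
      list.files(config$out_dir, full.names = TRUE, pattern = "\\.(csv|json)$")))
    names(manifest$checksums) <- basename(names(manifest$checksums))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$manifest <- manifest
  }
  out
}

#' @export
print.lfa_run <- function(x, ...) {
  cat(sprintf("LFA pipeline run: %d batches, %d strips quantified\n",
              length(x$calibrations),
              length(unique(x$signals$strip_id))))
  for (cal in x$calibrations)
    cat(sprintf("  batch %d: EC50 %.3g, MDC %.3g, RDL %.3g ug/l\n",
                cal$batch, cal$limits$EC50, cal$limits$MDC, cal$limits$RDL))
  invisible(x)
}

#' Merge calibration and characterization results into one report table
#'
#' One row per conjugate label combining the calibration figures of merit
#' (EC50, MDC, RDL) with the characterization quantities (synthesis
#' yield, plasmon peak shift, hydrodynamic diameter) where supplied.
#'
#' @param calibrations named list (one element per conjugate label) of
#'   lists with `fit` and `limits` entries, or of `lfa_run` calibration
#'   entries; at least one element, unique labels.
#' @param characterizations optional named list per label of lists with
#'   any of `yield`, `shift_nm`, `diameter_nm`.
#' @return Data frame with one row per label.
#' @export
make_report <- function(calibrations, characterizations = NULL) {
  if (length(calibrations) == 0L) stop("empty input: no calibrations")
  labels <- names(calibrations)
  if (is.null(labels) || any(labels == ""))
    stop("calibrations must be a named list (conjugate labels)")
  if (anyDuplicated(labels))
    stop("merge error: duplicate labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  rows <- lapply(labels, function(lb) {
    cal <- calibrations[[lb]]
    ch <- characterizations[[lb]]
    data.frame(
      label = lb,
      EC50 = cal$limits$EC50, MDC = cal$limits$MDC, RDL = cal$limits$RDL,
      yield = if (!is.null(ch$yield)) ch$yield else NA_real_,
      shift_nm = if (!is.null(ch$shift_nm)) ch$shift_nm else NA_real_,
      diameter_nm = if (!is.null(ch$diameter_nm)) ch$diameter_nm else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
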