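#' Extract the green colour plane of a strip image
#'
#' All downstream signal extraction works on the green channel only: the
#' colloidal-gold spots are red, and a red colorant absorbs green light,
#' so the green plane carries the strongest depletion contrast.
#'
#' @param image a `strip_image` (see [render_strip()], [read_strip_png()])
#'   or a bare H x W x 3 numeric array.
#' @return H x W numeric matrix of green intensities.
#' @export
green_plane <- function(image) {
  px <- if (inherits(image, "strip_image")) image$pixels else image
  if (!is.array(px) || length(dim(px)) != 3L || dim(px)[3L] != 3L)
    stop("format error: expected an RGB image with three colour planes")
  px[, , 2L]
}

#' Otsu threshold of a 256-bin intensity histogram
#'
#' Returns the threshold level `t` in 1..255 that maximizes the
#' between-class variance `w0*w1*(mu0-mu1)^2` of the split into levels
#' `< t` (class 0, here the dark spot pixels) and levels `>= t` (class 1,
#' background). Ties are broken towards the lowest level.
#'
#' @param histogram numeric vector of 256 counts for levels 0..255.
#' @return Integer threshold level in 1..255.
#' @examples
#' h <- numeric(256); h[10 + 1] <- 50; h[200 + 1] <- 50
#' otsu_threshold(h)  # 11: lowest level separating the two classes
#' @export
otsu_threshold <- function(histogram) {
  if (length(histogram) != 256L || any(histogram < 0))
    stop("'histogram' must be 256 non-negative counts")
  if (sum(histogram > 0) < 2L)
    stop("degenerate input: histogram needs >= 2 non-empty bins")
  levels <- 0:255
  n <- sum(histogram)
  w0 <- cumsum(histogram)                    # counts at levels <= k
  s0 <- cumsum(histogram * levels)
  total <- s0[256L]
  # candidate thresholds t = 1..255: class0 = levels < t = levels <= t-1
  w0t <- w0[1:255]
  s0t <- s0[1:255]
  w1t <- n - w0t
  valid <- w0t > 0 & w1t > 0
  mu0 <- s0t / w0t
  mu1 <- (total - s0t) / w1t
  bcv <- ifelse(valid, (w0t / n) * (w1t / n) * (mu0 - mu1)^2, -Inf)
  as.integer(which.max(bcv))                 # first maximum = lowest level
}

#' Planar illumination correction from background reference points
#'
#' Fits a first-order (planar) surface to the intensities at a set of
#' background reference points and divides it out, rescaling so that the
#' mean reference intensity is preserved. This removes global and local
#' linear illumination variation; a flat field is returned unchanged, and
#' the operation is idempotent up to numerical tolerance.
#'
#' @param plane H x W numeric intensity matrix (e.g. from [green_plane()]).
#' @param reference_points m x 2 integer matrix of (row, col) background
#'   coordinates; at least 3 non-collinear points are required.
#' @return Corrected H x W matrix.
#' @export
correct_illumination <- function(plane, reference_points) {
  if (!is.matrix(plane)) stop("'plane' must be a matrix")
  rp <- as.matrix(reference_points)
  if (nrow(rp) < 3L)
    stop("correction error: need >= 3 reference points")
  if (any(rp[, 1L] < 1L | rp[, 1L] > nrow(plane) |
          rp[, 2L] < 1L | rp[, 2L] > ncol(plane)))
    stop("correction error: reference point outside the image")
  X <- cbind(1, rp[, 1L], rp[, 2L])
  if (qr(X)$rank < 3L)
    stop("correction error: reference points are collinear")
  v <- plane[rp]
  beta <- qr.coef(qr(X), v)
  fitted <- outer(seq_len(nrow(plane)) * beta[2L],
                  seq_len(ncol(plane)) * beta[3L], `+`) + beta[1L]
  if (any(fitted <= 0))
    stop("correction error: fitted illumination surface is non-positive")
  plane / fitted * mean(v)
}

#' Locate zone boxes by matching the ablated-barrier fiducials
#'
#' Estimates a global integer pixel offset between the nominal layout and
#' the image by sliding the layout's barrier-pixel mask over the (dark)
#' barrier structures and minimizing the mean green intensity under the
#' mask. The search is exhaustive over `[-search, search]^2`, hence fully
#' deterministic; ties are resolved by scan order (row-major, smallest
#' offset first).
#'
#' @param image a `strip_image` or RGB array.
#' @param layout the nominal [strip_layout()].
#' @param search maximum absolute offset searched, px.
#' @param min_contrast minimum required contrast (median background minus
#'   mean intensity under the matched mask, intensity units) for the
#'   fiducials to count as found.
#' @return The layout shifted onto the image, with attribute `offset`
#'   (`c(dr, dc)`) and `contrast`.
#' @export
detect_zones <- function(image, layout, search = 8L, min_contrast = 15) {
  g <- green_plane(image)
  idx <- layout$barrier_idx
  H <- nrow(g); W <- ncol(g)
  offsets <- expand.grid(dr = -search:search, dc = -search:search)
  best <- NULL; best_score <- Inf
  for (i in seq_len(nrow(offsets))) {
    dr <- offsets$dr[i]; dc <- offsets$dc[i]
    r <- idx[, 1L] + dr; c <- idx[, 2L] + dc
    ok <- r >= 1L & r <= H & c >= 1L & c <= W
    if (mean(ok) < 0.9) next
    score <- mean(g[cbind(r[ok], c[ok])])
    if (score < best_score - 1e-12) {
      best_score <- score
      best <- c(dr, dc)
    }
  }
  bg <- stats::median(g)
  if (is.null(best) || (bg - best_score) < min_contrast)
    stop("detection error: channel-barrier fiducials not found in image")
  out <- shift_layout(layout, best)
  attr(out, "offset") <- best
  attr(out, "contrast") <- bg - best_score
  out
}

#' Quantify one zone: Otsu segmentation and reference-corrected signal
#'
#' Segments the zone box into spot (low-green class) and background with
#' an Otsu threshold computed on the 256-bin histogram of the zone box
#' only, then reports `signal = mean(reference box) - mean(spot pixels)`.
#' Because the signal is a difference, it is invariant under addition of
#' a constant to the whole plane.
#'
#' @param plane 2-D intensity matrix (usually illumination-corrected green).
#' @param zone_box,reference_box boxes `c(r0, r1, c0, c1)` within the plane;
#'   the reference box is the blank membrane band directly in front of the
#'   spot (between sample pad and spot).
#' @param on_blank what to do when the zone has no segmentable structure
#'   (single-valued histogram): `"error"` (default) or `"zero"` to return
#'   a zero-signal quantification flagged with `blank = TRUE`.
#' @return A list of class `zone_quant`: `spot_mean`, `reference_mean`,
#'   `signal`, `n_spot`, `threshold`, `blank`, `negative` (flag for
#'   signals below zero).
#' @export
quantify_zone <- function(plane, zone_box, reference_box,
                          on_blank = c("error", "zero")) {
  on_blank <- match.arg(on_blank)
  if (!box_in_bounds(zone_box, nrow(plane), ncol(plane)) ||
      !box_in_bounds(reference_box, nrow(plane), ncol(plane)))
    stop("quantification error: box outside the plane")
  zone <- plane[box_rows(zone_box), box_cols(zone_box)]
  ref_mean <- mean(plane[box_rows(reference_box), box_cols(reference_box)])
  lev <- floor(pmin(pmax(zone, 0), 255))
  h <- tabulate(as.vector(lev) + 1L, nbins = 256L)
  if (sum(h > 0) < 2L) {
    if (on_blank == "zero") {
      return(structure(list(spot_mean = ref_mean, reference_mean = ref_mean,
                            signal = 0, n_spot = 0L, threshold = NA_integer_,
                            blank = TRUE, negative = FALSE),
                       class = "zone_quant"))
    }
    stop("quantification error: no spot (zone is single-valued)")
  }
  t <- otsu_threshold(h)
  spot <- zone[lev < t]
  if (length(spot) == 0L)
    stop("quantification error: no spot (empty low-intensity class)")
  signal <- ref_mean - mean(spot)
  structure(list(spot_mean = mean(spot), reference_mean = ref_mean,
                 signal = signal, n_spot = length(spot),
                 threshold = t, blank = FALSE, negative = signal < 0),
            class = "zone_quant")
}

#' Per-channel test/control signals of one strip
#'
#' Runs the full single-image evaluation chain: fiducial-based zone
#' localization, green-channel extraction, planar illumination correction
#' from the layout's background reference points, Otsu quantification of
#' the test and control spots of every channel (each against the blank
#' band directly in front of it), the per-channel test/control ratio, and
#' the across-channel mean and sample SD of the ratios.
#'
#' @param image a `strip_image` or RGB array.
#' @param layout nominal [strip_layout()].
#' @param detect locate zones via [detect_zones()] first (default TRUE);
#'   set FALSE to trust the layout as-is.
#' @param correct apply [correct_illumination()] (default TRUE).
#' @param on_blank passed to [quantify_zone()].
#' @return List of class `strip_signals`: `channels` (data frame with one
#'   row per channel and role: spot_mean, reference_mean, signal, plus the
#'   per-channel `ratio`), `ratios`, `mean`, `sd` (sample SD over
#'   channels), `failed` (character vector of failed channels, normally
#'   empty), `offset`.
#' @export
strip_signals <- function(image, layout, detect = TRUE, correct = TRUE,
                          on_blank = "error") {
  lay <- if (detect) detect_zones(image, layout) else layout
  offset <- attr(lay, "offset")
  plane <- green_plane(image)
  if (correct)
    plane <- correct_illumination(plane, lay$reference_points)
  rows <- data.frame(); ratios <- rep(NA_real_, lay$n_channels)
  failed <- character(0)
  for (ch in seq_len(lay$n_channels)) {
    z <- lay$zones[[ch]]
    res <- tryCatch({
      qt <- quantify_zone(plane, z$test, z$reference, on_blank = on_blank)
      qc <- quantify_zone(plane, z$control, z$control_front,
                          on_blank = on_blank)
      if (qc$signal <= 0)
        stop("quantification error: non-positive control signal")
      list(qt = qt, qc = qc)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, sprintf("channel %d: %s", ch,
                                  conditionMessage(res)))
      next
    }
    ratios[ch] <- res$qt$signal / res$qc$signal
    rows <- rbind(rows, data.frame(
      channel = ch, role = c("test", "control"),
      spot_mean = c(res$qt$spot_mean, res$qc$spot_mean),
      reference_mean = c(res$qt$reference_mean, res$qc$reference_mean),
      signal = c(res$qt$signal, res$qc$signal),
      ratio = ratios[ch]
    ))
  }
  if (length(failed) > 0L)
    warning("partial result; failed: ", paste(failed, collapse = "; "))
  ok <- ratios[!is.na(ratios)]
  structure(list(
    channels = rows, ratios = ratios,
    mean = mean(ok),
    sd = if (length(ok) > 1L) stats::sd(ok) else NA_real_,
    failed = failed,
    offset = if (is.null(offset)) c(0L, 0L) else offset
  ), class = "strip_signals")
}

#' @export
print.strip_signals <- function(x, ...) {
  cat(sprintf("strip signals: %d channels, mean ratio %.4f (SD %.4f)\n",
              length(x$ratios), x$mean, x$sd))
  if (length(x$failed)) cat("  failed:", paste(x$failed, collapse = "; "), "\n")
  invisible(x)
}
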