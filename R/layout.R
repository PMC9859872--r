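#' Strip layout: channels, zones and fiducial landmarks
#'
#' Describes the geometry of a multi-channel LFA strip image: per-channel
#' zone boxes (reference, test, control, ordered from the sample-pad side
#' upwards in flow direction), the laser-ablated channel-barrier landmarks
#' used for deterministic localization, and background reference points
#' used for illumination correction.
#'
#' The default emulates a strip with four 1000-um-wide membrane channels
#' separated by ablated barriers; each channel carries a control spot
#' (furthest from the sample pad), a test spot, and a blank reference zone
#' directly in front of the test spot.
#'
#' All boxes are integer pixel ranges `c(r0, r1, c0, c1)` (rows then
#' columns, 1-based, inclusive).
#'
#' @param n_channels number of membrane channels (default 4).
#' @param channel_width channel width in pixels; the physical channel width
#'   is 1000 um, so this fixes the pixel scale (default 28 px/mm).
#' @param zone_height,zone_width zone box size in pixels.
#' @param spot_radius radius of the rendered colour spots, pixels.
#' @param barrier_width width of the ablated barrier lines, pixels.
#' @param margin outer margin, pixels.
#' @param zone_gap vertical gap between consecutive zone boxes, pixels.
#'
#' @return Object of class `strip_layout`: list with `width`, `height`,
#'   `n_channels`, `channel_width`, `spot_radius`, `zones` (list per channel
#'   with `reference`, `test`, `control` boxes and `control_front` — the
#'   blank band directly in front of the control spot), `barrier_idx`
#'   (n x 2 matrix of barrier pixel coordinates) and `reference_points`
#'   (m x 2 matrix of background coordinates).
#' @examples
#' lay <- strip_layout()
#' lay$zones[[1]]$test
#' @export
strip_layout <- function(n_channels = 4L, channel_width = 28L,
                         zone_height = 22L, zone_width = 22L,
                         spot_radius = 7, barrier_width = 3L,
                         margin = 6L, zone_gap = 8L) {
  n_channels <- as.integer(n_channels)
  if (n_channels < 1L) stop("'n_channels' must be >= 1")
  if (zone_width > channel_width)
    stop("'zone_width' must not exceed 'channel_width'")

  width <- 2L * margin + (n_channels + 1L) * barrier_width +
    n_channels * channel_width

  # vertical stack (top -> bottom): top barrier, control, gap(front-of-control),
  # test, gap, reference, bottom margin; flow runs bottom -> top
  top_barrier <- c(margin + 1L, margin + barrier_width)
  r_control <- top_barrier[2L] + zone_gap + 1L
  control <- c(r_control, r_control + zone_height - 1L)
  control_front <- c(control[2L] + 1L, control[2L] + zone_gap)
  test <- c(control_front[2L] + 1L, control_front[2L] + zone_height)
  ref_gap <- c(test[2L] + 1L, test[2L] + zone_gap)
  reference <- c(ref_gap[2L] + 1L, ref_gap[2L] + zone_height)
  height <- reference[2L] + zone_gap + margin

  barrier_cols <- integer(0)
  channel_cols <- vector("list", n_channels)
  cur <- margin
  for (i in seq_len(n_channels + 1L)) {
    barrier_cols <- c(barrier_cols, (cur + 1L):(cur + barrier_width))
    cur <- cur + barrier_width
    if (i <= n_channels) {
      channel_cols[[i]] <- c(cur + 1L, cur + channel_width)
      cur <- cur + channel_width
    }
  }

  zones <- vector("list", n_channels)
  for (i in seq_len(n_channels)) {
    cc <- channel_cols[[i]]
    pad <- (channel_width - zone_width) %/% 2L
    c0 <- cc[1L] + pad
    c1 <- c0 + zone_width - 1L
    zones[[i]] <- list(
      reference     = c(reference, c0, c1),
      test          = c(test, c0, c1),
      control       = c(control, c0, c1),
      control_front = c(control_front, c0, c1)
    )
  }

  # barrier pixel coordinates: vertical barrier lines spanning the zone
  # stack plus the horizontal top barrier (gives the detector both axes)
  v_rows <- (top_barrier[1L]):(reference[2L] + zone_gap)
  h_cols <- (margin + 1L):(width - margin)
  barrier_idx <- unique(rbind(
    cbind(rep(v_rows, times = length(barrier_cols)),
          rep(barrier_cols, each = length(v_rows))),
    as.matrix(expand.grid(top_barrier[1L]:top_barrier[2L], h_cols))
  ))
  dimnames(barrier_idx) <- NULL

  # background reference points: channel centres in the blank bands
  ref_rows <- c(control_front[1L] + zone_gap %/% 2L,
                ref_gap[1L] + zone_gap %/% 2L,
                reference[2L] + zone_gap %/% 2L,
                control[1L] - zone_gap %/% 2L)
  centres <- vapply(channel_cols, function(cc) (cc[1L] + cc[2L]) %/% 2L, 0L)
  reference_points <- as.matrix(expand.grid(ref_rows, centres))
  dimnames(reference_points) <- NULL

  structure(list(
    width = width, height = height,
    n_channels = n_channels, channel_width = channel_width,
    zone_height = zone_height, zone_width = zone_width,
    spot_radius = spot_radius, barrier_width = barrier_width,
    zones = zones, barrier_idx = barrier_idx,
    reference_points = reference_points
  ), class = "strip_layout")
}

#' @export
print.strip_layout <- function(x, ...) {
  cat(sprintf("LFA strip layout: %d channels, image %d x %d px\n",
              x$n_channels, x$height, x$width))
  cat(sprintf("  zone boxes %d x %d px, spot radius %.1f px, %d fiducial px\n",
              x$zone_height, x$zone_width, x$spot_radius, nrow(x$barrier_idx)))
  invisible(x)
}

box_rows <- function(box) box[1L]:box[2L]
box_cols <- function(box) box[3L]:box[4L]

box_in_bounds <- function(box, height, width) {
  box[1L] >= 1L && box[2L] <= height && box[3L] >= 1L && box[4L] <= width &&
    box[1L] <= box[2L] && box[3L] <= box[4L]
}

#' Shift every box and landmark of a layout by a pixel offset
#'
#' @param layout a [strip_layout()].
#' @param offset integer `c(dr, dc)` added to all row/column coordinates.
#' @return The shifted `strip_layout`.
#' @keywords internal
shift_layout <- function(layout, offset) {
  off <- as.integer(round(offset))
  layout$zones <- lapply(layout$zones, function(z)
    lapply(z, function(b) b + c(off[1L], off[1L], off[2L], off[2L])))
  layout$barrier_idx <- layout$barrier_idx +
    matrix(off, nrow(layout$barrier_idx), 2L, byrow = TRUE)
  layout$reference_points <- layout$reference_points +
    matrix(off, nrow(layout$reference_points), 2L, byrow = TRUE)
  layout
}
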