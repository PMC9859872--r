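#' Write a strip image as 8-bit RGB PNG
#'
#' Pixel values are rounded to whole 8-bit levels on export.
#'
#' @param image a `strip_image`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_strip_png <- function(image, path) {
  px <- if (inherits(image, "strip_image")) image$pixels else image
  q <- round(pmin(pmax(px, 0), 255)) / 255
  png::writePNG(q, target = path)
  invisible(path)
}

#' Read an 8-bit RGB PNG as a strip image
#'
#' @param path PNG file path.
#' @param source_id identifier stored in the metadata (default the file
#'   name).
#' @return A `strip_image` with intensities on the 0-255 scale.
#' @export
read_strip_png <- function(path, source_id = basename(path)) {
  if (!file.exists(path)) stop("image file not found: ", path)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L && dim(px)[3L] == 4L)
    px <- px[, , 1:3, drop = FALSE]          # drop alpha
  if (length(dim(px)) != 3L || dim(px)[3L] != 3L)
    stop("format error: expected an RGB image")
  structure(list(pixels = px * 255,
                 metadata = list(source_id = source_id)),
            class = "strip_image")
}

#' Write / read a two-column TSV spectrum
#'
#' Columns `wavelength_nm` and `absorbance`, tab separated, with header.
#'
#' @param spectrum data frame `wavelength_nm`, `absorbance`.
#' @param path file path.
#' @return `path` invisibly / the spectrum data frame.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  utils::write.table(spectrum[c("wavelength_nm", "absorbance")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_tsv
#' @export
read_spectrum_tsv <- function(path) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("wavelength_nm", "absorbance") %in% names(d)))
  structure(d, class = c("lfa_spectrum", "data.frame"))
}

#' Write / read a two-column TSV size distribution
#'
#' Columns `diameter_nm` and `weight`, tab separated, with header.
#'
#' @param dist data frame `diameter_nm`, `weight`.
#' @param path file path.
#' @return `path` invisibly / the distribution data frame.
#' @export
write_size_distribution_tsv <- function(dist, path) {
  utils::write.table(dist[c("diameter_nm", "weight")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_size_distribution_tsv
#' @export
read_size_distribution_tsv <- function(path) {
  if (!file.exists(path)) stop("size distribution file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("diameter_nm", "weight") %in% names(d)))
  structure(d, class = c("size_distribution", "data.frame"))
}
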