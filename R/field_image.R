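#' Construct a three-channel field image
#'
#' A `field_image` holds one imaged field of a well: three co-registered 2-D
#' intensity rasters — nuclei (405 nm excitation dye), mitochondria (640 nm
#' dye) and the superoxide reporter (561 nm dye) — together with the physical
#' pixel size and the plate coordinates of the field.
#'
#' @param nuclei_ch,mito_ch,mros_ch Numeric matrices of identical dimensions
#'   with finite, non-negative intensities.
#' @param well_id Plate coordinate such as `"B07"` (rows A-H, columns 01-12).
#' @param field_index Zero-based field index within the well.
#' @param pixel_size_um Physical pixel size in micrometres (> 0). Areas are
#'   reported in um^2 via `pixel_size_um^2`; the default 0.6 um/px is a
#'   typical 20x confocal HCS calibration.
#' @return An object of class `field_image`.
#' @seealso [read_field()], [write_field()], [simulate_field()]
#' @export
field_image <- function(nuclei_ch, mito_ch, mros_ch, well_id = "A01",
                        field_index = 0L, pixel_size_um = 0.6) {
  chans <- list(nuclei_ch = nuclei_ch, mito_ch = mito_ch, mros_ch = mros_ch)
  for (nm in names(chans)) {
    ch <- chans[[nm]]
    if (!is.matrix(ch) || !is.numeric(ch))
      stop(sprintf("%s must be a numeric matrix", nm), call. = FALSE)
    if (!all(is.finite(ch)))
      stop(sprintf("%s contains non-finite intensities", nm), call. = FALSE)
    if (any(ch < 0))
      stop(sprintf("%s contains negative intensities", nm), call. = FALSE)
  }
  if (!identical(dim(nuclei_ch), dim(mito_ch)) ||
      !identical(dim(nuclei_ch), dim(mros_ch)))
    stop("all three channel rasters must share identical dimensions",
         call. = FALSE)
  check_well_id(well_id)
  stopifnot(is.numeric(field_index), length(field_index) == 1L,
            field_index >= 0)
  stopifnot(is.numeric(pixel_size_um), length(pixel_size_um) == 1L,
            is.finite(pixel_size_um), pixel_size_um > 0)
  structure(
    list(well_id = well_id, field_index = as.integer(field_index),
         nuclei_ch = apply_storage(nuclei_ch),
         mito_ch = apply_storage(mito_ch),
         mros_ch = apply_storage(mros_ch),
         pixel_size_um = pixel_size_um),
    class = "field_image")
}

# promote integer rasters to double without rescaling values
apply_storage <- function(x) {
  storage.mode(x) <- "double"
  x
}

check_well_id <- function(well_id) {
  if (!is.character(well_id) || length(well_id) != 1L ||
      !grepl("^[A-H](0[1-9]|1[0-2])$", well_id))
    stop(sprintf(
      "'%s' is not a valid 96-well coordinate (A01-H12)",
      paste(well_id, collapse = ",")), call. = FALSE)
  invisible(well_id)
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$nuclei_ch)
  cat(sprintf(
    "field_image: well %s field %d, %d x %d px (%.3g um/px)\n",
    x$well_id, x$field_index, d[1], d[2], x$pixel_size_um))
  cat(sprintf("  channel ranges: nuclei [%g, %g], mito [%g, %g], mros [%g, %g]\n",
              min(x$nuclei_ch), max(x$nuclei_ch),
              min(x$mito_ch), max(x$mito_ch),
              min(x$mros_ch), max(x$mros_ch)))
  invisible(x)
}

#' Read a three-channel field from a multi-page TIFF
#'
#' Expects a 3-plane TIFF in fixed channel order (nuclei, mitochondria,
#' superoxide reporter). Integer sample values are preserved exactly and
#' promoted to double without rescaling.
#'
#' @param path Path to a `.tif` file. Well and field default to being parsed
#'   from a `<well>_f<field>.tif` file name.
#' @param well_id,field_index Optional overrides for the plate coordinates.
#' @inheritParams field_image
#' @return A [field_image()].
#' @export
read_field <- function(path, well_id = NULL, field_index = NULL,
                       pixel_size_um = 0.6) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  if (length(planes) != 3L)
    stop(sprintf("expected 3 channel planes, found %d in %s",
                 length(planes), path), call. = FALSE)
  dims <- lapply(planes, dim)
  if (any(vapply(dims, length, 1L) != 2L))
    stop("channel planes must be single 2-D grayscale rasters", call. = FALSE)
  if (!identical(dims[[1]], dims[[2]]) || !identical(dims[[1]], dims[[3]]))
    stop("channel planes have mismatched shapes", call. = FALSE)
  base <- tools::file_path_sans_ext(basename(path))
  m <- regmatches(base, regexec("^([A-H](?:0[1-9]|1[0-2]))_f([0-9]+)$", base))[[1]]
  if (is.null(well_id))
    well_id <- if (length(m)) m[2] else "A01"
  if (is.null(field_index))
    field_index <- if (length(m)) as.integer(m[3]) else 0L
  field_image(nuclei_ch = matrix(as.numeric(planes[[1]]), nrow(planes[[1]])),
              mito_ch = matrix(as.numeric(planes[[2]]), nrow(planes[[2]])),
              mros_ch = matrix(as.numeric(planes[[3]]), nrow(planes[[3]])),
              well_id = well_id, field_index = field_index,
              pixel_size_um = pixel_size_um)
}

#' Write a field to a 16-bit multi-page TIFF
#'
#' Planes are written in the fixed channel order (nuclei, mitochondria,
#' superoxide reporter). Intensities are rounded to integers and clamped to
#' the 16-bit range \[0, 65535\] (with a warning if clamping occurs), so
#' integer-valued images round-trip bit-identically through
#' [read_field()].
#'
#' @param field A [field_image()].
#' @param path Output path; the conventional name is `<well>_f<field>.tif`.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "field_image"))
  planes <- list(field$nuclei_ch, field$mito_ch, field$mros_ch)
  planes <- lapply(planes, function(ch) {
    ch <- round(ch)
    if (any(ch > 65535)) {
      warning("intensities above 65535 clamped on 16-bit write")
      ch[ch > 65535] <- 65535
    }
    ch / 65535
  })
  tiff::writeTIFF(planes, path, bits.per.sample = 16L)
  invisible(path)
}

#' Conventional file name for a field image
#' @param well_id Plate coordinate.
#' @param field_index Zero-based field index.
#' @return A file name of the form `<well>_f<field>.tif`.
#' @export
field_file_name <- function(well_id, field_index) {
  sprintf("%s_f%d.tif", well_id, as.integer(field_index))
}
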