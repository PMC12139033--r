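#' Read and write 16-bit grayscale micrograph TIFFs
#'
#' `writeMicrograph()` stores integer pixel counts in a single-plane 16-bit
#' TIFF plus a small YAML sidecar (`<stem>.yaml`) carrying the field width
#' and imaging mode, since baseline TIFF has no standard slot for them.
#' `readMicrograph()` restores the counts exactly; metadata comes from the
#' sidecar when present, otherwise from the arguments.
#'
#' @param micrograph a [Micrograph-class].
#' @param path TIFF file path.
#' @param fieldWidth,mode metadata fallbacks used when no sidecar exists.
#' @return `readMicrograph()` returns a [Micrograph-class];
#'   `writeMicrograph()` invisibly returns `path`.
#' @examples
#' mg <- Micrograph(matrix(120, 64, 64), fieldWidth = 20e-6)
#' f <- file.path(tempdir(), "scene.tif")
#' writeMicrograph(mg, f)
#' identical(pixelData(readMicrograph(f)), pixelData(mg))
#' @export
writeMicrograph <- function(micrograph, path) {
  stopifnot(is(micrograph, "Micrograph"))
  px <- micrograph@pixels
  if (any(px < 0) || max(px) > 65535)
    stop("pixel values outside the 16-bit range [0, 65535]")
  tiff::writeTIFF(round(px) / 65535, path, bits.per.sample = 16L)
  yaml::write_yaml(list(field_width_m = micrograph@fieldWidth,
                        mode = micrograph@mode),
                   sub("\\.tiff?$", ".yaml", path))
  invisible(path)
}

#' @rdname writeMicrograph
#' @export
readMicrograph <- function(path, fieldWidth = NA_real_,
    mode = "upconversion") {
  raw <- tiff::readTIFF(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
  meta <- sub("\\.tiff?$", ".yaml", path)
  if (file.exists(meta)) {
    m <- yaml::read_yaml(meta)
    fieldWidth <- m$field_width_m %||% fieldWidth
    mode <- m$mode %||% mode
  }
  if (is.na(fieldWidth))
    stop("fieldWidth not supplied and no metadata sidecar found for ", path)
  Micrograph(round(raw * 65535), fieldWidth = fieldWidth, mode = mode)
}

#' Read and write localization and spot-record tables
#'
#' CSV round-trip for the tables the pipeline exchanges between stages.
#' `readLocalizations()` requires columns `x_px` and `y_px`; any further
#' columns (score, intensities, flags) are preserved.
#'
#' @param records a data.frame of localizations or spot records using the
#'   package's internal column names (`x`, `y`, ...).
#' @param path CSV file path.
#' @return `readLocalizations()` returns a data.frame with internal column
#'   names; `writeLocalizations()` invisibly returns `path`.
#' @export
writeLocalizations <- function(records, path) {
  out <- records
  names(out)[names(out) == "x"] <- "x_px"
  names(out)[names(out) == "y"] <- "y_px"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLocalizations
#' @export
readLocalizations <- function(path) {
  tab <- utils::read.csv(path)
  miss <- setdiff(c("x_px", "y_px"), names(tab))
  if (length(miss))
    stop("localization table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  names(tab)[names(tab) == "x_px"] <- "x"
  names(tab)[names(tab) == "y_px"] <- "y"
  tab
}
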