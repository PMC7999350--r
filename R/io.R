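## Image and table I/O. Micrographs are read from 8-bit (or 16-bit,
## linearly rescaled) TIFF and PNG; fluorescence maps are written as
## single-channel 16-bit TIFF or tidy CSV; run metadata travels in a
## manifest CSV and per-image truth JSON.

readRaster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext))
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  a
}

#' Read a cross-section micrograph
#'
#' Reads a TIFF or PNG as an \code{\link{RgbSection}}. Values are linearly
#' rescaled to 0--255 regardless of source bit depth. Images acquired
#' abaxial-up should be read with \code{flip = TRUE} so the adaxial-top
#' orientation invariant holds; \code{mirror = TRUE} likewise puts the
#' midrib at column 1 for sections photographed margin-first.
#'
#' @param path image file path.
#' @param meta optional \code{\link{TreatmentLabel}}.
#' @param flip reverse rows (abaxial-up sources).
#' @param mirror reverse columns (margin-first sources).
#' @return An \code{\link{RgbSection}}.
#' @export
readSection <- function(path, meta = NULL, flip = FALSE, mirror = FALSE) {
  a <- readRaster(path)
  if (flip) a <- a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
  if (mirror) a <- a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
  rgbSection(array(as.integer(round(a * 255)), dim = dim(a)), meta = meta)
}

#' Write a section image as 8-bit TIFF
#' @param image an \code{\link{RgbSection}} or \code{\link{SyntheticSection}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSection <- function(image, path) {
  px <- pixelArray(image)
  tiff::writeTIFF(px / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write a fluorescence map
#'
#' Writes the scalar intensity raster either as a single-channel 16-bit
#' TIFF or as a tidy CSV with columns \code{row}, \code{col}, \code{value}.
#'
#' @param map a \code{\link{FluorescenceMap}}.
#' @param path output path.
#' @param format \code{"tiff"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
writeFluorescenceMap <- function(map, path, format = c("tiff", "csv")) {
  stopifnot(is(map, "FluorescenceMap"))
  format <- match.arg(format)
  if (format == "tiff") {
    tiff::writeTIFF(map@values, path, bits.per.sample = 16L)
  } else {
    v <- map@values
    df <- data.frame(row = as.integer(row(v)), col = as.integer(col(v)),
                     value = as.numeric(v))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

manifestColumns <- c("path", "variety", "co2", "light", "replicate",
                     "section", "seed")

validateManifest <- function(df, checkPaths = TRUE) {
  need <- setdiff(manifestColumns, "seed")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "))
  stopifnot(all(df$variety %in% c("BARKE", "BOJOS")),
            all(df$co2 %in% c("LC", "AC", "EC")),
            all(df$light %in% c("LL", "HL")))
  key <- interaction(df$variety, df$co2, df$light, df$replicate, df$section)
  if (anyDuplicated(key))
    stop("manifest has duplicate (treatment, replicate, section) entries")
  if (checkPaths && nrow(df) > 0L && !all(file.exists(df$path)))
    stop("manifest references missing image file(s)")
  df
}

#' Read or write a run manifest
#'
#' The manifest lists one image per row with its treatment metadata:
#' columns \code{path}, \code{variety}, \code{co2}, \code{light},
#' \code{replicate}, \code{section} and optionally \code{seed}.
#'
#' @param path CSV path.
#' @param checkPaths verify that referenced image files exist.
#' @return \code{data.frame} manifest.
#' @export
readManifest <- function(path, checkPaths = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateManifest(df, checkPaths = checkPaths)
}

#' @rdname readManifest
#' @param manifest manifest \code{data.frame}.
#' @export
writeManifest <- function(manifest, path) {
  validateManifest(manifest, checkPaths = FALSE)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

truthToList <- function(spec) {
  list(base = spec@base, adPeak = spec@adPeak, abPeak = spec@abPeak,
       lambda = spec@lambda, lmBump = spec@lmBump, lmCenter = spec@lmCenter,
       lmWidth = spec@lmWidth, totalScale = spec@totalScale,
       layerMeans = as.list(depthMeans(layerTruth(spec))))
}

writeTruthJson <- function(spec, path) {
  jsonlite::write_json(truthToList(spec), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
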