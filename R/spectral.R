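## Hue-window spectral separation.
##
## Under UV excitation a Naturstoff-stained cross-section emits three
## distinguishable colors: red (chlorophyll autofluorescence, mesophyll
## only), blue (cell walls, vascular bundles, sclerenchyma) and yellow
## (flavonoid-reagent chelates). Hue is the HSV axis that separates them, so
## each channel is isolated by a closed hue interval plus minimum
## saturation/brightness thresholds; the retained intensity is the HSV value
## channel ("pixel brightness", max of R,G,B scaled to [0, 1]).

#' Default hue windows for the three fluorescence colors
#'
#' Yellow (flavonoid) 30--90 deg; red (chlorophyll) as two wrap-around
#' sub-windows 330--360 and 0--30 deg; blue (cell wall / vascular) 190--270
#' deg. All use saturation >= 0.2 and value >= 0.04. The three channels are
#' disjoint in hue except at shared endpoints.
#'
#' @return named list of \code{\link{hueWindow}} objects
#'   (\code{yellow}, \code{red_a}, \code{red_b}, \code{blue}).
#' @export
defaultWindows <- function() {
  list(yellow = hueWindow(30, 90, 0.2, 0.04),
       red_a  = hueWindow(330, 360, 0.2, 0.04),
       red_b  = hueWindow(0, 30, 0.2, 0.04),
       blue   = hueWindow(190, 270, 0.2, 0.04))
}

# HSV decomposition of an RgbSection; hue in degrees [0, 360).
rgbToHsv <- function(pixels) {
  d <- dim(pixels)
  m <- rbind(as.vector(pixels[, , 1]), as.vector(pixels[, , 2]),
             as.vector(pixels[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  list(h = matrix(hsv[1L, ] * 360, d[1], d[2]),
       s = matrix(hsv[2L, ], d[1], d[2]),
       v = matrix(hsv[3L, ], d[1], d[2]))
}

windowMembership <- function(hsv, window) {
  hsv$h >= window@hueLow & hsv$h <= window@hueHigh &
    hsv$s >= window@satMin & hsv$v >= window@valMin
}

applyWindows <- function(image, windows, tag) {
  if (length(image@pixels) == 0L || any(dim(image@pixels)[1:2] == 0L))
    pdStop("EMPTY_IMAGE", "raster has no pixels")
  for (w in windows) {
    if (!is(w, "HueWindow")) pdStop("BAD_WINDOW", "window must be a HueWindow")
    v <- validObject(w, test = TRUE)
    if (!isTRUE(v)) pdStop("BAD_WINDOW", paste(v, collapse = "; "))
  }
  hsv <- rgbToHsv(image@pixels)
  inside <- Reduce(`|`, lapply(windows, windowMembership, hsv = hsv))
  vals <- ifelse(inside, hsv$v, 0)
  new("FluorescenceMap", values = vals, channelTag = tag)
}

#' Isolate phenolic-compound (yellow flavonoid) fluorescence
#'
#' Converts each pixel to HSV and keeps its value-channel brightness where
#' the pixel falls inside the yellow hue window (hue in
#' \code{[hueLow, hueHigh]}, saturation >= \code{satMin}, value >=
#' \code{valMin}); all other pixels are set to exactly 0. Deterministic.
#'
#' @param image an \code{\link{RgbSection}}.
#' @param window a \code{\link{hueWindow}}; defaults to the yellow window
#'   (30--90 deg, sat >= 0.2, val >= 0.04).
#' @return A \code{\link{FluorescenceMap}} tagged \code{PHC_YELLOW}.
#' @examples
#' img <- rgbSection(array(c(255, 255, 0), dim = c(1, 1, 3)))  # pure yellow
#' intensityValues(isolatePhC(img))  # 1
#' @seealso \code{\link{channelMask}} for the red and blue channels.
#' @export
isolatePhC <- function(image, window = defaultWindows()$yellow) {
  stopifnot(is(image, "RgbSection"))
  applyWindows(image, list(window), "PHC_YELLOW")
}

#' Isolate chlorophyll (red) or cell-wall (blue) autofluorescence
#'
#' As \code{\link{isolatePhC}} but with the default window of the requested
#' channel. The red channel wraps around hue 0 and is the OR-combination of
#' the 330--360 and 0--30 degree sub-windows. The red mask drives mesophyll
#' delineation (chlorophyll is absent from the epidermis); the blue mask
#' drives vascular-bundle exclusion.
#'
#' @param image an \code{\link{RgbSection}}.
#' @param tag \code{"CHLOROPHYLL_RED"} or \code{"WALL_BLUE"}.
#' @param windows named list of windows as \code{\link{defaultWindows}}.
#' @return A \code{\link{FluorescenceMap}} with the requested tag.
#' @export
channelMask <- function(image, tag, windows = defaultWindows()) {
  stopifnot(is(image, "RgbSection"))
  if (!(is.character(tag) && length(tag) == 1L &&
        tag %in% c("CHLOROPHYLL_RED", "WALL_BLUE")))
    pdStop("BAD_TAG", "tag must be CHLOROPHYLL_RED or WALL_BLUE")
  ws <- if (tag == "CHLOROPHYLL_RED") windows[c("red_a", "red_b")]
        else windows["blue"]
  applyWindows(image, ws, tag)
}
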