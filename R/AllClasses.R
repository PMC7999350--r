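## S4 class definitions. All raster containers store pixels in standard R
## matrix orientation: rows = image rows (row 1 = adaxial side), columns =
## image columns (column 1 = midrib side).

setClassUnion("TreatmentLabelOrNULL", "NULL")

#' Treatment metadata for one section
#'
#' Identifies the cultivation treatment and provenance of a half-lamina
#' cross-section: barley variety, growth CO2 concentration, light regime,
#' biological replicate and section number.
#'
#' @slot variety character, \code{"BARKE"} or \code{"BOJOS"}.
#' @slot co2 character, \code{"LC"} (200 ppm), \code{"AC"} (400 ppm) or
#'   \code{"EC"} (700 ppm).
#' @slot light character, \code{"LL"} (low light) or \code{"HL"} (high light).
#' @slot replicate integer replicate id.
#' @slot section integer section id within the replicate.
#' @exportClass TreatmentLabel
setClass("TreatmentLabel",
  representation(variety = "character", co2 = "character", light = "character",
                 replicate = "integer", section = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (!(object@variety %in% c("BARKE", "BOJOS")))
      msg <- c(msg, "variety must be BARKE or BOJOS")
    if (!(object@co2 %in% c("LC", "AC", "EC")))
      msg <- c(msg, "co2 must be LC, AC or EC")
    if (!(object@light %in% c("LL", "HL")))
      msg <- c(msg, "light must be LL or HL")
    if (length(object@replicate) != 1L || is.na(object@replicate) ||
        object@replicate < 1L)
      msg <- c(msg, "replicate must be a positive integer")
    if (length(object@section) != 1L || is.na(object@section) ||
        object@section < 1L)
      msg <- c(msg, "section must be a positive integer")
    if (length(msg)) msg else TRUE
  })

setIs("TreatmentLabel", "TreatmentLabelOrNULL")

#' @describeIn TreatmentLabel Constructor.
#' @param variety,co2,light,replicate,section see slots.
#' @return A \code{TreatmentLabel}.
#' @examples
#' treatmentLabel("BARKE", "AC", "LL", replicate = 1, section = 1)
#' @export
treatmentLabel <- function(variety, co2, light, replicate = 1L, section = 1L) {
  new("TreatmentLabel", variety = as.character(variety), co2 = as.character(co2),
      light = as.character(light), replicate = as.integer(replicate),
      section = as.integer(section))
}

#' An RGB micrograph of one half-lamina cross-section
#'
#' Holds an 8-bit three-channel raster (values 0--255) with the adaxial
#' epidermis at row 1 and the midrib side at column 1, plus optional
#' treatment metadata. Images flagged as abaxial-up are flipped on load so
#' that this orientation invariant always holds after ingestion.
#'
#' @slot pixels integer array \code{height x width x 3} in 0--255.
#' @slot meta a \code{\link{TreatmentLabel}} or \code{NULL}.
#' @exportClass RgbSection
setClass("RgbSection",
  representation(pixels = "array", meta = "TreatmentLabelOrNULL"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3L || d[3] != 3L)
      return("pixels must be a height x width x 3 array")
    if (d[1] < 1L || d[2] < 1L) return("EMPTY_IMAGE: raster has no pixels")
    rng <- range(object@pixels)
    if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
      return("channel values must lie in [0, 255]")
    TRUE
  })

#' @describeIn RgbSection Constructor from a numeric/integer array.
#' @param pixels integer array \code{height x width x 3} in 0--255.
#' @param meta optional \code{TreatmentLabel}.
#' @return An \code{RgbSection}.
#' @export
rgbSection <- function(pixels, meta = NULL) {
  if (length(pixels) == 0L)
    pdStop("EMPTY_IMAGE", "raster has no pixels")
  storage.mode(pixels) <- "integer"
  new("RgbSection", pixels = pixels, meta = meta)
}

#' A hue window in HSV space
#'
#' Defines the hue interval (degrees) and minimum saturation/value used to
#' select one fluorescence color. Hue intervals are closed; the red channel's
#' wrap-around at 0/360 degrees is represented by two separate windows.
#'
#' @slot hueLow,hueHigh hue bounds in degrees, \code{0 <= hueLow < hueHigh <= 360}.
#' @slot satMin,valMin minimum saturation and value (brightness), in [0, 1].
#' @exportClass HueWindow
setClass("HueWindow",
  representation(hueLow = "numeric", hueHigh = "numeric",
                 satMin = "numeric", valMin = "numeric"),
  validity = function(object) {
    ok <- isScalarNumber(object@hueLow) && isScalarNumber(object@hueHigh) &&
      isScalarNumber(object@satMin) && isScalarNumber(object@valMin) &&
      object@hueLow >= 0 && object@hueLow < object@hueHigh &&
      object@hueHigh <= 360 &&
      object@satMin >= 0 && object@satMin <= 1 &&
      object@valMin >= 0 && object@valMin <= 1
    if (!ok) "BAD_WINDOW: need 0 <= hueLow < hueHigh <= 360 and satMin, valMin in [0, 1]"
    else TRUE
  })

#' @describeIn HueWindow Constructor.
#' @param hueLow,hueHigh,satMin,valMin see slots.
#' @return A \code{HueWindow}.
#' @examples
#' hueWindow(30, 90, 0.2, 0.04)  # default yellow (flavonoid) window
#' @export
hueWindow <- function(hueLow, hueHigh, satMin = 0.2, valMin = 0.04) {
  w <- try(new("HueWindow", hueLow = as.numeric(hueLow),
               hueHigh = as.numeric(hueHigh), satMin = as.numeric(satMin),
               valMin = as.numeric(valMin)), silent = TRUE)
  if (inherits(w, "try-error")) pdStop("BAD_WINDOW", "malformed hue window")
  w
}

#' A scalar fluorescence-intensity raster
#'
#' One isolated fluorescence channel, values in [0, 1]; a pixel is exactly 0
#' wherever the source pixel falls outside the channel's hue window.
#'
#' @slot values numeric matrix in [0, 1], same height/width as the source.
#' @slot channelTag \code{"PHC_YELLOW"}, \code{"CHLOROPHYLL_RED"} or
#'   \code{"WALL_BLUE"}.
#' @exportClass FluorescenceMap
setClass("FluorescenceMap",
  representation(values = "matrix", channelTag = "character"),
  validity = function(object) {
    if (!(object@channelTag %in% c("PHC_YELLOW", "CHLOROPHYLL_RED", "WALL_BLUE")))
      return("channelTag must be PHC_YELLOW, CHLOROPHYLL_RED or WALL_BLUE")
    rng <- range(object@values)
    if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 1)
      return("values must lie in [0, 1]")
    TRUE
  })

#' A single vertical transect through the mesophyll
#'
#' Per-pixel PhC intensities along one image column, index 1 at the adaxial
#' mesophyll boundary.
#'
#' @slot column image column index.
#' @slot top,bottom row indices of the mesophyll span (inclusive).
#' @slot intensities numeric vector of length \code{bottom - top + 1}.
#' @exportClass Transect
setClass("Transect",
  representation(column = "integer", top = "integer", bottom = "integer",
                 intensities = "numeric"),
  validity = function(object) {
    if (object@top > object@bottom) return("top must be <= bottom")
    if (length(object@intensities) != object@bottom - object@top + 1L)
      return("intensities length must equal bottom - top + 1")
    rng <- range(object@intensities)
    if (rng[1] < 0 || rng[2] > 1) return("intensities must lie in [0, 1]")
    TRUE
  })

#' Mean intensity per depth layer
#'
#' Layer means for one transect, section or replicate, in fixed
#' adaxial-to-abaxial order (AD, UM, MM, LM, AB for the canonical five
#' layers). \code{nPixels} records how many transect pixels fed each bin;
#' bins that received no pixel (possible only for transects shorter than the
#' number of bins) carry the value of the nearest non-empty bin and a count
#' of 0.
#'
#' @slot means named numeric vector of layer means in [0, 1].
#' @slot nPixels integer vector of per-bin pixel counts.
#' @exportClass DepthBins
setClass("DepthBins",
  representation(means = "numeric", nPixels = "integer"),
  validity = function(object) {
    if (length(object@means) != length(object@nPixels))
      return("means and nPixels must have equal length")
    if (is.null(names(object@means))) return("means must be named")
    if (any(object@nPixels < 0L)) return("nPixels must be non-negative")
    TRUE
  })

#' Depth profile of one section
#'
#' Layer means averaged (unweighted) over a section's transects.
#'
#' @slot bins a \code{\link{DepthBins}}.
#' @slot nTransects number of transects averaged (target 5).
#' @slot meta a \code{TreatmentLabel} or \code{NULL}.
#' @exportClass SectionProfile
setClass("SectionProfile",
  representation(bins = "DepthBins", nTransects = "integer",
                 meta = "TreatmentLabelOrNULL"),
  validity = function(object)
    if (object@nTransects < 1L) "nTransects must be >= 1" else TRUE)

#' Depth profile of one biological replicate
#'
#' Layer means averaged (unweighted) over a replicate's sections.
#'
#' @slot bins a \code{\link{DepthBins}}.
#' @slot nSections number of sections averaged (target 3).
#' @slot meta a \code{TreatmentLabel} or \code{NULL}.
#' @exportClass ReplicateProfile
setClass("ReplicateProfile",
  representation(bins = "DepthBins", nSections = "integer",
                 meta = "TreatmentLabelOrNULL"),
  validity = function(object)
    if (object@nSections < 1L) "nSections must be >= 1" else TRUE)

#' Analytic ground-truth depth gradient
#'
#' Closed-form expected PhC intensity as a function of relative mesophyll
#' depth d in [0, 1] (0 = adaxial boundary):
#' \deqn{g(d) = s [b + A_{ad} e^{-d/\lambda} + A_{ab} e^{-(1-d)/\lambda}
#'   + B e^{-(d - c)^2 / (2 w^2)}]}
#' with surface-peak amplitudes \eqn{A_{ad}, A_{ab}} (decay length
#' \eqn{\lambda}), a lower-mesophyll Gaussian bump of amplitude \eqn{B}
#' centered at \eqn{c} with width \eqn{w}, and overall scale \eqn{s}.
#'
#' @slot base,adPeak,abPeak,lambda,lmBump,lmCenter,lmWidth,totalScale numeric
#'   parameters of the closed form above.
#' @exportClass GradientSpec
setClass("GradientSpec",
  representation(base = "numeric", adPeak = "numeric", abPeak = "numeric",
                 lambda = "numeric", lmBump = "numeric", lmCenter = "numeric",
                 lmWidth = "numeric", totalScale = "numeric"),
  validity = function(object) {
    p <- c(object@base, object@adPeak, object@abPeak, object@lambda,
           object@lmBump, object@lmCenter, object@lmWidth, object@totalScale)
    if (!all(vapply(p, isScalarNumber, logical(1)))) return("all parameters must be finite scalars")
    if (object@lambda <= 0 || object@lmWidth <= 0) return("lambda and lmWidth must be positive")
    d <- seq(0, 1, length.out = 201)
    if (min(gradientValues(object, d)) < 0) return("g(d) must be non-negative on [0, 1]")
    TRUE
  })

#' @describeIn GradientSpec Constructor.
#' @param base,adPeak,abPeak,lambda,lmBump,lmCenter,lmWidth,totalScale
#'   see slots.
#' @return A \code{GradientSpec}.
#' @export
gradientSpec <- function(base, adPeak = 0, abPeak = 0, lambda = 0.15,
                         lmBump = 0, lmCenter = 0.7, lmWidth = 0.15,
                         totalScale = 1) {
  new("GradientSpec", base = as.numeric(base), adPeak = as.numeric(adPeak),
      abPeak = as.numeric(abPeak), lambda = as.numeric(lambda),
      lmBump = as.numeric(lmBump), lmCenter = as.numeric(lmCenter),
      lmWidth = as.numeric(lmWidth), totalScale = as.numeric(totalScale))
}

#' Piecewise-linear diurnal irradiance profile
#'
#' Night value 0, linear ramp up, constant plateau, linear ramp down; the
#' default schedule ramps from 05:00 to 10:00, holds until 15:00 and ramps
#' down until 20:00 (15 h photoperiod).
#'
#' @slot quantity \code{"PAR"} (day maximum in umol m-2 s-1, daily integral
#'   in mol m-2 day-1) or \code{"UVA"} (W m-2; integral in kJ m-2 day-1).
#' @slot dayMax daytime maximum.
#' @slot rampUp,plateau,rampDown numeric length-2 vectors of clock hours.
#' @exportClass DiurnalProfile
setClass("DiurnalProfile",
  representation(quantity = "character", dayMax = "numeric",
                 rampUp = "numeric", plateau = "numeric", rampDown = "numeric"),
  validity = function(object) {
    if (!(object@quantity %in% c("PAR", "UVA")))
      return("quantity must be PAR or UVA")
    if (!isScalarNumber(object@dayMax) || object@dayMax < 0)
      return("dayMax must be a non-negative scalar")
    for (s in c("rampUp", "plateau", "rampDown"))
      if (length(slot(object, s)) != 2L) return(paste(s, "must have length 2"))
    TRUE
  })

#' @describeIn DiurnalProfile Constructor.
#' @param quantity,dayMax,rampUp,plateau,rampDown see slots.
#' @return A \code{DiurnalProfile}.
#' @examples
#' dailyIntegral(diurnalProfile("PAR", 1500))  # high-light regime: 54
#' @export
diurnalProfile <- function(quantity, dayMax, rampUp = c(5, 10),
                           plateau = c(10, 15), rampDown = c(15, 20)) {
  new("DiurnalProfile", quantity = as.character(quantity),
      dayMax = as.numeric(dayMax), rampUp = as.numeric(rampUp),
      plateau = as.numeric(plateau), rampDown = as.numeric(rampDown))
}

#' A synthetic half-lamina section with known ground truth
#'
#' The rendered image, the analytic gradient it encodes, the generator
#' geometry (per-column lamina and mesophyll bounds, vascular/midrib
#' columns) and the seed that makes the render reproducible.
#'
#' @slot image an \code{\link{RgbSection}}.
#' @slot truth the \code{\link{GradientSpec}} driving the PhC channel.
#' @slot geometry list with elements \code{laminaTop}, \code{laminaBottom},
#'   \code{mesoTop}, \code{mesoBottom} (per-column integer vectors),
#'   \code{vascularColumns}, \code{midribColumns} (integer vectors) and
#'   \code{epidermisPx}.
#' @slot seed integer seed used by the renderer.
#' @exportClass SyntheticSection
setClass("SyntheticSection",
  representation(image = "RgbSection", truth = "GradientSpec",
                 geometry = "list", seed = "integer"))
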