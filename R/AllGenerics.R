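## Generics and accessors. Slot access from user code should go through
## these rather than `@`.

#' Intensity values of a raster object
#' @param x a \code{FluorescenceMap} or \code{Transect}.
#' @return numeric matrix (map) or vector (transect) of intensities in [0, 1].
#' @export
setGeneric("intensityValues", function(x) standardGeneric("intensityValues"))

#' @rdname intensityValues
setMethod("intensityValues", "FluorescenceMap", function(x) x@values)

#' @rdname intensityValues
setMethod("intensityValues", "Transect", function(x) x@intensities)

#' Channel tag of a fluorescence map
#' @param x a \code{FluorescenceMap}.
#' @return character tag.
#' @export
setGeneric("channelTag", function(x) standardGeneric("channelTag"))

#' @rdname channelTag
setMethod("channelTag", "FluorescenceMap", function(x) x@channelTag)

#' Layer means of a depth-binned object
#' @param x a \code{DepthBins}, \code{SectionProfile} or
#'   \code{ReplicateProfile}.
#' @return named numeric vector of layer means (adaxial to abaxial order).
#' @export
setGeneric("depthMeans", function(x) standardGeneric("depthMeans"))

#' @rdname depthMeans
setMethod("depthMeans", "DepthBins", function(x) x@means)

#' @rdname depthMeans
setMethod("depthMeans", "SectionProfile", function(x) x@bins@means)

#' @rdname depthMeans
setMethod("depthMeans", "ReplicateProfile", function(x) x@bins@means)

#' Per-bin pixel counts of a depth-binned object
#' @param x a \code{DepthBins}, \code{SectionProfile} or
#'   \code{ReplicateProfile}.
#' @return integer vector of counts.
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))

#' @rdname binCounts
setMethod("binCounts", "DepthBins", function(x) x@nPixels)

#' @rdname binCounts
setMethod("binCounts", "SectionProfile", function(x) x@bins@nPixels)

#' @rdname binCounts
setMethod("binCounts", "ReplicateProfile", function(x) x@bins@nPixels)

#' Treatment metadata of an object
#' @param x an \code{RgbSection}, \code{SectionProfile},
#'   \code{ReplicateProfile} or \code{SyntheticSection}.
#' @return a \code{TreatmentLabel} or \code{NULL}.
#' @export
setGeneric("treatmentMeta", function(x) standardGeneric("treatmentMeta"))

#' @rdname treatmentMeta
setMethod("treatmentMeta", "RgbSection", function(x) x@meta)

#' @rdname treatmentMeta
setMethod("treatmentMeta", "SectionProfile", function(x) x@meta)

#' @rdname treatmentMeta
setMethod("treatmentMeta", "ReplicateProfile", function(x) x@meta)

#' @rdname treatmentMeta
setMethod("treatmentMeta", "SyntheticSection", function(x) x@image@meta)

#' Pixel array of an image object
#' @param x an \code{RgbSection} or \code{SyntheticSection}.
#' @return integer array \code{height x width x 3} in 0--255.
#' @export
setGeneric("pixelArray", function(x) standardGeneric("pixelArray"))

#' @rdname pixelArray
setMethod("pixelArray", "RgbSection", function(x) x@pixels)

#' @rdname pixelArray
setMethod("pixelArray", "SyntheticSection", function(x) x@image@pixels)

#' Ground truth gradient of a synthetic section
#' @param x a \code{SyntheticSection}.
#' @return a \code{GradientSpec}.
#' @export
setGeneric("sectionTruth", function(x) standardGeneric("sectionTruth"))

#' @rdname sectionTruth
setMethod("sectionTruth", "SyntheticSection", function(x) x@truth)

#' Generator geometry of a synthetic section
#' @param x a \code{SyntheticSection}.
#' @return list of geometry elements (see \linkS4class{SyntheticSection}).
#' @export
setGeneric("sectionGeometry", function(x) standardGeneric("sectionGeometry"))

#' @rdname sectionGeometry
setMethod("sectionGeometry", "SyntheticSection", function(x) x@geometry)

#' CO2 concentration in ppm for a treatment
#' @param x a \code{TreatmentLabel}.
#' @return numeric ppm (200, 400 or 700).
#' @export
setGeneric("co2Ppm", function(x) standardGeneric("co2Ppm"))

#' @rdname co2Ppm
setMethod("co2Ppm", "TreatmentLabel",
          function(x) c(LC = 200, AC = 400, EC = 700)[[x@co2]])

fmtTreatment <- function(m) {
  if (is.null(m)) return("<no metadata>")
  sprintf("%s %s %s rep %d sec %d", m@variety, m@co2, m@light,
          m@replicate, m@section)
}

setMethod("show", "TreatmentLabel", function(object) {
  cat("TreatmentLabel:", fmtTreatment(object), "\n")
})

setMethod("show", "RgbSection", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RgbSection: %d x %d px, 3 channels (8-bit), adaxial-up\n",
              d[1], d[2]))
  cat("  meta:", fmtTreatment(object@meta), "\n")
})

setMethod("show", "FluorescenceMap", function(object) {
  cat(sprintf("FluorescenceMap [%s]: %d x %d px, %.1f%% nonzero\n",
              object@channelTag, nrow(object@values), ncol(object@values),
              100 * mean(object@values > 0)))
})

setMethod("show", "DepthBins", function(object) {
  cat("DepthBins (adaxial -> abaxial):\n")
  print(round(object@means, 4))
  cat("  n pixels:", paste(object@nPixels, collapse = " "), "\n")
})

setMethod("show", "SectionProfile", function(object) {
  cat("SectionProfile over", object@nTransects, "transects |",
      fmtTreatment(object@meta), "\n")
  print(round(object@bins@means, 4))
})

setMethod("show", "ReplicateProfile", function(object) {
  cat("ReplicateProfile over", object@nSections, "sections |",
      fmtTreatment(object@meta), "\n")
  print(round(object@bins@means, 4))
})

setMethod("show", "GradientSpec", function(object) {
  cat(sprintf(paste0("GradientSpec: base %.3g, adPeak %.3g, abPeak %.3g ",
                     "(lambda %.3g), lmBump %.3g @ %.2f (w %.2f), scale %.3g\n"),
              object@base, object@adPeak, object@abPeak, object@lambda,
              object@lmBump, object@lmCenter, object@lmWidth,
              object@totalScale))
})

setMethod("show", "SyntheticSection", function(object) {
  d <- dim(object@image@pixels)
  cat(sprintf("SyntheticSection: %d x %d px, seed %d\n", d[1], d[2],
              object@seed))
  cat("  treatment:", fmtTreatment(object@image@meta), "\n")
  cat(sprintf("  vascular column groups: %d, midrib columns: %d\n",
              length(split(object@geometry$vascularColumns,
                           cumsum(c(1, diff(object@geometry$vascularColumns) != 1)))),
              length(object@geometry$midribColumns)))
})
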