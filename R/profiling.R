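## Depth profiling: systematic transect placement, per-transect intensity
## extraction, five-layer binning, and aggregation to section and replicate
## summaries.

#' Place equally spaced vertical transects with a shared random offset
#'
#' Systematic uniform random sampling: after trimming \code{edgeMarginFrac}
#' of the image width from each side, the usable width W is divided into a
#' stride s = W/n and a single offset u ~ Uniform(0, s) is drawn; nominal
#' columns sit at u + k s (k = 0, ..., n-1), counted from the midrib side
#' (column 1). One shared offset per section -- not independent offsets per
#' line -- is what makes the design unbiased. A nominal column that falls on
#' an excluded column is relocated to the nearest available column, ties
#' broken toward the midrib; chosen columns are distinct and returned in
#' increasing order.
#'
#' @param spans span table from \code{\link{mesophyllSpans}}.
#' @param excluded integer vector of excluded columns
#'   (\code{\link{vascularExclusion}}).
#' @param n number of transects (default 5).
#' @param edgeMarginFrac fraction of the width trimmed from each edge,
#'   in [0, 0.2) (default 0.03).
#' @param seed optional integer seed for the offset draw; \code{NULL} uses
#'   the current RNG stream.
#' @return Strictly increasing integer vector of n column indices.
#' @export
placeTransects <- function(spans, excluded = integer(0), n = 5L,
                           edgeMarginFrac = 0.03, seed = NULL) {
  stopifnot(is.data.frame(spans), n >= 1L,
            edgeMarginFrac >= 0, edgeMarginFrac < 0.2)
  W <- nrow(spans)
  m <- floor(edgeMarginFrac * W)
  usable <- (m + 1L):(W - m)
  candidates <- intersect(setdiff(usable, excluded),
                          spans$column[spans$valid])
  if (length(candidates) < n)
    pdStop("TOO_FEW_COLUMNS",
           sprintf("need %d non-excluded columns, have %d", n,
                   length(candidates)))
  s <- length(usable) / n
  u <- withSeed(seed, stats::runif(1L, 0, s))
  nominal <- usable[1L] - 1L + as.integer(ceiling(u + (seq_len(n) - 1L) * s))
  chosen <- integer(0)
  avail <- candidates
  for (nm in nominal) {
    d <- abs(avail - nm)
    pick <- avail[which(d == min(d))][1L]  # avail sorted: tie -> lower column
    chosen <- c(chosen, pick)
    avail <- setdiff(avail, pick)
  }
  sort(chosen)
}

#' Read the PhC intensity profile along one transect
#'
#' Vertical pixel-column read-off (no interpolation): the intensities are
#' the PhC map values from the span's adaxial boundary (index 1) down to the
#' abaxial boundary.
#'
#' @param phc the \code{PHC_YELLOW} \code{\link{FluorescenceMap}}.
#' @param span one row of the span table (list or single-row
#'   \code{data.frame} with \code{column}, \code{top}, \code{bottom},
#'   \code{valid}).
#' @return A \code{\link{Transect}}.
#' @export
extractProfile <- function(phc, span) {
  stopifnot(is(phc, "FluorescenceMap"))
  if (!isTRUE(as.logical(span$valid)) || is.na(span$top))
    pdStop("INVALID_SPAN", "span is not valid")
  top <- as.integer(span$top); bottom <- as.integer(span$bottom)
  col <- as.integer(span$column)
  new("Transect", column = col, top = top, bottom = bottom,
      intensities = as.numeric(phc@values[top:bottom, col]))
}

# Midpoint-rule bin index (1-based) for pixel i of L in nBins bins.
binIndex <- function(i, L, nBins) {
  pmin(floor(nBins * ((i - 1) + 0.5) / L), nBins - 1L) + 1L
}

#' Bin a transect into depth layers
#'
#' Pixel i (1-based) of a length-L transect is assigned to bin
#' \code{floor(nBins (i - 0.5) / L) + 1} (clamped to \code{nBins}): each
#' pixel goes to the layer containing its relative-depth midpoint, which is
#' symmetric under adaxial/abaxial flip and never lets bin counts differ by
#' more than one pixel. Bin values are arithmetic means; a bin left empty
#' (only possible when L < nBins) carries the value of the nearest non-empty
#' bin (ties toward the adaxial side) with a pixel count of 0.
#'
#' @param t a \code{\link{Transect}}.
#' @param nBins number of depth layers; the canonical analysis uses 5
#'   (AD, UM, MM, LM, AB).
#' @return A \code{\link{DepthBins}}.
#' @export
binProfile <- function(t, nBins = 5L) {
  stopifnot(is(t, "Transect"), nBins >= 1L)
  nBins <- as.integer(nBins)
  x <- t@intensities
  L <- length(x)
  if (L == 0L) pdStop("EMPTY_TRANSECT", "transect has no pixels")
  idx <- binIndex(seq_len(L), L, nBins)
  counts <- tabulate(idx, nBins)
  means <- rep(NA_real_, nBins)
  for (b in which(counts > 0L)) means[b] <- mean(x[idx == b])
  if (any(counts == 0L)) {
    filled <- which(counts > 0L)
    for (b in which(counts == 0L))
      means[b] <- means[filled[which.min(abs(filled - b))]]
  }
  new("DepthBins", means = stats::setNames(means, binLabels(nBins)),
      nPixels = as.integer(counts))
}

checkSameLayers <- function(meansList) {
  nm <- names(meansList[[1]])
  for (m in meansList)
    if (length(m) != length(nm) || !all(names(m) == nm))
      stop("layer labels differ between profiles")
  nm
}

checkSameTreatment <- function(metas, ignore = "section") {
  metas <- Filter(Negate(is.null), metas)
  if (length(metas) < 2L) return(invisible(NULL))
  fields <- setdiff(c("variety", "co2", "light", "replicate"), ignore)
  ref <- metas[[1]]
  for (m in metas[-1])
    for (f in fields)
      if (!identical(slot(m, f), slot(ref, f)))
        pdStop("META_MISMATCH",
               sprintf("profiles mix treatments (field '%s')", f))
  invisible(NULL)
}

#' Average transect bins into a section profile
#'
#' Unweighted arithmetic mean per layer over the section's transects
#' (transect lengths are not used as weights); total pixel counts are
#' recorded per layer.
#'
#' @param binsList list of \code{\link{DepthBins}}, one per transect.
#' @param meta optional \code{\link{TreatmentLabel}} for the section.
#' @return A \code{\link{SectionProfile}}.
#' @export
aggregateSection <- function(binsList, meta = NULL) {
  if (length(binsList) == 0L)
    pdStop("NOTHING_TO_AGGREGATE", "no transect bins supplied")
  stopifnot(all(vapply(binsList, is, logical(1), "DepthBins")))
  nm <- checkSameLayers(lapply(binsList, depthMeans))
  mat <- vapply(binsList, depthMeans, numeric(length(nm)))
  cnt <- vapply(binsList, binCounts, integer(length(nm)))
  bins <- new("DepthBins",
              means = stats::setNames(rowMeans(matrix(mat, nrow = length(nm))), nm),
              nPixels = as.integer(rowSums(matrix(cnt, nrow = length(nm)))))
  new("SectionProfile", bins = bins,
      nTransects = as.integer(length(binsList)), meta = meta)
}

#' Average section profiles into a replicate profile
#'
#' Unweighted mean per layer over a replicate's sections. All sections must
#' share treatment metadata (variety, CO2, light, replicate); mixing
#' treatments is an error.
#'
#' @param sections list of \code{\link{SectionProfile}}.
#' @param meta optional \code{\link{TreatmentLabel}} for the replicate; when
#'   \code{NULL}, taken from the first section.
#' @return A \code{\link{ReplicateProfile}}.
#' @export
aggregateReplicate <- function(sections, meta = NULL) {
  if (length(sections) == 0L)
    pdStop("NOTHING_TO_AGGREGATE", "no section profiles supplied")
  stopifnot(all(vapply(sections, is, logical(1), "SectionProfile")))
  checkSameTreatment(lapply(sections, treatmentMeta))
  nm <- checkSameLayers(lapply(sections, depthMeans))
  mat <- vapply(sections, depthMeans, numeric(length(nm)))
  cnt <- vapply(sections, binCounts, integer(length(nm)))
  bins <- new("DepthBins",
              means = stats::setNames(rowMeans(matrix(mat, nrow = length(nm))), nm),
              nPixels = as.integer(rowSums(matrix(cnt, nrow = length(nm)))))
  if (is.null(meta)) meta <- treatmentMeta(sections[[1]])
  new("ReplicateProfile", bins = bins,
      nSections = as.integer(length(sections)), meta = meta)
}
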