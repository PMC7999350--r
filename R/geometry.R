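## Leaf geometry: tissue mask, per-column mesophyll spans, vascular
## exclusion. The mesophyll is delimited biologically rather than by pixel
## offsets: chlorophyll autofluorescence fills the mesophyll but is absent
## from epidermal pavement cells, so the per-column chlorophyll run *is* the
## mesophyll span. Vascular bundles (and the midrib's sclerenchyma) are the
## dominant blue structures and are excluded by their per-column blue
## fraction.

# 8-connected component labelling via union-find over row runs; returns the
# mask restricted to its largest component. EBImage's labeller is
# 4-connected, hence this one.
largestComponent8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  parent <- integer(0)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unionRuns <- function(a, b) {
    ra <- findRoot(a); rb <- findRoot(b)
    if (ra != rb) parent[rb] <<- ra
  }
  runStart <- integer(0); runEnd <- integer(0); runRow <- integer(0)
  prevIdx <- integer(0)
  for (r in seq_len(H)) {
    x <- mask[r, ]
    if (!any(x)) { prevIdx <- integer(0); next }
    rl <- rle(x)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values
    s <- starts[keep]; e <- ends[keep]
    idx <- length(parent) + seq_along(s)
    parent <- c(parent, idx)
    runStart <- c(runStart, s); runEnd <- c(runEnd, e)
    runRow <- c(runRow, rep(r, length(s)))
    # 8-connectivity: runs in adjacent rows touch if column ranges overlap
    # when widened by one pixel on each side
    for (i in seq_along(idx)) {
      for (j in prevIdx) {
        if (runStart[idx[i]] <= runEnd[j] + 1L &&
            runEnd[idx[i]] >= runStart[j] - 1L)
          unionRuns(j, idx[i])
      }
    }
    prevIdx <- idx
  }
  roots <- vapply(seq_along(parent), findRoot, integer(1))
  sizes <- tapply(runEnd - runStart + 1L, roots, sum)
  best <- as.integer(names(sizes)[which.max(sizes)])
  out <- matrix(FALSE, H, W)
  for (k in which(roots == best))
    out[runRow[k], runStart[k]:runEnd[k]] <- TRUE
  out
}

#' Delimit the tissue in a cross-section image
#'
#' Thresholds the HSV value channel (pixel brightness) against a background
#' level, keeps the single largest 8-connected foreground component (this
#' drops dust specks and mounting-medium debris) and applies a morphological
#' closing with a 3x3 structuring element to fill pinholes.
#'
#' @param image an \code{\link{RgbSection}}.
#' @param bgThreshold background brightness threshold in (0, 1), default
#'   0.02.
#' @return Logical matrix (the leaf mask), \code{TRUE} = tissue.
#' @export
detectTissue <- function(image, bgThreshold = 0.02) {
  stopifnot(is(image, "RgbSection"))
  if (!isScalarNumber(bgThreshold) || bgThreshold <= 0 || bgThreshold >= 1)
    stop("bgThreshold must lie in (0, 1)")
  px <- image@pixels
  v <- pmax(px[, , 1], px[, , 2], px[, , 3]) / 255
  fg <- v > bgThreshold
  if (!any(fg)) pdStop("NO_TISSUE", "no pixel exceeds the background threshold")
  fg <- largestComponent8(fg)
  closed <- EBImage::closing(fg + 0, EBImage::makeBrush(3L, "box"))
  matrix(as.numeric(closed) > 0, nrow(fg), ncol(fg))
}

#' Per-column mesophyll spans from the chlorophyll map
#'
#' For each foreground column, the mesophyll span is the longest contiguous
#' vertical run of chlorophyll-positive pixels, with gaps of up to
#' \code{gapTolerancePx} rows bridged (intercellular air spaces). Columns
#' whose longest run is shorter than \code{minSpanPx} are marked invalid.
#' Spans never extend outside the tissue mask.
#'
#' @param chl the \code{CHLOROPHYLL_RED} \code{\link{FluorescenceMap}} of the
#'   same image.
#' @param mask logical tissue mask from \code{\link{detectTissue}}.
#' @param minSpanPx minimum valid span length in pixels (default 5).
#' @param gapTolerancePx largest bridged gap in rows (default 2).
#' @return \code{data.frame} with one row per image column: \code{column},
#'   \code{top}, \code{bottom} (NA when no chlorophyll run), \code{valid}.
#' @export
mesophyllSpans <- function(chl, mask, minSpanPx = 5L, gapTolerancePx = 2L) {
  stopifnot(is(chl, "FluorescenceMap"), is.logical(mask))
  if (!all(dim(chl@values) == dim(mask)))
    pdStop("SHAPE_MISMATCH", "chlorophyll map and mask differ in shape")
  stopifnot(minSpanPx >= 1L, gapTolerancePx >= 0L)
  W <- ncol(mask)
  out <- data.frame(column = seq_len(W), top = NA_integer_,
                    bottom = NA_integer_, valid = FALSE)
  for (cc in which(colSums(mask) > 0)) {
    pos <- which(chl@values[, cc] > 0 & mask[, cc])
    if (!length(pos)) next
    brk <- which(diff(pos) > gapTolerancePx + 1L)
    starts <- pos[c(1L, brk + 1L)]
    ends <- pos[c(brk, length(pos))]
    i <- which.max(ends - starts + 1L)
    out$top[cc] <- starts[i]
    out$bottom[cc] <- ends[i]
    out$valid[cc] <- (ends[i] - starts[i] + 1L) >= minSpanPx
  }
  out
}

#' Columns excluded from transect placement
#'
#' A column is excluded when the fraction of its mesophyll-span pixels with
#' nonzero blue (cell wall / vascular) fluorescence exceeds
#' \code{fracThreshold}; the excluded set is then dilated by
#' \code{dilateCols} columns on each side to keep transects clear of bundle
#' sheaths. Columns with invalid spans are always excluded (the midrib,
#' having no chlorophyll-backed span or a blue-saturated one, is excluded
#' implicitly).
#'
#' @param blue the \code{WALL_BLUE} \code{\link{FluorescenceMap}}.
#' @param spans span table from \code{\link{mesophyllSpans}}.
#' @param fracThreshold blue fraction above which a column is vascular
#'   (default 0.15).
#' @param dilateCols dilation half-width in columns (default 3).
#' @return Sorted integer vector of excluded column indices.
#' @export
vascularExclusion <- function(blue, spans, fracThreshold = 0.15,
                              dilateCols = 3L) {
  stopifnot(is(blue, "FluorescenceMap"), is.data.frame(spans))
  if (nrow(spans) != ncol(blue@values))
    pdStop("SHAPE_MISMATCH", "span table and blue map differ in width")
  stopifnot(fracThreshold > 0, fracThreshold < 1, dilateCols >= 0L)
  W <- nrow(spans)
  vascular <- integer(0)
  for (i in which(spans$valid)) {
    rows <- spans$top[i]:spans$bottom[i]
    if (mean(blue@values[rows, spans$column[i]] > 0) > fracThreshold)
      vascular <- c(vascular, spans$column[i])
  }
  if (length(vascular) && dilateCols > 0L)
    vascular <- unique(unlist(lapply(vascular, function(cc)
      max(1L, cc - dilateCols):min(W, cc + dilateCols))))
  sort(unique(c(vascular, spans$column[!spans$valid])))
}
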