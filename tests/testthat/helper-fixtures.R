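# Fixture builders shared across test files. Everything is generated in
# code; no image files ship with the package.

solidImage <- function(r, g, b, h = 1L, w = 1L) {
  px <- array(0L, dim = c(h, w, 3L))
  px[, , 1] <- as.integer(r); px[, , 2] <- as.integer(g)
  px[, , 3] <- as.integer(b)
  rgbSection(px)
}

randomImage <- function(h, w, seed) {
  set.seed(seed)
  rgbSection(array(sample(0:255, h * w * 3L, replace = TRUE),
                   dim = c(h, w, 3L)))
}

mapOf <- function(values, tag = "PHC_YELLOW") {
  new("FluorescenceMap", values = values, channelTag = tag)
}

fullSpans <- function(W, top = 1L, bottom = 50L) {
  data.frame(column = seq_len(W), top = as.integer(top),
             bottom = as.integer(bottom), valid = TRUE)
}

transectOf <- function(values, column = 1L, top = 1L) {
  new("Transect", column = as.integer(column), top = as.integer(top),
      bottom = as.integer(top + length(values) - 1L),
      intensities = as.numeric(values))
}

# Independent midpoint-rule oracle: pixel i goes to the bin whose
# relative-depth interval [ (b-1)/n, b/n ) contains the pixel midpoint.
binAssignOracle <- function(L, nBins) {
  vapply(seq_len(L), function(i) {
    mid <- (i - 0.5) / L
    b <- 1L
    while (b < nBins && mid >= b / nBins) b <- b + 1L
    b
  }, integer(1))
}

# Small noiseless effects config with a constant gradient (value `level`).
constantEffects <- function(level = 0.4) {
  eff <- gradientDefaults()
  eff$meanIntensity <- level
  eff$surface <- c(base = 1, adPeak = 0, abPeak = 0, lmBump = 0)
  eff$deep <- eff$surface
  eff$scale <- list(LL = c(LC = 1, AC = 1, EC = 1),
                    HL = c(LC = 1, AC = 1, EC = 1))
  eff$bojosEcBoost <- 1
  eff
}

noNoise <- function() list(fullWell = 0, gaussianSd = 0)

smallGeometry <- function() {
  g <- geometryDefaults()
  g$height <- 90L; g$width <- 220L
  g$midribCols <- 16L; g$nBundles <- 2L
  g
}
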