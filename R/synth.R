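## Synthetic half-lamina generator: diurnal light regime, treatment-driven
## analytic depth gradients, and the micrograph renderer used for
## ground-truth validation of the full pipeline.

#' Daily integral of a diurnal irradiance profile
#'
#' Exact trapezoidal integral of the piecewise-linear profile:
#' dayMax x (plateau duration + (ramp-up + ramp-down)/2), converted to
#' mol m-2 day-1 for PAR (from umol m-2 s-1) and kJ m-2 day-1 for UV-A
#' (from W m-2). With the default 05-10-15-20 schedule, the cultivation
#' maxima of 1500/400 umol m-2 s-1 give 54 and 14.4 mol m-2 day-1 and the
#' UV-A maxima of 4/0.75 W m-2 give 144 and 27 kJ m-2 day-1.
#'
#' @param p a \code{\link{DiurnalProfile}}.
#' @return Daily integral (mol m-2 day-1 for PAR, kJ m-2 day-1 for UV-A).
#' @export
dailyIntegral <- function(p) {
  stopifnot(is(p, "DiurnalProfile"))
  ru <- diff(p@rampUp); pl <- diff(p@plateau); rd <- diff(p@rampDown)
  if (any(c(ru, pl, rd) < 0))
    pdStop("BAD_SCHEDULE", "schedule has a negative duration")
  seconds <- (pl + (ru + rd) / 2) * 3600
  raw <- p@dayMax * seconds
  switch(p@quantity, PAR = raw * 1e-6, UVA = raw / 1000)
}

#' The two cultivation light regimes
#'
#' PAR and UV-A diurnal profiles for the low-light (LL: 400 umol m-2 s-1,
#' 0.75 W m-2) and high-light (HL: 1500 umol m-2 s-1, 4 W m-2) regimes.
#'
#' @param light \code{"LL"} or \code{"HL"}.
#' @return list with \code{par} and \code{uva} \code{\link{DiurnalProfile}}s.
#' @export
lightRegime <- function(light = c("LL", "HL")) {
  light <- match.arg(light)
  if (light == "HL")
    list(par = diurnalProfile("PAR", 1500), uva = diurnalProfile("UVA", 4))
  else
    list(par = diurnalProfile("PAR", 400), uva = diurnalProfile("UVA", 0.75))
}

# Evaluate the gradient closed form at relative depths d.
gradientValues <- function(spec, d) {
  spec@totalScale * (spec@base +
    spec@adPeak * exp(-d / spec@lambda) +
    spec@abPeak * exp(-(1 - d) / spec@lambda) +
    spec@lmBump * exp(-(d - spec@lmCenter)^2 / (2 * spec@lmWidth^2)))
}

#' Gradient as a function of relative depth
#' @param spec a \code{\link{GradientSpec}}.
#' @return function(d) evaluating g on relative depth d in [0, 1].
#' @export
gradientFunction <- function(spec) {
  stopifnot(is(spec, "GradientSpec"))
  function(d) gradientValues(spec, d)
}

# Mean of the unscaled shape over [0, 1], in closed form.
shapeMean <- function(base, adPeak, abPeak, lambda, lmBump, lmCenter, lmWidth) {
  surf <- lambda * (1 - exp(-1 / lambda))
  bump <- lmWidth * sqrt(2 * pi) *
    (stats::pnorm((1 - lmCenter) / lmWidth) - stats::pnorm(-lmCenter / lmWidth))
  base + (adPeak + abPeak) * surf + lmBump * bump
}

#' Default treatment-effect configuration for the gradient generator
#'
#' Two gradient shapes express the two observed localization patterns:
#' a surface-dominant shape (adaxial peak > abaxial peak, no bump) for
#' high-light or elevated-CO2 leaves, and a lower-mesophyll shape (Gaussian
#' bump at relative depth 0.7) for low-light leaves at low/ambient CO2. Both
#' shapes are normalized to unit depth-mean so that \code{totalScale} equals
#' the leaf's mean PhC intensity; the HL/LL scale ratio at low CO2 is 1.46
#' (the 46\% light effect) and the scales converge with rising CO2, elevated
#' CO2 partly substituting for high light.
#'
#' @return list of generator effect parameters; all amplitudes overridable.
#' @export
gradientDefaults <- function() {
  list(
    meanIntensity = 0.25,   # mean PhC brightness of the LL/LC reference leaf
    lambda = 0.15,          # surface-peak decay length (relative depth)
    surface = c(base = 0.25, adPeak = 0.55, abPeak = 0.35, lmBump = 0),
    deep    = c(base = 0.30, adPeak = 0.08, abPeak = 0.08, lmBump = 0.35),
    lmCenter = 0.7, lmWidth = 0.15,
    scale = list(LL = c(LC = 1.00, AC = 1.05, EC = 1.35),
                 HL = c(LC = 1.46, AC = 1.48, EC = 1.55)),
    bojosEcBoost = 1.08     # Bojos accumulates more under elevated CO2
  )
}

#' Ground-truth gradient for a treatment
#'
#' Deterministic map from a treatment to its \code{\link{GradientSpec}}:
#' high light or elevated CO2 select the surface-dominant shape; low light
#' at low/ambient CO2 selects the lower-mesophyll shape. The total scale is
#' \code{meanIntensity x scale[light][co2]}, times the Bojos boost under
#' elevated CO2.
#'
#' @param t a \code{\link{TreatmentLabel}}.
#' @param effects configuration list as \code{\link{gradientDefaults}}.
#' @return A \code{\link{GradientSpec}}.
#' @examples
#' treatmentGradient(treatmentLabel("BARKE", "AC", "LL"))  # bump at d = 0.7
#' @export
treatmentGradient <- function(t, effects = gradientDefaults()) {
  stopifnot(is(t, "TreatmentLabel"))
  surfacePattern <- t@light == "HL" || t@co2 == "EC"
  sh <- if (surfacePattern) effects$surface else effects$deep
  M <- shapeMean(sh[["base"]], sh[["adPeak"]], sh[["abPeak"]], effects$lambda,
                 sh[["lmBump"]], effects$lmCenter, effects$lmWidth)
  sc <- effects$scale[[t@light]][[t@co2]] * effects$meanIntensity / M
  if (t@variety == "BOJOS" && t@co2 == "EC") sc <- sc * effects$bojosEcBoost
  gradientSpec(base = sh[["base"]], adPeak = sh[["adPeak"]],
               abPeak = sh[["abPeak"]], lambda = effects$lambda,
               lmBump = sh[["lmBump"]], lmCenter = effects$lmCenter,
               lmWidth = effects$lmWidth, totalScale = sc)
}

#' Analytic layer means of a gradient
#'
#' The five (or \code{nBins}) layer means \eqn{(1/h)\int g(d)\,dd} over
#' equal fifths of [0, 1], by adaptive quadrature to relative tolerance
#' 1e-8. This is the ground-truth oracle that pipeline recoveries are
#' compared against.
#'
#' @param spec a \code{\link{GradientSpec}}.
#' @param nBins number of layers (default 5).
#' @return A \code{\link{DepthBins}} with pixel counts 0.
#' @export
layerTruth <- function(spec, nBins = 5L) {
  stopifnot(is(spec, "GradientSpec"), nBins >= 1L)
  g <- gradientFunction(spec)
  edges <- seq(0, 1, length.out = nBins + 1L)
  means <- vapply(seq_len(nBins), function(b)
    stats::integrate(g, edges[b], edges[b + 1L], rel.tol = 1e-8)$value /
      (edges[b + 1L] - edges[b]), numeric(1))
  new("DepthBins", means = stats::setNames(means, binLabels(nBins)),
      nPixels = integer(nBins))
}

#' Default geometry of the synthetic half-lamina
#'
#' @return list of geometry parameters: image size, epidermis thickness,
#'   lamina thickness fractions at midrib and margin, midrib and vascular
#'   bundle layout, and emission levels for the chlorophyll and blue
#'   channels.
#' @export
geometryDefaults <- function() {
  list(height = 160L, width = 480L,
       epidermisPx = 5L,
       thicknessMidrib = 0.78, thicknessMargin = 0.50,
       midrib = TRUE, midribCols = 28L,
       nBundles = 3L, bundleWidth = 9L,
       chlorophyllMean = 0.55, chlorophyllTexture = 0.08,
       blueEpidermis = 0.14, blueVascular = 0.75)
}

#' Default noise model for the renderer
#'
#' Signal-dependent Poisson noise (photon shot noise at a full-well depth of
#' \code{fullWell} counts) followed by additive Gaussian read noise.
#' Set both to 0 for a noiseless render.
#'
#' @return list with \code{fullWell} (counts; 0 disables shot noise) and
#'   \code{gaussianSd} (on the [0, 1] intensity scale).
#' @export
noiseDefaults <- function() list(fullWell = 500, gaussianSd = 2 / 255)

applyNoise <- function(v, noise) {
  if (noise$fullWell > 0)
    v <- stats::rpois(length(v), v * noise$fullWell) / noise$fullWell
  if (noise$gaussianSd > 0)
    v <- v + stats::rnorm(length(v), 0, noise$gaussianSd)
  pmin(pmax(v, 0), 1)
}

#' Render a synthetic half-lamina cross-section
#'
#' Renders, adaxial-up and midrib at the left edge: black background;
#' epidermis bands with faint blue cell-wall fluorescence and no
#' chlorophyll; a mesophyll band in which red chlorophyll emission
#' (constant mean plus texture) and yellow PhC emission following the
#' treatment's gradient g(d) occupy alternating pixel rows (so the
#' chlorophyll signal forms continuous per-column runs, gaps of one row,
#' while PhC pixels stay spectrally pure); vascular-bundle column groups and
#' the midrib with strong blue emission interleaved on the PhC rows; then
#' Poisson shot noise and Gaussian read noise, all drawn from the given
#' seed. The lamina tapers from midrib to margin. Same seed, same treatment
#' and configuration: bit-identical images.
#'
#' @param t a \code{\link{TreatmentLabel}}.
#' @param geometry list as \code{\link{geometryDefaults}}.
#' @param noise list as \code{\link{noiseDefaults}}.
#' @param effects gradient configuration as \code{\link{gradientDefaults}}.
#' @param seed integer seed.
#' @return A \code{\link{SyntheticSection}}.
#' @export
renderSection <- function(t, geometry = geometryDefaults(),
                          noise = noiseDefaults(),
                          effects = gradientDefaults(), seed = 1L) {
  stopifnot(is(t, "TreatmentLabel"))
  H <- as.integer(geometry$height); W <- as.integer(geometry$width)
  if (H < 60L || W < 200L)
    pdStop("GEOMETRY_TOO_SMALL", "need height >= 60 px and width >= 200 px")
  e <- as.integer(geometry$epidermisPx)
  spec <- treatmentGradient(t, effects)
  g <- gradientFunction(spec)

  # per-column lamina band, tapering linearly midrib -> margin
  frac <- (seq_len(W) - 1) / (W - 1)
  thick <- round(H * (geometry$thicknessMidrib +
                        (geometry$thicknessMargin - geometry$thicknessMidrib) * frac))
  laminaTop <- pmax(1L, as.integer(round((H - thick) / 2)) + 1L)
  laminaBottom <- pmin(H, laminaTop + as.integer(thick) - 1L)
  mesoTop <- laminaTop + e
  mesoBottom <- laminaBottom - e

  midribColumns <- if (isTRUE(geometry$midrib))
    seq_len(as.integer(geometry$midribCols)) else integer(0)
  nb <- as.integer(geometry$nBundles)
  bw <- as.integer(geometry$bundleWidth)
  centers <- round(seq(0.3, 0.85, length.out = max(nb, 1L)) * W)
  vascularColumns <- if (nb > 0L)
    sort(unique(unlist(lapply(centers, function(cc)
      max(1L, cc - bw %/% 2L):min(W, cc + bw %/% 2L))))) else integer(0)

  R <- matrix(0, H, W); G <- matrix(0, H, W); B <- matrix(0, H, W)
  withSeed(seed, {
    for (cc in seq_len(W)) {
      mt <- mesoTop[cc]; mb <- mesoBottom[cc]
      if (mb - mt + 1L < 4L) next
      rows <- mt:mb
      offs <- rows - mt
      depth <- (offs + 0.5) / length(rows)
      chlRows <- rows[offs %% 2L == 0L]
      phcRows <- rows[offs %% 2L == 1L]
      chl <- geometry$chlorophyllMean +
        stats::runif(length(chlRows), -1, 1) * geometry$chlorophyllTexture
      R[chlRows, cc] <- pmin(pmax(chl, 0), 1)
      blocked <- cc %in% vascularColumns || cc %in% midribColumns
      if (blocked) {
        B[phcRows, cc] <- geometry$blueVascular
      } else {
        y <- g(depth[offs %% 2L == 1L])
        R[phcRows, cc] <- y
        G[phcRows, cc] <- y
      }
      # epidermis: faint blue cell walls, no chlorophyll
      epiRows <- c(laminaTop[cc]:(mt - 1L), (mb + 1L):laminaBottom[cc])
      B[epiRows, cc] <- geometry$blueEpidermis
    }
    R[] <- applyNoise(R, noise)
    G[] <- applyNoise(G, noise)
    B[] <- applyNoise(B, noise)
  })
  px <- array(0L, dim = c(H, W, 3L))
  px[, , 1] <- as.integer(round(R * 255))
  px[, , 2] <- as.integer(round(G * 255))
  px[, , 3] <- as.integer(round(B * 255))
  new("SyntheticSection",
      image = rgbSection(px, meta = t),
      truth = spec,
      geometry = list(laminaTop = laminaTop, laminaBottom = laminaBottom,
                      mesoTop = mesoTop, mesoBottom = mesoBottom,
                      vascularColumns = vascularColumns,
                      midribColumns = midribColumns, epidermisPx = e),
      seed = as.integer(seed))
}
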