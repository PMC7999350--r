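# Diurnal light model, treatment gradients, ground-truth layer means,
# and the section renderer.

test_that("daily integrals reproduce the cultivation regimes", {
  expect_equal(dailyIntegral(diurnalProfile("PAR", 1500)), 54)
  expect_equal(dailyIntegral(diurnalProfile("PAR", 400)), 14.4)
  expect_equal(dailyIntegral(diurnalProfile("UVA", 4)), 144)
  expect_equal(dailyIntegral(diurnalProfile("UVA", 0.75)), 27)
  expect_equal(dailyIntegral(diurnalProfile("PAR", 0)), 0)
  expect_equal(dailyIntegral(lightRegime("HL")$par), 54)
  expect_equal(dailyIntegral(lightRegime("LL")$par), 14.4)
  expect_error(dailyIntegral(diurnalProfile("PAR", 100, rampUp = c(10, 5))),
               "BAD_SCHEDULE")
})

test_that("the closed-form integral matches numerical quadrature", {
  for (dayMax in c(0.75, 4, 400, 1500)) {
    p <- diurnalProfile("PAR", dayMax)
    f <- function(t) {  # piecewise-linear profile, t in hours
      ifelse(t < 5 | t > 20, 0,
        ifelse(t < 10, dayMax * (t - 5) / 5,
          ifelse(t <= 15, dayMax, dayMax * (20 - t) / 5)))
    }
    num <- stats::integrate(f, 0, 24, subdivisions = 2000L,
                            rel.tol = 1e-10)$value * 3600 * 1e-6
    expect_equal(dailyIntegral(p), num, tolerance = 1e-9)
  }
})

test_that("treatment gradients express the two localization patterns", {
  # elevated CO2 forces the surface pattern even under low light
  gEC <- treatmentGradient(treatmentLabel("BOJOS", "EC", "LL"))
  expect_equal(gEC@lmBump, 0)
  expect_gt(gEC@adPeak, gEC@abPeak)
  expect_gt(gEC@abPeak, 0)

  # low light at ambient CO2 peaks in the lower mesophyll
  gLL <- treatmentGradient(treatmentLabel("BARKE", "AC", "LL"))
  expect_gt(gLL@lmBump, 0)
  am <- stats::optimize(gradientFunction(gLL), c(0, 1), maximum = TRUE)
  expect_gt(am$maximum, 0.6)
  expect_lt(am$maximum, 0.8)

  # deterministic map
  expect_equal(treatmentGradient(treatmentLabel("BARKE", "AC", "LL")),
               gLL)

  # the 46% light effect on total intensity at low CO2
  tot <- function(li) mean(depthMeans(layerTruth(
    treatmentGradient(treatmentLabel("BARKE", "LC", li)))))
  expect_equal(tot("HL") / tot("LL"), 1.46, tolerance = 1e-6)
})

test_that("HL-LL differences converge with rising CO2", {
  tot <- function(co2, li) mean(depthMeans(layerTruth(
    treatmentGradient(treatmentLabel("BARKE", co2, li)))))
  gaps <- vapply(c("LC", "AC", "EC"),
                 function(cc) tot(cc, "HL") - tot(cc, "LL"), numeric(1))
  expect_true(all(diff(gaps) < 0))
})

test_that("layerTruth agrees with closed-form layer integrals", {
  spec <- gradientSpec(base = 0.2, adPeak = 0.5, abPeak = 0.3,
                       lambda = 0.15, lmBump = 0.25, lmCenter = 0.7,
                       lmWidth = 0.15, totalScale = 0.6)
  edges <- seq(0, 1, by = 0.2)
  analytic <- vapply(1:5, function(b) {
    a <- edges[b]; z <- edges[b + 1]
    expo <- spec@lambda * (exp(-a / spec@lambda) - exp(-z / spec@lambda))
    expo2 <- spec@lambda * (exp(-(1 - z) / spec@lambda) -
                              exp(-(1 - a) / spec@lambda))
    gauss <- spec@lmWidth * sqrt(2 * pi) *
      (pnorm((z - spec@lmCenter) / spec@lmWidth) -
         pnorm((a - spec@lmCenter) / spec@lmWidth))
    spec@totalScale * (spec@base * (z - a) + spec@adPeak * expo +
                         spec@abPeak * expo2 + spec@lmBump * gauss) / (z - a)
  }, numeric(1))
  expect_equal(unname(depthMeans(layerTruth(spec))), analytic,
               tolerance = 1e-7)

  # constant gradient: every layer equals the constant
  flat <- layerTruth(gradientSpec(base = 1, totalScale = 0.37))
  expect_equal(unname(depthMeans(flat)), rep(0.37, 5))

  # default surface (HL) gradient peaks in the adaxial layer
  hl <- layerTruth(treatmentGradient(treatmentLabel("BARKE", "LC", "HL")))
  expect_identical(names(which.max(depthMeans(hl))), "AD")
})

test_that("rendering is deterministic and respects the lamina geometry", {
  t0 <- treatmentLabel("BARKE", "AC", "HL")
  s1 <- renderSection(t0, seed = 77L)
  s2 <- renderSection(t0, seed = 77L)
  expect_identical(pixelArray(s1), pixelArray(s2))
  s3 <- renderSection(t0, seed = 78L)
  expect_false(identical(pixelArray(s1), pixelArray(s3)))

  # noiseless render: no emission of any channel outside the lamina band
  sn <- renderSection(t0, noise = noNoise(), seed = 5L)
  geo <- sectionGeometry(sn)
  px <- pixelArray(sn)
  for (cc in c(1L, 100L, 300L, 480L)) {
    outside <- setdiff(seq_len(nrow(px)),
                       geo$laminaTop[cc]:geo$laminaBottom[cc])
    expect_true(all(px[outside, cc, ] == 0L))
  }
  expect_error(renderSection(t0, geometry = within(geometryDefaults(),
                                                   height <- 40L)),
               "GEOMETRY_TOO_SMALL")
})

test_that("a constant noiseless gradient renders constant PhC pixels", {
  sec <- renderSection(treatmentLabel("BARKE", "AC", "LL"),
                       noise = noNoise(), effects = constantEffects(0.4),
                       seed = 2L)
  phc <- intensityValues(isolatePhC(sec@image))
  nz <- phc[phc > 0]
  expect_gt(length(nz), 1000L)
  expect_equal(unname(range(nz)), rep(round(0.4 * 255) / 255, 2))
})

test_that("generator-placed vascular columns exceed the blue threshold", {
  sec <- renderSection(treatmentLabel("BOJOS", "LC", "LL"), seed = 13L)
  img <- sec@image
  blue <- intensityValues(channelMask(img, "WALL_BLUE"))
  chl <- channelMask(img, "CHLOROPHYLL_RED")
  sp <- mesophyllSpans(chl, detectTissue(img))
  geo <- sectionGeometry(sec)
  fracs <- vapply(geo$vascularColumns, function(cc) {
    if (!sp$valid[cc]) return(1)
    mean(blue[sp$top[cc]:sp$bottom[cc], cc] > 0)
  }, numeric(1))
  expect_true(all(fracs > 0.15))
})
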