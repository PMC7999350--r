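# Hue-window separation of the three fluorescence colors.

test_that("hue windows reproduce hand-computed HSV conversions", {
  # pure red sits at hue 0, outside the yellow window
  expect_equal(intensityValues(isolatePhC(solidImage(255, 0, 0)))[1, 1], 0)
  # saturated yellow is the identity case: hue 60, sat 1, val 1
  expect_equal(intensityValues(isolatePhC(solidImage(255, 255, 0)))[1, 1], 1)
  # half-bright yellow keeps hue/sat, value drops to 128/255
  expect_equal(intensityValues(isolatePhC(solidImage(128, 128, 0)))[1, 1],
               128 / 255)
  # pure blue: hue 240 inside the wall window
  expect_equal(intensityValues(channelMask(solidImage(0, 0, 255),
                                           "WALL_BLUE"))[1, 1], 1)
  # yellow is not chlorophyll
  expect_equal(intensityValues(channelMask(solidImage(255, 255, 0),
                                           "CHLOROPHYLL_RED"))[1, 1], 0)
  # desaturated red: hue 0, sat 0.8, val 200/255
  expect_equal(intensityValues(channelMask(solidImage(200, 40, 40),
                                           "CHLOROPHYLL_RED"))[1, 1],
               200 / 255)
})

test_that("pixels outside a window are exactly zero and tags are set", {
  img <- randomImage(20, 20, seed = 101)
  phc <- isolatePhC(img)
  expect_s4_class(phc, "FluorescenceMap")
  expect_identical(channelTag(phc), "PHC_YELLOW")
  hsv <- grDevices::rgb2hsv(rbind(as.vector(pixelArray(img)[, , 1]),
                                  as.vector(pixelArray(img)[, , 2]),
                                  as.vector(pixelArray(img)[, , 3])),
                            maxColorValue = 255)
  outside <- hsv[1, ] * 360 < 30 | hsv[1, ] * 360 > 90 |
    hsv[2, ] < 0.2 | hsv[3, ] < 0.04
  expect_true(all(as.vector(intensityValues(phc))[outside] == 0))
})

test_that("malformed inputs raise coded errors", {
  expect_error(hueWindow(90, 30), "BAD_WINDOW")
  expect_error(hueWindow(30, 400), "BAD_WINDOW")
  expect_error(isolatePhC(solidImage(1, 1, 1), window = "nope"),
               "BAD_WINDOW")
  expect_error(rgbSection(array(integer(0), dim = c(0, 0, 3))),
               "EMPTY_IMAGE")
  expect_error(channelMask(solidImage(1, 1, 1), "MAGENTA"), "BAD_TAG")
  expect_error(channelMask(solidImage(1, 1, 1), "PHC_YELLOW"), "BAD_TAG")
})

test_that("the three default windows are mutually exclusive off boundaries", {
  for (seed in c(7, 8, 9)) {
    img <- randomImage(40, 40, seed = seed)
    y <- intensityValues(isolatePhC(img))
    r <- intensityValues(channelMask(img, "CHLOROPHYLL_RED"))
    b <- intensityValues(channelMask(img, "WALL_BLUE"))
    hsv <- grDevices::rgb2hsv(rbind(as.vector(pixelArray(img)[, , 1]),
                                    as.vector(pixelArray(img)[, , 2]),
                                    as.vector(pixelArray(img)[, , 3])),
                              maxColorValue = 255)
    onBoundary <- (hsv[1, ] * 360) %in% c(30, 90, 190, 270, 330)
    nHot <- (as.vector(y) > 0) + (as.vector(r) > 0) + (as.vector(b) > 0)
    expect_true(all(nHot[!onBoundary] <= 1))
  }
})

test_that("halving all channels halves the retained value", {
  set.seed(42)
  px <- array(2L * sample(0:127, 30 * 30 * 3, replace = TRUE),
              dim = c(30, 30, 3))
  img <- rgbSection(px)
  half <- rgbSection(px %/% 2L)
  v1 <- intensityValues(isolatePhC(img))
  v2 <- intensityValues(isolatePhC(half))
  # membership (hue, sat) is scale-invariant; compare where the halved
  # value still clears val_min
  sel <- v1 > 0 & v1 / 2 >= 0.04
  expect_equal(v2[sel], v1[sel] / 2, tolerance = 1e-12)
})

test_that("masking is idempotent within 8-bit quantization", {
  set.seed(17)
  img <- randomImage(25, 25, seed = 17)
  v <- intensityValues(isolatePhC(img))
  # keep reconstructed values clear of the val_min threshold so the
  # comparison is about quantization, not threshold straddling
  v[v > 0 & v < 0.05] <- 0.05
  recon <- rgbSection(array(as.integer(round(c(v, v, 0 * v) * 255)),
                            dim = c(dim(v), 3L)))
  v2 <- intensityValues(isolatePhC(recon))
  expect_lt(max(abs(v2 - v)), 1 / 255 + 1e-12)
})
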