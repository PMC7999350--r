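# Systematic transect placement, profile extraction, depth binning,
# aggregation.

test_that("transects form an arithmetic progression with a seeded offset", {
  spans <- fullSpans(100L)
  cols <- placeTransects(spans, n = 5L, edgeMarginFrac = 0, seed = 99L)
  u <- local({ set.seed(99L); stats::runif(1, 0, 20) })
  expect_identical(cols, as.integer(ceiling(u + (0:4) * 20)))
  expect_true(all(diff(cols) == 20L))
  # reproducible under the same seed, different under another
  expect_identical(cols, placeTransects(spans, n = 5L, edgeMarginFrac = 0,
                                        seed = 99L))
  expect_false(identical(cols, placeTransects(spans, n = 5L,
                                              edgeMarginFrac = 0,
                                              seed = 100L)))
})

test_that("excluded nominal columns relocate to the nearest allowed column", {
  spans <- fullSpans(100L)
  base <- placeTransects(spans, n = 5L, edgeMarginFrac = 0, seed = 7L)
  nm <- base[2]
  excluded <- (nm - 2L):(nm + 2L)
  got <- placeTransects(spans, excluded, n = 5L, edgeMarginFrac = 0,
                        seed = 7L)
  # equidistant candidates at nm - 3 and nm + 3; tie breaks toward the
  # midrib (lower column)
  expect_true((nm - 3L) %in% got)
  expect_false(any(got %in% excluded))
  expect_true(all(diff(got) > 0))
})

test_that("degenerate placement cases behave per contract", {
  spans <- fullSpans(50L)
  one <- placeTransects(spans, n = 1L, edgeMarginFrac = 0, seed = 3L)
  expect_length(one, 1L)
  expect_true(one >= 1L && one <= 50L)
  expect_error(placeTransects(spans, excluded = 4:50, n = 5L,
                              edgeMarginFrac = 0, seed = 1L),
               "TOO_FEW_COLUMNS")
})

test_that("extractProfile reads the span pixels verbatim", {
  v <- matrix(0, 10, 3)
  v[3:7, 2] <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  phc <- mapOf(v)
  tr <- extractProfile(phc, data.frame(column = 2L, top = 3L, bottom = 7L,
                                       valid = TRUE))
  expect_equal(intensityValues(tr), c(0.1, 0.2, 0.3, 0.4, 0.5))
  tr1 <- extractProfile(phc, data.frame(column = 1L, top = 5L, bottom = 5L,
                                        valid = TRUE))
  expect_length(intensityValues(tr1), 1L)
  expect_error(extractProfile(phc, data.frame(column = 1L, top = NA,
                                              bottom = NA, valid = FALSE)),
               "INVALID_SPAN")
})

test_that("binProfile matches the enumerated midpoint rule exhaustively", {
  for (L in 1:25) {
    x <- seq_len(L) / L
    got <- binProfile(transectOf(x), nBins = 5L)
    oracle <- binAssignOracle(L, 5L)
    want <- vapply(1:5, function(b)
      if (any(oracle == b)) mean(x[oracle == b]) else NA_real_, numeric(1))
    # empty bins carry the nearest non-empty value
    for (b in which(is.na(want))) {
      filled <- which(!is.na(want))
      want[b] <- want[filled[which.min(abs(filled - b))]]
    }
    expect_equal(unname(depthMeans(got)), want, tolerance = 1e-12)
    expect_identical(sum(binCounts(got)), L)  # partition invariant
  }
})

test_that("binProfile worked examples hold", {
  b10 <- binProfile(transectOf((1:10) / 10))
  expect_equal(unname(depthMeans(b10)), c(1.5, 3.5, 5.5, 7.5, 9.5) / 10)
  b7 <- binProfile(transectOf((1:7) / 7))
  expect_equal(unname(depthMeans(b7)), c(1, 2.5, 4, 5.5, 7) / 7)
  expect_equal(unname(binCounts(b7)), c(1L, 2L, 1L, 2L, 1L))
  bc <- binProfile(transectOf(rep(0.3, 13)))
  expect_equal(unname(depthMeans(bc)), rep(0.3, 5))
  # L = 2 leaves bins 1, 3, 5 empty with count 0
  b2 <- binProfile(transectOf(c(0.2, 0.8)))
  expect_equal(unname(binCounts(b2)), c(0L, 1L, 0L, 1L, 0L))
  expect_equal(unname(depthMeans(b2)), c(0.2, 0.2, 0.2, 0.8, 0.8))
})

test_that("strictly monotone profiles give strictly monotone bin means", {
  set.seed(5)
  for (L in c(5, 9, 23, 100)) {
    x <- sort(runif(L))
    expect_true(all(diff(depthMeans(binProfile(transectOf(x)))) > 0))
  }
})

test_that("aggregation is the unweighted mean with metadata checks", {
  b1 <- binProfile(transectOf(rep(0.2, 10)))
  b2 <- binProfile(transectOf(rep(0.4, 20)))
  sec <- aggregateSection(list(b1, b2))
  expect_equal(unname(depthMeans(sec)), rep(0.3, 5))
  expect_identical(sec@nTransects, 2L)

  five <- aggregateSection(rep(list(b1), 5))
  expect_equal(depthMeans(five), depthMeans(b1))

  m1 <- treatmentLabel("BARKE", "AC", "LL", 1, 1)
  m2 <- treatmentLabel("BARKE", "AC", "LL", 1, 2)
  m3 <- treatmentLabel("BARKE", "AC", "HL", 1, 3)
  s <- function(b, m) new("SectionProfile", bins = b, nTransects = 5L,
                          meta = m)
  b3 <- binProfile(transectOf(rep(0.9, 10)))
  rep1 <- aggregateReplicate(list(s(b1, m1), s(b2, m2)))
  expect_equal(unname(depthMeans(rep1)), rep(0.3, 5))
  expect_identical(rep1@nSections, 2L)
  # three sections with MM 0.2/0.4/0.9 average to 0.5
  rep2 <- aggregateReplicate(list(s(b1, m1), s(b2, m2), s(b3, NULL)))
  expect_equal(unname(depthMeans(rep2))[3], 0.5)

  expect_error(aggregateSection(list()), "NOTHING_TO_AGGREGATE")
  expect_error(aggregateReplicate(list(s(b1, m1), s(b2, m3))),
               "META_MISMATCH")
})
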