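# Factorial ANOVA, Fisher's LSD letters, pattern classification.

test_that("the balanced four-way design yields the canonical df column", {
  tab <- simulateLayerTable(nReplicates = 6L, seed = 21L)
  an <- anovaFixed(tab)
  want <- c(Var = 1L, CO2 = 2L, Light = 1L, Loc = 4L,
            `Var:CO2` = 2L, `Var:Light` = 1L, `CO2:Light` = 2L,
            `Var:Loc` = 4L, `CO2:Loc` = 8L, `Light:Loc` = 4L,
            `Var:CO2:Light` = 2L, `Var:CO2:Loc` = 8L,
            `Var:Light:Loc` = 4L, `CO2:Light:Loc` = 8L,
            `Var:CO2:Light:Loc` = 8L, Residuals = 300L)
  expect_identical(stats::setNames(an$df, an$term), want)
  expect_identical(sum(an$df), 359L)  # N - 1
})

test_that("df equals the product of (levels - 1) on random balanced designs", {
  set.seed(9)
  for (k in 1:5) {
    lv <- sample(2:4, 3, replace = TRUE)
    grid <- expand.grid(A = paste0("a", seq_len(lv[1])),
                        B = paste0("b", seq_len(lv[2])),
                        C = paste0("c", seq_len(lv[3])),
                        rep = 1:2, stringsAsFactors = FALSE)
    grid$response <- rnorm(nrow(grid))
    an <- anovaFixed(grid, factors = c("A", "B", "C"))
    dfOf <- function(term) an$df[an$term == term]
    expect_identical(dfOf("A"), lv[1] - 1L)
    expect_identical(dfOf("A:B"), (lv[1] - 1L) * (lv[2] - 1L))
    expect_identical(dfOf("A:B:C"), as.integer(prod(lv - 1L)))
    expect_identical(dfOf("Residuals"), as.integer(prod(lv)))
  }
})

test_that("a constant response gives F = 0 and p = 1 everywhere", {
  tab <- simulateLayerTable(nReplicates = 2L, seed = 1L)
  tab$response <- 3.7
  an <- anovaFixed(tab)
  terms <- an$term != "Residuals"
  expect_true(all(an$F[terms] == 0))
  expect_true(all(an$p[terms] == 1))
})

test_that("two-group ANOVA equals the pooled t-test squared", {
  set.seed(33)
  tab <- data.frame(Light = rep(c("LL", "HL"), each = 8),
                    response = c(rnorm(8, 0), rnorm(8, 1)))
  an <- anovaFixed(tab, factors = "Light")
  tt <- t.test(response ~ Light, data = tab, var.equal = TRUE)
  expect_equal(an$F[an$term == "Light"], unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_equal(an$p[an$term == "Light"], tt$p.value, tolerance = 1e-10)
})

test_that("unbalanced or deficient designs are rejected", {
  tab <- simulateLayerTable(nReplicates = 2L, seed = 2L)
  expect_error(anovaFixed(tab[-1, ]), "UNBALANCED")
  drop <- !(tab$Var == "BARKE" & tab$CO2 == "LC" & tab$Light == "LL" &
              tab$Loc == "AD")
  expect_error(anovaFixed(tab[drop, ]), "EMPTY_CELL")
  tab1 <- simulateLayerTable(nReplicates = 1L, seed = 3L)
  expect_error(anovaFixed(tab1), "NO_RESIDUAL")
})

test_that("Fisher LSD arithmetic and letters follow the share-iff rule", {
  # t(0.975, 10) = 2.2281, LSD = 2.2281 * sqrt(2/6) = 1.2864
  g <- fisherLSD(c(a = 10, b = 12), 6, 1, 10)
  expect_equal(attr(g, "lsd"), qt(0.975, 10) * sqrt(2 / 6))
  expect_equal(attr(g, "lsd"), 1.2864, tolerance = 1e-4)
  expect_false(g$letters[1] == g$letters[2])

  # overlap chain: 12 ~ 10.9 ~ 10 but 12 !~ 10
  g2 <- fisherLSD(c(x = 10, y = 10.9, z = 12), 6, 1, 10)
  expect_identical(g2$letters, c("a", "ab", "b"))
  # 10 and 10.5 share; 12 shares with neither (1.5 > LSD)
  g3 <- fisherLSD(c(x = 10, y = 10.5, z = 12), 6, 1, 10)
  expect_identical(stats::setNames(g3$letters, g3$cell),
                   c(z = "a", y = "b", x = "b"))
  # equal means share one letter
  g4 <- fisherLSD(c(p = 5, q = 5), 4, 1, 8)
  expect_identical(g4$letters, c("a", "a"))
  expect_error(fisherLSD(c(p = 5, q = 6), 4, 1, 0), "NO_RESIDUAL")
})

test_that("letter sharing is equivalent to mean differences within LSD", {
  for (seed in 1:10) {
    set.seed(seed)
    mu <- stats::setNames(round(runif(7, 0, 5), 2), paste0("c", 1:7))
    g <- fisherLSD(mu, 6, 1, 20)
    lsd <- attr(g, "lsd")
    lets <- strsplit(g$letters, "")
    for (i in seq_len(nrow(g))) for (j in seq_len(nrow(g))) {
      share <- length(intersect(lets[[i]], lets[[j]])) > 0
      expect_identical(share, abs(g$mean[i] - g$mean[j]) <= lsd,
                       info = sprintf("seed %d cells %d,%d", seed, i, j))
    }
  }
})

test_that("pattern classification matches the canonical contrasts", {
  bins <- function(v) new("DepthBins",
                          means = stats::setNames(v, c("AD", "UM", "MM",
                                                       "LM", "AB")),
                          nPixels = integer(5))
  expect_identical(classifyPattern(bins(c(5, 3, 2, 3, 4) / 10)),
                   "SURFACE_DOMINANT")
  expect_identical(classifyPattern(bins(c(2, 2, 3, 5, 4) / 10)),
                   "LOWER_MESOPHYLL_DOMINANT")
  expect_identical(classifyPattern(bins(rep(0.2, 5))), "FLAT")
  expect_warning(out <- classifyPattern(bins(c(1, 2, 5, 2, 1) / 10)),
                 "MM")
  expect_identical(out, "LOWER_MESOPHYLL_DOMINANT")
})
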