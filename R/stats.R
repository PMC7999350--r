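## Factorial fixed-effects ANOVA, Fisher's LSD letter groupings, and
## localization-pattern classification on the tidy layer-mean table. The
## analysis unit is the biological replicate (sections and transects are
## pre-averaged), matching the experimental design: Var (2) x CO2 (3) x
## Light (2) x Loc (5 mesophyll layers), n replicates per cell.

#' Build the tidy factorial table from replicate profiles
#'
#' One row per replicate and depth layer, with factors \code{Var},
#' \code{CO2}, \code{Light}, \code{Loc} and the layer-mean intensity as
#' \code{response}. Only replicate-level profiles enter the table: this
#' enforces the pre-averaging of sections and transects and avoids
#' pseudo-replication.
#'
#' @param replicates list of \code{\link{ReplicateProfile}} objects with
#'   metadata.
#' @return \code{data.frame} with columns \code{Var}, \code{CO2},
#'   \code{Light}, \code{Loc}, \code{replicate}, \code{response}.
#' @export
buildFactorialTable <- function(replicates) {
  stopifnot(length(replicates) > 0L,
            all(vapply(replicates, is, logical(1), "ReplicateProfile")))
  rows <- lapply(replicates, function(p) {
    m <- treatmentMeta(p)
    if (is.null(m)) stop("replicate profiles must carry treatment metadata")
    mu <- depthMeans(p)
    data.frame(Var = m@variety, CO2 = m@co2, Light = m@light,
               Loc = names(mu), replicate = m@replicate, response = unname(mu))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

checkBalance <- function(table, factors) {
  f <- interaction(table[factors], drop = FALSE)
  counts <- table(f)
  if (any(counts == 0L))
    pdStop("EMPTY_CELL", "design has empty cells")
  if (length(unique(counts)) != 1L)
    pdStop("UNBALANCED",
           "design is unbalanced; pre-average to equal replication per cell")
  as.integer(counts[1L])
}

#' Factorial fixed-effects ANOVA
#'
#' Classical fixed-effects decomposition of the full factorial over the
#' named factors; for a balanced design all sums-of-squares types coincide
#' (unbalanced designs are rejected rather than silently fitted with a
#' type-I/III choice). F = MS(term)/MS(residual), p from the F distribution.
#' A constant response yields F = 0 and p = 1 for every term.
#'
#' @param table \code{data.frame} as from \code{\link{buildFactorialTable}}.
#' @param factors factor column names (default
#'   \code{c("Var", "CO2", "Light", "Loc")}).
#' @param response response column name.
#' @return \code{data.frame} with one row per term plus a
#'   \code{Residuals} row: \code{term}, \code{df}, \code{sum_sq},
#'   \code{mean_sq}, \code{F}, \code{p}.
#' @examples
#' tab <- simulateLayerTable(nReplicates = 6, seed = 1)
#' anovaFixed(tab)
#' @export
anovaFixed <- function(table, factors = c("Var", "CO2", "Light", "Loc"),
                       response = "response") {
  stopifnot(is.data.frame(table), all(c(factors, response) %in% names(table)))
  n <- checkBalance(table, factors)
  if (n < 2L)
    pdStop("NO_RESIDUAL",
           "need >= 2 replicates per cell for a residual mean square")
  dat <- table
  for (f in factors) dat[[f]] <- factor(dat[[f]])
  fml <- stats::reformulate(paste(factors, collapse = " * "), response)
  fit <- stats::aov(fml, data = dat)
  sm <- summary(fit)[[1L]]
  term <- trimws(rownames(sm))
  out <- data.frame(term = term, df = as.integer(sm$Df), sum_sq = sm$`Sum Sq`,
                    mean_sq = sm$`Mean Sq`, F = sm$`F value`,
                    p = sm$`Pr(>F)`)
  resid <- out$term == "Residuals"
  # a (numerically) constant response has no variance to decompose:
  # report F = 0, p = 1 for vanished terms rather than 0/0
  tol <- 1e-10 * (max(abs(dat[[response]]))^2 + .Machine$double.xmin)
  if (out$mean_sq[resid] <= tol) {
    zero <- !resid & out$sum_sq <= tol
    out$F[!resid] <- ifelse(zero[!resid], 0, Inf)
    out$p[!resid] <- ifelse(zero[!resid], 1, 0)
  }
  rownames(out) <- NULL
  out
}

#' Fisher's LSD letter grouping
#'
#' Least significant difference at level alpha:
#' \code{LSD = t(1 - alpha/2, dfResid) * sqrt(2 msResid / n)}. Letters are
#' assigned so that two cell means share a letter if and only if their
#' absolute difference is at most the LSD: means are sorted in decreasing
#' order, every maximal run of means whose range is within the LSD receives
#' one letter, and a mean's letter set collects the runs covering it. No
#' multiplicity correction beyond the LSD itself is applied.
#'
#' @param cellMeans named numeric vector of cell means.
#' @param nPerCell common replication per cell.
#' @param msResid residual mean square from the ANOVA.
#' @param dfResid residual degrees of freedom.
#' @param alpha significance level (default 0.05).
#' @return \code{data.frame} with \code{cell}, \code{mean}, \code{letters}
#'   (decreasing mean order), with attributes \code{lsd} and \code{alpha}.
#' @export
fisherLSD <- function(cellMeans, nPerCell, msResid, dfResid, alpha = 0.05) {
  stopifnot(is.numeric(cellMeans), length(cellMeans) >= 1L,
            !is.null(names(cellMeans)), alpha > 0, alpha < 1)
  if (dfResid < 1) pdStop("NO_RESIDUAL", "residual df must be >= 1")
  lsd <- stats::qt(1 - alpha / 2, dfResid) * sqrt(2 * msResid / nPerCell)
  ord <- order(cellMeans, decreasing = TRUE)
  m <- cellMeans[ord]
  K <- length(m)
  # maximal runs of within-LSD means on the descending sequence
  ends <- vapply(seq_len(K), function(i) {
    j <- i
    while (j < K && m[i] - m[j + 1L] <= lsd) j <- j + 1L
    j
  }, integer(1))
  groups <- list()
  lastEnd <- 0L
  for (i in seq_len(K)) {
    if (i == 1L || ends[i] > lastEnd) {
      groups[[length(groups) + 1L]] <- i:ends[i]
      lastEnd <- ends[i]
    }
  }
  lab <- rep("", K)
  for (gi in seq_along(groups))
    lab[groups[[gi]]] <- paste0(lab[groups[[gi]]], letters[gi])
  out <- data.frame(cell = names(m), mean = unname(m), letters = lab)
  attr(out, "lsd") <- lsd
  attr(out, "alpha") <- alpha
  out
}

#' Classify the depth-localization pattern of a profile
#'
#' \code{FLAT} when the relative range (max - min)/mean of the layer means
#' is below 0.05; otherwise \code{SURFACE_DOMINANT} when the maximum layer
#' is AD or AB, and \code{LOWER_MESOPHYLL_DOMINANT} when it is LM. A
#' MM-maximal profile maps to \code{LOWER_MESOPHYLL_DOMINANT} and a
#' UM-maximal profile to \code{SURFACE_DOMINANT}, each with a warning, since
#' neither canonical pattern peaks mid-leaf.
#'
#' @param p a \code{\link{ReplicateProfile}}, \code{\link{SectionProfile}}
#'   or \code{\link{DepthBins}} with the five canonical layers.
#' @return \code{"SURFACE_DOMINANT"}, \code{"LOWER_MESOPHYLL_DOMINANT"} or
#'   \code{"FLAT"}.
#' @export
classifyPattern <- function(p) {
  mu <- depthMeans(p)
  stopifnot(length(mu) == 5L, all(names(mu) == binLabels(5L)))
  if (mean(mu) == 0 || (max(mu) - min(mu)) / mean(mu) < 0.05) return("FLAT")
  top <- names(mu)[which.max(mu)]
  switch(top,
    AD = , AB = "SURFACE_DOMINANT",
    LM = "LOWER_MESOPHYLL_DOMINANT",
    MM = { pdWarn("profile peaks in MM; classifying as LOWER_MESOPHYLL_DOMINANT")
           "LOWER_MESOPHYLL_DOMINANT" },
    UM = { pdWarn("profile peaks in UM; classifying as SURFACE_DOMINANT")
           "SURFACE_DOMINANT" })
}

#' Simulate a balanced factorial layer-mean table
#'
#' Gaussian response over the full Var (2) x CO2 (3) x Light (2) x Loc (5)
#' design with \code{nReplicates} per cell; optional additive main effects
#' for calibration studies (e.g. a Light effect expressed in residual-sd
#' units). With all effects 0 this is a null table for type-I error checks.
#'
#' @param nReplicates replicates per cell (default 6).
#' @param mean,sigma response mean and residual standard deviation.
#' @param lightEffect additive shift of HL vs LL (response units).
#' @param seed optional integer seed.
#' @return \code{data.frame} in the \code{\link{anovaFixed}} layout.
#' @export
simulateLayerTable <- function(nReplicates = 6L, mean = 1, sigma = 1,
                               lightEffect = 0, seed = NULL) {
  stopifnot(nReplicates >= 1L)
  grid <- expand.grid(Var = c("BARKE", "BOJOS"), CO2 = c("LC", "AC", "EC"),
                      Light = c("LL", "HL"), Loc = binLabels(5L),
                      replicate = seq_len(nReplicates),
                      stringsAsFactors = FALSE)
  grid$response <- withSeed(seed,
    mean + lightEffect * (grid$Light == "HL") +
      stats::rnorm(nrow(grid), 0, sigma))
  grid
}
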