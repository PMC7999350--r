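## The assembled pipeline and its batch front ends: simulate a factorial
## image set, profile a manifest of images into tidy layer-mean tables, and
## analyze the replicate table (ANOVA + LSD letters + pattern calls).

#' Depth-profile one section image
#'
#' Runs the full single-image pipeline: isolate the PhC (yellow),
#' chlorophyll (red) and wall (blue) channels; delimit tissue; find
#' per-column mesophyll spans; exclude vascular columns; place the
#' systematic transects; extract and bin each transect; average into a
#' section profile.
#'
#' @param image an \code{\link{RgbSection}}.
#' @param config configuration list (\code{\link{defaultRunConfig}}).
#' @param seed optional integer seed for the transect offset.
#' @param details also return the per-transect table.
#' @return A \code{\link{SectionProfile}}, or (with \code{details}) a list
#'   with elements \code{profile}, \code{transects} (tidy per-transect
#'   layer means) and \code{columns}.
#' @examples
#' sec <- renderSection(treatmentLabel("BARKE", "AC", "HL"), seed = 7)
#' profileSection(sec@image, seed = 7)
#' @export
profileSection <- function(image, config = defaultRunConfig(), seed = NULL,
                           details = FALSE) {
  stopifnot(is(image, "RgbSection"))
  wins <- windowsFromConfig(config)
  phc <- isolatePhC(image, wins$yellow)
  chl <- channelMask(image, "CHLOROPHYLL_RED", wins)
  blue <- channelMask(image, "WALL_BLUE", wins)
  mask <- detectTissue(image, config$geometry$bg_threshold)
  spans <- mesophyllSpans(chl, mask, config$geometry$min_span_px,
                          config$geometry$gap_tolerance_px)
  excl <- vascularExclusion(blue, spans, config$geometry$vascular_frac,
                            config$geometry$dilate_cols)
  cols <- placeTransects(spans, excl, config$sampling$n_transects,
                         config$sampling$edge_margin_frac, seed = seed)
  bins <- lapply(cols, function(cc)
    binProfile(extractProfile(phc, spans[cc, ]), config$binning$n_bins))
  profile <- aggregateSection(bins, meta = image@meta)
  if (!details) return(profile)
  tidy <- do.call(rbind, lapply(seq_along(cols), function(i)
    data.frame(transect = i, column = cols[i],
               layer = names(depthMeans(bins[[i]])),
               mean_intensity = unname(depthMeans(bins[[i]])),
               n_pixels = binCounts(bins[[i]]))))
  list(profile = profile, transects = tidy, columns = cols)
}

treatmentGrid <- function() {
  expand.grid(variety = c("BARKE", "BOJOS"), co2 = c("LC", "AC", "EC"),
              light = c("LL", "HL"), stringsAsFactors = FALSE)
}

#' Simulate a full factorial image set
#'
#' Renders the complete 2 (variety) x 3 (CO2) x 2 (light) factorial with
#' \code{nReplicates} replicates of \code{n_sections} sections each, writes
#' one TIFF and one ground-truth JSON per image plus a manifest CSV, all
#' deterministic under \code{seed} (each image draws its own sub-seed from
#' the global seed and its identity, so adding images does not perturb
#' existing ones).
#'
#' @param outDir output directory (created if needed).
#' @param nReplicates replicates per treatment cell.
#' @param seed global integer seed.
#' @param config configuration list.
#' @return The manifest \code{data.frame}, invisibly.
#' @export
runSimulate <- function(outDir, nReplicates = 6L, seed = 1L,
                        config = defaultRunConfig()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (nReplicates < 1L) {
    pdWarn("nReplicates is 0; writing an empty manifest")
    manifest <- data.frame(path = character(0), variety = character(0),
                           co2 = character(0), light = character(0),
                           replicate = integer(0), section = integer(0),
                           seed = integer(0))
    writeManifest(manifest, file.path(outDir, "manifest.csv"))
    return(invisible(manifest))
  }
  grid <- treatmentGrid()
  rows <- list()
  for (i in seq_len(nrow(grid))) for (r in seq_len(nReplicates))
    for (s in seq_len(config$generator$n_sections)) {
      id <- sprintf("%s_%s_%s_r%02d_s%d", grid$variety[i], grid$co2[i],
                    grid$light[i], r, s)
      subSeed <- deriveSeed(seed, id)
      t <- treatmentLabel(grid$variety[i], grid$co2[i], grid$light[i], r, s)
      sec <- renderSection(t, config$generator$geometry,
                           config$generator$noise,
                           config$generator$effects, seed = subSeed)
      img <- file.path(outDir, paste0(id, ".tif"))
      writeSection(sec, img)
      writeTruthJson(sectionTruth(sec), file.path(outDir, paste0(id, ".truth.json")))
      rows[[id]] <- data.frame(path = img, variety = grid$variety[i],
                               co2 = grid$co2[i], light = grid$light[i],
                               replicate = r, section = s, seed = subSeed)
    }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  writeManifest(manifest, file.path(outDir, "manifest.csv"))
  invisible(manifest)
}

#' Profile every image of a manifest
#'
#' Runs \code{\link{profileSection}} on each manifest row and writes three
#' tidy CSVs to \code{outDir}: \code{transects.csv} (one row per image,
#' transect and layer), \code{sections.csv} and \code{replicates.csv}
#' (section- and replicate-level layer means). Images that fail (e.g. no
#' tissue found) are logged and skipped, not fatal.
#'
#' @param manifest manifest \code{data.frame} or CSV path.
#' @param outDir output directory.
#' @param config configuration list.
#' @param seed global seed for transect offsets (per-image sub-seeds are
#'   taken from the manifest's \code{seed} column when present, otherwise
#'   derived from this seed and the image identity).
#' @return list with \code{transects}, \code{sections}, \code{replicates}
#'   data.frames and \code{skipped} (character vector of failed paths),
#'   invisibly.
#' @export
runProfile <- function(manifest, outDir, config = defaultRunConfig(),
                       seed = 1L) {
  if (is.character(manifest)) manifest <- readManifest(manifest)
  validateManifest(manifest)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  transects <- list(); sections <- list(); skipped <- character(0)
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    t <- treatmentLabel(row$variety, row$co2, row$light, row$replicate,
                        row$section)
    imgSeed <- if (!is.null(row$seed) && !is.na(row$seed)) row$seed
               else deriveSeed(seed, row$path)
    res <- tryCatch({
      img <- readSection(row$path, meta = t)
      profileSection(img, config, seed = imgSeed, details = TRUE)
    }, phcDepthError = function(e) e)
    if (inherits(res, "error")) {
      message("skipping ", row$path, ": ", conditionMessage(res))
      skipped <- c(skipped, row$path)
      next
    }
    tt <- res$transects
    meta <- data.frame(variety = row$variety, co2 = row$co2,
                       light = row$light, replicate = row$replicate,
                       section = row$section)
    transects[[i]] <- cbind(meta[rep(1L, nrow(tt)), , drop = FALSE], tt,
                            seed = imgSeed, row.names = NULL)
    mu <- depthMeans(res$profile)
    sections[[i]] <- cbind(meta[rep(1L, length(mu)), , drop = FALSE],
                           data.frame(layer = names(mu),
                                      mean_intensity = unname(mu),
                                      n_transects = res$profile@nTransects),
                           row.names = NULL)
  }
  transects <- do.call(rbind, transects)
  sections <- do.call(rbind, sections)
  replicates <- NULL
  if (!is.null(sections) && nrow(sections) > 0L) {
    agg <- stats::aggregate(
      mean_intensity ~ variety + co2 + light + replicate + layer,
      data = sections, FUN = mean)
    nsec <- stats::aggregate(
      mean_intensity ~ variety + co2 + light + replicate + layer,
      data = sections, FUN = length)
    agg$n_sections <- nsec$mean_intensity
    ord <- order(agg$variety, agg$co2, agg$light, agg$replicate,
                 match(agg$layer, binLabels(5L)))
    replicates <- agg[ord, ]
    rownames(replicates) <- NULL
  }
  for (nm in c("transects", "sections", "replicates")) {
    df <- get(nm)
    if (!is.null(df))
      utils::write.csv(df, file.path(outDir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  invisible(list(transects = transects, sections = sections,
                 replicates = replicates, skipped = skipped))
}

#' Analyze a replicate-level layer table
#'
#' Builds the factorial table from a replicate-level CSV (as written by
#' \code{\link{runProfile}}), fits the four-way fixed-effects ANOVA, assigns
#' Fisher's LSD letters to the CO2 x Light x Loc cell means (within each
#' variety or pooled across varieties), classifies each treatment's
#' localization pattern, and writes \code{anova.csv},
#' \code{lsd_letters.csv}, \code{patterns.csv} and a plain-text
#' \code{report.txt}.
#'
#' @param replicates replicate-level \code{data.frame} or CSV path with
#'   columns \code{variety}, \code{co2}, \code{light}, \code{replicate},
#'   \code{layer}, \code{mean_intensity}.
#' @param outDir output directory.
#' @param alpha LSD significance level.
#' @param grouping \code{"within_variety"} or \code{"pooled"}.
#' @return list with \code{anova}, \code{lsd}, \code{patterns}, invisibly.
#' @export
runAnalyze <- function(replicates, outDir, alpha = 0.05,
                       grouping = c("within_variety", "pooled")) {
  grouping <- match.arg(grouping)
  if (is.character(replicates))
    replicates <- utils::read.csv(replicates, stringsAsFactors = FALSE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tab <- data.frame(Var = replicates$variety, CO2 = replicates$co2,
                    Light = replicates$light, Loc = replicates$layer,
                    replicate = replicates$replicate,
                    response = replicates$mean_intensity)
  an <- anovaFixed(tab)
  res <- an[an$term == "Residuals", ]
  cellFactors <- if (grouping == "within_variety")
    c("CO2", "Light", "Loc") else c("Var", "CO2", "Light", "Loc")
  lsdTables <- list()
  varGroups <- if (grouping == "within_variety") unique(tab$Var) else "all"
  for (v in varGroups) {
    sub <- if (identical(v, "all")) tab else tab[tab$Var == v, ]
    mu <- tapply(sub$response, interaction(sub[cellFactors], sep = ":",
                                           drop = TRUE), mean)
    n <- length(unique(sub$replicate))
    lt <- fisherLSD(stats::setNames(as.numeric(mu), names(mu)), n,
                    res$mean_sq, res$df, alpha)
    lt$variety <- v
    lsdTables[[v]] <- lt
  }
  lsd <- do.call(rbind, lsdTables)
  rownames(lsd) <- NULL
  # pattern call per treatment from the replicate-averaged profile
  treat <- unique(tab[c("Var", "CO2", "Light")])
  patterns <- do.call(rbind, lapply(seq_len(nrow(treat)), function(i) {
    sub <- tab[tab$Var == treat$Var[i] & tab$CO2 == treat$CO2[i] &
                 tab$Light == treat$Light[i], ]
    mu <- tapply(sub$response, sub$Loc, mean)[binLabels(5L)]
    bins <- new("DepthBins",
                means = stats::setNames(as.numeric(mu), binLabels(5L)),
                nPixels = integer(5L))
    data.frame(treat[i, ], pattern = classifyPattern(bins),
               row.names = NULL)
  }))
  utils::write.csv(an, file.path(outDir, "anova.csv"), row.names = FALSE)
  utils::write.csv(lsd, file.path(outDir, "lsd_letters.csv"),
                   row.names = FALSE)
  utils::write.csv(patterns, file.path(outDir, "patterns.csv"),
                   row.names = FALSE)
  rpt <- c("Factorial fixed-effects ANOVA (replicate-level layer means)",
           utils::capture.output(print(an, digits = 4)),
           "", sprintf("Fisher's LSD letters (alpha = %g, %s)", alpha,
                       grouping),
           utils::capture.output(print(lsd, digits = 4)),
           "", "Localization patterns:",
           utils::capture.output(print(patterns)))
  writeLines(rpt, file.path(outDir, "report.txt"))
  invisible(list(anova = an, lsd = lsd, patterns = patterns))
}
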