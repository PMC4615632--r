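#' Read and write two-column spectrum files
#'
#' Spectra travel as two-column CSV with header `wavelength_nm,value`.
#' Reflectance on a percent scale (maximum above 1.5) is auto-detected and
#' divided by 100 with a warning; negative values are clipped to 0 with a
#' warning; non-monotone wavelengths are a parse error reporting the first
#' offending line.
#'
#' @param path CSV file path.
#' @param kind spectrum kind to assign on read.
#' @return `readSpectrumCSV`: a [Spectrum-class]; `writeSpectrumCSV`: the
#'   path, invisibly.
#' @export
readSpectrumCSV <- function(path, kind = "reflectance") {
  d <- utils::read.csv(path)
  if (ncol(d) < 2L) stop("expected two columns: wavelength_nm, value")
  w <- as.numeric(d[[1]])
  v <- as.numeric(d[[2]])
  if (anyNA(w) || anyNA(v)) stop("non-numeric entries in ", path)
  bad <- which(diff(w) <= 0)
  if (length(bad))
    stop(sprintf("wavelengths not strictly increasing at line %d of %s",
                 bad[1] + 2L, path))  # +1 header, +1 diff offset
  if (any(v < 0)) {
    warning("negative values clipped to 0 in ", path)
    v <- pmax(v, 0)
  }
  if (kind == "reflectance" && max(v) > 1.5) {
    warning("values look like percent reflectance; dividing by 100")
    v <- v / 100
  }
  Spectrum(w, v, kind)
}

#' @rdname readSpectrumCSV
#' @param spectrum a [Spectrum-class] to write.
#' @export
writeSpectrumCSV <- function(spectrum, path) {
  stopifnot(is(spectrum, "Spectrum"))
  utils::write.csv(
    data.frame(wavelength_nm = wavelengths(spectrum),
               value = specValues(spectrum)),
    path, row.names = FALSE)
  invisible(path)
}

.MEASUREMENT_COLS <- c("id", "morph", "week")

#' Read the tidy measurement table
#'
#' Parses the per-female measurement table (CSV; one row per female and
#' week) into the three analysis inputs: the feature table for morph
#' classification (rows flagged `peak = TRUE`, the week of peak colour
#' expression chosen per female), the hormone panel (rows with a `timepoint`
#' and `testosterone`), and the long colour time-course. Unknown columns
#' are preserved.
#'
#' Expected columns: `id`, `morph`, `week`, optional `peak` (logical),
#' optional `timepoint` + `testosterone` (ng/mL), and the colour variables
#' `prop_red`, `prop_yellow`, `prop_grey`, `throat_cc`, `throat_ac`,
#' `bib_cc`, `bib_ac`.
#'
#' @param path CSV file path.
#' @return list with `features` (data.frame, one row per female), `hormones`
#'   (female/timepoint/testosterone), `timecourse` (female/morph/week +
#'   colour variables) and `summary` (row counts).
#' @export
readMeasurementTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.MEASUREMENT_COLS, names(d))
  if (length(missing))
    stop("measurement table lacks mandatory columns: ",
         paste(missing, collapse = ", "))
  featCols <- intersect(.featureNames, names(d))
  features <- NULL
  if ("peak" %in% names(d) && length(featCols)) {
    features <- d[as.logical(d$peak) %in% TRUE, c("id", "morph", featCols)]
    if (anyDuplicated(features$id))
      stop("more than one peak-expression row per female")
  }
  hormones <- NULL
  if (all(c("timepoint", "testosterone") %in% names(d))) {
    h <- d[!is.na(d$timepoint) & !is.na(d$testosterone),
           c("id", "timepoint", "testosterone")]
    if (nrow(h)) {
      names(h)[1] <- "female"
      if (anyDuplicated(h[, c("female", "timepoint")]))
        stop("duplicate (female, timepoint) hormone records")
      hormones <- h
    }
  }
  timecourse <- NULL
  if (length(featCols)) {
    tc <- d[!is.na(d$week), c("id", "morph", "week", featCols)]
    names(tc)[1] <- "female"
    if (nrow(tc)) timecourse <- tc
  }
  list(features = features, hormones = hormones, timecourse = timecourse,
       summary = list(nRows = nrow(d),
                      nFemales = length(unique(d$id)),
                      nPeak = if (is.null(features)) 0L else nrow(features),
                      nHormone = if (is.null(hormones)) 0L else nrow(hormones)))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages of the colour-morph analysis from a configuration
#' list: optional synthetic simulation, image segmentation, spectral
#' contrasts, morph classification (canonical discriminant analysis plus
#' leave-one-out cross-validation), hormone ANOVA with adjusted contrasts,
#' the morph-frequency exact test and the colour time-course mixed models.
#' A stage whose inputs are absent is skipped; a stage error is recorded in
#' the bundle and downstream dependent stages are skipped. Results, the
#' echoed configuration and the seed are written as JSON to `outDir` when
#' given.
#'
#' @param config list with any of: `seed` (default 1), `simulate` (logical:
#'   generate all inputs synthetically), `measurementTable` (path or
#'   data.frame in [readMeasurementTable()] layout), `images` (list of
#'   scenes as from [genThroatImage()]), `maleCounts` (named morph counts
#'   for the sex-frequency test), `thresholds`, `prior`, `responses`
#'   (colour variables to model over time), `outDir`.
#' @return list of stage results (`segmentation`, `dfa`, `loo`, `hormone`,
#'   `pairwise`, `morphFrequency`, `timecourse`, `errors`, `config`).
#' @export
runPipeline <- function(config = list()) {
  cfg <- utils::modifyList(list(seed = 1L, simulate = FALSE,
                                thresholds = c(red = 0.20, yellow = 0.15),
                                prior = "equal",
                                responses = "prop_red"), config)
  errors <- list()
  note <- function(stage, e) errors[[stage]] <<- conditionMessage(e)
  features <- hormones <- timecourse <- NULL
  if (!is.null(cfg$measurementTable)) {
    tab <- if (is.character(cfg$measurementTable))
      readMeasurementTable(cfg$measurementTable)
    else cfg$measurementTable
    features <- tab$features; hormones <- tab$hormones
    timecourse <- tab$timecourse
  }
  if (isTRUE(cfg$simulate)) {
    features <- genFeatureTable(seed = cfg$seed)
    hormones <- genHormonePanel(seed = cfg$seed + 1L)
    timecourse <- genTimecourse(seed = cfg$seed + 2L)
  }
  segmentation <- NULL
  if (!is.null(cfg$images)) {
    segmentation <- lapply(cfg$images, function(sc) {
      tryCatch({
        model <- fitLinearization(sc$graySquares[, c("R", "G", "B")],
                                  sc$graySquares$reflectance)
        cal <- equalizeToStandard(applyCalibration(sc$image, model),
                                  sc$standardMask)
        seg <- segmentThroat(cal, sc$throatMask, cfg$thresholds)
        as.list(layerProportions(seg))
      }, error = function(e) list(error = conditionMessage(e)))
    })
  }
  dfa <- loo <- NULL
  if (!is.null(features)) {
    dfa <- tryCatch(canonicalDiscriminant(features, prior = cfg$prior),
                    error = function(e) { note("dfa", e); NULL })
    if (!is.null(dfa))
      loo <- tryCatch(crossValidateLOO(features, prior = cfg$prior),
                      error = function(e) { note("loo", e); NULL })
  }
  hormone <- pairwise <- NULL
  if (!is.null(hormones)) {
    hormone <- tryCatch(anovaTime(hormones),
                        error = function(e) { note("hormone", e); NULL })
    if (!is.null(hormone))
      pairwise <- tryCatch(pairwiseAdjusted(hormone),
                           error = function(e) { note("pairwise", e); NULL })
  }
  morphFrequency <- NULL
  if (!is.null(features) && !is.null(cfg$maleCounts)) {
    morphFrequency <- tryCatch({
      fem <- table(factor(features$morph, levels = names(cfg$maleCounts)))
      freemanHaltonExact(rbind(male = cfg$maleCounts,
                               female = as.vector(fem)))
    }, error = function(e) { note("morphFrequency", e); NULL })
  }
  tc <- NULL
  if (!is.null(timecourse)) {
    tc <- lapply(intersect(cfg$responses, names(timecourse)), function(v) {
      tryCatch(fitTimecourse(timecourse, v),
               error = function(e) { note(paste0("timecourse:", v), e); NULL })
    })
    names(tc) <- intersect(cfg$responses, names(timecourse))
  }
  bundle <- list(segmentation = segmentation, dfa = dfa, loo = loo,
                 hormone = hormone, pairwise = pairwise,
                 morphFrequency = morphFrequency, timecourse = tc,
                 errors = errors, config = cfg)
  if (!is.null(cfg$outDir)) .writeBundle(bundle, cfg$outDir)
  bundle
}

.writeBundle <- function(bundle, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  out <- list(
    seed = bundle$config$seed,
    version = as.character(utils::packageVersion("dragonmorph")),
    segmentation = bundle$segmentation,
    dfa = if (!is.null(bundle$dfa)) list(
      eigenvalues = bundle$dfa$eigenvalues,
      percentVariance = bundle$dfa$percentVariance,
      wilksLambda = bundle$dfa$wilksLambda,
      F = bundle$dfa$F, df1 = bundle$dfa$df1, df2 = bundle$dfa$df2,
      pValue = bundle$dfa$pValue),
    loo = if (!is.null(bundle$loo)) list(
      confusion = unclass(bundle$loo$confusion),
      perClassRate = as.list(bundle$loo$perClassRate),
      overallRate = bundle$loo$overallRate),
    hormone = if (!is.null(bundle$hormone)) list(
      F = bundle$hormone$F, df = bundle$hormone$df,
      pValue = bundle$hormone$pValue, lsmeans = bundle$hormone$lsmeans),
    pairwise = bundle$pairwise,
    morphFrequency = if (!is.null(bundle$morphFrequency))
      list(pValue = bundle$morphFrequency$pValue,
           nTables = bundle$morphFrequency$nTables),
    timecourse = lapply(bundle$timecourse, function(f)
      if (!is.null(f)) list(anova = f$anova,
                            varianceComponents = as.list(f$varianceComponents))),
    errors = bundle$errors)
  jsonlite::write_json(out, file.path(outDir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  cfgEcho <- bundle$config
  cfgEcho$images <- if (!is.null(cfgEcho$images)) length(cfgEcho$images)
  cfgEcho$measurementTable <- if (is.character(cfgEcho$measurementTable))
    cfgEcho$measurementTable
  else if (!is.null(cfgEcho$measurementTable)) "<in-memory>"
  jsonlite::write_json(cfgEcho, file.path(outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(outDir)
}
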