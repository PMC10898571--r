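#' Read a spectrum from a two-column CSV file
#'
#' Expects two numeric columns (wavenumber cm^-1, counts), an optional
#' header row, and optional leading metadata comment lines of the form
#' \code{# key: value}. A descending axis is sorted ascending with a
#' warning; duplicated wavenumbers and non-numeric rows are parse errors
#' naming the offending line.
#'
#' @param path file path.
#' @return A [RamanSpectrum-class].
#' @export
readSpectrum <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  metaLines <- grep("^#", lines)
  meta <- list()
  for (ln in metaLines) {
    kv <- sub("^#\\s*", "", lines[ln])
    if (grepl(":", kv)) {
      key <- trimws(sub(":.*$", "", kv))
      val <- trimws(sub("^[^:]*:", "", kv))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  body <- if (length(metaLines)) lines[-metaLines] else lines
  first <- strsplit(body[1], ",")[[1]]
  hasHeader <- any(is.na(suppressWarnings(as.numeric(first))))
  rows <- strsplit(body[if (hasHeader) -1 else TRUE], ",")
  bad <- which(vapply(rows, length, 1L) != 2)
  if (length(bad))
    stop("line ", bad[1] + hasHeader + length(metaLines),
         ": expected two comma-separated values")
  w <- suppressWarnings(as.numeric(vapply(rows, `[`, "", 1)))
  v <- suppressWarnings(as.numeric(vapply(rows, `[`, "", 2)))
  if (anyNA(w) || anyNA(v)) {
    bad <- which(is.na(w) | is.na(v))[1]
    stop("line ", bad + hasHeader + length(metaLines), ": non-numeric value")
  }
  if (length(w) < 4) stop("need at least 4 channels")
  if (anyDuplicated(w)) {
    d <- which(duplicated(w))[1]
    stop("line ", d + hasHeader + length(metaLines),
         ": duplicated wavenumber ", w[d])
  }
  if (is.unsorted(w)) {
    warning("wavenumber axis not ascending in ", basename(path),
            "; sorting")
    o <- order(w)
    w <- w[o]; v <- v[o]
  }
  RamanSpectrum(w, v, metadata = meta)
}

#' Write a spectrum to a two-column CSV file
#'
#' Scalar metadata entries are written as leading \code{# key: value}
#' comment lines, so that [readSpectrum()] round-trips values and metadata.
#'
#' @param spectrum a [RamanSpectrum-class].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeSpectrum <- function(spectrum, path) {
  md <- spectrum@metadata
  scal <- md[vapply(md, function(x)
    is.atomic(x) && length(x) == 1, logical(1))]
  hdr <- sprintf("# %s: %s", names(scal), vapply(scal, format, ""))
  body <- c("wavenumber,counts",
            sprintf("%.10g,%.10g", wavenumber(spectrum), counts(spectrum)))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Default run configuration
#'
#' The full set of configurable parameters for [runPipeline()], with the
#' study defaults: the 20 mm phantom with a 100 um collagen layer, 0.6 mm
#' base / 0.08 mm refined discretization, the 21 x 21 search grid over
#' +/- 5 mm under a 3 mW/mm^2 MPE, the 910-950 cm^-1 band, and the
#' 16-spectrum thickness series.
#'
#' @return Nested named list.
#' @export
defaultRunConfig <- function() {
  list(
    phantom = list(lateralExtent = 20, depthExtent = 20,
                   skinThickness = 0.75, fatThickness = 0.75,
                   implantRadius = 4, implantThickness = 2,
                   collagenThickness = 100),
    grid = list(spacing = 0.6, refinedSpacing = 0.08),
    optics = NULL,
    generator = list(countScale = 1000, noise = TRUE,
                     thicknesses = c(10, 20, 40, 60, 80, 100, 150, 200),
                     replicates = 2, targetSNR = NULL),
    instrument = list(preset = "linear", power = 45),
    search = list(surfaceN = 21, mpe = 3),
    calibrate = list(),
    predict = list(),
    band = c(910, 950),
    seed = 1,
    logLevel = "info")
}

#' Read and validate a run configuration
#'
#' Reads a YAML or JSON configuration file, rejects unknown keys, and fills
#' unset values from [defaultRunConfig()].
#'
#' @param path file path (.yaml/.yml or .json), or NULL for the defaults.
#' @return Validated configuration list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (is.null(path)) return(cfg)
  user <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                           simplifyVector = TRUE)
          else yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (k in names(user)) {
    if (k %in% c("calibrate", "predict")) {
      cfg[[k]] <- user[[k]]
    } else if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      unknown <- setdiff(names(user[[k]]), names(cfg[[k]]))
      if (length(unknown))
        stop("unknown configuration key(s) under '", k, "': ",
             paste(unknown, collapse = ", "))
      cfg[[k]] <- modifyList(cfg[[k]], user[[k]])
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  cfg
}

.log <- function(cfg, ...) {
  if (identical(cfg$logLevel, "silent")) return(invisible())
  message(format(Sys.time(), "%H:%M:%S "), ...)
}

## write a thickness series as spectra CSVs + manifest + generator spec
.writeSeries <- function(se, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  w <- SummarizedExperiment::rowData(se)$wavenumber
  m <- SummarizedExperiment::assay(se, "counts")
  files <- character(nrow(cd))
  for (i in seq_len(nrow(cd))) {
    files[i] <- sprintf("%s.csv", rownames(cd)[i])
    s <- RamanSpectrum(w, m[, i], metadata = c(as.list(cd[i, ]),
                                               list(label = rownames(cd)[i])))
    writeSpectrum(s, file.path(dir, files[i]))
  }
  manifest <- cbind(file = files, cd)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(S4Vectors::metadata(se)$generator,
                       file.path(dir, "generator.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, "manifest.csv"))
}

## read a manifest + spectra back into a SummarizedExperiment
.readSeries <- function(manifestPath) {
  dir <- dirname(manifestPath)
  manifest <- read.csv(manifestPath, stringsAsFactors = FALSE)
  spectra <- lapply(file.path(dir, manifest$file), readSpectrum)
  w <- wavenumber(spectra[[1]])
  m <- vapply(spectra, counts, numeric(length(w)))
  cd <- manifest[, setdiff(names(manifest), "file"), drop = FALSE]
  rownames(cd) <- sub("\\.csv$", "", manifest$file)
  colnames(m) <- rownames(cd)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    rowData = S4Vectors::DataFrame(wavenumber = w),
    colData = S4Vectors::DataFrame(cd))
}

.instrumentSource <- function(cfg) {
  switch(cfg$instrument$preset,
    "point-point" = pointSource(power = cfg$instrument$power),
    "linear" = lineSource(power = cfg$instrument$power),
    stop("unknown instrument preset: ", cfg$instrument$preset))
}

.cfgGenerator <- function(cfg, seed) {
  spec <- generatorSpec(countScale = cfg$generator$countScale,
                        noise = cfg$generator$noise, seed = seed)
  if (!is.null(cfg$generator$targetSNR))
    spec <- calibrateNoiseToSNR(spec, cfg$generator$targetSNR)
  spec
}

.cfgPhantom <- function(cfg) {
  do.call(buildPhantom, cfg$phantom)
}

#' Run a pipeline stage end to end
#'
#' Commands: \code{synth} (generate a thickness series and write spectra +
#' manifest), \code{simulate} (model SNR and LOD for an instrument preset),
#' \code{optimize} (constrained geometry search, ranked configurations +
#' SNR surface CSVs), \code{calibrate} (difference spectra + PLS
#' calibration, saved as a portable JSON archive), \code{predict} (apply a
#' saved calibration to a spectra manifest). Every command writes its
#' artifacts plus a machine-readable \code{report.json} (command, seed,
#' config snapshot, key numbers, MD5 of written files); rerunning with the
#' same config and seed reproduces the artifacts byte-identically.
#'
#' @param command one of "synth", "simulate", "optimize", "calibrate",
#'   "predict".
#' @param config configuration list from [readRunConfig()].
#' @param out output directory.
#' @param seed master seed (overrides the config's).
#' @return The report, invisibly.
#' @export
runPipeline <- function(command = c("synth", "simulate", "optimize",
                                    "calibrate", "predict"),
                        config = defaultRunConfig(), out = "drs-out",
                        seed = config$seed) {
  command <- match.arg(command)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  results <- list(); files <- character()
  cfg <- config

  if (command == "synth") {
    spec <- .cfgGenerator(cfg, seed)
    se <- makeThicknessSeries(cfg$generator$thicknesses,
                              cfg$generator$replicates, spec)
    .log(cfg, "synth: ", ncol(se), " spectra")
    .writeSeries(se, file.path(out, "data"))
    files <- file.path("data", c(list.files(file.path(out, "data"))))
    results$nSpectra <- ncol(se)
    results$countScale <- spec@countScale
  } else if (command == "simulate") {
    fbr <- .cfgPhantom(cfg)
    grid <- buildPhantomGrid(fbr, cfg$grid$spacing, cfg$grid$refinedSpacing)
    src <- .instrumentSource(cfg)
    model <- snrModel(src, fbr, grid = grid)
    surf <- snrSurface(model, n = cfg$search$surfaceN)
    am <- surfaceArgmax(surf)
    results$snrMaxPoint <- am$snr
    results$argmaxOffset <- am$offset
    results$lodPoint <- lodFromSNR(am$snr,
                                   referenceThickness = fbr@collagenThickness)
    if (src@shape %in% c("line", "rectangle")) {
      half <- .sourceHalfWidth(src)
      offs <- surf@x[surf@x - 1 >= half]
      best <- NULL
      for (off in offs) {
        r <- integrateDetectorArea(surf, off + c(-1, 1),
                                   thickness = fbr@collagenThickness)
        if (is.null(best) || r@snr > best@snr) best <- r
      }
      pair <- combineDetectors(list(best, best))
      results$snrRectangle <- best@snr
      results$snrRectanglePair <- pair@snr
      results$lodRectanglePair <- pair@lod
    }
    surfFile <- file.path(out, "snr_surface.csv")
    write.csv(data.frame(x = rep(surf@x, times = length(surf@y)),
                         y = rep(surf@y, each = length(surf@x)),
                         snr = as.numeric(surf@snr)),
              surfFile, row.names = FALSE)
    files <- "snr_surface.csv"
  } else if (command == "optimize") {
    fbr <- .cfgPhantom(cfg)
    grid <- buildPhantomGrid(fbr, cfg$grid$spacing, cfg$grid$refinedSpacing)
    opt <- optimizeGeometry(fbr = fbr, grid = grid, mpe = cfg$search$mpe,
                            surfaceN = cfg$search$surfaceN)
    write.csv(opt$ranked, file.path(out, "ranked.csv"), row.names = FALSE)
    files <- "ranked.csv"
    results$top <- if (nrow(opt$ranked)) as.list(opt$ranked[1, ]) else
      "no feasible configuration"
    results$nFeasible <- nrow(opt$ranked)
    results$nInfeasibleSources <- nrow(opt$infeasible)
  } else if (command == "calibrate") {
    manifest <- cfg$calibrate$data
    se <- if (!is.null(manifest)) .readSeries(manifest) else
      makeThicknessSeries(cfg$generator$thicknesses,
                          cfg$generator$replicates,
                          .cfgGenerator(cfg, seed))
    ds <- differenceSet(se)
    model <- fitPLS(ds)
    pm <- portableCalibration(model)
    arch <- list(ncomp = pm@ncomp, wavenumber = pm@wavenumber,
                 thickness = pm@thickness, looRMSE = pm@looRMSE,
                 preprocessing = pm@preprocessing,
                 B = pm@fit$B, xMeans = pm@fit$xMeans, yMean = pm@fit$yMean)
    jsonlite::write_json(arch, file.path(out, "calibration.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- "calibration.json"
    results$ncomp <- pm@ncomp
    results$looRMSE <- pm@looRMSE
  } else if (command == "predict") {
    arch <- jsonlite::read_json(cfg$predict$model, simplifyVector = TRUE)
    model <- new("CalibrationModel", ncomp = as.integer(arch$ncomp),
                 fit = list(B = arch$B, xMeans = arch$xMeans,
                            yMean = arch$yMean),
                 wavenumber = arch$wavenumber, thickness = arch$thickness,
                 looRMSE = arch$looRMSE, looPredictions = numeric(),
                 preprocessing = arch$preprocessing)
    se <- .readSeries(cfg$predict$data)
    ds <- differenceSet(se)
    pr <- predictThickness(model, ds)
    write.csv(data.frame(thickness = ds$thickness,
                         predicted = pr$predictions),
              file.path(out, "predictions.csv"), row.names = FALSE)
    files <- "predictions.csv"
    results$rmse <- pr$rmse
  }

  paths <- file.path(out, files)
  report <- list(command = command, seed = seed, config = cfg,
                 results = results,
                 files = as.list(stats::setNames(
                   unname(tools::md5sum(paths)), files)))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}
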