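#' @include AllClasses.R biometry.R
NULL

#' Reference summary statistics of the calibration cohort
#'
#' Per-parameter mean and standard deviation of the published IOLMaster 700
#' screening cohort the marginal generator is calibrated to: flat and steep
#' keratometry, maximum keratometry, central corneal thickness, axial
#' length, anterior chamber depth and corneal astigmatism magnitude. The
#' published min/max are reported cohort extremes and are carried for
#' documentation only — the generator treats them as descriptive, not as
#' truncation bounds, so that mean recovery stays unbiased.
#'
#' @return data.frame with columns param, mean, sd, min, max, unit.
#' @export
referenceCohortStats <- function() {
  data.frame(
    param = recordParamCols(),
    mean = c(43.21, 44.36, 46.02, 532.6, 24.18, 3.21, 1.15),
    sd   = c(1.18, 1.42, 2.15, 28.4, 1.12, 0.38, 0.72),
    min  = c(41.12, 42.08, 43.51, 486, 22.51, 2.61, 0.21),
    max  = c(45.07, 46.89, 50.14, 579, 26.34, 3.82, 2.94),
    unit = c("D", "D", "D", "um", "mm", "mm", "D"),
    stringsAsFactors = FALSE)
}

#' Default per-scan device noise (SDs)
#'
#' Zero-mean Gaussian measurement noise applied per scan, per parameter:
#' 0.10 D on keratometry, 3 um on pachymetry, 0.02 mm on axial length,
#' 0.03 mm on anterior chamber depth. These are explicit configuration
#' values of the simulator, order-of-magnitude consistent with optical
#' biometer repeatability.
#'
#' @return named numeric vector of SDs over the six scan parameters.
#' @export
defaultScanNoise <- function() {
  c(k1_D = 0.10, k2_D = 0.10, kmax_D = 0.10, cct_um = 3,
    axial_length_mm = 0.02, acd_mm = 0.03)
}

#' Specify a synthetic cohort
#'
#' Two modes: \code{"labeled"} (the default study condition) draws a
#' two-class cohort — normal corneas versus early keratoconus — with the
#' documented class-conditional effect sizes; \code{"marginal"} draws every
#' parameter independently from an untruncated normal at the reference
#' cohort mean/SD and is intended for calibration checks of the marginal
#' statistics only (cross-parameter clinical invariants are not enforced
#' there by design).
#'
#' @param nEyes number of eyes (>= 0).
#' @param mode "labeled" or "marginal".
#' @param kcFraction proportion of early-keratoconus eyes in labeled mode.
#' @param seed mandatory integer seed; all sampling derives from it.
#' @param scanNoise per-parameter scan-noise SDs, see [defaultScanNoise()].
#' @param mapGrid list(size, extent_mm): curvature-map grid edge in pixels
#'   and physical extent in mm.
#' @return a validated specification list.
#' @export
cohortSpec <- function(nEyes, mode = c("labeled", "marginal"),
                       kcFraction = 0.5, seed,
                       scanNoise = defaultScanNoise(),
                       mapGrid = list(size = 64, extent_mm = 9.0)) {
  mode <- match.arg(mode)
  if (!num1(nEyes) || nEyes < 0) stop("nEyes must be a non-negative count")
  if (!num1(kcFraction) || kcFraction < 0 || kcFraction > 1)
    stop("kcFraction must be in [0, 1]")
  if (missing(seed) || !num1(seed)) stop("a scalar integer seed is mandatory")
  if (any(scanNoise < 0)) stop("scan-noise SDs must be non-negative")
  list(nEyes = as.integer(nEyes), mode = mode, kcFraction = kcFraction,
       seed = as.integer(seed), scanNoise = scanNoise, mapGrid = mapGrid)
}

#' Sample a synthetic cohort of latent ground-truth eyes
#'
#' Marginal mode: each of the seven parameters is drawn independently from
#' N(mean, sd) at the reference cohort values; eyes are unlabeled and carry
#' no cone. Labeled mode: class labels are assigned at the requested
#' keratoconus fraction; the normal class draws K1 ~ N(43.0, 1.0), Kmax =
#' mean K + |N(0.8, 0.4)|, CCT ~ N(545, 25) um, astigmatism ~ |N(0.9, 0.5)|;
#' the early-keratoconus class shares K1 but draws Kmax = mean K +
#' max(N(4.5, 1.5), 2.5), CCT ~ N(495, 25) and astigmatism ~ |N(1.8, 0.8)|,
#' the steep-Kmax/thin-cornea signature of early ectasia. Axial length and
#' ACD are shared across classes at the reference values. Early-keratoconus
#' eyes get an inferior paracentral cone (center radius ~ U(1, 2) mm, angle
#' ~ N(270, 20) degrees, sigma ~ U(0.8, 1.4) mm) whose amplitude is set so
#' the rendered map peaks near Kmax. K2 is K1 + astigmatism and Kmax is
#' floored at K2 (a point maximum cannot undercut the steep meridian).
#' Fully reproducible from the spec seed.
#'
#' @param spec a [cohortSpec()].
#' @return list of [SyntheticEye-class].
#' @export
sampleCohort <- function(spec) {
  n <- spec$nEyes
  if (n == 0L) return(list())
  withSeed(spec$seed, {
    lat <- sample(c("OD", "OS"), n, replace = TRUE)
    ids <- sprintf("EYE%05d", seq_len(n))
    if (spec$mode == "marginal") {
      st <- referenceCohortStats()
      draws <- vapply(seq_len(nrow(st)),
                      function(i) stats::rnorm(n, st$mean[i], st$sd[i]),
                      numeric(n))
      if (n == 1L) draws <- matrix(draws, nrow = 1L)
      colnames(draws) <- st$param
      lapply(seq_len(n), function(i) {
        rec <- new("BiometricRecord", eyeId = ids[i], laterality = lat[i],
                   k1_D = draws[i, "k1_D"], k2_D = draws[i, "k2_D"],
                   kmax_D = draws[i, "kmax_D"], cct_um = draws[i, "cct_um"],
                   axial_length_mm = draws[i, "axial_length_mm"],
                   acd_mm = draws[i, "acd_mm"],
                   astigmatism_D = draws[i, "astigmatism_D"])
        new("SyntheticEye", eyeId = ids[i], label = "unlabeled",
            trueParams = rec,
            cone = c(amplitude_D = 0, center_radius_mm = NA_real_,
                     center_angle_deg = NA_real_, sigma_mm = NA_real_))
      })
    } else {
      nKC <- round(n * spec$kcFraction)
      labels <- sample(c(rep("early_kc", nKC), rep("normal", n - nKC)))
      k1 <- stats::rnorm(n, 43.0, 1.0)
      astig <- ifelse(labels == "early_kc",
                      abs(stats::rnorm(n, 1.8, 0.8)),
                      abs(stats::rnorm(n, 0.9, 0.5)))
      k2 <- k1 + astig
      meanK <- (k1 + k2) / 2
      excess <- ifelse(labels == "early_kc",
                       pmax(stats::rnorm(n, 4.5, 1.5), 2.5),
                       abs(stats::rnorm(n, 0.8, 0.4)))
      kmax <- pmax(meanK + excess, k2)
      cct <- ifelse(labels == "early_kc",
                    stats::rnorm(n, 495, 25), stats::rnorm(n, 545, 25))
      al <- stats::rnorm(n, 24.18, 1.12)
      acd <- stats::rnorm(n, 3.21, 0.38)
      coneR <- stats::runif(n, 1.0, 2.0)
      coneA <- stats::rnorm(n, 270, 20) %% 360
      coneS <- stats::runif(n, 0.8, 1.4)
      lapply(seq_len(n), function(i) {
        rec <- BiometricRecord(ids[i], lat[i], k1_D = k1[i], k2_D = k2[i],
                               kmax_D = kmax[i], cct_um = cct[i],
                               axial_length_mm = al[i], acd_mm = acd[i])
        cone <- if (labels[i] == "early_kc") {
          # amplitude so that power at the cone apex reaches Kmax given the
          # underlying astigmatic bowtie (with-the-rule axis, 90 degrees)
          amp <- kmax[i] - meanK[i] -
            (astig[i] / 2) * cos(2 * (coneA[i] - 90) * pi / 180)
          c(amplitude_D = max(amp, 0.1), center_radius_mm = coneR[i],
            center_angle_deg = coneA[i], sigma_mm = coneS[i])
        } else {
          c(amplitude_D = 0, center_radius_mm = NA_real_,
            center_angle_deg = NA_real_, sigma_mm = NA_real_)
        }
        new("SyntheticEye", eyeId = ids[i], label = labels[i],
            trueParams = rec, cone = cone)
      })
    }
  })
}

#' Simulate repeated device scans for one eye
#'
#' Each of the k scans is the eye's true parameter vector plus independent
#' zero-mean Gaussian noise per parameter. Within each scan the flat/steep
#' labels are reassigned after noising (K1 = min, K2 = max), as an optical
#' biometer labels meridians per acquisition, so the per-scan steep-minus-
#' flat difference is always non-negative. Kmax is floored at the scan's K2.
#'
#' @param eye a [SyntheticEye-class].
#' @param k number of scans (>= 1), default 3.
#' @param noise named SDs as in [defaultScanNoise()].
#' @param seed integer seed for the scan noise.
#' @return a [ScanSet-class].
#' @export
simulateRepeatScans <- function(eye, k = 3, noise = defaultScanNoise(),
                                seed) {
  stopifnot(is(eye, "SyntheticEye"))
  if (!num1(k) || k < 1) stop("k must be >= 1")
  if (any(noise < 0)) stop("scan-noise SDs must be non-negative")
  if (missing(seed) || !num1(seed)) stop("a scalar integer seed is mandatory")
  tp <- eye@trueParams
  withSeed(seed, {
    cols <- scanParamCols()
    mat <- vapply(cols, function(p)
      slot(tp, p) + stats::rnorm(k, 0, noise[[p]] %||% 0), numeric(k))
    if (k == 1L) mat <- matrix(mat, nrow = 1L, dimnames = list(NULL, cols))
    flat <- pmin(mat[, "k1_D"], mat[, "k2_D"])
    steep <- pmax(mat[, "k1_D"], mat[, "k2_D"])
    mat[, "k1_D"] <- flat
    mat[, "k2_D"] <- steep
    mat[, "kmax_D"] <- pmax(mat[, "kmax_D"], steep)
    scans <- data.frame(order = seq_len(k), mat)
    ScanSet(eye@eyeId, tp@laterality, scans)
  })
}

#' Render a synthetic axial curvature map
#'
#' Axial power at each pixel inside the corneal disc (radius = extent/2) is
#' \deqn{K(x, y) = \bar K + (\Delta K / 2)\cos 2(\theta - \phi) +
#'   A e^{-d^2 / 2\sigma^2}}
#' where \eqn{\bar K} is mean keratometry, \eqn{\Delta K} the astigmatism
#' magnitude producing a bowtie around axis \eqn{\phi} (default 90 degrees,
#' with-the-rule), and the Gaussian term is the localized steepening of the
#' eye's latent cone (amplitude \eqn{A}, center at its polar coordinates,
#' width \eqn{\sigma}). Pixels outside the disc take the constant
#' \code{background} value. Orientation: +y superior, +x temporal-for-OD;
#' matrix row 1 is the superior edge.
#'
#' @param eye a [SyntheticEye-class].
#' @param size grid edge length in pixels.
#' @param extent_mm physical edge length in mm.
#' @param axis_deg astigmatic axis in degrees.
#' @param background power value outside the corneal disc, diopters.
#' @return a [CurvatureMap-class].
#' @export
renderCurvatureMap <- function(eye, size = 64, extent_mm = 9.0,
                               axis_deg = 90, background = 38) {
  stopifnot(is(eye, "SyntheticEye"))
  if (!num1(size) || size < 2 || !num1(extent_mm) || extent_mm <= 0)
    stop("grid size and extent must be positive")
  tp <- eye@trueParams
  f <- deriveFeatures(tp)
  pix <- extent_mm / size
  # pixel centers; row 1 = superior (+y), columns increase with +x
  ax <- (seq_len(size) - 0.5) * pix - extent_mm / 2
  x <- matrix(ax, size, size, byrow = TRUE)
  y <- matrix(rev(ax), size, size)
  r <- sqrt(x^2 + y^2)
  theta <- atan2(y, x)
  K <- f@mean_k_D +
    (f@astig_kdiff_D / 2) * cos(2 * (theta - axis_deg * pi / 180))
  amp <- eye@cone[["amplitude_D"]]
  if (amp > 0) {
    ang <- eye@cone[["center_angle_deg"]] * pi / 180
    cx <- eye@cone[["center_radius_mm"]] * cos(ang)
    cy <- eye@cone[["center_radius_mm"]] * sin(ang)
    d2 <- (x - cx)^2 + (y - cy)^2
    K <- K + amp * exp(-d2 / (2 * eye@cone[["sigma_mm"]]^2))
  }
  K[r > extent_mm / 2] <- background
  new("CurvatureMap", values = K, pixelSize_mm = pix,
      background = background, eyeId = eye@eyeId)
}

#' Write a synthetic cohort to disk
#'
#' Writes schema-conformant \code{records.json} and \code{records.csv}
#' (raw scan sets), curvature maps as plain-text CSV grids under
#' \code{maps/} (plus optional color-mapped PNGs on the fixed 38-52 D
#' scale when the \pkg{png} package is available), class labels to a
#' separate \code{labels.csv} so the inference path cannot see them, and a
#' \code{manifest.json} listing every artifact with its MD5 checksum.
#'
#' @param cohort list of [SyntheticEye-class].
#' @param scanSets list of [ScanSet-class] parallel to \code{cohort}.
#' @param maps optional list of [CurvatureMap-class] parallel to
#'   \code{cohort}.
#' @param outDir output directory (created if needed).
#' @param writePNG also write color-mapped PNGs (requires \pkg{png}).
#' @return invisibly, the manifest as a data.frame (file, md5).
#' @export
writeCohort <- function(cohort, scanSets, maps = NULL, outDir,
                        writePNG = FALSE) {
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop("cannot create output directory: ", outDir)
  stopifnot(length(cohort) == length(scanSets))
  recs <- lapply(scanSets, function(s) {
    list(eye_id = s@eyeId, laterality = s@laterality,
         scans = lapply(seq_len(nrow(s@scans)), function(i)
           as.list(s@scans[i, c("order", scanParamCols())])))
  })
  files <- character()
  jf <- file.path(outDir, "records.json")
  writeJSONCanonical(recs, jf); files <- c(files, jf)
  csv <- do.call(rbind, lapply(scanSets, function(s)
    data.frame(eye_id = s@eyeId, laterality = s@laterality,
               s@scans[, c("order", scanParamCols())])))
  cf <- file.path(outDir, "records.csv")
  utils::write.csv(csv, cf, row.names = FALSE); files <- c(files, cf)
  lf <- file.path(outDir, "labels.csv")
  utils::write.csv(data.frame(
    eye_id = vapply(cohort, eyeId, character(1)),
    label = vapply(cohort, function(e) e@label, character(1))),
    lf, row.names = FALSE)
  files <- c(files, lf)
  if (!is.null(maps)) {
    stopifnot(length(maps) == length(cohort))
    mdir <- file.path(outDir, "maps")
    dir.create(mdir, showWarnings = FALSE)
    for (m in maps) {
      mf <- file.path(mdir, paste0(m@eyeId, ".csv"))
      writeCurvatureMapCSV(m, mf)
      files <- c(files, mf)
      if (writePNG && requireNamespace("png", quietly = TRUE)) {
        pf <- file.path(mdir, paste0(m@eyeId, ".png"))
        writeCurvatureMapPNG(m, pf)
        files <- c(files, pf)
      }
    }
  }
  manifest <- data.frame(file = basename(files),
                         path = sub(paste0("^", outDir, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  writeJSONCanonical(manifest, file.path(outDir, "manifest.json"))
  invisible(manifest)
}

#' @rdname writeCohort
#' @param m a [CurvatureMap-class].
#' @param path output path.
#' @export
writeCurvatureMapCSV <- function(m, path) {
  hdr <- sprintf("# curvature map eye_id=%s pixel_mm=%.17g background=%.17g",
                 m@eyeId, m@pixelSize_mm, m@background)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(m@values, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCurvatureMapCSV <- function(path) {
  hdr <- readLines(path, n = 1L)
  getv <- function(key) {
    mm <- regmatches(hdr, regexec(paste0(key, "=([^ ]+)"), hdr))[[1]]
    if (length(mm) < 2) stop("malformed curvature-map header in ", path)
    mm[2]
  }
  vals <- as.matrix(utils::read.csv(path, header = FALSE, skip = 1L))
  dimnames(vals) <- NULL
  new("CurvatureMap", values = vals,
      pixelSize_mm = as.numeric(getv("pixel_mm")),
      background = as.numeric(getv("background")), eyeId = getv("eye_id"))
}

#' @rdname writeCohort
#' @param scale_D fixed color scale (lo, hi) in diopters.
#' @export
writeCurvatureMapPNG <- function(m, path, scale_D = c(38, 52)) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export")
  z <- (m@values - scale_D[1]) / (scale_D[2] - scale_D[1])
  z <- pmin(pmax(z, 0), 1)
  # blue -> green -> red clinical color ramp
  r <- pmin(pmax(2 * z - 0.5, 0), 1)
  g <- 1 - abs(2 * z - 1)
  b <- pmin(pmax(1.5 - 2 * z, 0), 1)
  img <- array(c(r, g, b), dim = c(nrow(z), ncol(z), 3))
  png::writePNG(img, path)
  invisible(path)
}

#' Read a cohort directory written by writeCohort
#'
#' @param dir cohort directory.
#' @param withMaps also load curvature maps if present.
#' @return list with elements \code{scanSets}, \code{labels} (named
#'   character) and \code{maps} (named list or NULL).
#' @export
readCohort <- function(dir, withMaps = TRUE) {
  scanSets <- parseRecords(file.path(dir, "records.json"))
  labels <- NULL
  lf <- file.path(dir, "labels.csv")
  if (file.exists(lf)) {
    ldf <- utils::read.csv(lf, stringsAsFactors = FALSE)
    labels <- stats::setNames(ldf$label, ldf$eye_id)
  }
  maps <- NULL
  mdir <- file.path(dir, "maps")
  if (withMaps && dir.exists(mdir)) {
    mf <- list.files(mdir, pattern = "\\.csv$", full.names = TRUE)
    maps <- lapply(mf, readCurvatureMapCSV)
    names(maps) <- vapply(maps, eyeId, character(1))
  }
  list(scanSets = scanSets, labels = labels, maps = maps)
}
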