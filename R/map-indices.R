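#' @include AllClasses.R
NULL

#' Deterministic morphology indices of a curvature map
#'
#' Computes the classical inferior-superior asymmetry screening index and
#' the map maximum. The I-S index is the mean axial power over the inferior
#' half (polar angle in (180, 360) degrees, i.e. y < 0) of the 2-3 mm
#' mid-peripheral annulus minus the mean over the superior half (angle in
#' (0, 180)); positive values flag inferior steepening, the canonical early
#' keratoconus pattern. The maximum is taken over the whole corneal disc,
#' and its location is reported in polar coordinates.
#'
#' Adding a constant to the whole map leaves the I-S index unchanged and
#' shifts the maximum by the constant.
#'
#' @param m a [CurvatureMap-class] covering at least a 6 mm diameter.
#' @return list: \code{is_asymmetry_D}, \code{max_power_D},
#'   \code{max_radius_mm}, \code{max_angle_deg} (plus the annulus means
#'   \code{inferior_mean_D}, \code{superior_mean_D}).
#' @export
computeMapIndices <- function(m) {
  stopifnot(is(m, "CurvatureMap"))
  size <- nrow(m@values)
  extent <- size * m@pixelSize_mm
  if (extent < 6)
    stop("map extent ", format(extent), " mm is below the 6 mm required ",
         "for the 2-3 mm annulus indices")
  ax <- (seq_len(size) - 0.5) * m@pixelSize_mm - extent / 2
  x <- matrix(ax, size, size, byrow = TRUE)
  y <- matrix(rev(ax), size, size)
  r <- sqrt(x^2 + y^2)
  disc <- r <= extent / 2
  ann <- r >= 2 & r <= 3
  inf <- ann & y < 0
  sup <- ann & y > 0
  vals <- m@values
  infMean <- mean(vals[inf])
  supMean <- mean(vals[sup])
  iMax <- which.max(ifelse(disc, vals, -Inf))
  maxR <- r[iMax]
  maxA <- (atan2(y[iMax], x[iMax]) * 180 / pi) %% 360
  list(is_asymmetry_D = infMean - supMean,
       max_power_D = vals[iMax],
       max_radius_mm = maxR, max_angle_deg = maxA,
       inferior_mean_D = infMean, superior_mean_D = supMean)
}

#' Resample a curvature map to a new grid size
#'
#' Bilinear interpolation on the physical coordinate frame, preserving the
#' map extent. Used to adapt maps to an encoder's configured input size.
#'
#' @param m a [CurvatureMap-class].
#' @param size target grid edge length in pixels.
#' @return a [CurvatureMap-class] of the requested size.
#' @export
resampleMap <- function(m, size) {
  old <- nrow(m@values)
  if (old == size) return(m)
  extent <- old * m@pixelSize_mm
  newPix <- extent / size
  # target pixel centers expressed in source pixel index space
  src <- ((seq_len(size) - 0.5) * newPix) / m@pixelSize_mm + 0.5
  i0 <- pmin(pmax(floor(src), 1), old)
  i1 <- pmin(i0 + 1, old)
  w <- pmin(pmax(src - i0, 0), 1)
  V <- m@values
  rows <- V[i0, , drop = FALSE] * (1 - w) + V[i1, , drop = FALSE] * w
  out <- rows[, i0, drop = FALSE] * matrix(1 - w, size, size, byrow = TRUE) +
         rows[, i1, drop = FALSE] * matrix(w, size, size, byrow = TRUE)
  new("CurvatureMap", values = out, pixelSize_mm = newPix,
      background = m@background, eyeId = m@eyeId)
}
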