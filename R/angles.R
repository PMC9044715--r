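#' Construct a validated sample of angles
#'
#' Angles are stored internally in radians on `[0, 2*pi)` regardless of the
#' input unit. Directional field data are usually recorded in degrees; the
#' unit must be stated explicitly because downstream trigonometry silently
#' produces nonsense if it is guessed wrong.
#'
#' @param x numeric vector of angles. All values must be finite.
#' @param unit unit of `x`, `"degrees"` or `"radians"`.
#' @param axial logical; set by [axial_transform()], not normally by the
#'   caller. Marks a sample whose angles have already been doubled to map an
#'   axis (theta equivalent to theta + 180 degrees) onto the full circle.
#' @return An object of class `"angle_sample"`: a list with elements
#'   `angles` (radians in `[0, 2*pi)`), `n`, `source_unit` and `axial`.
#' @examples
#' angle_sample(c(0, 90, 355), unit = "degrees")
#' angle_sample(c(-pi / 2, 3 * pi), unit = "radians")
#' @export
angle_sample <- function(x, unit = c("degrees", "radians"), axial = FALSE) {
  if (inherits(x, "angle_sample")) return(x)
  unit <- match.arg(unit)
  x <- as.numeric(x)
  if (length(x) < 1L) stop("at least one angle is required")
  bad <- which(!is.finite(x))
  if (length(bad) > 0L) {
    stop(sprintf("non-finite angle at position %s", paste(bad, collapse = ", ")))
  }
  theta <- if (unit == "degrees") x * pi / 180 else x
  theta <- theta %% (2 * pi)
  structure(
    list(angles = theta, n = length(theta), source_unit = unit, axial = isTRUE(axial)),
    class = "angle_sample"
  )
}

#' @export
print.angle_sample <- function(x, ...) {
  cat(sprintf(
    "Angle sample: n = %d, unit of origin = %s%s\n", x$n, x$source_unit,
    if (x$axial) ", axially doubled" else ""
  ))
  cat("radians:", format(utils::head(x$angles, 6), digits = 4),
      if (x$n > 6) "...\n" else "\n")
  invisible(x)
}

#' Double angles for axial data
#'
#' Axial data (an axis rather than a direction: theta and theta + 180 degrees
#' are the same observation) are analyzed after doubling each angle and
#' reducing modulo 360 degrees, which maps both members of an axis pair to
#' one point on the circle.
#'
#' @param sample an [angle_sample()].
#' @return The transformed `angle_sample` with `axial = TRUE`.
#' @examples
#' s <- angle_sample(c(10, 190), unit = "degrees")
#' axial_transform(s) # both map to 20 degrees
#' @export
axial_transform <- function(sample) {
  sample <- angle_sample(sample)
  if (sample$axial) stop("sample is already axially doubled; refusing to double twice")
  out <- sample
  out$angles <- (2 * sample$angles) %% (2 * pi)
  out$axial <- TRUE
  out
}

#' Embed angles as (cos, sin) unit vectors
#'
#' The linearizing transform behind the whole package: each angle theta
#' becomes the point (cos theta, sin theta) on the unit circle, giving a
#' two-column response matrix suitable for a multivariate linear model.
#'
#' @param sample an [angle_sample()].
#' @return An `n x 2` numeric matrix with columns `cos` and `sin`; every row
#'   has unit Euclidean norm.
#' @examples
#' embed_angles(angle_sample(c(0, 90), unit = "degrees"))
#' @export
embed_angles <- function(sample) {
  sample <- angle_sample(sample)
  cbind(cos = cos(sample$angles), sin = sin(sample$angles))
}

#' Mean resultant length and mean direction
#'
#' The first trigonometric moment of the sample: `rbar` is the length of the
#' average unit vector (0 = perfectly dispersed, 1 = coincident) and
#' `mean_direction` its angle. When the mean vector is numerically zero
#' (rbar < 1e-12) the direction is undefined and reported as `NA`.
#'
#' @param sample an [angle_sample()].
#' @return A list with `rbar` in `[0, 1]` and `mean_direction` in radians on
#'   `[0, 2*pi)` (or `NA` when undefined).
#' @examples
#' mean_resultant(angle_sample(c(0, 90), unit = "degrees"))
#' @export
mean_resultant <- function(sample) {
  sample <- angle_sample(sample)
  cbar <- mean(cos(sample$angles))
  sbar <- mean(sin(sample$angles))
  rbar <- sqrt(cbar^2 + sbar^2)
  direction <- if (rbar < 1e-12) NA_real_ else atan2(sbar, cbar) %% (2 * pi)
  list(rbar = rbar, mean_direction = direction)
}

#' Aggregate angles into equal-width bins around the circle
#'
#' Emulates field measurements rounded to the nearest `width` degrees: each
#' angle is replaced by the nearest multiple of the bin width, with bins
#' `[k*w - w/2, k*w + w/2)` so an exact midpoint rounds up to the next bin.
#' The bin at 0 wraps across 360 degrees. Binning is idempotent.
#'
#' @param sample an [angle_sample()].
#' @param width bin width in degrees; must divide 360. Default 10.
#' @return An `angle_sample` of bin centers.
#' @examples
#' bin_angles(angle_sample(c(4.9, 5, 356), unit = "degrees")) # 0, 10, 0
#' @export
bin_angles <- function(sample, width = 10) {
  sample <- angle_sample(sample)
  if (width <= 0 || abs(360 / width - round(360 / width)) > 1e-9) {
    stop(sprintf("bin width (%g degrees) must divide 360", width))
  }
  deg <- sample$angles * 180 / pi
  centers <- (floor(deg / width + 0.5) * width) %% 360
  out <- sample
  out$angles <- (centers * pi / 180) %% (2 * pi)
  out
}
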