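#' Sample from the circular uniform distribution
#'
#' @param n number of draws.
#' @return An [angle_sample()] of `n` i.i.d. draws from Uniform`[0, 2*pi)`.
#'   Uses R's global random number generator; seed with [set.seed()].
#' @export
rcirc_uniform <- function(n) {
  if (n < 1) stop("n must be at least 1")
  angle_sample(stats::runif(n, 0, 2 * pi), unit = "radians")
}

#' Sample from the von Mises distribution
#'
#' Draws from the canonical unimodal circular distribution with mean
#' direction `mu` and concentration `kappa`, by the Best-Fisher
#' wrapped-Cauchy envelope rejection algorithm (exact, no tuning
#' parameters). `kappa = 0` degenerates to the circular uniform.
#'
#' @param n number of draws.
#' @param mu mean direction in radians.
#' @param kappa concentration parameter, `>= 0`.
#' @return An [angle_sample()] of `n` i.i.d. draws.
#' @export
rcirc_vonmises <- function(n, mu = 0, kappa = 1) {
  if (n < 1) stop("n must be at least 1")
  if (kappa < 0) stop("kappa must be nonnegative")
  if (kappa < 1e-10) return(rcirc_uniform(n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(n - length(out), 16L)
    # oversample to amortize rejections (acceptance rate > 65% for all kappa)
    m <- ceiling(m * 1.6)
    u1 <- stats::runif(m)
    u2 <- stats::runif(m)
    u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3[keep] - 0.5) * acos(f[keep])
    out <- c(out, theta)
  }
  angle_sample((mu + out[seq_len(n)]) %% (2 * pi), unit = "radians")
}

#' Sample from the wrapped skew-normal distribution
#'
#' A skew-normal variate is drawn on the line by the delta representation
#' (`delta = alpha / sqrt(1 + alpha^2)`; `z = delta * |u0| +
#' sqrt(1 - delta^2) * u1` with `u0, u1` independent standard normals), then
#' located, scaled and wrapped: `theta = (xi + omega * z) mod 2*pi`.
#' `alpha = 0` reduces to the wrapped normal with standard deviation
#' `omega`.
#'
#' @param n number of draws.
#' @param xi location parameter (radians before wrapping).
#' @param omega dispersion (scale) parameter, `> 0`.
#' @param alpha shape (skewness) parameter.
#' @return An [angle_sample()] of `n` i.i.d. draws.
#' @export
rcirc_wsn <- function(n, xi = 0, omega = 1, alpha = 0) {
  if (n < 1) stop("n must be at least 1")
  if (omega <= 0) stop("omega must be positive")
  delta <- alpha / sqrt(1 + alpha^2)
  u0 <- stats::rnorm(n)
  u1 <- stats::rnorm(n)
  z <- delta * abs(u0) + sqrt(1 - delta^2) * u1
  angle_sample((xi + omega * z) %% (2 * pi), unit = "radians")
}

#' Specify a circular mixture distribution
#'
#' A scenario description for the simulation study: a list of component
#' distributions with mixing weights. Supported families are `"uniform"`
#' (no parameters), `"vonmises"` (`mu`, `kappa`) and `"wsn"`
#' (`xi`, `omega`, `alpha`).
#'
#' @param components a list; each element a list with elements `family`,
#'   `weight`, and the family's parameters.
#' @return An object of class `"mixture_spec"`.
#' @examples
#' # symmetric bimodal von Mises, modes at 0 and 180 degrees
#' mixture_spec(list(
#'   list(family = "vonmises", weight = 0.5, mu = 0, kappa = 1),
#'   list(family = "vonmises", weight = 0.5, mu = pi, kappa = 1)
#' ))
#' @export
mixture_spec <- function(components) {
  if (!is.list(components) || length(components) < 1L) {
    stop("components must be a non-empty list")
  }
  fams <- c("uniform", "vonmises", "wsn")
  for (i in seq_along(components)) {
    comp <- components[[i]]
    if (is.null(comp$family) || !comp$family %in% fams) {
      stop(sprintf("component %d: family must be one of %s", i,
                   paste(fams, collapse = ", ")))
    }
    if (is.null(comp$weight) || comp$weight < 0) {
      stop(sprintf("component %d: weight must be nonnegative", i))
    }
    if (comp$family == "vonmises") {
      if (is.null(comp$mu) || is.null(comp$kappa) || comp$kappa < 0) {
        stop(sprintf("component %d: von Mises needs mu and kappa >= 0", i))
      }
      components[[i]]$mu <- comp$mu %% (2 * pi)
    }
    if (comp$family == "wsn") {
      if (is.null(comp$xi) || is.null(comp$omega) || comp$omega <= 0) {
        stop(sprintf("component %d: wrapped skew normal needs xi and omega > 0", i))
      }
      if (is.null(comp$alpha)) components[[i]]$alpha <- 0
    }
  }
  w <- vapply(components, function(comp) comp$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-9) {
    stop(sprintf("component weights must sum to 1 (got %.10g)", sum(w)))
  }
  structure(list(components = components), class = "mixture_spec")
}

#' Equal-weight von Mises mixture at given mean directions
#'
#' Convenience constructor for the multimodal simulation suites, e.g. the
#' symmetric bimodal (modes 0 and 180 degrees) and trimodal (0, 120, 240)
#' scenarios.
#'
#' @param mu_deg mean directions of the components, in degrees.
#' @param kappa common concentration parameter.
#' @return A [mixture_spec()].
#' @export
vm_mixture <- function(mu_deg, kappa = 1) {
  k <- length(mu_deg)
  mixture_spec(lapply(mu_deg, function(m) {
    list(family = "vonmises", weight = 1 / k, mu = m * pi / 180, kappa = kappa)
  }))
}

#' Sample from a circular mixture
#'
#' Each draw independently picks a component with probability equal to its
#' weight, then samples from that component.
#'
#' @param spec a [mixture_spec()].
#' @param n number of draws.
#' @return An [angle_sample()].
#' @export
rcirc_mixture <- function(spec, n) {
  if (!inherits(spec, "mixture_spec")) stop("spec must be a mixture_spec")
  if (n < 1) stop("n must be at least 1")
  w <- vapply(spec$components, function(comp) comp$weight, numeric(1))
  idx <- sample.int(length(w), n, replace = TRUE, prob = w)
  theta <- numeric(n)
  for (i in seq_along(spec$components)) {
    take <- idx == i
    m <- sum(take)
    if (m == 0L) next
    comp <- spec$components[[i]]
    theta[take] <- switch(comp$family,
      uniform  = rcirc_uniform(m)$angles,
      vonmises = rcirc_vonmises(m, comp$mu, comp$kappa)$angles,
      wsn      = rcirc_wsn(m, comp$xi, comp$omega, comp$alpha)$angles
    )
  }
  angle_sample(theta, unit = "radians")
}

#' Serialize a mixture specification to JSON
#'
#' @param spec a [mixture_spec()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
mixture_to_json <- function(spec, path = NULL) {
  if (!inherits(spec, "mixture_spec")) stop("spec must be a mixture_spec")
  txt <- jsonlite::toJSON(spec$components, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(as.character(txt))
}

#' Read a mixture specification from JSON
#'
#' @param x a JSON string or a path to a JSON file.
#' @return A [mixture_spec()].
#' @export
mixture_from_json <- function(x) {
  comps <- jsonlite::fromJSON(x, simplifyDataFrame = FALSE)
  mixture_spec(comps)
}
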