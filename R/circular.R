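#' Wrap an angle to the signed interval (-180, 180]
#'
#' All stimulus and response values live on a 360-degree circular space.
#' Signed quantities (offsets, distances) use the convention that the
#' antipode maps to +180, so ties at the half-turn are broken
#' deterministically toward the positive side.
#'
#' @param a numeric vector of angles in degrees.
#' @return numeric vector of the same length, each element in (-180, 180]
#'   and congruent to the input modulo 360.
#' @examples
#' wrap_signed(370)   # 10
#' wrap_signed(-190)  # 170
#' wrap_signed(180)   # 180
#' @export
wrap_signed <- function(a) {
  if (!is.numeric(a) || any(!is.finite(a))) {
    stop("invalid-angle: angles must be finite numeric", call. = FALSE)
  }
  x <- a %% 360
  ifelse(x > 180, x - 360, x)
}

#' Wrap an angle to the positional interval [0, 360)
#'
#' @param a numeric vector of angles in degrees.
#' @return numeric vector in [0, 360), congruent to the input modulo 360.
#' @export
wrap_position <- function(a) {
  if (!is.numeric(a) || any(!is.finite(a))) {
    stop("invalid-angle: angles must be finite numeric", call. = FALSE)
  }
  a %% 360
}

#' Signed circular distance between two angles
#'
#' Computes `wrap_signed(a - b)`: the shortest signed rotation taking `b`
#' to `a`, positive counterclockwise. Antisymmetric except at the antipode,
#' where both orders return +180.
#'
#' @param a,b numeric vectors of angles in degrees (recycled).
#' @return signed distances in (-180, 180].
#' @examples
#' signed_circ_dist(10, 350)  # 20
#' signed_circ_dist(270, 90)  # 180
#' @export
signed_circ_dist <- function(a, b) {
  wrap_signed(a - b)
}

#' Evenly spaced circular support
#'
#' The discrete support on which all model densities are evaluated.
#' The default of 360 points at 1-degree resolution matches the
#' 360-valued stimulus wheels of the experiments.
#'
#' @param n_points number of evenly spaced support points.
#' @return object of class `circular_grid` with elements `points`
#'   (degrees, starting at 0) and `resolution` (degrees per point).
#' @export
circular_grid <- function(n_points = 360L) {
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 1L) {
    stop("invalid-grid: n_points must be a positive integer", call. = FALSE)
  }
  res <- 360 / n_points
  structure(
    list(points = seq(0, 360 - res, by = res), resolution = res,
         n_points = n_points),
    class = "circular_grid"
  )
}

#' @export
print.circular_grid <- function(x, ...) {
  cat("Circular grid:", x$n_points, "points,", x$resolution, "deg resolution\n")
  invisible(x)
}

## Construct a grid_density from raw non-negative weights, normalizing mass.
new_grid_density <- function(mass, grid) {
  if (any(mass < 0) || any(!is.finite(mass))) {
    stop("invalid-density: masses must be finite and non-negative", call. = FALSE)
  }
  tot <- sum(mass)
  if (tot <= 0) stop("invalid-density: total mass must be positive", call. = FALSE)
  structure(list(mass = mass / tot, grid = grid), class = "grid_density")
}

#' @export
print.grid_density <- function(x, ...) {
  cat("Grid density on", x$grid$n_points, "points")
  m <- try(circ_mean(x), silent = TRUE)
  if (!inherits(m, "try-error")) cat("; circular mean", round(m, 2), "deg")
  cat("\n")
  invisible(x)
}

#' Von Mises probability mass on a circular grid
#'
#' Evaluates a von Mises density with mean direction `mu` and
#' concentration `kappa` at the grid points and normalizes so the masses
#' sum to one (probability mass per bin, not per-radian density).
#' `kappa = 0` gives the uniform distribution.
#'
#' @param mu mean direction in degrees.
#' @param kappa concentration parameter, `>= 0`. Higher values give a
#'   tighter distribution; `1/sqrt(kappa)` is roughly the circular SD in
#'   radians.
#' @param grid a [circular_grid()].
#' @return object of class `grid_density`: list with `mass` (sums to 1)
#'   and `grid`.
#' @examples
#' d <- vm_density(0, 5)
#' sum(d$mass)  # 1
#' @export
vm_density <- function(mu, kappa, grid = circular_grid()) {
  if (!is.finite(mu)) stop("invalid-angle: mu must be finite", call. = FALSE)
  if (!is.finite(kappa) || kappa < 0) {
    stop("invalid-parameter: kappa must be finite and >= 0", call. = FALSE)
  }
  # exp(kappa * (cos - 1)) keeps the unnormalized weights <= 1 for any kappa
  theta <- (grid$points - mu) * pi / 180
  w <- exp(kappa * (cos(theta) - 1))
  new_grid_density(w, grid)
}

#' Closed-form product of two von Mises densities
#'
#' The normalized pointwise product of two von Mises densities is itself
#' von Mises. This closed form serves as the analytic oracle for the
#' grid-based joint density: the resultant vector of the product has
#' concentration `sqrt(k1^2 + k2^2 + 2 k1 k2 cos(D))` and mean direction
#' `mu1 + atan2(k2 sin(D), k1 + k2 cos(D))`, with `D` the signed distance
#' from `mu1` to `mu2`.
#'
#' @param mu1,k1 mean direction (degrees) and concentration of the first
#'   density.
#' @param mu2,k2 mean direction and concentration of the second density.
#' @return list with `mu` (degrees in [0, 360)) and `kappa`.
#' @export
vm_product_closed_form <- function(mu1, k1, mu2, k2) {
  if (k1 < 0 || k2 < 0) {
    stop("invalid-parameter: concentrations must be >= 0", call. = FALSE)
  }
  d <- signed_circ_dist(mu2, mu1) * pi / 180
  kappa <- sqrt(k1^2 + k2^2 + 2 * k1 * k2 * cos(d))
  shift <- atan2(k2 * sin(d), k1 + k2 * cos(d)) * 180 / pi
  list(mu = wrap_position(mu1 + shift), kappa = kappa)
}

#' Circular mean of a grid density
#'
#' Argument of the resultant vector `sum(mass * exp(i * theta))`.
#' Undefined (error) when the resultant length is numerically zero,
#' e.g. for the uniform density.
#'
#' @param density a `grid_density`.
#' @return mean direction in degrees, in [0, 360).
#' @export
circ_mean <- function(density) {
  stopifnot(inherits(density, "grid_density"))
  theta <- density$grid$points * pi / 180
  cbar <- sum(density$mass * cos(theta))
  sbar <- sum(density$mass * sin(theta))
  if (sqrt(cbar^2 + sbar^2) < 1e-10) {
    stop("undefined-mean: resultant length is zero", call. = FALSE)
  }
  wrap_position(atan2(sbar, cbar) * 180 / pi)
}

#' Mode of a grid density
#'
#' Grid point with the largest mass; ties resolved to the first point in
#' grid order.
#'
#' @param density a `grid_density`.
#' @return modal angle in degrees.
#' @export
circ_mode <- function(density) {
  stopifnot(inherits(density, "grid_density"))
  density$grid$points[which.max(density$mass)]
}

#' Circular resultant length of a sample of angles
#'
#' @param x angles in degrees.
#' @return mean resultant length in [0, 1].
#' @export
circ_resultant <- function(x) {
  th <- x * pi / 180
  sqrt(mean(cos(th))^2 + mean(sin(th))^2)
}

#' Circular moving-average smoothing
#'
#' Box-filter smoothing of a per-bin circular signal, as used to display
#' response-offset distributions: each output bin is the mean of the
#' input bins inside a window of `window` degrees centered (up to the
#' half-bin convention for even windows) on that bin, wrapping around
#' the circle.
#'
#' @param x numeric vector of per-bin values (e.g. response proportions),
#'   one bin per degree for the default grid.
#' @param window width of the smoothing window in degrees (default 30).
#' @param resolution degrees per bin of `x`.
#' @return smoothed vector of the same length.
#' @export
smooth_circular <- function(x, window = 30, resolution = 360 / length(x)) {
  if (window >= 360) stop("invalid-window: window must be < 360 degrees", call. = FALSE)
  if (window <= 0) stop("invalid-window: window must be positive", call. = FALSE)
  n <- length(x)
  w <- max(1L, as.integer(round(window / resolution)))
  # offsets -floor((w-1)/2) .. ceil((w-1)/2): symmetric for odd w, the
  # extra bin goes clockwise for even w
  lo <- -floor((w - 1) / 2)
  hi <- ceiling((w - 1) / 2)
  out <- numeric(n)
  for (k in lo:hi) {
    idx <- ((seq_len(n) - 1 + k) %% n) + 1
    out <- out + x[idx]
  }
  out / w
}

#' Equiluminant CIELAB color wheel
#'
#' Constructs the circular color space used for continuous-report color
#' tasks: `n` equally spaced hues on a circle of radius `radius` in the
#' (a*, b*) plane centered at `(a0, b0)`, at fixed lightness `L`.
#' Index 1 sits at phase 0 (the positive a* axis); hue angle increases
#' counterclockwise. Conversion to RGB and monitor calibration are out of
#' scope.
#'
#' @param n number of colors.
#' @param a0,b0 center of the hue circle in CIELAB a*/b* coordinates.
#' @param radius chroma radius.
#' @param L lightness, constant across the wheel.
#' @return data.frame with columns `index` (0-based hue angle index),
#'   `L`, `a`, `b`.
#' @examples
#' w <- cielab_wheel()
#' w[1, ]  # L = 70, a = 80, b = 38
#' @export
cielab_wheel <- function(n = 360L, a0 = 20, b0 = 38, radius = 60, L = 70) {
  if (n < 1) stop("invalid-parameter: n must be >= 1", call. = FALSE)
  if (radius <= 0) stop("invalid-parameter: radius must be > 0", call. = FALSE)
  phi <- 2 * pi * (seq_len(n) - 1) / n
  data.frame(
    index = seq_len(n) - 1L,
    L = rep(L, n),
    a = a0 + radius * cos(phi),
    b = b0 + radius * sin(phi)
  )
}

#' Write a color wheel to CSV
#'
#' @param wheel data.frame from [cielab_wheel()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_wheel_csv <- function(wheel, path) {
  utils::write.csv(wheel, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
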