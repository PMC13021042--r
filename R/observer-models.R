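#' Standard working-memory mixture density
#'
#' The classic delayed-estimation response model: with probability
#' `1 - guess_rate` the report is drawn from a von Mises centered on the
#' memorized stimulus with concentration `kappa`; with probability
#' `guess_rate` it is a uniform guess on the wheel.
#'
#' @param kappa memory concentration, `>= 0`.
#' @param guess_rate probability of a uniform guess, in [0, 1].
#' @param S_M memorized stimulus angle in degrees.
#' @param grid a [circular_grid()].
#' @return a `grid_density`.
#' @export
standard_wm_density <- function(kappa, guess_rate, S_M = 0, grid = circular_grid()) {
  if (guess_rate < 0 || guess_rate > 1) {
    stop("invalid-parameter: guess_rate must be in [0, 1]", call. = FALSE)
  }
  vm <- vm_density(S_M, kappa, grid)
  mass <- (1 - guess_rate) * vm$mass + guess_rate / grid$n_points
  new_grid_density(mass, grid)
}

#' Joint density of a memory and a probe representation
#'
#' Representational integration of a working-memory item and a
#' subjectively similar probe: the normalized pointwise product of the
#' memory density (von Mises at `S_M`, concentration `kappa_M`) and the
#' probe density (von Mises at `S_P`, concentration `kappa_P`) on the
#' grid. The product is itself von Mises with its mean shifted toward
#' the probe; [vm_product_closed_form()] gives the analytic parameters.
#'
#' @param S_M,kappa_M memory stimulus angle (degrees) and concentration.
#' @param S_P,kappa_P probe stimulus angle and concentration.
#' @param grid a [circular_grid()].
#' @return a `grid_density`.
#' @export
joint_density <- function(S_M, kappa_M, S_P, kappa_P, grid = circular_grid()) {
  m <- vm_density(S_M, kappa_M, grid)
  p <- vm_density(S_P, kappa_P, grid)
  new_grid_density(m$mass * p$mass, grid)
}

#' Mixture density of a memory and a probe representation
#'
#' The swap account of probe-induced bias: reports are memory-based with
#' probability `alpha` and probe-based otherwise, so the response density
#' is `alpha * vM(S_M, kappa_M) + (1 - alpha) * vM(S_P, kappa_P)`.
#' Unlike the joint density, the memory component itself is not shifted;
#' the mixture skews the response distribution without moving its
#' dominant mode (for `alpha > 0.5`).
#'
#' @param S_M,kappa_M memory stimulus angle (degrees) and concentration.
#' @param S_P,kappa_P probe stimulus angle and concentration.
#' @param alpha proportion of memory-based reports, in [0, 1].
#' @param grid a [circular_grid()].
#' @return a `grid_density`.
#' @export
mixture_density <- function(S_M, kappa_M, S_P, kappa_P, alpha,
                            grid = circular_grid()) {
  if (alpha < 0 || alpha > 1) {
    stop("invalid-parameter: alpha must be in [0, 1]", call. = FALSE)
  }
  m <- vm_density(S_M, kappa_M, grid)
  p <- vm_density(S_P, kappa_P, grid)
  new_grid_density(alpha * m$mass + (1 - alpha) * p$mass, grid)
}

#' Signed model bias toward the probe
#'
#' Displacement of a response density's circular mean away from the
#' memorized stimulus, signed so that displacement toward the probe is
#' positive.
#'
#' @param density a `grid_density` over responses.
#' @param S_M memorized stimulus angle (degrees).
#' @param S_P probe angle (degrees); defines the positive direction.
#' @return signed bias in degrees.
#' @export
model_bias <- function(density, S_M, S_P) {
  raw <- signed_circ_dist(circ_mean(density), S_M)
  dir <- signed_circ_dist(S_P, S_M)
  if (dir == 0) {
    stop("undefined-direction: probe coincides with the memory item", call. = FALSE)
  }
  raw * sign(dir)
}

#' Analytic joint-model bias
#'
#' Closed form for the bias of the joint (product) density toward the
#' probe at probe distance `delta`: `atan2(kP sin(delta), kM + kP cos(delta))`.
#' Used as the fitting-time prediction and as the oracle for the
#' grid-based [model_bias()].
#'
#' @param delta probe distance(s) in degrees (positive toward the probe).
#' @param kappa_M,kappa_P memory and probe concentrations.
#' @return bias in degrees, same sign convention as [model_bias()].
#' @export
joint_bias <- function(delta, kappa_M, kappa_P) {
  d <- delta * pi / 180
  atan2(kappa_P * sin(d), kappa_M + kappa_P * cos(d)) * 180 / pi
}

## Mean resultant length of a von Mises: A1(kappa) = I1(kappa)/I0(kappa).
## Scaled Bessel functions keep this finite for large kappa.
vm_A1 <- function(kappa) {
  ifelse(kappa == 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

#' Analytic mixture-model mean bias
#'
#' Circular-mean displacement of the two-component von Mises mixture
#' toward the probe, from the vector sum of the component resultants:
#' the memory component contributes `alpha * A1(kappa_M)` at angle 0 and
#' the probe component `(1 - alpha) * A1(kappa_P)` at angle `delta`,
#' where `A1` is the Bessel-function ratio `I1/I0`.
#'
#' @param delta probe distance(s) in degrees.
#' @param kappa_M,kappa_P memory and probe concentrations.
#' @param alpha proportion of memory-based reports.
#' @return mean bias in degrees toward the probe.
#' @export
mixture_bias <- function(delta, kappa_M, kappa_P, alpha) {
  d <- delta * pi / 180
  rm <- alpha * vm_A1(kappa_M)
  rp <- (1 - alpha) * vm_A1(kappa_P)
  atan2(rp * sin(d), rm + rp * cos(d)) * 180 / pi
}

#' Sample responses from a grid density
#'
#' I.i.d. draws of grid angles with probabilities given by the density's
#' masses. Uses the current RNG state; seed with [set.seed()] for
#' reproducibility.
#'
#' @param density a `grid_density`.
#' @param n number of draws.
#' @return numeric vector of `n` angles (grid points, degrees).
#' @export
sample_response <- function(density, n = 1L) {
  stopifnot(inherits(density, "grid_density"), n >= 1)
  sample(density$grid$points, size = n, replace = TRUE, prob = density$mass)
}

#' Export a model density as a two-column table
#'
#' @param density a `grid_density`.
#' @param path optional CSV path; when given the table is also written.
#' @return data.frame with columns `angle` and `mass`.
#' @export
density_table <- function(density, path = NULL) {
  df <- data.frame(angle = density$grid$points, mass = density$mass)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  df
}
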