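#' Branching-angle cumulative distribution table
#'
#' Validates a tabulated CDF of the polar branching angle theta for one
#' branch of a bifurcation. The table is interpreted piecewise-linearly and
#' inverted for inverse-transform sampling.
#'
#' @param theta polar angles in radians, strictly increasing, within
#'   `[0, pi]`.
#' @param p cumulative probabilities, non-decreasing from 0 to 1.
#' @return a `data.frame` of class `angle_cdf`.
#' @export
angle_cdf <- function(theta, p) {
  if (length(theta) != length(p) || length(theta) < 2L)
    stop("theta and p must have equal length >= 2")
  if (any(!is.finite(theta)) || any(!is.finite(p)))
    stop("angle CDF contains non-finite values")
  if (any(theta < -1e-12) || any(theta > pi + 1e-12))
    stop("theta must lie in [0, pi]")
  dth <- diff(theta)
  if (any(dth <= 0)) {
    i <- which(dth <= 0)[1]
    stop(sprintf("theta must be strictly increasing; row %d (theta = %g) violates this", i + 1L, theta[i + 1L]))
  }
  dp <- diff(p)
  if (any(dp < 0)) {
    i <- which(dp < 0)[1]
    stop(sprintf("cumulative probability must be non-decreasing; row %d (p = %g) violates this", i + 1L, p[i + 1L]))
  }
  if (abs(p[1]) > 1e-12 || abs(p[length(p)] - 1) > 1e-12)
    stop("cumulative probability must start at 0 and end at 1")
  out <- data.frame(theta = as.numeric(theta), p = as.numeric(p))
  class(out) <- c("angle_cdf", class(out))
  out
}

#' Read an angle CDF from a two-column CSV
#'
#' Column 1 is theta in radians, column 2 the cumulative probability.
#'
#' @param path CSV file path.
#' @return an [angle_cdf].
#' @export
read_angle_cdf <- function(path) {
  tab <- utils::read.csv(path)
  if (ncol(tab) < 2L) stop("angle CDF CSV needs two columns (theta_radians, cumulative_probability)")
  angle_cdf(tab[[1]], tab[[2]])
}

#' Default branching-angle CDF tables
#'
#' The published branching statistics are given only graphically, so these
#' piecewise-linear tables are a documented synthetic approximation of that
#' figure: branch 1 favours small deflections from the parent direction
#' (continuation branch), branch 2 larger ones. Any user-supplied table (see
#' [read_angle_cdf()]) can be used instead; every property of the sampler is
#' stated against whichever table is supplied.
#'
#' @return a list with elements `branch1` and `branch2`, each an
#'   [angle_cdf].
#' @export
default_angle_cdfs <- function() {
  deg <- function(x) x * pi / 180
  list(
    branch1 = angle_cdf(deg(c(0, 10, 20, 30, 45, 60, 90, 180)),
                        c(0, 0.05, 0.20, 0.45, 0.72, 0.88, 0.97, 1)),
    branch2 = angle_cdf(deg(c(0, 20, 40, 60, 80, 100, 130, 180)),
                        c(0, 0.04, 0.18, 0.45, 0.72, 0.89, 0.98, 1))
  )
}

#' Build an inverse-transform sampler from an angle CDF
#'
#' Returns the inverse of the piecewise-linear interpolated CDF: a function
#' mapping `u` in `[0, 1]` to theta. Flat stretches of the CDF (zero
#' probability mass) are inverted to their left endpoint.
#'
#' @param cdf an [angle_cdf].
#' @return `function(u)` returning theta (radians), vectorised.
#' @export
build_angle_sampler <- function(cdf) {
  cdf <- angle_cdf(cdf$theta, cdf$p)     # re-validate
  theta <- cdf$theta; p <- cdf$p
  # collapse exactly duplicated p so approx() has a function to invert;
  # ties = left endpoint
  keep <- !duplicated(p)
  pth <- theta[keep]; pp <- p[keep]
  function(u) {
    if (any(u < -1e-12 | u > 1 + 1e-12)) stop("u must lie in [0, 1]")
    u <- pmin(pmax(u, 0), 1)
    stats::approx(pp, pth, xout = u, method = "linear",
                  yleft = theta[1], yright = theta[length(theta)])$y
  }
}

#' Sample the two branch directions of a bifurcation
#'
#' Polar angles are drawn by inverse-transform sampling from the respective
#' branch CDF; azimuthal angles are uniform on `[0, 2*pi)`. Draw order is
#' fixed (theta1, theta2, phi1, phi2), so a given RNG state yields identical
#' output.
#'
#' @param samplers list of two samplers from [build_angle_sampler()].
#' @param n number of bifurcations to sample.
#' @return a list with matrices `theta` and `phi`, each `n x 2`.
#' @export
sample_branch_pair <- function(samplers, n = 1L) {
  u <- matrix(stats::runif(2L * n), ncol = 2L)
  theta <- cbind(samplers[[1]](u[, 1]), samplers[[2]](u[, 2]))
  phi <- matrix(stats::runif(2L * n, 0, 2 * pi), ncol = 2L)
  list(theta = theta, phi = phi)
}

#' Rotate a branch-local direction into the global frame
#'
#' A local direction given as polar angle `theta` (deflection from the
#' parent direction) and azimuth `phi` (rotation about it) is converted to a
#' global unit vector using direction cosines: an orthonormal frame
#' `(e1, e2, parent)` is constructed deterministically around the parent
#' direction and the spherical coordinates evaluated in it.
#'
#' @param theta polar angle (radians) relative to the parent direction.
#' @param phi azimuthal angle (radians) about the parent direction.
#' @param parent_direction global unit 3-vector of the parent segment.
#' @return a global unit 3-vector; its angle with `parent_direction` is
#'   `theta`.
#' @export
to_global_frame <- function(theta, phi, parent_direction) {
  d <- as.numeric(parent_direction)
  nrm <- sqrt(sum(d^2))
  if (nrm < 1e-12) stop("parent direction has zero norm")
  d <- d / nrm
  # reference axis least aligned with d, for a stable frame
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- c(ref[2] * d[3] - ref[3] * d[2],
          ref[3] * d[1] - ref[1] * d[3],
          ref[1] * d[2] - ref[2] * d[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  v <- sin(theta) * (cos(phi) * e1 + sin(phi) * e2) + cos(theta) * d
  v / sqrt(sum(v^2))
}
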