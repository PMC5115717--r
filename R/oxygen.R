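#' Physiological and numerical parameters of the oxygen computation
#'
#' Defaults are the standard parameter set of the model: oxygen diffusion
#' coefficient in tissue `D_O` = 2000 um^2/s, maximal consumption
#' `C_0` = 15 mmHg/s, Michaelis constant `K_M` = 1 mmHg (the pO2 at which
#' consumption is half-maximal), time step `t` = 0.1 s, and arterial/venous
#' vessel oxygen levels 100/40 mmHg. The Green's-function normalisation
#' constant `k = 1000 * (4 * D_O * t * pi)^(-3/2)` is recorded verbatim; the
#' discrete kernel is renormalised to sum to 1, so `k` does not enter the
#' computation (its 1000 is the 10 um voxel volume in um^3, which is what
#' makes the sampled continuous Gaussian sum to about one).
#'
#' @param D_O diffusion coefficient (um^2/s).
#' @param C_0 oxygen demand at unlimited supply (mmHg/s).
#' @param K_M Michaelis constant (mmHg).
#' @param t time step (s).
#' @param p_arterial,p_venous vessel oxygen bounds (mmHg).
#' @param truncation_sigmas where to truncate the discrete Gaussian kernel,
#'   in units of its standard deviation (default 4).
#' @return an object of class `phys_params`.
#' @export
phys_params <- function(D_O = 2000, C_0 = 15, K_M = 1, t = 0.1,
                        p_arterial = 100, p_venous = 40,
                        truncation_sigmas = 4) {
  vals <- c(D_O = D_O, C_0 = C_0, K_M = K_M, t = t,
            p_arterial = p_arterial, p_venous = p_venous,
            truncation_sigmas = truncation_sigmas)
  if (any(!is.finite(vals)) || any(vals[c("D_O", "K_M", "t", "p_arterial",
                                          "p_venous", "truncation_sigmas")] <= 0))
    stop("all physical parameters must be finite and positive")
  if (C_0 < 0) stop("C_0 must be >= 0")
  if (p_arterial <= p_venous) stop("p_arterial must exceed p_venous")
  structure(list(D_O = D_O, C_0 = C_0, K_M = K_M, t = t,
                 k = 1000 * (4 * D_O * t * pi)^(-3 / 2),
                 p_arterial = p_arterial, p_venous = p_venous,
                 truncation_sigmas = truncation_sigmas),
            class = "phys_params")
}

#' Diffusion length of one time step
#'
#' The per-axis standard deviation of the Green's-function Gaussian,
#' `sigma = sqrt(2 * D_O * t)` (20 um at the defaults).
#'
#' @param phys a [phys_params].
#' @return sigma in um.
#' @export
diffusion_sigma <- function(phys) sqrt(2 * phys$D_O * phys$t)

#' Discrete diffusion kernel
#'
#' Samples the Green's function of the diffusion equation (an isotropic
#' Gaussian with per-axis variance `2 * D_O * t`) at voxel centres,
#' truncates it at `truncation_sigmas * sigma` per axis, and renormalises it
#' to sum exactly to 1, so that one application conserves interior mass.
#'
#' @param phys a [phys_params].
#' @param spacing voxel spacing in um.
#' @param dims return the full 3D kernel (`dims = 3`, for inspection) or the
#'   1D factor (`dims = 1`) used by the separable convolution. The 3D kernel
#'   is the outer product of the 1D factor with itself.
#' @return numeric array (3D) or vector (1D), summing to 1.
#' @export
diffusion_kernel <- function(phys, spacing = 10, dims = 3) {
  sigma <- diffusion_sigma(phys)
  if (sigma < spacing / 2)
    stop("diffusion length per step (", signif(sigma, 3), " um) is below half ",
         "the voxel spacing; increase the time step t so that measurable ",
         "diffusion occurs between iterations")
  R <- as.integer(ceiling(phys$truncation_sigmas * sigma / spacing))
  x <- ((-R):R) * spacing
  k1 <- exp(-x^2 / (4 * phys$D_O * phys$t))
  k1 <- k1 / sum(k1)
  if (dims == 1) return(k1)
  k3 <- array(outer(outer(k1, k1), k1), dim = rep(length(k1), 3))
  k3 / sum(k3)
}

#' Assign intravascular oxygen levels
#'
#' Every vessel voxel receives a fixed oxygen value falling linearly with
#' centreline path distance from the tree root (the emerging point):
#' `p_arterial` (100 mmHg) at the root down to `p_venous` (40 mmHg) at the
#' most distant vessel voxel. Tissue voxels start at 0.
#'
#' @param vgrid a `vessel_grid` from [rasterize_tree()].
#' @param phys a [phys_params].
#' @return an `oxygen_field`: list with `values` (3D array, mmHg), `mask`
#'   (0/1 vessel array), `source` (fixed vessel values, 0 off-vessel),
#'   `spacing`, `origin`.
#' @export
assign_vessel_po2 <- function(vgrid, phys = phys_params()) {
  stopifnot(inherits(vgrid, "vessel_grid"))
  on_v <- vgrid$mask > 0
  src <- array(0, dim = dim(vgrid$mask))
  if (any(on_v)) {
    d <- vgrid$pathdist[on_v]
    dmax <- max(d)
    src[on_v] <- if (dmax <= 0) phys$p_arterial else
      phys$p_arterial - (phys$p_arterial - phys$p_venous) * d / dmax
  }
  oxygen_field(values = src, mask = vgrid$mask, source = src,
               spacing = vgrid$spacing, origin = vgrid$origin)
}

#' Construct an oxygen field container
#'
#' @param values pO2 array (mmHg).
#' @param mask 0/1 vessel mask of the same shape.
#' @param source fixed vessel source values (mmHg), same shape; 0 off-vessel.
#' @param spacing,origin grid geometry (um).
#' @return an object of class `oxygen_field`.
#' @export
oxygen_field <- function(values, mask, source, spacing = 10,
                         origin = c(0, 0, 0)) {
  stopifnot(identical(dim(values), dim(mask)),
            identical(dim(values), dim(source)))
  structure(list(values = values, mask = mask, source = source,
                 spacing = spacing, origin = as.numeric(origin)),
            class = "oxygen_field")
}

#' @export
print.oxygen_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<oxygen_field> %d x %d x %d voxels, spacing %g um\n",
              d[1], d[2], d[3], x$spacing))
  cat(sprintf("  pO2 range [%.3g, %.3g] mmHg; %d vessel voxels\n",
              min(x$values), max(x$values), sum(x$mask > 0)))
  invisible(x)
}

#' One Green's-function diffusion step
#'
#' Convolves the whole field (tissue and vessel voxels alike) with the
#' Gaussian kernel under zero padding (values outside the grid are treated
#' as zero), then re-imposes the fixed vessel source values, which act as
#' Dirichlet boundary conditions of constant vessel oxygen content.
#'
#' @param field an `oxygen_field`.
#' @param kernel1d the 1D kernel factor from
#'   `diffusion_kernel(phys, spacing, dims = 1)`.
#' @return the updated `oxygen_field`.
#' @export
diffusion_step <- function(field, kernel1d) {
  stopifnot(inherits(field, "oxygen_field"))
  d <- dim(field$values)
  v <- conv3d_separable(as.numeric(field$values), as.integer(d),
                        as.numeric(kernel1d))
  v <- array(v, dim = d)
  on_v <- field$mask > 0
  v[on_v] <- field$source[on_v]
  field$values <- v
  field
}

#' Michaelis-Menten consumption rate
#'
#' `C = C_0 * pO2 / (pO2 + K_M)`: zero at anoxia, half-maximal at
#' `pO2 = K_M`, saturating at `C_0`.
#'
#' @param po2 oxygen tension (mmHg), vectorised.
#' @param phys a [phys_params].
#' @return consumption rate (mmHg/s).
#' @export
consumption_rate <- function(po2, phys = phys_params()) {
  if (any(po2 < 0)) stop("po2 must be >= 0")
  phys$C_0 * po2 / (po2 + phys$K_M)
}

#' Subtract one time step of tissue oxygen consumption
#'
#' Tissue voxels are updated explicitly,
#' `pO2 <- max(0, pO2 - t * C(pO2))`; the clamp at zero absorbs the
#' overshoot of the explicit update at very low pO2 (where `t * C_0`
#' exceeds the remaining oxygen). Vessel voxels are untouched.
#'
#' @param field an `oxygen_field`.
#' @param phys a [phys_params].
#' @return the updated `oxygen_field`.
#' @export
apply_consumption <- function(field, phys = phys_params()) {
  tis <- field$mask <= 0
  p <- field$values[tis]
  field$values[tis] <- pmax(0, p - phys$t * phys$C_0 * p / (p + phys$K_M))
  field
}

#' Iterate diffusion and consumption to steady state
#'
#' Alternates [diffusion_step()] (with vessel re-clamping) and
#' [apply_consumption()] until the total tissue oxygen changes by less than
#' `tolerance` (relative) for three consecutive iterations, or `max_iter` is
#' reached.
#'
#' @param field initial `oxygen_field` from [assign_vessel_po2()].
#' @param phys a [phys_params].
#' @param tolerance relative change threshold (default 1e-4).
#' @param max_iter iteration cap (default 2000).
#' @return a list: `field` (converged `oxygen_field`), `iterations`,
#'   `converged` (logical).
#' @export
solve_steady_state <- function(field, phys = phys_params(),
                               tolerance = 1e-4, max_iter = 2000) {
  k1 <- diffusion_kernel(phys, field$spacing, dims = 1)
  tis <- field$mask <= 0
  s_prev <- sum(field$values[tis])
  streak <- 0L
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    field <- diffusion_step(field, k1)
    field <- apply_consumption(field, phys)
    s <- sum(field$values[tis])
    rel <- abs(s - s_prev) / max(s_prev, .Machine$double.eps)
    s_prev <- s
    streak <- if (rel < tolerance) streak + 1L else 0L
    if (streak >= 3L) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("steady state not reached after %d iterations", it))
  list(field = field, iterations = it, converged = converged)
}
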