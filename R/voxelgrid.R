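#' 3D voxel grid
#'
#' A minimal container for a 3D scalar field on an isotropic grid: a numeric
#' array in R's native column-major layout (first index fastest), a voxel
#' spacing in micrometres and the physical position (micrometres) of the
#' centre of voxel `[1,1,1]`.
#'
#' @param values numeric 3D array.
#' @param spacing voxel edge length in micrometres (isotropic, > 0).
#' @param origin length-3 numeric, physical position (um) of the first voxel
#'   centre.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, spacing = 10, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("`spacing` must be a single positive number (um)")
  if (length(origin) != 3L) stop("`origin` must have length 3")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing %g um\n",
              d[1], d[2], d[3], x$spacing))
  cat(sprintf("  origin (um): [%g, %g, %g]; value range [%g, %g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

#' Crop a uniform margin from every face of a grid
#'
#' Used to remove the padding region after an oxygen computation, so that
#' statistics are taken over the actual sample only.
#'
#' @param grid a `voxel_grid` (or a bare 3D array).
#' @param margin number of voxels to strip from each face (scalar).
#' @return object of the same kind, cropped; the origin is shifted inward.
#' @export
crop_margin <- function(grid, margin) {
  margin <- as.integer(margin)
  if (margin < 0L) stop("`margin` must be >= 0")
  if (margin == 0L) return(grid)
  arr <- if (inherits(grid, "voxel_grid")) grid$values else grid
  d <- dim(arr)
  if (any(d <= 2L * margin)) stop("margin larger than grid allows")
  idx <- lapply(d, function(n) (margin + 1L):(n - margin))
  out <- arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  if (inherits(grid, "voxel_grid")) {
    voxel_grid(out, grid$spacing, grid$origin + margin * grid$spacing)
  } else out
}
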