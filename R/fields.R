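#' Build a library of microvessel tree archetypes
#'
#' Generates `n_archetypes` microvessel trees (random isotropic root
#' directions), voxelises each once at the working resolution and stores the
#' vessel voxel cloud relative to the tree root together with the fixed
#' intravascular oxygen values (100 mmHg at the root falling linearly to
#' 40 mmHg at the most distant vessel voxel of that tree). Each archetype is
#' later reused at many macrotree leaves.
#'
#' @param n_archetypes library size (the full-scale model uses 100).
#' @param micro_params a [tree_params] (default [micro_tree_params()]).
#' @param phys a [phys_params].
#' @param spacing working resolution (um, default 10).
#' @param seed integer seed.
#' @return list of archetypes; each has `tree`, `rel_idx` (vessel voxel
#'   offsets from the root voxel), `source` (mmHg per vessel voxel),
#'   `pathdist` (um), `bbox_lo_um`/`bbox_hi_um` (dilated extent relative to
#'   the root), `volume_mm3` (vessel volume), `spacing`.
#' @export
build_micro_library <- function(n_archetypes, micro_params = micro_tree_params(),
                                phys = phys_params(), spacing = 10, seed = 1L) {
  lapply(seq_len(n_archetypes), function(i) {
    si <- derive_seed(seed, i)
    set.seed(si)
    dirv <- stats::rnorm(3)
    dirv <- dirv / sqrt(sum(dirv^2))
    tree <- generate_tree(micro_params, root_position = c(0, 0, 0),
                          root_direction = dirv, seed = derive_seed(si, 2))
    archetype_from_tree(tree, phys, spacing)
  })
}

# voxelize one tree into an archetype record (deduplicated, with sources)
archetype_from_tree <- function(tree, phys = phys_params(), spacing = 10) {
  vox <- voxelize_tree(tree, spacing)
  lin_span <- apply(vox$idx, 2, range)
  key <- paste(vox$idx[, 1], vox$idx[, 2], vox$idx[, 3])
  o <- order(key, vox$dist)
  first <- !duplicated(key[o])
  idx <- vox$idx[o, , drop = FALSE][first, , drop = FALSE]
  dist <- vox$dist[o][first]
  dmax <- max(dist)
  src <- if (dmax <= 0) rep(phys$p_arterial, length(dist)) else
    phys$p_arterial - (phys$p_arterial - phys$p_venous) * dist / dmax
  rel <- sweep(idx, 2, vox$root_voxel)
  list(tree = tree,
       rel_idx = rel,
       source = src,
       pathdist = dist,
       bbox_lo_um = (lin_span[1, ] - vox$root_voxel) * spacing,
       bbox_hi_um = (lin_span[2, ] - vox$root_voxel) * spacing,
       volume_mm3 = nrow(rel) * spacing^3 / 1e9,
       spacing = spacing)
}

#' Precompute the steady-state oxygen field of every archetype
#'
#' Solves each archetype individually in its own zero-padded box and stores
#' both the high-resolution field and its block-mean down-sampled version on
#' the coarse grid; these per-tree fields are what the individual tree
#' method combines.
#'
#' @param micro_library from [build_micro_library()].
#' @param phys a [phys_params].
#' @param pad_um zero-padding around each archetype during the solve.
#' @param coarse_spacing coarse grid spacing (um, default 100).
#' @param tolerance,max_iter forwarded to [solve_steady_state()].
#' @return the library with `field` (high-res `oxygen_field`), `root_voxel`,
#'   `coarse` (down-sampled `voxel_grid`), `coarse_root_voxel` and
#'   `iterations` added to each archetype.
#' @export
precompute_archetype_fields <- function(micro_library, phys = phys_params(),
                                        pad_um = 150, coarse_spacing = 100,
                                        tolerance = 1e-4, max_iter = 2000) {
  lapply(micro_library, function(a) {
    spacing <- a$spacing
    pad <- as.integer(ceiling(pad_um / spacing))
    lo <- apply(a$rel_idx, 2, min) - pad
    hi <- apply(a$rel_idx, 2, max) + pad
    shape <- hi - lo + 1L
    vox <- list(idx = a$rel_idx, dist = a$pathdist, root_voxel = c(0L, 0L, 0L))
    vg <- build_vessel_grid(vox, lo, shape, spacing, root_voxel = -lo + 1L)
    f0 <- assign_vessel_po2(vg, phys)
    sol <- solve_steady_state(f0, phys, tolerance, max_iter)
    factor <- as.integer(round(coarse_spacing / spacing))
    coarse <- downsample_block_mean(
      voxel_grid(sol$field$values, spacing, as.numeric(lo) * spacing), factor)
    a$field <- sol$field
    a$root_voxel <- vg$root_voxel
    a$iterations <- sol$iterations
    a$converged <- sol$converged
    a$coarse <- coarse
    # coarse cell (1-based) containing the root voxel
    a$coarse_root_voxel <- as.integer(ceiling(vg$root_voxel / factor))
    a
  })
}

#' Block-mean down-sampling
#'
#' Each output voxel is the mean of its `factor^3` input block, which
#' preserves the global mean exactly on divisible shapes. Non-divisible
#' shapes are cropped to the largest leading multiple of `factor` first.
#'
#' @param field a [voxel_grid] or bare 3D array.
#' @param factor positive integer down-sampling factor per axis.
#' @return same kind of object, down-sampled; for a `voxel_grid` the spacing
#'   is multiplied by `factor` and the origin moved to the new voxel
#'   centres.
#' @export
downsample_block_mean <- function(field, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor <= 0L) stop("factor must be a positive integer")
  arr <- if (inherits(field, "voxel_grid")) field$values else field
  if (factor == 1L) return(field)
  d <- dim(arr)
  dc <- (d %/% factor) * factor
  if (any(dc == 0L)) stop("grid smaller than one block")
  arr <- arr[seq_len(dc[1]), seq_len(dc[2]), seq_len(dc[3]), drop = FALSE]
  mean_axis1 <- function(a, f) {
    d <- dim(a)
    m <- array(a, dim = c(f, d[1] %/% f, d[2], d[3]))
    colMeans(m)
  }
  out <- mean_axis1(arr, factor)
  out <- aperm(mean_axis1(aperm(out, c(2, 1, 3)), factor), c(2, 1, 3))
  out <- aperm(mean_axis1(aperm(out, c(3, 2, 1)), factor), c(3, 2, 1))
  if (inherits(field, "voxel_grid")) {
    voxel_grid(out, field$spacing * factor,
               field$origin + (factor - 1) / 2 * field$spacing)
  } else out
}

#' Combined tree method: joint high-resolution solve of a sample
#'
#' Rasterizes every tree of the sample spec into one padded grid (vessel
#' union; where vessel voxels of different trees collide, the source value
#' is the maximum of the contributors), solves the whole sample jointly to
#' steady state, and crops the padding, so inter-tree interaction is fully
#' represented.
#'
#' @param spec a `sample_spec` from [extract_sample()], or a list with
#'   `leaves`, `centre`, `side_um`, `pad_um`, `micro_library`.
#' @param phys a [phys_params].
#' @param spacing working resolution (um, default 10).
#' @param tolerance,max_iter forwarded to [solve_steady_state()].
#' @return list: `field` (pad-cropped `oxygen_field`), `iterations`,
#'   `converged`.
#' @export
ctm_field <- function(spec, phys = phys_params(), spacing = 10,
                      tolerance = 1e-4, max_iter = 2000) {
  pad <- as.integer(ceiling(spec$pad_um / spacing))
  nside <- as.integer(round(spec$side_um / spacing))
  shape <- rep(nside + 2L * pad, 3L)
  lo_um <- spec$centre - spec$side_um / 2 - pad * spacing
  lo_vox <- round(lo_um / spacing)
  dep <- deposit_sample(spec, spacing, lo_vox, shape)
  f0 <- oxygen_field(values = dep$source, mask = dep$mask, source = dep$source,
                     spacing = spacing, origin = as.numeric(lo_vox) * spacing)
  sol <- solve_steady_state(f0, phys, tolerance, max_iter)
  f <- sol$field
  cropped <- oxygen_field(values = crop_margin(f$values, pad),
                          mask = crop_margin(f$mask, pad),
                          source = crop_margin(f$source, pad),
                          spacing = spacing,
                          origin = f$origin + pad * spacing)
  list(field = cropped, iterations = sol$iterations, converged = sol$converged)
}

# union-deposit all trees of a sample spec into mask/source arrays
deposit_sample <- function(spec, spacing, lo_vox, shape) {
  mask <- array(0, dim = shape)
  source <- array(0, dim = shape)
  lib <- spec$micro_library
  for (i in seq_len(nrow(spec$leaves))) {
    a <- lib[[spec$leaves$archetype_id[i]]]
    if (a$spacing != spacing) stop("archetype spacing does not match the sample grid")
    root <- round(as.numeric(spec$leaves[i, c("x", "y", "z")]) / spacing)
    rel <- sweep(a$rel_idx, 2, as.integer(root - lo_vox) - 1L, "+") + 1L
    keep <- rel[, 1] >= 1L & rel[, 1] <= shape[1] &
            rel[, 2] >= 1L & rel[, 2] <= shape[2] &
            rel[, 3] >= 1L & rel[, 3] <= shape[3]
    if (!any(keep)) next
    lin <- (rel[keep, 3] - 1) * (as.numeric(shape[1]) * shape[2]) +
           (rel[keep, 2] - 1) * as.numeric(shape[1]) + rel[keep, 1]
    mask[lin] <- 1
    source[lin] <- pmax(source[lin], a$source[keep])
  }
  list(mask = mask, source = source)
}

#' Individual tree method: max-combined precomputed fields on a coarse grid
#'
#' Places each leaf's precomputed, down-sampled archetype oxygen field at
#' the leaf position on the coarse grid (nearest-voxel placement); where a
#' voxel is reached by the fields of several trees, the highest oxygen value
#' is assigned. Voxels reached by no field stay 0. Inter-tree interaction is
#' by construction not represented.
#'
#' @param leaves data.frame with `x`, `y`, `z` (um) and `archetype_id`.
#' @param micro_library library with precomputed `coarse` fields (see
#'   [precompute_archetype_fields()]).
#' @param box_lo_um,box_hi_um bounds (um) of the coarse output grid.
#' @param coarse_spacing coarse grid spacing (um, default 100).
#' @param allow_outside if `FALSE`, a leaf outside the grid is an error;
#'   if `TRUE` (default) its field still contributes where it reaches in.
#' @return a [voxel_grid] of pO2 on the coarse grid.
#' @export
itm_field <- function(leaves, micro_library, box_lo_um, box_hi_um,
                      coarse_spacing = 100, allow_outside = TRUE) {
  shape <- as.integer(round((box_hi_um - box_lo_um) / coarse_spacing))
  if (any(shape <= 0L)) stop("empty coarse grid")
  vals <- array(0, dim = shape)
  for (i in seq_len(nrow(leaves))) {
    a <- micro_library[[leaves$archetype_id[i]]]
    if (is.null(a$coarse)) stop("archetype has no precomputed coarse field; run precompute_archetype_fields()")
    p <- as.numeric(leaves[i, c("x", "y", "z")])
    cell <- floor((p - box_lo_um) / coarse_spacing) + 1L
    if (any(cell < 1L) || any(cell > shape)) {
      if (!allow_outside)
        stop(sprintf("leaf %d lies outside the coarse grid", i))
    }
    cd <- dim(a$coarse$values)
    # output cells covered by this field, clipped to the grid
    off <- cell - a$coarse_root_voxel      # translation in coarse cells
    xr <- max(1L, 1L + off[1]):min(shape[1], cd[1] + off[1])
    yr <- max(1L, 1L + off[2]):min(shape[2], cd[2] + off[2])
    zr <- max(1L, 1L + off[3]):min(shape[3], cd[3] + off[3])
    if (length(xr) < 1L || length(yr) < 1L || length(zr) < 1L ||
        xr[1] > xr[length(xr)] || yr[1] > yr[length(yr)] || zr[1] > zr[length(zr)])
      next
    sub <- a$coarse$values[xr - off[1], yr - off[2], zr - off[3], drop = FALSE]
    vals[xr, yr, zr] <- pmax(vals[xr, yr, zr], sub)
  }
  voxel_grid(vals, coarse_spacing, box_lo_um + coarse_spacing / 2)
}
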