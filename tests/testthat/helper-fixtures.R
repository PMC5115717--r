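# shared helpers: all fixtures are generated in code, no binary files

# a hand-built vessel grid: straight axis-aligned segment of given length
# (voxels) along x, one voxel wide, with path distances from the first voxel
straight_vessel_grid <- function(n_vox = 7, shape = c(21, 21, 21),
                                 spacing = 10, extra_voxel = NULL) {
  m <- array(0, dim = shape)
  pd <- array(NA_real_, dim = shape)
  mid <- ceiling(shape / 2)
  xs <- seq(mid[1] - floor(n_vox / 2), length.out = n_vox)
  m[xs, mid[2], mid[3]] <- 1
  pd[xs, mid[2], mid[3]] <- (seq_len(n_vox) - 1) * spacing
  if (!is.null(extra_voxel)) {
    m[extra_voxel[1], extra_voxel[2], extra_voxel[3]] <- 1
    pd[extra_voxel[1], extra_voxel[2], extra_voxel[3]] <- n_vox * spacing
  }
  structure(list(mask = m, pathdist = pd, spacing = spacing,
                 origin = c(0, 0, 0), root_voxel = c(xs[1], mid[2], mid[3])),
            class = "vessel_grid")
}

# a literal straight tree: root at origin, one child at `length_um` along x
straight_tree <- function(length_um, radius_um) {
  nodes <- data.frame(id = 1:2, parent = c(NA, 1L),
                      x = c(0, length_um), y = c(0, 0), z = c(0, 0),
                      radius = radius_um, generation = 0:1)
  structure(nodes, class = c("vessel_tree", "data.frame"))
}

# independent dense 3D convolution oracle (zero padding), direct shift-sum
dense_conv3d <- function(arr, kernel3d) {
  d <- dim(arr)
  kd <- dim(kernel3d)
  R <- (kd - 1) %/% 2
  out <- array(0, dim = d)
  for (i in seq_len(kd[1])) for (j in seq_len(kd[2])) for (k in seq_len(kd[3])) {
    w <- kernel3d[i, j, k]
    if (w == 0) next
    dx <- i - 1 - R[1]; dy <- j - 1 - R[2]; dz <- k - 1 - R[3]
    sx <- max(1, 1 - dx):min(d[1], d[1] - dx)
    sy <- max(1, 1 - dy):min(d[2], d[2] - dy)
    sz <- max(1, 1 - dz):min(d[3], d[3] - dz)
    out[sx + dx, sy + dy, sz + dz] <-
      out[sx + dx, sy + dy, sz + dz] + w * arr[sx, sy, sz]
  }
  out
}

# distance from a voxel centre to the continuous segment a-b (voxel units)
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  den <- sum(ab^2)
  t <- if (den == 0) 0 else max(0, min(1, sum((p - a) * ab) / den))
  sqrt(sum((p - a - t * ab)^2))
}

# archetype list + sample spec for a set of trees rooted at their positions
spec_from_trees <- function(trees, phys = phys_params(), spacing = 10,
                            centre = c(500, 500, 500), side_um = 1000,
                            pad_um = 150, precompute = FALSE) {
  lib <- lapply(trees, vascox:::archetype_from_tree, phys = phys,
                spacing = spacing)
  if (precompute)
    lib <- precompute_archetype_fields(lib, phys, pad_um = pad_um)
  leaves <- data.frame(
    x = vapply(trees, function(t) t$x[1], numeric(1)),
    y = vapply(trees, function(t) t$y[1], numeric(1)),
    z = vapply(trees, function(t) t$z[1], numeric(1)),
    macrotree_id = seq_along(trees), leaf_id = seq_along(trees),
    archetype_id = seq_along(trees))
  structure(list(leaves = leaves, centre = centre, side_um = side_um,
                 pad_um = pad_um, micro_library = lib),
            class = "sample_spec")
}
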