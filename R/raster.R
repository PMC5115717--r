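#' 3D Bresenham line
#'
#' Discrete approximation of the segment between two voxel index triples,
#' generalising Bresenham's line algorithm to 3D. The driving axis is the
#' axis of largest absolute difference (ties broken x > y > z); the path is
#' 26-connected with no gaps and has `max(|delta|) + 1` voxels.
#'
#' @param a,b integer length-3 voxel indices.
#' @return integer matrix, one row per voxel, ordered from `a` to `b`.
#' @export
bresenham_3d <- function(a, b) {
  a <- as.integer(round(a)); b <- as.integer(round(b))
  d <- abs(b - a)
  s <- as.integer(sign(b - a))
  n <- max(d)
  if (n == 0L) return(matrix(a, nrow = 1L))
  m <- which.max(d)                  # first max: tie priority x > y > z
  others <- setdiff(1:3, m)
  o1 <- others[1]; o2 <- others[2]
  out <- matrix(0L, nrow = n + 1L, ncol = 3L)
  p <- a
  e1 <- 2L * d[o1] - d[m]
  e2 <- 2L * d[o2] - d[m]
  out[1L, ] <- p
  for (i in seq_len(n)) {
    if (e1 > 0L) { p[o1] <- p[o1] + s[o1]; e1 <- e1 - 2L * d[m] }
    if (e2 > 0L) { p[o2] <- p[o2] + s[o2]; e2 <- e2 - 2L * d[m] }
    e1 <- e1 + 2L * d[o1]
    e2 <- e2 + 2L * d[o2]
    p[m] <- p[m] + s[m]
    out[i + 1L, ] <- p
  }
  out
}

#' Spherical structuring kernel
#'
#' Binary ball used to dilate a one-voxel-wide centreline to the vessel
#' calibre: voxel centres within `radius_um` of the centre (boundary
#' included) are 1, all others 0.
#'
#' @param radius_um sphere radius in um.
#' @param spacing_um voxel spacing in um.
#' @return a 3D 0/1 array with odd side length.
#' @export
spherical_kernel <- function(radius_um, spacing_um) {
  if (radius_um < spacing_um / 2) {
    warning("radius below half the voxel spacing; using a single-voxel kernel")
    return(array(1, dim = c(1L, 1L, 1L)))
  }
  R <- floor(radius_um / spacing_um + 1e-9)
  ax <- (-R):R
  n <- length(ax)
  d2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  array(as.numeric(d2 * spacing_um^2 <= radius_um^2 + 1e-9), dim = c(n, n, n))
}

# offsets (m x 3 integer) of the ball voxels, used for dilation by stamping
ball_offsets <- function(radius_um, spacing_um) {
  R <- max(floor(radius_um / spacing_um + 1e-9), 0L)
  ax <- (-R):R
  g <- as.matrix(expand.grid(ix = ax, iy = ax, iz = ax))
  keep <- rowSums(g^2) * spacing_um^2 <= radius_um^2 + 1e-9
  g[keep, , drop = FALSE]
}

#' Rasterize a vessel tree into a binary voxel grid
#'
#' Every segment's centreline is voxelised with [bresenham_3d()], dilated by
#' the spherical kernel of the segment's radius (equivalent to convolution
#' with the ball followed by thresholding at any positive level), and the
#' union taken over segments. Each vessel voxel carries the arc length from
#' the tree root along the centreline of the segment that deposited it; where
#' several segments deposit the same voxel the minimum distance wins.
#'
#' @param tree a `vessel_tree`.
#' @param spacing voxel spacing in um (default 10).
#' @param pad_um padding added around the tree's dilated bounding box.
#' @return a `vessel_grid`: list with `mask` (0/1 3D array), `pathdist`
#'   (array, um; `NA` off-vessel), `spacing`, `origin` (um of first voxel
#'   centre), `root_voxel` (index triple of the root).
#' @export
rasterize_tree <- function(tree, spacing = 10, pad_um = 0) {
  vox <- voxelize_tree(tree, spacing)
  pad <- as.integer(ceiling(pad_um / spacing))
  lo <- apply(vox$idx, 2, min) - pad
  hi <- apply(vox$idx, 2, max) + pad
  shape <- hi - lo + 1L
  if (prod(as.numeric(shape)) > 2^31 - 1)
    stop(sprintf("tree exceeds addressable grid; required shape %d x %d x %d",
                 shape[1], shape[2], shape[3]))
  build_vessel_grid(vox, lo, shape, spacing,
                    root_voxel = vox$root_voxel - lo + 1L)
}

# Voxelize the centrelines + dilation of a tree in absolute voxel
# coordinates (position / spacing, rounded). Returns idx (m x 3 int),
# dist (um from root) per deposited voxel (duplicates possible), and the
# root voxel.
voxelize_tree <- function(tree, spacing) {
  stopifnot(inherits(tree, "vessel_tree"))
  nidx <- round(as.matrix(tree[, c("x", "y", "z")]) / spacing)
  storage.mode(nidx) <- "integer"
  # cumulative root path length at every node
  seglen <- rep(0, nrow(tree))
  has_par <- !is.na(tree$parent)
  seglen[has_par] <- sqrt((tree$x[has_par] - tree$x[tree$parent[has_par]])^2 +
                          (tree$y[has_par] - tree$y[tree$parent[has_par]])^2 +
                          (tree$z[has_par] - tree$z[tree$parent[has_par]])^2)
  cum <- rep(0, nrow(tree))
  for (i in order(tree$generation)) {
    if (has_par[i]) cum[i] <- cum[tree$parent[i]] + seglen[i]
  }

  idx_list <- list(); dist_list <- list()
  k <- 0L
  # root voxel itself (covers the root-only tree)
  k <- k + 1L; idx_list[[k]] <- nidx[1, , drop = FALSE]; dist_list[[k]] <- 0
  for (i in which(has_par)) {
    p <- tree$parent[i]
    line <- bresenham_3d(nidx[p, ], nidx[i, ])
    nl <- nrow(line)
    frac <- if (nl > 1L) (seq_len(nl) - 1) / (nl - 1) else 0
    dist <- cum[p] + frac * seglen[i]
    off <- ball_offsets(tree$radius[i], spacing)
    m <- nrow(off)
    rep_line <- line[rep(seq_len(nl), each = m), , drop = FALSE] +
      off[rep(seq_len(m), times = nl), , drop = FALSE]
    k <- k + 1L
    idx_list[[k]] <- rep_line
    dist_list[[k]] <- rep(dist, each = m)
  }
  idx <- do.call(rbind, idx_list)
  dist <- unlist(dist_list, use.names = FALSE)
  list(idx = idx, dist = dist, root_voxel = nidx[1, ])
}

# Deposit voxel clouds into a grid with given lower corner (absolute voxel
# coords) and shape; duplicate voxels keep the minimum path distance.
build_vessel_grid <- function(vox, lo, shape, spacing, root_voxel) {
  rel <- sweep(vox$idx, 2, lo - 1L)   # 1-based indices in the grid
  keep <- rel[, 1] >= 1L & rel[, 1] <= shape[1] &
          rel[, 2] >= 1L & rel[, 2] <= shape[2] &
          rel[, 3] >= 1L & rel[, 3] <= shape[3]
  rel <- rel[keep, , drop = FALSE]
  dist <- vox$dist[keep]
  lin <- (rel[, 3] - 1) * (as.numeric(shape[1]) * shape[2]) +
         (rel[, 2] - 1) * as.numeric(shape[1]) + rel[, 1]
  o <- order(lin, dist)
  first <- !duplicated(lin[o])
  lin_u <- lin[o][first]
  dist_u <- dist[o][first]
  mask <- array(0, dim = shape)
  mask[lin_u] <- 1
  pd <- array(NA_real_, dim = shape)
  pd[lin_u] <- dist_u
  structure(list(mask = mask, pathdist = pd, spacing = spacing,
                 origin = as.numeric(lo) * spacing,
                 root_voxel = as.integer(root_voxel)),
            class = "vessel_grid")
}

#' @export
print.vessel_grid <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<vessel_grid> %d x %d x %d voxels, spacing %g um, %d vessel voxels\n",
              d[1], d[2], d[3], x$spacing, sum(x$mask > 0)))
  invisible(x)
}

#' Number of 26-connected components of a binary mask
#'
#' Flood fill over the 26-neighbourhood; used to verify that a rasterized
#' tree forms a single connected vessel component.
#'
#' @param mask 0/1 3D array.
#' @return number of connected components of the foreground.
#' @export
count_components_26 <- function(mask) {
  d <- dim(mask)
  fg <- which(mask > 0)
  if (length(fg) == 0L) return(0L)
  remaining <- new.env(hash = TRUE, size = length(fg))
  for (v in fg) assign(as.character(v), TRUE, envir = remaining)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  lin_off <- offs[, 1] + offs[, 2] * d[1] + offs[, 3] * d[1] * d[2]
  ncomp <- 0L
  arr_ind <- function(lin) {
    lin0 <- lin - 1
    c(lin0 %% d[1], (lin0 %/% d[1]) %% d[2], lin0 %/% (d[1] * d[2])) + 1
  }
  for (v in fg) {
    if (!exists(as.character(v), envir = remaining)) next
    ncomp <- ncomp + 1L
    queue <- v
    rm(list = as.character(v), envir = remaining)
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ai <- arr_ind(cur)
      nb <- cur + lin_off
      # exclude wrap-around neighbours
      nbi <- cbind(ai[1] + offs[, 1], ai[2] + offs[, 2], ai[3] + offs[, 3])
      ok <- nbi[, 1] >= 1 & nbi[, 1] <= d[1] &
            nbi[, 2] >= 1 & nbi[, 2] <= d[2] &
            nbi[, 3] >= 1 & nbi[, 3] <= d[3]
      for (w in nb[ok]) {
        key <- as.character(w)
        if (exists(key, envir = remaining)) {
          rm(list = key, envir = remaining)
          queue <- c(queue, w)
        }
      }
    }
  }
  ncomp
}
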