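#' Convex hull of a 3D point cloud
#'
#' Incremental convex hull: starting from an extreme tetrahedron, each point
#' outside the current hull removes its visible faces and is stitched to the
#' horizon edges. Face normals are oriented outward against the centroid of
#' the initial tetrahedron.
#'
#' @param points numeric matrix, one row per point, 3 columns (um or any
#'   consistent unit).
#' @return list: `faces` (integer matrix, one row per triangle, indices into
#'   `points`), `vertices` (indices of hull vertices), `volume` (in the cube
#'   of the input unit).
#' @export
convex_hull_3d <- function(points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 3L) stop("points must have 3 columns")
  n <- nrow(pts)
  if (n < 4L) stop("need at least 4 points")
  scale <- max(apply(pts, 2, function(v) diff(range(v))))
  if (scale <= 0) stop("degenerate input: all points coincide")
  eps <- 1e-9 * scale

  # initial extreme tetrahedron
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (i1 == i2) { i1 <- which.min(pts[, 2]); i2 <- which.max(pts[, 2]) }
  ab <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2, pts[i1, ])
  cr <- cbind(rel[, 2] * ab[3] - rel[, 3] * ab[2],
              rel[, 3] * ab[1] - rel[, 1] * ab[3],
              rel[, 1] * ab[2] - rel[, 2] * ab[1])
  d_line <- sqrt(rowSums(cr^2))
  i3 <- which.max(d_line)
  if (d_line[i3] < eps) stop("degenerate input: points are collinear")
  nrm0 <- crossv(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  d_plane <- abs(rel %*% nrm0)
  i4 <- which.max(d_plane)
  if (d_plane[i4] < eps * sqrt(sum(nrm0^2))) stop("degenerate input: points are coplanar")

  centroid <- colMeans(pts[c(i1, i2, i3, i4), ])
  V <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  faces <- lapply(seq_len(4), function(f) orient_face(V[f, ], pts, centroid))
  N <- do.call(rbind, lapply(faces, `[[`, "n"))
  D <- vapply(faces, `[[`, numeric(1), "d")
  V <- do.call(rbind, lapply(faces, `[[`, "v"))

  for (p in setdiff(seq_len(n), c(i1, i2, i3, i4))) {
    vis <- which(drop(N %*% pts[p, ]) - D > eps)
    if (length(vis) == 0L) next
    # horizon: undirected edges of visible faces occurring exactly once
    ed <- rbind(V[vis, c(1, 2), drop = FALSE],
                V[vis, c(2, 3), drop = FALSE],
                V[vis, c(3, 1), drop = FALSE])
    key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    horizon <- ed[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    keepf <- setdiff(seq_len(nrow(V)), vis)
    V <- V[keepf, , drop = FALSE]; N <- N[keepf, , drop = FALSE]; D <- D[keepf]
    for (e in seq_len(nrow(horizon))) {
      f <- orient_face(c(horizon[e, ], p), pts, centroid)
      V <- rbind(V, f$v); N <- rbind(N, f$n); D <- c(D, f$d)
    }
  }
  verts <- sort(unique(as.vector(V)))
  vol <- 0
  for (f in seq_len(nrow(V))) {
    a <- pts[V[f, 1], ] - centroid
    b <- pts[V[f, 2], ] - centroid
    cc <- pts[V[f, 3], ] - centroid
    vol <- vol + abs(sum(a * crossv(b, cc))) / 6
  }
  list(faces = V, vertices = verts, volume = vol)
}

crossv <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

orient_face <- function(v, pts, interior) {
  nrm <- crossv(pts[v[2], ] - pts[v[1], ], pts[v[3], ] - pts[v[1], ])
  d <- sum(nrm * pts[v[1], ])
  if (sum(nrm * interior) > d) { v <- v[c(1, 3, 2)]; nrm <- -nrm; d <- -d }
  list(v = v, n = nrm, d = d)
}

#' Hull and volume of the leaf-node cloud
#'
#' The tumour perimeter is the surface containing all (leaf) points,
#' obtained by triangulation of the convex hull; the volume is reported in
#' cm^3 for inputs in um.
#'
#' @param points numeric matrix (um), one row per point.
#' @return list: `faces` (triangle index matrix), `volume_cm3`.
#' @export
hull_and_volume <- function(points) {
  h <- convex_hull_3d(points)
  list(faces = h$faces, vertices = h$vertices,
       volume_cm3 = h$volume / 1e12)  # um^3 -> cm^3
}

#' Remove overlapping leaf nodes
#'
#' Leaves falling in the same occupancy cell of a coarse grid (default
#' 100 um, the resolution of the individual-tree method) are collapsed to
#' the first comer in (macrotree id, leaf id) order.
#'
#' @param leaves data.frame with columns `x`, `y`, `z` (um), `macrotree_id`,
#'   `leaf_id`.
#' @param cell_size_um occupancy cell edge (um), > 0.
#' @return the filtered data.frame; attribute `n_removed` gives the count
#'   removed.
#' @export
remove_overlapping_leaves <- function(leaves, cell_size_um = 100) {
  if (cell_size_um <= 0) stop("cell_size_um must be > 0")
  o <- order(leaves$macrotree_id, leaves$leaf_id)
  leaves <- leaves[o, , drop = FALSE]
  cell <- paste(floor(leaves$x / cell_size_um),
                floor(leaves$y / cell_size_um),
                floor(leaves$z / cell_size_um))
  keep <- !duplicated(cell)
  out <- leaves[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Assemble a macroscopic tumour model
#'
#' Generates `n_macrotrees` macrovessel trees from random start points in a
#' seeding ball, pools their leaf nodes, removes overlapping leaves, assigns
#' one microvessel archetype id per surviving leaf uniformly at random,
#' triangulates the hull of the leaves and reports the tumour volume and the
#' functional microvessel density
#' `n_leaves * mean(archetype volume) / tumour volume`.
#'
#' @param n_macrotrees number of macrovessel trees.
#' @param macro_params a [tree_params] for the macrotrees (default
#'   [macro_tree_params()]).
#' @param micro_library a list of archetypes (see [build_micro_library()]);
#'   must be non-empty. Only `volume_mm3` is needed at assembly time.
#' @param seed integer seed; tree `i` uses a deterministic child seed so each
#'   tree is independently reproducible.
#' @param seeding_radius_um radius of the ball in which macrotree roots are
#'   placed uniformly.
#' @return a `tumour_model`: list with `leaves` (data.frame `x`, `y`, `z`,
#'   `macrotree_id`, `leaf_id`, `archetype_id`), `hull`, `volume_cm3`,
#'   `density`, `n_removed`, `micro_library`.
#' @export
assemble_tumour <- function(n_macrotrees, macro_params = macro_tree_params(),
                            micro_library, seed = 1L,
                            seeding_radius_um = 5000) {
  if (length(micro_library) == 0L) stop("micro_library must be non-empty")
  leaf_list <- vector("list", n_macrotrees)
  for (i in seq_len(n_macrotrees)) {
    si <- derive_seed(seed, i)
    set.seed(si)
    # isotropic random root position in the seeding ball and direction
    repeat {
      pos <- stats::runif(3, -1, 1)
      if (sum(pos^2) <= 1) break
    }
    pos <- pos * seeding_radius_um
    dirv <- stats::rnorm(3)
    dirv <- dirv / sqrt(sum(dirv^2))
    tr <- generate_tree(macro_params, root_position = pos,
                        root_direction = dirv, seed = derive_seed(si, 1))
    lp <- leaf_positions(tr)
    leaf_list[[i]] <- data.frame(x = lp[, 1], y = lp[, 2], z = lp[, 3],
                                 macrotree_id = i, leaf_id = seq_len(nrow(lp)))
  }
  leaves <- do.call(rbind, leaf_list)
  leaves <- remove_overlapping_leaves(leaves, cell_size_um = 100)
  n_removed <- attr(leaves, "n_removed")
  set.seed(derive_seed(seed, n_macrotrees + 1L))
  leaves$archetype_id <- sample.int(length(micro_library), nrow(leaves),
                                    replace = TRUE)
  hull <- hull_and_volume(as.matrix(leaves[, c("x", "y", "z")]))
  mean_vol_mm3 <- mean(vapply(micro_library, function(a) a$volume_mm3,
                              numeric(1)))
  vol_mm3 <- hull$volume_cm3 * 1000
  structure(list(leaves = leaves, hull = hull,
                 volume_cm3 = hull$volume_cm3,
                 density = nrow(leaves) * mean_vol_mm3 / vol_mm3,
                 n_removed = n_removed,
                 micro_library = micro_library,
                 seed = as.integer(seed)),
            class = "tumour_model")
}

#' @export
print.tumour_model <- function(x, ...) {
  cat(sprintf("<tumour_model> %d leaves (%d overlapping removed), volume %.3g cm^3, density %.4g\n",
              nrow(x$leaves), x$n_removed, x$volume_cm3, x$density))
  invisible(x)
}

#' Select the trees intersecting a sample box
#'
#' Lists every (leaf, archetype) whose archetype bounding box, translated to
#' the leaf position, intersects the padded axis-aligned sample box.
#'
#' @param model a `tumour_model`.
#' @param centre box centre (um).
#' @param side_um box edge length (um).
#' @param pad_um extra padding around the box (um).
#' @return a `sample_spec`: list with `leaves` (subset data.frame), `centre`,
#'   `side_um`, `pad_um`, `micro_library`.
#' @export
extract_sample <- function(model, centre, side_um, pad_um = 150) {
  half <- side_um / 2 + pad_um
  lo <- centre - half; hi <- centre + half
  lib <- model$micro_library
  sel <- logical(nrow(model$leaves))
  for (i in seq_len(nrow(model$leaves))) {
    a <- lib[[model$leaves$archetype_id[i]]]
    p <- as.numeric(model$leaves[i, c("x", "y", "z")])
    blo <- p + a$bbox_lo_um; bhi <- p + a$bbox_hi_um
    sel[i] <- all(bhi >= lo) && all(blo <= hi)
  }
  structure(list(leaves = model$leaves[sel, , drop = FALSE],
                 centre = as.numeric(centre), side_um = side_um,
                 pad_um = pad_um, micro_library = lib),
            class = "sample_spec")
}
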