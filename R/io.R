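#' Read a raw binary 3D volume
#'
#' Reads the raw-volume dialect used for the deposited sub-volume data:
#' single-precision (4-byte) floats, little-endian, column-major element
#' order (first index fastest), no header. The file size must equal
#' `4 * prod(shape)` bytes.
#'
#' @param path path to the raw file.
#' @param shape integer length-3 vector, e.g. `c(300, 300, 300)`.
#' @param spacing voxel spacing in um attached to the returned grid.
#' @param origin origin (um) attached to the returned grid.
#' @return a [voxel_grid].
#' @export
read_raw_volume <- function(path, shape, spacing = 10, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape <= 0L)) stop("`shape` must be 3 positive integers")
  if (!file.exists(path)) stop("file not found: ", path)
  n <- prod(shape)
  expected <- 4 * n
  actual <- file.size(path)
  if (actual != expected)
    stop(sprintf("size mismatch for %s: expected %d bytes (4 x %d), found %d",
                 path, expected, n, actual))
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = "numeric", n = n, size = 4L, endian = "little")
  bad <- sum(!is.finite(v))
  if (bad > 0L) warning(sprintf("%d non-finite values in %s", bad, path))
  voxel_grid(array(v, dim = shape), spacing = spacing, origin = origin)
}

#' Write a raw binary 3D volume
#'
#' Inverse of [read_raw_volume()]: single-precision little-endian,
#' column-major, with a JSON sidecar (`<path>.json`) recording shape,
#' spacing and origin.
#'
#' @param grid a [voxel_grid] (or bare 3D array).
#' @param path output path.
#' @param sidecar write the JSON sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_raw_volume <- function(grid, path, sidecar = TRUE) {
  if (inherits(grid, "voxel_grid")) {
    arr <- grid$values; spacing <- grid$spacing; origin <- grid$origin
  } else {
    arr <- grid; spacing <- NA_real_; origin <- rep(NA_real_, 3)
  }
  if (max(abs(arr[is.finite(arr)]), 0) > 3.4e38) stop("values overflow single precision")
  con <- file(path, "wb")
  writeBin(as.numeric(arr), con, size = 4L, endian = "little")
  close(con)
  if (sidecar) {
    jsonlite::write_json(
      list(shape = dim(arr), spacing_um = spacing, origin_um = origin,
           dtype = "float32", endianness = "little", order = "column-major"),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Deterministic synthetic fixtures
#'
#' Small, fully reproducible objects used throughout the test-suite and the
#' examples: each `kind` is generated in code from the seed, so no binary
#' fixture files are needed.
#'
#' Kinds:
#' \describe{
#'   \item{`two-generation-tree`}{a 2-generation microvessel-style tree.}
#'   \item{`single-segment`}{a `vessel_grid` containing one straight segment.}
#'   \item{`two-adjacent-trees`}{a list of two small trees whose oxygen
#'     fields overlap; used for the method-bias checks.}
#'   \item{`four-adjacent-trees`}{four small 3-generation trees rooted around
#'     the centre of a 1 mm^3 sample; the scaled-down CTM-vs-ITM study.}
#'   \item{`gaussian-blob`}{a 21^3 `voxel_grid` holding an isotropic Gaussian
#'     of known sigma (40 um), for analytic comparisons.}
#' }
#'
#' @param kind fixture name, see Details.
#' @param seed integer seed.
#' @return the fixture object.
#' @export
make_fixture <- function(kind, seed = 1L) {
  kinds <- c("two-generation-tree", "single-segment", "two-adjacent-trees",
             "four-adjacent-trees", "gaussian-blob")
  if (!kind %in% kinds)
    stop("unknown fixture kind '", kind, "'; available: ",
         paste(kinds, collapse = ", "))
  small_params <- tree_params(
    n_generations = 3,
    segment_length_by_generation = c(250, 150, 90),
    radius_schedule = c(25, 15, 8),
    length_jitter = 0.2)
  switch(kind,
    "two-generation-tree" = {
      p <- tree_params(n_generations = 2,
                       segment_length_by_generation = c(200, 120),
                       radius_schedule = c(20, 10), length_jitter = 0.2)
      generate_tree(p, root_position = c(0, 0, 0),
                    root_direction = c(0, 0, 1), seed = seed)
    },
    "single-segment" = {
      p <- tree_params(n_generations = 1,
                       segment_length_by_generation = 300,
                       radius_schedule = 15, length_jitter = 0)
      tr <- generate_tree(p, c(0, 0, 0), c(1, 0, 0), seed = seed)
      rasterize_tree(tr, spacing = 10, pad_um = 40)
    },
    "two-adjacent-trees" = {
      lapply(1:2, function(i)
        generate_tree(small_params,
                      root_position = c(300 * (i - 1), 0, 0),
                      root_direction = c(0, 0, 1),
                      seed = derive_seed(seed, i)))
    },
    "four-adjacent-trees" = {
      # roots on a 0.4 mm square around the centre of a [0,1000]^3 um box,
      # directions tilted inward so the oxygen fields interact
      centres <- rbind(c(300, 300, 400), c(700, 300, 500),
                       c(300, 700, 600), c(700, 700, 500))
      dirs <- rbind(c(1, 1, 1), c(-1, 1, 0.5), c(1, -1, -0.5), c(-1, -1, -1))
      lapply(1:4, function(i)
        generate_tree(small_params,
                      root_position = centres[i, ],
                      root_direction = dirs[i, ] / sqrt(sum(dirs[i, ]^2)),
                      seed = derive_seed(seed, i)))
    },
    "gaussian-blob" = {
      n <- 21L; spacing <- 10; sigma <- 40
      ax <- (seq_len(n) - (n + 1) / 2) * spacing
      g1 <- exp(-ax^2 / (2 * sigma^2))
      arr <- array(outer(outer(g1, g1), g1), dim = c(n, n, n))
      voxel_grid(arr, spacing = spacing)
    })
}

# deterministic per-object child seed, kept well inside 32-bit integer range
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 1e6) * 1009 + 7919 * as.numeric(index)) %% 2147483629L
}
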