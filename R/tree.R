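#' Parameters of a stochastic vessel tree
#'
#' Describes one tree generation run: number of bifurcation generations,
#' the mean segment length per generation with a uniform relative jitter,
#' and the radius rule. The radius is either decremented per generation by a
#' uniform draw from `radius_decrement_range` (macrovessel style, range
#' 5-15 um), or follows an explicit per-generation `radius_schedule`
#' (microvessel style, where the printed data give only endpoints).
#'
#' @param n_generations number of generations (>= 1).
#' @param segment_length_by_generation mean segment length (um) per
#'   generation; length `n_generations`.
#' @param radius_start root segment radius (um); required with
#'   `radius_decrement_range`.
#' @param radius_decrement_range length-2 numeric, uniform range (um) of the
#'   per-generation radius decrement.
#' @param radius_schedule explicit radius (um) per generation; overrides the
#'   decrement rule.
#' @param length_jitter relative half-width of the uniform length jitter
#'   (0.2 means lengths are drawn from `mean * U(0.8, 1.2)`).
#' @param min_length_um segments drawn shorter than this are discarded
#'   together with their subtree (finite-resolution floor, 40 um for
#'   microvessels); `0` disables discarding.
#' @param angle_cdfs list of two [angle_cdf] tables (branch 1 and 2);
#'   default [default_angle_cdfs()].
#' @return an object of class `tree_params`.
#' @export
tree_params <- function(n_generations,
                        segment_length_by_generation,
                        radius_start = NULL,
                        radius_decrement_range = c(5, 15),
                        radius_schedule = NULL,
                        length_jitter = 0.2,
                        min_length_um = 0,
                        angle_cdfs = default_angle_cdfs()) {
  n_generations <- as.integer(n_generations)
  if (n_generations < 1L) stop("n_generations must be >= 1")
  L <- as.numeric(segment_length_by_generation)
  if (length(L) == 1L) L <- rep(L, n_generations)
  if (length(L) != n_generations || any(L <= 0))
    stop("segment_length_by_generation must give one positive length per generation")
  if (is.null(radius_schedule)) {
    if (is.null(radius_start) || radius_start <= 0)
      stop("radius_start must be positive when no radius_schedule is given")
    r <- as.numeric(radius_decrement_range)
    if (length(r) != 2L || r[1] > r[2] || r[1] < 0)
      stop("radius_decrement_range must be c(low, high) with 0 <= low <= high")
    if (radius_start - n_generations * r[2] <= 0 &&
        radius_start - n_generations * r[1] <= 0)
      stop("radius schedule reaches <= 0 before the last generation; ",
           "increase radius_start or reduce the decrement range / n_generations")
  } else {
    radius_schedule <- as.numeric(radius_schedule)
    if (length(radius_schedule) != n_generations || any(radius_schedule <= 0))
      stop("radius_schedule must give one positive radius per generation")
    if (any(diff(radius_schedule) > 0))
      stop("radius_schedule must be non-increasing")
  }
  if (length_jitter < 0 || length_jitter >= 1) stop("length_jitter must be in [0, 1)")
  if (!is.list(angle_cdfs) || length(angle_cdfs) != 2L)
    stop("angle_cdfs must be a list of two angle_cdf tables")
  structure(list(n_generations = n_generations,
                 segment_length_by_generation = L,
                 radius_start = radius_start,
                 radius_decrement_range = as.numeric(radius_decrement_range),
                 radius_schedule = radius_schedule,
                 length_jitter = length_jitter,
                 min_length_um = as.numeric(min_length_um),
                 angle_cdfs = angle_cdfs),
            class = "tree_params")
}

#' Generate a stochastic binary vessel tree
#'
#' Iteratively grows a bifurcating tree: at every branch point two daughter
#' directions are drawn (polar angle by inverse-transform sampling from the
#' branch CDFs, azimuth uniform), rotated into the global frame by direction
#' cosines, and daughter segments of the per-generation length (with uniform
#' jitter) are attached, until all branches reach the requested generation.
#' Radii decrease according to the parameter rule. Segments shorter than
#' `min_length_um` are discarded with their subtree.
#'
#' @param params a [tree_params].
#' @param root_position length-3 numeric (um).
#' @param root_direction initial direction (normalised internally).
#' @param seed integer seed; the same seed and parameters give a
#'   bit-identical tree.
#' @return a `vessel_tree`: a `data.frame` of nodes with columns `id`,
#'   `parent` (NA for the root), `x`, `y`, `z` (um), `radius` (um),
#'   `generation` (root = 0).
#' @export
generate_tree <- function(params, root_position = c(0, 0, 0),
                          root_direction = c(0, 0, 1), seed = 1L) {
  stopifnot(inherits(params, "tree_params"))
  set.seed(as.integer(seed))
  d0 <- as.numeric(root_direction)
  nrm <- sqrt(sum(d0^2))
  if (nrm < 1e-12) stop("root direction has zero norm")
  d0 <- d0 / nrm
  samplers <- list(build_angle_sampler(params$angle_cdfs[[1]]),
                   build_angle_sampler(params$angle_cdfs[[2]]))
  ng <- params$n_generations
  use_schedule <- !is.null(params$radius_schedule)
  r0 <- if (use_schedule) params$radius_schedule[1] * 1.0 else params$radius_start

  # grow iteratively; pre-size generously and trim
  nmax <- 2^(ng + 1)
  pos <- matrix(NA_real_, nmax, 3)
  radius <- rep(NA_real_, nmax)
  parent <- rep(NA_integer_, nmax)
  gen <- rep(NA_integer_, nmax)
  dirm <- matrix(NA_real_, nmax, 3)

  pos[1, ] <- root_position; radius[1] <- r0; gen[1] <- 0L; dirm[1, ] <- d0
  n_nodes <- 1L
  frontier <- 1L
  for (g in seq_len(ng)) {
    Lmean <- params$segment_length_by_generation[g]
    jit <- params$length_jitter
    new_frontier <- integer(0)
    for (node in frontier) {
      draws <- sample_branch_pair(samplers, 1L)
      for (b in 1:2) {
        len <- Lmean * stats::runif(1, 1 - jit, 1 + jit)
        if (use_schedule) {
          r <- params$radius_schedule[g]
        } else {
          dec <- stats::runif(1, params$radius_decrement_range[1],
                              params$radius_decrement_range[2])
          r <- radius[node] - dec
          if (r <= 0)
            stop("radius schedule reached <= 0 at generation ", g,
                 "; increase radius_start or reduce the decrement range")
        }
        if (params$min_length_um > 0 && len < params$min_length_um) next
        dirv <- to_global_frame(draws$theta[1, b], draws$phi[1, b], dirm[node, ])
        n_nodes <- n_nodes + 1L
        pos[n_nodes, ] <- pos[node, ] + len * dirv
        radius[n_nodes] <- r
        parent[n_nodes] <- node
        gen[n_nodes] <- g
        dirm[n_nodes, ] <- dirv
        new_frontier <- c(new_frontier, n_nodes)
      }
    }
    frontier <- new_frontier
    if (length(frontier) == 0L) break
  }
  nodes <- data.frame(id = seq_len(n_nodes), parent = parent[seq_len(n_nodes)],
                      x = pos[seq_len(n_nodes), 1], y = pos[seq_len(n_nodes), 2],
                      z = pos[seq_len(n_nodes), 3],
                      radius = radius[seq_len(n_nodes)],
                      generation = gen[seq_len(n_nodes)])
  structure(nodes, class = c("vessel_tree", "data.frame"),
            params = params, seed = as.integer(seed))
}

#' Positions of the terminal (leaf) nodes of a tree
#'
#' Leaf coordinates are what the macrovessel stage stores: they become the
#' attachment points of the microvessel trees.
#'
#' @param tree a `vessel_tree`.
#' @return numeric matrix, one row per leaf, columns `x`, `y`, `z` (um).
#' @export
leaf_positions <- function(tree) {
  is_leaf <- !(tree$id %in% tree$parent)
  as.matrix(tree[is_leaf, c("x", "y", "z")])
}

#' Write a tree node table to CSV
#'
#' @param tree a `vessel_tree`.
#' @param path output CSV path.
#' @export
write_tree_csv <- function(tree, path) {
  out <- data.frame(id = tree$id, parent_id = tree$parent,
                    x = tree$x, y = tree$y, z = tree$z,
                    radius_um = tree$radius, generation = tree$generation)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Default macrovessel tree parameters
#'
#' Nine generations; segment lengths decrease geometrically from 10 mm to
#' 0.4 mm (the cited vessel-dimension regressions are not printed, so the
#' schedule is a documented default matching the stated endpoints); radius
#' starts at 140 um and is decremented by a uniform 5-15 um per generation,
#' which puts end branches near a 100 um diameter.
#'
#' @param n_generations number of generations (default 9).
#' @return a [tree_params].
#' @export
macro_tree_params <- function(n_generations = 9) {
  lengths <- 10000 * (400 / 10000)^((seq_len(n_generations) - 1) /
                                      max(n_generations - 1, 1))
  tree_params(n_generations = n_generations,
              segment_length_by_generation = lengths,
              radius_start = 140,
              radius_decrement_range = c(5, 15),
              length_jitter = 0.2)
}

#' Default microvessel tree parameters
#'
#' Five generations; mean segment lengths decrease geometrically from 400 um
#' to 50 um with a +-20% uniform jitter (so minima reach the 40 um
#' resolution floor); radii follow a geometric schedule from 50 um (the
#' macrovessel end-branch radius) down to 5 um (capillary scale). Segments
#' shorter than 40 um are discarded.
#'
#' @param n_generations number of generations (default 5).
#' @return a [tree_params].
#' @export
micro_tree_params <- function(n_generations = 5) {
  gens <- seq_len(n_generations)
  lengths <- 400 * (50 / 400)^((gens - 1) / max(n_generations - 1, 1))
  radii <- 50 * (5 / 50)^((gens - 1) / max(n_generations - 1, 1))
  tree_params(n_generations = n_generations,
              segment_length_by_generation = lengths,
              radius_schedule = radii,
              length_jitter = 0.2,
              min_length_um = 40)
}
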