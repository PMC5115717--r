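test_that("diffusion kernel is a normalised Gaussian with sigma = sqrt(2*D*t)", {
  phys <- phys_params()
  expect_equal(diffusion_sigma(phys), 20)       # sqrt(2 * 2000 * 0.1)
  k1 <- diffusion_kernel(phys, 10, dims = 1)
  expect_equal(sum(k1), 1, tolerance = 1e-14)
  k3 <- diffusion_kernel(phys, 10, dims = 3)
  expect_equal(sum(k3), 1, tolerance = 1e-12)
  # second moment of the discrete 1D kernel ~ sigma^2
  R <- (length(k1) - 1) / 2
  x <- ((-R):R) * 10
  expect_equal(sqrt(sum(k1 * x^2)), 20, tolerance = 0.01)
  # isotropy
  expect_equal(k3, aperm(k3, c(3, 1, 2)))
  expect_equal(k3, k3[rev(seq_len(dim(k3)[1])), , ])
  # too-small diffusion length per step is refused
  expect_error(diffusion_kernel(phys_params(t = 1e-4), 10), "time step")
})

test_that("diffusion step matches a dense convolution oracle and conserves mass", {
  phys <- phys_params()
  k1 <- diffusion_kernel(phys, 10, dims = 1)
  k3 <- diffusion_kernel(phys, 10, dims = 3)
  n <- 11L
  set.seed(31)
  arr <- array(stats::runif(n^3), dim = rep(n, 3))
  empty <- array(0, dim = rep(n, 3))
  f <- oxygen_field(arr, empty, empty, spacing = 10)
  got <- diffusion_step(f, k1)$values
  want <- dense_conv3d(arr, k3)
  expect_equal(got, want, tolerance = 1e-12)

  # single hot voxel: blob with the same total sum (kernel fits interior)
  hot <- array(0, dim = c(35, 35, 35)); hot[18, 18, 18] <- 5
  fh <- oxygen_field(hot, array(0, dim = dim(hot)), array(0, dim = dim(hot)),
                     spacing = 10)
  out <- diffusion_step(fh, k1)$values
  expect_equal(sum(out), 5, tolerance = 1e-12)
  expect_equal(out[18, 18, 18], 5 * max(k3), tolerance = 1e-12)

  # uniform field far from the boundary is unchanged
  u <- array(1, dim = c(41, 41, 41))
  fu <- oxygen_field(u, array(0, dim = dim(u)), array(0, dim = dim(u)),
                     spacing = 10)
  outu <- diffusion_step(fu, k1)$values
  expect_equal(outu[21, 21, 21], 1, tolerance = 1e-12)

  # vessel voxels are re-clamped to their sources
  mask <- empty; mask[6, 6, 6] <- 1
  src <- empty; src[6, 6, 6] <- 100
  fv <- oxygen_field(src, mask, src, spacing = 10)
  expect_equal(diffusion_step(fv, k1)$values[6, 6, 6], 100)
})

test_that("heat-kernel semigroup: two t-steps equal one 2t-step", {
  k_t <- diffusion_kernel(phys_params(), 10, dims = 1)
  k_2t <- diffusion_kernel(phys_params(t = 0.2), 10, dims = 1)
  n <- 31L
  set.seed(7)
  arr <- array(stats::runif(n^3), dim = rep(n, 3))
  empty <- array(0, dim = rep(n, 3))
  f <- oxygen_field(arr, empty, empty, spacing = 10)
  two <- diffusion_step(diffusion_step(f, k_t), k_t)$values
  one <- diffusion_step(f, k_2t)$values
  idx <- 13:19                 # interior, away from zero-padding influence
  rel <- max(abs(two[idx, idx, idx] - one[idx, idx, idx])) /
    max(abs(one[idx, idx, idx]))
  expect_lt(rel, 1e-3)
})

test_that("Michaelis-Menten consumption has the right fixed points", {
  phys <- phys_params()
  expect_equal(consumption_rate(0, phys), 0)
  expect_equal(consumption_rate(1, phys), 7.5)          # C0/2 at pO2 = K_M
  expect_equal(consumption_rate(15, phys), 15 * 15 / 16)
  expect_lt(consumption_rate(1e6, phys), phys$C_0)
  p <- seq(0, 60, by = 0.5)
  expect_true(all(diff(consumption_rate(p, phys)) > 0))
  expect_error(consumption_rate(-1, phys), ">= 0")
})

test_that("consumption update clamps at zero and spares vessels", {
  phys <- phys_params()
  vals <- array(0, dim = c(3, 3, 3))
  mask <- vals; src <- vals
  vals[1, 1, 1] <- 50                      # tissue
  vals[2, 2, 2] <- 0.05                    # tissue, would overshoot
  mask[3, 3, 3] <- 1; src[3, 3, 3] <- 100; vals[3, 3, 3] <- 100
  out <- apply_consumption(oxygen_field(vals, mask, src, 10), phys)$values
  expect_equal(out[1, 1, 1], 50 - 0.1 * 15 * 50 / 51)   # 48.5294...
  expect_equal(out[2, 2, 2], 0)                          # clamped
  expect_equal(out[3, 3, 3], 100)                        # vessel untouched
  expect_equal(out[1, 2, 3], 0)
})

test_that("vessel pO2 falls linearly from 100 to 40 with path distance", {
  vg <- straight_vessel_grid(n_vox = 7)
  f <- assign_vessel_po2(vg, phys_params())
  v <- f$values[f$mask > 0]
  d <- vg$pathdist[vg$mask > 0]
  expect_equal(v[d == 0], 100)
  expect_equal(v[d == max(d)], 40)
  expect_equal(v[d == max(d) / 2], 70)
  expect_equal(f$values[f$mask == 0], rep(0, sum(f$mask == 0)))
  # single-voxel tree: all-vessel value is arterial
  vg1 <- straight_vessel_grid(n_vox = 1)
  expect_equal(assign_vessel_po2(vg1)$values[vg1$mask > 0], 100)
})

test_that("steady state obeys the maximum principle and radial decay", {
  # no vessels: zero field, immediate convergence
  vg0 <- straight_vessel_grid(n_vox = 7)
  vg0$mask[] <- 0; vg0$pathdist[] <- NA_real_
  sol0 <- solve_steady_state(assign_vessel_po2(vg0), max_iter = 50)
  expect_true(all(sol0$field$values == 0))
  expect_true(sol0$converged)

  # single vessel voxel: monotone radial decay along an axis
  vg1 <- straight_vessel_grid(n_vox = 1, shape = c(41, 41, 41))
  sol1 <- solve_steady_state(assign_vessel_po2(vg1), tolerance = 1e-6,
                             max_iter = 1500)
  prof <- sol1$field$values[21:41, 21, 21]
  expect_true(all(diff(prof) <= 1e-12))
  expect_equal(prof[1], 100)

  # maximum principle on a solved tree field
  tr <- make_fixture("two-generation-tree", seed = 2)
  vg <- rasterize_tree(tr, spacing = 10, pad_um = 100)
  sol <- solve_steady_state(assign_vessel_po2(vg), max_iter = 1000)
  expect_true(sol$converged)
  expect_gte(min(sol$field$values), 0)
  expect_lte(max(sol$field$values), 100 + 1e-9)
  expect_lte(max(sol$field$values[sol$field$mask == 0]),
             max(sol$field$source))
})

test_that("adding a vessel voxel never lowers the steady-state field", {
  base <- straight_vessel_grid(n_vox = 7)
  more <- straight_vessel_grid(n_vox = 7, extra_voxel = c(11, 15, 11))
  f1 <- solve_steady_state(assign_vessel_po2(base), tolerance = 1e-6,
                           max_iter = 1500)$field$values
  f2 <- solve_steady_state(assign_vessel_po2(more), tolerance = 1e-6,
                           max_iter = 1500)$field$values
  expect_gte(min(f2 - f1), -1e-9)
  expect_gt(sum(f2 - f1), 0)
})

test_that("without consumption the field rises monotonically toward a plateau", {
  phys0 <- phys_params(C_0 = 0)
  vg <- straight_vessel_grid(n_vox = 5, shape = c(25, 25, 25))
  f <- assign_vessel_po2(vg, phys0)
  k1 <- diffusion_kernel(phys0, 10, dims = 1)
  probe <- c(20, 20, 20)                       # far-field voxel
  prev <- f$values[probe[1], probe[2], probe[3]]
  for (i in 1:30) {
    f <- apply_consumption(diffusion_step(f, k1), phys0)
    cur <- f$values[probe[1], probe[2], probe[3]]
    expect_gte(cur, prev - 1e-12)
    prev <- cur
  }
  expect_gt(prev, 0)
})

test_that("non-convergence is reported with a warning and flag", {
  vg <- straight_vessel_grid(n_vox = 7)
  expect_warning(sol <- solve_steady_state(assign_vessel_po2(vg), max_iter = 2),
                 "not reached")
  expect_false(sol$converged)
  expect_equal(sol$iterations, 2L)
})
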