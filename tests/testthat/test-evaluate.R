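test_that("hypoxic and vascular fractions count voxels as defined", {
  z <- array(0, dim = c(2, 2, 2))
  expect_equal(hypoxic_fraction(z, 1), 1)
  v8 <- array(c(0, 0, 0, 2, 2, 6, 6, 6), dim = c(2, 2, 2))
  expect_equal(hypoxic_fraction(v8, 1), 0.375)
  expect_equal(hypoxic_fraction(v8, 2), 0.375)   # strict <
  expect_equal(hypoxic_fraction(v8, 2.01), 0.625)
  expect_error(hypoxic_fraction(numeric(0), 1), "empty")

  expect_equal(vascular_fraction(array(0, dim = c(3, 3, 3))), 0)
  expect_equal(vascular_fraction(array(1, dim = c(3, 3, 3))), 1)
  m <- array(0, dim = c(4, 4, 4)); m[2:3, 2:3, 2:3] <- 1
  expect_equal(vascular_fraction(m), 8 / 64)
  expect_equal(vascular_fraction(m, crop_margin_voxels = 1), 1)
})

test_that("field statistics use the population SD", {
  cst <- array(7, dim = c(3, 3, 3))
  expect_equal(field_stats(cst), c(mean = 7, sd = 0))
  two <- c(0, 10)
  expect_equal(field_stats(two), c(mean = 5, sd = 5))
})

test_that("distribution summaries are normalised and self-consistent", {
  delta <- array(50.2, dim = c(4, 4, 4))
  d <- po2_distribution(delta)
  expect_equal(sum(d$histogram), 1, tolerance = 1e-12)
  expect_equal(d$histogram[51], 1)                    # bin [50, 51)
  expect_equal(d$cumulative[length(d$cumulative)], 1, tolerance = 1e-12)
  expect_true(all(diff(d$cumulative) >= 0))

  set.seed(14)
  v <- array(stats::runif(1000, 0, 30), dim = c(10, 10, 10))
  dv <- po2_distribution(v)
  expect_equal(dv$hf_1, dv$cumulative[1])             # mass strictly below 1
  expect_equal(dv$hf_5, mean(v < 5))
  expect_true(dv$hf_0.01 <= dv$hf_1 && dv$hf_1 <= dv$hf_5)
  expect_error(po2_distribution(array(-1, dim = c(2, 2, 2))), ">= 0")
})

test_that("RMSD of cumulative distributions is a metric with the stated extremes", {
  lo <- po2_distribution(array(0, dim = c(3, 3, 3)))       # all mass at 0
  hi <- po2_distribution(array(150, dim = c(3, 3, 3)))     # all mass at top bin
  expect_equal(rmsd(lo, lo), 0)
  expect_equal(rmsd(lo, hi), sqrt(100 / 101), tolerance = 1e-12)
  set.seed(3)
  a <- po2_distribution(stats::runif(500, 0, 60))
  b <- po2_distribution(stats::runif(500, 10, 80))
  c3 <- po2_distribution(stats::runif(500, 0, 100))
  expect_equal(rmsd(a, b), rmsd(b, a))                     # symmetry
  expect_gt(rmsd(a, b), 0)
  expect_lte(rmsd(a, c3), rmsd(a, b) + rmsd(b, c3) + 1e-12) # triangle
  bad <- po2_distribution(stats::runif(100), bin_width = 2)
  expect_error(rmsd(a, bad), "binning")
})

test_that("two-sample KS matches the reference implementation to 1e-12", {
  set.seed(77)
  for (i in 1:100) {
    n1 <- sample(5:60, 1); n2 <- sample(5:60, 1)
    a <- stats::rnorm(n1)
    b <- stats::rnorm(n2, mean = stats::runif(1, -1, 1))
    if (i %% 3 == 0) { a <- round(a, 1); b <- round(b, 1) }  # ties
    ours <- ks_two_sample(a, b)
    ref <- suppressWarnings(stats::ks.test(a, b))
    expect_equal(ours$D, unname(ref$statistic), tolerance = 1e-12)
  }
})

test_that("KS large-sample criterion uses c(alpha)*sqrt((n1+n2)/(n1*n2))", {
  x <- c(1, 2, 3); y <- c(1, 2, 3)
  same <- ks_two_sample(x, y)
  expect_equal(same$D, 0)
  expect_false(same$reject)
  # printed critical constants: c(0.05) = 1.36, c(0.001) = 1.95
  expect_equal(ks_two_sample(x, y, alpha = 0.05)$c_alpha, 1.36, tolerance = 0.005)
  k <- ks_two_sample(x, y, alpha = 0.001)
  expect_equal(k$c_alpha, 1.95, tolerance = 0.005)
  # threshold arithmetic at the deposited sample size
  n <- 2.7e7
  thr <- k$c_alpha * sqrt((n + n) / (n * n))
  expect_equal(thr, 1.95 * sqrt(2 / 2.7e7), tolerance = 0.005)
  expect_true(ks_two_sample(stats::runif(500), stats::runif(500) + 0.5)$reject)
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
})

test_that("correlation matrix gives Pearson r with t-based p-values", {
  tab <- data.frame(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10),
                    c = c(5, 3, 4, 1, 2))
  cm <- correlation_matrix(tab)
  expect_true(all(is.na(diag(cm$r))))
  expect_equal(cm$r["a", "b"], 1, tolerance = 1e-12)
  expect_lt(cm$p["a", "b"], 0.001)
  expect_equal(cm$r, t(cm$r))
  # against the direct formula for a vs c
  r_direct <- stats::cor(tab$a, tab$c)
  expect_equal(cm$r["a", "c"], r_direct, tolerance = 1e-12)
  tst <- r_direct * sqrt(3 / (1 - r_direct^2))
  expect_equal(cm$p["a", "c"], 2 * stats::pt(-abs(tst), df = 3),
               tolerance = 1e-12)
  # x vs -x
  tab2 <- data.frame(x = 1:5, y = -(1:5), z = rep(1, 5))
  cm2 <- correlation_matrix(tab2)
  expect_equal(cm2$r["x", "y"], -1, tolerance = 1e-12)
  expect_true(all(is.na(cm2$r["z", c("x", "y")])))     # zero variance flagged
  expect_error(correlation_matrix(tab[1:2, ]), "at least 3")
})

test_that("correlation signs on the printed summary reproduce the reported pattern", {
  # per-sample properties of the five high-resolution samples as printed
  ctm <- data.frame(
    hf_1 = c(0.523, 0.607, 0.5864, 0.5296, 0.5141),
    hf_5 = c(0.595, 0.675, 0.6577, 0.5877, 0.5964),
    vf = c(0.0396, 0.0272, 0.0291, 0.0398, 0.0325),
    mean_po2 = c(15.61, 11.97, 12.20, 16.43, 14.63))
  cm <- correlation_matrix(ctm)
  expect_gt(cm$r["mean_po2", "vf"], 0)
  expect_lt(cm$r["hf_1", "vf"], 0)
  expect_lt(cm$r["hf_5", "vf"], 0)
})

test_that("table reproduction pipeline works end to end on synthetic volumes", {
  # a miniature deposited-data set: fine 20^3 oxygen volumes, 50^3-padded
  # vessel masks (pad 15 at ds_factor 10 would not fit; use ds_factor 2,
  # pad 3), coarse 10^3 volumes
  dir <- withr::local_tempdir()
  set.seed(55)
  fine <- lapply(1:5, function(i) array(stats::runif(20^3, 0, 60),
                                        dim = rep(20, 3)))
  for (i in 1:5) {
    write_raw_volume(downsample_block_mean(fine[[i]], 2L),
                     file.path(dir, sprintf("S%d.raw", i)), sidecar = FALSE)
    write_raw_volume(fine[[i]], file.path(dir, sprintf("S%d.raw", i + 5)),
                     sidecar = FALSE)
    m <- array(0, dim = rep(26, 3))
    m[4:23, 4:23, 4:23][fine[[i]] > 55] <- 1
    write_raw_volume(m, file.path(dir, sprintf("S%d.raw", i + 10)),
                     sidecar = FALSE)
  }
  rep <- reproduce_tables(dir, alpha = 0.001, fine_shape = 20, ds_factor = 2)
  expect_equal(nrow(rep$summary), 11L)
  ctm1 <- rep$summary[rep$summary$sample == "CTM 1", ]
  expect_equal(ctm1$hf_1, mean(fine[[1]] < 1))
  expect_equal(ctm1$vf, mean(fine[[1]] > 55))
  expect_equal(ctm1$mean_po2, mean(fine[[1]]))
  # down-sampled row preserves the mean
  ds1 <- rep$summary[rep$summary$sample == "CTM_DS 1", ]
  expect_equal(ds1$mean_po2, ctm1$mean_po2, tolerance = 1e-6)
  expect_equal(diag(rep$rmsd_ctm), rep(0, 5))
  expect_true(isSymmetric(rep$rmsd_ctm))
  # the coarse volumes here are the down-sampled fine ones, so the
  # per-sample fine-vs-coarse RMSD equals the CTM1-vs-CTM_DS1 one
  expect_equal(rep$rmsd_itm[1], rep$rmsd_ctm_ds1, tolerance = 1e-6)
  # iid uniforms from the same distribution: large-sample KS rejects all
  # pairs only if the distributions truly differ; here they are identical
  # in law, so with n = 8000 per sample none of the pairs should reject
  expect_false(any(rep$ks_reject))
})
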