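#' Hypoxic fraction of a field
#'
#' Fraction of voxels with pO2 strictly below the threshold, over all voxels
#' of the (pad-cropped) field. Conventional thresholds are 0.01, 1 and
#' 5 mmHg.
#'
#' @param field an `oxygen_field`, [voxel_grid] or bare array (mmHg).
#' @param threshold_mmHg threshold (mmHg).
#' @return fraction in `[0, 1]`.
#' @export
hypoxic_fraction <- function(field, threshold_mmHg) {
  v <- field_values(field)
  if (length(v) == 0L) stop("empty field")
  mean(v < threshold_mmHg)
}

field_values <- function(field) {
  if (inherits(field, "oxygen_field") || inherits(field, "voxel_grid"))
    as.numeric(field$values)
  else as.numeric(field)
}

#' Vascular fraction of a vessel mask
#'
#' Fraction of nonzero voxels of the vessel mask, after optionally cropping
#' a padding margin.
#'
#' @param vessel_grid a `vessel_grid`, `oxygen_field` (its mask) or 0/1
#'   array.
#' @param crop_margin_voxels margin to strip from each face first.
#' @return fraction in `[0, 1]`.
#' @export
vascular_fraction <- function(vessel_grid, crop_margin_voxels = 0) {
  m <- if (inherits(vessel_grid, "vessel_grid") ||
           inherits(vessel_grid, "oxygen_field")) vessel_grid$mask else vessel_grid
  if (crop_margin_voxels > 0) m <- crop_margin(m, crop_margin_voxels)
  mean(m != 0)
}

#' Mean and population standard deviation of a field
#'
#' @param field field object or array (mmHg).
#' @return named numeric `c(mean, sd)`; the SD is the population SD
#'   (divisor `n`).
#' @export
field_stats <- function(field) {
  v <- field_values(field)
  m <- mean(v)
  c(mean = m, sd = sqrt(mean((v - m)^2)))
}

#' pO2 distribution summary
#'
#' Histogram of the field at fixed bin width on `[0, n_bins * bin_width)`
#' (bins are left-closed; values beyond the top break fall in the last
#' bin), normalised to sum to 1, with the cumulative distribution, hypoxic
#' fractions at 0.01/1/5 mmHg, vascular fraction, mean and SD.
#'
#' @param field field object or array (mmHg, >= 0).
#' @param bin_width bin width in mmHg (default 1, the conventional
#'   resolution).
#' @param n_bins number of bins; default 101 covers 0-100 mmHg plus a top
#'   bin.
#' @param vessel_mask optional 0/1 array for the vascular fraction.
#' @return a `distribution_summary`: list with `breaks`, `histogram`,
#'   `cumulative`, `hf_0.01`, `hf_1`, `hf_5`, `vf`, `mean`, `sd`,
#'   `bin_width`, `n`.
#' @export
po2_distribution <- function(field, bin_width = 1, n_bins = 101,
                             vessel_mask = NULL) {
  v <- field_values(field)
  if (length(v) == 0L) stop("empty field")
  if (any(v < 0)) stop("pO2 must be >= 0")
  breaks <- seq(0, n_bins * bin_width, by = bin_width)
  bin <- findInterval(v, breaks, rightmost.closed = FALSE, left.open = FALSE)
  bin[bin > n_bins] <- n_bins
  h <- tabulate(bin, nbins = n_bins) / length(v)
  st <- field_stats(v)
  structure(list(breaks = breaks, histogram = h, cumulative = cumsum(h),
                 hf_0.01 = mean(v < 0.01), hf_1 = mean(v < 1),
                 hf_5 = mean(v < 5),
                 vf = if (is.null(vessel_mask)) NA_real_ else mean(vessel_mask != 0),
                 mean = unname(st["mean"]), sd = unname(st["sd"]),
                 bin_width = bin_width, n = length(v)),
            class = "distribution_summary")
}

#' RMSD between two distribution summaries
#'
#' Root mean square deviation between the two cumulative normalised
#' distributions over their common binning: 0 for identical distributions
#' and close to 1 for fully separated single-bin distributions at opposite
#' ends of the range (which is the reading under which "1 means total lack
#' of agreement" holds).
#'
#' @param distA,distB `distribution_summary` objects with identical binning.
#' @param on compare `"cumulative"` (default) or `"density"` histograms.
#' @return the RMSD value.
#' @export
rmsd <- function(distA, distB, on = c("cumulative", "density")) {
  on <- match.arg(on)
  if (length(distA$histogram) != length(distB$histogram) ||
      distA$bin_width != distB$bin_width)
    stop("distributions have different binning; recompute with matching bin_width/n_bins")
  a <- if (on == "cumulative") distA$cumulative else distA$histogram
  b <- if (on == "cumulative") distB$cumulative else distB$histogram
  sqrt(mean((a - b)^2))
}

#' Two-sample Kolmogorov-Smirnov test with the large-sample criterion
#'
#' Computes the exact sup-distance between the two empirical CDFs by a
#' merged sort, and rejects the null hypothesis of a common distribution
#' when `D > c(alpha) * sqrt((n1 + n2) / (n1 * n2))`, with
#' `c(alpha) = sqrt(-ln(alpha / 2) / 2)` (1.36 at alpha = 0.05, 1.95 at
#' alpha = 0.001).
#'
#' @param valuesA,valuesB numeric samples (non-empty).
#' @param alpha significance level (default 0.05).
#' @return a `ks_result`: list with `D`, `n1`, `n2`, `alpha`, `c_alpha`,
#'   `threshold`, `reject`.
#' @export
ks_two_sample <- function(valuesA, valuesB, alpha = 0.05) {
  n1 <- length(valuesA); n2 <- length(valuesB)
  if (n1 == 0L || n2 == 0L) stop("both samples must be non-empty")
  all_v <- c(valuesA, valuesB)
  o <- order(all_v)
  w <- c(rep(1 / n1, n1), rep(-1 / n2, n2))[o]
  cdf_diff <- cumsum(w)
  # at tied values only the last of the tie group is a valid ECDF point
  v_sorted <- all_v[o]
  last_of_tie <- c(v_sorted[-1] != v_sorted[-length(v_sorted)], TRUE)
  D <- max(abs(cdf_diff[last_of_tie]))
  c_alpha <- sqrt(-log(alpha / 2) / 2)
  threshold <- c_alpha * sqrt((n1 + n2) / (n1 * n2))
  structure(list(D = D, n1 = n1, n2 = n2, alpha = alpha, c_alpha = c_alpha,
                 threshold = threshold, reject = D > threshold),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Two-sample KS: D = %.4g, threshold = %.4g (alpha = %g, c = %.3f), H0 %s\n",
              x$D, x$threshold, x$alpha, x$c_alpha,
              if (x$reject) "rejected" else "not rejected"))
  invisible(x)
}

#' Pairwise Pearson correlations with p-values
#'
#' Pearson r for every pair of columns of a per-sample property table, with
#' two-sided p-values from the t distribution on `n - 2` degrees of
#' freedom. The diagonal carries no information and is set to `NA`;
#' zero-variance columns give `NA` for their pairs.
#'
#' @param sample_table data.frame or matrix of per-sample properties
#'   (rows = samples, `n >= 3`).
#' @return list with matrices `r` and `p`.
#' @export
correlation_matrix <- function(sample_table) {
  m <- as.matrix(sample_table)
  if (nrow(m) < 3L) stop("need at least 3 samples")
  k <- ncol(m)
  r <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
  p <- r
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    if (stats::sd(m[, i]) == 0 || stats::sd(m[, j]) == 0) next
    ct <- stats::cor.test(m[, i], m[, j], method = "pearson")
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  list(r = r, p = p)
}

#' Recompute the sample comparison tables from deposited raw volumes
#'
#' Given a directory with the deposited sub-volume files (`S1.raw` ...
#' `S5.raw`: 30^3 ITM oxygen; `S6.raw` ... `S10.raw`: 300^3 CTM oxygen;
#' `S11.raw` ... `S15.raw`: 330^3 vessel masks), recomputes the per-sample
#' summary table (hypoxic fractions, vascular fraction, mean, SD, with a
#' down-sampled CTM 1 row) and the pairwise RMSD/KS comparisons.
#'
#' @param dir directory containing `S1.raw` .. `S15.raw`.
#' @param alpha significance level for the KS tests (default 0.001).
#' @param fine_shape edge length (voxels) of the high-resolution oxygen
#'   volumes (default 300); the vessel volumes are assumed padded by
#'   `ds_factor * 3 / 2` voxels per face beyond this and the coarse volumes
#'   to have edge `fine_shape / ds_factor`.
#' @param ds_factor down-sampling factor between the fine and coarse grids
#'   (default 10).
#' @return list: `summary` (data.frame, one row per sample), `rmsd_ctm`
#'   (5x5 matrix), `rmsd_ctm_ds1` (CTM 1 vs its down-sampled self),
#'   `rmsd_itm` (per-sample CTM vs ITM), `ks_reject` (logical 5x5 for CTM
#'   pairs).
#' @export
reproduce_tables <- function(dir, alpha = 0.001, fine_shape = 300,
                             ds_factor = 10) {
  pth <- function(i) file.path(dir, sprintf("S%d.raw", i))
  coarse <- fine_shape %/% ds_factor
  pad <- as.integer(3 * ds_factor / 2)
  itm <- lapply(1:5, function(i)
    read_raw_volume(pth(i), rep(coarse, 3), spacing = 10 * ds_factor))
  ctm <- lapply(6:10, function(i)
    read_raw_volume(pth(i), rep(fine_shape, 3), spacing = 10))
  ves <- lapply(11:15, function(i) {
    g <- read_raw_volume(pth(i), rep(fine_shape + 2L * pad, 3), spacing = 10)
    crop_margin(g$values, pad)
  })
  ctm_ds1 <- downsample_block_mean(ctm[[1]], ds_factor)
  row_of <- function(vals, mask, label) {
    st <- field_stats(vals)
    data.frame(sample = label,
               hf_0.01 = hypoxic_fraction(vals, 0.01),
               hf_1 = hypoxic_fraction(vals, 1),
               hf_5 = hypoxic_fraction(vals, 5),
               vf = if (is.null(mask)) NA_real_ else mean(mask != 0),
               mean_po2 = st["mean"], sd_po2 = st["sd"],
               row.names = NULL)
  }
  summary <- rbind(
    do.call(rbind, lapply(1:5, function(i)
      row_of(ctm[[i]], ves[[i]], sprintf("CTM %d", i)))),
    row_of(ctm_ds1, ves[[1]], "CTM_DS 1"),
    do.call(rbind, lapply(1:5, function(i)
      row_of(itm[[i]], ves[[i]], sprintf("ITM %d", i)))))
  dists_ctm <- lapply(ctm, po2_distribution)
  dists_itm <- lapply(itm, po2_distribution)
  rmsd_ctm <- matrix(0, 5, 5)
  ks_reject <- matrix(FALSE, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    if (i == j) next
    rmsd_ctm[i, j] <- rmsd(dists_ctm[[i]], dists_ctm[[j]])
    ks_reject[i, j] <- ks_two_sample(as.numeric(ctm[[i]]$values),
                                     as.numeric(ctm[[j]]$values),
                                     alpha = alpha)$reject
  }
  list(summary = summary,
       rmsd_ctm = rmsd_ctm,
       rmsd_ctm_ds1 = rmsd(dists_ctm[[1]], po2_distribution(ctm_ds1)),
       rmsd_itm = vapply(1:5, function(i)
         rmsd(dists_ctm[[i]], dists_itm[[i]]), numeric(1)),
       ks_reject = ks_reject)
}
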