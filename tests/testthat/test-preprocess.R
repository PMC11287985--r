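noiseless_series <- function(b, s0 = 1000, adc = 1.5e-3, shape = c(6, 5, 4)) {
  arr <- array(0, c(length(b), shape))
  for (i in seq_along(b)) arr[i, , , ] <- s0 * exp(-b[i] * adc)
  arr
}

B_SCHEMES <- list(c(0, 100, 400, 800), c(0, 250, 500, 800), c(50, 400, 800))

test_that("noiseless mono-exponential data is recovered exactly for every b-scheme", {
  for (b in B_SCHEMES) {
    fit <- fit_adc(noiseless_series(b), b)
    expect_rel_equal(fit$adc, array(1.5e-3, c(6, 5, 4)), 1e-9)
    # S0 is the extrapolated intercept even without a b = 0 acquisition
    expect_rel_equal(fit$s0, array(1000, c(6, 5, 4)), 1e-9)
    expect_lt(max(fit$fit_residual), 1e-9)
  }
})

test_that("fit_adc validates its inputs", {
  b <- c(0, 100, 400, 800)
  expect_error(fit_adc(noiseless_series(b), c(0, 100)), "b-values")
  expect_error(fit_adc(noiseless_series(c(500, 500)), c(500, 500)), "distinct")
})

test_that("noisy ADC fits stay close to truth and match a grid-search oracle", {
  set.seed(42)
  shape <- c(32, 32, 32)
  b <- c(0, 100, 400, 800)
  s0 <- 1000
  adc_true <- 1.3e-3
  series <- array(0, c(length(b), shape))
  for (i in seq_along(b))
    series[i, , , ] <- s0 * exp(-b[i] * adc_true) +
      rnorm(prod(shape), 0, 0.02 * s0)
  fit <- fit_adc(series, b)
  med_err <- median(abs(fit$adc - adc_true) / adc_true)
  expect_lt(med_err, 0.05)
  # grid-search oracle on a voxel subsample: the closed-form LSQ fit must
  # achieve a log-domain objective at least as good as the best grid point
  Y <- log(pmax(matrix(series, nrow = length(b)), 1e-6))
  adc_grid <- seq(0, 4e-3, length.out = 161)
  s0_grid <- seq(600, 1400, length.out = 81)
  pred <- outer(b, -adc_grid)  # (b x adc)
  vox <- sample(prod(shape), 40)
  for (v in vox) {
    obj <- sapply(s0_grid, function(s) colSums((Y[, v] - pred - log(s))^2))
    best <- min(obj)
    fit_obj <- sum((Y[, v] - (log(fit$s0[v]) - b * fit$adc[v]))^2)
    expect_lte(fit_obj, best + 1e-9)
  }
})

test_that("high b-value synthesis evaluates the closed form", {
  shape <- c(4, 4, 4)
  fit0 <- list(s0 = array(777, shape), adc = array(0, shape))
  expect_equal(synthesize_high_b(fit0, 1400), fit0$s0)
  fit1 <- list(s0 = array(1000, shape), adc = array(1.5e-3, shape))
  hb <- synthesize_high_b(fit1, 1400)
  expect_rel_equal(hb, array(1000 * exp(-2.1), shape), 1e-12)
  expect_lt(abs(hb[1] - 122.456), 5e-3)
})

test_that("fit + synthesis reproduces acquired and extrapolated volumes to 1e-6", {
  for (b in B_SCHEMES) {
    series <- noiseless_series(b, s0 = 850, adc = 1.1e-3)
    fit <- fit_adc(series, b)
    # round trip at an acquired b-value
    expect_rel_equal(synthesize_high_b(fit, b[2]), series[2, , , ], 1e-6)
    # extrapolation to b = 1400
    expect_rel_equal(synthesize_high_b(fit, 1400),
                     850 * exp(-1400 * 1.1e-3) * array(1, c(6, 5, 4)), 1e-6)
  }
})

test_that("gland-FOV cropping records an invertible box and never edits voxels", {
  set.seed(7)
  vols <- volume_set(array(rnorm(2 * 20 * 18 * 12), c(2, 20, 18, 12)),
                     c("T2W", "ADC"), spacing = c(2, 2, 4))
  gland <- array(0, c(20, 18, 12)); gland[8:14, 5:9, 4:8] <- 1
  cr <- crop_to_fov(vols, mask_volume(gland, c(2, 2, 4)), margin_mm = 4)
  # margin 4 mm -> 2 voxels in x/y, 1 voxel in z
  expect_equal(dim(cr$volumes$data)[-1], c(11, 9, 7))
  sl <- lapply(1:3, function(ax) (cr$crop_box$start[ax] + 1):cr$crop_box$end[ax])
  expect_identical(cr$volumes$data[, sl[[1]] - cr$crop_box$start[1],
                                   sl[[2]] - cr$crop_box$start[2],
                                   sl[[3]] - cr$crop_box$start[3]],
                   cr$volumes$data)
  expect_equal(cr$volumes$data[1, , , ],
               vols$data[1, sl[[1]], sl[[2]], sl[[3]]])
  # crop then un-crop a prediction lands on the original voxel positions
  pred <- array(runif(prod(dim(cr$volumes$data)[-1])), dim(cr$volumes$data)[-1])
  full <- uncrop_prediction(pred, cr$crop_box)
  expect_equal(full[sl[[1]], sl[[2]], sl[[3]]], pred)
  expect_equal(sum(full) - sum(pred), 0)

  # degenerate single-voxel mask with margin 0
  one <- array(0, c(20, 18, 12)); one[3, 4, 5] <- 1
  cr1 <- crop_to_fov(vols, mask_volume(one, c(2, 2, 4)), margin_mm = 0)
  expect_equal(dim(cr1$volumes$data)[-1], c(1, 1, 1))
  # margin larger than the volume clips to the full grid without error
  crbig <- crop_to_fov(vols, mask_volume(one, c(2, 2, 4)), margin_mm = 1000)
  expect_equal(dim(crbig$volumes$data)[-1], c(20, 18, 12))
  expect_error(crop_to_fov(vols, mask_volume(array(0, c(20, 18, 12))), 5),
               "empty")
})

test_that("normalization policies behave per definition including degenerate channels", {
  set.seed(1)
  dat <- array(rnorm(2 * 6 * 6 * 6, 50, 5), c(2, 6, 6, 6))
  dat[2, , , ] <- 3  # constant channel
  vols <- volume_set(dat, c("T2W", "ADC"))
  mask <- mask_volume(array(rbinom(216, 1, 0.5), c(6, 6, 6)))
  z <- normalize_channels(vols, "zscore_within_mask", mask)
  sel <- mask$data == 1
  expect_lt(abs(mean(z$data[1, , , ][sel])), 1e-6)
  expect_lt(abs(sd(z$data[1, , , ][sel]) - 1), 1e-6)
  expect_equal(max(abs(z$data[2, , , ])), 0)  # zero variance -> centered at 0
  mm <- normalize_channels(vols, "minmax")
  expect_equal(range(mm$data[1, , , ]), c(0, 1))
  expect_equal(max(abs(mm$data[2, , , ])), 0)
  expect_identical(normalize_channels(vols, "none"), vols)
  expect_named(attr(z, "normalization"), c("T2W", "ADC"))
})

test_that("clinical broadcast appends four constant channels in canonical order", {
  vols <- volume_set(array(rnorm(3 * 4 * 4 * 4), c(3, 4, 4, 4)),
                     c("T2W", "ADC", "HIGHB"))
  rec <- clinical_record("P001", psa = 8.8, psad = 8.8 / 40.8,
                         gland_volume = 40.8, gtv = 1.8)
  out <- broadcast_clinical(rec, vols)  # identity scaling
  expect_equal(out$channel_names,
               c("T2W", "ADC", "HIGHB", "PSA", "PSAD", "GLAND_VOL", "GTV"))
  expect_equal(dim(out$data)[1], 7)
  expect_true(all(out$data[4, , , ] == 8.8))
  # broadcast channels are spatially constant
  for (i in 4:7) expect_equal(diff(range(out$data[i, , , ])), 0)
  # reference scaling divides by the cohort-level reference
  ref <- c(PSA = 88, PSAD = 2, GLAND_VOL = 100, GTV = 10)
  out2 <- broadcast_clinical(rec, vols, ref)
  expect_equal(out2$data[4, 1, 1, 1], 0.1)
  # zero-valued covariates broadcast as zero channels
  rec0 <- clinical_record("P0", psa = 1e-9, psad = 1e-9 / 40, gland_volume = 40,
                          gtv = 0)
  out0 <- broadcast_clinical(rec0, vols)
  expect_equal(max(abs(out0$data[7, , , ])), 0)
  bad <- rec; bad$gtv <- NULL
  expect_error(broadcast_clinical(bad, vols), "gtv")
})
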