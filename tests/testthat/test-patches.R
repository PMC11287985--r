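make_vols <- function(shape = c(32, 32, 16), nch = 2, seed = 1) {
  set.seed(seed)
  volume_set(array(rnorm(nch * prod(shape)), c(nch, shape)),
             c("T2W", "ADC")[seq_len(nch)])
}

test_that("a patch-sized volume yields only the full-volume patch", {
  vols <- make_vols(c(16, 16, 8))
  lab <- mask_volume(random_mask(c(16, 16, 8)))
  ps <- sample_patches(vols, lab, n_patches = 5, patch_size = c(16, 16, 8),
                       seed = 3)
  for (p in ps) {
    expect_identical(p$data, vols$data)
    expect_identical(p$label, lab$data)
  }
})

test_that("patch sampling is deterministic and in bounds", {
  vols <- make_vols()
  lab <- mask_volume(random_mask(c(32, 32, 16)))
  a <- sample_patches(vols, lab, 20, c(16, 16, 8), seed = 9)
  b <- sample_patches(vols, lab, 20, c(16, 16, 8), seed = 9)
  expect_identical(lapply(a, `[[`, "center_index"),
                   lapply(b, `[[`, "center_index"))
  expect_error(sample_patches(vols, lab, 1, c(64, 64, 64), seed = 1), NA)
  # oversized patches trigger padding, not an error; label padding is 0
  big <- sample_patches(vols, lab, 1, c(64, 64, 64), seed = 1)
  expect_equal(dim(big[[1]]$label), c(64, 64, 64))
  expect_equal(sum(big[[1]]$label), sum(lab$data))
})

test_that("sampled centers follow the clipped rounded-Gaussian law", {
  vols <- make_vols(c(48, 32, 16), nch = 1)
  lab <- mask_volume(array(0, c(48, 32, 16)))
  ps <- sample_patches(vols, lab, 4000, c(16, 16, 8), seed = 11)
  cx <- vapply(ps, function(p) p$center_index[1], 0)
  # analytic law along x: round(N(24.5, 12)) clipped to [9, 41]
  lo <- 9; hi <- 41
  ks <- lo:hi
  pr <- vapply(ks, function(k) {
    if (k == lo) pnorm(lo + 0.5, 24.5, 12)
    else if (k == hi) 1 - pnorm(hi - 0.5, 24.5, 12)
    else pnorm(k + 0.5, 24.5, 12) - pnorm(k - 0.5, 24.5, 12)
  }, 0)
  obs <- tabulate(factor(cx, levels = ks))
  # merge sparse tail bins for a valid chi-square
  grp <- pmin(pmax(ks, lo + 2), hi - 2)
  obs_g <- tapply(obs, grp, sum)
  pr_g <- tapply(pr, grp, sum)
  gof <- suppressWarnings(chisq.test(obs_g, p = pr_g / sum(pr_g)))
  expect_gt(gof$p.value, 0.01)
})

test_that("rotation augmentation preserves shapes, binariness and identity cases", {
  vols <- make_vols(c(16, 16, 8))
  lab <- array(0, c(16, 16, 8)); lab[5:9, 7:10, 2:5] <- 1
  p <- sample_patches(vols, mask_volume(lab), 1, c(16, 16, 8), seed = 1)[[1]]
  expect_identical(augment_rotation(p, probability = 0, seed = 2), p)
  r360 <- augment_rotation(p, probability = 1, angle_range = c(360, 360),
                           seed = 2)
  expect_lt(max(abs(r360$data - p$data)), 1e-8)
  expect_equal(r360$label, p$label)
  expect_equal(r360$applied_rotation_deg, 360)
  r <- augment_rotation(p, probability = 1, angle_range = c(0, 360), seed = 5)
  expect_true(all(r$label %in% c(0, 1)))
  expect_equal(dim(r$data), dim(p$data))
})

test_that("a 90-degree rotation matches the index-permutation oracle", {
  shape <- c(12, 12, 4)
  vols <- volume_set(array(rnorm(prod(shape)), c(1, shape)), "T2W")
  bar <- array(0, shape); bar[3:10, 6:7, ] <- 1   # x-aligned bar
  p <- sample_patches(vols, mask_volume(bar), 1, shape, seed = 1)[[1]]
  r <- augment_rotation(p, probability = 1, angle_range = c(90, 90), seed = 1)
  # oracle: on a square slice a 90-degree rotation is an exact index
  # permutation (clockwise or counter-clockwise depending on convention)
  n <- shape[1]
  ccw <- cw <- array(0, shape)
  for (z in 1:shape[3]) {
    ccw[, , z] <- t(bar[, , z])[n:1, ]
    cw[, , z] <- t(bar[, , z])[, n:1]
  }
  expect_true(identical(r$label, ccw) || identical(r$label, cw))
  # the x-aligned bar is now y-aligned, with its voxel count preserved
  expect_equal(sum(r$label), sum(bar))
  expect_gt(diff(range(which(apply(r$label, 2, sum) > 0))), 5)
})

test_that("rotation changes convex label volume by less than 5%", {
  shape <- c(24, 24, 8)
  vols <- volume_set(array(0, c(1, shape)), "T2W")
  lab <- array(0, shape)
  ctr <- c(12.5, 12.5)
  for (i in 1:24) for (j in 1:24)
    if ((i - ctr[1])^2 + (j - ctr[2])^2 <= 36) lab[i, j, 3:6] <- 1
  p <- sample_patches(vols, mask_volume(lab), 1, shape, seed = 1)[[1]]
  for (ang in c(17, 45, 133, 301)) {
    r <- augment_rotation(p, probability = 1, angle_range = c(ang, ang),
                          seed = 1)
    expect_lt(abs(sum(r$label) - sum(lab)) / sum(lab), 0.05)
  }
})

test_that("reassembly averages overlaps and matches a brute-force accumulator", {
  # single patch covering the whole volume is the identity
  m <- array(runif(16 * 16 * 8), c(16, 16, 8))
  out <- reassemble(list(list(map = m, center = c(9, 9, 5))), c(16, 16, 8))
  expect_equal(out, m)
  # two half-overlapping constant patches average to 0.4 in the overlap
  a <- array(0.2, c(8, 8, 8)); b <- array(0.6, c(8, 8, 8))
  out2 <- reassemble(list(list(map = a, center = c(5, 5, 5)),
                          list(map = b, center = c(9, 5, 5))),
                     c(12, 8, 8))
  expect_equal(unique(as.vector(out2[5:8, , ])), 0.4)
  expect_equal(unique(as.vector(out2[1:4, , ])), 0.2)
  expect_equal(unique(as.vector(out2[9:12, , ])), 0.6)
  # random tiling vs brute-force sum/count oracle
  set.seed(3)
  shape <- c(24, 16, 8)
  cents <- tile_centers(shape, c(8, 8, 8), overlap = 0.5)
  acc <- array(0, shape); cnt <- array(0, shape)
  patches <- lapply(seq_len(ncol(cents)), function(i) {
    map <- array(runif(1), c(8, 8, 8))  # constant per patch
    st <- cents[, i] - 4
    acc[st[1]:(st[1] + 7), st[2]:(st[2] + 7), st[3]:(st[3] + 7)] <<-
      acc[st[1]:(st[1] + 7), st[2]:(st[2] + 7), st[3]:(st[3] + 7)] + map
    cnt[st[1]:(st[1] + 7), st[2]:(st[2] + 7), st[3]:(st[3] + 7)] <<-
      cnt[st[1]:(st[1] + 7), st[2]:(st[2] + 7), st[3]:(st[3] + 7)] + 1
    list(map = map, center = cents[, i])
  })
  expect_equal(reassemble(patches, shape), acc / cnt)
  # a coverage gap is rejected with the uncovered region
  expect_error(reassemble(list(list(map = a, center = c(5, 5, 5))),
                          c(12, 8, 8)), "uncovered")
})
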