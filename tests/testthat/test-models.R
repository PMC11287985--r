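# The CNN engine has hand-derived backpropagation; finite-difference
# gradient checks pin its correctness for the single-encoder U-Net and the
# multi-head intermediate-fusion network (which together exercise every
# layer type: 3x3x3 and 1x1x1 convolution, instance norm, ReLU, max pool,
# nearest upsampling, channel concat/split, dense layers, broadcast merge).

ns <- asNamespace("fuseseg")

flat_params <- function(p) rapply(p, as.vector, how = "unlist")

unflat_params <- function(vec, template) {
  i <- 0
  walk <- function(t) {
    if (is.list(t)) return(lapply(t, walk))
    v <- vec[(i + 1):(i + length(t))]
    i <<- i + length(t)
    if (!is.null(dim(t))) dim(v) <- dim(t)
    v
  }
  walk(template)
}

randomize_norm_shift <- function(params) {
  # beta = 0 at a size-1 instance-norm grid parks activations exactly on the
  # ReLU kink, where two-sided differences straddle the nondifferentiability;
  # random shifts keep the finite-difference check well posed
  rapply(params, function(x) x, how = "replace") -> params
  walk <- function(p) {
    if (is.list(p)) return(lapply(p, walk))
    p
  }
  up <- function(p) {
    if (is.list(p)) {
      if (!is.null(p$beta)) p$beta <- rnorm(length(p$beta), 0, 0.3)
      return(lapply(p, up))
    }
    p
  }
  up(params)
}

gradcheck <- function(loss_of, params, analytic, n_pick = 35, seed = 1) {
  set.seed(seed)
  pf <- flat_params(params)
  gf <- flat_params(analytic)
  pick <- sort(sample(length(pf), n_pick))
  num <- vapply(pick, function(i) {
    e <- 1e-5
    (loss_of(unflat_params(replace(pf, i, pf[i] + e), params)) -
       loss_of(unflat_params(replace(pf, i, pf[i] - e), params))) / (2 * e)
  }, 0)
  max(abs(num - gf[pick]) / pmax(abs(num) + abs(gf[pick]), 1e-3))
}

test_that("U-Net backpropagation matches finite differences", {
  set.seed(4)
  spec <- build_baseline_unet(2, base_filters = 2, convs_per_block = 1)
  params <- randomize_norm_shift(ns$unet_params_init(2, 2, 1))
  x <- array(rnorm(2 * 16 * 16 * 8), c(2, 16, 16, 8))
  g <- array(rbinom(16 * 16 * 8, 1, 0.2), c(1, 16, 16, 8))
  loss_of <- function(p) ns$seg_loss(ns$unet_fwd_full(p, x)$p, g)$loss
  fw <- ns$unet_fwd_full(params, x)
  bw <- ns$unet_bwd_full(params, fw$cache, ns$seg_loss(fw$p, g)$glogit)
  expect_lt(gradcheck(loss_of, params, bw$grads), 1e-4)
})

test_that("intermediate-fusion backpropagation matches finite differences", {
  set.seed(5)
  params <- randomize_norm_shift(ns$if_params_init(2, 1, c(4L, 4L, 3L)))
  x <- array(rnorm(3 * 16 * 16 * 8), c(3, 16, 16, 8))
  g <- array(rbinom(16 * 16 * 8, 1, 0.2), c(1, 16, 16, 8))
  clin <- c(0.5, 0.2, 0.8, 0.1)
  loss_of <- function(p) ns$seg_loss(ns$if_fwd_full(p, x, clin)$p, g)$loss
  fw <- ns$if_fwd_full(params, x, clin)
  gr <- ns$if_bwd_full(params, fw$cache, ns$seg_loss(fw$p, g)$glogit)
  expect_lt(gradcheck(loss_of, params, gr), 1e-4)
})

test_that("forward passes keep the probability contract on the input geometry", {
  p1 <- fuseseg:::init_params(build_baseline_unet(1, 2, convs_per_block = 1), 1)
  x <- array(rnorm(64 * 64 * 16), c(1, 64, 64, 16))
  out <- ns$unet_fwd_full(p1, x)$p
  expect_equal(dim(out), c(1, 64, 64, 16))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("family builders encode the canonical channel layouts", {
  expect_equal(build_ef(clinical = TRUE)$in_channels, 7)
  expect_equal(build_ef(clinical = TRUE)$channel_names[4:7],
               c("PSA", "PSAD", "GLAND_VOL", "GTV"))
  expect_equal(build_ef(clinical = FALSE)$in_channels, 3)
  expect_null(build_if(clinical = FALSE)$mlp_widths)   # image-only IF variant
  lf <- build_lf(clinical = FALSE)
  expect_length(lf$members, 3)                         # image-only LF: 3 members
  expect_equal(lf$aggregation, "mean")
  expect_error(build_baseline_unet(1, patch_size = c(60, 64, 16)),
               "divisible")
  expect_error(build_if(mlp_widths = c(8, 8)), "3 entries")
})

test_that("parameter count grows with base_filters and bottleneck width adds up", {
  n2 <- ns$n_params(fuseseg:::init_params(build_baseline_unet(3, 2), 1))
  n4 <- ns$n_params(fuseseg:::init_params(build_baseline_unet(3, 4), 1))
  n8 <- ns$n_params(fuseseg:::init_params(build_baseline_unet(3, 8), 1))
  expect_true(n2 < n4 && n4 < n8)
  # IF bottleneck input = 3 encoder heads (4b each) + MLP feature width
  p <- ns$if_params_init(2, 1, c(8L, 8L, 4L))
  expect_equal(dim(p$bott[[1]]$W)[2], 3 * 8 + 4)
  # image-only IF omits the MLP contribution
  p0 <- ns$if_params_init(2, 1, NULL)
  expect_equal(dim(p0$bott[[1]]$W)[2], 3 * 8)
})

test_that("every IF encoder head is connected to the output", {
  set.seed(8)
  params <- ns$if_params_init(2, 1, c(4L, 4L, 3L))
  x <- array(rnorm(3 * 16 * 16 * 8), c(3, 16, 16, 8))
  clin <- c(0.4, 0.3, 0.2, 0.1)
  base <- ns$if_fwd_full(params, x, clin)$p
  for (hd in 1:3) {
    x0 <- x
    x0[hd, , , ] <- 0
    expect_gt(max(abs(ns$if_fwd_full(params, x0, clin)$p - base)), 1e-6)
  }
  # and the clinical head matters too
  expect_gt(max(abs(ns$if_fwd_full(params, x, clin * 4)$p - base)), 1e-8)
})

test_that("LF aggregation equals the mean of independent member predictions", {
  cases <- toy_cohort(2)
  cfg <- train_config("desk", epochs = 2, patches_per_image = 2, seed = 4)
  spec <- build_lf(base_filters = 2, mlp_widths = c(4, 4, 2), clinical = TRUE,
                   convs_per_block = 1)
  ref <- clinical_reference(lapply(cases, `[[`, "clinical"))
  ens <- train(spec, cases, cfg, clinical_ref = ref)
  expect_named(ens$members, c("T2W", "ADC", "HIGHB", "CLINICAL"))
  vols <- cases[[1]]$vols
  agg <- predict(ens, vols, clinical = cases[[1]]$clinical)
  manual <- member_predictions(ens, vols, clinical = cases[[1]]$clinical)
  expect_equal(agg, Reduce(`+`, manual) / 4, tolerance = 1e-12)
  # the clinical member is a spatially constant probability map
  expect_equal(diff(range(manual$CLINICAL)), 0)
  # members predicting identical maps aggregate to that map
  same <- list(manual[[1]], manual[[1]], manual[[1]])
  expect_equal(Reduce(`+`, same) / 3, manual[[1]])
})

test_that("prediction is invariant to channel storage order and survives save/load", {
  cases <- toy_cohort(2)
  cfg <- train_config("desk", epochs = 2, patches_per_image = 2, seed = 6)
  spec <- build_ef(base_filters = 2, clinical = FALSE, convs_per_block = 1)
  m <- train(spec, cases, cfg)
  vols <- cases[[1]]$vols
  p1 <- predict(m, vols)
  shuffled <- volume_set(vols$data[c(3, 1, 2), , , ],
                         vols$channel_names[c(3, 1, 2)], vols$spacing)
  expect_equal(predict(m, shuffled), p1, tolerance = 1e-12)
  expect_true(all(p1 >= 0 & p1 <= 1))
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  expect_identical(predict(load_model(f), vols), p1)
  unlink(f)
  # channel mismatch is rejected naming the expectation
  expect_error(predict(m, volume_set(vols$data[1:2, , , , drop = FALSE],
                                     c("T2W", "ADC"), vols$spacing)),
               "expected channels")
})
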