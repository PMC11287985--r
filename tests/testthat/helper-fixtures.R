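# Shared fixtures, all generated in code at test time.

# A small phantom spec that keeps per-test generation cheap.
small_spec <- function(n_patients = 2, ...) {
  phantom_spec(grid_shape = c(32, 32, 32), n_patients = n_patients,
               seed = 101, ...)
}

# Linearly separable toy case: a bright box lesion on all three channels.
toy_case <- function(seed, shape = c(16, 16, 8), contrast = 2) {
  set.seed(seed)
  L <- array(0, shape)
  L[6:11, 6:11, 3:6] <- 1
  x <- array(rnorm(3 * prod(shape), 0, 0.1), c(3, shape))
  for (c_ in 1:3) x[c_, , , ] <- x[c_, , , ] + contrast * L
  train_case(volume_set(x, c("T2W", "ADC", "HIGHB")), mask_volume(L),
             clinical_record(sprintf("T%03d", seed), psa = 8 + seed,
                             psad = (8 + seed) / 40, gland_volume = 40,
                             gtv = sum(L) / 1000, check_identity = FALSE))
}

toy_cohort <- function(n = 2, ...) lapply(seq_len(n), toy_case, ...)

# Random binary mask on a small grid.
random_mask <- function(shape = c(16, 16, 16), p = 0.2) {
  array(rbinom(prod(shape), 1, p), shape)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected) / pmax(abs(expected), 1e-12)), tol)
}
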