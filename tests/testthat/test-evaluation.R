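test_that("DSC identities and the worked overlap example hold", {
  a <- array(0, c(8, 8, 8)); a[1:4, , 1:4] <- 1
  b <- array(0, c(8, 8, 8)); b[5:8, , 5:8] <- 1
  expect_equal(dsc(a, a), 1)
  expect_equal(dsc(a, b), 0)
  expect_equal(dsc(a, array(0, c(8, 8, 8))), 0)
  expect_equal(dsc(b, a), dsc(a, b))
  # |A| = |B| = 100, |A n B| = 50 -> 0.5 (direct set-count oracle)
  A <- array(0, c(10, 10, 10)); A[1:100] <- 1
  B <- array(0, c(10, 10, 10)); B[51:150] <- 1
  expect_equal(dsc(A, B), 2 * 50 / (100 + 100))
  both <- dsc(array(0, c(4, 4, 4)), array(0, c(4, 4, 4)))
  expect_equal(as.numeric(both), 1)
  expect_true(attr(both, "both_empty"))
  expect_error(dsc(a, array(0, c(4, 4, 4))), "grids differ")
})

test_that("voxel precision/recall match counting oracles including saturation", {
  t <- array(0, c(6, 6, 6)); t[1:10] <- 1
  expect_equal(precision_recall(t, t), c(precision = 1, recall = 1))
  all1 <- array(1, c(6, 6, 6))
  pr <- precision_recall(all1, t)
  expect_equal(unname(pr), c(10 / 216, 1))  # precision = prevalence, recall 1
  # printed toy: pred 8 voxels, truth 10, overlap 6
  p <- array(0, c(6, 6, 6)); p[5:12] <- 1   # overlaps truth at 5..10
  expect_equal(unname(precision_recall(p, t)), c(6 / 8, 6 / 10))
})

test_that("lesion-level precision/recall use connected components with flags", {
  t <- array(0, c(12, 12, 4))
  t[2:4, 2:4, 1:2] <- 1   # lesion A
  t[8:10, 8:10, 3:4] <- 1 # lesion B
  p <- array(0, c(12, 12, 4))
  p[3:5, 3:5, 1:2] <- 1   # hits A
  p[2:3, 9:10, 3:4] <- 1  # false positive blob
  pr <- precision_recall(p, t, level = "lesion")
  expect_equal(unname(pr), c(1 / 2, 1 / 2))
  und <- precision_recall(p, array(0, c(12, 12, 4)), level = "lesion")
  expect_true(all(is.na(und)))
  expect_match(attr(und, "flag"), "empty truth")
})

test_that("F-score matches the printed image-only results and identities", {
  expect_equal(round(f_score(0.36, 0.13), 2), 0.19)
  expect_equal(round(f_score(0.56, 0.23), 2), 0.33)
  for (x in c(0.1, 0.5, 0.9)) expect_equal(f_score(x, x), x)
  z <- f_score(0, 0)
  expect_equal(as.numeric(z), 0)
  expect_match(attr(z, "flag"), "P = R = 0")
})

test_that("average precision matches hand enumeration and ranking limits", {
  # perfectly ranked probabilities
  t <- array(0, c(4, 4, 4)); t[1:8] <- 1
  prob <- array(0, c(4, 4, 4)); prob[1:8] <- seq(0.9, 0.95, length.out = 8)
  prob[9:64] <- seq(0.05, 0.4, length.out = 56)
  expect_equal(average_precision(prob, t)$ap, 1)
  # 6-voxel worked example, enumerated by hand over descending thresholds:
  # ranked labels 1,1,0,1,0,0 -> AP = 1/3 + 1/3 + (1/3)(3/4) = 11/12
  ap6 <- average_precision(c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4),
                           c(1, 1, 0, 1, 0, 0))
  expect_equal(ap6$ap, 11 / 12)
  expect_true(all(diff(ap6$pr_curve$recall) >= 0))
  # probabilities independent of the truth -> AP ~ prevalence (1e5 voxels)
  set.seed(31)
  y <- rbinom(1e5, 1, 0.1)
  s <- runif(1e5)
  expect_lt(abs(average_precision(s, y)$ap - 0.1), 0.02)
  # degenerate constant map is flagged
  cst <- average_precision(rep(0.5, 64), c(rep(1, 8), rep(0, 56)))
  expect_match(cst$flag, "single-point")
})

test_that("AP and AUC-PR agree as estimators of the same curve", {
  set.seed(12)
  for (i in 1:5) {
    y <- rbinom(4000, 1, 0.15)
    s <- y * rnorm(4000, 0.6, 0.3) + (1 - y) * rnorm(4000, 0.3, 0.3)
    r <- average_precision(s, y)
    expect_gt(nrow(r$pr_curve), 100)
    expect_lt(abs(r$ap - r$auc_pr), 0.02)
  }
})

test_that("paired t-tests match the textbook formula and detect real shifts", {
  set.seed(5)
  a <- rnorm(20, 0.5, 0.05)
  expect_lt(paired_t_test(a + 0.3, a + rnorm(20, 0, 0.01)), 1e-3)
  # formula oracle: differences (1, -1, 1, -1) give t = 0, p = 1
  b <- c(2, 1, 4, 3); d <- c(1, -1, 1, -1)
  t_stat <- mean(d) / (sd(d) / sqrt(4))
  p_manual <- 2 * pt(-abs(t_stat), df = 3)
  expect_equal(paired_t_test(b + d, b), p_manual)
  # a generic case against the same closed form
  d2 <- c(0.12, -0.05, 0.31, 0.02, -0.2, 0.16)
  t2 <- mean(d2) / (sd(d2) / sqrt(6))
  expect_equal(paired_t_test(b2 <- rnorm(6) + d2, b2 - d2),
               2 * pt(-abs(t2), df = 5))
  z <- paired_t_test(a, a)
  expect_true(is.na(z))
  expect_match(attr(z, "flag"), "zero-variance")
  expect_error(paired_t_test(1:3, 1:4), "pair up")
})

test_that("arm reports carry the threshold and feed pairwise comparisons", {
  set.seed(8)
  truths <- lapply(1:5, function(i) random_mask(c(8, 8, 8), 0.15))
  probs_good <- lapply(truths, function(t)
    pmin(pmax(t * 0.8 + runif(length(t), 0, 0.3), 0), 1))
  probs_bad <- lapply(truths, function(t) array(runif(length(t)), dim(t)))
  ra <- evaluate_arm(probs_good, truths)
  rb <- evaluate_arm(probs_bad, truths)
  expect_equal(ra$threshold, 0.5)
  expect_equal(nrow(ra$per_patient), 5)
  expect_true(all(ra$per_patient$dsc >= 0 & ra$per_patient$dsc <= 1))
  expect_gt(ra$cohort$mean[ra$cohort$metric == "dsc"],
            rb$cohort$mean[rb$cohort$metric == "dsc"])
  pw <- pairwise_arm_tests(list(good = ra, bad = rb))
  expect_equal(dim(pw), c(2, 2))
  expect_equal(pw["good", "bad"], pw["bad", "good"])
  expect_lt(pw["good", "bad"], 0.05)
})

test_that("channel ablation emits one row per subset reproducibly", {
  cases <- toy_cohort(3, contrast = 3)
  cfg <- train_config("desk", epochs = 2, patches_per_image = 2, seed = 5)
  tab <- run_ablation(cases[1:2], cases[3],
                      channel_subsets = list("T2W", "ADC", "HIGHB"),
                      config = cfg, base_filters = 2)
  expect_equal(tab$input_data, c("T2W", "ADC", "HIGHB"))
  expect_true(all(is.finite(tab$mean_dsc)))
  tab2 <- run_ablation(cases[1:2], cases[3],
                       channel_subsets = list("T2W", "ADC", "HIGHB"),
                       config = cfg, base_filters = 2)
  expect_equal(tab, tab2, ignore_attr = TRUE)
  expect_error(run_ablation(cases[1:2], cases[3], list("DCE"), cfg),
               "unknown channels")
})
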