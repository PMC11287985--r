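## Segmentation metrics and statistical comparisons: Dice, voxel- and
## lesion-level precision/recall, F-score, average precision and PR curves,
## paired t-tests, channel ablation.

as_mask_array <- function(x) {
  if (inherits(x, "mask_volume")) x$data else x
}

check_same_grid <- function(a, b, what) {
  if (!all(dim(a) == dim(b)))
    stopf("%s: grids differ (%s vs %s)", what,
          paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
}

#' Dice-Sorensen coefficient
#'
#' `2|A n B| / (|A| + |B|)`.  When both masks are empty the DSC is defined
#' as 1 (perfect agreement on absence) and flagged via the `both_empty`
#' attribute.
#' @param pred,truth binary masks ([mask_volume()] or 0/1 arrays) on one grid.
#' @return scalar in `[0, 1]`.
#' @export
dsc <- function(pred, truth) {
  a <- as_mask_array(pred); b <- as_mask_array(truth)
  check_same_grid(a, b, "dsc")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(structure(1, both_empty = TRUE))
  2 * sum(a * b) / (sa + sb)
}

#' Voxel- or lesion-level precision and recall
#'
#' Voxel level: `TP/(TP+FP)` and `TP/(TP+FN)` over voxels.  Lesion level:
#' connected components (6-connectivity) of prediction and truth; a
#' predicted component counts as TP if it overlaps a truth component
#' (`"any"` criterion, default) or if the overlap exceeds half of the truth
#' component (`"majority"`).  Undefined ratios (empty prediction or truth)
#' are returned as `NA` with a `flag` attribute.
#'
#' @param pred,truth binary masks on one grid.
#' @param level `"voxel"` (default) or `"lesion"`.
#' @param overlap_criterion `"any"` or `"majority"` (lesion level).
#' @return named vector `c(precision, recall)`.
#' @export
precision_recall <- function(pred, truth, level = c("voxel", "lesion"),
                             overlap_criterion = c("any", "majority")) {
  level <- match.arg(level)
  overlap_criterion <- match.arg(overlap_criterion)
  a <- as_mask_array(pred); b <- as_mask_array(truth)
  check_same_grid(a, b, "precision_recall")
  if (level == "voxel") {
    tp <- sum(a * b); fp <- sum(a * (1 - b)); fn <- sum((1 - a) * b)
    p <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    r <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    out <- c(precision = p, recall = r)
    if (anyNA(out)) attr(out, "flag") <- "undefined ratio (empty set)"
    return(out)
  }
  pl <- label_components(a)
  tl <- label_components(b)
  if (tl$n == 0) {
    out <- c(precision = NA_real_, recall = NA_real_)
    attr(out, "flag") <- "empty truth: lesion-level recall undefined"
    return(out)
  }
  hit <- function(comp_vox, other_lab) {
    ov <- other_lab[comp_vox]
    ov <- ov[ov > 0]
    if (!length(ov)) return(FALSE)
    if (overlap_criterion == "any") return(TRUE)
    tab <- table(ov)
    sizes <- tabulate(other_lab[other_lab > 0])
    any(as.integer(tab) > 0.5 * sizes[as.integer(names(tab))])
  }
  p_tp <- sum(vapply(seq_len(pl$n), function(k)
    hit(which(pl$labels == k), tl$labels), TRUE))
  t_tp <- sum(vapply(seq_len(tl$n), function(k)
    hit(which(tl$labels == k), pl$labels), TRUE))
  p <- if (pl$n == 0) NA_real_ else p_tp / pl$n
  r <- t_tp / tl$n
  out <- c(precision = p, recall = r)
  if (anyNA(out)) attr(out, "flag") <- "no predicted components"
  out
}

## 6-connected component labeling by union-find over axis-neighbor pairs.
label_components <- function(mask) {
  idx <- which(mask == 1)
  n <- length(idx)
  if (n == 0) return(list(labels = array(0L, dim(mask)), n = 0L))
  d <- dim(mask)
  pos <- arrayInd(idx, d)
  key <- integer(prod(d))
  key[idx] <- seq_len(n)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  strides <- c(1L, d[1], d[1] * d[2])
  for (ax in 1:3) {
    ok <- pos[, ax] < d[ax]
    nb <- idx[ok] + strides[ax]
    both <- key[nb] > 0
    a <- key[idx[ok]][both]; b <- key[nb][both]
    for (i in seq_along(a)) {
      ra <- find(a[i]); rb <- find(b[i])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  lab_ids <- match(roots, unique(roots))
  labels <- array(0L, d)
  labels[idx] <- lab_ids
  list(labels = labels, n = length(unique(roots)))
}

#' F-score (harmonic mean of precision and recall)
#'
#' `2PR/(P+R)`; defined as 0 (with a flag attribute) when both are 0.
#' @param p,r precision and recall in `[0, 1]`.
#' @return scalar.
#' @export
f_score <- function(p, r) {
  if (anyNA(c(p, r))) return(NA_real_)
  if (p < 0 || p > 1 || r < 0 || r > 1) stopf("f_score: P, R must be in [0,1]")
  if (p + r == 0) return(structure(0, flag = "P = R = 0"))
  2 * p * r / (p + r)
}

#' Average precision, PR curve and AUC-PR of a probability map
#'
#' Sweeps all unique probability values as thresholds (descending), records
#' `(threshold, precision, recall)`, computes AP as the sum of precision
#' times recall increments, and AUC-PR by the trapezoid rule on the stored
#' curve.
#'
#' @param prob 3D probability map (or numeric vector).
#' @param truth binary mask on the same grid; must be nonempty.
#' @return list with `ap`, `pr_curve` (data.frame, recall non-decreasing),
#'   `auc_pr`, and `flag` for degenerate (constant-probability) maps.
#' @export
average_precision <- function(prob, truth) {
  b <- as_mask_array(truth)
  if (!is.null(dim(prob))) check_same_grid(prob, b, "average_precision")
  y <- as.vector(b); s <- as.vector(prob)
  npos <- sum(y)
  if (npos == 0) stopf("average_precision: truth mask is empty")
  ord <- order(s, decreasing = TRUE)
  ys <- y[ord]; ss <- s[ord]
  ctp <- cumsum(ys)
  k <- seq_along(ys)
  last_of_thr <- which(c(ss[-1] != ss[-length(ss)], TRUE))
  prec <- ctp[last_of_thr] / k[last_of_thr]
  rec <- ctp[last_of_thr] / npos
  thr <- ss[last_of_thr]
  ap <- sum(diff(c(0, rec)) * prec)
  auc <- if (length(rec) > 1)
    sum(diff(rec) * (head(prec, -1) + prec[-1]) / 2) else NA_real_
  out <- list(ap = ap,
              pr_curve = data.frame(threshold = thr, precision = prec,
                                    recall = rec),
              auc_pr = auc)
  if (length(thr) == 1) out$flag <- "constant probability map: single-point curve"
  out
}

#' Two-sided paired t-test on per-patient scores
#'
#' @param scores_a,scores_b numeric vectors of equal length (>= 2), paired
#'   by patient.
#' @return two-sided p-value (`NA` with a flag if the differences have zero
#'   variance).
#' @export
paired_t_test <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b))
    stopf("paired_t_test: score vectors must pair up (got %d vs %d)",
          length(scores_a), length(scores_b))
  if (length(scores_a) < 2) stopf("paired_t_test: need >= 2 pairs")
  d <- scores_a - scores_b
  if (stats::sd(d) < .Machine$double.eps^0.5)
    return(structure(NA_real_, flag = "zero-variance differences"))
  stats::t.test(scores_a, scores_b, paired = TRUE)$p.value
}

#' Rank-based (Mann-Whitney) AUC of values against binary labels
#' @param values numeric scores.
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
voxel_auc <- function(values, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stopf("voxel_auc: need both classes")
  r <- rank(values)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-patient and cohort metrics for one method arm
#'
#' Binarizes each probability map at `threshold`, computes per-patient DSC,
#' voxel precision/recall and F-score, cohort mean and sd, plus AP / PR
#' curve / AUC-PR over the pooled voxels of the cohort.
#'
#' @param probs list of 3D probability maps.
#' @param truths list of truth masks (same order).
#' @param ids patient ids.
#' @param threshold binarization threshold (default 0.5; recorded in the
#'   report).
#' @return A `metrics_report`.
#' @export
evaluate_arm <- function(probs, truths, ids = NULL, threshold = 0.5) {
  stopifnot(length(probs) == length(truths))
  ids <- ids %||% sprintf("P%03d", seq_along(probs))
  rows <- lapply(seq_along(probs), function(i) {
    tr <- as_mask_array(truths[[i]])
    bin <- (probs[[i]] >= threshold) * 1
    pr <- precision_recall(bin, tr)
    data.frame(patient_id = ids[i], dsc = as.numeric(dsc(bin, tr)),
               precision = unname(pr["precision"]),
               recall = unname(pr["recall"]),
               f_score = as.numeric(f_score(
                 if (is.na(pr["precision"])) 0 else pr["precision"],
                 if (is.na(pr["recall"])) 0 else pr["recall"])))
  })
  per_patient <- do.call(rbind, rows)
  pooled <- average_precision(unlist(lapply(probs, as.vector)),
                              unlist(lapply(truths, function(t)
                                as.vector(as_mask_array(t)))))
  cohort <- data.frame(
    metric = c("dsc", "precision", "recall", "f_score"),
    mean = vapply(c("dsc", "precision", "recall", "f_score"),
                  function(m) mean(per_patient[[m]], na.rm = TRUE), 0),
    sd = vapply(c("dsc", "precision", "recall", "f_score"),
                function(m) stats::sd(per_patient[[m]], na.rm = TRUE), 0),
    row.names = NULL)
  structure(list(per_patient = per_patient, cohort = cohort, ap = pooled$ap,
                 pr_curve = pooled$pr_curve, auc_pr = pooled$auc_pr,
                 threshold = threshold),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d patients, threshold %.2f\n",
              nrow(x$per_patient), x$threshold))
  print(x$cohort)
  cat(sprintf("pooled AP %.3f, AUC-PR %.3f\n", x$ap, x$auc_pr))
  invisible(x)
}

#' Pairwise paired t-tests between method arms
#' @param reports named list of `metrics_report` on the same patients.
#' @param metric per-patient column to compare (default `"dsc"`).
#' @return symmetric matrix of two-sided p-values.
#' @export
pairwise_arm_tests <- function(reports, metric = "dsc") {
  k <- length(reports)
  p <- matrix(NA_real_, k, k, dimnames = list(names(reports), names(reports)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j) {
      pv <- tryCatch(paired_t_test(reports[[i]]$per_patient[[metric]],
                                   reports[[j]]$per_patient[[metric]]),
                     error = function(e) NA_real_)
      p[i, j] <- p[j, i] <- as.numeric(pv)
    }
  }
  p
}

#' Channel-ablation experiment
#'
#' Trains one baseline U-Net per channel subset on the training cases and
#' reports mean and sd of per-patient test DSC, mirroring a
#' single-sequence-importance table.
#'
#' @param train_cases,test_cases lists of [train_case()].
#' @param channel_subsets list of character vectors drawn from
#'   `c("T2W", "ADC", "HIGHB")`.
#' @param config a [train_config()].
#' @param base_filters U-Net width (default 4).
#' @return data.frame `input_data`, `mean_dsc`, `sd_dsc`, plus the reports
#'   as the `reports` attribute.
#' @export
run_ablation <- function(train_cases, test_cases, channel_subsets,
                         config = train_config("desk"), base_filters = 4) {
  bad <- setdiff(unlist(channel_subsets), CANONICAL_IMAGE_CHANNELS)
  if (length(bad)) stopf("run_ablation: unknown channels %s",
                         paste(bad, collapse = ", "))
  reports <- list()
  rows <- lapply(channel_subsets, function(chs) {
    spec <- build_baseline_unet(length(chs), base_filters,
                                convs_per_block = config_convs(config),
                                channel_names = chs,
                                patch_size = config$patch_size)
    model <- train(spec, train_cases, config)
    probs <- lapply(test_cases, function(tc)
      predict(model, tc$vols, tc$clinical))
    rep_ <- evaluate_arm(probs, lapply(test_cases, `[[`, "label"),
                         threshold = config$threshold)
    nm <- paste(chs, collapse = "+")
    reports[[nm]] <<- rep_
    data.frame(input_data = nm,
               mean_dsc = rep_$cohort$mean[rep_$cohort$metric == "dsc"],
               sd_dsc = rep_$cohort$sd[rep_$cohort$metric == "dsc"])
  })
  out <- do.call(rbind, rows)
  attr(out, "reports") <- reports
  out
}

config_convs <- function(config) {
  if (identical(config$scale_preset, "desk")) 1L else 2L
}
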