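## End-to-end orchestration: generate -> preprocess -> train (comparison
## arms) -> evaluate -> compare, deterministic under one master seed.

#' Configuration for a full fusion-comparison experiment
#'
#' @param n_train,n_test patients in the training and test split.
#' @param arms method arms to run; singletons (`"T2W"`, `"ADC"`, `"HIGHB"`),
#'   fused with clinical data (`"EF"`, `"IF"`, `"LF"`) and image-only
#'   variants (`"EF_IMG"`, `"IF_IMG"`, `"LF_IMG"`).
#' @param phantom named list of [phantom_spec()] overrides (e.g.
#'   `fusion_advantage_mode = TRUE`).
#' @param train a [train_config()] (defaults to the desk preset).
#' @param base_filters network width for every arm.
#' @param margin_mm crop margin around the gland.
#' @param normalization policy passed to [normalize_channels()].
#' @param seed master seed; fixes the cohort, all initializations, patch
#'   draws and augmentations.
#' @param out_dir optional directory for reports and the manifest.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(n_train = 12, n_test = 4,
                              arms = c("T2W", "ADC", "HIGHB",
                                       "EF", "IF", "LF",
                                       "EF_IMG", "IF_IMG", "LF_IMG"),
                              phantom = list(fusion_advantage_mode = TRUE),
                              train = train_config("desk"),
                              base_filters = 2,
                              margin_mm = 10,
                              normalization = "zscore_within_mask",
                              seed = 1L, out_dir = NULL) {
  known <- c("T2W", "ADC", "HIGHB", "EF", "IF", "LF",
             "EF_IMG", "IF_IMG", "LF_IMG")
  bad <- setdiff(arms, known)
  if (length(bad)) stopf("experiment_config: unknown arm(s) %s",
                         paste(bad, collapse = ", "))
  structure(list(n_train = n_train, n_test = n_test, arms = arms,
                 phantom = phantom, train = train,
                 base_filters = base_filters, margin_mm = margin_mm,
                 normalization = normalization, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "experiment_config")
}

## Crop to the gland FOV, normalize, and bundle as a training case.
preprocess_patient <- function(patient, margin_mm, normalization) {
  cr <- crop_to_fov(patient$volumes, patient$gland_mask, margin_mm,
                    extra_masks = list(lesion = patient$lesion_mask))
  vols <- normalize_channels(cr$volumes, normalization,
                             mask = cr$gland_mask)
  list(case = train_case(vols, cr$extra_masks$lesion, patient$clinical),
       crop_box = cr$crop_box, gland_mask = cr$gland_mask)
}

arm_plan <- function(arm, base_filters, convs, patch_size, mlp_widths) {
  switch(arm,
    T2W = , ADC = , HIGHB =
      list(spec = build_baseline_unet(1, base_filters, convs,
                                      channel_names = arm,
                                      patch_size = patch_size),
           clinical = FALSE, input = "image",
           label = sprintf("%s only", arm), fusion = "-"),
    EF = list(spec = build_ef(base_filters, TRUE, convs, patch_size),
              clinical = TRUE, input = "clinical",
              label = "mpMRI & clinical", fusion = "EF"),
    IF = list(spec = build_if(base_filters, mlp_widths, TRUE, convs, patch_size),
              clinical = TRUE, input = "image",
              label = "mpMRI & clinical", fusion = "IF"),
    LF = list(spec = build_lf(base_filters, mlp_widths, TRUE, convs, patch_size),
              clinical = TRUE, input = "image",
              label = "mpMRI & clinical", fusion = "LF"),
    EF_IMG = list(spec = build_ef(base_filters, FALSE, convs, patch_size),
                  clinical = FALSE, input = "image",
                  label = "mpMRI only", fusion = "EF"),
    IF_IMG = list(spec = build_if(base_filters, mlp_widths, FALSE, convs,
                                  patch_size),
                  clinical = FALSE, input = "image",
                  label = "mpMRI only", fusion = "IF"),
    LF_IMG = list(spec = build_lf(base_filters, mlp_widths, FALSE, convs,
                                  patch_size),
                  clinical = FALSE, input = "image",
                  label = "mpMRI only", fusion = "LF"))
}

#' Run a full fusion-comparison experiment
#'
#' Generates the synthetic cohort, preprocesses every patient (gland-FOV
#' crop, per-channel normalization, clinical broadcast for EF), trains every
#' configured arm, predicts the test patients, evaluates each arm
#' ([evaluate_arm()]), and compares arms with paired t-tests on per-patient
#' DSC.  A rerun with the same config reproduces every metric exactly (the
#' pipeline is deterministic end to end).
#'
#' @param config an [experiment_config()].
#' @return An `experiment_result`: `table` (one row per arm with mean/sd
#'   DSC, AP, AUC-PR), `reports` (named [evaluate_arm()] reports),
#'   `pairwise_p` (paired t-test matrix on DSC), `clinical_vs_image_p`
#'   (per-family p-values), `cohort_summary`, `manifest`.
#' @export
run_experiment <- function(config) {
  stage <- "generate"
  result <- tryCatch({
    n_total <- config$n_train + config$n_test
    pspec <- do.call(phantom_spec,
                     modifyList(config$phantom,
                                list(n_patients = n_total,
                                     seed = derive_seed(config$seed, "phantom"))))
    cohort <- generate_cohort(pspec)
    train_pat <- cohort$patients[seq_len(config$n_train)]
    test_pat <- cohort$patients[config$n_train + seq_len(config$n_test)]

    stage <- "preprocess"
    prep_train <- lapply(train_pat, preprocess_patient,
                         config$margin_mm, config$normalization)
    prep_test <- lapply(test_pat, preprocess_patient,
                        config$margin_mm, config$normalization)
    clin_ref <- clinical_reference(lapply(train_pat, `[[`, "clinical"))
    image_train <- lapply(prep_train, `[[`, "case")
    image_test <- lapply(prep_test, `[[`, "case")
    with_clinical_channels <- function(cases) lapply(cases, function(cs)
      train_case(broadcast_clinical(cs$clinical, cs$vols, clin_ref),
                 cs$label, cs$clinical))
    ef_train <- if (any(config$arms == "EF")) with_clinical_channels(image_train)
    ef_test <- if (any(config$arms == "EF")) with_clinical_channels(image_test)

    convs <- config_convs(config$train)
    mlp_widths <- if (identical(config$train$scale_preset, "desk"))
      c(8L, 8L, 4L) else c(16L, 16L, 8L)

    reports <- list()
    rows <- list()
    for (arm in config$arms) {
      stage <- paste0("train:", arm)
      plan <- arm_plan(arm, config$base_filters, convs,
                       config$train$patch_size, mlp_widths)
      tr_cases <- if (plan$input == "clinical") ef_train else image_train
      te_cases <- if (plan$input == "clinical") ef_test else image_test
      cfg <- config$train
      cfg$seed <- derive_seed(config$seed, "arm", arm)
      model <- train(plan$spec, tr_cases, cfg, clinical_ref = clin_ref)
      stage <- paste0("evaluate:", arm)
      probs <- lapply(te_cases, function(tc)
        predict(model, tc$vols, clinical = tc$clinical))
      rep_ <- evaluate_arm(probs, lapply(te_cases, `[[`, "label"),
                           ids = vapply(test_pat, `[[`, "", "patient_id"),
                           threshold = cfg$threshold)
      reports[[arm]] <- rep_
      rows[[arm]] <- data.frame(
        arm = arm, input_data = plan$label, fusion = plan$fusion,
        mean_dsc = rep_$cohort$mean[rep_$cohort$metric == "dsc"],
        sd_dsc = rep_$cohort$sd[rep_$cohort$metric == "dsc"],
        ap = rep_$ap, auc_pr = rep_$auc_pr)
    }
    tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

    stage <- "compare"
    pw <- if (length(reports) > 1) pairwise_arm_tests(reports) else NULL
    cvi <- clinical_vs_image_tests(reports)

    manifest <- list(config = manifest_config(config),
                     seeds = list(master = config$seed,
                                  phantom = derive_seed(config$seed, "phantom"),
                                  arms = stats::setNames(
                                    lapply(config$arms, function(a)
                                      derive_seed(config$seed, "arm", a)),
                                    config$arms)),
                     software_version = as.character(utils::packageVersion("fuseseg")),
                     artifacts = list())
    res <- structure(list(table = tab, reports = reports, pairwise_p = pw,
                          clinical_vs_image_p = cvi,
                          cohort_summary = cohort$summary,
                          manifest = manifest),
                     class = "experiment_result")
    if (!is.null(config$out_dir)) res <- write_experiment_outputs(res, config)
    res
  }, error = function(e) {
    stopf("run_experiment failed at stage '%s': %s", stage, conditionMessage(e))
  })
  result
}

## Per-family paired t-tests between the clinical and image-only arms,
## mirroring the headline comparison of fused vs image-only networks.
clinical_vs_image_tests <- function(reports) {
  fams <- c(EF = "EF_IMG", IF = "IF_IMG", LF = "LF_IMG")
  out <- c()
  for (f in names(fams)) {
    if (!is.null(reports[[f]]) && !is.null(reports[[fams[f]]])) {
      out[f] <- tryCatch(
        as.numeric(paired_t_test(reports[[f]]$per_patient$dsc,
                                 reports[[fams[f]]]$per_patient$dsc)),
        error = function(e) NA_real_)
    }
  }
  out
}

manifest_config <- function(config) {
  cfg <- unclass(config)
  cfg$train <- unclass(cfg$train)
  cfg
}

write_experiment_outputs <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(summary = file.path(config$out_dir, "summary.csv"))
  write.csv(res$table, paths["summary"], row.names = FALSE)
  for (arm in names(res$reports)) {
    p1 <- file.path(config$out_dir, sprintf("per_patient_%s.csv", arm))
    write.csv(res$reports[[arm]]$per_patient, p1, row.names = FALSE)
    p2 <- file.path(config$out_dir, sprintf("pr_curve_%s.csv", arm))
    write.csv(res$reports[[arm]]$pr_curve, p2, row.names = FALSE)
    paths[paste0("per_patient_", arm)] <- p1
    paths[paste0("pr_curve_", arm)] <- p2
  }
  res$manifest$artifacts <- as.list(tools::md5sum(paths))
  jsonlite::write_json(res$manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  res
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>\n")
  print(x$table, digits = 3)
  if (length(x$clinical_vs_image_p)) {
    cat("clinical vs image-only paired t-tests (DSC):\n")
    print(round(x$clinical_vs_image_p, 3))
  }
  invisible(x)
}

#' Fusion-vs-singleton ordering study over several seeds
#'
#' Runs the desk-scale comparison (single-channel baselines vs the three
#' fusion families trained with clinical data) on fusion-advantage phantoms
#' for each seed, and summarizes per seed whether every fusion family's mean
#' test DSC exceeds every single-channel baseline's.
#'
#' @param seeds integer vector of master seeds.
#' @param n_train,n_test split sizes (default 12 / 4).
#' @param base_filters network width (default 2).
#' @param train a [train_config()] (desk preset default).
#' @param phantom phantom overrides; `fusion_advantage_mode = TRUE` default.
#' @return list with `per_seed` (data.frame seed x arm mean DSC),
#'   `ordering_holds` (logical per seed), `fraction` (share of seeds where
#'   the full ordering holds).
#' @export
compare_fusion_families <- function(seeds, n_train = 12, n_test = 4,
                                    base_filters = 2,
                                    train = train_config("desk"),
                                    phantom = list(fusion_advantage_mode = TRUE)) {
  arms <- c("T2W", "ADC", "HIGHB", "EF", "IF", "LF")
  per_seed <- list()
  holds <- logical(length(seeds))
  for (i in seq_along(seeds)) {
    cfg <- experiment_config(n_train = n_train, n_test = n_test, arms = arms,
                             phantom = phantom, train = train,
                             base_filters = base_filters, seed = seeds[i])
    res <- run_experiment(cfg)
    tab <- res$table
    per_seed[[i]] <- data.frame(seed = seeds[i], arm = tab$arm,
                                mean_dsc = tab$mean_dsc)
    singles <- tab$mean_dsc[tab$fusion == "-"]
    fused <- tab$mean_dsc[tab$fusion != "-"]
    holds[i] <- all(vapply(fused, function(d) all(d > singles), TRUE))
  }
  list(per_seed = do.call(rbind, per_seed), ordering_holds = holds,
       fraction = mean(holds))
}
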