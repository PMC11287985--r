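## Optimization protocol: Adam, soft-Dice + BCE loss, patch-based epochs,
## deterministic under a master seed, with a reduced "desk" preset that
## shrinks epochs / filters / grid but never the fusion topology.

#' Training configuration
#'
#' The `"paper"` preset carries the full-scale protocol (50 epochs, learning
#' rate 1e-5, batch size 4, 64x64x16 patches, 50 patches per image, Adam,
#' 70% axial rotation augmentation).  The `"desk"` preset is a reduced
#' protocol for CPU-scale experiments on small phantoms (16x16x8 patches, 8
#' patches per image, 8 epochs, learning rate 5e-3); it changes scale only,
#' never the fusion topology.
#'
#' @param scale_preset `"paper"` or `"desk"`.
#' @param ... any of `epochs`, `learning_rate`, `batch_size`,
#'   `patches_per_image`, `patch_size`, `rotation_probability`,
#'   `angle_range`, `center_policy`, `overlap`, `val_fraction`, `loss`,
#'   `optimizer`, `seed`, `threshold` to override the preset.
#' @return A `train_config` list.
#' @export
train_config <- function(scale_preset = c("paper", "desk"), ...) {
  scale_preset <- match.arg(scale_preset)
  base <- list(epochs = 50L, learning_rate = 1e-5, batch_size = 4L,
               patches_per_image = 50L, patch_size = c(64L, 64L, 16L),
               rotation_probability = 0.7, angle_range = c(0, 360),
               center_policy = "gaussian_center", overlap = 0.5,
               val_fraction = 0.1, loss = "dice_bce", optimizer = "adam",
               seed = 0L, threshold = 0.5, scale_preset = scale_preset)
  if (scale_preset == "desk") {
    base$epochs <- 30L
    base$learning_rate <- 5e-3
    base$batch_size <- 2L
    base$patches_per_image <- 8L
    base$patch_size <- c(16L, 16L, 8L)
    base$val_fraction <- 0
  }
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) stopf("train_config: unknown option(s) %s",
                         paste(bad, collapse = ", "))
  cfg <- modifyList(base, over)
  check_patch_divisible(cfg$patch_size)
  if (cfg$loss != "dice_bce") stopf("train_config: unknown loss '%s'", cfg$loss)
  if (cfg$optimizer != "adam") stopf("train_config: unknown optimizer '%s'", cfg$optimizer)
  structure(cfg, class = "train_config")
}

#' Assemble a training case
#'
#' A case bundles the (preprocessed) input volumes, the voxelwise label and
#' the clinical record of one patient.
#' @param vols [volume_set()] whose channels cover the model's inputs.
#' @param label [mask_volume()] lesion ground truth on the same grid.
#' @param clinical optional [clinical_record()].
#' @return a `train_case`.
#' @export
train_case <- function(vols, label, clinical = NULL) {
  if (!all(dim(vols$data)[-1] == dim(label$data)))
    stopf("train_case: label grid does not match volume grid")
  structure(list(vols = vols, label = label, clinical = clinical),
            class = "train_case")
}

#' Train a fusion network
#'
#' Runs the patch-based protocol: per epoch, `patches_per_image` patches are
#' sampled per training patient (Gaussian-around-center policy), rotation
#' augmentation is applied, and Adam updates are taken on mini-batches under
#' the soft-Dice + BCE loss.  Fully deterministic under
#' `(cohort, config, config$seed)`.  For family `"LF"` this dispatches to
#' [train_lf_members()].
#'
#' @param spec a `network_spec`.
#' @param cohort list of [train_case()].
#' @param config a [train_config()].
#' @param clinical_ref named reference vector for clinical scaling (see
#'   [clinical_reference()]); stored on the model for prediction.
#' @return A `trained_model` with `spec`, `params`, `training_log`
#'   (data.frame epoch / loss / val_loss), `seed`, `config`.
#' @export
train <- function(spec, cohort, config = train_config(), clinical_ref = NULL) {
  if (length(cohort) == 0) stopf("train: empty cohort")
  if (spec$family == "LF")
    return(train_lf_members(spec, cohort, config, clinical_ref))
  split <- split_cohort(cohort, config)
  params <- init_params(spec, derive_seed(config$seed, "init", spec$family))
  model <- structure(list(spec = spec, params = params,
                          training_log = empty_log(), seed = config$seed,
                          config = config, clinical_ref = clinical_ref),
                     class = "trained_model")
  if (config$epochs == 0) return(model)
  state <- NULL
  t <- 0
  log <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    batches <- epoch_batches(split$train, spec, config, epoch, clinical_ref)
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      acc <- NULL
      bl <- 0
      for (s in batches[[bi]]) {
        fb <- model_fwd_bwd(params, spec, s)
        bl <- bl + fb$loss
        acc <- grads_add(acc, fb$grads)
      }
      nb <- length(batches[[bi]])
      bl <- bl / nb
      if (!is.finite(bl))
        stopf("train(%s): loss diverged (non-finite) at epoch %d", spec$family, epoch)
      t <- t + 1
      st <- adam_step(params, grads_scale(acc, 1 / nb), state,
                      config$learning_rate, t)
      params <- st$p
      state <- st$s
      losses[bi] <- bl
    }
    val_loss <- validation_loss(params, spec, split$val, config, clinical_ref)
    log[[epoch]] <- data.frame(epoch = epoch, loss = mean(losses),
                               val_loss = val_loss)
  }
  model$params <- params
  model$training_log <- do.call(rbind, log)
  model
}

empty_log <- function() data.frame(epoch = integer(), loss = numeric(),
                                   val_loss = numeric())

split_cohort <- function(cohort, config) {
  n <- length(cohort)
  n_val <- floor(n * config$val_fraction)
  if (n_val == 0 || n - n_val < 1) return(list(train = cohort, val = list()))
  idx <- with_seed(derive_seed(config$seed, "split"), sample.int(n))
  list(train = cohort[idx[seq_len(n - n_val)]],
       val = cohort[idx[(n - n_val + 1):n]])
}

## Samples (data, label, clin) grouped into shuffled mini-batches for one epoch.
epoch_batches <- function(cases, spec, config, epoch, clinical_ref) {
  samples <- list()
  for (ci in seq_along(cases)) {
    case <- cases[[ci]]
    vols <- reorder_channels(case$vols, spec$channel_names)
    patches <- sample_patches(vols, case$label, config$patches_per_image,
                              config$patch_size,
                              seed = derive_seed(config$seed, "patch", epoch, ci),
                              center_policy = config$center_policy)
    for (pi in seq_along(patches)) {
      p <- augment_rotation(patches[[pi]], config$rotation_probability,
                            config$angle_range,
                            seed = derive_seed(config$seed, "rot", epoch, ci, pi))
      samples[[length(samples) + 1]] <-
        list(data = p$data, label = p$label,
             clin = case_clin(spec, case, clinical_ref))
    }
  }
  ord <- with_seed(derive_seed(config$seed, "shuffle", epoch),
                   sample.int(length(samples)))
  samples <- samples[ord]
  split(samples, ceiling(seq_along(samples) / config$batch_size))
}

case_clin <- function(spec, case, clinical_ref) {
  if (spec$family == "IF" && isTRUE(spec$clinical)) {
    if (is.null(case$clinical)) stopf("train: IF with clinical head needs clinical records")
    v <- clinical_vector(case$clinical)
    ref <- clinical_ref %||% rep(1, 4)
    unname(v / ref[names(clinical_vector(case$clinical))])
  } else NULL
}

model_fwd_bwd <- function(params, spec, s) {
  if (spec$family %in% c("UNET", "EF")) {
    fw <- unet_fwd_full(params, s$data)
    ls <- seg_loss(fw$p, array(s$label, dim(fw$p)))
    bw <- unet_bwd_full(params, fw$cache, ls$glogit)
    list(loss = ls$loss, grads = bw$grads)
  } else if (spec$family == "IF") {
    fw <- if_fwd_full(params, s$data, s$clin)
    ls <- seg_loss(fw$p, array(s$label, dim(fw$p)))
    gr <- if_bwd_full(params, fw$cache, ls$glogit)
    list(loss = ls$loss, grads = gr)
  } else stopf("model_fwd_bwd: unsupported family %s", spec$family)
}

validation_loss <- function(params, spec, val_cases, config, clinical_ref) {
  if (length(val_cases) == 0) return(NA_real_)
  tot <- 0; n <- 0
  for (ci in seq_along(val_cases)) {
    case <- val_cases[[ci]]
    vols <- reorder_channels(case$vols, spec$channel_names)
    patches <- sample_patches(vols, case$label,
                              max(1L, config$patches_per_image %/% 2L),
                              config$patch_size,
                              seed = derive_seed(config$seed, "valpatch", ci))
    clin <- case_clin(spec, case, clinical_ref)
    for (p in patches) {
      pm <- forward_patch(params, spec, p$data, clin)
      tot <- tot + seg_loss(pm, array(p$label, dim(pm)))$loss
      n <- n + 1
    }
  }
  tot / n
}

#' Train the members of a late-fusion ensemble
#'
#' The three single-channel U-Nets and (when the spec has a clinical head)
#' the clinical MLP are trained independently: member seeds are distinct
#' deterministic functions of the master seed, and no member's loss
#' references another member.  A member failure is recorded on the ensemble
#' (with the member name) without discarding completed members.
#'
#' @param spec an LF `network_spec` from [build_lf()].
#' @param cohort list of [train_case()].
#' @param config a [train_config()].
#' @param clinical_ref reference vector for clinical scaling.
#' @return A `trained_ensemble` with named `members` (per-modality
#'   `trained_model`s plus `"CLINICAL"` MLP member when enabled),
#'   `aggregation = "mean"`, and a manifest of member seeds.
#' @export
train_lf_members <- function(spec, cohort, config = train_config(),
                             clinical_ref = NULL) {
  members <- list()
  failures <- list()
  for (i in seq_along(spec$members)) {
    mn <- names(spec$members)[i]
    mcfg <- config
    mcfg$seed <- derive_seed(config$seed, "member", i)
    res <- tryCatch(train(spec$members[[i]], cohort, mcfg, clinical_ref),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[mn]] <- conditionMessage(res)
      warning(sprintf("LF member %s failed: %s", mn, conditionMessage(res)))
    } else members[[mn]] <- res
  }
  if (isTRUE(spec$clinical)) {
    mcfg <- config
    mcfg$seed <- derive_seed(config$seed, "member", length(spec$members) + 1)
    res <- tryCatch(train_mlp_member(spec$mlp_widths, cohort, mcfg, clinical_ref),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[["CLINICAL"]] <- conditionMessage(res)
      warning(sprintf("LF member CLINICAL failed: %s", conditionMessage(res)))
    } else members[["CLINICAL"]] <- res
  }
  structure(list(spec = spec, members = members, aggregation = "mean",
                 failures = failures, seed = config$seed, config = config,
                 clinical_ref = clinical_ref,
                 member_seeds = vapply(seq_along(members), function(i)
                   members[[i]]$seed %||% NA_integer_, 0L)),
            class = "trained_ensemble")
}

## The scalar LF member: an MLP mapping scaled clinical covariates to one
## patient-level lesion-probability score (probability that the patient
## carries a csPCa lesion), trained under BCE.  The score is broadcast to a
## constant voxel map before mean aggregation.
train_mlp_member <- function(mlp_widths, cohort, config, clinical_ref = NULL) {
  widths <- c(mlp_widths[1:2], 1L)
  params <- with_seed(derive_seed(config$seed, "init", "mlp"),
                      mlp_init(widths, 4L))
  ref <- clinical_ref %||% rep(1, 4)
  xs <- lapply(cohort, function(case) {
    if (is.null(case$clinical)) stopf("LF clinical member needs clinical records")
    unname(clinical_vector(case$clinical) / ref)
  })
  ys <- vapply(cohort, function(case)
    as.numeric(case$clinical$gtv > 0), 0)
  state <- NULL; t <- 0
  log <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    tot <- 0
    for (i in seq_along(xs)) {
      fw <- mlp_fwd(params, xs[[i]], final = "sigmoid")
      p <- min(max(fw$out, 1e-7), 1 - 1e-7)
      tot <- tot - (ys[i] * log(p) + (1 - ys[i]) * log(1 - p))
      bw <- mlp_bwd(params, fw$caches, fw$out - ys[i], final = "sigmoid",
                    grad_is_logit = TRUE)
      t <- t + 1
      st <- adam_step(params, bw$grads, state, config$learning_rate, t)
      params <- st$p; state <- st$s
    }
    log[[epoch]] <- data.frame(epoch = epoch, loss = tot / length(xs),
                               val_loss = NA_real_)
  }
  structure(list(params = params, widths = widths,
                 training_log = do.call(rbind, log),
                 seed = config$seed, config = config, clinical_ref = ref),
            class = c("trained_mlp_member"))
}
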