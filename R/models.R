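## Fusion network families: baseline 3D U-Net, early fusion (EF, channels
## concatenated at the input), intermediate fusion (IF, per-modality encoder
## heads + clinical MLP merged at the bottleneck), late fusion (LF,
## independent per-modality U-Nets + clinical MLP, mean-aggregated).
## All families share the encoder/decoder depth (3 + 3), instance norm,
## ReLU, zero padding, a sigmoid single-class output, and the same patch
## geometry (spatial dims divisible by 2^3).

#' Build a baseline patch-based 3D U-Net specification
#'
#' Three encoder blocks, three decoder blocks with skip connections between
#' matching levels, filter widths doubling per level from `base_filters`,
#' 2x2x2 max pooling, nearest-neighbor upsampling, sigmoid voxelwise output.
#'
#' @param in_channels number of input channels (>= 1).
#' @param base_filters filters of the first level (doubled per level).
#' @param convs_per_block convolutions per encoder/decoder block (default 2).
#' @param channel_names expected input channel names (optional; defaults to
#'   the first `in_channels` canonical names).
#' @param patch_size optional; if given, validated to be divisible by
#'   `2^3 = 8` per axis (three pooling stages).
#' @return A `network_spec`.
#' @export
build_baseline_unet <- function(in_channels, base_filters = 8,
                                convs_per_block = 2, channel_names = NULL,
                                patch_size = NULL) {
  if (in_channels < 1) stopf("build_baseline_unet: in_channels must be >= 1")
  check_patch_divisible(patch_size)
  if (is.null(channel_names))
    channel_names <- CANONICAL_IMAGE_CHANNELS[seq_len(min(in_channels, 3))]
  structure(list(family = "UNET", fusion_point = "none",
                 in_channels = as.integer(in_channels),
                 base_filters = as.integer(base_filters),
                 convs_per_block = as.integer(convs_per_block),
                 encoder_depth = 3L, decoder_depth = 3L,
                 clinical = FALSE, mlp_widths = NULL,
                 channel_names = channel_names,
                 norm = "instance", activation = "relu", padding = "zero",
                 out = "sigmoid_1class"),
            class = "network_spec")
}

#' Build an early-fusion (input-level) network specification
#'
#' A baseline U-Net whose input stacks the three mpMRI channels and, when
#' `clinical = TRUE`, the four broadcast clinical channels (7 channels total,
#' mpMRI as channels 1-3 and clinical as channels 4-7).
#'
#' @inheritParams build_baseline_unet
#' @param clinical include the broadcast clinical channels (default TRUE).
#' @return A `network_spec` with family `"EF"`.
#' @export
build_ef <- function(base_filters = 8, clinical = TRUE, convs_per_block = 2,
                     patch_size = NULL) {
  ch <- c(CANONICAL_IMAGE_CHANNELS,
          if (clinical) CANONICAL_CLINICAL_CHANNELS)
  spec <- build_baseline_unet(length(ch), base_filters, convs_per_block,
                              channel_names = ch, patch_size = patch_size)
  spec$family <- "EF"
  spec$fusion_point <- "input"
  spec$clinical <- isTRUE(clinical)
  spec
}

#' Build an intermediate-fusion (feature-level) network specification
#'
#' Three independent single-channel encoder heads (3 blocks each, one per
#' mpMRI channel) plus, when `clinical = TRUE`, a shallow MLP with three
#' fully connected layers on the clinical covariates.  Per-level features of
#' the three heads are concatenated into the shared decoder's skip paths;
#' the pooled head features and the MLP feature vector (broadcast over the
#' bottleneck grid) are concatenated at the bottleneck, followed by one
#' shared 3-block decoder.
#'
#' @inheritParams build_ef
#' @param mlp_widths integer length-3, widths of the clinical MLP layers;
#'   the last width is the fused feature-vector size.
#' @return A `network_spec` with family `"IF"`.
#' @export
build_if <- function(base_filters = 8, mlp_widths = c(16, 16, 8),
                     clinical = TRUE, convs_per_block = 2, patch_size = NULL) {
  if (length(mlp_widths) != 3) stopf("build_if: mlp_widths must have 3 entries")
  check_patch_divisible(patch_size)
  structure(list(family = "IF", fusion_point = "bottleneck",
                 in_channels = 3L, base_filters = as.integer(base_filters),
                 convs_per_block = as.integer(convs_per_block),
                 encoder_depth = 3L, decoder_depth = 3L,
                 clinical = isTRUE(clinical),
                 mlp_widths = if (clinical) as.integer(mlp_widths),
                 channel_names = CANONICAL_IMAGE_CHANNELS,
                 norm = "instance", activation = "relu", padding = "zero",
                 out = "sigmoid_1class"),
            class = "network_spec")
}

#' Build a late-fusion (decision-level) ensemble specification
#'
#' Three independent single-channel baseline U-Nets (one per mpMRI channel)
#' and, when `clinical = TRUE`, an MLP member mapping the clinical covariates
#' to a single lesion-probability scalar (broadcast to a constant voxel map).
#' The final prediction is the arithmetic mean of the members' probability
#' outputs.
#'
#' @inheritParams build_if
#' @return A `network_spec` with family `"LF"` carrying one member spec per
#'   modality and `aggregation = "mean"`.
#' @export
build_lf <- function(base_filters = 8, mlp_widths = c(16, 16, 8),
                     clinical = TRUE, convs_per_block = 2, patch_size = NULL) {
  members <- lapply(CANONICAL_IMAGE_CHANNELS, function(ch)
    build_baseline_unet(1L, base_filters, convs_per_block,
                        channel_names = ch, patch_size = patch_size))
  names(members) <- CANONICAL_IMAGE_CHANNELS
  structure(list(family = "LF", fusion_point = "decision",
                 in_channels = 3L, base_filters = as.integer(base_filters),
                 convs_per_block = as.integer(convs_per_block),
                 encoder_depth = 3L, decoder_depth = 3L,
                 clinical = isTRUE(clinical),
                 mlp_widths = if (clinical) as.integer(mlp_widths),
                 channel_names = CANONICAL_IMAGE_CHANNELS,
                 members = members, aggregation = "mean",
                 norm = "instance", activation = "relu", padding = "zero",
                 out = "sigmoid_1class"),
            class = "network_spec")
}

check_patch_divisible <- function(patch_size) {
  if (!is.null(patch_size) && any(patch_size %% 8 != 0))
    stopf("patch size (%s) must be divisible by 2^3 = 8 per axis (three pooling stages)",
          paste(patch_size, collapse = "x"))
  invisible(TRUE)
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec %s> in=%d ch, base_filters=%d, clinical=%s\n",
              x$family, x$in_channels, x$base_filters, x$clinical))
  invisible(x)
}

## Parameter initialization ----------------------------------------------------

unet_filter_plan <- function(base, skip_mult = 1L) {
  f <- base * c(1L, 2L, 4L)
  list(enc = f, bott = base * 8L, skip = f * skip_mult)
}

unet_params_init <- function(in_channels, base, n_convs) {
  fp <- unet_filter_plan(base)
  enc <- list(stack_init(in_channels, fp$enc[1], n_convs),
              stack_init(fp$enc[1], fp$enc[2], n_convs),
              stack_init(fp$enc[2], fp$enc[3], n_convs))
  bott <- stack_init(fp$enc[3], fp$bott, n_convs)
  dec <- list(stack_init(fp$enc[2] + fp$skip[1], fp$enc[1], n_convs),
              stack_init(fp$enc[3] + fp$skip[2], fp$enc[2], n_convs),
              stack_init(fp$bott + fp$skip[3], fp$enc[3], n_convs))
  out <- list(W = he_conv(1, fp$enc[1], 1), b = 0)
  list(enc = enc, bott = bott, dec = dec, out = out)
}

if_params_init <- function(base, n_convs, mlp_widths) {
  fp <- unet_filter_plan(base, skip_mult = 3L)
  head_init <- function() list(stack_init(1L, fp$enc[1], n_convs),
                               stack_init(fp$enc[1], fp$enc[2], n_convs),
                               stack_init(fp$enc[2], fp$enc[3], n_convs))
  mlp_w <- if (!is.null(mlp_widths)) mlp_widths[3] else 0L
  p <- list(heads = list(head_init(), head_init(), head_init()),
            bott = stack_init(3L * fp$enc[3] + mlp_w, fp$bott, n_convs),
            dec = list(stack_init(fp$enc[2] + fp$skip[1], fp$enc[1], n_convs),
                       stack_init(fp$enc[3] + fp$skip[2], fp$enc[2], n_convs),
                       stack_init(fp$bott + fp$skip[3], fp$enc[3], n_convs)),
            out = list(W = he_conv(1, fp$enc[1], 1), b = 0))
  if (!is.null(mlp_widths)) p$mlp <- mlp_init(mlp_widths, 4L)
  p
}

#' Initialize network parameters for a specification
#' @param spec a `network_spec` (not LF; LF members are initialized per
#'   member by the trainer).
#' @param seed integer.
#' @return nested list of parameter arrays.
#' @export
init_params <- function(spec, seed = 0) {
  with_seed(seed, switch(spec$family,
    UNET = , EF = unet_params_init(spec$in_channels, spec$base_filters,
                                   spec$convs_per_block),
    IF = if_params_init(spec$base_filters, spec$convs_per_block,
                        spec$mlp_widths),
    LF = stopf("init_params: LF is an ensemble; initialize its members"),
    stopf("init_params: unknown family '%s'", spec$family)))
}

## Forward/backward ------------------------------------------------------------

unet_fwd_full <- function(params, x) {
  skips <- enc_caches <- pools <- vector("list", 3)
  h <- x
  for (l in 1:3) {
    r <- stack_fwd(params$enc[[l]], h)
    skips[[l]] <- r$out; enc_caches[[l]] <- r$caches
    pl <- maxpool3d_fwd_cpp(r$out)
    pools[[l]] <- list(argmax = pl$argmax, in_dim = dim(r$out))
    h <- pl$out
  }
  rb <- stack_fwd(params$bott, h)
  h <- rb$out
  dec_caches <- cc_sizes <- vector("list", 3)
  for (l in 3:1) {
    u <- up_fwd(h)
    cc <- concat_ch(u, skips[[l]])
    cc_sizes[[l]] <- c(dim(u)[1], dim(skips[[l]])[1])
    rd <- stack_fwd(params$dec[[l]], cc)
    dec_caches[[l]] <- rd$caches
    h <- rd$out
  }
  logits <- conv3d_fwd_cpp(h, params$out$W, params$out$b)
  list(p = sigmoid(logits), logits = logits,
       cache = list(enc = enc_caches, pools = pools, bott = rb$caches,
                    dec = dec_caches, cc_sizes = cc_sizes, last = h))
}

unet_bwd_full <- function(params, cache, glogit) {
  co <- conv3d_bwd_cpp(cache$last, params$out$W, glogit)
  out_g <- list(W = co$gw, b = co$gb)
  g <- co$gx
  gskip <- dec_g <- vector("list", 3)
  for (l in 1:3) {  # decoder ran at levels 3,2,1; reverse order is 1,2,3
    r <- stack_bwd(params$dec[[l]], cache$dec[[l]], g)
    dec_g[[l]] <- r$grads
    sp <- split_ch(r$gx, cache$cc_sizes[[l]])
    gskip[[l]] <- sp[[2]]
    g <- up_bwd(sp[[1]])
  }
  r <- stack_bwd(params$bott, cache$bott, g)
  bott_g <- r$grads
  g <- r$gx
  enc_g <- vector("list", 3)
  for (l in 3:1) {
    g <- maxpool3d_bwd_cpp(g, cache$pools[[l]]$argmax, cache$pools[[l]]$in_dim)
    g <- g + gskip[[l]]
    r <- stack_bwd(params$enc[[l]], cache$enc[[l]], g)
    enc_g[[l]] <- r$grads
    g <- r$gx
  }
  list(gx = g, grads = list(enc = enc_g, bott = bott_g, dec = dec_g,
                            out = out_g))
}

if_fwd_full <- function(params, x, clin = NULL) {
  nheads <- length(params$heads)
  skips <- enc_caches <- pools <- vector("list", nheads)
  pooled <- vector("list", nheads)
  for (hd in seq_len(nheads)) {
    h <- x[hd, , , , drop = FALSE]
    skips[[hd]] <- enc_caches[[hd]] <- pools[[hd]] <- vector("list", 3)
    for (l in 1:3) {
      r <- stack_fwd(params$heads[[hd]][[l]], h)
      skips[[hd]][[l]] <- r$out; enc_caches[[hd]][[l]] <- r$caches
      pl <- maxpool3d_fwd_cpp(r$out)
      pools[[hd]][[l]] <- list(argmax = pl$argmax, in_dim = dim(r$out))
      h <- pl$out
    }
    pooled[[hd]] <- h
  }
  bdim <- dim(pooled[[1]])
  parts <- pooled
  mlp_cache <- NULL
  if (!is.null(params$mlp)) {
    if (is.null(clin)) stopf("IF forward: clinical vector required")
    mr <- mlp_fwd(params$mlp, clin, final = "relu")
    mlp_cache <- mr$caches
    feat <- array(rep(mr$out, prod(bdim[-1])),
                  dim = c(length(mr$out), bdim[-1]))
    parts <- c(parts, list(feat))
  }
  bin <- do.call(concat_ch, parts)
  bin_sizes <- vapply(parts, function(p) dim(p)[1], 0L)
  rb <- stack_fwd(params$bott, bin)
  h <- rb$out
  dec_caches <- cc_sizes <- vector("list", 3)
  for (l in 3:1) {
    u <- up_fwd(h)
    skip_l <- do.call(concat_ch, lapply(skips, `[[`, l))
    cc <- concat_ch(u, skip_l)
    cc_sizes[[l]] <- c(dim(u)[1], rep(dim(skips[[1]][[l]])[1], nheads))
    rd <- stack_fwd(params$dec[[l]], cc)
    dec_caches[[l]] <- rd$caches
    h <- rd$out
  }
  logits <- conv3d_fwd_cpp(h, params$out$W, params$out$b)
  list(p = sigmoid(logits), logits = logits,
       cache = list(enc = enc_caches, pools = pools, bott = rb$caches,
                    dec = dec_caches, cc_sizes = cc_sizes, last = h,
                    bin = bin, bin_sizes = bin_sizes, mlp = mlp_cache,
                    clin = clin))
}

if_bwd_full <- function(params, cache, glogit) {
  nheads <- length(params$heads)
  co <- conv3d_bwd_cpp(cache$last, params$out$W, glogit)
  out_g <- list(W = co$gw, b = co$gb)
  g <- co$gx
  gskip <- dec_g <- vector("list", 3)
  for (l in 1:3) {
    r <- stack_bwd(params$dec[[l]], cache$dec[[l]], g)
    dec_g[[l]] <- r$grads
    sp <- split_ch(r$gx, cache$cc_sizes[[l]])
    gskip[[l]] <- sp[-1]           # one chunk per head
    g <- up_bwd(sp[[1]])
  }
  r <- stack_bwd(params$bott, cache$bott, g)
  bott_g <- r$grads
  bsp <- split_ch(r$gx, cache$bin_sizes)
  heads_g <- vector("list", nheads)
  gskip_by_l <- vector("list", 3)
  ## note: gskip[[l]] was overwritten each level loop iteration above; keep
  ## per-level copies indexed [level][head]
  ## (gskip is assigned inside the loop; collect now)
  for (hd in seq_len(nheads)) {
    g <- bsp[[hd]]
    heads_g[[hd]] <- vector("list", 3)
    for (l in 3:1) {
      g <- maxpool3d_bwd_cpp(g, cache$pools[[hd]][[l]]$argmax,
                             cache$pools[[hd]][[l]]$in_dim)
      g <- g + dec_skip_grad(gskip, l, hd)
      r <- stack_bwd(params$heads[[hd]][[l]], cache$enc[[hd]][[l]], g)
      heads_g[[hd]][[l]] <- r$grads
      g <- r$gx
    }
  }
  grads <- list(heads = heads_g, bott = bott_g, dec = dec_g, out = out_g)
  if (!is.null(params$mlp)) {
    gfeat_map <- bsp[[nheads + 1]]
    gfeat <- rowSums(matrix(gfeat_map, nrow = dim(gfeat_map)[1]))
    mr <- mlp_bwd(params$mlp, cache$mlp, gfeat, final = "relu")
    grads$mlp <- mr$grads
  }
  grads
}

dec_skip_grad <- function(gskip, l, hd) gskip[[l]][[hd]]

## One-patch forward probability for any non-ensemble family.
forward_patch <- function(params, spec, patch_data, clin = NULL) {
  if (spec$family %in% c("UNET", "EF")) unet_fwd_full(params, patch_data)$p
  else if (spec$family == "IF") if_fwd_full(params, patch_data, clin)$p
  else stopf("forward_patch: unsupported family %s", spec$family)
}

## Prediction ------------------------------------------------------------------

#' Predict a voxelwise lesion-probability map for a patient volume
#'
#' Channels are canonicalized to the model's expected `channel_names` (so
#' prediction is invariant to channel storage order), the volume is tiled by
#' sliding-window patches at the configured overlap, each patch is forwarded,
#' and overlapping predictions are averaged back onto the full grid.
#'
#' @param object a `trained_model` (or `trained_ensemble` for LF).
#' @param vols a [volume_set()] with at least the expected channels.
#' @param clinical optional [clinical_record()] (required by IF/LF models
#'   with a clinical head).
#' @param ... unused.
#' @return 3D probability map in `[0, 1]` on the grid of `vols`.
#' @export
predict.trained_model <- function(object, vols, clinical = NULL, ...) {
  spec <- object$spec
  vols <- reorder_channels(vols, spec$channel_names)
  ps <- object$config$patch_size
  shape <- dim(vols$data)[-1]
  clin <- model_clinical_input(object, clinical)
  cents <- tile_centers(shape, ps, object$config$overlap %||% 0.5)
  patches <- lapply(seq_len(ncol(cents)), function(i) {
    cen <- cents[, i]
    start <- cen - floor(ps / 2)
    sl <- lapply(1:3, function(ax) start[ax]:(start[ax] + ps[ax] - 1))
    pd <- vols$data[, sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
    pm <- forward_patch(object$params, spec, pd, clin)
    list(map = array(pm, dim(pm)[-1]), center = cen)
  })
  reassemble(patches, shape)
}

model_clinical_input <- function(object, clinical) {
  if (is.null(object$spec$mlp_widths) && object$spec$family != "EF")
    return(NULL)
  if (object$spec$family %in% c("IF") && object$spec$clinical) {
    if (is.null(clinical)) stopf("predict: model has a clinical head but no clinical record was given")
    v <- clinical_vector(clinical)
    ref <- object$clinical_ref %||% rep(1, 4)
    unname(v / ref[names(v)])
  } else NULL
}

#' @rdname predict.trained_model
#' @export
predict.trained_ensemble <- function(object, vols, clinical = NULL, ...) {
  maps <- member_predictions(object, vols, clinical)
  Reduce(`+`, maps) / length(maps)
}

#' Per-member probability maps of a late-fusion ensemble
#' @param object a `trained_ensemble`.
#' @param vols a [volume_set()].
#' @param clinical optional [clinical_record()].
#' @return named list of 3D probability maps (one per member; the clinical
#'   MLP member is a spatially constant map).
#' @export
member_predictions <- function(object, vols, clinical = NULL) {
  maps <- lapply(object$members, function(m) {
    if (inherits(m, "trained_mlp_member")) {
      if (is.null(clinical)) stopf("LF ensemble: clinical record required for the MLP member")
      v <- clinical_vector(clinical)
      ref <- m$clinical_ref %||% rep(1, 4)
      p <- mlp_fwd(m$params, unname(v / ref[names(v)]), final = "sigmoid")$out
      array(p, dim(vols$data)[-1])
    } else {
      predict.trained_model(m, vols, clinical)
    }
  })
  names(maps) <- names(object$members)
  maps
}

#' Save / load a trained model
#'
#' The checkpoint is a self-describing container (spec + weights + seed +
#' training log); a reloaded model predicts bit-identically.
#' @param model a `trained_model` or `trained_ensemble`.
#' @param path file path.
#' @return `load_model` returns the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
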