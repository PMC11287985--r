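## Preprocessing: voxelwise mono-exponential ADC fitting, synthetic high
## b-value computation, FOV cropping, intensity normalization, and clinical
## scalar broadcasting for early fusion.

ADC_CLAMP_MAX <- 4e-3   # mm2/s; physiological upper bound for fitted ADC
SIGNAL_EPS <- 1e-6      # signals clamped here before the log transform

#' Voxelwise mono-exponential diffusion fit
#'
#' Fits `log(S) = log(S0) - b * ADC` by least squares at every voxel over the
#' provided b-values (the standard model behind PI-RADS synthetic b-value
#' computation).  Signals are clamped at a small epsilon before the log;
#' fitted ADC is clamped to `[0, 4e-3]` mm2/s and S0 is the (positive)
#' exponentiated intercept.  A b = 0 acquisition is not required: S0 is the
#' extrapolated intercept.
#'
#' @param dwi_series 4D array `(n_b, X, Y, Z)`.
#' @param b_values numeric vector of b-values (s/mm2), length `n_b`, at least
#'   2 distinct values.
#' @return A `dwi_fit`: list with 3D maps `s0`, `adc`, `fit_residual`
#'   (root-mean-square log-domain residual of the stored, clamped fit).
#' @export
fit_adc <- function(dwi_series, b_values) {
  d <- dim(dwi_series)
  if (length(d) != 4) stopf("fit_adc: dwi_series must be 4D (b, X, Y, Z)")
  if (d[1] != length(b_values))
    stopf("fit_adc: %d volumes but %d b-values", d[1], length(b_values))
  if (length(unique(b_values)) < 2)
    stopf("fit_adc: need >= 2 distinct b-values")
  shape <- d[-1]
  Y <- log(pmax(matrix(dwi_series, nrow = d[1]), SIGNAL_EPS))
  b <- as.numeric(b_values)
  bc <- b - mean(b)
  slope <- colSums(Y * bc) / sum(bc^2)
  intercept <- colMeans(Y) - slope * mean(b)
  adc <- pmin(pmax(-slope, 0), ADC_CLAMP_MAX)
  s0 <- exp(intercept)
  fitted <- outer(b, -adc) + rep(intercept, each = d[1])
  resid <- sqrt(colMeans((Y - fitted)^2))
  structure(list(s0 = array(s0, shape), adc = array(adc, shape),
                 fit_residual = array(resid, shape), b_values = b),
            class = "dwi_fit")
}

#' Synthesize a high b-value image from a diffusion fit
#'
#' Evaluates `S0 * exp(-b_target * ADC)` voxelwise, the mono-exponential
#' extrapolation used to compute synthetic b = 1400 s/mm2 images.
#'
#' @param fit a [fit_adc()] result (or any list with `s0` and `adc` maps).
#' @param b_target target b-value in s/mm2 (default 1400).
#' @return 3D array of synthesized signal.
#' @export
synthesize_high_b <- function(fit, b_target = 1400) {
  if (is.null(fit$s0) || is.null(fit$adc)) stopf("synthesize_high_b: invalid fit")
  if (!is.finite(b_target) || b_target < 0)
    stopf("synthesize_high_b: b_target must be a non-negative number")
  fit$s0 * exp(-b_target * fit$adc)
}

#' Crop a volume set (and masks) to the gland field of view
#'
#' Returns the gland bounding box dilated by `margin_mm` (converted to voxels
#' per axis, rounded up) and clipped to the original grid.  Voxel values are
#' unchanged; only the extent shrinks.  The crop box is recorded (0-based,
#' half-open intervals per axis) so predictions can be mapped back with
#' [uncrop_prediction()].
#'
#' @param vols a [volume_set()].
#' @param gland_mask a [mask_volume()] on the same grid; must be nonempty.
#' @param margin_mm margin in millimetres (default 10).
#' @param extra_masks optional named list of further masks to crop alongside.
#' @return list with `volumes`, `gland_mask`, `extra_masks`, `crop_box`
#'   (list of `start` 0-based inclusive, `end` exclusive, `full_shape`).
#' @export
crop_to_fov <- function(vols, gland_mask, margin_mm = 10, extra_masks = list()) {
  shape <- dim(vols$data)[-1]
  if (!all(dim(gland_mask$data) == shape))
    stopf("crop_to_fov: mask grid %s does not match volume grid %s",
          paste(dim(gland_mask$data), collapse = "x"),
          paste(shape, collapse = "x"))
  if (sum(gland_mask$data) == 0) stopf("crop_to_fov: gland mask is empty")
  idx <- which(gland_mask$data == 1, arr.ind = TRUE)
  marg <- ceiling(margin_mm / vols$spacing)
  start <- pmax(apply(idx, 2, min) - marg, 1)
  end <- pmin(apply(idx, 2, max) + marg, shape)
  box <- list(start = as.integer(start - 1), end = as.integer(end),
              full_shape = as.integer(shape))
  sl <- lapply(1:3, function(ax) (box$start[ax] + 1):box$end[ax])
  crop3 <- function(a) a[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
  cd <- vols$data[, sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
  new_origin <- vols$origin + box$start * vols$spacing
  list(volumes = volume_set(cd, vols$channel_names, vols$spacing, new_origin),
       gland_mask = mask_volume(crop3(gland_mask$data), vols$spacing,
                                new_origin, gland_mask$label),
       extra_masks = lapply(extra_masks, function(m)
         mask_volume(crop3(m$data), vols$spacing, new_origin, m$label)),
       crop_box = box)
}

#' Map a cropped-grid 3D map back onto the original grid
#' @param map3d 3D array on the cropped grid.
#' @param crop_box the `crop_box` returned by [crop_to_fov()].
#' @param fill value outside the crop (default 0).
#' @return 3D array with `crop_box$full_shape` dims.
#' @export
uncrop_prediction <- function(map3d, crop_box, fill = 0) {
  out <- array(fill, dim = crop_box$full_shape)
  sl <- lapply(1:3, function(ax) (crop_box$start[ax] + 1):crop_box$end[ax])
  if (!all(dim(map3d) == lengths(sl)))
    stopf("uncrop_prediction: map dims %s do not match crop box %s",
          paste(dim(map3d), collapse = "x"), paste(lengths(sl), collapse = "x"))
  out[sl[[1]], sl[[2]], sl[[3]]] <- map3d
  out
}

#' Per-channel intensity normalization
#'
#' Policies: `zscore_within_mask` (mean 0, sd 1 over the mask voxels, applied
#' to the whole channel; with no mask, statistics use all voxels),
#' `minmax` (maps to `[0,1]`), `none` (identity).  Zero-variance channels
#' under z-score are left centered at 0; constant channels under minmax
#' become all zeros.  The transform parameters are recorded in the
#' `normalization` attribute for provenance.
#'
#' @param vols a [volume_set()].
#' @param policy one of `"zscore_within_mask"`, `"minmax"`, `"none"`.
#' @param mask optional [mask_volume()] restricting the statistics.
#' @return normalized [volume_set()].
#' @export
normalize_channels <- function(vols,
                               policy = c("zscore_within_mask", "minmax", "none"),
                               mask = NULL) {
  policy <- match.arg(policy)
  if (policy == "none") return(vols)
  data <- vols$data
  sel <- if (!is.null(mask)) mask$data == 1 else TRUE
  log_ <- list()
  for (i in seq_len(dim(data)[1])) {
    ch <- array(data[i, , , ], dim(data)[-1])
    v <- if (isTRUE(sel[1]) && length(sel) == 1) as.vector(ch) else ch[sel]
    if (policy == "zscore_within_mask") {
      m <- mean(v); s <- stats::sd(v)
      data[i, , , ] <- if (is.na(s) || s < 1e-12) ch - m else (ch - m) / s
      log_[[vols$channel_names[i]]] <- list(policy = policy, mean = m, sd = s)
    } else {
      lo <- min(v); hi <- max(v)
      data[i, , , ] <- if (hi - lo < 1e-12) array(0, dim(ch))
                       else (ch - lo) / (hi - lo)
      log_[[vols$channel_names[i]]] <- list(policy = policy, min = lo, max = hi)
    }
  }
  out <- volume_set(data, vols$channel_names, vols$spacing, vols$origin)
  attr(out, "normalization") <- log_
  out
}

#' Cohort-level clinical reference values for channel scaling
#'
#' Returns the per-covariate maximum over a (training) cohort, the default
#' reference by which clinical scalars are divided before being broadcast as
#' image channels, so that clinical and normalized image channels share a
#' dynamic range.
#' @param records list of [clinical_record()] (or `phantom_patient`s).
#' @return named numeric vector over `PSA, PSAD, GLAND_VOL, GTV`.
#' @export
clinical_reference <- function(records) {
  vecs <- vapply(records, function(r) {
    if (inherits(r, "phantom_patient")) r <- r$clinical
    clinical_vector(r)
  }, numeric(4))
  apply(vecs, 1, max)
}

#' Broadcast clinical scalars to image-shaped channels (early fusion)
#'
#' Appends four spatially constant channels (PSA, PSAD, GLAND_VOL, GTV) after
#' the image channels, giving the canonical 7-channel early-fusion input.
#' Each scalar is divided by its `reference` value before broadcasting
#' (identity scaling by default).
#'
#' @param record a [clinical_record()].
#' @param vols [volume_set()] with the image channels (canonically T2W, ADC,
#'   HIGHB).
#' @param reference named numeric vector over `PSA, PSAD, GLAND_VOL, GTV`,
#'   e.g. from [clinical_reference()]; `NULL` means identity scaling.
#' @return [volume_set()] with `ncol + 4` channels in canonical order.
#' @export
broadcast_clinical <- function(record, vols, reference = NULL) {
  for (f in c("psa", "psad", "gland_volume", "gtv")) {
    if (is.null(record[[f]]) || !is.finite(record[[f]]))
      stopf("broadcast_clinical: missing clinical covariate '%s'", f)
  }
  vals <- clinical_vector(record)
  if (!is.null(reference)) {
    if (!all(names(vals) %in% names(reference)))
      stopf("broadcast_clinical: reference must cover %s",
            paste(names(vals), collapse = ", "))
    vals <- vals / reference[names(vals)]
  }
  shape <- dim(vols$data)[-1]
  nc <- dim(vols$data)[1]
  data <- array(0, dim = c(nc + 4, shape))
  data[seq_len(nc), , , ] <- vols$data
  for (i in 1:4) data[nc + i, , , ] <- vals[i]
  volume_set(data, c(vols$channel_names, CANONICAL_CLINICAL_CHANNELS),
             vols$spacing, vols$origin)
}
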