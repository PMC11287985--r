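## Core data containers: multi-channel volumes, binary masks, clinical records.

CANONICAL_IMAGE_CHANNELS <- c("T2W", "ADC", "HIGHB")
CANONICAL_CLINICAL_CHANNELS <- c("PSA", "PSAD", "GLAND_VOL", "GTV")

#' Multi-channel co-registered 3D volume
#'
#' Stores image data in channel-first layout (`channels x X x Y x Z`) together
#' with voxel spacing and origin in millimetres.  All channels share one grid.
#' Canonical channel order is T2W, ADC, HIGHB, then broadcast clinical
#' channels (PSA, PSAD, GLAND_VOL, GTV).
#'
#' @param data 4D numeric array `(channels, X, Y, Z)`, or a 3D array for a
#'   single channel.
#' @param channel_names character vector, one unique name per channel.
#' @param spacing numeric length-3, voxel spacing in mm per axis (X, Y, Z).
#' @param origin numeric length-3, position of voxel (1,1,1) in mm.
#' @return A `volume_set` object.
#' @export
volume_set <- function(data, channel_names, spacing = c(1, 1, 1),
                       origin = c(0, 0, 0)) {
  if (length(dim(data)) == 3) {
    data <- array(data, dim = c(1, dim(data)))
  }
  if (length(dim(data)) != 4) stopf("volume_set: data must be a 3D or 4D array")
  if (length(channel_names) != dim(data)[1])
    stopf("volume_set: %d channel names for %d channels",
          length(channel_names), dim(data)[1])
  if (anyDuplicated(channel_names)) stopf("volume_set: duplicate channel names")
  if (length(spacing) != 3 || any(spacing <= 0))
    stopf("volume_set: spacing must be 3 positive numbers")
  structure(list(data = data, channel_names = as.character(channel_names),
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "volume_set")
}

#' @export
print.volume_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_set> %d channel(s) [%s], grid %dx%dx%d, spacing %s mm\n",
              d[1], paste(x$channel_names, collapse = ","), d[2], d[3], d[4],
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' Extract one channel of a volume set as a 3D array
#' @param vols a `volume_set`.
#' @param name channel name.
#' @return 3D numeric array.
#' @export
get_channel <- function(vols, name) {
  i <- match(name, vols$channel_names)
  if (is.na(i)) stopf("channel '%s' not found (have: %s)", name,
                      paste(vols$channel_names, collapse = ", "))
  array(vols$data[i, , , ], dim = dim(vols$data)[-1])
}

#' Reorder channels of a volume set into a requested order
#'
#' Used to canonicalize inputs before prediction, so results do not depend on
#' the storage order of the channels.
#' @param vols a `volume_set`.
#' @param names channel names in the desired order; must all be present.
#' @return A `volume_set` with channels reordered.
#' @export
reorder_channels <- function(vols, names) {
  i <- match(names, vols$channel_names)
  if (anyNA(names) || anyNA(i))
    stopf("reorder_channels: expected channels [%s] but found [%s]",
          paste(names, collapse = ","), paste(vols$channel_names, collapse = ","))
  volume_set(vols$data[i, , , , drop = FALSE], names, vols$spacing, vols$origin)
}

#' Binary 3D mask on the same grid conventions as [volume_set()]
#'
#' @param data 3D array of 0/1 (logical or numeric).
#' @param spacing,origin grid geometry in mm.
#' @param label free-text label ("gland", "lesion", ...).
#' @return A `mask_volume` object.
#' @export
mask_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        label = "mask") {
  if (length(dim(data)) != 3) stopf("mask_volume: data must be a 3D array")
  v <- unique(as.vector(data))
  if (!all(v %in% c(0, 1, TRUE, FALSE)))
    stopf("mask_volume: mask is not binary (values beyond {0,1} found)")
  structure(list(data = array(as.numeric(data), dim = dim(data)),
                 spacing = as.numeric(spacing), origin = as.numeric(origin),
                 label = label),
            class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("<mask_volume:%s> grid %s, %d foreground voxel(s)\n", x$label,
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

#' Voxel volume of a grid in millilitres
#' @param spacing voxel spacing in mm.
#' @return scalar, mL per voxel.
#' @export
voxel_volume_ml <- function(spacing) prod(spacing) / 1000

#' Scalar clinical covariates for one patient
#'
#' PSA in ng/mL, PSA density (PSAD) in ng/mL/mL, prostate gland volume and
#' gross tumor volume (GTV) in mL.  PSAD is PSA divided by gland volume;
#' [clinical_record()] verifies the identity rather than recomputing it, so
#' external tables with inconsistent values are caught at the boundary.
#'
#' @param patient_id character id.
#' @param psa PSA (ng/mL), positive.
#' @param psad PSA density (ng/mL/mL).
#' @param gland_volume prostate gland volume (mL), positive.
#' @param gtv gross tumor (lesion) volume (mL), non-negative.
#' @param check_identity verify `psad == psa / gland_volume` to 1e-3 relative.
#' @return A `clinical_record` object.
#' @export
clinical_record <- function(patient_id, psa, psad, gland_volume, gtv,
                            check_identity = TRUE) {
  vals <- c(psa = psa, psad = psad, gland_volume = gland_volume, gtv = gtv)
  for (nm in names(vals)) {
    if (!is.finite(vals[[nm]])) stopf("clinical_record: '%s' is not finite", nm)
  }
  if (psa <= 0) stopf("clinical_record: PSA must be positive (got %g)", psa)
  if (gland_volume <= 0) stopf("clinical_record: gland volume must be positive")
  if (gtv < 0) stopf("clinical_record: GTV must be non-negative")
  if (check_identity && abs(psad - psa / gland_volume) >
        1e-3 * max(1, abs(psad)))
    warning(sprintf("clinical_record %s: PSAD %.4g inconsistent with PSA/volume %.4g",
                    patient_id, psad, psa / gland_volume))
  structure(list(patient_id = as.character(patient_id), psa = psa, psad = psad,
                 gland_volume = gland_volume, gtv = gtv),
            class = "clinical_record")
}

#' @export
print.clinical_record <- function(x, ...) {
  cat(sprintf("<clinical_record %s> PSA %.2f ng/mL, PSAD %.3f, gland %.1f mL, GTV %.2f mL\n",
              x$patient_id, x$psa, x$psad, x$gland_volume, x$gtv))
  invisible(x)
}

#' Clinical covariates as a named numeric vector (canonical channel order)
#' @param record a `clinical_record`.
#' @return named numeric vector `PSA, PSAD, GLAND_VOL, GTV`.
#' @export
clinical_vector <- function(record) {
  c(PSA = record$psa, PSAD = record$psad, GLAND_VOL = record$gland_volume,
    GTV = record$gtv)
}
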