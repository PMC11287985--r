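## NIfTI and CSV I/O.  Volumes and masks travel as (gzipped) NIfTI files;
## DWI stacks as 4D NIfTI with a JSON b-value sidecar; clinical data as CSV
## with header patient_id,psa,psad,gland_volume_ml,gtv_ml.

#' Write a 3D volume (or 4D stack) to NIfTI
#'
#' @param data 3D array, or 4D array in `(X, Y, Z, T)` order.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing voxel spacing in mm.
#' @param origin position of the first voxel in mm.
#' @return the path, invisibly.
#' @export
write_volume <- function(data, path, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  nd <- length(dim(data))
  attr(data, "pixdim") <- c(spacing, rep(1, nd - 3))
  img <- RNifti::asNifti(data, datatype = "double")
  RNifti::sform(img) <- structure(aff, code = 2L)
  tryCatch(RNifti::writeNifti(img, path),
           error = function(e) stopf("write_volume: failed writing '%s': %s",
                                     path, conditionMessage(e)))
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI file (possibly gzipped).
#' @param as_mask validate the voxel values as binary \{0, 1\}.
#' @return list with `data` (array), `spacing` (mm), `origin` (mm).
#' @export
read_volume <- function(path, as_mask = FALSE) {
  if (!file.exists(path)) stopf("read_volume: file not found: %s", path)
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim(img))
  spacing <- as.numeric(RNifti::pixdim(img)[1:3])
  origin <- as.numeric(RNifti::xform(img)[1:3, 4])
  if (as_mask) {
    if (!all(unique(as.vector(data)) %in% c(0, 1)))
      stopf("read_volume: '%s' read as mask but is not binary", path)
  }
  list(data = data, spacing = spacing, origin = origin)
}

#' Export one phantom patient to a directory
#'
#' Writes one NIfTI per image channel and mask, a 4D NIfTI DWI stack with a
#' JSON b-value sidecar, and a one-row clinical CSV.  The layout round-trips
#' losslessly through [import_patient()].
#'
#' @param patient a `phantom_patient`.
#' @param directory output directory (created if missing).
#' @return named character vector of the written paths.
#' @export
export_patient <- function(patient, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("export_patient: cannot create directory '%s'", directory)
  }
  sp <- patient$volumes$spacing
  orig <- patient$volumes$origin
  paths <- c()
  for (ch in patient$volumes$channel_names) {
    p <- file.path(directory, sprintf("%s.nii.gz", tolower(ch)))
    write_volume(get_channel(patient$volumes, ch), p, sp, orig)
    paths[tolower(ch)] <- p
  }
  for (mk in c("gland_mask", "lesion_mask")) {
    p <- file.path(directory, sprintf("%s.nii.gz", mk))
    write_volume(patient[[mk]]$data, p, sp, orig)
    paths[mk] <- p
  }
  ## DWI: stored internally as (b, X, Y, Z); NIfTI wants the series last
  dwi4 <- aperm(patient$dwi_series, c(2, 3, 4, 1))
  paths["dwi"] <- file.path(directory, "dwi.nii.gz")
  write_volume(dwi4, paths[["dwi"]], sp, orig)
  paths["dwi_sidecar"] <- file.path(directory, "dwi_bvalues.json")
  jsonlite::write_json(list(b_values = patient$b_values),
                       paths[["dwi_sidecar"]], digits = NA)
  paths["clinical"] <- file.path(directory, "clinical.csv")
  write_clinical(list(patient$clinical), paths[["clinical"]])
  paths
}

#' Import a patient exported by [export_patient()]
#' @param directory directory holding the exported files.
#' @return list with `volumes`, `dwi_series` (b-values first), `b_values`,
#'   `gland_mask`, `lesion_mask`, `clinical`, `patient_id`.
#' @export
import_patient <- function(directory) {
  chs <- CANONICAL_IMAGE_CHANNELS
  vols <- lapply(chs, function(ch)
    read_volume(file.path(directory, sprintf("%s.nii.gz", tolower(ch)))))
  sp <- vols[[1]]$spacing
  orig <- vols[[1]]$origin
  data <- abind_ch(stats::setNames(lapply(vols, `[[`, "data"), chs))
  gm <- read_volume(file.path(directory, "gland_mask.nii.gz"), as_mask = TRUE)
  lm <- read_volume(file.path(directory, "lesion_mask.nii.gz"), as_mask = TRUE)
  dwi <- read_volume(file.path(directory, "dwi.nii.gz"))
  side <- jsonlite::read_json(file.path(directory, "dwi_bvalues.json"),
                              simplifyVector = TRUE)
  clin <- read_clinical(file.path(directory, "clinical.csv"))
  list(volumes = volume_set(data, chs, sp, orig),
       dwi_series = aperm(dwi$data, c(4, 1, 2, 3)),
       b_values = as.numeric(side$b_values),
       gland_mask = mask_volume(gm$data, sp, orig, "gland"),
       lesion_mask = mask_volume(lm$data, sp, orig, "lesion"),
       clinical = clin[[1]], patient_id = clin[[1]]$patient_id)
}

CLINICAL_HEADER <- c("patient_id", "psa", "psad", "gland_volume_ml", "gtv_ml")

#' Write clinical records to CSV
#' @param records list of [clinical_record()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_clinical <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r)
    data.frame(patient_id = r$patient_id, psa = r$psa, psad = r$psad,
               gland_volume_ml = r$gland_volume, gtv_ml = r$gtv)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a clinical CSV into typed records
#'
#' Expects the header `patient_id,psa,psad,gland_volume_ml,gtv_ml` (units
#' ng/mL for PSA, mL for volumes).  Missing columns and non-numeric cells
#' are rejected naming the offending row and column; negative PSA is
#' rejected; a PSAD inconsistent with PSA / gland volume (1e-3 relative)
#' raises a warning.
#'
#' @param path CSV file path.
#' @return list of [clinical_record()] (empty, with a warning, for an empty
#'   file).
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stopf("read_clinical: file not found: %s", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stopf("read_clinical: cannot parse '%s': %s",
                                           path, conditionMessage(e)))
  missing_cols <- setdiff(CLINICAL_HEADER, names(df))
  if (length(missing_cols))
    stopf("read_clinical: missing column(s) %s", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) {
    warning(sprintf("read_clinical: '%s' has no rows", path))
    return(list())
  }
  lapply(seq_len(nrow(df)), function(i) {
    for (col in CLINICAL_HEADER[-1]) {
      v <- suppressWarnings(as.numeric(df[[col]][i]))
      if (is.na(v))
        stopf("read_clinical: row %d, column '%s': non-numeric value '%s'",
              i, col, df[[col]][i])
    }
    clinical_record(df$patient_id[i], psa = as.numeric(df$psa[i]),
                    psad = as.numeric(df$psad[i]),
                    gland_volume = as.numeric(df$gland_volume_ml[i]),
                    gtv = as.numeric(df$gtv_ml[i]))
  })
}
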