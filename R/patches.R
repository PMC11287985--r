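## Patch extraction, axial rotation augmentation, and sliding-window
## probability-map reassembly.

#' Sample training patches from a volume
#'
#' Centers are drawn per axis from a Gaussian centered on the image center
#' with sd = 1/4 of the axis extent (the `"gaussian_center"` policy), rounded
#' to voxels and clipped so the patch stays inside the (padded) volume; the
#' `"uniform"` policy draws centers uniformly over the valid range.  Volumes
#' smaller than the patch are padded symmetrically (channel minimum for image
#' data, 0 for the label).  Deterministic under `seed`.
#'
#' @param vols a [volume_set()].
#' @param label a [mask_volume()] on the same grid.
#' @param n_patches number of patches (default 50).
#' @param patch_size integer length-3 (default `c(64, 64, 16)`).
#' @param seed non-negative integer.
#' @param center_policy `"gaussian_center"` (default) or `"uniform"`.
#' @return list of `patch_sample`: `data` (channels x patch), `label`,
#'   `source_patient`, `center_index` (1-based voxel triple on the padded
#'   grid), `applied_rotation_deg` (NA until augmented).
#' @export
sample_patches <- function(vols, label, n_patches = 50,
                           patch_size = c(64, 64, 16), seed = 0,
                           center_policy = c("gaussian_center", "uniform")) {
  center_policy <- match.arg(center_policy)
  if (seed < 0) stopf("sample_patches: seed must be >= 0")
  ps <- as.integer(patch_size)
  padded <- pad_to_patch(vols, label, ps)
  shape <- dim(padded$data)[-1]
  if (any(shape < ps))
    stopf("sample_patches: patch %s larger than padded volume %s",
          paste(ps, collapse = "x"), paste(shape, collapse = "x"))
  lo <- floor(ps / 2) + 1L
  hi <- shape - ceiling(ps / 2) + 1L
  with_seed(seed, {
    centers <- vapply(seq_len(n_patches), function(i) {
      vapply(1:3, function(ax) {
        c0 <- if (center_policy == "gaussian_center")
          round((shape[ax] + 1) / 2 + rnorm(1, 0, shape[ax] / 4))
        else round(runif(1, lo[ax], hi[ax]))
        min(max(c0, lo[ax]), hi[ax])
      }, 0)
    }, numeric(3))
  })
  lapply(seq_len(n_patches), function(i) {
    cen <- centers[, i]
    start <- cen - lo + 1L
    sl <- lapply(1:3, function(ax) start[ax]:(start[ax] + ps[ax] - 1L))
    structure(list(
      data = padded$data[, sl[[1]], sl[[2]], sl[[3]], drop = FALSE],
      label = padded$label[sl[[1]], sl[[2]], sl[[3]], drop = FALSE],
      source_patient = attr(vols, "patient_id") %||% "unknown",
      center_index = as.integer(cen),
      applied_rotation_deg = NA_real_), class = "patch_sample")
  })
}

pad_to_patch <- function(vols, label, ps) {
  shape <- dim(vols$data)[-1]
  if (all(shape >= ps))
    return(list(data = vols$data, label = label$data))
  pad <- pmax(ps - shape, 0)
  lo <- floor(pad / 2)
  new <- shape + pad
  nc <- dim(vols$data)[1]
  data <- array(0, dim = c(nc, new))
  for (i in seq_len(nc)) data[i, , , ] <- min(vols$data[i, , , ])
  lab <- array(0, dim = new)
  sl <- lapply(1:3, function(ax) (lo[ax] + 1):(lo[ax] + shape[ax]))
  data[, sl[[1]], sl[[2]], sl[[3]]] <- vols$data
  lab[sl[[1]], sl[[2]], sl[[3]]] <- label$data
  list(data = data, label = lab)
}

#' Randomly rotate a patch in the axial plane
#'
#' With the stated probability, every axial (X-Y) slice of the patch and its
#' label is rotated by one shared angle drawn uniformly from `angle_range`.
#' Image channels use bilinear interpolation with out-of-bounds fill at the
#' channel minimum; the label uses nearest-neighbor so it stays binary.
#'
#' @param patch a `patch_sample`.
#' @param probability chance of applying a rotation (default 0.7).
#' @param angle_range degrees, default `c(0, 360)`.
#' @param seed integer.
#' @return the (possibly rotated) `patch_sample`, with
#'   `applied_rotation_deg` recorded.
#' @export
augment_rotation <- function(patch, probability = 0.7,
                             angle_range = c(0, 360), seed = 0) {
  if (probability < 0 || probability > 1)
    stopf("augment_rotation: probability must be in [0,1]")
  with_seed(seed, {
    if (runif(1) >= probability) return(patch)
    theta <- runif(1, angle_range[1], angle_range[2])
    patch$data <- rotate_channels_axial(patch$data, theta, "linear")
    patch$label <- round(rotate_stack_axial(patch$label, theta, "nearest",
                                            fill = 0))
    patch$applied_rotation_deg <- theta
    patch
  })
}

rotate_channels_axial <- function(data4, theta, interp) {
  for (i in seq_len(dim(data4)[1])) {
    ch <- array(data4[i, , , ], dim(data4)[-1])
    data4[i, , , ] <- rotate_stack_axial(ch, theta, interp, fill = min(ch))
  }
  data4
}

## Rotate every X-Y slice of a 3D array about the slice center.
rotate_stack_axial <- function(arr, theta_deg, interp = c("linear", "nearest"),
                               fill = 0) {
  interp <- match.arg(interp)
  d <- dim(arr)
  nx <- d[1]; ny <- d[2]
  t <- -theta_deg * pi / 180  # inverse map: output -> source
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  xo <- rep(seq_len(nx) - cx, times = ny)
  yo <- rep(seq_len(ny) - cy, each = nx)
  sx <- cos(t) * xo - sin(t) * yo + cx
  sy <- sin(t) * xo + cos(t) * yo + cy
  out <- array(fill, dim = d)
  if (interp == "nearest") {
    ix <- round(sx); iy <- round(sy)
    ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
    lin <- ix[ok] + (iy[ok] - 1) * nx
    for (z in seq_len(d[3])) {
      sl <- array(fill, c(nx, ny))
      sl[ok] <- arr[, , z][lin]
      out[, , z] <- sl
    }
  } else {
    ok <- sx >= 1 - 1e-9 & sx <= nx + 1e-9 & sy >= 1 - 1e-9 & sy <= ny + 1e-9
    x0 <- pmin(pmax(floor(sx), 1), nx - 1)
    y0 <- pmin(pmax(floor(sy), 1), ny - 1)
    fx <- sx - x0; fy <- sy - y0
    l00 <- x0[ok] + (y0[ok] - 1) * nx
    w00 <- (1 - fx[ok]) * (1 - fy[ok]); w10 <- fx[ok] * (1 - fy[ok])
    w01 <- (1 - fx[ok]) * fy[ok];       w11 <- fx[ok] * fy[ok]
    for (z in seq_len(d[3])) {
      slc <- arr[, , z]
      sl <- array(fill, c(nx, ny))
      sl[ok] <- w00 * slc[l00] + w10 * slc[l00 + 1] +
                w01 * slc[l00 + nx] + w11 * slc[l00 + nx + 1]
      out[, , z] <- sl
    }
  }
  out
}

#' Sliding-window tile centers for inference
#'
#' Tiles a volume with patches at the given overlap fraction; the final
#' position per axis is clamped so the whole volume is covered.
#' @param vol_shape integer length-3.
#' @param patch_size integer length-3.
#' @param overlap fraction in `[0, 1)` (default 0.5).
#' @return matrix (3 x n_tiles) of 1-based center indices.
#' @export
tile_centers <- function(vol_shape, patch_size, overlap = 0.5) {
  ps <- as.integer(patch_size)
  if (any(vol_shape < ps))
    stopf("tile_centers: volume %s smaller than patch %s",
          paste(vol_shape, collapse = "x"), paste(ps, collapse = "x"))
  stride <- pmax(1L, as.integer(round(ps * (1 - overlap))))
  starts <- lapply(1:3, function(ax) {
    s <- unique(c(seq(1L, vol_shape[ax] - ps[ax] + 1L, by = stride[ax]),
                  vol_shape[ax] - ps[ax] + 1L))
    s
  })
  grid <- as.matrix(expand.grid(starts[[1]], starts[[2]], starts[[3]]))
  t(grid + matrix(floor(ps / 2), nrow(grid), 3, byrow = TRUE))
}

#' Reassemble a full probability map from patch predictions
#'
#' Uniform-average sliding-window accumulation: overlapping voxels are
#' averaged.  Every voxel of `out_shape` must be covered by at least one
#' patch.
#'
#' @param prob_patches list of `list(map = 3D array, center = voxel triple)`
#'   with 1-based centers as produced by [tile_centers()]/[sample_patches()].
#' @param out_shape integer length-3.
#' @return 3D array in `[0, 1]` (if patch maps are probabilities).
#' @export
reassemble <- function(prob_patches, out_shape) {
  acc <- array(0, dim = out_shape)
  cnt <- array(0, dim = out_shape)
  for (p in prob_patches) {
    ps <- dim(p$map)
    start <- p$center - floor(ps / 2)
    if (any(start < 1) || any(start + ps - 1 > out_shape))
      stopf("reassemble: patch at center (%s) exceeds output grid",
            paste(p$center, collapse = ","))
    sl <- lapply(1:3, function(ax) start[ax]:(start[ax] + ps[ax] - 1))
    acc[sl[[1]], sl[[2]], sl[[3]]] <- acc[sl[[1]], sl[[2]], sl[[3]]] + p$map
    cnt[sl[[1]], sl[[2]], sl[[3]]] <- cnt[sl[[1]], sl[[2]], sl[[3]]] + 1
  }
  if (any(cnt == 0)) {
    miss <- which(cnt == 0, arr.ind = TRUE)
    stopf("reassemble: %d voxel(s) uncovered (first at %s)", nrow(miss),
          paste(miss[1, ], collapse = ","))
  }
  acc / cnt
}
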