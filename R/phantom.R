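## Synthetic mpMRI phantom cohorts: ellipsoidal gland, spherical lesions,
## mono-exponential diffusion signal, lognormal clinical covariates.

#' Specification of a synthetic phantom cohort
#'
#' Defines the geometry, signal model, noise and clinical-covariate
#' distributions of a simulated prostate mpMRI cohort.  Defaults target the
#' cohort statistics the analysis assumes: PSA median 8.8 ng/mL (range
#' 2.1-66), gland volume median 40.8 mL (range 10.8-167.7), DWI b-values
#' (0, 100, 400, 800) s/mm2, restricted diffusion in the lesion
#' (ADC 0.8e-3 vs 1.5e-3 mm2/s in gland tissue).
#'
#' When `fusion_advantage = TRUE` the three image channels are replaced by a
#' construction in which lesion evidence is split across channels and masked
#' per channel by shared smooth confounder fields with opposite signs: no
#' single channel separates lesion from gland well at the voxel level, but a
#' linear combination of the channels does.  This makes the benefit of
#' multi-channel fusion a testable property of the simulator.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_spacing mm per axis.
#' @param n_patients cohort size.
#' @param lesion_count_range integer interval, lesions per patient.
#' @param lesion_radius_range mm interval for lesion radii.
#' @param channel_contrast named list/vector of lesion-vs-gland signal ratios
#'   for directly simulated channels (only `t2w` is used; ADC contrast is set
#'   by `adc_lesion`/`adc_gland`, and the high-b contrast follows from the
#'   diffusion model).
#' @param adc_gland,adc_lesion apparent diffusion coefficients in mm2/s;
#'   `adc_lesion < adc_gland` (restricted diffusion in tumor).
#' @param b_values DWI b-values in s/mm2 (>= 3 distinct, all >= 0).
#' @param noise_sigma Rician noise sigma in signal units for T2W and the DWI
#'   series (0 disables noise).
#' @param psa_lognormal_params `c(mu, sigma)` of log-PSA.
#' @param psa_range truncation interval for PSA draws (ng/mL).
#' @param gland_volume_lognormal_params `c(mu, sigma)` of log gland volume.
#' @param gland_volume_range truncation interval (mL).
#' @param fusion_advantage_mode logical, see Details.
#' @param advantage_delta lesion shift per channel (z-score units).
#' @param advantage_confounder_sd amplitude of the shared smooth confounder
#'   fields.  Channels stay individually weak (voxel AUC well below 0.7)
#'   while the channel combination cancels the confounders exactly; member
#'   errors of a decision-level ensemble are anticorrelated across channels.
#' @param advantage_noise_sd white (spatially independent) noise sd in the
#'   same units.
#' @param advantage_smooth_vox Gaussian smoothing sd (voxels) of the
#'   confounder fields; comparable to the lesion radius so the confounders
#'   cannot be removed by local spatial averaging.
#' @param seed master seed for the cohort.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(32, 32, 32),
                         voxel_spacing = c(3, 3, 3),
                         n_patients = 16,
                         lesion_count_range = c(1, 3),
                         lesion_radius_range = c(4, 9),
                         channel_contrast = c(t2w = 0.7),
                         adc_gland = 1.5e-3,
                         adc_lesion = 0.8e-3,
                         b_values = c(0, 100, 400, 800),
                         noise_sigma = 10,
                         psa_lognormal_params = c(mu = log(8.8), sigma = 0.65),
                         psa_range = c(2.1, 66),
                         gland_volume_lognormal_params = c(mu = log(40.8),
                                                           sigma = 0.5),
                         gland_volume_range = c(10.8, 167.7),
                         fusion_advantage_mode = FALSE,
                         advantage_delta = 0.35,
                         advantage_confounder_sd = 0.5,
                         advantage_noise_sd = 0.15,
                         advantage_smooth_vox = 4,
                         seed = 1L) {
  if (length(grid_shape) != 3 || any(grid_shape < 8))
    stopf("phantom_spec: grid_shape must be 3 integers >= 8")
  if (n_patients < 0) stopf("phantom_spec: n_patients must be >= 0")
  if (adc_lesion >= adc_gland)
    stopf("phantom_spec: adc_lesion must be < adc_gland (restricted diffusion)")
  if (any(b_values < 0) || length(unique(b_values)) < 3)
    stopf("phantom_spec: need >= 3 distinct non-negative b-values")
  if (diff(lesion_radius_range) < 0 || lesion_radius_range[1] <= 0)
    stopf("phantom_spec: bad lesion_radius_range")
  ## lesions must fit inside the smallest gland the spec can draw
  min_semi <- min(gland_semi_axes(gland_volume_range[1]))
  if (lesion_radius_range[2] >= min_semi)
    stopf("phantom_spec: max lesion radius %.1f mm does not fit inside the smallest gland (min semi-axis %.1f mm)",
          lesion_radius_range[2], min_semi)
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_spacing = as.numeric(voxel_spacing),
                 n_patients = as.integer(n_patients),
                 lesion_count_range = as.integer(lesion_count_range),
                 lesion_radius_range = as.numeric(lesion_radius_range),
                 channel_contrast = channel_contrast,
                 adc_gland = adc_gland, adc_lesion = adc_lesion,
                 b_values = as.numeric(b_values), noise_sigma = noise_sigma,
                 psa_lognormal_params = psa_lognormal_params,
                 psa_range = psa_range,
                 gland_volume_lognormal_params = gland_volume_lognormal_params,
                 gland_volume_range = gland_volume_range,
                 fusion_advantage_mode = isTRUE(fusion_advantage_mode),
                 advantage_delta = advantage_delta,
                 advantage_confounder_sd = advantage_confounder_sd,
                 advantage_noise_sd = advantage_noise_sd,
                 advantage_smooth_vox = advantage_smooth_vox,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

## Ellipsoid semi-axes (mm) for a gland of given volume (mL); fixed axis
## ratios 1 : 0.85 : 0.7 approximate the transverse-dominant prostate shape.
gland_semi_axes <- function(volume_ml) {
  r <- c(1, 0.85, 0.7)
  s <- (3 * volume_ml * 1000 / (4 * pi * prod(r)))^(1 / 3)
  s * r
}

## Truncated lognormal draw by rejection (bounds are a few sd out, so the
## acceptance rate is high).
rlnorm_trunc <- function(n, mu, sigma, range) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- exp(rnorm(n, mu, sigma))
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

## Zero-mean, unit-variance smooth Gaussian random field via separable
## Gaussian smoothing of white noise (empirically re-standardized).
smooth_field <- function(dims, sigma_vox) {
  a <- array(rnorm(prod(dims)), dim = dims)
  if (sigma_vox > 0) {
    half <- ceiling(3 * sigma_vox)
    k <- exp(-0.5 * ((-half:half) / sigma_vox)^2)
    for (ax in 1:3) {
      n <- dims[ax]
      K <- matrix(0, n, n)
      for (i in seq_len(n)) {
        j <- (i - half):(i + half)
        ok <- j >= 1 & j <= n
        K[i, j[ok]] <- k[ok] / sum(k[ok])
      }
      a <- apply_axis(a, ax, K)
    }
  }
  (a - mean(a)) / stats::sd(as.vector(a))
}

## Multiply a (n_ax x n_ax) matrix along one axis of a 3D array.
apply_axis <- function(a, axis, K) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- K %*% matrix(ap, nrow = d[axis])
  ap <- array(m, dim = d[perm])
  aperm(ap, order(perm))
}

## Voxel-center coordinates (mm) relative to the grid center, per axis.
grid_coords <- function(shape, spacing) {
  lapply(1:3, function(ax) {
    (seq_len(shape[ax]) - (shape[ax] + 1) / 2) * spacing[ax]
  })
}

rician <- function(signal, sigma) {
  if (sigma <= 0) return(signal)
  n <- length(signal)
  sqrt((signal + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
}

#' Generate one synthetic phantom patient
#'
#' Builds an ellipsoidal gland with a smooth boundary, 1..k spherical lesions
#' fully inside the gland, three co-registered image channels (T2W, ADC,
#' synthetic high b-value computed from the mono-exponential model at
#' b = 1400 s/mm2), the raw DWI series `S0 * exp(-b * ADC) + Rician noise`
#' for every b-value in the spec, and exact clinical covariates
#' (`PSAD = PSA / gland volume`; `GTV = lesion voxels x voxel volume`).
#' Identical `(spec$seed, patient_seed)` gives a bit-identical patient.
#'
#' @param spec a [phantom_spec()].
#' @param patient_seed non-negative integer, per-patient stream.
#' @return A `phantom_patient`: list with `volumes` (a [volume_set()] with
#'   channels T2W/ADC/HIGHB), `dwi_series` (4D array, b-values first), `s0`
#'   (3D array), `gland_mask`, `lesion_mask` ([mask_volume()]),
#'   `clinical` ([clinical_record()]), `patient_id`, `meta`.
#' @export
generate_patient <- function(spec, patient_seed) {
  if (patient_seed < 0) stopf("generate_patient: patient_seed must be >= 0")
  with_seed(derive_seed(spec$seed, "patient", patient_seed), {
    shape <- spec$grid_shape; sp <- spec$voxel_spacing
    co <- grid_coords(shape, sp)

    gland_vol <- rlnorm_trunc(1, spec$gland_volume_lognormal_params[1],
                              spec$gland_volume_lognormal_params[2],
                              spec$gland_volume_range)
    semi <- gland_semi_axes(gland_vol)
    ## small center jitter, keeping the gland inside the grid
    half_fov <- shape * sp / 2
    slack <- pmax(half_fov - semi, 0)
    center <- runif(3, -pmin(slack, sp), pmin(slack, sp))

    q <- ellipsoid_q(co, center, semi)
    gland <- q <= 1

    ## lesions: spheres whose continuous extent stays inside the ellipsoid
    n_les <- if (diff(spec$lesion_count_range) == 0) spec$lesion_count_range[1]
             else sample(spec$lesion_count_range[1]:spec$lesion_count_range[2], 1)
    lesion <- array(FALSE, dim = shape)
    lesion_params <- vector("list", n_les)
    for (l in seq_len(n_les)) {
      r <- runif(1, spec$lesion_radius_range[1],
                 min(spec$lesion_radius_range[2], 0.95 * min(semi)))
      placed <- FALSE
      for (try in 1:200) {
        cen <- center + runif(3, -semi, semi)
        ## sphere of radius r inside the ellipsoid: shrink semi-axes by r
        if (ellipsoid_q(list(cen[1], cen[2], cen[3]), center, semi - r)[1] <= 1) {
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stopf("generate_patient %d: could not place lesion %d (radius %.1f mm) inside the gland after 200 tries; spec is inconsistent",
              patient_seed, l, r)
      lesion_params[[l]] <- list(center = cen, radius = r)
      d2 <- outer(outer((co[[1]] - cen[1])^2, (co[[2]] - cen[2])^2, `+`),
                  (co[[3]] - cen[3])^2, `+`)
      lesion <- lesion | (d2 <= r^2)
    }
    lesion <- lesion & gland  # guaranteed by construction; enforce exactly

    ch <- phantom_channels(spec, q, lesion, shape)

    ## DWI series from the stored ADC and S0 maps (+ Rician noise)
    nb <- length(spec$b_values)
    dwi <- array(0, dim = c(nb, shape))
    for (i in seq_len(nb)) {
      s <- ch$s0 * exp(-spec$b_values[i] * ch$adc)
      dwi[i, , , ] <- array(rician(as.vector(s), spec$noise_sigma), dim = shape)
    }

    psa <- rlnorm_trunc(1, spec$psa_lognormal_params[1],
                        spec$psa_lognormal_params[2], spec$psa_range)
    gtv <- sum(lesion) * voxel_volume_ml(sp)
    pid <- sprintf("P%03d", patient_seed)
    clin <- clinical_record(pid, psa = psa, psad = psa / gland_vol,
                            gland_volume = gland_vol, gtv = gtv)

    vols <- volume_set(abind_ch(list(T2W = ch$t2w, ADC = ch$adc,
                                     HIGHB = ch$highb)),
                       CANONICAL_IMAGE_CHANNELS, sp)
    structure(list(volumes = vols, dwi_series = dwi,
                   b_values = spec$b_values, s0 = ch$s0,
                   gland_mask = mask_volume(gland, sp, label = "gland"),
                   lesion_mask = mask_volume(lesion, sp, label = "lesion"),
                   clinical = clin, patient_id = pid,
                   meta = list(age = round(runif(1, 48, 85)),
                               gleason = sample(c("6", "7a", "7b", "8", "9"), 1,
                                                prob = c(.15, .3, .3, .17, .08)),
                               gland_center = center, gland_semi_axes = semi,
                               lesions = lesion_params)),
              class = "phantom_patient")
  })
}

ellipsoid_q <- function(co, center, semi) {
  if (any(semi <= 0)) return(Inf)
  outer(outer(((co[[1]] - center[1]) / semi[1])^2,
              ((co[[2]] - center[2]) / semi[2])^2, `+`),
        ((co[[3]] - center[3]) / semi[3])^2, `+`)
}

## Stack named 3D arrays into a channel-first 4D array.
abind_ch <- function(chlist) {
  d <- dim(chlist[[1]])
  out <- array(0, dim = c(length(chlist), d))
  for (i in seq_along(chlist)) out[i, , , ] <- chlist[[i]]
  out
}

## Image channels for one patient.  Realistic mode: T2W bright gland with a
## mildly hypointense lesion; ADC channel stores the diffusion coefficient
## map; high-b channel is S0*exp(-1400*ADC).  Advantage mode: lesion evidence
## split across channels behind cancelling smooth confounders; S0 is defined
## as HIGHB*exp(+1400*ADC) so the diffusion identity holds exactly.
phantom_channels <- function(spec, q, lesion, shape) {
  b_target <- 1400
  if (!spec$fusion_advantage_mode) {
    inside <- stats::plogis((1 - q) / 0.08)  # smooth gland boundary
    t2w_clean <- 200 + 800 * inside
    contrast <- unname(spec$channel_contrast[["t2w"]])
    t2w_clean[lesion] <- t2w_clean[lesion] * contrast
    adc <- array(2.2e-3, dim = shape)
    adc[q <= 1] <- spec$adc_gland
    adc[lesion] <- spec$adc_lesion
    s0 <- 600 + 300 * inside
    highb <- s0 * exp(-b_target * adc)
    t2w <- array(rician(as.vector(t2w_clean), spec$noise_sigma), dim = shape)
    list(t2w = t2w, adc = adc, highb = highb, s0 = s0)
  } else {
    d <- spec$advantage_delta
    a <- spec$advantage_confounder_sd
    L <- as.numeric(lesion)
    f <- a * smooth_field(shape, spec$advantage_smooth_vox)
    g <- a * smooth_field(shape, spec$advantage_smooth_vox)
    eps <- function() array(rnorm(prod(shape), 0, spec$advantage_noise_sd),
                            dim = shape)
    z1 <- d * L + f + eps()
    z2 <- d * L - f - g + eps()
    z3 <- d * L + g + eps()
    t2w <- 1000 * (1 + 0.15 * z1)
    adc <- pmax(spec$adc_gland * (1 + 0.1 * z2), 1e-5)
    h0 <- 900 * exp(-b_target * spec$adc_gland)
    highb <- pmax(h0 * (1 + 0.15 * z3), 1e-3)
    s0 <- highb * exp(b_target * adc)  # makes HIGHB = S0*exp(-1400*ADC) exact
    list(t2w = t2w, adc = array(adc, dim = shape), highb = highb, s0 = s0)
  }
}

#' Generate a synthetic cohort
#'
#' Deterministic under `spec$seed`; patient `i` uses patient seed `i`.
#'
#' @param spec a [phantom_spec()].
#' @return list with `patients` (list of `phantom_patient`) and `summary`
#'   (cohort-level median/min/max of the clinical covariates).
#' @export
generate_cohort <- function(spec) {
  if (spec$n_patients < 1) stopf("generate_cohort: n_patients must be >= 1")
  patients <- vector("list", spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    patients[[i]] <- tryCatch(generate_patient(spec, i),
                              error = function(e)
                                stopf("generate_cohort: patient %d failed: %s",
                                      i, conditionMessage(e)))
  }
  list(patients = patients, summary = cohort_summary(patients))
}

#' Cohort summary table (median, min, max per covariate)
#' @param patients list of `phantom_patient`.
#' @return data.frame with one row per covariate.
#' @export
cohort_summary <- function(patients) {
  tab <- do.call(rbind, lapply(patients, function(p) {
    data.frame(patient_id = p$patient_id, age = p$meta$age, psa = p$clinical$psa,
               psad = p$clinical$psad, gland_volume_ml = p$clinical$gland_volume,
               gtv_ml = p$clinical$gtv)
  }))
  cov <- c("age", "psa", "psad", "gland_volume_ml", "gtv_ml")
  data.frame(covariate = cov,
             median = vapply(cov, function(v) median(tab[[v]]), 0),
             min = vapply(cov, function(v) min(tab[[v]]), 0),
             max = vapply(cov, function(v) max(tab[[v]]), 0),
             row.names = NULL)
}

#' Draw clinical covariates only (no volumes)
#'
#' Cheap path for studying the covariate distributions at large n (e.g.
#' convergence of cohort medians to the spec targets).
#' @param spec a [phantom_spec()].
#' @param n number of draws.
#' @param seed seed (default: derived from `spec$seed`).
#' @return data.frame with columns `psa`, `gland_volume_ml`, `psad`.
#' @export
sample_clinical_cohort <- function(spec, n, seed = NULL) {
  with_seed(seed %||% derive_seed(spec$seed, "clinical"), {
    psa <- rlnorm_trunc(n, spec$psa_lognormal_params[1],
                        spec$psa_lognormal_params[2], spec$psa_range)
    vol <- rlnorm_trunc(n, spec$gland_volume_lognormal_params[1],
                        spec$gland_volume_lognormal_params[2],
                        spec$gland_volume_range)
    data.frame(psa = psa, gland_volume_ml = vol, psad = psa / vol)
  })
}
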