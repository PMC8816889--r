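# Seeded synthetic FLAIR-like brain phantoms: an ellipsoidal skull-stripped
# "brain" with white-matter, cortical gray-matter and ventricular CSF
# compartments, hyperintense superellipsoid lesions of controllable in-plane
# area and sub-label substructure, optional radial mass-effect deformation,
# and Gaussian acquisition noise confined to the brain mask. Every other
# module of the package is testable on these phantoms without downloads.

#' Specify one synthetic lesion
#'
#' Lesions are superellipsoids: the maximal axial cross-section is a
#' superellipse whose pixel membership is chosen by ranking pixels on the
#' superellipse implicit value and keeping exactly the number needed for the
#' requested area, so the achieved in-plane area is within one pixel area of
#' the request. Away from the central slice the cross-section tapers with an
#' ellipsoidal profile. `contrast` gives one intensity multiplier per
#' concentric sub-label shell (innermost first); a multiplier of 1 produces
#' a lesion isointense with the surrounding slice on average.
#'
#' @param center_mm Physical center (mm, cell-centered coordinates).
#' @param area_cm2 Requested in-plane area (cm^2) of the maximal axial
#'   cross-section.
#' @param z_extent_slices Number of axial slices the lesion spans.
#' @param contrast Numeric vector of intensity multipliers, one per
#'   sub-label (length K >= 1), applied to the slice's non-lesional in-mask
#'   mean intensity.
#' @param exponent Superellipse exponent (2 = ellipse).
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center_mm, area_cm2, z_extent_slices = 3L,
                        contrast = 1.8, exponent = 2) {
  stopifnot(length(center_mm) == 3L, all(is.finite(center_mm)),
            length(area_cm2) == 1L, area_cm2 > 0,
            z_extent_slices >= 1L, length(contrast) >= 1L,
            all(contrast >= 0), exponent > 0)
  structure(list(center_mm = as.numeric(center_mm),
                 area_cm2 = as.numeric(area_cm2),
                 z_extent_slices = as.integer(z_extent_slices),
                 contrast = as.numeric(contrast),
                 exponent = exponent),
            class = "lesion_spec")
}

#' Specify a synthetic brain phantom
#'
#' @param grid_shape Voxels per axis (each >= 16).
#' @param spacing_mm Voxel edge lengths (mm), strictly positive.
#' @param tissue_means Named intensities for `background`, `wm`, `gm`,
#'   `csf` in arbitrary units (FLAIR-like defaults: CSF suppressed, gray
#'   matter slightly brighter than white matter). Intensities are rescaled
#'   so the within-brain mean is about 1 before noise, making lesion
#'   contrast multipliers and histogram-moment matching scale-free.
#' @param lesion_specs List of [lesion_spec()] objects (may be empty).
#' @param deform_amplitude_mm Radial mass-effect displacement (mm) applied
#'   around each lesion centroid; 0 disables deformation.
#' @param partial_volume_sigma_mm Gaussian smoothing (mm) applied to the
#'   composed tissue volume, emulating the partial-volume blurring of real
#'   acquisitions so tissue interfaces are not razor-sharp steps; 0
#'   disables.
#' @param noise_sd Standard deviation of the zero-mean Gaussian acquisition
#'   noise added within the brain mask. The default emulates a high-field
#'   FLAIR acquisition (tissue SNR of order 50-100); the low-field
#'   transform, not the phantom, is responsible for low-field noise.
#' @param seed Integer seed; identical specs produce bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 36),
                         spacing_mm = c(1, 1, 3),
                         tissue_means = c(background = 0, wm = 1, gm = 1.2,
                                          csf = 0.35),
                         lesion_specs = list(),
                         deform_amplitude_mm = 0,
                         partial_volume_sigma_mm = 0.6,
                         noise_sd = 0.005,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stop("grid_shape must have 3 axes with at least 16 voxels each")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be strictly positive")
  req <- c("background", "wm", "gm", "csf")
  if (!all(req %in% names(tissue_means)))
    stop("tissue_means must name background, wm, gm and csf")
  pix_area_cm2 <- spacing_mm[1] * spacing_mm[2] / 100
  for (i in seq_along(lesion_specs)) {
    ls <- lesion_specs[[i]]
    stopifnot(inherits(ls, "lesion_spec"))
    if (ls$area_cm2 < pix_area_cm2)
      stop(sprintf("lesion %d: requested area %.4g cm^2 is below one in-plane pixel area (%.4g cm^2)",
                   i, ls$area_cm2, pix_area_cm2))
  }
  stopifnot(deform_amplitude_mm >= 0, partial_volume_sigma_mm >= 0,
            noise_sd >= 0)
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 tissue_means = tissue_means, lesion_specs = lesion_specs,
                 deform_amplitude_mm = deform_amplitude_mm,
                 partial_volume_sigma_mm = partial_volume_sigma_mm,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Trilinear gather at continuous 0-based voxel coordinates.
#' @noRd
interp3_at <- function(a, xi, yi, zi) {
  d <- dim(a)
  xi <- pmin(pmax(xi, 0), d[1] - 1)
  yi <- pmin(pmax(yi, 0), d[2] - 1)
  zi <- pmin(pmax(zi, 0), d[3] - 1)
  x0 <- floor(xi); y0 <- floor(yi); z0 <- floor(zi)
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
  z1 <- pmin(z0 + 1, d[3] - 1)
  g <- function(ix, iy, iz) a[1 + ix + d[1] * (iy + d[2] * iz)]
  out <- (1 - fx) * (1 - fy) * (1 - fz) * g(x0, y0, z0) +
         fx * (1 - fy) * (1 - fz) * g(x1, y0, z0) +
         (1 - fx) * fy * (1 - fz) * g(x0, y1, z0) +
         fx * fy * (1 - fz) * g(x1, y1, z0) +
         (1 - fx) * (1 - fy) * fz * g(x0, y0, z1) +
         fx * (1 - fy) * fz * g(x1, y0, z1) +
         (1 - fx) * fy * fz * g(x0, y1, z1) +
         fx * fy * fz * g(x1, y1, z1)
  array(out, dim = dim(xi))
}

# Lesion pixel membership for every slice: central slice picks exactly the
# number of pixels matching the requested area (ranked on the superellipse
# implicit value), other slices use the same threshold shrunk by an
# ellipsoidal z profile. Returns a list of per-voxel (x, y, z, sublabel).
#' @noRd
lesion_voxels <- function(ls, grid_shape, spacing_mm) {
  sp <- spacing_mm
  pix_area_mm2 <- sp[1] * sp[2]
  n_req <- max(1L, as.integer(round(ls$area_cm2 * 100 / pix_area_mm2)))
  ci <- floor(ls$center_mm / sp - 0.5) + 1
  cz <- as.integer(round(ls$center_mm[3] / sp[3] - 0.5)) + 1L
  # generous in-plane search window around the center
  r_mm <- sqrt(ls$area_cm2 * 100 / pi)
  wx <- ceiling(2.5 * r_mm / sp[1]) + 2
  wy <- ceiling(2.5 * r_mm / sp[2]) + 2
  xs <- max(1, ci[1] - wx):min(grid_shape[1], ci[1] + wx)
  ys <- max(1, ci[2] - wy):min(grid_shape[2], ci[2] + wy)
  dx <- abs((xs - 0.5) * sp[1] - ls$center_mm[1])
  dy <- abs((ys - 0.5) * sp[2] - ls$center_mm[2])
  dmat <- outer(dx^ls$exponent, dy^ls$exponent, `+`)
  ord <- order(dmat)                 # deterministic tie-break by index
  if (length(ord) < n_req)
    stop("lesion search window smaller than requested area; enlarge the grid")
  dv <- dmat[ord]
  thr <- dv[n_req]
  K <- length(ls$contrast)
  shell_bounds <- stats::quantile(dv[seq_len(n_req)], probs = seq_len(K) / K,
                                  type = 1, names = FALSE)
  shell_bounds[K] <- thr
  nz <- ls$z_extent_slices
  z0 <- cz - (nz - 1L) %/% 2L
  zs <- z0:(z0 + nz - 1L)
  zeta <- if (nz == 1L) 0 else (zs - mean(zs)) / (nz / 2)
  j_central <- which.min(abs(zeta))
  out <- list()
  for (j in seq_along(zs)) {
    z <- zs[j]
    if (z < 1L || z > grid_shape[3]) next
    s <- sqrt(max(0, 1 - zeta[j]^2))
    if (s == 0) next
    scl <- s^ls$exponent
    sel_lin <- if (j == j_central) ord[seq_len(n_req)]   # exact pixel count
               else which(dmat <= thr * scl)
    if (length(sel_lin) == 0L) next
    sel <- arrayInd(sel_lin, dim(dmat))
    dsel <- dmat[sel_lin]
    sub <- pmin(findInterval(dsel / scl, shell_bounds[-K]) + 1L, K)
    out[[length(out) + 1L]] <- cbind(x = xs[sel[, 1]], y = ys[sel[, 2]],
                                     z = z, sublabel = sub)
  }
  do.call(rbind, out)
}

#' Generate a synthetic brain phantom
#'
#' Builds the tissue compartments, applies the optional radial mass-effect
#' deformation (a displacement field decaying exponentially with distance
#' from each lesion centroid, applied by backward trilinear resampling),
#' normalizes the within-brain mean intensity to 1, paints the lesions
#' (each sub-label shell is set to its contrast multiplier times the
#' slice's non-lesional in-mask mean), and finally adds seeded Gaussian
#' noise within the brain mask so the background stays exactly 0.
#'
#' @param spec A [phantom_spec()].
#' @return A list with components `volume` (an [lf_volume()] carrying the
#'   brain mask), `labels` (a [label_map()]; identically 0 when no lesions
#'   are specified) and `mask` (the logical brain mask array).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  sp <- spec$spacing_mm
  extent <- d * sp
  ctr <- extent / 2
  xs <- (seq_len(d[1]) - 0.5) * sp[1] - ctr[1]
  ys <- (seq_len(d[2]) - 0.5) * sp[2] - ctr[2]
  zs <- (seq_len(d[3]) - 0.5) * sp[3] - ctr[3]
  semi <- c(0.42, 0.45, 0.44) * extent
  R2 <- outer(outer((xs / semi[1])^2, (ys / semi[2])^2, `+`),
              (zs / semi[3])^2, `+`)
  mask <- R2 <= 1
  tm <- spec$tissue_means
  tissue <- array(tm[["background"]], dim = d)
  tissue[mask] <- ifelse(R2[mask] > 0.67, tm[["gm"]], tm[["wm"]])
  # lateral ventricles: two mirrored CSF ellipsoids near the midline
  for (sgn in c(-1, 1)) {
    vc <- c(sgn * 0.11 * extent[1], 0, 0)
    vsemi <- c(0.07, 0.17, 0.26) * extent
    V2 <- outer(outer(((xs - vc[1]) / vsemi[1])^2, ((ys - vc[2]) / vsemi[2])^2, `+`),
                ((zs - vc[3]) / vsemi[3])^2, `+`)
    tissue[V2 <= 1 & mask] <- tm[["csf"]]
  }

  lesions <- spec$lesion_specs
  vox <- lapply(lesions, lesion_voxels, grid_shape = d, spacing_mm = sp)

  if (spec$deform_amplitude_mm > 0 && length(lesions) > 0L) {
    X <- array(rep((seq_len(d[1]) - 0.5) * sp[1], times = d[2] * d[3]), dim = d)
    Y <- aperm(array(rep((seq_len(d[2]) - 0.5) * sp[2], times = d[1] * d[3]),
                     dim = d[c(2, 1, 3)]), c(2, 1, 3))
    Z <- aperm(array(rep((seq_len(d[3]) - 0.5) * sp[3], times = d[1] * d[2]),
                     dim = d[c(3, 1, 2)]), c(2, 3, 1))
    ux <- array(0, d); uy <- array(0, d); uz <- array(0, d)
    lambda <- 18
    for (ls in lesions) {
      rx <- X - ls$center_mm[1]; ry <- Y - ls$center_mm[2]
      rz <- Z - ls$center_mm[3]
      r <- sqrt(rx^2 + ry^2 + rz^2)
      f <- spec$deform_amplitude_mm * exp(-r / lambda) / pmax(r, 1e-6)
      ux <- ux + f * rx; uy <- uy + f * ry; uz <- uz + f * rz
    }
    tissue <- interp3_at(tissue,
                         (X - ux) / sp[1] - 0.5,
                         (Y - uy) / sp[2] - 0.5,
                         (Z - uz) / sp[3] - 0.5)
    tissue <- tissue * mask
  }

  tissue <- tissue / mean(tissue[mask])

  labels <- array(0L, dim = d)
  for (i in seq_along(vox)) {
    v <- vox[[i]]
    if (is.null(v) || nrow(v) == 0L)
      stop(sprintf("lesion %d: no voxels could be placed on the grid", i))
    ii <- cbind(v[, "x"], v[, "y"], v[, "z"])
    if (!all(mask[ii]))
      stop(sprintf("lesion %d extends outside the brain mask; move its center", i))
    labels[ii] <- v[, "sublabel"]
  }
  # paint lesions slice by slice relative to the slice's non-lesional mean
  if (length(vox) > 0L) {
    all_vox <- do.call(rbind, vox)
    for (z in unique(all_vox[, "z"])) {
      sl_mask <- mask[, , z] & labels[, , z] == 0L
      m_slice <- mean(tissue[, , z][sl_mask])
      rows <- all_vox[all_vox[, "z"] == z, , drop = FALSE]
      li <- 0L
      for (i in seq_along(vox)) {
        vi <- vox[[i]]
        vi <- vi[vi[, "z"] == z, , drop = FALSE]
        if (nrow(vi) == 0L) next
        mult <- lesions[[i]]$contrast[vi[, "sublabel"]]
        tissue[cbind(vi[, "x"], vi[, "y"], z)] <- mult * m_slice
      }
    }
  }

  if (spec$partial_volume_sigma_mm > 0) {
    tissue <- gaussian_smooth3(tissue, spec$partial_volume_sigma_mm / sp)
    tissue <- tissue * mask
  }

  if (spec$noise_sd > 0) {
    noise <- with_seed(derive_seed(spec$seed, "phantom-noise"),
                       array(stats::rnorm(prod(d), sd = spec$noise_sd), dim = d))
    tissue <- tissue + noise * mask
  }
  tissue <- tissue * mask

  list(volume = lf_volume(tissue, sp, mask),
       labels = label_map(labels, sp),
       mask = mask)
}

#' Generate a paired low-field target for a high-field phantom
#'
#' Re-slices the volume to the low-field grid (when needed) and applies the
#' degradation cascade with known ground-truth parameters. Such pairs stand
#' in for paired 64 mT / same-day 3 T acquisitions and serve as fitting
#' targets in parameter-recovery experiments.
#'
#' @param volume A masked [lf_volume()].
#' @param true_params The ground-truth [transform_params()].
#' @param seed Integer noise seed.
#' @param target_spacing_mm Low-field grid; defaults to
#'   [lf_target_spacing()].
#' @return The degraded [lf_volume()] on the low-field grid.
#' @export
generate_paired_lf_target <- function(volume, true_params, seed,
                                      target_spacing_mm = lf_target_spacing()) {
  stopifnot(inherits(volume, "lf_volume"))
  if (is.null(volume$mask)) stop("volume must carry a brain mask")
  apply_lf_transform(reslice(volume, target_spacing_mm), true_params, seed)
}

#' Generate a seeded phantom cohort for a simulated trial
#'
#' Draws per-patient lesion geometry and acquisition characteristics:
#' maximal in-plane lesion areas log-uniform over `area_range_cm2`, lesion
#' contrast multipliers uniform over `contrast_range` (with a brighter core
#' sub-label when `sublabels > 1`), z extent proportional to the in-plane
#' diameter, mass-effect amplitude `deform_scale * sqrt(area)` mm, and
#' per-patient noise levels uniform over `noise_sd_range`. Control patients
#' carry no lesion and no deformation.
#'
#' @param n_lesional,n_control Patient counts.
#' @param seed Top-level cohort seed.
#' @param grid_shape,spacing_mm Phantom grid (see [phantom_spec()]).
#' @param area_range_cm2 Range of maximal in-plane lesion areas (cm^2).
#' @param contrast_range Range of the rim contrast multiplier.
#' @param sublabels Number of concentric lesion sub-labels.
#' @param deform_scale Mass-effect amplitude per sqrt(cm^2) of lesion area;
#'   0 disables deformation.
#' @param noise_sd_range Range of per-patient acquisition noise sd.
#' @return A list of patients, each a list with `patient_id`, `volume`,
#'   `labels`, `mask`, `lesional`, `area_cm2` and `spec`.
#' @export
generate_cohort <- function(n_lesional = 30L, n_control = 30L, seed = 1L,
                            grid_shape = c(96, 96, 36),
                            spacing_mm = c(1, 1, 3),
                            area_range_cm2 = c(0.5, 20),
                            contrast_range = c(1.6, 2.0),
                            sublabels = 2L,
                            deform_scale = 1.0,
                            noise_sd_range = c(0.004, 0.008)) {
  stopifnot(n_lesional >= 0L, n_control >= 0L)
  extent <- grid_shape * spacing_mm
  draw <- with_seed(derive_seed(seed, "cohort"), {
    n <- n_lesional
    list(area = exp(stats::runif(n, log(area_range_cm2[1]), log(area_range_cm2[2]))),
         cx = stats::runif(n, -0.10, 0.10), cy = stats::runif(n, -0.12, 0.12),
         cz = stats::runif(n, -0.10, 0.10),
         contrast = stats::runif(n, contrast_range[1], contrast_range[2]),
         noise_les = stats::runif(n, noise_sd_range[1], noise_sd_range[2]),
         noise_ctl = stats::runif(n_control, noise_sd_range[1], noise_sd_range[2]))
  })
  patients <- vector("list", n_lesional + n_control)
  for (i in seq_len(n_lesional)) {
    area <- draw$area[i]
    diam_mm <- 2 * sqrt(area * 100 / pi)
    z_mm <- min(max(0.9 * diam_mm, 2.2 * spacing_mm[3]), 0.55 * extent[3])
    nz <- max(1L, as.integer(round(z_mm / spacing_mm[3])))
    if (nz %% 2L == 0L) nz <- nz + 1L
    ctr <- extent / 2 + c(draw$cx[i] * extent[1], draw$cy[i] * extent[2],
                          draw$cz[i] * extent[3])
    mult <- draw$contrast[i]
    contrast <- if (sublabels > 1L) c(mult + 0.25, rep(mult, sublabels - 1L)) else mult
    ls <- lesion_spec(ctr, area, nz, contrast = contrast)
    sp <- phantom_spec(grid_shape, spacing_mm,
                       lesion_specs = list(ls),
                       deform_amplitude_mm = deform_scale * sqrt(area),
                       noise_sd = draw$noise_les[i],
                       seed = derive_seed(seed, paste0("patient-", i)))
    ph <- NULL
    shrink <- 1
    for (try in 1:6) {
      ph <- tryCatch(generate_phantom(sp), error = function(e) NULL)
      if (!is.null(ph)) break
      shrink <- shrink * 0.6
      ls <- lesion_spec(extent / 2 + shrink * (ctr - extent / 2), area, nz,
                        contrast = contrast)
      sp$lesion_specs <- list(ls)
    }
    if (is.null(ph))
      stop(sprintf("could not place lesion for patient %d", i))
    patients[[i]] <- list(patient_id = sprintf("P%03d", i),
                          volume = ph$volume, labels = ph$labels,
                          mask = ph$mask, lesional = TRUE,
                          area_cm2 = area, spec = sp)
  }
  for (j in seq_len(n_control)) {
    i <- n_lesional + j
    sp <- phantom_spec(grid_shape, spacing_mm,
                       noise_sd = draw$noise_ctl[j],
                       seed = derive_seed(seed, paste0("patient-", i)))
    ph <- generate_phantom(sp)
    patients[[i]] <- list(patient_id = sprintf("P%03d", i),
                          volume = ph$volume, labels = ph$labels,
                          mask = ph$mask, lesional = FALSE,
                          area_cm2 = 0, spec = sp)
  }
  patients
}
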