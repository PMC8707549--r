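#' Define a reconstruction-kernel profile
#'
#' A kernel profile describes how a CT reconstruction kernel reshapes the
#' in-plane frequency content of an image and how much pixel noise it leaves
#' behind. Rendering multiplies each axial slice's 2D spectrum by the radial
#' response \eqn{R(f) = 1 + g \, s(f / f_c)} where \eqn{s(u) = u^2/(1+u^2)} is
#' a smooth ramp that is 0 at DC and saturates at 1, so the mean intensity is
#' always preserved. A negative `mtf_gain` attenuates high frequencies
#' (a "smooth" kernel such as B30f), a positive one boosts them (a "sharp"
#' kernel such as B70f); sharper kernels also carry more noise.
#'
#' @param name Short label, e.g. `"smooth"` or `"sharp"`.
#' @param mtf_gain Unitless amplitude of the frequency-response boost
#'   (negative = attenuation, positive = enhancement). Must be > -1 so the
#'   response stays positive.
#' @param mtf_cutoff Spatial frequency (cycles/voxel, in (0, 0.5]) at which
#'   the ramp transitions.
#' @param noise_sigma Standard deviation of additive zero-mean Gaussian noise
#'   in intensity (HU-like) units; must be >= 0.
#' @return A `kernel_profile` object.
#' @examples
#' smooth <- kernel_profile("smooth", mtf_gain = -0.6, mtf_cutoff = 0.2,
#'                          noise_sigma = 10)
#' @export
kernel_profile <- function(name, mtf_gain, mtf_cutoff, noise_sigma) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(noise_sigma) || noise_sigma < 0) {
    abort("noise_sigma must be >= 0")
  }
  if (!is.numeric(mtf_cutoff) || mtf_cutoff <= 0 || mtf_cutoff > 0.5) {
    abort("mtf_cutoff must lie in (0, 0.5] cycles/voxel")
  }
  if (!is.numeric(mtf_gain) || mtf_gain <= -1) {
    abort("mtf_gain must be > -1 (response must stay positive)")
  }
  structure(
    list(name = name, mtf_gain = mtf_gain, mtf_cutoff = mtf_cutoff,
         noise_sigma = noise_sigma),
    class = "kernel_profile"
  )
}

#' @export
print.kernel_profile <- function(x, ...) {
  cat(sprintf("<kernel_profile '%s'> gain %+0.2f, cutoff %.3f cyc/voxel, noise sd %.1f\n",
              x$name, x$mtf_gain, x$mtf_cutoff, x$noise_sigma))
  invisible(x)
}

#' Define a synthetic lung phantom
#'
#' The phantom is a uniform lung-like background holding one spherical lesion
#' whose interior carries a stationary correlated Gaussian texture (white
#' noise smoothed to a chosen correlation length and scaled to a chosen
#' contrast). A binary label multiplies the texture contrast and correlation
#' length by `label_effect`, so intensity and texture features differ in
#' distribution between the two classes — a stand-in for a mutation-linked
#' texture signal.
#'
#' @param grid_shape Integer vector of 3 voxel counts (x, y, z).
#' @param voxel_spacing Numeric vector of 3 spacings in mm.
#' @param background_level Background intensity (HU-like); default -800
#'   approximates aerated lung.
#' @param lesion_center Voxel coordinates of the lesion center (1-based);
#'   default is the grid center.
#' @param lesion_radius Central lesion radius in voxels.
#' @param lesion_radius_jitter Half-width of the per-patient uniform radius
#'   draw in [generate_cohort()] (0 gives identical lesions; the default
#'   varies tumor size across patients, as real cohorts do, which also makes
#'   across-patient shape-feature variance nonzero so their reproducibility
#'   is well defined).
#' @param lesion_level Mean interior intensity; default 0 HU (soft tissue).
#' @param texture_correlation_length Gaussian correlation length of the
#'   interior texture, in voxels.
#' @param texture_contrast Marginal standard deviation of the interior
#'   texture in intensity units (>= 0; 0 gives an exactly uniform interior).
#' @param label_effect Multiplicative shift applied to `texture_contrast` and
#'   `texture_correlation_length` when the label is positive (> 0).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 24L),
                         voxel_spacing = c(1, 1, 1),
                         background_level = -800,
                         lesion_center = NULL,
                         lesion_radius = 5,
                         lesion_radius_jitter = 1.5,
                         lesion_level = 0,
                         texture_correlation_length = 1.5,
                         texture_contrast = 60,
                         label_effect = 1.5) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L),
            length(voxel_spacing) == 3L, all(voxel_spacing > 0))
  if (is.null(lesion_center)) lesion_center <- (grid_shape + 1) / 2
  stopifnot(length(lesion_center) == 3L)
  if (texture_contrast < 0) abort("texture_contrast must be >= 0")
  if (label_effect <= 0) abort("label_effect must be > 0")
  if (lesion_radius_jitter < 0 ||
      lesion_radius - lesion_radius_jitter < 1.5) {
    abort("lesion_radius - lesion_radius_jitter must be >= 1.5 voxels")
  }
  lo <- lesion_center - (lesion_radius + lesion_radius_jitter)
  hi <- lesion_center + (lesion_radius + lesion_radius_jitter)
  if (any(lo < 3) || any(hi > grid_shape - 2)) {
    abort("lesion must fit inside the grid with a >= 2-voxel margin")
  }
  structure(
    list(grid_shape = grid_shape, voxel_spacing = voxel_spacing,
         background_level = background_level, lesion_center = lesion_center,
         lesion_radius = lesion_radius,
         lesion_radius_jitter = lesion_radius_jitter,
         lesion_level = lesion_level,
         texture_correlation_length = texture_correlation_length,
         texture_contrast = texture_contrast, label_effect = label_effect),
    class = "phantom_spec"
  )
}

# Periodic (FFT) Gaussian smoothing of a 3D white-noise field, scaled so the
# marginal sd of the output is `contrast` in expectation.
correlated_texture <- function(dims, corr_length, contrast) {
  w <- array(rnorm(prod(dims)), dim = dims)
  if (contrast == 0) return(array(0, dim = dims))
  freq_axis <- function(n) {
    k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2)):-1) / n
    k[seq_len(n)]
  }
  fx <- freq_axis(dims[1]); fy <- freq_axis(dims[2]); fz <- freq_axis(dims[3])
  g1 <- exp(-2 * pi^2 * corr_length^2 * fx^2)
  g2 <- exp(-2 * pi^2 * corr_length^2 * fy^2)
  g3 <- exp(-2 * pi^2 * corr_length^2 * fz^2)
  gk <- outer(outer(g1, g2), g3)
  dim(gk) <- dims
  y <- Re(fft(fft(w) * gk, inverse = TRUE)) / prod(dims)
  theo_sd <- sqrt(mean(gk^2))
  y * (contrast / theo_sd)
}

#' Generate one phantom: ground-truth volume plus lesion mask
#'
#' @param spec A [phantom_spec()].
#' @param label Binary class label (0 = wildtype-like, 1 = mutant-like). When
#'   1, the texture contrast and correlation length are multiplied by
#'   `spec$label_effect`.
#' @param seed Integer seed; identical arguments reproduce the phantom
#'   bit-identically.
#' @return A list with `truth` (a `ct_volume`) and `mask` (a `lesion_mask`).
#' @export
generate_phantom <- function(spec, label, seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!label %in% c(0, 1)) abort("label must be 0 or 1")
  dims <- spec$grid_shape
  idx <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
  dx2 <- outer(outer((idx[[1]] - spec$lesion_center[1])^2,
                     (idx[[2]] - spec$lesion_center[2])^2, `+`),
               (idx[[3]] - spec$lesion_center[3])^2, `+`)
  mask <- dx2 <= spec$lesion_radius^2
  dim(mask) <- dims
  if (sum(mask) < 27) abort("lesion mask has fewer than 27 voxels")

  contrast <- spec$texture_contrast
  corr_len <- spec$texture_correlation_length
  if (label == 1) {
    contrast <- contrast * spec$label_effect
    corr_len <- corr_len * spec$label_effect
  }
  values <- array(spec$background_level, dim = dims)
  with_seed(seed, {
    tex <- correlated_texture(dims, corr_len, contrast)
    values[mask] <- spec$lesion_level + tex[mask]
  })
  list(
    truth = new_ct_volume(values, spec$voxel_spacing),
    mask = structure(list(values = mask, spacing = spec$voxel_spacing),
                     class = "lesion_mask")
  )
}

new_ct_volume <- function(values, spacing) {
  structure(list(values = values, spacing = as.numeric(spacing)),
            class = "ct_volume")
}

# Accept a ct_volume or a bare 3D array.
volume_values <- function(x) {
  if (inherits(x, "ct_volume")) x$values else x
}

volume_spacing <- function(x, default = c(1, 1, 1)) {
  if (inherits(x, "ct_volume")) x$spacing else default
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ct_volume> %dx%dx%d voxels, spacing %s mm, range [%.1f, %.1f]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

# Radial frequency response applied to one axial slice (2D FFT filtering).
kernel_response_2d <- function(dims2, kernel) {
  freq_axis <- function(n) c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2)):-1) / n
  fx <- freq_axis(dims2[1]); fy <- freq_axis(dims2[2])
  r <- sqrt(outer(fx^2, fy^2, `+`))
  u <- r / kernel$mtf_cutoff
  1 + kernel$mtf_gain * (u^2 / (1 + u^2))
}

#' Render a ground-truth volume under a reconstruction kernel
#'
#' Slice-by-slice along the axial (third) axis: 2D Fourier transform,
#' multiplication by the kernel's radial frequency response, inverse
#' transform, then additive Gaussian noise at the kernel's `noise_sigma`.
#' The response is exactly 1 at zero frequency, so a noise-free rendering
#' preserves each slice's mean intensity.
#'
#' @param truth A `ct_volume` (or 3D array) of ground-truth intensities.
#' @param kernel A [kernel_profile()].
#' @param seed Integer seed for the noise draw.
#' @return A `ct_volume` of the same shape.
#' @export
apply_kernel <- function(truth, kernel, seed) {
  stopifnot(inherits(kernel, "kernel_profile"))
  vals <- volume_values(truth)
  assert_finite_array(vals, "truth")
  dims <- dim(vals)
  stopifnot(length(dims) == 3L)
  resp <- kernel_response_2d(dims[1:2], kernel)
  out <- vals
  npix <- prod(dims[1:2])
  for (z in seq_len(dims[3])) {
    sl <- vals[, , z]
    out[, , z] <- Re(fft(fft(sl) * resp, inverse = TRUE)) / npix
  }
  if (kernel$noise_sigma > 0) {
    with_seed(seed, {
      out <- out + array(rnorm(prod(dims), 0, kernel$noise_sigma), dim = dims)
    })
  }
  new_ct_volume(out, volume_spacing(truth))
}

#' Generate a synthetic paired-kernel cohort
#'
#' Each record holds the ground truth, its smooth- and sharp-kernel
#' renderings, the shared lesion mask, and a binary label. Labels match the
#' requested prevalence within rounding; per-record seeds are derived
#' deterministically from the master seed, so regenerating with identical
#' parameters yields bit-identical records.
#'
#' @param n Number of patients (>= 2).
#' @param prevalence Fraction of positive labels, in (0, 1).
#' @param spec A [phantom_spec()].
#' @param smooth,sharp [kernel_profile()]s for the two renderings.
#' @param seed Master integer seed.
#' @return A `kernel_cohort` object; `as_tibble()` gives the id/label
#'   manifest.
#' @examples
#' coh <- generate_cohort(4, 0.5, phantom_spec(grid_shape = c(24, 24, 8),
#'                                             lesion_radius = 4),
#'                        kernel_profile("smooth", -0.6, 0.2, 5),
#'                        kernel_profile("sharp", 1.5, 0.2, 20), seed = 1)
#' tibble::as_tibble(coh)
#' @export
generate_cohort <- function(n, prevalence, spec, smooth, sharp, seed) {
  if (n < 2) abort("n must be >= 2")
  if (prevalence <= 0 || prevalence >= 1) abort("prevalence must be in (0, 1)")
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(smooth, "kernel_profile"),
            inherits(sharp, "kernel_profile"))
  n_pos <- round(prevalence * n)
  labels <- with_seed(derive_seed(seed, "labels"),
                      sample(c(rep(1L, n_pos), rep(0L, n - n_pos))))
  records <- vector("list", n)
  for (i in seq_len(n)) {
    spec_i <- spec
    if (spec$lesion_radius_jitter > 0) {
      # per-patient tumor size, drawn deterministically from the record seed
      spec_i$lesion_radius <- with_seed(
        derive_seed(seed, "radius", i),
        runif(1, spec$lesion_radius - spec$lesion_radius_jitter,
              spec$lesion_radius + spec$lesion_radius_jitter)
      )
      spec_i$lesion_radius_jitter <- 0
    }
    ph <- generate_phantom(spec_i, labels[i], derive_seed(seed, "phantom", i))
    smo <- apply_kernel(ph$truth, smooth, derive_seed(seed, "smooth", i))
    shp <- apply_kernel(ph$truth, sharp, derive_seed(seed, "sharp", i))
    records[[i]] <- list(
      id = sprintf("P%03d", i), truth = ph$truth,
      smooth_image = smo, sharp_image = shp,
      mask = ph$mask, label = labels[i]
    )
  }
  structure(
    list(records = records,
         generation_params = list(n = n, prevalence = prevalence, spec = spec,
                                  smooth = smooth, sharp = sharp, seed = seed)),
    class = "kernel_cohort"
  )
}

#' @export
print.kernel_cohort <- function(x, ...) {
  labs <- vapply(x$records, `[[`, integer(1), "label")
  cat(sprintf("<kernel_cohort> %d patients (%d positive / %d negative), grid %s\n",
              length(x$records), sum(labs == 1L), sum(labs == 0L),
              paste(x$generation_params$spec$grid_shape, collapse = "x")))
  invisible(x)
}

#' @export
as_tibble.kernel_cohort <- function(x, ...) {
  tibble(
    patient_id = vapply(x$records, `[[`, character(1), "id"),
    label = vapply(x$records, `[[`, integer(1), "label")
  )
}

#' Cohort labels as a named vector
#' @param cohort A `kernel_cohort`.
#' @return Named integer vector of labels, names are patient ids.
#' @export
cohort_labels <- function(cohort) {
  stopifnot(inherits(cohort, "kernel_cohort"))
  labs <- vapply(cohort$records, `[[`, integer(1), "label")
  names(labs) <- vapply(cohort$records, `[[`, character(1), "id")
  labs
}

#' Write a cohort to disk as NIfTI volumes plus a manifest
#'
#' One NIfTI file per record per rendering (truth, smooth, sharp) plus one
#' mask file, a `manifest.csv` (id, label, file paths) and a
#' `generation_params.json` sidecar.
#'
#' @param cohort A `kernel_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "kernel_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map(cohort$records, function(rec) {
    paths <- c(truth = file.path(dir, paste0(rec$id, "_truth.nii.gz")),
               smooth = file.path(dir, paste0(rec$id, "_ori_smo.nii.gz")),
               sharp = file.path(dir, paste0(rec$id, "_ori_shp.nii.gz")),
               mask = file.path(dir, paste0(rec$id, "_mask.nii.gz")))
    write_volume(rec$truth, paths["truth"])
    write_volume(rec$smooth_image, paths["smooth"])
    write_volume(rec$sharp_image, paths["sharp"])
    write_volume(new_ct_volume(rec$mask$values + 0, rec$mask$spacing),
                 paths["mask"])
    tibble(patient_id = rec$id, label = rec$label,
           truth = paths[["truth"]], smooth = paths[["smooth"]],
           sharp = paths[["sharp"]], mask = paths[["mask"]])
  }) |> dplyr::bind_rows()
  utils::write.csv(rows, file.path(dir, "manifest.csv"), row.names = FALSE)
  gp <- cohort$generation_params
  jsonlite::write_json(
    list(n = gp$n, prevalence = gp$prevalence, seed = gp$seed,
         spec = unclass(gp$spec), smooth = unclass(gp$smooth),
         sharp = unclass(gp$sharp)),
    file.path(dir, "generation_params.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(rows)
}
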