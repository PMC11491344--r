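#' A 3D image volume
#'
#' Light container for a scalar 3D grid with voxel spacing in mm and an
#' optional diffusion b-value. Axis 1 of the array is the left-right
#' axis; the inter-hemispheric mirror plane sits at the grid midpoint
#' along that axis (between columns for even extents, on the centre
#' column for odd ones).
#'
#' @param data Numeric 3D array.
#' @param spacing Numeric length-3, mm per voxel along each axis.
#' @param b_value Diffusion weighting in s/mm^2 (`NULL` for FLAIR).
#' @return Object of class `mri_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), b_value = NULL) {
  if (length(dim(data)) != 3L || any(dim(data) < 1L)) {
    abort("data must be a 3D array with all dimensions >= 1",
          class = "flairsir_input_error")
  }
  if (length(spacing) != 3L || any(spacing <= 0)) {
    abort("spacing must be 3 positive values", class = "flairsir_input_error")
  }
  structure(list(data = data, spacing = as.numeric(spacing),
                 b_value = b_value),
            class = "mri_volume")
}

#' @export
print.mri_volume <- function(x, ...) {
  cat(sprintf("mri_volume %s, spacing %s mm%s\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              if (is.null(x$b_value)) "" else sprintf(", b = %g s/mm^2", x$b_value)))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$spacing, b$spacing))
}

# reflect a 3D array about the mid-plane along axis 1
mirror_axis1 <- function(x) {
  x[dim(x)[1]:1, , , drop = FALSE]
}

#' Specification of a synthetic DWI/FLAIR phantom
#'
#' Defines a mirror-symmetric "brain" (an ellipse in the axial plane
#' extruded across slices) carrying a single spherical ischemic lesion in
#' one hemisphere. DWI signals follow the mono-exponential decay
#' `S_b = S0 exp(-b ADC)`; the FLAIR lesion is hyperintense by the factor
#' `target_sir` relative to the tissue baseline, so the phantom's true
#' SIR is known by construction.
#'
#' @param dim Grid extents (axis 1 = left-right).
#' @param spacing Voxel size in mm.
#' @param brain_semiaxes Ellipse semi-axes (voxels) in the axial plane;
#'   the ellipse is centred on the grid so the brain is mirror-symmetric.
#' @param lesion_center Voxel coordinates of the lesion centre (1-based).
#' @param lesion_radius Lesion radius in voxels (0 = no lesion).
#' @param lesion_adc,background_adc Diffusion coefficients in mm^2/s;
#'   the lesion must be the slower-diffusing compartment.
#' @param s0 DWI baseline signal (b = 0), arbitrary units.
#' @param flair_baseline FLAIR tissue signal, arbitrary units.
#' @param target_sir True lesion/mirror FLAIR ratio, >= 1.
#' @param noise_sd Additive Gaussian noise SD (signal units), applied to
#'   all three volumes and clamped at zero.
#' @param b_low,b_high Diffusion b-values in s/mm^2.
#' @param seed Seed for the noise draws.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(48L, 48L, 12L),
                         spacing = c(4, 4, 6),
                         brain_semiaxes = c(20, 21),
                         lesion_center = c(14, 24, 6),
                         lesion_radius = 4,
                         lesion_adc = 4.0e-4,
                         background_adc = 8.0e-4,
                         s0 = 1000,
                         flair_baseline = 200,
                         target_sir = 1.15,
                         noise_sd = 0,
                         b_low = 0, b_high = 1000,
                         seed = 1L) {
  spec <- list(dim = as.integer(dim), spacing = spacing,
               brain_semiaxes = brain_semiaxes,
               lesion_center = lesion_center, lesion_radius = lesion_radius,
               lesion_adc = lesion_adc, background_adc = background_adc,
               s0 = s0, flair_baseline = flair_baseline,
               target_sir = target_sir, noise_sd = noise_sd,
               b_low = b_low, b_high = b_high, seed = as.integer(seed))
  if (lesion_adc >= background_adc) {
    abort("lesion ADC must be below background ADC",
          class = "flairsir_config_error")
  }
  if (target_sir < 1) {
    abort("target_sir must be >= 1", class = "flairsir_config_error")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0", class = "flairsir_config_error")
  structure(spec, class = "phantom_spec")
}

#' Generate a co-registered DWI/FLAIR phantom with known truth
#'
#' @param spec A [phantom_spec()].
#' @return List with `mri_volume` elements `b0`, `b1000`, `flair`, the
#'   logical `brain_mask`, and `truth` (list: logical lesion `mask`, the
#'   `adc` map used, `true_sir`).
#' @examples
#' ph <- make_phantom(phantom_spec(target_sir = 1.25))
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$dim
  ctr <- (dm + 1) / 2
  ax <- slice.index(array(0, dm), 1)
  ay <- slice.index(array(0, dm), 2)
  brain <- ((ax - ctr[1]) / spec$brain_semiaxes[1])^2 +
    ((ay - ctr[2]) / spec$brain_semiaxes[2])^2 <= 1

  lesion <- array(FALSE, dm)
  if (spec$lesion_radius > 0) {
    az <- slice.index(array(0, dm), 3)
    lesion <- (ax - spec$lesion_center[1])^2 +
      (ay - spec$lesion_center[2])^2 +
      (az - spec$lesion_center[3])^2 <= spec$lesion_radius^2
    lesion <- lesion & brain
    if (any(lesion & mirror_axis1(lesion))) {
      abort("lesion crosses the mirror mid-plane",
            class = "flairsir_config_error")
    }
    if (!any(lesion)) {
      abort("lesion lies outside the brain", class = "flairsir_config_error")
    }
  }

  adc <- array(spec$background_adc, dm)
  adc[lesion] <- spec$lesion_adc
  adc[!brain] <- NA_real_

  b0 <- array(0, dm)
  b0[brain] <- spec$s0 * exp(-spec$b_low * adc[brain])
  bh <- array(0, dm)
  bh[brain] <- spec$s0 * exp(-spec$b_high * adc[brain])
  flair <- array(0, dm)
  flair[brain] <- spec$flair_baseline
  flair[lesion] <- spec$flair_baseline * spec$target_sir

  if (spec$noise_sd > 0) {
    with_seed(spec$seed, {
      b0 <- pmax(b0 + array(rnorm(prod(dm), 0, spec$noise_sd), dm), 0)
      bh <- pmax(bh + array(rnorm(prod(dm), 0, spec$noise_sd), dm), 0)
      flair <- pmax(flair + array(rnorm(prod(dm), 0, spec$noise_sd), dm), 0)
    })
  }

  list(
    b0 = image_volume(b0, spec$spacing, b_value = spec$b_low),
    b1000 = image_volume(bh, spec$spacing, b_value = spec$b_high),
    flair = image_volume(flair, spec$spacing),
    brain_mask = brain,
    truth = list(mask = lesion, adc = adc, true_sir = spec$target_sir)
  )
}

#' Write / read an `mri_volume` as NIfTI-1
#'
#' Voxel spacing is stored in the NIfTI header; the b-value, which NIfTI
#' has no standard slot for, can be re-attached on read.
#'
#' @param vol An [image_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "mri_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param b_value Optional b-value to attach to the volume read.
#' @export
read_volume <- function(path, b_value = NULL) {
  img <- RNifti::readNifti(path)
  image_volume(array(as.numeric(img), dim(img)),
               spacing = RNifti::pixdim(img)[1:3], b_value = b_value)
}

#' Write / read a phantom spec as YAML
#' @param spec A [phantom_spec()].
#' @param path YAML path.
#' @export
write_phantom_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  do.call(phantom_spec, yaml::read_yaml(path))
}
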