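#' Apparent diffusion coefficient map from two diffusion weightings
#'
#' Inverts the mono-exponential decay `S_b = S0 exp(-b ADC)` voxelwise:
#' `ADC = log(S_low / S_high) / (b_high - b_low)` in mm^2/s. Voxels with
#' non-positive signal in either input are set to `NA` (invalid) and are
#' excluded from all downstream masking.
#'
#' @param b0 Low-b `mri_volume` (typically b = 0).
#' @param b_high High-b `mri_volume` (typically b = 1000 s/mm^2).
#' @return An `mri_volume` holding the ADC map (mm^2/s, no b-value).
#' @examples
#' ph <- make_phantom(phantom_spec())
#' adc <- compute_adc(ph$b0, ph$b1000)
#' @export
compute_adc <- function(b0, b_high) {
  stopifnot(inherits(b0, "mri_volume"), inherits(b_high, "mri_volume"))
  if (!same_grid(b0, b_high)) {
    abort("volumes must share grid and spacing", class = "flairsir_input_error")
  }
  if (is.null(b0$b_value) || is.null(b_high$b_value) ||
      b_high$b_value <= b0$b_value) {
    abort("b_high must exceed the low b-value", class = "flairsir_input_error")
  }
  lo <- b0$data
  hi <- b_high$data
  adc <- array(NA_real_, dim(lo))
  ok <- is.finite(lo) & is.finite(hi) & lo > 0 & hi > 0
  adc[ok] <- log(lo[ok] / hi[ok]) / (b_high$b_value - b0$b_value)
  image_volume(adc, b0$spacing)
}

# 26-connectivity labelling of a logical 3D mask (flood fill)
label_components_26 <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  cur <- 0L
  for (seed_vox in idx) {
    if (lab[seed_vox] != 0L) next
    cur <- cur + 1L
    queue <- seed_vox
    lab[seed_vox] <- cur
    head_ptr <- 1L
    while (head_ptr <= length(queue)) {
      v <- queue[head_ptr]
      head_ptr <- head_ptr + 1L
      co <- arrayInd(v, dm)
      nb <- sweep(offs, 2, as.integer(co), `+`)
      keep <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
        nb[, 2] >= 1 & nb[, 2] <= dm[2] &
        nb[, 3] >= 1 & nb[, 3] <= dm[3]
      nb <- nb[keep, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * dm[1] + (nb[, 3] - 1L) * dm[1] * dm[2]
      lin <- lin[mask[lin] & lab[lin] == 0L]
      if (length(lin)) {
        lab[lin] <- cur
        queue <- c(queue, lin)
      }
    }
  }
  lab
}

#' Segment the acute ischemic lesion by ADC thresholding
#'
#' The lesion mask is the set of brain voxels with `ADC < threshold`
#' (strict inequality; acute cytotoxic edema restricts diffusion below
#' about 600e-6 mm^2/s), filtered to 26-connected components of at least
#' `min_component_voxels` voxels. The contralateral reference mask is the
#' reflection of the lesion about the mid-sagittal grid plane,
#' intersected with the brain mask.
#'
#' @param adc ADC `mri_volume` from [compute_adc()].
#' @param brain_mask Logical array on the same grid.
#' @param threshold ADC threshold in mm^2/s.
#' @param min_component_voxels Minimum connected-component size.
#' @return Object of class `lesion_mask`: logical `mask` and `mirrored`
#'   arrays, `n_voxels`, `volume_ml`, `spacing`. An empty mask is a valid
#'   result.
#' @export
segment_lesion <- function(adc, brain_mask, threshold = 600e-6,
                           min_component_voxels = 5L) {
  stopifnot(inherits(adc, "mri_volume"))
  if (!identical(dim(adc$data), dim(brain_mask))) {
    abort("ADC map and brain mask grids differ", class = "flairsir_input_error")
  }
  if (threshold <= 0) abort("threshold must be > 0", class = "flairsir_input_error")
  raw <- brain_mask & !is.na(adc$data) & adc$data < threshold
  if (any(raw) && min_component_voxels > 1L) {
    lab <- label_components_26(raw)
    sizes <- tabulate(lab)
    keep <- which(sizes >= min_component_voxels)
    raw <- array(lab %in% keep & lab > 0L, dim(raw))
  }
  mirrored <- mirror_axis1(raw) & brain_mask
  if (any(raw & mirrored)) {
    warn("lesion mask overlaps its own mirror image (midline lesion?)")
  }
  structure(
    list(mask = raw, mirrored = mirrored,
         n_voxels = sum(raw),
         volume_ml = sum(raw) * prod(adc$spacing) / 1000,
         spacing = adc$spacing),
    class = "lesion_mask"
  )
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("lesion_mask: %d voxels (%.2f mL), mirror %d voxels\n",
              x$n_voxels, x$volume_ml, sum(x$mirrored)))
  invisible(x)
}

#' FLAIR signal-intensity ratio over a lesion and its mirror region
#'
#' `SIR = mean(FLAIR over lesion) / mean(FLAIR over reference)`, the
#' quantitative marker of lesion age: FLAIR hyperintensity develops over
#' hours as vasogenic edema follows the acute diffusion restriction.
#' The reference region is the mirrored lesion ROI by default, or the
#' whole contralateral hemisphere restricted to the lesion's slices
#' (`reference = "hemisphere_slice_mean"`, which requires `brain_mask`).
#'
#' @param flair FLAIR `mri_volume`.
#' @param lesion A [segment_lesion()] result.
#' @param reference `"mirror_roi"` or `"hemisphere_slice_mean"`.
#' @param brain_mask Logical array, required for the hemisphere reference.
#' @param min_voxels Minimum lesion size; smaller lesions raise a
#'   no-lesion error.
#' @return Object of class `sir_result`: `sir`, `lesion_mean_si`,
#'   `mirror_mean_si`, `n_voxels`, `reference`.
#' @export
compute_sir <- function(flair, lesion,
                        reference = c("mirror_roi", "hemisphere_slice_mean"),
                        brain_mask = NULL, min_voxels = 1L) {
  stopifnot(inherits(flair, "mri_volume"), inherits(lesion, "lesion_mask"))
  reference <- match.arg(reference)
  if (!identical(dim(flair$data), dim(lesion$mask))) {
    abort("FLAIR and lesion grids differ", class = "flairsir_input_error")
  }
  if (lesion$n_voxels < max(1L, min_voxels)) {
    abort("no lesion voxels to measure", class = "flairsir_no_lesion_error")
  }
  ref_mask <- if (reference == "mirror_roi") {
    lesion$mirrored
  } else {
    if (is.null(brain_mask)) {
      abort("brain_mask is required for the hemisphere reference",
            class = "flairsir_input_error")
    }
    contralateral_hemisphere(lesion, brain_mask)
  }
  if (!any(ref_mask)) {
    abort("empty reference region", class = "flairsir_input_error")
  }
  lm_si <- mean(flair$data[lesion$mask])
  mm_si <- mean(flair$data[ref_mask])
  if (!is.finite(mm_si) || mm_si <= 0) {
    abort("non-positive reference signal: invalid image",
          class = "flairsir_invalid_image_error")
  }
  structure(
    list(sir = lm_si / mm_si, lesion_mean_si = lm_si, mirror_mean_si = mm_si,
         n_voxels = lesion$n_voxels, reference = reference),
    class = "sir_result"
  )
}

# contralateral hemisphere of the lesion, on the lesion's axial slices
contralateral_hemisphere <- function(lesion, brain_mask) {
  dm <- dim(lesion$mask)
  co <- arrayInd(which(lesion$mask), dm)
  mid <- (dm[1] + 1) / 2
  lesion_left <- mean(co[, 1]) < mid
  ax <- slice.index(brain_mask, 1)
  side <- if (lesion_left) ax > mid else ax < mid
  slices <- unique(co[, 3])
  az <- slice.index(brain_mask, 3)
  brain_mask & side & (az %in% slices) & !lesion$mask
}

#' @export
print.sir_result <- function(x, ...) {
  cat(sprintf("SIR = %.4f (lesion %.1f / %s %.1f over %d voxels)\n",
              x$sir, x$lesion_mean_si, x$reference, x$mirror_mean_si,
              x$n_voxels))
  invisible(x)
}

#' Classify the onset window from a SIR value
#'
#' Returns `TRUE` (predicted late, onset > 4.5 h) when `sir > cutoff`,
#' strictly: a value exactly at the cutoff is classified early. The
#' default cutoff 1.115 is the Youden-optimal SIR operating point.
#'
#' @param sir Numeric SIR value(s), > 0.
#' @param cutoff Decision threshold.
#' @return Logical vector.
#' @export
classify_window <- function(sir, cutoff = 1.115) {
  if (any(sir <= 0, na.rm = TRUE)) {
    abort("SIR must be positive", class = "flairsir_input_error")
  }
  sir > cutoff
}

#' Thresholded surrogate for the visual DWI-FLAIR mismatch rating
#'
#' Mismatch (lesion visible on DWI but not yet on FLAIR) is declared when
#' `sir < threshold`. This is a quantitative surrogate for the human
#' visual rating, not a replication of it.
#'
#' @param sir Numeric SIR value(s).
#' @param threshold Mismatch threshold.
#' @return Logical vector, `TRUE` = mismatch present.
#' @export
mismatch_surrogate <- function(sir, threshold) {
  sir < threshold
}

#' One-call SIR measurement from raw volumes
#'
#' Convenience wrapper chaining [compute_adc()], [segment_lesion()] and
#' [compute_sir()], returning the measured SIR together with the masks
#' and window classification; this is what the `sir` CLI subcommand runs.
#'
#' @param b0,b_high,flair `mri_volume` inputs on a shared grid.
#' @param brain_mask Logical array.
#' @param adc_threshold Segmentation threshold, mm^2/s.
#' @param cutoff SIR decision threshold for a late window.
#' @param mismatch_threshold SIR threshold of the mismatch surrogate.
#' @param reference Reference-region mode, see [compute_sir()].
#' @param min_component_voxels Component-size filter for segmentation.
#' @return List: `sir_result`, `lesion`, `adc`, `predicted_late`,
#'   `mismatch`.
#' @export
measure_sir <- function(b0, b_high, flair, brain_mask,
                        adc_threshold = 600e-6, cutoff = 1.115,
                        mismatch_threshold = 1.115,
                        reference = "mirror_roi",
                        min_component_voxels = 5L) {
  adc <- compute_adc(b0, b_high)
  lesion <- segment_lesion(adc, brain_mask, threshold = adc_threshold,
                           min_component_voxels = min_component_voxels)
  res <- compute_sir(flair, lesion, reference = reference,
                     brain_mask = brain_mask)
  list(sir_result = res, lesion = lesion, adc = adc,
       predicted_late = classify_window(res$sir, cutoff),
       mismatch = mismatch_surrogate(res$sir, mismatch_threshold))
}
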