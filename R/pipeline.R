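#' Quantify hemispheric vein-volume asymmetry for one subject
#'
#' Wires the full pipeline: deep-grey exclusion, hemisphere splitting,
#' slice-wise vein segmentation on SWI and MinIP, intersection, and
#' volumetry. Inputs are assumed co-registered on a common symmetric
#' template grid (mid-sagittal plane at world x = 0); use
#' [resample_to_grid()] beforehand if an affine is needed.
#'
#' @param swi SWI [swi_volume].
#' @param minip MinIP [swi_volume] on the same grid, or `NULL` to derive
#'   one from the SWI volume with [compute_minip()] and `slab`.
#' @param brain_mask binary [swi_volume].
#' @param exclusion binary [swi_volume] of deep grey to exclude, or `NULL`
#'   for the default midline ellipsoid of [make_exclusion_mask()].
#' @param params segmentation parameters, see [vein_params()].
#' @param slab slab specification used when `minip` is `NULL`.
#' @return List with `result` (an `asymmetry_result`), `veins` (a
#'   `vein_mask`), and `hemispheres` (a `hemisphere_mask`).
#' @export
quantify_veins <- function(swi, minip = NULL, brain_mask, exclusion = NULL,
                           params = vein_params(), slab = slab_spec()) {
  stopifnot(inherits(swi, "swi_volume"), inherits(brain_mask, "swi_volume"))
  if (is.null(minip)) minip <- compute_minip(swi, slab)
  if (is.null(exclusion)) exclusion <- make_exclusion_mask(brain_mask)
  hemis <- split_hemispheres(brain_mask, exclusion)
  veins <- extract_veins(swi, minip, hemis, params)
  res <- asymmetry(acvv(veins$left, swi$spacing),
                   acvv(veins$right, swi$spacing))
  list(result = res, veins = veins, hemispheres = hemis)
}

#' Quantify a generated phantom
#'
#' Convenience wrapper running [quantify_veins()] on a `phantom_truth`.
#'
#' @param phantom a `phantom_truth` from [generate_phantom()].
#' @param params segmentation parameters.
#' @return As [quantify_veins()].
#' @export
quantify_phantom <- function(phantom, params = vein_params()) {
  stopifnot(inherits(phantom, "phantom_truth"))
  quantify_veins(phantom$swi, phantom$minip, phantom$brain_mask,
                 params = params)
}

#' Calibrate the VVA classifier from a per-subject results table
#'
#' @param table data.frame with numeric column `dcvv_ml` (or `dcvv`) and a
#'   label column `vva_label` (yes/no or logical/0-1).
#' @return A `cutoff_calibration`, see [roc_youden()].
#' @export
calibrate_vva <- function(table) {
  dc <- if ("dcvv_ml" %in% names(table)) table$dcvv_ml
        else if ("dcvv" %in% names(table)) table$dcvv
        else stop("table must contain a 'dcvv_ml' or 'dcvv' column")
  if (!"vva_label" %in% names(table))
    stop("table must contain a 'vva_label' column")
  roc_youden(dc, table$vva_label)
}
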