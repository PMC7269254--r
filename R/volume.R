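#' Construct a 3D analysis volume
#'
#' A `swi_volume` is the carrier for all image data in the package: native
#' SWI magnitude images, MinIP reconstructions, and binary masks. It couples
#' a 3D scalar array with its voxel spacing (mm) and a 4x4 grid-to-world
#' affine. World coordinates are template-space mm with the mid-sagittal
#' plane at x = 0; axes follow the canonical RAS convention
#' (left-to-right, posterior-to-anterior, inferior-to-superior).
#'
#' @param data 3D numeric array; must be finite everywhere.
#' @param spacing numeric(3), voxel edge lengths in mm, all strictly positive.
#' @param affine 4x4 grid-to-world matrix mapping 0-based voxel indices to
#'   world mm. Defaults to `diag(c(spacing, 1))` (origin at the first voxel).
#' @return An object of class `swi_volume` with fields `data`, `spacing`,
#'   `affine`.
#' @examples
#' v <- swi_volume(array(0, c(10, 10, 10)))
#' voxel_volume_ml(v) # 0.001
#' @export
swi_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3D array, got ", length(dim(data)), " dimensions")
  if (!all(is.finite(data)))
    stop("volume data contains non-finite values (NaN/Inf)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive voxel edge lengths (mm)")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps)
    stop("'affine' is singular (non-invertible)")
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "swi_volume")
}

#' @export
print.swi_volume <- function(x, ...) {
  cat("<swi_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm (", format(voxel_volume_ml(x)), " ml/voxel)\n", sep = "")
  invisible(x)
}

#' @export
dim.swi_volume <- function(x) dim(x$data)

#' Voxel volume in millilitres
#'
#' @param vol a [swi_volume].
#' @return `prod(spacing) / 1000`, the volume of one voxel in ml.
#' @export
voxel_volume_ml <- function(vol) {
  stopifnot(inherits(vol, "swi_volume"))
  prod(vol$spacing) / 1000
}

is_binary <- function(x) is.logical(x) || all(x == 0 | x == 1)

#' Read a NIfTI volume onto the canonical analysis grid
#'
#' Loads a 3D single-channel NIfTI file, applies header intensity scaling
#' (`scl_slope` / `scl_inter`), and reorients the array to the canonical
#' RAS axis order so that the first array axis always runs left to right.
#' Files stored in a flipped axis convention therefore load to the same
#' world-space content.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [swi_volume].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    dim(img) <- d[1:3]
  } else if (length(d) != 3L) {
    stop("expected a 3D single-channel NIfTI, got dimensions ",
         paste(d, collapse = " x "), ": ", path)
  }
  hdr <- RNifti::niftiHeader(img)
  if (hdr$qform_code > 0 || hdr$sform_code > 0)
    RNifti::orientation(img) <- "RAS" # reorient to canonical axis order
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  if (abs(det(aff)) < .Machine$double.eps)
    stop("non-invertible affine in NIfTI header: ", path)
  dat <- array(as.numeric(img), dim = dim(img))
  if (!all(is.finite(dat)))
    stop("volume contains non-finite values after loading: ", path)
  spacing <- abs(c(RNifti::pixdim(img)))[1:3]
  swi_volume(dat, spacing = spacing, affine = aff)
}

#' Write a volume to NIfTI
#'
#' Intensities are stored as float32; a read/write round trip reproduces
#' the data to float32 precision and the spacing exactly. Binary masks
#' (0/1) round-trip exactly.
#'
#' @param vol a [swi_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "swi_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  ok <- tryCatch({
    RNifti::writeNifti(img, path, datatype = "float")
    TRUE
  }, error = function(e) {
    stop("cannot write NIfTI to '", path, "': ", conditionMessage(e))
  })
  invisible(path)
}

# World x-coordinate of every voxel centre, exploiting separability when the
# affine has no cross-terms in its first row (the canonical case).
voxel_world_x <- function(vol) {
  M <- vol$affine
  d <- dim(vol$data)
  if (M[1, 2] == 0 && M[1, 3] == 0) {
    x <- M[1, 1] * (seq_len(d[1]) - 1) + M[1, 4]
    array(x, dim = d) # recycles along the first axis
  } else {
    i <- slice.index(vol$data, 1) - 1
    j <- slice.index(vol$data, 2) - 1
    k <- slice.index(vol$data, 3) - 1
    M[1, 1] * i + M[1, 2] * j + M[1, 3] * k + M[1, 4]
  }
}

# World coordinates (list of three arrays) of all voxel centres.
voxel_world_coords <- function(vol) {
  M <- vol$affine
  d <- dim(vol$data)
  i <- slice.index(vol$data, 1) - 1
  j <- slice.index(vol$data, 2) - 1
  k <- slice.index(vol$data, 3) - 1
  list(x = M[1, 1] * i + M[1, 2] * j + M[1, 3] * k + M[1, 4],
       y = M[2, 1] * i + M[2, 2] * j + M[2, 3] * k + M[2, 4],
       z = M[3, 1] * i + M[3, 2] * j + M[3, 3] * k + M[3, 4])
}

#' Split a brain mask into left and right hemispheres
#'
#' Voxels whose world x-coordinate is negative belong to the left
#' hemisphere, positive to the right; voxels centred on the mid-sagittal
#' plane (|x| <= `midline_tol` mm) are assigned to neither, which keeps the
#' split deterministic and prevents double counting. An optional exclusion
#' mask (by default the deep grey nuclei, which have intrinsically low SWI
#' signal) is removed from both hemispheres.
#'
#' @param brain_mask binary [swi_volume] on the analysis grid.
#' @param exclusion optional binary [swi_volume] of voxels to exclude from
#'   both hemispheres (e.g. from [make_exclusion_mask()]).
#' @param midline_tol half-width (mm) of the excluded mid-sagittal band.
#' @return An object of class `hemisphere_mask`: logical arrays `left`,
#'   `right`, `excluded` (pairwise disjoint, all within the brain mask),
#'   plus `spacing` and `affine`.
#' @export
split_hemispheres <- function(brain_mask, exclusion = NULL, midline_tol = 1e-6) {
  stopifnot(inherits(brain_mask, "swi_volume"))
  if (!is_binary(brain_mask$data))
    stop("brain mask must be binary (0/1)")
  x <- voxel_world_x(brain_mask)
  if (!(min(x) < 0 && max(x) > 0))
    stop("grid x-range does not straddle the mid-sagittal plane x = 0; ",
         "cannot split hemispheres")
  inb <- brain_mask$data > 0
  mid <- abs(x) <= midline_tol
  excl <- mid
  if (!is.null(exclusion)) {
    stopifnot(inherits(exclusion, "swi_volume"))
    if (!all(dim(exclusion$data) == dim(brain_mask$data)))
      stop("exclusion mask grid does not match the brain mask grid")
    if (!is_binary(exclusion$data)) stop("exclusion mask must be binary (0/1)")
    excl <- excl | (exclusion$data > 0)
  }
  structure(list(left = inb & (x < 0) & !excl,
                 right = inb & (x > 0) & !excl,
                 excluded = inb & excl,
                 spacing = brain_mask$spacing,
                 affine = brain_mask$affine),
            class = "hemisphere_mask")
}

#' Ellipsoidal deep-grey exclusion mask
#'
#' The thalami and basal ganglia are excluded from vein quantification
#' because their intrinsically low SWI signal would otherwise be segmented
#' as vein. In the absence of an atlas the excluded region is modelled as a
#' single midline-centred ellipsoid in template coordinates; both centre
#' and radii are configurable, and a user-supplied mask can be used instead.
#'
#' @param grid a [swi_volume] defining the analysis grid (data ignored).
#' @param center ellipsoid centre, template-space mm.
#' @param radii ellipsoid semi-axes, mm, all strictly positive.
#' @return Binary [swi_volume] on `grid`.
#' @export
make_exclusion_mask <- function(grid,
                                center = c(0, -18, 8),
                                radii = c(32, 38, 26)) {
  stopifnot(inherits(grid, "swi_volume"))
  if (length(radii) != 3L || any(radii <= 0))
    stop("'radii' must be 3 strictly positive semi-axes (mm)")
  M <- grid$affine
  d <- dim(grid$data)
  offdiag <- M[1:3, 1:3]; diag(offdiag) <- 0
  if (all(offdiag == 0)) { # axis-aligned: separable ellipsoid test
    qx <- ((M[1, 1] * (seq_len(d[1]) - 1) + M[1, 4] - center[1]) / radii[1])^2
    qy <- ((M[2, 2] * (seq_len(d[2]) - 1) + M[2, 4] - center[2]) / radii[2])^2
    qz <- ((M[3, 3] * (seq_len(d[3]) - 1) + M[3, 4] - center[3]) / radii[3])^2
    q <- outer(outer(qx, qy, "+"), qz, "+")
  } else {
    co <- voxel_world_coords(grid)
    q <- ((co$x - center[1]) / radii[1])^2 +
         ((co$y - center[2]) / radii[2])^2 +
         ((co$z - center[3]) / radii[3])^2
  }
  swi_volume(array(as.numeric(q <= 1), dim = d),
             spacing = grid$spacing, affine = grid$affine)
}

#' Mirror a volume across the mid-sagittal plane
#'
#' Requires the grid to be symmetric about x = 0 (voxel centre x-coordinates
#' form a sign-symmetric set), so the flipped array represents the exact
#' mirror image on the same grid. Used for left/right equivariance checks.
#'
#' @param vol a [swi_volume].
#' @return The mirrored [swi_volume].
#' @export
mirror_volume <- function(vol) {
  stopifnot(inherits(vol, "swi_volume"))
  M <- vol$affine
  if (M[1, 2] != 0 || M[1, 3] != 0)
    stop("mirroring requires an axis-aligned x-coordinate")
  nx <- dim(vol$data)[1]
  xs <- M[1, 1] * (seq_len(nx) - 1) + M[1, 4]
  if (max(abs(xs + rev(xs))) > 1e-6)
    stop("grid is not symmetric about x = 0; cannot mirror exactly")
  swi_volume(vol$data[rev(seq_len(nx)), , , drop = FALSE],
             spacing = vol$spacing, affine = vol$affine)
}
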