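#' Resample a volume onto a target grid
#'
#' Applies an affine world-to-world transform and interpolates the source
#' volume at every target voxel centre. Linear interpolation is for
#' intensity images, nearest for label masks (labels are preserved
#' exactly). Voxels that map outside the source field of view are filled
#' with 0. An identity transform onto the identical grid returns the input
#' bitwise unchanged.
#'
#' @param vol source [swi_volume].
#' @param target_grid [swi_volume] defining the output grid (data ignored).
#' @param transform 4x4 affine mapping source world coordinates to target
#'   world coordinates; default identity.
#' @param interpolation `"linear"` or `"nearest"`.
#' @return A [swi_volume] on the target grid.
#' @export
resample_to_grid <- function(vol, target_grid, transform = diag(4),
                             interpolation = c("linear", "nearest")) {
  stopifnot(inherits(vol, "swi_volume"), inherits(target_grid, "swi_volume"))
  interpolation <- match.arg(interpolation)
  transform <- as.matrix(transform)
  if (!all(dim(transform) == c(4L, 4L)) ||
      abs(det(transform)) < .Machine$double.eps)
    stop("'transform' must be an invertible 4x4 affine")
  if (any(target_grid$spacing <= 0))
    stop("target grid has non-positive spacing")

  same_grid <- all(dim(vol$data) == dim(target_grid$data)) &&
    max(abs(vol$affine - target_grid$affine)) == 0
  if (same_grid && max(abs(transform - diag(4))) == 0) return(vol)

  # target voxel (0-based) -> target world -> source world -> source voxel
  map <- solve(vol$affine) %*% solve(transform) %*% target_grid$affine
  dt <- dim(target_grid$data)
  i <- as.vector(slice.index(target_grid$data, 1)) - 1
  j <- as.vector(slice.index(target_grid$data, 2)) - 1
  k <- as.vector(slice.index(target_grid$data, 3)) - 1
  sx <- map[1, 1] * i + map[1, 2] * j + map[1, 3] * k + map[1, 4]
  sy <- map[2, 1] * i + map[2, 2] * j + map[2, 3] * k + map[2, 4]
  sz <- map[3, 1] * i + map[3, 2] * j + map[3, 3] * k + map[3, 4]
  ds <- dim(vol$data)
  src <- vol$data

  gather <- function(ii, jj, kk) {
    # 0-based integer indices; out-of-field reads contribute 0
    ok <- ii >= 0 & ii < ds[1] & jj >= 0 & jj < ds[2] & kk >= 0 & kk < ds[3]
    out <- numeric(length(ii))
    idx <- ii[ok] + ds[1] * (jj[ok] + ds[2] * kk[ok]) + 1
    out[ok] <- src[idx]
    out
  }

  if (interpolation == "nearest") {
    vals <- gather(round(sx), round(sy), round(sz))
  } else {
    # snap near-integer coordinates so identity-like maps stay exact
    snap <- function(u) { r <- round(u); ifelse(abs(u - r) < 1e-9, r, u) }
    sx <- snap(sx); sy <- snap(sy); sz <- snap(sz)
    x0 <- floor(sx); y0 <- floor(sy); z0 <- floor(sz)
    fx <- sx - x0; fy <- sy - y0; fz <- sz - z0
    vals <- numeric(length(sx))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx == 1) fx else 1 - fx) *
           (if (dy == 1) fy else 1 - fy) *
           (if (dz == 1) fz else 1 - fz)
      nz <- w != 0
      if (any(nz)) {
        vals[nz] <- vals[nz] +
          w[nz] * gather(x0[nz] + dx, y0[nz] + dy, z0[nz] + dz)
      }
    }
  }
  swi_volume(array(vals, dim = dt),
             spacing = target_grid$spacing, affine = target_grid$affine)
}

#' Slab specification for minimum intensity projection
#'
#' @param thickness_mm slab thickness in mm (clinically 12.8-16 mm, mean
#'   about 14 mm). Must cover at least one slice.
#' @param mode `"sliding"` (one slab centred on every slice; default) or
#'   `"block"` (contiguous non-overlapping slabs, each slab's minimum
#'   broadcast to all of its slices). Both leave the result on the input
#'   grid so it is voxelwise comparable to the SWI volume.
#' @return A `slab_spec` object.
#' @export
slab_spec <- function(thickness_mm = 14, mode = c("sliding", "block")) {
  if (thickness_mm <= 0) stop("slab thickness must be positive")
  structure(list(thickness_mm = thickness_mm, mode = match.arg(mode)),
            class = "slab_spec")
}

#' Minimum intensity projection of an SWI volume
#'
#' For each axial output slice, every in-plane position carries the minimum
#' intensity over the axial slices whose centres fall within the slab
#' window. The output is stored slice-replicated on the input grid, so the
#' later SWI/MinIP intersection is defined voxelwise.
#'
#' @param swi [swi_volume] in canonical orientation.
#' @param slab a [slab_spec()] (or a thickness in mm).
#' @return MinIP [swi_volume] on the same grid; voxelwise `<=` the input.
#' @export
compute_minip <- function(swi, slab = slab_spec()) {
  stopifnot(inherits(swi, "swi_volume"))
  if (is.numeric(slab)) slab <- slab_spec(slab)
  dz <- swi$spacing[3]
  if (slab$thickness_mm < dz)
    stop("slab (", slab$thickness_mm, " mm) is thinner than one slice (",
         dz, " mm)")
  nz <- dim(swi$data)[3]
  zc <- (seq_len(nz) - 1) * dz
  out <- swi$data
  half <- slab$thickness_mm / 2 + 1e-9
  if (slab$mode == "sliding") {
    for (k in seq_len(nz)) {
      win <- which(abs(zc - zc[k]) <= half)
      if (length(win) > 1L)
        out[, , k] <- Reduce(pmin, lapply(win, function(w) swi$data[, , w]))
    }
  } else {
    block <- pmin(floor(zc / slab$thickness_mm) + 1, nz)
    for (b in unique(block)) {
      win <- which(block == b)
      m <- Reduce(pmin, lapply(win, function(w) swi$data[, , w]))
      for (k in win) out[, , k] <- m
    }
  }
  swi_volume(out, spacing = swi$spacing, affine = swi$affine)
}
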