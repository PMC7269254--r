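#' @name segmentation
#' @title Slice-wise vein segmentation chain
#' @description
#' Veins are hypointense on SWI, so each axial slice is processed as:
#' contrast-limited adaptive histogram equalization ([enhance_contrast()]),
#' automatic threshold selection with Otsu's method ([otsu_threshold()]),
#' binarization with the dark-vein (inverted) convention
#' ([binarize_invert()]), and a morphological top-hat transform ([tophat()])
#' that removes bulky inverted-background structures while retaining thin
#' vessels. [extract_veins()] runs the chain independently on the SWI and
#' MinIP volumes and intersects the results with the hemisphere masks.
NULL

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# --- tile geometry for CLAHE -------------------------------------------------
#
# Positions are handled in exact integer arithmetic (pixel centre c = i - 1/2
# in units of 1/2 pixel) so that the tile assignment and the interpolation
# weights of a left-right mirrored slice are bit-exact mirrors of the
# originals. This makes the whole pipeline exactly equivariant under
# mirroring across the mid-sagittal plane.

# Hard tile assignment for histogram accumulation. A pixel centre exactly on
# an interior tile edge is pushed toward the image centre (mirror-symmetric
# tie rule); a centre that lies on an edge *and* on the image midline cannot
# be assigned symmetrically and is split half/half between the two tiles.
tile_assign <- function(n, ntiles) {
  pos <- 2L * seq_len(n) - 1L           # 2 * pixel centre
  a <- pos * ntiles
  den <- 2L * n
  q <- a %/% den
  r <- a %% den
  tile <- q + 1L
  on_edge <- r == 0L & q >= 1L & q <= ntiles - 1L
  tile[on_edge & pos > n] <- q[on_edge & pos > n]
  split <- on_edge & pos == n
  tile[split] <- NA_integer_
  list(tile = pmin(pmax(tile, 1L), ntiles), split = split, q = q)
}

# Bilinear interpolation weights between tile centres, exact rationals with
# denominator 2*n evaluated with a single floating-point division.
interp_weights <- function(n, ntiles) {
  a <- (2L * seq_len(n) - 1L) * ntiles
  den <- 2L * n
  vmax <- den * (ntiles - 1L)
  v <- pmin(pmax(a - n, 0L), vmax)
  q <- v %/% den
  r <- v %% den
  list(lo = q + 1L, hi = pmin(q + 2L, ntiles),
       wlo = (den - r) / den, whi = r / den)
}

clip_redistribute <- function(h, clip, iters = 50L) {
  for (i in seq_len(iters)) {
    excess <- sum(pmax(h - clip, 0))
    if (excess <= 0) break
    h <- pmin(h, clip) + excess / length(h)
  }
  h
}

# Same recurrence applied column-wise to a bins x ntile histogram matrix;
# converged tiles redistribute an excess of 0 and are left unchanged.
clip_redistribute_mat <- function(H, clip, iters = 50L) {
  bins <- nrow(H)
  clipm <- matrix(clip, bins, length(clip), byrow = TRUE)
  for (i in seq_len(iters)) {
    over <- pmax(H - clipm, 0)
    excess <- colSums(over)
    if (all(excess <= 0)) break
    H <- pmin(H, clipm) + matrix(excess / bins, bins, length(clip), byrow = TRUE)
  }
  H
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Equalizes grey values tile-wise with a clipped histogram, interpolating
#' the tile mappings bilinearly between tile centres. The operation is
#' restricted to the bounding box of the in-slice mask; pixels outside the
#' mask keep their original values. A slice whose in-mask region is empty
#' or constant is passed through unchanged.
#'
#' @param pixels numeric matrix, values in `[0, 1]` (clamped if slightly
#'   outside).
#' @param mask logical/0-1 matrix of valid brain pixels, same shape.
#' @param tiles integer(2), tile grid (default 8 x 8); reduced automatically
#'   when the bounding box is smaller than the tile grid.
#' @param clip_limit histogram clip limit as a fraction of the tile pixel
#'   count (default 0.01).
#' @param bins histogram bin count (default 256).
#' @return Matrix of the same shape with in-mask values equalized into
#'   `[0, 1]`.
#' @export
enhance_contrast <- function(pixels, mask, tiles = c(8, 8),
                             clip_limit = 0.01, bins = 256L) {
  stopifnot(is.matrix(pixels), all(dim(mask) == dim(pixels)))
  if (!all(is.finite(pixels))) stop("slice contains non-finite pixels")
  if (any(tiles < 1)) stop("'tiles' must be >= 1 in both directions")
  if (clip_limit <= 0 || clip_limit > 1) stop("'clip_limit' must be in (0, 1]")
  m <- mask > 0
  if (!any(m)) return(pixels)
  vals <- pixels[m]
  if (max(vals) == min(vals)) return(pixels)

  ri <- range(which(rowSums(m) > 0))
  ci <- range(which(colSums(m) > 0))
  sub <- clamp01(pixels[ri[1]:ri[2], ci[1]:ci[2], drop = FALSE])
  w <- nrow(sub); h <- ncol(sub)
  # each tile must span at least 8 pixels per axis: equalizing histograms of
  # only a handful of pixels amplifies noise instead of contrast
  ntx <- max(1L, min(as.integer(tiles[1]), w %/% 8L))
  nty <- max(1L, min(as.integer(tiles[2]), h %/% 8L))
  bins <- as.integer(bins)
  b <- matrix(pmin(floor(sub * bins), bins - 1L) + 1L, w, h)

  tx <- tile_assign(w, ntx)
  ty <- tile_assign(h, nty)
  ty$tile[is.na(ty$tile)] <- ty$q[is.na(ty$tile)] # y ties need no symmetry

  ntile <- ntx * nty
  tyi <- matrix(rep(ty$tile, each = w), w, h)
  txi <- matrix(tx$tile, w, h)
  key <- (txi - 1L) + ntx * (tyi - 1L)
  hist <- matrix(0, bins, ntile)
  main <- !is.na(key)
  acc <- tabulate(b[main] + bins * key[main], nbins = bins * ntile)
  hist <- hist + matrix(acc, bins, ntile)
  if (any(tx$split)) { # midline rows: half weight to both adjacent tiles
    rows <- which(tx$split)
    for (side in 0:1) {
      t_split <- tx$q[rows] + side
      keys <- (rep(t_split, times = h) - 1L) + ntx * (rep(ty$tile, each = length(rows)) - 1L)
      acc <- tabulate(b[rows, , drop = FALSE] + bins * keys, nbins = bins * ntile)
      hist <- hist + 0.5 * matrix(acc, bins, ntile)
    }
  }

  mids <- (seq_len(bins) - 0.5) / bins
  totals <- colSums(hist)
  clip <- pmax(clip_limit * totals, totals / bins)
  hc <- clip_redistribute_mat(hist, clip)
  csum <- apply(hc, 2, cumsum)
  tots <- colSums(hc)
  lut <- sweep(csum, 2, ifelse(tots > 0, tots, 1), "/")
  if (any(totals <= 0)) lut[, totals <= 0] <- mids

  ix <- interp_weights(w, ntx)
  iy <- interp_weights(h, nty)
  bx_lo <- matrix(ix$lo, w, h); bx_hi <- matrix(ix$hi, w, h)
  wx_lo <- matrix(ix$wlo, w, h); wx_hi <- matrix(ix$whi, w, h)
  by_lo <- matrix(rep(iy$lo, each = w), w, h)
  by_hi <- matrix(rep(iy$hi, each = w), w, h)
  wy_lo <- matrix(rep(iy$wlo, each = w), w, h)
  wy_hi <- matrix(rep(iy$whi, each = w), w, h)
  lu <- function(tx_, ty_) matrix(lut[cbind(as.vector(b),
                                            as.vector((ty_ - 1L) * ntx + tx_))], w, h)
  # symmetric summation order: the inner sums commute under x-mirroring
  out <- wy_lo * (wx_lo * lu(bx_lo, by_lo) + wx_hi * lu(bx_hi, by_lo)) +
         wy_hi * (wx_lo * lu(bx_lo, by_hi) + wx_hi * lu(bx_hi, by_hi))

  res <- pixels
  res[ri[1]:ri[2], ci[1]:ci[2]] <- out
  res[!m] <- pixels[!m]
  res[m] <- clamp01(res[m])
  res
}

#' Otsu's automatic threshold
#'
#' Computes the histogram of the in-mask pixels over `[0, 1]` and returns
#' the bin boundary that maximizes the between-class variance, equivalent
#' to an exhaustive search over all candidate cuts. Ties are broken toward
#' the smallest threshold. The two classes are `pixel < threshold` and
#' `pixel >= threshold`.
#'
#' @param pixels numeric matrix in `[0, 1]`.
#' @param mask logical/0-1 matrix of valid pixels.
#' @param bins histogram bin count (default 256).
#' @return The threshold value in `(0, 1)`.
#' @export
otsu_threshold <- function(pixels, mask, bins = 256L) {
  m <- mask > 0
  vals <- pixels[m]
  if (length(vals) == 0L || max(vals) == min(vals))
    stop(degenerate_slice_condition("degenerate slice: in-mask pixels are empty or constant"))
  bins <- as.integer(bins)
  b <- pmin(floor(clamp01(vals) * bins), bins - 1L) + 1L
  h <- tabulate(b, nbins = bins)
  n <- sum(h)
  mids <- (seq_len(bins) - 0.5) / bins
  w0 <- cumsum(h)[-bins]
  w1 <- n - w0
  mu0 <- cumsum(h * mids)[-bins]
  muT <- sum(h * mids)
  valid <- w0 > 0 & w1 > 0
  sb <- rep(-Inf, bins - 1L)
  sb[valid] <- (muT * w0[valid] - n * mu0[valid])^2 / (w0[valid] * w1[valid])
  t_idx <- which.max(sb) # first maximum = smallest threshold
  t_idx / bins
}

degenerate_slice_condition <- function(msg) {
  structure(class = c("swivein_degenerate_slice", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Binarize a slice with the dark-vein convention
#'
#' The clinical convention inverts the slice so veins appear white and then
#' thresholds; because `1 - x > 1 - t` is equivalent to `x < t`, inversion
#' and thresholding are fused into a single strict comparison. A pixel
#' exactly at the threshold maps to background.
#'
#' @param pixels numeric matrix in `[0, 1]`.
#' @param mask logical/0-1 matrix; only in-mask pixels can be foreground.
#' @param threshold scalar in `(0, 1)`.
#' @return Integer 0/1 matrix: 1 where `pixels < threshold` inside the mask.
#' @export
binarize_invert <- function(pixels, mask, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 1)
  out <- (pixels < threshold) & (mask > 0)
  storage.mode(out) <- "integer"
  out
}

#' Structuring elements for binary morphology
#'
#' @param shape `"square"` (n x n, default 3 x 3) or `"disk"` (radius given
#'   in mm, converted to pixels with the in-plane spacing).
#' @param size side length in pixels for `"square"`, radius in mm for
#'   `"disk"`.
#' @param spacing in-plane voxel spacing (mm), used for `"disk"` only.
#' @return 0/1 matrix with odd dimensions.
#' @export
structuring_element <- function(shape = c("square", "disk"), size = 3,
                                spacing = c(1, 1)) {
  shape <- match.arg(shape)
  if (shape == "square") {
    n <- as.integer(size)
    if (n < 1L) stop("square structuring element needs size >= 1")
    matrix(1L, n, n)
  } else {
    if (size <= 0) stop("disk radius must be positive")
    ri <- ceiling(size / spacing[1]); ci <- ceiling(size / spacing[2])
    x <- (-ri:ri) * spacing[1]; y <- (-ci:ci) * spacing[2]
    se <- outer(x^2, y^2, "+") <= size^2
    storage.mode(se) <- "integer"
    se
  }
}

shift_pad0 <- function(m, di, dj) {
  # shift a matrix by (di, dj), padding with 0 (background)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + di):min(nr, nr + di)
  cs <- max(1, 1 + dj):min(nc, nc + dj)
  if (length(rs) > 0 && length(cs) > 0)
    out[rs, cs] <- m[rs - di, cs - dj]
  out
}

se_offsets <- function(se) {
  ctr <- (dim(se) + 1) %/% 2
  w <- which(se > 0, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("structuring element is empty")
  cbind(w[, 1] - ctr[1], w[, 2] - ctr[2])
}

#' Binary erosion, dilation, opening
#'
#' Out-of-image pixels are treated as background (zero padding), so
#' foreground touching the border erodes.
#'
#' @param m 0/1 matrix.
#' @param se 0/1 structuring element matrix.
#' @return 0/1 matrix.
#' @export
binary_erode <- function(m, se = structuring_element()) {
  off <- se_offsets(se)
  out <- matrix(1L, nrow(m), ncol(m))
  for (r in seq_len(nrow(off)))
    out <- out & shift_pad0(m, -off[r, 1], -off[r, 2])
  storage.mode(out) <- "integer"
  out
}

#' @rdname binary_erode
#' @export
binary_dilate <- function(m, se = structuring_element()) {
  off <- se_offsets(se)
  out <- matrix(0L, nrow(m), ncol(m))
  for (r in seq_len(nrow(off)))
    out <- out | shift_pad0(m, off[r, 1], off[r, 2])
  storage.mode(out) <- "integer"
  out
}

#' @rdname binary_erode
#' @export
binary_opening <- function(m, se = structuring_element()) {
  binary_dilate(binary_erode(m, se), se)
}

#' Morphological white top-hat of a binary slice
#'
#' `tophat(I) = I - opening(I, se)`: the difference between the slice and
#' its morphological opening (erosion followed by dilation). Connected
#' structures that contain a full translate of the structuring element are
#' removed, so the bulky inverted background disappears while thin vein
#' cross-sections survive.
#'
#' @param m 0/1 matrix.
#' @param se structuring element (default 3 x 3 square).
#' @return 0/1 matrix, a subset of the input.
#' @export
tophat <- function(m, se = structuring_element()) {
  if (!is_binary(m)) stop("top-hat input must be binary")
  out <- (m > 0) & !(binary_opening(m, se) > 0)
  storage.mode(out) <- "integer"
  out
}

#' Segmentation chain parameters
#'
#' @param clahe_tiles CLAHE tile grid (default 8 x 8).
#' @param clahe_clip CLAHE clip limit, fraction of tile pixels (default 0.01).
#' @param otsu_bins histogram bins for Otsu thresholding (default 256).
#' @param tophat_shape `"square"` or `"disk"`.
#' @param tophat_size square side in pixels, or disk radius in mm.
#' @return A `vein_params` list.
#' @export
vein_params <- function(clahe_tiles = c(8, 8), clahe_clip = 0.01,
                        otsu_bins = 256L,
                        tophat_shape = "square", tophat_size = 3) {
  structure(list(clahe_tiles = clahe_tiles, clahe_clip = clahe_clip,
                 otsu_bins = otsu_bins, tophat_shape = tophat_shape,
                 tophat_size = tophat_size),
            class = "vein_params")
}

# Run the full slice-wise chain on one volume -> binary 3D vein candidate map.
process_volume_slicewise <- function(vol, slice_mask, params) {
  d <- dim(vol$data)
  se <- structuring_element(params$tophat_shape, params$tophat_size,
                            spacing = vol$spacing[1:2])
  out <- array(0L, dim = d)
  skipped <- integer(0)
  for (k in seq_len(d[3])) {
    m <- slice_mask[, , k]
    if (!any(m)) { skipped <- c(skipped, k); next }
    px <- vol$data[, , k]
    v <- px[m]
    rng <- range(v)
    if (rng[1] == rng[2]) { skipped <- c(skipped, k); next }
    p01 <- clamp01((px - rng[1]) / (rng[2] - rng[1]))
    enh <- enhance_contrast(p01, m, tiles = params$clahe_tiles,
                            clip_limit = params$clahe_clip,
                            bins = params$otsu_bins)
    thr <- tryCatch(otsu_threshold(enh, m, bins = params$otsu_bins),
                    swivein_degenerate_slice = function(e) NA_real_)
    if (is.na(thr)) { skipped <- c(skipped, k); next }
    out[, , k] <- tophat(binarize_invert(enh, m, thr), se)
  }
  attr(out, "skipped_slices") <- skipped
  out
}

#' Extract per-hemisphere vein masks from SWI and MinIP
#'
#' Runs the slice-wise chain (CLAHE, Otsu, binarize-invert, top-hat)
#' independently on the SWI volume (giving the candidate map I1) and on the
#' MinIP volume (I2), then intersects with the hemisphere masks:
#' `V_left = I1 & I2 & H_left`, `V_right = I1 & I2 & H_right`. Slices with
#' empty or constant in-mask regions contribute no veins and are recorded
#' in `skipped_slices`.
#'
#' @param swi SWI [swi_volume].
#' @param minip MinIP [swi_volume] on the same grid (e.g. from
#'   [compute_minip()]).
#' @param hemis a `hemisphere_mask` from [split_hemispheres()].
#' @param params a [vein_params()] list.
#' @return An object of class `vein_mask`: logical arrays `left`, `right`,
#'   candidate maps `i1`, `i2` (0/1), `spacing`, `affine`,
#'   `skipped_slices`.
#' @export
extract_veins <- function(swi, minip, hemis, params = vein_params()) {
  stopifnot(inherits(swi, "swi_volume"), inherits(minip, "swi_volume"),
            inherits(hemis, "hemisphere_mask"))
  if (!all(dim(swi$data) == dim(minip$data)) ||
      max(abs(swi$affine - minip$affine)) > 1e-6)
    stop("SWI and MinIP are not on the same grid")
  if (!all(dim(swi$data) == dim(hemis$left)))
    stop("hemisphere masks are not on the SWI grid")
  hmask <- hemis$left | hemis$right
  if (!any(hmask)) stop("brain mask (minus exclusion) is empty")
  i1 <- process_volume_slicewise(swi, hmask, params)
  i2 <- process_volume_slicewise(minip, hmask, params)
  both <- (i1 > 0) & (i2 > 0)
  structure(list(left = both & hemis$left,
                 right = both & hemis$right,
                 i1 = i1, i2 = i2,
                 spacing = hemis$spacing, affine = hemis$affine,
                 skipped_slices = sort(unique(c(attr(i1, "skipped_slices"),
                                                attr(i2, "skipped_slices"))))),
            class = "vein_mask")
}
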