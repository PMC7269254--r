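#' Specification for a synthetic SWI vascular phantom
#'
#' The phantom emulates the appearance that the segmentation chain relies
#' on: a mirror-symmetric ellipsoidal "brain" of homogeneous bright
#' parenchyma on a dark background, thin hypointense tubular veins of
#' roughly 1-3 voxel diameter drawn as smooth random polyline tubes in a
#' cortical shell, a smooth low-order multiplicative intensity bias, and
#' additive Gaussian noise. Left/right vein load is controlled
#' independently so hemispheric asymmetry is a known ground truth.
#'
#' @param dim grid shape (default 96 x 112 x 80).
#' @param spacing voxel spacing in mm (default 1 mm isotropic).
#' @param n_veins_left,n_veins_right vein counts per hemisphere.
#' @param vein_radius_mm range the tube radius is drawn from (mm).
#' @param vein_contrast fractional intensity drop of vein voxels relative
#'   to parenchyma, in `(0, 1]`.
#' @param bias_amplitude amplitude of the multiplicative bias field,
#'   fraction of parenchyma intensity.
#' @param noise_sd additive Gaussian noise SD, fraction of parenchyma
#'   intensity.
#' @param seed integer seed fixing all randomness.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(dim = c(96, 112, 80), spacing = c(1, 1, 1),
                         n_veins_left = 45, n_veins_right = 45,
                         vein_radius_mm = c(0.5, 1.2),
                         vein_contrast = 0.6,
                         bias_amplitude = 0.1,
                         noise_sd = 0.03,
                         seed = 1L) {
  if (n_veins_left < 0 || n_veins_right < 0) stop("vein counts must be >= 0")
  if (vein_contrast <= 0 || vein_contrast > 1)
    stop("'vein_contrast' must be in (0, 1]")
  if (min(vein_radius_mm) < min(spacing) / 2)
    stop("vein radius must be at least half the smallest voxel spacing")
  if (noise_sd < 0 || bias_amplitude < 0)
    stop("noise and bias amplitudes must be >= 0")
  structure(list(dim = as.integer(dim), spacing = as.numeric(spacing),
                 n_veins_left = n_veins_left, n_veins_right = n_veins_right,
                 vein_radius_mm = vein_radius_mm,
                 vein_contrast = vein_contrast,
                 bias_amplitude = bias_amplitude, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Symmetric grid: voxel centres straddle x = 0 (no voxel on the midline for
# even dimensions), so mirroring and hemisphere splitting are exact.
phantom_affine <- function(dim, spacing) {
  M <- diag(c(spacing, 1))
  M[1:3, 4] <- -(dim - 1) * spacing / 2
  M
}

# Linear voxel indices within radius r (mm) of the segment p -> q.
rasterize_segment <- function(p, q, r, xs, ys, zs, d) {
  lo <- pmin(p, q) - r; hi <- pmax(p, q) + r
  ii <- which(xs >= lo[1] & xs <= hi[1])
  jj <- which(ys >= lo[2] & ys <= hi[2])
  kk <- which(zs >= lo[3] & zs <= hi[3])
  if (!length(ii) || !length(jj) || !length(kk)) return(integer(0))
  nx <- length(ii); ny <- length(jj); nz <- length(kk)
  X <- rep(xs[ii], times = ny * nz)
  Y <- rep(rep(ys[jj], each = nx), times = nz)
  Z <- rep(zs[kk], each = nx * ny)
  dv <- q - p
  len2 <- sum(dv^2)
  if (len2 == 0) {
    d2 <- (X - p[1])^2 + (Y - p[2])^2 + (Z - p[3])^2
  } else {
    t <- ((X - p[1]) * dv[1] + (Y - p[2]) * dv[2] + (Z - p[3]) * dv[3]) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (X - (p[1] + t * dv[1]))^2 + (Y - (p[2] + t * dv[2]))^2 +
          (Z - (p[3] + t * dv[3]))^2
  }
  w <- which(d2 <= r^2) - 1L
  i <- w %% nx; rest <- w %/% nx
  j <- rest %% ny; k <- rest %/% ny
  (ii[i + 1L] - 1L) + d[1] * ((jj[j + 1L] - 1L) + d[2] * (kk[k + 1L] - 1L)) + 1L
}

draw_vein <- function(start, radius, semi, xs, ys, zs, dims) {
  total_len <- stats::runif(1, 15, 35)
  step <- 2
  n_steps <- max(2L, round(total_len / step))
  # superficial cortical veins run roughly radially inward from the cortex
  # and ascend toward the dural sinuses, so seed the walk with an
  # inward-radial plus superior direction rather than an isotropic one
  inward <- -start / semi^2
  inward <- inward / sqrt(sum(inward^2))
  dir <- 0.5 * inward + c(0, 0, 0.9) + stats::rnorm(3, sd = 0.25)
  dir <- dir / sqrt(sum(dir^2))
  pts <- matrix(0, n_steps + 1, 3)
  pts[1, ] <- start
  for (s in seq_len(n_steps)) {
    dir <- dir + stats::rnorm(3, sd = 0.2)
    dir <- dir / sqrt(sum(dir^2))
    pts[s + 1, ] <- pts[s, ] + step * dir
  }
  idx <- lapply(seq_len(n_steps), function(s)
    rasterize_segment(pts[s, ], pts[s + 1, ], radius, xs, ys, zs, dims))
  unique(unlist(idx))
}

#' Generate a synthetic SWI/MinIP phantom with ground truth
#'
#' Deterministic under the spec's seed: identical specs produce
#' bit-identical volumes. Veins are placed with their seed points in the
#' cortical shell (outer 40% of the normalized brain-ellipsoid radius) of
#' their hemisphere and clipped to that hemisphere, so the ground-truth
#' left/right vein masks are disjoint by construction. The MinIP volume is
#' derived from the noisy SWI volume with [compute_minip()].
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom_truth` list: `swi`, `minip`, `brain_mask`
#'   ([swi_volume]s), logical `vein_mask_left`/`vein_mask_right`,
#'   `true_acvv_left`/`true_acvv_right` (ml), `true_ndcvv` (%),
#'   `true_side`, and the `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  d <- spec$dim; sp <- spec$spacing
  aff <- phantom_affine(d, sp)
  xs <- aff[1, 1] * (seq_len(d[1]) - 1) + aff[1, 4]
  ys <- aff[2, 2] * (seq_len(d[2]) - 1) + aff[2, 4]
  zs <- aff[3, 3] * (seq_len(d[3]) - 1) + aff[3, 4]
  semi <- 0.84 * d * sp / 2 # brain ellipsoid semi-axes within grid extents

  r2 <- outer(outer((xs / semi[1])^2, (ys / semi[2])^2, "+"),
              (zs / semi[3])^2, "+")
  brain <- r2 <= 1

  shell <- brain & r2 >= 0.36 # outer 40% of the normalized radius
  xarr <- array(xs, d)
  place_hemi <- function(n_veins, left) {
    out <- array(FALSE, d)
    hemi_ok <- function(idx) if (left) xarr[idx] < 0 else xarr[idx] > 0
    pool <- which(shell & (if (left) xarr < 0 else xarr > 0))
    if (n_veins > 0 && length(pool) == 0)
      stop("no cortical-shell voxels available for vein placement")
    for (v in seq_len(n_veins)) {
      placed <- FALSE
      for (try in 1:10) {
        vox <- pool[sample.int(length(pool), 1)]
        idx <- arrayInd(vox, d)
        start <- c(xs[idx[1]], ys[idx[2]], zs[idx[3]])
        radius <- stats::runif(1, spec$vein_radius_mm[1], spec$vein_radius_mm[2])
        tube <- draw_vein(start, radius, semi, xs, ys, zs, d)
        tube <- tube[brain[tube] & hemi_ok(tube)] # clip to hemisphere
        if (length(tube)) { out[tube] <- TRUE; placed <- TRUE; break }
      }
      if (!placed)
        stop("failed to place a vein after bounded retries; ",
             "check the phantom spec")
    }
    out
  }
  vein_left <- place_hemi(spec$n_veins_left, left = TRUE)
  vein_right <- place_hemi(spec$n_veins_right, left = FALSE)

  parenchyma <- 1
  img <- array(0, d)
  img[brain] <- parenchyma
  img[vein_left | vein_right] <- parenchyma * (1 - spec$vein_contrast)

  if (spec$bias_amplitude > 0) {
    u <- array(xs / max(abs(xs)), d)
    v <- array(rep(ys / max(abs(ys)), each = d[1]), d)
    w <- array(rep(zs / max(abs(zs)), each = d[1] * d[2]), d)
    cf <- stats::runif(6, -1, 1)
    f <- cf[1] * u + cf[2] * v + cf[3] * w +
         cf[4] * u * v + cf[5] * v * w + cf[6] * (u^2 - v^2)
    f <- f / max(abs(f))
    img <- img * (1 + spec$bias_amplitude * f)
  }
  if (spec$noise_sd > 0)
    img <- img + stats::rnorm(length(img), 0, spec$noise_sd * parenchyma)

  swi <- swi_volume(img, spacing = sp, affine = aff)
  minip <- compute_minip(swi, slab_spec(14))
  brain_vol <- swi_volume(array(as.numeric(brain), d), spacing = sp, affine = aff)

  vml <- acvv(vein_left, sp)
  vmr <- acvv(vein_right, sp)
  truth <- asymmetry(vml, vmr)
  structure(list(swi = swi, minip = minip, brain_mask = brain_vol,
                 vein_mask_left = vein_left, vein_mask_right = vein_right,
                 true_acvv_left = vml, true_acvv_right = vmr,
                 true_ndcvv = truth$ndcvv, true_side = truth$cdh_side,
                 spec = spec),
            class = "phantom_truth")
}

#' Sweep the phantom asymmetry level and measure recovery
#'
#' For each left/right load ratio and seed, generates a phantom with
#' `n_veins_left = round(ratio * n_veins_right)`, runs the full
#' quantification pipeline, and tabulates true versus measured asymmetry.
#'
#' @param base_spec a [phantom_spec()]; its `n_veins_right` is the base
#'   load and its other fields are held fixed.
#' @param levels numeric vector (`>= 2` values) of left/right load ratios.
#' @param seeds_per_level number of seeds per level.
#' @param base_seed seeds are `base_seed + 1000 * level_index + s`.
#' @param params segmentation parameters ([vein_params()]).
#' @return data.frame with columns `level`, `seed`, `true_ndcvv`,
#'   `measured_ndcvv`, `true_side`, `measured_side`, `side_correct`
#'   (a tie counts as incorrect when the truth is asymmetric),
#'   `measured_dcvv`.
#' @export
sweep_asymmetry <- function(base_spec, levels, seeds_per_level = 20,
                            base_seed = 100L, params = vein_params()) {
  stopifnot(inherits(base_spec, "phantom_spec"))
  if (length(levels) < 2) stop("need at least 2 asymmetry levels")
  rows <- list()
  for (li in seq_along(levels)) {
    for (s in seq_len(seeds_per_level)) {
      sp <- base_spec
      sp$n_veins_left <- round(levels[li] * base_spec$n_veins_right)
      sp$seed <- as.integer(base_seed + 1000L * li + s)
      ph <- generate_phantom(sp)
      res <- quantify_phantom(ph, params = params)$result
      correct <- if (ph$true_side == "tie") res$cdh_side == "tie"
                 else res$cdh_side == ph$true_side
      rows[[length(rows) + 1L]] <- data.frame(
        level = levels[li], seed = sp$seed,
        true_ndcvv = ph$true_ndcvv, measured_ndcvv = res$ndcvv,
        true_side = ph$true_side, measured_side = res$cdh_side,
        side_correct = correct, measured_dcvv = res$dcvv,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
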