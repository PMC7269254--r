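test_that("volume construction enforces invariants and voxel volume in ml", {
  v <- swi_volume(array(0, c(10, 10, 10)))
  expect_equal(v$spacing, c(1, 1, 1))
  expect_equal(voxel_volume_ml(v), 0.001)
  expect_equal(voxel_volume_ml(swi_volume(array(0, c(2, 2, 2)),
                                          spacing = c(1.1, 0.9, 1.8))),
               1.1 * 0.9 * 1.8 / 1000)
  expect_error(swi_volume(array(NA_real_, c(2, 2, 2))), "non-finite")
  expect_error(swi_volume(array(0, c(2, 2, 2)), spacing = c(1, -1, 1)),
               "positive")
  expect_error(swi_volume(array(0, c(2, 2))), "3D")
  expect_error(swi_volume(array(0, c(2, 2, 2)), affine = matrix(0, 4, 4)),
               "singular")
})

test_that("NIfTI round trip preserves intensities, masks, and spacing", {
  withr::local_seed(1)
  v <- swi_volume(array(runif(4 * 5 * 6, 0, 100), c(4, 5, 6)),
                  spacing = c(1.1, 0.9, 1.8),
                  affine = diag(c(1.1, 0.9, 1.8, 1)))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f)
  # pixdim is float32 in the NIfTI-1 header
  expect_equal(v2$spacing, c(1.1, 0.9, 1.8), tolerance = 1e-6)
  expect_lt(max(abs(v2$data - v$data)) / diff(range(v$data)), 1e-5)

  m <- swi_volume(array(as.numeric(runif(4 * 5 * 6) > 0.5), c(4, 5, 6)))
  fm <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(m, fm)
  expect_identical(read_volume(fm)$data, m$data) # 0/1 exact in float32

  expect_error(read_volume(file.path(tempdir(), "nope.nii.gz")), "not found")
})

test_that("header scaling slope/intercept is applied on load", {
  skip_if_not_installed("oro.nifti")
  raw <- array(50, c(4, 4, 4))
  img <- oro.nifti::nifti(raw, datatype = 4) # int16
  img@scl_slope <- 2
  img@scl_inter <- 1
  f <- withr::local_tempfile()
  oro.nifti::writeNIfTI(img, f) # adds .nii.gz
  v <- read_volume(paste0(f, ".nii.gz"))
  expect_equal(unique(as.vector(v$data)), 101) # 50 * 2 + 1
})

test_that("a file stored in a flipped axis convention canonicalizes to the same world content", {
  withr::local_seed(2)
  dat <- array(runif(6 * 5 * 4), c(6, 5, 4))
  aff <- diag(c(1, 1, 1, 1)); aff[1:3, 4] <- c(-2.5, -2, -1.5)
  v <- swi_volume(dat, affine = aff)
  f1 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, f1)
  # same world content stored with a flipped first axis
  aff_f <- aff; aff_f[1, 1] <- -1; aff_f[1, 4] <- 2.5
  v_f <- swi_volume(dat[6:1, , ], affine = aff_f)
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v_f, f2)
  a <- read_volume(f1); b <- read_volume(f2)
  expect_equal(a$data, b$data, tolerance = 1e-6)
  expect_equal(a$affine, b$affine, tolerance = 1e-6)
})

test_that("hemisphere split assigns voxels by the sign of world x", {
  # 4x1x1 grid with centres at x = -1.5, -0.5, 0.5, 1.5
  aff <- diag(4); aff[1, 4] <- -1.5
  m <- swi_volume(array(1, c(4, 1, 1)), affine = aff)
  hs <- split_hemispheres(m)
  expect_equal(which(hs$left), c(1L, 2L))
  expect_equal(which(hs$right), c(3L, 4L))
  expect_equal(sum(hs$excluded), 0)
})

test_that("midline voxels are excluded from both hemispheres", {
  aff <- diag(4); aff[1, 4] <- -1 # centres at -1, 0, 1
  m <- swi_volume(array(1, c(3, 1, 1)), affine = aff)
  hs <- split_hemispheres(m)
  expect_equal(which(hs$left), 1L)
  expect_equal(which(hs$right), 3L)
  expect_equal(which(hs$excluded), 2L)
})

test_that("symmetric masks split into equal hemispheres and partition the brain", {
  sp <- small_phantom_spec(seed = 3)
  ph <- generate_phantom(sp)
  hs <- split_hemispheres(ph$brain_mask)
  expect_equal(sum(hs$left), sum(hs$right))
  # empty exclusion: left + right + midline partition the brain mask
  expect_equal(sum(hs$left) + sum(hs$right) + sum(hs$excluded),
               sum(ph$brain_mask$data > 0))
  expect_false(any(hs$left & hs$right))
  aff_s <- diag(4); aff_s[1, 4] <- -1.5
  expect_error(split_hemispheres(swi_volume(array(2, c(4, 4, 4)), affine = aff_s)),
               "binary")
  # grid entirely on one side of x = 0 cannot be split
  aff <- diag(4); aff[1, 4] <- 5
  expect_error(split_hemispheres(swi_volume(array(1, c(4, 4, 4)), affine = aff)),
               "straddle")
})

test_that("exclusion mask is removed from both hemispheres and matches brute force", {
  grid_aff <- diag(4); grid_aff[1:3, 4] <- c(-34.5, -44.5, -29.5)
  grid <- swi_volume(array(0, c(70, 90, 60)), affine = grid_aff)
  radii <- c(30, 40, 25)
  ex <- make_exclusion_mask(grid, center = c(0, 0, 0), radii = radii)
  # independent brute-force point-in-ellipsoid scan
  pts <- expand.grid(x = (0:69) - 34.5, y = (0:89) - 44.5, z = (0:59) - 29.5)
  n_oracle <- sum((pts$x / 30)^2 + (pts$y / 40)^2 + (pts$z / 25)^2 <= 1)
  expect_equal(sum(ex$data), n_oracle)
  expect_error(make_exclusion_mask(grid, radii = c(0, 0, 0)), "positive")

  brain <- swi_volume(array(1, c(70, 90, 60)), affine = grid_aff)
  hs <- split_hemispheres(brain, ex)
  expect_false(any((hs$left | hs$right) & (ex$data > 0)))
  expect_equal(sum(hs$excluded), sum(ex$data > 0)) # no midline voxels here
})

test_that("hemisphere split is an involution under mirroring", {
  withr::local_seed(4)
  aff <- diag(4); aff[1:3, 4] <- c(-5.5, -5.5, -2.5) # symmetric 12-wide grid
  for (i in 1:5) {
    m <- array(as.numeric(runif(12 * 12 * 6) > 0.4), c(12, 12, 6))
    v <- swi_volume(m, affine = aff)
    hs <- split_hemispheres(v)
    hm <- split_hemispheres(mirror_volume(v))
    expect_identical(hm$left, hs$right[12:1, , ])
    expect_identical(hm$right, hs$left[12:1, , ])
  }
})
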