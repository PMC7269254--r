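#' Absolute cerebral vein volume (ACVV) in ml
#'
#' Voxel count of a binary vein mask times the voxel volume, over all axial
#' slices of one hemisphere.
#'
#' @param mask binary 3D array (or logical array) of vein voxels.
#' @param spacing numeric(3), voxel edge lengths in mm.
#' @return Volume in ml.
#' @examples
#' acvv(array(1, c(10, 10, 10)), c(1, 1, 1)) # 1 ml
#' @export
acvv <- function(mask, spacing) {
  if (!is_binary(mask)) stop("vein mask must be binary (0/1)")
  if (any(spacing <= 0)) stop("spacing must be positive")
  sum(mask > 0) * prod(spacing) / 1000
}

#' Hemispheric vein-volume asymmetry statistics
#'
#' The hemisphere with the higher ACVV is the calculated dominant
#' hemisphere (CDH), the other the calculated non-dominant hemisphere
#' (CNDH). The asymmetry statistics are `DCVV = CDH - CNDH` (ml) and its
#' normalized form `nDCVV = 100 * DCVV / (CDH + CNDH)` (%). Equal volumes
#' are a tie: `cdh_side = "tie"`, DCVV = 0, and nDCVV is defined as 0
#' (including the degenerate case of two empty masks).
#'
#' @param acvv_left,acvv_right per-hemisphere vein volumes in ml, `>= 0`.
#' @return An `asymmetry_result` list: `acvv_left`, `acvv_right`,
#'   `cdh_side` (`"left"`, `"right"` or `"tie"`), `cdh`, `cndh`, `dcvv`
#'   (ml), `ndcvv` (percent).
#' @examples
#' asymmetry(3, 1) # dcvv 2 ml, ndcvv 50%
#' @export
asymmetry <- function(acvv_left, acvv_right) {
  if (acvv_left < 0 || acvv_right < 0) stop("vein volumes must be >= 0")
  cdh <- max(acvv_left, acvv_right)
  cndh <- min(acvv_left, acvv_right)
  side <- if (acvv_left == acvv_right) "tie"
          else if (acvv_left > acvv_right) "left" else "right"
  dcvv <- cdh - cndh
  ndcvv <- if (cdh + cndh == 0) 0 else 100 * dcvv / (cdh + cndh)
  structure(list(acvv_left = acvv_left, acvv_right = acvv_right,
                 cdh_side = side, cdh = cdh, cndh = cndh,
                 dcvv = dcvv, ndcvv = ndcvv),
            class = "asymmetry_result")
}

#' @export
print.asymmetry_result <- function(x, ...) {
  cat(sprintf(
    "ACVV left %.3f ml, right %.3f ml | CDH %s | DCVV %.3f ml | nDCVV %.2f%%\n",
    x$acvv_left, x$acvv_right, x$cdh_side, x$dcvv, x$ndcvv))
  invisible(x)
}

#' One-row per-subject data frame of asymmetry results
#'
#' @param result an `asymmetry_result`.
#' @param subject_id subject identifier.
#' @return data.frame with columns `subject_id`, `acvv_left`, `acvv_right`,
#'   `cdh_side`, `dcvv_ml`, `ndcvv_pct`.
#' @export
asymmetry_row <- function(result, subject_id = NA_character_) {
  stopifnot(inherits(result, "asymmetry_result"))
  data.frame(subject_id = subject_id,
             acvv_left = result$acvv_left, acvv_right = result$acvv_right,
             cdh_side = result$cdh_side, dcvv_ml = result$dcvv,
             ndcvv_pct = result$ndcvv, stringsAsFactors = FALSE)
}
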