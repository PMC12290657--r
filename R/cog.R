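# Quadrant centre-of-gravity analysis: four hemisphere-by-superior/inferior
# ROIs, z-weighted centroids of supra-zero activation, and per-axis paired
# tests of the MCFT - SUFF shift across subjects.

#' Quadrant ROIs from a label volume
#'
#' Four masks: hemisphere (left/right) crossed with a superior and an
#' inferior lobule set.  Quadrant codes: `RU`, `RL`, `LU`, `LL` (right/left
#' upper/lower).
#'
#' @param labels integer label array.
#' @param superior_lobules,inferior_lobules non-empty per-hemisphere label
#'   sets, given as base labels common to both hemispheres when
#'   `hemi_labels` is supplied, or as explicit labels.
#' @param hemi_labels list with `left` and `right` label vectors defining
#'   hemisphere membership (e.g. `anatomy$hemispheres`).
#' @return named list of logical masks (`RU`, `RL`, `LU`, `LL`), pairwise
#'   disjoint.
#' @export
quadrant_rois <- function(labels, superior_lobules, inferior_lobules,
                          hemi_labels) {
  if (!length(superior_lobules) || !length(inferior_lobules))
    stop("quadrant_rois: superior and inferior lobule sets must be non-empty")
  pick <- function(hemi, set) {
    lb <- intersect(hemi_labels[[hemi]], set)
    if (!length(lb))
      stop("quadrant_rois: no ", hemi, " labels in the requested set")
    array(labels %in% lb, dim(labels))
  }
  out <- list(RU = pick("right", superior_lobules),
              RL = pick("right", inferior_lobules),
              LU = pick("left", superior_lobules),
              LL = pick("left", inferior_lobules))
  ov <- out$RU & out$RL | out$LU & out$LL | (out$RU | out$RL) & (out$LU | out$LL)
  if (any(ov)) stop("quadrant_rois: quadrant masks overlap")
  out
}

#' Centre of gravity of supra-zero activation
#'
#' z-weighted centroid over mask voxels with `z > 0` (strict), in the mm
#' frame with the origin at voxel (1,1,1) and the first axis running
#' left-to-right (positive delta-x = rightward).
#'
#' @param zmap `contrast_map` or z array.
#' @param mask non-empty logical ROI.
#' @param voxel_size_mm voxel size (taken from the map if absent).
#' @param weighted z-weighted centroid (default) or unweighted binary
#'   centroid.
#' @return object of class `cog_result`: `cog_mm` (length 3),
#'   `total_weight`, `n_voxels`.
#' @export
centre_of_gravity <- function(zmap, mask, voxel_size_mm = c(1, 1, 1),
                              weighted = TRUE) {
  z <- if (inherits(zmap, "contrast_map")) zmap$z else zmap
  if (!any(mask > 0)) stop("centre_of_gravity: empty mask")
  sel <- which(mask > 0 & !is.na(z) & z > 0)
  if (!length(sel))
    stop(errorCondition("centre_of_gravity: no voxel with z > 0 in the mask",
                        class = "lobulae_empty_cluster_error"))
  w <- if (weighted) z[sel] else rep(1, length(sel))
  pos <- voxel_to_mm(arrayInd(sel, dim(z)), voxel_size_mm)
  structure(list(cog_mm = colSums(pos * w) / sum(w), total_weight = sum(w),
                 n_voxels = length(sel)),
            class = "cog_result")
}

#' Centre-of-gravity shift analysis across subjects
#'
#' Per quadrant and axis: the per-subject shift `delta = cog(MCFT) -
#' cog(SUFF)` (sign convention: positive delta-x = rightward), its mean and
#' SD, and a two-sided paired t-test across subjects.
#'
#' @param cog_table data frame with columns `subject`, `quadrant`,
#'   `condition`, `x`, `y`, `z` (one row per subject x quadrant x
#'   condition; incomplete pairs are dropped).
#' @param conditions length-2 character: the minuend and subtrahend
#'   conditions (default `c("MCFT", "SUFF")`).
#' @return data frame with one row per quadrant x axis: `quadrant`, `axis`,
#'   `n`, `mean_delta_mm`, `sd_delta_mm`, `t`, `df`, `p`.
#' @export
cog_shift_analysis <- function(cog_table, conditions = c("MCFT", "SUFF")) {
  stopifnot(all(c("subject", "quadrant", "condition", "x", "y", "z") %in%
                  names(cog_table)))
  res <- list()
  for (q in unique(cog_table$quadrant)) {
    tq <- cog_table[cog_table$quadrant == q, ]
    a <- tq[tq$condition == conditions[1], ]
    b <- tq[tq$condition == conditions[2], ]
    common <- intersect(a$subject, b$subject)
    if (length(common) < 2) next
    a <- a[match(common, a$subject), ]
    b <- b[match(common, b$subject), ]
    for (ax in c("x", "y", "z")) {
      tt <- paired_t(a[[ax]], b[[ax]])
      res[[length(res) + 1L]] <- data.frame(
        quadrant = q, axis = ax, n = length(common),
        mean_delta_mm = tt$mean_diff, sd_delta_mm = tt$sd_diff,
        t = tt$t, df = tt$df, p = tt$p)
    }
  }
  if (!length(res)) stop("cog_shift_analysis: no quadrant with >= 2 complete pairs")
  do.call(rbind, res)
}
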