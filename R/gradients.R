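# Iso-distance gradient steps between two boundary masks: the cerebellar
# analogue of cortical-depth layering.  Distances are geodesic within the
# ROI (26-connected, metric edge weights) so that layers cannot jump across
# fissure gaps in folded geometry.

#' Geodesic distance to a source mask
#'
#' Multi-source shortest-path distance over the 26-connected voxel graph,
#' with edge weights equal to the Euclidean distance between voxel centres
#' in mm.  Paths are confined to `roi | sources` (`metric = "geodesic"`) or
#' may cross the whole grid (`metric = "euclidean"`, a 26-connected
#' approximation of the ambient Euclidean distance).
#'
#' @param roi logical mask of voxels to receive distances.
#' @param sources non-empty logical mask of distance-zero seed voxels.
#' @param voxel_size_mm length-3 voxel size in mm.
#' @param metric `"geodesic"` (default) or `"euclidean"`.
#' @return numeric array: distance in mm; `Inf` for unreachable domain
#'   voxels, `NA` outside the propagation domain.
#' @export
geodesic_distance <- function(roi, sources, voxel_size_mm = c(1, 1, 1),
                              metric = c("geodesic", "euclidean")) {
  metric <- match.arg(metric)
  roi <- roi > 0; sources <- sources > 0
  stopifnot(identical(dim(roi), dim(sources)), length(dim(roi)) == 3L)
  if (!any(sources)) stop("geodesic_distance: empty source mask")
  domain <- if (metric == "geodesic") roi | sources else array(TRUE, dim(roi))
  d <- .geodesic_dijkstra(as.logical(domain), as.logical(sources),
                          as.integer(dim(roi)), as.numeric(voxel_size_mm))
  array(d, dim(roi))
}

step_from_ratio <- function(ratio, n_steps, tol = 1e-9) {
  # half-open bins ((s-1)/K, s/K]; exact edges fall to the lower step,
  # ratio 0 is assigned step 1
  s <- as.integer(ceiling(ratio * n_steps - tol))
  pmin(pmax(s, 1L), as.integer(n_steps))
}

make_step_map <- function(d0, d1, roi, n_steps, direction, lobule, hemisphere,
                          voxel_size_mm, max_unreachable = 0.2) {
  ratio <- array(NA_real_, dim(roi))
  reach <- roi & is.finite(d0) & is.finite(d1)
  ratio[reach] <- d0[reach] / (d0[reach] + d1[reach])
  n_unreach <- sum(roi) - sum(reach)
  if (sum(roi) > 0 && n_unreach / sum(roi) > max_unreachable)
    stop(errorCondition(
      sprintf("gradient steps: %d of %d ROI voxels unreachable from a boundary",
              n_unreach, sum(roi)),
      class = "lobulae_connectivity_error"))
  steps <- array(0L, dim(roi))
  steps[reach] <- step_from_ratio(ratio[reach], n_steps)
  structure(
    list(steps = steps, ratio = ratio, direction = direction, lobule = lobule,
         hemisphere = hemisphere, n_steps = as.integer(n_steps),
         voxel_size_mm = voxel_size_mm, n_unreachable = n_unreach),
    class = "gradient_step_map"
  )
}

#' Iso-distance gradient steps between two boundaries
#'
#' For each reachable ROI voxel the normalised position
#' `ratio = d_origin / (d_origin + d_destination)` (geodesic distances to
#' the two boundary masks) is binned into `n_steps` equal-width half-open
#' intervals: step 1 starts at the origin boundary, step `n_steps` ends at
#' the destination boundary.  Voxels unreachable from either boundary get
#' step 0 and are counted in `n_unreachable`.
#'
#' @param roi logical lobule ROI, disjoint from both boundaries.
#' @param origin_boundary,destination_boundary non-empty boundary masks.
#' @param n_steps number of iso-distance steps (default 7).
#' @param voxel_size_mm length-3 voxel size in mm.
#' @param direction,lobule,hemisphere metadata carried on the result.
#' @param metric passed to [geodesic_distance()].
#' @return object of class `gradient_step_map` with integer `steps`
#'   (0 outside ROI/unreachable, 1..K inside) and continuous `ratio`.
#' @export
compute_steps <- function(roi, origin_boundary, destination_boundary,
                          n_steps = 7L, voxel_size_mm = c(1, 1, 1),
                          direction = NA_character_, lobule = NA_integer_,
                          hemisphere = NA_character_,
                          metric = c("geodesic", "euclidean")) {
  metric <- match.arg(metric)
  roi <- roi > 0
  o <- origin_boundary > 0; d <- destination_boundary > 0
  stopifnot(n_steps >= 1L)
  if (!any(o) || !any(d)) stop("compute_steps: empty boundary mask")
  if (any(roi & o) || any(roi & d))
    stop("compute_steps: ROI must be disjoint from both boundary masks")
  d0 <- geodesic_distance(roi, o, voxel_size_mm, metric)
  d1 <- geodesic_distance(roi, d, voxel_size_mm, metric)
  make_step_map(d0, d1, roi, n_steps, direction, lobule, hemisphere,
                voxel_size_mm)
}

# Pure-R exhaustive shortest-path engine: Bellman-Ford label-correcting
# sweeps over all 26 offsets until a fixed point.  Shares no code with the
# compiled Dijkstra engine; used as the independent test oracle.
bellman_distance <- function(domain, sources, voxel_size_mm) {
  offs <- neighbour_offsets_26()
  w <- sqrt(colSums((t(offs) * voxel_size_mm)^2))
  dist <- array(Inf, dim(domain))
  dist[sources] <- 0
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(offs))) {
      cand <- shift3d(dist, offs[k, ], fill = Inf) + w[k]
      upd <- domain & (cand < dist)
      if (any(upd)) {
        dist[upd] <- cand[upd]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  dist[!domain & !sources] <- NA_real_
  dist
}

#' Brute-force iso-distance steps (test oracle)
#'
#' Identical contract to [compute_steps()], but distances come from an
#' exhaustive pure-R Bellman-Ford relaxation to a fixed point rather than
#' the compiled Dijkstra engine.  Intended for verification on instances up
#' to about 32^3.
#'
#' @inheritParams compute_steps
#' @return `gradient_step_map`.
#' @export
brute_force_steps <- function(roi, origin_boundary, destination_boundary,
                              n_steps = 7L, voxel_size_mm = c(1, 1, 1),
                              direction = NA_character_, lobule = NA_integer_,
                              hemisphere = NA_character_) {
  roi <- roi > 0
  o <- origin_boundary > 0; d <- destination_boundary > 0
  if (!any(o) || !any(d)) stop("brute_force_steps: empty boundary mask")
  d0 <- bellman_distance(roi | o, o, voxel_size_mm)
  d1 <- bellman_distance(roi | d, d, voxel_size_mm)
  make_step_map(d0, d1, roi, n_steps, direction, lobule, hemisphere,
                voxel_size_mm)
}

#' Continuous intrinsic coordinates of a lobule
#'
#' Applies the gradient ratio computation to the three boundary pairs of a
#' [boundary_set()]: fissure depth (deep to superficial), mediolateral
#' (lateral to medial) and posterior-anterior (posterior to anterior).
#' For the pairs whose boundary masks intersect the lobule (medial,
#' anterior, posterior, lateral) the ROI excludes those boundary voxels, as
#' the propagation contract requires.
#'
#' @param boundaries `boundary_set`.
#' @param roi optional ROI override; defaults to the lobule mask.
#' @param voxel_size_mm length-3 voxel size in mm.
#' @param n_steps steps for the returned step maps (default 7).
#' @return list with elements `fissure_depth`, `mediolateral`,
#'   `posterior_anterior`, each a `gradient_step_map` (the `ratio` field is
#'   the continuous coordinate in `[0, 1]`).
#' @export
intrinsic_coordinates <- function(boundaries, roi = NULL,
                                  voxel_size_mm = c(1, 1, 1), n_steps = 7L) {
  stopifnot(inherits(boundaries, "boundary_set"))
  if (is.null(roi)) roi <- boundaries$lobule_mask
  pairs <- list(
    fissure_depth = list(boundaries$deep, boundaries$superficial),
    mediolateral = list(boundaries$lateral, boundaries$medial),
    posterior_anterior = list(boundaries$posterior, boundaries$anterior)
  )
  out <- lapply(names(pairs), function(nm) {
    o <- pairs[[nm]][[1]]; d <- pairs[[nm]][[2]]
    compute_steps(roi & !o & !d, o, d, n_steps = n_steps,
                  voxel_size_mm = voxel_size_mm, direction = nm,
                  lobule = boundaries$lobule,
                  hemisphere = boundaries$hemisphere)
  })
  names(out) <- names(pairs)
  out
}

#' @export
print.gradient_step_map <- function(x, ...) {
  cat("gradient_step_map:", x$direction, "lobule", x$lobule,
      paste0("(", x$hemisphere, "), K = ", x$n_steps, "\n"))
  tab <- table(factor(x$steps[x$steps > 0], levels = seq_len(x$n_steps)))
  cat("  voxels per step:", paste(as.integer(tab), collapse = " "), "\n")
  cat("  unreachable:", x$n_unreachable, "\n")
  invisible(x)
}
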