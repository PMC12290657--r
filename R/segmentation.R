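# Boundary-mask construction per lobule: the six seed masks (deep,
# superficial, anterior, posterior, medial, lateral) that define the three
# intrinsic gradient directions of a folded cerebellar lobule.

seg_error <- function(msg) stop(errorCondition(msg, class = "lobulae_boundary_error"))

as_mask <- function(x) {
  stopifnot(length(dim(x)) == 3L)
  x > 0
}

#' Deep fissure boundary from a WM probability map
#'
#' The deep end of the fissure-depth gradient: all voxels whose cerebellar
#' white-matter probability strictly exceeds the threshold (default 0.99).
#'
#' @param wm_probability 3D array of probabilities in `[0, 1]`.
#' @param threshold exceedance threshold; comparison is strict (`>`).
#' @return logical mask.
#' @export
deep_fissure_boundary <- function(wm_probability, threshold = 0.99) {
  if (any(wm_probability < 0 | wm_probability > 1, na.rm = TRUE))
    stop("deep_fissure_boundary: probabilities must lie in [0, 1]")
  m <- wm_probability > threshold
  if (!any(m))
    seg_error("deep_fissure_boundary: no voxel exceeds the WM threshold")
  m
}

#' Superficial boundary of a lobule
#'
#' The cerebellar surface adjacent to the lobule: the lobule mask dilated by
#' one voxel in each direction in 3D (26-neighbourhood), minus the
#' cerebellum mask.
#'
#' @param lobule_mask logical mask of the lobule (must lie inside
#'   `cerebellum_mask`).
#' @param cerebellum_mask binary mask of the entire cerebellum.
#' @return logical mask, entirely outside `cerebellum_mask`.
#' @export
superficial_boundary <- function(lobule_mask, cerebellum_mask) {
  lobule_mask <- as_mask(lobule_mask)
  cerebellum_mask <- as_mask(cerebellum_mask)
  if (any(lobule_mask & !cerebellum_mask))
    stop("superficial_boundary: lobule mask extends outside the cerebellum mask")
  m <- dilate26(lobule_mask) & !cerebellum_mask
  if (!any(m))
    seg_error("superficial_boundary: lobule does not touch the cerebellar surface")
  m
}

#' Anterior/posterior boundaries from neighbouring lobules
#'
#' Hard label maps are disjoint, so "overlap" with a neighbouring lobule is
#' taken after one-voxel dilation of both masks: the boundary is
#' `dilate(lobule) & dilate(neighbour)`, i.e. the two facing voxel layers.
#'
#' @param lobule_mask,anterior_neighbour_mask,posterior_neighbour_mask
#'   logical masks on a common grid.
#' @return list with elements `anterior` and `posterior`.
#' @export
ap_boundaries <- function(lobule_mask, anterior_neighbour_mask,
                          posterior_neighbour_mask) {
  lobule_mask <- as_mask(lobule_mask)
  a <- as_mask(anterior_neighbour_mask)
  p <- as_mask(posterior_neighbour_mask)
  stopifnot(identical(dim(lobule_mask), dim(a)),
            identical(dim(lobule_mask), dim(p)))
  if (!any(a) || !any(p))
    stop("ap_boundaries: neighbour masks must be non-empty")
  dl <- dilate26(lobule_mask)
  ant <- dl & dilate26(a)
  pos <- dl & dilate26(p)
  if (!any(ant))
    seg_error("ap_boundaries: lobule is not adjacent to its anterior neighbour")
  if (!any(pos))
    seg_error("ap_boundaries: lobule is not adjacent to its posterior neighbour")
  list(anterior = ant, posterior = pos)
}

#' Medial boundary from the mirrored hemisphere pair
#'
#' The midline contact between the left and right instance of the same
#' lobule, computed as the overlap of their one-voxel dilations.
#'
#' @param lobule_left_mask,lobule_right_mask logical masks.
#' @return logical mask straddling the midline.
#' @export
medial_boundary <- function(lobule_left_mask, lobule_right_mask) {
  l <- as_mask(lobule_left_mask)
  r <- as_mask(lobule_right_mask)
  stopifnot(identical(dim(l), dim(r)))
  if (!any(l) || !any(r))
    stop("medial_boundary: hemisphere masks must be non-empty")
  m <- dilate26(l) & dilate26(r)
  if (!any(m))
    seg_error("medial_boundary: hemispheres do not meet at the midline")
  m
}

#' Outline of a lobule mask
#'
#' Voxels of the lobule having at least one 26-neighbour outside the lobule
#' (voxels beyond the grid edge count as outside).
#'
#' @param lobule_mask logical mask.
#' @return logical mask, a subset of `lobule_mask`.
#' @export
lobule_outline <- function(lobule_mask) {
  m <- as_mask(lobule_mask)
  m & !erode26(m)
}

#' Lateral boundary of a lobule
#'
#' Removes from the lobule outline everything already claimed by the other
#' five boundaries: the posterior, anterior and medial masks are subtracted
#' directly, and outline voxels 26-adjacent to the deep or superficial masks
#' are subtracted as well (those masks themselves lie outside the lobule so
#' a literal subtraction would be a no-op).  The remainder is restricted to
#' connected components on the lateral side of the lobule centroid.
#'
#' @param outline lobule outline mask (see [lobule_outline()]).
#' @param posterior,anterior,medial,deep,superficial the other boundary
#'   masks.
#' @param midline_x x-index of the midline plane used to decide which side
#'   is lateral; defaults to the grid centre.
#' @param component `"lateral_all"` (default) keeps every lateral-side
#'   component; `"largest"` keeps only the largest lateral-side component.
#' @return logical mask.
#' @export
lateral_boundary <- function(outline, posterior, anterior, medial, deep,
                             superficial, midline_x = NULL,
                             component = c("lateral_all", "largest")) {
  component <- match.arg(component)
  outline <- as_mask(outline)
  m <- outline & !as_mask(posterior) & !as_mask(anterior) & !as_mask(medial) &
    !dilate26(as_mask(deep)) & !dilate26(as_mask(superficial))
  if (!any(m))
    seg_error("lateral_boundary: outline fully covered by the other boundaries")
  dm <- dim(outline)
  if (is.null(midline_x)) midline_x <- (dm[1] + 1) / 2
  cen_out <- mean(abs(arrayInd(which(outline), dm)[, 1] - midline_x))
  lab <- label_components(m)
  ncomp <- max(lab)
  keep <- integer(0)
  sizes <- integer(ncomp)
  for (k in seq_len(ncomp)) {
    idx <- which(lab == k)
    sizes[k] <- length(idx)
    cen_k <- mean(abs(arrayInd(idx, dm)[, 1] - midline_x))
    if (cen_k >= cen_out) keep <- c(keep, k)
  }
  if (!length(keep)) keep <- which.max(sizes)
  if (component == "largest") keep <- keep[which.max(sizes[keep])]
  out <- array(lab %in% keep, dm) & m
  if (!any(out)) seg_error("lateral_boundary: empty lateral component")
  out
}

#' Build the full boundary set for one lobule
#'
#' Convenience constructor used by the pipeline: derives all six boundary
#' masks for one lobule/hemisphere from a label map, WM probability map and
#' cerebellum mask, then enforces pairwise disjointness with the fixed
#' precedence deep > superficial > medial > anterior > posterior > lateral.
#'
#' @param labels integer 3D label array (0 = background).
#' @param lobule label of the target lobule.
#' @param anterior_label,posterior_label labels of the neighbouring lobules
#'   in the same hemisphere.
#' @param mirror_label label of the same lobule in the other hemisphere.
#' @param wm_probability WM probability array.
#' @param cerebellum_mask binary cerebellum mask.
#' @param hemisphere `"left"` or `"right"`.
#' @param wm_threshold deep-fissure threshold (default 0.99, strict `>`).
#' @param midline_x midline plane x-index (default grid centre).
#' @return object of class `boundary_set`: the six masks plus `lobule_mask`,
#'   `lobule`, `hemisphere`.
#' @export
boundary_set <- function(labels, lobule, anterior_label, posterior_label,
                         mirror_label, wm_probability, cerebellum_mask,
                         hemisphere = c("left", "right"),
                         wm_threshold = 0.99, midline_x = NULL) {
  hemisphere <- match.arg(hemisphere)
  lob <- labels == lobule
  if (!any(lob)) stop("boundary_set: lobule ", lobule, " absent from label map")
  deep <- deep_fissure_boundary(wm_probability, wm_threshold)
  # restrict the global deep-WM mask to the fissure core adjacent to this
  # lobule, so every boundary voxel is within one voxel of the lobule
  deep <- deep & dilate26(lob)
  if (!any(deep))
    seg_error(paste0("boundary_set: lobule ", lobule, " has no adjacent deep WM"))
  sup <- superficial_boundary(lob, cerebellum_mask)
  ap <- ap_boundaries(lob, labels == anterior_label, labels == posterior_label)
  med <- medial_boundary(
    if (hemisphere == "left") lob else labels == mirror_label,
    if (hemisphere == "left") labels == mirror_label else lob
  )
  out <- lobule_outline(lob)
  lat <- lateral_boundary(out, ap$posterior, ap$anterior, med, deep, sup,
                          midline_x = midline_x)
  # precedence: deep > superficial > medial > anterior > posterior > lateral
  taken <- deep
  sup <- sup & !taken; taken <- taken | sup
  med <- med & !taken; taken <- taken | med
  ant <- ap$anterior & !taken; taken <- taken | ant
  pos <- ap$posterior & !taken; taken <- taken | pos
  lat <- lat & !taken
  for (nm in c("sup", "med", "ant", "pos", "lat"))
    if (!any(get(nm)))
      seg_error(paste0("boundary_set: boundary '", nm,
                       "' empty after precedence for lobule ", lobule))
  structure(
    list(lobule = lobule, hemisphere = hemisphere, lobule_mask = lob,
         deep = deep, superficial = sup, anterior = ant, posterior = pos,
         medial = med, lateral = lat),
    class = "boundary_set"
  )
}

#' @export
print.boundary_set <- function(x, ...) {
  cat("boundary_set: lobule", x$lobule, paste0("(", x$hemisphere, ")\n"))
  for (nm in c("deep", "superficial", "anterior", "posterior", "medial",
               "lateral"))
    cat(sprintf("  %-12s %d voxels\n", nm, sum(x[[nm]])))
  invisible(x)
}
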