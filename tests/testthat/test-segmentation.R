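test_that("deep fissure boundary thresholds strictly at 0.99", {
  p <- array(c(0.98, 0.991, 1.0), c(3, 1, 1))
  expect_identical(as.vector(deep_fissure_boundary(p)), c(FALSE, TRUE, TRUE))
  expect_error(deep_fissure_boundary(array(0.5, c(3, 3, 3))),
               class = "lobulae_boundary_error")
  expect_error(deep_fissure_boundary(array(1.5, c(2, 2, 2))), "0, 1")
  # independent full-scan count on the phantom
  an <- fixture_anatomy()
  m <- deep_fissure_boundary(an$wm_probability)
  n_scan <- 0L
  for (s in seq_len(dim(m)[3]))
    n_scan <- n_scan + sum(an$wm_probability[, , s] > 0.99)
  expect_identical(sum(m), n_scan)
})

test_that("superficial boundary is the dilated lobule minus the cerebellum", {
  dm <- c(5, 5, 5)
  lob <- empty_array(dm); lob[3, 3, 3] <- TRUE
  m <- superficial_boundary(lob, lob)
  expect_identical(sum(m), 26L)          # the 26 neighbours of the voxel
  expect_false(m[3, 3, 3])
  expect_true(all(which(m) %in% which(dilate26(lob))))
  # fully interior lobule
  cereb <- array(TRUE, dm)
  expect_error(superficial_boundary(lob, cereb),
               class = "lobulae_boundary_error")
  # pre: lobule must be inside the cerebellum
  expect_error(superficial_boundary(lob, empty_array(dm)), "outside")
  # phantom: superficial lies entirely outside the cerebellum
  an <- fixture_anatomy()
  sup <- superficial_boundary(an$lobule_labels == 2, an$cerebellum_mask)
  expect_false(any(sup & an$cerebellum_mask))
})

test_that("anterior/posterior boundaries are the facing dilated layers", {
  dm <- c(4, 1, 1)
  lob <- empty_array(dm); lob[2, 1, 1] <- TRUE
  ant <- empty_array(dm); ant[3, 1, 1] <- TRUE
  pos <- empty_array(dm); pos[1, 1, 1] <- TRUE
  b <- ap_boundaries(lob, ant, pos)
  expect_identical(which(b$anterior), which(empty_array(dm) |
                                              c(FALSE, TRUE, TRUE, FALSE)))
  expect_identical(which(b$posterior), c(1L, 2L))
  # non-adjacent lobules three voxels apart
  dm2 <- c(7, 3, 3)
  l1 <- empty_array(dm2); l1[1, , ] <- TRUE
  l2 <- empty_array(dm2); l2[5, , ] <- TRUE
  l3 <- empty_array(dm2); l3[7, , ] <- TRUE
  expect_error(ap_boundaries(l1, l2, l3), class = "lobulae_boundary_error")
})

test_that("phantom lobule boundaries touch both participating labels", {
  an <- fixture_anatomy()
  lab <- an$lobule_labels
  set.seed(42)
  b <- ap_boundaries(lab == 2, lab == 3, lab == 1)
  # distance-check oracle: every boundary voxel within one voxel (Chebyshev)
  # of both participating labels
  cheb <- function(voxels, target) {
    ti <- arrayInd(which(target), dim(lab))
    vapply(seq_len(nrow(voxels)), function(i)
      min(pmax(abs(ti[, 1] - voxels[i, 1]),
               pmax(abs(ti[, 2] - voxels[i, 2]), abs(ti[, 3] - voxels[i, 3])))),
      0)
  }
  for (mk in list(list(b$anterior, 3L), list(b$posterior, 1L))) {
    m <- mk[[1]]
    expect_gt(sum(m), 0)
    vi <- arrayInd(which(m), dim(lab))
    vi <- vi[sample(nrow(vi), min(60, nrow(vi))), , drop = FALSE]
    expect_true(all(cheb(vi, lab == 2) <= 1))
    expect_true(all(cheb(vi, lab == mk[[2]]) <= 1))
  }
})

test_that("medial boundary straddles the midline", {
  dm <- c(6, 3, 3)
  left <- empty_array(dm); left[3, , ] <- TRUE
  right <- empty_array(dm); right[4, , ] <- TRUE
  m <- medial_boundary(left, right)
  expect_identical(sort(unique(arrayInd(which(m), dm)[, 1])), c(3L, 4L))
  far <- empty_array(dm); far[1, , ] <- TRUE
  far2 <- empty_array(dm); far2[6, , ] <- TRUE
  expect_error(medial_boundary(far, far2), class = "lobulae_boundary_error")
  an <- fixture_anatomy()
  pm <- medial_boundary(an$lobule_labels == 2, an$lobule_labels == 5)
  xs <- arrayInd(which(pm), dim(pm))[, 1]
  expect_true(all(abs(xs - an$midline_x) <= 1))
})

test_that("lobule outline matches the combinatorial counts", {
  dm <- c(5, 5, 5)
  cube <- empty_array(dm); cube[2:4, 2:4, 2:4] <- TRUE
  out <- lobule_outline(cube)
  expect_identical(sum(out), 26L)        # 3^3 minus the centre
  expect_false(out[3, 3, 3])
  single <- empty_array(dm); single[3, 3, 3] <- TRUE
  expect_identical(which(lobule_outline(single)), which(single))
  an <- fixture_anatomy()
  lo <- lobule_outline(an$lobule_labels == 2)
  expect_true(all(an$lobule_labels[lo] == 2))   # outline subset of the lobule
})

test_that("lateral boundary is the remaining outer face of a cube", {
  dm <- c(9, 9, 9)
  cube <- empty_array(dm); cube[3:7, 3:7, 3:7] <- TRUE
  out <- lobule_outline(cube)
  ii <- function(cond) {
    m <- empty_array(dm); m[cond] <- TRUE; m
  }
  xg <- slice.index(cube, 1); yg <- slice.index(cube, 2); zg <- slice.index(cube, 3)
  posterior <- out & yg == 3
  anterior <- out & yg == 7
  medial <- out & xg == 7
  deep <- ii(zg == 2 & xg >= 3 & xg <= 7 & yg >= 3 & yg <= 7)      # below
  superficial <- ii(zg == 8 & xg >= 3 & xg <= 7 & yg >= 3 & yg <= 7) # above
  lat <- lateral_boundary(out, posterior, anterior, medial, deep, superficial,
                          midline_x = 12)
  # independent enumeration: x = 3 face minus all claimed layers
  want <- out & xg == 3 & yg > 3 & yg < 7 & zg > 3 & zg < 7
  expect_identical(which(lat), which(want))
  expect_identical(sum(lat), 9L)
  # outline fully covered by the other boundaries
  expect_error(lateral_boundary(out, out, anterior, medial, deep, superficial),
               class = "lobulae_boundary_error")
})

test_that("boundary_set yields six non-empty pairwise disjoint masks near the lobule", {
  an <- fixture_anatomy()
  bs <- fixture_coords()[["2"]]$boundaries
  nms <- c("deep", "superficial", "anterior", "posterior", "medial", "lateral")
  for (nm in nms) expect_gt(sum(bs[[nm]]), 0)
  for (i in seq_along(nms))
    for (j in seq_len(i - 1L))
      expect_false(any(bs[[nms[i]]] & bs[[nms[j]]]),
                   label = paste(nms[i], "vs", nms[j]))
  # every boundary voxel within one voxel (26-connectivity) of the lobule
  halo <- dilate26(bs$lobule_mask)
  for (nm in nms) expect_true(all(halo[bs[[nm]]]))
  expect_false(any(bs$lateral & bs$medial))
  # purity: inputs unmodified
  lab_before <- an$lobule_labels
  invisible(boundary_set(an$lobule_labels, 2L, 3L, 1L, 5L, an$wm_probability,
                         an$cerebellum_mask, "left", midline_x = an$midline_x))
  expect_identical(an$lobule_labels, lab_before)
})
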