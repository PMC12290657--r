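test_that("geodesic distances along a corridor are the path lengths", {
  dm <- c(10, 3, 3)
  roi <- empty_array(dm); roi[2:10, 2, 2] <- TRUE
  src <- empty_array(dm); src[1, 2, 2] <- TRUE
  d <- geodesic_distance(roi, src)
  expect_equal(d[1:10, 2, 2], as.numeric(0:9))
  expect_true(all(is.na(d[1, 1, 1])))
  # source covering the whole roi
  d0 <- geodesic_distance(roi, roi | src)
  expect_true(all(d0[roi] == 0))
  expect_error(geodesic_distance(roi, empty_array(dm)), "empty source")
})

test_that("geodesic distance dominates straight-line Euclidean distance", {
  # U-shaped corridor
  dm <- c(9, 9, 3)
  roi <- empty_array(dm)
  roi[2, 2:8, 2] <- TRUE; roi[2:8, 8, 2] <- TRUE; roi[8, 2:8, 2] <- TRUE
  src <- empty_array(dm); src[2, 2, 2] <- TRUE
  roi[2, 2, 2] <- FALSE
  d <- geodesic_distance(roi, src)
  idx <- which(roi & is.finite(d))
  co <- arrayInd(idx, dm)
  eu <- sqrt((co[, 1] - 2)^2 + (co[, 2] - 2)^2 + (co[, 3] - 2)^2)
  expect_true(all(d[idx] >= eu - 1e-9))
  # far corridor arm: straight-line distance 6, path around the U much longer
  expect_gt(d[8, 2, 2], 10)
})

test_that("a 21-plane slab splits into exactly 3 planes per step", {
  dm <- c(23, 5, 5)
  roi <- empty_array(dm); roi[2:22, , ] <- TRUE
  o <- empty_array(dm); o[1, , ] <- TRUE
  d <- empty_array(dm); d[23, , ] <- TRUE
  sm <- compute_steps(roi, o, d, n_steps = 7)
  for (x in 2:22)
    expect_identical(unique(as.vector(sm$steps[x, , ])),
                     as.integer(ceiling((x - 1) / 3)))
  counts <- tabulate(sm$steps[sm$steps > 0], 7)
  expect_identical(counts, rep(75L, 7))
  expect_identical(sum(counts), sum(roi))          # partition
  # K = 1 degenerate
  sm1 <- compute_steps(roi, o, d, n_steps = 1)
  expect_identical(sort(unique(as.vector(sm1$steps[roi]))), 1L)
  # oracle agreement on the analytic case
  smb <- brute_force_steps(roi, o, d, n_steps = 7)
  expect_steps_equivalent(sm, smb)
})

test_that("steps are 0 exactly off the ROI and consistent with the ratio", {
  inst <- random_layering_instance(501)
  sm <- compute_steps(inst$roi, inst$origin, inst$destination,
                      voxel_size_mm = inst$vox)
  expect_true(all(sm$steps[!inst$roi] == 0L))
  reach <- inst$roi & !is.na(sm$ratio)
  expect_true(all(sm$steps[reach] >= 1L & sm$steps[reach] <= 7L))
  expect_true(all(sm$ratio[reach] >= 0 & sm$ratio[reach] <= 1))
  expect_identical(sum(tabulate(sm$steps[sm$steps > 0], 7)), sum(reach))
  expect_error(compute_steps(inst$roi | inst$origin, inst$origin,
                             inst$destination),
               "disjoint")
})

test_that("reversing the gradient maps ratio to 1 - ratio and step s to K+1-s", {
  inst <- random_layering_instance(777)
  a <- compute_steps(inst$roi, inst$origin, inst$destination,
                     voxel_size_mm = inst$vox)
  b <- compute_steps(inst$roi, inst$destination, inst$origin,
                     voxel_size_mm = inst$vox)
  reach <- !is.na(a$ratio) & !is.na(b$ratio)
  expect_equal(b$ratio[reach], 1 - a$ratio[reach], tolerance = 1e-12)
  sa <- a$steps[reach]; sb <- b$steps[reach]
  flip_ok <- sb == 8L - sa
  near_edge <- abs(a$ratio[reach] * 7 - round(a$ratio[reach] * 7)) < 7e-9
  expect_true(all(flip_ok | near_edge))
})

test_that("step index is non-decreasing along shortest paths", {
  inst <- random_layering_instance(1234)
  sm <- compute_steps(inst$roi, inst$origin, inst$destination,
                      voxel_size_mm = inst$vox)
  d0 <- geodesic_distance(inst$roi, inst$origin, inst$vox)
  dm <- dim(inst$roi)
  offs <- lobulae:::neighbour_offsets_26()
  reach <- which(inst$roi & is.finite(d0) & !is.na(sm$ratio))
  # walk back from the farthest voxel towards the origin, always stepping to
  # the neighbour with smallest d0: along that shortest path the step index
  # must be non-increasing (i.e. non-decreasing origin -> destination)
  cur <- reach[which.max(d0[reach])]
  path_steps <- sm$steps[cur]
  for (it in 1:2000) {
    co <- arrayInd(cur, dm)
    nb <- sweep(offs, 2L, as.integer(co), "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    nb <- nb[ok, , drop = FALSE]
    lin <- nb[, 1] + dm[1] * (nb[, 2] - 1) + dm[1] * dm[2] * (nb[, 3] - 1)
    lin <- lin[(inst$roi[lin] | inst$origin[lin]) & is.finite(d0[lin])]
    nxt <- lin[which.min(d0[lin])]
    if (d0[nxt] >= d0[cur]) break
    cur <- nxt
    if (inst$origin[cur]) break
    path_steps <- c(path_steps, sm$steps[cur])
  }
  expect_gt(length(path_steps), 2)
  expect_true(all(diff(path_steps) <= 0))
})

test_that("compute_steps matches the brute-force oracle on small instances", {
  for (seed in c(11, 22, 33)) {
    inst <- random_layering_instance(seed)
    a <- compute_steps(inst$roi, inst$origin, inst$destination,
                       voxel_size_mm = inst$vox)
    b <- brute_force_steps(inst$roi, inst$origin, inst$destination,
                           voxel_size_mm = inst$vox)
    expect_steps_equivalent(a, b)
    expect_equal(a$ratio, b$ratio, tolerance = 1e-9)
  }
  # empty roi: all-zero maps from both engines
  dm <- c(6, 6, 6)
  o <- empty_array(dm); o[1, , ] <- TRUE
  d <- empty_array(dm); d[6, , ] <- TRUE
  za <- compute_steps(empty_array(dm), o, d)
  zb <- brute_force_steps(empty_array(dm), o, d)
  expect_identical(za$steps, zb$steps)
  expect_true(all(za$steps == 0L))
})

test_that("intrinsic coordinates are affine on a rectangular block", {
  dm <- c(12, 12, 12)
  blk <- empty_array(dm); blk[2:11, 2:11, 2:11] <- TRUE
  face <- function(axis, at) {
    m <- empty_array(dm)
    idx <- list(2:11, 2:11, 2:11); idx[[axis]] <- at
    m[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
    m
  }
  bs <- structure(list(lobule = 1L, hemisphere = "left", lobule_mask = blk,
                       deep = face(1, 1), superficial = face(1, 12),
                       lateral = face(2, 1), medial = face(2, 12),
                       posterior = face(3, 1), anterior = face(3, 12)),
                  class = "boundary_set")
  co <- intrinsic_coordinates(bs)
  # closed form: distance x-1 to one plane, 12-x to the other
  for (x in 2:11)
    expect_equal(unique(as.vector(co$fissure_depth$ratio[x, 2:11, 2:11])),
                 (x - 1) / 11, tolerance = 1e-12)
  for (y in 2:11)
    expect_equal(unique(as.vector(co$mediolateral$ratio[2:11, y, 2:11])),
                 (y - 1) / 11, tolerance = 1e-12)
  for (z in 2:11)
    expect_equal(unique(as.vector(co$posterior_anterior$ratio[2:11, 2:11, z])),
                 (z - 1) / 11, tolerance = 1e-12)
})

test_that("phantom intrinsic coordinates are complete and bounded", {
  co <- fixture_coords()[["2"]]$coords
  for (nm in names(co)) {
    r <- co[[nm]]$ratio
    expect_true(all(r[!is.na(r)] >= 0 & r[!is.na(r)] <= 1))
    expect_identical(sort(unique(as.vector(co[[nm]]$steps))), 0:7)
  }
  # voxels adjacent to the deep boundary sit in the first depth bin
  bs <- fixture_coords()[["2"]]$boundaries
  adj <- dilate26(bs$deep) & bs$lobule_mask & !is.na(co$fissure_depth$ratio)
  expect_true(all(co$fissure_depth$ratio[adj] < 0.5))
  expect_true(median(co$fissure_depth$steps[adj]) <= 2)
})
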