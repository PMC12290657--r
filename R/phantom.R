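# Synthetic folded-cortex phantom: two mirrored hemispheres of a
# sinusoidally folded grey-matter band wrapped around a deep white-matter
# core, consecutive lobule labels along the posterior-anterior axis, and
# block-design BOLD runs with activation blobs planted at chosen intrinsic
# coordinates.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Generate the synthetic two-hemisphere folded anatomy
#'
#' Each hemisphere is an annular grey-matter band of constant radial
#' thickness in the (x, z) plane, wrapped around a white-matter core whose
#' radius varies sinusoidally with polar angle (`fold_count` folds), and
#' extruded along y.  Consecutive y-sectors carry the lobule labels (left
#' hemisphere `1..n_lobules`, right `n_lobules+1..2*n_lobules`), so every
#' interior lobule has an anterior and a posterior neighbour.  A lateral
#' wedge of the band is left open and filled with non-fissure white matter
#' (the "peduncle"), exposing the lateral free edges of the band.  The WM
#' probability exceeds 0.99 exactly on the fissure core; it decays from
#' 0.99 to 0 across the grey-matter band.  The right hemisphere is the
#' exact mirror image of the left about the mid-sagittal plane.
#'
#' @param grid_shape integer length-3 grid size, each entry >= 24.
#' @param n_lobules lobules per hemisphere, >= 3.
#' @param fold_count number of sinusoidal folds of the WM core, >= 1.
#' @param seed integer seed (jitters the fold phase and vertical centre;
#'   the construction is deterministic given the seed).
#' @param voxel_size_mm voxel size in mm (default 1 mm isotropic).
#' @param band_thickness_vox grey-matter band thickness in voxels; default
#'   scales from 7 at a 48-voxel grid, floor 3 (below 3 is a sizing error).
#' @param fold_amp_vox fold amplitude in voxels (default scales from 1.5).
#' @param wedge_deg angular width of the lateral opening (default 70).
#' @return object of class `phantom_anatomy`: `lobule_labels` (integer
#'   array), `wm_probability`, `cerebellum_mask`, `gm_mask`,
#'   `voxel_size_mm`, `n_lobules`, `hemispheres` (label sets), `midline_x`,
#'   and the geometry parameters used.
#' @export
generate_anatomy <- function(grid_shape = c(48L, 48L, 48L), n_lobules = 3L,
                             fold_count = 4L, seed = 1L,
                             voxel_size_mm = c(1, 1, 1),
                             band_thickness_vox = NULL, fold_amp_vox = NULL,
                             wedge_deg = 70) {
  stopifnot(length(grid_shape) == 3L, n_lobules >= 3L, fold_count >= 1L)
  if (any(grid_shape < 24L))
    stop(errorCondition("generate_anatomy: grid_shape entries must be >= 24",
                        class = "lobulae_sizing_error"))
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  sc <- min(nx, nz) / 48
  if (is.null(band_thickness_vox)) band_thickness_vox <- max(3, round(7 * sc))
  if (is.null(fold_amp_vox)) fold_amp_vox <- 1.5 * sc
  r_core <- max(2, round(4 * sc))
  if (band_thickness_vox < 3)
    stop(errorCondition(
      "generate_anatomy: grid too small for a 3-voxel grey-matter band",
      class = "lobulae_sizing_error"))

  jit <- with_seed(seed, list(phase = runif(1, 0, 2 * pi),
                              dz = sample(-1:1, 1)))
  mid <- nx / 2                       # left hemisphere: x <= mid
  cz <- (nz + 1) / 2 + jit$dz
  # medial contact: the outer band radius at theta = 0 must reach the
  # midline plane, so the centre is solved from the phase-dependent radius
  r_out0 <- r_core + fold_amp_vox * sin(jit$phase) + band_thickness_vox
  cx <- mid + 0.5 - r_out0

  # lobule y-sectors, centred, with a margin
  margin <- max(2L, round(ny / 12))
  sect <- (ny - 2L * margin) %/% n_lobules
  if (sect < 3L)
    stop(errorCondition("generate_anatomy: grid too small for the lobule sectors",
                        class = "lobulae_sizing_error"))
  y0 <- margin + 1L
  y1 <- y0 + n_lobules * sect - 1L

  xg <- array(rep(seq_len(nx), times = ny * nz), c(nx, ny, nz))
  yg <- array(rep(rep(seq_len(ny), each = nx), times = nz), c(nx, ny, nz))
  zg <- array(rep(seq_len(nz), each = nx * ny), c(nx, ny, nz))

  rho <- sqrt((xg - cx)^2 + (zg - cz)^2)
  theta <- atan2(zg - cz, xg - cx)    # 0 = medial (towards midline), +-pi = lateral
  r_wm <- r_core + fold_amp_vox * sin(fold_count * theta + jit$phase)
  in_y <- yg >= y0 & yg <= y1
  in_x <- xg <= mid
  open_wedge <- abs(theta) > pi - (wedge_deg * pi / 180) / 2

  core <- in_x & in_y & !open_wedge & rho <= r_wm
  gm <- in_x & in_y & !open_wedge & rho > r_wm &
    rho <= r_wm + band_thickness_vox
  peduncle <- in_x & in_y & open_wedge &
    rho <= r_core + fold_amp_vox + band_thickness_vox

  wm_prob <- array(0, grid_shape)
  wm_prob[core] <- 1 - 0.009 * pmin(rho[core] / pmax(r_wm[core], 1e-6), 1)
  wm_prob[gm] <- 0.99 * pmax(0, 1 - (rho[gm] - r_wm[gm]) / band_thickness_vox)
  wm_prob[peduncle] <- 0.95

  labels <- array(0L, grid_shape)
  for (k in seq_len(n_lobules)) {
    yk <- yg >= y0 + (k - 1L) * sect & yg <= y0 + k * sect - 1L
    labels[gm & yk] <- k
  }

  mirror <- function(a) a[rev(seq_len(nx)), , , drop = FALSE]
  labels_r <- mirror(labels)
  labels_r[labels_r > 0L] <- labels_r[labels_r > 0L] + n_lobules
  labels <- labels + labels_r
  wm_prob <- pmax(wm_prob, mirror(wm_prob))
  cereb <- (core | gm | peduncle)
  cereb <- cereb | mirror(cereb)
  gm_all <- labels > 0L

  structure(
    list(lobule_labels = labels, wm_probability = wm_prob,
         cerebellum_mask = cereb, gm_mask = gm_all,
         voxel_size_mm = voxel_size_mm, n_lobules = as.integer(n_lobules),
         hemispheres = list(left = seq_len(n_lobules),
                            right = n_lobules + seq_len(n_lobules)),
         midline_x = mid + 0.5, grid_shape = as.integer(grid_shape),
         params = list(fold_count = fold_count, seed = seed,
                       band_thickness_vox = band_thickness_vox,
                       fold_amp_vox = fold_amp_vox, r_core = r_core,
                       wedge_deg = wedge_deg, phase = jit$phase,
                       cx = cx, cz = cz, y0 = y0, sect = sect)),
    class = "phantom_anatomy"
  )
}

#' @export
print.phantom_anatomy <- function(x, ...) {
  cat("phantom_anatomy:", paste(x$grid_shape, collapse = "x"), "voxels,",
      x$n_lobules, "lobules/hemisphere\n")
  cat("  GM voxels:", sum(x$gm_mask), " deep WM voxels:",
      sum(x$wm_probability > 0.99), "\n")
  invisible(x)
}

#' Build a block task design for one run
#'
#' Tiles the run with ON/OFF cycles (default paradigm: 20 s ON,
#' 10 s OFF), assigning conditions to the ON blocks cyclically from
#' `order`.
#'
#' @param run_length_s run duration in seconds (default 300, a 5-minute run).
#' @param tr_s repetition time in seconds (default 3.3).
#' @param on_s,off_s ON and OFF durations in seconds (defaults 20 and 10).
#' @param order character vector of condition labels cycled over the ON
#'   blocks (default alternating `MCFT`, `SUFF`).
#' @param run_id integer run identifier.
#' @return object of class `task_design`: `blocks` data frame
#'   (`onset_s`, `duration_s`, `condition`), `tr_s`, `n_volumes`, `run_id`.
#' @export
build_task_design <- function(run_length_s = 300, tr_s = 3.3, on_s = 20,
                              off_s = 10, order = c("MCFT", "SUFF"),
                              run_id = 1L) {
  stopifnot(run_length_s > 0, tr_s > 0, on_s > 0, off_s > 0,
            length(order) >= 1L)
  cycle <- on_s + off_s
  n_cycles <- floor(run_length_s / cycle + 1e-9)
  if (n_cycles < 1L)
    stop(errorCondition("build_task_design: run shorter than one ON+OFF cycle",
                        class = "lobulae_design_error"))
  n_volumes <- floor(run_length_s / tr_s + 1e-9)
  onsets <- (seq_len(n_cycles) - 1) * cycle
  blocks <- data.frame(
    onset_s = onsets,
    duration_s = on_s,
    condition = rep(order, length.out = n_cycles),
    stringsAsFactors = FALSE
  )
  structure(list(blocks = blocks, tr_s = tr_s,
                 n_volumes = as.integer(n_volumes),
                 run_id = as.integer(run_id)),
            class = "task_design")
}

#' Write a task design as a 3-column TSV
#'
#' Columns `onset`, `duration` (seconds) and `condition`.
#'
#' @param design `task_design`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_task_design <- function(design, path) {
  df <- data.frame(onset = design$blocks$onset_s,
                   duration = design$blocks$duration_s,
                   condition = design$blocks$condition)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Specify a planted activation effect
#'
#' @param condition condition label (`"MCFT"` or `"SUFF"`).
#' @param lobule lobule label the effect sits in.
#' @param centre_intrinsic length-3 ratios in `[0, 1]`: (fissure depth,
#'   mediolateral, posterior-anterior); 0 = deep/lateral/posterior.
#' @param spatial_sd_mm Gaussian spatial extent of the blob (default 2.5).
#' @param amplitude_pct peak percent signal change (default 2.5).
#' @return `effect_spec` list.
#' @export
effect_spec <- function(condition, lobule, centre_intrinsic,
                        spatial_sd_mm = 2.5, amplitude_pct = 2.5) {
  stopifnot(length(centre_intrinsic) == 3L,
            all(centre_intrinsic >= 0 & centre_intrinsic <= 1),
            spatial_sd_mm > 0, amplitude_pct >= 0)
  structure(list(condition = condition, lobule = lobule,
                 centre_intrinsic = centre_intrinsic,
                 spatial_sd_mm = spatial_sd_mm,
                 amplitude_pct = amplitude_pct),
            class = "effect_spec")
}

#' Specify the noise model
#'
#' @param sigma_pct noise SD as percent of the baseline (default 2);
#'   0 gives the exact noiseless limit.
#' @param ar1_rho lag-1 temporal autocorrelation in `[0, 1)` (default 0).
#' @param seed integer seed.
#' @return `noise_spec` list.
#' @export
noise_spec <- function(sigma_pct = 2, ar1_rho = 0, seed = 1L) {
  stopifnot(sigma_pct >= 0, ar1_rho >= 0, ar1_rho < 1)
  structure(list(sigma_pct = sigma_pct, ar1_rho = ar1_rho,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Intrinsic coordinate fields for a set of phantom lobules
#'
#' Convenience wrapper: builds the boundary set and the three continuous
#' ratio fields for each requested lobule of a phantom anatomy.  Used to
#' plant effects and reused across synthetic subjects.
#'
#' @param anatomy `phantom_anatomy`.
#' @param lobules integer labels (must be interior lobules, i.e. have both
#'   neighbours).
#' @param n_steps steps for the returned step maps (default 7).
#' @return named list (by label) of lists with `boundaries` and `coords`
#'   (the [intrinsic_coordinates()] output).
#' @export
phantom_intrinsic_coords <- function(anatomy, lobules, n_steps = 7L) {
  L <- anatomy$n_lobules
  out <- lapply(lobules, function(lb) {
    hemi <- if (lb <= L) "left" else "right"
    base <- if (lb <= L) lb else lb - L
    if (base <= 1L || base >= L)
      stop("phantom_intrinsic_coords: lobule ", lb,
           " has no anterior/posterior neighbour")
    mirror <- if (lb <= L) lb + L else lb - L
    bs <- boundary_set(anatomy$lobule_labels, lb,
                       anterior_label = lb + 1L, posterior_label = lb - 1L,
                       mirror_label = mirror,
                       wm_probability = anatomy$wm_probability,
                       cerebellum_mask = anatomy$cerebellum_mask,
                       hemisphere = hemi, midline_x = anatomy$midline_x)
    list(boundaries = bs,
         coords = intrinsic_coordinates(bs, voxel_size_mm = anatomy$voxel_size_mm,
                                        n_steps = n_steps))
  })
  names(out) <- as.character(lobules)
  out
}

find_effect_centre <- function(coords, centre_intrinsic) {
  r1 <- coords$fissure_depth$ratio
  r2 <- coords$mediolateral$ratio
  r3 <- coords$posterior_anterior$ratio
  ok <- which(!is.na(r1) & !is.na(r2) & !is.na(r3))
  if (!length(ok)) stop("find_effect_centre: no voxel with all three coordinates")
  d2 <- (r1[ok] - centre_intrinsic[1])^2 + (r2[ok] - centre_intrinsic[2])^2 +
    (r3[ok] - centre_intrinsic[3])^2
  ok[which.min(d2)]
}

#' Generate synthetic BOLD runs
#'
#' Baseline 100 (arbitrary units) everywhere inside the sampling mask,
#' plus, for each effect, a Gaussian spatial blob centred at the voxel
#' whose intrinsic coordinates are nearest the requested centre, modulated
#' in time by that condition's HRF-convolved, unit-peak boxcar and scaled
#' to the requested percent signal change; plus white or AR(1) Gaussian
#' noise.  Deterministic given `noise$seed`.
#'
#' @param anatomy `phantom_anatomy`.
#' @param designs list of `task_design`s (one per run).
#' @param effects list of `effect_spec`s (may be empty for a null phantom).
#' @param noise `noise_spec`.
#' @param baseline baseline signal level (default 100).
#' @param coords optional precomputed [phantom_intrinsic_coords()] output
#'   covering every lobule referenced by `effects` (computed on the fly
#'   otherwise).
#' @param sample_mask logical array of voxels to simulate; defaults to the
#'   cerebellum mask.
#' @param amplitude_scale per-effect multiplicative scale (recycled;
#'   e.g. per-subject amplitude variability), default 1.
#' @return list of `bold_run` objects: `data` (`n_volumes x V` matrix),
#'   `voxel_idx` (linear indices into the grid), `dim`, `voxel_size_mm`,
#'   `tr_s`, `design`, `run_id`, `effect_centres`.
#' @export
generate_bold <- function(anatomy, designs, effects, noise,
                          baseline = 100, coords = NULL, sample_mask = NULL,
                          amplitude_scale = 1) {
  stopifnot(inherits(anatomy, "phantom_anatomy"), length(designs) >= 1L,
            inherits(noise, "noise_spec"))
  if (is.null(sample_mask)) sample_mask <- anatomy$cerebellum_mask
  voxel_idx <- which(sample_mask > 0)
  V <- length(voxel_idx)
  dm <- dim(sample_mask)
  amplitude_scale <- rep(amplitude_scale, length.out = max(1L, length(effects)))

  eff_lobs <- unique(vapply(effects, `[[`, 0, "lobule"))
  if (length(eff_lobs)) {
    present <- unique(anatomy$lobule_labels[anatomy$lobule_labels > 0])
    missing <- setdiff(eff_lobs, present)
    if (length(missing))
      stop("generate_bold: effect lobule(s) absent from anatomy: ",
           paste(missing, collapse = ", "))
    if (is.null(coords))
      coords <- phantom_intrinsic_coords(anatomy, eff_lobs)
  }

  # spatial weight per effect over the sampled voxels
  pos <- voxel_to_mm(arrayInd(voxel_idx, dm), anatomy$voxel_size_mm)
  centres <- list()
  weights <- list()
  for (i in seq_along(effects)) {
    ef <- effects[[i]]
    ci <- find_effect_centre(coords[[as.character(ef$lobule)]]$coords,
                             ef$centre_intrinsic)
    cmm <- voxel_to_mm(arrayInd(ci, dm), anatomy$voxel_size_mm)
    d2 <- rowSums(sweep(pos, 2L, as.numeric(cmm))^2)
    weights[[i]] <- exp(-d2 / (2 * ef$spatial_sd_mm^2))
    centres[[i]] <- ci
  }

  with_seed(noise$seed, {
    lapply(seq_along(designs), function(ri) {
      des <- designs[[ri]]
      nt <- des$n_volumes
      regs <- lapply(unique(vapply(effects, `[[`, "", "condition")),
                     function(cc) condition_regressor(des, cc))
      names(regs) <- unique(vapply(effects, `[[`, "", "condition"))
      S <- matrix(baseline, nt, V)
      for (i in seq_along(effects)) {
        ef <- effects[[i]]
        amp <- baseline * ef$amplitude_pct / 100 * amplitude_scale[i]
        S <- S + (amp * regs[[ef$condition]]) %*% t(weights[[i]])
      }
      sd_n <- baseline * noise$sigma_pct / 100
      eps <- matrix(rnorm(nt * V), nt, V)
      if (noise$ar1_rho > 0) {
        r <- noise$ar1_rho
        for (t in 2:nt) eps[t, ] <- r * eps[t - 1, ] + sqrt(1 - r^2) * eps[t, ]
      }
      structure(list(data = S + sd_n * eps, voxel_idx = voxel_idx, dim = dm,
                     voxel_size_mm = anatomy$voxel_size_mm, tr_s = des$tr_s,
                     design = des, run_id = des$run_id,
                     effect_centres = centres),
                class = "bold_run")
    })
  })
}

#' Expand a bold_run to a full 4D array
#'
#' Unsampled voxels are 0.
#'
#' @param run `bold_run`.
#' @return 4D array `(x, y, z, t)`.
#' @export
bold_run_to_array <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  nt <- nrow(run$data)
  a <- array(0, c(run$dim, nt))
  step <- prod(run$dim)
  for (t in seq_len(nt)) a[(t - 1) * step + run$voxel_idx] <- run$data[t, ]
  a
}
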