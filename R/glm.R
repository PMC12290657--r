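# First-level block-design GLM: HRF, design matrix, per-voxel OLS, contrast
# z-maps, fixed-effects combination across runs, thresholding.

#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities (unit scale), parameterised by the
#' modes of the response and undershoot lobes: the positive lobe uses shape
#' `peak_s + 1` so its mode falls exactly at `peak_s`, likewise the
#' undershoot.  The value at `t = 0` is 0.
#'
#' @param t_s time in seconds (vectorised).
#' @param peak_s response peak time (default 6 s).
#' @param undershoot_s undershoot peak time (default 16 s).
#' @param ratio undershoot-to-peak amplitude ratio (default 1/6).
#' @return numeric vector of responses (arbitrary units).
#' @export
hrf_double_gamma <- function(t_s, peak_s = 6, undershoot_s = 16, ratio = 1 / 6) {
  out <- dgamma(t_s, shape = peak_s + 1, scale = 1) -
    ratio * dgamma(t_s, shape = undershoot_s + 1, scale = 1)
  out[t_s < 0] <- 0
  out
}

# boxcar for one condition on a fine time grid, convolved with the HRF and
# sampled at volume acquisition times; unit-peak normalised.
condition_regressor <- function(design, condition, hrf_params = list(),
                                dt = 0.1) {
  run_t <- design$n_volumes * design$tr_s
  fine_t <- seq(0, run_t, by = dt)
  box <- numeric(length(fine_t))
  bl <- design$blocks[design$blocks$condition == condition, , drop = FALSE]
  for (i in seq_len(nrow(bl)))
    box[fine_t >= bl$onset_s[i] & fine_t < bl$onset_s[i] + bl$duration_s[i]] <- 1
  hrf_t <- seq(0, 32, by = dt)
  h <- do.call(hrf_double_gamma, c(list(t_s = hrf_t), hrf_params))
  conv <- convolve(box, rev(h), type = "open")[seq_along(fine_t)] * dt
  vol_t <- (seq_len(design$n_volumes) - 1) * design$tr_s
  reg <- approx(fine_t, conv, xout = vol_t, rule = 2)$y
  pk <- max(abs(reg))
  if (pk > 0) reg <- reg / pk
  reg
}

legendre_poly <- function(x, order) {
  # recurrence (n+1)P_{n+1} = (2n+1)xP_n - nP_{n-1} on [-1, 1]
  P <- matrix(0, length(x), order + 1)
  P[, 1] <- 1
  if (order >= 1) P[, 2] <- x
  if (order >= 2)
    for (n in 1:(order - 1))
      P[, n + 2] <- ((2 * n + 1) * x * P[, n + 1] - n * P[, n]) / (n + 1)
  P
}

#' Build a first-level design matrix
#'
#' One HRF-convolved, unit-peak-normalised boxcar column per condition (in
#' order of first appearance in the block table), Legendre polynomial drift
#' columns up to `drift_order`, and an intercept column last.
#'
#' @param design a `task_design` (see [build_task_design()]).
#' @param hrf_params named list of overrides for [hrf_double_gamma()].
#' @param drift_order highest Legendre drift order (0 = none; default 1).
#' @return object of class `design_matrix`: list with `matrix`
#'   (`n_volumes x p`), `column_names`, `tr_s`, `conditions`.
#' @export
build_design_matrix <- function(design, hrf_params = list(), drift_order = 1L) {
  stopifnot(inherits(design, "task_design"))
  conds <- unique(as.character(design$blocks$condition))
  cols <- lapply(conds, function(cc)
    condition_regressor(design, cc, hrf_params))
  X <- do.call(cbind, c(cols, list(matrix(0, design$n_volumes, 0))))
  nms <- conds
  if (drift_order >= 1) {
    x <- seq(-1, 1, length.out = design$n_volumes)
    P <- legendre_poly(x, drift_order)[, -1, drop = FALSE]
    X <- cbind(X, P)
    nms <- c(nms, paste0("drift", seq_len(drift_order)))
  }
  X <- cbind(X, 1)
  nms <- c(nms, "intercept")
  colnames(X) <- nms
  if (qr(X)$rank < ncol(X))
    stop(errorCondition("build_design_matrix: rank-deficient design matrix",
                        class = "lobulae_design_error"))
  structure(list(matrix = X, column_names = nms, tr_s = design$tr_s,
                 conditions = conds),
            class = "design_matrix")
}

bold_matrix <- function(bold, mask = NULL) {
  # Returns list(Y = nt x V matrix, voxel_idx, dim)
  if (inherits(bold, "bold_run")) {
    Y <- bold$data; idx <- bold$voxel_idx; dm <- bold$dim
  } else if (is.array(bold) && length(dim(bold)) == 4L) {
    dm <- dim(bold)[1:3]
    nt <- dim(bold)[4]
    Y <- t(matrix(bold, prod(dm), nt))
    idx <- seq_len(prod(dm))
  } else stop("fit_glm: bold must be a bold_run or a 4D array")
  if (!is.null(mask)) {
    keep <- which(as.vector(mask > 0)[idx])
    Y <- Y[, keep, drop = FALSE]
    idx <- idx[keep]
  }
  list(Y = Y, voxel_idx = idx, dim = dm)
}

#' Fit the GLM per voxel by ordinary least squares
#'
#' @param bold a `bold_run` (masked time-series matrix, see
#'   [generate_bold()]) or a 4D array `(x, y, z, t)`.
#' @param X a `design_matrix`.
#' @param mask optional logical 3D array restricting the fit.
#' @return object of class `glm_fit`: per-voxel `beta` (`p x V`), `sigma2`,
#'   residual `dof`, `xtx_inv`, plus voxel bookkeeping for mapping back to
#'   volumes.
#' @export
fit_glm <- function(bold, X, mask = NULL) {
  stopifnot(inherits(X, "design_matrix"))
  bm <- bold_matrix(bold, mask)
  Xm <- X$matrix
  if (nrow(bm$Y) != nrow(Xm))
    stop("fit_glm: number of volumes differs between data (", nrow(bm$Y),
         ") and design (", nrow(Xm), ")")
  p <- ncol(Xm)
  dof <- nrow(Xm) - p
  stopifnot(dof > 0)
  xtx_inv <- chol2inv(chol(crossprod(Xm)))
  beta <- xtx_inv %*% crossprod(Xm, bm$Y)
  rownames(beta) <- colnames(Xm)
  resid <- bm$Y - Xm %*% beta
  sigma2 <- colSums(resid^2) / dof
  structure(list(beta = beta, sigma2 = sigma2, dof = dof, xtx_inv = xtx_inv,
                 column_names = X$column_names, conditions = X$conditions,
                 voxel_idx = bm$voxel_idx, dim = bm$dim),
            class = "glm_fit")
}

# t -> z through tail-stable log-probability transforms; finite out to
# |z| ~ 38.
t_to_z <- function(t, dof) {
  z <- numeric(length(t))
  neg <- t <= 0
  z[neg] <- qnorm(pt(t[neg], dof, log.p = TRUE), log.p = TRUE)
  z[!neg] <- -qnorm(pt(-t[!neg], dof, log.p = TRUE), log.p = TRUE)
  z
}

#' Contrast z-map from a GLM fit
#'
#' Computes `cope = c'beta`, `varcope = sigma2 * c'(X'X)^-1 c`, the
#' t-statistic, and its z-equivalent via the t CDF.  Degenerate noiseless
#' voxels (`sigma2 = 0`, nonzero cope) get `sign(cope) * z_max` with a
#' warning.
#'
#' @param fit `glm_fit`.
#' @param contrast numeric contrast over the design columns; may be named
#'   length-p, or a named vector over condition columns (others 0).
#' @param name contrast label, e.g. `"MCFT>SUFF"`.
#' @param z_max z value substituted at degenerate voxels (default 38).
#' @return object of class `contrast_map` with 3D arrays `z`, `cope`,
#'   `varcope` (NA outside the fitted voxels), `dof`, `name`.
#' @export
contrast_zmap <- function(fit, contrast, name = "contrast", z_max = 38) {
  stopifnot(inherits(fit, "glm_fit"))
  p <- length(fit$column_names)
  if (length(contrast) != p) {
    if (is.null(names(contrast)))
      stop("contrast_zmap: contrast must be length p or named")
    cv <- setNames(numeric(p), fit$column_names)
    unknown <- setdiff(names(contrast), fit$column_names)
    if (length(unknown))
      stop("contrast_zmap: unknown design columns: ",
           paste(unknown, collapse = ", "))
    cv[names(contrast)] <- contrast
    contrast <- cv
  }
  cope <- drop(crossprod(contrast, fit$beta))
  cvar <- drop(crossprod(contrast, fit$xtx_inv %*% contrast))
  varcope <- fit$sigma2 * cvar
  z <- numeric(length(cope))
  ok <- varcope > 0
  z[ok] <- t_to_z(cope[ok] / sqrt(varcope[ok]), fit$dof)
  if (any(!ok & cope != 0)) {
    warning("contrast_zmap: ", sum(!ok & cope != 0),
            " degenerate noiseless voxels set to +/- z_max")
    z[!ok] <- sign(cope[!ok]) * z_max
  }
  to_vol <- function(v) {
    a <- array(NA_real_, fit$dim)
    a[fit$voxel_idx] <- v
    a
  }
  structure(list(name = name, z = to_vol(z), cope = to_vol(cope),
                 varcope = to_vol(varcope), dof = fit$dof,
                 voxel_idx = fit$voxel_idx, dim = fit$dim),
            class = "contrast_map")
}

#' Fixed-effects combination of contrast maps across runs
#'
#' Inverse-variance weighting of the per-run effect estimates; the combined
#' z is the normal deviate `cope* / sqrt(varcope*)`.
#'
#' @param maps list of `contrast_map`s with identical grids and names.
#' @return combined `contrast_map` (`dof` = sum of run dofs, informational).
#' @export
fixed_effects_combine <- function(maps) {
  stopifnot(length(maps) >= 1L, all(vapply(maps, inherits, TRUE, "contrast_map")))
  nm <- unique(vapply(maps, `[[`, "", "name"))
  if (length(nm) != 1L)
    stop("fixed_effects_combine: contrast names differ: ",
         paste(nm, collapse = ", "))
  dims <- vapply(maps, function(m) paste(m$dim, collapse = "x"), "")
  if (length(unique(dims)) != 1L)
    stop("fixed_effects_combine: grid dimensions differ across maps")
  if (length(maps) == 1L) return(maps[[1]])
  wsum <- csum <- array(0, maps[[1]]$dim)
  for (m in maps) {
    w <- 1 / m$varcope
    w[is.na(w)] <- 0
    cc <- m$cope; cc[is.na(cc)] <- 0
    wsum <- wsum + w
    csum <- csum + cc * w
  }
  cope <- csum / wsum
  varcope <- 1 / wsum
  z <- cope / sqrt(varcope)
  cope[wsum == 0] <- NA_real_
  varcope[wsum == 0] <- NA_real_
  z[wsum == 0] <- NA_real_
  structure(list(name = nm, z = z, cope = cope, varcope = varcope,
                 dof = sum(vapply(maps, `[[`, 0, "dof")),
                 voxel_idx = maps[[1]]$voxel_idx, dim = maps[[1]]$dim),
            class = "contrast_map")
}

#' Threshold a contrast map
#'
#' @param map `contrast_map` (or bare numeric array of z values).
#' @param z_thresh threshold; strict exceedance `z > z_thresh` (default 3.1).
#' @return logical 3D array (NA z treated as below threshold).
#' @export
threshold_map <- function(map, z_thresh = 3.1) {
  z <- if (inherits(map, "contrast_map")) map$z else map
  out <- z > z_thresh
  out[is.na(out)] <- FALSE
  out
}

#' @export
print.contrast_map <- function(x, ...) {
  cat("contrast_map:", x$name, "dof", x$dof, "\n")
  cat(sprintf("  z range [%.2f, %.2f], %d voxels > 3.1\n",
              min(x$z, na.rm = TRUE), max(x$z, na.rm = TRUE),
              sum(threshold_map(x))))
  invisible(x)
}
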