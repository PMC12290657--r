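# Step-profile extraction and the statistical battery: mean z per gradient
# step, overlap counts, paired t-tests, one-way repeated-measures ANOVA with
# Mauchly's sphericity test and Greenhouse-Geisser correction, and Holm
# step-down post-hoc comparisons.

#' Mean z per gradient step
#'
#' @param zmap `contrast_map` (or bare z array).
#' @param stepmap `gradient_step_map`.
#' @param gm_mask logical grey-matter mask.
#' @param subject_id optional identifier carried on the result.
#' @return object of class `step_profile`: `mean_z` and `voxel_counts`
#'   (length `n_steps`; an empty step yields `NA`, never 0), plus the
#'   lobule/hemisphere/direction/contrast metadata.
#' @export
step_profile <- function(zmap, stepmap, gm_mask, subject_id = NA) {
  stopifnot(inherits(stepmap, "gradient_step_map"))
  z <- if (inherits(zmap, "contrast_map")) zmap$z else zmap
  K <- stepmap$n_steps
  mean_z <- rep(NA_real_, K)
  counts <- integer(K)
  for (s in seq_len(K)) {
    sel <- stepmap$steps == s & gm_mask > 0 & !is.na(z)
    counts[s] <- sum(sel)
    if (counts[s] > 0) mean_z[s] <- mean(z[sel])
  }
  structure(list(subject_id = subject_id, lobule = stepmap$lobule,
                 hemisphere = stepmap$hemisphere,
                 direction = stepmap$direction,
                 contrast_name = if (inherits(zmap, "contrast_map")) zmap$name else NA,
                 mean_z = mean_z, voxel_counts = counts, n_steps = K),
            class = "step_profile")
}

#' Mean z over the grey matter
#'
#' @param zmap `contrast_map` or z array.
#' @param gm_mask logical mask.
#' @return scalar mean of z over the mask (NA voxels excluded).
#' @export
mean_gm_z <- function(zmap, gm_mask) {
  z <- if (inherits(zmap, "contrast_map")) zmap$z else zmap
  mean(z[gm_mask > 0], na.rm = TRUE)
}

#' Overlap voxel counts of two activation masks
#'
#' @param mask_a,mask_b logical activation masks.
#' @param roi optional region restriction.
#' @return list `only_a`, `only_b`, `both` (integers).
#' @export
overlap_counts <- function(mask_a, mask_b, roi = NULL) {
  a <- mask_a > 0; b <- mask_b > 0
  if (!is.null(roi)) {
    a <- a & roi > 0
    b <- b & roi > 0
  }
  list(only_a = sum(a & !b), only_b = sum(!a & b), both = sum(a & b))
}

#' Paired t-test
#'
#' Two-sided paired t-test of `a - b`.
#'
#' @param a,b numeric vectors of equal length `n >= 2`.
#' @return object of class `paired_test`: `t`, `df = n - 1`, `p`,
#'   `mean_diff`, `sd_diff`, `n`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) stop(errorCondition("paired_t: need n >= 2 pairs",
                                 class = "lobulae_degenerate_error"))
  d <- a - b
  m <- mean(d); s <- sd(d)
  if (s == 0) {
    if (m != 0)
      stop(errorCondition("paired_t: zero variance with nonzero mean difference",
                          class = "lobulae_degenerate_error"))
    t <- 0
  } else t <- m / (s / sqrt(n))
  structure(list(t = t, df = n - 1L, p = 2 * pt(-abs(t), n - 1),
                 mean_diff = m, sd_diff = s, n = n),
            class = "paired_test")
}

orthonormal_contrasts <- function(K) {
  # (K-1) x K rows, orthonormal, each orthogonal to the unit vector
  H <- stats::contr.helmert(K)          # K x (K-1)
  t(sweep(H, 2L, sqrt(colSums(H^2)), "/"))
}

#' One-way repeated-measures ANOVA with sphericity diagnostics
#'
#' Within-subject decomposition `SS_total = SS_subjects + SS_steps +
#' SS_error` with `F = MS_steps / MS_error` on `(K-1, (K-1)(n-1))` degrees
#' of freedom; Mauchly's W on the orthonormal-contrast covariance with its
#' chi-squared approximation; Greenhouse-Geisser epsilon from the
#' eigenvalues of the double-centred step covariance.  The corrected p is
#' reported whenever Mauchly's p falls below `alpha` ("whenever
#' appropriate"); both corrected and uncorrected p-values are always
#' returned.
#'
#' @param table numeric `n_subjects x K` matrix (rows = subjects).
#' @param alpha sphericity-test level triggering the correction (default
#'   0.05).
#' @return object of class `rm_anova`: `F`, `df1`, `df2`, `p` (the
#'   operative p), `p_uncorrected`, `p_gg`, `mauchly_W`, `mauchly_p`,
#'   `gg_epsilon`, `corrected`, `n`, `K`.
#' @export
rm_anova <- function(table, alpha = 0.05) {
  table <- as.matrix(table)
  n <- nrow(table); K <- ncol(table)
  if (n < 2 || K < 2)
    stop("rm_anova: need at least 2 subjects and 2 steps")
  if (anyNA(table))
    stop("rm_anova: missing cells; exclude incomplete subjects first")
  g <- mean(table)
  rm_ <- rowMeans(table); cm <- colMeans(table)
  ss_tot <- sum((table - g)^2)
  ss_subj <- K * sum((rm_ - g)^2)
  ss_steps <- n * sum((cm - g)^2)
  ss_err <- ss_tot - ss_subj - ss_steps
  ss_err <- max(ss_err, 0)
  df1 <- K - 1; df2 <- (K - 1) * (n - 1)

  if (ss_steps + ss_err <= 1e-12 * max(ss_tot, 1)) {
    # all columns identical: no step effect, trivially sphericity-perfect
    return(structure(list(F = 0, df1 = df1, df2 = df2, p = 1,
                          p_uncorrected = 1, p_gg = 1, mauchly_W = 1,
                          mauchly_p = 1, gg_epsilon = 1, corrected = FALSE,
                          n = n, K = K), class = "rm_anova"))
  }
  if (ss_err <= 1e-12 * (ss_steps + ss_err))
    stop(errorCondition("rm_anova: zero within-subject error variance",
                        class = "lobulae_degenerate_error"))
  Fval <- (ss_steps / df1) / (ss_err / df2)
  p_unc <- pf(Fval, df1, df2, lower.tail = FALSE)

  # Greenhouse-Geisser epsilon from the double-centred covariance
  S <- stats::cov(table)
  C <- diag(K) - 1 / K
  Sc <- C %*% S %*% C
  lam <- eigen(Sc, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  eps <- if (sum(lam^2) > 0) sum(lam)^2 / ((K - 1) * sum(lam^2)) else 1
  eps <- min(max(eps, 1 / (K - 1)), 1)

  # Mauchly's test on the orthonormal-contrast covariance
  M <- orthonormal_contrasts(K)
  S1 <- M %*% S %*% t(M)
  ev <- eigen(S1, symmetric = TRUE, only.values = TRUE)$values
  if (K == 2 || any(ev <= 0)) {
    # K = 2: sphericity trivially holds; singular contrast covariance
    # (n - 1 < K - 1): report the boundary values
    W <- if (K == 2) 1 else .Machine$double.xmin
    mauchly_p <- if (K == 2) 1 else 0
  } else {
    W <- exp(sum(log(ev)) - (K - 1) * log(mean(ev)))
    fcorr <- 1 - (2 * (K - 1)^2 + (K - 1) + 2) / (6 * (K - 1) * (n - 1))
    chi2 <- -(n - 1) * fcorr * log(W)
    dfm <- K * (K - 1) / 2 - 1
    mauchly_p <- pchisq(chi2, dfm, lower.tail = FALSE)
  }
  p_gg <- pf(Fval, eps * df1, eps * df2, lower.tail = FALSE)
  corrected <- is.finite(mauchly_p) && mauchly_p < alpha
  structure(list(F = Fval,
                 df1 = if (corrected) eps * df1 else df1,
                 df2 = if (corrected) eps * df2 else df2,
                 p = if (corrected) p_gg else p_unc,
                 p_uncorrected = p_unc, p_gg = p_gg,
                 mauchly_W = W, mauchly_p = mauchly_p, gg_epsilon = eps,
                 corrected = corrected, n = n, K = K),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("rm_anova: F(%.3g, %.3g) = %.4g, p = %.4g%s\n",
              x$df1, x$df2, x$F, x$p,
              if (x$corrected) " (Greenhouse-Geisser corrected)" else ""))
  cat(sprintf("  Mauchly W = %.4g (p = %.4g), epsilon = %.4g\n",
              x$mauchly_W, x$mauchly_p, x$gg_epsilon))
  invisible(x)
}

#' Holm step-down adjustment
#'
#' `adj_p(i) = max_(j <= i) min(1, (m - j + 1) * p(j))` over the ascending
#' raw p-values.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the original order.
#' @export
holm_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' All pairwise step comparisons with Holm adjustment
#'
#' Paired t-tests between every pair of steps of a subjects-by-steps table;
#' the `K(K-1)/2` comparisons form one Holm family.
#'
#' @param table numeric `n x K` matrix.
#' @return data frame with one row per pair: `step_a`, `step_b`, `t`, `df`,
#'   `mean_diff`, `p_raw`, `p_holm`.
#' @export
holm_posthoc <- function(table) {
  table <- as.matrix(table)
  K <- ncol(table)
  stopifnot(K >= 2)
  pairs <- which(upper.tri(matrix(0, K, K)), arr.ind = TRUE)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    tt <- paired_t(table[, a], table[, b])
    data.frame(step_a = a, step_b = b, t = tt$t, df = tt$df,
               mean_diff = tt$mean_diff, p_raw = tt$p)
  })
  out <- do.call(rbind, res)
  out$p_holm <- holm_adjust(out$p_raw)
  out
}

#' Assemble subject step-profiles into an ANOVA table
#'
#' @param profiles list of `step_profile`s for one
#'   lobule/hemisphere/direction, one per subject.
#' @return list with `table` (`n x K` matrix of complete subjects) and
#'   `excluded` (subject ids dropped for having an empty step).
#' @export
profile_table <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  M <- do.call(rbind, lapply(profiles, `[[`, "mean_z"))
  rownames(M) <- vapply(profiles, function(p) as.character(p$subject_id), "")
  bad <- apply(M, 1L, anyNA)
  if (any(bad))
    warning("profile_table: excluding subjects with empty steps: ",
            paste(rownames(M)[bad], collapse = ", "))
  list(table = M[!bad, , drop = FALSE], excluded = rownames(M)[bad])
}
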