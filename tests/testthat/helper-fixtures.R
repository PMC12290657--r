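# Shared fixtures, built once per session, and the independent statistical
# oracles used by the equivalence tests.

.fix <- new.env(parent = emptyenv())

fixture_anatomy <- function() {
  if (is.null(.fix$anatomy)) .fix$anatomy <- generate_anatomy(seed = 7)
  .fix$anatomy
}

fixture_coords <- function() {
  if (is.null(.fix$coords))
    .fix$coords <- phantom_intrinsic_coords(fixture_anatomy(), c(2L, 5L))
  .fix$coords
}

empty_array <- function(dm) array(FALSE, dm)

# --- from-first-principles repeated-measures ANOVA oracle -------------------
# Explicit loops for every sum of squares, the covariance and its double
# centring, and Gram-Schmidt (difference contrasts) for Mauchly's W.  No
# code shared with rm_anova().
oracle_rm_anova <- function(tab) {
  n <- nrow(tab); K <- ncol(tab)
  g <- 0
  for (i in 1:n) for (j in 1:K) g <- g + tab[i, j]
  g <- g / (n * K)
  rowm <- numeric(n); colm <- numeric(K)
  for (i in 1:n) rowm[i] <- sum(tab[i, ]) / K
  for (j in 1:K) colm[j] <- sum(tab[, j]) / n
  ss_steps <- n * sum((colm - g)^2)
  ss_err <- 0
  for (i in 1:n) for (j in 1:K)
    ss_err <- ss_err + (tab[i, j] - rowm[i] - colm[j] + g)^2
  Fval <- (ss_steps / (K - 1)) / (ss_err / ((K - 1) * (n - 1)))

  S <- matrix(0, K, K)
  for (a in 1:K) for (b in 1:K)
    S[a, b] <- sum((tab[, a] - colm[a]) * (tab[, b] - colm[b])) / (n - 1)
  Sm_row <- numeric(K)
  for (a in 1:K) Sm_row[a] <- mean(S[a, ])
  Sm <- mean(S)
  Sc <- matrix(0, K, K)
  for (a in 1:K) for (b in 1:K) Sc[a, b] <- S[a, b] - Sm_row[a] - Sm_row[b] + Sm
  lam <- eigen(Sc, symmetric = TRUE, only.values = TRUE)$values
  eps <- sum(lam)^2 / ((K - 1) * sum(lam^2))

  # orthonormal basis of the contrast space by Gram-Schmidt on differences
  M <- matrix(0, K - 1, K)
  for (r in 1:(K - 1)) {
    v <- numeric(K); v[r] <- 1; v[r + 1] <- -1
    if (r > 1) for (q in 1:(r - 1)) v <- v - sum(v * M[q, ]) * M[q, ]
    M[r, ] <- v / sqrt(sum(v^2))
  }
  S1 <- M %*% S %*% t(M)
  W <- det(S1) / (sum(diag(S1)) / (K - 1))^(K - 1)
  fcorr <- 1 - (2 * (K - 1)^2 + (K - 1) + 2) / (6 * (K - 1) * (n - 1))
  chi2 <- -(n - 1) * fcorr * log(W)
  dfm <- K * (K - 1) / 2 - 1
  list(F = Fval, df1 = K - 1, df2 = (K - 1) * (n - 1), eps = eps, W = W,
       mauchly_p = pchisq(chi2, dfm, lower.tail = FALSE),
       ss_steps = ss_steps, ss_err = ss_err)
}

# hand application of the Holm step-down formula
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run_max <- 0
  for (i in 1:m) {
    run_max <- max(run_max, min(1, (m - i + 1) * p[o[i]]))
    adj[o[i]] <- run_max
  }
  adj
}

# --- random layering instances for the oracle-equivalence checks ------------
# Mix of slabs, corridors, random-walk blobs and folded annuli, each with a
# random anisotropic voxel size; grids <= 32^3, ROIs of modest size.
random_layering_instance <- function(seed) {
  set.seed(seed)
  kind <- sample(c("slab", "corridor", "blob", "annulus"), 1)
  vox <- round(runif(3, 0.8, 2.2), 2)
  if (kind == "slab") {
    nthick <- sample(5:18, 1)
    dm <- c(nthick + 2L, sample(3:6, 1), sample(3:6, 1))
    roi <- empty_array(dm); roi[2:(nthick + 1), , ] <- TRUE
    o <- empty_array(dm); o[1, , ] <- TRUE
    d <- empty_array(dm); d[nthick + 2L, , ] <- TRUE
  } else if (kind == "corridor") {
    n <- sample(10:25, 1)
    dm <- c(n, 8L, 8L)
    roi <- empty_array(dm)
    y <- 4L; z <- 4L
    path <- cbind(seq_len(n),
                  pmin(pmax(cumsum(sample(-1:1, n, TRUE)) + y, 2L), 7L),
                  pmin(pmax(cumsum(sample(-1:1, n, TRUE)) + z, 2L), 7L))
    roi[path] <- TRUE
    o <- empty_array(dm); o[path[1, , drop = FALSE]] <- TRUE
    d <- empty_array(dm); d[path[n, , drop = FALSE]] <- TRUE
    roi <- roi & !o & !d
  } else if (kind == "blob") {
    dm <- rep(sample(14:20, 1), 3)
    m <- empty_array(dm)
    pos <- round(dm / 2)
    for (i in 1:400) {
      pos <- pmin(pmax(pos + sample(-1:1, 3, TRUE), 2), dm - 1)
      m[pos[1], pos[2], pos[3]] <- TRUE
    }
    m <- dilate26(m)
    xg <- slice.index(m, 1)
    o <- m & xg == min(xg[m])
    d <- m & xg == max(xg[m])
    roi <- m & !o & !d
    if (!any(o) || !any(d)) return(random_layering_instance(seed + 1000))
  } else {
    dm <- rep(sample(24:32, 1), 3)
    cx <- dm[1] / 2; cz <- dm[3] / 2
    xg <- slice.index(empty_array(dm), 1)
    zg <- slice.index(empty_array(dm), 3)
    rho <- sqrt((xg - cx)^2 + (zg - cz)^2)
    th <- atan2(zg - cz, xg - cx)
    r0 <- runif(1, 3, 5); amp <- runif(1, 0.5, 1.5); Tt <- sample(4:6, 1)
    rwm <- r0 + amp * sin(sample(2:5, 1) * th)
    ys <- 2:(dm[2] - 1)
    band <- rho > rwm & rho <= rwm + Tt
    m <- empty_array(dm); m[, ys, ] <- band[, ys, ]
    o <- empty_array(dm); inner <- rho <= rwm
    o[, ys, ] <- inner[, ys, ]
    o <- o & dilate26(m)
    d <- dilate26(m) & !m & !o & !inner
    roi <- m
    if (!any(o) || !any(d)) return(random_layering_instance(seed + 1000))
  }
  list(roi = roi, origin = o, destination = d, vox = vox, kind = kind)
}

# step maps agree everywhere, allowing +-1 step where the ratio sits within
# tol of a bin edge
expect_steps_equivalent <- function(a, b, tol = 1e-9) {
  K <- a$n_steps
  same <- a$steps == b$steps
  if (all(same)) return(invisible(TRUE))
  idx <- which(!same)
  near_edge <- abs(a$ratio[idx] * K - round(a$ratio[idx] * K)) < K * tol
  off_by_one <- abs(a$steps[idx] - b$steps[idx]) == 1L
  expect_true(all(near_edge & off_by_one),
              label = paste("step maps differ beyond bin-edge ties at",
                            sum(!(near_edge & off_by_one)), "voxels"))
}
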