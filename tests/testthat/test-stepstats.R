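test_that("step profiles average z within steps and record empty steps as NA", {
  co <- fixture_coords()[["2"]]$coords$fissure_depth
  an <- fixture_anatomy()
  # constant field
  zconst <- array(5, dim(co$steps))
  p <- step_profile(zconst, co, an$gm_mask, subject_id = 1)
  expect_equal(p$mean_z, rep(5, 7))
  expect_identical(sum(p$voxel_counts), sum(co$steps > 0 & an$gm_mask))
  # plant the step index itself as the statistic
  zplant <- array(NA_real_, dim(co$steps))
  zplant[co$steps > 0] <- co$steps[co$steps > 0]
  p2 <- step_profile(zplant, co, an$gm_mask)
  expect_equal(p2$mean_z, as.numeric(1:7))
  # an emptied step is reported missing, never zero
  co3 <- co
  co3$steps[co3$steps == 4L] <- 0L
  p3 <- step_profile(zconst, co3, an$gm_mask)
  expect_true(is.na(p3$mean_z[4]))
  expect_identical(p3$voxel_counts[4], 0L)
})

test_that("mean grey-matter z matches an independent scan", {
  an <- fixture_anatomy()
  set.seed(8)
  z <- array(rnorm(prod(dim(an$gm_mask))), dim(an$gm_mask))
  got <- mean_gm_z(z, an$gm_mask)
  acc <- 0; n <- 0
  for (s in seq_len(dim(z)[3])) {
    sel <- an$gm_mask[, , s]
    acc <- acc + sum(z[, , s][sel]); n <- n + sum(sel)
  }
  expect_equal(got, acc / n, tolerance = 1e-12)
  half <- array(rep(c(0, 4), length.out = 64), c(4, 4, 4))
  expect_equal(mean_gm_z(half, array(TRUE, c(4, 4, 4))), 2)
})

test_that("overlap counts decompose the two activation masks", {
  dm <- c(4, 1, 1)
  a <- empty_array(dm); a[1:2, 1, 1] <- TRUE
  b <- empty_array(dm); b[2:3, 1, 1] <- TRUE
  oc <- overlap_counts(a, b)
  expect_identical(oc, list(only_a = 1L, only_b = 1L, both = 1L))
  oc2 <- overlap_counts(a, a)
  expect_identical(oc2, list(only_a = 0L, only_b = 0L, both = 2L))
  expect_identical(oc$only_a + oc$both, sum(a))
  # roi restriction matches an exhaustive scan
  an <- fixture_anatomy()
  set.seed(9)
  za <- array(rnorm(prod(dim(an$gm_mask))), dim(an$gm_mask)) > 1
  zb <- array(rnorm(prod(dim(an$gm_mask))), dim(an$gm_mask)) > 1
  oc3 <- overlap_counts(za, zb, an$gm_mask)
  expect_identical(oc3$both, sum(za & zb & an$gm_mask))
  expect_identical(oc3$only_a, sum(za & !zb & an$gm_mask))
})

test_that("paired t matches the closed form and its symmetries", {
  r <- paired_t(c(1, 2, 3), c(0, 0, 0))
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_identical(r$df, 2L)
  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  fl <- paired_t(c(0, 0, 0), c(1, 2, 3))
  expect_equal(fl$t, -r$t)
  expect_equal(fl$p, r$p)
  expect_error(paired_t(1, 2), class = "lobulae_degenerate_error")
  expect_error(paired_t(c(1, 1), c(0, 0)), class = "lobulae_degenerate_error")
})

test_that("rm_anova matches the brute-force oracle and conserves SS", {
  set.seed(101)
  for (rep in 1:5) {
    tab <- matrix(rnorm(8 * 7), 8, 7) + outer(rnorm(8), rep(0, 7), "+") +
      outer(rep(1, 8), rnorm(7, sd = 0.5))
    a <- rm_anova(tab)
    o <- oracle_rm_anova(tab)
    expect_equal(a$F, o$F, tolerance = 1e-8)
    expect_equal(a$gg_epsilon, o$eps, tolerance = 1e-8)
    expect_equal(a$mauchly_W, o$W, tolerance = 1e-8)
    expect_equal(a$mauchly_p, o$mauchly_p, tolerance = 1e-8)
    # SS conservation from the oracle pieces
    g <- mean(tab)
    ss_tot <- sum((tab - g)^2)
    ss_subj <- 7 * sum((rowMeans(tab) - g)^2)
    expect_equal(ss_subj + o$ss_steps + o$ss_err, ss_tot, tolerance = 1e-8)
    expect_gte(a$gg_epsilon, 1 / 6)
    expect_lte(a$gg_epsilon, 1)
  }
})

test_that("rm_anova handles the degenerate and K = 2 cases", {
  flat <- matrix(rep(rnorm(6), 4), 6, 4)          # identical columns
  a <- rm_anova(flat)
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)
  # K = 2 reduces to the paired t-test
  set.seed(11)
  tab2 <- matrix(rnorm(12), 6, 2)
  a2 <- rm_anova(tab2)
  tt <- paired_t(tab2[, 1], tab2[, 2])
  expect_equal(a2$F, tt$t^2, tolerance = 1e-10)
  expect_equal(a2$p, tt$p, tolerance = 1e-10)
  expect_equal(a2$gg_epsilon, 1)
  # compound-symmetric covariance gives epsilon = 1: subject offsets plus iid
  set.seed(12)
  cs <- outer(rnorm(200, sd = 3), rep(1, 4)) + matrix(rnorm(800), 200, 4)
  expect_gt(rm_anova(cs)$gg_epsilon, 0.95)
  expect_error(rm_anova(matrix(1:4, 1)), "2 subjects")
  # perfect additivity: zero error SS with a nonzero step effect
  expect_error(rm_anova(cbind(1:3, 2:4)), class = "lobulae_degenerate_error")
})

test_that("Holm adjustment follows the step-down formula", {
  expect_equal(sort(holm_adjust(c(0.01, 0.04, 0.03))), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)             # single comparison
  set.seed(13)
  for (m in c(3, 6, 10)) {
    p <- runif(m)^2
    adj <- holm_adjust(p)
    expect_equal(adj, oracle_holm(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= 0))    # monotone in sorted order
    expect_true(all(adj <= pmin(1, m * p) + 1e-12))  # dominates Bonferroni
  }
})

test_that("holm_posthoc runs every pair once and adjusts jointly", {
  set.seed(14)
  tab <- matrix(rnorm(48), 8, 6) + outer(rep(1, 8), seq(0, 2, length.out = 6))
  ph <- holm_posthoc(tab)
  expect_identical(nrow(ph), 15L)                 # 6*5/2 pairs
  expect_identical(anyDuplicated(ph[, c("step_a", "step_b")]), 0L)
  i <- which(ph$step_a == 1 & ph$step_b == 6)
  tt <- paired_t(tab[, 1], tab[, 6])
  expect_equal(ph$t[i], tt$t)
  expect_equal(ph$p_holm, holm_adjust(ph$p_raw))
})

test_that("profile_table drops subjects with empty steps", {
  co <- fixture_coords()[["2"]]$coords$fissure_depth
  an <- fixture_anatomy()
  zc <- array(1, dim(co$steps))
  good <- step_profile(zc, co, an$gm_mask, subject_id = "s1")
  bad <- good
  bad$mean_z[3] <- NA
  bad$subject_id <- "s2"
  expect_warning(pt <- profile_table(list(good, bad)), "excluding")
  expect_identical(rownames(pt$table), "s1")
  expect_identical(pt$excluded, "s2")
})
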