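# End-to-end orchestration: phantom -> segmentation -> gradients -> GLM ->
# step statistics -> COG, with every product written under one output
# directory and logged in a JSON manifest.

#' Default analysis configuration
#'
#' All pipeline constants in one structured list; see the methods vignette
#' for the rationale behind each default.  The analysis constants are
#' `n_steps = 7`, `wm_threshold = 0.99`, `z_threshold = 3.1`,
#' `alpha = 0.05`, `tr_s = 3.3`, 20 s-ON/10 s-OFF blocks and four 5-minute
#' runs.
#'
#' @param seed master seed; every random stage derives its seed from it.
#' @return named list of class `analysis_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    # phantom anatomy
    grid_shape = c(48L, 48L, 48L), n_lobules = 3L, fold_count = 4L,
    voxel_size_mm = c(1, 1, 1),
    # task/design
    n_subjects = 8L, n_runs = 4L,
    run_length_s = 300, tr_s = 3.3, on_s = 20, off_s = 10,
    task_order = c("MCFT", "SUFF"),
    # planted effects: centre_intrinsic = (depth, mediolateral, post-ant)
    effects = list(
      list(condition = "MCFT", centre_intrinsic = c(0.25, 0.8, 0.5),
           spatial_sd_mm = 2.5, amplitude_pct = 2.5),
      list(condition = "SUFF", centre_intrinsic = c(0.75, 0.4, 0.5),
           spatial_sd_mm = 2.5, amplitude_pct = 2.5)
    ),
    baseline = 100, sigma_pct = 2, ar1_rho = 0, subject_amp_sd = 0.1,
    # analysis constants
    n_steps = 7L, wm_threshold = 0.99, z_threshold = 3.1, alpha = 0.05,
    drift_order = 1L,
    # lobule lists (base labels, common to both hemispheres)
    target_lobules = NULL,          # default: interior lobules 2..L-1
    superior_lobules = NULL,        # default: base labels 1..L-1
    inferior_lobules = NULL,        # default: base label L
    write_bold = FALSE              # write per-run 4D NIfTIs (large)
  ), class = "analysis_config")
}

apply_config_defaults <- function(config) {
  L <- config$n_lobules
  if (is.null(config$target_lobules))
    config$target_lobules <- seq(2L, L - 1L)
  if (is.null(config$superior_lobules))
    config$superior_lobules <- seq_len(L - 1L)
  if (is.null(config$inferior_lobules))
    config$inferior_lobules <- L
  config
}

expand_hemi <- function(base_labels, anatomy) {
  c(base_labels, base_labels + anatomy$n_lobules)
}

derive_seed <- function(master, stage, k = 0L) {
  # keep derived seeds positive and below 2^31
  as.integer((as.numeric(master) * 7919 + stage * 104729 + k * 7907) %% 2147483629)
}

contrast_list <- function() {
  list("MCFT>rest" = c(MCFT = 1),
       "SUFF>rest" = c(SUFF = 1),
       "MCFT>SUFF" = c(MCFT = 1, SUFF = -1))
}

#' Fit one subject's runs and combine them
#'
#' First-level GLM per run, contrast z-maps for MCFT>rest, SUFF>rest and
#' MCFT>SUFF, and fixed-effects combination across runs.
#'
#' @param runs list of `bold_run`s.
#' @param drift_order Legendre drift order.
#' @param hrf_params HRF parameter overrides.
#' @return named list of combined `contrast_map`s.
#' @export
fit_subject <- function(runs, drift_order = 1L, hrf_params = list()) {
  cons <- contrast_list()
  per_run <- lapply(runs, function(run) {
    X <- build_design_matrix(run$design, hrf_params = hrf_params,
                             drift_order = drift_order)
    fit <- fit_glm(run, X)
    lapply(names(cons), function(nm) contrast_zmap(fit, cons[[nm]], nm))
  })
  combined <- lapply(seq_along(cons), function(i)
    fixed_effects_combine(lapply(per_run, `[[`, i)))
  names(combined) <- names(cons)
  combined
}

#' Run the full analysis pipeline
#'
#' Generates (or, via `anatomy`, accepts) the phantom anatomy, builds the
#' boundary sets and three gradient step maps per target lobule, simulates
#' and fits every subject's runs, extracts MCFT>SUFF step profiles, runs
#' the repeated-measures ANOVA with Holm post-hocs per lobule/direction,
#' performs the quadrant COG shift analysis, writes all volumes and TSV
#' tables under `out_dir`, and returns a manifest with md5 checksums of
#' every product.  Deterministic given `config$seed`.
#'
#' @param config `analysis_config` (see [default_config()]).
#' @param out_dir output directory (created if missing).
#' @param keep_maps return the per-subject combined contrast maps
#'   (memory-heavy; default FALSE).
#' @return object of class `run_manifest` (also written as
#'   `manifest.json`): tool version, config, per-file md5 checksums,
#'   per-stage warnings, and the headline statistics tables.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("lobulae_"),
                         keep_maps = FALSE) {
  config <- apply_config_defaults(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  warnings_log <- list()
  note <- function(...) {
    warnings_log[[length(warnings_log) + 1L]] <<- paste0(...)
  }
  vx <- config$voxel_size_mm
  emit <- function(data, name, ...) {
    p <- file.path(out_dir, name)
    write_volume(data, p, voxel_size_mm = vx, ...)
    files <<- c(files, p)
    p
  }
  emit_tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, p)
    p
  }

  ## stage: phantom anatomy -------------------------------------------------
  anatomy <- generate_anatomy(config$grid_shape, config$n_lobules,
                              config$fold_count,
                              seed = derive_seed(config$seed, 1L),
                              voxel_size_mm = vx)
  emit(anatomy$lobule_labels, "lobule_labels.nii", datatype = "int16")
  emit(anatomy$wm_probability, "wm_probability.nii")
  emit(anatomy$cerebellum_mask + 0L, "cerebellum_mask.nii", datatype = "uint8")
  emit(anatomy$gm_mask + 0L, "gm_mask.nii", datatype = "uint8")

  ## stage: segmentation + gradients ----------------------------------------
  targets <- expand_hemi(config$target_lobules, anatomy)
  coords <- phantom_intrinsic_coords(anatomy, targets, n_steps = config$n_steps)
  step_counts <- list()
  for (lb in as.character(targets)) {
    bs <- coords[[lb]]$boundaries
    for (nm in c("deep", "superficial", "anterior", "posterior", "medial",
                 "lateral"))
      emit(bs[[nm]] + 0L,
           sprintf("lobule%s_%s_%s.nii", lb, bs$hemisphere, nm),
           datatype = "uint8")
    for (dir in names(coords[[lb]]$coords)) {
      sm <- coords[[lb]]$coords[[dir]]
      emit(sm$steps, sprintf("lobule%s_%s_steps_%s.nii", lb, bs$hemisphere, dir),
           datatype = "int16")
      if (sm$n_unreachable > 0)
        note("gradients: lobule ", lb, " ", dir, ": ", sm$n_unreachable,
             " unreachable voxels excluded (step 0)")
      tab <- table(factor(sm$steps[sm$steps > 0], levels = seq_len(sm$n_steps)))
      step_counts[[length(step_counts) + 1L]] <- data.frame(
        lobule = lb, hemisphere = bs$hemisphere, direction = dir,
        step = seq_len(sm$n_steps), voxels = as.integer(tab))
    }
  }
  emit_tsv(do.call(rbind, step_counts), "step_voxel_counts.tsv")

  ## stage: task designs -----------------------------------------------------
  designs <- lapply(seq_len(config$n_runs), function(r)
    build_task_design(config$run_length_s, config$tr_s, config$on_s,
                      config$off_s, config$task_order, run_id = r))
  for (d in designs) {
    p <- file.path(out_dir, sprintf("design_run%d.tsv", d$run_id))
    write_task_design(d, p)
    files <- c(files, p)
  }

  ## stage: per-subject BOLD + GLM -------------------------------------------
  effects <- list()
  for (ef in config$effects)
    for (lb in targets)
      effects[[length(effects) + 1L]] <-
        effect_spec(ef$condition, lb, ef$centre_intrinsic,
                    ef$spatial_sd_mm, ef$amplitude_pct)

  quadrants <- quadrant_rois(anatomy$lobule_labels,
                             expand_hemi(config$superior_lobules, anatomy),
                             expand_hemi(config$inferior_lobules, anatomy),
                             anatomy$hemispheres)
  profiles <- list()   # [[lobule]][[direction]][[subject]]
  cog_rows <- list()
  overlap_rows <- list()
  gm_rows <- list()
  subject_maps <- if (keep_maps) list() else NULL

  for (s in seq_len(config$n_subjects)) {
    amp_scale <- if (length(effects) && config$subject_amp_sd > 0) {
      with_seed(derive_seed(config$seed, 2L, s),
                exp(rnorm(length(effects), 0, config$subject_amp_sd)))
    } else 1
    runs <- generate_bold(
      anatomy, designs, effects,
      noise_spec(config$sigma_pct, config$ar1_rho,
                 derive_seed(config$seed, 3L, s)),
      baseline = config$baseline, coords = coords,
      amplitude_scale = amp_scale)
    if (isTRUE(config$write_bold))
      for (run in runs)
        emit(bold_run_to_array(run),
             sprintf("sub%02d_run%d_bold.nii", s, run$run_id),
             tr_s = run$tr_s, datatype = "float32")
    combined <- fit_subject(runs, drift_order = config$drift_order)
    rm(runs)
    if (keep_maps) subject_maps[[s]] <- combined
    if (s == 1L)
      for (nm in names(combined))
        emit(combined[[nm]]$z,
             sprintf("sub01_z_%s.nii", gsub(">", "_gt_", nm)))

    for (nm in names(combined))
      gm_rows[[length(gm_rows) + 1L]] <- data.frame(
        subject = s, contrast = nm,
        mean_gm_z = mean_gm_z(combined[[nm]], anatomy$gm_mask))
    ov <- overlap_counts(threshold_map(combined[["MCFT>rest"]], config$z_threshold),
                         threshold_map(combined[["SUFF>rest"]], config$z_threshold),
                         anatomy$gm_mask)
    overlap_rows[[length(overlap_rows) + 1L]] <- data.frame(
      subject = s, only_mcft = ov$only_a, only_suff = ov$only_b, both = ov$both)

    for (lb in as.character(targets))
      for (dir in names(coords[[lb]]$coords))
        profiles[[lb]][[dir]][[s]] <- step_profile(
          combined[["MCFT>SUFF"]], coords[[lb]]$coords[[dir]],
          anatomy$gm_mask, subject_id = s)

    for (q in names(quadrants))
      for (cond in c("MCFT", "SUFF")) {
        cg <- tryCatch(
          centre_of_gravity(combined[[paste0(cond, ">rest")]], quadrants[[q]],
                            voxel_size_mm = vx),
          lobulae_empty_cluster_error = function(e) NULL)
        if (is.null(cg)) {
          note("cog: subject ", s, " quadrant ", q, " condition ", cond,
               " excluded (no z > 0 voxels)")
        } else {
          cog_rows[[length(cog_rows) + 1L]] <- data.frame(
            subject = s, quadrant = q, condition = cond,
            x = cg$cog_mm[1], y = cg$cog_mm[2], z = cg$cog_mm[3],
            total_weight = cg$total_weight)
        }
      }
  }

  ## stage: step statistics ---------------------------------------------------
  prof_rows <- list()
  anova_rows <- list()
  posthoc_rows <- list()
  anova_results <- list()
  for (lb in as.character(targets))
    for (dir in names(profiles[[lb]])) {
      pl <- profiles[[lb]][[dir]]
      for (p in pl)
        prof_rows[[length(prof_rows) + 1L]] <- data.frame(
          subject = p$subject_id, lobule = lb, hemisphere = p$hemisphere,
          direction = dir, step = seq_len(p$n_steps), mean_z = p$mean_z,
          voxels = p$voxel_counts)
      pt <- withCallingHandlers(
        profile_table(pl),
        warning = function(w) {
          note(conditionMessage(w)); invokeRestart("muffleWarning")
        })
      if (length(pt$excluded))
        note("stats: lobule ", lb, " ", dir, ": excluded subjects ",
             paste(pt$excluded, collapse = ", "))
      if (config$n_steps < 2L) {
        note("stats: n_steps < 2, ANOVA skipped for lobule ", lb, " ", dir)
        next
      }
      if (nrow(pt$table) < 2L) {
        note("stats: fewer than 2 complete subjects, ANOVA skipped for lobule ",
             lb, " ", dir)
        next
      }
      an <- rm_anova(pt$table, alpha = config$alpha)
      anova_results[[paste(lb, dir, sep = "_")]] <- an
      anova_rows[[length(anova_rows) + 1L]] <- data.frame(
        lobule = lb, direction = dir, n = an$n, K = an$K, F = an$F,
        df1 = an$df1, df2 = an$df2, p = an$p,
        p_uncorrected = an$p_uncorrected, p_gg = an$p_gg,
        mauchly_W = an$mauchly_W, mauchly_p = an$mauchly_p,
        gg_epsilon = an$gg_epsilon, corrected = an$corrected)
      ph <- holm_posthoc(pt$table)
      ph <- cbind(lobule = lb, direction = dir, ph)
      posthoc_rows[[length(posthoc_rows) + 1L]] <- ph
    }

  emit_tsv(do.call(rbind, prof_rows), "step_profiles.tsv")
  if (length(anova_rows)) {
    emit_tsv(do.call(rbind, anova_rows), "anova.tsv")
    emit_tsv(do.call(rbind, posthoc_rows), "posthoc_holm.tsv")
  }
  emit_tsv(do.call(rbind, gm_rows), "mean_gm_z.tsv")
  emit_tsv(do.call(rbind, overlap_rows), "overlap_counts.tsv")
  cog_df <- if (length(cog_rows)) do.call(rbind, cog_rows) else NULL
  shift_df <- NULL
  if (!is.null(cog_df)) {
    emit_tsv(cog_df, "cog_per_subject.tsv")
    shift_df <- cog_shift_analysis(cog_df)
    emit_tsv(shift_df, "cog_shift.tsv")
  }

  ## manifest -----------------------------------------------------------------
  sums <- tools::md5sum(files)
  names(sums) <- basename(files)
  manifest <- structure(list(
    tool = paste0("lobulae ", as.character(utils::packageVersion("lobulae"))),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    config = config[setdiff(names(config), "effects")],
    effects = config$effects,
    sign_convention = "positive delta-x = rightward (axis 1 runs left-to-right)",
    checksums = as.list(sums),
    warnings = unlist(warnings_log),
    out_dir = out_dir
  ), class = "run_manifest")
  json <- jsonlite::toJSON(unclass(manifest[setdiff(names(manifest),
                                                    "out_dir")]),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA,
                           null = "null")
  writeLines(json, file.path(out_dir, "manifest.json"))
  manifest$anova <- anova_results
  manifest$anova_table <- if (length(anova_rows)) do.call(rbind, anova_rows) else NULL
  manifest$posthoc <- if (length(posthoc_rows)) do.call(rbind, posthoc_rows) else NULL
  manifest$cog_shift <- shift_df
  manifest$cog_table <- cog_df
  manifest$overlap <- do.call(rbind, overlap_rows)
  manifest$mean_gm_z <- do.call(rbind, gm_rows)
  if (keep_maps) manifest$subject_maps <- subject_maps
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(x$tool, "- seed", x$seed, "\n")
  cat("  products:", length(x$checksums), "files in", x$out_dir, "\n")
  if (!is.null(x$anova_table)) {
    cat("  repeated-measures ANOVA (MCFT>SUFF step profiles):\n")
    print(x$anova_table[, c("lobule", "direction", "F", "df1", "df2", "p")],
          row.names = FALSE)
  }
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}
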