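# Orchestration of the two published analysis styles: stride-level
# (within-subjects, multilevel) and participant-average (between-subjects),
# each preceded by signal-level feature extraction.

map_to_force_idx <- function(marker_idx, marker_rate, force_rate, n_force) {
  idx <- round((marker_idx - 1L) / marker_rate * force_rate) + 1L
  pmin(pmax(idx, 1L), n_force)
}

# extract the full per-stride feature set for one participant
extract_subject <- function(markers, forces, meta, cfg = gait_config()) {
  if (is.character(markers)) markers <- read_marker_trial(markers, cfg)
  if (is.character(forces)) forces <- read_force_trial(forces, cfg)

  filt <- markers
  for (m in seq_along(markers$marker_names)) for (k in 1:3)
    filt$positions[, m, k] <- lowpass_filter(markers$positions[, m, k],
                                             markers$rate_hz, cfg$marker_cutoff_hz,
                                             cfg$filter_order)
  ev <- gait_events(
    detect_events(filt$positions[, "L_malleolus", "x"], filt$rate_hz, cfg$min_peak_period_s),
    detect_events(filt$positions[, "R_malleolus", "x"], filt$rate_hz, cfg$min_peak_period_s)
  )
  p_lab <- side_of(meta, TRUE)
  np_lab <- side_of(meta, FALSE)

  tv <- temporal_params(ev)
  ang <- joint_angles(filt)
  kin <- peak_kinematics(ang, ev)
  ffilt <- filter_grf(forces, cfg$grf_cutoff_hz, cfg$filter_order)
  mom <- inverse_dynamics(filt, ffilt, meta, winter_anthropometrics())
  momp <- moment_peaks(mom, ev)
  sl <- step_lengths(filt, ev, meta)

  side_feats <- function(lab, stride) {
    idx_f <- map_to_force_idx(ev[[lab]]$ic, filt$rate_hz, ffilt$rate_hz, length(ffilt$time))
    win <- idx_f[stride]:idx_f[stride + 1L]
    imp <- impulses(ffilt$grf[, match(lab, c("L", "R")), 1], win, ffilt$rate_hz, meta$mass_kg)
    pk <- grf_peaks(ffilt, win, meta$mass_kg, lab)
    tvr <- tv[tv$side == lab & tv$stride == stride, ]
    kir <- kin[kin$side == lab & kin$stride == stride, ]
    mor <- momp[momp$side == lab & momp$stride == stride, ]
    c(stance_time = tvr$stance_s, swing_time = tvr$swing_s,
      double_support_time = tvr$double_support_s,
      peak_ankle_dorsiflexion = kir$peak_ankle_dorsiflexion,
      peak_ankle_plantarflexion = kir$peak_ankle_plantarflexion,
      peak_knee_flexion = kir$peak_knee_flexion,
      peak_knee_extension = kir$peak_knee_extension,
      peak_hip_flexion = kir$peak_hip_flexion,
      peak_hip_extension = kir$peak_hip_extension,
      peak_braking_force = unname(pk["peak_braking"]),
      peak_propulsive_force = unname(pk["peak_propulsive"]),
      peak_vertical_grf = unname(pk["peak_vertical"]),
      braking_impulse = unname(imp["braking_impulse"]),
      propulsive_impulse = unname(imp["propulsive_impulse"]),
      peak_ankle_dorsiflexion_moment = mor$peak_ankle_dorsiflexion_moment,
      peak_ankle_plantarflexion_moment = mor$peak_ankle_plantarflexion_moment,
      peak_knee_flexion_moment = mor$peak_knee_flexion_moment,
      peak_knee_extension_moment = mor$peak_knee_extension_moment,
      peak_hip_flexion_moment = mor$peak_hip_flexion_moment,
      peak_hip_extension_moment = mor$peak_hip_extension_moment)
  }

  n_strides_avail <- min(length(ev$L$ic), length(ev$R$ic)) - 1L
  keep <- select_strides(n_strides_avail, cfg$n_strides)
  rows <- vector("list", length(keep))
  ri <- 0L
  for (k in keep) {
    ic_p <- ev[[p_lab]]$ic[k]
    ic_p_next <- ev[[p_lab]]$ic[k + 1L]
    sl_p <- sl$step_length_mm[sl$side == "P" & sl$ic_idx == ic_p]
    ic_np <- ev[[np_lab]]$ic[ev[[np_lab]]$ic > ic_p & ev[[np_lab]]$ic < ic_p_next]
    if (length(ic_np) != 1L) next
    np_stride <- match(ic_np, ev[[np_lab]]$ic)
    if (is.na(np_stride) || np_stride >= length(ev[[np_lab]]$ic)) next
    sl_np <- sl$step_length_mm[sl$side == "NP" & sl$ic_idx == ic_np]
    fp <- side_feats(p_lab, k)
    fnp <- side_feats(np_lab, np_stride)
    ri <- ri + 1L
    rows[[ri]] <- data.frame(
      subject_id = meta$subject_id, stride_idx = k,
      SLA_mm = compute_sla(sl_np, sl_p),
      as.list(stats::setNames(fp, paste0(names(fp), "_P"))),
      as.list(stats::setNames(fnp, paste0(names(fnp), "_NP"))),
      check.names = FALSE
    )
  }
  do.call(rbind, rows[seq_len(ri)])
}

#' Extract stride-level features for a set of participants
#'
#' Runs the full signal-level pipeline per participant (filtering, event
#' detection, temporal variables, joint angles, force processing, inverse
#' dynamics, per-stride peaks and impulses), selects the mid-trial strides,
#' computes stride-level SLA, classifies each participant's asymmetry
#' direction, drops participants whose CI spans zero, removes
#' opposite-direction strides and returns the pooled feature table.
#'
#' @param trials A list; each element is a list with `markers`, `forces`
#'   (objects or file paths) and `meta` (one [trial_metadata()] row).
#' @param cfg A [gait_config()].
#' @return An `extraction_result`: `table` (pooled rows with a `group`
#'   column), `assignments` (per-participant direction classification),
#'   `n_removed` (opposite-direction stride counts).
#' @export
run_extract <- function(trials, cfg = gait_config()) {
  tabs <- list(); assigns <- list(); removed <- integer(0)
  for (tr in trials) {
    tbl <- extract_subject(tr$markers, tr$forces, tr$meta, cfg)
    asg <- classify_direction(tbl$SLA_mm, cfg$ci_level, tbl$subject_id[1])
    assigns[[length(assigns) + 1L]] <- as.data.frame(unclass(asg))
    if (asg$group == "excluded") next
    tbl <- drop_opposite_strides(tbl, asg)
    removed[tbl$subject_id[1]] <- attr(tbl, "n_removed")
    tbl$group <- asg$group
    tabs[[length(tabs) + 1L]] <- tbl
  }
  structure(list(table = if (length(tabs)) do.call(rbind, tabs) else NULL,
                 assignments = do.call(rbind, assigns),
                 n_removed = removed, cfg = cfg),
            class = "extraction_result")
}

#' Within-subjects (stride-level) analysis for one direction group
#'
#' Exhaustive (components x sparsity) grid search with leave-one-out
#' cross-validation on the multilevel sparse PLS regression of stride-level
#' |SLA| on the 40 z-scored predictors, one-standard-error sparsest-model
#' selection, a final full-data fit with per-component variance accounted
#' for, and validation by a random-intercept linear mixed model (coefficient
#' CIs, marginal/conditional R-squared, per-participant intercepts, and -
#' when metadata is supplied - the regression of the random intercepts on
#' walking speed and Fugl-Meyer score).
#'
#' @param tbl Stride feature table for one direction group (must contain
#'   `abs_SLA_mm`).
#' @param meta Optional [trial_metadata()] for the intercept regression.
#' @param cfg A [gait_config()].
#' @return An `sla_within_report`.
#' @export
run_within <- function(tbl, meta = NULL, cfg = gait_config()) {
  preds <- intersect(feature_column_names(), names(tbl))
  if (length(unique(tbl$subject_id)) < 2)
    stop_stridesla("parameter_error", "need at least two participants in the group")
  X <- as.matrix(tbl[, preds, drop = FALSE])
  y <- tbl$abs_SLA_mm
  grid <- search_grid(X, y, tbl$subject_id,
                      maxK = cfg$grid_maxK_within,
                      max_keepX = cfg$grid_max_keepX_within, multilevel = TRUE)
  sel <- one_se_select(grid)

  sc <- zscore_predictors(tbl)
  Xs <- as.matrix(sc$table[, preds, drop = FALSE])
  sp <- within_decompose(Xs, y, tbl$subject_id)
  model <- fit_spls(sp$X_within, sp$y_within, K = sel$K, keepX = sel$keepX)
  predictors <- preds[model$support]

  lmm <- fit_random_intercept_lmm(Xs[, predictors, drop = FALSE], y,
                                  tbl$subject_id, cfg$ci_level)
  intercept_reg <- NULL
  if (!is.null(meta)) {
    i <- match(lmm$random_intercepts$subject_id, meta$subject_id)
    if (!anyNA(i) && nrow(lmm$random_intercepts) >= 4)
      intercept_reg <- tryCatch(
        regress_intercepts(lmm$random_intercepts$intercept_mm,
                           meta$walk_speed_mps[i], meta$fm_score[i]),
        collinearity_error = function(e) NULL)
  }
  structure(list(
    group = if ("group" %in% names(tbl)) tbl$group[1] else NA_character_,
    n_strides = nrow(tbl), n_subjects = length(unique(tbl$subject_id)),
    grid = grid, selection = sel, spls = model, predictors = predictors,
    vaf = stats::setNames(model$vaf, apply(model$loadings, 2, function(w)
      paste(preds[w != 0], collapse = "+"))),
    lmm = lmm, fixed_effects = lmm$fixed_effects,
    r2_marginal = lmm$r2_marginal, r2_conditional = lmm$r2_conditional,
    random_intercepts = lmm$random_intercepts,
    intercept_regression = intercept_reg,
    seed = cfg$seed, config = config_hash(cfg)
  ), class = "sla_within_report")
}

#' Between-subjects (participant-average) analysis for one direction group
#'
#' Averages |SLA| and every predictor over each participant's strides,
#' appends walking speed as a 41st candidate predictor, searches the smaller
#' (5 x 5) grid by leave-one-out cross-validation over participants, selects
#' by the one-standard-error rule, refits, and derives percentile bootstrap
#' CIs by resampling participants. If a within-subjects report is supplied,
#' each of its selected predictors is also regressed (participant averages,
#' univariate) against average |SLA| and coefficient signs are compared,
#' flagging between- vs within-subjects sign reversals.
#'
#' @param tbl Stride feature table for one direction group.
#' @param meta [trial_metadata()] (needed for walking speed).
#' @param cfg A [gait_config()].
#' @param within_report Optional `sla_within_report` to compare against.
#' @return An `sla_between_report`.
#' @export
run_between <- function(tbl, meta, cfg = gait_config(), within_report = NULL) {
  avg <- subject_averages(tbl, meta)
  if (nrow(avg) < 3)
    stop_stridesla("parameter_error", "need at least three participants")
  preds <- intersect(feature_column_names_all(), names(avg))
  X <- as.matrix(avg[, preds, drop = FALSE])
  y <- avg$abs_SLA_mm
  grid <- search_grid(X, y, maxK = cfg$grid_maxK_between,
                      max_keepX = cfg$grid_max_keepX_between, multilevel = FALSE)
  sel <- one_se_select(grid)
  model <- fit_between_spls(avg, sel$K, sel$keepX, preds)
  predictors <- preds[model$support]
  boot <- bootstrap_between(avg, sel$K, sel$keepX, B = cfg$n_bootstrap,
                            seed = cfg$seed, ci_level = cfg$ci_level)

  comparison <- NULL
  if (!is.null(within_report)) {
    rows <- lapply(within_report$predictors, function(pn) {
      xz <- as.numeric(scale(avg[[pn]]))
      uv <- stats::lm(y ~ xz)
      ct <- summary(uv)$coefficients
      wf <- within_report$fixed_effects
      wrow <- wf[wf$term == pn, ]
      data.frame(predictor = pn,
                 within_coef = wrow$estimate,
                 within_ci_low = wrow$ci_low, within_ci_high = wrow$ci_high,
                 between_slope = ct[2, 1],
                 between_p = ct[2, 4],
                 sign_reversal = sign(wrow$estimate) != sign(ct[2, 1]) &&
                   (wrow$ci_low > 0 || wrow$ci_high < 0) && ct[2, 4] < 0.05)
    })
    comparison <- do.call(rbind, rows)
  }
  structure(list(
    n_subjects = nrow(avg), grid = grid, selection = sel, spls = model,
    predictors = predictors, vaf = model$vaf, bootstrap = boot,
    comparison = comparison, averages = avg,
    seed = cfg$seed, config = config_hash(cfg)
  ), class = "sla_between_report")
}

#' @export
print.sla_within_report <- function(x, ...) {
  cat(sprintf("Within-subjects |SLA| analysis (%s): %d strides, %d participants\n",
              x$group, x$n_strides, x$n_subjects))
  cat(sprintf("  selected K=%d keepX=%d -> %d predictor(s): %s\n",
              x$selection$K, x$selection$keepX, length(x$predictors),
              paste(x$predictors, collapse = ", ")))
  cat(sprintf("  VAF per component: %s\n", paste(sprintf("%.1f%%", 100 * x$spls$vaf), collapse = " + ")))
  cat(sprintf("  marginal R2 = %.3f, conditional R2 = %.3f\n", x$r2_marginal, x$r2_conditional))
  print(x$fixed_effects, digits = 4)
  if (!is.null(x$intercept_regression))
    cat(sprintf("  intercepts ~ speed + FM: F = %.3f, p = %.3f\n",
                x$intercept_regression$F_stat, x$intercept_regression$p))
  invisible(x)
}

#' @export
print.sla_between_report <- function(x, ...) {
  cat(sprintf("Between-subjects |SLA| analysis: %d participants\n", x$n_subjects))
  cat(sprintf("  selected K=%d keepX=%d -> %s\n", x$selection$K, x$selection$keepX,
              paste(x$predictors, collapse = ", ")))
  print(x$bootstrap$coefficients[x$bootstrap$coefficients$estimate != 0, ], digits = 4)
  if (!is.null(x$comparison)) {
    cat("  within vs between comparison:\n")
    print(x$comparison, digits = 3)
  }
  invisible(x)
}
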