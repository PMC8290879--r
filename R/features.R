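# Stride selection, SLA, asymmetry-direction groups, feature-matrix assembly.

#' Select mid-trial strides
#'
#' Identifies the halfway stride and returns the `n/2` strides before it and
#' `n/2` from it onwards, giving `n` consecutive strides centred mid-trial.
#' If the window would run past either end of the trial it is shifted to fit
#' (with a warning); fewer than `n + 1` strides is an error.
#'
#' @param n_available Number of strides in the trial, or a [gait_events()]
#'   object (strides counted on the side with fewer).
#' @param n Number of strides to keep (default 50).
#' @return Integer vector of `n` consecutive 1-based stride indices.
#' @export
select_strides <- function(n_available, n = 50L) {
  if (inherits(n_available, "gait_events"))
    n_available <- min(length(n_available$L$ic), length(n_available$R$ic)) - 1L
  n_available <- as.integer(n_available)
  if (n_available < n + 1L)
    stop_stridesla("too_few_strides_error",
                   sprintf("trial has %d strides; need at least %d", n_available, n + 1L))
  halfway <- (n_available + 1L) %/% 2L
  start <- halfway - n %/% 2L
  end <- start + n - 1L
  if (start <= 1L || end >= n_available) {
    warn_stridesla("clipped_window_warning",
                   "mid-trial stride window touches the trial margin; clipped to fit")
    start <- max(1L, min(start, n_available - n + 1L))
    end <- start + n - 1L
  }
  seq.int(start, end)
}

#' Step length asymmetry
#'
#' SLA is the non-paretic minus the paretic step length in millimetres;
#' negative values indicate longer paretic steps.
#'
#' @param sl_np_mm,sl_p_mm Non-paretic and paretic step lengths (mm).
#' @return SLA in mm.
#' @export
compute_sla <- function(sl_np_mm, sl_p_mm) {
  sl_np_mm - sl_p_mm
}

#' Classify a participant's asymmetry direction
#'
#' Student-t confidence interval for the mean stride-level SLA. A CI entirely
#' below zero assigns the participant to the longer-paretic group, entirely
#' above zero to the shorter-paretic group; a CI spanning zero excludes the
#' participant (direction cannot be assigned).
#'
#' @param sla_per_stride Numeric vector of stride-level SLA (mm).
#' @param ci_level Confidence level (default 0.95).
#' @param subject_id Optional label carried into the result.
#' @return A `group_assignment` list: `subject_id`, `mean_sla_mm`, `ci_low`,
#'   `ci_high`, `group` (one of `"longer_paretic"`, `"shorter_paretic"`,
#'   `"excluded"`).
#' @export
classify_direction <- function(sla_per_stride, ci_level = 0.95, subject_id = NA_character_) {
  n <- length(sla_per_stride)
  if (n < 2)
    stop_stridesla("too_few_strides_error", "need at least 2 strides to form a CI")
  m <- mean(sla_per_stride)
  half <- stats::qt((1 + ci_level) / 2, df = n - 1) * stats::sd(sla_per_stride) / sqrt(n)
  ci <- c(m - half, m + half)
  group <- if (ci[2] < 0) "longer_paretic" else if (ci[1] > 0) "shorter_paretic" else "excluded"
  structure(list(subject_id = subject_id, mean_sla_mm = m,
                 ci_low = ci[1], ci_high = ci[2], group = group),
            class = "group_assignment")
}

#' Remove strides whose asymmetry opposes the participant's group
#'
#' For a longer-paretic participant, strides with positive SLA are dropped
#' (and vice versa); the magnitude column `abs_SLA_mm` is then populated.
#' The number of removed strides is recorded in the `n_removed` attribute.
#'
#' @param tbl Stride feature table rows for one participant.
#' @param assignment The participant's [classify_direction()] result; must
#'   not be `"excluded"`.
#' @return The filtered table with `abs_SLA_mm` added.
#' @export
drop_opposite_strides <- function(tbl, assignment) {
  if (assignment$group == "excluded")
    stop_stridesla("parameter_error", "cannot drop strides for an excluded participant")
  keep <- if (assignment$group == "longer_paretic") tbl$SLA_mm <= 0 else tbl$SLA_mm >= 0
  n_removed <- sum(!keep)
  out <- tbl[keep, , drop = FALSE]
  if (!nrow(out))
    stop_stridesla("empty_subject_error",
                   sprintf("all strides of %s oppose the assigned direction", assignment$subject_id))
  out$abs_SLA_mm <- abs(out$SLA_mm)
  attr(out, "n_removed") <- n_removed
  out
}

#' Z-score the predictor columns of a feature table
#'
#' Standardizes each of the 40 predictor columns over all rows, pooled across
#' participants (the response stays in millimetres so regression coefficients
#' remain interpretable as mm per predictor standard deviation).
#'
#' @param tbl Stride feature table.
#' @return List with the scaled `table` and the training `means` and `sds`.
#' @export
zscore_predictors <- function(tbl) {
  preds <- intersect(feature_column_names_all(), names(tbl))
  X <- as.matrix(tbl[, preds, drop = FALSE])
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop_stridesla("zero_variance_error",
                   paste("zero-variance predictors:",
                         paste(preds[sds == 0], collapse = ", ")),
                   columns = preds[sds == 0])
  tbl[, preds] <- sweep(sweep(X, 2, mu), 2, sds, "/")
  list(table = tbl, means = mu, sds = sds)
}

# predictor name set including the between-subjects walking-speed column
feature_column_names_all <- function() c(feature_column_names(), "walking_speed")

#' Participant-average feature table
#'
#' Arithmetic mean of `abs_SLA_mm` and every predictor over each
#' participant's strides, with overground walking speed appended as an
#' additional candidate predictor, as used in the between-subjects analysis.
#' Averages are returned on the raw scale; model-fitting routines z-score
#' across participants at fit time (so resampling procedures can refit the
#' scaling).
#'
#' @param tbl Stride feature table with `abs_SLA_mm`.
#' @param meta [trial_metadata()] with one row per participant.
#' @return Data frame, one row per participant.
#' @export
subject_averages <- function(tbl, meta) {
  num <- c("abs_SLA_mm", intersect(feature_column_names(), names(tbl)))
  agg <- stats::aggregate(tbl[, num, drop = FALSE],
                          by = list(subject_id = tbl$subject_id), FUN = mean)
  i <- match(agg$subject_id, meta$subject_id)
  if (anyNA(i))
    stop_stridesla("format_error", "metadata missing for some participants")
  agg$walking_speed <- meta$walk_speed_mps[i]
  agg
}
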