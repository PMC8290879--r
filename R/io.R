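# On-disk exchange formats. Everything is tab-separated text with a '#'
# comment header carrying the config hash and seed. Axis convention,
# package-wide: x = fore-aft (anterior positive), y = mediolateral,
# z = vertical (up positive). Positions in metres, forces in newtons.

MARKER_SET <- c("MTP5", "malleolus", "tibial_condyle", "trochanter", "iliac_crest")

required_markers <- function() {
  as.vector(outer(c("L", "R"), MARKER_SET, paste, sep = "_"))
}

#' Construct a marker trial
#'
#' A validated container for synchronized 3-D marker trajectories: `time`
#' (seconds, strictly increasing, uniformly sampled), `positions` a
#' `[T x M x 3]` array in metres, `marker_names`, and the sampling rate.
#'
#' @param time Numeric vector of sample times (s).
#' @param positions `[T x M x 3]` array (m); third dimension is (x, y, z).
#' @param marker_names Character vector of length M; must contain the ten
#'   required markers (`L_`/`R_` + MTP5, malleolus, tibial_condyle,
#'   trochanter, iliac_crest).
#' @param rate_hz Sampling rate (Hz).
#' @return An object of class `marker_trial`.
#' @export
marker_trial <- function(time, positions, marker_names, rate_hz) {
  if (length(dim(positions)) != 3L || dim(positions)[3] != 3L)
    stop_stridesla("format_error", "positions must be a [T x M x 3] array")
  if (dim(positions)[1] != length(time))
    stop_stridesla("format_error", "time and positions disagree on T")
  if (dim(positions)[2] != length(marker_names))
    stop_stridesla("format_error", "marker_names and positions disagree on M")
  dt <- diff(time)
  if (length(dt) && (any(dt <= 0) || max(abs(dt - 1 / rate_hz)) > 1e-9))
    stop_stridesla("format_error",
                   "time must be strictly increasing and uniform at rate_hz (tol 1e-9 s)")
  missing <- setdiff(required_markers(), marker_names)
  if (length(missing))
    stop_stridesla("missing_marker_error",
                   paste("missing required markers:", paste(missing, collapse = ", ")),
                   markers = missing)
  if (!all(is.finite(positions)))
    stop_stridesla("format_error", "non-finite marker positions")
  dimnames(positions) <- list(NULL, marker_names, c("x", "y", "z"))
  structure(list(time = time, positions = positions,
                 marker_names = marker_names, rate_hz = rate_hz),
            class = "marker_trial")
}

#' Construct a force trial
#'
#' Per-belt ground reaction forces and centre of pressure. `grf` is
#' `[T x 2 x 3]` (sides L, R; components x, y, z in N), `cop` is
#' `[T x 2 x 2]` (fore-aft and mediolateral CoP in m, `NA` while unloaded).
#'
#' @param time Sample times (s).
#' @param grf `[T x 2 x 3]` force array (N).
#' @param cop `[T x 2 x 2]` centre-of-pressure array (m).
#' @param rate_hz Sampling rate (Hz).
#' @return An object of class `force_trial`.
#' @export
force_trial <- function(time, grf, cop, rate_hz) {
  if (any(dim(grf) != c(length(time), 2L, 3L)))
    stop_stridesla("format_error", "grf must be [T x 2 x 3]")
  if (any(dim(cop) != c(length(time), 2L, 2L)))
    stop_stridesla("format_error", "cop must be [T x 2 x 2]")
  if (any(grf[, , 3] < 0, na.rm = TRUE))
    stop_stridesla("format_error", "vertical GRF must be >= 0 after zeroing")
  dimnames(grf) <- list(NULL, c("L", "R"), c("x", "y", "z"))
  dimnames(cop) <- list(NULL, c("L", "R"), c("x", "y"))
  structure(list(time = time, grf = grf, cop = cop, rate_hz = rate_hz),
            class = "force_trial")
}

# linear interpolation over interior NA runs of length <= max_gap; longer runs
# (or NA runs touching either end of the record) are an error naming the channel
fill_gaps <- function(v, max_gap, channel) {
  na <- is.na(v)
  if (!any(na)) return(v)
  r <- rle(na)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bad <- which(r$values)
  for (i in bad) {
    span <- c(starts[i], ends[i])
    if (r$lengths[i] > max_gap || starts[i] == 1L || ends[i] == length(v))
      stop_stridesla("gap_error",
                     sprintf("gap of %d frames in channel '%s' (samples %d-%d) exceeds the %d-frame limit",
                             r$lengths[i], channel, span[1], span[2], max_gap),
                     channel = channel, span = span)
  }
  stats::approx(seq_along(v), v, xout = seq_along(v))$y
}

read_table_checked <- function(path) {
  utils::read.delim(path, sep = "\t", comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read a marker trial from a delimited file
#'
#' Expects a tab-separated table with a `time` column and one
#' `<marker>_x/_y/_z` triple per marker. Interior gaps (empty cells) of at
#' most `cfg$max_gap_frames` frames are bridged by linear interpolation;
#' longer gaps raise a `gap_error` naming the channel and span.
#'
#' @param path File path.
#' @param cfg A [gait_config()].
#' @return A [marker_trial()].
#' @export
read_marker_trial <- function(path, cfg = gait_config()) {
  df <- read_table_checked(path)
  if (!"time" %in% names(df))
    stop_stridesla("format_error", "marker file must have a 'time' column")
  time <- df$time
  if (any(diff(time) <= 0))
    stop_stridesla("format_error", "non-monotone time column")
  cols <- setdiff(names(df), "time")
  base <- unique(sub("_[xyz]$", "", cols))
  missing <- setdiff(required_markers(), base)
  if (length(missing))
    stop_stridesla("missing_marker_error",
                   paste("missing required markers:", paste(missing, collapse = ", ")),
                   markers = missing)
  pos <- array(NA_real_, dim = c(nrow(df), length(base), 3L))
  for (j in seq_along(base)) for (k in 1:3) {
    cn <- paste0(base[j], "_", c("x", "y", "z")[k])
    if (!cn %in% names(df))
      stop_stridesla("format_error", paste("missing column", cn))
    pos[, j, k] <- fill_gaps(df[[cn]], cfg$max_gap_frames, cn)
  }
  rate <- 1 / stats::median(diff(time))
  marker_trial(time, pos, base, rate)
}

#' Read a force trial from a delimited file
#'
#' Expects `time` plus `L_Fx, L_Fy, L_Fz, L_copx, L_copy` and the `R_`
#' equivalents. Samples whose vertical force is below `cfg$fz_threshold_N`
#' are zeroed (all three force components) and their CoP set to `NA`.
#'
#' @inheritParams read_marker_trial
#' @return A [force_trial()].
#' @export
read_force_trial <- function(path, cfg = gait_config()) {
  df <- read_table_checked(path)
  if (!"time" %in% names(df))
    stop_stridesla("format_error", "force file must have a 'time' column")
  if (any(diff(df$time) <= 0))
    stop_stridesla("format_error", "non-monotone time column")
  grf <- array(0, dim = c(nrow(df), 2L, 3L))
  cop <- array(NA_real_, dim = c(nrow(df), 2L, 2L))
  for (s in 1:2) {
    side <- c("L", "R")[s]
    need <- paste0(side, "_", c("Fx", "Fy", "Fz", "copx", "copy"))
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop_stridesla("format_error", paste("missing columns:", paste(miss, collapse = ", ")))
    grf[, s, ] <- as.matrix(df[, need[1:3]])
    cop[, s, ] <- as.matrix(df[, need[4:5]])
    unloaded <- grf[, s, 3] < cfg$fz_threshold_N
    grf[unloaded, s, ] <- 0
    cop[unloaded, s, ] <- NA_real_
  }
  force_trial(df$time, grf, cop, 1 / stats::median(diff(df$time)))
}

write_tsv_full_precision <- function(df, path, cfg) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(file_header(cfg), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a marker trial
#'
#' @param trial A [marker_trial()].
#' @param path File path.
#' @param cfg A [gait_config()] (stamped into the file header).
#' @return The path, invisibly (writer); a `marker_trial` (reader).
#' @export
write_marker_trial <- function(trial, path, cfg = gait_config()) {
  df <- data.frame(time = trial$time)
  for (m in trial$marker_names) for (k in 1:3)
    df[[paste0(m, "_", c("x", "y", "z")[k])]] <- trial$positions[, m, k]
  write_tsv_full_precision(df, path, cfg)
}

#' Write a force trial
#'
#' @param trial A [force_trial()].
#' @inheritParams write_marker_trial
#' @export
write_force_trial <- function(trial, path, cfg = gait_config()) {
  df <- data.frame(time = trial$time)
  for (s in 1:2) {
    side <- c("L", "R")[s]
    df[[paste0(side, "_Fx")]] <- trial$grf[, s, 1]
    df[[paste0(side, "_Fy")]] <- trial$grf[, s, 2]
    df[[paste0(side, "_Fz")]] <- trial$grf[, s, 3]
    df[[paste0(side, "_copx")]] <- trial$cop[, s, 1]
    df[[paste0(side, "_copy")]] <- trial$cop[, s, 2]
  }
  write_tsv_full_precision(df, path, cfg)
}

#' Participant metadata table
#'
#' One row per participant: `subject_id`, `mass_kg`, `paretic_side`
#' (`"left"`/`"right"`), `treadmill_speed_mps`, `walk_speed_mps` (overground
#' walking speed used as a between-subjects predictor) and the
#' lower-extremity Fugl-Meyer motor score `fm_score` (0-34).
#'
#' @param df A data frame with the columns above.
#' @return The validated data frame, classed `trial_metadata`.
#' @export
trial_metadata <- function(df) {
  need <- c("subject_id", "mass_kg", "paretic_side", "treadmill_speed_mps",
            "walk_speed_mps", "fm_score")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_stridesla("format_error", paste("metadata missing:", paste(miss, collapse = ", ")))
  if (any(df$mass_kg <= 0)) stop_stridesla("format_error", "mass_kg must be > 0")
  if (!all(df$paretic_side %in% c("left", "right")))
    stop_stridesla("format_error", "paretic_side must be 'left' or 'right'")
  if (any(df$fm_score < 0 | df$fm_score > 34))
    stop_stridesla("format_error", "fm_score must be in 0..34")
  class(df) <- c("trial_metadata", "data.frame")
  df
}

#' @rdname trial_metadata
#' @param path File path.
#' @param cfg A [gait_config()].
#' @export
read_metadata <- function(path, cfg = gait_config()) {
  trial_metadata(read_table_checked(path))
}

#' @rdname trial_metadata
#' @export
write_metadata <- function(df, path, cfg = gait_config()) {
  write_tsv_full_precision(as.data.frame(df), path, cfg)
}

#' Write / read the stride-level feature table
#'
#' The canonical exchange table: one row per stride with columns
#' `subject_id`, `stride_idx`, `SLA_mm`, optionally `abs_SLA_mm` (present
#' once opposite-direction strides have been removed), then the 40 predictor
#' columns (paretic block first, then non-paretic). Values are printed at
#' full precision so a write/read round trip is exact.
#'
#' @param tbl A stride feature table (see [feature_column_names()]).
#' @param path File path.
#' @param cfg A [gait_config()].
#' @return The path, invisibly (writer); the table (reader).
#' @export
write_feature_table <- function(tbl, path, cfg = gait_config()) {
  key <- paste(tbl$subject_id, tbl$stride_idx)
  if (anyDuplicated(key))
    stop_stridesla("duplicate_error",
                   paste("duplicated (subject, stride) keys:",
                         paste(unique(key[duplicated(key)]), collapse = ", ")))
  fixed <- intersect(c("subject_id", "stride_idx", "SLA_mm", "abs_SLA_mm"), names(tbl))
  tbl <- tbl[, c(fixed, intersect(feature_column_names(), names(tbl)))]
  write_tsv_full_precision(as.data.frame(tbl), path, cfg)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, cfg = gait_config()) {
  df <- read_table_checked(path)
  df$subject_id <- as.character(df$subject_id)
  df
}

#' Names of the 40 stride-level predictor columns
#'
#' Twenty gait variables per limb: temporal (stance, swing, double-support
#' time), kinematic peaks (ankle/knee/hip, both directions), ground-kinetic
#' peaks and impulses, and joint-moment peaks; paretic (`_P`) block first,
#' then non-paretic (`_NP`).
#'
#' @return Character vector of length 40.
#' @export
feature_column_names <- function() {
  vars <- c("stance_time", "swing_time", "double_support_time",
            "peak_ankle_dorsiflexion", "peak_ankle_plantarflexion",
            "peak_knee_flexion", "peak_knee_extension",
            "peak_hip_flexion", "peak_hip_extension",
            "peak_braking_force", "peak_propulsive_force", "peak_vertical_grf",
            "braking_impulse", "propulsive_impulse",
            "peak_ankle_dorsiflexion_moment", "peak_ankle_plantarflexion_moment",
            "peak_knee_flexion_moment", "peak_knee_extension_moment",
            "peak_hip_flexion_moment", "peak_hip_extension_moment")
  c(paste0(vars, "_P"), paste0(vars, "_NP"))
}
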