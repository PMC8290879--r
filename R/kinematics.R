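# Marker-side processing: filtering, gait events from malleolus fore-aft
# excursions, step lengths, temporal stride variables, sagittal joint angles.

#' Zero-phase low-pass Butterworth filter
#'
#' Forward-backward (zero-phase) Butterworth smoothing. `order` is the final
#' effective order: the filter is designed at `order/2` and applied twice, so
#' the squared magnitude response has the stated order and no phase shift is
#' introduced (a phase lag would bias gait-event timing). The signal mean is
#' removed before filtering and restored afterwards, and the signal is
#' reflection-padded, so a constant input is returned exactly and edge
#' transients are suppressed.
#'
#' @param x Numeric vector.
#' @param rate_hz Sampling rate (Hz).
#' @param cutoff_hz Low-pass cutoff (Hz); must be below the Nyquist rate.
#' @param order Effective filter order (even; default 4).
#' @return Filtered vector, same length as `x`, DC gain 1.
#' @export
lowpass_filter <- function(x, rate_hz, cutoff_hz, order = 4L) {
  if (cutoff_hz >= rate_hz / 2)
    stop_stridesla("parameter_error", "cutoff must be below the Nyquist frequency")
  if (order < 2 || order %% 2 != 0)
    stop_stridesla("parameter_error", "order must be a positive even integer")
  if (length(x) <= 3 * order)
    stop_stridesla("parameter_error", "signal too short for the requested order")
  bf <- signal::butter(order / 2, cutoff_hz / (rate_hz / 2), type = "low")
  mu <- mean(x)
  xc <- x - mu
  n <- length(xc)
  # odd reflection padding long enough for the startup transient to die out
  np <- min(n - 1L, max(3L * ceiling(rate_hz / cutoff_hz), 25L))
  head_pad <- 2 * xc[1] - xc[(np + 1L):2L]
  tail_pad <- 2 * xc[n] - xc[(n - 1L):(n - np)]
  xp <- c(head_pad, xc, tail_pad)
  y <- signal::filter(bf, xp)
  y <- rev(signal::filter(bf, rev(y)))
  as.numeric(y[(np + 1L):(np + n)]) + mu
}

# indices of strict local maxima (sign = 1) or minima (sign = -1)
local_extrema <- function(x, sign = 1) {
  d <- diff(sign * x)
  which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
}

# suppress extrema of one kind closer than min_gap samples, keeping the one
# with the larger excursion
suppress_close <- function(idx, value, min_gap) {
  if (length(idx) < 2) return(idx)
  keep <- idx
  repeat {
    gaps <- diff(keep)
    j <- which(gaps < min_gap)
    if (!length(gaps) || !length(j)) break
    j <- j[1]
    drop <- if (value[match(keep[j], idx)] >= value[match(keep[j + 1], idx)]) j + 1 else j
    keep <- keep[-drop]
  }
  keep
}

#' Detect gait events for one limb from malleolus fore-aft excursion
#'
#' On a treadmill the malleolus fore-aft position is quasi-periodic: initial
#' contact (IC) coincides with the peak anterior excursion and foot-off (FO)
#' with the peak posterior excursion. Peaks closer than `min_period_s` are
#' suppressed, keeping the larger excursion, and the output is trimmed to a
#' strict IC, FO, IC, ... alternation starting at an IC.
#'
#' @param malleolus_ap Low-pass-filtered fore-aft malleolus position (m),
#'   anterior positive, treadmill frame.
#' @param rate_hz Sampling rate (Hz).
#' @param min_period_s Minimum admissible interval between same-type events (s).
#' @return A `gait_side_events` list with integer sample indices `ic`, `fo`
#'   and `rate_hz`.
#' @export
detect_events <- function(malleolus_ap, rate_hz, min_period_s = 0.4) {
  min_gap <- ceiling(min_period_s * rate_hz)
  ic <- local_extrema(malleolus_ap, 1)
  fo <- local_extrema(malleolus_ap, -1)
  ic <- suppress_close(ic, malleolus_ap[ic], min_gap)
  fo <- suppress_close(fo, -malleolus_ap[fo], min_gap)
  # enforce alternation: between consecutive ICs keep the single deepest FO
  if (length(ic) >= 2 && length(fo)) {
    fo_keep <- integer(0)
    for (k in seq_len(length(ic) - 1L)) {
      cand <- fo[fo > ic[k] & fo < ic[k + 1L]]
      if (length(cand))
        fo_keep <- c(fo_keep, cand[which.min(malleolus_ap[cand])])
    }
    fo <- fo_keep
  }
  if (length(ic) < 2 || length(fo) < 1)
    stop_stridesla("too_few_strides_error",
                   sprintf("detected %d initial contacts and %d foot-offs; need at least one full cycle",
                           length(ic), length(fo)))
  structure(list(ic = as.integer(ic), fo = as.integer(fo), rate_hz = rate_hz),
            class = "gait_side_events")
}

#' Combine per-side events into a validated two-side set
#'
#' @param left,right `gait_side_events` for the left and right limb.
#' @return A `gait_events` object (`$L`, `$R`, `$rate_hz`).
#' @export
gait_events <- function(left, right) {
  for (ev in list(left, right)) {
    if (is.unsorted(ev$ic, strictly = TRUE) || is.unsorted(ev$fo, strictly = TRUE))
      stop_stridesla("event_pairing_error", "event indices must be strictly increasing")
    for (k in seq_along(ev$fo)) {
      covered <- any(ev$ic < ev$fo[k]) && any(ev$ic > ev$fo[k])
      if (!covered)
        stop_stridesla("event_pairing_error",
                       "every foot-off must lie between two initial contacts of the same side")
    }
  }
  if (left$rate_hz != right$rate_hz)
    stop_stridesla("event_pairing_error", "sides disagree on sampling rate")
  structure(list(L = left, R = right, rate_hz = left$rate_hz), class = "gait_events")
}

side_of <- function(meta, paretic = TRUE) {
  ps <- if (meta$paretic_side[1] == "left") "L" else "R"
  if (paretic) ps else setdiff(c("L", "R"), ps)
}

#' Step lengths at each initial contact
#'
#' Step length of a limb is the fore-aft distance between the two lateral
#' malleolus markers at that limb's initial contact, in millimetres; the
#' leading limb ahead of the contralateral one gives a positive length.
#' Steps are labelled `P`/`NP` using the paretic side in `meta`.
#'
#' @param markers A (filtered) [marker_trial()].
#' @param events A [gait_events()] object.
#' @param meta One row of [trial_metadata()].
#' @return Data frame with `side` (`"P"`/`"NP"`), `ic_idx`, `step_length_mm`.
#' @export
step_lengths <- function(markers, events, meta) {
  t_len <- length(markers$time)
  out <- list()
  for (s in c("L", "R")) {
    o <- setdiff(c("L", "R"), s)
    ic <- events[[s]]$ic
    if (any(ic < 1 | ic > t_len))
      stop_stridesla("index_error", "initial-contact index outside marker record")
    sl <- (markers$positions[ic, paste0(s, "_malleolus"), "x"] -
             markers$positions[ic, paste0(o, "_malleolus"), "x"]) * 1000
    lab <- if (s == side_of(meta, paretic = TRUE)) "P" else "NP"
    out[[s]] <- data.frame(side = lab, ic_idx = ic, step_length_mm = as.numeric(sl))
  }
  res <- rbind(out$L, out$R)
  res[order(res$ic_idx), , drop = FALSE]
}

#' Temporal stride variables
#'
#' Per stride (IC to next IC of the same limb): stance time (IC to FO),
#' swing time (FO to next IC) and double-support time, defined for a limb as
#' the interval from contralateral initial contact to ipsilateral foot-off.
#'
#' @param events A [gait_events()] object.
#' @return Data frame with `side` (`"L"`/`"R"`), `stride`, `ic_idx`,
#'   `stance_s`, `swing_s`, `double_support_s`.
#' @export
temporal_params <- function(events) {
  rate <- events$rate_hz
  res <- list()
  for (s in c("L", "R")) {
    o <- setdiff(c("L", "R"), s)
    ic <- events[[s]]$ic
    fo <- events[[s]]$fo
    ic_c <- events[[o]]$ic
    n_str <- length(ic) - 1L
    rows <- vector("list", n_str)
    for (k in seq_len(n_str)) {
      f <- fo[fo > ic[k] & fo < ic[k + 1L]]
      if (length(f) != 1L)
        stop_stridesla("event_pairing_error",
                       sprintf("side %s stride %d has %d foot-offs", s, k, length(f)))
      contra <- ic_c[ic_c > ic[k] & ic_c <= f]
      if (!length(contra))
        stop_stridesla("event_pairing_error",
                       sprintf("side %s stride %d has no contralateral initial contact before foot-off", s, k))
      rows[[k]] <- data.frame(
        side = s, stride = k, ic_idx = ic[k],
        stance_s = (f - ic[k]) / rate,
        swing_s = (ic[k + 1L] - f) / rate,
        double_support_s = (f - max(contra)) / rate
      )
    }
    res[[s]] <- do.call(rbind, rows)
  }
  rbind(res$L, res$R)
}

# signed angle (degrees) from vector u to vector v in the sagittal (x-z) plane
sagittal_angle <- function(ux, uz, vx, vz) {
  atan2(ux * vz - uz * vx, ux * vx + uz * vz) * 180 / pi
}

segment_vector <- function(markers, from, to) {
  v <- markers$positions[, to, c("x", "z")] - markers$positions[, from, c("x", "z")]
  if (any(sqrt(rowSums(v^2)) < 1e-9))
    stop_stridesla("degenerate_segment_error",
                   sprintf("zero-length segment %s-%s", from, to))
  v
}

#' Sagittal-plane joint angles
#'
#' Segments follow standard link-segment conventions: foot (5th
#' metatarsophalangeal joint to lateral malleolus), shank (malleolus to
#' lateral tibial condyle), thigh (condyle to greater trochanter), pelvis
#' (trochanter to iliac crest); mediolateral coordinates are ignored. The
#' ankle angle is the foot-shank angle minus 90 degrees so that anatomical
#' neutral (foot perpendicular to shank) is 0, dorsiflexion positive. Knee
#' and hip flexion are positive.
#'
#' @param markers A (filtered) [marker_trial()].
#' @return A `joint_angle_series`: per side `ankle`, `knee`, `hip` arrays in
#'   degrees, plus `time` and `rate_hz`.
#' @export
joint_angles <- function(markers) {
  out <- list(time = markers$time, rate_hz = markers$rate_hz)
  for (s in c("L", "R")) {
    foot <- segment_vector(markers, paste0(s, "_MTP5"), paste0(s, "_malleolus"))
    shank <- segment_vector(markers, paste0(s, "_malleolus"), paste0(s, "_tibial_condyle"))
    thigh <- segment_vector(markers, paste0(s, "_tibial_condyle"), paste0(s, "_trochanter"))
    pelvis <- segment_vector(markers, paste0(s, "_trochanter"), paste0(s, "_iliac_crest"))
    out[[s]] <- list(
      ankle = sagittal_angle(shank[, 1], shank[, 2], foot[, 1], foot[, 2]) - 90,
      knee = sagittal_angle(shank[, 1], shank[, 2], thigh[, 1], thigh[, 2]),
      hip = sagittal_angle(pelvis[, 1], pelvis[, 2], thigh[, 1], thigh[, 2])
    )
  }
  structure(out, class = "joint_angle_series")
}

stride_windows <- function(events, side) {
  ic <- events[[side]]$ic
  if (length(ic) < 2) stop_stridesla("index_error", "need at least one full stride")
  data.frame(stride = seq_len(length(ic) - 1L), from = ic[-length(ic)], to = ic[-1])
}

#' Per-stride peak joint angles
#'
#' For each stride (IC to next IC) and each joint, the extreme value in the
#' flexion direction (maximum on the flexion/dorsiflexion-positive scale) and
#' in the extension direction (minimum), i.e. the six kinematic predictor
#' variables per limb.
#'
#' @param angles A [joint_angles()] result.
#' @param events A [gait_events()] object.
#' @return Data frame, one row per side and stride, with the six peak columns.
#' @export
peak_kinematics <- function(angles, events) {
  res <- list()
  for (s in c("L", "R")) {
    w <- stride_windows(events, s)
    if (any(w$to > length(angles$time)))
      stop_stridesla("index_error", "stride window outside angle record")
    a <- angles[[s]]
    rows <- lapply(seq_len(nrow(w)), function(k) {
      i <- w$from[k]:w$to[k]
      data.frame(
        side = s, stride = k,
        peak_ankle_dorsiflexion = max(a$ankle[i]),
        peak_ankle_plantarflexion = min(a$ankle[i]),
        peak_knee_flexion = max(a$knee[i]),
        peak_knee_extension = min(a$knee[i]),
        peak_hip_flexion = max(a$hip[i]),
        peak_hip_extension = min(a$hip[i])
      )
    })
    res[[s]] <- do.call(rbind, rows)
  }
  rbind(res$L, res$R)
}
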