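# Force-side processing: GRF filtering, braking/propulsive impulses, force
# peaks, and sagittal-plane bottom-up link-segment inverse dynamics.

#' Proportional anthropometric table
#'
#' Segment inertial parameters as fractions of body mass and segment length,
#' after Winter's classical proportional tables: segment mass fraction,
#' centre-of-mass location as a fraction of segment length from the proximal
#' end, and radius of gyration about the centre of mass as a fraction of
#' segment length. Swappable via the `anthropometry` field of
#' [gait_config()] or by passing any data frame with the same columns.
#'
#' @return Data frame with columns `segment`, `mass_frac`, `com_frac`,
#'   `gyration_frac`.
#' @export
winter_anthropometrics <- function() {
  tbl <- data.frame(
    segment = c("foot", "shank", "thigh"),
    mass_frac = c(0.0145, 0.0465, 0.100),
    com_frac = c(0.500, 0.433, 0.433),
    gyration_frac = c(0.475, 0.302, 0.323)
  )
  stopifnot(all(tbl$mass_frac > 0 & tbl$mass_frac < 1),
            all(tbl$com_frac > 0 & tbl$com_frac < 1),
            all(tbl$gyration_frac > 0 & tbl$gyration_frac < 1))
  tbl
}

GRAVITY <- 9.81

#' Low-pass filter ground reaction forces
#'
#' Zero-phase Butterworth smoothing of every force and CoP channel.
#' Samples that are unloaded (vertical force exactly zero) are restored to
#' exactly zero after filtering so swing phases stay force-free, and any
#' residual negative vertical force from filter ringing is clamped at zero.
#'
#' @param force A [force_trial()].
#' @param cutoff_hz Cutoff frequency (default 100 Hz).
#' @param order Effective filter order.
#' @return A filtered [force_trial()].
#' @export
filter_grf <- function(force, cutoff_hz = 100, order = 4L) {
  out <- force
  for (s in 1:2) {
    unloaded <- force$grf[, s, 3] == 0
    for (k in 1:3) {
      out$grf[, s, k] <- lowpass_filter(force$grf[, s, k], force$rate_hz, cutoff_hz, order)
      out$grf[unloaded, s, k] <- 0
    }
    out$grf[, s, 3] <- pmax(out$grf[, s, 3], 0)
  }
  out
}

trapezoid <- function(y, dt) {
  if (length(y) < 2) return(0)
  dt * (sum(y) - (y[1] + y[length(y)]) / 2)
}

#' Braking and propulsive impulses over one gait cycle
#'
#' Trapezoidal integrals of the negative-portion magnitude and positive
#' portion of the fore-aft ground reaction force over a limb's gait cycle,
#' normalized by body mass.
#'
#' @param fore_aft Fore-aft GRF (N), anterior positive.
#' @param window Integer sample range of one gait cycle of that limb.
#' @param rate_hz Force sampling rate (Hz).
#' @param mass_kg Body mass (kg).
#' @return Named vector `c(braking_impulse, propulsive_impulse)` in N s/kg,
#'   both stored as magnitudes.
#' @export
impulses <- function(fore_aft, window, rate_hz, mass_kg) {
  if (!length(window) || any(window < 1 | window > length(fore_aft)))
    stop_stridesla("index_error", "impulse window outside force record")
  f <- fore_aft[window]
  dt <- 1 / rate_hz
  c(braking_impulse = trapezoid(pmax(-f, 0), dt) / mass_kg,
    propulsive_impulse = trapezoid(pmax(f, 0), dt) / mass_kg)
}

#' Peak ground-reaction forces over one gait cycle
#'
#' Magnitudes of the braking (posterior), propulsive (anterior) and vertical
#' GRF extrema within the limb's loaded portion of the window, normalized by
#' body mass.
#'
#' @param force A [force_trial()].
#' @param window Integer sample range of one gait cycle.
#' @param mass_kg Body mass (kg).
#' @param side `"L"` or `"R"`.
#' @return Named vector `c(peak_braking, peak_propulsive, peak_vertical)` in N/kg.
#' @export
grf_peaks <- function(force, window, mass_kg, side) {
  s <- match(side, c("L", "R"))
  if (!length(window) || any(window < 1 | window > length(force$time)))
    stop_stridesla("index_error", "window outside force record")
  fz <- force$grf[window, s, 3]
  if (all(fz == 0))
    stop_stridesla("unloaded_stride_error",
                   sprintf("side %s carries no load in the window", side))
  fx <- force$grf[window, s, 1]
  c(peak_braking = max(-fx, 0) / mass_kg,
    peak_propulsive = max(fx, 0) / mass_kg,
    peak_vertical = max(fz) / mass_kg)
}

# first and second time derivatives, central differences with one-sided ends
time_deriv <- function(x, dt) {
  n <- length(x)
  d <- c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) / dt
  d
}

# y-axis moment of force f = (fx, fz) applied at lever r = (rx, rz)
cross_y <- function(rx, rz, fx, fz) rz * fx - rx * fz

# interpolate one force/CoP channel onto the marker clock
interp_to <- function(t_from, v, t_to) {
  stats::approx(t_from, v, xout = t_to, rule = 2)$y
}

#' Sagittal-plane joint moments by bottom-up inverse dynamics
#'
#' Planar Newton-Euler recursion foot -> shank -> thigh. Segment masses,
#' centre-of-mass positions and moments of inertia come from the
#' anthropometric table scaled by body mass and marker-derived segment
#' lengths; linear and angular accelerations are obtained by central
#' differences of the (already filtered) marker kinematics. The ankle moment
#' balances the ground reaction force acting at the centre of pressure plus
#' foot dynamics; knee and hip moments follow by propagation. Forces are
#' interpolated down to the marker clock. Output is normalized by body mass
#' with the extensor/plantarflexor direction positive (internal moments).
#'
#' @param markers A filtered [marker_trial()].
#' @param force A (filtered) [force_trial()]; its rate must be at least the
#'   marker rate.
#' @param meta One row of [trial_metadata()].
#' @param anthro Anthropometric table, default [winter_anthropometrics()].
#' @return A `joint_moment_series`: per side `ankle`, `knee`, `hip` arrays in
#'   N m/kg, plus `time` and `rate_hz`.
#' @export
inverse_dynamics <- function(markers, force, meta,
                             anthro = winter_anthropometrics()) {
  if (force$rate_hz < markers$rate_hz)
    stop_stridesla("parameter_error", "force rate must be >= marker rate")
  mass <- meta$mass_kg[1]
  dt <- 1 / markers$rate_hz
  tt <- markers$time
  out <- list(time = tt, rate_hz = markers$rate_hz)
  seg_par <- function(name) anthro[anthro$segment == name, ]

  for (sn in 1:2) {
    side <- c("L", "R")[sn]
    p <- function(m, ax) markers$positions[, paste0(side, "_", m), ax]
    joints <- list(
      foot = list(prox = cbind(p("malleolus", "x"), p("malleolus", "z")),
                  dist = cbind(p("MTP5", "x"), p("MTP5", "z")), par = seg_par("foot")),
      shank = list(prox = cbind(p("tibial_condyle", "x"), p("tibial_condyle", "z")),
                   dist = cbind(p("malleolus", "x"), p("malleolus", "z")), par = seg_par("shank")),
      thigh = list(prox = cbind(p("trochanter", "x"), p("trochanter", "z")),
                   dist = cbind(p("tibial_condyle", "x"), p("tibial_condyle", "z")), par = seg_par("thigh"))
    )

    fx <- interp_to(force$time, force$grf[, sn, 1], tt)
    fz <- interp_to(force$time, force$grf[, sn, 3], tt)
    loaded <- fz > 0
    cop_x <- rep(NA_real_, length(tt))
    if (any(!is.na(force$cop[, sn, 1]))) {
      ok <- !is.na(force$cop[, sn, 1])
      cop_x <- stats::approx(force$time[ok], force$cop[ok, sn, 1], xout = tt, rule = 2)$y
    }
    if (any(loaded & !is.finite(cop_x)))
      stop_stridesla("cop_error", "centre of pressure undefined during a loaded phase")
    fx[!loaded] <- 0
    fz[!loaded] <- 0

    seg <- lapply(joints, function(j) {
      vec <- j$dist - j$prox
      len <- sqrt(rowSums(vec^2))
      if (any(len < 1e-9)) stop_stridesla("degenerate_segment_error", "zero-length segment")
      m <- j$par$mass_frac * mass
      com <- j$prox + j$par$com_frac * vec
      inertia <- m * (j$par$gyration_frac * mean(len))^2
      theta <- atan2(vec[, 2], vec[, 1])
      theta <- theta[1] + cumsum(c(0, atan2(sin(diff(theta)), cos(diff(theta)))))  # unwrap
      alpha_y <- -time_deriv(time_deriv(theta, dt), dt)  # +y rotation maps +x to -z
      list(m = m, com = com, inertia = inertia, alpha_y = alpha_y,
           acc = cbind(time_deriv(time_deriv(com[, 1], dt), dt),
                       time_deriv(time_deriv(com[, 2], dt), dt)))
    })

    ankle <- joints$foot$prox
    knee <- joints$shank$prox
    hip <- joints$thigh$prox

    # foot: proximal reaction at the ankle
    f <- seg$foot
    Rax <- f$m * f$acc[, 1] - fx
    Raz <- f$m * f$acc[, 2] + f$m * GRAVITY - fz
    grf_mom <- ifelse(loaded,
                      cross_y(cop_x - f$com[, 1], 0 - f$com[, 2], fx, fz), 0)
    Ma <- f$inertia * f$alpha_y -
      cross_y(ankle[, 1] - f$com[, 1], ankle[, 2] - f$com[, 2], Rax, Raz) -
      grf_mom

    # shank
    s2 <- seg$shank
    Rkx <- s2$m * s2$acc[, 1] + Rax
    Rkz <- s2$m * s2$acc[, 2] + s2$m * GRAVITY + Raz
    Mk <- s2$inertia * s2$alpha_y + Ma -
      cross_y(knee[, 1] - s2$com[, 1], knee[, 2] - s2$com[, 2], Rkx, Rkz) +
      cross_y(ankle[, 1] - s2$com[, 1], ankle[, 2] - s2$com[, 2], Rax, Raz)

    # thigh
    t2 <- seg$thigh
    Rhx <- t2$m * t2$acc[, 1] + Rkx
    Rhz <- t2$m * t2$acc[, 2] + t2$m * GRAVITY + Rkz
    Mh <- t2$inertia * t2$alpha_y + Mk -
      cross_y(hip[, 1] - t2$com[, 1], hip[, 2] - t2$com[, 2], Rhx, Rhz) +
      cross_y(knee[, 1] - t2$com[, 1], knee[, 2] - t2$com[, 2], Rkx, Rkz)

    # internal moments, extensor/plantarflexor positive, mass-normalized
    out[[side]] <- list(ankle = Ma / mass, knee = -Mk / mass, hip = Mh / mass)
  }
  structure(out, class = "joint_moment_series")
}

#' Per-stride peak joint moments
#'
#' For each stride and joint, the magnitude of the moment extremum in each
#' anatomical direction (plantarflexion/dorsiflexion at the ankle,
#' flexion/extension at knee and hip), clamped at zero when the moment never
#' acts in that direction.
#'
#' @param moments A [inverse_dynamics()] result.
#' @param events A [gait_events()] object on the same clock.
#' @return Data frame, one row per side and stride, six peak-moment columns
#'   (N m/kg).
#' @export
moment_peaks <- function(moments, events) {
  res <- list()
  for (s in c("L", "R")) {
    w <- stride_windows(events, s)
    if (any(w$to > length(moments$time)))
      stop_stridesla("index_error", "stride window outside moment record")
    m <- moments[[s]]
    rows <- lapply(seq_len(nrow(w)), function(k) {
      i <- w$from[k]:w$to[k]
      data.frame(
        side = s, stride = k,
        peak_ankle_plantarflexion_moment = max(m$ankle[i], 0),
        peak_ankle_dorsiflexion_moment = max(-m$ankle[i], 0),
        peak_knee_extension_moment = max(m$knee[i], 0),
        peak_knee_flexion_moment = max(-m$knee[i], 0),
        peak_hip_extension_moment = max(m$hip[i], 0),
        peak_hip_flexion_moment = max(-m$hip[i], 0)
      )
    })
    res[[s]] <- do.call(rbind, rows)
  }
  rbind(res$L, res$R)
}
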