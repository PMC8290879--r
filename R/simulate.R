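# Synthetic data with exact ground truth: (a) signal-level hemiparetic
# treadmill gait (markers + forces) and (b) feature-level stride tables with
# a known sparse linear dependence of |SLA| on correlated predictors.
#
# The signal generator is kinematically simple by design - periodic waveforms
# whose extrema fall at prescribed event times - so that every quantity the
# extraction code computes has a closed-form truth. It is not a physics model.

#' Configuration for the signal-level gait simulator
#'
#' Prescribes timing (stride period, stance and double-support fractions per
#' side), spatial targets (paretic and non-paretic step lengths), joint-angle
#' waveform amplitudes, ground-reaction-force profile parameters (vertical
#' double-bump peak, braking/propulsive amplitudes in body weights), marker
#' noise, and anthropometry of the simulated walker. Initial contacts are
#' aligned to marker frames so event truth is exact. Defaults emulate a
#' longer-paretic hemiparetic walker on a slow treadmill.
#'
#' @param n_strides Number of full strides to simulate (plus padding).
#' @param stride_period_s Stride period (s); snapped to the marker frame grid.
#' @param step_length_P_mm,step_length_NP_mm Prescribed step lengths (mm).
#' @param stance_fraction Named vector `c(P=, NP=)`, fraction of the stride.
#' @param double_support_fraction_P Paretic double-support fraction; the
#'   non-paretic value follows from periodicity and is validated.
#' @param ankle_amp_deg,knee_peak_deg,shank_amp_deg Kinematic waveform
#'   amplitudes (degrees).
#' @param grf_vertical_peak_bw,grf_braking_peak_bw,grf_propulsive_peak_bw
#'   Named `c(P=, NP=)` force amplitudes in body weights.
#' @param marker_noise_mm Gaussian marker noise standard deviation (mm).
#' @param mass_kg,paretic_side,fm_score Walker anthropometry and impairment.
#' @param marker_rate_hz,force_rate_hz Sampling rates.
#' @param seed Integer seed.
#' @return A `signal_sim_config` list.
#' @export
signal_sim_config <- function(n_strides = 60,
                              stride_period_s = 1.2,
                              step_length_P_mm = 520,
                              step_length_NP_mm = 440,
                              stance_fraction = c(P = 0.62, NP = 0.62),
                              double_support_fraction_P = 0.12,
                              ankle_amp_deg = 15,
                              knee_peak_deg = 60,
                              shank_amp_deg = 20,
                              grf_vertical_peak_bw = c(P = 1.1, NP = 1.1),
                              grf_braking_peak_bw = c(P = 0.15, NP = 0.15),
                              grf_propulsive_peak_bw = c(P = 0.15, NP = 0.15),
                              marker_noise_mm = 0.5,
                              mass_kg = 80,
                              paretic_side = "left",
                              fm_score = 20L,
                              marker_rate_hz = 100,
                              force_rate_hz = 1000,
                              seed = 1L) {
  cfg <- as.list(environment())
  st <- cfg$stance_fraction
  dsP <- cfg$double_support_fraction_P
  if (any(st <= 0 | st >= 1) || dsP <= 0)
    stop_stridesla("config_error", "fractions must lie in (0, 1)")
  if (dsP >= st["P"])
    stop_stridesla("config_error", "double support fraction must be below the stance fraction")
  ds_np <- (st[["P"]] - dsP) + st[["NP"]] - 1
  if (ds_np <= 0 || ds_np >= st[["NP"]])
    stop_stridesla("config_error",
                   "timing inconsistent: implied non-paretic double support outside (0, stance)")
  structure(cfg, class = "signal_sim_config")
}

# phase-warped cosine: a monotone C1 phase through (knot_t, k*pi) makes the
# track C2 with extrema exactly at the knots and locally symmetric curvature,
# so zero-phase low-pass filtering does not displace the extrema
phase_track <- function(knot_t) {
  theta <- stats::splinefun(knot_t, (seq_along(knot_t) - 1) * pi, method = "monoH.FC")
  function(t) cos(theta(t))
}

#' Simulate marker and force signals for hemiparetic treadmill gait
#'
#' Builds malleolus fore-aft trajectories as phase-shifted periodic waves
#' whose anterior/posterior extrema occur exactly at the prescribed initial
#' contacts and foot-offs and whose excursions and per-side offsets are
#' solved so the prescribed step lengths hold exactly at each initial
#' contact. The remaining leg markers follow a planar chain with prescribed
#' sinusoidal ankle/knee waveforms; vertical GRF is a double-bump profile and
#' the fore-aft GRF a braking-then-propulsion wave, both active only during
#' prescribed stance and scaled to prescribed peaks. All promised quantities
#' are recorded in `$truth`.
#'
#' @param cfg A [signal_sim_config()].
#' @return A `gait_simulation` list: `markers` ([marker_trial()]), `forces`
#'   ([force_trial()]), `meta` ([trial_metadata()] row), `truth`, `cfg`.
#' @export
simulate_gait_signals <- function(cfg = signal_sim_config()) {
  rate <- cfg$marker_rate_hz
  Tf <- round(cfg$stride_period_s * rate)      # stride period in frames
  Tp <- Tf / rate
  st <- cfg$stance_fraction
  sides <- c("P", "NP")
  # paretic ICs on exact frames; non-paretic offset snapped to a frame
  off_frames <- round((st[["P"]] - cfg$double_support_fraction_P) * Tf)
  off <- off_frames / rate
  # knot sequences extend one stride beyond the record at both ends so the
  # reported ground-truth events sit well inside the phase spline's support
  n_all <- cfg$n_strides + 5L
  ic_all <- list(P = (seq_len(n_all) - 2L) * Tp,
                 NP = (seq_len(n_all) - 2L) * Tp + off)
  keep_ic <- 3:(cfg$n_strides + 3L)
  ic_t <- lapply(ic_all, function(x) x[keep_ic])
  total_t <- (cfg$n_strides + 3L) * Tp
  t_m <- seq(0, total_t, by = 1 / rate)
  t_f <- seq(0, total_t, by = 1 / cfg$force_rate_hz)

  # unit-excursion fore-aft phase tracks (IC = +1, FO = -1 exactly at knots)
  fo_all <- list(); track <- list()
  for (s in sides) {
    fo_all[[s]] <- ic_all[[s]] + st[[s]] * Tp
    knot_t <- as.vector(rbind(ic_all[[s]], fo_all[[s]]))
    track[[s]] <- phase_track(knot_t)
  }
  fo_t <- lapply(fo_all, function(x) x[keep_ic])

  # solve shared excursion E and per-side fore-aft offset for the prescribed
  # step lengths, using the contralateral track value at an interior IC
  c_np <- track$NP(ic_t$P[3])   # NP track when the paretic limb strikes
  c_p <- track$P(ic_t$NP[3])    # P track at a non-paretic strike
  slP <- cfg$step_length_P_mm / 1000
  slNP <- cfg$step_length_NP_mm / 1000
  E <- (slP + slNP) / (2 - c_p - c_np)
  delta <- slP - E * (1 - c_np)
  offset <- c(P = delta / 2, NP = -delta / 2)
  ap <- lapply(stats::setNames(sides, sides),
               function(s) offset[[s]] + E * track[[s]](t_m))

  # stride phase relative to the side's own IC sequence
  phase <- function(s) ((t_m - ic_all[[s]][1]) / Tp) %% 1
  swing_bump <- function(s) {
    ph <- phase(s)
    sw <- ph > st[[s]]
    z <- numeric(length(ph))
    z[sw] <- (1 - cos(2 * pi * (ph[sw] - st[[s]]) / (1 - st[[s]]))) / 2
    z
  }
  # kinematic waveforms (degrees); extrema exactly +/- amplitude each stride
  ankle_w <- function(s) cfg$ankle_amp_deg * sin(2 * pi * phase(s))
  knee_w <- function(s) {
    ph_pk <- st[[s]] + (1 - st[[s]]) / 2   # peak mid-swing
    q <- (phase(s) - ph_pk + 0.5) %% 1
    cfg$knee_peak_deg * (1 - cos(2 * pi * q)) / 2
  }
  shank_w <- function(s) cfg$shank_amp_deg * cos(2 * pi * phase(s))

  L_foot <- 0.15; L_shank <- 0.40; L_thigh <- 0.40; L_pelvis <- 0.15
  mal_z <- 0.08 + 0.05 * vapply(sides, swing_bump, numeric(length(t_m)))
  colnames(mal_z) <- sides

  p_side <- if (cfg$paretic_side == "left") "L" else "R"
  lab_of <- c(P = p_side, NP = setdiff(c("L", "R"), p_side))
  y_of <- c(L = 0.10, R = -0.10)

  marker_names <- required_markers()
  pos <- array(0, dim = c(length(t_m), length(marker_names), 3L),
               dimnames = list(NULL, marker_names, c("x", "y", "z")))
  deg <- pi / 180
  for (s in sides) {
    lab <- lab_of[[s]]
    th_sh <- (90 - shank_w(s)) * deg
    th_th <- th_sh + knee_w(s) * deg
    th_ft <- th_sh + (ankle_w(s) + 90) * deg
    mal <- cbind(ap[[s]], mal_z[, s])
    con <- mal + L_shank * cbind(cos(th_sh), sin(th_sh))
    tro <- con + L_thigh * cbind(cos(th_th), sin(th_th))
    ili <- tro + matrix(c(0, L_pelvis), nrow(tro), 2, byrow = TRUE)
    mtp <- mal - L_foot * cbind(cos(th_ft), sin(th_ft))
    put <- function(name, xz) {
      pos[, paste0(lab, "_", name), "x"] <<- xz[, 1]
      pos[, paste0(lab, "_", name), "y"] <<- y_of[[lab]]
      pos[, paste0(lab, "_", name), "z"] <<- xz[, 2]
    }
    put("malleolus", mal); put("tibial_condyle", con)
    put("trochanter", tro); put("iliac_crest", ili); put("MTP5", mtp)
  }
  if (cfg$marker_noise_mm > 0)
    pos <- with_seed(cfg$seed,
                     pos + stats::rnorm(length(pos), sd = cfg$marker_noise_mm / 1000))
  markers <- marker_trial(t_m, pos, marker_names, rate)

  # forces
  g <- GRAVITY
  m <- cfg$mass_kg
  vert_shape <- function(u) sin(pi * u) + 0.4 * sin(3 * pi * u)
  w_max <- max(vert_shape(seq(0, 1, length.out = 4096)))
  grf <- array(0, dim = c(length(t_f), 2L, 3L))
  cop <- array(NA_real_, dim = c(length(t_f), 2L, 2L))
  for (s in sides) {
    sn <- match(lab_of[[s]], c("L", "R"))
    T_st <- st[[s]] * Tp
    for (k in seq_len(n_all)) {
      inw <- which(t_f >= ic_all[[s]][k] & t_f <= ic_all[[s]][k] + T_st)
      if (!length(inw)) next
      u <- (t_f[inw] - ic_all[[s]][k]) / T_st
      grf[inw, sn, 3] <- m * g * cfg$grf_vertical_peak_bw[[s]] * vert_shape(u) / w_max
      fx <- ifelse(u < 0.5,
                   -cfg$grf_braking_peak_bw[[s]] * m * g * sin(2 * pi * u),
                   cfg$grf_propulsive_peak_bw[[s]] * m * g * sin(2 * pi * (u - 0.5)))
      grf[inw, sn, 1] <- fx
      ap_ic <- E + offset[[s]]
      cop[inw, sn, 1] <- ap_ic - 0.05 + 0.15 * u
      cop[inw, sn, 2] <- y_of[[lab_of[[s]]]]
    }
  }
  grf[, , 3] <- pmax(grf[, , 3], 0)
  forces <- force_trial(t_f, grf, cop, cfg$force_rate_hz)

  meta <- trial_metadata(data.frame(
    subject_id = "SIM01", mass_kg = m, paretic_side = cfg$paretic_side,
    treadmill_speed_mps = (slP + slNP) / Tp,
    walk_speed_mps = (slP + slNP) / Tp, fm_score = cfg$fm_score
  ))

  ds_np <- (st[["P"]] - cfg$double_support_fraction_P) + st[["NP"]] - 1
  # hip waveform truth on a dense grid (one stride)
  hip_truth <- function(s) {
    phd <- seq(0, 1, length.out = 8192)
    ph_pk <- st[[s]] + (1 - st[[s]]) / 2
    kn <- cfg$knee_peak_deg * (1 - cos(2 * pi * ((phd - ph_pk + 0.5) %% 1))) / 2
    sh <- cfg$shank_amp_deg * cos(2 * pi * phd)
    h <- kn - sh
    c(max = max(h), min = min(h))
  }
  truth <- list(
    ic_t = ic_t, fo_t = fo_t,
    ic_idx = lapply(ic_t, function(tt) round(tt * rate) + 1L),
    fo_idx = lapply(fo_t, function(tt) round(tt * rate) + 1L),
    step_length_mm = c(P = cfg$step_length_P_mm, NP = cfg$step_length_NP_mm),
    sla_mm = cfg$step_length_NP_mm - cfg$step_length_P_mm,
    stance_s = c(P = st[["P"]], NP = st[["NP"]]) * Tp,
    swing_s = c(P = 1 - st[["P"]], NP = 1 - st[["NP"]]) * Tp,
    double_support_s = c(P = st[["P"]] * Tp - off,       # NP IC -> P FO
                         NP = off + st[["NP"]] * Tp - Tp), # P IC -> NP FO

    peak_ankle_dorsiflexion = cfg$ankle_amp_deg,
    peak_ankle_plantarflexion = -cfg$ankle_amp_deg,
    peak_knee_flexion = cfg$knee_peak_deg,
    peak_knee_extension = 0,
    hip_peaks = lapply(stats::setNames(sides, sides), hip_truth),
    braking_impulse = vapply(sides, function(s)
      cfg$grf_braking_peak_bw[[s]] * g * st[[s]] * Tp / pi, 0),
    propulsive_impulse = vapply(sides, function(s)
      cfg$grf_propulsive_peak_bw[[s]] * g * st[[s]] * Tp / pi, 0),
    peak_braking = vapply(sides, function(s) cfg$grf_braking_peak_bw[[s]] * g, 0),
    peak_propulsive = vapply(sides, function(s) cfg$grf_propulsive_peak_bw[[s]] * g, 0),
    peak_vertical = vapply(sides, function(s) cfg$grf_vertical_peak_bw[[s]] * g, 0),
    excursion_m = E, fore_aft_offset_m = offset, stride_period_s = Tp
  )
  structure(list(markers = markers, forces = forces, meta = meta,
                 truth = truth, cfg = cfg),
            class = "gait_simulation")
}

#' Configuration for the feature-level simulator
#'
#' Generates stride-level feature matrices with a known sparse linear model:
#' `|SLA|_ij = b0 + sum_k beta_k x_ijk + b_i + e_ij`, `b_i ~ N(0, tau^2)`,
#' `e ~ N(0, sigma^2)`, floored at 0 mm. Predictors are standard Gaussian
#' with block-exchangeable correlation `rho` within the paretic and
#' non-paretic 20-column blocks (gait variables are correlated in real
#' data). Optional subject-level predictor means with their own effect on
#' the intercept allow between-subjects and within-subjects relationships to
#' be set independently (Simpson's-paradox constructions).
#'
#' @param n_subjects Number of participants.
#' @param strides_per_subject Strides per participant (study convention: 50).
#' @param true_support Names (or indices) of predictors with nonzero effects.
#' @param beta_true Effects, mm per predictor SD.
#' @param intercept_mm Fixed intercept (mm).
#' @param tau_mm Between-subject intercept SD (mm).
#' @param sigma_mm Residual SD (mm).
#' @param rho Within-block exchangeable correlation.
#' @param group `"longer"` (signed SLA negative) or `"shorter"` (positive).
#' @param subject_effect_sd SD of subject-level predictor means (0 disables).
#' @param gamma_between Named vector: effect of a subject-level predictor
#'   mean on that subject's intercept (mm per unit), for sign-reversal
#'   constructions.
#' @param seed Integer seed.
#' @return A `feature_sim_config` list.
#' @export
feature_sim_config <- function(n_subjects = 12,
                               strides_per_subject = 50,
                               true_support = c("double_support_time_P",
                                                "braking_impulse_P",
                                                "peak_ankle_plantarflexion_moment_P"),
                               beta_true = c(-32, 22, -17),
                               intercept_mm = 140,
                               tau_mm = 30,
                               sigma_mm = 20,
                               rho = 0.4,
                               group = c("longer", "shorter"),
                               subject_effect_sd = 0,
                               gamma_between = NULL,
                               seed = 1L) {
  group <- match.arg(group)
  cfg <- c(as.list(environment()))
  if (tau_mm < 0 || sigma_mm < 0)
    stop_stridesla("config_error", "variance parameters must be nonnegative")
  if (rho < 0 || rho >= 1)
    stop_stridesla("config_error", "rho must be in [0, 1)")
  if (is.numeric(cfg$true_support))
    cfg$true_support <- feature_column_names()[cfg$true_support]
  if (!all(cfg$true_support %in% feature_column_names()))
    stop_stridesla("config_error", "unknown predictor in true_support")
  if (length(cfg$beta_true) != length(cfg$true_support))
    stop_stridesla("config_error", "beta_true and true_support lengths differ")
  structure(cfg, class = "feature_sim_config")
}

# block-exchangeable covariance of the 40 predictors implied by a config
feature_sim_sigma <- function(cfg) {
  p <- 40L
  S <- matrix(0, p, p)
  block <- rep(1:2, each = 20L)
  for (b in 1:2) S[block == b, block == b] <- cfg$rho
  diag(S) <- 1
  dimnames(S) <- list(feature_column_names(), feature_column_names())
  S
}

#' Simulate a stride-level feature table with known ground truth
#'
#' @param cfg A [feature_sim_config()].
#' @return A `feature_simulation` list: `table` (stride feature table with
#'   `SLA_mm` and `abs_SLA_mm`), and `truth` (`beta` over all 40 predictors,
#'   `support`, per-subject intercepts, variance components, generative
#'   marginal/conditional R-squared, flooring count).
#' @export
simulate_feature_data <- function(cfg = feature_sim_config()) {
  p <- 40L
  preds <- feature_column_names()
  n <- cfg$n_subjects * cfg$strides_per_subject
  subj <- rep(sprintf("S%02d", seq_len(cfg$n_subjects)), each = cfg$strides_per_subject)
  beta <- stats::setNames(numeric(p), preds)
  beta[cfg$true_support] <- cfg$beta_true

  out <- with_seed(cfg$seed, {
    f_blk <- matrix(stats::rnorm(n * 2L), n, 2L)      # shared block factors
    e <- matrix(stats::rnorm(n * p), n, p)
    block <- rep(1:2, each = 20L)
    X <- sqrt(cfg$rho) * f_blk[, block] + sqrt(1 - cfg$rho) * e
    colnames(X) <- preds
    mu_subj <- matrix(0, cfg$n_subjects, p, dimnames = list(NULL, preds))
    if (cfg$subject_effect_sd > 0 && length(cfg$gamma_between)) {
      cols <- names(cfg$gamma_between)
      mu_subj[, cols] <- stats::rnorm(cfg$n_subjects * length(cols),
                                      sd = cfg$subject_effect_sd)
      X <- X + mu_subj[rep(seq_len(cfg$n_subjects), each = cfg$strides_per_subject), ]
    }
    b <- stats::rnorm(cfg$n_subjects, sd = cfg$tau_mm)
    if (length(cfg$gamma_between))
      b <- b + as.numeric(mu_subj[, names(cfg$gamma_between), drop = FALSE] %*%
                            cfg$gamma_between)
    eps <- stats::rnorm(n, sd = cfg$sigma_mm)
    y <- cfg$intercept_mm + as.numeric(X %*% beta) +
      b[rep(seq_len(cfg$n_subjects), each = cfg$strides_per_subject)] + eps
    list(X = X, y = y, b = b, mu_subj = mu_subj)
  })
  n_floored <- sum(out$y < 0)
  abs_sla <- pmax(out$y, 0)
  sla <- if (cfg$group == "longer") -abs_sla else abs_sla

  tbl <- data.frame(subject_id = subj,
                    stride_idx = rep(seq_len(cfg$strides_per_subject), cfg$n_subjects),
                    SLA_mm = sla, abs_SLA_mm = abs_sla,
                    group = paste0(cfg$group, "_paretic"),
                    out$X, check.names = FALSE)
  var_fixed <- as.numeric(beta %*% feature_sim_sigma(cfg) %*% beta)
  truth <- list(beta = beta, support = cfg$true_support,
                intercept_mm = cfg$intercept_mm,
                subject_intercepts = out$b, tau_mm = cfg$tau_mm,
                sigma_mm = cfg$sigma_mm, var_fixed = var_fixed,
                r2_design = r2_from_variances(var_fixed, cfg$tau_mm^2, cfg$sigma_mm^2),
                n_floored = n_floored, subject_means = out$mu_subj)
  structure(list(table = tbl, truth = truth, cfg = cfg),
            class = "feature_simulation")
}

#' Scenario configurations mirroring published hemiparetic findings
#'
#' Returns [feature_sim_config()]s whose true supports, coefficient signs and
#' magnitudes mirror reported stride-level predictors of |SLA| in chronic
#' stroke: for the longer-paretic-steps group, five predictors (paretic
#' double-support time -, paretic braking impulse +, paretic peak vertical
#' GRF -, non-paretic peak dorsiflexion moment -, paretic peak plantarflexion
#' moment -); for the shorter-paretic group, paretic braking impulse -,
#' non-paretic braking impulse +, and a weak non-paretic propulsive impulse
#' term. The intercept variance `tau` and residual `sigma` are solved so the
#' generative marginal/conditional R-squared equal the design targets
#' (0.59/0.84 for longer, 0.19/0.77 for shorter).
#'
#' @param group `"longer"` or `"shorter"`.
#' @param seed Integer seed.
#' @return A `feature_sim_config`.
#' @export
stroke_gait_scenario <- function(group = c("longer", "shorter"), seed = 1L) {
  group <- match.arg(group)
  if (group == "longer") {
    support <- c("double_support_time_P", "braking_impulse_P", "peak_vertical_grf_P",
                 "peak_ankle_dorsiflexion_moment_NP", "peak_ankle_plantarflexion_moment_P")
    beta <- c(-32.268, 22.072, -8.277, -3.989, -17.182)
    intercept <- 97.218
    r2m <- 0.59; r2c <- 0.84
    n_subjects <- 11
  } else {
    support <- c("braking_impulse_P", "braking_impulse_NP", "propulsive_impulse_NP")
    beta <- c(-8.429, 6.395, -1.338)
    intercept <- 69.469
    r2m <- 0.19; r2c <- 0.77
    n_subjects <- 8
  }
  base <- feature_sim_config(true_support = support, beta_true = beta, seed = seed)
  S <- feature_sim_sigma(base)
  bfull <- stats::setNames(numeric(40), feature_column_names())
  bfull[support] <- beta
  var_fixed <- as.numeric(bfull %*% S %*% bfull)
  tau <- sqrt(var_fixed * (r2c - r2m) / r2m)
  sigma <- sqrt(var_fixed * (1 - r2c) / r2m)
  feature_sim_config(n_subjects = n_subjects, strides_per_subject = 50,
                     true_support = support, beta_true = beta,
                     intercept_mm = intercept, tau_mm = tau, sigma_mm = sigma,
                     rho = 0.4, group = group, seed = seed)
}

#' Sign-reversal (Simpson's paradox) scenario
#'
#' One predictor (paretic braking impulse) whose within-subject effect on
#' |SLA| is negative while subjects with larger average braking have larger
#' average |SLA|, so the between-subjects slope is positive - the
#' constellation in which between-subjects conclusions do not transfer to
#' stride-by-stride variation.
#'
#' @param seed Integer seed.
#' @return A `feature_sim_config`.
#' @export
simpson_scenario <- function(seed = 1L) {
  feature_sim_config(
    n_subjects = 11, strides_per_subject = 50,
    true_support = "braking_impulse_P", beta_true = -9,
    intercept_mm = 70, tau_mm = 5, sigma_mm = 15, rho = 0.4,
    group = "shorter", subject_effect_sd = 1.2,
    gamma_between = c(braking_impulse_P = 41), seed = seed
  )
}
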