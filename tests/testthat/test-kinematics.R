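# Filtering, event detection, step lengths, temporal variables, joint angles.

test_that("zero-phase filter has unit DC gain, passband fidelity and stopband attenuation", {
  expect_equal(lowpass_filter(rep(3.7, 400), 100, 10), rep(3.7, 400))

  t <- (0:2999) / 100
  # fit amplitude/phase on the central section to avoid edge effects
  fit_sine <- function(y, f) {
    i <- 500:2500
    co <- unname(coef(lm(y[i] ~ sin(2 * pi * f * t[i]) + cos(2 * pi * f * t[i]))))
    c(amp = sqrt(co[2]^2 + co[3]^2), phase = atan2(co[3], co[2]))
  }
  y1 <- lowpass_filter(sin(2 * pi * 1 * t), 100, 10)
  p <- fit_sine(y1, 1)
  expect_lt(abs(p["amp"] - 1), 0.01)
  expect_lt(abs(p["phase"]), 1e-6)

  y40 <- lowpass_filter(sin(2 * pi * 40 * t), 100, 10)
  expect_lt(fit_sine(y40, 40)["amp"], 0.01)
  # attenuation consistent with the designed squared magnitude response
  gain_design <- 1 / (1 + (40 / 10)^4)   # order-2 Butterworth applied twice
  expect_equal(unname(fit_sine(y40, 40)["amp"]), gain_design, tolerance = 0.25)

  expect_error_class(lowpass_filter(rnorm(100), 100, 60), "parameter_error")
})

test_that("events sit at the fore-aft extrema of a sinusoidal malleolus track", {
  t <- seq(0, 10, by = 0.01)
  x <- 0.2 * sin(2 * pi * t / 1.2)
  ev <- detect_events(x, 100)
  ic_true <- round((0.3 + 1.2 * (0:8)) * 100) + 1
  fo_true <- round((0.9 + 1.2 * (0:7)) * 100) + 1
  expect_equal(length(ev$ic), 9L)
  expect_true(all(abs(ev$ic - ic_true) <= 1))
  expect_true(all(abs(ev$fo - fo_true[seq_along(ev$fo)]) <= 1))

  # strict alternation
  merged <- sort(c(ev$ic, ev$fo))
  types <- ifelse(merged %in% ev$ic, "ic", "fo")
  expect_true(all(types[seq(1, length(types), by = 2)] == "ic"))

  noisy <- x + withr::with_seed(4, rnorm(length(x), sd = 0.002))
  evn <- detect_events(lowpass_filter(noisy, 100, 10), 100)
  expect_equal(length(evn$ic), length(ev$ic))
  expect_true(all(abs(evn$ic - ev$ic) <= 2))

  expect_error_class(detect_events(seq(0, 1, by = 0.01), 100), "too_few_strides_error")
})

test_that("step length is the fore-aft malleolus separation at initial contact", {
  # left malleolus 0.30 m anterior, right -0.25 m at the left IC
  nm <- stridesla:::required_markers()
  n <- 7
  pos <- array(0, dim = c(n, length(nm), 3), dimnames = list(NULL, nm, c("x", "y", "z")))
  pos[, "L_malleolus", "x"] <- 0.30
  pos[, "R_malleolus", "x"] <- -0.25
  mk <- marker_trial((0:(n - 1)) / 100, pos, nm, 100)
  ev <- gait_events(
    structure(list(ic = c(2L, 6L), fo = 4L, rate_hz = 100), class = "gait_side_events"),
    structure(list(ic = c(3L, 7L), fo = 5L, rate_hz = 100), class = "gait_side_events")
  )
  sl <- step_lengths(mk, ev, toy_meta(paretic_side = "left"))
  expect_equal(sl$step_length_mm[sl$side == "P"], c(550, 550))    # left = paretic
  expect_equal(sl$step_length_mm[sl$side == "NP"], c(-550, -550))

  expect_error_class(
    step_lengths(mk, gait_events(
      structure(list(ic = c(2L, 60L), fo = 4L, rate_hz = 100), class = "gait_side_events"),
      structure(list(ic = c(3L, 7L), fo = 5L, rate_hz = 100), class = "gait_side_events")
    ), toy_meta()), "index_error")
})

test_that("temporal variables follow their event definitions", {
  ev <- gait_events(
    structure(list(ic = c(1L, 121L, 241L), fo = c(73L, 193L), rate_hz = 100),
              class = "gait_side_events"),
    structure(list(ic = c(61L, 181L), fo = 133L, rate_hz = 100),
              class = "gait_side_events")
  )
  tv <- temporal_params(ev)
  left1 <- tv[tv$side == "L" & tv$stride == 1, ]
  expect_equal(left1$stance_s, 0.72)
  expect_equal(left1$swing_s, 0.48)
  expect_equal(left1$double_support_s, 0.12)   # right IC 0.60 -> left FO 0.72
  expect_equal(tv$stance_s + tv$swing_s,
               rep(1.2, nrow(tv)), tolerance = 1e-12)
  expect_true(all(tv$double_support_s < tv$stance_s))
})

test_that("perfectly symmetric gait gives identical paretic and non-paretic outputs", {
  cfg <- signal_sim_config(n_strides = 6, step_length_P_mm = 480, step_length_NP_mm = 480,
                           marker_noise_mm = 0)
  sim <- simulate_gait_signals(cfg)
  ev <- gait_events(
    detect_events(sim$markers$positions[, "L_malleolus", "x"], 100),
    detect_events(sim$markers$positions[, "R_malleolus", "x"], 100)
  )
  sl <- step_lengths(sim$markers, ev, sim$meta)
  expect_lt(max(abs(sl$step_length_mm[sl$side == "P"] -
                      sl$step_length_mm[sl$side == "NP"][1])), 0.5)
  tv <- temporal_params(ev)
  expect_equal(mean(tv$stance_s[tv$side == "L"]), mean(tv$stance_s[tv$side == "R"]),
               tolerance = 1e-6)
})

test_that("relabelling left/right swaps paretic and non-paretic outputs exactly", {
  sim <- simulate_gait_signals(signal_sim_config(n_strides = 6, marker_noise_mm = 0))
  mirror <- sim$markers
  nm <- sim$markers$marker_names
  swapped <- ifelse(startsWith(nm, "L_"), sub("^L_", "R_", nm), sub("^R_", "L_", nm))
  mirror$positions <- mirror$positions[, match(nm, swapped), ]
  mirror$marker_names <- nm
  dimnames(mirror$positions)[[2]] <- nm

  ev <- function(mk) gait_events(
    detect_events(mk$positions[, "L_malleolus", "x"], 100),
    detect_events(mk$positions[, "R_malleolus", "x"], 100)
  )
  meta_l <- toy_meta(paretic_side = "left")
  meta_r <- toy_meta(paretic_side = "right")
  a <- step_lengths(sim$markers, ev(sim$markers), meta_l)
  b <- step_lengths(mirror, ev(mirror), meta_r)
  expect_equal(a$step_length_mm[a$side == "P"], b$step_length_mm[b$side == "P"])
  expect_equal(a$step_length_mm[a$side == "NP"], b$step_length_mm[b$side == "NP"])
})

test_that("joint angles honour segment conventions and neutral offsets", {
  # shank vertical, foot horizontal anterior -> ankle 0; collinear leg -> knee 0;
  # thigh 30 deg anterior of a vertical pelvis -> hip 30
  geom_neutral <- list(MTP5 = c(0.15, 0.05), malleolus = c(0, 0.05),
                       tibial_condyle = c(0, 0.45),
                       trochanter = c(0, 0.85), iliac_crest = c(0, 1.0))
  a <- joint_angles(static_trial(geom_neutral, n = 5))
  expect_equal(a$L$ankle[1], 0, tolerance = 1e-10)
  expect_equal(a$L$knee[1], 0, tolerance = 1e-10)
  expect_equal(a$R$hip[1], 0, tolerance = 1e-10)

  s30 <- sin(30 * pi / 180) * 0.4
  c30 <- cos(30 * pi / 180) * 0.4
  geom_flex <- list(MTP5 = c(0.15 + s30, 0.05), malleolus = c(s30, 0.05),
                    tibial_condyle = c(s30, 0.45),
                    trochanter = c(s30 - s30, 0.45 + c30),     # thigh 30 deg anterior
                    iliac_crest = c(0, 0.45 + c30 + 0.15))     # pelvis vertical
  b <- joint_angles(static_trial(geom_flex, n = 5))
  expect_equal(b$L$hip[1], 30, tolerance = 1e-10)
  expect_equal(b$L$knee[1], 30, tolerance = 1e-10)  # shank vertical under flexed thigh
  expect_equal(b$L$ankle[1], 0, tolerance = 1e-10)

  degen <- geom_neutral
  degen$MTP5 <- degen$malleolus
  expect_error_class(joint_angles(static_trial(degen, n = 5)), "degenerate_segment_error")
})

test_that("per-stride angle peaks report both direction extrema", {
  n <- 121
  ang <- structure(list(
    time = (0:(n - 1)) / 100, rate_hz = 100,
    L = list(ankle = rep(10, n), knee = 20 * sin(2 * pi * (0:(n - 1)) / 60),
             hip = rep(0, n)),
    R = list(ankle = rep(0, n), knee = rep(0, n), hip = rep(0, n))
  ), class = "joint_angle_series")
  ev <- gait_events(
    structure(list(ic = c(1L, 61L, 121L), fo = c(40L, 100L), rate_hz = 100),
              class = "gait_side_events"),
    structure(list(ic = c(31L, 91L), fo = 61L, rate_hz = 100),
              class = "gait_side_events")
  )
  pk <- peak_kinematics(ang, ev)
  l1 <- pk[pk$side == "L" & pk$stride == 1, ]
  expect_equal(l1$peak_ankle_dorsiflexion, 10)   # constant signal: both peaks equal
  expect_equal(l1$peak_ankle_plantarflexion, 10)
  expect_equal(l1$peak_knee_flexion, 20, tolerance = 1e-6)
  expect_equal(l1$peak_knee_extension, -20, tolerance = 1e-6)
})

test_that("simulator angle amplitudes are recovered through the full kinematic chain", {
  sim <- simulate_gait_signals(signal_sim_config(n_strides = 6, marker_noise_mm = 0,
                                                 knee_peak_deg = 60))
  ev <- gait_events(
    detect_events(sim$markers$positions[, "L_malleolus", "x"], 100),
    detect_events(sim$markers$positions[, "R_malleolus", "x"], 100)
  )
  ang <- joint_angles(sim$markers)
  pk <- peak_kinematics(ang, ev)
  mid <- pk[pk$stride == 3, ]
  expect_equal(mid$peak_knee_flexion, rep(60, 2), tolerance = 0.5)
  expect_equal(mid$peak_ankle_dorsiflexion, rep(sim$truth$peak_ankle_dorsiflexion, 2),
               tolerance = 0.5)
  expect_equal(mid$peak_ankle_plantarflexion, rep(sim$truth$peak_ankle_plantarflexion, 2),
               tolerance = 0.5)
  expect_equal(mid$peak_hip_flexion[1], sim$truth$hip_peaks$P[["max"]], tolerance = 0.5)
})
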