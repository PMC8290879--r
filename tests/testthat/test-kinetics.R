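# Impulses, force peaks, GRF filtering, inverse dynamics oracles.

test_that("impulses match closed-form integrals of analytic curves", {
  # half-sine braking: F(t) = -F0 sin(pi t / tau) on [0, tau]
  rate <- 1000; F0 <- 100; tau <- 0.2; mass <- 80
  t <- (0:999) / rate
  f <- ifelse(t <= tau, -F0 * sin(pi * t / tau), 0)
  imp <- impulses(f, seq_along(t), rate, mass)
  expect_equal(unname(imp["braking_impulse"]), 2 * F0 * tau / pi / mass, tolerance = 1e-4)
  expect_equal(unname(imp["propulsive_impulse"]), 0)

  # antisymmetric braking-then-propulsion: equal magnitudes
  f2 <- ifelse(t <= 0.3, -sin(2 * pi * t / 0.6) * 50, 0)
  f2[t > 0.3 & t <= 0.6] <- sin(2 * pi * (t[t > 0.3 & t <= 0.6] - 0.3) / 0.6) * 50
  imp2 <- impulses(f2, seq_along(t), rate, mass)
  expect_equal(unname(imp2["braking_impulse"]), unname(imp2["propulsive_impulse"]),
               tolerance = 1e-6)

  expect_error_class(impulses(f, 2000:2100, rate, mass), "index_error")
})

test_that("force peaks are mass-normalized extremum magnitudes", {
  n <- 100
  grf <- array(0, dim = c(n, 2, 3))
  grf[, 1, 3] <- 784.8
  grf[, 1, 1] <- -40          # pure braking
  ft <- force_trial((0:(n - 1)) / 1000, grf, array(NA_real_, dim = c(n, 2, 2)), 1000)
  pk <- grf_peaks(ft, 1:n, 80, "L")
  expect_equal(unname(pk["peak_vertical"]), 9.81)
  expect_equal(unname(pk["peak_braking"]), 0.5)
  expect_equal(unname(pk["peak_propulsive"]), 0)
  expect_error_class(grf_peaks(ft, 1:n, 80, "R"), "unloaded_stride_error")
})

test_that("GRF filtering preserves plateaus, keeps unloaded samples at zero, attenuates noise", {
  n <- 2000; rate <- 1000
  grf <- array(0, dim = c(n, 2, 3))
  loaded <- 501:1500
  grf[loaded, 1, 3] <- 700
  grf[loaded, 1, 1] <- 20 * sin(2 * pi * 300 * (loaded / rate))  # 300 Hz noise
  ft <- force_trial((0:(n - 1)) / rate, grf, array(NA_real_, dim = c(n, 2, 2)), rate)
  out <- filter_grf(ft, 100)
  expect_equal(out$grf[900:1100, 1, 3], rep(700, 201), tolerance = 1e-6)  # mid-plateau
  expect_true(all(out$grf[1:500, 1, ] == 0))                              # swing stays zero
  expect_lt(max(abs(out$grf[800:1200, 1, 1])), 20 / (1 + (300 / 100)^4) * 1.5)
})

test_that("inverse dynamics satisfies static equilibrium to 1e-6 N m/kg", {
  mass <- 80
  geom <- list(MTP5 = c(0.15, 0.08), malleolus = c(0, 0.08),
               tibial_condyle = c(0.02, 0.48), trochanter = c(-0.03, 0.88),
               iliac_crest = c(-0.03, 1.03))
  mk <- static_trial(geom)
  ft <- static_force(fz_left = mass * 9.81, cop_x = 0.05)
  meta <- toy_meta(mass_kg = mass)

  # massless limit: pure GRF levers
  anthro0 <- data.frame(segment = c("foot", "shank", "thigh"), mass_frac = 0,
                        com_frac = 0.5, gyration_frac = 0.3)
  out0 <- inverse_dynamics(mk, ft, meta, anthro0)
  expect_equal(out0$L$ankle[100], 9.81 * 0.05, tolerance = 1e-6)            # 0.4905
  expect_equal(out0$L$knee[100], -9.81 * (0.05 - 0.02), tolerance = 1e-6)
  expect_equal(out0$L$hip[100], 9.81 * (0.05 + 0.03), tolerance = 1e-6)
  # force-free side with no segment mass: exactly zero everywhere
  expect_equal(max(abs(c(out0$R$ankle, out0$R$knee, out0$R$hip))), 0)

  # full anthropometrics: independent static lever-arm oracle
  an <- winter_anthropometrics()
  out <- inverse_dynamics(mk, ft, meta, an)
  g <- 9.81
  com <- function(p, d, f) geom[[p]] + f * (geom[[d]] - geom[[p]])
  cf <- com("malleolus", "MTP5", 0.5)
  cs <- com("tibial_condyle", "malleolus", 0.433)
  ct <- com("trochanter", "tibial_condyle", 0.433)
  mf <- an$mass_frac[1] * mass; ms <- an$mass_frac[2] * mass; mt <- an$mass_frac[3] * mass
  Fz <- mass * g
  lever <- function(x_joint)
    Fz * (0.05 - x_joint) - g * (mf * (cf[1] - x_joint) + ms * (cs[1] - x_joint) +
                                   mt * (ct[1] - x_joint))
  ankle_oracle <- Fz * (0.05 - 0) - mf * g * (cf[1] - 0)
  knee_oracle <- Fz * (0.05 - 0.02) - g * (mf * (cf[1] - 0.02) + ms * (cs[1] - 0.02))
  hip_oracle <- lever(-0.03)
  expect_equal(out$L$ankle[100] * mass, ankle_oracle, tolerance = 1e-6)
  expect_equal(out$L$knee[100] * mass, -knee_oracle, tolerance = 1e-6)
  expect_equal(out$L$hip[100] * mass, hip_oracle, tolerance = 1e-6)
})

test_that("a driven pendulum reproduces the analytic moment within 1%", {
  n <- 500; rate <- 100; mass <- 80
  t <- (0:(n - 1)) / rate
  phi0 <- 20 * pi / 180; om <- 2 * pi * 0.8
  phi <- phi0 * sin(om * t)
  L_th <- 0.4; L_sh <- 0.4; L_f <- 0.15
  hip <- c(0, 1.0)
  nm <- stridesla:::required_markers()
  pos <- array(0, dim = c(n, length(nm), 3), dimnames = list(NULL, nm, c("x", "y", "z")))
  con <- cbind(hip[1] + L_th * sin(phi), hip[2] - L_th * cos(phi))
  mal <- cbind(con[, 1] + L_sh * sin(phi), con[, 2] - L_sh * cos(phi))
  mtp <- cbind(mal[, 1] + L_f * cos(phi), mal[, 2] + L_f * sin(phi))
  for (s in c("L", "R")) {
    pos[, paste0(s, "_trochanter"), c(1, 3)] <- matrix(hip, n, 2, byrow = TRUE)
    pos[, paste0(s, "_iliac_crest"), c(1, 3)] <- matrix(hip + c(0, 0.15), n, 2, byrow = TRUE)
    pos[, paste0(s, "_tibial_condyle"), c(1, 3)] <- con
    pos[, paste0(s, "_malleolus"), c(1, 3)] <- mal
    pos[, paste0(s, "_MTP5"), c(1, 3)] <- mtp
  }
  mk <- marker_trial(t, pos, nm, rate)
  ft <- force_trial(t, array(0, dim = c(n, 2, 3)), array(NA_real_, dim = c(n, 2, 2)), rate)
  an <- data.frame(segment = c("foot", "shank", "thigh"), mass_frac = c(0, 0, 0.1),
                   com_frac = c(0.5, 0.433, 0.433), gyration_frac = c(0.3, 0.3, 0.323))
  out <- inverse_dynamics(mk, ft, toy_meta(mass_kg = mass), an)

  m_th <- 0.1 * mass; d <- 0.433 * L_th
  I_p <- m_th * (0.323 * L_th)^2 + m_th * d^2
  analytic <- -(I_p * (-om^2 * phi0 * sin(om * t)) + m_th * 9.81 * d * sin(phi))
  i <- 10:(n - 10)
  expect_lt(max(abs(out$L$hip[i] * mass - analytic[i])) / max(abs(analytic)), 0.01)
  expect_equal(max(abs(out$L$knee[i])), 0)  # massless distal segments
})

test_that("mass-normalized moments are invariant to body mass at fixed normalized inputs", {
  mk <- static_trial()
  meta1 <- toy_meta(mass_kg = 70)
  meta2 <- toy_meta(mass_kg = 140)
  out1 <- inverse_dynamics(mk, static_force(fz_left = 70 * 9.81), meta1)
  out2 <- inverse_dynamics(mk, static_force(fz_left = 140 * 9.81), meta2)
  expect_equal(out1$L$ankle, out2$L$ankle, tolerance = 1e-12)
  expect_equal(out1$L$hip, out2$L$hip, tolerance = 1e-12)
})

test_that("loaded samples without a centre of pressure are rejected", {
  n <- 200
  grf <- array(0, dim = c(n, 2, 3))
  grf[, 1, 3] <- 700
  ft <- force_trial((0:(n - 1)) / 100, grf, array(NA_real_, dim = c(n, 2, 2)), 100)
  expect_error_class(inverse_dynamics(static_trial(), ft, toy_meta()), "cop_error")
})

test_that("per-stride moment peaks are direction-specific magnitudes", {
  n <- 121
  mom <- structure(list(
    time = (0:(n - 1)) / 100, rate_hz = 100,
    L = list(ankle = rep(1.2, n), knee = 0.8 * sin(2 * pi * (0:(n - 1)) / 60),
             hip = rep(0, n)),
    R = list(ankle = rep(0, n), knee = rep(0, n), hip = rep(0, n))
  ), class = "joint_moment_series")
  ev <- gait_events(
    structure(list(ic = c(1L, 61L, 121L), fo = c(40L, 100L), rate_hz = 100),
              class = "gait_side_events"),
    structure(list(ic = c(31L, 91L), fo = 61L, rate_hz = 100),
              class = "gait_side_events")
  )
  mp <- moment_peaks(mom, ev)
  l1 <- mp[mp$side == "L" & mp$stride == 1, ]
  expect_equal(l1$peak_ankle_plantarflexion_moment, 1.2)
  expect_equal(l1$peak_ankle_dorsiflexion_moment, 0)
  expect_equal(l1$peak_knee_extension_moment, 0.8, tolerance = 1e-6)
  expect_equal(l1$peak_knee_flexion_moment, 0.8, tolerance = 1e-6)
})

test_that("simulator GRF truths are recovered: impulses within 1%, peaks exact, scaling linear", {
  base <- signal_sim_config(n_strides = 6, marker_noise_mm = 0)
  sim <- simulate_gait_signals(base)
  ev <- gait_events(
    detect_events(sim$markers$positions[, "L_malleolus", "x"], 100),
    detect_events(sim$markers$positions[, "R_malleolus", "x"], 100)
  )
  ff <- filter_grf(sim$forces, 100)
  win <- function(k, side) {
    idx <- round((ev[[side]]$ic - 1) / 100 * 1000) + 1
    idx[k]:idx[k + 1]
  }
  imp <- impulses(ff$grf[, 1, 1], win(2, "L"), 1000, sim$meta$mass_kg)
  expect_equal(unname(imp["braking_impulse"]),
               unname(sim$truth$braking_impulse["P"]), tolerance = 0.01)
  pk <- grf_peaks(ff, win(2, "L"), sim$meta$mass_kg, "L")
  expect_equal(unname(pk["peak_vertical"]),
               unname(sim$truth$peak_vertical["P"]), tolerance = 1e-3)

  # doubling the braking amplitude doubles truth exactly and extraction within 1%
  cfg2 <- base
  cfg2$grf_braking_peak_bw["NP"] <- 2 * base$grf_braking_peak_bw["NP"]
  sim2 <- simulate_gait_signals(cfg2)
  expect_equal(sim2$truth$braking_impulse[["NP"]], 2 * sim$truth$braking_impulse[["NP"]])
  ff2 <- filter_grf(sim2$forces, 100)
  imp2 <- impulses(ff2$grf[, 2, 1], win(2, "R"), 1000, sim$meta$mass_kg)
  expect_equal(unname(imp2["braking_impulse"]) / unname(imp["braking_impulse"]), 2,
               tolerance = 0.01)
})
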