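# Shared fixture builders (everything generated in code; no files on disk).

toy_meta <- function(subject_id = "X", mass_kg = 80, paretic_side = "left",
                     walk_speed = 0.5, fm = 20) {
  trial_metadata(data.frame(
    subject_id = subject_id, mass_kg = mass_kg, paretic_side = paretic_side,
    treadmill_speed_mps = walk_speed, walk_speed_mps = walk_speed, fm_score = fm
  ))
}

# static posture trial: both legs identical geometry, constant in time
static_trial <- function(geom = list(MTP5 = c(0.15, 0.08), malleolus = c(0, 0.08),
                                     tibial_condyle = c(0.02, 0.48),
                                     trochanter = c(-0.03, 0.88),
                                     iliac_crest = c(-0.03, 1.03)),
                         n = 200, rate = 100) {
  nm <- stridesla:::required_markers()
  pos <- array(0, dim = c(n, length(nm), 3), dimnames = list(NULL, nm, c("x", "y", "z")))
  for (s in c("L", "R")) for (m in names(geom)) {
    pos[, paste0(s, "_", m), "x"] <- geom[[m]][1]
    pos[, paste0(s, "_", m), "z"] <- geom[[m]][2]
    pos[, paste0(s, "_", m), "y"] <- if (s == "L") 0.1 else -0.1
  }
  marker_trial((0:(n - 1)) / rate, pos, nm, rate)
}

static_force <- function(n = 200, rate = 100, fz_left = 80 * 9.81, cop_x = 0.05) {
  grf <- array(0, dim = c(n, 2, 3))
  cop <- array(NA_real_, dim = c(n, 2, 2))
  grf[, 1, 3] <- fz_left
  cop[, 1, 1] <- cop_x
  cop[, 1, 2] <- 0.1
  force_trial((0:(n - 1)) / rate, grf, cop, rate)
}

# small stride feature table with arbitrary predictor values
toy_feature_table <- function(n_subjects = 2, strides = 3, seed = 1) {
  withr::with_seed(seed, {
    n <- n_subjects * strides
    tbl <- data.frame(
      subject_id = rep(sprintf("S%02d", seq_len(n_subjects)), each = strides),
      stride_idx = rep(seq_len(strides), n_subjects),
      SLA_mm = rnorm(n, -80, 10)
    )
    for (v in feature_column_names()) tbl[[v]] <- rnorm(n)
    tbl
  })
}

# marker file content written to a temp path (for reader tests)
write_marker_file <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

expect_error_class <- function(expr, class) {
  expect_error(expr, class = class)
}
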