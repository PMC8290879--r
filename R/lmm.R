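# Validation of selected predictor sets with random-intercept linear mixed
# models, variance-explained summaries, and participant-level bootstrap for
# the between-subjects sparse PLS coefficients.

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

#' Random-intercept linear mixed model for selected predictors
#'
#' Fits `y = b0 + X b + u_subject + e` by REML with a random intercept per
#' participant. When every latent component of the selected sparse PLS model
#' carries a single distinct predictor, this model reproduces the sparse PLS
#' regression coefficients, which is what makes it a useful validation: it
#' adds Wald confidence intervals, p-values, variance components and
#' variance-explained summaries the PLS fit does not provide.
#'
#' @param X_sel Matrix `[N x q]` of selected (z-scored) predictors.
#' @param y Response (mm).
#' @param subject_index Participant per row.
#' @param ci_level Confidence level for Wald intervals.
#' @return An `lmm_fit` list: `fixed_effects` (term, estimate, ci, p),
#'   `random_intercepts` (BLUP and conditional-sd interval per participant),
#'   `sigma2`, `tau2`, `var_fixed`, `r2_marginal`, `r2_conditional`, and the
#'   underlying `lme4` fit.
#' @export
fit_random_intercept_lmm <- function(X_sel, y, subject_index, ci_level = 0.95) {
  X_sel <- as.matrix(X_sel)
  if (ncol(X_sel) < 1) stop_stridesla("parameter_error", "need at least one predictor")
  if (length(unique(subject_index)) < 2)
    stop_stridesla("parameter_error", "need at least two participants")
  if (is.null(colnames(X_sel)))
    colnames(X_sel) <- paste0("x", seq_len(ncol(X_sel)))
  dat <- data.frame(.y = y, .subj = factor(subject_index), X_sel, check.names = FALSE)
  fml <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", colnames(X_sel)), collapse = " + "),
                                 "+ (1 | .subj)"))
  fit <- tryCatch(
    lme4::lmer(fml, data = dat, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) stop_stridesla("convergence_error",
                                       paste("mixed model failed:", conditionMessage(e)))
  )
  conv <- fit@optinfo$conv$opt
  if (!is.null(conv) && conv != 0)
    stop_stridesla("convergence_error", "mixed-model optimizer did not converge",
                   trace = fit@optinfo)

  z <- stats::qnorm((1 + ci_level) / 2)
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  fixed <- data.frame(
    term = c("(Intercept)", colnames(X_sel)),
    estimate = as.numeric(est), se = as.numeric(se),
    ci_low = as.numeric(est - z * se), ci_high = as.numeric(est + z * se),
    p = 2 * stats::pnorm(-abs(as.numeric(est) / as.numeric(se)))
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau2 <- vc$vcov[vc$grp == ".subj"]
  sigma2 <- stats::sigma(fit)^2
  re <- lme4::ranef(fit, condVar = TRUE)$.subj
  csd <- sqrt(as.numeric(attr(re, "postVar")))
  rand <- data.frame(subject_id = rownames(re), intercept_mm = re[[1]],
                     ci_low = re[[1]] - z * csd, ci_high = re[[1]] + z * csd)
  var_fixed <- stats::var(as.numeric(X_sel %*% est[-1]))
  r2 <- r2_from_variances(var_fixed, tau2, sigma2)
  structure(list(fixed_effects = fixed, random_intercepts = rand,
                 sigma2 = sigma2, tau2 = tau2, var_fixed = var_fixed,
                 r2_marginal = r2[["r2_marginal"]],
                 r2_conditional = r2[["r2_conditional"]],
                 ci_level = ci_level, fit = fit),
            class = "lmm_fit")
}

#' Marginal and conditional R-squared
#'
#' Variance-component formulation: the marginal R-squared is the variance of
#' the fixed-effect linear predictor over the total
#' (fixed + intercept + residual) variance; the conditional R-squared adds
#' the random-intercept variance to the numerator, so it can never be
#' smaller.
#'
#' @param var_fixed Variance of the fixed-effect linear predictor.
#' @param tau2 Random-intercept variance.
#' @param sigma2 Residual variance.
#' @return Named vector `c(r2_marginal, r2_conditional)`.
#' @export
r2_from_variances <- function(var_fixed, tau2, sigma2) {
  tot <- var_fixed + tau2 + sigma2
  c(r2_marginal = var_fixed / tot, r2_conditional = (var_fixed + tau2) / tot)
}

#' @rdname r2_from_variances
#' @param fit An `lmm_fit`.
#' @export
r2_marginal_conditional <- function(fit) {
  r2_from_variances(fit$var_fixed, fit$tau2, fit$sigma2)
}

#' Regress participant random intercepts on speed and impairment
#'
#' Ordinary least squares of the per-participant random intercepts on
#' walking speed and the Fugl-Meyer score, with the overall F test: a
#' non-significant F indicates that between-participant differences in
#' asymmetry magnitude are not explained by speed or impairment.
#'
#' @param intercepts Per-participant random intercepts (mm).
#' @param speed Walking speed (m/s).
#' @param fm Fugl-Meyer lower-extremity score.
#' @return List with `F_stat`, `p`, `coefficients`, and the `lm` fit.
#' @export
regress_intercepts <- function(intercepts, speed, fm) {
  P <- length(intercepts)
  if (P < 4)
    stop_stridesla("parameter_error",
                   "need at least 4 participants (residual df) for the intercept regression")
  dat <- data.frame(b = intercepts, speed = speed, fm = fm)
  fit <- stats::lm(b ~ speed + fm, data = dat)
  if (any(is.na(stats::coef(fit))))
    stop_stridesla("collinearity_error", "speed and FM are collinear")
  fs <- summary(fit)$fstatistic
  list(F_stat = unname(fs[1]),
       p = unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
       coefficients = stats::coef(fit), fit = fit)
}

# z-score predictors of an average table and fit a sparse PLS model;
# shared by run_between and the bootstrap
fit_between_spls <- function(avg, K, keepX, predictors) {
  X <- as.matrix(avg[, predictors, drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) return(NULL)  # degenerate resample
  Xs <- sweep(sweep(X, 2, colMeans(X)), 2, sds, "/")
  m <- fit_spls(Xs, avg$abs_SLA_mm, K = K, keepX = keepX)
  m$predictor_sds <- sds
  m
}

#' Participant bootstrap for between-subjects coefficients
#'
#' Resamples participants with replacement, refits the z-scoring and the
#' between-subjects sparse PLS model on each resample, and reports percentile
#' confidence intervals for the response-scale coefficients. Resamples in
#' which a predictor collapses to zero variance are skipped and counted;
#' more than 20% degenerate resamples aborts.
#'
#' @param avg_table Participant-average table from [subject_averages()].
#' @param K,keepX Model size (fixed over resamples).
#' @param B Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param ci_level Confidence level.
#' @return A `bootstrap_ci` list: `coefficients` (term, estimate, ci_low,
#'   ci_high), `B`, `n_degenerate`, `seed`.
#' @export
bootstrap_between <- function(avg_table, K, keepX, B = 1000, seed = 1L, ci_level = 0.95) {
  n <- nrow(avg_table)
  if (n < 3) stop_stridesla("parameter_error", "need at least 3 participants")
  predictors <- intersect(feature_column_names_all(), names(avg_table))
  full <- fit_between_spls(avg_table, K, keepX, predictors)
  if (is.null(full))
    stop_stridesla("zero_variance_error", "zero-variance predictor in the full sample")
  draws <- matrix(NA_real_, B, length(predictors), dimnames = list(NULL, predictors))
  n_degen <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      res <- avg_table[sample.int(n, n, replace = TRUE), , drop = FALSE]
      m <- fit_between_spls(res, K, keepX, predictors)
      # coefficients re-expressed in full-sample SD units so resamples are
      # comparable (each resample refits its own scaling)
      if (is.null(m)) n_degen <- n_degen + 1L
      else draws[b, ] <- m$beta / m$predictor_sds * full$predictor_sds
    }
  })
  if (n_degen > 0.2 * B)
    stop_stridesla("bootstrap_instability_error",
                   sprintf("%d of %d resamples degenerate", n_degen, B))
  a <- (1 - ci_level) / 2
  qs <- apply(draws[stats::complete.cases(draws), , drop = FALSE], 2,
              stats::quantile, probs = c(a, 1 - a))
  structure(list(
    coefficients = data.frame(term = predictors, estimate = full$beta,
                              ci_low = qs[1, ], ci_high = qs[2, ],
                              row.names = NULL),
    B = B, n_degenerate = n_degen, seed = seed, ci_level = ci_level
  ), class = "bootstrap_ci")
}
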