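# Exhaustive (K, keepX) grid search with leave-one-out cross-validation and
# one-standard-error sparsest-model selection.
#
# The LOOCV protocol refits everything inside each fold: predictor z-scoring,
# the within-participant split (the held-out row is centred with its
# participant's training-fold mean, so the fold never sees the held-out
# value), and the sparse PLS fit. Fits for K = 1..maxK share their component
# path, so each fold costs one path per keepX value rather than one fit per
# grid cell.

# squared LOOCV prediction errors for every (K <= maxK, keepX in keepX_values).
# Returns err[N, maxK, length(keepX_values)]. The fold loop runs in compiled
# code; loocv_sqerr_r is the plain-R equivalent kept for verification.
loocv_sqerr <- function(X, y, subject_index, maxK, keepX_values, multilevel) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (N < 3) stop_stridesla("parameter_error", "need at least 3 rows for LOOCV")
  if (multilevel) {
    subj <- as.integer(factor(subject_index, levels = unique(subject_index))) - 1L
    if (any(table(subj) < 2))
      stop_stridesla("singleton_subject_error",
                     "every participant needs at least 2 rows for stride-level LOOCV")
  } else {
    subj <- integer(N)
  }
  .loocv_sqerr_cpp(X, y, subj, as.integer(maxK), as.integer(keepX_values), multilevel)
}

loocv_sqerr_r <- function(X, y, subject_index, maxK, keepX_values, multilevel) {
  X <- as.matrix(X)
  N <- nrow(X)
  err <- array(NA_real_, dim = c(N, maxK, length(keepX_values)))
  for (i in seq_len(N)) {
    Xt <- X[-i, , drop = FALSE]
    yt <- y[-i]
    mu <- colMeans(Xt)
    sds <- apply(Xt, 2, stats::sd)
    sds[sds == 0] <- 1
    Xs <- sweep(sweep(Xt, 2, mu), 2, sds, "/")
    xh <- (X[i, ] - mu) / sds
    if (multilevel) {
      st <- subject_index[-i]
      if (!subject_index[i] %in% st)
        stop_stridesla("singleton_subject_error",
                       "held-out row's participant absent from the training fold")
      sp <- within_decompose(Xs, yt, st, check_singletons = FALSE)
      own <- st == subject_index[i]
      xh_w <- xh - colMeans(Xs[own, , drop = FALSE])
      base <- mean(yt[own])
      Xf <- sp$X_within
      yf <- sp$y_within
    } else {
      xh_w <- xh - colMeans(Xs)   # Xs already has zero column means; kept explicit
      base <- mean(yt)
      Xf <- sweep(Xs, 2, colMeans(Xs))
      yf <- yt - base
    }
    for (j in seq_along(keepX_values)) {
      eng <- spls_engine(Xf, yf, maxK, keepX_values[j])
      pred <- base + as.numeric(xh_w %*% eng$beta_path)
      err[i, , j] <- (y[i] - pred)^2
    }
  }
  err
}

#' Leave-one-out cross-validated prediction error for one model
#'
#' For each observation, the scaling, the within-participant split and the
#' sparse PLS fit are recomputed on the remaining N - 1 rows and the
#' held-out observation is predicted. Returns the mean squared prediction
#' error and its standard error over the N per-observation squared errors.
#'
#' @param X Raw (unscaled) predictor matrix.
#' @param y Response (mm).
#' @param subject_index Participant per row (required when `multilevel`).
#' @param K Components; `keepX` nonzero loadings per component.
#' @param keepX Sparsity per component.
#' @param multilevel Fit on within-participant deviations (stride-level
#'   analysis) or on rows as independent units (participant-average analysis).
#' @return Named vector `c(mspe, se)` in mm^2.
#' @export
loocv_mspe <- function(X, y, subject_index = NULL, K, keepX, multilevel = !is.null(subject_index)) {
  e <- loocv_sqerr(X, y, subject_index, maxK = K, keepX_values = keepX,
                   multilevel = multilevel)[, K, 1]
  c(mspe = mean(e), se = stats::sd(e) / sqrt(length(e)))
}

#' Exhaustive grid search over components and sparsity
#'
#' Evaluates every combination of `K = 1..maxK` components and
#' `keepX = 1..max_keepX` nonzero loadings per component by leave-one-out
#' cross-validation, and records the distinct-predictor count of the
#' full-data refit for each cell. Cells requesting more components than the
#' full-data fit can extract are marked infeasible (`mspe = Inf`) and are
#' ignored by [one_se_select()].
#'
#' @inheritParams loocv_mspe
#' @param maxK,max_keepX Upper grid bounds (10 x 10 for the stride-level
#'   analysis, 5 x 5 for the participant-average analysis).
#' @return An `mspe_grid` data frame with columns `K`, `keepX`, `mspe`, `se`,
#'   `support_size`.
#' @export
search_grid <- function(X, y, subject_index = NULL, maxK, max_keepX,
                        multilevel = !is.null(subject_index)) {
  if (maxK < 1 || max_keepX < 1)
    stop_stridesla("parameter_error", "grid bounds must be >= 1")
  X <- as.matrix(X)
  err <- loocv_sqerr(X, y, subject_index, maxK, seq_len(max_keepX), multilevel)
  N <- nrow(X)

  # full-data refit per keepX: feasibility and cumulative support sizes
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sds, "/")
  if (multilevel) {
    sp <- within_decompose(Xs, y, subject_index, check_singletons = FALSE)
    Xf <- sp$X_within; yf <- sp$y_within
  } else {
    Xf <- sweep(Xs, 2, colMeans(Xs)); yf <- y - mean(y)
  }
  cells <- vector("list", maxK * max_keepX)
  idx <- 0L
  for (j in seq_len(max_keepX)) {
    eng <- spls_engine(Xf, yf, maxK, j)
    nz <- abs(eng$W) > 0
    for (K in seq_len(maxK)) {
      idx <- idx + 1L
      feasible <- K <= eng$K_done
      supp <- if (feasible) sum(rowSums(nz[, seq_len(K), drop = FALSE]) > 0) else NA_integer_
      e <- err[, K, j]
      cells[[idx]] <- data.frame(
        K = K, keepX = j,
        mspe = if (feasible) mean(e) else Inf,
        se = if (feasible) stats::sd(e) / sqrt(N) else NA_real_,
        support_size = supp
      )
    }
  }
  grid <- do.call(rbind, cells)
  grid <- grid[order(grid$K, grid$keepX), ]
  rownames(grid) <- NULL
  structure(grid, class = c("mspe_grid", "data.frame"), n = N, multilevel = multilevel)
}

#' One-standard-error sparsest-model selection
#'
#' Finds the grid cell with the minimum cross-validated MSPE, forms the bound
#' `min MSPE + its SE`, and among all cells with MSPE within the bound picks
#' the one using the fewest distinct predictors; ties are broken by fewer
#' components, then lower MSPE.
#'
#' @param grid An `mspe_grid` from [search_grid()].
#' @return An `spls_selection` list: `K`, `keepX`, `support_size`,
#'   `one_se_bound`, `min_cell` (row of the minimising cell) and
#'   `candidates` (all cells within the bound).
#' @export
one_se_select <- function(grid) {
  ok <- is.finite(grid$mspe)
  if (!any(ok)) stop_stridesla("parameter_error", "no feasible grid cell")
  g <- grid[ok, , drop = FALSE]
  imin <- which.min(g$mspe)
  bound <- g$mspe[imin] + g$se[imin]
  cand <- g[g$mspe <= bound, , drop = FALSE]
  cand <- cand[order(cand$support_size, cand$K, cand$mspe), , drop = FALSE]
  structure(list(K = cand$K[1], keepX = cand$keepX[1],
                 support_size = cand$support_size[1],
                 one_se_bound = bound, min_cell = g[imin, ],
                 candidates = cand),
            class = "spls_selection")
}

#' @export
print.spls_selection <- function(x, ...) {
  cat(sprintf("<spls_selection> K=%d keepX=%d (%d distinct predictors)\n",
              x$K, x$keepX, x$support_size))
  cat(sprintf("  one-SE bound %.4g (min MSPE %.4g +/- %.4g at K=%d keepX=%d); %d candidate cell(s)\n",
              x$one_se_bound, x$min_cell$mspe, x$min_cell$se,
              x$min_cell$K, x$min_cell$keepX, nrow(x$candidates)))
  invisible(x)
}
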