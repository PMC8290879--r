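# Sparse partial least squares regression (univariate response) with a
# multilevel (within-subject) variance decomposition. The sparse NIPALS
# iteration soft-thresholds each loading vector at the (keepX+1)-largest
# magnitude so exactly keepX loadings survive per component, then deflates
# predictors and response by the extracted score.

#' Within/between decomposition of repeated-measures data
#'
#' Splits every variable into its participant mean (between part) and the
#' deviation from that mean (within part), so that `X = X_within + X_between`
#' exactly. Analysing the within part is the variance-decomposition analogue
#' of including a random intercept per participant.
#'
#' @param X Numeric matrix `[N x p]`.
#' @param y Numeric response vector, length N.
#' @param subject_index Participant identifier per row.
#' @param check_singletons Error on participants contributing a single row
#'   (default). Cross-validation folds disable this: a participant reduced to
#'   one training row still defines a valid (zero) within part.
#' @return A `multilevel_split` list: `X_within`, `X_between`, `y_within`,
#'   `y_between`, `subject_index`.
#' @export
within_decompose <- function(X, y, subject_index, check_singletons = TRUE) {
  X <- as.matrix(X)
  subject_index <- as.character(subject_index)
  if (nrow(X) != length(y) || nrow(X) != length(subject_index))
    stop_stridesla("shape_error", "X, y and subject_index disagree on N")
  counts <- table(subject_index)
  if (check_singletons && any(counts < 2) && length(counts) > 1)
    stop_stridesla("singleton_subject_error",
                   paste("participants with a single row:",
                         paste(names(counts)[counts < 2], collapse = ", ")))
  g <- factor(subject_index, levels = unique(subject_index))
  Xb <- rowsum(X, g) / as.vector(table(g))
  yb <- rowsum(y, g) / as.vector(table(g))
  Xb_full <- Xb[as.integer(g), , drop = FALSE]
  dimnames(Xb_full) <- dimnames(X)
  yb_full <- as.numeric(yb[as.integer(g)])
  structure(list(X_within = X - Xb_full, X_between = Xb_full,
                 y_within = y - yb_full, y_between = yb_full,
                 subject_index = subject_index),
            class = "multilevel_split")
}

# soft-threshold w so exactly keepX entries survive; ties at the boundary are
# broken deterministically in favour of the lower column index
soft_threshold_keep <- function(w, keepX) {
  p <- length(w)
  if (keepX >= p) return(w)
  ord <- order(-abs(w), seq_len(p))
  thr <- abs(w[ord[keepX + 1L]])
  out <- numeric(p)
  sel <- ord[seq_len(keepX)]
  out[sel] <- sign(w[sel]) * (abs(w[sel]) - thr)
  if (all(out == 0)) out[sel] <- w[sel]  # complete tie: fall back to hard selection
  out
}

# core sparse-PLS1 iteration shared by fit_spls and the cross-validation path.
# Returns per-component loadings W, x-loadings P, y-weights d, score norms,
# plus the cumulative regression vector after each component.
spls_engine <- function(Xc, yc, K, keepX, tol = 1e-12) {
  p <- ncol(Xc)
  W <- matrix(0, p, K)
  P <- matrix(0, p, K)
  d <- numeric(K)
  tt <- numeric(K)
  scores <- matrix(0, nrow(Xc), K)
  beta_path <- matrix(0, p, K)
  y0 <- sum(yc^2)
  k_done <- 0L
  for (k in seq_len(K)) {
    w <- as.numeric(crossprod(Xc, yc))
    if (sqrt(sum(w^2)) < tol * max(1, sqrt(y0))) break
    w <- soft_threshold_keep(w, keepX)
    nw <- sqrt(sum(w^2))
    if (nw < tol) break
    w <- w / nw
    t_k <- as.numeric(Xc %*% w)
    tk2 <- sum(t_k^2)
    if (tk2 < tol) break
    d_k <- sum(t_k * yc) / tk2
    p_k <- as.numeric(crossprod(Xc, t_k)) / tk2
    Xc <- Xc - tcrossprod(t_k, p_k)
    yc <- yc - d_k * t_k
    W[, k] <- w; P[, k] <- p_k; d[k] <- d_k; tt[k] <- tk2
    scores[, k] <- t_k
    k_done <- k
    Wk <- W[, seq_len(k), drop = FALSE]
    Pk <- P[, seq_len(k), drop = FALSE]
    beta_path[, k] <- as.numeric(Wk %*% solve(crossprod(Pk, Wk), d[seq_len(k)]))
  }
  # past saturation the fit no longer changes: carry the last beta forward so
  # predictions at larger K equal the saturated fit
  if (k_done >= 1L && k_done < K)
    beta_path[, (k_done + 1L):K] <- beta_path[, k_done]
  list(W = W[, seq_len(max(k_done, 1L)), drop = FALSE],
       P = P[, seq_len(max(k_done, 1L)), drop = FALSE],
       d = d[seq_len(max(k_done, 1L))], tt = tt[seq_len(max(k_done, 1L))],
       scores = scores[, seq_len(max(k_done, 1L)), drop = FALSE],
       beta_path = beta_path, K_done = k_done)
}

#' Fit a sparse PLS regression with a univariate response
#'
#' For each component the raw loading is proportional to the covariance of
#' the (deflated) predictors with the response; it is soft-thresholded so
#' exactly `keepX` loadings survive, renormalized, and the score is
#' extracted. Predictors are deflated by their regression on the score and
#' the response by its fitted part. Response-scale regression coefficients
#' accumulate over components, so with `keepX = p` and `K` equal to the
#' predictor rank the fit reproduces ordinary least squares.
#'
#' @param X Predictor matrix `[N x p]` (typically z-scored upstream).
#' @param y Response (mm; not scaled).
#' @param K Number of latent components.
#' @param keepX Number of nonzero loadings per component (same for every
#'   component).
#' @return An `spls_model`: loadings `[p x K]`, x-loadings, scores,
#'   y-weights, response-scale `beta`, per-component variance accounted for
#'   (`vaf`), the selected-variable `support`, and the training centres.
#' @export
fit_spls <- function(X, y, K, keepX) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (keepX < 1 || keepX > p)
    stop_stridesla("parameter_error", sprintf("keepX must be in 1..%d", p))
  if (K < 1)
    stop_stridesla("parameter_error", "K must be >= 1")
  if (stats::var(y) == 0)
    stop_stridesla("degenerate_response_error", "response has zero variance")
  x_means <- colMeans(X)
  y_mean <- mean(y)
  eng <- spls_engine(sweep(X, 2, x_means), y - y_mean, K, keepX)
  if (eng$K_done < 1)
    stop_stridesla("degenerate_response_error", "no component could be extracted")
  yc <- y - y_mean
  vaf <- eng$d^2 * eng$tt / sum(yc^2)
  beta <- eng$beta_path[, eng$K_done]
  structure(list(
    K = eng$K_done, K_requested = as.integer(K), keepX = as.integer(keepX),
    loadings = eng$W, x_loadings = eng$P, x_scores = eng$scores,
    y_weights = eng$d, beta = beta, x_means = x_means, y_mean = y_mean,
    vaf = vaf, support = which(rowSums(abs(eng$W)) > 0),
    x_sumsq = sum(sweep(X, 2, x_means)^2), col_names = colnames(X)
  ), class = "spls_model")
}

#' Predict from a sparse PLS model
#'
#' `y_hat = y_mean_train + (X_new - x_means_train) %*% beta`. New rows must
#' be on the training scale (same z-scoring).
#'
#' @param object An `spls_model`.
#' @param newdata Matrix (or vector for a single row) with `p` columns.
#' @param ... Unused.
#' @return Predicted response (mm).
#' @export
predict.spls_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != length(object$beta))
    stop_stridesla("shape_error",
                   sprintf("newdata has %d columns, model expects %d",
                           ncol(newdata), length(object$beta)))
  object$y_mean + as.numeric(sweep(as.matrix(newdata), 2, object$x_means) %*% object$beta)
}

#' Variance accounted for per latent component
#'
#' Fraction of response variance explained by each component (default), or
#' the fraction of predictor variance carried by each component
#' (`denominator = "predictor"`); the response-variance reading is the one
#' used throughout the package.
#'
#' @param model An `spls_model`.
#' @param X,y Optional data to recompute on (defaults to stored training
#'   quantities).
#' @param denominator `"response"` or `"predictor"`.
#' @return Numeric vector of length `K`; the sum over components is at most 1.
#' @export
vaf_per_component <- function(model, X = NULL, y = NULL,
                              denominator = c("response", "predictor")) {
  denominator <- match.arg(denominator)
  if (denominator == "response") {
    if (is.null(y)) return(model$vaf)
    yc <- y - mean(y)
    tk2 <- colSums(model$x_scores^2)
    model$y_weights^2 * tk2 / sum(yc^2)
  } else {
    # per-component predictor variance: ||t_k p_k'||^2 / ||X - x_means||^2
    tk2 <- colSums(model$x_scores^2)
    xss <- if (is.null(X)) model$x_sumsq else sum(sweep(as.matrix(X), 2, colMeans(X))^2)
    tk2 * colSums(model$x_loadings^2) / xss
  }
}

#' Number of distinct predictors used by a model
#'
#' Counts variables with a nonzero loading in any component; the sparsity
#' measure minimized by the one-standard-error selection rule.
#'
#' @param model An `spls_model`.
#' @return Integer.
#' @export
unique_support_size <- function(model) {
  length(model$support)
}

#' @export
print.spls_model <- function(x, ...) {
  cat(sprintf("<spls_model> K=%d keepX=%d | %d distinct predictors | VAF %s\n",
              x$K, x$keepX, unique_support_size(x),
              paste(sprintf("%.3f", x$vaf), collapse = " + ")))
  invisible(x)
}
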