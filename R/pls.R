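# PLS1 via SIMPLS (de Jong 1993). X and y are mean-centered, not
# variance-scaled: scatter conditioning belongs to SNV/MSC upstream.
#
# Returns the full coefficient path: B[, a] are the regression coefficients
# using the first a latent factors, so cross-validation over factor counts
# needs a single decomposition per training set.
simpls_path <- function(X, y, A) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  s <- crossprod(Xc, yc)               # p x 1
  R <- matrix(0, p, A); V <- matrix(0, p, A); q <- numeric(A)
  a_done <- 0L
  for (a in seq_len(A)) {
    r <- s
    t <- Xc %*% r
    nt <- sqrt(sum(t^2))
    if (nt < 1e-12) break               # X variance exhausted
    t <- t / nt; r <- r / nt
    pa <- crossprod(Xc, t)
    q[a] <- sum(yc * t)
    v <- pa
    if (a > 1) {
      Vp <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pa)
    }
    v <- v / sqrt(sum(v^2))
    V[, a] <- v; R[, a] <- r
    s <- s - v %*% crossprod(v, s)
    a_done <- a
  }
  if (a_done == 0L)
    stop_scc("X has no variance: cannot extract a latent factor",
             class = "scc_degenerate")
  B <- matrix(0, p, a_done)
  for (a in seq_len(a_done))
    B[, a] <- R[, seq_len(a), drop = FALSE] %*% q[seq_len(a)]
  list(B = B, x_means = xm, y_mean = ym, n_extracted = a_done)
}

#' Fit a PLS1 regression model
#'
#' Partial least squares regression (SIMPLS algorithm) of a single response
#' on a spectral matrix, on mean-centered data. With `n_factors` equal to the
#' rank of the centered predictor matrix, the fit coincides with ordinary
#' least squares.
#'
#' @param X Numeric matrix, samples by channels.
#' @param y Numeric response vector (SCC, percent).
#' @param n_factors Number of latent factors, in
#'   `1..min(nrow(X) - 1, ncol(X))`.
#' @return An object of class `plsr_model` with `coefficients` (per-channel
#'   slopes), `intercept`, `n_factors`, and the training means.
#' @examples
#' X <- matrix(rnorm(40), 10, 4); y <- X[, 2] * 2 + 1
#' fit <- fit_plsr(X, y, 1)
#' max(abs(predict(fit, X) - y)) < 1e-8
#' @export
fit_plsr <- function(X, y, n_factors) {
  X <- as.matrix(X)
  if (nrow(X) != length(y) || length(y) < 2)
    stop_scc("X rows (%d) must match length(y) (%d), with at least 2 samples",
             nrow(X), length(y), class = "scc_invalid")
  if (stats::var(y) == 0)
    stop_scc("y has zero variance", class = "scc_degenerate")
  cap <- min(nrow(X) - 1L, ncol(X))
  if (n_factors < 1 || n_factors > cap)
    stop_scc("n_factors (%d) must be in 1..%d", n_factors, cap,
             class = "scc_invalid")
  fit <- simpls_path(X, y, n_factors)
  a <- min(n_factors, fit$n_extracted)
  b <- fit$B[, a]
  structure(list(coefficients = b,
                 intercept = fit$y_mean - sum(fit$x_means * b),
                 n_factors = a, x_means = fit$x_means, y_mean = fit$y_mean,
                 n_channels = ncol(X)),
            class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d factors over %d channels\n",
              x$n_factors, x$n_channels))
  invisible(x)
}

#' @rdname fit_plsr
#' @param object A `plsr_model`.
#' @param newdata Matrix (or vector for a single sample) with the same number
#'   of channels as the training matrix.
#' @param ... Unused.
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(X) != object$n_channels)
    stop_scc("newdata has %d channels, model expects %d", ncol(X),
             object$n_channels, class = "scc_invalid")
  as.vector(X %*% object$coefficients + object$intercept)
}

#' Root mean square error
#'
#' `sqrt(mean((pred - obs)^2))`, the RMSEC/RMSEV statistic (same units as the
#' response, percent SCC here).
#'
#' @param pred,obs Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
rmse <- function(pred, obs) {
  if (length(pred) != length(obs) || !length(pred))
    stop_scc("pred and obs must have equal, positive length",
             class = "scc_invalid")
  sqrt(mean((pred - obs)^2))
}

#' Pearson correlation between predictions and observations
#'
#' @param pred,obs Numeric vectors of length at least 2, each with nonzero
#'   variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(pred, obs) {
  if (length(pred) != length(obs) || length(pred) < 2)
    stop_scc("need equal lengths >= 2", class = "scc_invalid")
  if (stats::var(pred) == 0 || stats::var(obs) == 0)
    stop_scc("zero variance input", class = "scc_degenerate")
  stats::cor(pred, obs)
}

#' Choose the PLSR factor count by cross-validation
#'
#' Venetian-blind (index-stride) k-fold cross-validation: sample `i` belongs
#' to fold `((i - 1) mod folds) + 1`, so the scheme is deterministic without
#' a seed. Returns the factor count minimizing CV RMSE; ties go to the
#' smaller count.
#'
#' @param X Numeric matrix.
#' @param y Response vector.
#' @param max_factors Upper bound on factors (default 10).
#' @param folds Number of folds (default 10, reduced to `nrow(X)` if larger).
#' @return Selected factor count.
#' @export
choose_factors <- function(X, y, max_factors = 10, folds = 10) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (max_factors < 1) stop_scc("max_factors must be >= 1", class = "scc_invalid")
  folds <- min(folds, n)
  if (folds < 2 || n - ceiling(n / folds) < 2)
    stop_scc("too few samples (%d) for %d-fold CV", n, folds,
             class = "scc_invalid")
  fold_id <- ((seq_len(n) - 1L) %% folds) + 1L
  A <- min(max_factors, n - ceiling(n / folds) - 1L, ncol(X))
  press <- numeric(A)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit <- simpls_path(X[tr, , drop = FALSE], y[tr], A)
    Xte <- sweep(X[!tr, , drop = FALSE], 2, fit$x_means)
    pred <- Xte %*% fit$B + fit$y_mean          # n_test x a_done
    err <- (pred - y[!tr])^2
    a_av <- fit$n_extracted
    press[seq_len(a_av)] <- press[seq_len(a_av)] + colSums(err)
    if (a_av < A)  # reuse last available factor for unextractable counts
      press[(a_av + 1L):A] <- press[(a_av + 1L):A] + sum(err[, a_av])
  }
  which.min(press)  # first minimum = fewest factors on ties
}
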