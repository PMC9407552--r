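#' Support vector regression parameters
#'
#' @param c Penalty factor C (> 0).
#' @param g RBF kernel width parameter (> 0), in the gamma convention
#'   `K(u, v) = exp(-g * ||u - v||^2)`.
#' @param epsilon Insensitive-tube half-width on the standardized response
#'   scale (>= 0, default 0.01).
#' @return An object of class `svr_params`.
#' @export
svr_params <- function(c, g, epsilon = 0.01) {
  stopifnot(is.numeric(c), is.numeric(g), c > 0, g > 0, epsilon >= 0)
  structure(list(c = c, g = g, epsilon = epsilon), class = "svr_params")
}

#' Train an epsilon-SVR model with RBF kernel
#'
#' Trains epsilon-insensitive support vector regression on column-standardized
#' predictors and a standardized response (training statistics), so that a
#' single kernel width `g` is meaningful across channels; predictions are
#' returned on the original response scale. The quadratic program is solved
#' by \pkg{e1071} (libsvm).
#'
#' If every standardized target lies inside the epsilon tube the optimizer
#' returns no support vectors; the model then degenerates to the constant
#' mean predictor, which is the correct epsilon-insensitive solution.
#'
#' @param X Numeric matrix (samples x channels).
#' @param y Numeric response.
#' @param p An [svr_params()].
#' @param tolerance Termination tolerance of the quadratic-program solver
#'   (default 0.001, the libsvm default).
#' @return An object of class `svr_model` wrapping the fitted machine and the
#'   standardization vectors.
#' @export
train_svr <- function(X, y, p, tolerance = 0.001) {
  stopifnot(inherits(p, "svr_params"))
  X <- as.matrix(X)
  if (nrow(X) < 2 || nrow(X) != length(y))
    stop_scc("need >= 2 samples with matching response", class = "scc_invalid")
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop_scc("non-finite training inputs", class = "scc_invalid")
  # population (1/n) SDs: standardization is then invariant under sample
  # duplication, and so is the trained machine
  x_mu <- colMeans(X)
  x_sd <- sqrt(colMeans(sweep(X, 2, x_mu)^2))
  x_sd[x_sd == 0] <- 1              # constant channels carry no information
  y_mu <- mean(y)
  y_sd <- sqrt(mean((y - y_mu)^2))
  if (y_sd == 0) y_sd <- 1
  Xs <- sweep(sweep(X, 2, x_mu), 2, x_sd, `/`)
  ys <- (y - y_mu) / y_sd
  fit <- if (max(abs(ys)) > p$epsilon)
    e1071::svm(Xs, ys, type = "eps-regression", kernel = "radial",
               cost = p$c, gamma = p$g, epsilon = p$epsilon,
               tolerance = tolerance, scale = FALSE, fitted = FALSE)
  if (!is.null(fit) && fit$tot.nSV == 0) fit <- NULL
  structure(list(params = p, fit = fit, x_mu = x_mu, x_sd = x_sd,
                 y_mu = y_mu, y_sd = y_sd, n_channels = ncol(X)),
            class = "svr_model")
}

#' @rdname train_svr
#' @param object An `svr_model`.
#' @param newdata Matrix with the training channel count.
#' @param ... Unused.
#' @export
predict.svr_model <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1)
       else as.matrix(newdata)
  if (ncol(X) != object$n_channels)
    stop_scc("newdata has %d channels, model expects %d", ncol(X),
             object$n_channels, class = "scc_invalid")
  if (is.null(object$fit)) return(rep(object$y_mu, nrow(X)))
  Xs <- sweep(sweep(X, 2, object$x_mu), 2, object$x_sd, `/`)
  as.vector(stats::predict(object$fit, Xs)) * object$y_sd + object$y_mu
}

#' @export
print.svr_model <- function(x, ...) {
  cat(sprintf("<svr_model> C = %.4g, g = %.4g, %d support vectors\n",
              x$params$c, x$params$g,
              if (is.null(x$fit)) 0L else x$fit$tot.nSV))
  invisible(x)
}

#' Cross-validated RMSE fitness of an SVR parameter pair
#'
#' k-fold cross-validated RMSE of [train_svr()] on the calibration set: the
#' objective minimized when tuning (C, g). Fold assignment is a seeded random
#' permutation, so the value is deterministic given the seed.
#'
#' @param X,y Calibration data.
#' @param p An [svr_params()].
#' @param folds Number of folds (default 5).
#' @param seed Integer seed for the fold permutation.
#' @return Cross-validated RMSE (same units as `y`).
#' @export
svr_fitness <- function(X, y, p, folds = 5, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (folds < 2 || folds > n)
    stop_scc("folds must be in 2..%d", n, class = "scc_invalid")
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  pred <- numeric(n)
  for (f in seq_len(folds)) {
    te <- fold_id == f
    m <- train_svr(X[!te, , drop = FALSE], y[!te], p)
    pred[te] <- predict(m, X[te, , drop = FALSE])
  }
  rmse(pred, y)
}

#' Particle swarm optimization of SVR hyperparameters
#'
#' Standard global-best PSO over `(C, g)`, searched in log10 space within the
#' configured bounds: particle velocities are updated with linearly decaying
#' inertia plus cognitive and social pulls toward the personal and global
#' bests, positions are clipped to the bounds, and each particle's fitness is
#' the cross-validated RMSE of [svr_fitness()]. Fully reproducible given the
#' seed; the best-so-far fitness is non-increasing by construction.
#'
#' @param X,y Calibration data (selected wavelengths).
#' @param cfg A [pso_config()].
#' @return A list with `params` (the best [svr_params()]), `fitness` (its CV
#'   RMSE), `trajectory` (best fitness per iteration) and `evaluations`.
#' @export
pso_optimize <- function(X, y, cfg = pso_config()) {
  stopifnot(inherits(cfg, "pso_config"))
  lb <- log10(c(cfg$c_range[1], cfg$g_range[1]))
  ub <- log10(c(cfg$c_range[2], cfg$g_range[2]))
  fit_fun <- function(pos) {
    svr_fitness(X, y, svr_params(10^pos[1], 10^pos[2], cfg$epsilon),
                folds = cfg$folds, seed = cfg$seed)
  }
  if (all(ub - lb == 0)) {
    f <- fit_fun(lb)
    return(list(params = svr_params(10^lb[1], 10^lb[2], cfg$epsilon),
                fitness = f, trajectory = f, evaluations = 1L))
  }
  ns <- cfg$swarm_size
  with_seed(cfg$seed, {
    pos <- cbind(stats::runif(ns, lb[1], ub[1]), stats::runif(ns, lb[2], ub[2]))
    vel <- cbind(stats::runif(ns, -1, 1) * (ub[1] - lb[1]) / 10,
                 stats::runif(ns, -1, 1) * (ub[2] - lb[2]) / 10)
    pbest <- pos
    pbest_f <- apply(pos, 1, fit_fun)
    g_idx <- which.min(pbest_f)
    gbest <- pbest[g_idx, ]; gbest_f <- pbest_f[g_idx]
    traj <- numeric(cfg$iterations)
    for (it in seq_len(cfg$iterations)) {
      w <- cfg$inertia[1] +
        (cfg$inertia[2] - cfg$inertia[1]) *
          (it - 1) / max(cfg$iterations - 1, 1)
      r1 <- matrix(stats::runif(ns * 2), ns, 2)
      r2 <- matrix(stats::runif(ns * 2), ns, 2)
      vel <- w * vel + cfg$cognitive * r1 * (pbest - pos) +
        cfg$social * r2 * (sweep(-pos, 2, gbest, `+`))
      pos <- pos + vel
      pos[, 1] <- pmin(pmax(pos[, 1], lb[1]), ub[1])
      pos[, 2] <- pmin(pmax(pos[, 2], lb[2]), ub[2])
      f <- apply(pos, 1, fit_fun)
      improved <- f < pbest_f
      pbest[improved, ] <- pos[improved, , drop = FALSE]
      pbest_f[improved] <- f[improved]
      if (min(pbest_f) < gbest_f) {
        g_idx <- which.min(pbest_f)
        gbest <- pbest[g_idx, ]; gbest_f <- pbest_f[g_idx]
      }
      traj[it] <- gbest_f
    }
    list(params = svr_params(10^gbest[1], 10^gbest[2], cfg$epsilon),
         fitness = gbest_f, trajectory = traj,
         evaluations = ns * (cfg$iterations + 1L))
  })
}

#' PSO configuration
#'
#' Defaults: 20 particles, 100 iterations, inertia decaying 0.9 to 0.4,
#' cognitive and social coefficients 1.7, `C` searched in `[0.01, 100]` and
#' `g` in `[0.001, 10]` (log10 space), 5-fold CV fitness.
#'
#' @param swarm_size Number of particles (>= 2).
#' @param iterations PSO iterations (>= 1).
#' @param inertia `c(start, end)` inertia weights.
#' @param cognitive,social Acceleration coefficients.
#' @param c_range,g_range Positive search bounds for C and g.
#' @param folds CV folds for the fitness.
#' @param epsilon SVR tube width on the standardized scale.
#' @param seed Integer seed.
#' @return An object of class `pso_config`.
#' @export
pso_config <- function(swarm_size = 20, iterations = 100,
                       inertia = c(0.9, 0.4), cognitive = 1.7, social = 1.7,
                       c_range = c(0.01, 100), g_range = c(0.001, 10),
                       folds = 5, epsilon = 0.01, seed = 1L) {
  stopifnot(swarm_size >= 2, iterations >= 1, length(inertia) == 2,
            all(c_range > 0), all(g_range > 0),
            c_range[1] <= c_range[2], g_range[1] <= g_range[2], folds >= 2)
  structure(list(swarm_size = swarm_size, iterations = iterations,
                 inertia = inertia, cognitive = cognitive, social = social,
                 c_range = c_range, g_range = g_range, folds = folds,
                 epsilon = epsilon, seed = seed), class = "pso_config")
}

#' Final model evaluation
#'
#' Scores a fitted model on calibration and validation sets: Pearson
#' correlation and RMSE per set, per-sample relative errors and the maximum
#' relative error per set (`max |pred - obs| / obs * 100`).
#'
#' @param model A model with a `predict` method (`svr_model` or
#'   `plsr_model`).
#' @param split A `dataset_split`.
#' @param X Full predictor matrix the split indexes into (selected channels).
#' @param y Full response vector.
#' @return A list of class `model_evaluation` with `r_cal`, `rmse_cal`,
#'   `r_val`, `rmse_val`, `max_rel_err_cal`, `max_rel_err_val` (percent) and
#'   the per-sample predictions.
#' @export
evaluate_model <- function(model, split, X, y) {
  if (any(y == 0))
    stop_scc("relative error undefined: zero reference value",
             class = "scc_invalid")
  X <- as.matrix(X)
  ic <- split$calibration_idx; iv <- split$validation_idx
  pc <- predict(model, X[ic, , drop = FALSE])
  pv <- predict(model, X[iv, , drop = FALSE])
  rel <- function(p, o) abs(p - o) / abs(o) * 100
  structure(list(
    r_cal = pearson_r(pc, y[ic]), rmse_cal = rmse(pc, y[ic]),
    r_val = pearson_r(pv, y[iv]), rmse_val = rmse(pv, y[iv]),
    max_rel_err_cal = max(rel(pc, y[ic])),
    max_rel_err_val = max(rel(pv, y[iv])),
    pred_cal = pc, obs_cal = y[ic], pred_val = pv, obs_val = y[iv]),
    class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf(
    "calibration: R = %.4f, RMSE = %.4f%%, max rel err = %.2f%%\n",
    x$r_cal, x$rmse_cal, x$max_rel_err_cal))
  cat(sprintf(
    "validation:  R = %.4f, RMSE = %.4f%%, max rel err = %.2f%%\n",
    x$r_val, x$rmse_val, x$max_rel_err_val))
  invisible(x)
}
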