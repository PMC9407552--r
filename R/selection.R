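#' Configuration for the successive projections algorithm
#'
#' @param n_min Minimum candidate chain length (default 5).
#' @param n_max Maximum chain length; default `min(n_cal - 1, K, 100)` at run
#'   time (`NULL`). The 100-channel cap reflects the goal of simplifying the
#'   evaluation model to fewer than 100 wavelengths.
#' @param alpha Significance level of the final F-test elimination
#'   (default 0.25).
#' @param max_factors PLSR factor cap used inside the evaluation phases
#'   (default 10).
#' @return An object of class `spa_config`.
#' @export
spa_config <- function(n_min = 5, n_max = NULL, alpha = 0.25,
                       max_factors = 10) {
  stopifnot(n_min >= 1, is.null(n_max) || n_max >= n_min,
            alpha > 0, alpha < 1, max_factors >= 1)
  structure(list(n_min = n_min, n_max = n_max, alpha = alpha,
                 max_factors = max_factors), class = "spa_config")
}

#' Configuration for Monte-Carlo uninformative variable elimination
#'
#' @param n_runs Number of Monte-Carlo resampled PLSR fits (default 500).
#' @param sample_fraction Fraction of calibration samples drawn (without
#'   replacement) per run (default 0.8).
#' @param max_factors PLSR factor cap (default 10).
#' @param max_channels Largest subset size scanned when minimizing RMSEV
#'   (default 100; the model is meant to stay below 100 wavelengths).
#' @param stability_cap Magnitude assigned to the stability of a channel
#'   whose coefficient SD underflows (default 1e6).
#' @param seed Integer seed for the Monte-Carlo draws.
#' @return An object of class `mcuve_config`.
#' @export
mcuve_config <- function(n_runs = 500, sample_fraction = 0.8,
                         max_factors = 10, max_channels = 100,
                         stability_cap = 1e6, seed = 1L) {
  stopifnot(n_runs >= 2, sample_fraction > 0, sample_fraction < 1,
            max_factors >= 1, max_channels >= 1, stability_cap > 0)
  structure(list(n_runs = n_runs, sample_fraction = sample_fraction,
                 max_factors = max_factors, max_channels = max_channels,
                 stability_cap = stability_cap, seed = seed),
            class = "mcuve_config")
}

# ---- SPA phase 1: projection chains -----------------------------------------

#' SPA phase 1: build projection chains
#'
#' For every starting channel, grows a chain by repeatedly appending the
#' channel whose projection orthogonal to the span of the chain so far has
#' the largest norm (successive orthogonal projections on the column-centered
#' calibration matrix). Chains therefore collect minimally collinear channel
#' sets; an exact duplicate of a chained channel has projection norm zero and
#' is appended last. Ties go to the lowest channel index.
#'
#' @param Xcal Calibration spectra matrix (samples x channels).
#' @param cfg An [spa_config()].
#' @return Integer matrix, one row per starting channel, `n_max` columns of
#'   channel indices; rows for zero-norm starting channels are `NA` (skipped
#'   with a warning).
#' @export
spa_chains <- function(Xcal, cfg = spa_config()) {
  Xc <- scale(as.matrix(Xcal), center = TRUE, scale = FALSE)
  K <- ncol(Xc)
  n_max <- cfg$n_max %||% min(nrow(Xc) - 1L, K, 100L)
  if (K < n_max)
    stop_scc("n_max (%d) exceeds channel count (%d)", n_max, K,
             class = "scc_invalid")
  norms0 <- colSums(Xc^2)
  chains <- matrix(NA_integer_, K, n_max)
  for (k in seq_len(K)) {
    if (norms0[k] < 1e-24) {
      warning(sprintf("channel %d has zero variance: chain skipped", k))
      next
    }
    Xp <- Xc
    chain <- integer(n_max)
    chain[1] <- k
    j <- k
    for (step in seq_len(n_max - 1L)) {
      xj <- Xp[, j]
      nj <- sum(xj^2)
      if (nj > 1e-24)
        Xp <- Xp - xj %*% (crossprod(xj, Xp) / nj)
      nrm <- colSums(Xp^2)
      nrm[chain[seq_len(step)]] <- -1
      j <- which.max(nrm)      # ties -> lowest index
      chain[step + 1L] <- j
    }
    chains[k, ] <- chain
  }
  chains
}

# Lean RMSEV of a PLSR fit on a column subset; NA on degenerate subproblems.
subset_rmsev <- function(cols, Xcal, ycal, Xval, yval, max_factors) {
  A <- min(max_factors, length(cols), nrow(Xcal) - 1L)
  fit <- tryCatch(simpls_path(Xcal[, cols, drop = FALSE], ycal, A),
                  error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  a <- fit$n_extracted
  pred <- sweep(Xval[, cols, drop = FALSE], 2, fit$x_means) %*%
    fit$B[, a] + fit$y_mean
  sqrt(mean((pred - yval)^2))
}

#' SPA phase 2: score chain prefixes by validation RMSE
#'
#' Every prefix of length `n_min..n_max` of every chain is used as a
#' candidate wavelength set: a PLSR model is fitted on the calibration
#' columns and scored by RMSEV on the validation set. The candidate with the
#' minimal RMSEV wins; ties prefer the shorter prefix, then the lower
#' starting channel.
#'
#' @param chains Output of [spa_chains()].
#' @param Xcal,ycal,Xval,yval Calibration/validation matrices and responses.
#' @param cfg An [spa_config()].
#' @return List with `subset` (winning channel indices, in chain order),
#'   `rmsev` (the winning RMSEV), `table` (starts x prefix-lengths RMSEV
#'   matrix, `NA` where invalid) and `lengths` (the prefix lengths scored).
#' @export
spa_evaluate <- function(chains, Xcal, ycal, Xval, yval, cfg = spa_config()) {
  starts <- which(!is.na(chains[, 1]))
  if (!length(starts)) stop_scc("no valid chains", class = "scc_invalid")
  if (!length(yval)) stop_scc("empty validation set", class = "scc_invalid")
  n_max <- ncol(chains)
  lens <- seq.int(min(cfg$n_min, n_max), n_max)
  tab <- matrix(NA_real_, nrow(chains), length(lens))
  for (k in starts) {
    for (li in seq_along(lens)) {
      tab[k, li] <- subset_rmsev(chains[k, seq_len(lens[li])],
                                 Xcal, ycal, Xval, yval, cfg$max_factors)
    }
  }
  if (all(is.na(tab)))
    stop_scc("all candidate subsets degenerate", class = "scc_degenerate")
  # argmin with ties -> shorter prefix, then lower start
  best <- which(tab == min(tab, na.rm = TRUE), arr.ind = TRUE)
  best <- best[order(best[, 2], best[, 1]), , drop = FALSE][1, ]
  list(subset = chains[best[1], seq_len(lens[best[2]])],
       rmsev = tab[best[1], best[2]],
       table = tab, lengths = lens)
}

#' SPA phase 3: F-test elimination of uninformative wavelengths
#'
#' Each channel of the phase-2 subset gets a relevance index, the absolute
#' product of its PLSR regression coefficient and its calibration standard
#' deviation. Channels are reordered by descending index, PLSR models are
#' fitted on the first `j` channels for every `j`, and the smallest `j` whose
#' RMSEV is statistically indistinguishable from the minimum is kept: RMSEV(j)
#' must not exceed `min RMSEV * sqrt(F^{-1}(1 - alpha; n_val, n_val))`.
#'
#' @param subset Channel indices from [spa_evaluate()].
#' @param Xcal,ycal,Xval,yval Data matrices and responses.
#' @param cfg An [spa_config()].
#' @return List with `selected` (final channel indices, relevance order),
#'   `trajectory` (RMSEV per prefix size), `relevance` (index per channel of
#'   `subset`), `threshold` and `ratios` (the Eq.-style RMSEV ratios).
#' @export
spa_eliminate <- function(subset, Xcal, ycal, Xval, yval, cfg = spa_config()) {
  m <- length(subset)
  if (m == 1)
    return(list(selected = subset, trajectory = NA_real_,
                relevance = NA_real_, threshold = NA_real_,
                ratios = NA_real_))
  A <- min(cfg$max_factors, m, nrow(Xcal) - 1L)
  fit <- simpls_path(Xcal[, subset, drop = FALSE], ycal, A)
  b <- fit$B[, fit$n_extracted]
  relevance <- abs(b) * apply(Xcal[, subset, drop = FALSE], 2, stats::sd)
  ord <- order(-relevance, seq_len(m))
  ranked <- subset[ord]
  traj <- vapply(seq_len(m), function(j)
    subset_rmsev(ranked[seq_len(j)], Xcal, ycal, Xval, yval, cfg$max_factors),
    numeric(1))
  rmin <- min(traj, na.rm = TRUE)
  thr <- rmin * sqrt(stats::qf(1 - cfg$alpha, length(yval), length(yval)))
  ratios <- traj / rmin
  pass <- !is.na(traj) & traj <= max(thr, rmin)  # the argmin always passes
  j_star <- which(pass)[1]
  list(selected = ranked[seq_len(j_star)], trajectory = traj,
       relevance = relevance[ord], threshold = thr, ratios = ratios)
}

#' Select characteristic wavelengths with SPA
#'
#' Runs the three SPA phases ([spa_chains()], [spa_evaluate()],
#' [spa_eliminate()]) on a calibration/validation split.
#'
#' @param Xcal,ycal,Xval,yval Data matrices and responses.
#' @param cfg An [spa_config()].
#' @param wavelengths Optional wavelength grid for labelling.
#' @return A `wavelength_selection` object: `method`, `selected` (channel
#'   indices), `wavelengths` (nm, if a grid was given), `trajectory`
#'   (data.frame of subset size and RMSEV from the elimination phase),
#'   `rmsev` (final RMSEV) and `diagnostics`.
#' @export
spa_select <- function(Xcal, ycal, Xval, yval, cfg = spa_config(),
                       wavelengths = NULL) {
  chains <- spa_chains(Xcal, cfg)
  ev <- spa_evaluate(chains, Xcal, ycal, Xval, yval, cfg)
  el <- spa_eliminate(ev$subset, Xcal, ycal, Xval, yval, cfg)
  final_rmsev <- subset_rmsev(el$selected, Xcal, ycal, Xval, yval,
                              cfg$max_factors)
  traj <- if (length(ev$subset) > 1)
    data.frame(size = seq_along(el$trajectory), rmsev = el$trajectory)
  else data.frame(size = 1L, rmsev = ev$rmsev)
  new_selection("spa", el$selected, wavelengths, traj, final_rmsev,
                diagnostics = list(phase2_subset = ev$subset,
                                   phase2_rmsev = ev$rmsev,
                                   relevance = el$relevance,
                                   f_threshold = el$threshold,
                                   rmsev_ratios = el$ratios))
}

# ---- MCUVE ------------------------------------------------------------------

#' MCUVE stability of PLSR coefficients
#'
#' Draws `n_runs` random subsets of the calibration samples (without
#' replacement, seeded), fits a PLSR model on each, and computes for every
#' channel the stability `C(k) = mean(beta_k) / sd(beta_k)` of its regression
#' coefficient across runs. Channels with large `|C|` contribute stable,
#' informative signal; channels whose coefficients fluctuate around zero are
#' uninformative.
#'
#' Degenerate channels (coefficient SD below 1e-12) get `C = 0` when the mean
#' is also zero, otherwise `sign(mean) * stability_cap`, each with a warning.
#'
#' @param Xcal Calibration matrix.
#' @param ycal Calibration response.
#' @param cfg An [mcuve_config()].
#' @return Numeric stability vector, one value per channel, with the run
#'   count as attribute `n_runs`.
#' @export
mcuve_stability <- function(Xcal, ycal, cfg = mcuve_config()) {
  Xcal <- as.matrix(Xcal)
  n <- nrow(Xcal)
  m <- ceiling(cfg$sample_fraction * n)
  if (m < cfg$max_factors + 2)
    warning(sprintf("subsample size %d is small for %d factors", m,
                    cfg$max_factors))
  if (m < 3)
    stop_scc("subsample size %d too small", m, class = "scc_invalid")
  betas <- matrix(0, ncol(Xcal), cfg$n_runs)
  with_seed(cfg$seed, {
    for (run in seq_len(cfg$n_runs)) {
      rows <- sample.int(n, m)
      A <- min(cfg$max_factors, m - 1L, ncol(Xcal))
      fit <- simpls_path(Xcal[rows, , drop = FALSE], ycal[rows], A)
      betas[, run] <- fit$B[, fit$n_extracted]
    }
  })
  mu <- rowMeans(betas)
  sdv <- apply(betas, 1, stats::sd)
  C <- mu / sdv
  degen <- sdv < 1e-12
  if (any(degen)) {
    warning(sprintf("%d channel(s) with degenerate coefficient SD", sum(degen)))
    C[degen] <- ifelse(abs(mu[degen]) < 1e-12, 0,
                       sign(mu[degen]) * cfg$stability_cap)
  }
  attr(C, "n_runs") <- cfg$n_runs
  C
}

#' MCUVE forward selection by stability ranking
#'
#' Orders channels by decreasing stability magnitude `|C|` (a strongly
#' negative but stable coefficient is as informative as a positive one), then
#' grows the wavelength set one channel at a time, scoring each top-`j`
#' subset by the RMSEV of a PLSR model; the subset size minimizing RMSEV is
#' returned (ties towards fewer channels).
#'
#' @param C Stability vector from [mcuve_stability()].
#' @param Xcal,ycal,Xval,yval Data matrices and responses.
#' @param cfg An [mcuve_config()].
#' @param wavelengths Optional wavelength grid for labelling.
#' @return A `wavelength_selection` object (see [spa_select()]).
#' @export
mcuve_select <- function(C, Xcal, ycal, Xval, yval, cfg = mcuve_config(),
                         wavelengths = NULL) {
  K <- ncol(as.matrix(Xcal))
  stopifnot(length(C) == K)
  if (any(!is.finite(C)))
    stop_scc("non-finite stability values", class = "scc_invalid")
  ord <- order(-abs(C), seq_len(K))
  j_max <- min(K, cfg$max_channels)
  traj <- vapply(seq_len(j_max), function(j)
    subset_rmsev(ord[seq_len(j)], Xcal, ycal, Xval, yval, cfg$max_factors),
    numeric(1))
  j_star <- which.min(traj)   # first minimum -> smaller j on ties
  new_selection("mcuve", ord[seq_len(j_star)], wavelengths,
                data.frame(size = seq_len(j_max), rmsev = traj),
                traj[j_star],
                diagnostics = list(stability = C, ranking = ord))
}

#' Select characteristic wavelengths with MCUVE
#'
#' Convenience wrapper running [mcuve_stability()] then [mcuve_select()].
#'
#' @inheritParams mcuve_select
#' @inheritParams mcuve_stability
#' @export
mcuve_run <- function(Xcal, ycal, Xval, yval, cfg = mcuve_config(),
                      wavelengths = NULL) {
  C <- mcuve_stability(Xcal, ycal, cfg)
  mcuve_select(C, Xcal, ycal, Xval, yval, cfg, wavelengths)
}

new_selection <- function(method, selected, wavelengths, trajectory, rmsev,
                          diagnostics) {
  if (!length(selected)) stop_scc("empty selection", class = "scc_invalid")
  structure(list(method = method, selected = as.integer(selected),
                 wavelengths = if (!is.null(wavelengths))
                   wavelengths[selected],
                 trajectory = trajectory, rmsev = rmsev,
                 diagnostics = diagnostics),
            class = "wavelength_selection")
}

#' @export
print.wavelength_selection <- function(x, ...) {
  cat(sprintf("<wavelength_selection> %s: %d channels, RMSEV %.4g\n",
              toupper(x$method), length(x$selected), x$rmsev))
  invisible(x)
}
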