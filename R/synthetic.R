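#' Configuration for the synthetic pear spectra generator
#'
#' The generator emulates Vis/NIR diffuse reflectance spectra of pear fruit:
#' a smooth envelope carrying Gaussian reflectance peaks near 550 and 750 nm
#' and valleys near 680 and 980 nm, with the carbohydrate-linked bands (750
#' and 980 nm by default) tied linearly to stone cell content. Each replicate
#' spectrum is corrupted by a multiplicative gain, a linear additive baseline
#' drift and white channel noise -- exactly the nuisance structure that
#' SNV/MSC preprocessing is designed to remove.
#'
#' @param n_samples Number of fruit samples.
#' @param replicates_per_sample Replicate spectra per fruit (default 3,
#'   matching acquisition at three 120-degree rotations).
#' @param grid Numeric `c(low, high, step)` in nm; default 498-1020 nm at
#'   0.5 nm spacing (1045 channels).
#' @param scc_range SCC range in percent, default `c(0.240, 0.657)`.
#' @param scc_distribution `"uniform"` (default) or `"truncnorm"`; the
#'   truncated normal uses mean 0.486 and SD 0.100 within `scc_range`.
#' @param band_centers Band centres in nm.
#' @param band_signs `+1` for a reflectance peak, `-1` for a valley; one per
#'   band.
#' @param band_amplitudes Baseline band amplitude (reflectance units) at
#'   SCC = 0, one per band.
#' @param band_sd Gaussian band SD in nm (common to all bands).
#' @param informative_bands Subset of `band_centers` whose amplitude depends
#'   on SCC; empty vector for a pure-noise (no-signal) dataset.
#' @param scc_slope Change of informative-band amplitude per percent SCC
#'   (negative by default: higher SCC, weaker carbohydrate bands).
#' @param envelope_level Flat envelope reflectance level.
#' @param scatter_sd SD of the per-replicate multiplicative gain (around 1).
#' @param drift_sd SD of the per-replicate additive baseline slope (per nm).
#' @param noise_sd SD of white per-channel noise.
#' @param seed Integer seed; identical configuration and seed give identical
#'   output.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 120,
                             replicates_per_sample = 3,
                             grid = c(498, 1020, 0.5),
                             scc_range = c(0.240, 0.657),
                             scc_distribution = c("uniform", "truncnorm"),
                             band_centers = c(550, 680, 750, 980),
                             band_signs = c(1, -1, 1, -1),
                             band_amplitudes = c(0.12, 0.18, 0.28, 0.22),
                             band_sd = 30,
                             informative_bands = c(750, 980),
                             scc_slope = -0.25,
                             envelope_level = 0.60,
                             scatter_sd = 0.05,
                             drift_sd = 1e-4,
                             noise_sd = 0.004,
                             seed = 1L) {
  scc_distribution <- match.arg(scc_distribution)
  stopifnot(n_samples >= 1, replicates_per_sample >= 1,
            length(grid) == 3, grid[3] > 0, grid[1] < grid[2],
            length(scc_range) == 2,
            length(band_signs) == length(band_centers),
            length(band_amplitudes) == length(band_centers),
            band_sd > 0,
            all(informative_bands %in% band_centers),
            scatter_sd >= 0, drift_sd >= 0, noise_sd >= 0)
  if (scc_range[1] >= scc_range[2] || scc_range[1] <= 0 || scc_range[2] >= 100)
    stop_scc("scc_range must satisfy 0 < min < max < 100", class = "scc_invalid")
  structure(as.list(environment()), class = "synthetic_config")
}

# Noise-free deterministic band model: matrix n x K of base spectra given SCC.
base_spectra <- function(cfg, wl, scc) {
  n <- length(scc)
  out <- matrix(cfg$envelope_level, n, length(wl))
  for (b in seq_along(cfg$band_centers)) {
    shape <- exp(-(wl - cfg$band_centers[b])^2 / (2 * cfg$band_sd^2))
    amp <- rep(cfg$band_amplitudes[b], n)
    if (cfg$band_centers[b] %in% cfg$informative_bands)
      amp <- amp + cfg$scc_slope * scc
    out <- out + cfg$band_signs[b] * (amp %o% shape)
  }
  out
}

#' Generate synthetic pear spectra with known ground truth
#'
#' @param cfg A [synthetic_config()].
#' @return A list with elements `spectra` (a [spectra_set()] of replicate
#'   rows, ids `"<sample>_r<k>"`), `reference` (a [reference_set()] per
#'   sample), `group_map` (replicate id to sample id, for
#'   [average_replicates()]) and `truth` (a `ground_truth` list holding the
#'   drawn `scc`, per-replicate `gains` and `drifts`, the noise-free base
#'   spectra, and the indices of SCC-informative channels).
#' @examples
#' d <- simulate_pear_spectra(synthetic_config(n_samples = 5, grid = c(500, 900, 10)))
#' d$spectra
#' @export
simulate_pear_spectra <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  wl <- seq(cfg$grid[1], cfg$grid[2], by = cfg$grid[3])
  if (length(wl) < 10)
    stop_scc("grid yields %d channels; need at least 10", length(wl),
             class = "scc_invalid")
  n <- cfg$n_samples
  rep_n <- cfg$replicates_per_sample
  with_seed(cfg$seed, {
    scc <- if (cfg$scc_distribution == "uniform") {
      stats::runif(n, cfg$scc_range[1], cfg$scc_range[2])
    } else {
      draw_truncnorm(n, 0.486, 0.100, cfg$scc_range)
    }
    base <- base_spectra(cfg, wl, scc)
    gains <- matrix(stats::rnorm(n * rep_n, 1, cfg$scatter_sd), n, rep_n)
    drifts <- matrix(stats::rnorm(n * rep_n, 0, cfg$drift_sd), n, rep_n)
    mid <- (wl[1] + wl[length(wl)]) / 2
    refl <- matrix(0, n * rep_n, length(wl))
    ids <- character(n * rep_n)
    sample_ids <- sprintf("S%03d", seq_len(n))
    row <- 1L
    for (i in seq_len(n)) {
      for (k in seq_len(rep_n)) {
        noise <- if (cfg$noise_sd > 0)
          stats::rnorm(length(wl), 0, cfg$noise_sd) else 0
        refl[row, ] <- gains[i, k] * base[i, ] +
          drifts[i, k] * (wl - mid) + noise
        ids[row] <- if (rep_n == 1) sample_ids[i]
                    else sprintf("%s_r%d", sample_ids[i], k)
        row <- row + 1L
      }
    }
    refl[refl < 0] <- 0
    informative <- which(vapply(cfg$band_centers, function(ctr) {
      ctr %in% cfg$informative_bands
    }, logical(1)))
    info_channels <- integer(0)
    for (b in informative)
      info_channels <- union(info_channels,
        which(abs(wl - cfg$band_centers[b]) <= 2 * cfg$band_sd))
    list(
      spectra = spectra_set(wl, refl, ids),
      reference = reference_set(sample_ids, scc),
      group_map = stats::setNames(rep(sample_ids, each = rep_n), ids),
      truth = structure(list(scc = scc, gains = gains, drifts = drifts,
                             base = base, wavelengths = wl,
                             informative_channels = sort(info_channels),
                             config = cfg),
                        class = "ground_truth"))
  })
}

# Rejection-free truncated normal via inverse CDF.
draw_truncnorm <- function(n, mean, sd, range) {
  lo <- stats::pnorm(range[1], mean, sd)
  hi <- stats::pnorm(range[2], mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Registered deterministic fixtures
#'
#' Named, documented datasets used throughout the test-suite and examples:
#' \describe{
#'   \item{`"paper-like-120"`}{120 samples, 3 replicates, full 498-1020 nm
#'     grid at 0.5 nm, SCC uniform on (0.240, 0.657), default nuisance levels;
#'     the study-scale conditions.}
#'   \item{`"tiny-10x8"`}{10 samples, 1 replicate, 8 channels, noise-free;
#'     fully enumerable by hand.}
#'   \item{`"noise-only"`}{120 samples whose spectra carry no SCC information
#'     (no informative bands): a negative control on which any apparent
#'     modelling skill is leakage.}
#' }
#'
#' @param name Fixture id.
#' @param seed Optional seed overriding the fixture default (used for
#'   repeated negative-control draws).
#' @return As [simulate_pear_spectra()].
#' @export
make_fixture <- function(name, seed = NULL) {
  fixtures <- c("paper-like-120", "tiny-10x8", "noise-only")
  if (!name %in% fixtures)
    stop_scc("unknown fixture '%s'; available: %s", name,
             paste(fixtures, collapse = ", "), class = "scc_invalid")
  switch(name,
    "paper-like-120" =
      simulate_pear_spectra(synthetic_config(seed = seed %||% 20220809L)),
    "noise-only" =
      simulate_pear_spectra(synthetic_config(grid = c(498, 1020, 4),
                                             informative_bands = numeric(0),
                                             seed = seed %||% 99L)),
    "tiny-10x8" = {
      # Noise-free, RNG-free: band model evaluated on an 8-channel grid at 10
      # equally spaced SCC values; every entry recomputable by hand.
      cfg <- synthetic_config(n_samples = 10, replicates_per_sample = 1,
                              grid = c(500, 850, 50), scatter_sd = 0,
                              drift_sd = 0, noise_sd = 0, seed = 0L)
      wl <- seq(500, 850, by = 50)
      scc <- seq(0.25, 0.65, length.out = 10)
      base <- base_spectra(cfg, wl, scc)
      ids <- sprintf("S%03d", 1:10)
      info <- which(vapply(wl, function(w)
        any(abs(w - cfg$informative_bands) <= 2 * cfg$band_sd), logical(1)))
      list(spectra = spectra_set(wl, base, ids),
           reference = reference_set(ids, scc),
           group_map = stats::setNames(ids, ids),
           truth = structure(list(scc = scc,
                                  gains = matrix(1, 10, 1),
                                  drifts = matrix(0, 10, 1),
                                  base = base, wavelengths = wl,
                                  informative_channels = info, config = cfg),
                             class = "ground_truth"))
    })
}
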