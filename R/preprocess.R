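#' Standard normal variate transform
#'
#' Centres and scales each spectrum to mean 0 and unit sample SD (n-1
#' denominator), removing multiplicative scatter and additive offset
#' differences between samples.
#'
#' @param s A [spectra_set()] with at least 2 channels.
#' @return The transformed [spectra_set()].
#' @export
snv <- function(s) {
  x <- s$reflectance
  if (ncol(x) < 2)
    stop_scc("SNV needs at least 2 channels", class = "scc_invalid")
  mu <- rowMeans(x)
  sdv <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
  if (any(sdv == 0))
    stop_scc("constant spectrum for sample '%s' (row SD is 0)",
             s$sample_ids[which(sdv == 0)[1]], class = "scc_degenerate")
  spectra_set(s$wavelengths, (x - mu) / sdv, s$sample_ids)
}

#' Multiplicative scatter correction
#'
#' Regresses every spectrum on a reference spectrum by ordinary least squares,
#' `x ~ a + b * reference`, and returns `(x - a) / b`; this inverts per-sample
#' gain and offset relative to the reference (by default the mean spectrum of
#' the set).
#'
#' @param s A [spectra_set()].
#' @param reference Optional reference spectrum (numeric, one value per
#'   channel); defaults to the column-wise mean of `s`.
#' @return The corrected [spectra_set()].
#' @export
msc <- function(s, reference = NULL) {
  x <- s$reflectance
  if (ncol(x) < 2)
    stop_scc("MSC needs at least 2 channels", class = "scc_invalid")
  ref <- reference %||% colMeans(x)
  if (length(ref) != ncol(x))
    stop_scc("reference has %d values, expected %d", length(ref), ncol(x),
             class = "scc_invalid")
  rc <- ref - mean(ref)
  den <- sum(rc^2)
  if (den == 0)
    stop_scc("reference spectrum is constant", class = "scc_degenerate")
  b <- as.vector((x - rowMeans(x)) %*% rc) / den
  if (any(abs(b) < 1e-12))
    stop_scc("MSC slope numerically zero for sample '%s'",
             s$sample_ids[which(abs(b) < 1e-12)[1]], class = "scc_degenerate")
  a <- rowMeans(x) - b * mean(ref)
  spectra_set(s$wavelengths, (x - a) / b, s$sample_ids)
}

# Savitzky-Golay weight vector: value at position `at` (1-based within the
# window) of the least-squares polynomial of degree `order` fitted to the
# window samples. Interior windows use at = centre.
sg_weights <- function(len, order, at) {
  z <- seq_len(len) - at
  deg <- min(order, len - 1)
  V <- outer(z, 0:deg, `^`)
  # first row of (V'V)^{-1} V' evaluates the fitted polynomial at z = 0
  as.vector(solve(crossprod(V), t(V))[1, ])
}

#' Savitzky-Golay smoothing
#'
#' Convolves each spectrum with the least-squares polynomial smoothing
#' coefficients for the given window (`frame`) and polynomial `order`. Edges
#' are handled by refitting the polynomial on the truncated window, so the
#' output length equals the input length. S-G reproduces polynomials of
#' degree at most `order` exactly.
#'
#' @param s A [spectra_set()].
#' @param frame Odd window size in 3..9.
#' @param order Polynomial order in 1..7, `order < frame`.
#' @return The smoothed [spectra_set()].
#' @export
savgol <- function(s, frame, order) {
  check_savgol(frame, order)
  K <- ncol(s$reflectance)
  if (frame > K)
    stop_scc("frame (%d) exceeds channel count (%d)", frame, K,
             class = "scc_invalid")
  h <- (frame - 1L) %/% 2L
  w_int <- sg_weights(frame, order, h + 1L)
  out <- s$reflectance
  x <- s$reflectance
  # interior: filter along rows
  if (K >= frame) {
    for (j in seq.int(h + 1L, K - h)) {
      win <- seq.int(j - h, j + h)
      out[, j] <- x[, win, drop = FALSE] %*% w_int
    }
  }
  # truncated edge windows
  for (j in seq_len(h)) {
    win <- seq_len(j + h)
    out[, j] <- x[, win, drop = FALSE] %*% sg_weights(length(win), order, j)
    jr <- K - j + 1L
    win <- seq.int(jr - h, K)
    out[, jr] <- x[, win, drop = FALSE] %*%
      sg_weights(length(win), order, length(win) - j + 1L)
  }
  spectra_set(s$wavelengths, out, s$sample_ids)
}

check_savgol <- function(frame, order) {
  if (frame %% 2 == 0 || frame < 3 || frame > 9)
    stop_scc("frame must be odd and in 3..9, got %s", frame,
             class = "scc_invalid")
  if (order < 1 || order > 7 || order >= frame)
    stop_scc("order must be in 1..7 and < frame, got %s", order,
             class = "scc_invalid")
  invisible(TRUE)
}

#' Preprocessing pipelines
#'
#' A `preprocess_spec` is an ordered list of steps drawn from `"none"`,
#' `"snv"`, `"msc"` and `"savgol:<frame>:<order>"`; [apply_preprocess()]
#' applies them left to right.
#'
#' @param steps Character vector of step descriptors.
#' @return A validated object of class `preprocess_spec`.
#' @examples
#' apply_preprocess(preprocess_spec(c("savgol:7:5", "snv")),
#'                  make_fixture("tiny-10x8")$spectra)
#' @export
preprocess_spec <- function(steps = "none") {
  steps <- as.character(steps)
  if (!length(steps)) stop_scc("empty step list", class = "scc_invalid")
  parsed <- lapply(steps, function(st) {
    if (st %in% c("none", "snv", "msc")) return(list(kind = st))
    if (grepl("^savgol:[0-9]+:[0-9]+$", st)) {
      p <- as.integer(strsplit(st, ":", fixed = TRUE)[[1]][2:3])
      check_savgol(p[1], p[2])
      return(list(kind = "savgol", frame = p[1], order = p[2]))
    }
    stop_scc("unknown preprocessing step '%s'", st, class = "scc_invalid")
  })
  structure(list(steps = steps, parsed = parsed), class = "preprocess_spec")
}

#' @export
format.preprocess_spec <- function(x, ...) paste(x$steps, collapse = "+")

#' @export
print.preprocess_spec <- function(x, ...) {
  cat("<preprocess_spec>", format(x), "\n"); invisible(x)
}

#' @rdname preprocess_spec
#' @param spec A `preprocess_spec`.
#' @param s A [spectra_set()].
#' @export
apply_preprocess <- function(spec, s) {
  stopifnot(inherits(spec, "preprocess_spec"), inherits(s, "spectra_set"))
  for (st in spec$parsed) {
    s <- switch(st$kind,
                none = s,
                snv = snv(s),
                msc = msc(s),
                savgol = savgol(s, st$frame, st$order))
  }
  s
}

#' Savitzky-Golay parameter grid search
#'
#' Scores every admissible (frame, order) combination (odd frames 3, 5, 7, 9;
#' orders 1..7 with order < frame) by the validation-set correlation of a
#' PLSR model fitted on the smoothed calibration spectra, mirroring how the
#' smoothing window is chosen before comparing preprocessing pipelines.
#'
#' @param s A [spectra_set()] (full matrix; the split indexes into it).
#' @param r A [reference_set()] aligned by id.
#' @param split A [spxy_split()] result (or compatible `dataset_split`).
#' @param max_factors PLSR factor cap (default 10).
#' @return A list with `table` (data.frame of frame, order, r_cal, r_val) and
#'   `best` (`c(frame, order)` maximizing validation correlation, ties broken
#'   by calibration correlation then grid order).
#' @export
best_savgol <- function(s, r, split, max_factors = 10) {
  grid <- expand.grid(order = 1:7, frame = c(3, 5, 7, 9))
  grid <- grid[grid$order < grid$frame, c("frame", "order")]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sm <- savgol(s, grid$frame[i], grid$order[i])
    m <- eval_plsr_candidate(sm, r, split, max_factors)
    data.frame(frame = grid$frame[i], order = grid$order[i],
               factors = m$factors, r_cal = m$r_cal, r_val = m$r_val)
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$r_val, -tab$r_cal)
  list(table = tab, best = c(frame = tab$frame[ord[1]],
                             order = tab$order[ord[1]]))
}

# Fit a PLSR model on the calibration rows of a (preprocessed) spectra set and
# score both sets; factor count chosen by venetian-blind CV up to max_factors.
eval_plsr_candidate <- function(s, r, split, max_factors) {
  y <- align_reference(s, r)
  Xc <- s$reflectance[split$calibration_idx, , drop = FALSE]
  yc <- y[split$calibration_idx]
  Xv <- s$reflectance[split$validation_idx, , drop = FALSE]
  yv <- y[split$validation_idx]
  nf <- choose_factors(Xc, yc, max_factors = max_factors)
  fit <- fit_plsr(Xc, yc, nf)
  pc <- predict(fit, Xc)
  pv <- predict(fit, Xv)
  list(factors = nf,
       r_cal = pearson_r(pc, yc), rmse_cal = rmse(pc, yc),
       r_val = pearson_r(pv, yv), rmse_val = rmse(pv, yv))
}

#' Compare preprocessing pipelines by PLSR performance
#'
#' Fits a PLSR model per candidate pipeline (on the calibration rows of the
#' preprocessed full matrix) and tabulates R and RMSE on both sets. The
#' winner is the candidate with the highest validation correlation; ties are
#' broken by lower validation RMSE, then by the smaller calibration/validation
#' correlation gap (a robustness criterion), then by list order.
#'
#' @param s Raw (trimmed, replicate-averaged) [spectra_set()].
#' @param r A [reference_set()].
#' @param split A `dataset_split`.
#' @param candidates List of [preprocess_spec()] objects; `NULL` for the
#'   default slate: none, MSC, SNV, S-G(f*,o*), S-G(f*,o*)+MSC and
#'   S-G(f*,o*)+SNV, with (f*, o*) chosen by [best_savgol()].
#' @param max_factors PLSR factor cap (default 10).
#' @return A list of class `preprocess_comparison` with `table` (one row per
#'   candidate: label, factors, r_cal, rmse_cal, r_val, rmse_val), `chosen`
#'   (row index of the winner) and `specs` (the candidate list).
#' @export
compare_preprocessing <- function(s, r, split, candidates = NULL,
                                  max_factors = 10) {
  if (is.null(candidates)) {
    sg <- best_savgol(s, r, split, max_factors)$best
    sg_step <- sprintf("savgol:%d:%d", sg["frame"], sg["order"])
    candidates <- lapply(
      list("none", "msc", "snv", sg_step, c(sg_step, "msc"), c(sg_step, "snv")),
      preprocess_spec)
  }
  if (!length(candidates))
    stop_scc("empty candidate list", class = "scc_invalid")
  if (!length(split$calibration_idx) || !length(split$validation_idx))
    stop_scc("degenerate split: both sets must be non-empty",
             class = "scc_invalid")
  rows <- lapply(candidates, function(cand) {
    m <- eval_plsr_candidate(apply_preprocess(cand, s), r, split, max_factors)
    data.frame(preprocessing = format(cand), factors = m$factors,
               r_cal = m$r_cal, rmse_cal = m$rmse_cal,
               r_val = m$r_val, rmse_val = m$rmse_val,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$r_val, tab$rmse_val, abs(tab$r_cal - tab$r_val),
               seq_len(nrow(tab)))
  structure(list(table = tab, chosen = ord[1], specs = candidates),
            class = "preprocess_comparison")
}

#' @export
print.preprocess_comparison <- function(x, ...) {
  tab <- x$table
  tab$chosen <- ifelse(seq_len(nrow(tab)) == x$chosen, "*", "")
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}
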