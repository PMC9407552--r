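#' SPXY calibration/validation partitioning
#'
#' Sample-set partitioning based on joint x-y distances (the y-aware
#' extension of Kennard-Stone): pairwise Euclidean distances are computed
#' separately on the spectra and on the response, each normalized by its
#' maximum, and summed; the calibration set is grown deterministically by
#' seeding with the pair at maximal joint distance and repeatedly adding the
#' sample whose minimum distance to the chosen set is largest. The remainder
#' forms the validation set. Extremes of both spaces are pushed into the
#' calibration set by construction, so the calibration y-range covers the
#' validation y-range.
#'
#' Ties are broken towards the lowest position in the canonical (sorted-id)
#' sample order, so the selected id sets do not depend on row order.
#'
#' @param s A [spectra_set()] (use the spectra that will enter modelling).
#' @param r A [reference_set()] aligned by id.
#' @param ratio Length-2 integer vector `c(cal_parts, val_parts)`, e.g.
#'   `c(3, 1)` puts `round(n * 3/4)` samples in calibration.
#' @return An object of class `dataset_split` with integer
#'   `calibration_idx` and `validation_idx` (sorted row indices into `s`),
#'   `selection_order` (the calibration indices in the order the algorithm
#'   chose them, starting with the seeding pair) and the ratio.
#' @examples
#' d <- make_fixture("tiny-10x8")
#' spxy_split(d$spectra, d$reference, c(3, 1))
#' @export
spxy_split <- function(s, r, ratio = c(3, 1)) {
  stopifnot(length(ratio) == 2, all(ratio >= 0), sum(ratio) > 0)
  y <- align_reference(s, r)
  n <- length(y)
  if (n < 4) stop_scc("need at least 4 samples, got %d", n, class = "scc_invalid")
  n_cal <- round(n * ratio[1] / sum(ratio))
  if (n_cal == n) {
    return(structure(list(calibration_idx = seq_len(n),
                          validation_idx = integer(0), ratio = ratio,
                          selection_order = seq_len(n)),
                     class = "dataset_split"))
  }
  ord <- order(s$sample_ids)            # canonical order for tie-breaking
  X <- s$reflectance[ord, , drop = FALSE]
  yo <- y[ord]
  dx <- as.matrix(stats::dist(X))
  dy <- abs(outer(yo, yo, `-`))
  if (max(dx) == 0 && max(dy) == 0)
    stop_scc("all spectra and responses identical: joint distance degenerate",
             class = "scc_degenerate")
  d <- 0
  if (max(dx) > 0) d <- d + dx / max(dx)
  if (max(dy) > 0) d <- d + dy / max(dy)
  if (n_cal < 2)
    stop_scc("ratio %d:%d leaves fewer than 2 calibration samples",
             ratio[1], ratio[2], class = "scc_invalid")
  sel <- logical(n)
  # seed: pair with maximal joint distance; which.max scans column-major so
  # ties resolve to the lexicographically first pair in canonical order
  pair <- sort(arrayInd(which.max(d), dim(d)))
  sel[pair] <- TRUE
  order_sel <- pair
  while (sum(sel) < n_cal) {
    cand <- which(!sel)
    mind <- apply(d[cand, sel, drop = FALSE], 1, min)
    nxt <- cand[which.max(mind)]        # ties -> lowest canonical position
    sel[nxt] <- TRUE
    order_sel <- c(order_sel, nxt)
  }
  structure(list(calibration_idx = sort(ord[sel]),
                 validation_idx = sort(ord[!sel]),
                 ratio = ratio,
                 selection_order = ord[order_sel]),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d calibration / %d validation (ratio %d:%d)\n",
              length(x$calibration_idx), length(x$validation_idx),
              x$ratio[1], x$ratio[2]))
  invisible(x)
}

#' Audit a calibration/validation split
#'
#' Reports whether the calibration y-range covers the validation y-range,
#' per-set descriptive statistics, and the two-group one-way ANOVA of the
#' response. Purely diagnostic: a significant ANOVA difference is reported,
#' never used to gate the pipeline.
#'
#' @param split A `dataset_split`.
#' @param r A [reference_set()] whose order matches the indices of `split`
#'   (i.e. the same `s` used to build the split), or a numeric vector.
#' @return A list with `covered` (logical), `stats_cal`, `stats_val`
#'   ([summarize_reference()] results) and `anova` (`F`, `p`).
#' @export
validate_split <- function(split, r) {
  y <- if (inherits(r, "reference_set")) r$scc else as.numeric(r)
  yc <- y[split$calibration_idx]
  yv <- y[split$validation_idx]
  covered <- min(yc) <= min(yv) && max(yv) <= max(yc)
  list(covered = covered,
       stats_cal = summarize_reference(yc),
       stats_val = summarize_reference(yv),
       anova = anova_two_groups(yc, yv))
}
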