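#' Gravimetric stone cell content
#'
#' Stone cell content is measured gravimetrically: pulp cubes are homogenised,
#' the lignified sclereids are sedimented, filtered and dried, and SCC is the
#' dried stone-cell mass as a percentage of the fresh pulp mass:
#' \deqn{X = \frac{m_{total} - m_{filter}}{m_{pulp}} \times 100\%}
#'
#' @param m_total Mass of filter paper plus dried stone cells (g).
#' @param m_filter Mass of the filter paper alone (g).
#' @param m_pulp Mass of the selected fresh pulp (g).
#' @return An object of class `scc_measurement`.
#' @examples
#' compute_scc(scc_measurement(1.5, 1.0, 100))  # 0.5 percent
#' @export
scc_measurement <- function(m_total, m_filter, m_pulp) {
  stopifnot(is.numeric(m_total), is.numeric(m_filter), is.numeric(m_pulp))
  if (any(c(m_total, m_filter, m_pulp) <= 0))
    stop_scc("all masses must be > 0", class = "scc_invalid")
  if (m_total < m_filter)
    stop_scc("m_total (%g g) < m_filter (%g g): negative stone mass",
             m_total, m_filter, class = "scc_invalid")
  structure(list(m_total = m_total, m_filter = m_filter, m_pulp = m_pulp),
            class = "scc_measurement")
}

#' @rdname scc_measurement
#' @param m An `scc_measurement`.
#' @return `compute_scc()` returns the SCC in percent.
#' @export
compute_scc <- function(m) {
  stopifnot(inherits(m, "scc_measurement"))
  (m$m_total - m$m_filter) / m$m_pulp * 100
}

#' Descriptive statistics of reference SCC values
#'
#' @param r A [reference_set()] or numeric vector of SCC values (percent).
#' @return A list of class `set_statistics` with `n`, `min`, `max`, `mean` and
#'   `sd` (sample SD, n-1 denominator). For a single value the SD is reported
#'   as 0 with a warning.
#' @export
summarize_reference <- function(r) {
  x <- if (inherits(r, "reference_set")) r$scc else as.numeric(r)
  if (length(x) == 0) stop_scc("empty reference set", class = "scc_invalid")
  s <- if (length(x) == 1) {
    warning("single value: SD reported as 0")
    0
  } else stats::sd(x)
  structure(list(n = length(x), min = min(x), max = max(x),
                 mean = mean(x), sd = s),
            class = "set_statistics")
}

#' @export
print.set_statistics <- function(x, ...) {
  cat(sprintf("n = %d  min = %.3f%%  max = %.3f%%  mean = %.3f%%  SD = %.3f%%\n",
              x$n, x$min, x$max, x$mean, x$sd))
  invisible(x)
}

#' One-way ANOVA between two sample sets
#'
#' Checks whether the calibration and validation SCC distributions differ in
#' mean, as done when auditing an SPXY split. For two groups the F statistic
#' is the square of the pooled-variance two-sample t statistic.
#'
#' @param a,b Numeric vectors with at least two values each.
#' @return A list with elements `F` and `p`.
#' @export
anova_two_groups <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop_scc("each group needs at least 2 values", class = "scc_invalid")
  y <- c(a, b)
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  if (stats::var(y) == 0) return(list(F = 0, p = 1))
  fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic), p = unname(fit$p.value))
}
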