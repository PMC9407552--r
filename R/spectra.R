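#' Spectra container
#'
#' A `spectra_set` couples a strictly increasing wavelength grid (nm) with a
#' samples-by-channels reflectance matrix and unique sample identifiers. It is
#' the object that flows through trimming, replicate averaging, preprocessing,
#' partitioning and wavelength selection.
#'
#' @param wavelengths Numeric vector of channel centres in nm, strictly
#'   increasing.
#' @param reflectance Numeric matrix of non-negative reflectance values, one
#'   row per sample, one column per channel.
#' @param sample_ids Character vector of unique sample labels, one per row.
#' @return An object of class `spectra_set` with fields `wavelengths`,
#'   `reflectance` and `sample_ids`.
#' @examples
#' s <- spectra_set(c(500, 600, 700), matrix(1:6 / 10, 2, 3), c("a", "b"))
#' s
#' @export
spectra_set <- function(wavelengths, reflectance, sample_ids) {
  wavelengths <- as.numeric(wavelengths)
  reflectance <- as.matrix(reflectance)
  storage.mode(reflectance) <- "double"
  sample_ids <- as.character(sample_ids)
  if (ncol(reflectance) != length(wavelengths))
    stop_scc("reflectance has %d columns but there are %d wavelengths",
             ncol(reflectance), length(wavelengths), class = "scc_invalid")
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0))
    stop_scc("wavelengths must be strictly increasing", class = "scc_invalid")
  if (nrow(reflectance) != length(sample_ids))
    stop_scc("reflectance has %d rows but there are %d sample ids",
             nrow(reflectance), length(sample_ids), class = "scc_invalid")
  if (anyDuplicated(sample_ids)) {
    dup <- sample_ids[duplicated(sample_ids)][1]
    stop_scc("duplicate sample id '%s'", dup, class = "scc_invalid")
  }
  if (any(!is.finite(reflectance)))
    stop_scc("reflectance contains non-finite values", class = "scc_invalid")
  dimnames(reflectance) <- list(sample_ids, NULL)
  structure(list(wavelengths = wavelengths, reflectance = reflectance,
                 sample_ids = sample_ids),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d samples x %d channels, %.1f-%.1f nm\n",
              nrow(x$reflectance), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$reflectance)

# Row subset keeping the class invariants.
subset_samples <- function(s, idx) {
  spectra_set(s$wavelengths, s$reflectance[idx, , drop = FALSE],
              s$sample_ids[idx])
}

#' Reference SCC values
#'
#' Holds gravimetric stone cell content values (percent by mass) aligned to a
#' [spectra_set()] by sample id. Values must be finite, strictly positive and
#' below 100.
#'
#' @param sample_ids Character vector of unique sample labels.
#' @param scc Numeric vector of SCC values in percent, one per id.
#' @return An object of class `reference_set`.
#' @export
reference_set <- function(sample_ids, scc) {
  sample_ids <- as.character(sample_ids)
  scc <- as.numeric(scc)
  if (length(sample_ids) != length(scc))
    stop_scc("%d ids but %d SCC values", length(sample_ids), length(scc),
             class = "scc_invalid")
  if (anyDuplicated(sample_ids))
    stop_scc("duplicate sample id '%s'", sample_ids[duplicated(sample_ids)][1],
             class = "scc_invalid")
  if (any(!is.finite(scc)) || any(scc <= 0) || any(scc >= 100))
    stop_scc("SCC values must be finite and in (0, 100) percent",
             class = "scc_invalid")
  structure(list(sample_ids = sample_ids, scc = scc), class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d samples, SCC %.3f-%.3f%%\n",
              length(x$scc), min(x$scc), max(x$scc)))
  invisible(x)
}

# Return scc values ordered to match the rows of a spectra_set; errors loudly
# on any id mismatch (alignment is by exact label, never by row order).
align_reference <- function(s, r) {
  pos <- match(s$sample_ids, r$sample_ids)
  if (anyNA(pos))
    stop_scc("sample id '%s' has no reference SCC value",
             s$sample_ids[which(is.na(pos))[1]], class = "scc_align")
  r$scc[pos]
}

#' Read and write spectra tables
#'
#' The canonical dialect is UTF-8 comma-separated text with a `.` decimal
#' separator: the header row is `id` followed by the wavelength values in nm;
#' each subsequent row is a sample id followed by one reflectance value per
#' channel. `write_spectra()` followed by `read_spectra()` round-trips
#' bit-identically (values are written with full precision).
#'
#' @param path Path to a CSV file.
#' @return `read_spectra()` returns a validated [spectra_set()].
#' @export
read_spectra <- function(path) {
  if (!file.exists(path))
    stop_scc("file '%s' does not exist", path, class = "scc_io")
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2)
    stop_scc("'%s': need a header row and at least one sample row", path,
             class = "scc_parse")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (length(header) < 2 || header[1] != "id")
    stop_scc("'%s': malformed header (row 1 must be 'id' then wavelengths)",
             path, class = "scc_parse")
  wl <- suppressWarnings(as.numeric(header[-1]))
  if (anyNA(wl))
    stop_scc("'%s': non-numeric wavelength in header column %d", path,
             which(is.na(wl))[1] + 1L, class = "scc_parse")
  body <- strsplit(lines[-1], ",", fixed = TRUE)
  nfield <- lengths(body)
  if (any(nfield != length(header)))
    stop_scc("'%s': row %d has %d fields, expected %d", path,
             which(nfield != length(header))[1] + 1L,
             nfield[which(nfield != length(header))[1]], length(header),
             class = "scc_parse")
  ids <- vapply(body, `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop_scc("'%s': duplicate sample id '%s'", path,
             ids[duplicated(ids)][1], class = "scc_parse")
  vals <- vapply(body, function(f) suppressWarnings(as.numeric(f[-1])),
                 numeric(length(wl)))
  vals <- t(matrix(vals, nrow = length(wl)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop_scc("'%s': non-numeric cell at row %d, column %d", path,
             bad[1] + 1L, bad[2] + 1L, class = "scc_parse")
  }
  spectra_set(wl, vals, ids)
}

#' @rdname read_spectra
#' @param s A [spectra_set()].
#' @export
write_spectra <- function(s, path) {
  header <- paste(c("id", format(s$wavelengths, digits = 17, trim = TRUE,
                                 scientific = FALSE)), collapse = ",")
  rows <- vapply(seq_along(s$sample_ids), function(i) {
    paste(c(s$sample_ids[i],
            format(s$reflectance[i, ], digits = 17, trim = TRUE)),
          collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read and write reference SCC tables
#'
#' CSV dialect: columns `id,scc_percent`, UTF-8, `.` decimal separator.
#'
#' @param path Path to a CSV file.
#' @return `read_reference()` returns a [reference_set()].
#' @export
read_reference <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "numeric"))
  if (!identical(names(df), c("id", "scc_percent")))
    stop_scc("'%s': expected columns 'id,scc_percent'", path,
             class = "scc_parse")
  reference_set(df$id, df$scc_percent)
}

#' @rdname read_reference
#' @param r A [reference_set()].
#' @export
write_reference <- function(r, path) {
  df <- data.frame(id = r$sample_ids,
                   scc_percent = format(r$scc, digits = 17, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Trim spectra to an effective wavelength range
#'
#' Noisy channels at both ends of the acquired grid carry no usable signal;
#' this keeps exactly the channels whose centres lie in the closed interval
#' `[low_nm, high_nm]`, preserving order. For the pear SCC application the
#' effective window is 498-1020 nm.
#'
#' @param s A [spectra_set()].
#' @param low_nm,high_nm Bounds of the retained window in nm (`low_nm <
#'   high_nm`), both inclusive.
#' @return A [spectra_set()] restricted to the retained channels.
#' @export
trim_wavelengths <- function(s, low_nm, high_nm) {
  stopifnot(is.numeric(low_nm), is.numeric(high_nm))
  if (low_nm >= high_nm)
    stop_scc("low_nm (%g) must be < high_nm (%g)", low_nm, high_nm,
             class = "scc_invalid")
  keep <- s$wavelengths >= low_nm & s$wavelengths <= high_nm
  if (!any(keep))
    stop_scc("no channel lies in [%g, %g] nm", low_nm, high_nm,
             class = "scc_invalid")
  spectra_set(s$wavelengths[keep], s$reflectance[, keep, drop = FALSE],
              s$sample_ids)
}

#' Average replicate spectra
#'
#' Acquisition records several spectra per fruit (three points 120 degrees
#' apart around the equator); the per-sample spectrum is their arithmetic
#' channel-wise mean.
#'
#' @param s A [spectra_set()] of replicate rows.
#' @param group_map Named character vector mapping each replicate id (names)
#'   to its sample id (values).
#' @return A [spectra_set()] with one row per sample, ordered by first
#'   appearance of each sample id in `s`.
#' @export
average_replicates <- function(s, group_map) {
  if (is.null(names(group_map)))
    stop_scc("group_map must be named by replicate id", class = "scc_invalid")
  grp <- group_map[s$sample_ids]
  if (anyNA(grp))
    stop_scc("replicate id '%s' missing from group_map",
             s$sample_ids[which(is.na(grp))[1]], class = "scc_invalid")
  groups <- unique(unname(grp))
  if (length(setdiff(unname(group_map), groups)))
    stop_scc("group '%s' has zero member rows",
             setdiff(unname(group_map), groups)[1], class = "scc_invalid")
  out <- matrix(0, length(groups), length(s$wavelengths))
  for (g in seq_along(groups)) {
    rows <- which(grp == groups[g])
    out[g, ] <- colMeans(s$reflectance[rows, , drop = FALSE])
  }
  spectra_set(s$wavelengths, out, groups)
}
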