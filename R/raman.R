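#' Read a Raman spectrum from two-column text
#'
#' Accepts whitespace- or comma-separated `shift, intensity` pairs; a header
#' line is detected and skipped. Shifts must be strictly increasing.
#'
#' @param path File path.
#' @return A `raman_spectrum` tibble: `shift` (cm^-1), `intensity`.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path),
                                class = "spicoda_format_error")
  first <- readLines(path, n = 1)
  has_header <- is.na(suppressWarnings(as.numeric(
    strsplit(trimws(first), "[,\\s]+")[[1]][1])))
  sep <- if (grepl(",", first)) "," else ""
  df <- utils::read.table(path, header = has_header, sep = sep,
                          comment.char = "#")
  names(df)[1:2] <- c("shift", "intensity")
  as_spectrum(df)
}

#' Coerce a data frame to a Raman spectrum
#' @param df Data frame with numeric `shift` and `intensity` columns.
#' @return A `raman_spectrum` tibble.
#' @export
as_spectrum <- function(df) {
  stopifnot(all(c("shift", "intensity") %in% names(df)))
  if (nrow(df) == 0) abort("Empty spectrum.", class = "spicoda_validation_error")
  if (any(diff(df$shift) <= 0)) {
    abort("shift grid must be strictly increasing.",
          class = "spicoda_validation_error")
  }
  structure(as_tibble(df[, c("shift", "intensity")]),
            class = c("raman_spectrum", class(tibble())))
}

.roll_stat <- function(v, half_window, fun) {
  n <- length(v)
  k <- 2L * half_window + 1L
  if (k > n) abort("Window exceeds spectrum length.",
                   class = "spicoda_validation_error")
  pad <- c(rep(v[1], half_window), v, rep(v[n], half_window))
  vapply(seq_len(n), function(i) fun(pad[i:(i + k - 1L)]), numeric(1))
}

#' Subtract an instrumental baseline
#'
#' Estimates the baseline as a morphological opening — a rolling minimum
#' (erosion) followed by a rolling maximum (dilation) over the same window —
#' smoothed by a moving average, and subtracts it. The opening removes
#' features narrower than the window while following slow trends without the
#' downward slope bias of a plain rolling minimum; with a half-window much
#' wider than the peak widths, peak heights are preserved and applying the
#' correction twice changes essentially nothing.
#'
#' @param s A `raman_spectrum`.
#' @param half_window Half-width of the rolling window in grid points
#'   (window = `2 * half_window + 1`).
#' @return A new baseline-corrected `raman_spectrum`; the input is
#'   unmodified. The estimated baseline is attached as attribute
#'   `"baseline"`.
#' @export
subtract_baseline <- function(s, half_window = 50) {
  stopifnot(inherits(s, "raman_spectrum"))
  if (half_window < 1) abort("half_window must be >= 1.",
                             class = "spicoda_validation_error")
  env <- .roll_stat(.roll_stat(s$intensity, half_window, min),
                    half_window, max)
  base <- .roll_stat(env, half_window, mean)
  out <- as_spectrum(tibble(shift = s$shift, intensity = s$intensity - base))
  attr(out, "baseline") <- base
  out
}

#' Detect peaks by prominence relative to the noise floor
#'
#' Finds local maxima whose topographic prominence exceeds
#' `min_prominence_snr` times the noise estimate — the robust scale of the
#' first differences, `mad(diff(y))`. Because differencing inflates the
#' point noise by `sqrt(2)`, the default threshold of 5 difference-scales
#' sits near 7 point-noise SDs, above the extreme-value range of pure noise
#' on grids of a few thousand points. Peak positions are refined by 3-point
#' parabolic interpolation on the grid. Run on a baseline-corrected
#' spectrum.
#'
#' @param s A `raman_spectrum`.
#' @param min_prominence_snr Minimum prominence in noise units.
#' @return A `peak_set`: tibble `position`, `height`, `prominence`, with the
#'   `noise_estimate` attached as an attribute.
#' @export
detect_peaks <- function(s, min_prominence_snr = 5) {
  stopifnot(inherits(s, "raman_spectrum"))
  y <- s$intensity; x <- s$shift; n <- length(y)
  if (n < 3) abort("Spectrum too short for peak detection.",
                   class = "spicoda_validation_error")
  noise <- stats::mad(diff(y))
  if (noise == 0) noise <- .Machine$double.eps
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  rows <- lapply(cand, function(i) {
    # prominence: descend left and right until a higher point (or the edge);
    # the key saddle is the higher of the two interval minima
    left <- if (any(y[1:(i - 1)] > y[i])) {
      j <- max(which(y[1:(i - 1)] > y[i]))
      min(y[j:i])
    } else min(y[1:i])
    right <- if (any(y[(i + 1):n] > y[i])) {
      j <- i + min(which(y[(i + 1):n] > y[i]))
      min(y[i:j])
    } else min(y[i:n])
    prom <- y[i] - max(left, right)
    if (prom < min_prominence_snr * noise) return(NULL)
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    dx <- if (denom < 0) 0.5 * (y[i - 1] - y[i + 1]) / denom else 0
    dx <- max(min(dx, 0.5), -0.5)
    step <- mean(diff(x[max(1, i - 1):min(n, i + 1)]))
    tibble(position = x[i] + dx * step, height = y[i], prominence = prom)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) out <- tibble(position = numeric(), height = numeric(),
                                    prominence = numeric())
  structure(out, noise_estimate = noise,
            class = c("peak_set", class(tibble())))
}

#' Characteristic Raman windows of the calcite family
#'
#' The three diagnostic bands of biogenic calcite / magnesian calcite: the
#' lattice mode near 281-283 cm^-1, the nu4 in-plane bend at 707-720 cm^-1,
#' and the nu1 symmetric carbonate stretch at 1087-1088 cm^-1.
#'
#' @return Tibble: `window`, `lo`, `hi` (cm^-1).
#' @export
calcite_windows <- function() {
  tibble(window = c("nu_lattice", "nu4", "nu1"),
         lo = c(281, 707, 1087),
         hi = c(283, 720, 1088))
}

#' Classify a peak set against the calcite-family windows
#'
#' A window is matched when any detected peak lies within it after widening
#' by `tolerance` on both sides. The call is `calcite_family` iff the nu1
#' carbonate-stretch window is matched; `partial = TRUE` flags spectra where
#' nu1 is present but the lattice or nu4 band is not expressed. Calcite and
#' magnesian calcite are deliberately not distinguished.
#'
#' @param peaks A `peak_set` from [detect_peaks()].
#' @param tolerance Window widening in cm^-1.
#' @return A `mineral_call`: list with `label` (`"calcite_family"` or
#'   `"unidentified"`), `windows_matched` (character), `partial` (flag),
#'   `peaks`.
#' @export
match_mineral <- function(peaks, tolerance = 4) {
  stopifnot(inherits(peaks, "peak_set") || is.data.frame(peaks))
  w <- calcite_windows()
  matched <- vapply(seq_len(nrow(w)), function(i) {
    any(peaks$position >= w$lo[i] - tolerance &
        peaks$position <= w$hi[i] + tolerance)
  }, logical(1))
  names(matched) <- w$window
  label <- if (matched[["nu1"]]) "calcite_family" else "unidentified"
  structure(list(label = label,
                 windows_matched = w$window[matched],
                 partial = matched[["nu1"]] && !all(matched),
                 peaks = peaks),
            class = "mineral_call")
}

#' @export
print.mineral_call <- function(x, ...) {
  cat("Mineral call:", x$label,
      if (x$partial) "(partial: nu1 only or missing companion bands)" else "",
      "\n  windows matched:",
      if (length(x$windows_matched)) paste(x$windows_matched, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Write a spectrum as two-column text
#' @param s A `raman_spectrum`.
#' @param path Output path.
#' @return `s`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "raman_spectrum"))
  utils::write.table(as.data.frame(s), path, row.names = FALSE,
                     quote = FALSE, sep = "\t")
  invisible(s)
}
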