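# MALDI-TOF spectrum container, text readers/writers, baseline correction,
# smoothing and S/N-thresholded peak picking.
#
# The preprocessing contract is explicit so results are reproducible:
# rolling-minimum baseline (window a fraction of the m/z span) with linear
# interpolation, Savitzky-Golay smoothing, and MAD-based local noise.

#' MALDI spectrum
#'
#' @param mz Ascending m/z values (Da).
#' @param intensity Nonnegative finite intensities, same length.
#' @param sample_id Sample label.
#' @param centroided `NULL` to auto-detect from point density (median m/z
#'   step > 0.15 Da is treated as a centroided peak list), else logical.
#' @param metadata Optional named list.
#' @return Object of class `maldi_spectrum`.
#' @export
maldi_spectrum <- function(mz, intensity, sample_id = "",
                           centroided = NULL, metadata = list()) {
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be finite and nonnegative")
  if (is.unsorted(mz, strictly = TRUE)) {
    if (anyDuplicated(mz)) stop("m/z values must be distinct")
    warning("m/z not ascending; sorting")
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
  }
  if (is.null(centroided))
    centroided <- length(mz) < 2L ||
      stats::median(diff(mz)) > 0.15
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 sample_id = sample_id, centroided = isTRUE(centroided),
                 metadata = metadata),
            class = "maldi_spectrum")
}

#' @export
print.maldi_spectrum <- function(x, ...) {
  cat(sprintf("<maldi_spectrum> %s: %d points, m/z %.1f..%.1f%s\n",
              if (nzchar(x$sample_id)) x$sample_id else "(unnamed)",
              length(x$mz),
              if (length(x$mz)) min(x$mz) else NA,
              if (length(x$mz)) max(x$mz) else NA,
              if (x$centroided) " (centroided)" else ""))
  invisible(x)
}

#' @export
plot.maldi_spectrum <- function(x, ...) {
  plot(x$mz, x$intensity, type = if (x$centroided) "h" else "l",
       xlab = "m/z", ylab = "intensity", main = x$sample_id, ...)
  invisible(x)
}

#' Preprocessing and peak-picking parameters
#'
#' @param baseline_frac Rolling-minimum baseline window as a fraction of the
#'   m/z span (default 0.05).
#' @param smooth_points Savitzky-Golay window (odd point count, default 7).
#' @param smooth_order Savitzky-Golay polynomial order (default 2).
#' @param noise_window Width (Da) of the sliding window for MAD noise
#'   estimation (default 100).
#' @param snr Signal-to-noise threshold for peak acceptance (default 3.0;
#'   the conventional working range for collagen fingerprints is 3.0-5.0).
#' @return List of class `preprocess_params`.
#' @export
preprocess_params <- function(baseline_frac = 0.05, smooth_points = 7L,
                              smooth_order = 2L, noise_window = 100,
                              snr = 3.0) {
  if (baseline_frac <= 0 || noise_window <= 0 || snr <= 0)
    stop("windows and snr threshold must be positive")
  if (smooth_points %% 2L == 0L) stop("smooth_points must be odd")
  if (smooth_order >= smooth_points) stop("smooth_order must be < smooth_points")
  structure(list(baseline_frac = baseline_frac,
                 smooth_points = as.integer(smooth_points),
                 smooth_order = as.integer(smooth_order),
                 noise_window = noise_window, snr = snr),
            class = "preprocess_params")
}

#' Read a spectrum from disk
#'
#' The primary dialect is a two-column (m/z, intensity) text peak list,
#' whitespace- or comma-separated, with an optional header line.  `"mzml"`
#' reads the first scan of an mzML file via \pkg{mzR} (if installed).
#'
#' @param path File path.
#' @param dialect `"peaklist"` or `"mzml"`.
#' @param sample_id Sample label (default: file name without extension).
#' @return A [maldi_spectrum()].
#' @export
read_spectrum <- function(path, dialect = c("peaklist", "mzml"),
                          sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  if (dialect == "mzml") {
    if (!requireNamespace("mzR", quietly = TRUE))
      stop("reading mzML requires the 'mzR' package")
    h <- mzR::openMSfile(path)
    on.exit(mzR::close(h))
    pk <- mzR::peaks(h, 1L)
    return(maldi_spectrum(pk[, 1L], pk[, 2L], sample_id = sample_id,
                          metadata = list(source = path)))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && !grepl("^\\s*[0-9.+-]", lines[1L]))
    lines <- lines[-1L]  # header line
  if (!length(lines))
    return(maldi_spectrum(numeric(), numeric(), sample_id = sample_id))
  fields <- strsplit(trimws(lines), "[,;\t ]+")
  mz <- as.numeric(vapply(fields, `[[`, "", 1L))
  it <- as.numeric(vapply(fields, `[[`, "", 2L))
  if (anyNA(mz) || anyNA(it))
    stop("unparseable line in ", path, ": '",
         lines[which(is.na(mz) | is.na(it))[1L]], "'")
  if (any(it < 0)) stop("negative intensity in ", path)
  maldi_spectrum(mz, it, sample_id = sample_id,
                 metadata = list(source = path))
}

#' Write a spectrum as a two-column text peak list
#'
#' @param s A [maldi_spectrum()].
#' @param path Output path.
#' @param digits Significant digits (default 8).
#' @export
write_spectrum <- function(s, path, digits = 8) {
  stopifnot(inherits(s, "maldi_spectrum"))
  writeLines(c("m/z intensity",
               paste(signif(s$mz, digits), signif(s$intensity, digits))),
             path)
  invisible(path)
}

# Rolling-minimum baseline: window minima anchored at window centres,
# linearly interpolated.  Windows are laid out from min(mz), so the
# estimate is invariant under a global m/z shift.
.baseline <- function(mz, intensity, frac) {
  span <- diff(range(mz))
  w <- frac * span
  if (w <= 0) return(rep(min(intensity), length(mz)))
  bin <- .mz_bins(mz, w)
  mins <- tapply(intensity, bin, min)
  ctrs <- tapply(mz, bin, function(z) mean(range(z)))
  if (length(mins) < 2L) return(rep(min(intensity), length(mz)))
  stats::approx(ctrs, mins, xout = mz, rule = 2)$y
}

#' Baseline-correct and smooth a spectrum
#'
#' Subtracts a rolling-minimum baseline (linear interpolation between
#' window minima, result floored at zero), then applies a Savitzky-Golay
#' moving-polynomial smoother.  Centroided input is returned unchanged:
#' centroid lists carry no baseline.
#'
#' @param s A [maldi_spectrum()].
#' @param params A [preprocess_params()].
#' @return The preprocessed [maldi_spectrum()].
#' @export
preprocess_spectrum <- function(s, params = preprocess_params()) {
  stopifnot(inherits(s, "maldi_spectrum"),
            inherits(params, "preprocess_params"))
  if (length(s$mz) == 0L) stop("empty spectrum")
  if (s$centroided) return(s)
  if (params$smooth_points > length(s$mz))
    stop("smoothing window larger than spectrum")
  y <- s$intensity - .baseline(s$mz, s$intensity, params$baseline_frac)
  y <- pmax(y, 0)
  y <- signal::sgolayfilt(y, p = params$smooth_order,
                          n = params$smooth_points)
  s$intensity <- pmax(y, 0)
  s$metadata$preprocessed <- TRUE
  s
}

# Windows of `width` Da laid out from min(mz); the trailing partial window
# is merged into the last full one so no block is starved of points.
# Anchoring at min(mz) keeps the layout invariant under a global m/z shift.
.mz_bins <- function(mz, width) {
  bin <- floor((mz - min(mz)) / width) + 1L
  nb <- max(1L, floor(diff(range(mz)) / width))
  pmin(bin, nb)
}

# Blockwise robust noise level: 1.4826 * MAD of (intensity - block median)
# in windows of `window` Da laid out from min(mz); interpolated to each m/z.
.noise_level <- function(mz, intensity, window) {
  bin <- .mz_bins(mz, window)
  med <- tapply(intensity, bin, stats::median)
  noi <- tapply(intensity, bin, function(v) stats::mad(v))
  ctr <- tapply(mz, bin, function(z) mean(range(z)))
  eps <- max(1e-12, 1e-9 * max(intensity))
  noi <- pmax(as.numeric(noi), eps)
  if (length(ctr) < 2L)
    return(list(noise = rep(noi[1L], length(mz)),
                center = rep(as.numeric(med)[1L], length(mz))))
  list(noise = stats::approx(ctr, noi, xout = mz, rule = 2)$y,
       center = stats::approx(ctr, as.numeric(med), xout = mz, rule = 2)$y)
}

# Parabolic apex refinement.  A Gaussian is an exact parabola in log space,
# so when all three intensities are positive the fit is done on log
# intensities; otherwise on raw intensities.
.refine_apex <- function(x, y) {
  use_log <- all(y > 0)
  v <- if (use_log) log(y) else y
  denom <- v[1L] - 2 * v[2L] + v[3L]
  if (denom >= 0) return(x[2L])  # not concave; keep grid apex
  delta <- 0.5 * (v[1L] - v[3L]) / denom
  if (abs(delta) > 1) return(x[2L])
  x[2L] + delta * (x[3L] - x[2L])
}

#' Pick peaks at a signal-to-noise threshold
#'
#' Local intensity maxima whose S/N exceeds the threshold, where S/N is
#' (intensity - local median) / local noise and local noise is the scaled
#' median absolute deviation in a sliding window (`noise_window` Da).  Apex
#' m/z is refined by three-point parabolic interpolation (log-parabola when
#' possible, exact for Gaussian profiles).  Centroided spectra skip the
#' local-maximum and refinement steps.
#'
#' @param s A preprocessed [maldi_spectrum()].
#' @param params A [preprocess_params()]; `params$snr` is the threshold.
#' @return `data.frame` with columns `mz`, `intensity`, `snr`, ascending in
#'   m/z.
#' @export
pick_peaks <- function(s, params = preprocess_params()) {
  stopifnot(inherits(s, "maldi_spectrum"),
            inherits(params, "preprocess_params"))
  empty <- data.frame(mz = numeric(), intensity = numeric(),
                      snr = numeric())
  n <- length(s$mz)
  if (n == 0L) return(empty)
  nl <- .noise_level(s$mz, s$intensity, params$noise_window)
  snr_all <- (s$intensity - nl$center) / nl$noise
  if (s$centroided) {
    keep <- which(snr_all >= params$snr & s$intensity > 0)
    return(data.frame(mz = s$mz[keep], intensity = s$intensity[keep],
                      snr = snr_all[keep]))
  }
  if (n < 3L) return(empty)
  y <- s$intensity
  cand <- which(y[-c(1L, n)] > y[-c(n - 1L, n)] &
                y[-c(1L, n)] >= y[-c(1L, 2L)] &
                y[-c(1L, n)] > 0) + 1L
  cand <- cand[snr_all[cand] >= params$snr]
  if (!length(cand)) return(empty)
  apex <- vapply(cand, function(i)
    .refine_apex(s$mz[(i - 1L):(i + 1L)], y[(i - 1L):(i + 1L)]),
    numeric(1))
  out <- data.frame(mz = apex, intensity = y[cand], snr = snr_all[cand])
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}
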