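#' Mass spectrum container
#'
#' Either a dense grid (strictly increasing m/z axis with intensities) or a
#' peak list (discrete peaks). Intensities must be non-negative.
#'
#' @param mz m/z axis or peak positions.
#' @param intensity intensities.
#' @param kind `"dense"` or `"peaks"`.
#' @return A `mass_spectrum` tibble with columns `mz`, `intensity`.
#' @export
mass_spectrum <- function(mz, intensity, kind = c("dense", "peaks")) {
  kind <- match.arg(kind)
  stopifnot(length(mz) == length(intensity))
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (kind == "dense" && any(diff(mz) <= 0)) {
    stop("dense m/z axis must be strictly increasing")
  }
  structure(tibble::tibble(mz = mz, intensity = intensity),
            class = c("mass_spectrum", class(tibble::tibble())),
            kind = kind)
}

#' Time-of-flight calibration
#'
#' Fits the linear-TOF law `t = t0 + k * sqrt(m/z)` to reference peaks:
#' exactly for two references, least squares for more. Calibrations in this
#' kind of experiment are anchored on two well-identified fragment peaks
#' (here typically m/z 45, COOH+, and m/z 64, SS+).
#'
#' @param refs tibble/data.frame with columns `time` and `mz` (>= 2 rows,
#'   distinct positive m/z).
#' @return Object of class `tof_calibration` with fields `t0`, `k`.
#' @export
#' @examples
#' tof_calibrate(data.frame(time = 10 + 2 * sqrt(c(45, 64)), mz = c(45, 64)))
tof_calibrate <- function(refs) {
  refs <- tibble::as_tibble(refs)
  stopifnot(all(c("time", "mz") %in% names(refs)))
  if (nrow(refs) < 2) stop("need at least two reference peaks")
  if (any(refs$mz <= 0)) stop("reference m/z must be positive")
  if (anyDuplicated(refs$mz)) stop("duplicate reference m/z")
  fit <- stats::lm(time ~ sqrt(mz), data = refs)
  k <- unname(stats::coef(fit)[2])
  if (!is.finite(k) || k <= 0) stop("calibration slope must be positive")
  structure(list(t0 = unname(stats::coef(fit)[1]), k = k, fit = fit,
                 n_refs = nrow(refs)),
            class = "tof_calibration")
}

#' @export
print.tof_calibration <- function(x, ...) {
  cat("<tof_calibration> t = t0 + k*sqrt(m/z); t0 =", format(x$t0),
      ", k =", format(x$k), "(", x$n_refs, "refs )\n")
  invisible(x)
}

#' Convert flight times to m/z
#'
#' Inverse of the calibration model: `m/z = ((t - t0) / k)^2`.
#'
#' @param times flight times (same units as the calibration).
#' @param calib a [tof_calibrate()] result.
#' @return m/z values.
#' @export
tof_to_mz <- function(times, calib) {
  stopifnot(inherits(calib, "tof_calibration"))
  if (any(times < calib$t0)) stop("times before the calibration offset t0")
  ((times - calib$t0) / calib$k)^2
}

#' Convert m/z to flight times (forward calibration model)
#'
#' @param mz m/z values (non-negative).
#' @param calib a [tof_calibrate()] result.
#' @return Flight times.
#' @export
mz_to_tof <- function(mz, calib) {
  stopifnot(inherits(calib, "tof_calibration"))
  if (any(mz < 0)) stop("m/z must be non-negative")
  calib$t0 + calib$k * sqrt(mz)
}

#' Integrate a peak window of a mass spectrum
#'
#' Dense spectra are integrated with the trapezoidal rule over the window
#' (with linear interpolation at the window edges); peak lists sum the peak
#' intensities inside the window.
#'
#' @param spectrum a [mass_spectrum()].
#' @param lo,hi window bounds (m/z), `lo < hi`.
#' @return The integrated intensity (dense: area; peaks: summed intensity).
#' @export
integrate_peak <- function(spectrum, lo, hi) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  if (lo >= hi) stop("inverted window: lo must be < hi")
  kind <- attr(spectrum, "kind")
  if (kind == "peaks") {
    return(sum(spectrum$intensity[spectrum$mz >= lo & spectrum$mz <= hi]))
  }
  x <- spectrum$mz; y <- spectrum$intensity
  if (hi <= x[1] || lo >= x[length(x)]) return(0)
  lo <- max(lo, x[1]); hi <- min(hi, x[length(x)])
  inside <- x > lo & x < hi
  xs <- c(lo, x[inside], hi)
  ys <- c(stats::approx(x, y, lo)$y, y[inside], stats::approx(x, y, hi)$y)
  pracma::trapz(xs, ys)
}

#' Partial ion yields over a photon-energy scan
#'
#' For each photon energy the per-fragment peak windows are integrated in
#' that energy's mass spectrum, building the partial ion yield (PIY) curves.
#' The energy grid must be strictly increasing with spacing inside the
#' configured bounds (the scan protocol uses 40-70 meV steps).
#'
#' @param spectra tibble with columns `energy`, `mz`, `intensity`: one dense
#'   mass spectrum per photon energy (all sharing the same calibration).
#' @param windows tibble with columns `fragment`, `lo`, `hi`;
#'   windows must not overlap.
#' @param spacing_ev length-2 numeric: allowed grid-spacing range (eV);
#'   `NULL` skips the check.
#' @param kind passed to [mass_spectrum()] (`"dense"` default).
#' @return An `ion_yield_scan`: long tibble `energy`, `fragment`, `yield`.
#' @export
piy_scan <- function(spectra, windows, spacing_ev = c(0.040, 0.070),
                     kind = "dense") {
  spectra <- tibble::as_tibble(spectra)
  windows <- tibble::as_tibble(windows)
  stopifnot(all(c("energy", "mz", "intensity") %in% names(spectra)),
            all(c("fragment", "lo", "hi") %in% names(windows)))
  w <- windows[order(windows$lo), ]
  if (any(w$lo >= w$hi)) stop("inverted fragment window")
  if (nrow(w) > 1 && any(w$lo[-1] < w$hi[-nrow(w)])) {
    stop("fragment windows overlap")
  }
  grid <- sort(unique(spectra$energy))
  if (!is.null(spacing_ev) && length(grid) > 1) {
    dg <- diff(grid)
    if (any(dg < spacing_ev[1] - 1e-12 | dg > spacing_ev[2] + 1e-12)) {
      stop("photon-energy grid spacing outside [",
           spacing_ev[1], ", ", spacing_ev[2], "] eV")
    }
  }
  out <- purrr::map_dfr(grid, function(e) {
    sp <- spectra[spectra$energy == e, ]
    ms <- mass_spectrum(sp$mz, sp$intensity, kind = kind)
    tibble::tibble(
      energy = e,
      fragment = windows$fragment,
      yield = purrr::map2_dbl(windows$lo, windows$hi,
                              ~ integrate_peak(ms, .x, .y))
    )
  })
  structure(out, class = c("ion_yield_scan", class(out)))
}

#' Summed ion yield
#'
#' Elementwise sum of the partial ion yields at every grid energy; the SIY
#' approximates the absorption (NEXAFS) spectrum when every significant
#' cationic fragment is included.
#'
#' @param scan an [piy_scan()] result.
#' @return Tibble `energy`, `yield`.
#' @export
siy <- function(scan) {
  stopifnot(inherits(scan, "ion_yield_scan"))
  out <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(scan), .data$energy),
                          yield = sum(.data$yield), .groups = "drop")
  dplyr::arrange(out, .data$energy)
}

#' Gaussian broadening of a stick spectrum
#'
#' Convolves computed transitions (energy, strength) with a unit-area
#' Gaussian of the given full width at half-maximum, after shifting every
#' stick by `shift` (the rigid energy shift used to align a calculated
#' spectrum with experiment; the defaults 0.7 eV / 7.23 eV are match
#' parameters, not constants). The integrated area of the result equals the
#' summed stick strength up to quadrature error.
#'
#' @param sticks tibble with columns `energy` (eV) and `strength` (>= 0).
#' @param fwhm Gaussian full width at half-maximum (eV, > 0).
#' @param shift rigid shift applied to every stick (eV).
#' @param grid energy grid (eV); default covers the shifted sticks +- 5 fwhm
#'   at `resolution` spacing.
#' @param resolution default grid spacing (eV), `fwhm / 20`.
#' @return Tibble `energy`, `intensity`.
#' @export
#' @examples
#' broaden_sticks(data.frame(energy = 165, strength = 1))
broaden_sticks <- function(sticks, fwhm = 0.7, shift = 7.23, grid = NULL,
                           resolution = fwhm / 20) {
  sticks <- tibble::as_tibble(sticks)
  stopifnot(all(c("energy", "strength") %in% names(sticks)))
  if (fwhm <= 0) stop("fwhm must be positive")
  if (any(sticks$strength < 0)) stop("stick strengths must be non-negative")
  if (any(!is.finite(sticks$energy))) stop("stick energies must be finite")
  e0 <- sticks$energy + shift
  if (is.null(grid)) {
    grid <- seq(min(e0) - 5 * fwhm, max(e0) + 5 * fwhm, by = resolution)
  }
  sigma <- fwhm / sqrt(8 * log(2))
  intensity <- rowSums(vapply(seq_along(e0), function(k) {
    sticks$strength[k] * stats::dnorm(grid, e0[k], sigma)
  }, numeric(length(grid))))
  tibble::tibble(energy = grid, intensity = intensity)
}

#' Synthesize a dense Gaussian-peak mass spectrum
#'
#' Utility for building test and demonstration spectra: unit-resolution
#' Gaussian peaks of known area at given m/z positions on a dense grid.
#'
#' @param peaks tibble with columns `mz` and `area`.
#' @param sigma peak width (m/z units).
#' @param mz_range axis range; default covers peaks +- 5 sigma.
#' @param step axis spacing.
#' @return A dense [mass_spectrum()].
#' @export
synth_mass_spectrum <- function(peaks, sigma = 0.08, mz_range = NULL,
                                step = 0.01) {
  peaks <- tibble::as_tibble(peaks)
  if (is.null(mz_range)) {
    mz_range <- range(peaks$mz) + c(-5, 5) * sigma
  }
  axis <- seq(mz_range[1], mz_range[2], by = step)
  intensity <- rowSums(vapply(seq_len(nrow(peaks)), function(k) {
    peaks$area[k] * stats::dnorm(axis, peaks$mz[k], sigma)
  }, numeric(length(axis))))
  mass_spectrum(axis, intensity, kind = "dense")
}
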