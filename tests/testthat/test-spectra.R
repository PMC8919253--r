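test_that("two-point TOF calibration recovers the injected parameters exactly", {
  refs <- tibble::tibble(mz = c(45, 64), time = 10 + 2 * sqrt(c(45, 64)))
  cal <- tof_calibrate(refs)
  expect_equal(cal$t0, 10)
  expect_equal(cal$k, 2)

  # three collinear references give the identical fit
  refs3 <- tibble::tibble(mz = c(45, 64, 241.3),
                          time = 10 + 2 * sqrt(c(45, 64, 241.3)))
  cal3 <- tof_calibrate(refs3)
  expect_equal(cal3$t0, 10, tolerance = 1e-10)
  expect_equal(cal3$k, 2, tolerance = 1e-10)

  expect_error(tof_calibrate(tibble::tibble(mz = c(45, 45), time = c(1, 2))),
               "duplicate")
  expect_error(tof_calibrate(tibble::tibble(mz = 45, time = 1)), "two reference")
  expect_error(tof_calibrate(tibble::tibble(mz = c(-1, 4), time = c(1, 2))),
               "positive")
})

test_that("time <-> m/z conversion round-trips through the square-root law", {
  cal <- tof_calibrate(tibble::tibble(mz = c(45, 64),
                                      time = 3 + 1.7 * sqrt(c(45, 64))))
  for (m in c(45, 64, 74, 241.3)) {
    expect_equal(tof_to_mz(mz_to_tof(m, cal), cal), m, tolerance = 1e-12)
  }
  expect_equal(tof_to_mz(cal$t0, cal), 0)               # boundary
  expect_equal(tof_to_mz(cal$t0 + cal$k * 8, cal), 64)  # 8^2
  expect_error(tof_to_mz(cal$t0 - 1, cal), "before")
})

test_that("peak integration handles dense grids, peak lists and windows", {
  # unit-intensity rectangle of width 1 fully inside the window
  ax <- seq(40, 50, by = 0.01)
  rect <- mass_spectrum(ax, as.numeric(ax >= 44 & ax <= 45), kind = "dense")
  expect_equal(integrate_peak(rect, 43, 46), 1.0, tolerance = 0.02)
  # empty window
  expect_equal(integrate_peak(rect, 47, 49), 0)
  expect_error(integrate_peak(rect, 46, 43), "inverted")

  # narrow Gaussian of known area
  gs <- synth_mass_spectrum(tibble::tibble(mz = 45, area = 2.5),
                            sigma = 0.08, step = 0.005)
  expect_equal(integrate_peak(gs, 44.5, 45.5), 2.5, tolerance = 0.001)

  pk <- mass_spectrum(c(44.9, 45.1, 64), c(1, 2, 5), kind = "peaks")
  expect_equal(integrate_peak(pk, 44.5, 45.5), 3)
})

test_that("PIY curves recover injected per-fragment areas and SIY is their sum", {
  energies <- seq(160, 161, by = 0.05)  # 50 meV steps pass validation
  area45 <- 1 + (energies - 160)        # injected photon-energy dependence
  area64 <- 2 * sin(energies - 160)^2 + 0.1
  spectra <- purrr::map_dfr(seq_along(energies), function(k) {
    sp <- synth_mass_spectrum(
      tibble::tibble(mz = c(45, 64), area = c(area45[k], area64[k])),
      sigma = 0.08, mz_range = c(40, 70), step = 0.01
    )
    tibble::tibble(energy = energies[k], mz = sp$mz, intensity = sp$intensity)
  })
  windows <- tibble::tibble(fragment = c("COOH+", "SS+"),
                            lo = c(44.5, 63.5), hi = c(45.5, 64.5))
  scan <- piy_scan(spectra, windows)
  piy45 <- scan$yield[scan$fragment == "COOH+"]
  piy64 <- scan$yield[scan$fragment == "SS+"]
  expect_equal(piy45, area45, tolerance = 1e-3)
  expect_equal(piy64, area64, tolerance = 1e-3)

  # SIY identity holds bit-exactly, and is permutation invariant
  s <- siy(scan)
  expect_identical(s$yield, piy45 + piy64)
  scan_perm <- scan[order(scan$fragment, scan$energy), ]
  class(scan_perm) <- class(scan)
  expect_equal(siy(scan_perm)$yield, s$yield)

  # grid spacing outside the 40-70 meV protocol is rejected
  bad <- dplyr::mutate(spectra, energy = energy * 2)
  expect_error(piy_scan(bad, windows), "spacing")
  # overlapping windows are rejected
  expect_error(piy_scan(spectra, tibble::tibble(fragment = c("a", "b"),
                                                lo = c(44, 44.8),
                                                hi = c(45, 45.8))),
               "overlap")
})

test_that("Gaussian broadening conserves area, width and shift", {
  # single unit stick at 165 eV with the standard 0.7 eV FWHM / 7.23 eV shift
  sticks <- tibble::tibble(energy = 165, strength = 1)
  sp <- broaden_sticks(sticks, fwhm = 0.7, shift = 7.23)
  expect_equal(sp$energy[which.max(sp$intensity)], 165 + 7.23,
               tolerance = 0.7 / 20)

  # half-maximum points separated by the FWHM
  half <- max(sp$intensity) / 2
  above <- range(sp$energy[sp$intensity >= half])
  expect_equal(diff(above), 0.70, tolerance = 2 * 0.7 / 20)

  # area conservation within 0.1% for an arbitrary stick set
  set.seed(3)
  many <- tibble::tibble(energy = stats::runif(12, 160, 175),
                         strength = stats::runif(12, 0, 5))
  spm <- broaden_sticks(many)
  expect_equal(pracma::trapz(spm$energy, spm$intensity), sum(many$strength),
               tolerance = 1e-3)

  expect_error(broaden_sticks(sticks, fwhm = 0), "positive")
})

test_that("broadening is linear and shift-equivariant", {
  grid <- seq(150, 200, by = 0.02)
  s1 <- tibble::tibble(energy = c(165, 168), strength = c(1, 2))
  s2 <- tibble::tibble(energy = c(166.5), strength = c(3))
  a <- 2.5
  lhs <- broaden_sticks(tibble::tibble(
    energy = c(s1$energy, s2$energy),
    strength = c(a * s1$strength, s2$strength)
  ), grid = grid)
  rhs <- a * broaden_sticks(s1, grid = grid)$intensity +
    broaden_sticks(s2, grid = grid)$intensity
  expect_equal(lhs$intensity, rhs, tolerance = 1e-12)

  # shifting then evaluating at E equals unshifted at E - s
  sh <- broaden_sticks(s1, shift = 7.23, grid = grid)
  un <- broaden_sticks(s1, shift = 0, grid = grid - 7.23)
  expect_equal(sh$intensity, un$intensity, tolerance = 1e-12)
})

test_that("tidy and glance methods expose the calibration fit", {
  cal <- tof_calibrate(tibble::tibble(mz = c(45, 64, 100),
                                      time = 5 + 3 * sqrt(c(45, 64, 100))))
  td <- generics::tidy(cal)
  expect_equal(td$term, c("t0", "k"))
  expect_equal(td$estimate, c(5, 3), tolerance = 1e-10)
  gl <- generics::glance(cal)
  expect_equal(gl$n_refs, 3)
  expect_gt(gl$r.squared, 0.999)
})
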