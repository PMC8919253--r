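test_that("thermalization is deterministic for a fixed seed", {
  cfg <- sim_config(duration_ps = 0.05, seed = 9)
  t1 <- thermalize(fixture_graph, fixture_ff_thermal, cfg)
  t2 <- thermalize(fixture_graph, fixture_ff_thermal, cfg)
  expect_identical(t1$coords, t2$coords)
  expect_identical(t1$velocities, t2$velocities)
  expect_identical(t1$times, t2$times)
})

test_that("the weak-coupling thermostat drives the system toward 300 K", {
  # from rest: the residual strain of the fixture provides the seed motion,
  # and the thermostat amplifies it toward the target
  tr <- thermalize(fixture_graph, fixture_ff_thermal,
                   sim_config(duration_ps = 1.5, seed = 3),
                   minimize = FALSE, zero_velocities = TRUE)
  kt <- kinetic_temperature(tr)
  late <- mean(kt$temperature_k[kt$time_fs > 750])
  expect_gt(late, 0.85 * 300)
  expect_lt(late, 1.15 * 300)
  # and temperature rose from zero
  expect_equal(kt$temperature_k[1], 0)
  expect_gt(late, 100)
})

test_that("equilibrated bonds fluctuate with positive spread", {
  expect_true(all(fixture_baselines$sigma > 0))
  expect_true(all(fixture_baselines$d0 > fixture_baselines$mu))
})

test_that("starting-configuration sampling honors the pairwise separation", {
  # 1000 frames at 1 fs
  tr <- linear_two_atom_trajectory(rep(1.5, 1000))
  one <- sample_starting_configs(tr, n = 1, separation_ps = 0.001)
  expect_equal(one[[1]]$time_fs, tr$times[length(tr$times)])  # last frame

  # the 999 fs span cannot host 20 frames 55 fs apart (needs 1045 fs)
  expect_error(sample_starting_configs(tr, n = 20, separation_ps = 0.055),
               "need at least")

  got <- sample_starting_configs(tr, n = 20, separation_ps = 0.05)
  times <- vapply(got, function(f) f$time_fs, numeric(1))
  expect_equal(length(got), 20)
  gaps <- abs(outer(times, times, "-"))[lower.tri(diag(20))]
  expect_true(all(gaps >= 50))  # every pair, not just neighbours
})

test_that("a neutral relaxed molecule at rest stays put under NVE", {
  g <- fixture_graph
  ff0 <- force_field(g, charges = rep(0, 27), total_charge = 0)
  pos <- minimize_geometry(g, ff0, ftol = 1e-3)
  tr <- explode(list(pos = pos), g, ff0, sim_config(duration_ps = 0.05))
  # residual minimization strain allows only small oscillation about the
  # minimum: nothing moves appreciably and no bond comes near breaking
  disp <- sqrt(rowSums((tr$coords[n_frames(tr), , ] - tr$coords[1, , ])^2))
  expect_lt(max(disp), 0.25)
  bl <- fixture_baselines
  an <- break_analysis(tr, g, bl)
  expect_false(any(an$broken))
})

test_that("two-body Coulomb dissociation approaches the closed-form energy", {
  # KE(inf) = k q1 q2 / r0 for two free charges released at rest
  sys <- two_charge_system(1, 2, r0 = 2)
  tr <- explode(list(pos = sys$graph$coords), sys$graph, sys$ff,
                sim_config(duration_ps = 3))
  ke_final <- tr$energy$kinetic[n_frames(tr)]
  sep <- sqrt(sum((tr$coords[n_frames(tr), 2, ] - tr$coords[n_frames(tr), 1, ])^2))
  expect_gt(sep, 20 * 2)  # ran long enough
  expect_equal(ke_final, xp_constants$coulomb * 1 * 2 / 2, tolerance = 0.01)
})

test_that("NVE conserves energy and momentum; halving the step reduces drift", {
  g <- fixture_graph
  ff3 <- cystine_force_field(g, total_charge = 3)
  start <- sample_starting_configs(fixture_thermal, 1, 0.5)[[1]]
  tr <- explode(start, g, ff3, sim_config(duration_ps = 1, dt_fs = 0.5))
  expect_lt(energy_drift(tr), 0.01)

  # momentum conservation
  masses <- element_masses()$average[match(tr$elements, element_masses()$element)]
  p0 <- colSums(tr$velocities[1, , ] * masses)
  pT <- colSums(tr$velocities[n_frames(tr), , ] * masses)
  expect_equal(pT, p0, tolerance = 1e-8)

  tr_half <- explode(start, g, ff3, sim_config(duration_ps = 1, dt_fs = 0.25))
  expect_lt(energy_drift(tr_half), energy_drift(tr))
})

test_that("explosions are reproducible and report instability with a frame index", {
  g <- fixture_graph
  ff3 <- cystine_force_field(g, total_charge = 3)
  start <- sample_starting_configs(fixture_thermal, 1, 0.5)[[1]]
  cfg <- sim_config(duration_ps = 0.1)
  a <- explode(start, g, ff3, cfg)
  b <- explode(start, g, ff3, cfg)
  expect_identical(a$coords, b$coords)

  # an absurd time step blows the integration up with a frame report
  expect_error(explode(start, g, ff3, sim_config(duration_ps = 2, dt_fs = 50)),
               "frame")
})

test_that("the default +3 ensemble breaks bonds in a majority of runs", {
  g <- fixture_graph
  ff3 <- cystine_force_field(g, total_charge = 3)
  cfg <- sim_config(seed = 11, n_configs = 18, separation_ps = 0.1,
                    duration_ps = 1)
  ens <- explode_ensemble(g, fixture_ff_thermal, ff3, cfg,
                          thermal = fixture_thermal)
  bl <- fixture_baselines
  n_broken <- vapply(ens$runs, function(tr) {
    sum(break_analysis(tr, g, bl)$broken)
  }, numeric(1))
  expect_gt(sum(n_broken > 0), length(ens$runs) / 2)
})
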