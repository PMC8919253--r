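# shared fixtures, built once per test run

fixture_graph <- cystine_topology()
fixture_ff_thermal <- cystine_force_field(fixture_graph)

# short thermal run used wherever a test needs baselines; 2 ps is enough for
# stable per-bond moments
fixture_thermal <- thermalize(fixture_graph, fixture_ff_thermal,
                              sim_config(duration_ps = 2, seed = 42))
fixture_baselines <- thermal_baselines(fixture_thermal, fixture_graph)

# a two-free-charge system (q1, q2 at separation r0 on the x axis), no bonds
two_charge_system <- function(q1, q2, r0, elements = c("C", "C")) {
  atoms <- tibble::tibble(element = elements, label = c("A1", "A2"))
  g <- molecular_graph(atoms, tibble::tibble(i = integer(), j = integer()),
                       charge = round(q1 + q2),
                       coords = rbind(c(0, 0, 0), c(r0, 0, 0)))
  ff <- force_field(g, charges = c(q1, q2), total_charge = q1 + q2,
                    rep_eps = 0)
  list(graph = g, ff = ff)
}

# a hand-rolled trajectory with prescribed per-frame positions for two atoms
linear_two_atom_trajectory <- function(d_of_t, dt_fs = 1) {
  nf <- length(d_of_t)
  coords <- array(0, c(nf, 2, 3))
  coords[, 2, 1] <- d_of_t
  new_trajectory(seq(0, by = dt_fs, length.out = nf), coords,
                 array(0, c(nf, 2, 3)), c("C", "C"),
                 metadata = list(seed = NA, total_charge = 0,
                                 thermostat = FALSE, dt_fs = dt_fs))
}

# independent brute-force reimplementation of the integrity + persistence
# logic, used as the classification oracle
oracle_classify <- function(d, d0, decay_scale = 0.5, threshold = 0.5,
                            persistence_fs = 100, dt_fs = 1) {
  xi <- numeric(length(d))
  for (t in seq_along(d)) {
    xi[t] <- if (d[t] <= d0) 1 else exp(-((d[t] - d0) / decay_scale)^2)
  }
  n_win <- min(length(d), max(1, ceiling(persistence_fs / dt_fs)))
  ok <- TRUE
  for (t in (length(d) - n_win + 1):length(d)) {
    if (xi[t] >= threshold) ok <- FALSE
  }
  ok && TRUE
}
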