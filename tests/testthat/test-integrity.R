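test_that("bond distances come out on the trajectory time grid", {
  tr <- linear_two_atom_trajectory(rep(1.5, 10))
  d <- bond_distance_series(tr, 1, 2)
  expect_equal(d$distance, rep(1.5, 10))
  expect_equal(d$time_fs, 0:9)

  # 3-4-5 triangle
  tr$coords[1, 2, ] <- c(3, 4, 0)
  expect_equal(bond_distance_series(tr, 1, 2)$distance[1], 5)

  # linear motion d(t) = d0 + v t matches the closed form frame by frame
  d0 <- 1.2; v <- 0.01; t <- 0:99
  trl <- linear_two_atom_trajectory(d0 + v * t)
  expect_equal(bond_distance_series(trl, 1, 2)$distance, d0 + v * t)

  expect_error(bond_distance_series(tr, 1, 7), "invalid atom indices")
})

test_that("thermal baselines use the population sd shifted mean", {
  b <- thermal_baseline(rep(1.5, 8))
  expect_equal(unlist(b), c(mu = 1.5, sigma = 0, d0 = 1.5))

  b2 <- thermal_baseline(c(1.4, 1.6))
  expect_equal(b2$mu, 1.5)
  expect_equal(b2$sigma, 0.1)  # population, not sample (0.1414...)
  expect_equal(b2$d0, 1.6)

  # order invariance: pooling is a symmetric function
  x <- c(1.42, 1.55, 1.61, 1.47, 1.50)
  expect_equal(thermal_baseline(x), thermal_baseline(rev(x)))
  expect_error(thermal_baseline(numeric()), "at least one")
})

test_that("baseline exceeds the median for right-skewed thermal series", {
  # Morse-like thermal distance distribution: long tail toward stretch
  set.seed(1)
  d <- 1.5 + 0.05 * (exp(stats::rnorm(5000, 0, 0.5)) - 1)
  b <- thermal_baseline(d)
  expect_gt(b$d0, stats::median(d))
})

test_that("integrity satisfies its endpoint and monotonicity contract", {
  b <- tibble::tibble(d0 = 2.0)
  # intact: d <= d0 gives exactly 1
  expect_true(all(integrity(seq(0.1, 2.0, by = 0.1), b$d0) == 1))
  # broken limit
  expect_lt(integrity(10 * b$d0, b$d0), 0.01)
  # monotone non-increasing beyond d0
  d <- seq(2.0, 8, by = 0.01)
  expect_true(all(diff(integrity(d, b$d0)) <= 0))
  # scalar oracle at one decay length past d0: hand value exp(-1)
  expect_equal(integrity(2.5, 2.0, decay_scale = 0.5), exp(-1))
  expect_error(integrity(-1, 2.0), "non-negative")
})

test_that("integrity stays within [0,1] on random series", {
  set.seed(7)
  for (k in 1:1000) {
    d <- stats::runif(50, 0, 20)
    xi <- integrity(d, d0 = stats::runif(1, 0.5, 3))
    expect_true(all(xi >= 0 & xi <= 1))
  }
})

test_that("break classification honors threshold and persistence", {
  # always intact
  expect_false(classify_break(rep(1, 500), dt_fs = 1))
  # ends broken for 100 fs
  xi <- c(rep(1, 400), rep(0, 100))
  expect_true(classify_break(xi, dt_fs = 1))
  # transient dip with recovery: intact
  xi_dip <- c(rep(1, 200), rep(0.1, 100), rep(1, 200))
  expect_false(classify_break(xi_dip, dt_fs = 1))
  expect_error(classify_break(numeric()), "empty")
})

test_that("classification equals an independently coded brute-force oracle", {
  set.seed(99)
  for (k in 1:50) {
    d0 <- stats::runif(1, 1, 2.5)
    # random walks that sometimes stretch away, sometimes return
    d <- abs(d0 + cumsum(stats::rnorm(300, mean = stats::runif(1, -0.002, 0.01),
                                      sd = 0.05)))
    got <- classify_break(
      integrity_series(d, tibble::tibble(d0 = d0), time_fs = seq_along(d)),
      threshold = 0.5, persistence_fs = 100
    )
    expect_identical(got, oracle_classify(d, d0), info = paste("case", k))
  }
})

test_that("break counting follows both conventions and Table-style rounding", {
  # synthetic per-run outcomes through real trajectories would be slow here;
  # instead drive the counting path with engineered integrity outcomes
  g <- fixture_graph
  bl <- fixture_baselines
  # construct 18 fake single-frame-style trajectories where the C4-C6 bond
  # is stretched far in 7 runs (and C1-C3 never)
  mk_run <- function(stretch) {
    tr <- fixture_thermal
    nf <- 40
    coords <- tr$coords[seq_len(nf), , ]
    if (stretch) {
      i <- match("C4", g$atoms$label); j <- match("C6", g$atoms$label)
      dir <- coords[, i, ] - coords[, j, ]
      nrm <- sqrt(rowSums(dir^2))
      for (ax in 1:3) coords[, i, ax] <- coords[, i, ax] + 8 * dir[, ax] / nrm
    }
    new_trajectory(tr$times[seq_len(nf)], coords,
                   tr$velocities[seq_len(nf), , ], tr$elements, tr$metadata)
  }
  ens <- c(lapply(1:7, function(i) mk_run(TRUE)),
           lapply(1:11, function(i) mk_run(FALSE)))
  bt <- break_probability_table(ens, g, bl, persistence_fs = 10)
  row <- bt[bt$bond_class == "Calpha-Cbeta (C4-C6 and C1-C3)", ]
  expect_equal(row$n_events, 7)
  expect_equal(row$n_opportunities, 18)
  expect_equal(round(row$probability_pct), 39)      # 7/18 -> 38.9 -> 39
  expect_true(row$ci_low < row$probability_pct &
                row$probability_pct < row$ci_high)

  # per-bond counting doubles the opportunities for a two-member class
  bt_b <- break_probability_table(ens, g, bl, persistence_fs = 10,
                                  counting = "bond")
  row_b <- bt_b[bt_b$bond_class == "Calpha-Cbeta (C4-C6 and C1-C3)", ]
  expect_equal(row_b$n_opportunities, 36)
  expect_equal(row_b$n_events, 7)

  # degenerate edges of the probability scale
  bt0 <- break_probability_table(ens[8:9], g, bl, persistence_fs = 10)
  expect_equal(bt0$probability_pct[bt0$bond_class ==
                                     "Calpha-Cbeta (C4-C6 and C1-C3)"], 0)
  bt1 <- break_probability_table(ens[1:2], g, bl, persistence_fs = 10)
  expect_equal(bt1$probability_pct[bt1$bond_class ==
                                     "Calpha-Cbeta (C4-C6 and C1-C3)"], 100)

  expect_error(break_probability_table(ens, g, bl,
                                       classes = list(bad = "C1-C9")),
               "unknown bond class")
})

test_that("the fragment census closes mass and maps known break patterns", {
  g <- fixture_graph
  bl <- fixture_baselines
  nf <- 40
  intact <- new_trajectory(fixture_thermal$times[seq_len(nf)],
                           fixture_thermal$coords[seq_len(nf), , ],
                           fixture_thermal$velocities[seq_len(nf), , ],
                           fixture_thermal$elements, fixture_thermal$metadata)
  cen <- fragment_census(list(intact), g, bl, persistence_fs = 10)
  expect_equal(nrow(cen), 1)
  expect_equal(cen$nominal, 241)  # intact protonated parent

  # separate the three S-C-cleavage fragments rigidly: exactly the two S-C
  # bonds break, every intra-fragment distance is preserved
  pieces <- fragments_from_broken_bonds(g, c("C3-S1", "C6-S2"))
  co <- fixture_thermal$coords[seq_len(nf), , ]
  offsets <- c(-25, 0, 25)
  for (k in seq_len(nrow(pieces))) {
    co[, pieces$atoms[[k]], 3] <- co[, pieces$atoms[[k]], 3] + offsets[k]
  }
  broken_tr <- new_trajectory(intact$times, co, intact$velocities,
                              intact$elements, intact$metadata)
  cen2 <- fragment_census(list(broken_tr), g, bl, persistence_fs = 10)
  expect_true("S2" %in% cen2$formula)
  expect_true(64 %in% cen2$mz_plus1)
  # mass closure: the three fragments of this run partition the parent
  expect_equal(sum(cen2$count), 3)
  expect_equal(sum(cen2$nominal * cen2$count), 64 + 88 + 89)  # = parent 241
  expect_error(fragment_census(list(), g, bl), "empty ensemble")
})
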