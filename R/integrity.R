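#' Bond distance series from a trajectory
#'
#' Euclidean inter-atomic distance per frame for one bond, on the
#' trajectory's time grid.
#'
#' @param traj a `trajectory`.
#' @param i,j atom indices, or `bond` a bond label resolved through `graph`.
#' @param graph optional [molecular_graph()] for label lookup.
#' @param bond bond label such as `"S1-S2"`.
#' @return Tibble `time_fs`, `distance` (A).
#' @export
#' @examples
#' g <- cystine_topology()
#' ff <- cystine_force_field(g)
#' tr <- thermalize(g, ff, sim_config(duration_ps = 0.01))
#' bond_distance_series(tr, bond = "S1-S2", graph = g)
bond_distance_series <- function(traj, i = NULL, j = NULL,
                                 bond = NULL, graph = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (!is.null(bond)) {
    if (is.null(graph)) stop("a graph is needed to resolve bond labels")
    lbl <- normalize_bond(bond)
    row <- match(lbl, graph$bonds$label)
    if (is.na(row)) stop("not a bond of the graph: ", bond)
    i <- graph$bonds$i[row]; j <- graph$bonds$j[row]
  }
  na <- dim(traj$coords)[2]
  if (is.null(i) || is.null(j) || i < 1 || j < 1 || i > na || j > na) {
    stop("invalid atom indices")
  }
  dv <- traj$coords[, i, , drop = FALSE] - traj$coords[, j, , drop = FALSE]
  tibble::tibble(time_fs = traj$times,
                 distance = sqrt(rowSums(matrix(dv, ncol = 3)^2)))
}

#' Thermal baseline of a bond
#'
#' The reference distance for the integrity parameter: the mean thermalized
#' bond distance shifted by one standard deviation, `d0 = mu + sigma`. The
#' shift accounts for the right skew of an anharmonic thermal bond-length
#' distribution (the mean alone would flag ordinary thermal excursions).
#' `sigma` is the population standard deviation: the baseline is a
#' descriptive moment of the thermal series, fixed for reproducibility.
#'
#' @param distances numeric vector of thermalized bond distances (A),
#'   pooled over thermalization frames (and runs, if several).
#' @return Tibble with one row: `mu`, `sigma`, `d0`.
#' @export
#' @examples
#' thermal_baseline(c(1.4, 1.6))  # mu 1.5, sigma 0.1, d0 1.6
thermal_baseline <- function(distances) {
  distances <- as.numeric(distances)
  if (length(distances) == 0 || anyNA(distances)) {
    stop("need at least one finite distance sample")
  }
  mu <- mean(distances)
  sigma <- sqrt(mean((distances - mu)^2))  # population sd
  tibble::tibble(mu = mu, sigma = sigma, d0 = mu + sigma)
}

#' Thermal baselines for every bond of a graph
#'
#' @param thermal a thermalization `trajectory` (or list of them, pooled).
#' @param graph the [molecular_graph()].
#' @param burn_in fraction of each run discarded before pooling (default
#'   0.5: baselines use the equilibrated second half).
#' @return Tibble `bond`, `mu`, `sigma`, `d0`.
#' @export
thermal_baselines <- function(thermal, graph, burn_in = 0.5) {
  runs <- if (inherits(thermal, "trajectory")) list(thermal) else thermal
  purrr::map_dfr(seq_len(nrow(graph$bonds)), function(b) {
    pooled <- unlist(lapply(runs, function(tr) {
      d <- bond_distance_series(tr, graph$bonds$i[b], graph$bonds$j[b])$distance
      d[seq_along(d) > burn_in * length(d)]
    }))
    dplyr::bind_cols(tibble::tibble(bond = graph$bonds$label[b]),
                     thermal_baseline(pooled))
  })
}

#' Bond integrity parameter
#'
#' Per-frame statistic in [0, 1] referenced to the thermal baseline
#' `d0 = mu + sigma`: exactly 1 while the bond distance stays at or below
#' `d0` (an intact bond), decaying smoothly as
#' `exp(-((d - d0) / decay_scale)^2)` beyond it and approaching 0 for a
#' broken bond.
#'
#' @param distance numeric vector of bond distances (A), all non-negative.
#' @param d0 reference distance (A), from [thermal_baseline()].
#' @param decay_scale kernel decay length (A, default 0.5): the stretch
#'   beyond `d0` at which integrity has fallen to `exp(-1)`.
#' @return Numeric vector of integrity values in [0, 1].
#' @export
#' @examples
#' integrity(c(1.5, 2.0, 10), d0 = 1.6)
integrity <- function(distance, d0, decay_scale = 0.5) {
  if (any(distance < 0)) stop("distances must be non-negative")
  stopifnot(d0 > 0, decay_scale > 0)
  exp(-(pmax(distance - d0, 0) / decay_scale)^2)
}

#' Integrity series of a bond along a trajectory
#'
#' @param dist_series tibble from [bond_distance_series()] (or a numeric
#'   distance vector with `time_fs` supplied).
#' @param baseline one-row tibble with `d0` (from [thermal_baseline()]).
#' @param decay_scale see [integrity()].
#' @param time_fs time grid when `dist_series` is a bare vector.
#' @return Tibble `time_fs`, `distance`, `xi`.
#' @export
integrity_series <- function(dist_series, baseline, decay_scale = 0.5,
                             time_fs = NULL) {
  if (is.numeric(dist_series)) {
    dist_series <- tibble::tibble(
      time_fs = if (is.null(time_fs)) seq_along(dist_series) else time_fs,
      distance = dist_series
    )
  }
  dplyr::mutate(dist_series,
                xi = integrity(.data$distance, baseline$d0[1], decay_scale))
}

#' Classify a bond as broken or intact
#'
#' A bond is broken when its integrity stays below `threshold` for every
#' frame of the trailing persistence window; a transient stretch that
#' recovers is intact. The paper-style endpoint contract (1 intact, 0
#' broken) leaves the cut value open; the default is the midpoint 0.5 with
#' a 100 fs window.
#'
#' @param xi integrity values (vector or tibble with `xi`).
#' @param threshold break threshold in (0, 1).
#' @param persistence_fs trailing window length (fs).
#' @param dt_fs frame spacing (fs); taken from the `time_fs` column when
#'   `xi` is a tibble.
#' @return Logical: TRUE if broken.
#' @export
classify_break <- function(xi, threshold = 0.5, persistence_fs = 100,
                           dt_fs = NULL) {
  if (is.data.frame(xi)) {
    if (is.null(dt_fs) && nrow(xi) > 1) dt_fs <- diff(xi$time_fs[1:2])
    xi <- xi$xi
  }
  if (length(xi) == 0) stop("empty integrity series")
  stopifnot(threshold > 0, threshold < 1)
  if (is.null(dt_fs)) dt_fs <- 1
  n_win <- min(length(xi), max(1L, ceiling(persistence_fs / dt_fs)))
  tail_xi <- xi[(length(xi) - n_win + 1):length(xi)]
  all(tail_xi < threshold)
}

#' Break analysis of one explosion trajectory
#'
#' @param traj an explosion `trajectory`.
#' @param graph the [molecular_graph()].
#' @param baselines tibble from [thermal_baselines()].
#' @param bonds bond labels to monitor (default: all bonds in `baselines`).
#' @param decay_scale,threshold,persistence_fs see [integrity()] and
#'   [classify_break()].
#' @return Tibble `bond`, `final_distance`, `min_xi`, `final_xi`, `broken`.
#' @export
break_analysis <- function(traj, graph, baselines, bonds = baselines$bond,
                           decay_scale = 0.5, threshold = 0.5,
                           persistence_fs = 100) {
  purrr::map_dfr(bonds, function(b) {
    bl <- baselines[baselines$bond == b, ]
    if (nrow(bl) != 1) stop("no baseline for bond ", b)
    xi <- integrity_series(bond_distance_series(traj, bond = b, graph = graph),
                           bl, decay_scale)
    tibble::tibble(
      bond = b,
      final_distance = xi$distance[nrow(xi)],
      min_xi = min(xi$xi),
      final_xi = xi$xi[nrow(xi)],
      broken = classify_break(xi, threshold, persistence_fs)
    )
  })
}

#' Symmetry-equivalent bond classes of cystine
#'
#' The three classes tracked in the fragmentation analysis (each pairing
#' the two symmetric copies), plus the disulfide bridge itself.
#'
#' @return Named list of bond-label vectors.
#' @export
cystine_bond_classes <- function() {
  list(
    "Calpha-Cbeta (C4-C6 and C1-C3)" = c("C4-C6", "C1-C3"),
    "Calpha-Ccarboxyl (C1-C2 and C4-C5)" = c("C1-C2", "C4-C5"),
    "S-C (S1-C3 and S2-C6)" = c("S1-C3", "S2-C6"),
    "S-S (S1-S2)" = "S1-S2"
  )
}

#' Ensemble break-probability table
#'
#' Counts breaking events over an ensemble of explosion trajectories for
#' symmetry-equivalent bond classes and reports percentages with Wilson 95%
#' confidence intervals. Two counting conventions are provided:
#' `"trajectory"` (default) counts a class as broken in a trajectory if ANY
#' member bond broke (opportunities = number of trajectories);
#' `"bond"` counts every member bond separately (opportunities =
#' trajectories x members).
#'
#' @param ensemble list of explosion trajectories.
#' @param graph the [molecular_graph()].
#' @param baselines tibble from [thermal_baselines()].
#' @param classes named list of bond-label vectors
#'   (default [cystine_bond_classes()]).
#' @param counting `"trajectory"` or `"bond"`.
#' @param decay_scale,threshold,persistence_fs analysis parameters.
#' @return A `break_table`: tibble `bond_class`, `n_events`,
#'   `n_opportunities`, `probability_pct`, `ci_low`, `ci_high`, `fragments`
#'   (formulas created by breaking the class alone, from the molecular
#'   graph).
#' @export
break_probability_table <- function(ensemble, graph, baselines,
                                    classes = cystine_bond_classes(),
                                    counting = c("trajectory", "bond"),
                                    decay_scale = 0.5, threshold = 0.5,
                                    persistence_fs = 100) {
  counting <- match.arg(counting)
  if (length(ensemble) < 1) stop("empty ensemble")
  members <- unlist(classes)
  unknown <- setdiff(normalize_bond(members), graph$bonds$label)
  if (length(unknown)) stop("unknown bond class member(s): ",
                            paste(unknown, collapse = ", "))
  per_run <- purrr::map(ensemble, break_analysis, graph = graph,
                        baselines = baselines,
                        bonds = unique(normalize_bond(members)),
                        decay_scale = decay_scale, threshold = threshold,
                        persistence_fs = persistence_fs)
  tab <- purrr::imap_dfr(classes, function(mem, cls) {
    mem <- normalize_bond(mem)
    broken_per_run <- purrr::map(per_run, function(an) {
      an$broken[match(mem, an$bond)]
    })
    if (counting == "trajectory") {
      events <- sum(purrr::map_lgl(broken_per_run, any))
      opps <- length(ensemble)
    } else {
      events <- sum(unlist(broken_per_run))
      opps <- length(ensemble) * length(mem)
    }
    ci <- wilson_ci(events, opps)
    frags <- fragments_from_broken_bonds(graph, mem)
    frags <- frags[frags$n_atoms < nrow(graph$atoms), ]
    tibble::tibble(
      bond_class = cls, n_events = events, n_opportunities = opps,
      probability_pct = 100 * events / opps,
      ci_low = ci[1], ci_high = ci[2],
      fragments = paste(sort(unique(frags$formula)), collapse = "; ")
    )
  })
  structure(tab, class = c("break_table", class(tab)),
            n_trajectories = length(ensemble), counting = counting,
            threshold = threshold, persistence_fs = persistence_fs)
}

#' Wilson score interval
#'
#' @param events,opportunities counts.
#' @param conf confidence level.
#' @return Length-2 vector (low, high), on the percentage scale.
#' @export
wilson_ci <- function(events, opportunities, conf = 0.95) {
  if (opportunities == 0) return(c(NA_real_, NA_real_))
  ci <- suppressWarnings(
    stats::prop.test(events, opportunities, conf.level = conf,
                     correct = FALSE)$conf.int
  )
  100 * as.numeric(ci)
}

#' Fragment census of an explosion ensemble
#'
#' For each trajectory the bonds broken at the end of the run (final-frame
#' fragmentation; intermediate recombination is ignored) define a partition
#' of the molecular graph into fragments. Counts are aggregated over the
#' ensemble by neutral formula. Charge is not assigned: the experiment
#' selects cations, but a classical trajectory cannot partition charge, so
#' the census reports neutral formulas plus the nominal m/z of the
#' hypothetical +1 cation.
#'
#' @inheritParams break_probability_table
#' @return Tibble `formula`, `nominal`, `mz_plus1`, `count`,
#'   `frac_trajectories`.
#' @export
fragment_census <- function(ensemble, graph, baselines,
                            decay_scale = 0.5, threshold = 0.5,
                            persistence_fs = 100) {
  if (length(ensemble) < 1) stop("empty ensemble")
  all_frags <- purrr::map_dfr(ensemble, function(traj) {
    an <- break_analysis(traj, graph, baselines,
                         decay_scale = decay_scale, threshold = threshold,
                         persistence_fs = persistence_fs)
    fragments_from_broken_bonds(graph, an$bond[an$broken])
  })
  out <- dplyr::summarise(
    dplyr::group_by(all_frags, .data$formula, .data$nominal, .data$mz_plus1),
    count = dplyr::n(), .groups = "drop"
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$count), .data$nominal)
  out$frac_trajectories <- out$count / length(ensemble)
  out
}
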