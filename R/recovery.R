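#' Engineered force field for parameter-recovery checks
#'
#' An ionized (+3) cystine force field in which only the two carboxyl C-C
#' bonds (C1-C2 and C4-C5) are weakened, by `depth_factor`, while every
#' other bond keeps its full well depth. With the default factor 0.155 the
#' carboxyl bond class breaks with probability very close to 0.5 over 0.5 ps
#' explosions started from the relaxed geometry with 300 K
#' Maxwell-Boltzmann velocities — a known ground truth against which the
#' whole break-counting pipeline can be validated.
#'
#' @param graph cystine topology.
#' @param depth_factor Morse-depth scaling of the carboxyl bonds.
#' @return A `force_field`.
#' @export
recovery_force_field <- function(graph = cystine_topology(),
                                 depth_factor = 0.155) {
  cystine_force_field(graph, total_charge = 3,
                      depth_scale = c("C1-C2" = depth_factor,
                                      "C4-C5" = depth_factor))
}

#' Estimate a bond-class break probability over seeded independent runs
#'
#' Runs `n_runs` independent explosions (relaxed geometry, fresh seeded
#' Maxwell-Boltzmann velocities at `temperature`, seeds `seed + 1 ... seed +
#' n_runs`) and classifies the bond class as broken per run, giving a
#' binomial estimate of the class break probability with a Wilson 95% CI.
#'
#' @param ff the exploding-state force field (e.g. [recovery_force_field()]).
#' @param graph the molecular graph.
#' @param baselines thermal baselines for the monitored bonds.
#' @param class_bonds bond labels forming the class (any member breaking
#'   counts).
#' @param n_runs number of independent trajectories.
#' @param seed base seed.
#' @param duration_ps explosion length per run (ps).
#' @param temperature initial-velocity temperature (K).
#' @param ... analysis parameters passed to [break_analysis()].
#' @return Tibble: `n_events`, `n_runs`, `p_hat`, `ci_low`, `ci_high`
#'   (probabilities on the 0-1 scale).
#' @export
estimate_break_probability <- function(ff, graph, baselines,
                                       class_bonds = c("C1-C2", "C4-C5"),
                                       n_runs = 50, seed = 1,
                                       duration_ps = 0.5, temperature = 300,
                                       ...) {
  ff_thermal <- cystine_force_field(graph)
  pos0 <- minimize_geometry(graph, ff_thermal)
  cfg <- sim_config(duration_ps = duration_ps)
  class_bonds <- normalize_bond(class_bonds)
  hits <- vapply(seq_len(n_runs), function(k) {
    set.seed(seed + k)
    st <- list(pos = pos0, vel = maxwell_velocities(ff$masses, temperature))
    an <- break_analysis(explode(st, graph, ff, cfg), graph, baselines,
                         bonds = class_bonds, ...)
    any(an$broken)
  }, logical(1))
  ci <- wilson_ci(sum(hits), n_runs) / 100
  tibble::tibble(n_events = sum(hits), n_runs = n_runs,
                 p_hat = mean(hits), ci_low = ci[1], ci_high = ci[2])
}
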