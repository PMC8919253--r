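#' Simulation configuration
#'
#' Defaults mirror the study protocol: 0.5 fs velocity-Verlet step, 1 ps
#' production runs, thermalization near 300 K with a 0.1 ps weak-coupling
#' constant, ensembles of 18 starting configurations sampled at least 1 ps
#' apart.
#'
#' @param dt_fs integration time step (fs).
#' @param duration_ps run length (ps).
#' @param temperature thermostat target (K).
#' @param tau_ps thermostat coupling time (ps).
#' @param n_configs ensemble size.
#' @param separation_ps minimum time separation between sampled starting
#'   configurations (ps).
#' @param seed integer random seed.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(dt_fs = 0.5, duration_ps = 1, temperature = 300,
                       tau_ps = 0.1, n_configs = 18, separation_ps = 1,
                       seed = 1L) {
  stopifnot(dt_fs > 0, duration_ps * 1000 >= dt_fs, temperature >= 0,
            tau_ps > 0, n_configs >= 1, separation_ps > 0)
  structure(list(dt_fs = dt_fs, duration_ps = duration_ps,
                 temperature = temperature, tau_ps = tau_ps,
                 n_configs = as.integer(n_configs),
                 separation_ps = separation_ps, seed = as.integer(seed)),
            class = "sim_config")
}

new_trajectory <- function(times, coords, velocities, elements, metadata,
                           energy = NULL) {
  structure(list(times = times, coords = coords, velocities = velocities,
                 elements = elements, metadata = metadata, energy = energy),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", dim(x$coords)[1], " frames x ", dim(x$coords)[2],
      " atoms, dt = ", x$metadata$dt_fs, " fs, charge ",
      format(x$metadata$total_charge), " e",
      if (isTRUE(x$metadata$thermostat)) ", thermostatted" else "",
      "\n", sep = "")
  invisible(x)
}

#' Trajectory as a long tibble
#'
#' @param x a trajectory.
#' @param ... unused.
#' @return Tibble with columns `frame`, `time_fs`, `atom`, `element`,
#'   `x`, `y`, `z` (A).
#' @export
as_tibble.trajectory <- function(x, ...) {
  nf <- dim(x$coords)[1]; na <- dim(x$coords)[2]
  tibble::tibble(
    frame = rep(seq_len(nf), each = na),
    time_fs = rep(x$times, each = na),
    atom = rep(seq_len(na), nf),
    element = rep(x$elements, nf),
    x = as.vector(t(x$coords[, , 1])),
    y = as.vector(t(x$coords[, , 2])),
    z = as.vector(t(x$coords[, , 3]))
  )
}

#' Number of frames in a trajectory
#' @param traj a trajectory.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

# instantaneous kinetic temperature; 3N - 3 degrees of freedom (net momentum
# is removed at initialisation)
.kinetic_energy <- function(vel, masses) {
  0.5 * sum(masses * rowSums(vel * vel)) * xp_constants$u_ev
}
.temperature <- function(ke, n) 2 * ke / ((3 * n - 3) * xp_constants$kB)

#' Per-frame kinetic temperature of a trajectory
#'
#' @param traj a trajectory.
#' @return Tibble `time_fs`, `kinetic_ev`, `temperature_k`.
#' @export
kinetic_temperature <- function(traj) {
  masses <- .element_mass(traj$elements, "average")
  n <- length(traj$elements)
  ke <- vapply(seq_len(n_frames(traj)), function(f) {
    .kinetic_energy(traj$velocities[f, , ], masses)
  }, numeric(1))
  tibble::tibble(time_fs = traj$times, kinetic_ev = ke,
                 temperature_k = .temperature(ke, n))
}

#' Maxwell-Boltzmann velocities
#'
#' Component-wise normal draws at temperature `T`, with the net momentum
#' removed and the kinetic energy rescaled to match the target exactly.
#' Uses the current RNG state (seed upstream).
#'
#' @param masses atomic masses (u).
#' @param temperature target temperature (K).
#' @return N x 3 matrix of velocities (A/fs).
#' @export
maxwell_velocities <- function(masses, temperature) {
  n <- length(masses)
  sd_v <- sqrt(xp_constants$kB * temperature / (masses * xp_constants$u_ev))
  v <- matrix(stats::rnorm(3 * n), n, 3) * sd_v
  v <- sweep(v, 2, colSums(v * masses) / sum(masses))  # zero net momentum
  ke <- .kinetic_energy(v, masses)
  target <- 0.5 * (3 * n - 3) * xp_constants$kB * temperature
  if (ke > 0 && target > 0) v <- v * sqrt(target / ke)
  v
}

# velocity-Verlet core. thermostat = NULL (NVE) or list(T0, tau_fs).
.run_md <- function(pos, vel, ff, n_steps, dt, thermostat = NULL) {
  n <- ff$n
  masses <- ff$masses
  inv_m <- 1 / (masses * xp_constants$u_ev)  # (A/fs^2) per (eV/A)
  coords <- array(NA_real_, c(n_steps + 1, n, 3))
  vels <- array(NA_real_, c(n_steps + 1, n, 3))
  pot <- kin <- numeric(n_steps + 1)
  ev <- .ff_eval(pos, ff)
  coords[1, , ] <- pos; vels[1, , ] <- vel
  pot[1] <- ev$potential; kin[1] <- .kinetic_energy(vel, masses)
  for (s in seq_len(n_steps)) {
    vel <- vel + (0.5 * dt) * ev$F * inv_m
    pos <- pos + dt * vel
    if (!all(is.finite(pos)) || max(abs(pos)) > 1e6) {
      stop("integration became unstable (non-finite or runaway coordinates) ",
           "at frame ", s)
    }
    ev <- .ff_eval(pos, ff)
    vel <- vel + (0.5 * dt) * ev$F * inv_m
    if (!is.null(thermostat)) {
      ke <- .kinetic_energy(vel, masses)
      Tinst <- .temperature(ke, n)
      if (Tinst > 0) {
        lambda <- sqrt(1 + (dt / thermostat$tau_fs) * (thermostat$T0 / Tinst - 1))
        vel <- vel * min(max(lambda, 0.9), 1.1)
      }
    }
    coords[s + 1, , ] <- pos; vels[s + 1, , ] <- vel
    pot[s + 1] <- ev$potential; kin[s + 1] <- .kinetic_energy(vel, masses)
  }
  list(coords = coords, vels = vels, pot = pot, kin = kin)
}

#' Relax a geometry against the force field
#'
#' Adaptive steepest descent; used to clean up the rough fixture geometry
#' before thermalization so dynamics starts near the potential minimum.
#'
#' @param graph a [molecular_graph()] with coordinates.
#' @param ff a [force_field()].
#' @param max_iter iteration budget.
#' @param ftol stop when the largest force component is below this (eV/A).
#' @return N x 3 matrix of relaxed coordinates.
#' @export
minimize_geometry <- function(graph, ff, max_iter = 800, ftol = 0.05) {
  pos <- graph$coords
  if (is.null(pos)) stop("graph carries no coordinates")
  gamma <- 0.005
  ev <- .ff_eval(pos, ff)
  for (it in seq_len(max_iter)) {
    if (max(abs(ev$F)) < ftol) break
    cand <- pos + gamma * ev$F
    ev2 <- .ff_eval(cand, ff)
    if (is.finite(ev2$potential) && ev2$potential < ev$potential) {
      pos <- cand; ev <- ev2; gamma <- min(gamma * 1.2, 0.05)
    } else {
      gamma <- gamma / 2
      if (gamma < 1e-8) break
    }
  }
  pos
}

#' Thermalize a molecule with a Berendsen-style weak-coupling thermostat
#'
#' Velocity Verlet with per-step velocity rescaling by
#' `lambda = sqrt(1 + (dt/tau)(T0/T - 1))` toward the target temperature.
#' The run starts from the (optionally relaxed) fixture geometry with seeded
#' Maxwell-Boltzmann velocities, so a fixed seed reproduces the trajectory
#' frame by frame.
#'
#' @param graph a [molecular_graph()] with coordinates.
#' @param ff a [force_field()] covering every bond of `graph`.
#' @param cfg a [sim_config()]; `duration_ps`, `dt_fs`, `temperature`,
#'   `tau_ps` and `seed` are used.
#' @param minimize relax the geometry first (default TRUE).
#' @param zero_velocities start at rest instead of Maxwell-Boltzmann draws.
#' @return A `trajectory` with per-frame energies.
#' @export
thermalize <- function(graph, ff, cfg = sim_config(), minimize = TRUE,
                       zero_velocities = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  .check_ff_coverage(graph, ff)
  set.seed(cfg$seed)
  pos <- if (minimize) minimize_geometry(graph, ff) else graph$coords
  vel <- if (zero_velocities) matrix(0, ff$n, 3)
         else maxwell_velocities(ff$masses, cfg$temperature)
  n_steps <- round(cfg$duration_ps * 1000 / cfg$dt_fs)
  out <- .run_md(pos, vel, ff, n_steps, cfg$dt_fs,
                 thermostat = list(T0 = cfg$temperature,
                                   tau_fs = cfg$tau_ps * 1000))
  .finish_traj(out, graph, ff, cfg, thermostat = TRUE)
}

.check_ff_coverage <- function(graph, ff) {
  if (ff$n != nrow(graph$atoms)) stop("force field atom count does not match graph")
  missing <- setdiff(graph$bonds$label, ff$bonds$label)
  if (length(missing)) {
    stop("force field lacks parameters for bonds: ", paste(missing, collapse = ", "))
  }
}

.finish_traj <- function(out, graph, ff, cfg, thermostat) {
  times <- seq(0, by = cfg$dt_fs, length.out = length(out$pot))
  new_trajectory(
    times, out$coords, out$vels, graph$atoms$element,
    metadata = list(seed = cfg$seed, total_charge = ff$total_charge,
                    thermostat = thermostat, dt_fs = cfg$dt_fs),
    energy = tibble::tibble(time_fs = times, kinetic = out$kin,
                            potential = out$pot, total = out$kin + out$pot)
  )
}

#' Sample starting configurations from a thermal trajectory
#'
#' Returns `n` frames, pairwise separated in time by at least
#' `separation_ps`, ending at the final frame (positions and velocities are
#' copied).
#'
#' @param traj a thermal `trajectory`.
#' @param n number of configurations.
#' @param separation_ps minimum pairwise time separation (ps).
#' @return List of frames, each `list(time_fs, pos, vel)`.
#' @export
sample_starting_configs <- function(traj, n = 18, separation_ps = 1) {
  stopifnot(inherits(traj, "trajectory"), n >= 1)
  nf <- length(traj$times)
  dt <- traj$metadata$dt_fs
  sep_fs <- separation_ps * 1000
  step <- ceiling(sep_fs / dt - 1e-9)  # frames per separation, rounded up
  if (nf - 1 < (n - 1) * step) {
    stop("trajectory spans ", (nf - 1) * dt, " fs; need at least ",
         (n - 1) * step * dt, " fs for ", n, " configurations ",
         separation_ps, " ps apart")
  }
  idx <- nf - (n - seq_len(n)) * step
  lapply(idx, function(f) {
    list(time_fs = traj$times[f],
         pos = traj$coords[f, , ],
         vel = traj$velocities[f, , ])
  })
}

#' Microcanonical Coulomb-explosion run
#'
#' Velocity-Verlet integration with no temperature coupling, from a given
#' starting frame, under a (typically ionized, bond-weakened) force field.
#' Energy is conserved up to integrator drift; non-finite coordinates abort
#' with the failing frame index.
#'
#' @param start a frame from [sample_starting_configs()], or a list with
#'   `pos` (N x 3) and optionally `vel` (defaults to rest).
#' @param graph the [molecular_graph()] the frame belongs to.
#' @param ff the force field of the exploding state (e.g.
#'   `cystine_force_field(total_charge = 3)`).
#' @param cfg a [sim_config()]; `duration_ps` and `dt_fs` are used.
#' @return A `trajectory` with per-frame energies.
#' @export
explode <- function(start, graph, ff, cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  .check_ff_coverage(graph, ff)
  pos <- as.matrix(start$pos)
  stopifnot(nrow(pos) == ff$n, ncol(pos) == 3)
  vel <- if (is.null(start$vel)) matrix(0, ff$n, 3) else as.matrix(start$vel)
  n_steps <- round(cfg$duration_ps * 1000 / cfg$dt_fs)
  out <- .run_md(pos, vel, ff, n_steps, cfg$dt_fs, thermostat = NULL)
  .finish_traj(out, graph, ff, cfg, thermostat = FALSE)
}

#' Relative total-energy drift of a trajectory
#'
#' @param traj a trajectory with recorded energies.
#' @return `max |E(t) - E(0)| / |E(0)|`.
#' @export
energy_drift <- function(traj) {
  stopifnot(!is.null(traj$energy))
  e <- traj$energy$total
  max(abs(e - e[1])) / abs(e[1])
}

#' Run a seeded ensemble of explosion trajectories
#'
#' Thermalizes once, samples `cfg$n_configs` starting frames at least
#' `cfg$separation_ps` apart, and explodes each under `ff_charged`.
#' Per-trajectory seeds are derived as `cfg$seed + index`.
#'
#' @param graph molecular graph with coordinates.
#' @param ff_thermal force field of the thermal (+1) state.
#' @param ff_charged force field of the ionized state.
#' @param cfg a [sim_config()]; the thermalization run is stretched to cover
#'   the sampling span plus a 2 ps burn-in.
#' @param thermal optionally a precomputed thermal trajectory (skips the
#'   thermalization stage).
#' @return List with `thermal` (trajectory) and `runs` (list of
#'   trajectories).
#' @export
explode_ensemble <- function(graph, ff_thermal, ff_charged, cfg = sim_config(),
                             thermal = NULL) {
  if (is.null(thermal)) {
    therm_cfg <- cfg
    therm_cfg$duration_ps <- (cfg$n_configs - 1) * cfg$separation_ps + 2
    thermal <- thermalize(graph, ff_thermal, therm_cfg)
  }
  starts <- sample_starting_configs(thermal, cfg$n_configs, cfg$separation_ps)
  runs <- lapply(seq_along(starts), function(k) {
    run_cfg <- cfg
    run_cfg$seed <- cfg$seed + k
    explode(starts[[k]], graph, ff_charged, run_cfg)
  })
  list(thermal = thermal, runs = runs)
}
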