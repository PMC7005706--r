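# Molecular dynamics: velocity-Verlet with no thermostat (NVE),
# Nose-Hoover (single thermostat variable) or Langevin (BAOAB), fixed
# atom masks, harmonic positional restraints, Maxwell-Boltzmann
# velocity initialization.  Times in femtoseconds at the interface;
# internally the Amber-class unit system is used (1 time unit =
# 48.8882 fs).

#' MD run configuration
#'
#' @param timestep_fs Integration step (fs); production default 0.5,
#'   perturbation moves use 2.
#' @param n_steps Number of steps.
#' @param temperature Target temperature (K) for NVT / velocity init.
#' @param thermostat `"nose_hoover"`, `"langevin"` or `"none"` (NVE).
#'   Nose-Hoover is the default; the Langevin option exists for tiny
#'   systems where a single Nose-Hoover chain is not ergodic.
#' @param tau_fs Nose-Hoover coupling time constant (fs).
#' @param gamma_ps Langevin friction (1/ps).
#' @param restraints Optional restraint list (`idx`, `anchors`, `k`).
#' @param seed RNG seed for velocity init and Langevin noise.
#' @param stride Trajectory recording stride (steps per frame).
#' @param velocities Optional n x 3 initial velocities (internal units);
#'   by default Maxwell-Boltzmann at `temperature`.
#' @return `md_config` list.
#' @export
md_config <- function(timestep_fs = 0.5, n_steps = 1000, temperature = 300,
                      thermostat = "nose_hoover", tau_fs = 25,
                      gamma_ps = 5, restraints = NULL, seed = 1,
                      stride = 10, velocities = NULL) {
  stopifnot(timestep_fs > 0, n_steps >= 0, temperature > 0,
            thermostat %in% c("nose_hoover", "langevin", "none"))
  if (!is.null(restraints) && !is.null(restraints$idx)) {
    structure_ok <- all(c("idx", "anchors", "k") %in% names(restraints))
    if (!structure_ok) stop("restraints need idx, anchors, k", call. = FALSE)
  }
  structure(list(timestep_fs = timestep_fs, n_steps = n_steps,
                 temperature = temperature, thermostat = thermostat,
                 tau_fs = tau_fs, gamma_ps = gamma_ps,
                 restraints = restraints, seed = seed, stride = stride,
                 velocities = velocities),
            class = "md_config")
}

#' Maxwell-Boltzmann velocities
#'
#' Draws velocities for the mobile atoms at the target temperature,
#' removes the net momentum of the mobile set and rescales to the exact
#' target.  Fixed atoms get zero velocity.
#'
#' @param system A `molsys`.
#' @param temperature Kelvin.
#' @return n x 3 matrix of velocities in internal units (A per time
#'   unit). Uses the current RNG state; seed outside for reproducibility.
#' @export
init_velocities <- function(system, temperature) {
  n <- n_atoms(system)
  mobile <- !system$atoms$fixed
  m <- system$atoms$mass
  v <- matrix(0, n, 3)
  nm <- sum(mobile)
  v[mobile, ] <- stats::rnorm(3 * nm) * sqrt(KB_KCAL * temperature /
                                               m[mobile])
  # remove net momentum of the mobile set
  p <- colSums(v[mobile, , drop = FALSE] * m[mobile])
  v[mobile, ] <- sweep(v[mobile, , drop = FALSE], 2,
                       p / sum(m[mobile]))
  g <- .md_dof(system)
  ke <- 0.5 * sum(m[mobile] * rowSums(v[mobile, , drop = FALSE]^2))
  t_now <- 2 * ke / (g * KB_KCAL)
  if (t_now > 0) v[mobile, ] <- v[mobile, ] * sqrt(temperature / t_now)
  v
}

#' @keywords internal
.md_dof <- function(system) {
  nm <- sum(!system$atoms$fixed)
  # COM momentum is conserved only when nothing external acts on the
  # mobile atoms (no fixed substrate, no restraints)
  if (any(system$atoms$fixed)) 3 * nm else max(1, 3 * nm - 3)
}

#' @keywords internal
.md_forces <- function(system, params, restraints, step) {
  k <- .kernel_eval(system, params)
  f <- k$forces
  e_pot <- k$e_bond + k$e_angle + k$e_dihedral + k$e_lj + k$e_coul
  if (!is.null(restraints)) {
    r <- .restraint_energy(system$coords, restraints)
    f[restraints$idx, ] <- f[restraints$idx, ] + r$f
    e_pot <- e_pot + r$e
  }
  if (any(!is.finite(f)))
    stop("non-finite forces at MD step ", step, call. = FALSE)
  f[system$atoms$fixed, ] <- 0
  list(f = f, e_pot = e_pot)
}

#' Run molecular dynamics
#'
#' Core integrator behind [nvt_run()] and [nve_run()].
#'
#' @param system A `molsys`.
#' @param config `md_config`.
#' @param params `ff_params`.
#' @return `md_trajectory`: list with `frames` (coordinate matrices,
#'   frame 0 included), `energies` (data frame: step, time_fs, e_pot,
#'   e_kin, temperature, e_total), `final_system`, `final_velocities`,
#'   `config`, `seed`.
#' @export
run_md <- function(system, config, params = default_forcefield()) {
  stopifnot(inherits(config, "md_config"))
  set.seed(config$seed)
  sys <- system
  n <- n_atoms(sys)
  mobile <- !sys$atoms$fixed
  m <- sys$atoms$mass
  dt <- config$timestep_fs / TIME_UNIT_FS
  g <- .md_dof(sys)
  kbt <- KB_KCAL * config$temperature

  v <- if (!is.null(config$velocities)) config$velocities else
    init_velocities(sys, config$temperature)
  v[!mobile, ] <- 0

  zeta <- 0
  q_nh <- g * kbt * (config$tau_fs / TIME_UNIT_FS)^2
  c_lang <- exp(-config$gamma_ps * 1e-3 * config$timestep_fs)

  fe <- .md_forces(sys, params, config$restraints, 0L)
  frames <- list(); erec <- list()
  record <- function(step, e_pot, e_kin) {
    frames[[length(frames) + 1L]] <<- sys$coords
    erec[[length(erec) + 1L]] <<- c(step = step,
                                    time_fs = step * config$timestep_fs,
                                    e_pot = e_pot, e_kin = e_kin,
                                    temperature = 2 * e_kin / (g * KB_KCAL),
                                    e_total = e_pot + e_kin)
  }
  kin <- function(v) 0.5 * sum(m[mobile] * rowSums(v[mobile, , drop = FALSE]^2))
  record(0L, fe$e_pot, kin(v))

  for (step in seq_len(config$n_steps)) {
    if (config$thermostat == "nose_hoover") {
      ke <- kin(v)
      zeta <- zeta + 0.5 * dt * (2 * ke - g * kbt) / q_nh
      v[mobile, ] <- (v[mobile, ] + 0.5 * dt * fe$f[mobile, ] / m[mobile]) /
        (1 + 0.5 * dt * zeta)
      sys$coords[mobile, ] <- sys$coords[mobile, ] + dt * v[mobile, ]
      fe <- .md_forces(sys, params, config$restraints, step)
      v[mobile, ] <- v[mobile, ] * (1 - 0.5 * dt * zeta) +
        0.5 * dt * fe$f[mobile, ] / m[mobile]
      ke <- kin(v)
      zeta <- zeta + 0.5 * dt * (2 * ke - g * kbt) / q_nh
    } else if (config$thermostat == "langevin") {
      v[mobile, ] <- v[mobile, ] + 0.5 * dt * fe$f[mobile, ] / m[mobile]
      sys$coords[mobile, ] <- sys$coords[mobile, ] + 0.5 * dt * v[mobile, ]
      v[mobile, ] <- c_lang * v[mobile, ] +
        sqrt((1 - c_lang^2) * kbt / m[mobile]) *
        matrix(stats::rnorm(3 * sum(mobile)), ncol = 3)
      sys$coords[mobile, ] <- sys$coords[mobile, ] + 0.5 * dt * v[mobile, ]
      fe <- .md_forces(sys, params, config$restraints, step)
      v[mobile, ] <- v[mobile, ] + 0.5 * dt * fe$f[mobile, ] / m[mobile]
    } else { # NVE velocity Verlet
      v[mobile, ] <- v[mobile, ] + 0.5 * dt * fe$f[mobile, ] / m[mobile]
      sys$coords[mobile, ] <- sys$coords[mobile, ] + dt * v[mobile, ]
      fe <- .md_forces(sys, params, config$restraints, step)
      v[mobile, ] <- v[mobile, ] + 0.5 * dt * fe$f[mobile, ] / m[mobile]
    }
    if (step %% config$stride == 0L) record(step, fe$e_pot, kin(v))
  }

  energies <- as.data.frame(do.call(rbind, erec))
  structure(list(frames = frames, energies = energies,
                 final_system = sys, final_velocities = v,
                 config = config, seed = config$seed,
                 system = system),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("<md_trajectory> ", length(x$frames), " frames, ",
      x$config$n_steps, " steps of ", x$config$timestep_fs, " fs (",
      x$config$thermostat, ")\n", sep = "")
  invisible(x)
}

#' Constant-temperature (NVT) dynamics
#'
#' @inheritParams run_md
#' @export
nvt_run <- function(system, config, params = default_forcefield()) {
  if (config$thermostat == "none")
    stop("NVT requires a thermostat", call. = FALSE)
  run_md(system, config, params)
}

#' Constant-energy (NVE) dynamics
#'
#' @inheritParams run_md
#' @export
nve_run <- function(system, config, params = default_forcefield()) {
  config$thermostat <- "none"
  run_md(system, config, params)
}

#' Restrained relaxation
#'
#' Short NVT run with a harmonic positional restraint (energy
#' `k |dx|^2`) holding every peptide atom at its input position --
#' the equilibration stage used before releasing a peptide in water.
#' The restraint contributes to the reported potential energy while
#' active and is dropped from the returned system.
#'
#' @param system A `molsys`.
#' @param k Spring constant, kcal/mol/A^2 (default 10).
#' @param duration_fs Length of the restrained run (fs).
#' @param config Base `md_config` (its restraints/n_steps are
#'   overwritten).
#' @param params `ff_params`.
#' @return List: `system` (relaxed, unrestrained), `trajectory`,
#'   `rmsd` (peptide RMSD from the anchors at the final frame, A).
#' @export
restrained_relax <- function(system, k = 10, duration_fs = 1000,
                             config = md_config(), params = default_forcefield()) {
  idx <- which(system$atoms$group == "peptide" & !system$atoms$fixed)
  config$restraints <- if (k > 0)
    list(idx = idx, anchors = system$coords[idx, , drop = FALSE], k = k)
  else NULL
  config$n_steps <- max(1L, round(duration_fs / config$timestep_fs))
  traj <- nvt_run(system, config, params)
  out <- traj$final_system
  dx <- out$coords[idx, , drop = FALSE] - system$coords[idx, , drop = FALSE]
  list(system = out, trajectory = traj,
       rmsd = sqrt(mean(rowSums(dx^2))))
}
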