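#' Interaction strength parameters
#'
#' One positive strength per interaction class (energy per nm^2 for bonds,
#' per rad^2 for angles, in the model's reduced energy unit).  The study
#' protocol sweeps each over `{3, 9, 18, 30, 39, 48, 57}`.
#'
#' @param LatAssoc,LongAssoc,LatAngle,LongAngle,QuadAngles Positive reals.
#' @return An `interaction_params` list.
#' @export
interaction_params <- function(LatAssoc = 30, LongAssoc = 30, LatAngle = 30,
                               LongAngle = 30, QuadAngles = 30) {
  p <- list(LatAssoc = LatAssoc, LongAssoc = LongAssoc, LatAngle = LatAngle,
            LongAngle = LongAngle, QuadAngles = QuadAngles)
  if (any(unlist(p) <= 0)) stop("all interaction strengths must be positive")
  structure(p, class = "interaction_params")
}

# per-interaction spring constants and resting values in simulator units
# (lengths nm, angles radians)
lattice_coefficients <- function(geom, params) {
  bond_k <- unlist(params)[ifelse(geom$bond_type == "LatAssoc",
                                  "LatAssoc", "LongAssoc")]
  angle_class <- c(LatAngle = "LatAngle", LongAngle = "LongAngle",
                   QuadAcute = "QuadAngles", QuadObtuse = "QuadAngles")
  angle_k <- unlist(params)[angle_class[geom$angle_type]]
  list(bonds = matrix(as.integer(geom$bonds[, 1:2] - 1L), ncol = 2),
       bond_k = unname(bond_k), bond_r0 = geom$bond_r0,
       angles = matrix(as.integer(geom$angles[, 1:3] - 1L), ncol = 3),
       angle_k = unname(angle_k), angle_phi0 = geom$angle_phi0 * pi / 180)
}

#' Harmonic lattice potential energy with per-node attribution
#'
#' Bond terms `L (r - r0)^2` plus angle terms `L (phi - phi0)^2` (`phi` in
#' radians, resting angles converted from degrees).  Each interaction's
#' energy is split equally among its 2 (bond) or 3 (angle) participants, so
#' the per-node energies sum exactly to the total.
#'
#' @param geom A `lattice_geometry`.
#' @param positions `n x 3` coordinate matrix (nm).
#' @param params An [interaction_params()].
#' @return List `total` (scalar) and `per_node` (length-n vector).
#' @export
potential_energy <- function(geom, positions, params) {
  if (!is.matrix(positions) || ncol(positions) != 3 ||
      nrow(positions) != nrow(geom$coordinates))
    stop("positions must be node_count x 3")
  cf <- lattice_coefficients(geom, params)
  lattice_energy_cpp(positions, cf$bonds, cf$bond_k, cf$bond_r0,
                     cf$angles, cf$angle_k, cf$angle_phi0)
}

#' Analytic forces of the harmonic lattice
#'
#' Negative gradient of [potential_energy()] with respect to positions;
#' matches central finite differences of the energy.
#'
#' @inheritParams potential_energy
#' @return `n x 3` force matrix.
#' @export
lattice_forces <- function(geom, positions, params) {
  cf <- lattice_coefficients(geom, params)
  lattice_forces_cpp(positions, cf$bonds, cf$bond_k, cf$bond_r0,
                     cf$angles, cf$angle_k, cf$angle_phi0)
}

#' Simulation configuration
#'
#' Defaults are the study protocol: the load on the forced nodes ramps
#' linearly from zero over `ramp_steps` to `max_force` (applied along -y),
#' then holds for `hold_steps`; a frame is saved every `save_interval` steps
#' (12 frames at the defaults).  The first two rings are clamped and the last
#' two rings carry the load.  The integrator works in reduced units (length
#' nm, arbitrary energy unit, unit monomer mass, timestep chosen for
#' stability); no physical-unit fidelity is claimed for time or mass.
#'
#' @param n_nodes Node count of the simulated lattice (used to default the
#'   clamped/forced sets to the first/last two rings of a 13-wide tube).
#' @param k_per_turn Ring width used for those defaults.
#' @param timestep Integrator step (reduced time unit).
#' @param ramp_steps,hold_steps,save_interval Step counts; `save_interval`
#'   must divide `ramp_steps + hold_steps`.
#' @param max_force External force magnitude per forced node (reduced units),
#'   applied along `force_dir`.
#' @param force_dir Unit direction of the load (default -y).
#' @param clamped,forced 1-based node id vectors; must be disjoint.
#' @param temperature Langevin temperature (kT, reduced; small).
#' @param damping Langevin friction rate (1/time).
#' @param mass Monomer mass (reduced).
#' @param seed Integer seed for the thermal noise.
#' @return A `sim_config`.
#' @export
sim_config <- function(n_nodes = 624, k_per_turn = 13, timestep = 0.005,
                       ramp_steps = 128000, hold_steps = 256000,
                       save_interval = 32000, max_force = 2,
                       force_dir = c(0, -1, 0),
                       clamped = seq_len(2 * k_per_turn),
                       forced = (n_nodes - 2 * k_per_turn + 1):n_nodes,
                       temperature = 1e-4, damping = 0.5, mass = 1,
                       seed = 1) {
  if ((ramp_steps + hold_steps) %% save_interval != 0)
    stop("save_interval must divide ramp_steps + hold_steps")
  if (length(intersect(clamped, forced)) > 0)
    stop("clamped and forced node sets must be disjoint")
  structure(list(timestep = timestep, ramp_steps = as.integer(ramp_steps),
                 hold_steps = as.integer(hold_steps),
                 save_interval = as.integer(save_interval),
                 max_force = max_force,
                 force_dir = force_dir / sqrt(sum(force_dir^2)),
                 clamped = as.integer(clamped), forced = as.integer(forced),
                 temperature = temperature, damping = damping, mass = mass,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Desk-scale simulation preset
#'
#' A laptop-sized variant of the protocol: 12-ring tube, short ramp/hold
#' (1200 + 2400 steps), saving every 300 steps so each run still yields 12
#' frames.
#'
#' @param n_nodes,k_per_turn Lattice dimensions.
#' @param seed Thermal-noise seed.
#' @param ramp_steps,hold_steps,save_interval Desk-scale step counts.
#' @param ... Further overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_desk <- function(n_nodes = 156, k_per_turn = 13, seed = 1,
                            ramp_steps = 1200, hold_steps = 2400,
                            save_interval = 300, ...) {
  sim_config(n_nodes = n_nodes, k_per_turn = k_per_turn,
             ramp_steps = ramp_steps, hold_steps = hold_steps,
             save_interval = save_interval, seed = seed, ...)
}

#' Advance a Langevin state by a number of steps
#'
#' Velocity-Verlet integration with friction `-damping * m * v`, seeded
#' Gaussian thermal noise, pinned (clamped) nodes, and the ramped external
#' load on the forced nodes.  `start_step` positions the call on the force
#' ramp (steps are counted from the beginning of the run).
#'
#' @param state List with `positions` and `velocities` (`n x 3` each).
#' @param geom A `lattice_geometry`.
#' @param params An [interaction_params()].
#' @param config A [sim_config()].
#' @param n_steps Number of steps to take.
#' @param start_step Global step index of the first step taken.
#' @return Updated state list.
#' @export
step_langevin <- function(state, geom, params, config, n_steps = 1,
                          start_step = 1) {
  cf <- lattice_coefficients(geom, params)
  res <- langevin_run_cpp(state$positions, state$velocities,
                          cf$bonds, cf$bond_k, cf$bond_r0,
                          cf$angles, cf$angle_k, cf$angle_phi0,
                          config$mass, config$timestep, config$damping,
                          config$temperature, as.integer(n_steps),
                          config$ramp_steps, as.integer(start_step - 1L),
                          0L, config$force_dir, config$max_force,
                          config$clamped - 1L, config$forced - 1L)
  list(positions = res$positions, velocities = res$velocities)
}

#' Run one loaded-relaxation simulation
#'
#' Ramps the bending load over `ramp_steps`, holds it for `hold_steps`, and
#' records a frame every `save_interval` steps.  Each frame carries the
#' node-feature matrix `X` (`n x 10`: position, velocity, and the four
#' interaction coefficients, constant across nodes) and the per-node
#' potential energy target `y`.  Per-node forces are kept in the frame
#' metadata.
#'
#' @param geom A `lattice_geometry` (its coordinates are the initial state).
#' @param params An [interaction_params()].
#' @param config A [sim_config()].
#' @return List of `frame_record`s; each has `X`, `y`, `step`,
#'   `energy_total`, `forces`.
#' @export
run_simulation <- function(geom, params, config) {
  set.seed(config$seed)
  cf <- lattice_coefficients(geom, params)
  res <- langevin_run_cpp(geom$coordinates,
                          matrix(0, nrow(geom$coordinates), 3),
                          cf$bonds, cf$bond_k, cf$bond_r0,
                          cf$angles, cf$angle_k, cf$angle_phi0,
                          config$mass, config$timestep, config$damping,
                          config$temperature,
                          config$ramp_steps + config$hold_steps,
                          config$ramp_steps, 0L, config$save_interval,
                          config$force_dir, config$max_force,
                          config$clamped - 1L, config$forced - 1L)
  coeffs <- feature_coefficients(params)
  lapply(res$frames, function(fr) {
    n <- nrow(fr$positions)
    X <- cbind(fr$positions, fr$velocities,
               matrix(coeffs, n, 4, byrow = TRUE))
    colnames(X) <- c("x", "y", "z", "vx", "vy", "vz", names(coeffs))
    structure(list(X = X, y = fr$energy_per_node, step = fr$step,
                   energy_total = fr$energy_total, forces = fr$forces),
              class = "frame_record")
  })
}

# The input features carry exactly four interaction coefficients (the
# QuadAngles class is tied to LatAngle in the feature vector, honoring the
# 10-column input layout).
feature_coefficients <- function(params) {
  c(LatAssoc = params$LatAssoc, LongAssoc = params$LongAssoc,
    LatAngle = params$LatAngle, LongAngle = params$LongAngle)
}

#' Generate a simulated training dataset
#'
#' Runs one loaded-relaxation simulation per combination of interaction
#' strengths (Cartesian product of `grid`'s value lists) and concatenates
#' all saved frames.  The full study grid is 7 values for each of the 5
#' strength classes (7^5 runs); [generate_dataset_desk()] provides the
#' laptop-scale preset.
#'
#' @param geom A `lattice_geometry`.
#' @param grid Named list of value vectors for `LatAssoc`, `LongAssoc`,
#'   `LatAngle`, `LongAngle`, `QuadAngles`.  A class may instead be the
#'   string `"LatAngle"` etc. to tie it to another class's values.
#' @param config A [sim_config()].
#' @param progress Print a line per run.
#' @return An `mt_dataset`: `x` (`frames x n x 10` array), `y`
#'   (`frames x n`), `meta` (run/step bookkeeping data.frame), `geom`,
#'   `grid`.
#' @export
generate_dataset <- function(geom, grid, config, progress = FALSE) {
  classes <- c("LatAssoc", "LongAssoc", "LatAngle", "LongAngle", "QuadAngles")
  stopifnot(all(classes %in% names(grid)))
  tied <- vapply(grid, is.character, TRUE)
  combos <- do.call(expand.grid, grid[!tied])
  n <- nrow(geom$coordinates)
  xs <- list(); ys <- list(); meta <- list()
  for (r in seq_len(nrow(combos))) {
    vals <- as.list(combos[r, , drop = FALSE])
    for (cl in classes[tied]) vals[[cl]] <- vals[[grid[[cl]]]]
    params <- do.call(interaction_params, vals[classes])
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    frames <- tryCatch(run_simulation(geom, params, cfg), error = function(e) {
      warning("run ", r, " failed: ", conditionMessage(e)); NULL
    })
    if (is.null(frames)) {
      meta[[length(meta) + 1]] <- data.frame(run = r, step = NA, ok = FALSE)
      next
    }
    for (fr in frames) {
      xs[[length(xs) + 1]] <- fr$X
      ys[[length(ys) + 1]] <- fr$y
      meta[[length(meta) + 1]] <-
        data.frame(run = r, step = fr$step, ok = TRUE,
                   energy_total = fr$energy_total)
    }
    if (progress)
      message(sprintf("run %d/%d done", r, nrow(combos)))
  }
  nf <- length(xs)
  x <- array(0, c(nf, n, 10),
             dimnames = list(NULL, NULL, colnames(xs[[1]])))
  for (f in seq_len(nf)) x[f, , ] <- xs[[f]]
  structure(list(x = x, y = do.call(rbind, ys),
                 meta = do.call(rbind, meta), geom = geom, grid = grid),
            class = "mt_dataset")
}

#' @export
print.mt_dataset <- function(x, ...) {
  cat(sprintf("mt_dataset: %d frames x %d nodes x %d features\n",
              dim(x$x)[1], dim(x$x)[2], dim(x$x)[3]))
  invisible(x)
}

#' Desk-scale dataset preset
#'
#' A 12-ring microtubule (156 nodes) in geometric equilibrium at zero load,
#' with the four feature coefficient classes each swept over `{3, 57}`
#' (QuadAngles tied to LatAngle), one short loaded-relaxation run per
#' combination: 16 runs x 12 frames = 192 frames.
#'
#' @param seed Base seed for the runs' thermal noise.
#' @param values Strength values swept per class.
#' @param n_rings Tube length.
#' @param progress Print per-run progress.
#' @return An `mt_dataset`.
#' @export
generate_dataset_desk <- function(seed = 1, values = c(3, 57), n_rings = 12,
                                  progress = FALSE) {
  geom <- build_lattice_geometry(tube_spec(n_rings, 13, 3),
                                 resting = "geometry")
  grid <- list(LatAssoc = values, LongAssoc = values, LatAngle = values,
               LongAngle = values, QuadAngles = "LatAngle")
  cfg <- sim_config_desk(n_nodes = n_rings * 13, seed = seed)
  generate_dataset(geom, grid, cfg, progress = progress)
}
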