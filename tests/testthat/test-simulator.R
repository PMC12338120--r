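toy_geom <- function(n_rings = 3, k = 5, p = 1) {
  suppressWarnings(build_lattice_geometry(tube_spec(n_rings, k, p),
                                          resting = "geometry"))
}

test_that("potential energy: resting zero, single-bond formula, per-node sum", {
  geom <- toy_geom()
  params <- interaction_params(11, 13, 17, 19, 23)
  pe0 <- potential_energy(geom, geom$coordinates, params)
  expect_lt(abs(pe0$total), 1e-9)
  expect_lt(max(abs(pe0$per_node)), 1e-9)
  # stretch one longitudinal bond axially by delta: energy L * delta^2 in
  # that bond, plus whatever the moved node's angles contribute; isolate by
  # a 2-node toy geometry
  g2 <- list(spec = tube_spec(2, 3, 0), coordinates = rbind(c(0, 0, 0), c(0, 0, 5)),
             bonds = cbind(1, 2, 1), bond_type = "LongAssoc",
             angle_type = character(0),
             angles = matrix(integer(0), 0, 4), bond_r0 = 5,
             angle_phi0 = numeric(0),
             resting_lengths = list(LongAssoc = 5),
             resting_angles = list())
  class(g2) <- "lattice_geometry"
  delta <- 0.3
  pe <- potential_energy(g2, rbind(c(0, 0, 0), c(0, 0, 5 + delta)),
                         interaction_params(LongAssoc = 19))
  expect_equal(pe$total, 19 * delta^2, tolerance = 1e-12)
  expect_equal(pe$per_node, rep(19 * delta^2 / 2, 2), tolerance = 1e-12)
  # randomized configuration: per-node attribution conserves the total and
  # matches a term-by-term R oracle
  set.seed(211)
  pos <- geom$coordinates + matrix(rnorm(length(geom$coordinates), sd = 0.2),
                                   ncol = 3)
  pe <- potential_energy(geom, pos, params)
  expect_equal(sum(pe$per_node), pe$total, tolerance = 1e-9 * abs(pe$total))
  oracle <- 0
  kmap <- c(LatAssoc = params$LatAssoc, LongAssoc = params$LongAssoc)
  for (b in seq_len(nrow(geom$bonds))) {
    d <- sqrt(sum((pos[geom$bonds[b, 1], ] - pos[geom$bonds[b, 2], ])^2))
    oracle <- oracle + kmap[geom$bond_type[b]] * (d - geom$bond_r0[b])^2
  }
  amap <- c(LatAngle = params$LatAngle, LongAngle = params$LongAngle,
            QuadAcute = params$QuadAngles, QuadObtuse = params$QuadAngles)
  for (a in seq_len(nrow(geom$angles))) {
    v1 <- pos[geom$angles[a, 1], ] - pos[geom$angles[a, 2], ]
    v2 <- pos[geom$angles[a, 3], ] - pos[geom$angles[a, 2], ]
    phi <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
    oracle <- oracle + amap[geom$angle_type[a]] *
      (phi - geom$angle_phi0[a] * pi / 180)^2
  }
  expect_equal(pe$total, unname(oracle), tolerance = 1e-9)
})

test_that("analytic forces match central finite differences", {
  set.seed(221)
  geom <- toy_geom(4, 5, 1)
  params <- interaction_params(7, 11, 13, 17, 19)
  for (trial in 1:4) {
    pos <- geom$coordinates +
      matrix(rnorm(length(geom$coordinates), sd = 0.15), ncol = 3)
    F <- lattice_forces(geom, pos, params)
    h <- 1e-6
    for (probe in 1:25) {
      i <- sample(nrow(pos), 1); c <- sample(3, 1)
      pp <- pos; pp[i, c] <- pp[i, c] + h
      pm <- pos; pm[i, c] <- pm[i, c] - h
      fd <- -(potential_energy(geom, pp, params)$total -
              potential_energy(geom, pm, params)$total) / (2 * h)
      expect_equal(F[i, c], fd, tolerance = 1e-5 * max(1, abs(fd)))
    }
  }
  # stretched single bond: equal and opposite axial forces
  g2 <- list(spec = tube_spec(2, 3, 0), coordinates = rbind(c(0, 0, 0), c(0, 0, 5)),
             bonds = cbind(1, 2, 1), bond_type = "LongAssoc",
             angle_type = character(0), angles = matrix(integer(0), 0, 4),
             bond_r0 = 5, angle_phi0 = numeric(0),
             resting_lengths = list(LongAssoc = 5), resting_angles = list())
  class(g2) <- "lattice_geometry"
  F <- lattice_forces(g2, rbind(c(0, 0, 0), c(0, 0, 5.4)),
                      interaction_params(LongAssoc = 10))
  expect_equal(F[1, ], -F[2, ])
  expect_equal(F[1, 1:2], c(0, 0))
  expect_equal(F[2, 3], -2 * 10 * 0.4, tolerance = 1e-10)
})

test_that("langevin stepping: equilibrium fixed point and pinned clamps", {
  geom <- toy_geom(4, 5, 1)
  params <- interaction_params()
  cfg <- sim_config(n_nodes = 20, k_per_turn = 5, ramp_steps = 100,
                    hold_steps = 100, save_interval = 50, max_force = 0,
                    temperature = 0, seed = 1)
  st0 <- list(positions = geom$coordinates,
              velocities = matrix(0, 20, 3))
  st1 <- step_langevin(st0, geom, params, cfg, n_steps = 50)
  expect_equal(st1$positions, geom$coordinates, tolerance = 1e-12)
  expect_equal(max(abs(st1$velocities)), 0)
  # under load, clamped nodes never move
  cfg2 <- sim_config(n_nodes = 20, k_per_turn = 5, ramp_steps = 50,
                     hold_steps = 50, save_interval = 50, max_force = 1,
                     temperature = 1e-4, seed = 2)
  set.seed(2)
  st2 <- step_langevin(st0, geom, params, cfg2, n_steps = 100)
  expect_equal(st2$positions[cfg2$clamped, ],
               geom$coordinates[cfg2$clamped, ], tolerance = 0)
  expect_gt(max(abs(st2$positions[-cfg2$clamped, ] -
                    geom$coordinates[-cfg2$clamped, ])), 1e-4)
})

test_that("undamped oscillator conserves energy to integrator order", {
  g2 <- list(spec = tube_spec(2, 3, 0), coordinates = rbind(c(0, 0, 0), c(0, 0, 5)),
             bonds = cbind(1, 2, 1), bond_type = "LongAssoc",
             angle_type = character(0), angles = matrix(integer(0), 0, 4),
             bond_r0 = 5, angle_phi0 = numeric(0),
             resting_lengths = list(LongAssoc = 5), resting_angles = list())
  class(g2) <- "lattice_geometry"
  params <- interaction_params(LongAssoc = 10)
  cfg <- sim_config(n_nodes = 2, timestep = 0.002, ramp_steps = 0,
                    hold_steps = 4000, save_interval = 4000, max_force = 0,
                    temperature = 0, damping = 0, clamped = integer(0),
                    forced = integer(0), seed = 1)
  st <- list(positions = rbind(c(0, 0, 0), c(0, 0, 5.5)),
             velocities = matrix(0, 2, 3))
  e0 <- potential_energy(g2, st$positions, params)$total
  st2 <- step_langevin(st, g2, params, cfg, n_steps = 4000)
  e2 <- potential_energy(g2, st2$positions, params)$total +
    0.5 * sum(st2$velocities^2)   # unit mass
  expect_equal(e2, e0, tolerance = 1e-3)
})

test_that("simulation runs save the protocol's frame count", {
  # full-scale step counts: 128000 ramp + 256000 hold / 32000 = 12 frames
  cfg <- sim_config()
  expect_equal((cfg$ramp_steps + cfg$hold_steps) / cfg$save_interval, 12)
  geom <- toy_geom(4, 5, 1)
  cfg2 <- sim_config(n_nodes = 20, k_per_turn = 5, ramp_steps = 200,
                     hold_steps = 200, save_interval = 100, seed = 3,
                     max_force = 0.5)
  frames <- run_simulation(geom, interaction_params(), cfg2)
  expect_length(frames, 4)
  # one frame when the interval equals the run length
  cfg3 <- sim_config(n_nodes = 20, k_per_turn = 5, ramp_steps = 200,
                     hold_steps = 200, save_interval = 400, seed = 3,
                     max_force = 0.5)
  expect_length(run_simulation(geom, interaction_params(), cfg3), 1)
  # frame payload: X is n x 10 with constant coefficient columns; y sums to
  # the recorded total
  fr <- frames[[4]]
  expect_equal(dim(fr$X), c(20L, 10L))
  expect_equal(unname(fr$X[1, 7:10]), unname(fr$X[20, 7:10]))
  expect_equal(sum(fr$y), fr$energy_total,
               tolerance = 1e-9 * max(1, abs(fr$energy_total)))
})

test_that("late-hold frames approach an energy plateau on a stiff toy", {
  geom <- toy_geom(3, 5, 1)
  cfg <- sim_config(n_nodes = 15, k_per_turn = 5, ramp_steps = 600,
                    hold_steps = 7800, save_interval = 600, seed = 4,
                    max_force = 0.5, damping = 3, temperature = 0,
                    clamped = 1:5, forced = 11:15)
  frames <- run_simulation(geom, interaction_params(57, 57, 57, 57, 57), cfg)
  e <- vapply(frames, function(f) f$energy_total, 1)
  n <- length(e)
  expect_lt(abs(e[n] - e[n - 1]) / abs(e[n]), 0.01)
})

test_that("datasets assemble the Cartesian strength grid", {
  ds <- tiny_dataset()
  # 2 x 1 x 2 x 1 grid with QuadAngles tied: 4 runs x 12 frames
  expect_equal(dim(ds$x), c(48, 52, 10))
  expect_equal(dim(ds$y), c(48, 52))
  expect_equal(length(unique(ds$meta$run)), 4)
  expect_true(all(table(ds$meta$run) == 12))
  # exactly four coefficient columns, constant across nodes and matching the
  # swept grid values
  expect_equal(dimnames(ds$x)[[3]][7:10],
               c("LatAssoc", "LongAssoc", "LatAngle", "LongAngle"))
  expect_true(all(ds$x[, , "LongAssoc"] == 30))
  expect_setequal(unique(as.numeric(ds$x[, 1, "LatAssoc"])), c(3, 57))
  expect_true(all(is.finite(ds$x)) && all(is.finite(ds$y)))
  # full protocol grid size: 7 values x 5 classes
  full <- expand.grid(rep(list(c(3, 9, 18, 30, 39, 48, 57)), 5))
  expect_equal(nrow(full), 7^5)
  # single-combination grid produces one run
  geom <- toy_geom(3, 5, 1)
  cfg <- sim_config(n_nodes = 15, k_per_turn = 5, ramp_steps = 100,
                    hold_steps = 100, save_interval = 100, seed = 5,
                    max_force = 0.2, clamped = 1:5, forced = 11:15)
  one <- generate_dataset(geom, list(LatAssoc = 30, LongAssoc = 30,
                                     LatAngle = 30, LongAngle = 30,
                                     QuadAngles = 30), cfg)
  expect_equal(length(unique(one$meta$run)), 1)
  expect_equal(dim(one$x)[1], 2)
})

test_that("stiffer lattices deflect less under the same load", {
  geom <- suppressWarnings(build_lattice_geometry(tube_spec(8, 13, 3),
                                                  resting = "geometry"))
  cfg <- sim_config_desk(n_nodes = 104, seed = 6, ramp_steps = 800,
                         hold_steps = 1600, save_interval = 600)
  soft <- run_simulation(geom, interaction_params(3, 3, 3, 3, 3), cfg)
  stiff <- run_simulation(geom, interaction_params(57, 57, 57, 57, 57), cfg)
  tipdef <- function(frames) {
    f <- frames[[length(frames)]]
    tips <- 92:104
    mean(abs(f$X[tips, "y"] - geom$coordinates[tips, 2]))
  }
  expect_gt(tipdef(soft), tipdef(stiff))
})
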