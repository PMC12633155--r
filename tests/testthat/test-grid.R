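test_that("the periodic 8-neighborhood wraps and is symmetric", {
  nb <- neighbor_coords(5, 5, 100)
  expect_equal(nrow(nb), 8L)
  want <- expand.grid(row = 4:6, col = 4:6)
  want <- want[!(want$row == 5 & want$col == 5), ]
  expect_setequal(paste(nb[, 1], nb[, 2]), paste(want$row, want$col))

  corner <- neighbor_coords(0, 0, 100)
  keys <- paste(corner[, 1], corner[, 2])
  expect_true(all(c("99 99", "99 0", "0 99") %in% keys))
  expect_false("0 0" %in% keys)

  expect_error(neighbor_coords(5, 5, 5), "out of range")
  expect_error(neighbor_coords(-1, 0, 5), "out of range")

  # a is b's neighbor iff b is a's neighbor: exhaustive over a 5x5 grid
  key <- function(m) paste(m[, 1], m[, 2])
  nbs <- lapply(0:24, function(c0)
    key(neighbor_coords(c0 %% 5, c0 %/% 5, 5)))
  for (a in 0:24) for (b in 0:24) {
    a_in_b <- paste(a %% 5, a %/% 5) %in% nbs[[b + 1]]
    b_in_a <- paste(b %% 5, b %/% 5) %in% nbs[[a + 1]]
    expect_identical(a_in_b, b_in_a)
  }
})

test_that("the diffusion operator matches hand enumeration and conserves mass", {
  expect_equal(diffusion_term(matrix(0.37, 6, 6), 0.25), matrix(0, 6, 6))

  f <- matrix(0, 5, 5); f[3, 3] <- 1
  out <- diffusion_term(f, 0.25)
  expect_equal(out[3, 3], 0.25 * 8 * (0 - 1))
  expect_equal(out[2:4, 2:4][-5], rep(0.25, 8))
  expect_equal(sum(out), 0)

  set.seed(7)
  for (k in 1:20) {
    plane <- matrix(runif(15^2), 15, 15)
    expect_lt(abs(sum(diffusion_term(plane, runif(1, 0, 0.5)))), 1e-12)
  }
  expect_error(diffusion_term(matrix(c(1, NA, 1, 1), 2, 2), 0.1), "finite")
})

test_that("the adaptive step caps at dt_max and scales with the peak rate", {
  pol <- step_policy()
  expect_equal(adaptive_dt(0, pol), 0.1)
  expect_equal(adaptive_dt(2.0, pol), 0.05)
  expect_equal(adaptive_dt(0.5, pol), 0.1)
  expect_equal(adaptive_dt(100, step_policy(dt_max = 0.2, safety_theta = 0.5)),
               0.005)
})

test_that("zero state with zero inputs is a global fixed point", {
  net <- build_reference_network()
  cfg <- simulation_config(grid_size = 5, seed = 1,
                           initial_noise_amplitude = 0)
  st <- grid_state(net, cfg)
  expect_true(all(st$X == 0) && all(st$ecm == 0))
  st2 <- grid_step(st, net, cfg)
  expect_true(all(st2$X == 0))
  expect_true(all(st2$fb == 0))
  expect_true(all(st2$ecm == 0))
})

test_that("spatially uniform states stay uniform under uniform inputs", {
  net <- build_reference_network()
  cfg <- simulation_config(grid_size = 6, seed = 3,
                           initial_noise_amplitude = 0)
  st <- grid_state(net, cfg)
  st$X[] <- rep(runif(ncol(st$X), 0, 0.5), each = 36)
  inputs <- array(0, c(6, 6, 10)); inputs[, , 1] <- 1
  for (k in 1:10) st <- grid_step(st, net, cfg, inputs = inputs)
  for (s in seq_len(ncol(st$X)))
    expect_equal(max(st$X[, s]) - min(st$X[, s]), 0)
  for (k in seq_len(ncol(st$fb)))
    expect_equal(max(st$fb[, k]) - min(st$fb[, k]), 0)
})

test_that("diffusion-only dynamics conserve each field's grid total", {
  net <- diffusion_only_network()
  cfg <- simulation_config(grid_size = 12, seed = 11,
                           initial_noise_amplitude = 0)
  st <- grid_state(net, cfg)
  set.seed(11)
  st$fb[, 1] <- runif(144)
  total0 <- sum(st$fb[, 1])
  for (k in 1:100) st <- grid_step(st, net, cfg, fixed_dt = 0.1)
  expect_lt(abs(sum(st$fb[, 1]) - total0), 1e-9)
  expect_gt(max(st$fb[, 1]) - min(st$fb[, 1]), 0)  # not yet fully mixed
  expect_lt(stats::sd(st$fb[, 1]), stats::sd(runif(144)))
})

test_that("diffusion commutes with periodic translation of the field", {
  net <- diffusion_only_network()
  cfg <- simulation_config(grid_size = 9, seed = 5,
                           initial_noise_amplitude = 0)
  set.seed(5)
  plane <- matrix(runif(81), 9, 9)
  shift <- function(m, di, dj) {
    m[((seq_len(9) - 1 - di) %% 9) + 1, ((seq_len(9) - 1 - dj) %% 9) + 1]
  }
  run_from <- function(p) {
    st <- grid_state(net, cfg)
    st$fb[, 1] <- as.vector(p)
    for (k in 1:25) st <- grid_step(st, net, cfg, fixed_dt = 0.1)
    matrix(st$fb[, 1], 9, 9)
  }
  base <- run_from(plane)
  for (d in list(c(2, 0), c(0, 3), c(4, 7))) {
    shifted <- run_from(shift(plane, d[1], d[2]))
    expect_equal(shifted, shift(base, d[1], d[2]), tolerance = 1e-14)
  }
})

test_that("every concentration stays inside [0, 1] after every step", {
  net <- build_reference_network()
  set.seed(99)
  for (rep in 1:3) {
    cfg <- simulation_config(grid_size = 5, seed = sample.int(1000, 1),
                             initial_noise_amplitude = runif(1, 0, 1))
    st <- grid_state(net, cfg)
    inputs <- array(runif(5 * 5 * 10), c(5, 5, 10))
    for (k in 1:30) {
      st <- grid_step(st, net, cfg, inputs = inputs)
      expect_gte(min(st$X, st$fb, st$ecm), 0)
      expect_lte(max(st$X, st$fb, st$ecm), 1)
    }
  }
})

test_that("state-variable accounting scales as (species + fields) * N^2", {
  net <- build_reference_network()
  expect_identical(count_state_variables(net, 100), 1360000)
  expect_identical(count_state_variables(net, 10), 13600)
  toy <- network_spec(
    species = data.frame(name = c("A", "B"), module = "other"),
    edges = list(list(target = "B", activators = "A", sign = "production")))
  expect_identical(count_state_variables(toy, 3), 18)
})

test_that("trajectories are reproducible and snapshots respect the contract", {
  net <- build_reference_network()
  cfg <- simulation_config(grid_size = 8, seed = 21)
  scen <- scenario(make_brush_mask("x_shape", N = 8), c(TGFB = 1),
                   duration_iterations = 20L,
                   snapshot_iterations = c(0L, 10L, 20L),
                   probe_cells = rbind(c(0, 0), c(4, 4)))
  sim1 <- run_simulation(scen, net, cfg)
  sim2 <- run_simulation(scen, net, cfg)
  expect_identical(sim1$final, sim2$final)
  expect_identical(sim1$probes, sim2$probes)
  # iteration-0 snapshot is exactly the seeded initial state
  expect_identical(sim1$snapshots[["0"]]$ecm, grid_state(net, cfg)$ecm)
  # changing the seed changes the trajectory
  sim3 <- run_simulation(scen, net,
                         simulation_config(grid_size = 8, seed = 22))
  expect_false(identical(sim1$final$X, sim3$final$X))
  expect_error(
    scenario(make_brush_mask("x_shape", N = 8), c(TGFB = 1),
             duration_iterations = 10L, snapshot_iterations = c(0L, 50L)),
    "snapshot_iterations")
})

test_that("a corrupted state names the offending cell and species", {
  net <- toy_chain_network()
  cfg <- simulation_config(grid_size = 3, seed = 1)
  st <- grid_state(net, cfg)
  st$X[5, 2] <- NaN  # cell (1, 1), species A
  expect_error(grid_step(st, net, cfg), "cell \\(1, 1\\), species A")
})
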