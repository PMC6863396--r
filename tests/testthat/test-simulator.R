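# Single-species model with only turnover: closed-form exponential decay.
decay_wiring <- function(k = 0.01) {
  sp <- rbind(
    species_def("Solo", "protein", initial_active = 100),
    species_def("Input", "biophysical", has_turnover = FALSE,
                is_clamped_input = TRUE))
  wiring_diagram(sp, edge_def("Input", "Solo", "activate", "one_step")[0, ])
}

decay_model <- function(k = 0.01) {
  w <- decay_wiring()
  prof <- data.frame(name = "kt_Solo", value = k, class = "turnover",
                     is_reverse = FALSE, paired_forward = NA,
                     stringsAsFactors = FALSE)
  compile_model(w, prof)
}

test_that("turnover-only model matches the exponential decay closed form", {
  m <- decay_model(k = 0.01)
  traj <- simulate_model(m, settings = sim_settings(1000, 25))
  sol <- observable(traj, "Solo")
  expect_equal(sol$value, 100 * exp(-0.01 * sol$time), tolerance = 1e-8)
  # absolute solver error (atol 1e-10) dominates at this tiny value
  expect_equal(sol$value[sol$time == 1000], 100 * exp(-10), tolerance = 1e-6)
})

test_that("default grid covers 0..10000 s in 25 s steps (401 points)", {
  m <- decay_model()
  traj <- simulate_model(m)
  expect_length(traj$time, 401L)
  expect_equal(traj$time[2] - traj$time[1], 25)
  expect_equal(max(traj$time), 10000)
})

test_that("mass-action time rescaling: 10x rates at t/10 reproduces the state", {
  m <- compile_model(canonical_wiring())
  fast <- m
  fast$parameters$value <- m$parameters$value * 10
  slow_traj <- simulate_model(m, settings = sim_settings(10000, 250))
  fast_traj <- simulate_model(fast, settings = sim_settings(1000, 25))
  expect_equal(unname(fast_traj$state), unname(slow_traj$state),
               tolerance = 1e-8)
  expect_lt(max(abs(fast_traj$state - slow_traj$state)), 1e-6)
})

test_that("halving the output interval leaves shared-grid values unchanged", {
  m <- compile_model(canonical_wiring())
  coarse <- simulate_model(m, settings = sim_settings(2000, 50))
  fine <- simulate_model(m, settings = sim_settings(2000, 25))
  shared <- match(coarse$time, fine$time)
  expect_lt(max(abs(fine$state[shared, ] - coarse$state)), 1e-6)
})

test_that("canonical trajectories conserve moieties and respect bounds", {
  m <- compile_model(canonical_wiring())
  traj <- simulate_model(m, settings = sim_settings(10000, 100))
  expect_true(as.logical(trajectory_conservation(traj, tol = 1e-6)))
  expect_true(min(traj$state) >= -1e-8)
  # no active pool exceeds its 100-unit moiety
  act <- traj$state[, grep("_(a|i)$", colnames(traj$state))]
  expect_true(max(act) <= 100 + 1e-6)
})

test_that("agreement with a fixed-step classical RK4 reference integrator", {
  m <- compile_model(canonical_wiring())
  t_end <- 500
  traj <- simulate_model(m, settings = sim_settings(t_end, 25))
  ref <- deSolve::rk4(
    y = stats::setNames(as.numeric(default_initial_conditions(m$wiring))[
      match(m$pools, names(default_initial_conditions(m$wiring)))], m$pools),
    times = seq(0, t_end, by = 0.25),
    func = function(t, y, p) list(model_derivatives(m, y)),
    parms = NULL)
  shared <- match(traj$time, ref[, 1])
  expect_lt(max(abs(traj$state - ref[shared, -1])), 1e-3)
})

test_that("events split the integration and reassign targets", {
  m <- decay_model(k = 0.01)
  # halve the decay rate at t = 500
  traj <- simulate_model(m, events = list(
    sim_event(500, "set_parameter", "kt_Solo", 0.005)),
    settings = sim_settings(1000, 25))
  sol <- observable(traj, "Solo")
  expect_equal(sol$value[sol$time == 500], 100 * exp(-5), tolerance = 1e-7)
  expect_equal(sol$value[sol$time == 1000], 100 * exp(-5 - 0.005 * 500),
               tolerance = 1e-7)
  # set_species jump
  traj2 <- simulate_model(m, events = list(
    sim_event(500, "set_species", "Solo", 100)),
    settings = sim_settings(1000, 25))
  s2 <- observable(traj2, "Solo")
  expect_equal(s2$value[s2$time == 525], 100 * exp(-0.01 * 25),
               tolerance = 1e-6)
  # unknown event target is rejected
  expect_error(simulate_model(m, events = list(
    sim_event(500, "set_parameter", "nope", 1))), "unknown")
  # event outside (0, t_end) is rejected
  expect_error(simulate_model(m, events = list(
    sim_event(2000, "set_parameter", "kt_Solo", 1)),
    settings = sim_settings(1000, 25)), "event times")
})

test_that("steady-state detection distinguishes plateau, decay and oscillation", {
  m <- decay_model(k = 0.01)
  # decay sampled far past 10 half-lives converges near zero
  traj <- simulate_model(m, settings = sim_settings(20000, 100))
  ss <- steady_state(traj, window = 1000, rel_tol = 0.01)
  expect_true(ss$converged)
  expect_lt(ss$final_state[["Solo_a"]], 1e-10)
  # early transient does not converge
  early <- simulate_model(m, settings = sim_settings(500, 25))
  expect_false(steady_state(early, window = 250, rel_tol = 0.01)$converged)
  # synthetic sinusoid is not converged; constant trajectory is
  fake <- traj
  fake$state[, "Solo_a"] <- 50 + 10 * sin(fake$time / 300)
  expect_false(steady_state(fake, window = 1000, rel_tol = 0.01)$converged)
  const <- traj
  const$state[] <- 42
  ssc <- steady_state(const, window = 1000, rel_tol = 0.01)
  expect_true(ssc$converged)
  expect_equal(unname(ssc$final_state[["Solo_a"]]), 42)
  expect_error(steady_state(traj, window = 1e6), "window")
})

test_that("observable extraction validates names and stays in bounds", {
  m <- compile_model(canonical_wiring())
  traj <- simulate_model(m, settings = sim_settings(1000, 25))
  rr <- observable(traj, "RearRetraction")
  expect_true(all(rr$value >= -1e-9 & rr$value <= 100 + 1e-9))
  expect_error(observable(traj, "NoSuchNode"), "unknown species")
})

test_that("trajectory CSV round trip is lossless at double precision", {
  m <- decay_model()
  traj <- simulate_model(m, settings = sim_settings(500, 25))
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  back <- read_trajectory_csv(path)
  expect_equal(back$time_s, traj$time)
  expect_identical(colnames(back), c("time_s", colnames(traj$state)))
  expect_equal(as.matrix(back[, -1]), traj$state, ignore_attr = TRUE)
})
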