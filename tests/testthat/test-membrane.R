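test_that("gating rates take their analytic limits at the removable singularities", {
  r25 <- gating_rates(25)
  expect_equal(r25$a_m, 1.0, tolerance = 1e-12)
  r10 <- gating_rates(10)
  expect_equal(r10$a_n, 0.1, tolerance = 1e-12)
  # continuity across the singular points
  eps <- 1e-9
  expect_equal(gating_rates(25 + eps)$a_m, gating_rates(25 - eps)$a_m,
               tolerance = 1e-6)
  # positivity over the physiological range
  v <- seq(-50, 150, by = 0.5)
  r <- gating_rates(v)
  for (nm in names(r)) expect_true(all(r[[nm]] >= 0))
})

test_that("resting steady states match an independent ODE oracle", {
  # independent oracle: integrate dx/dt = a(1-x) - b x at fixed V = 0 to
  # equilibrium with an adaptive solver, from a far-away start
  library(deSolve)
  rhs <- function(t, y, parms) {
    r <- gating_rates(0)
    list(c(r$a_n * (1 - y[1]) - r$b_n * y[1],
           r$a_m * (1 - y[2]) - r$b_m * y[2],
           r$a_h * (1 - y[3]) - r$b_h * y[3]))
  }
  sol <- ode(c(0.9, 0.9, 0.1), times = c(0, 200), func = rhs, parms = NULL,
             rtol = 1e-10, atol = 1e-12)
  ss <- gating_steady_state(0)
  expect_equal(unname(sol[2, 2:4]), c(ss$n, ss$m, ss$h), tolerance = 1e-8)
  expect_equal(ss$n, 0.3177, tolerance = 1e-3)
  expect_equal(ss$m, 0.0529, tolerance = 1e-3)
  expect_equal(ss$h, 0.5961, tolerance = 1e-3)
})

test_that("channel current vanishes at reversal and with closed channels", {
  p <- hh_parameters(g_k = 0, g_l = 0)
  expect_equal(hh_current(p$e_na, n = 0.5, m = 1, h = 1, p), 0)
  p2 <- hh_parameters(g_l = 0)
  expect_equal(hh_current(-30, n = 0, m = 0, h = 1, p2), 0)
  expect_equal(hh_current(80, n = 0, m = 0, h = 0.3, p2), 0)
  # independent term-by-term arithmetic at rest
  ss <- gating_steady_state(0)
  p3 <- hh_parameters()
  j <- hh_current(0, ss$n, ss$m, ss$h, p3)
  j_oracle <- ss$m^3 * ss$h * 120 * (0 - 115) +
    ss$n^4 * 36 * (0 + 12) + 0.3 * (0 - 10.6)
  expect_equal(j, j_oracle, tolerance = 1e-12)
  expect_error(hh_current(0, n = 1.2, m = 0, h = 0), "n")
})

test_that("gating advance matches the exact relaxation and a reference ODE", {
  # rush_larsen is the exact solution of the frozen-voltage linear ODE
  v <- 20
  r <- gating_rates(v)
  g0 <- list(n = 0.2, m = 0.7, h = 0.4)
  g1 <- advance_gating(g0, v, dt = 3, scheme = "rush_larsen")
  ninf <- r$a_n / (r$a_n + r$b_n)
  expect_equal(g1$n, ninf + (0.2 - ninf) * exp(-3 * (r$a_n + r$b_n)),
               tolerance = 1e-13)
  # steady state is stationary
  ss <- gating_steady_state(-5)
  g2 <- advance_gating(list(n = ss$n, m = ss$m, h = ss$h), -5, dt = 0.5)
  expect_equal(g2$n, ss$n, tolerance = 1e-12)
  # implicit stepping at dt = 1e-3 ms against a high-accuracy adaptive
  # integration of the same equations
  library(deSolve)
  vstep <- 50
  rhs <- function(t, y, parms) {
    r <- gating_rates(vstep)
    list(c(r$a_n * (1 - y[1]) - r$b_n * y[1],
           r$a_m * (1 - y[2]) - r$b_m * y[2],
           r$a_h * (1 - y[3]) - r$b_h * y[3]))
  }
  ss0 <- gating_steady_state(0)
  ref <- ode(c(ss0$n, ss0$m, ss0$h), times = c(0, 1), func = rhs,
             parms = NULL, rtol = 1e-12, atol = 1e-14)
  # exponential (Rush-Larsen) stepping is exact at frozen voltage
  g <- list(n = ss0$n, m = ss0$m, h = ss0$h)
  for (k in 1:1000) g <- advance_gating(g, vstep, dt = 1e-3,
                                        scheme = "rush_larsen")
  expect_equal(c(g$n, g$m, g$h), unname(ref[2, 2:4]), tolerance = 1e-9)
  # backward Euler carries its first-order global error
  g <- list(n = ss0$n, m = ss0$m, h = ss0$h)
  for (k in 1:1000) g <- advance_gating(g, vstep, dt = 1e-3)
  expect_equal(c(g$n, g$m, g$h), unname(ref[2, 2:4]), tolerance = 1e-3)
})

test_that("gating stays in [0, 1] for arbitrary voltage trajectories", {
  set.seed(42)
  for (rep_ in 1:20) {
    g <- list(n = runif(1), m = runif(1), h = runif(1))
    for (k in 1:50) {
      v <- runif(1, -200, 300)
      dt <- 10^runif(1, -3, 1)
      g <- advance_gating(g, v, dt,
                          scheme = sample(c("implicit", "rush_larsen"), 1))
      expect_true(all(unlist(g) >= 0 & unlist(g) <= 1))
    }
  }
})

test_that("synapse latch fires once and persists for the pulse duration", {
  syn <- synapse_spec(1, 2, threshold = 5, amplitude_nA = 3, duration = 2)
  st <- list(fired = FALSE, t_fire = NA_real_)
  # below threshold: never any current
  for (t in seq(0, 5, by = 0.5)) {
    st <- update_synapse(syn, st, v_m_pre = 4.9, t = t)
    expect_equal(synaptic_current(syn, st, t), 0)
  }
  # crossing at t0 = 1: rectangular pulse on (t0, t0 + 2], even though the
  # presynaptic potential falls back below threshold
  st <- list(fired = FALSE, t_fire = NA_real_)
  st <- update_synapse(syn, st, v_m_pre = 2, t = 0.5)
  st <- update_synapse(syn, st, v_m_pre = 8, t = 1)
  st <- update_synapse(syn, st, v_m_pre = -60, t = 1.5)  # repolarized
  expect_equal(synaptic_current(syn, st, 1.5), 3)
  expect_equal(synaptic_current(syn, st, 3.0), 3)
  expect_equal(synaptic_current(syn, st, 3.1), 0)
  # second crossing within the pulse: latch idempotent (single pulse)
  st2 <- update_synapse(syn, st, v_m_pre = 50, t = 2.5)
  expect_identical(st2$t_fire, st$t_fire)
  expect_error(synapse_spec(1, 1), "distinct cells")
})

test_that("total current density honors patch dynamics", {
  model <- membrane_model()
  ss <- gating_steady_state(0)
  g <- list(n = ss$n, m = ss$m, h = ss$h)
  # myelin: purely capacitive
  expect_equal(total_current_density("MYELIN", v_m = 30, dvdt = 0, g, model), 0)
  expect_equal(total_current_density("MYELIN", v_m = 30, dvdt = 10, g, model),
               model$params$c_m_myelin * 10)
  # dendrite: capacitive + leak only, independent of gating
  j_d <- total_current_density("DENDRITE", v_m = 7, dvdt = 2, g, model)
  expect_equal(j_d, 1 * 2 + 0.3 * (7 - 0), tolerance = 1e-12)
  g_open <- list(n = 1, m = 1, h = 1)
  expect_equal(total_current_density("DENDRITE", 7, 2, g_open, model), j_d)
  # active at rest: term-by-term oracle
  j_a <- total_current_density("ACTIVE", v_m = 0, dvdt = 0, g, model)
  expect_equal(j_a, hh_current(0, ss$n, ss$m, ss$h, model$params),
               tolerance = 1e-12)
  expect_error(total_current_density("AXON", 0, 0, g, model), "unknown")
})

test_that("a space-clamped active patch fires and repolarizes", {
  # short cable (well below the space constant) behaves as one compartment
  cfg <- cable1d_config(50, 20, sigma_in = 2, n_comp = 5,
                        stim_amplitude_nA = 2, stim_length = 50,
                        stim_t_off = 0.5, dt = 0.01, t_end = 20,
                        probes = 25)
  tr <- solve_cable_1d(cfg)
  expect_gt(max(tr$v), 80)   # spike overshoot above 80 mV over rest
  expect_lt(tr$v[nrow(tr$v), 1], 20)  # repolarized within 20 ms
})
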