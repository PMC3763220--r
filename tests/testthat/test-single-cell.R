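test_that("sigmoid gating function matches its closed form and saturates", {
  expect_equal(gate_sigmoid(-34, 34, 6.5), 0.5)
  expect_equal(gate_sigmoid(-51, 51, 5), 0.5) # n_inf at V = -51
  expect_equal(gate_sigmoid(1e4, 0, 5), 1)
  expect_equal(gate_sigmoid(-1e4, 0, 5), 0)
  # strictly monotone in x for z > 0
  x <- seq(-100, 40, by = 0.5)
  expect_true(all(diff(gate_sigmoid(x, 51, 5)) > 0))
  expect_error(gate_sigmoid(0, 0, 0), "nonzero")
})

test_that("gating kinetics match the printed rate functions", {
  k <- kinetics_at(c(-80, -60, -40, 0), sigma = 1)
  expect_true(all(k$tau_d == 50))
  # d gate carries no sigma shift: half activation exactly at -34 mV
  expect_equal(kinetics_at(-34, sigma = 1)$d_inf, 0.5)
  expect_equal(kinetics_at(-34, sigma = 5)$d_inf, 0.5)
  # time constants positive, steady states in [0, 1] across the range
  V <- seq(-120, 60, by = 0.25)
  k <- kinetics_at(V)
  for (nm in c("tau_h", "tau_c", "tau_d", "tau_e", "tau_f", "tau_t"))
    expect_true(all(k[[nm]] > 0), info = nm)
  for (nm in c("m_inf", "n_inf", "h_inf", "c_inf", "d_inf", "e_inf",
               "f_inf", "t_inf"))
    expect_true(all(k[[nm]] >= 0 & k[[nm]] <= 1), info = nm)
})

test_that("removable singularities are evaluated by their analytic limits", {
  sg <- 1
  # alpha_m at V = -30 + sigma has limit 1.0
  k0 <- kinetics_at(-30 + sg, sigma = sg)
  expect_equal(k0$alpha_m, 1.0, tolerance = 1e-9)
  kp <- kinetics_at(-30 + sg + 1e-6, sigma = sg)
  km <- kinetics_at(-30 + sg - 1e-6, sigma = sg)
  expect_lt(abs(kp$alpha_m - k0$alpha_m), 1e-6)
  expect_lt(abs(km$alpha_m - k0$alpha_m), 1e-6)
  # alpha_c at V = -34 + sigma has limit 10 * prefactor = 2.857
  k0 <- kinetics_at(-34 + sg, sigma = sg)
  expect_equal(k0$alpha_c, 2.857, tolerance = 1e-9)
  # continuity of all outputs across the singular points
  for (v0 in c(-30 + sg, -34 + sg)) {
    a <- kinetics_at(v0, sigma = sg)
    b <- kinetics_at(v0 + 1e-6, sigma = sg)
    for (nm in names(a))
      expect_lt(abs(a[[nm]] - b[[nm]]), 1e-5)
  }
})

test_that("ionic currents vanish at their reversal potentials", {
  p <- cell_parameters()
  st <- function(V) cell_state(V = V, h = 0.5, c = 0.5, d = 0.5,
                               e = 0.5, f = 0.5, t_gate = 0.5)
  cur <- ionic_currents(st(55), p)
  expect_equal(unname(cur["I_Na"]), 0)
  expect_equal(unname(cur["I_Nap"]), 0)
  cur <- ionic_currents(st(-90), p)
  expect_equal(unname(cur["I_Kd"]), 0)
  expect_equal(unname(cur["I_Ks"]), 0)
  cur <- ionic_currents(st(-60), p)
  expect_equal(unname(cur["I_l"]), 0)
  bad <- st(-60)
  bad["h"] <- 1.2
  expect_error(ionic_currents(unclass(bad), p), "invariant")
})

test_that("membrane derivative is linear in the injected current", {
  s <- cell_state(V = -52, h = 0.8, c = 0.1, d = 0.3, e = 0.6, f = 0.4,
                  t_gate = 0.2)
  p1 <- cell_parameters(I_inj = 0.1)
  p2 <- cell_parameters(I_inj = 0.5)
  d1 <- cell_derivative(s, p1)
  d2 <- cell_derivative(s, p2)
  expect_equal(unname(d2["V"] - d1["V"]), 0.4 / p1$C_m)
  expect_equal(d1[-1], d2[-1]) # gates unaffected
})

test_that("R reference derivative agrees with the simulation engine", {
  p <- cell_parameters(I_inj = 0.2, sigma = 1.5)
  set.seed(42)
  for (i in 1:20) {
    s <- cell_state(V = runif(1, -90, 20), h = runif(1), c = runif(1),
                    d = runif(1), e = runif(1), f = runif(1),
                    t_gate = runif(1))
    ie <- runif(1, -2, 2)
    is <- runif(1, -2, 2)
    dR <- cell_derivative(s, p, I_elec = ie, I_syn = is)
    dC <- iowave:::.cell_rhs_cpp(unclass(s), iowave:::.cell_consts(p),
                                 p$sigma, p$I_inj, ie, is)
    expect_lt(max(abs(dR - dC)), 1e-12)
  }
})

test_that("the vector field has a numerically consistent fixed point", {
  # at equilibrium every gate sits at its steady state, so the 7-D fixed
  # point reduces to a 1-D root of the membrane current balance in V
  p <- cell_parameters(I_inj = 0)
  f_V <- function(V) unname(cell_derivative(iowave:::.steady_state_at(V, p),
                                            p)["V"])
  # the single equilibrium sits in the depolarized range where the fast
  # sodium and delayed-rectifier currents balance
  V_star <- stats::uniroot(f_V, c(-35, -25), tol = 1e-14)$root
  st <- iowave:::.steady_state_at(V_star, p)
  expect_lt(max(abs(cell_derivative(st, p))), 1e-10)
  expect_true(all(unclass(st)[-1] >= 0 & unclass(st)[-1] <= 1))
})

test_that("gates stay in [0, 1] along trajectories from extreme states", {
  p <- cell_parameters(I_inj = 1.5) # tonic spiking
  rec <- simulate_cell(p, 800, record_states = TRUE,
                       state0 = cell_state(V = 20, h = 1, c = 1, d = 1,
                                           e = 1, f = 1, t_gate = 1))
  g <- rec$states[, -1]
  expect_true(all(g >= 0 & g <= 1))
  rec <- simulate_cell(cell_parameters(I_inj = 0), 800, record_states = TRUE,
                       state0 = cell_state(V = -110, h = 0, c = 0, d = 0,
                                           e = 0, f = 0, t_gate = 0))
  g <- rec$states[, -1]
  expect_true(all(g >= 0 & g <= 1))
})

test_that("the attractor is oscillatory across the subthreshold drive range", {
  for (I in c(0, 0.2, 0.35)) {
    rec <- simulate_cell(cell_parameters(I_inj = I), 5000,
                         integrator = integrator_config(max_error = 1e-8,
                                                        dt_max = 0.5,
                                                        dt_record = 0.5))
    V <- rec$V[rec$t > 4000]
    expect_gt(diff(range(V)), 1) # non-constant
    n_peaks <- sum(diff(sign(diff(V))) == -2)
    expect_gt(n_peaks, 3) # recurring maxima
  }
})

test_that("single-cell trajectory matches an independent ODE solver", {
  skip_if_not_installed("deSolve")
  p <- cell_parameters(I_inj = 0.1)
  s0 <- cell_state(V = -55, h = 0.85, c = 0.08, d = 0.15, e = 0.45,
                   f = 0.45, t_gate = 0.3)
  f <- function(t, y, parms) {
    st <- pmin(1, pmax(0, y))
    st[1] <- y[1]
    names(st) <- c("V", "h", "c", "d", "e", "f", "t_gate")
    list(unname(cell_derivative(st, p)))
  }
  ref <- deSolve::ode(unclass(s0), seq(0, 400, 0.5), f, NULL,
                      method = "ode45", atol = 1e-11, rtol = 1e-11)
  mine <- simulate_cell(p, 400, state0 = s0,
                        integrator = integrator_config(max_error = 1e-10,
                                                       dt_max = 0.5,
                                                       dt_record = 0.5))
  expect_lt(max(abs(ref[, 2] - mine$V)), 1e-5)
})

test_that("spiking frequency is non-decreasing in the injected current", {
  rate <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(I) {
    rec <- simulate_cell(cell_parameters(I_inj = I), 3000,
                         integrator = integrator_config(max_error = 1e-8,
                                                        dt_max = 0.5,
                                                        dt_record = 0.5))
    sum(rec$spikes > 1000) / 2
  }, 0)
  expect_true(all(diff(rate) >= 0))
  expect_gt(rate[5], rate[1])
})

test_that("threshold estimation needs a regenerative sodium current", {
  expect_error(estimate_spike_threshold(cell_parameters(gbar_Na = 0),
                                        ramp_duration = 1500),
               "no spike")
})
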