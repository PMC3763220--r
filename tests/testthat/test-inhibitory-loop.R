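test_that("synaptic conductance is converted to a membrane-area density", {
  il <- il_parameters()
  expect_equal(il$gsyn_density, 0.1 * 1e-6 / 1e-5) # 0.01 mS/cm^2
  expect_error(il_parameters(p_conn = 1.2), "p_conn")
  expect_error(il_parameters(sync_fraction = 0), "sync_fraction")
  expect_error(il_parameters(window = 0), "window")
})

test_that("loop wiring follows the connection probability", {
  top <- build_topology(20, 20, 4)
  w0 <- wire_loop(top, il_parameters(p_conn = 0), seed = 1)
  expect_true(all(lengths(w0$sense) == 0))
  expect_true(all(lengths(w0$feedback) == 0))
  w1 <- wire_loop(top, il_parameters(p_conn = 1), seed = 1)
  expect_true(all(lengths(w1$sense) == 10))
  expect_true(all(lengths(w1$feedback) == 10))
  # empirical connection fraction near 0.75
  wd <- wire_loop(top, il_parameters(), seed = 2)
  frac <- (sum(lengths(wd$sense)) + sum(lengths(wd$feedback))) /
    (2 * 400 * 10)
  expect_lt(abs(frac - 0.75), 0.03)
  # deterministic given seed
  wd2 <- wire_loop(top, il_parameters(), seed = 2)
  expect_identical(wd$sense, wd2$sense)
})

test_that("IF units fire on synchrony, schedule delayed IPSPs, and respect
           the refractory period", {
  top <- build_topology(5, 5, 4)
  il <- il_parameters(p_conn = 1)
  w <- wire_loop(top, il, seed = 3)
  st <- il_state(25)
  # no spikes, no events
  st2 <- detect_and_schedule(st, data.frame(cell = integer(),
                                            time = numeric()), w, il, t = 50)
  expect_equal(nrow(st2$events), 0)
  # all sensed cells of every unit spike at t = 100
  spikes <- data.frame(cell = 1:25, time = 100)
  st3 <- detect_and_schedule(st, spikes, w, il, t = 100)
  expect_equal(nrow(st3$fires), 25)
  expect_true(all(st3$events$onset == 110)) # delay 10 ms
  expect_true(all(st3$next_allowed == 110)) # refractory 10 ms
  # a second full-synchrony episode 4 ms later is ignored
  spikes2 <- rbind(spikes, data.frame(cell = 1:25, time = 104))
  st4 <- detect_and_schedule(st3, spikes2, w, il, t = 104)
  expect_equal(nrow(st4$fires), 25) # unchanged
  # sub-threshold synchrony (less than half the sensed cells) is ignored
  few <- data.frame(cell = 1:3, time = 200)
  st5 <- detect_and_schedule(st, few, w, il, t = 200)
  expect_lt(nrow(st5$fires), 25)
})

test_that("synaptic current follows the kinetic gate and reversal", {
  il <- il_parameters()
  expect_equal(synaptic_current(0, -60, il), 0)
  expect_equal(synaptic_current(0.5, il$E_syn, il), 0)
  expect_lt(synaptic_current(0.5, il$E_syn - 10, il), 0)
  expect_gt(synaptic_current(0.5, -60, il), 0) # hyperpolarizing above E_syn
  expect_error(synaptic_current(1.5, -60, il), "0, 1")
})

test_that("gate dynamics match the closed-form pulse response", {
  il <- il_parameters()
  a <- il$alpha * il$T_conc
  b <- il$beta
  s_inf <- a / (a + b)
  tau <- 1 / (a + b)
  tt <- c(0, 0.25, 0.5, 0.9, 1, 1.5, 3, 10, 25)
  closed <- ifelse(tt <= il$T_dur,
                   s_inf * (1 - exp(-tt / tau)),
                   s_inf * (1 - exp(-il$T_dur / tau)) *
                     exp(-b * (tt - il$T_dur)))
  num <- synapse_gate_series(tt, onsets = 0, il, dt = 5e-4)
  expect_lt(max(abs(num - closed)), 1e-6)
})

test_that("a zero-conductance loop reproduces the autonomous record exactly", {
  top <- build_topology(6, 6, 4)
  lib <- ic_lib_default()
  il0 <- il_parameters(gbar_syn = 0)
  r_auto <- simulate_network(top, 0.05, 200, ic_library = lib, seed = 17,
                             integrator = test_integrator())
  r_il0 <- simulate_network(top, 0.05, 200, ic_library = lib, seed = 17,
                            il_params = il0,
                            il_wiring = wire_loop(top, il0, seed = 99),
                            integrator = test_integrator())
  expect_identical(r_auto$frames, r_il0$frames)
  expect_identical(r_auto$spikes, r_il0$spikes)
})

test_that("IPSP volleys hyperpolarize their feedback targets", {
  # drive a small lattice to spike synchronously; with the loop wired at
  # full probability the IPSP (arriving after the 10 ms delay) must pull
  # the membrane below the loop-free trajectory
  top <- build_topology(5, 5, 4)
  il <- il_parameters(p_conn = 1, gbar_syn = 10) # strong, clearly visible
  w <- wire_loop(top, il, seed = 5)
  s0 <- cell_state(V = -55, h = 0.8, c = 0.1, d = 0.2, e = 0.5, f = 0.5,
                   t_gate = 0.4)
  base <- simulate_network(top, 0.05, 1500, state0 = s0, I_baseline = 1.5,
                           integrator = test_integrator())
  with_il <- simulate_network(top, 0.05, 1500, state0 = s0, I_baseline = 1.5,
                              il_params = il, il_wiring = w,
                              integrator = test_integrator())
  expect_gt(nrow(with_il$il_log), 0)
  t_fire <- min(with_il$il_log$time)
  win <- with_il$times > t_fire + il$delay &
    with_il$times < t_fire + il$delay + 15
  expect_lt(mean(with_il$frames[win, , ]), mean(base$frames[win, , ]) - 0.5)
})
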