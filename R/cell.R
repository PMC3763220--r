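#' Parameters of the conductance-based inferior-olive neuron
#'
#' Constructs the parameter set of the single-compartment Hodgkin-Huxley type
#' IO cell used throughout the package. The cell carries five active currents
#' (fast sodium `I_Na`, persistent sodium `I_Nap`, delayed-rectifier potassium
#' `I_Kd`, slow potassium `I_Ks`, hyperpolarization-activated `I_h`), a leak,
#' and a constant depolarizing drive `I_inj`. The defaults generate
#' subthreshold membrane-potential oscillations with occasional spikes; the
#' excitability parameters `rho` (mixing weight of the two slow `I_Ks` gates)
#' and `sigma` (a voltage offset in the Na/Kd rate functions) tune the spike
#' threshold of the model.
#'
#' @param C_m membrane capacitance density (uF/cm^2).
#' @param g_l leak conductance density (mS/cm^2).
#' @param V_l leak reversal potential (mV).
#' @param gbar_Na,gbar_Nap,gbar_Kd,gbar_Ks,gbar_h maximal conductance
#'   densities (mS/cm^2).
#' @param V_Na,V_K,V_h reversal potentials (mV).
#' @param rho mixing weight of the slow `I_Ks` gates, in \[0, 1\].
#' @param sigma threshold-shift offset (mV-like) entering the Na and Kd
#'   rate functions; larger values lower excitability.
#' @param I_inj constant depolarizing current density (uA/cm^2).
#' @param alpha_c_pref prefactor of the `alpha_c` rate function of the
#'   delayed-rectifier activation gate.
#' @return An object of class `io_cell_params` (a validated named list).
#' @examples
#' p <- cell_parameters()
#' p$gbar_Na
#' @export
cell_parameters <- function(C_m = 1, g_l = 0.1, V_l = -60,
                            gbar_Na = 52, gbar_Nap = 0.1, gbar_Kd = 20,
                            gbar_Ks = 14, gbar_h = 0.1,
                            V_Na = 55, V_K = -90, V_h = -43,
                            rho = 0.6, sigma = 1, I_inj = 0,
                            alpha_c_pref = 0.2857) {
  p <- list(C_m = C_m, g_l = g_l, V_l = V_l, gbar_Na = gbar_Na,
            gbar_Nap = gbar_Nap, gbar_Kd = gbar_Kd, gbar_Ks = gbar_Ks,
            gbar_h = gbar_h, V_Na = V_Na, V_K = V_K, V_h = V_h,
            rho = rho, sigma = sigma, I_inj = I_inj,
            alpha_c_pref = alpha_c_pref)
  g <- c(C_m, g_l, gbar_Na, gbar_Nap, gbar_Kd, gbar_Ks, gbar_h)
  if (any(!is.finite(unlist(p)))) stop("all cell parameters must be finite")
  if (any(g < 0)) stop("conductance and capacitance densities must be >= 0")
  if (rho < 0 || rho > 1) stop("'rho' must lie in [0, 1]")
  structure(p, class = "io_cell_params")
}

#' @export
print.io_cell_params <- function(x, ...) {
  cat("IO cell parameters (densities in mS/cm^2, potentials in mV):\n")
  print(unlist(x))
  invisible(x)
}

#' Dynamic state of one IO cell
#'
#' The model integrates seven variables per cell: the membrane potential `V`
#' and six gating variables. The fast-sodium activation `m` and the
#' persistent-sodium activation `n` are instantaneous (set to their steady
#' states at every instant) and are therefore not part of the state.
#'
#' @param V membrane potential (mV).
#' @param h fast-sodium inactivation gate in \[0, 1\].
#' @param c delayed-rectifier activation gate in \[0, 1\].
#' @param d,e,f slow-potassium gates in \[0, 1\].
#' @param t_gate h-current gate in \[0, 1\].
#' @return A named numeric vector of length 7, class `io_cell_state`.
#' @export
cell_state <- function(V = -60, h = 0.9, c = 0.05, d = 0.1,
                       e = 0.5, f = 0.5, t_gate = 0.1) {
  s <- c(V = V, h = h, c = c, d = d, e = e, f = f, t_gate = t_gate)
  gates <- s[-1]
  if (any(gates < 0 | gates > 1))
    stop("gating variables must lie in [0, 1]")
  structure(s, class = "io_cell_state")
}

#' Sigmoid gating function
#'
#' The Boltzmann-type sigmoid `1 / (1 + exp(-(X + Y) / Z))` used by several
#' steady-state gating curves of the cell model.
#'
#' @param x,y,z numeric (mV-like); `z` must be nonzero.
#' @return Values in (0, 1), strictly increasing in `x` for `z > 0`.
#' @examples
#' gate_sigmoid(-34, 34, 6.5) # 0.5 at the half-activation voltage
#' @export
gate_sigmoid <- function(x, y, z) {
  if (any(z == 0)) stop("'z' must be nonzero")
  1 / (1 + exp(-(x + y) / z))
}

# pref * u / (1 - exp(-0.1 u)); removable singularity at u = 0 evaluated by
# its second-order Taylor expansion for |u| < 1e-6.
.ratefun <- function(pref, u) {
  out <- numeric(length(u))
  small <- abs(u) < 1e-6
  out[small] <- pref * 10 * (1 + 0.05 * u[small])
  out[!small] <- pref * u[!small] / (1 - exp(-0.1 * u[!small]))
  out
}

#' Gating kinetics of the IO cell at a given voltage
#'
#' Evaluates the steady states and time constants of all gating variables,
#' including the instantaneous activations `m_inf` (fast sodium, used as
#' `m_inf^3`) and `n_inf` (persistent sodium). The rate functions of the
#' sodium and delayed-rectifier gates are shifted by the excitability offset
#' `sigma`; the slow-potassium and h-current gates are not. The removable
#' singularities of `alpha_m` (at `V = -30 + sigma`) and `alpha_c`
#' (at `V = -34 + sigma`) are evaluated by their analytic limits.
#'
#' @param V membrane potential (mV), vectorized.
#' @param sigma threshold-shift offset.
#' @param alpha_c_pref prefactor of `alpha_c`.
#' @return A list of numeric vectors: `m_inf`, `n_inf`, and `x_inf`/`tau_x`
#'   pairs for `h`, `c`, `d`, `e`, `f` and `t_gate` (time constants in ms).
#' @export
kinetics_at <- function(V, sigma = 1, alpha_c_pref = 0.2857) {
  if (any(!is.finite(V))) stop("'V' must be finite")
  a_m <- .ratefun(0.1, V + 30 - sigma)
  b_m <- 4 * exp((-V - 55 + sigma) / 18)
  a_h <- 1.99 * exp((-V - 44 + sigma) / 20)
  b_h <- 28.57 / (1 + exp(-0.1 * (V + 14 - sigma)))
  a_c <- .ratefun(alpha_c_pref, V + 34 - sigma)
  b_c <- 3.57 * exp((-V - 44 + sigma) / 80)
  list(
    m_inf  = a_m / (a_m + b_m),
    tau_m  = 1 / (a_m + b_m),
    n_inf  = gate_sigmoid(V, 51, 5),
    h_inf  = a_h / (a_h + b_h),
    tau_h  = 1 / (a_h + b_h),
    c_inf  = a_c / (a_c + b_c),
    tau_c  = 1 / (a_c + b_c),
    d_inf  = gate_sigmoid(V, 34, 6.5),
    tau_d  = rep(50, length(V)),
    e_inf  = gate_sigmoid(-V, -65, 6.6),
    tau_e  = 200 + 220 * gate_sigmoid(V, 71.6, 6.85),
    f_inf  = gate_sigmoid(-V, -65, 6.6),
    tau_f  = 200 + 3200 * gate_sigmoid(V, 63.6, 4),
    t_inf  = gate_sigmoid(-V, -45, 5.5),
    tau_t  = 1 / (exp(-14.59 - 0.089 * V) + exp(-1.87 + 0.0701 * V)),
    alpha_m = a_m, beta_m = b_m, alpha_c = a_c, beta_c = b_c
  )
}

#' Per-current ionic current densities
#'
#' @param state an [cell_state()] vector (or any named numeric with the same
#'   seven components).
#' @param params an [cell_parameters()] object.
#' @return Named vector of current densities (uA/cm^2): `I_Na`, `I_Nap`,
#'   `I_Kd`, `I_Ks`, `I_h`, `I_l`. Outward currents are positive.
#' @export
ionic_currents <- function(state, params = cell_parameters()) {
  s <- unclass(state)
  gates <- s[c("h", "c", "d", "e", "f", "t_gate")]
  if (any(gates < 0 | gates > 1))
    stop("invariant violation: gating variables outside [0, 1]")
  V <- s[["V"]]
  k <- kinetics_at(V, params$sigma, params$alpha_c_pref)
  c(
    I_Na  = params$gbar_Na * k$m_inf^3 * s[["h"]] * (V - params$V_Na),
    I_Nap = params$gbar_Nap * k$n_inf * (V - params$V_Na),
    I_Kd  = params$gbar_Kd * s[["c"]]^4 * (V - params$V_K),
    I_Ks  = params$gbar_Ks * s[["d"]] *
      (params$rho * s[["e"]] + (1 - params$rho) * s[["f"]]) *
      (V - params$V_K),
    I_h   = params$gbar_h * s[["t_gate"]] * (V - params$V_h),
    I_l   = params$g_l * (V - params$V_l)
  )
}

#' Time derivative of the cell state
#'
#' Membrane equation: `C_m dV/dt = -(I_Na + I_Nap + I_Kd + I_Ks + I_h + I_l)
#' + I_inj - I_elec - I_syn`. The injected current enters with positive sign
#' so that positive `I_inj` depolarizes; the gap-junction current `I_elec`
#' and the inhibitory synaptic current `I_syn` enter with negative sign, so a
#' cell more depolarized than its neighbors loses current to them and an
#' active inhibitory conductance (reversal below rest) hyperpolarizes.
#' Gates follow first-order relaxation `dx/dt = (x_inf - x) / tau_x`.
#'
#' @inheritParams ionic_currents
#' @param I_elec gap-junction current density (uA/cm^2).
#' @param I_syn inhibitory synaptic current density (uA/cm^2).
#' @return Named vector of the seven state derivatives (per ms).
#' @export
cell_derivative <- function(state, params = cell_parameters(),
                            I_elec = 0, I_syn = 0) {
  s <- unclass(state)
  V <- s[["V"]]
  cur <- ionic_currents(state, params)
  k <- kinetics_at(V, params$sigma, params$alpha_c_pref)
  c(
    V = (-sum(cur) + params$I_inj - I_elec - I_syn) / params$C_m,
    h = (k$h_inf - s[["h"]]) / k$tau_h,
    c = (k$c_inf - s[["c"]]) / k$tau_c,
    d = (k$d_inf - s[["d"]]) / k$tau_d,
    e = (k$e_inf - s[["e"]]) / k$tau_e,
    f = (k$f_inf - s[["f"]]) / k$tau_f,
    t_gate = (k$t_inf - s[["t_gate"]]) / k$tau_t
  )
}

# cell state with all gates at their steady state for the given voltage
.steady_state_at <- function(V, params) {
  k <- kinetics_at(V, params$sigma, params$alpha_c_pref)
  cell_state(V = V, h = k$h_inf, c = k$c_inf, d = k$d_inf,
             e = k$e_inf, f = k$f_inf, t_gate = k$t_inf)
}

#' Estimate the spike threshold of the isolated cell
#'
#' Integrates one isolated cell under a slow linear ramp of the injected
#' current and reports the membrane potential at which `dV/dt` first exceeds
#' the upstroke criterion, i.e. where the regenerative sodium upstroke
#' departs from the subthreshold envelope. With default parameters the
#' estimate is close to -47 mV and insensitive to halving the ramp speed.
#'
#' @param params an [cell_parameters()] object.
#' @param upstroke upstroke criterion on `dV/dt` (mV/ms). The default
#'   3 mV/ms sits in the middle of the take-off knee of the model's spikes.
#' @param I_max final ramp current (uA/cm^2), starting from 0.
#' @param ramp_duration ramp length (ms); halve to double the ramp speed.
#' @param max_error integrator absolute local error tolerance.
#' @return Threshold estimate (mV), with attribute `t` (ms into the ramp)
#'   and `I_inj` (current at threshold).
#' @export
estimate_spike_threshold <- function(params = cell_parameters(),
                                     upstroke = 3, I_max = 1,
                                     ramp_duration = 6000,
                                     max_error = 1e-9) {
  p <- params
  p$I_inj <- 0
  # settle onto the attractor before ramping, so initial-condition
  # transients cannot masquerade as an upstroke
  settle <- simulate_cell(p, duration = 4000, record_states = TRUE,
                          integrator = integrator_config(
                            max_error = max_error, dt_max = 0.5,
                            dt_record = 0.5))
  s0 <- do.call(cell_state, as.list(settle$states[nrow(settle$states), ]))
  rec <- simulate_cell(p, duration = ramp_duration, state0 = s0,
                       ramp_rate = I_max / ramp_duration,
                       integrator = integrator_config(
                         max_error = max_error, dt_max = 0.5,
                         dt_record = 0.02))
  V <- rec$V
  dVdt <- diff(V) / diff(rec$t)
  # first full spike of the ramp, then the criterion crossing on its upstroke
  peak <- which(V > -20)[1]
  if (is.na(peak))
    stop("no spike elicited within the ramp range; ",
         "increase 'I_max' or lower 'upstroke'")
  below <- which(dVdt[seq_len(peak - 1)] < upstroke)
  i <- below[length(below)] + 1L
  structure(V[i], t = rec$t[i], I_inj = I_max * rec$t[i] / ramp_duration)
}
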