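#' Parameters of the cerebellar inhibitory loop
#'
#' The loop is a lattice of event-driven integrate-and-fire (IF) units, one
#' per IO cell position, each bidirectionally connected to up to
#' `max_cluster` nearby IO cells with probability `p_conn` per direction.
#' A unit fires when at least `sync_fraction` of its sensed cells spiked
#' within the synchrony `window`; firing delivers a delayed IPSP (Destexhe
#' type first-order kinetic synapse) to its feedback targets after `delay`
#' ms, and the unit is refractory for `refractory` ms.
#'
#' The synaptic maximal conductance is specified as an absolute value in nS
#' and converted to a density through the assumed membrane area, since the
#' membrane equation works in current densities:
#' `gsyn_density = gbar_syn * 1e-6 / membrane_area` (mS/cm^2).
#'
#' @param window synchrony window (ms).
#' @param delay IPSP delay (ms).
#' @param refractory IF refractory period (ms).
#' @param p_conn connection probability, each direction.
#' @param max_cluster maximum IO cells per IF unit, each direction.
#' @param gbar_syn maximal synaptic conductance (nS).
#' @param membrane_area assumed membrane area (cm^2) converting `gbar_syn`
#'   to a density; the default 1e-5 cm^2 is a ~1000 um^2 soma-scale patch.
#' @param E_syn synaptic reversal potential (mV); hyperpolarized for GABAergic
#'   inhibition.
#' @param alpha,beta transmitter binding/unbinding rates (1/(ms mM), 1/ms).
#' @param T_conc transmitter pulse concentration (mM).
#' @param T_dur transmitter pulse duration (ms).
#' @param sync_fraction fraction of sensed cells that must spike within the
#'   window to count as a synchronous event.
#' @param check_dt cadence (ms) at which units test their synchrony rule.
#' @return An object of class `io_il_params` including the derived
#'   `gsyn_density`.
#' @export
il_parameters <- function(window = 5, delay = 10, refractory = 10,
                          p_conn = 0.75, max_cluster = 10,
                          gbar_syn = 0.1, membrane_area = 1e-5,
                          E_syn = -80, alpha = 5, beta = 0.18,
                          T_conc = 1, T_dur = 1,
                          sync_fraction = 0.5, check_dt = 1) {
  if (window <= 0 || delay <= 0 || refractory <= 0)
    stop("'window', 'delay' and 'refractory' must be > 0")
  if (p_conn < 0 || p_conn > 1) stop("'p_conn' must lie in [0, 1]")
  if (sync_fraction <= 0 || sync_fraction > 1)
    stop("'sync_fraction' must lie in (0, 1]")
  structure(list(window = window, delay = delay, refractory = refractory,
                 p_conn = p_conn, max_cluster = max_cluster,
                 gbar_syn = gbar_syn, membrane_area = membrane_area,
                 gsyn_density = gbar_syn * 1e-6 / membrane_area,
                 E_syn = E_syn, alpha = alpha, beta = beta,
                 T_conc = T_conc, T_dur = T_dur,
                 sync_fraction = sync_fraction, check_dt = check_dt),
            class = "io_il_params")
}

# candidate IO cells for the IF unit mirroring cell (r, c): the max_cluster
# nearest lattice positions, ties broken deterministically by (distance^2,
# row offset, col offset)
.il_candidates <- function(topology, max_cluster) {
  span <- 0
  while ((2 * span + 1)^2 < max_cluster) span <- span + 1
  span <- span + 1
  off <- expand.grid(dr = -span:span, dc = -span:span)
  off$d2 <- off$dr^2 + off$dc^2
  off <- off[order(off$d2, off$dr, off$dc), ]
  off[seq_len(max_cluster), c("dr", "dc")]
}

#' Wire the inhibitory loop to the IO lattice
#'
#' Each IF unit mirrors one IO lattice position (the IF lattice has the same
#' dimensions, preserving the topology). Its candidate set is the
#' `max_cluster` IO cells nearest the mirror position; each candidate is
#' included independently with probability `p_conn`, separately for the
#' sensing (IO to IF) and feedback (IF to IO) direction.
#'
#' @param topology an [build_topology()] object.
#' @param il_params an [il_parameters()] object.
#' @param seed optional RNG seed; when `NULL` the current RNG state is used
#'   (as inside [simulate_network()], where the master seed governs).
#' @return An object of class `io_il_wiring`: lists `sense` and `feedback`
#'   of 1-based IO cell indices per IF unit.
#' @export
wire_loop <- function(topology, il_params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- topology$rows
  cols <- topology$cols
  N <- rows * cols
  cand <- .il_candidates(topology, il_params$max_cluster)
  r <- rep(seq_len(rows), each = cols)
  c_ <- rep(seq_len(cols), times = rows)
  sense <- vector("list", N)
  feedback <- vector("list", N)
  for (u in seq_len(N)) {
    rr <- (r[u] + cand$dr - 1) %% rows + 1
    cc <- (c_[u] + cand$dc - 1) %% cols + 1
    idx <- as.integer((rr - 1) * cols + cc)
    sense[[u]] <- idx[stats::runif(length(idx)) < il_params$p_conn]
    feedback[[u]] <- idx[stats::runif(length(idx)) < il_params$p_conn]
  }
  structure(list(sense = sense, feedback = feedback, rows = rows,
                 cols = cols, p_conn = il_params$p_conn,
                 max_cluster = il_params$max_cluster),
            class = "io_il_wiring")
}

#' Initial state of the inhibitory-loop event logic
#'
#' @param n_units number of IF units.
#' @return An `io_il_state`: per-unit next-allowed-fire times and an empty
#'   IPSP event queue.
#' @export
il_state <- function(n_units) {
  structure(list(next_allowed = rep(0, n_units),
                 events = data.frame(unit = integer(), onset = numeric()),
                 fires = data.frame(unit = integer(), time = numeric())),
            class = "io_il_state")
}

#' Detect synchronous IO spiking and schedule IPSPs
#'
#' Pure event-logic step used by the simulation engine (and testable on its
#' own): at time `t`, an IF unit that is not refractory fires if at least
#' `sync_fraction` of its sensed IO cells spiked within `[t - window, t]`.
#' Firing enqueues an IPSP onset at `t + delay` for the unit's feedback
#' targets and sets the unit's next allowed fire time to `t + refractory`.
#'
#' @param state an [il_state()] object.
#' @param spikes data.frame with columns `cell` and `time` covering at least
#'   `[t - window, t]`.
#' @param wiring an [wire_loop()] object.
#' @param il_params an [il_parameters()] object.
#' @param t current time (ms).
#' @return The updated `io_il_state`; newly scheduled IPSP onsets are
#'   appended to `state$events` and discharges to `state$fires`.
#' @export
detect_and_schedule <- function(state, spikes, wiring, il_params, t) {
  recent <- unique(spikes$cell[spikes$time >= t - il_params$window &
                                 spikes$time <= t])
  if (!length(recent)) return(state)
  for (u in seq_along(wiring$sense)) {
    if (t < state$next_allowed[u]) next
    sensed <- wiring$sense[[u]]
    if (!length(sensed)) next
    n_hit <- sum(sensed %in% recent)
    if (n_hit >= ceiling(il_params$sync_fraction * length(sensed))) {
      state$next_allowed[u] <- t + il_params$refractory
      state$events <- rbind(state$events,
                            data.frame(unit = u,
                                       onset = t + il_params$delay))
      state$fires <- rbind(state$fires,
                           data.frame(unit = u, time = t))
    }
  }
  state
}

#' Inhibitory synaptic current
#'
#' First-order kinetic synapse: the gate `s` relaxes as
#' `ds/dt = alpha * T * (1 - s) - beta * s`, where the transmitter
#' concentration `T` is a rectangular pulse of duration `T_dur` starting at
#' each IPSP onset. The current is `I_syn = gsyn_density * s * (V - E_syn)`.
#'
#' @param s synaptic gate in \[0, 1\].
#' @param V postsynaptic membrane potential (mV).
#' @param il_params an [il_parameters()] object.
#' @return Current density (uA/cm^2), positive = hyperpolarizing for
#'   `V > E_syn`.
#' @export
synaptic_current <- function(s, V, il_params = il_parameters()) {
  if (any(s < 0 | s > 1)) stop("'s' must lie in [0, 1]")
  il_params$gsyn_density * s * (V - il_params$E_syn)
}

#' Numerically integrate the synaptic gate under IPSP pulses
#'
#' Steps the gate kinetics with classical fixed-step RK4 (the full network
#' engine embeds the same first-order kinetics in its adaptive solver). The
#' transmitter is `T_conc` whenever `t` lies within `T_dur` of any onset.
#'
#' @param times increasing evaluation times (ms).
#' @param onsets IPSP onset times (ms).
#' @param il_params an [il_parameters()] object.
#' @param s0 initial gate value.
#' @param dt internal RK4 step (ms).
#' @return Numeric vector of gate values at `times`.
#' @export
synapse_gate_series <- function(times, onsets, il_params = il_parameters(),
                                s0 = 0, dt = 0.001) {
  bounds <- sort(unique(c(onsets, onsets + il_params$T_dur)))
  Tof <- function(t) {
    if (any(t >= onsets & t < onsets + il_params$T_dur)) il_params$T_conc
    else 0
  }
  out <- numeric(length(times))
  s <- s0
  t <- times[1]
  out[1] <- s
  for (i in seq_along(times)[-1]) {
    while (t < times[i] - 1e-12) {
      h <- min(dt, times[i] - t)
      nb <- bounds[bounds > t + 1e-12]
      if (length(nb)) h <- min(h, nb[1] - t)
      # transmitter is constant within [t, t + h]; evaluate at the midpoint
      Tv <- Tof(t + h / 2)
      f <- function(s) il_params$alpha * Tv * (1 - s) - il_params$beta * s
      k1 <- f(s)
      k2 <- f(s + h / 2 * k1)
      k3 <- f(s + h / 2 * k2)
      k4 <- f(s + h * k3)
      s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[i] <- s
  }
  out
}
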