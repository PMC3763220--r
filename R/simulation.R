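#' Integrator settings
#'
#' The network equations are solved with an embedded Verner 6(5) variable
#' step Runge-Kutta pair controlled by the maximum absolute local error per
#' step. The default tolerance of 1e-13 matches the original study protocol;
#' analyses in this package's tests and scenarios relax it to 1e-8, which
#' changes trajectories by well under 0.1 mV (see the robustness tests).
#'
#' @param max_error absolute local error tolerance per step.
#' @param dt_max maximum step size (ms).
#' @param dt_record frame recording cadence (ms); 0.5 ms per frame is the
#'   cadence used for all pattern analyses.
#' @return An object of class `io_integrator`.
#' @export
integrator_config <- function(max_error = 1e-13, dt_max = 1, dt_record = 0.5) {
  if (max_error <= 0) stop("'max_error' must be > 0")
  if (dt_record <= 0) stop("'dt_record' must be > 0")
  structure(list(max_error = max_error, dt_max = dt_max,
                 dt_record = dt_record),
            class = "io_integrator")
}

# shared constants: spike detection threshold and re-arm guard
.SPIKE_THRESHOLD <- -47
.SPIKE_REARM <- 3

.cell_consts <- function(params) {
  unlist(params[c("C_m", "g_l", "V_l", "gbar_Na", "gbar_Nap", "gbar_Kd",
                  "gbar_Ks", "gbar_h", "V_Na", "V_K", "V_h", "rho",
                  "alpha_c_pref")])
}

#' Simulate one isolated IO cell
#'
#' Integrates a single cell (no coupling, no inhibitory loop), optionally
#' under a linear ramp of the injected current. Used for single-cell
#' characterization, the initial-condition library and threshold estimation.
#'
#' @param params an [cell_parameters()] object; `params$I_inj` is the
#'   constant drive and `params$sigma` the excitability offset.
#' @param duration simulated time (ms).
#' @param state0 initial [cell_state()]; default: all gates at steady state
#'   for `V = -60` mV.
#' @param ramp_rate additional injected current ramp (uA/cm^2 per ms).
#' @param integrator an [integrator_config()]; single-cell runs default to a
#'   1e-9 tolerance and a 0.05 ms recording cadence.
#' @param record_states record all seven state variables per frame instead of
#'   only `V`.
#' @return A list with `t`, `V`, spike times `spikes`, and (if requested)
#'   the full `states` matrix (frames x 7).
#' @export
simulate_cell <- function(params = cell_parameters(), duration = 2000,
                          state0 = NULL, ramp_rate = 0,
                          integrator = integrator_config(max_error = 1e-9,
                                                         dt_max = 0.5,
                                                         dt_record = 0.05),
                          record_states = FALSE) {
  if (is.null(state0)) state0 <- .steady_state_at(-60, params)
  y0 <- matrix(unclass(state0), nrow = 1)
  nbr <- matrix(0L, 1, 1)
  res <- .sim_network_cpp(nbr, 0, .cell_consts(params), y0,
                          matrix(params$I_inj, 1, 1),
                          matrix(params$sigma, 1, 1),
                          0, ramp_rate, duration,
                          integrator$max_error, integrator$dt_max,
                          integrator$dt_record, .SPIKE_THRESHOLD,
                          .SPIKE_REARM, list(), list(), list(),
                          record_states)
  out <- list(t = res$frame_times,
              V = res$frames[, 1],
              spikes = res$spikes$time,
              n_steps = res$n_steps)
  if (record_states) {
    st <- res$frames
    colnames(st) <- c("V", "h", "c", "d", "e", "f", "t_gate")
    out$states <- st
  }
  out
}

#' Library of coherent initial conditions
#'
#' Integrates one isolated cell past its transient (at least 2 s of model
#' time) and samples `n` states at uniformly random phases of the attractor
#' trajectory, so that network simulations start from dynamically coherent
#' values of all seven variables. If the cell is non-oscillatory (late V
#' range below 0.5 mV), the library falls back to the settled state plus
#' small Gaussian jitter on V (sd 0.5 mV, gates clipped to \[0, 1\]).
#'
#' @param params an [cell_parameters()] object.
#' @param n number of stored states (the study protocol uses 10,000).
#' @param seed RNG seed making the library reproducible.
#' @param settle transient discarded before sampling (ms, >= 2000; the
#'   default 4000 ms is comfortably past the slow mixed-mode transient).
#' @param sample_window trajectory window sampled after the transient (ms).
#' @return An object of class `io_ic_library`: `states` (n x 7 matrix),
#'   `seed`, and the sampled trajectory's voltage range.
#' @export
build_ic_library <- function(params = cell_parameters(), n = 10000,
                             seed = 1, settle = 4000, sample_window = 1000) {
  if (n < 1) stop("'n' must be >= 1")
  settle <- max(settle, 2000)
  rec <- simulate_cell(params, duration = settle + sample_window,
                       record_states = TRUE,
                       integrator = integrator_config(max_error = 1e-9,
                                                      dt_max = 0.5,
                                                      dt_record = 0.05))
  keep <- rec$t >= settle
  traj <- rec$states[keep, , drop = FALSE]
  vr <- range(traj[, "V"])
  set.seed(seed)
  if (diff(vr) < 0.5) {
    base <- traj[nrow(traj), ]
    states <- matrix(rep(base, each = n), nrow = n,
                     dimnames = list(NULL, colnames(traj)))
    states[, "V"] <- states[, "V"] + stats::rnorm(n, 0, 0.5)
    for (j in 2:7)
      states[, j] <- pmin(1, pmax(0, states[, j] + stats::rnorm(n, 0, 0.01)))
  } else {
    idx <- sample.int(nrow(traj), n, replace = n > nrow(traj))
    states <- traj[idx, , drop = FALSE]
  }
  structure(list(states = states, seed = seed, V_range = vr, n = n),
            class = "io_ic_library")
}

#' Simulate the coupled IO network
#'
#' Integrates the full lattice of conductance-based IO cells coupled by
#' diffusive gap junctions, with optional stimulus/excitability clusters and
#' an optional inhibitory feedback loop. Per-cell baseline injected currents
#' are drawn uniformly from `I_baseline` (default \[0, 0.35\] uA/cm^2) and
#' initial states from the coherent-state library, both reproducibly from
#' `seed`. Membrane potential frames are recorded every
#' `integrator$dt_record` ms and spikes as upward crossings of -47 mV with a
#' 3 ms re-arm guard.
#'
#' All randomness (initial conditions, baseline currents, inhibitory-loop
#' wiring) flows from the single `seed` in a fixed draw order, so two runs
#' with the same arguments and seed are identical.
#'
#' @param topology an [build_topology()] object.
#' @param g_c electrical coupling conductance density (mS/cm^2).
#' @param duration simulated time (ms).
#' @param params an [cell_parameters()] object (baseline `sigma` comes from
#'   here).
#' @param clusters list of [cluster_spec()] overrides.
#' @param I_baseline baseline injected current: length-2 range for uniform
#'   per-cell draws, a scalar for a homogeneous drive, or a length-N vector.
#' @param il_params an [il_parameters()] object to enable the inhibitory
#'   loop, or `NULL`.
#' @param il_wiring an [wire_loop()] object; wired from `seed` if omitted.
#' @param integrator an [integrator_config()].
#' @param ic_library an [build_ic_library()] object; built from `seed` (with
#'   1000 states) if omitted. Pass `ic_library = "uniform"` with a `state0`
#'   attribute-free start to use one identical state for all cells.
#' @param state0 optional single [cell_state()] used for every cell
#'   (overrides the library; useful for synchrony-manifold checks).
#' @param seed master seed (integer) or `NULL` to use the current RNG state.
#' @return An object of class `io_record`: `frames` (time x rows x cols
#'   array of mV), `times` (ms), `spikes` (data.frame cell/time), the
#'   configuration echo and integrator statistics.
#' @export
simulate_network <- function(topology, g_c, duration,
                             params = cell_parameters(),
                             clusters = list(),
                             I_baseline = c(0, 0.35),
                             il_params = NULL, il_wiring = NULL,
                             integrator = integrator_config(),
                             ic_library = NULL, state0 = NULL,
                             seed = NULL) {
  if (g_c < 0) stop("'g_c' must be >= 0")
  N <- topology$rows * topology$cols
  if (!is.null(seed)) set.seed(seed)

  # draw order: (1) initial states, (2) baseline currents, (3) IL wiring
  if (is.null(state0)) {
    if (is.null(ic_library))
      ic_library <- build_ic_library(params, n = min(10000, max(1000, N)),
                                     seed = if (is.null(seed)) 1 else seed)
    idx <- sample.int(nrow(ic_library$states), N, replace = TRUE)
    y0 <- ic_library$states[idx, , drop = FALSE]
  } else {
    y0 <- matrix(rep(unclass(state0), each = N), nrow = N)
  }

  if (length(I_baseline) == 2 && diff(I_baseline) != 0) {
    I_base <- stats::runif(N, I_baseline[1], I_baseline[2])
  } else {
    I_base <- rep_len(if (length(I_baseline) == 2) I_baseline[1]
                      else I_baseline, N)
  }

  il_conf <- list()
  il_sense <- list()
  il_feedback <- list()
  il_inert <- FALSE
  if (!is.null(il_params) && il_params$gsyn_density == 0) {
    # a loop with zero synaptic conductance cannot influence the network:
    # integrate the autonomous system (bit-identical to il_params = NULL)
    # and reconstruct the IF discharge log from the spike raster afterwards
    if (is.null(il_wiring)) il_wiring <- wire_loop(topology, il_params)
    il_inert <- TRUE
  } else if (!is.null(il_params)) {
    if (is.null(il_wiring)) il_wiring <- wire_loop(topology, il_params)
    il_conf <- list(window = il_params$window, delay = il_params$delay,
                    refractory = il_params$refractory,
                    sync_fraction = il_params$sync_fraction,
                    gsyn_density = il_params$gsyn_density,
                    E_syn = il_params$E_syn, alpha = il_params$alpha,
                    beta = il_params$beta, T_conc = il_params$T_conc,
                    T_dur = il_params$T_dur, check_dt = il_params$check_dt)
    il_sense <- il_wiring$sense
    il_feedback <- il_wiring$feedback
  }

  ep <- .drive_epochs(topology, clusters, I_base, params$sigma, duration)
  res <- .sim_network_cpp(topology$nbr, g_c, .cell_consts(params), y0,
                          ep$I_inj, ep$sigma, ep$start, 0, duration,
                          integrator$max_error, integrator$dt_max,
                          integrator$dt_record, .SPIKE_THRESHOLD,
                          .SPIKE_REARM, il_conf, il_sense, il_feedback,
                          FALSE)

  nf <- nrow(res$frames)
  frames <- aperm(array(res$frames, dim = c(nf, topology$cols,
                                            topology$rows)), c(1, 3, 2))
  spikes <- data.frame(cell = res$spikes$cell, time = res$spikes$time)
  il_log <- data.frame(unit = res$il_log$unit, time = res$il_log$time)
  if (il_inert && nrow(spikes)) {
    # reconstruct the IF discharge log from the spike raster
    st <- il_state(length(il_wiring$sense))
    for (tc in seq(0, duration, by = il_params$check_dt)) {
      recent <- spikes[spikes$time >= tc - il_params$window &
                         spikes$time <= tc, , drop = FALSE]
      if (nrow(recent)) st <- detect_and_schedule(st, recent, il_wiring,
                                                  il_params, tc)
    }
    il_log <- st$fires
  }
  structure(list(frames = frames, times = res$frame_times, spikes = spikes,
                 topology = topology, g_c = g_c, params = params,
                 clusters = clusters, duration = duration,
                 integrator = integrator, seed = seed,
                 il_params = il_params, il_log = il_log,
                 I_inj_baseline = I_base, y0 = y0,
                 n_steps = res$n_steps, n_rejected = res$n_rejected),
            class = "io_record")
}

#' @export
print.io_record <- function(x, ...) {
  cat(sprintf("IO network record: %d x %d lattice, k = %d, g_c = %g mS/cm^2\n",
              x$topology$rows, x$topology$cols, x$topology$k, x$g_c))
  cat(sprintf("  %d frames over %g ms (every %g ms), %d spikes from %d cells\n",
              length(x$times), x$duration, x$integrator$dt_record,
              nrow(x$spikes), length(unique(x$spikes$cell))))
  if (!is.null(x$il_params))
    cat(sprintf("  inhibitory loop active: %d IF discharges\n",
                nrow(x$il_log)))
  if (length(x$clusters))
    cat(sprintf("  %d stimulus/excitability clusters\n", length(x$clusters)))
  invisible(x)
}

#' @export
plot.io_record <- function(x, frame = length(x$times), ...) {
  f <- x$frames[frame, , ]
  pal <- .activity_palette(200)
  graphics::image(t(f)[, nrow(f):1], col = pal, zlim = c(-80, 20),
                  axes = FALSE,
                  main = sprintf("t = %g ms", x$times[frame]), ...)
  invisible(x)
}

#' Spike times of one cell
#'
#' @param record an [simulate_network()] record.
#' @param cell 1-based cell index (row-major).
#' @return Sorted numeric vector of spike times (ms).
#' @export
spike_times <- function(record, cell) {
  sort(record$spikes$time[record$spikes$cell == cell])
}

#' Network-average firing rate
#'
#' Total number of spikes in the window divided by the number of cells and
#' the window length.
#'
#' @param record an [simulate_network()] record.
#' @param window `c(t0, t1)` in ms; defaults to the whole run.
#' @return Mean firing rate in Hz (spikes per cell per second).
#' @export
mean_firing_rate <- function(record, window = NULL) {
  if (is.null(window)) window <- c(0, record$duration)
  if (diff(window) <= 0) stop("'window' must have positive length")
  N <- record$topology$rows * record$topology$cols
  nsp <- sum(record$spikes$time >= window[1] & record$spikes$time < window[2])
  nsp / (N * diff(window) / 1000)
}

#' Voltage trace of one cell
#'
#' @param record an [simulate_network()] record.
#' @param row,col cell coordinates (1-based).
#' @return Numeric vector of membrane potentials at the frame times.
#' @export
voltage_trace <- function(record, row, col) {
  record$frames[, row, col]
}
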