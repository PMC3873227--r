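#' Membrane parameter sets for the model cells
#'
#' Builds the parameter set of a single-compartment Hodgkin-Huxley-type cell.
#' Two presets are provided: `"tc"`, a thalamocortical relay cell carrying
#' leak, transient sodium and delayed-rectifier potassium spike currents, a
#' low-threshold calcium current and a hyperpolarization-activated cation
#' current, with a simple intracellular calcium pool; and `"ctx"`, a layer-4
#' cortical cell carrying leak, spike currents and a slow non-inactivating
#' potassium current.
#'
#' Passive parameters follow the published circuit values (TC: leak 9.12 nS,
#' leak reversal -76.5 mV, capacitance 0.21 nF; cortical: 29.0 nS, -70.0 mV,
#' 0.29 nF). Active maximal conductances and the spike-current threshold
#' shift `vt` are calibration parameters: they are fixed so that the relaxed
#' cells reproduce the published resting potential and resting input
#' conductance pairs (-74.3 mV / 8.34 nS for the TC cell, -70.6 mV / 33.4 nS
#' for the cortical cell), the TC rebound burst, and the ~80 nS minimal
#' single-event AMPA amplitude that reliably fires the resting cortical cell.
#' See the methods vignette for the calibration protocol.
#'
#' All conductances are in nS at the soma, potentials in mV, capacitance in
#' nF, times in ms.
#'
#' @param type `"tc"` or `"ctx"`.
#' @param ... named overrides of individual fields (e.g. `g_T = 0`).
#' @return An object of class `membrane_params`: a named list with fields
#'   `cm`, `g_L`, `E_L`, `g_Na`, `E_Na`, `g_K`, `E_K`, `vt`, `g_T`, `E_Ca`,
#'   `g_h`, `E_h`, `g_M`, `E_M`, `m_vhalf`, `m_slope`, `m_taumax`, calcium
#'   pool constants `ca_tau`, `ca_rest`, `ca_gain`, and `type`.
#' @export
#' @examples
#' tc <- membrane_params("tc")
#' passive <- membrane_params("tc", g_Na = 0, g_K = 0, g_T = 0, g_h = 0)
membrane_params <- function(type = c("tc", "ctx"), ...) {
  type <- match.arg(type)
  p <- if (type == "tc") {
    list(cm = 0.21, g_L = 9.12, E_L = -76.5,
         g_Na = 11000, E_Na = 50, g_K = 2200, E_K = -90, vt = -38.6,
         g_T = 141.9046, E_Ca = 120,
         g_h = 0.19645, E_h = -43,
         g_M = 0, E_M = -90, m_vhalf = -35, m_slope = 10, m_taumax = 400,
         ca_tau = 5, ca_rest = 2.4e-4, ca_gain = 5e-6)
  } else {
    list(cm = 0.29, g_L = 29.0, E_L = -70.0,
         g_Na = 10000, E_Na = 50, g_K = 2100, E_K = -90, vt = -27.207,
         g_T = 0, E_Ca = 120,
         g_h = 0, E_h = -43,
         g_M = 65.811, E_M = -90, m_vhalf = -49.619, m_slope = 4.9,
         m_taumax = 400,
         ca_tau = 5, ca_rest = 2.4e-4, ca_gain = 5e-6)
  }
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown membrane parameter(s): ",
                        paste(bad, collapse = ", "))
  p[names(over)] <- over
  stopifnot(p$cm > 0, p$g_L > 0,
            all(unlist(p[c("g_Na", "g_K", "g_T", "g_h", "g_M")]) >= 0))
  p$type <- type
  class(p) <- "membrane_params"
  p
}

#' @export
print.membrane_params <- function(x, ...) {
  cat(sprintf("<membrane_params: %s cell>\n", x$type))
  cat(sprintf("  passive: Cm %.3g nF, gL %.3g nS, EL %.4g mV\n",
              x$cm, x$g_L, x$E_L))
  act <- c(g_Na = x$g_Na, g_K = x$g_K, g_T = x$g_T, g_h = x$g_h, g_M = x$g_M)
  act <- act[act > 0]
  cat("  active (nS):", paste(sprintf("%s=%.4g", names(act), act),
                              collapse = ", "), "\n")
  invisible(x)
}

# fixed-order numeric vector consumed by the C++ core
pack_params <- function(p) {
  stopifnot(inherits(p, "membrane_params"))
  as.numeric(c(p$cm, p$g_L, p$E_L,
               p$g_Na, p$E_Na, p$g_K, p$E_K, p$vt,
               p$g_T, p$E_Ca,
               p$g_h, p$E_h,
               p$g_M, p$E_M, p$m_vhalf, p$m_slope, p$m_taumax,
               p$ca_tau, p$ca_rest, p$ca_gain))
}

# channel -> gate codes used by the C++ kinetics
.GATES <- list(
  I_Na = c(m = 0L, h = 1L),
  I_K  = c(n = 2L),
  I_T  = c(m = 3L, h = 4L),
  I_h  = c(m = 5L),
  I_M  = c(m = 6L)
)

# gating exponents of each channel, I = gbar * m^a * h^b * (V - E)
.GATE_EXPONENTS <- list(I_Na = c(m = 3, h = 1), I_K = c(n = 4),
                        I_T = c(m = 2, h = 1), I_h = c(m = 1), I_M = c(m = 1))

#' Voltage-dependent gate rate constants
#'
#' Forward (`alpha`) and backward (`beta`) rate constants of the two-state
#' gating scheme dx/dt = alpha(V) (1 - x) - beta(V) x for every gate of a
#' channel, together with the steady state `inf = alpha/(alpha+beta)` and
#' time constant `tau = 1/(alpha+beta)`. Removable singularities in the
#' rate expressions are evaluated by their series limits.
#'
#' @param channel one of `"I_Na"`, `"I_K"`, `"I_T"`, `"I_h"`, `"I_M"`.
#' @param v membrane potential (mV), scalar.
#' @param params a [membrane_params()] object (supplies the spike-current
#'   threshold shift and the slow-potassium midpoint/slope).
#' @return named list, one element per gate, each a named numeric vector
#'   with `alpha`, `beta` (1/ms), `inf`, `tau` (ms).
#' @export
#' @examples
#' gate_rates("I_T", -65, membrane_params("tc"))
gate_rates <- function(channel, v, params = membrane_params("tc")) {
  if (!is.character(channel) || length(channel) != 1 ||
      is.na(match(channel, names(.GATES))))
    stop("unknown channel: must be one of ",
         paste(names(.GATES), collapse = ", "))
  stopifnot(is.finite(v))
  codes <- .GATES[[channel]]
  pv <- pack_params(params)
  out <- lapply(codes, function(g) gate_kinetics_cpp(g, v, pv))
  names(out) <- names(codes)
  out
}

#' Membrane and gate derivatives (reference implementation)
#'
#' Pure-R right-hand side of the membrane equation
#' `Cm dV/dt = -gL (V - EL) - sum(I_ch) + I_syn + I_fluct + I_inj`
#' with each intrinsic current `I_ch = gbar m^a h^b (V - E_ch)` and gate
#' kinetics `dx/dt = alpha (1 - x) - beta x`. Positive currents depolarize.
#' This is the slow reference form used to cross-check the compiled
#' integrator; currents are in nA.
#'
#' @param state list with `v` (mV) and `gates`, a named list per channel of
#'   gate values in `[0, 1]` (e.g. `list(I_Na = c(m = 0, h = 1), ...)`).
#' @param params a [membrane_params()] object.
#' @param i_syn,i_fluct,i_inj currents in nA (positive = depolarizing).
#' @return list with `dv` (mV/ms) and `dgates` (same shape as
#'   `state$gates`, 1/ms).
#' @export
membrane_derivative <- function(state, params, i_syn = 0, i_fluct = 0,
                                i_inj = 0) {
  v <- state$v
  stopifnot(is.finite(v), is.finite(i_syn), is.finite(i_fluct),
            is.finite(i_inj))
  gbar <- c(I_Na = params$g_Na, I_K = params$g_K, I_T = params$g_T,
            I_h = params$g_h, I_M = params$g_M)
  erev <- c(I_Na = params$E_Na, I_K = params$E_K, I_T = params$E_Ca,
            I_h = params$E_h, I_M = params$E_M)
  i_intr <- 0
  dgates <- list()
  for (ch in names(state$gates)) {
    rates <- gate_rates(ch, v, params)
    x <- state$gates[[ch]]
    ex <- .GATE_EXPONENTS[[ch]]
    open <- prod(x ^ ex[names(x)])
    i_intr <- i_intr + gbar[[ch]] * open * (v - erev[[ch]])   # pA
    dgates[[ch]] <- vapply(names(x), function(g) {
      r <- rates[[g]]
      unname(r["alpha"] * (1 - x[[g]]) - r["beta"] * x[[g]])
    }, numeric(1))
  }
  i_total <- -params$g_L * (v - params$E_L) - i_intr +
    1000 * (i_syn + i_fluct + i_inj)                           # pA
  list(dv = i_total / (params$cm * 1000), dgates = dgates)
}

#' Randomize a cell's intrinsic parameters
#'
#' Cellular heterogeneity: each randomized parameter `p0` is replaced by
#' `p0 * (1 + H * (2u - 1))` with `u ~ Uniform(0, 1)` drawn independently
#' per parameter, so that parameters vary by up to 100 * H percent around
#' their original values. The randomized set comprises the maximal
#' conductances of the low-threshold calcium, hyperpolarization-activated
#' and spike sodium/potassium currents, the leak conductance and the
#' capacitance.
#'
#' @param params a [membrane_params()] object.
#' @param h cellular heterogeneity index in `[0, 1]`.
#' @param fields character vector of fields to randomize.
#' @return a new `membrane_params` object.
#' @export
randomize_cell <- function(params, h,
                           fields = c("g_T", "g_h", "g_Na", "g_K",
                                      "g_L", "cm")) {
  if (!is.numeric(h) || length(h) != 1 || is.na(h) || h < 0 || h > 1)
    stop("heterogeneity index h must be a scalar in [0, 1]")
  if (h == 0) return(params)
  for (f in fields) {
    u <- runif(1)
    params[[f]] <- params[[f]] * (1 + h * (2 * u - 1))
  }
  params
}

#' Simulate one isolated model cell
#'
#' Integrates a single cell at fixed step `dt` under an optional
#' piecewise-constant injected current protocol, optional discrete synaptic
#' conductance events (alpha kernels) and optional background conductance
#' traces.
#'
#' @param params a [membrane_params()] object.
#' @param duration simulated time (ms).
#' @param dt integration step (ms), default 0.025.
#' @param i_protocol two-column matrix `(t_ms, I_nA)`: the injected current
#'   takes value `I` from time `t` onward. `NULL` for none.
#' @param events data frame with columns `time` (ms), `weight` (nS) and
#'   optionally `gaba` (0/1) for synaptic events delivered to the cell
#'   (AMPA alpha kernel, 1 ms to peak, unless `gaba`; GABA_A: 2 ms, -75 mV).
#' @param noise optional [conductance_trace()] sampled at `dt` providing
#'   background excitatory/inhibitory conductances.
#' @param v0 initial potential (mV); defaults to the leak reversal.
#' @param record_every record membrane potential every this many steps
#'   (0 = no trace).
#' @return list with `spikes` (ms), `v` (recorded trace, mV), `time`
#'   (matching times, ms), `dt`.
#' @export
simulate_cell <- function(params, duration, dt = 0.025, i_protocol = NULL,
                          events = NULL, noise = NULL, v0 = params$E_L,
                          record_every = max(1L, round(0.1 / dt))) {
  stopifnot(duration > 0, dt > 0)
  iprot <- if (is.null(i_protocol)) matrix(numeric(0), 0, 2) else {
    stopifnot(ncol(i_protocol) == 2)
    matrix(as.numeric(i_protocol), ncol = 2)
  }
  nsteps <- round(duration / dt)
  noise_par <- c(0, 0, 1, 0, 0, 0, 1, -75, 0, 0, 0, 0, 1)
  noise_tr <- matrix(numeric(0), 0, 0)
  noise_mode <- 0L
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "conductance_trace"))
    if (abs(noise$dt - dt) > 1e-12)
      stop("noise trace must be sampled at the simulation dt")
    if (length(noise$g_exc) < nsteps) stop("noise trace too short")
    noise_tr <- cbind(noise$g_exc[seq_len(nsteps)],
                      noise$g_inh[seq_len(nsteps)])
    noise_par[4] <- noise$E_exc
    noise_par[8] <- noise$E_inh
    noise_mode <- 2L
  }
  is_tc <- params$type == "tc"
  ev <- if (is.null(events)) matrix(numeric(0), 0, 3) else {
    gaba <- if ("gaba" %in% names(events)) as.numeric(events$gaba) else 0
    cbind(events$time, events$weight, gaba)
  }
  if (is_tc) {
    if (any(ev[, 3] != 0))
      stop("GABA events are only delivered to the cortical cell")
    res <- sim_network_cpp(
      par_tc = matrix(pack_params(params), 1, byrow = TRUE),
      par_ctx = numeric(0),
      ret_ev_t = list(ev[, 1]), ret_ev_w = list(ev[, 2]),
      ctx_ev = matrix(numeric(0), 0, 3),
      noise_par = noise_par, noise_tr = noise_tr, noise_mode = noise_mode,
      i_const = 0, sine_par = matrix(0, 1, 3),
      iprot = iprot, w_tc = 0, ffi_w = 0, ffi_lag = 0, thal_jitter = 0,
      duration = duration, dt = dt,
      v_spike = .SPIKE_THRESHOLD, v_rearm = .SPIKE_REARM,
      v0_tc = v0, v0_ctx = -70, record_every = record_every,
      record_idx = 1L)
    spikes <- res$spikes[[1]]
  } else {
    if (noise_mode == 2L) stop("background traces on the cortical cell are ",
                               "not supported; it receives no bombardment")
    res <- sim_network_cpp(
      par_tc = matrix(numeric(0), 0, 20),
      par_ctx = pack_params(params),
      ret_ev_t = list(), ret_ev_w = list(),
      ctx_ev = ev,
      noise_par = noise_par, noise_tr = noise_tr, noise_mode = 0L,
      i_const = numeric(0), sine_par = matrix(0, 0, 3),
      iprot = iprot, w_tc = numeric(0), ffi_w = 0, ffi_lag = 0,
      thal_jitter = 0,
      duration = duration, dt = dt,
      v_spike = .SPIKE_THRESHOLD, v_rearm = .SPIKE_REARM,
      v0_tc = -74, v0_ctx = v0, record_every = record_every,
      record_idx = 1L)
    spikes <- res$spikes[[1]]
  }
  v <- if (record_every > 0) res$v[, 1] else numeric(0)
  list(spikes = spikes, v = v,
       time = if (record_every > 0)
         seq_along(v) * res$dt_record else numeric(0),
       dt = dt)
}

#' Resting potential and resting input conductance
#'
#' Relaxes the cell with no input, reports the resting potential, then
#' probes the input conductance with small (+/- `di` nA) current steps held
#' until a new steady state, `g_in = dI/dV`. An oscillatory or drifting
#' rest (membrane SD over the final probe window above `stable_tol`) is
#' reported as a failure rather than a number.
#'
#' @param params a [membrane_params()] object.
#' @param dt integration step (ms).
#' @param settle relaxation time per stage (ms).
#' @param di probe current (nA).
#' @param stable_tol maximal membrane SD (mV) over the last 500 ms for the
#'   rest to count as stationary.
#' @return list with `v_rest` (mV), `g_in` (nS), `stable` (logical).
#' @export
#' @examples
#' \donttest{rest_properties(membrane_params("tc"))}
rest_properties <- function(params, dt = 0.025, settle = 4000, di = 0.01,
                            stable_tol = 0.01) {
  probe <- function(i_nA) {
    r <- simulate_cell(params, duration = settle, dt = dt,
                       i_protocol = matrix(c(0, i_nA), 1),
                       record_every = max(1L, round(0.5 / dt)))
    n <- length(r$v)
    win <- r$v[r$time > settle - 500]
    list(v = mean(r$v[seq(max(1, n - 20), n)]), sd = sd(win))
  }
  p0 <- probe(0)
  if (!is.finite(p0$sd) || p0$sd > stable_tol)
    return(list(v_rest = NA_real_, g_in = NA_real_, stable = FALSE))
  pp <- probe(di)
  pm <- probe(-di)
  g_in <- 2 * di / (pp$v - pm$v) * 1000        # nA/mV -> uS -> nS
  list(v_rest = p0$v, g_in = g_in, stable = TRUE)
}
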