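#' Alpha-function synaptic conductance kernel
#'
#' Unitary conductance time course of one synaptic event:
#' `g(s) = w (s / tau_peak) exp(1 - s / tau_peak)` for `s >= 0` and 0
#' before the event, peaking at exactly `w` when `s = tau_peak`. Kernels of
#' successive presynaptic spikes sum linearly.
#'
#' @param w synaptic weight = peak conductance (nS).
#' @param tau_peak time to peak (ms), > 0.
#' @param s time since the presynaptic spike (ms), vectorized.
#' @return conductance (nS).
#' @export
#' @examples
#' alpha_conductance(12.5, 1, 1)   # peak: 12.5 nS
alpha_conductance <- function(w, tau_peak, s) {
  stopifnot(tau_peak > 0, w >= 0)
  ifelse(s >= 0, w * (s / tau_peak) * exp(1 - s / tau_peak), 0)
}

#' Build a retino-thalamo-cortical circuit
#'
#' Two topology presets. `"single_retina"`: one retinal cell contacts every
#' TC cell through one 12.5 nS AMPA synapse. `"mixed"`: `n_ret` retinal
#' cells and `n_tc = 2 n_ret` TC cells wired so that every retinal cell
#' contacts exactly 4 TC cells and every TC cell receives exactly 2 retinal
#' cells; the 12.5 nS weight is split 75%/25% (9.375 and 3.125 nS) between
#' the two afferents of each TC cell. The default 15 retina / 30 TC mixed
#' circuit matches the documented divergence/convergence ratios.
#'
#' The thalamocortical AMPA weight defaults to the optimized presets
#' 2.33 nS (90 cells), 7 nS (30 cells), 21 nS (10 cells) and otherwise to
#' the constant-drive rule `w = 210 / n_tc` nS.
#'
#' @param preset `"single_retina"` or `"mixed"`.
#' @param n_tc number of TC cells.
#' @param n_ret number of retinal cells (mixed preset; must satisfy
#'   `2 * n_ret == n_tc`).
#' @param w_tc thalamocortical AMPA weight (nS); `NULL` for the preset.
#' @param w_ret total retinothalamic weight per TC cell (nS).
#' @param tc_params,ctx_params [membrane_params()] presets; `tc_params` may
#'   be a single object (shared) or a list of `n_tc` objects.
#' @return object of class `circuit_spec`: fields `n_ret`, `n_tc`,
#'   `afferents` (per-TC data frame of `ret` index and `weight`), `w_tc`
#'   (length `n_tc`), `ffi_w`, `ffi_lag`, `tc_params`, `ctx_params`.
#' @export
#' @examples
#' build_circuit("single_retina", n_tc = 30)
#' build_circuit("mixed", n_tc = 30, n_ret = 15)
build_circuit <- function(preset = c("single_retina", "mixed"), n_tc = 30,
                          n_ret = if (preset == "mixed") n_tc / 2 else 1,
                          w_tc = NULL, w_ret = 12.5,
                          tc_params = membrane_params("tc"),
                          ctx_params = membrane_params("ctx")) {
  preset <- match.arg(preset)
  stopifnot(n_tc >= 1, w_ret >= 0)
  if (is.null(w_tc))
    w_tc <- switch(as.character(n_tc), "90" = 2.33, "30" = 7, "10" = 21,
                   210 / n_tc)
  w_tc <- rep_len(w_tc, n_tc)
  if (preset == "single_retina") {
    n_ret <- 1
    aff <- lapply(seq_len(n_tc), function(i)
      data.frame(ret = 1L, weight = w_ret))
  } else {
    if (4 * n_ret != 2 * n_tc)
      stop("mixed preset requires 4 * n_ret == 2 * n_tc ",
           "(each retina contacts 4 TC cells, each TC receives 2)")
    aff <- lapply(seq_len(n_tc), function(j) {
      r1 <- ((j - 1) %% n_ret) + 1L          # primary afferent, 75%
      r2 <- (j %% n_ret) + 1L                # secondary afferent, 25%
      data.frame(ret = c(r1, r2), weight = w_ret * c(0.75, 0.25))
    })
  }
  if (inherits(tc_params, "membrane_params"))
    tc_params <- rep(list(tc_params), n_tc)
  stopifnot(length(tc_params) == n_tc)
  structure(list(preset = preset, n_ret = n_ret, n_tc = n_tc,
                 afferents = aff, w_tc = w_tc, ffi_w = 0, ffi_lag = 0,
                 tc_params = tc_params, ctx_params = ctx_params,
                 v_spike = .SPIKE_THRESHOLD),
            class = "circuit_spec")
}

#' @export
print.circuit_spec <- function(x, ...) {
  cat(sprintf(
    "<circuit_spec: %s, %d retina -> %d TC -> 1 cortical, w_tc %.3g nS%s>\n",
    x$preset, x$n_ret, x$n_tc, x$w_tc[1],
    if (x$ffi_w > 0) sprintf(", FFI %.3g nS lag %.3g ms", x$ffi_w, x$ffi_lag)
    else ""))
  invisible(x)
}

#' Attach feedforward inhibition to the cortical cell
#'
#' Couples a GABA_A synapse (reversal -75 mV, 2 ms to peak) to the
#' thalamocortical pathway: every TC spike additionally triggers an
#' inhibitory kernel on the cortical cell after `lag` ms.
#'
#' @param circuit a [build_circuit()] spec.
#' @param w_gaba GABA_A weight (nS), 0-10.
#' @param lag IPSP lag relative to the EPSP (ms), 0-10.
#' @return the modified `circuit_spec`.
#' @export
attach_ffi <- function(circuit, w_gaba, lag = 0) {
  stopifnot(inherits(circuit, "circuit_spec"),
            w_gaba >= 0, w_gaba <= 10, lag >= 0, lag <= 10)
  circuit$ffi_w <- w_gaba
  circuit$ffi_lag <- lag
  circuit
}

#' Noise field specification for a simulation
#'
#' Bundles the per-cell OU law with the across-population correlation
#' schema for [simulate()].
#'
#' @param spec an [ou_spec()].
#' @param c_pop population correlation in `[0, 1]`.
#' @param schema `"homogeneous"` or `"heterogeneous"`.
#' @param c_ei,lag_ei within-cell excitation-inhibition correlation and lag
#'   (ms).
#' @return object of class `noise_field`.
#' @export
noise_field <- function(spec = ou_spec(), c_pop = 0,
                        schema = c("homogeneous", "heterogeneous"),
                        c_ei = 0, lag_ei = 0) {
  schema <- match.arg(schema)
  stopifnot(inherits(spec, "ou_spec"), c_pop >= 0, c_pop <= 1,
            c_ei >= 0, c_ei <= 1, lag_ei >= 0)
  structure(list(spec = spec, c_pop = c_pop, schema = schema,
                 c_ei = c_ei, lag_ei = lag_ei),
            class = "noise_field")
}

#' Simulate the full circuit
#'
#' Integrates all TC cells and the cortical cell at fixed step `dt`. TC
#' spikes (upward crossing of -30 mV, re-armed below -45 mV) drive the
#' cortical AMPA synapses with zero conduction delay (optionally jittered
#' per spike), plus the FFI GABA_A kernel if attached. The bombardment is
#' generated inside the integrator when `noise` is a [noise_field()] (one
#' shared realization stream drawn first, then per-cell streams, so
#' conditions with the same seed are comparable), or taken verbatim when
#' `noise` is a list of [conductance_trace()]s.
#'
#' @param circuit a [build_circuit()] spec.
#' @param retinal list of [spike_train()]s, one per retinal cell (a single
#'   train is recycled for the single-retina preset).
#' @param noise `NULL`, a [noise_field()], or a list of `n_tc`
#'   [conductance_trace()]s.
#' @param currents `NULL`, a single [current_spec()] shared by all TC
#'   cells, or a list of `n_tc` specs.
#' @param duration simulated time (ms).
#' @param dt step (ms).
#' @param thal_jitter mean exponential jitter on TC spike delivery to the
#'   cortical synapse (ms).
#' @param impaired integer indices of TC cells deprived of retinal input
#'   (they keep their bombardment); `NULL` for none.
#' @param record `FALSE`, `TRUE` (all cells) or integer cell indices
#'   (`n_tc + 1` = cortical) whose membrane potential is recorded.
#' @param record_dt trace sampling step (ms), rounded to a multiple of
#'   `dt`.
#' @return object of class `sim_result`: `spikes_tc` (list of
#'   [spike_train()]), `spikes_ctx`, `v` (matrix, one column per recorded
#'   cell), `time`, `recorded`, `dt`, `duration`.
#' @export
simulate <- function(circuit, retinal, noise = NULL, currents = NULL,
                     duration = 100e3, dt = 0.025, thal_jitter = 0,
                     impaired = NULL, record = FALSE, record_dt = 0.2) {
  stopifnot(inherits(circuit, "circuit_spec"), duration > 0, dt > 0)
  n_tc <- circuit$n_tc
  if (inherits(retinal, "spike_train")) retinal <- list(retinal)
  stopifnot(length(retinal) >= circuit$n_ret)

  # per-TC merged retinal event lists
  ev_t <- vector("list", n_tc); ev_w <- vector("list", n_tc)
  for (i in seq_len(n_tc)) {
    if (i %in% impaired) {
      ev_t[[i]] <- numeric(0); ev_w[[i]] <- numeric(0); next
    }
    aff <- circuit$afferents[[i]]
    tt <- unlist(lapply(seq_len(nrow(aff)), function(k)
      retinal[[aff$ret[k]]]$times))
    ww <- unlist(lapply(seq_len(nrow(aff)), function(k)
      rep(aff$weight[k], length(retinal[[aff$ret[k]]]$times))))
    o <- order(tt)
    ev_t[[i]] <- tt[o]; ev_w[[i]] <- ww[o]
  }

  # noise
  noise_par <- c(0, 0, 1, 0, 0, 0, 1, -75, 0, 0, 0, 0, 1)
  noise_tr <- matrix(numeric(0), 0, 0)
  noise_mode <- 0L
  if (inherits(noise, "noise_field")) {
    s <- noise$spec
    noise_par <- c(s$g0_exc, s$sigma_exc, s$tau_exc, s$e_exc,
                   s$g0_inh, s$sigma_inh, s$tau_inh, s$e_inh,
                   noise$c_pop, match(noise$schema,
                                      c("homogeneous", "heterogeneous")) - 1,
                   noise$c_ei, noise$lag_ei, 1)
    noise_mode <- 1L
  } else if (is.list(noise) && length(noise) &&
             inherits(noise[[1]], "conductance_trace")) {
    stopifnot(length(noise) == n_tc)
    nsteps <- round(duration / dt)
    noise_tr <- matrix(0, nsteps, 2 * n_tc)
    for (i in seq_len(n_tc)) {
      if (abs(noise[[i]]$dt - dt) > 1e-12)
        stop("noise traces must be sampled at the simulation dt")
      if (length(noise[[i]]$g_exc) < nsteps) stop("noise trace too short")
      noise_tr[, 2 * i - 1] <- noise[[i]]$g_exc[seq_len(nsteps)]
      noise_tr[, 2 * i] <- noise[[i]]$g_inh[seq_len(nsteps)]
    }
    noise_par[4] <- noise[[1]]$e_exc
    noise_par[8] <- noise[[1]]$e_inh
    noise_mode <- 2L
  } else if (!is.null(noise)) stop("unrecognized noise argument")

  # injected currents
  i_const <- numeric(n_tc)
  sine_par <- matrix(0, max(n_tc, 1), 3)
  if (!is.null(currents)) {
    if (inherits(currents, "current_spec"))
      currents <- rep(list(currents), n_tc)
    stopifnot(length(currents) == n_tc)
    for (i in seq_len(n_tc)) {
      i_const[i] <- currents[[i]]$i_const
      sine_par[i, ] <- c(currents[[i]]$a, currents[[i]]$f, currents[[i]]$phi)
    }
  }

  rec_idx <- if (isTRUE(record)) seq_len(n_tc + 1L)
             else if (is.numeric(record)) as.integer(record)
             else integer(0)
  record_every <- if (length(rec_idx)) max(1L, round(record_dt / dt)) else 0L

  par_tc <- do.call(rbind, lapply(circuit$tc_params, pack_params))
  res <- sim_network_cpp(
    par_tc = par_tc, par_ctx = pack_params(circuit$ctx_params),
    ret_ev_t = ev_t, ret_ev_w = ev_w,
    ctx_ev = matrix(numeric(0), 0, 3),
    noise_par = noise_par, noise_tr = noise_tr, noise_mode = noise_mode,
    i_const = i_const, sine_par = sine_par,
    iprot = matrix(numeric(0), 0, 2),
    w_tc = circuit$w_tc, ffi_w = circuit$ffi_w, ffi_lag = circuit$ffi_lag,
    thal_jitter = thal_jitter,
    duration = duration, dt = dt,
    v_spike = circuit$v_spike, v_rearm = .SPIKE_REARM,
    v0_tc = -74.3, v0_ctx = -70.6,
    record_every = record_every, record_idx = rec_idx)

  spikes_tc <- lapply(seq_len(n_tc), function(i)
    spike_train(res$spikes[[i]], duration, "thalamic"))
  out <- list(spikes_tc = spikes_tc,
              spikes_ctx = spike_train(res$spikes[[n_tc + 1]], duration,
                                       "cortical"),
              v = res$v,
              time = if (length(rec_idx))
                seq_len(nrow(res$v)) * res$dt_record else numeric(0),
              recorded = rec_idx, dt = dt, duration = duration,
              circuit = circuit)
  class(out) <- "sim_result"
  out
}

#' @export
print.sim_result <- function(x, ...) {
  rates <- vapply(x$spikes_tc, function(s)
    1000 * length(s$times) / s$duration, numeric(1))
  cat(sprintf(
    "<sim_result: %.4g s, %d TC cells (mean %.3g Hz), cortical %.3g Hz>\n",
    x$duration / 1000, length(x$spikes_tc), mean(rates),
    1000 * length(x$spikes_ctx$times) / x$duration))
  invisible(x)
}
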