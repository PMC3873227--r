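#' Ornstein-Uhlenbeck bombardment specification
#'
#' The corticothalamic synaptic bombardment is the sum of two fluctuating
#' conductances (excitatory, reversal 0 mV, correlation time 2.7 ms;
#' inhibitory, reversal -75 mV, correlation time 10.5 ms), each an
#' Ornstein-Uhlenbeck process `dg = -(g - g0)/tau dt + sigma sqrt(2/tau) dW`.
#' Means are normalized by the cell's rest conductance (`amplitude
#' a = g0 / g_in0`) and standard deviations by the mean (`variation ratio
#' v = sigma / g0`), so an amplitude of 0 also nullifies the fluctuations.
#'
#' @param a_exc,a_inh conductance amplitudes (dimensionless, >= 0).
#' @param v_exc,v_inh conductance variation ratios (dimensionless, >= 0).
#' @param g_in0 reference rest input conductance (nS); default the TC
#'   cell's 8.34 nS.
#' @param tau_exc,tau_inh correlation times (ms).
#' @param e_exc,e_inh reversal potentials (mV).
#' @return object of class `ou_spec` with derived fields `g0_exc`,
#'   `sigma_exc`, `g0_inh`, `sigma_inh` (nS).
#' @export
#' @examples
#' ou_spec(a_exc = 1.5, a_inh = 1.0, v_exc = 0.2, v_inh = 0.2)
ou_spec <- function(a_exc = 1.5, a_inh = 1.0, v_exc = 0.2, v_inh = 0.2,
                    g_in0 = 8.34, tau_exc = 2.7, tau_inh = 10.5,
                    e_exc = 0, e_inh = -75) {
  stopifnot(a_exc >= 0, a_inh >= 0, v_exc >= 0, v_inh >= 0, g_in0 > 0,
            tau_exc > 0, tau_inh > 0)
  exc <- normalize_conductance(a_exc, v_exc, g_in0)
  inh <- normalize_conductance(a_inh, v_inh, g_in0)
  structure(list(a_exc = a_exc, a_inh = a_inh, v_exc = v_exc, v_inh = v_inh,
                 g_in0 = g_in0,
                 g0_exc = exc[["g0"]], sigma_exc = exc[["sigma"]],
                 g0_inh = inh[["g0"]], sigma_inh = inh[["sigma"]],
                 tau_exc = tau_exc, tau_inh = tau_inh,
                 e_exc = e_exc, e_inh = e_inh),
            class = "ou_spec")
}

#' Normalized bombardment statistics
#'
#' Converts a conductance amplitude `a = g0 / g_in0` and variation ratio
#' `v = sigma / g0` into the absolute mean and SD of one bombardment
#' component: `g0 = a * g_in0`, `sigma = v * g0`.
#'
#' @param a conductance amplitude (>= 0).
#' @param v conductance variation ratio (>= 0).
#' @param g_in0 rest input conductance (nS).
#' @return named numeric vector `c(g0, sigma)` in nS.
#' @export
#' @examples
#' normalize_conductance(3, 0, 8.34)    # g0 = 25.02 nS
normalize_conductance <- function(a, v, g_in0 = 8.34) {
  stopifnot(a >= 0, v >= 0, g_in0 > 0)
  g0 <- a * g_in0
  c(g0 = g0, sigma = v * g0)
}

#' Total mean bombardment conductance
#'
#' `G_total = g0_exc + g0_inh`, also expressed normalized to the rest
#' conductance (`G_norm = G_total / g_in0`).
#'
#' @param g0_exc,g0_inh mean conductances (nS).
#' @param g_in0 rest input conductance (nS).
#' @return named numeric vector `c(g_total, g_norm)`.
#' @export
#' @examples
#' total_conductance(1.5 * 8.34, 1.0 * 8.34)   # 20.85 nS, G_norm 2.5
total_conductance <- function(g0_exc, g0_inh, g_in0 = 8.34) {
  stopifnot(g0_exc >= 0, g0_inh >= 0, g_in0 > 0)
  g_total <- g0_exc + g0_inh
  c(g_total = g_total, g_norm = g_total / g_in0)
}

#' Conductance trace container
#'
#' Time-sampled excitatory/inhibitory bombardment conductances for one
#' cell, on the simulation grid. The OU law allows transient negative
#' excursions; they are clipped to zero only at current evaluation inside
#' the integrator, not in the stored process.
#'
#' @param g_exc,g_inh conductance samples (nS).
#' @param dt sampling step (ms).
#' @param e_exc,e_inh reversal potentials (mV).
#' @return object of class `conductance_trace`.
#' @export
conductance_trace <- function(g_exc, g_inh, dt, e_exc = 0, e_inh = -75) {
  stopifnot(length(g_exc) == length(g_inh), dt > 0,
            all(is.finite(g_exc)), all(is.finite(g_inh)))
  structure(list(g_exc = as.numeric(g_exc), g_inh = as.numeric(g_inh),
                 dt = dt, e_exc = e_exc, e_inh = e_inh,
                 E_exc = e_exc, E_inh = e_inh),
            class = "conductance_trace")
}

#' Generate a dual-OU conductance trace
#'
#' Exact discretization of the stationary OU update,
#' `g(t+dt) = g0 + (g(t) - g0) exp(-dt/tau) + sigma sqrt(1 - exp(-2dt/tau))
#' xi`, `xi ~ N(0,1)`, initialized at `g0`. With `c_ei > 0` the inhibitory
#' innovations are mixed from the (lagged) excitatory innovations as
#' `xi_inh = sqrt(1 - c_ei) zeta + sqrt(c_ei) xi_exc(t - lag_ei)`, which
#' preserves their zero mean and unit variance; a positive lag makes
#' inhibition trail excitation.
#'
#' @param spec an [ou_spec()].
#' @param duration duration (ms).
#' @param dt step (ms); must be smaller than both correlation times.
#' @param c_ei excitation-inhibition correlation in `[0, 1]`.
#' @param lag_ei inhibition lag (ms, >= 0); rounded to the grid with a
#'   warning if not a multiple of `dt`.
#' @return a [conductance_trace()] with `duration/dt + 1` samples.
#' @export
ou_generate <- function(spec, duration, dt = 0.025, c_ei = 0, lag_ei = 0) {
  stopifnot(inherits(spec, "ou_spec"), duration > 0,
            c_ei >= 0, c_ei <= 1, lag_ei >= 0)
  if (dt >= spec$tau_exc || dt >= spec$tau_inh)
    stop("dt must be smaller than the OU correlation times")
  n <- round(duration / dt)
  lag_steps <- round(lag_ei / dt)
  if (abs(lag_steps * dt - lag_ei) > 1e-9)
    warning("lag_ei rounded to the simulation grid: ",
            format(lag_steps * dt), " ms")
  xi_e <- rnorm(n)
  xi_i <- if (c_ei > 0) {
    lagged <- if (lag_steps == 0) xi_e else
      c(rnorm(lag_steps), xi_e[seq_len(n - lag_steps)])
    sqrt(1 - c_ei) * rnorm(n) + sqrt(c_ei) * lagged
  } else rnorm(n)
  ge <- ou_path_cpp(spec$g0_exc, spec$sigma_exc, spec$tau_exc, dt, xi_e,
                    spec$g0_exc)
  gi <- ou_path_cpp(spec$g0_inh, spec$sigma_inh, spec$tau_inh, dt, xi_i,
                    spec$g0_inh)
  conductance_trace(ge, gi, dt, spec$e_exc, spec$e_inh)
}

#' Correlate an inhibitory innovation stream with an excitatory one
#'
#' Standalone form of the mixing used by [ou_generate()]:
#' `xi_inh(t) = sqrt(1 - c_ei) zeta(t) + sqrt(c_ei) xi_exc(t - lag)`, with
#' `zeta` independent standard normal, preserving zero mean and unit
#' variance.
#'
#' @param c_ei correlation in `[0, 1]`.
#' @param lag_ei lag (ms, >= 0).
#' @param xi_exc excitatory innovation stream (standard normal draws).
#' @param dt grid step (ms).
#' @return numeric vector, same length as `xi_exc`.
#' @export
correlate_exc_inh <- function(c_ei, lag_ei, xi_exc, dt = 0.025) {
  stopifnot(c_ei >= 0, c_ei <= 1, lag_ei >= 0)
  n <- length(xi_exc)
  lag_steps <- round(lag_ei / dt)
  if (abs(lag_steps * dt - lag_ei) > 1e-9)
    warning("lag_ei rounded to the grid: ", format(lag_steps * dt), " ms")
  lagged <- if (lag_steps == 0) xi_exc else
    c(rnorm(min(lag_steps, n)), xi_exc[seq_len(max(0, n - lag_steps))])
  sqrt(1 - c_ei) * rnorm(n) + sqrt(c_ei) * lagged
}

#' Population field of bombardment conductances
#'
#' Builds per-cell conductance traces with a controlled correlation across
#' the thalamic population.
#'
#' Homogeneous schema: every cell receives
#' `g_i = g0 + sqrt(1 - c_pop) (g_ind,i - g0) + sqrt(c_pop) (g_com - g0)`
#' with `g_ind,i` cell-specific and `g_com` shared realizations of the same
#' OU law, so each cell's mean and variance are invariant to `c_pop`.
#'
#' Heterogeneous schema: `M = 1 + round(c_pop (N - 1))` cells receive the
#' identical shared realization and the rest independent ones, so the
#' realized correlation strength is `(M - 1)/(N - 1)`.
#'
#' The shared realization is always generated first from the random
#' stream, so for a fixed seed the cell-specific realizations are identical
#' across `c_pop` values, making correlated and uncorrelated conditions
#' directly comparable.
#'
#' @param spec an [ou_spec()].
#' @param n_tc population size (>= 1).
#' @param c_pop population correlation in `[0, 1]`.
#' @param schema `"homogeneous"` or `"heterogeneous"`.
#' @param duration duration (ms).
#' @param dt step (ms).
#' @param c_ei,lag_ei within-cell excitation-inhibition correlation.
#' @return list of `n_tc` [conductance_trace()]s; attribute `m_common`
#'   holds M for the heterogeneous schema.
#' @export
population_field <- function(spec, n_tc, c_pop,
                             schema = c("homogeneous", "heterogeneous"),
                             duration, dt = 0.025, c_ei = 0, lag_ei = 0) {
  schema <- match.arg(schema)
  stopifnot(n_tc >= 1, c_pop >= 0, c_pop <= 1)
  common <- ou_generate(spec, duration, dt, c_ei, lag_ei)
  ind <- lapply(seq_len(n_tc), function(i)
    ou_generate(spec, duration, dt, c_ei, lag_ei))
  if (schema == "homogeneous") {
    se <- sqrt(1 - c_pop); sc <- sqrt(c_pop)
    out <- lapply(ind, function(tr) conductance_trace(
      spec$g0_exc + se * (tr$g_exc - spec$g0_exc) +
        sc * (common$g_exc - spec$g0_exc),
      spec$g0_inh + se * (tr$g_inh - spec$g0_inh) +
        sc * (common$g_inh - spec$g0_inh),
      dt, spec$e_exc, spec$e_inh))
    attr(out, "m_common") <- NA_integer_
  } else {
    m <- if (n_tc == 1) 1L else 1L + as.integer(floor(c_pop * (n_tc - 1) + 0.5))
    out <- ind
    for (i in seq_len(m)) out[[i]] <- common
    attr(out, "m_common") <- m
  }
  out
}

#' Bombardment current at a given potential
#'
#' `I = g_exc (E_exc - V) + g_inh (E_inh - V)` in the depolarizing-positive
#' convention; conductances are clipped at zero before evaluation
#' (the stored OU process itself is never clipped).
#'
#' @param g_exc,g_inh conductances (nS), vectorized.
#' @param v membrane potential (mV).
#' @param e_exc,e_inh reversal potentials (mV).
#' @return current in nA.
#' @export
#' @examples
#' fluct_current(10, 0, -70)   # 0.7 nA depolarizing
fluct_current <- function(g_exc, g_inh, v, e_exc = 0, e_inh = -75) {
  stopifnot(all(is.finite(g_exc)), all(is.finite(g_inh)), all(is.finite(v)))
  (pmax(g_exc, 0) * (e_exc - v) + pmax(g_inh, 0) * (e_inh - v)) / 1000
}
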