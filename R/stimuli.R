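#' Spike train objects
#'
#' A spike train is a strictly increasing vector of event times (ms) with a
#' duration and a source label. Coincident events are collapsed.
#'
#' @param times numeric vector of spike times (ms).
#' @param duration total duration (ms).
#' @param source label, e.g. `"retinal"`, `"thalamic"`, `"cortical"`.
#' @return object of class `spike_train`.
#' @export
spike_train <- function(times, duration, source = "unknown") {
  times <- sort(as.numeric(times))
  stopifnot(duration > 0, !anyNA(times))
  times <- times[times >= 0 & times <= duration]
  times <- unique(times)
  structure(list(times = times, duration = duration, source = source),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train: %d events over %.4g s, source %s, rate %.3g Hz>\n",
              length(x$times), x$duration / 1000, x$source,
              1000 * length(x$times) / x$duration))
  invisible(x)
}

#' Retinal generator specification
#'
#' The model retinal cell is a renewal gamma process mimicking the
#' discharge of an ON-center Y cell: interspike intervals are i.i.d.
#' Gamma(shape `k`, scale `mu_isi / k`). Defaults: 30 Hz mean rate
#' (`mu_isi` = 100/3 ms) and shape 3.
#'
#' @param mu_isi mean interspike interval (ms).
#' @param k gamma shape parameter (>= 1).
#' @param duration train duration (ms).
#' @param n_ret number of retinal lines.
#' @param s_ret synchronization of the retinal lines in `[0, 1]`.
#' @return object of class `retinal_spec`.
#' @export
retinal_spec <- function(mu_isi = 100 / 3, k = 3, duration = 100e3,
                         n_ret = 1, s_ret = 0) {
  stopifnot(mu_isi > 0, k >= 1, duration > 0, n_ret >= 1,
            s_ret >= 0, s_ret <= 1)
  structure(list(mu_isi = mu_isi, k = k, theta = mu_isi / k,
                 duration = duration, n_ret = n_ret, s_ret = s_ret),
            class = "retinal_spec")
}

#' Generate one gamma-process retinal spike train
#'
#' Draws i.i.d. Gamma(`k`, `theta`) interspike intervals and accumulates
#' them until `duration` is exceeded. A duration shorter than one typical
#' interval may produce an empty (still valid) train.
#'
#' @param spec a [retinal_spec()].
#' @return a [spike_train()].
#' @export
#' @examples
#' set.seed(1)
#' tr <- gamma_spike_train(retinal_spec(duration = 10e3))
gamma_spike_train <- function(spec) {
  stopifnot(inherits(spec, "retinal_spec"))
  # draw in blocks until past the duration
  rate <- 1 / spec$mu_isi
  times <- numeric(0)
  t_end <- 0
  repeat {
    n <- max(16L, ceiling((spec$duration - t_end) * rate * 1.25))
    isi <- rgamma(n, shape = spec$k, scale = spec$theta)
    times <- c(times, t_end + cumsum(isi))
    t_end <- times[length(times)]
    if (t_end > spec$duration) break
  }
  spike_train(times[times <= spec$duration], spec$duration, "retinal")
}

#' Generate synchronized retinal lines
#'
#' Produces `n_ret` retinal trains of which `M = 1 + round(s_ret *
#' (n_ret - 1))` replay one common pattern and the remaining `n_ret - M`
#' are independent draws, so that the realized synchronization is
#' `(M - 1) / (n_ret - 1)`. `s_ret = 0` gives fully independent lines,
#' `s_ret = 1` identical lines.
#'
#' @param spec a [retinal_spec()] (fields `n_ret` and `s_ret` are used).
#' @return list of [spike_train()]s; the first `M` entries share the common
#'   pattern. Attribute `m_common` gives `M`.
#' @export
synchronize_lines <- function(spec) {
  stopifnot(inherits(spec, "retinal_spec"))
  n <- spec$n_ret
  if (n == 1) {
    out <- list(gamma_spike_train(spec))
    attr(out, "m_common") <- 1L
    return(out)
  }
  m <- 1L + as.integer(floor(spec$s_ret * (n - 1) + 0.5))
  common <- gamma_spike_train(spec)
  out <- vector("list", n)
  for (i in seq_len(m)) out[[i]] <- common
  for (i in seq_len(n - m)) out[[m + i]] <- gamma_spike_train(spec)
  attr(out, "m_common") <- m
  out
}

#' Jitter spike times
#'
#' Each spike is delayed by an independent draw from an exponential
#' distribution with mean `j_ms`; the train is re-sorted (jitter can
#' reorder spikes). `j_ms = 0` returns the input unchanged. Spike count is
#' preserved; jittered spikes may exceed the nominal duration, so the
#' returned train's duration is extended to cover them.
#'
#' @param train a [spike_train()].
#' @param j_ms mean jitter (ms), >= 0.
#' @return a [spike_train()].
#' @export
jitter_spikes <- function(train, j_ms) {
  stopifnot(inherits(train, "spike_train"), j_ms >= 0)
  if (j_ms == 0 || length(train$times) == 0) return(train)
  t2 <- sort(train$times + rexp(length(train$times), rate = 1 / j_ms))
  spike_train(t2, max(train$duration, t2[length(t2)]), train$source)
}

#' Injected current specification and evaluation
#'
#' Constant plus sine-wave current `I(t) = I_const + A sin(2 pi f t / 1000
#' + phi)` (t in ms, f in Hz). The sine term has zero time average (no
#' offset). In the "coherent oscillations" condition every TC cell shares
#' `phi = 0`; in the "desynchronized" condition phases are uniform on
#' `[0, 2 pi)` across the population.
#'
#' @param i_const constant amplitude (nA).
#' @param a sine amplitude (nA), >= 0.
#' @param f sine frequency (Hz).
#' @param phi phase (rad).
#' @return object of class `current_spec`.
#' @export
current_spec <- function(i_const = 0, a = 0, f = 0, phi = 0) {
  stopifnot(a >= 0, f >= 0)
  structure(list(i_const = i_const, a = a, f = f, phi = phi),
            class = "current_spec")
}

#' @rdname current_spec
#' @param spec a `current_spec`.
#' @param t time (ms), vectorized.
#' @return `injected_current`: current in nA.
#' @export
injected_current <- function(spec, t) {
  stopifnot(inherits(spec, "current_spec"))
  spec$i_const + spec$a * sin(2 * pi * spec$f * t / 1000 + spec$phi)
}

#' Read or write a spike train as two-column CSV
#'
#' Column `time_ms` holds event times and `unit_id` the source unit; the
#' loader validates sorting within units.
#'
#' @param trains list of [spike_train()]s (or one train).
#' @param path CSV file path.
#' @export
write_spike_csv <- function(trains, path) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  df <- do.call(rbind, lapply(seq_along(trains), function(i)
    if (length(trains[[i]]$times))
      data.frame(time_ms = trains[[i]]$times, unit_id = i)
    else NULL))
  if (is.null(df)) df <- data.frame(time_ms = numeric(0),
                                    unit_id = integer(0))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_csv
#' @param duration duration to stamp on the loaded trains (ms); defaults to
#'   the last event time.
#' @return `read_spike_csv`: list of [spike_train()]s indexed by unit.
#' @export
read_spike_csv <- function(path, duration = NULL) {
  df <- read.csv(path)
  stopifnot(all(c("time_ms", "unit_id") %in% names(df)))
  if (is.null(duration))
    duration <- if (nrow(df)) max(df$time_ms) else 1
  lapply(split(df$time_ms, factor(df$unit_id)), function(tt) {
    if (is.unsorted(tt)) stop("spike times not sorted within unit")
    spike_train(tt, duration)
  })
}
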