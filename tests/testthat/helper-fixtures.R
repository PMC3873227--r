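# shared fixtures: small circuits and analysis settings used across files

lc_noise <- function(...) noise_field(ou_spec(), ...)

quick_circuit <- function(n_tc = 10, w_tc = 7, ...)
  build_circuit("single_retina", n_tc = n_tc, w_tc = w_tc, ...)

quick_retina <- function(duration, ...)
  gamma_spike_train(retinal_spec(duration = duration, ...))

# spike train whose binarization (bin_ms = 1) equals the given 0/1 vector
train_from_bits <- function(bits, bin_ms = 1) {
  spike_train((which(bits == 1L) - 0.5) * bin_ms,
              length(bits) * bin_ms)
}

model_settings <- function(lag_ms = 6, ...)
  mi_settings(bin_ms = 1, lag_ms = lag_ms, ...)
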