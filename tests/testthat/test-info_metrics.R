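test_that("binarization uses right-open 1 ms bins with saturation", {
  expect_identical(binarize(numeric(0), 1, 5), integer(5))
  # two spikes in one bin -> a single 1
  expect_identical(binarize(c(2.1, 2.9), 1, 5), c(0L, 0L, 1L, 0L, 0L))
  # bin-edge spike goes to the right-open bin, cross-checked by brute force
  tt <- c(0, 1, 3.9999, 4.0)
  brute <- vapply(0:4, function(i)
    as.integer(any(tt >= i & tt < i + 1)), integer(1))
  expect_identical(binarize(tt, 1, 5), brute)
  expect_identical(binarize(spike_train(c(0.5, 2.5), 4), 1, 4),
                   c(1L, 0L, 1L, 0L))
})

test_that("MI estimator matches the binary symmetric channel closed form", {
  # oracle: I = H2(p0 * (1-f) + (1-p0) * f ... ) simplified for p0 = 0.5:
  # I = 1 - H2(f) bits for uniform input flipped with probability f
  h2 <- function(p) -p * log2(p) - (1 - p) * log2(1 - p)
  set.seed(61)
  n <- 1e5
  for (f in c(0.05, 0.1, 0.3)) {
    s_bits <- rbinom(n, 1, 0.5)
    r_bits <- ifelse(rbinom(n, 1, f) == 1, 1 - s_bits, s_bits)
    res <- mutual_information(train_from_bits(s_bits),
                              train_from_bits(r_bits),
                              mi_settings(window_ms = 1, bin_ms = 1,
                                          lag_ms = 0))
    expect_equal(res$mi_corrected, 1 - h2(f), tolerance = 0.02)
  }
})

test_that("identity channel recovers the word entropy, independence zero", {
  set.seed(62)
  s <- gamma_spike_train(retinal_spec(duration = 60e3))
  idn <- mutual_information(s, s, model_settings(lag_ms = 0))
  # oracle: plug-in MI of (X, X) is exactly H(X-words); the bootstrap
  # correction then removes the (here substantial) pairing-chance term
  b <- binarize(s, 1, s$duration)
  words <- apply(matrix(b[1:(2000 * 30)], nrow = 30), 2, paste,
                 collapse = "")
  p <- table(words) / length(words)
  expect_equal(idn$mi_raw, -sum(p * log2(p)), tolerance = 1e-10)
  expect_gt(idn$mi_corrected, 0.6 * idn$mi_raw)
  expect_lt(idn$mi_corrected, idn$mi_raw)

  r <- gamma_spike_train(retinal_spec(duration = 60e3))
  ind <- mutual_information(s, r, model_settings(lag_ms = 0))
  expect_lt(ind$mi_corrected, 0.05)
  expect_equal(ind$te, ind$mi_corrected / 0.03)

  silent <- spike_train(numeric(0), 60e3)
  z <- mutual_information(silent, r, model_settings())
  expect_identical(z$te, 0)
  expect_true("zero_entropy_stimulus" %in% z$flags)
})

test_that("bias-corrected MI is centred on zero for independent streams", {
  set.seed(63)
  devs <- replicate(60, {
    s <- train_from_bits(rbinom(600, 1, 0.3))
    r <- train_from_bits(rbinom(600, 1, 0.3))
    mutual_information(s, r, mi_settings(window_ms = 3, bin_ms = 1,
                                         lag_ms = 0, n_shuffle = 20),
                       duration = 600)
  }, simplify = FALSE)
  raw_minus_bias <- vapply(devs, function(d) d$mi_raw - d$bias, numeric(1))
  expect_lt(abs(mean(raw_minus_bias)),
            2 * sd(raw_minus_bias) / sqrt(length(devs)) + 0.003)
})

test_that("finite-size diagnostic flags undersampled data", {
  set.seed(64)
  s <- gamma_spike_train(retinal_spec(duration = 120e3))   # 4000 windows
  long <- finite_size_check(s, s, model_settings(lag_ms = 0))
  expect_lt(long$fraction, 0.01)
  expect_false(long$flag)
  short <- finite_size_check(
    spike_train(s$times[s$times < 3000], 3000),
    spike_train(s$times[s$times < 3000], 3000),
    model_settings(lag_ms = 0))
  expect_gt(short$fraction, 0.01)
  expect_true(short$flag)
})

test_that("partial TEs coincide on a fully deterministic relay", {
  set.seed(65)
  s <- gamma_spike_train(retinal_spec(duration = 60e3))
  pt <- partial_te(s, s, s, model_settings(), lags = c(rt = 0, tc = 0,
                                                       rc = 0))
  expect_identical(pt$retinothalamic$mi_raw, pt$thalamocortical$mi_raw)
  expect_identical(pt$retinothalamic$mi_raw, pt$retinocortical$mi_raw)
  # only the seeded bootstrap draw differs between the three estimates
  expect_equal(pt$retinothalamic$te, pt$thalamocortical$te,
               tolerance = 0.005)
  expect_equal(pt$retinothalamic$te, pt$retinocortical$te,
               tolerance = 0.005)
})

test_that("efficacy and contribution behave at the boundaries", {
  set.seed(66)
  s <- gamma_spike_train(retinal_spec(duration = 50e3))
  same <- efficacy_contribution(s, s)
  expect_equal(same$efficacy, 1)
  expect_equal(same$contribution, 1)
  silent <- efficacy_contribution(s, spike_train(numeric(0), 50e3))
  expect_equal(silent$efficacy, 0)
  expect_true(is.na(silent$contribution))
  expect_identical(silent$flags, "no_cortical_spikes")
  # Poisson cortex independent of retina: efficacy ~ 1 - exp(-rate * 0.03)
  rate <- 20
  pois <- spike_train(cumsum(rexp(3000, rate / 1000)), 50e3)
  ec <- efficacy_contribution(s, pois)
  expect_equal(ec$efficacy, 1 - exp(-rate * 0.03), tolerance = 0.05)
})

test_that("pairwise and population correlations detect shared structure", {
  set.seed(67)
  x <- gamma_spike_train(retinal_spec(duration = 40e3))
  expect_equal(as.numeric(pairwise_correlation(x, x)), 1)
  y <- gamma_spike_train(retinal_spec(duration = 40e3))
  expect_lt(abs(pairwise_correlation(x, y)), 3 / sqrt(40e3))
  z <- pairwise_correlation(spike_train(numeric(0), 40e3), x)
  expect_true(is.na(z))
  expect_identical(attr(z, "flag"), "zero_variance")
  pop <- population_correlation(list(x, x, y))
  expect_length(pop$rho, 3)
  expect_equal(sort(pop$rho)[3], 1)
})

test_that("STA reconstructs constructed lags and Poisson baselines", {
  ct <- spike_train(seq(100, 5000, by = 50), 5100, "cortical")
  th <- spike_train(ct$times - 5, 5100, "thalamic")   # always 5 ms before
  sta <- spike_triggered_average(ct, list(th))
  expect_equal(sta$mean[sta$lag_ms == 5], 1)
  expect_equal(sum(sta$mean[sta$lag_ms != 5]), 0)  # delta reconstruction
  expect_true(all(sta$sd == 0))

  set.seed(68)
  rate <- 30
  pois <- lapply(1:5, function(i)
    spike_train(cumsum(rexp(2500, rate / 1000)), 60e3))
  ctx <- spike_train(cumsum(rexp(600, 10 / 1000)), 60e3)
  flat <- spike_triggered_average(ctx, pois)
  expect_equal(mean(flat$mean), 5 * rate / 1000, tolerance = 0.1)
  expect_lt(max(abs(flat$mean - mean(flat$mean))), 0.1)
  empty <- spike_triggered_average(spike_train(numeric(0), 100), pois)
  expect_identical(nrow(empty), 0L)
})

test_that("rates and ISI CV match analytic cases", {
  per <- spike_train(seq(0, 99999, by = 1000 / 30), 100e3)
  rc <- rate_and_cv(per)
  expect_equal(rc$rate, 30, tolerance = 0.001)
  expect_equal(rc$cv, 0, tolerance = 1e-10)
  set.seed(69)
  g3 <- gamma_spike_train(retinal_spec(duration = 300e3))
  expect_equal(rate_and_cv(g3)$cv, 1 / sqrt(3), tolerance = 0.03)
  pop <- rate_and_cv(list(g3, g3))
  expect_equal(pop$rate, 30, tolerance = 0.1)
  expect_identical(pop$rate_sd, 0)
  two <- rate_and_cv(spike_train(c(1, 2), 1000))
  expect_true("cv_undefined" %in% two$flags)
})

test_that("count MI is bounded by word MI and cross-correlation normalizes", {
  set.seed(70)
  dur <- 60e3
  s <- gamma_spike_train(retinal_spec(duration = dur))
  jit <- jitter_spikes(s, 2)
  w <- mutual_information(s, jit, model_settings(lag_ms = 2))
  k <- spike_count_mi(s, jit, model_settings(lag_ms = 2))
  expect_lte(k$mi_corrected, w$mi_corrected + 0.02)   # data processing
  r <- gamma_spike_train(retinal_spec(duration = dur))
  k0 <- spike_count_mi(s, r, model_settings(lag_ms = 0))
  expect_lt(k0$mi_corrected, 0.02)

  cc <- cross_correlation(s, s)
  expect_equal(cc$cc[cc$lag_ms == 0], 1)
  expect_lt(max(cc$cc[cc$lag_ms != 0]), 0.3)
})

test_that("membrane SD excises the configured window around spikes", {
  tt <- seq(0, 1000, by = 0.2)
  v <- rep(-70, length(tt))
  spikes <- c(250, 600)
  for (s in spikes) v[tt >= s - 0.6 & tt <= s + 2] <- 20   # fake APs
  expect_gt(sd(v), 5)
  expect_equal(membrane_sd(v, tt, spikes), 0, tolerance = 1e-12)
  expect_gt(membrane_sd(v, tt, spikes, window = c(0.2, 0.2)), 0)
})
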