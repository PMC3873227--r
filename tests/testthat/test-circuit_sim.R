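test_that("alpha kernel peaks at the weight and sums linearly", {
  expect_equal(alpha_conductance(12.5, 1, 1), 12.5)     # g(tau_peak) = w
  expect_equal(alpha_conductance(12.5, 1, 0), 0)
  expect_equal(alpha_conductance(12.5, 1, -3), 0)
  expect_lt(alpha_conductance(12.5, 1, 500), 1e-10)
  # numeric argmax oracle: time-to-peak equals tau_peak to within the grid
  s <- seq(0, 20, by = 0.001)
  for (tp in c(1, 2)) {
    g <- alpha_conductance(7, tp, s)
    expect_equal(s[which.max(g)], tp, tolerance = 0.002)
  }
  # linear superposition of two events
  g2 <- alpha_conductance(3, 1, s) + alpha_conductance(3, 1, s - 2.5)
  expect_equal(g2, vapply(s, function(x)
    sum(alpha_conductance(3, 1, c(x, x - 2.5))), numeric(1)))
})

test_that("circuit presets honor the documented topology", {
  c30 <- build_circuit("single_retina", n_tc = 30)
  expect_identical(c30$n_ret, 1)
  expect_true(all(vapply(c30$afferents, nrow, 1L) == 1L))
  expect_true(all(vapply(c30$afferents, function(a) a$weight, 1) == 12.5))
  expect_equal(unique(c30$w_tc), 7)                 # 30-cell preset
  expect_equal(sum(c30$w_tc), 210)                  # constant total drive
  expect_equal(unique(build_circuit("single_retina", 90)$w_tc), 2.33)
  expect_equal(unique(build_circuit("single_retina", 10)$w_tc), 21)
  expect_equal(unique(build_circuit("single_retina", 60)$w_tc), 210 / 60)

  mx <- build_circuit("mixed", n_tc = 30, n_ret = 15)
  indeg <- vapply(mx$afferents, nrow, 1L)
  expect_true(all(indeg == 2L))                     # 2 retinal per TC
  outdeg <- table(unlist(lapply(mx$afferents, function(a) a$ret)))
  expect_true(all(outdeg == 4))                     # 4 TC per retina
  w <- do.call(rbind, mx$afferents)$weight
  expect_setequal(unique(w), c(9.375, 3.125))       # 75/25 split of 12.5
  expect_true(all(vapply(mx$afferents, function(a) sum(a$weight), 1) == 12.5))
  expect_true(all(vapply(mx$afferents, function(a)
    length(unique(a$ret)) == 2L, logical(1))))
  expect_error(build_circuit("mixed", n_tc = 30, n_ret = 10),
               "4 \\* n_ret")
})

test_that("a silent circuit stays silent and a strong event fires cortex", {
  circ <- quick_circuit(n_tc = 3)
  quiet <- simulate(circ, spike_train(numeric(0), 2000), duration = 2000)
  expect_true(all(vapply(quiet$spikes_tc, function(s)
    length(s$times) == 0L, logical(1))))
  expect_length(quiet$spikes_ctx$times, 0)

  one85 <- simulate_cell(membrane_params("ctx"), 300,
                         events = data.frame(time = 100, weight = 85),
                         v0 = -70.6, record_every = 1)
  expect_length(one85$spikes, 1)
  expect_gt(max(one85$v), 0)                        # full action potential
  one40 <- simulate_cell(membrane_params("ctx"), 300,
                         events = data.frame(time = 100, weight = 40),
                         v0 = -70.6, record_every = 1)
  expect_length(one40$spikes, 0)
  expect_lt(max(one40$v), -30)
})

test_that("identical seeds and specs give bit-identical results", {
  run <- function() {
    set.seed(99)
    circ <- quick_circuit(n_tc = 5)
    ret <- quick_retina(4e3)
    simulate(circ, ret, noise = lc_noise(), duration = 4e3,
             thal_jitter = 1)
  }
  a <- run(); b <- run()
  expect_identical(lapply(a$spikes_tc, function(s) s$times),
                   lapply(b$spikes_tc, function(s) s$times))
  expect_identical(a$spikes_ctx$times, b$spikes_ctx$times)
})

test_that("feedforward inhibition with zero weight is a no-op", {
  base <- quick_circuit(n_tc = 5)
  with0 <- attach_ffi(base, 0, 3)
  run <- function(circ) {
    set.seed(7)
    simulate(circ, quick_retina(5e3), noise = lc_noise(), duration = 5e3)
  }
  expect_identical(run(base)$spikes_ctx$times, run(with0)$spikes_ctx$times)
  expect_error(attach_ffi(base, 50, 0))
  # nonzero FFI suppresses or delays some cortical spikes
  strong <- run(attach_ffi(base, 8, 0))
  expect_lte(length(strong$spikes_ctx$times),
             length(run(base)$spikes_ctx$times))
})

test_that("impaired cells lose retinal drive but keep bombarding noise", {
  set.seed(17)
  circ <- quick_circuit(n_tc = 4)
  sim <- simulate(circ, quick_retina(10e3), noise = lc_noise(),
                  duration = 10e3, impaired = c(1, 2))
  r <- vapply(sim$spikes_tc, function(s) 1000 * length(s$times) / 10e3,
              numeric(1))
  # impaired cells fire only noise-driven spikes, far below relay rate
  expect_lt(max(r[1:2]), min(r[3:4]) / 2)
  expect_gt(min(r[1:2]), 0)     # bombardment still drives some spikes
})

test_that("cortical STA peaks in the last few ms before cortical spikes", {
  set.seed(23)
  dur <- 20e3
  circ <- quick_circuit(n_tc = 10)
  ret <- quick_retina(dur)
  sim <- simulate(circ, ret, noise = lc_noise(), duration = dur)
  sta <- spike_triggered_average(sim$spikes_ctx, sim$spikes_tc)
  expect_identical(nrow(sta), 30L)
  expect_lte(sta$lag_ms[which.max(sta$mean)], 5)
})

test_that("supplied conductance traces reproduce the internal noise path", {
  # statistics only: both paths realize the same OU law
  set.seed(41)
  dur <- 5e3
  circ <- quick_circuit(n_tc = 2)
  tr <- lapply(1:2, function(i) ou_generate(ou_spec(), dur, 0.025))
  sim <- simulate(circ, quick_retina(dur), noise = tr, duration = dur)
  set.seed(41)
  sim2 <- simulate(circ, quick_retina(dur), noise = lc_noise(),
                   duration = dur)
  r1 <- mean(vapply(sim$spikes_tc, function(s) length(s$times), 1))
  r2 <- mean(vapply(sim2$spikes_tc, function(s) length(s$times), 1))
  expect_gt(r1, 0); expect_gt(r2, 0)
  expect_lt(abs(r1 - r2) / max(r1, r2), 0.35)
})

test_that("numerical blow-up is reported rather than silently produced", {
  circ <- quick_circuit(n_tc = 1)
  expect_error(
    simulate(circ, spike_train(numeric(0), 100),
             currents = current_spec(i_const = 1e5), duration = 100),
    "blow-up")
})
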