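test_that("normalization conventions give the published endpoints", {
  expect_equal(normalize_conductance(3, 0, 8.34)[["g0"]], 25.02)
  expect_equal(normalize_conductance(1.5, 1, 8.34)[["sigma"]], 12.51)
  z <- normalize_conductance(0, 0.7, 8.34)
  expect_identical(unname(z), c(0, 0))   # amplitude 0 nullifies fluctuations
  tot <- total_conductance(1.5 * 8.34, 1.0 * 8.34, 8.34)
  expect_equal(tot[["g_total"]], 20.85)
  expect_equal(tot[["g_norm"]], 2.5)
  hc <- total_conductance(2 * 8.34, 2 * 8.34, 8.34)
  expect_equal(hc[["g_total"]], 33.36)
  expect_equal(hc[["g_norm"]], 4)
  expect_equal(total_conductance(0, 0)[["g_total"]], 0)
})

test_that("OU traces have the stationary moments and autocorrelation", {
  frozen <- ou_spec(v_exc = 0, v_inh = 0)
  tr0 <- ou_generate(frozen, 100, dt = 0.05)
  expect_true(all(tr0$g_exc == frozen$g0_exc))
  expect_true(all(tr0$g_inh == frozen$g0_inh))

  set.seed(12)
  spec <- ou_spec()                          # LC: 12.51/2.502, 8.34/1.668 nS
  tr <- ou_generate(spec, 100e3, dt = 0.05)
  expect_equal(mean(tr$g_exc), spec$g0_exc, tolerance = 0.02)
  expect_equal(sd(tr$g_exc), spec$sigma_exc, tolerance = 0.03)
  expect_equal(mean(tr$g_inh), spec$g0_inh, tolerance = 0.02)
  expect_equal(sd(tr$g_inh), spec$sigma_inh, tolerance = 0.03)
  lag_e <- round(spec$tau_exc / 0.05)
  n <- length(tr$g_exc)
  ac <- cor(tr$g_exc[-(1:lag_e)], tr$g_exc[1:(n - lag_e)])
  expect_equal(ac, exp(-1), tolerance = 0.05)
  lag_i <- round(spec$tau_inh / 0.05)
  ac_i <- cor(tr$g_inh[-(1:lag_i)], tr$g_inh[1:(n - lag_i)])
  expect_equal(ac_i, exp(-1), tolerance = 0.05)
  expect_error(ou_generate(spec, 100, dt = 5), "smaller than")
})

test_that("excitation-inhibition mixing preserves moments and correlation", {
  set.seed(3)
  n <- 2e5
  xi <- rnorm(n)
  expect_equal(correlate_exc_inh(1, 0, xi), xi)
  ind <- correlate_exc_inh(0, 0, xi)
  expect_lt(abs(cor(ind, xi)), 3 / sqrt(n))
  half <- correlate_exc_inh(0.5, 0, xi)
  expect_equal(cor(half, xi), sqrt(0.5), tolerance = 0.01)
  expect_equal(mean(half), 0, tolerance = 0.01)
  expect_equal(sd(half), 1, tolerance = 0.01)
  # lagged mixing: correlation appears at the configured lag
  lagged <- correlate_exc_inh(1, 1, xi, dt = 0.5)   # 2-step lag
  expect_equal(cor(lagged[-(1:2)], xi[1:(n - 2)]), 1)
  expect_warning(correlate_exc_inh(0.5, 0.3, xi[1:100], dt = 0.2),
                 "rounded")
})

test_that("population schemas control pairwise correlation as specified", {
  set.seed(8)
  spec <- ou_spec()
  dur <- 20e3; dt <- 0.1
  pc <- function(field) {
    g <- vapply(field, function(f) f$g_exc, numeric(dur / dt + 1))
    cm <- cor(g)
    cm[upper.tri(cm)]
  }
  ind <- population_field(spec, 6, 0, "homogeneous", dur, dt)
  expect_lt(max(abs(pc(ind))), 0.05)
  same <- population_field(spec, 4, 1, "homogeneous", dur, dt)
  expect_equal(max(abs(pc(same) - 1)), 0, tolerance = 1e-12)
  hom <- population_field(spec, 8, 0.8, "homogeneous", dur, dt)
  rho_h <- pc(hom)
  expect_equal(mean(rho_h), 0.8, tolerance = 0.05)
  expect_lt(sd(rho_h), 0.05)                         # unimodal near 0.8
  het <- population_field(spec, 30, 0.8, "heterogeneous", dur, dt)
  expect_identical(attr(het, "m_common"), 1L + as.integer(round(0.8 * 29)))
  rho_t <- pc(het[c(1:4, 27:30)])                    # shared + independent
  expect_true(all(rho_t > 0.99 | abs(rho_t) < 0.1))  # bimodal
  expect_error(population_field(spec, 4, 0.5, "elsewise", dur, dt))
})

test_that("per-cell conductance statistics are invariant to c_pop", {
  spec <- ou_spec()
  for (schema in c("homogeneous", "heterogeneous")) {
    stats_at <- function(cpop, seed) {
      set.seed(seed)
      f <- population_field(spec, 4, cpop, schema, 50e3, 0.1)
      c(mean = mean(vapply(f, function(x) mean(x$g_exc), 1)),
        sd = mean(vapply(f, function(x) sd(x$g_exc), 1)))
    }
    a <- stats_at(0, 7); b <- stats_at(0.6, 7); c3 <- stats_at(1, 7)
    for (s in list(a, b, c3)) {
      expect_equal(s[["mean"]], spec$g0_exc, tolerance = 0.03)
      expect_equal(s[["sd"]], spec$sigma_exc, tolerance = 0.08)
    }
  }
})

test_that("mean pairwise conductance correlation is monotone in c_pop", {
  spec <- ou_spec()
  for (schema in c("homogeneous", "heterogeneous")) {
    set.seed(15)
    m <- vapply(c(0, 0.3, 0.6, 1), function(cp) {
      f <- population_field(spec, 8, cp, schema, 10e3, 0.1)
      g <- vapply(f, function(x) x$g_exc, numeric(10e3 / 0.1 + 1))
      cm <- cor(g)
      mean(cm[upper.tri(cm)])
    }, numeric(1))
    expect_true(all(diff(m) > -0.05))
    expect_lt(m[1], 0.1)
    expect_gt(m[4], 0.95)
  }
})

test_that("homogeneous mixing preserves the OU autocorrelation time", {
  set.seed(21)
  f <- population_field(ou_spec(), 2, 0.5, "homogeneous", 100e3, 0.1)
  g <- f[[1]]$g_exc
  lag <- round(2.7 / 0.1)
  ac <- cor(g[-(1:lag)], g[1:(length(g) - lag)])
  expect_equal(ac, exp(-1), tolerance = 0.05)
})

test_that("bombardment current uses reversal driving forces with clipping", {
  expect_equal(fluct_current(10, 5, 0), 5 * (-75) / 1000)   # exc term 0
  expect_equal(fluct_current(10, 5, -75), 10 * 75 / 1000)   # inh term 0
  expect_equal(fluct_current(10, 0, -70), 0.7)
  expect_equal(fluct_current(-3, 0, -70), 0)                # clipped
})
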