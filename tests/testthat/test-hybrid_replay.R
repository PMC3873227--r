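# pseudo-recording generation uses short sequences and few cells so that the
# whole file stays within a desk-scale run; the statistical assertions are
# sized accordingly

test_that("zero trial variability makes common-noise repetitions identical", {
  set.seed(81)
  sets <- generate_pseudo_recordings(
    n_cells = 1, spec = retinal_spec(duration = 5e3), duration = 5e3,
    cell_heterogeneity = 0, trial_jitter = 0)
  s <- sets[[1]]
  common <- s$spikes[s$condition == "common"]
  for (k in 2:10)
    expect_identical(common[[k]]$times, common[[1]]$times)
  # independent-noise sequences differ from the common ones
  indep <- s$spikes[s$condition == "independent"]
  expect_false(identical(indep[[1]]$times, common[[1]]$times))
  expect_identical(s$pattern_id,
                   c(rep(1L, 10), 2:11))
})

test_that("default trial variability lands membrane SD in the observed band", {
  set.seed(82)
  sets <- generate_pseudo_recordings(
    n_cells = 2, spec = retinal_spec(duration = 8e3), duration = 8e3)
  for (s in sets) {
    expect_true(all(s$membrane_sd > 0.9 & s$membrane_sd < 3.5))
    # trial-to-trial variability: common-noise trials differ but are far
    # more similar than independent-noise trials
    common <- s$spikes[s$condition == "common"]
    rho_c <- pairwise_correlation(common[[1]], common[[2]], bin_ms = 5)
    indep <- s$spikes[s$condition == "independent"]
    rho_i <- pairwise_correlation(indep[[1]], indep[[2]], bin_ms = 5)
    expect_gt(rho_c, rho_i)
  }
  # distinct cells: perturbed parameters differ
  expect_false(identical(sets[[1]]$params$g_T, sets[[2]]$params$g_T))
})

test_that("small single-cell layers mix common/independent as 1-9 ... 10-0", {
  set.seed(83)
  sets <- generate_pseudo_recordings(
    n_cells = 1, spec = retinal_spec(duration = 3e3), duration = 3e3,
    trial_jitter = 0)
  for (m in c(1, 4, 10)) {
    layer <- assemble_layer(sets, "small_single", n_common = m)
    expect_length(layer, 10)
    expect_equal(attr(layer, "c_pop"), (m - 1) / 9)
    comp <- attr(layer, "composition")
    expect_identical(sum(comp$sequence <= 10), as.integer(m))
  }
})

test_that("large layers sample or duplicate sequences per the stated rules", {
  set.seed(84)
  sets <- generate_pseudo_recordings(
    n_cells = 3, spec = retinal_spec(duration = 2e3), duration = 2e3,
    trial_jitter = 0)
  big <- assemble_layer(sets, "large_mixed", n = 25, condition = "correlated")
  expect_length(big, 25)
  comp <- attr(big, "composition")
  expect_lte(max(table(paste(comp$cell, comp$sequence))), 1)  # distinct
  expect_error(assemble_layer(sets, "large_mixed", n = 31),
               "only 30 are available")

  solo <- assemble_layer(sets, "large_single", n = 130,
                         condition = "correlated", set_index = 2)
  expect_length(solo, 130)
  comp2 <- attr(solo, "composition")
  expect_true(all(table(comp2$sequence) == 13))   # duplicated 13 times
  # partially decorrelated condition has no defined correlation strength
  dec <- assemble_layer(sets, "large_single", n = 20,
                        condition = "decorrelated")
  expect_true(is.na(attr(dec, "c_pop")))
})

test_that("replay is output-equivalent to direct simulation", {
  set.seed(85)
  dur <- 5e3
  n <- 4
  circ <- quick_circuit(n_tc = n, w_tc = 21)
  traces <- lapply(seq_len(n), function(i) ou_generate(ou_spec(), dur, 0.025))
  ret <- quick_retina(dur)
  direct <- simulate(circ, ret, noise = traces, duration = dur)
  rp <- replay(direct$spikes_tc, w_tc = 21, duration = dur)
  expect_identical(rp$spikes_ctx$times, direct$spikes_ctx$times)
})

test_that("replay handles empty layers and is deterministic", {
  empty <- replay(list(spike_train(numeric(0), 1000)), duration = 1000)
  expect_length(empty$spikes_ctx$times, 0)
  set.seed(86)
  layer <- list(quick_retina(3e3), quick_retina(3e3))
  a <- replay(layer, w_tc = 45)
  b <- replay(layer, w_tc = 45)
  expect_identical(a$spikes_ctx$times, b$spikes_ctx$times)
  expect_gt(length(a$spikes_ctx$times), 0)
  expect_error(replay(list(quick_retina(3e3), quick_retina(4e3))),
               "mismatched")
})

test_that("transfer drops between uncorrelated and correlated hybrid layers", {
  set.seed(87)
  dur <- 12e3
  n_sets <- 3
  sets <- generate_pseudo_recordings(
    n_cells = n_sets, spec = retinal_spec(duration = dur), duration = dur)
  te_at <- function(set, m) {
    layer <- assemble_layer(list(set), "small_single", n_common = m)
    rp <- replay(layer, w_tc = 21, duration = dur)
    mutual_information(set$retinal, rp$spikes_ctx,
                       mi_settings(bin_ms = 3, lag_ms = 6))$te
  }
  te0 <- vapply(sets, te_at, numeric(1), m = 1)    # c_pop = 0
  te1 <- vapply(sets, te_at, numeric(1), m = 10)   # c_pop = 1
  # direction per the population-decorrelation principle, paired by set
  expect_gt(mean(te0 - te1), 0)
  expect_true(sum(te0 > te1) >= n_sets - 1)
})
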