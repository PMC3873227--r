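#' Parametric experiment specification
#'
#' Config object for [run_experiment()]. Each experiment id reproduces one
#' of the published parametric sweeps; the default grids are transcribed
#' from the corresponding figure axes and can be overridden. A `scale`
#' in (0, 1] shortens durations and repetition counts (analysis settings
#' are untouched) so every experiment also runs at desk scale.
#'
#' Experiment ids: `fig2a` (population size sweep), `fig2b` (TC weight
#' sweep), `fig2c` (retinal synchronization x jitter), `fig2d` (thalamic
#' jitter), `fig3a` (conductance amplitude grid), `fig3b` (variation-ratio
#' grid), `fig3d` (impaired layer), `fig4` (population correlation sweep,
#' both schemas), `fig5_synthetic` (small single-cell hybrid layers),
#' `fig6` (cellular heterogeneity), `fig7` (coherent vs desynchronized
#' oscillations), `s2` (single AMPA event threshold), `s3` (no-bombardment
#' baseline with constant current), `s4` (feedforward inhibition grid),
#' `s5` (excitation-inhibition correlation grid).
#'
#' @param id experiment identifier (see Details).
#' @param grid data frame of grid points; `NULL` for the preset.
#' @param repetitions repeats per grid point (different bombardment
#'   realizations); `NULL` for 10 at full scale, 3 below.
#' @param duration per-simulation duration (ms); `NULL` for 100 s scaled.
#' @param dt integration step (ms).
#' @param seed base seed; expanded deterministically per grid point,
#'   repeat and stream.
#' @param scale scale factor in (0, 1].
#' @return object of class `experiment_spec`.
#' @export
experiment_spec <- function(id, grid = NULL, repetitions = NULL,
                            duration = NULL, dt = 0.025, seed = 1,
                            scale = 1) {
  ids <- c("fig2a", "fig2b", "fig2c", "fig2d", "fig3a", "fig3b", "fig3d",
           "fig4", "fig5_synthetic", "fig6", "fig7", "s2", "s3", "s4", "s5")
  if (!id %in% ids) stop("unknown experiment id; one of: ",
                         paste(ids, collapse = ", "))
  stopifnot(scale > 0, scale <= 1)
  if (is.null(grid)) grid <- .default_grid(id, scale)
  if (is.null(repetitions)) repetitions <- if (scale >= 1) 10 else 3
  if (is.null(duration)) duration <- max(10e3, 100e3 * scale)
  structure(list(id = id, grid = grid, repetitions = repetitions,
                 duration = duration, dt = dt, seed = seed, scale = scale),
            class = "experiment_spec")
}

.default_grid <- function(id, scale) {
  red <- scale < 1
  switch(id,
    fig2a = expand.grid(n_tc = if (red) c(10, 30, 60, 90, 120, 180)
                        else c(10, 30, 60, 90, 120, 180, 240),
                        w_tc = 2.33),
    fig2b = expand.grid(n_tc = 90,
                        w_tc = if (red) c(0.5, 1, 2.33, 5, 10)
                        else c(0.25, 0.5, 1, 2.33, 5, 10, 20)),
    fig2c = expand.grid(s_ret = if (red) c(0, 0.5, 1) else seq(0, 1, 0.25),
                        jitter = if (red) c(0, 3, 10) else c(0, 1, 3, 5, 10)),
    fig2d = expand.grid(thal_jitter = if (red) c(0, 3, 10)
                        else c(0, 1, 3, 5, 10)),
    fig3a = expand.grid(a_exc = if (red) seq(0, 3, 0.6) else seq(0, 3, 0.25),
                        a_inh = if (red) seq(0, 3, 0.6) else seq(0, 3, 0.25)),
    fig3b = expand.grid(v_exc = if (red) c(0, 0.2, 0.5, 1)
                        else seq(0, 1, 0.1),
                        v_inh = if (red) c(0, 0.2, 0.5, 1)
                        else seq(0, 1, 0.1)),
    fig3d = expand.grid(a_exc = if (red) seq(0, 3, 0.75) else seq(0, 3, 0.25),
                        a_inh = if (red) seq(0, 3, 0.75) else seq(0, 3, 0.25),
                        impaired = c(FALSE, TRUE)),
    fig4 = expand.grid(c_pop = seq(0, 1, if (red) 0.25 else 0.2),
                       schema = c("homogeneous", "heterogeneous"),
                       stringsAsFactors = FALSE),
    fig5_synthetic = expand.grid(n_common = if (red) c(1, 4, 7, 10)
                                 else 1:10),
    fig6 = expand.grid(h = if (red) c(0, 0.2, 0.6, 1) else seq(0, 1, 0.2),
                       correlated = c(FALSE, TRUE)),
    fig7 = expand.grid(a = if (red) c(0.1, 0.3) else c(0.1, 0.2, 0.4, 0.6),
                       f = if (red) c(10, 40) else c(5, 10, 20, 40, 60),
                       coherent = c(TRUE, FALSE)),
    s2 = expand.grid(w_event = c(20, 40, 60, 70, 75, 80, 85, 90, 120),
                     bombardment = FALSE),
    s3 = expand.grid(i_const = if (red) c(0, 0.6) else c(0, 0.2, 0.4, 0.6)),
    s4 = expand.grid(w_gaba = if (red) c(0, 4) else c(0, 1, 3, 4, 5, 10),
                     lag = if (red) c(0, 3) else c(0, 1, 3, 5, 10),
                     regime = c("lc", "saturated"),
                     stringsAsFactors = FALSE),
    s5 = expand.grid(c_ei = if (red) c(0, 0.5, 1) else seq(0, 1, 0.25),
                     lag_ei = if (red) c(0, 5) else c(0, 2, 5, 10)))
}

# deterministic sub-seed per (point, repeat); kept below 2^31
.sub_seed <- function(base, point, rep)
  (base + 1000003 * point + 7919 * rep) %% 2147483629L + 1

# one grid point, one repeat -> named numeric metrics
.run_point <- function(id, pt, duration, dt) {
  lc <- ou_spec(a_exc = 1.5, a_inh = 1.0, v_exc = 0.2, v_inh = 0.2)
  set_mi <- mi_settings(bin_ms = 1, lag_ms = 6)
  te_of <- function(sim, retinal)
    mutual_information(retinal, sim$spikes_ctx, set_mi)$te
  run_simple <- function(circ, retinal, nf, ...) {
    sim <- simulate(circ, retinal, noise = nf, duration = duration,
                    dt = dt, ...)
    c(te = te_of(sim, retinal[[1]]),
      tc_rate = mean(vapply(sim$spikes_tc, function(s)
        1000 * length(s$times) / s$duration, numeric(1))),
      ctx_rate = 1000 * length(sim$spikes_ctx$times) / duration)
  }
  spec_ret <- retinal_spec(duration = duration)
  switch(id,
    fig2a = ,
    fig2b = {
      circ <- build_circuit("single_retina", n_tc = pt$n_tc,
                            w_tc = pt$w_tc)
      run_simple(circ, list(gamma_spike_train(spec_ret)), noise_field(lc))
    },
    fig2c = {
      circ <- build_circuit("mixed", n_tc = 30, n_ret = 15, w_tc = 7)
      spec15 <- retinal_spec(duration = duration, n_ret = 15,
                             s_ret = pt$s_ret)
      lines <- synchronize_lines(spec15)
      if (pt$jitter > 0)
        lines <- lapply(lines, jitter_spikes, j_ms = pt$jitter)
      sim <- simulate(circ, lines, noise = noise_field(lc),
                      duration = duration, dt = dt)
      c(te = te_of(sim, lines[[1]]))
    },
    fig2d = {
      circ <- build_circuit("single_retina", n_tc = 30, w_tc = 7)
      ret <- gamma_spike_train(spec_ret)
      sim <- simulate(circ, list(ret), noise = noise_field(lc),
                      duration = duration, dt = dt,
                      thal_jitter = pt$thal_jitter)
      c(te = te_of(sim, ret))
    },
    fig3a = ,
    fig3d = {
      ou <- ou_spec(a_exc = pt$a_exc, a_inh = pt$a_inh,
                    v_exc = 0.2, v_inh = 0.2)
      n_tc <- if (id == "fig3d") 90 else 30
      circ <- build_circuit("single_retina", n_tc = n_tc,
                            w_tc = if (id == "fig3d") 2.33 else 7)
      imp <- if (id == "fig3d" && isTRUE(pt$impaired))
        seq_len(n_tc %/% 2) else NULL
      run_simple(circ, list(gamma_spike_train(spec_ret)), noise_field(ou),
                 impaired = imp)
    },
    fig3b = {
      ou <- ou_spec(a_exc = 1.5, a_inh = 1.0, v_exc = pt$v_exc,
                    v_inh = pt$v_inh)
      circ <- build_circuit("single_retina", n_tc = 30, w_tc = 7)
      run_simple(circ, list(gamma_spike_train(spec_ret)), noise_field(ou))
    },
    fig4 = {
      circ <- build_circuit("single_retina", n_tc = 30, w_tc = 7)
      ret <- gamma_spike_train(spec_ret)
      sim <- simulate(circ, list(ret),
                      noise = noise_field(lc, c_pop = pt$c_pop,
                                          schema = pt$schema),
                      duration = duration, dt = dt)
      pc <- population_correlation(sim$spikes_tc)
      ptes <- partial_te(ret, sim$spikes_tc[[1]], sim$spikes_ctx, set_mi)
      rates <- rate_and_cv(sim$spikes_tc)
      crate <- rate_and_cv(sim$spikes_ctx)
      c(te = te_of(sim, ret),
        te_rt = ptes$retinothalamic$te, te_tc = ptes$thalamocortical$te,
        pair_rho = pc$mean,
        tc_rate = rates$rate, tc_cv = rates$cv,
        ctx_rate = crate$rate, ctx_cv = crate$cv)
    },
    fig5_synthetic = {
      sets <- generate_pseudo_recordings(
        n_cells = 1, spec = retinal_spec(duration = duration),
        duration = duration, dt = dt)
      layer <- assemble_layer(sets, "small_single", n_common = pt$n_common)
      rp <- replay(layer, w_tc = 21)
      res <- mutual_information(sets[[1]]$retinal, rp$spikes_ctx,
                                mi_settings(bin_ms = 3, lag_ms = 6))
      c(te = res$te, c_pop = attr(layer, "c_pop"))
    },
    fig6 = {
      tcp <- lapply(seq_len(30), function(i)
        randomize_cell(membrane_params("tc"), pt$h))
      circ <- build_circuit("single_retina", n_tc = 30, w_tc = 7,
                            tc_params = tcp)
      nf <- noise_field(lc, c_pop = if (pt$correlated) 1 else 0)
      ret <- gamma_spike_train(spec_ret)
      sim <- simulate(circ, list(ret), noise = nf, duration = duration,
                      dt = dt)
      c(te = te_of(sim, ret))
    },
    fig7 = {
      circ <- build_circuit("single_retina", n_tc = 30, w_tc = 7)
      phis <- if (pt$coherent) rep(0, 30) else runif(30, 0, 2 * pi)
      cur <- lapply(phis, function(p)
        current_spec(a = pt$a, f = pt$f, phi = p))
      ret <- gamma_spike_train(spec_ret)
      sim <- simulate(circ, list(ret), noise = noise_field(lc),
                      currents = cur, duration = duration, dt = dt)
      c(te = te_of(sim, ret))
    },
    s2 = {
      ev <- data.frame(time = seq(100, by = 200,
                                  length.out = floor(duration / 200)),
                       weight = pt$w_event)
      r <- simulate_cell(membrane_params("ctx"), duration, dt,
                         events = ev, v0 = -70.6)
      evoked <- vapply(ev$time, function(t0)
        any(r$spikes > t0 & r$spikes <= t0 + 10), logical(1))
      c(p_spike = mean(evoked))
    },
    s3 = {
      circ <- build_circuit("single_retina", n_tc = 30, w_tc = 7)
      ret <- gamma_spike_train(spec_ret)
      sim <- simulate(circ, list(ret), noise = NULL,
                      currents = current_spec(i_const = pt$i_const),
                      duration = duration, dt = dt)
      c(te = te_of(sim, ret))
    },
    s4 = {
      ou <- if (pt$regime == "lc") lc
            else ou_spec(a_exc = 3, a_inh = 0.5, v_exc = 0.2, v_inh = 0.2)
      circ <- attach_ffi(build_circuit("single_retina", n_tc = 30,
                                       w_tc = 7), pt$w_gaba, pt$lag)
      run_simple(circ, list(gamma_spike_train(spec_ret)), noise_field(ou))
    },
    s5 = {
      circ <- build_circuit("single_retina", n_tc = 30, w_tc = 7)
      nf <- noise_field(lc, c_ei = pt$c_ei, lag_ei = pt$lag_ei)
      run_simple(circ, list(gamma_spike_train(spec_ret)), nf)
    })
}

#' Run a parametric experiment
#'
#' Executes every grid point for the requested number of repetitions, with
#' deterministic per-point per-repeat seeds derived from the base seed,
#' and returns a long-format result table (one row per grid point and
#' repeat). Failures at individual grid points are recorded (`error`
#' column) and the sweep continues.
#'
#' @param spec an [experiment_spec()].
#' @param verbose print progress to stderr.
#' @return data frame of class `sweep_result`: grid columns, `rep`,
#'   `seed`, one column per metric, and `error`.
#' @export
run_experiment <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  rows <- list()
  for (gi in seq_len(nrow(spec$grid))) {
    pt <- as.list(spec$grid[gi, , drop = FALSE])
    for (rp in seq_len(spec$repetitions)) {
      sd_ <- .sub_seed(spec$seed, gi, rp)
      set.seed(sd_)
      met <- tryCatch(.run_point(spec$id, pt, spec$duration, spec$dt),
                      error = function(e) e)
      row <- cbind(spec$grid[gi, , drop = FALSE],
                   data.frame(rep = rp, seed = sd_))
      if (inherits(met, "error")) {
        row$error <- conditionMessage(met)
        if (verbose) message(sprintf("point %d rep %d FAILED: %s", gi, rp,
                                     row$error))
      } else {
        for (nm in names(met)) row[[nm]] <- unname(met[nm])
        row$error <- NA_character_
        if (verbose) message(sprintf("point %d rep %d: %s", gi, rp,
                                     paste(sprintf("%s=%.3g", names(met),
                                                   met), collapse = " ")))
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(unique(unlist(lapply(rows, names))), names(r))
    for (m in miss) r[[m]] <- NA
    r
  }))
  rownames(out) <- NULL
  class(out) <- c("sweep_result", class(out))
  out
}

#' Locate the optimum of a sweep
#'
#' Argmax of the repeat-averaged metric over grid points, with ties broken
#' toward the smaller parameter value and optional 3-point smoothing for
#' noisy one-dimensional sweeps.
#'
#' @param sweep a [run_experiment()] result (or any data frame with grid
#'   columns and a metric column).
#' @param metric metric column name.
#' @param smoothing apply 3-point moving-average smoothing (1-D sweeps
#'   only).
#' @return list with `point` (one-row data frame of grid values), `value`
#'   (averaged metric), `table` (per-point averages).
#' @export
find_optimum <- function(sweep, metric = "te", smoothing = FALSE) {
  stopifnot(nrow(sweep) > 0, metric %in% names(sweep))
  # grid columns = everything before the rep column
  grid_cols <- names(sweep)[seq_len(match("rep", names(sweep)) - 1)]
  grid_cols <- setdiff(grid_cols, metric)
  key <- interaction(sweep[grid_cols], drop = TRUE, lex.order = TRUE)
  vals <- tapply(sweep[[metric]], key, mean, na.rm = TRUE)
  if (all(is.na(vals))) stop("metric is NA at every grid point")
  tab <- unique(sweep[grid_cols])
  rownames(tab) <- NULL
  key_u <- interaction(tab, drop = TRUE, lex.order = TRUE)
  tab[[metric]] <- as.numeric(vals[match(as.character(key_u), names(vals))])
  v <- tab[[metric]]
  if (smoothing && length(grid_cols) == 1 && nrow(tab) >= 3) {
    o <- order(tab[[grid_cols]])
    tab <- tab[o, , drop = FALSE]
    v <- tab[[metric]]
    v <- (c(v[1], head(v, -1)) + v + c(tail(v, -1), v[length(v)])) / 3
    tab[[metric]] <- v
  }
  best <- which(v == max(v, na.rm = TRUE))[1]   # first = smaller parameter
  list(point = tab[best, grid_cols, drop = FALSE], value = v[best],
       table = tab)
}
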