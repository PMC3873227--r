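#' Analysis settings for windowed mutual information
#'
#' @param window_ms window length (ms), default 30; must be divisible by
#'   the bin size.
#' @param bin_ms bin size (ms): 1 for model-circuit analysis, 3 for
#'   replayed/hybrid layers.
#' @param lag_ms stimulus-to-response lag (ms): the response is shifted
#'   back by this amount before windowing. Documented estimates: 6 ms
#'   retinocortical, 4 ms retinothalamic, 2 ms thalamocortical.
#' @param n_shuffle bootstrap re-pairings used for the bias estimate.
#' @param subsample_fractions nested data fractions for the finite-size
#'   diagnostic.
#' @return object of class `mi_settings`.
#' @export
mi_settings <- function(window_ms = 30, bin_ms = 1, lag_ms = 6,
                        n_shuffle = 20,
                        subsample_fractions = c(1, 1 / 2, 1 / 4, 1 / 8)) {
  stopifnot(window_ms > 0, bin_ms > 0, lag_ms >= 0, n_shuffle >= 2)
  if (abs(window_ms / bin_ms - round(window_ms / bin_ms)) > 1e-9)
    stop("window_ms must be divisible by bin_ms")
  structure(list(window_ms = window_ms, bin_ms = bin_ms, lag_ms = lag_ms,
                 n_shuffle = n_shuffle,
                 subsample_fractions = subsample_fractions),
            class = "mi_settings")
}

#' Binarize a spike train
#'
#' Right-open binning: bin `i` is 1 iff at least one spike falls in
#' `[i b, (i+1) b)`; multiple spikes in one bin still count as a single 1.
#'
#' @param train a [spike_train()] or numeric spike times (ms).
#' @param bin_ms bin size (ms).
#' @param duration analysis duration (ms).
#' @return integer 0/1 vector of length `floor(duration / bin_ms)`.
#' @export
binarize <- function(train, bin_ms, duration) {
  stopifnot(bin_ms > 0, duration > 0)
  tt <- if (inherits(train, "spike_train")) train$times else
    sort(as.numeric(train))
  n <- floor(duration / bin_ms)
  out <- integer(n)
  idx <- floor(tt / bin_ms) + 1
  idx <- idx[idx >= 1 & idx <= n]
  out[unique(idx)] <- 1L
  out
}

# cut a binary sequence into consecutive non-overlapping word strings
.words <- function(bits, bins_per_word) {
  nw <- length(bits) %/% bins_per_word
  if (nw == 0) return(character(0))
  m <- matrix(bits[seq_len(nw * bins_per_word)], nrow = bins_per_word)
  # pack into strings; words are sparse so strings are a fine dictionary key
  apply(m, 2, paste, collapse = "")
}

.entropy_bits <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

.plugin_mi <- function(sw, rw) {
  hs <- .entropy_bits(table(sw))
  hr <- .entropy_bits(table(rw))
  hsr <- .entropy_bits(table(paste(sw, rw, sep = "|")))
  hs + hr - hsr
}

#' Windowed binary-word mutual information and transfer efficiency
#'
#' Shifts the response back by the configured lag, binarizes both trains,
#' cuts them into consecutive non-overlapping windows and computes the
#' plug-in mutual information between stimulus and response window words.
#' The residual estimator bias is measured by randomly re-pairing stimulus
#' and response windows (`n_shuffle` times) and subtracted; the transfer
#' efficiency is the corrected information per window divided by the window
#' length, in bits/s. Small negative corrected values are clipped to 0 and
#' flagged.
#'
#' @param s_train,r_train stimulus and response [spike_train()]s covering
#'   the analysis duration.
#' @param settings an [mi_settings()].
#' @param duration analysis duration (ms); defaults to the stimulus
#'   train's duration.
#' @return object of class `transfer_result`: `mi_raw`, `bias`,
#'   `mi_corrected` (bits/window), `te` (bits/s), `n_windows`,
#'   `n_words_s`, `n_words_r`, `flags` (character), `settings`.
#' @export
#' @examples
#' set.seed(1)
#' s <- gamma_spike_train(retinal_spec(duration = 20e3))
#' mutual_information(s, s, mi_settings(lag_ms = 0))  # identity channel
mutual_information <- function(s_train, r_train, settings = mi_settings(),
                               duration = NULL) {
  stopifnot(inherits(settings, "mi_settings"))
  if (is.null(duration))
    duration <- if (inherits(s_train, "spike_train")) s_train$duration
                else max(unlist(s_train))
  st <- if (inherits(s_train, "spike_train")) s_train$times else s_train
  rt <- if (inherits(r_train, "spike_train")) r_train$times else r_train
  rt <- rt - settings$lag_ms                       # response shifted back
  flags <- character(0)
  sb <- binarize(st, settings$bin_ms, duration)
  rb <- binarize(rt[rt >= 0], settings$bin_ms, duration)
  bpw <- as.integer(round(settings$window_ms / settings$bin_ms))
  sw <- .words(sb, bpw)
  rw <- .words(rb, bpw)
  nw <- length(sw)
  if (nw < 500) flags <- c(flags, "few_windows")
  if (!any(sb == 1L)) {
    res <- list(mi_raw = 0, bias = 0, mi_corrected = 0, te = 0,
                n_windows = nw, n_words_s = 1L, n_words_r = 1L,
                flags = c(flags, "zero_entropy_stimulus"),
                settings = settings)
    class(res) <- "transfer_result"
    return(res)
  }
  mi_raw <- .plugin_mi(sw, rw)
  bias <- mean(vapply(seq_len(settings$n_shuffle), function(i)
    .plugin_mi(sw, sample(rw)), numeric(1)))
  mi_c <- mi_raw - bias
  if (mi_c < 0) {
    flags <- c(flags, "negative_clipped")
    mi_c <- 0
  }
  res <- list(mi_raw = mi_raw, bias = bias, mi_corrected = mi_c,
              te = mi_c / (settings$window_ms / 1000),
              n_windows = nw,
              n_words_s = length(unique(sw)),
              n_words_r = length(unique(rw)),
              flags = flags, settings = settings)
  class(res) <- "transfer_result"
  res
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf(
    "<transfer_result: TE %.4g bits/s (MI %.4g - bias %.4g bits/window, %d windows)%s>\n",
    x$te, x$mi_raw, x$bias, x$n_windows,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
    else ""))
  invisible(x)
}

#' Finite-size (undersampling) diagnostic
#'
#' Recomputes the raw mutual information on nested fractions of the
#' windows, fits a line in the inverse number of windows and extrapolates
#' to infinite data; returns `|extrapolated - full| / full`. Values above
#' 1% indicate that the window/bin configuration undersamples the word
#' distribution.
#'
#' @inheritParams mutual_information
#' @return list with `fraction` (relative correction), `flag` (`TRUE` if
#'   above 1%), `mi_by_fraction`.
#' @export
finite_size_check <- function(s_train, r_train, settings = mi_settings(),
                              duration = NULL) {
  stopifnot(length(settings$subsample_fractions) >= 4)
  if (is.null(duration))
    duration <- if (inherits(s_train, "spike_train")) s_train$duration
                else max(unlist(s_train))
  st <- if (inherits(s_train, "spike_train")) s_train$times else s_train
  rt <- if (inherits(r_train, "spike_train")) r_train$times else r_train
  rt <- rt - settings$lag_ms
  sb <- binarize(st, settings$bin_ms, duration)
  rb <- binarize(rt[rt >= 0], settings$bin_ms, duration)
  bpw <- as.integer(round(settings$window_ms / settings$bin_ms))
  sw <- .words(sb, bpw)
  rw <- .words(rb, bpw)
  nw <- length(sw)
  fr <- sort(settings$subsample_fractions, decreasing = TRUE)
  mi <- vapply(fr, function(f) {
    k <- max(2L, floor(nw * f))
    .plugin_mi(sw[seq_len(k)], rw[seq_len(k)])
  }, numeric(1))
  ns <- pmax(2L, floor(nw * fr))
  fit <- lm(mi ~ I(1 / ns))
  mi_inf <- unname(coef(fit)[1])
  full <- mi[1]
  fraction <- if (full > 0) abs(mi_inf - full) / full else 0
  list(fraction = fraction, flag = fraction > 0.01,
       mi_by_fraction = data.frame(fraction = fr, n_windows = ns, mi = mi))
}

#' Partial transfer efficiencies along the pathway
#'
#' Computes the retinothalamic (retina to one chosen TC cell, 4 ms lag),
#' thalamocortical (that TC cell to cortex, 2 ms lag) and global
#' retinocortical (6 ms lag) transfer efficiencies with shared window/bin
#' settings.
#'
#' @param retinal,thalamic,cortical [spike_train()]s of equal duration.
#' @param settings an [mi_settings()]; its `lag_ms` is overridden per
#'   pathway by `lags`.
#' @param lags named numeric vector with elements `rt`, `tc`, `rc` (ms).
#' @return list of three `transfer_result`s: `retinothalamic`,
#'   `thalamocortical`, `retinocortical`.
#' @export
partial_te <- function(retinal, thalamic, cortical,
                       settings = mi_settings(),
                       lags = c(rt = 4, tc = 2, rc = 6)) {
  with_lag <- function(l) {
    s <- settings; s$lag_ms <- l; s
  }
  list(retinothalamic = mutual_information(retinal, thalamic,
                                           with_lag(lags[["rt"]])),
       thalamocortical = mutual_information(thalamic, cortical,
                                            with_lag(lags[["tc"]])),
       retinocortical = mutual_information(retinal, cortical,
                                           with_lag(lags[["rc"]])))
}

#' Transfer efficacy and contribution
#'
#' Efficacy: probability that a retinal spike is followed by at least one
#' cortical spike within `window_ms`. Contribution: ratio of transmitted
#' retinal spikes (the efficacy numerator) to the total number of cortical
#' spikes; undefined (flagged, `NA`) when the cortex is silent.
#'
#' @param retinal,cortical [spike_train()]s.
#' @param window_ms follow window (ms), default 30.
#' @return list with `efficacy`, `contribution`, `flags`.
#' @export
efficacy_contribution <- function(retinal, cortical, window_ms = 30) {
  rt <- retinal$times
  ct <- cortical$times
  stopifnot(length(rt) > 0)
  if (length(ct) == 0)
    return(list(efficacy = 0, contribution = NA_real_,
                flags = "no_cortical_spikes"))
  nxt <- findInterval(rt, ct, left.open = TRUE) + 1  # first ct spike >= rt
  transmitted <- nxt <= length(ct) & (ct[pmin(nxt, length(ct))] - rt) <=
    window_ms
  list(efficacy = mean(transmitted),
       contribution = min(1, sum(transmitted) / length(ct)),
       flags = character(0))
}

#' Pairwise spike-train correlation
#'
#' Pearson correlation between binarized (1 ms default) spike sequences,
#' and a population wrapper averaging over all unique pairs.
#'
#' @param x,y [spike_train()]s of equal duration.
#' @param bin_ms bin size (ms).
#' @return correlation coefficient, `NA` (with attribute `flag`) if either
#'   sequence has zero variance.
#' @export
pairwise_correlation <- function(x, y, bin_ms = 1) {
  stopifnot(abs(x$duration - y$duration) < bin_ms)
  bx <- binarize(x, bin_ms, x$duration)
  by <- binarize(y, bin_ms, x$duration)
  if (var(bx) == 0 || var(by) == 0)
    return(structure(NA_real_, flag = "zero_variance"))
  cor(bx, by)
}

#' @rdname pairwise_correlation
#' @param trains list of [spike_train()]s.
#' @return `population_correlation`: list with `mean` over unique pairs and
#'   the vector of pairwise `rho` values.
#' @export
population_correlation <- function(trains, bin_ms = 1) {
  n <- length(trains)
  stopifnot(n >= 2)
  dur <- trains[[1]]$duration
  b <- vapply(trains, binarize, integer(floor(dur / bin_ms)),
              bin_ms = bin_ms, duration = dur)
  keep <- apply(b, 2, var) > 0
  rho <- if (sum(keep) >= 2) {
    cm <- cor(b[, keep, drop = FALSE])
    cm[upper.tri(cm)]
  } else numeric(0)
  list(mean = if (length(rho)) mean(rho) else NA_real_, rho = rho,
       n_zero_variance = sum(!keep))
}

#' Spike-triggered average of thalamic counts
#'
#' For each cortical spike, sums the thalamic spikes falling in each 1 ms
#' bin of the 30 ms region preceding it; bin `j` counts spikes `j` ms
#' before the cortical spike. Returns the across-spike mean and SD per bin.
#'
#' @param cortical [spike_train()] with at least one spike.
#' @param thalamic list of thalamic [spike_train()]s.
#' @param window_ms preceding region (ms).
#' @param bin_ms bin size (ms).
#' @return data frame with `lag_ms` (1..window), `mean`, `sd`; empty if
#'   there are no cortical spikes.
#' @export
spike_triggered_average <- function(cortical, thalamic, window_ms = 30,
                                    bin_ms = 1) {
  ct <- cortical$times
  nb <- round(window_ms / bin_ms)
  if (length(ct) == 0)
    return(data.frame(lag_ms = numeric(0), mean = numeric(0),
                      sd = numeric(0)))
  th <- sort(unlist(lapply(thalamic, function(s) s$times)))
  counts <- matrix(0L, length(ct), nb)
  for (j in seq_len(nb)) {
    lo <- ct - j * bin_ms
    hi <- lo + bin_ms
    counts[, j] <- findInterval(hi, th, left.open = TRUE) -
      findInterval(lo, th, left.open = TRUE)
  }
  data.frame(lag_ms = seq_len(nb) * bin_ms,
             mean = colMeans(counts),
             sd = apply(counts, 2, sd))
}

#' Firing rate and interspike-interval CV
#'
#' Rates in Hz; CV = SD(ISI)/mean(ISI). For a list of trains (thalamic
#' population) the SD is taken across cells; for a single train (cortical)
#' the rate SD is taken across non-overlapping windows of the train.
#'
#' @param trains a [spike_train()] or list of them.
#' @param window_s window length (s) for the single-train rate SD.
#' @return list with `rate`, `rate_sd`, `cv`, `cv_sd`, `flags`.
#' @export
rate_and_cv <- function(trains, window_s = 1) {
  one_cv <- function(s) {
    if (length(s$times) < 3) return(NA_real_)
    isi <- diff(s$times)
    sd(isi) / mean(isi)
  }
  if (inherits(trains, "spike_train")) {
    dur_s <- trains$duration / 1000
    rate <- length(trains$times) / dur_s
    edges <- seq(0, trains$duration, by = window_s * 1000)
    wins <- if (length(edges) > 2)
      tabulate(findInterval(trains$times, edges, left.open = FALSE),
               nbins = length(edges) - 1) / window_s
    else rate
    cv <- one_cv(trains)
    list(rate = rate, rate_sd = sd(wins), cv = cv, cv_sd = NA_real_,
         flags = if (is.na(cv)) "cv_undefined" else character(0))
  } else {
    rates <- vapply(trains, function(s)
      1000 * length(s$times) / s$duration, numeric(1))
    cvs <- vapply(trains, one_cv, numeric(1))
    list(rate = mean(rates), rate_sd = sd(rates),
         cv = mean(cvs, na.rm = TRUE), cv_sd = sd(cvs, na.rm = TRUE),
         flags = if (anyNA(cvs)) "cv_undefined_some_cells" else character(0))
  }
}

#' Spike-count mutual information per window
#'
#' As [mutual_information()] but with each window reduced to its spike
#' count, a coarsening of the binary word; by the data-processing
#' inequality it is bounded above by the word information on the same data.
#'
#' @inheritParams mutual_information
#' @return a `transfer_result` (fields as for [mutual_information()]).
#' @export
spike_count_mi <- function(s_train, r_train, settings = mi_settings(),
                           duration = NULL) {
  if (is.null(duration))
    duration <- if (inherits(s_train, "spike_train")) s_train$duration
                else max(unlist(s_train))
  st <- if (inherits(s_train, "spike_train")) s_train$times else s_train
  rt <- if (inherits(r_train, "spike_train")) r_train$times else r_train
  rt <- rt - settings$lag_ms
  count_words <- function(tt) {
    nw <- floor(duration / settings$window_ms)
    counts <- tabulate(pmin(floor(tt / settings$window_ms) + 1, nw),
                       nbins = nw)
    as.character(counts)
  }
  sw <- count_words(st[st >= 0 & st < duration])
  rw <- count_words(rt[rt >= 0 & rt < duration])
  flags <- character(0)
  mi_raw <- .plugin_mi(sw, rw)
  bias <- mean(vapply(seq_len(settings$n_shuffle), function(i)
    .plugin_mi(sw, sample(rw)), numeric(1)))
  mi_c <- max(0, mi_raw - bias)
  if (mi_raw - bias < 0) flags <- "negative_clipped"
  res <- list(mi_raw = mi_raw, bias = bias, mi_corrected = mi_c,
              te = mi_c / (settings$window_ms / 1000),
              n_windows = length(sw),
              n_words_s = length(unique(sw)),
              n_words_r = length(unique(rw)),
              flags = flags, settings = settings)
  class(res) <- "transfer_result"
  res
}

#' Normalized cross-correlation of two spike trains
#'
#' Cross-correlation of the binarized (1 ms) sequences, normalized so that
#' both autocorrelations at zero lag are identically 1 (i.e. the Pearson
#' correlation at each lag).
#'
#' @param s_train,r_train [spike_train()]s of equal duration.
#' @param max_lag_ms maximal lag (ms).
#' @param bin_ms bin size (ms).
#' @return data frame with `lag_ms` and `cc`.
#' @export
cross_correlation <- function(s_train, r_train, max_lag_ms = 30,
                              bin_ms = 1) {
  dur <- s_train$duration
  sb <- binarize(s_train, bin_ms, dur)
  rb <- binarize(r_train, bin_ms, dur)
  if (var(sb) == 0 || var(rb) == 0)
    return(structure(data.frame(lag_ms = numeric(0), cc = numeric(0)),
                     flag = "zero_variance"))
  lags <- seq(-max_lag_ms, max_lag_ms, by = bin_ms)
  n <- length(sb)
  cc <- vapply(lags, function(l) {
    k <- round(l / bin_ms)
    if (k >= 0) cor(sb[seq_len(n - k)], rb[seq_len(n - k) + k])
    else cor(sb[seq_len(n + k) - k], rb[seq_len(n + k)])
  }, numeric(1))
  data.frame(lag_ms = lags, cc = cc)
}

#' Membrane SD after spike removal
#'
#' Standard deviation of a membrane trace after excising a window around
#' each spike peak (default -1 to +4 ms), the convention used to compare
#' model and pseudo-recorded voltage fluctuation amplitudes.
#'
#' @param v membrane samples (mV).
#' @param times sample times (ms).
#' @param spikes spike times (ms).
#' @param window excision window around each spike (ms, `c(before, after)`).
#' @return SD in mV.
#' @export
membrane_sd <- function(v, times, spikes, window = c(1, 4)) {
  if (length(spikes) == 0) return(sd(v))
  spikes <- sort(spikes)
  # a sample at t is excised iff some spike lies in [t - after, t + before]
  lo <- findInterval(times - window[2], spikes, left.open = TRUE)
  hi <- findInterval(times + window[1], spikes)
  sd(v[hi <= lo])
}
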