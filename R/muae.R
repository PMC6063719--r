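# Multiunit-activity-envelope (MUAe) pipeline: synthetic electrode fixtures,
# Butterworth high-pass + rectify + 4-ms binning, and the pre/post-stimulus
# trial-averaged connectivity workflow.

#' Synthetic multielectrode fixture (SYNTHETIC stand-in for array recordings)
#'
#' Generates trials of broadband noise carriers whose amplitude envelopes
#' follow a ground-truth MVAR(1) process at 4-ms resolution: each channel's
#' (log-)envelope obeys `u_t = A_env u_{t-1} + noise` with self-coefficients
#' `self_coef` and the requested directed couplings, the envelope is the
#' positive multiplicative process
#' `e_c(t) = gain(t) * baseline_c * exp(u_c(t) - sd(u)^2/2)`, and `gain(t)`
#' jumps from 1 to `onset_gain` at stimulus onset (emulating the
#' poststimulus activity peak).  The modulation depth (about 50% relative
#' s.d. at the default `env_noise_sd`) keeps the envelope's exponentially
#' decaying autocovariance visible above the rectification noise of the
#' carrier, as in strongly modulated population activity.  The raw
#' 1-kHz signal of a channel is white noise scaled by its envelope.  The
#' generated object is fully synthetic — it emulates the *shape* of
#' multielectrode recordings (trials x channels x samples, stimulus onset,
#' envelope couplings), not any real data set.
#'
#' @param C number of channels (>= 2).
#' @param n_trials number of trials (>= 1).
#' @param coupling optional data frame with columns `from`, `to`, `gain`:
#'   directed envelope couplings `from -> to` at one 4-ms lag.
#' @param onset_gain multiplicative envelope increase after onset.
#' @param seed integer seed; the fixture is deterministic given the seed.
#' @param coupling_window `"post"` (couplings active only after onset) or
#'   `"all"`.
#' @param self_coef envelope AR self-coefficient (exponential autocovariance
#'   decay with this ratio per 4-ms lag).
#' @param env_noise_sd innovation sd of the envelope process.
#' @param duration_ms trial length; `onset_ms` stimulus onset time.
#' @param fs sampling frequency in Hz.
#' @return an object of class `muae_raw`: list with `signals`
#'   (`n_trials x C x L` array), `onset_index` (sample index of onset),
#'   `fs`, `coupling`, `onset_gain`, and `envelope_truth` (the ground-truth
#'   `C x bins x trials` envelope).
#' @export
synth_electrode_fixture <- function(C = 25, n_trials = 200, coupling = NULL,
                                    onset_gain = 2, seed = NULL,
                                    coupling_window = c("post", "all"),
                                    self_coef = 0.7, env_noise_sd = 0.33,
                                    duration_ms = 1200, onset_ms = 500,
                                    fs = 1000) {
  coupling_window <- match.arg(coupling_window)
  if (C < 2) stop("need at least 2 channels", call. = FALSE)
  if (n_trials < 1) stop("need at least 1 trial", call. = FALSE)
  bin_ms <- 4L
  n_bins <- duration_ms %/% bin_ms
  onset_bin <- onset_ms %/% bin_ms + 1L
  spb <- as.integer(fs * bin_ms / 1000)        # samples per bin
  L <- n_bins * spb
  a_env <- diag(self_coef, C)
  if (!is.null(coupling)) {
    stopifnot(all(c("from", "to", "gain") %in% names(coupling)))
    for (k in seq_len(nrow(coupling)))
      a_env[coupling$to[k], coupling$from[k]] <-
        a_env[coupling$to[k], coupling$from[k]] + coupling$gain[k]
  }
  if (max(Mod(eigen(a_env, only.values = TRUE)$values)) >= 1)
    stop("unstable ground-truth envelope dynamics", call. = FALSE)
  a_base <- diag(self_coef, C)                 # couplings gated off pre-onset

  with_seed(seed, {
    baseline <- runif(C, 0.8, 1.2)
    sd_u <- env_noise_sd / sqrt(1 - self_coef^2)
    env_truth <- array(0, dim = c(C, n_bins, n_trials))
    signals <- array(0, dim = c(n_trials, C, L))
    for (r in seq_len(n_trials)) {
      u <- matrix(0, C, n_bins)
      up <- rnorm(C, sd = sd_u)
      for (t in seq_len(n_bins)) {
        a_t <- if (coupling_window == "all" || t > onset_bin) a_env else a_base
        up <- drop(a_t %*% up) + rnorm(C, sd = env_noise_sd)
        u[, t] <- up
      }
      gain <- ifelse(seq_len(n_bins) > onset_bin, onset_gain, 1)
      e <- baseline * exp(u - sd_u^2 / 2) * rep(gain, each = C)
      env_truth[, , r] <- e
      carrier <- matrix(rnorm(C * L), C, L)
      signals[r, , ] <- carrier * e[, rep(seq_len(n_bins), each = spb)]
    }
    structure(list(signals = signals, onset_index = onset_ms * fs / 1000 + 1,
                   fs = fs, coupling = coupling, onset_gain = onset_gain,
                   envelope_truth = env_truth, baseline = baseline,
                   self_coef = self_coef, bin_ms = bin_ms),
              class = "muae_raw")
  })
}

#' @export
print.muae_raw <- function(x, ...) {
  d <- dim(x$signals)
  cat(sprintf("Synthetic electrode fixture: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  onset at sample %d, onset gain %.2f, %d planted couplings\n",
              as.integer(x$onset_index), x$onset_gain,
              if (is.null(x$coupling)) 0L else nrow(x$coupling)))
  invisible(x)
}

# Integer-factor decimation with a Butterworth anti-alias low-pass.
decimate_signal <- function(v, factor) {
  if (factor == 1L) return(v)
  bf <- signal::butter(8, 0.8 / factor, type = "low")
  f <- signal::filtfilt(bf, v)
  f[seq(1L, length(v), by = factor)]
}

#' Extract the multiunit activity envelope from raw electrode-like signals
#'
#' Per trial and channel: (optionally) decimate to 1000 Hz, high-pass with a
#' third-order Butterworth filter at 400 Hz (0.8 of the Nyquist frequency,
#' zero-phase via forward-backward filtering), rectify, and average in
#' contiguous 4-ms bins.  The 1000-ms window around stimulus onset is
#' retained — 400 ms before to 600 ms after, i.e. exactly 250 bins with the
#' onset at bin 101.
#'
#' @param raw a [`muae_raw`][synth_electrode_fixture] object (or a list with
#'   `signals`, `onset_index`, `fs`).
#' @param high_pass high-pass corner as a fraction of Nyquist (default 0.8,
#'   i.e. 400 Hz at 1 kHz).
#' @param filter_order Butterworth order.
#' @param bin_ms envelope bin width in ms.
#' @param window_ms c(before, after) onset, in ms; defaults to the 1000-ms
#'   window `c(400, 600)`.
#' @return an object of class `muae_panel`: list with `envelope`
#'   (`n_trials x C x n_bins`), `onset_bin`, `pre_bins`, `post_bins` (50
#'   bins = 200 ms each), `bin_ms`, `fs`.
#' @export
preprocess_muae <- function(raw, high_pass = 0.8, filter_order = 3,
                            bin_ms = 4, window_ms = c(400, 600)) {
  signals <- raw$signals
  fs <- raw$fs
  onset <- raw$onset_index
  if (fs < 1000) stop("need fs >= 1000 Hz", call. = FALSE)
  dec <- fs / 1000
  if (dec != round(dec))
    stop("downsampling to 1000 Hz requires an integer factor", call. = FALSE)
  dec <- as.integer(dec)
  d <- dim(signals)
  n_trials <- d[1]; C <- d[2]
  bf <- signal::butter(filter_order, high_pass, type = "high")
  spb <- as.integer(bin_ms)                    # samples per bin at 1 kHz
  pre_ms <- window_ms[1]; post_ms <- window_ms[2]
  n_bins <- as.integer((pre_ms + post_ms) / bin_ms)

  L1 <- ceiling(d[3] / dec)
  onset1 <- as.integer(ceiling(onset / dec))
  first <- onset1 - pre_ms
  last <- onset1 + post_ms - 1L
  if (first < 1L || last > L1)
    stop("onset window exceeds the recording", call. = FALSE)

  env <- array(0, dim = c(n_trials, C, n_bins))
  for (r in seq_len(n_trials)) {
    for (c_ in seq_len(C)) {
      v <- signals[r, c_, ]
      v <- decimate_signal(v, dec)
      rect <- abs(signal::filtfilt(bf, v))
      w <- rect[first:last]
      env[r, c_, ] <- colMeans(matrix(w, nrow = spb))
    }
  }
  structure(list(envelope = env, onset_bin = pre_ms / bin_ms + 1L,
                 pre_bins = (pre_ms / bin_ms - 49L):(pre_ms / bin_ms),
                 post_bins = (pre_ms / bin_ms + 1L):(pre_ms / bin_ms + 50L),
                 n_bins = n_bins, bin_ms = bin_ms, fs = 1000),
            class = "muae_panel")
}

#' @export
print.muae_panel <- function(x, ...) {
  d <- dim(x$envelope)
  cat(sprintf("MUAe panel: %d trials x %d channels x %d bins (%d ms each), onset at bin %d\n",
              d[1], d[2], d[3], x$bin_ms, x$onset_bin))
  invisible(x)
}

#' Outlier screen for channels with excessive activity
#'
#' Flags channels whose mean envelope exceeds `k` times the median of the
#' per-channel means (default `k = 5`).
#'
#' @param panel a [`muae_panel`][preprocess_muae].
#' @param k multiplier of the median.
#' @return integer indices of the channels to keep.
#' @export
muae_screen_channels <- function(panel, k = 5) {
  m <- apply(panel$envelope, 2L, mean)
  which(m <= k * stats::median(m))
}

#' Per-channel mean MUAe in a window
#'
#' @param panel a `muae_panel`.
#' @param window `"pre"` or `"post"` (the 50-bin / 200-ms windows around
#'   onset).
#' @return numeric vector of per-channel means over trials and bins.
#' @export
muae_activity <- function(panel, window = c("post", "pre")) {
  window <- match.arg(window)
  bins <- if (window == "pre") panel$pre_bins else panel$post_bins
  apply(panel$envelope[, , bins, drop = FALSE], 2L, mean)
}

muae_window_trials <- function(panel, window, channels = NULL) {
  bins <- if (window == "pre") panel$pre_bins else panel$post_bins
  n_trials <- dim(panel$envelope)[1L]
  if (is.null(channels)) channels <- seq_len(dim(panel$envelope)[2L])
  lapply(seq_len(n_trials), function(r) {
    m <- panel$envelope[r, channels, bins, drop = FALSE]
    matrix(m, nrow = length(channels))
  })
}

#' Trial-averaged MVAR connectivity of an MUAe window with surrogate test
#'
#' Restricts the panel to the pre- or post-stimulus window, centers each
#' trial individually, averages the lagged covariances over trials, fits the
#' MVAR(1) coefficients, builds a per-trial-shuffled surrogate ensemble and
#' applies the local (or global) two-tailed test.
#'
#' @param panel a [`muae_panel`][preprocess_muae].
#' @param window `"pre"` or `"post"`.
#' @param surrogate `"RP"` or `"CS"`.
#' @param S number of surrogates.
#' @param alpha nominal false-alarm rate (split over the two tails).
#' @param tails 2 (default) or 1.
#' @param test `"local"` or `"global"`.
#' @param channels optional channel subset (e.g. from
#'   [muae_screen_channels()]).
#' @param seed master seed.
#' @return list with `report` (an `mvar_detect`), `fit` (the [mvar] fit) and
#'   `window`.
#' @export
trial_connectivity <- function(panel, window = c("post", "pre"),
                               surrogate = c("RP", "CS"), S = 400,
                               alpha = 0.01, tails = 2,
                               test = c("local", "global"),
                               channels = NULL, seed = NULL) {
  window <- match.arg(window)
  surrogate <- match.arg(surrogate)
  test <- match.arg(test)
  trials <- muae_window_trials(panel, window, channels)
  if (ncol(trials[[1L]]) < 3L) stop("window too short", call. = FALSE)
  if (length(trials) < 2L) stop("need at least 2 trials", call. = FALSE)
  fit <- mvar(trials, keep_data = FALSE)
  null <- build_null(trials, S = S, method = surrogate, estimator = "order1",
                     seed = seed)
  fun <- if (test == "local") local_test else global_test
  rep_ <- fun(fit, null, alpha = alpha, tails = tails)
  list(report = rep_, fit = fit, window = window)
}

#' Change in significant connection strength versus activity change
#'
#' For each channel, sums the absolute weights of its significant incoming
#' and outgoing connections in the pre- and post-stimulus reports, and
#' relates the post-minus-pre change to the change in mean MUAe.
#'
#' @param pre,post results of [trial_connectivity()] for the two windows
#'   (lists with `report` and `fit`).
#' @param activity_pre,activity_post per-channel mean MUAe (e.g. from
#'   [muae_activity()]).
#' @return data frame with one row per channel: `d_incoming`, `d_outgoing`,
#'   `d_activity`; attribute `"correlations"` holds Pearson tests of each
#'   weight-change column against the activity change (NA when a column is
#'   constant, e.g. no significant connections at all).
#' @export
node_strength_change <- function(pre, post, activity_pre, activity_post) {
  strength <- function(res) {
    a <- detect_input_matrix(res$fit)
    dec <- res$report$decisions
    dec[is.na(dec)] <- FALSE
    diag(dec) <- FALSE
    w <- abs(a) * dec
    list(incoming = rowSums(w), outgoing = colSums(w))
  }
  s_pre <- strength(pre); s_post <- strength(post)
  if (length(activity_pre) != length(s_pre$incoming))
    stop("channel sets do not match", call. = FALSE)
  out <- data.frame(channel = seq_along(activity_pre),
                    d_incoming = s_post$incoming - s_pre$incoming,
                    d_outgoing = s_post$outgoing - s_pre$outgoing,
                    d_activity = activity_post - activity_pre)
  ct <- function(v) {
    if (sd(v) == 0 || sd(out$d_activity) == 0)
      return(list(estimate = NA_real_, p_value = NA_real_))
    h <- cor.test(v, out$d_activity)
    list(estimate = unname(h$estimate), p_value = h$p.value)
  }
  attr(out, "correlations") <- list(incoming = ct(out$d_incoming),
                                    outgoing = ct(out$d_outgoing))
  out
}
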