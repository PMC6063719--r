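# MUAe preprocessing and the pre/post-stimulus connectivity workflow on
# synthetic electrode fixtures.

test_that("the preprocessing chain yields exactly 250 bins and matches an
           independent signal-chain computation", {
  raw <- synth_electrode_fixture(C = 3, n_trials = 2, seed = 1)
  pan <- preprocess_muae(raw)
  expect_equal(dim(pan$envelope), c(2L, 3L, 250L))
  expect_equal(pan$onset_bin, 101L)
  expect_length(pan$pre_bins, 50L)
  expect_length(pan$post_bins, 50L)
  expect_true(all(pan$envelope >= 0))

  # zero input -> zero envelope
  raw0 <- raw
  raw0$signals[] <- 0
  expect_true(all(preprocess_muae(raw0)$envelope == 0))

  # 450-Hz unit sine: compare against a direct filter + rectify + bin chain
  L <- dim(raw$signals)[3]
  sine <- sin(2 * pi * 450 * seq_len(L) / 1000)
  raw1 <- raw
  for (r in 1:2) for (c_ in 1:3) raw1$signals[r, c_, ] <- sine
  pan1 <- preprocess_muae(raw1)
  bf <- signal::butter(3, 0.8, type = "high")
  rect <- abs(signal::filtfilt(bf, sine))
  onset <- as.integer(raw$onset_index)
  w <- rect[(onset - 400):(onset + 599)]
  oracle <- colMeans(matrix(w, nrow = 4))
  expect_equal(as.numeric(pan1$envelope[1, 2, ]), oracle, tolerance = 1e-10)
})

test_that("fixtures are deterministic and the onset gain scales the
           poststimulus envelope", {
  a <- synth_electrode_fixture(C = 4, n_trials = 3, seed = 7)
  b <- synth_electrode_fixture(C = 4, n_trials = 3, seed = 7)
  expect_identical(a$signals, b$signals)

  # onset_gain = 1, no coupling: pre and post envelope means agree
  raw1 <- synth_electrode_fixture(C = 5, n_trials = 120, onset_gain = 1,
                                  seed = 8)
  pan1 <- preprocess_muae(raw1)
  m_pre <- muae_activity(pan1, "pre"); m_post <- muae_activity(pan1, "post")
  expect_lt(max(abs(m_post / m_pre - 1)), 0.1)

  # onset_gain = 2 doubles the poststimulus envelope
  raw2 <- synth_electrode_fixture(C = 5, n_trials = 120, onset_gain = 2,
                                  seed = 9)
  pan2 <- preprocess_muae(raw2)
  ratio <- muae_activity(pan2, "post") / muae_activity(pan2, "pre")
  expect_lt(max(abs(ratio - 2)), 0.2)
})

test_that("the channel screen drops channels above k times the median
           activity", {
  raw <- synth_electrode_fixture(C = 6, n_trials = 10, seed = 11)
  raw$signals[, 3, ] <- raw$signals[, 3, ] * 10
  pan <- preprocess_muae(raw)
  expect_identical(muae_screen_channels(pan, k = 5), c(1:2, 4:6))
})

test_that("fixture MUAe autocovariances decay exponentially over lags 1-3", {
  raw <- synth_electrode_fixture(C = 5, n_trials = 80, seed = 13)
  pan <- preprocess_muae(raw)
  cs <- lagged_covariance(mvarnet:::muae_window_trials(pan, "post"),
                          tau_max = 3)
  ac <- sapply(1:3, function(tau) mean(diag(cs$q[[tau + 1]])))
  expect_true(all(ac > 0))
  fitlm <- lm(log(ac) ~ seq_along(ac))
  expect_gt(summary(fitlm)$r.squared, 0.9)
  expect_lt(coef(fitlm)[2], 0)
})

test_that("planted couplings are recovered post- but not prestimulus, and a
           coupling-free fixture stays at the nominal rate", {
  cp <- data.frame(from = 1:5, to = 2:6, gain = 0.35)
  truth <- matrix(FALSE, 8, 8); truth[cbind(cp$to, cp$from)] <- TRUE
  hits_post <- 0; hits_pre <- 0; extras <- 0
  for (s in 1:2) {
    raw <- synth_electrode_fixture(C = 8, n_trials = 150, coupling = cp,
                                   onset_gain = 1.5, seed = 100 + s)
    pan <- preprocess_muae(raw)
    post <- trial_connectivity(pan, "post", "RP", S = 199, alpha = 0.01,
                               seed = 200 + s)
    pre <- trial_connectivity(pan, "pre", "RP", S = 199, alpha = 0.01,
                              seed = 300 + s)
    hits_post <- hits_post + sum(post$report$decisions[truth])
    hits_pre <- hits_pre + sum(pre$report$decisions[truth])
    extras <- extras +
      sum(post$report$decisions[!truth & row(truth) != col(truth)],
          na.rm = TRUE)
  }
  expect_gte(hits_post, 6)       # majority of 10 planted edge-instances
  expect_lte(hits_pre, 2)
  # detected interactions are predominantly the planted unidirectional ones
  expect_lt(extras, hits_post)

  # no couplings: detected fraction close to the 1% level
  raw0 <- synth_electrode_fixture(C = 8, n_trials = 120, seed = 17)
  pan0 <- preprocess_muae(raw0)
  r0 <- trial_connectivity(pan0, "post", "RP", S = 199, alpha = 0.01,
                           seed = 18)
  expect_lte(sum(off_diag(r0$report$decisions)), 4)   # 56 pairs at ~1%
})

test_that("RP and CS detections of planted couplings agree (Jaccard > 0.5)", {
  cp <- data.frame(from = c(1, 3, 5), to = c(2, 4, 6), gain = 0.4)
  jac <- sapply(1:2, function(s) {
    raw <- synth_electrode_fixture(C = 7, n_trials = 120, coupling = cp,
                                   seed = 400 + s)
    pan <- preprocess_muae(raw)
    rp <- trial_connectivity(pan, "post", "RP", S = 199, alpha = 0.01,
                             seed = 500 + s)
    cs <- trial_connectivity(pan, "post", "CS", S = 199, alpha = 0.01,
                             seed = 600 + s)
    off <- row(matrix(0, 7, 7)) != col(matrix(0, 7, 7))
    a <- which(rp$report$decisions & off); b <- which(cs$report$decisions & off)
    length(intersect(a, b)) / max(length(union(a, b)), 1)
  })
  expect_gt(mean(jac), 0.5)
})

test_that("node strength changes match hand computation on a 3-channel toy", {
  mk <- function(a, dec) {
    fit <- structure(list(coefficients = a, order = 1L, N = 3), class = "mvar")
    list(fit = fit, report = structure(list(decisions = dec),
                                       class = "mvar_detect"))
  }
  a_pre <- matrix(0, 3, 3); a_post <- matrix(0, 3, 3)
  a_post[2, 1] <- 0.5; a_post[3, 1] <- -0.2; a_post[1, 3] <- 0.1
  dec_pre <- matrix(FALSE, 3, 3)
  dec_post <- matrix(c(FALSE, TRUE, TRUE,
                       FALSE, FALSE, FALSE,
                       TRUE, FALSE, FALSE), 3, 3)
  out <- node_strength_change(mk(a_pre, dec_pre), mk(a_post, dec_post),
                              activity_pre = c(1, 1, 1),
                              activity_post = c(2, 1.5, 1))
  # incoming sums: ch1 gets |0.1| (edge 3->1), ch2 |0.5|, ch3 |-0.2|
  expect_equal(out$d_incoming, c(0.1, 0.5, 0.2))
  # outgoing sums: ch1 emits |0.5| + |-0.2|, ch3 emits |0.1|
  expect_equal(out$d_outgoing, c(0.7, 0, 0.1))
  expect_equal(out$d_activity, c(1, 0.5, 0))
  expect_true(is.list(attr(out, "correlations")))

  # no detections anywhere: zero deltas, undefined correlation
  out0 <- node_strength_change(mk(a_pre, dec_pre), mk(a_pre, dec_pre),
                               c(1, 1, 1), c(1, 1, 1))
  expect_true(all(out0$d_incoming == 0) && all(out0$d_outgoing == 0))
  expect_true(is.na(attr(out0, "correlations")$incoming$estimate))
})

test_that("an onset that multiplies input gains raises incoming strength with
           activity", {
  # plant couplings into channels 1-3 only, active post-onset
  cp <- data.frame(from = c(4, 5, 6, 5, 6, 4), to = c(1, 2, 3, 1, 2, 3),
                   gain = 0.3)
  raw <- synth_electrode_fixture(C = 6, n_trials = 150, coupling = cp,
                                 onset_gain = 1.5, seed = 21)
  pan <- preprocess_muae(raw)
  post <- trial_connectivity(pan, "post", "RP", S = 199, alpha = 0.01,
                             seed = 22)
  pre <- trial_connectivity(pan, "pre", "RP", S = 199, alpha = 0.01,
                            seed = 23)
  out <- node_strength_change(pre, post, muae_activity(pan, "pre"),
                              muae_activity(pan, "post"))
  # receivers of planted couplings gain more incoming strength than senders
  expect_gt(mean(out$d_incoming[1:3]), mean(out$d_incoming[4:6]))
})
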