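test_that("band-pass behaviour matches the filter's analytic response", {
  fs <- 200
  t <- seq(0, 120, by = 1 / fs)
  mid <- seq(30 * fs, 90 * fs)  # away from filtfilt edge transients

  # 10 Hz tone through the 0.0159-5 Hz band: strongly attenuated
  tone10 <- ds_recording(sin(2 * pi * 10 * t), fs)
  out10 <- bandpass_filter(tone10, 0.0159, 5)
  expect_lt(max(abs(out10$samples[mid])), 0.1)

  # constant series: DC removed (interior of a long record; the 0.0159 Hz
  # edge has a ~10 s time constant, so judge after ~100 s of settling)
  tl <- seq(0, 300, by = 1 / fs)
  const <- ds_recording(rep(3.7, length(tl)), fs)
  interior <- seq(100 * fs, 200 * fs)
  expect_lt(max(abs(bandpass_filter(const, 0.0159, 5)$samples[interior])),
            0.01 * 3.7)

  # 1 Hz tone through 0.05-1 Hz: measured gain equals |H|^2 evaluated from
  # the transfer function (the filter is applied forward and backward)
  tone1 <- ds_recording(sin(2 * pi * 1 * t), fs)
  out1 <- bandpass_filter(tone1, 0.05, 1)
  bf <- signal::butter(2, c(0.05, 1) / (fs / 2), type = "pass")
  z <- exp(-1i * 2 * pi * 1 / fs)
  H <- sum(bf$b * z^(0:(length(bf$b) - 1))) /
    sum(bf$a * z^(0:(length(bf$a) - 1)))
  expect_equal(max(abs(out1$samples[mid])), Mod(H)^2, tolerance = 0.05)

  expect_error(bandpass_filter(tone1, 0.05, 600), "Nyquist")
})

test_that("epoching uses inclusive endpoints, onset alignment, and exclusion flags", {
  fs <- 1000
  x <- seq(0, 10, by = 1 / fs)        # sample value equals its time
  rec <- ds_recording(x, fs)
  ep <- epoch_and_downsample(rec, events = 3, window = c(-2, 6),
                             target_hz = 100)
  expect_equal(ncol(ep$data), 801L)
  expect_equal(ep$data[1, ep$onset_index], 3, tolerance = 1e-9)
  expect_equal(ep$data[1, 1], 1, tolerance = 1e-9)
  expect_equal(ep$data[1, 801], 9, tolerance = 1e-9)

  # naive stride-decimation oracle
  oracle <- x[seq((3 - 2) * fs + 1, (3 + 6) * fs + 1, by = 10)]
  expect_equal(unname(ep$data[1, ]), oracle)

  short <- ds_recording(x[1:(5 * fs)], fs)
  ep2 <- epoch_and_downsample(short, events = 1, window = c(-2, 6),
                              target_hz = 100)
  expect_true(ep2$excluded[1])
  expect_match(ep2$reason[1], "outside")
})

test_that("jack-knife exclusion matches a brute-force leave-one-out oracle", {
  set.seed(12)
  make_ep <- function(data) {
    structure(list(data = data, fs = 10, window = c(-2, 6), onset_index = 21L,
                   event_type = "cue", excluded = rep(FALSE, nrow(data)),
                   reason = rep("", nrow(data))),
              class = "epoch_set")
  }

  flat <- make_ep(matrix(1.5, nrow = 6, ncol = 81))
  expect_false(any(jackknife_outlier_mask(flat)$excluded))

  spiked <- matrix(rnorm(6 * 81), nrow = 6)
  spiked[4, 40] <- 100 * diff(range(spiked[-4, ]))
  expect_true(jackknife_outlier_mask(make_ep(spiked))$excluded[4])
  expect_false(any(jackknife_outlier_mask(make_ep(spiked))$excluded[-4]))

  for (rep in 1:10) {
    d <- matrix(rnorm(8 * 30), nrow = 8)
    if (rep %% 2 == 0) d[sample(8, 1), sample(30, 2)] <- rnorm(2, 0, 40)
    got <- jackknife_outlier_mask(make_ep(d), threshold = 4.89)$excluded
    want <- vapply(1:8, function(tr) {
      rest <- as.numeric(d[-tr, ])
      any(abs(d[tr, ] - mean(rest)) > 4.89 * sd(rest))
    }, logical(1))
    expect_identical(got, want)
  }

  two <- make_ep(matrix(rnorm(2 * 30), nrow = 2))
  expect_warning(res <- jackknife_outlier_mask(two), "fewer than 3")
  expect_false(any(res$excluded))
})

test_that("peak-to-peak scoring reproduces the hand-enumerated epoch", {
  vals <- c(0.10, 0.08, 0.20, 0.30, 0.50, 0.45, 0.40)  # t = 0..6 s at 1 Hz
  s <- peak_to_peak_score(vals, fs = 1, onset_index = 1L)
  expect_equal(s$raw, 0.42, tolerance = 1e-12)
  expect_equal(s$transformed, log(1.42), tolerance = 1e-12)

  expect_equal(peak_to_peak_score(rep(0.3, 7), 1, 1L)$raw, 0)
  expect_equal(peak_to_peak_score(rep(0.3, 7), 1, 1L)$transformed, 0)

  below <- c(0.100, 0.100, 0.100, 0.100, 0.119, 0.100, 0.100)
  expect_equal(peak_to_peak_score(below, 1, 1L)$raw, 0)
})

test_that("peak-to-peak is translation-invariant and never negative", {
  set.seed(3)
  for (i in 1:25) {
    v <- cumsum(rnorm(81, 0, 0.05))
    s <- peak_to_peak_score(v, fs = 10, onset_index = 21L)
    expect_gte(s$raw, 0)
    shifted <- peak_to_peak_score(v + runif(1, -5, 5), fs = 10,
                                  onset_index = 21L)
    expect_equal(shifted$raw, s$raw, tolerance = 1e-9)
  }
})

test_that("the pain-expression composite follows the AU formula", {
  zero <- setNames(rep(0, 8), dyadsynch:::PAIN_AUS)
  expect_equal(fau_pain_expression(zero), 0)

  ex <- c(AU04_r = 1.2, AU06_r = 0.5, AU07_r = 2.0, AU09_r = 0.0,
          AU10_r = 1.0, AU12_r = 0.3, AU25_r = 0.0, AU26_r = 0.7)
  expect_identical(fau_pain_expression(ex), 5.2)

  set.seed(8)
  for (i in 1:20) {
    au <- setNames(runif(8, 0, 5), dyadsynch:::PAIN_AUS)
    oracle <- au[["AU04_r"]] + max(au[["AU06_r"]], au[["AU07_r"]]) +
      max(au[["AU09_r"]], au[["AU10_r"]]) + au[["AU12_r"]] +
      max(au[["AU25_r"]], au[["AU26_r"]])
    expect_equal(fau_pain_expression(au), oracle, tolerance = 1e-12)
    # monotone non-decreasing in every AU input
    j <- sample(8, 1)
    bumped <- au; bumped[j] <- bumped[j] + runif(1, 0, 2)
    expect_gte(fau_pain_expression(bumped), fau_pain_expression(au))
  }

  expect_error(fau_pain_expression(ex[-3]), class = "ds_format_error")
})

test_that("epoch maxima of the expression series handle windows and missingness", {
  fs <- 10
  mono <- seq(0, 5, length.out = 51)        # 5 s, increasing
  m <- epoch_max_fau(mono, fs, onset_index = 11L)     # window (1, 4] s
  expect_equal(m$raw, mono[41])

  gap <- mono; gap[12:41] <- NA
  expect_true(epoch_max_fau(gap, fs, onset_index = 11L)$excluded)

  set.seed(5)
  for (i in 1:15) {
    v <- runif(51); v[sample(51, 5)] <- NA
    got <- epoch_max_fau(v, fs, onset_index = 11L)
    win <- v[12:41]
    if (all(is.na(win))) expect_true(got$excluded)
    else expect_equal(got$raw, max(win, na.rm = TRUE))
  }
})

test_that("trial-pair averaging follows the surviving-value contract", {
  sc <- data.table::data.table(
    cue = rep("Tx", 6), trial = 1:6,
    value = c(1, 3, 5, 7, 9, 11), excluded = rep(FALSE, 6))
  out <- average_trial_pairs(sc)
  expect_equal(out$value, c(2, 6, 10))

  sc2 <- data.table::copy(sc)
  sc2$excluded[3] <- TRUE          # pair (excluded, 4) -> 4 (value 7 here)
  out2 <- average_trial_pairs(sc2)
  expect_equal(out2$value[2], 7)

  sc3 <- data.table::copy(sc)
  sc3$excluded[5:6] <- TRUE
  expect_true(is.na(average_trial_pairs(sc3)$value[3]))

  set.seed(2)
  both <- data.table::data.table(
    cue = rep(c("Tx", "NT"), each = 6), trial = rep(1:6, 2),
    value = rnorm(12), excluded = rep(FALSE, 12))
  out4 <- average_trial_pairs(both)
  oracle <- tapply(both$value,
                   list(both$cue, ceiling(both$trial / 2)), mean)
  for (cu in c("Tx", "NT"))
    expect_equal(out4[out4$cue == cu, ]$value, unname(oracle[cu, ]))
})

test_that("session scoring excludes at most the expected order of magnitude", {
  cfg <- fast_config()
  sessions <- suppressWarnings(simulate_cohort(cfg, n_sessions = 3, seed = 77))
  sc <- data.table::rbindlist(lapply(sessions, score_session))
  # exclusions counted per participant over EDA outcomes, as in the source
  # analysis: on average fewer than one excluded trial per participant
  eda <- sc[grepl("^EDA", sc$outcome), ]
  per_part <- tapply(eda$excluded, eda$participant, sum)
  expect_lt(mean(per_part), 2)   # two epoch types; < 1 per epoch type
  expect_true(all(c("EDA_cue", "EDA_heat", "FAU_cue", "FAU_heat") %in%
                    sc$outcome))
})
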