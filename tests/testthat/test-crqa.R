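test_that("time-delay embedding follows the definition", {
  e <- embed_series(c(1, 2, 3, 4), delay = 1, dim = 2)
  expect_equal(e, rbind(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(embed_series(1:5, delay = 2, dim = 1), matrix(1:5, ncol = 1))
  set.seed(6)
  for (i in 1:15) {
    n <- sample(20:60, 1); d <- sample(1:4, 1); tau <- sample(1:5, 1)
    if (n - (d - 1) * tau < 1) next
    e <- embed_series(rnorm(n), tau, d)
    expect_equal(nrow(e), n - (d - 1) * tau)
    expect_equal(ncol(e), d)
  }
  expect_error(embed_series(1:4, delay = 3, dim = 3), "too short")
})

test_that("cross-recurrence matrices match hand enumeration", {
  x <- c(0, 1, 0, 1)
  R <- cross_recurrence_matrix(x, x, radius = 0.5)
  expect_equal(sum(R), 8L)
  m <- crqa_measures(R)
  expect_equal(m$RR, 0.5)
  expect_equal(m$DET, 1.0)

  same <- rnorm(6)
  expect_true(all(diag(cross_recurrence_matrix(same, same, 0)) == 1L))

  distinct <- c(1, 2, 4, 8)
  expect_equal(sum(cross_recurrence_matrix(distinct, distinct + 0.5, 0)), 0L)

  allones <- matrix(1L, 5, 5)
  m1 <- crqa_measures(allones)
  expect_equal(m1$RR, 1)
  expect_equal(m1$LAM, 1)
  # the two corner cells sit on length-1 diagonals, below the minimum line
  # length of 2, so DET is (25 - 2) / 25 rather than exactly 1
  expect_equal(m1$DET, 23 / 25)

  iso <- diag(5)[, 5:1] * 0L
  iso[cbind(c(1, 3, 5), c(2, 5, 1))] <- 1L
  m2 <- crqa_measures(iso)
  expect_equal(m2$DET, 0)
  expect_equal(m2$LAM, 0)

  zero <- matrix(0L, 4, 4)
  m3 <- crqa_measures(zero)
  expect_true(is.na(m3$DET) && is.na(m3$LAM))
})

test_that("matrix, streamed and naive implementations agree exactly", {
  set.seed(13)
  for (i in 1:30) {
    n <- sample(15:40, 1)
    tau <- sample(1:3, 1); d <- sample(1:3, 1)
    if (n - (d - 1) * tau < 5) next
    x <- rnorm(n); y <- rnorm(n)
    r <- runif(1, 0.2, 1.5)
    oracle <- naive_crqa(x, y, tau, d, r)
    xe <- embed_series(x, tau, d); ye <- embed_series(y, tau, d)
    mat <- crqa_measures(cross_recurrence_matrix(xe, ye, r))
    streamed <- crqa_run(x, y, list(delay = tau, dim = d, radius = r,
                                    min_diag = 2, min_vert = 2))
    expect_identical(unname(cross_recurrence_matrix(xe, ye, r)),
                     unname(oracle$R))
    expect_equal(mat$RR, oracle$RR, tolerance = 1e-14)
    expect_equal(mat$DET, oracle$DET, tolerance = 1e-14)
    expect_equal(mat$LAM, oracle$LAM, tolerance = 1e-14)
    expect_equal(streamed$RR, oracle$RR, tolerance = 1e-14)
    expect_equal(streamed$DET, oracle$DET, tolerance = 1e-14)
    expect_equal(streamed$LAM, oracle$LAM, tolerance = 1e-14)
  }
})

test_that("swapping the series transposes the plot and preserves RR and DET", {
  set.seed(14)
  x <- rnorm(30); y <- rnorm(30)
  xe <- embed_series(x, 1, 2); ye <- embed_series(y, 1, 2)
  Rxy <- cross_recurrence_matrix(xe, ye, 0.8)
  Ryx <- cross_recurrence_matrix(ye, xe, 0.8)
  expect_identical(Ryx, t(Rxy))
  mxy <- crqa_measures(Rxy); myx <- crqa_measures(Ryx)
  expect_equal(mxy$RR, myx$RR)
  expect_equal(mxy$DET, myx$DET)  # diagonals map onto diagonals
})

test_that("DET and LAM are non-increasing in the minimum line length", {
  set.seed(15)
  x <- as.numeric(arima.sim(list(ar = 0.9), 60))
  y <- as.numeric(arima.sim(list(ar = 0.9), 60))
  R <- cross_recurrence_matrix(embed_series(x, 1, 2), embed_series(y, 1, 2), 1)
  prev_det <- 1; prev_lam <- 1
  for (l in 2:6) {
    m <- crqa_measures(R, min_diag = l, min_vert = l)
    expect_lte(m$DET, prev_det + 1e-12)
    expect_lte(m$LAM, prev_lam + 1e-12)
    prev_det <- m$DET; prev_lam <- m$LAM
  }
})

test_that("series preparation z-scores and suppresses out-of-band power", {
  fs <- 64
  t <- seq(0, 120, by = 1 / fs)
  raw <- ds_recording(2 + sin(2 * pi * 0.3 * t) + sin(2 * pi * 2 * t), fs)
  z <- prepare_series(raw, target_hz = 8)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)

  # periodogram oracle: power at 2 Hz (in band before filtering, above the
  # 1 Hz cutoff) must be tiny relative to 0.3 Hz after preparation
  spec <- Mod(fft(z))^2
  freqs <- (seq_along(z) - 1) * 8 / length(z)
  p_at <- function(f0) max(spec[abs(freqs - f0) < 0.05])
  expect_lt(p_at(2) / p_at(0.3), 0.01)

  expect_error(prepare_series(ds_recording(rep(1, 100), fs)), "constant")
})

test_that("recurrence rate is monotone in the radius and the optimizer hits the band", {
  set.seed(16)
  n <- 400
  x <- as.numeric(arima.sim(list(ar = 0.95), n))
  y <- 0.7 * x + 0.3 * as.numeric(arima.sim(list(ar = 0.95), n))
  xe <- embed_series(x, 2, 3); ye <- embed_series(y, 2, 3)
  radii <- seq(0.1, 3, by = 0.29)
  rrs <- vapply(radii, function(r)
    sum(cross_recurrence_matrix(xe, ye, r)) / (nrow(xe) * nrow(ye)),
    numeric(1))
  expect_true(all(diff(rrs) >= 0))

  pars <- optimize_parameters(scale(x)[, 1], scale(y)[, 1])
  expect_gte(pars$achieved_rr, 0.02)
  expect_lte(pars$achieved_rr, 0.04)
  expect_lte(pars$delay, 40L)
  expect_lte(pars$dim, 10L)
})

test_that("the exponential transform standardises and de-skews synchrony metrics", {
  set.seed(17)
  # left-skewed sample of proportions, like DET across dyads
  det <- 1 - rbeta(60, 1.5, 8)
  z <- transform_synchrony_metrics(det)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
  expect_identical(order(z), order(det))        # exp is increasing
  expect_lt(abs(sample_skewness(exp(det))), abs(sample_skewness(det)))
  expect_error(transform_synchrony_metrics(c(0.5, 0.6)), "at least 3")
})

test_that("dyadic determinism increases with the generator's coupling", {
  cfg <- fast_config(generate_au = FALSE)
  kappas <- c(0.1, 0.5, 0.9)
  set.seed(18)
  mean_det <- vapply(kappas, function(kap) {
    dets <- vapply(1:50, function(i) {
      blk <- simulate_dyad_block(cfg, "G2", new_participant_state("responder"),
                                 new_participant_state("responder"),
                                 kappa = kap)
      x <- prepare_series(blk$eda$dem); y <- prepare_series(blk$eda$obs)
      pars <- optimize_parameters(x, y)
      crqa_run(x, y, pars)$DET
    }, numeric(1))
    mean(dets)
  }, numeric(1))
  expect_true(all(diff(mean_det) > 0))
})
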