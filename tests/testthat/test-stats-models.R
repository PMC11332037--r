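make_rm_data <- function(n_per_group = 8, cue_effect = 0, seed = 1,
                         noise = 5) {
  set.seed(seed)
  n <- 2 * n_per_group
  ids <- sprintf("P%02d", seq_len(n))
  dat <- data.table::CJ(participant = ids, cue = c("Tx", "NT"), cue_trial = 1:3)
  grp <- setNames(rep(c("G2", "G3"), each = n_per_group), ids)
  cov <- setNames(rbinom(n, 1, 0.5), ids)
  subj <- setNames(rnorm(n, 0, 6), ids)
  dat[, generation := grp[participant]]
  dat[, gender_match := cov[participant]]
  dat[, pain_dem := 30 + subj[participant] +
        (cue_effect / 2) * ifelse(cue == "Tx", 1, -1) + rnorm(.N, 0, noise)]
  dat
}

test_that("a null within-subject contrast yields a zero cue F statistic", {
  dat <- make_rm_data(seed = 2)
  # make Tx cells identical to NT cells per subject and trial
  wide <- data.table::dcast(dat, participant + generation + gender_match +
                              cue_trial ~ cue, value.var = "pain_dem")
  wide[, Tx := NT]
  long <- data.table::melt(wide, measure.vars = c("Tx", "NT"),
                           variable.name = "cue", value.name = "pain_dem")
  fit <- fit_mixed_ancova(long, outcome = "pain_dem")
  f_cue <- fit$effects[fit$effects$effect == "cue", ]
  expect_lt(f_cue$F, 1e-18)
  expect_equal(unname(fit$cue_diff["estimate"]), 0, tolerance = 1e-12)
})

test_that("ANCOVA F statistics match an independent contrast-projection oracle", {
  dat <- make_rm_data(n_per_group = 7, cue_effect = 6, seed = 3)
  fit <- fit_mixed_ancova(dat, outcome = "pain_dem")

  # oracle: per-subject summaries regressed on the between design by
  # explicit normal equations; within effects via contrast scores
  wide <- data.table::dcast(dat, participant + generation + gender_match ~
                              cue + cue_trial, value.var = "pain_dem")
  g <- ifelse(wide$generation == "G2", 1, -1)
  cv <- wide$gender_match - mean(wide$gender_match)
  X <- cbind(1, g, cv)
  n <- nrow(X)
  hat_t2 <- function(yv, col) {
    b <- solve(t(X) %*% X, t(X) %*% yv)
    res <- yv - X %*% b
    s2 <- sum(res^2) / (n - 3)
    vb <- s2 * solve(t(X) %*% X)
    (b[col]^2) / vb[col, col]
  }
  cue_cols <- grepl("^Tx_", names(wide))
  nt_cols <- grepl("^NT_", names(wide))
  cue_score <- rowMeans(wide[, names(wide)[cue_cols], with = FALSE]) -
    rowMeans(wide[, names(wide)[nt_cols], with = FALSE])
  subj_mean <- rowMeans(wide[, names(wide)[cue_cols | nt_cols], with = FALSE])

  eff <- function(e) fit$effects[fit$effects$effect == e, ]
  expect_equal(eff("cue")$F, hat_t2(cue_score, 1), tolerance = 1e-8)
  expect_equal(eff("generation:cue")$F, hat_t2(cue_score, 2), tolerance = 1e-8)
  expect_equal(eff("gender_match:cue")$F, hat_t2(cue_score, 3),
               tolerance = 1e-8)
  expect_equal(eff("generation")$F, hat_t2(subj_mean, 2), tolerance = 1e-8)
  expect_equal(eff("gender_match")$F, hat_t2(subj_mean, 3), tolerance = 1e-8)
  expect_equal(eff("cue")$df_den, n - 3)

  # adjusted cue means equal the intercept of the normal-equations fit on
  # the per-cue subject means
  for (cu in c("Tx", "NT")) {
    ym <- rowMeans(wide[, names(wide)[grepl(paste0("^", cu, "_"),
                                            names(wide))], with = FALSE])
    b <- solve(t(X) %*% X, t(X) %*% ym)
    expect_equal(fit$emmeans$emmean[fit$emmeans$cue == cu], b[1],
                 tolerance = 1e-8)
  }
})

test_that("the ANCOVA recovers an injected cue effect with a covering interval", {
  dat <- make_rm_data(n_per_group = 18, cue_effect = 7, seed = 4, noise = 6)
  fit <- fit_mixed_ancova(dat, outcome = "pain_dem")
  expect_lt(fit$cue_diff["lo"], 7)
  expect_gt(fit$cue_diff["hi"], 7)
  expect_equal(unname(fit$cue_diff["estimate"]), 7, tolerance = 1.5)
  pes <- fit$effects[fit$effects$effect == "cue", ]
  expect_true(pes$pes >= pes$pes_lo && pes$pes <= pes$pes_hi)
  expect_true(all(fit$effects$pes >= 0 & fit$effects$pes <= 1))
})

test_that("partial eta-squared intervals invert the noncentral F distribution", {
  ci <- partial_eta_squared(18.14, 1, 62)
  # published values to printed precision: 0.23, 95% CI [0.07, 0.39]
  expect_equal(round(unname(ci["pes"]), 2), 0.23)
  expect_equal(round(unname(ci["lo"]), 2), 0.07)
  expect_equal(round(unname(ci["hi"]), 2), 0.39)
  none <- partial_eta_squared(0.2, 1, 60)
  expect_equal(unname(none["lo"]), 0)
})

test_that("hierarchical regression matches the normal-equations oracle", {
  set.seed(31)
  n <- 40
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), g = rep(c(1, -1), n / 2))
  d$y <- 2 + 1.5 * d$x1 - 0.8 * d$x2 + rnorm(n, 0, 1)

  perfect <- data.frame(x = rnorm(20))
  perfect$y <- 3 * perfect$x
  # noiseless by construction; lm warns about the perfect fit
  hp <- suppressWarnings(fit_hierarchical_regression(perfect, "y", list("x")))
  expect_equal(hp$stages[[1]]$coefficients$B[2], 3, tolerance = 1e-10)
  expect_equal(hp$stages[[1]]$r2_adj, 1, tolerance = 1e-10)

  hr <- fit_hierarchical_regression(d, "y", list("x1", "x2", c("g", "x1:g")))
  X <- cbind(1, d$x1, d$x2)
  b_oracle <- solve(t(X) %*% X) %*% t(X) %*% d$y
  expect_equal(hr$stages[[2]]$coefficients$B, as.numeric(b_oracle),
               tolerance = 1e-10)
  # standardised coefficients: B * sd(x) / sd(y)
  expect_equal(hr$stages[[2]]$coefficients$beta[2],
               b_oracle[2] * sd(d$x1) / sd(d$y), tolerance = 1e-10)
  # nested stages cannot lose unadjusted R^2
  r2 <- vapply(hr$stages, function(s) summary(s$model)$r.squared, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))

  # identical sample across stages when late-stage predictors have NAs
  d2 <- d; d2$x2[1:4] <- NA
  hr2 <- fit_hierarchical_regression(d2, "y", list("x1", "x2"))
  expect_equal(hr2$n, n - 4)
  expect_equal(stats::nobs(hr2$stages[[1]]$model), n - 4)

  d3 <- d; d3$x3 <- d3$x1 * 2
  expect_error(fit_hierarchical_regression(d3, "y", list(c("x1", "x3"))),
               "collinear")
})

test_that("simple slopes reconstruct the published conditional effects", {
  # noiseless construction with the printed stage-3 coefficients
  set.seed(32)
  n <- 60
  d <- data.frame(synchrony = rnorm(n), generation_ec = rep(c(1, -1), n / 2))
  d$nocebo <- 5 + 3.62 * d$synchrony + 2.18 * d$generation_ec -
    4.65 * d$synchrony * d$generation_ec
  fit <- lm(nocebo ~ synchrony * generation_ec, data = d)
  sl <- suppressWarnings(
    simple_slopes(fit, "synchrony", "generation_ec", levels = c(1, -1)))
  expect_equal(sl$slope[1], -1.03, tolerance = 1e-9)   # G2 (printed as -1.0)
  expect_equal(sl$slope[2], 8.27, tolerance = 1e-9)    # G3

  # zero interaction: identical slopes everywhere
  d$flat <- 2 + 1.2 * d$synchrony + 0.5 * d$generation_ec
  fit0 <- lm(flat ~ synchrony * generation_ec, data = d)
  sl0 <- suppressWarnings(
    simple_slopes(fit0, "synchrony", "generation_ec", levels = c(1, 0, -1)))
  expect_equal(diff(range(sl0$slope)), 0, tolerance = 1e-9)

  expect_error(simple_slopes(fit, "synchrony", "absent"), "interaction")
})

test_that("delta-method slope intervals agree with a bootstrap oracle", {
  set.seed(33)
  n <- 50
  d <- data.frame(s = rnorm(n), g = rep(c(1, -1), n / 2))
  d$y <- 1 + 2 * d$s + 0.5 * d$g - 1.5 * d$s * d$g + rnorm(n, 0, 2)
  fit <- lm(y ~ s * g, data = d)
  sl <- simple_slopes(fit, "s", "g", levels = 1)

  boots <- replicate(10000, {
    idx <- sample.int(n, replace = TRUE)
    db <- d[idx, ]
    Xb <- cbind(1, db$s, db$g, db$s * db$g)
    cb <- .lm.fit(Xb, db$y)$coefficients
    cb[2] + cb[4]
  })
  boot_ci <- quantile(boots, c(0.025, 0.975))
  half_delta <- (sl$hi - sl$lo) / 2
  half_boot <- diff(boot_ci) / 2
  expect_equal(unname(half_delta), unname(half_boot), tolerance = 0.25)
  expect_equal(sl$slope, mean(boots), tolerance = 0.2)
})
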