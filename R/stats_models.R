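# Inference stages: mixed ANCOVA with Type-III tests and adjusted marginal
# means, partial eta-squared with noncentral-F intervals, hierarchical
# moderation regressions, and simple slopes.

#' Partial eta-squared with a noncentral-F confidence interval
#'
#' The interval inverts the noncentral-F distribution at the two-sided
#' `conf` level (95% by default) and maps the noncentrality bounds to
#' eta_p^2 = ncp / (ncp + df1 + df2 + 1).
#'
#' @param f observed F statistic.
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @param conf confidence level.
#' @return Named vector: pes, lo, hi.
#' @export
partial_eta_squared <- function(f, df1, df2, conf = 0.95) {
  if (!is.finite(f)) return(c(pes = NA_real_, lo = NA_real_, hi = NA_real_))
  pes <- f * df1 / (f * df1 + df2)
  alpha <- (1 - conf) / 2
  ncp_root <- function(target) {
    g <- function(ncp) pf(f, df1, df2, ncp) - target
    if (g(0) < 0) return(0)
    hi <- max(f * df1 * 5, 10)
    while (g(hi) > 0 && hi < 1e7) hi <- hi * 4
    stats::uniroot(g, c(0, hi))$root
  }
  lo_ncp <- ncp_root(1 - alpha)
  hi_ncp <- ncp_root(alpha)
  to_pes <- function(ncp) ncp / (ncp + df1 + df2 + 1)
  c(pes = pes, lo = to_pes(lo_ncp), hi = to_pes(hi_ncp))
}

#' Mixed ANCOVA on per-trial phasic scores
#'
#' Between-subjects factor (generation), fully crossed within-subjects factors
#' (cue, trial), and a subject-constant covariate. Fitted as a multivariate
#' linear model on the subject-by-cell matrix with Type-III univariate
#' repeated-measures tests assuming sphericity (integer degrees of freedom, no
#' correction), which is the split-plot decomposition the printed statistics
#' use. Generation is effect-coded (first level +1, second -1) and the
#' covariate centred, so adjusted marginal means are the unweighted average
#' over groups at the covariate mean. Subjects missing any cell are dropped.
#'
#' @param data tidy data with one row per subject, cue and trial level.
#' @param outcome name of the response column.
#' @param subject,between,within,covariate column names; `within` is
#'   c(cue_column, trial_column).
#' @return Object of class `ancova_fit`: `effects` table (F, df, p, partial
#'   eta-squared with CI), `emmeans` for the cue factor (adjusted mean, SE,
#'   CI), the cue-difference estimate with CI, and sample size `n`.
#' @export
fit_mixed_ancova <- function(data, outcome, subject = "participant",
                             between = "generation",
                             within = c("cue", "cue_trial"),
                             covariate = "gender_match") {
  dt <- data.table::as.data.table(data)
  need <- c(subject, between, within, covariate, outcome)
  stopifnot(all(need %in% names(dt)))
  if (any(dt[, stats::var(get(covariate)), by = subject]$V1 > 0, na.rm = TRUE))
    stop("covariate must be constant within subject", call. = FALSE)
  cue_col <- within[1L]; trial_col <- within[2L]
  wide <- data.table::dcast(
    dt, stats::as.formula(sprintf("%s + %s + %s ~ %s + %s",
                                  subject, between, covariate,
                                  cue_col, trial_col)),
    value.var = outcome)
  cell_cols <- setdiff(names(wide), c(subject, between, covariate))
  wide <- wide[stats::complete.cases(wide)]
  n <- nrow(wide)
  if (n < 4L) stop("too few complete subjects for the ANCOVA", call. = FALSE)

  cue_lv <- sort(unique(as.character(dt[[cue_col]])), decreasing = TRUE) # Tx, NT
  trial_lv <- sort(unique(dt[[trial_col]]))
  # cell columns are "<cue>_<trial>"; order them cue-major to match idata
  ord <- as.vector(outer(trial_lv, cue_lv,
                         function(tr, cu) paste(cu, tr, sep = "_")))
  stopifnot(all(ord %in% cell_cols))
  Y <- as.matrix(wide[, ord, with = FALSE])

  gen <- factor(wide[[between]])
  if (nlevels(gen) != 2L)
    stop("between factor must have exactly 2 levels", call. = FALSE)
  gen_ec <- ifelse(gen == levels(gen)[1L], 1, -1)
  cov_c <- as.numeric(wide[[covariate]])
  cov_c <- cov_c - mean(cov_c)

  mod <- lm(Y ~ gen_ec + cov_c)
  idata <- data.frame(
    cue = factor(rep(cue_lv, each = length(trial_lv)), levels = cue_lv),
    trial = factor(rep(trial_lv, times = length(cue_lv))))
  av <- car::Anova(mod, idata = idata, idesign = ~ cue * trial, type = 3)
  # sphericity-corrected tests are not used; suppress the HF-epsilon note
  um <- suppressWarnings(summary(av, multivariate = FALSE))$univariate.tests

  eff_names <- setdiff(rownames(um), "(Intercept)")
  effects <- data.table::rbindlist(lapply(eff_names, function(e) {
    ss <- um[e, "Sum Sq"]; ess <- um[e, "Error SS"]
    f <- um[e, "F value"]; d1 <- um[e, "num Df"]; d2 <- um[e, "den Df"]
    p <- um[e, "Pr(>F)"]
    if (!is.finite(f) && ss < 1e-10) {
      # a contrast that is identically zero in every subject (no effect and
      # no error variance by construction)
      f <- 0; p <- 1
    }
    ci <- partial_eta_squared(f, d1, d2)
    data.table::data.table(
      effect = e, F = f, df_num = d1, df_den = d2, p = p,
      pes = if (ss + ess > 0) ss / (ss + ess) else 0,
      pes_lo = ci[["lo"]], pes_hi = ci[["hi"]])
  }))
  effects[, effect := gsub("gen_ec", between, effect)]
  effects[, effect := gsub("cov_c", covariate, effect)]

  # covariate-adjusted marginal means for the cue factor
  B <- coef(mod)                        # 3 x 12
  XtXi <- solve(crossprod(cbind(1, gen_ec, cov_c)))
  S <- crossprod(resid(mod)) / (n - 3L)
  x0 <- c(1, 0, 0)
  vx <- drop(t(x0) %*% XtXi %*% x0)
  df_err <- n - 3L
  emm <- data.table::rbindlist(lapply(cue_lv, function(cu) {
    w <- as.numeric(startsWith(ord, paste0(cu, "_"))) / length(trial_lv)
    est <- drop(t(x0) %*% B %*% w)
    se <- sqrt(vx * drop(t(w) %*% S %*% w))
    data.table::data.table(cue = cu, emmean = est, se = se,
                           lo = est - qt(0.975, df_err) * se,
                           hi = est + qt(0.975, df_err) * se)
  }))
  wd <- (as.numeric(startsWith(ord, paste0(cue_lv[1L], "_"))) -
           as.numeric(startsWith(ord, paste0(cue_lv[2L], "_")))) /
    length(trial_lv)
  dest <- drop(t(x0) %*% B %*% wd)
  dse <- sqrt(vx * drop(t(wd) %*% S %*% wd))
  cue_diff <- c(estimate = dest, se = dse,
                lo = dest - qt(0.975, df_err) * dse,
                hi = dest + qt(0.975, df_err) * dse)

  structure(list(effects = effects[], emmeans = emm[], cue_diff = cue_diff,
                 n = n, model = mod, idata = idata),
            class = "ancova_fit")
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat(sprintf("Mixed ANCOVA (n = %d complete subjects)\n", x$n))
  print(as.data.frame(x$effects), digits = 4)
  cat("\nAdjusted marginal means (cue):\n")
  print(as.data.frame(x$emmeans), digits = 4)
  invisible(x)
}

#' Hierarchical (staged) moderation regression
#'
#' Ordinary least squares refit at each stage on the identical sample
#' (complete cases on all final-stage variables). Standardised coefficients
#' use beta = B * sd(x) / sd(y) with product terms standardised as columns.
#'
#' @param data data frame.
#' @param outcome response column name.
#' @param stages list of character vectors of predictor terms; each stage adds
#'   its terms to the previous stage's.
#' @return Object of class `hier_reg`: per-stage tables (B, SE, beta, t, p,
#'   CI), stage fit statistics (adjusted R-squared, F, p), models and data.
#' @export
fit_hierarchical_regression <- function(data, outcome, stages) {
  dt <- as.data.frame(data)
  all_terms <- unique(unlist(stages))
  vars <- unique(c(outcome, all.vars(stats::reformulate(all_terms))))
  dt <- dt[complete.cases(dt[, vars, drop = FALSE]), , drop = FALSE]
  sdy <- sd(dt[[outcome]])
  cum_terms <- character()
  out <- vector("list", length(stages))
  for (s in seq_along(stages)) {
    cum_terms <- unique(c(cum_terms, stages[[s]]))
    f <- stats::reformulate(cum_terms, response = outcome)
    fit <- lm(f, data = dt)
    if (any(is.na(coef(fit)))) {
      k <- kappa(stats::model.matrix(fit), exact = TRUE)
      stop(sprintf("collinear predictors at stage %d (condition number %.3g)",
                   s, k), call. = FALSE)
    }
    mm <- stats::model.matrix(fit)
    cf <- summary(fit)$coefficients
    ci <- stats::confint(fit)
    beta <- vapply(rownames(cf), function(term) {
      if (term == "(Intercept)") return(NA_real_)
      cf[term, "Estimate"] * sd(mm[, term]) / sdy
    }, numeric(1L))
    sm <- summary(fit)
    fstat <- sm$fstatistic
    out[[s]] <- list(
      stage = s,
      coefficients = data.table::data.table(
        term = rownames(cf), B = cf[, "Estimate"], SE = cf[, "Std. Error"],
        beta = beta, t = cf[, "t value"], p = cf[, "Pr(>|t|)"],
        lo = ci[, 1L], hi = ci[, 2L]),
      r2_adj = sm$adj.r.squared,
      F = unname(fstat[1L]),
      df = unname(fstat[2:3]),
      p = pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE),
      model = fit)
  }
  structure(list(stages = out, data = dt, outcome = outcome, n = nrow(dt)),
            class = "hier_reg")
}

#' @export
print.hier_reg <- function(x, ...) {
  cat(sprintf("Hierarchical regression on '%s' (n = %d)\n", x$outcome, x$n))
  for (st in x$stages) {
    cat(sprintf("\nStage %d: R2_adj = %.3f, F(%d, %d) = %.2f, p = %.4g\n",
                st$stage, st$r2_adj, st$df[1L], st$df[2L], st$F, st$p))
    print(as.data.frame(st$coefficients), digits = 3)
  }
  invisible(x)
}

#' Conditional (simple) slopes of a moderated regression
#'
#' The slope of the focal predictor at chosen moderator levels,
#' `B_focal + level * B_interaction`, with delta-method standard errors from
#' the model covariance. For a continuous moderator the default levels are
#' the mean and +/- 1 SD; for an effect-coded group the group codes.
#'
#' @param model fitted `lm` containing the focal-by-moderator interaction.
#' @param focal,moderator predictor names.
#' @param levels moderator levels at which to evaluate (default as above).
#' @return data.table: level, slope, se, lo, hi.
#' @export
simple_slopes <- function(model, focal, moderator, levels = NULL) {
  cf <- coef(model)
  int_name <- intersect(c(paste(focal, moderator, sep = ":"),
                          paste(moderator, focal, sep = ":")), names(cf))
  if (!focal %in% names(cf) || !length(int_name))
    stop("model must contain the focal predictor and its interaction with the moderator",
         call. = FALSE)
  int_name <- int_name[1L]
  if (is.null(levels)) {
    mv <- stats::model.frame(model)[[moderator]]
    u <- sort(unique(mv))
    levels <- if (length(u) <= 3L) u else mean(mv) + c(-1, 0, 1) * sd(mv)
  }
  V <- vcov(model)
  df <- stats::df.residual(model)
  data.table::rbindlist(lapply(levels, function(l) {
    slope <- cf[[focal]] + l * cf[[int_name]]
    se <- sqrt(V[focal, focal] + l^2 * V[int_name, int_name] +
                 2 * l * V[focal, int_name])
    data.table::data.table(level = l, slope = slope, se = se,
                           lo = slope - qt(0.975, df) * se,
                           hi = slope + qt(0.975, df) * se)
  }))
}
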