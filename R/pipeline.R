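# Orchestration: simulate -> score -> synchrony -> responders -> analyze as a
# reproducible, resumable pipeline over a cohort of chain sessions.

#' Simulate a cohort of chain sessions
#'
#' Session seeds are derived from the root seed so each session is
#' independently reproducible.
#'
#' @param config a [generator_config()].
#' @param n_sessions number of sessions (defaults to the config value).
#' @param seed root seed (defaults to the config value).
#' @return List of `dyad_session` objects.
#' @export
simulate_cohort <- function(config, n_sessions = config$n_sessions,
                            seed = config$seed) {
  set.seed(seed)
  session_seeds <- sample.int(.Machine$integer.max, n_sessions)
  lapply(seq_len(n_sessions), function(i) {
    s <- simulate_chain_session(config, session_id = sprintf("S%03d", i),
                                seed = session_seeds[i])
    if (config$missing_expectancy_rate > 0)
      s <- inject_missingness(s, config$missing_expectancy_rate)
    s
  })
}

#' Tidy trial-log table for a cohort
#'
#' One row per session, block and trial with demonstrator/observer identity,
#' generation, gender match, per-cue trial rank and all ratings.
#'
#' @param sessions list of `dyad_session` objects.
#' @return data.table.
#' @export
ratings_table <- function(sessions) {
  rows <- lapply(sessions, function(s) {
    man <- s$manifest
    gen_of <- setNames(as.character(man$participants$generation),
                       man$participants$participant_id)
    data.table::rbindlist(lapply(seq_along(s$blocks), function(k) {
      binfo <- man$blocks[man$blocks$block == k, ]
      tr <- data.table::copy(s$blocks[[k]]$trials)
      tr[, `:=`(session = man$session_id, block = k,
                demonstrator = as.character(binfo$demonstrator_id),
                observer = as.character(binfo$observer_id),
                dem_generation = gen_of[[as.character(binfo$demonstrator_id)]],
                gender_match = as.integer(binfo$gender_match))]
      tr[, cue_trial := seq_len(.N), by = cue]
      tr
    }))
  })
  data.table::rbindlist(rows)
}

#' Nocebo magnitude per demonstrator block
#'
#' The classifier statistic: mean Tx pain minus mean NT pain for each
#' demonstrator.
#'
#' @param ratings output of [ratings_table()].
#' @return data.table: session, block, participant, generation, nocebo.
#' @export
nocebo_magnitudes <- function(ratings) {
  dt <- data.table::as.data.table(ratings)
  dt[, .(nocebo = mean(pain_dem[cue == "Tx"]) - mean(pain_dem[cue == "NT"]),
         generation = dem_generation[1L]),
     by = .(session, block, participant = demonstrator)]
}

#' Psychological synchrony table for a cohort
#'
#' Per analysed dyad (blocks 1 and 2): the demonstrator/observer expectancy
#' correlation, the usable-trial count, and the correlation standardised
#' across dyads.
#'
#' @param sessions list of `dyad_session` objects.
#' @param blocks blocks carrying analysed dyads.
#' @return data.table: session, block, demonstrator, observer, r,
#'   n_trials_used, z.
#' @export
psych_synchrony_table <- function(sessions, blocks = 1:2) {
  rows <- lapply(sessions, function(s) {
    man <- s$manifest
    data.table::rbindlist(lapply(blocks, function(k) {
      binfo <- man$blocks[man$blocks$block == k, ]
      tr <- s$blocks[[k]]$trials
      ps <- psychological_synchrony(tr$expectancy_dem, tr$expectancy_obs)
      data.table::data.table(
        session = man$session_id, block = k,
        demonstrator = as.character(binfo$demonstrator_id),
        observer = as.character(binfo$observer_id),
        r = ps$r, n_trials_used = ps$n_trials_used)
    }))
  })
  out <- data.table::rbindlist(rows)
  ok <- !is.na(out$r)
  out[, z := NA_real_]
  if (sum(ok) >= 3L) out[ok, z := (r - mean(r)) / sd(r)]
  out[]
}

#' Responder classification table for a cohort
#'
#' Classifies every demonstrator from their 12 pain ratings.
#'
#' @param ratings output of [ratings_table()].
#' @param n_perm,exact,seed passed to [classify_responder()].
#' @return data.table with observed_diff, p_upper, p_lower and class.
#' @export
responder_table <- function(ratings, n_perm = 10000L, exact = FALSE,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dt <- data.table::as.data.table(ratings)
  dt[, {
    r <- classify_responder(pain_dem, cue, n_perm = n_perm, exact = exact)
    .(generation = dem_generation[1L], observed_diff = r$observed_diff,
      p_upper = r$p_upper, p_lower = r$p_lower, class = r$class)
  }, by = .(session, block, participant = demonstrator)]
}

#' Assemble the dyad-level analysis table
#'
#' Joins each analysed dyad's synchrony metrics to the nocebo magnitude its
#' observer later produced as demonstrator, with generation effect-coded
#' (G2 = +1, G3 = -1). Dyads without a psychological-synchrony score are
#' dropped from all synchrony metrics so the samples are identical.
#'
#' @param psync output of [psych_synchrony_table()].
#' @param nocebo output of [nocebo_magnitudes()].
#' @param physio optional output of [physiological_synchrony()] rows for the
#'   same dyads (adds exp-transformed, standardised DET/LAM).
#' @return data.table, one row per usable dyad.
#' @export
dyad_analysis_table <- function(psync, nocebo, physio = NULL) {
  ps <- data.table::as.data.table(psync)
  nb <- data.table::as.data.table(nocebo)
  dt <- merge(ps, nb[, .(session, participant, nocebo, generation)],
              by.x = c("session", "observer"), by.y = c("session", "participant"))
  if (!is.null(physio)) {
    ph <- data.table::as.data.table(physio)
    dt <- merge(dt, ph[, .(session, block, RR, DET, LAM)],
                by = c("session", "block"), all.x = TRUE)
  }
  dt <- dt[!is.na(r)]
  if (nrow(dt) >= 3L) {
    dt[, psync_z := (r - mean(r)) / sd(r)]
    if (!is.null(physio)) {
      dt[, det_z := transform_synchrony_metrics(DET)]
      dt[, lam_z := transform_synchrony_metrics(LAM)]
    }
  }
  dt[, generation_ec := ifelse(generation == "G2", 1, -1)]
  dt[]
}

#' Staged synchrony regression on nocebo magnitude
#'
#' Stage 1: synchrony z-score; stage 2 adds effect-coded generation; stage 3
#' the synchrony-by-generation interaction, whose conditional effects are
#' summarised by simple slopes at the group codes.
#'
#' @param dyads output of [dyad_analysis_table()].
#' @param metric synchrony column ("psync_z", "det_z" or "lam_z").
#' @return List: `fit` (a `hier_reg`) and `slopes`.
#' @export
synchrony_regression <- function(dyads, metric = "psync_z") {
  dat <- as.data.frame(dyads)
  dat$synchrony <- dat[[metric]]
  fit <- fit_hierarchical_regression(
    dat, outcome = "nocebo",
    stages = list("synchrony", "generation_ec",
                  "synchrony:generation_ec"))
  slopes <- simple_slopes(fit$stages[[3L]]$model, "synchrony",
                          "generation_ec", levels = c(1, -1))
  slopes[, generation := c("G2", "G3")]
  list(fit = fit, slopes = slopes[])
}

stage_table <- function(hr, model_label) {
  data.table::rbindlist(lapply(hr$stages, function(st) {
    tab <- data.table::copy(st$coefficients)
    tab[, `:=`(model = model_label, stage = st$stage, r2_adj = st$r2_adj,
               stage_F = st$F, stage_p = st$p)]
    tab
  }))
}

#' Run the full pipeline
#'
#' simulate (or load) -> score -> physiological + psychological synchrony ->
#' responder classification -> ANCOVA and synchrony regressions. Every stage
#' writes a CSV under `out_dir` and is skipped when its table already exists
#' (delete a table to regenerate it identically from upstream tables). A
#' `manifest.json` records the configuration hash and seeds.
#'
#' @param out_dir results directory.
#' @param config a [generator_config()].
#' @param n_sessions,seed cohort size and root seed.
#' @param n_perm,exact responder-classifier settings.
#' @param sessions optionally, a pre-built list of sessions (skips simulation).
#' @param force recompute stages even when their tables exist.
#' @return Invisibly, a list with every stage table.
#' @export
run_pipeline <- function(out_dir, config = generator_config(),
                         n_sessions = config$n_sessions, seed = config$seed,
                         n_perm = 10000L, exact = FALSE, sessions = NULL,
                         force = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)
  stage <- function(file, compute) {
    if (!force && file.exists(path(file)))
      return(data.table::fread(path(file)))
    tab <- compute()
    write_num_csv(tab, path(file))
    tab
  }
  if (is.null(sessions)) sessions <- simulate_cohort(config, n_sessions, seed)
  ratings <- stage("ratings.csv", function() ratings_table(sessions))
  scores <- if (isTRUE(config$generate_signals))
    stage("scores.csv", function()
      data.table::rbindlist(lapply(sessions, score_session)))
  physio <- if (isTRUE(config$generate_signals))
    stage("synchrony.csv", function()
      data.table::rbindlist(lapply(sessions, physiological_synchrony)))
  psync <- stage("psync.csv", function() psych_synchrony_table(sessions))
  nocebo <- stage("nocebo.csv", function() nocebo_magnitudes(ratings))
  responders <- stage("responders.csv", function()
    responder_table(ratings, n_perm = n_perm, exact = exact,
                    seed = seed + 1L))

  # primary mixed ANCOVA: G2/G3 demonstrator pain, cue x per-cue trial, with
  # the observation dyad's gender match as covariate
  primary <- ratings[ratings$dem_generation %in% c("G2", "G3"), ]
  obs_match <- ratings[, c("session", "observer", "gender_match")]
  obs_match <- unique(obs_match)
  names(obs_match)[3L] <- "obs_gender_match"
  primary <- merge(primary, obs_match,
                   by.x = c("session", "demonstrator"),
                   by.y = c("session", "observer"))
  ancova <- fit_mixed_ancova(
    primary, outcome = "pain_dem", subject = "demonstrator",
    between = "dem_generation", within = c("cue", "cue_trial"),
    covariate = "obs_gender_match")
  if (force || !file.exists(path("ancova_pain.csv")))
    write_num_csv(ancova$effects, path("ancova_pain.csv"))
  if (force || !file.exists(path("ancova_emmeans.csv")))
    write_num_csv(ancova$emmeans, path("ancova_emmeans.csv"))

  dyads <- dyad_analysis_table(psync, nocebo, physio)
  regs <- list(psync = synchrony_regression(dyads, "psync_z"))
  if (!is.null(physio)) {
    regs$det <- synchrony_regression(dyads, "det_z")
    regs$lam <- synchrony_regression(dyads, "lam_z")
  }
  reg_tab <- data.table::rbindlist(
    lapply(names(regs), function(nm) stage_table(regs[[nm]]$fit, nm)))
  if (force || !file.exists(path("regressions.csv")))
    write_num_csv(reg_tab, path("regressions.csv"))
  slope_tab <- data.table::rbindlist(
    lapply(names(regs), function(nm) {
      s <- data.table::copy(regs[[nm]]$slopes); s[, model := nm]; s
    }))
  if (force || !file.exists(path("simple_slopes.csv")))
    write_num_csv(slope_tab, path("simple_slopes.csv"))

  cfg_for_hash <- unclass(config)
  manifest <- list(
    package_version = as.character(utils::packageVersion("dyadsynch")),
    r_version = R.version.string,
    seed = seed, n_sessions = n_sessions, n_perm = n_perm, exact = exact,
    config_hash = rlang::hash(cfg_for_hash),
    n_excluded_scores = if (!is.null(scores)) sum(scores$excluded) else NA)
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(ratings = ratings, scores = scores, physio = physio,
                 psync = psync, nocebo = nocebo, responders = responders,
                 ancova = ancova, dyads = dyads, regressions = regs,
                 manifest = manifest))
}

#' Ratings-only recovery dataset
#'
#' Fast path for validation experiments: simulates chains without continuous
#' signals and returns, per analysed dyad, the generator coupling, the
#' measured psychological synchrony, and the nocebo magnitude the observer
#' later produced as demonstrator.
#'
#' @param config a [generator_config()] (signals are disabled internally).
#' @param n_sessions sessions to simulate (2 analysed dyads each).
#' @param seed root seed.
#' @return data.table: session, block, generation, kappa, psync_r, nocebo.
#' @export
recovery_dataset <- function(config, n_sessions, seed) {
  config$generate_signals <- FALSE
  sessions <- simulate_cohort(config, n_sessions, seed)
  ratings <- ratings_table(sessions)
  nocebo <- nocebo_magnitudes(ratings)
  psync <- psych_synchrony_table(sessions)
  kappa <- data.table::rbindlist(lapply(sessions, function(s)
    data.table::data.table(session = s$manifest$session_id, block = 1:3,
                           kappa = vapply(s$truth, `[[`, 0, "kappa"))))
  dt <- merge(psync, kappa, by = c("session", "block"))
  dt <- merge(dt, nocebo[, .(session, participant, nocebo, generation)],
              by.x = c("session", "observer"),
              by.y = c("session", "participant"))
  dt[!is.na(r), .(session, block, generation, kappa, psync_r = r, nocebo)]
}
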