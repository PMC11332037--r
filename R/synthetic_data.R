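# Synthetic transmission-chain generator.
#
# Emulates the study design: 3-generation chains (G1 conditioned with 45/54 degC
# contingent on cue; G2/G3 always 45 degC), 12-trial blocks (6 Tx / 6 NT) under
# the pseudorandomisation rules, coupled dyadic arousal with tunable synchrony,
# SCR-shaped phasic responses, social expectancy learning, and
# responder/non-responder/reverse-responder mixtures.

#' Generator configuration
#'
#' Defaults encode the study conditions: 1 kHz EDA, 60 fps action-unit tables,
#' 12-trial blocks with the published trial timing, a 15-VAS-point nocebo
#' shift for responders (which, under the 0.45/0.50/0.05
#' responder/non-responder/reverse-responder mixture, yields a cohort-level
#' Tx - NT difference near the ~7 VAS points group analyses report), and an
#' 8.2% missing-expectancy rate.
#'
#' @param seed root seed for [simulate_chain_session()].
#' @param n_sessions number of chain sessions for cohort-level simulation.
#' @param sampling_rate native EDA sampling rate, Hz.
#' @param au_fps frame rate of the action-unit tables, Hz.
#' @param coupling_range range of the per-dyad arousal coupling kappa in
#'   \[0, 1\]; each dyad draws kappa uniformly from it. A scalar fixes kappa.
#' @param nocebo_effect_size mean Tx - NT pain shift for responders, VAS points.
#' @param nocebo_coupling_slope relative modulation of the responder effect
#'   size by (kappa - centre of `coupling_range`); 0 decouples them.
#' @param psync_noise_slope how strongly observer expectancy-rating noise grows
#'   with (1 - kappa); links measured psychological synchrony to coupling.
#' @param responder_mix probabilities over responder, non_responder,
#'   reverse_responder (must sum to 1).
#' @param scr_amplitude_by_temperature base heat-locked SCR amplitude (uS) per
#'   temperature level, named "45"/"54".
#' @param scr_cue_amplitude base amplitude (uS) of anticipatory cue-locked SCRs.
#' @param scr_vicarious_gain scaling of the observer's heat-locked SCRs
#'   relative to the demonstrator's.
#' @param scr_amp_sd log-normal jitter SD of SCR amplitudes.
#' @param eda_level tonic skin-conductance baseline, uS.
#' @param eda_tonic_amp amplitude (uS) of the Ornstein-Uhlenbeck arousal
#'   fluctuation around the baseline.
#' @param eda_noise_sd measurement white-noise SD, uS.
#' @param ou_theta mean-reversion rate of the shared (slow) arousal process,
#'   1/s.
#' @param ou_theta_fast mean-reversion rate of the fast idiosyncratic arousal
#'   component, 1/s.
#' @param indep_fast_frac fraction of the independent arousal variance carried
#'   by the fast component; shared arousal is slow co-fluctuation, so coupling
#'   expresses itself in the recurrence structure of the dyad's EDA.
#' @param rating_sd trial-to-trial pain-rating noise SD, VAS points.
#' @param expectancy_rating_sd expectancy-rating noise SD, VAS points.
#' @param expectancy_learning_rate delta-rule learning rate in \[0, 1\].
#' @param suppressed_weight multiplier on the learning rate for trials whose
#'   pain rating is suppressed (face-only observation).
#' @param expectancy_prior naive expectancy, VAS points.
#' @param nociception mean felt pain per temperature, named "45"/"54", VAS.
#' @param min_separation learned Tx/NT expectancy separation (VAS) at which
#'   the expectancy contribution to pain saturates.
#' @param missing_expectancy_rate proportion of expectancy ratings deleted by
#'   [inject_missingness()].
#' @param au_fail_rate proportion of frames with failed face detection.
#' @param au_noise_sd AU intensity noise SD.
#' @param timing trial-phase durations in seconds (`iti1` is a min/max range).
#' @param generate_signals generate continuous EDA? (`FALSE` = ratings only).
#' @param generate_au generate action-unit tables?
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(
    seed = 1L,
    n_sessions = 36L,
    sampling_rate = 1000,
    au_fps = 60,
    coupling_range = c(0.2, 0.8),
    nocebo_effect_size = 15,
    nocebo_coupling_slope = 0.5,
    psync_noise_slope = 1,
    responder_mix = c(responder = 0.45, non_responder = 0.50,
                      reverse_responder = 0.05),
    scr_amplitude_by_temperature = c("45" = 0.35, "54" = 0.9),
    scr_cue_amplitude = 0.15,
    scr_vicarious_gain = 0.5,
    scr_amp_sd = 0.3,
    eda_level = 8,
    eda_tonic_amp = 0.8,
    eda_noise_sd = 0.01,
    ou_theta = 0.1,
    ou_theta_fast = 3,
    indep_fast_frac = 0.5,
    rating_sd = 8,
    expectancy_rating_sd = 5,
    expectancy_learning_rate = 0.5,
    suppressed_weight = 0.5,
    expectancy_prior = 30,
    nociception = c("45" = 30, "54" = 75),
    min_separation = 10,
    missing_expectancy_rate = 0.082,
    au_fail_rate = 0.02,
    au_noise_sd = 0.15,
    timing = list(fixation = 2, cue = 6, expectancy = 6, iti1 = c(7, 10),
                  heat = 2, post_heat = 5, rating = 4, iti2 = 12, tail = 15),
    generate_signals = TRUE,
    generate_au = TRUE) {
  cfg <- as.list(environment())
  if (length(cfg$coupling_range) == 1L)
    cfg$coupling_range <- rep(cfg$coupling_range, 2L)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  stopifnot(
    "responder_mix must sum to 1" =
      abs(sum(cfg$responder_mix) - 1) < 1e-8,
    "responder_mix probabilities must be non-negative" =
      all(cfg$responder_mix >= 0),
    "coupling_range must lie in [0, 1]" =
      all(cfg$coupling_range >= 0 & cfg$coupling_range <= 1) &&
      cfg$coupling_range[1] <= cfg$coupling_range[2],
    "missing_expectancy_rate must lie in [0, 1]" =
      cfg$missing_expectancy_rate >= 0 && cfg$missing_expectancy_rate <= 1,
    "expectancy_learning_rate must lie in [0, 1]" =
      cfg$expectancy_learning_rate >= 0 && cfg$expectancy_learning_rate <= 1,
    "sampling_rate must be positive" = cfg$sampling_rate > 0
  )
  invisible(cfg)
}

# ---- trial sequences --------------------------------------------------------

seq_cache <- new.env(parent = emptyenv())

sequence_ok <- function(cues) {
  if (sum(cues == "Tx") != 6L || sum(cues == "NT") != 6L) return(FALSE)
  if (max(rle(cues)$lengths) > 3L) return(FALSE)
  h1 <- sum(cues[1:6] == "Tx")
  if (h1 < 2L || h1 > 4L) return(FALSE)
  # transitions from each cue split as evenly as possible between successors
  for (c0 in c("Tx", "NT")) {
    idx <- which(cues[-12L] == c0)
    nxt <- cues[idx + 1L]
    if (abs(sum(nxt == "Tx") - sum(nxt == "NT")) > 1L) return(FALSE)
  }
  TRUE
}

#' All cue sequences satisfying the pseudorandomisation rules
#'
#' Enumerates the 924 placements of 6 Tx cues among 12 trials and filters by
#' the design rules: no more than 3 repeats of the same cue, each cue shown
#' 2-4 times per half, and transition counts from each cue balanced (each
#' trial type follows every other with equal probability relative to its
#' occurrence).
#'
#' @return Character matrix, one valid sequence per row.
#' @export
valid_trial_sequences <- function() {
  if (!is.null(seq_cache$valid)) return(seq_cache$valid)
  combs <- utils::combn(12L, 6L)
  seqs <- apply(combs, 2L, function(tx) {
    cues <- rep("NT", 12L); cues[tx] <- "Tx"; cues
  })
  keep <- apply(seqs, 2L, sequence_ok)
  seq_cache$valid <- t(seqs[, keep, drop = FALSE])
  seq_cache$valid
}

#' Draw a pseudorandomised 12-trial cue sequence
#'
#' Samples uniformly from the set enumerated by [valid_trial_sequences()].
#'
#' @param seed optional seed (sets the RNG).
#' @return Character vector of 12 cue labels ("Tx"/"NT").
#' @export
generate_trial_sequence <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- valid_trial_sequences()
  v[sample.int(nrow(v), 1L), ]
}

# Which trials display the demonstrator's pain rating to the observer: the
# first Tx and first NT always shown; 3 shown per half; never 3 in a row.
draw_rating_shown <- function(cues) {
  must <- c(match("Tx", cues), match("NT", cues))
  for (i in 1:2000) {
    shown <- logical(12L)
    shown[must] <- TRUE
    need1 <- 3L - sum(shown[1:6]); need2 <- 3L - sum(shown[7:12])
    pool1 <- setdiff(1:6, must); pool2 <- setdiff(7:12, must)
    if (need1 < 0L || need2 < 0L) break
    shown[sample(pool1, need1)] <- TRUE
    shown[sample(pool2, need2)] <- TRUE
    if (max(rle(shown)$lengths[rle(shown)$values]) <= 2L) return(shown)
  }
  shown # fall back on the last candidate (constraint nearly always met)
}

# ---- signal primitives ------------------------------------------------------

# Standardized Ornstein-Uhlenbeck path (stationary, unit variance).
ou_path <- function(n, fs, theta) {
  a <- exp(-theta / fs)
  innov_sd <- sqrt(1 - a^2)
  as.numeric(stats::filter(c(rnorm(1L), rnorm(n - 1L) * innov_sd),
                           a, method = "recursive"))
}

#' Canonical skin-conductance-response kernel
#'
#' Bateman bi-exponential with 0.75 s rise, 2.0 s decay and 1.0 s latency,
#' normalised to unit peak.
#'
#' @param fs sampling rate, Hz.
#' @param rise,decay,latency time constants and onset latency, seconds.
#' @param duration kernel support, seconds.
#' @return Numeric vector of kernel samples.
#' @export
scr_kernel <- function(fs, rise = 0.75, decay = 2.0, latency = 1.0,
                       duration = 12) {
  t <- seq(0, duration, by = 1 / fs)
  tt <- pmax(t - latency, 0)
  k <- exp(-tt / decay) - exp(-tt / rise)
  k[t < latency] <- 0
  k / max(k)
}

add_scrs <- function(signal, fs, onsets, amplitudes, kernel) {
  n <- length(signal); lk <- length(kernel)
  for (i in seq_along(onsets)) {
    j0 <- round(onsets[i] * fs) + 1L
    if (j0 > n) next
    j1 <- min(j0 + lk - 1L, n)
    signal[j0:j1] <- signal[j0:j1] + amplitudes[i] * kernel[seq_len(j1 - j0 + 1L)]
  }
  signal
}

# Saturating contribution of learned expectancies to felt pain: +-1/2 once the
# learned Tx/NT separation reaches min_separation, proportionally smaller below.
expectancy_term <- function(e, cue, min_sep) {
  sep <- e[["Tx"]] - e[["NT"]]
  (e[[cue]] - mean(e)) / max(abs(sep), min_sep)
}

# ---- dyad block -------------------------------------------------------------

#' Simulate one demonstrator/observer testing block
#'
#' Uses the current RNG state (seed at the session level). EDA for each member
#' is shared latent arousal (weight kappa) plus independent arousal (weight
#' sqrt(1 - kappa^2)), both Ornstein-Uhlenbeck, with SCR-shaped phasic
#' responses at cue and heat onsets. Demonstrator felt pain is nociception
#' (temperature) plus the learned-expectancy term scaled by responder type,
#' plus noise, clipped to \[0, 100\]. The observer's expectancies track the
#' demonstrator's expressed pain by a delta rule, with attenuated weight on
#' rating-suppressed trials.
#'
#' @param config a [generator_config()].
#' @param dem_generation demonstrator generation ("G1", "G2" or "G3").
#' @param dem_state demonstrator state: list with `e` (named expectancies) and
#'   `responder_type`; see [new_participant_state()].
#' @param obs_state observer state (same shape).
#' @param kappa dyadic arousal coupling in \[0, 1\].
#' @param cues optional fixed cue sequence (drawn if `NULL`).
#' @return List with `trials` (data.table), `eda`, `au`, updated `dem_state` /
#'   `obs_state`, and `truth` (kappa, responder types, realised effect size).
#' @export
simulate_dyad_block <- function(config, dem_generation, dem_state, obs_state,
                                kappa, cues = NULL) {
  validate_generator_config(config)
  stopifnot(kappa >= 0, kappa <= 1)
  tm <- config$timing
  if (is.null(cues)) cues <- generate_trial_sequence()
  n_tr <- length(cues)
  temps <- if (dem_generation == "G1") ifelse(cues == "Tx", 54, 45)
           else rep(45, n_tr)
  shown <- draw_rating_shown(cues)

  # event timing
  cue_on <- heat_on <- numeric(n_tr)
  t <- 0
  for (i in seq_len(n_tr)) {
    t <- t + tm$fixation
    cue_on[i] <- t
    t <- t + tm$cue + tm$expectancy + runif(1, tm$iti1[1], tm$iti1[2])
    heat_on[i] <- t
    t <- t + tm$heat + tm$post_heat + tm$rating + tm$iti2
  }
  block_dur <- t + tm$tail

  w_dem <- switch(dem_state$responder_type,
                  responder = 1, non_responder = 0, reverse_responder = -1)
  kap_c <- mean(config$coupling_range)
  es_dyad <- config$nocebo_effect_size *
    (1 + config$nocebo_coupling_slope * (kappa - kap_c))

  exp_dem <- exp_obs <- pain_dem <- numeric(n_tr)
  lambda <- config$expectancy_learning_rate
  obs_noise_sd <- config$expectancy_rating_sd *
    (1 + config$psync_noise_slope * (1 - kappa))
  # the nocebo modulation is anchored to the expectancies the demonstrator
  # brings into the block (what they learned while observing); their running
  # expectancies still update trial by trial and drive the expectancy ratings
  e_entry <- dem_state$e
  for (i in seq_len(n_tr)) {
    cue <- cues[i]
    exp_dem[i] <- clip01(dem_state$e[[cue]] + rnorm(1, 0, config$expectancy_rating_sd))
    exp_obs[i] <- clip01(obs_state$e[[cue]] + rnorm(1, 0, obs_noise_sd))
    felt <- config$nociception[[as.character(temps[i])]] +
      w_dem * es_dyad * expectancy_term(e_entry, cue, config$min_separation) +
      rnorm(1, 0, config$rating_sd)
    pain_dem[i] <- clip01(felt)
    # demonstrator updates own expectancy from felt pain; observer from the
    # expressed pain (full weight when the rating is shown, attenuated when
    # only the face is available)
    dem_state$e[[cue]] <- dem_state$e[[cue]] + lambda * (pain_dem[i] - dem_state$e[[cue]])
    lam_o <- lambda * if (shown[i]) 1 else config$suppressed_weight
    obs_state$e[[cue]] <- obs_state$e[[cue]] + lam_o * (pain_dem[i] - obs_state$e[[cue]])
  }

  trials <- data.table::data.table(
    trial_index = seq_len(n_tr), cue = cues, temperature = temps,
    cue_onset = cue_on, heat_onset = heat_on,
    expectancy_dem = exp_dem, expectancy_obs = exp_obs,
    pain_dem = pain_dem, rating_shown = as.integer(shown))

  out <- list(trials = trials, dem_state = dem_state, obs_state = obs_state,
              truth = list(kappa = kappa, es_dyad = es_dyad,
                           dem_responder_type = dem_state$responder_type,
                           obs_responder_type = obs_state$responder_type))

  if (isTRUE(config$generate_signals)) {
    fs <- config$sampling_rate
    n <- ceiling(block_dur * fs)
    shared <- ou_path(n, fs, config$ou_theta)
    kern <- scr_kernel(fs)
    amp_jit <- function(k) exp(rnorm(k, 0, config$scr_amp_sd))
    temp_amp <- config$scr_amplitude_by_temperature[as.character(temps)]
    eda <- list()
    for (role in c("dem", "obs")) {
      # idiosyncratic arousal mixes slow drift with faster fluctuation; the
      # shared component is slow co-adaptation, so higher coupling yields
      # smoother, more interconnected joint dynamics
      f <- config$indep_fast_frac
      indep <- sqrt(1 - f) * ou_path(n, fs, config$ou_theta) +
        sqrt(f) * ou_path(n, fs, config$ou_theta_fast)
      tonic <- config$eda_level + config$eda_tonic_amp *
        (kappa * shared + sqrt(1 - kappa^2) * indep)
      if (role == "dem") {
        heat_amp <- temp_amp * (0.5 + pain_dem / 100) * amp_jit(n_tr)
        cue_amp <- config$scr_cue_amplitude * (0.5 + exp_dem / 100) * amp_jit(n_tr)
      } else {
        heat_amp <- config$scr_vicarious_gain * temp_amp *
          (0.5 + pain_dem / 100) * amp_jit(n_tr)
        cue_amp <- config$scr_cue_amplitude * (0.5 + exp_obs / 100) * amp_jit(n_tr)
      }
      x <- add_scrs(tonic, fs, heat_on, heat_amp, kern)
      x <- add_scrs(x, fs, cue_on, cue_amp, kern)
      if (config$eda_noise_sd > 0) x <- x + rnorm(n, 0, config$eda_noise_sd)
      eda[[role]] <- ds_recording(x, fs = fs, channel = paste0("eda_", role))
    }
    out$eda <- eda
    if (isTRUE(config$generate_au)) {
      out$au <- list(
        dem = simulate_au_channels(config, block_dur, cue_on, heat_on,
                                   exp_dem, pain_dem),
        obs = simulate_au_channels(config, block_dur, cue_on, heat_on,
                                   exp_obs, 0.6 * pain_dem))
    }
  }
  out
}

clip01 <- function(x) pmin(pmax(x, 0), 100)

# Frame-wise AU intensities: a smooth pain-expression bump after heat onset
# scaled by (vicarious) pain, a smaller anticipatory bump after cue onset
# scaled by expectancy, split across the eight AUs, plus noise and occasional
# failed detections.
simulate_au_channels <- function(config, block_dur, cue_on, heat_on,
                                 expectancy, pain) {
  fps <- config$au_fps
  n <- ceiling(block_dur * fps)
  tvec <- (seq_len(n) - 1L) / fps
  bump <- function(onsets, gains) {
    p <- numeric(n)
    for (i in seq_along(onsets)) {
      j0 <- floor(onsets[i] * fps) + 1L
      j1 <- min(j0 + round(2.5 * fps), n)
      idx <- j0:j1
      shape <- sin(pi * seq(0, 1, length.out = length(idx)))
      p[idx] <- p[idx] + gains[i] * shape
    }
    p
  }
  # pain-expression drive on a 0-1 scale
  drive <- bump(heat_on + 0.3, pain / 100) + bump(cue_on + 0.5, 0.3 * expectancy / 100)
  weights <- c(AU04_r = 0.22, AU06_r = 0.16, AU07_r = 0.10, AU09_r = 0.12,
               AU10_r = 0.06, AU12_r = 0.14, AU25_r = 0.12, AU26_r = 0.08)
  failed <- runif(n) < config$au_fail_rate
  aus <- lapply(names(weights), function(au) {
    v <- pmax(weights[[au]] * 5 * drive + abs(rnorm(n, 0, config$au_noise_sd)), 0)
    v[failed] <- NA_real_
    ds_recording(v, fs = fps, channel = au)
  })
  names(aus) <- names(weights)
  aus
}

#' Fresh participant state
#'
#' @param responder_type one of responder, non_responder, reverse_responder.
#' @param prior naive expectancy (VAS) for both cues.
#' @return List with named expectancies `e` and the responder type.
#' @export
new_participant_state <- function(responder_type = "responder", prior = 30) {
  list(e = c(Tx = prior, NT = prior), responder_type = responder_type)
}

# ---- chain session ----------------------------------------------------------

#' Simulate a full three-block transmission-chain session
#'
#' Block 1 pairs a directly conditioned G1 demonstrator (54 degC on Tx, 45 degC
#' on NT) with a G2 observer; blocks 2 and 3 deliver 45 degC on every trial.
#' Each observer's learned expectancies seed their own demonstrator block.
#'
#' @param config a [generator_config()].
#' @param session_id identifier used in the manifest.
#' @param seed optional seed; defaults to `config$seed`.
#' @return A [dyad_session()] with a `truth` element recording per-dyad
#'   coupling, responder types and realised effect sizes.
#' @export
simulate_chain_session <- function(config, session_id = "S001", seed = config$seed) {
  validate_generator_config(config)
  if (!is.null(seed)) set.seed(seed)
  types <- sample(names(config$responder_mix), 3L, replace = TRUE,
                  prob = config$responder_mix)
  genders <- sample(c("female", "male", "non-binary"), 4L, replace = TRUE,
                    prob = c(0.65, 0.28, 0.07))
  pid <- paste0(session_id, "_P", 1:4)
  participants <- data.table::data.table(
    participant_id = pid, generation = GENERATIONS, gender = genders)
  states <- list(new_participant_state(types[1], config$expectancy_prior),
                 new_participant_state(types[2], config$expectancy_prior),
                 new_participant_state(types[3], config$expectancy_prior),
                 new_participant_state("non_responder", config$expectancy_prior))
  kappas <- runif(3L, config$coupling_range[1], config$coupling_range[2])
  blocks <- vector("list", 3L)
  truth <- vector("list", 3L)
  for (k in 1:3) {
    blk <- simulate_dyad_block(config, dem_generation = paste0("G", k),
                               dem_state = states[[k]],
                               obs_state = states[[k + 1L]],
                               kappa = kappas[k])
    states[[k]] <- blk$dem_state
    states[[k + 1L]] <- blk$obs_state
    truth[[k]] <- blk$truth
    blocks[[k]] <- blk[intersect(c("trials", "eda", "au"), names(blk))]
  }
  manifest <- list(
    session_id = session_id,
    cue_colour_assignment = sample(c("green_tx", "blue_tx"), 1L),
    participants = participants,
    blocks = data.table::data.table(
      block = 1:3, demonstrator_id = pid[1:3], observer_id = pid[2:4],
      gender_match = as.integer(genders[1:3] == genders[2:4])))
  out <- dyad_session(manifest, blocks)
  out$truth <- truth
  out
}

#' Delete expectancy ratings at random
#'
#' Emulates participants missing the rating window: each demonstrator and
#' observer expectancy cell is deleted independently at the configured rate.
#'
#' @param session a `dyad_session`.
#' @param rate deletion probability per rating (defaults to the config value).
#' @param seed optional seed for reproducibility.
#' @return The session with expectancy cells set to `NA`.
#' @export
inject_missingness <- function(session, rate, seed = NULL) {
  if (rate < 0 || rate > 1) stop("missingness rate must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  for (k in seq_along(session$blocks)) {
    tr <- data.table::copy(session$blocks[[k]]$trials)
    for (col in c("expectancy_dem", "expectancy_obs")) {
      drop <- runif(nrow(tr)) < rate
      tr[drop, (col) := NA_real_]
    }
    session$blocks[[k]]$trials <- tr
  }
  session
}
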