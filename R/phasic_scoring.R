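# Per-trial phasic scoring: zero-phase band-pass filtering, epoching with
# decimation, jack-knife outlier exclusion, peak-to-peak electrodermal
# amplitudes, and the facial pain-expression composite.

#' Zero-phase Butterworth band-pass filter
#'
#' 2nd-order Butterworth applied forward-backward (`signal::filtfilt`), so the
#' pass band is applied twice and no phase shift distorts onset alignment.
#'
#' @param rec a [ds_recording()].
#' @param low_hz,high_hz band edges in Hz; `high_hz` must be below Nyquist.
#' @param order filter order of the underlying one-pass design.
#' @return The filtered recording (length preserved).
#' @export
bandpass_filter <- function(rec, low_hz, high_hz, order = 2L) {
  nyq <- rec$fs / 2
  if (low_hz <= 0 || high_hz >= nyq || low_hz >= high_hz)
    stop(sprintf("band [%g, %g] Hz invalid for Nyquist %g Hz",
                 low_hz, high_hz, nyq), call. = FALSE)
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  out <- rec
  out$samples <- as.numeric(signal::filtfilt(bf, rec$samples))
  out
}

#' Cut onset-locked epochs and downsample by decimation
#'
#' Extracts a trials-by-samples matrix on a uniform grid from `window[1]` to
#' `window[2]` seconds around each event (closed endpoints); the sample at
#' offset 0 is the onset sample. Downsampling is stride decimation, which
#' requires `fs / target_hz` to be an integer; the band-pass applied upstream
#' acts as the anti-alias filter. Events whose window falls outside the
#' recording are flagged excluded rather than dropped.
#'
#' @param rec a [ds_recording()].
#' @param events event onset times, seconds from block start.
#' @param window c(lo, hi) epoch window in seconds relative to onset.
#' @param target_hz output sampling rate (defaults to the recording rate).
#' @param event_type label stored on the epoch set ("cue" or "heat").
#' @return An object of class `epoch_set`: matrix `data`, sampling rate `fs`,
#'   `onset_index`, and per-trial `excluded` flags with `reason`s.
#' @export
epoch_and_downsample <- function(rec, events, window, target_hz = rec$fs,
                                 event_type = "cue") {
  stride <- rec$fs / target_hz
  if (abs(stride - round(stride)) > 1e-8)
    stop("fs / target_hz must be an integer for stride decimation",
         call. = FALSE)
  stride <- as.integer(round(stride))
  n_samp <- as.integer(round((window[2] - window[1]) * target_hz)) + 1L
  n <- length(rec$samples)
  data <- matrix(NA_real_, nrow = length(events), ncol = n_samp)
  excluded <- logical(length(events))
  reason <- character(length(events))
  for (i in seq_along(events)) {
    i0 <- as.integer(round((events[i] + window[1] - rec$t0) * rec$fs)) + 1L
    idx <- i0 + (seq_len(n_samp) - 1L) * stride
    if (idx[1L] < 1L || idx[n_samp] > n) {
      excluded[i] <- TRUE
      reason[i] <- "window outside recording"
      next
    }
    data[i, ] <- rec$samples[idx]
  }
  structure(list(data = data, fs = target_hz, window = window,
                 onset_index = as.integer(round(-window[1] * target_hz)) + 1L,
                 event_type = event_type, excluded = excluded,
                 reason = reason),
            class = "epoch_set")
}

#' Jack-knife extreme-trial exclusion
#'
#' A trial is excluded when any of its samples deviates from the
#' leave-that-trial-out mean by more than `threshold` times the
#' leave-that-trial-out SD (mean and SD pooled over all samples of the
#' remaining usable trials). Leaving the assessed trial out keeps an extreme
#' trial from inflating its own exclusion criterion. Applied separately per
#' epoch type and participant.
#'
#' @param epochs an `epoch_set`.
#' @param threshold SD multiple (4.89 in this pipeline).
#' @return The epoch set with updated `excluded` / `reason`.
#' @export
jackknife_outlier_mask <- function(epochs, threshold = 4.89) {
  usable <- which(!epochs$excluded)
  if (length(usable) < 3L) {
    warning("fewer than 3 usable trials; no jack-knife exclusions applied")
    return(epochs)
  }
  flag <- logical(length(usable))
  for (j in seq_along(usable)) {
    rest <- epochs$data[usable[-j], , drop = FALSE]
    mu <- mean(rest)
    sdev <- sd(as.numeric(rest))
    dev <- abs(epochs$data[usable[j], ] - mu)
    flag[j] <- any(dev > threshold * sdev)
  }
  hit <- usable[flag]
  epochs$excluded[hit] <- TRUE
  epochs$reason[hit] <- sprintf("jack-knife outlier (> %.2f SD)", threshold)
  epochs
}

#' Peak-to-peak skin-conductance response amplitude
#'
#' The maximum amplitude from 3 s after onset to the end of the epoch, minus
#' the minimum amplitude from that maximum back to the onset (closed windows,
#' so the result is never negative). Values below the 0.02 uS resolution floor
#' are set to 0; the transformed score is ln(1 + raw).
#'
#' @param values one epoch's samples.
#' @param fs epoch sampling rate, Hz.
#' @param onset_index index of the onset sample.
#' @return List with `raw` and `transformed`.
#' @export
peak_to_peak_score <- function(values, fs, onset_index) {
  i3 <- onset_index + as.integer(round(3 * fs))
  if (i3 > length(values))
    stop("epoch must extend at least 3 s past onset", call. = FALSE)
  late <- values[i3:length(values)]
  tau <- i3 + which.max(late) - 1L
  m <- values[tau]
  v <- min(values[onset_index:tau])
  raw <- m - v
  if (raw < 0.02) raw <- 0
  list(raw = raw, transformed = log1p(raw))
}

#' Facial pain-expression composite
#'
#' `AU04 + max(AU06, AU07) + max(AU09, AU10) + AU12 + max(AU25, AU26)`,
#' the PSPI-style summary of pain-related action-unit engagement. Frames with
#' any required AU missing yield `NA`.
#'
#' @param au named numeric vector, or a frames-by-AU matrix/data.frame, with
#'   columns `AU04_r` ... `AU26_r`.
#' @return Numeric score(s).
#' @export
fau_pain_expression <- function(au) {
  if (is.null(dim(au))) au <- matrix(au, nrow = 1L,
                                     dimnames = list(NULL, names(au)))
  au <- as.matrix(au)
  missing_aus <- setdiff(PAIN_AUS, colnames(au))
  if (length(missing_aus))
    ds_format_error(paste("missing AU columns:",
                          paste(missing_aus, collapse = ", ")))
  score <- au[, "AU04_r"] +
    pmax(au[, "AU06_r"], au[, "AU07_r"]) +
    pmax(au[, "AU09_r"], au[, "AU10_r"]) +
    au[, "AU12_r"] +
    pmax(au[, "AU25_r"], au[, "AU26_r"])
  unname(score)
}

#' Epoch maximum of the pain-expression series
#'
#' The maximum score over the 3 s following onset (open at onset, closed at
#' +3 s). Frames with failed detections are skipped; epochs with no usable
#' frame are excluded.
#'
#' @param values pain-expression samples for one epoch.
#' @param fs frame rate, Hz.
#' @param onset_index index of the onset frame.
#' @param span seconds after onset to search.
#' @return List with `raw` (`NA` when excluded) and `excluded`.
#' @export
epoch_max_fau <- function(values, fs, onset_index, span = 3) {
  j1 <- min(onset_index + as.integer(round(span * fs)), length(values))
  if (onset_index + 1L > j1) stop("epoch does not extend past onset")
  win <- values[(onset_index + 1L):j1]
  if (all(is.na(win))) return(list(raw = NA_real_, excluded = TRUE))
  list(raw = max(win, na.rm = TRUE), excluded = FALSE)
}

#' Average sequential trial pairs within cue
#'
#' Collapses the 6 per-cue trials to 3 levels (mean of trials 1-2, 3-4, 5-6).
#' A pair with one excluded member keeps the surviving value; a pair with both
#' members excluded is missing. Reduces listwise deletion in the
#' repeated-measures models.
#'
#' @param scores tidy score table with columns `cue`, per-cue `trial` (1-6),
#'   `value` and `excluded`, one row per trial, plus any grouping columns
#'   already subset.
#' @return data.table with columns `cue`, `trial_pair` (1-3) and `value`.
#' @export
average_trial_pairs <- function(scores) {
  dt <- data.table::as.data.table(scores)
  stopifnot(all(c("cue", "trial", "value", "excluded") %in% names(dt)))
  dt <- dt[order(cue, trial)]
  dt[, trial_pair := ceiling(trial / 2)]
  dt[excluded == TRUE, value := NA_real_]
  out <- dt[, .(value = if (all(is.na(value))) NA_real_
                else mean(value, na.rm = TRUE)),
            by = .(cue, trial_pair)]
  out[]
}

# ---- session-level scoring --------------------------------------------------

pain_series_from_au <- function(au_list) {
  mat <- do.call(cbind, lapply(PAIN_AUS, function(a) au_list[[a]]$samples))
  colnames(mat) <- PAIN_AUS
  fau_pain_expression(mat)
}

score_eda_channel <- function(rec, trials, band, target_hz, jack_sd) {
  filt <- bandpass_filter(rec, band[1], band[2])
  rows <- list()
  for (ev in c("cue", "heat")) {
    onsets <- if (ev == "cue") trials$cue_onset else trials$heat_onset
    ep <- epoch_and_downsample(filt, onsets, window = c(-2, 6),
                               target_hz = target_hz, event_type = ev)
    ep <- jackknife_outlier_mask(ep, threshold = jack_sd)
    raw <- transformed <- rep(NA_real_, nrow(ep$data))
    for (i in seq_len(nrow(ep$data))) {
      if (ep$excluded[i]) next
      s <- peak_to_peak_score(ep$data[i, ], ep$fs, ep$onset_index)
      raw[i] <- s$raw; transformed[i] <- s$transformed
    }
    rows[[ev]] <- data.table::data.table(
      trial_index = trials$trial_index, cue = trials$cue,
      outcome = paste0("EDA_", ev), raw = raw, transformed = transformed,
      excluded = ep$excluded, reason = ep$reason)
  }
  data.table::rbindlist(rows)
}

score_fau_channel <- function(au_list, trials) {
  pain <- pain_series_from_au(au_list)
  fs <- au_list[[1L]]$fs
  t0 <- au_list[[1L]]$t0
  rows <- list()
  for (ev in c("cue", "heat")) {
    onsets <- if (ev == "cue") trials$cue_onset else trials$heat_onset
    raw <- rep(NA_real_, length(onsets))
    excl <- logical(length(onsets)); reason <- character(length(onsets))
    for (i in seq_along(onsets)) {
      oi <- as.integer(round((onsets[i] - t0) * fs)) + 1L
      if (oi < 1L || oi + 3 * fs > length(pain) + 1) {
        excl[i] <- TRUE; reason[i] <- "window outside recording"; next
      }
      s <- epoch_max_fau(pain, fs, oi)
      raw[i] <- s$raw
      if (s$excluded) { excl[i] <- TRUE; reason[i] <- "no usable frames" }
    }
    rows[[ev]] <- data.table::data.table(
      trial_index = trials$trial_index, cue = trials$cue,
      outcome = paste0("FAU_", ev), raw = raw, transformed = raw,
      excluded = excl, reason = reason)
  }
  data.table::rbindlist(rows)
}

#' Score every phasic outcome of a session
#'
#' Runs the full chain per block and participant: band-pass filter, epoch,
#' downsample, jack-knife exclusion, peak-to-peak (EDA) and windowed maximum
#' of the pain-expression composite (FAU), for both cue- and heat-locked
#' epochs. Self-report ratings are carried through from the trial log.
#'
#' @param session a `dyad_session`.
#' @param eda_band analysis band for phasic EDA, Hz.
#' @param eda_target_hz post-epoch sampling rate for EDA.
#' @param jack_sd jack-knife exclusion threshold in SD units.
#' @return Tidy data.table: session, block, participant, role, generation,
#'   trial_index, cue, outcome, raw, transformed, excluded, reason.
#' @export
score_session <- function(session, eda_band = c(0.0159, 5),
                          eda_target_hz = 100, jack_sd = 4.89) {
  man <- session$manifest
  gen_of <- setNames(as.character(man$participants$generation),
                     man$participants$participant_id)
  out <- list()
  for (k in seq_along(session$blocks)) {
    blk <- session$blocks[[k]]
    binfo <- man$blocks[man$blocks$block == k, ]
    ids <- c(dem = as.character(binfo$demonstrator_id),
             obs = as.character(binfo$observer_id))
    for (role in c("dem", "obs")) {
      parts <- list()
      if (!is.null(blk$eda))
        parts$eda <- score_eda_channel(blk$eda[[role]], blk$trials,
                                       eda_band, eda_target_hz, jack_sd)
      if (!is.null(blk$au) && !is.null(blk$au[[role]]))
        parts$fau <- score_fau_channel(blk$au[[role]], blk$trials)
      if (!length(parts)) next
      sc <- data.table::rbindlist(parts)
      sc[, `:=`(session = man$session_id, block = k,
                participant = ids[[role]], role = role,
                generation = gen_of[[ids[[role]]]])]
      out[[length(out) + 1L]] <- sc
    }
  }
  res <- data.table::rbindlist(out)
  data.table::setcolorder(res, c("session", "block", "participant", "role",
                                 "generation", "trial_index", "cue",
                                 "outcome", "raw", "transformed",
                                 "excluded", "reason"))
  res[]
}
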