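#' @useDynLib dyadsynch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
#' @importFrom stats cor sd var median qt pt pf qf rnorm runif rbinom quantile
#'   coef vcov lm resid fitted complete.cases setNames pchisq approx
#' @importFrom utils head tail
NULL

# The eight action units entering the pain-expression composite.
PAIN_AUS <- c("AU04_r", "AU06_r", "AU07_r", "AU09_r", "AU10_r",
              "AU12_r", "AU25_r", "AU26_r")

#' Construct a continuous recording
#'
#' A uniformly sampled amplitude series: electrodermal activity in microsiemens
#' or a facial action-unit intensity channel. Times are seconds from block
#' start, 0-based.
#'
#' @param samples numeric vector of amplitudes (`NA` marks failed frames).
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample, seconds from block start.
#' @param channel channel label.
#' @return An object of class `ds_recording`.
#' @export
ds_recording <- function(samples, fs, t0 = 0, channel = "eda") {
  if (!is.numeric(samples) || length(samples) == 0L)
    stop("recording must contain at least one numeric sample", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("sampling_rate must be a positive scalar", call. = FALSE)
  structure(list(samples = as.numeric(samples), fs = as.numeric(fs),
                 t0 = as.numeric(t0), channel = as.character(channel)),
            class = "ds_recording")
}

#' @export
print.ds_recording <- function(x, ...) {
  cat(sprintf("<ds_recording '%s': %d samples @ %g Hz, t0 = %g s>\n",
              x$channel, length(x$samples), x$fs, x$t0))
  invisible(x)
}

#' @export
length.ds_recording <- function(x) length(x$samples)

#' Sample times of a recording
#' @param rec a `ds_recording`.
#' @return numeric vector of times in seconds.
#' @export
recording_times <- function(rec) {
  rec$t0 + (seq_along(rec$samples) - 1L) / rec$fs
}

ds_format_error <- function(msg) {
  stop(errorCondition(msg, class = c("ds_format_error", "error")))
}

# Infer a uniform sampling rate from a time column; reject non-monotone or
# irregular sampling beyond tolerance.
infer_fs <- function(tvec, tol = 1e-6) {
  if (length(tvec) < 2L) return(NA_real_)
  dt <- diff(tvec)
  if (any(dt <= 0)) ds_format_error("time column is not strictly increasing")
  if ((max(dt) - min(dt)) > tol * median(dt))
    ds_format_error("time stamps are not uniformly spaced within tolerance")
  1 / median(dt)
}

#' Read a continuous recording from delimited text
#'
#' Expects a header with a time column (seconds from block start) and one or
#' more amplitude columns; the header names the channels.
#'
#' @param path file path (CSV by default).
#' @param channel name of the amplitude column to extract.
#' @param time_col name of the time column.
#' @param sep field separator (`"auto"` lets the reader sniff it).
#' @return A [ds_recording()].
#' @export
read_recording <- function(path, channel, time_col = "t", sep = "auto") {
  dt <- data.table::fread(path, sep = sep)
  if (!time_col %in% names(dt))
    ds_format_error(sprintf("time column '%s' not found in %s", time_col, path))
  if (!channel %in% names(dt))
    ds_format_error(sprintf("channel '%s' not found in %s (has: %s)",
                            channel, path, paste(names(dt), collapse = ", ")))
  tvec <- as.numeric(dt[[time_col]])
  fs <- infer_fs(tvec)
  if (is.na(fs)) fs <- 1
  ds_recording(as.numeric(dt[[channel]]), fs = fs, t0 = tvec[1L],
               channel = channel)
}

#' Default action-unit table dialect
#'
#' Mirrors OpenFace 2.x column naming; adjust when consuming tables from a
#' different facial-behaviour toolkit.
#'
#' @param time_col frame timestamp column (seconds).
#' @param success_col detection-success column (0/1) or `NULL` if absent.
#' @param au_cols names of the eight required AU intensity columns.
#' @return A named list describing the dialect.
#' @export
au_dialect <- function(time_col = "timestamp", success_col = "success",
                       au_cols = PAIN_AUS) {
  list(time_col = time_col, success_col = success_col, au_cols = au_cols)
}

#' Read a facial action-unit intensity table
#'
#' Returns one recording per required AU; frames flagged as failed detections
#' are marked missing in every channel.
#'
#' @param path file path.
#' @param dialect column mapping, see [au_dialect()].
#' @return Named list of [ds_recording()], one per AU column.
#' @export
read_au_table <- function(path, dialect = au_dialect()) {
  dt <- data.table::fread(path)
  if (!dialect$time_col %in% names(dt))
    ds_format_error(sprintf("AU time column '%s' not found in %s",
                            dialect$time_col, path))
  missing_aus <- setdiff(dialect$au_cols, names(dt))
  if (length(missing_aus))
    ds_format_error(sprintf("required AU columns missing from %s: %s",
                            path, paste(missing_aus, collapse = ", ")))
  tvec <- as.numeric(dt[[dialect$time_col]])
  fs <- infer_fs(tvec, tol = 1e-3)
  failed <- if (!is.null(dialect$success_col) &&
                dialect$success_col %in% names(dt)) {
    dt[[dialect$success_col]] == 0
  } else rep(FALSE, nrow(dt))
  out <- lapply(dialect$au_cols, function(au) {
    v <- as.numeric(dt[[au]])
    v[failed] <- NA_real_
    ds_recording(v, fs = fs, t0 = tvec[1L], channel = au)
  })
  names(out) <- dialect$au_cols
  out
}

# ---- session objects --------------------------------------------------------

GENERATIONS <- c("G1", "G2", "G3", "G4")

#' Assemble a dyad-chain session object
#'
#' @param manifest list with `session_id`, `participants` (data.frame:
#'   participant_id, generation, gender), `blocks` (data.frame: block,
#'   demonstrator_id, observer_id, gender_match), `cue_colour_assignment`.
#' @param blocks list (by block index) of lists with elements `trials`
#'   (data.table), `eda` (list dem/obs of recordings) and `au` (list dem/obs of
#'   AU recording lists).
#' @return Object of class `dyad_session`.
#' @export
dyad_session <- function(manifest, blocks) {
  structure(list(manifest = manifest, blocks = blocks),
            class = "dyad_session")
}

#' @export
print.dyad_session <- function(x, ...) {
  cat(sprintf("<dyad_session '%s': %d blocks, %d participants>\n",
              x$manifest$session_id, length(x$blocks),
              nrow(x$manifest$participants)))
  invisible(x)
}

#' Validate a session against the transmission-chain design
#'
#' Checks the chain roles (block k pairs a Gk demonstrator with a G(k+1)
#' observer; G4 never demonstrates), trial counts and cue balance, onset
#' ordering, the fixed-low-temperature rule for socially conditioned
#' demonstrators, and rating ranges. Every violated invariant is reported.
#'
#' @param session a `dyad_session`.
#' @return Character vector of violations (length 0 when valid).
#' @export
validate_session <- function(session) {
  errs <- character()
  man <- session$manifest
  parts <- as.data.frame(man$participants)
  blocks_tab <- as.data.frame(man$blocks)
  gen_of <- setNames(as.character(parts$generation), parts$participant_id)
  if (any(!parts$generation %in% GENERATIONS))
    errs <- c(errs, "participant with generation outside G1-G4")
  for (i in seq_len(nrow(blocks_tab))) {
    b <- blocks_tab[i, ]
    dg <- gen_of[[as.character(b$demonstrator_id)]]
    og <- gen_of[[as.character(b$observer_id)]]
    if (identical(dg, "G4"))
      errs <- c(errs, sprintf("block %d: G4 must never demonstrate", b$block))
    want_d <- paste0("G", b$block); want_o <- paste0("G", b$block + 1L)
    if (!identical(dg, want_d))
      errs <- c(errs, sprintf("block %d: demonstrator is %s, chain requires %s",
                              b$block, dg, want_d))
    if (!identical(og, want_o))
      errs <- c(errs, sprintf("block %d: observer is %s, chain requires %s",
                              b$block, og, want_o))
  }
  for (k in seq_along(session$blocks)) {
    tr <- session$blocks[[k]]$trials
    if (is.null(tr)) { errs <- c(errs, sprintf("block %d: no trial log", k)); next }
    n_tx <- sum(tr$cue == "Tx"); n_nt <- sum(tr$cue == "NT")
    if (n_tx != 6L || n_nt != 6L)
      errs <- c(errs, sprintf("block %d: needs 6 Tx and 6 NT trials, has %d/%d",
                              k, n_tx, n_nt))
    if (any(tr$heat_onset <= tr$cue_onset))
      errs <- c(errs, sprintf("block %d: heat onset not after cue onset", k))
    if (!all(tr$temperature %in% c(45, 54)))
      errs <- c(errs, sprintf("block %d: temperature outside {45, 54}", k))
    dem_gen <- gen_of[[as.character(blocks_tab$demonstrator_id[
      blocks_tab$block == k])]]
    if (dem_gen %in% c("G2", "G3") && any(tr$temperature != 45))
      errs <- c(errs, sprintf(
        "block %d: %s demonstrator must receive 45 degC on every trial",
        k, dem_gen))
    for (col in intersect(c("expectancy_dem", "expectancy_obs", "pain_dem"),
                          names(tr))) {
      v <- tr[[col]]
      if (any(!is.na(v) & (v < 0 | v > 100)))
        errs <- c(errs, sprintf("block %d: %s outside [0, 100]", k, col))
    }
  }
  errs
}

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

write_num_csv <- function(dt, path) {
  out <- data.table::as.data.table(lapply(dt, function(col) {
    if (is.double(col)) fmt_num(col) else col
  }))
  data.table::fwrite(out, path, quote = FALSE)
}

#' Write a session to disk in the package's layout
#'
#' Layout: `manifest.yaml` plus one `blockK/` directory per block holding
#' `eda.csv` (t, eda_dem, eda_obs), `trials.csv` and `au_dem.csv` /
#' `au_obs.csv` when AU tables are present. CSV, UTF-8, "." decimal; numeric
#' values are serialised with 17 significant digits so the round trip is
#' bit-identical. Missing values are empty fields.
#'
#' @param session a `dyad_session`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- session$manifest
  yaml::write_yaml(list(
    session_id = man$session_id,
    cue_colour_assignment = man$cue_colour_assignment,
    participants = lapply(seq_len(nrow(man$participants)), function(i)
      as.list(man$participants[i, , drop = FALSE])),
    blocks = lapply(seq_len(nrow(man$blocks)), function(i)
      as.list(man$blocks[i, , drop = FALSE]))
  ), file.path(dir, "manifest.yaml"))
  for (k in seq_along(session$blocks)) {
    bdir <- file.path(dir, sprintf("block%d", k))
    dir.create(bdir, showWarnings = FALSE)
    blk <- session$blocks[[k]]
    if (!is.null(blk$eda)) {
      dem <- blk$eda$dem; obs <- blk$eda$obs
      tvec <- dem$t0 + (seq_along(dem$samples) - 1L) / dem$fs
      write_num_csv(data.table::data.table(
        t = tvec, eda_dem = dem$samples, eda_obs = obs$samples),
        file.path(bdir, "eda.csv"))
    }
    if (!is.null(blk$au)) {
      for (role in names(blk$au)) {
        aus <- blk$au[[role]]
        a1 <- aus[[1L]]
        tvec <- a1$t0 + (seq_along(a1$samples) - 1L) / a1$fs
        cols <- c(list(timestamp = tvec,
                       success = as.integer(!is.na(aus[[1L]]$samples))),
                  lapply(aus, function(a) {
                    v <- a$samples; v[is.na(v)] <- 0; v
                  }))
        write_num_csv(data.table::as.data.table(cols),
                      file.path(bdir, sprintf("au_%s.csv", role)))
      }
    }
    write_num_csv(blk$trials, file.path(bdir, "trials.csv"))
  }
  invisible(dir)
}

read_manifest <- function(path) {
  y <- yaml::read_yaml(path)
  list(
    session_id = y$session_id,
    cue_colour_assignment = y$cue_colour_assignment,
    participants = data.table::rbindlist(lapply(y$participants, as.list)),
    blocks = data.table::rbindlist(lapply(y$blocks, as.list))
  )
}

#' Load and validate a session directory
#'
#' @param dir session directory produced by [write_session()] (or laid out the
#'   same way).
#' @param validate raise an error listing every violated invariant?
#' @return A `dyad_session`.
#' @export
load_session <- function(dir, validate = TRUE) {
  man_path <- file.path(dir, "manifest.yaml")
  if (!file.exists(man_path))
    ds_format_error(sprintf("no manifest.yaml under %s", dir))
  man <- read_manifest(man_path)
  blocks <- lapply(sort(man$blocks$block), function(k) {
    bdir <- file.path(dir, sprintf("block%d", k))
    if (!dir.exists(bdir))
      ds_format_error(sprintf("missing block directory %s", bdir))
    blk <- list(trials = data.table::fread(file.path(bdir, "trials.csv")))
    eda_path <- file.path(bdir, "eda.csv")
    if (file.exists(eda_path)) {
      blk$eda <- list(dem = read_recording(eda_path, "eda_dem"),
                      obs = read_recording(eda_path, "eda_obs"))
    }
    blk$au <- list()
    for (role in c("dem", "obs")) {
      au_path <- file.path(bdir, sprintf("au_%s.csv", role))
      if (file.exists(au_path)) blk$au[[role]] <- read_au_table(au_path)
    }
    if (!length(blk$au)) blk$au <- NULL
    blk
  })
  session <- dyad_session(man, blocks)
  if (validate) {
    errs <- validate_session(session)
    if (length(errs))
      stop(errorCondition(
        paste0("session validation failed:\n  - ",
               paste(errs, collapse = "\n  - ")),
        class = c("ds_validation_error", "error")))
  }
  session
}
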