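# From-scratch cross-recurrence quantification of dyadic electrodermal
# activity: time-delay embedding, cross-recurrence plots, RR/DET/LAM, and
# automatic parameter selection targeting a 2-4% recurrence rate.

#' Prepare an EDA series for cross-recurrence analysis
#'
#' Band-pass filters (0.05-1 Hz by default), downsamples to 8 Hz by stride
#' decimation, and z-scores. Constant (zero-variance) input is rejected.
#'
#' @param rec a [ds_recording()] spanning a testing block.
#' @param band analysis band in Hz.
#' @param target_hz output rate, Hz.
#' @return Numeric z-scored series at `target_hz`.
#' @export
prepare_series <- function(rec, band = c(0.05, 1), target_hz = 8) {
  if (sd(rec$samples) < 1e-12)
    stop("constant series cannot be prepared for CRQA", call. = FALSE)
  filt <- bandpass_filter(rec, band[1], band[2])
  stride <- filt$fs / target_hz
  if (abs(stride - round(stride)) > 1e-8)
    stop("fs / target_hz must be an integer for stride decimation",
         call. = FALSE)
  x <- filt$samples[seq(1L, length(filt$samples), by = as.integer(round(stride)))]
  s <- sd(x)
  if (s < 1e-12) stop("prepared series has zero variance", call. = FALSE)
  (x - mean(x)) / s
}

#' Time-delay embedding
#'
#' @param x numeric series.
#' @param delay delay in samples (>= 1).
#' @param dim embedding dimension (>= 1); `dim = 1` returns the series as a
#'   one-column matrix.
#' @return Matrix with `length(x) - (dim - 1) * delay` rows and `dim` columns.
#' @export
embed_series <- function(x, delay, dim) {
  stopifnot(delay >= 1, dim >= 1)
  np <- length(x) - (dim - 1L) * delay
  if (np < 1L)
    stop("series too short for the requested embedding", call. = FALSE)
  out <- matrix(NA_real_, nrow = np, ncol = dim)
  for (k in seq_len(dim)) out[, k] <- x[(1L + (k - 1L) * delay):((k - 1L) * delay + np)]
  out
}

#' Cross-recurrence matrix
#'
#' Entry (i, j) is 1 when the Euclidean distance between embedded point `x_i`
#' (rows) and `y_j` (columns) is at most `radius`. Intended for inspection and
#' small problems; [crqa_run()] streams the same quantities without building
#' the matrix.
#'
#' @param x_emb,y_emb embedded matrices with matching dimension.
#' @param radius recurrence threshold.
#' @return Binary integer matrix, `nrow(x_emb)` by `nrow(y_emb)`.
#' @export
cross_recurrence_matrix <- function(x_emb, y_emb, radius) {
  if (is.null(dim(x_emb))) x_emb <- matrix(x_emb, ncol = 1L)
  if (is.null(dim(y_emb))) y_emb <- matrix(y_emb, ncol = 1L)
  stopifnot(ncol(x_emb) == ncol(y_emb))
  d2 <- matrix(0, nrow(x_emb), nrow(y_emb))
  for (k in seq_len(ncol(x_emb)))
    d2 <- d2 + outer(x_emb[, k], y_emb[, k], "-")^2
  (d2 <= radius^2) * 1L
}

run_hist <- function(lengths, maxlen) {
  h <- numeric(maxlen)
  if (length(lengths)) {
    tab <- table(lengths)
    h[as.integer(names(tab))] <- as.numeric(tab)
  }
  h
}

#' Recurrence measures of a binary cross-recurrence matrix
#'
#' RR is the density of recurrent points; DET the fraction of recurrent points
#' on diagonal runs of at least `min_diag` (interconnection of the two
#' trajectories); LAM the fraction on vertical runs of at least `min_vert`
#' (shared stable periods). DET and LAM are undefined when RR = 0. Rows index
#' the first series, so a vertical line is a stretch of first-series time
#' spent near one second-series state; transposing the matrix (swapping the
#' series) leaves RR and DET unchanged.
#'
#' @param rmat binary matrix from [cross_recurrence_matrix()].
#' @param min_diag,min_vert minimum run lengths (>= 2).
#' @return List: RR, DET, LAM, diag_hist, vert_hist, n_recurrent.
#' @export
crqa_measures <- function(rmat, min_diag = 2L, min_vert = 2L) {
  stopifnot(min_diag >= 2L, min_vert >= 2L)
  nx <- nrow(rmat); ny <- ncol(rmat)
  ones <- sum(rmat)
  diag_lengths <- unlist(lapply((-(nx - 1L)):(ny - 1L), function(off) {
    v <- rmat[cbind(seq(max(1L, 1L - off), length.out = min(nx, ny, nx + off, ny - off)),
                    seq(max(1L, 1L + off), length.out = min(nx, ny, nx + off, ny - off)))]
    r <- rle(v); r$lengths[r$values == 1L]
  }))
  vert_lengths <- unlist(apply(rmat, 2L, function(col) {
    r <- rle(col); r$lengths[r$values == 1L]
  }, simplify = FALSE))
  maxlen <- max(nx, ny)
  out <- list(RR = ones / (nx * ny),
              DET = NA_real_, LAM = NA_real_,
              n_recurrent = ones,
              diag_hist = run_hist(diag_lengths, maxlen),
              vert_hist = run_hist(vert_lengths, maxlen))
  if (ones > 0) {
    out$DET <- sum(diag_lengths[diag_lengths >= min_diag]) / ones
    out$LAM <- sum(vert_lengths[vert_lengths >= min_vert]) / ones
  }
  out
}

#' Streamed cross-recurrence quantification
#'
#' Embeds both series (truncated to the shorter length) and computes RR, DET
#' and LAM with run-length histograms without materialising the plot.
#'
#' @param x,y prepared series.
#' @param params list with `delay`, `dim`, `radius`, `min_diag`, `min_vert`
#'   (see [optimize_parameters()]).
#' @return List of class `crqa_result` with measures, histograms and params.
#' @export
crqa_run <- function(x, y, params) {
  n <- min(length(x), length(y))
  xe <- embed_series(x[seq_len(n)], params$delay, params$dim)
  ye <- embed_series(y[seq_len(n)], params$delay, params$dim)
  m <- cpp_crqa_measures(xe, ye, params$radius,
                         as.integer(params$min_diag %||% 2L),
                         as.integer(params$min_vert %||% 2L))
  m$diag_hist <- m$diag_hist[-1L]  # drop length-0 slot
  m$vert_hist <- m$vert_hist[-1L]
  m$params <- params
  class(m) <- "crqa_result"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.crqa_result <- function(x, ...) {
  cat(sprintf("<crqa_result: RR = %.4f, DET = %.4f, LAM = %.4f (delay %d, dim %d, radius %.4g)>\n",
              x$RR, x$DET, x$LAM, x$params$delay, x$params$dim,
              x$params$radius))
  invisible(x)
}

#' Delay selection by average mutual information
#'
#' Histogram-based mutual information between the series and its lagged copy;
#' the selected delay is the first local minimum (capped).
#'
#' @param x numeric series.
#' @param max_delay cap in samples (40 = 5 s at 8 Hz).
#' @param bins histogram bins.
#' @return Integer delay.
#' @export
select_delay_ami <- function(x, max_delay = 40L, bins = 16L) {
  n <- length(x)
  max_delay <- min(max_delay, n - 10L)
  brk <- seq(min(x), max(x), length.out = bins + 1L)
  cut_idx <- findInterval(x, brk, all.inside = TRUE)
  ami <- vapply(seq_len(max_delay), function(lag) {
    a <- cut_idx[1:(n - lag)]; b <- cut_idx[(1 + lag):n]
    joint <- table(a, b) / (n - lag)
    px <- rowSums(joint); py <- colSums(joint)
    nz <- joint > 0
    sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
  }, numeric(1L))
  for (lag in 2:(max_delay - 1L))
    if (ami[lag] < ami[lag - 1L] && ami[lag] <= ami[lag + 1L])
      return(lag)
  which.min(ami)
}

#' Embedding dimension by false nearest neighbours
#'
#' Smallest dimension whose false-nearest-neighbour fraction (Kennel
#' criterion) drops below `threshold`, capped at `max_dim`.
#'
#' @param x numeric series.
#' @param delay embedding delay, samples.
#' @param max_dim dimension cap.
#' @param rtol relative distance-growth tolerance.
#' @param threshold acceptable FNN fraction.
#' @return Integer dimension.
#' @export
select_embedding_fnn <- function(x, delay, max_dim = 10L, rtol = 10,
                                 threshold = 0.1) {
  frac <- cpp_fnn(as.numeric(x), as.integer(delay), as.integer(max_dim), rtol)
  ok <- which(!is.na(frac) & frac < threshold)
  if (length(ok)) ok[1L] else max_dim
}

#' Select CRQA parameters targeting a recurrence-rate band
#'
#' Delay is the larger of the two series' first AMI minima (capped at
#' `max_delay`); embedding dimension the larger of the two FNN choices (capped
#' at `max_dim`); the radius is then found by bisection so that the recurrence
#' rate falls inside `target_rr` (RR is monotone non-decreasing in the
#' radius). Fails with diagnostics when the target cannot be bracketed.
#'
#' @param x,y prepared series (see [prepare_series()]).
#' @param target_rr acceptable recurrence-rate range, proportions.
#' @param max_delay,max_dim caps on delay (samples) and dimension.
#' @param fnn_threshold acceptable false-nearest-neighbour fraction.
#' @param min_diag,min_vert minimum line lengths for DET/LAM.
#' @param max_iter bisection iteration cap.
#' @return List of class `crqa_params`: delay, dim, radius, min_diag,
#'   min_vert, achieved_rr.
#' @export
optimize_parameters <- function(x, y, target_rr = c(0.02, 0.04),
                                max_delay = 40L, max_dim = 10L,
                                fnn_threshold = 0.1,
                                min_diag = 2L, min_vert = 2L,
                                max_iter = 60L) {
  n <- min(length(x), length(y))
  x <- x[seq_len(n)]; y <- y[seq_len(n)]
  delay <- max(select_delay_ami(x, max_delay), select_delay_ami(y, max_delay))
  dim <- max(select_embedding_fnn(x, delay, max_dim, threshold = fnn_threshold),
             select_embedding_fnn(y, delay, max_dim, threshold = fnn_threshold))
  xe <- embed_series(x, delay, dim)
  ye <- embed_series(y, delay, dim)
  npairs <- as.double(nrow(xe)) * nrow(ye)
  rr_at <- function(r) cpp_count_recurrent(xe, ye, r) / npairs
  # seed the search at the subsampled distance quantile matching the band
  # centre, then bisect; RR is monotone non-decreasing in the radius
  guess <- cpp_dist_quantile(xe, ye, mean(target_rr), 200000L)
  lo <- 0; hi <- sqrt(dim) * (max(c(x, y)) - min(c(x, y)))
  rr_hi <- rr_at(hi)
  if (rr_hi < target_rr[1])
    stop(sprintf("cannot reach target recurrence rate: RR at max radius = %.4g",
                 rr_hi), call. = FALSE)
  radius <- NA_real_; achieved <- NA_real_
  mid <- min(max(guess, 1e-12), hi)
  for (i in seq_len(max_iter)) {
    rr <- rr_at(mid)
    if (rr >= target_rr[1] && rr <= target_rr[2]) {
      radius <- mid; achieved <- rr; break
    }
    if (rr < target_rr[1]) lo <- mid else hi <- mid
    mid <- (lo + hi) / 2
  }
  if (is.na(radius))
    stop(sprintf(paste0("radius bisection failed to enter [%.3g, %.3g] after ",
                        "%d iterations (last RR %.4g); series may be degenerate"),
                 target_rr[1], target_rr[2], max_iter, rr), call. = FALSE)
  structure(list(delay = delay, dim = dim, radius = radius,
                 min_diag = min_diag, min_vert = min_vert,
                 achieved_rr = achieved),
            class = "crqa_params")
}

#' Exponential transform and standardisation of synchrony metrics
#'
#' DET/LAM proportions are left-skewed across dyads; exponentiating before
#' z-scoring corrects the skew. Operates on proportions in \[0, 1\].
#'
#' @param values DET (or LAM) proportions across dyads (`NA` allowed).
#' @return z-scores of `exp(values)` (NA preserved).
#' @export
transform_synchrony_metrics <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 3L)
    stop("need at least 3 dyads with defined values to standardise",
         call. = FALSE)
  t <- exp(values)
  (t - mean(t[ok])) / sd(t[ok])
}

#' Physiological synchrony of the analysed dyads in a session
#'
#' Runs the full CRQA chain (prepare, parameter selection, streamed measures)
#' on the demonstrator/observer EDA of the requested blocks (blocks 1 and 2
#' carry the dyads whose observers later demonstrate).
#'
#' @param session a `dyad_session` with EDA recordings.
#' @param blocks block indices to analyse.
#' @param ... passed to [optimize_parameters()].
#' @return data.table: session, block, demonstrator, observer, RR, DET, LAM,
#'   delay, dim, radius.
#' @export
physiological_synchrony <- function(session, blocks = 1:2, ...) {
  man <- session$manifest
  rows <- lapply(blocks, function(k) {
    blk <- session$blocks[[k]]
    if (is.null(blk$eda)) return(NULL)
    x <- prepare_series(blk$eda$dem)
    y <- prepare_series(blk$eda$obs)
    pars <- optimize_parameters(x, y, ...)
    res <- crqa_run(x, y, pars)
    binfo <- man$blocks[man$blocks$block == k, ]
    data.table::data.table(
      session = man$session_id, block = k,
      demonstrator = as.character(binfo$demonstrator_id),
      observer = as.character(binfo$observer_id),
      RR = res$RR, DET = res$DET, LAM = res$LAM,
      delay = pars$delay, dim = pars$dim, radius = pars$radius)
  })
  data.table::rbindlist(rows)
}
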