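# Shared fixtures: compressed trial timing and reduced sampling rates keep the
# signal-level tests quick while exercising the same code paths as the
# full-scale configuration.

short_timing <- list(fixation = 2, cue = 4, expectancy = 3, iti1 = c(3, 4),
                     heat = 2, post_heat = 3, rating = 2, iti2 = 4, tail = 8)

fast_config <- function(...) {
  generator_config(sampling_rate = 200, au_fps = 30, timing = short_timing,
                   ...)
}

ratings_config <- function(...) {
  generator_config(generate_signals = FALSE, ...)
}

# Independent naive cross-recurrence oracle: full distance matrix, explicit
# run scans. Deliberately written with plain loops, separate from the package
# implementation.
naive_crqa <- function(x, y, delay, dim, radius, lmin = 2, vmin = 2) {
  npx <- length(x) - (dim - 1) * delay
  npy <- length(y) - (dim - 1) * delay
  R <- matrix(0L, npx, npy)
  for (i in seq_len(npx)) {
    for (j in seq_len(npy)) {
      s <- 0
      for (k in seq_len(dim)) {
        d <- x[i + (k - 1) * delay] - y[j + (k - 1) * delay]
        s <- s + d * d
      }
      if (sqrt(s) <= radius) R[i, j] <- 1L
    }
  }
  ones <- sum(R)
  diag_runs <- c()
  for (off in (-(npx - 1)):(npy - 1)) {
    run <- 0
    i <- max(1, 1 - off); j <- i + off
    while (i <= npx && j <= npy) {
      if (R[i, j] == 1L) run <- run + 1
      else { if (run > 0) diag_runs <- c(diag_runs, run); run <- 0 }
      i <- i + 1; j <- j + 1
    }
    if (run > 0) diag_runs <- c(diag_runs, run)
  }
  vert_runs <- c()
  for (j in seq_len(npy)) {
    run <- 0
    for (i in seq_len(npx)) {
      if (R[i, j] == 1L) run <- run + 1
      else { if (run > 0) vert_runs <- c(vert_runs, run); run <- 0 }
    }
    if (run > 0) vert_runs <- c(vert_runs, run)
  }
  list(R = R,
       RR = ones / (npx * npy),
       DET = if (ones > 0) sum(diag_runs[diag_runs >= lmin]) / ones
             else NA_real_,
       LAM = if (ones > 0) sum(vert_runs[vert_runs >= vmin]) / ones
             else NA_real_)
}

sample_skewness <- function(v) {
  m <- mean(v)
  mean((v - m)^3) / (mean((v - m)^2))^1.5
}
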