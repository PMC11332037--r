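# Trial-level psychological synchrony, the Monte-Carlo permutation responder
# classifier, and the responder-proportion contingency test.

#' Psychological synchrony of a dyad
#'
#' Product-moment correlation between the demonstrator's and the observer's
#' trial-level expectancy ratings; trials with either rating missing are
#' dropped pairwise. Dyads with fewer than 3 usable pairs or zero variance in
#' either member get a missing score and are excluded downstream.
#'
#' @param dem_expectancies,obs_expectancies numeric vectors, one per trial.
#' @param method correlation type ("pearson"; "spearman" available).
#' @return List: `r`, `n_trials_used`.
#' @export
psychological_synchrony <- function(dem_expectancies, obs_expectancies,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(dem_expectancies) == length(obs_expectancies))
  ok <- !is.na(dem_expectancies) & !is.na(obs_expectancies)
  n <- sum(ok)
  if (n < 3L || sd(dem_expectancies[ok]) == 0 || sd(obs_expectancies[ok]) == 0)
    return(list(r = NA_real_, n_trials_used = n))
  list(r = cor(dem_expectancies[ok], obs_expectancies[ok], method = method),
       n_trials_used = n)
}

combo_cache <- new.env(parent = emptyenv())

# All C(n, n_tx) relabelings as an n_combos x n logical matrix (Tx positions).
tx_relabelings <- function(n, n_tx) {
  key <- sprintf("c%d_%d", n, n_tx)
  if (!is.null(combo_cache[[key]])) return(combo_cache[[key]])
  combs <- utils::combn(n, n_tx)
  m <- matrix(FALSE, nrow = ncol(combs), ncol = n)
  m[cbind(rep(seq_len(ncol(combs)), each = n_tx), as.vector(combs))] <- TRUE
  combo_cache[[key]] <- m
  m
}

#' Permutation-based responder classification
#'
#' The statistic is the observed nocebo response, mean(Tx) - mean(NT) pain.
#' The null distribution relabels the ratings preserving the 6/6 cue split:
#' either `n_perm` Monte-Carlo draws (add-one p-value estimator, never exactly
#' zero) or exact enumeration of all C(12, 6) = 924 relabelings. A response in
#' the upper 95% of the null classifies the subject as a responder; the
#' symmetric lower tail marks reverse-responders; ties count toward the null.
#'
#' @param pain_ratings numeric pain ratings.
#' @param cue_labels "Tx"/"NT" labels, one per rating.
#' @param n_perm Monte-Carlo permutations (ignored for `exact = TRUE`).
#' @param seed optional RNG seed.
#' @param exact enumerate all relabelings instead of sampling?
#' @param alpha one-sided classification level.
#' @return List of class `responder_result`: observed_diff, p_upper, p_lower,
#'   class, n_perm.
#' @export
classify_responder <- function(pain_ratings, cue_labels, n_perm = 10000L,
                               seed = NULL, exact = FALSE, alpha = 0.05) {
  keep <- !is.na(pain_ratings)
  pain_ratings <- pain_ratings[keep]
  cue_labels <- cue_labels[keep]
  n <- length(pain_ratings)
  n_tx <- sum(cue_labels == "Tx")
  if (n < 12L)
    warning(sprintf("classifying from %d ratings (12 expected)", n))
  if (n_tx == 0L || n_tx == n)
    stop("need ratings under both cues to classify", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  obs <- mean(pain_ratings[cue_labels == "Tx"]) -
    mean(pain_ratings[cue_labels == "NT"])
  # ties count toward the null; the tolerance absorbs floating-point jitter
  # between the observed statistic and its own relabeling in the null set
  tol <- 1e-9 * (max(abs(pain_ratings)) + 1)
  if (exact) {
    lab <- tx_relabelings(n, n_tx)
    null <- as.numeric(lab %*% pain_ratings) / n_tx -
      as.numeric((!lab) %*% pain_ratings) / (n - n_tx)
    p_upper <- mean(null >= obs - tol)
    p_lower <- mean(null <= obs + tol)
    n_used <- nrow(lab)
  } else {
    null <- cpp_perm_null(pain_ratings, n_tx, as.integer(n_perm))
    p_upper <- (1 + sum(null >= obs - tol)) / (1 + n_perm)
    p_lower <- (1 + sum(null <= obs + tol)) / (1 + n_perm)
    n_used <- n_perm
  }
  cls <- if (p_upper <= alpha) "responder"
         else if (p_lower <= alpha) "reverse_responder"
         else "non_responder"
  structure(list(observed_diff = obs, p_upper = p_upper, p_lower = p_lower,
                 class = cls, n_perm = n_used),
            class = "responder_result")
}

#' @export
print.responder_result <- function(x, ...) {
  cat(sprintf("<responder_result: diff = %.2f, p_upper = %.4f, class = %s>\n",
              x$observed_diff, x$p_upper, x$class))
  invisible(x)
}

#' Responder-proportion contingency test
#'
#' Pearson chi-square without continuity correction on a 2x2
#' generation-by-responder-status table, with Cramer's V = sqrt(chi2 / N).
#'
#' @param counts 2x2 matrix of non-negative integer counts.
#' @return List: chisq, df, p, cramers_v, n.
#' @export
responder_proportions_test <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("contingency table has a zero marginal", call. = FALSE)
  n <- sum(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / n
  chisq <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  list(chisq = chisq, df = df, p = pchisq(chisq, df, lower.tail = FALSE),
       cramers_v = sqrt(chisq / (n * (min(dim(counts)) - 1L))), n = n)
}
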