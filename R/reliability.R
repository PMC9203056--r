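#' Spearman-Brown prophecy correction
#'
#' Maps a half-test correlation to full-length reliability:
#' r' = 2r / (1 + r). Undefined at r = -1.
#'
#' @param r correlation in \[-1, 1\].
#' @return corrected reliability.
#' @export
spearmanBrown <- function(r) {
  if (any(r < -1 | r > 1, na.rm = TRUE))
    stop("r must lie in [-1, 1]", call. = FALSE)
  if (any(r == -1, na.rm = TRUE))
    stop("Spearman-Brown correction undefined at r = -1", call. = FALSE)
  2 * r / (1 + r)
}

#' Permutation split-half reliability
#'
#' For each permutation, splits every participant's trials into two random
#' halves (sizes floor(n/2) and ceiling(n/2)), takes the mean of each half,
#' correlates the half-means across participants and applies the
#' Spearman-Brown correction. The summary is the mean, sd and 2.5/97.5
#' percentiles of the corrected correlations over permutations. Negative
#' corrected values are reported as-is with a flag, never truncated.
#'
#' @param values numeric vector of per-trial values.
#' @param participant vector of participant ids aligned with `values`.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed for reproducibility.
#' @param method correlation method across participants (`"pearson"`
#'   default, `"spearman"` available).
#' @param metric label stored in the result.
#' @return a list of class `reliability_estimate`: `metric`, `r_mean`,
#'   `r_sd`, `ci` (2.5th, 97.5th percentiles), `n_perm`, `n_trials_used`,
#'   `n_participants`, `n_excluded`, `negative_flag`.
#' @export
splitHalf <- function(values, participant, n_perm = 10000, seed = NULL,
                      method = c("pearson", "spearman"),
                      metric = "value") {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  ok <- !is.na(values)
  byp <- split(values[ok], participant[ok])
  small <- vapply(byp, length, integer(1)) < 2L
  if (any(small))
    message(sprintf("excluding %d participant(s) with < 2 trials",
                    sum(small)))
  byp <- byp[!small]
  if (length(byp) < 3L)
    stop("need at least 3 participants with >= 2 trials", call. = FALSE)
  ns <- vapply(byp, length, integer(1))
  half <- ns %/% 2L
  rs <- vapply(seq_len(n_perm), function(p) {
    h <- vapply(seq_along(byp), function(j) {
      idx <- sample.int(ns[j])
      v <- byp[[j]]
      c(mean(v[idx[seq_len(half[j])]]),
        mean(v[idx[(half[j] + 1L):ns[j]]]))
    }, numeric(2))
    stats::cor(h[1, ], h[2, ], method = method)
  }, numeric(1))
  rc <- spearmanBrown(pmax(rs, -1 + 1e-12))
  structure(list(metric = metric,
                 r_mean = mean(rc), r_sd = stats::sd(rc),
                 ci = unname(stats::quantile(rc, c(0.025, 0.975))),
                 n_perm = n_perm, n_trials_used = sum(ns),
                 n_participants = length(byp),
                 n_excluded = sum(small),
                 negative_flag = any(rc < 0)),
            class = "reliability_estimate")
}

#' @export
print.reliability_estimate <- function(x, ...) {
  cat(sprintf(paste0("Split-half reliability [%s]: %.3f (sd %.3f, ",
                     "95%% CI %.3f-%.3f)\n  %d permutations, %d trials, ",
                     "%d participants\n"),
              x$metric, x$r_mean, x$r_sd, x$ci[1], x$ci[2],
              x$n_perm, x$n_trials_used, x$n_participants))
  invisible(x)
}

#' Reliability-versus-trial-count titration
#'
#' Repeats the split-half analysis at increasing trial counts k: at each k,
#' keeps only participants with at least k trials, subsamples exactly k
#' trials per participant without replacement, and runs the permutation
#' split-half (one fresh subsample per permutation). The curve is truncated
#' when fewer than 3 participants remain eligible.
#'
#' @param values numeric vector of per-trial values.
#' @param participant aligned participant ids.
#' @param k_min smallest trial count (default 6).
#' @param k_max largest trial count (default: largest k with >= 3 eligible
#'   participants).
#' @param n_reps permutations per trial count (default 1000).
#' @param seed RNG seed.
#' @param method correlation method, see [splitHalf()].
#' @return data.frame with `k`, `n_participants`, `r_mean`, `r_sd`,
#'   `ci_low`, `ci_high`.
#' @export
titration <- function(values, participant, k_min = 6, k_max = NULL,
                      n_reps = 1000, seed = NULL,
                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  ok <- !is.na(values)
  byp <- split(values[ok], participant[ok])
  ns <- vapply(byp, length, integer(1))
  if (is.null(k_max)) {
    k_max <- max(ns[rank(-ns, ties.method = "first") <= 3])
  }
  rows <- list()
  for (k in k_min:k_max) {
    elig <- byp[ns >= k]
    if (length(elig) < 3L) break
    half <- k %/% 2L
    rs <- vapply(seq_len(n_reps), function(p) {
      h <- vapply(elig, function(v) {
        idx <- sample.int(length(v), k)   # subsample, then split
        c(mean(v[idx[seq_len(half)]]),
          mean(v[idx[(half + 1L):k]]))
      }, numeric(2))
      stats::cor(h[1, ], h[2, ], method = method)
    }, numeric(1))
    rc <- spearmanBrown(pmax(rs, -1 + 1e-12))
    rows[[length(rows) + 1L]] <- data.frame(
      k = k, n_participants = length(elig),
      r_mean = mean(rc), r_sd = stats::sd(rc),
      ci_low = unname(stats::quantile(rc, 0.025)),
      ci_high = unname(stats::quantile(rc, 0.975)))
  }
  do.call(rbind, rows)
}
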