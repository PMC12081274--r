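# Significance of dPWM scores: exact small-motif oracle and importance sampling.
#
# Null model: the (2*flank+1)-bp window is drawn iid from a zeroth-order
# background; the center base is substituted by one of the 3 other bases,
# uniformly. The statistic is delta = ref_best - alt_best with both alleles
# scored as in score_alleles (max over motif subwindows covering the center,
# both strands). The null does not depend on the observed variant, so one
# null sample serves every observed delta for a given (pwm, background, flank).

# Per-component subwindow scores of a code matrix. Returns list with
# `scores`: n x K matrix (K = 2 * n_offsets, plus-strand components first),
# `offsets`, `strands`, `j0` (motif column covering the window center, per
# component).
component_scores <- function(windows, pwm) {
  w <- ncol(windows)
  L <- pwm$length
  center <- (w + 1L) %/% 2L
  offs <- center_offsets(w, L)
  if (!length(offs)) stop("no motif subwindow can cover the center: flank too small")
  mats <- list(`+` = pwm$log_odds, `-` = reverse_complement_pwm(pwm)$log_odds)
  n <- nrow(windows)
  K <- 2L * length(offs)
  scores <- matrix(NA_real_, n, K)
  strands <- character(K)
  offsets <- integer(K)
  k <- 0L
  for (strand in names(mats)) {
    W <- mats[[strand]]
    for (s in offs) {
      k <- k + 1L
      sc <- rep(0, n)
      for (j in seq_len(L)) sc <- sc + W[cbind(windows[, s + j - 1L], j)]
      scores[, k] <- sc
      strands[k] <- strand
      offsets[k] <- s
    }
  }
  list(scores = scores, offsets = offsets, strands = strands,
       j0 = center - offsets + 1L, center = center)
}

# ref_best and alt_best (per alt code) from component scores.
best_from_components <- function(cs, windows, alt_codes, pwm) {
  mats <- list(`+` = pwm$log_odds, `-` = reverse_complement_pwm(pwm)$log_odds)
  cc <- windows[, cs$center]
  ref_best <- do.call(pmax, c(asplit(cs$scores, 2), list(na.rm = TRUE)))
  alt_best <- rep(-Inf, nrow(windows))
  for (k in seq_along(cs$offsets)) {
    W <- mats[[cs$strands[k]]]
    j0 <- cs$j0[k]
    altsc <- cs$scores[, k] + (W[cbind(alt_codes, j0)] - W[cbind(cc, j0)])
    alt_best <- pmax(alt_best, altsc, na.rm = TRUE)
  }
  list(ref_best = ref_best, alt_best = alt_best)
}

enumerate_windows <- function(w) {
  n <- 4^w
  if (n > 4^10) {
    stop("window length ", w, " exceeds the exact-enumeration bound (4^w windows, w <= 10)")
  }
  idx <- seq_len(n) - 1
  codes <- matrix(0L, n, w)
  for (j in seq_len(w)) {
    codes[, j] <- as.integer((idx %/% 4^(w - j)) %% 4) + 1L
  }
  codes
}

#' Exact tail probability of the dPWM change statistic (small motifs)
#'
#' Enumerates every background window and every center substitution and sums
#' their probabilities in the tail of the observed delta: `P(delta >=
#' delta_obs)` when `delta_obs > 0` (loss direction), `P(delta <= delta_obs)`
#' when `delta_obs <= 0` (gain direction). Feasible only for small motifs and
#' flanks (at most 4^10 windows, i.e. flank <= 4); intended as the oracle for
#' [importance_sampling_pvalue()].
#'
#' @param delta_obs observed delta (bits); vectorized.
#' @param pwm a `cbs_pwm`.
#' @param background null base composition (default: the PWM's background).
#' @param flank flanking bases on each side of the substituted position.
#' @return numeric vector of exact one-sided p-values.
#' @export
exact_change_pvalue <- function(delta_obs, pwm, background = NULL, flank = 3) {
  stopifnot(inherits(pwm, "cbs_pwm"))
  background <- check_background(background %||% pwm$background)
  w <- 2L * as.integer(flank) + 1L
  if (w < pwm$length) stop("window shorter than motif: increase flank")
  windows <- enumerate_windows(w)
  lp <- rowSums(matrix(log(background)[windows], nrow(windows), w))
  pw <- exp(lp)
  cs <- component_scores(windows, pwm)
  cc <- windows[, cs$center]
  deltas <- numeric(0)
  masses <- numeric(0)
  for (shift in 1:3) {
    alt <- ((cc - 1L + shift) %% 4L) + 1L
    best <- best_from_components(cs, windows, alt, pwm)
    deltas <- c(deltas, best$ref_best - best$alt_best)
    masses <- c(masses, pw / 3)
  }
  vapply(delta_obs, function(d) {
    if (d > 0) sum(masses[deltas >= d]) else sum(masses[deltas <= d])
  }, numeric(1))
}

#' Draw an importance sample of the dPWM null
#'
#' The proposal is a mixture of (a) the background model and (b) the motif
#' emission model embedded at a uniformly chosen valid offset and strand,
#' with remaining positions drawn from the background. Because the motif
#' component's density ratio against the background is `2^score` of the
#' embedded subwindow, importance weights are computed from the same
#' component scores used for the statistic itself.
#'
#' @param pwm a `cbs_pwm`.
#' @param background null base composition (default: the PWM's background).
#' @param flank flanking bases each side of the center (default 14).
#' @param n_samples number of draws (>= 1000).
#' @param seed integer seed; the sample is a pure function of it.
#' @param mixture weight of the background component in the proposal
#'   (default 0.5).
#' @return object of class `cbs_delta_null`: list with `delta`, `weight`
#'   (mean 1 in expectation), `n_samples`, `flank`, `motif_id`.
#' @export
delta_null_sample <- function(pwm, background = NULL, flank = 14, n_samples = 1e5,
                              seed = 1, mixture = 0.5) {
  stopifnot(inherits(pwm, "cbs_pwm"))
  stopifnot(n_samples >= 1000, mixture > 0, mixture < 1)
  background <- check_background(background %||% pwm$background)
  w <- 2L * as.integer(flank) + 1L
  if (w < pwm$length) stop("window shorter than motif: increase flank")
  L <- pwm$length
  center <- flank + 1L
  offs <- center_offsets(w, L)
  K <- 2L * length(offs)
  emis <- list(`+` = pwm$probs, `-` = reverse_complement_pwm(pwm)$probs)
  n <- as.integer(n_samples)
  withr::with_seed(seed, {
    comp <- ifelse(stats::runif(n) < mixture, 0L, sample.int(K, n, replace = TRUE))
    windows <- matrix(0L, n, w)
    comp_strand <- rep(names(emis), each = length(offs))
    comp_offset <- rep(offs, times = 2L)
    for (cid in 0:K) {
      rows <- which(comp == cid)
      if (!length(rows)) next
      for (j in seq_len(w)) {
        if (cid == 0L) {
          prob <- background
        } else {
          s <- comp_offset[cid]
          prob <- if (j >= s && j < s + L) emis[[comp_strand[cid]]][, j - s + 1L] else background
        }
        windows[rows, j] <- sample.int(4L, length(rows), replace = TRUE, prob = prob)
      }
    }
    cc <- windows[, center]
    alt <- ((cc - 1L + sample.int(3L, n, replace = TRUE)) %% 4L) + 1L
  })
  cs <- component_scores(windows, pwm)
  # density ratio q(x)/bg(x) = mixture + (1 - mixture)/K * sum_k r_k(x) with
  # r_k(x) = prod over motif positions of emission/background. Computed from
  # the emission matrices directly: the score-based shortcut 2^score only
  # holds on the plus strand (minus-strand log-odds divide by the
  # complementary base's background).
  lbg <- log(background)
  ratio_sum <- numeric(n)
  k <- 0L
  for (strand in names(emis)) {
    P <- emis[[strand]]
    for (s in offs) {
      k <- k + 1L
      lr <- numeric(n)
      for (j in seq_len(L)) {
        col <- windows[, s + j - 1L]
        lr <- lr + log(P[cbind(col, j)]) - lbg[col]
      }
      ratio_sum <- ratio_sum + exp(lr)
    }
  }
  ratio <- mixture + (1 - mixture) / K * ratio_sum
  weight <- 1 / ratio
  best <- best_from_components(cs, windows, alt, pwm)
  structure(
    list(
      delta = best$ref_best - best$alt_best,
      weight = weight,
      n_samples = n,
      flank = as.integer(flank),
      motif_id = pwm$motif_id,
      mixture = mixture,
      seed = seed
    ),
    class = "cbs_delta_null"
  )
}

#' Evaluate importance-sampling tail probabilities for observed deltas
#'
#' @param null a `cbs_delta_null` from [delta_null_sample()].
#' @param delta_obs numeric vector of observed deltas (bits).
#' @return tibble with `delta_obs`, `p_value` (clamped to [0, 1]), `se`
#'   (standard error of the unclamped estimate).
#' @export
delta_null_tail <- function(null, delta_obs) {
  stopifnot(inherits(null, "cbs_delta_null"))
  n <- null$n_samples
  ord <- order(null$delta)
  d_sorted <- null$delta[ord]
  w_sorted <- null$weight[ord]
  # suffix/prefix sums for O(log n) tail evaluation per observed delta
  cw <- cumsum(w_sorted)
  cw2 <- cumsum(w_sorted^2)
  total_w <- cw[n]
  total_w2 <- cw2[n]
  res <- vapply(delta_obs, function(d) {
    if (d > 0) {
      # P(delta >= d): draws with sorted index > findInterval(d-, ...)
      i <- findInterval(d, d_sorted, left.open = TRUE)  # count of delta < d
      sw <- total_w - (if (i > 0) cw[i] else 0)
      sw2 <- total_w2 - (if (i > 0) cw2[i] else 0)
    } else {
      # P(delta <= d)
      i <- findInterval(d, d_sorted)                    # count of delta <= d
      sw <- if (i > 0) cw[i] else 0
      sw2 <- if (i > 0) cw2[i] else 0
    }
    est <- sw / n
    se <- sqrt(pmax(sw2 / n - est^2, 0) / n)
    c(est, se)
  }, numeric(2))
  tibble::tibble(
    delta_obs = delta_obs,
    p_value = clip01(res[1, ]),
    se = res[2, ]
  )
}

#' Importance-sampling p-value for an observed dPWM change
#'
#' Estimates the same one-sided tail probability as [exact_change_pvalue()]
#' by importance sampling. The null sample is a pure function of
#' (pwm, background, flank, n_samples, seed); pass a precomputed `null` to
#' score many observed deltas against one sample.
#'
#' @inheritParams delta_null_sample
#' @param delta_obs observed delta(s) (bits).
#' @param null optional precomputed `cbs_delta_null`.
#' @return tibble with `delta_obs`, `p_value`, `se`.
#' @export
importance_sampling_pvalue <- function(delta_obs, pwm = NULL, background = NULL,
                                       flank = 14, n_samples = 1e5, seed = 1,
                                       mixture = 0.5, null = NULL) {
  if (is.null(null)) {
    null <- delta_null_sample(pwm, background, flank, n_samples, seed, mixture)
  }
  delta_null_tail(null, delta_obs)
}
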