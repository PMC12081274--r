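# Quantile-stratified summaries: threshold proportions with bootstrap CIs,
# per-quantile means, correlations, group comparisons, count summaries.

#' Proportion of values at or above a threshold
#'
#' "Conserved" / "pathogenic" calls use `>=` (a value exactly at the
#' threshold counts).
#'
#' @param values numeric vector (non-empty; NAs dropped with a tally message).
#' @param threshold numeric scalar.
#' @return fraction in [0, 1].
#' @export
proportion_above <- function(values, threshold) {
  miss <- sum(is.na(values))
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no non-missing values")
  if (miss > 0) message(miss, " missing value(s) excluded from proportion")
  mean(values >= threshold)
}

#' Bootstrap mean and percentile CI of a thresholded proportion
#'
#' Runs `iterations` independent iterations of `B` bootstrap resamples of
#' size n from the 0/1 indicator `values >= threshold`; the resampled
#' success count is Binomial(n, phat), which is drawn directly. The reported
#' mean is the average of per-iteration means and the 95% CI the 2.5/97.5
#' percentiles of the pooled resampled proportions.
#'
#' @param values numeric vector.
#' @param threshold numeric scalar.
#' @param B resamples per iteration (default 10000, >= 100).
#' @param iterations number of iterations (default 10).
#' @param seed integer seed (the result is a pure function of it).
#' @return list with `mean`, `ci_low`, `ci_high`, `n`.
#' @export
bootstrap_proportion <- function(values, threshold, B = 10000, iterations = 10,
                                 seed = 1) {
  stopifnot(B >= 100, iterations >= 1)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) stop("no non-missing values")
  phat <- mean(values >= threshold)
  withr::with_seed(seed, {
    props <- matrix(stats::rbinom(B * iterations, n, phat) / n, nrow = B)
  })
  list(
    mean = mean(colMeans(props)),
    ci_low = unname(stats::quantile(props, 0.025, type = 7)),
    ci_high = unname(stats::quantile(props, 0.975, type = 7)),
    n = n
  )
}

#' Per-quantile mean of a statistic
#'
#' @param df tibble with a `quantile` column and the value column.
#' @param value name of the value column.
#' @return tibble `quantile`, `n`, `statistic` (mean), sorted by quantile;
#'   empty quantiles are absent.
#' @export
per_quantile_mean <- function(df, value) {
  stopifnot("quantile" %in% names(df), value %in% names(df))
  df |>
    dplyr::group_by(.data$quantile) |>
    dplyr::summarise(
      n = dplyr::n(),
      statistic = mean(.data[[value]], na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$quantile)
}

#' Correlation with significance
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r` and `p_value` (two-sided).
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero-variance input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Two-sample t-test on group proportions
#'
#' Compares per-quantile (or per-iteration) proportion samples between two
#' groups with a two-sided two-sample Student's t-test (equal variances).
#'
#' @param a,b numeric vectors (each length >= 2).
#' @return list with `t`, `p_value`, `mean_a`, `mean_b`. Degenerate zero
#'   variance in both groups with equal means yields `t = 0`, `p = 1`; with
#'   unequal means, a non-finite `t` and `p = 0` with an explanatory message.
#' @export
compare_group_proportions <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(list(t = 0, p_value = 1, mean_a = mean(a), mean_b = mean(b)))
    }
    message("zero variance in both groups with unequal means: t is infinite")
    return(list(t = sign(mean(a) - mean(b)) * Inf, p_value = 0,
                mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean_a = mean(a), mean_b = mean(b))
}

#' Count summaries of the CBS catalog and variant set
#'
#' @param motifs motif tibble (`chrom`, `start`, `end`).
#' @param rdhs rDHS tibble (`rdhs_id`, `chrom`, `start`, `end`).
#' @param variants optional variant tibble with `AC`, `AF`.
#' @return list with `motifs_per_rdhs` (tibble `n_motifs`, `n_rdhs`),
#'   `fraction_motifs_with_rdhs`, and (if variants given) `af_spectrum`
#'   (tibble `bin`, `n`).
#' @export
count_summaries <- function(motifs, rdhs, variants = NULL) {
  check_intervals(motifs)
  check_intervals(rdhs)
  mg <- df_to_granges(motifs)
  rg <- df_to_granges(rdhs)
  per_rdhs <- GenomicRanges::countOverlaps(rg, mg, minoverlap = 1L)
  hist <- tibble::as_tibble(as.data.frame(table(n_motifs = per_rdhs),
                                          stringsAsFactors = FALSE))
  names(hist) <- c("n_motifs", "n_rdhs")
  hist$n_motifs <- as.integer(as.character(hist$n_motifs))
  with_support <- GenomicRanges::countOverlaps(mg, rg, minoverlap = 1L) > 0
  out <- list(
    motifs_per_rdhs = hist,
    fraction_motifs_with_rdhs = if (nrow(motifs)) mean(with_support) else NA_real_,
    fraction_rdhs_with_motif = if (nrow(rdhs)) mean(per_rdhs > 0) else NA_real_
  )
  if (!is.null(variants) && nrow(variants)) {
    bin <- dplyr::case_when(
      variants$AC == 1 ~ "AC=1",
      variants$AC == 2 ~ "AC=2",
      variants$AF < 0.001 ~ "AF<0.1%",
      variants$AF < 0.01 ~ "AF<1%",
      TRUE ~ "AF>=1%"
    )
    lv <- c("AC=1", "AC=2", "AF<0.1%", "AF<1%", "AF>=1%")
    tab <- table(factor(bin, levels = lv))
    out$af_spectrum <- tibble::tibble(bin = lv, n = as.integer(tab))
  }
  out
}
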