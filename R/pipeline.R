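# End-to-end analysis: from raw inputs (or a simulated bundle) to the
# stratified MAPS and enrichment results.

#' Run the full CBS prioritization pipeline
#'
#' Stages: (1) mask and summarize the activity matrix, assign 100-bin
#' quantiles and 10-bin deciles; (2) scan the genome with the PWM, apply the
#' contig/exclusion filters and annotate motifs with activity (max over
#' overlapped rDHSs) — the CBS catalog; (3) QC the variants, intersect them
#' with the catalog, score REF/ALT alleles (dPWM) and attach
#' importance-sampling p-values from a single shared null sample; (4)
#' deduplicate to one row per variant, calibrate MAPS on the synonymous
#' class and compute MAPS per (binding class x confidence x activity
#' decile) stratum; (5) summarize: decile-vs-MAPS correlations, CADD
#' pathogenic proportions, count summaries.
#'
#' @param bundle a `cbs_bundle` (from [simulate_cbs_bundle()]) or a
#'   `cbs_sim_config` (simulated on the fly).
#' @param scan_threshold relative-score threshold for motif discovery
#'   (default 0.8).
#' @param activity_method `"mean"` or `"stouffer_sqrt"`.
#' @param flank flanking bases for allelic scoring (default 14).
#' @param n_is_samples importance-sampling draws for the shared dPWM null.
#' @param alpha confidence threshold on the p-value (strict <, default 0.05).
#' @param dummy_floor truncated-p dummy value (default 1e-7).
#' @param min_AN strict allele-number QC bound (default 76000).
#' @param cadd_cutoff scaled-CADD pathogenicity cutoff (default 10).
#' @param min_stratum_n strata below this size are flagged wide-uncertainty.
#' @param seed seed for the importance-sampling null.
#' @return list of class `cbs_pipeline_result` with elements `rdhs_scores`,
#'   `cbs_catalog`, `scored_variants`, `maps_model`, `maps_by_stratum`,
#'   `maps_calibration_self`, `decile_maps_correlation`, `cadd_by_decile`,
#'   `counts`, `n_is_samples`, and the filter tallies.
#' @export
run_cbs_pipeline <- function(bundle,
                             scan_threshold = 0.8,
                             activity_method = "mean",
                             flank = 14,
                             n_is_samples = 5e4,
                             alpha = 0.05,
                             dummy_floor = 1e-7,
                             min_AN = 76000,
                             cadd_cutoff = 10,
                             min_stratum_n = 200,
                             seed = 1) {
  if (inherits(bundle, "cbs_sim_config")) bundle <- simulate_cbs_bundle(bundle)
  stopifnot(inherits(bundle, "cbs_bundle"))

  # -- activity annotation ---------------------------------------------------
  mat <- bundle$activity_matrix
  scores <- summarize_activity(mat, method = activity_method)
  q100 <- assign_activity_quantiles(scores, k = min(100, sum(!is.na(scores$activity))))
  q10 <- assign_activity_quantiles(scores, k = 10)
  rdhs <- bundle$rdhs[, c("rdhs_id", "chrom", "start", "end")]
  rdhs$activity <- scores$activity[match(rdhs$rdhs_id, scores$rdhs_id)]
  rdhs$quantile <- q100$quantile[match(rdhs$rdhs_id, q100$rdhs_id)]
  rdhs$decile <- q10$quantile[match(rdhs$rdhs_id, q10$rdhs_id)]

  # -- CBS catalog -----------------------------------------------------------
  pwm <- pfm_to_pwm(bundle$pfm)
  hits <- scan_genome(bundle$genome, pwm, report_threshold = scan_threshold)
  hits <- filter_motifs(hits, autosomes = bundle$autosomes,
                        exclusions = bundle$exclusions)
  motif_tally <- attr(hits, "removal_tally")
  cbs <- annotate_motifs_with_activity(hits, rdhs)
  cbs$decile <- rdhs$decile[match(cbs$rdhs_id, rdhs$rdhs_id)]

  # -- variant QC + allelic scoring -----------------------------------------
  variants <- filter_variants(bundle$variants, min_AN = min_AN)
  variant_tally <- attr(variants, "removal_counts")
  pairs <- intersect_variants_with_cbs(variants, cbs)
  scored <- score_alleles(pairs, bundle$genome, pwm, flank = flank)
  null <- delta_null_sample(pwm, flank = flank, n_samples = n_is_samples,
                            seed = seed)
  tails <- delta_null_tail(null, scored$delta_pwm)
  scored$p_value <- encode_truncated_pvalues(tails$p_value, dummy_floor)
  scored$p_se <- tails$se
  scored <- flag_confident(scored, alpha = alpha)
  scored <- dedupe_per_variant(scored)

  # -- MAPS ------------------------------------------------------------------
  genome <- bundle$genome
  scored$context3 <- NULL
  scored <- annotate_context(scored, genome)
  calib <- variants[variants$consequence == "synonymous_variant", , drop = FALSE]
  calib$context3 <- NULL
  calib <- annotate_context(calib, genome)
  model <- maps_calibrate(calib, bundle$rates)
  maps_self <- maps_score(calib, model, bundle$rates,
                          class_label = "synonymous_variant")
  strata <- maps_by_stratum(scored, c("binding_class", "confident", "decile"),
                            model, bundle$rates, min_n = min_stratum_n)

  # -- summaries -------------------------------------------------------------
  loss_conf <- strata[strata$binding_class == "loss" & strata$confident, ,
                      drop = FALSE]
  loss_conf <- loss_conf[!is.na(loss_conf$decile), , drop = FALSE]
  corr <- NULL
  if (nrow(loss_conf) >= 3) {
    corr <- list(
      pearson = correlate(loss_conf$decile, loss_conf$maps, "pearson"),
      spearman = correlate(loss_conf$decile, loss_conf$maps, "spearman")
    )
  }
  cadd <- NULL
  if ("cadd_phred" %in% names(scored)) {
    cadd <- scored |>
      dplyr::filter(.data$binding_class == "loss", !is.na(.data$decile)) |>
      dplyr::group_by(.data$confident, .data$decile) |>
      dplyr::summarise(
        n = dplyr::n(),
        prop_pathogenic = proportion_above(.data$cadd_phred, cadd_cutoff),
        .groups = "drop"
      )
  }
  counts <- count_summaries(cbs, rdhs, variants)

  structure(
    list(
      rdhs_scores = rdhs,
      cbs_catalog = cbs,
      scored_variants = scored,
      maps_model = model,
      maps_by_stratum = strata,
      maps_calibration_self = maps_self,
      decile_maps_correlation = corr,
      cadd_by_decile = cadd,
      counts = counts,
      motif_removal_tally = motif_tally,
      variant_removal_counts = variant_tally,
      n_is_samples = n_is_samples
    ),
    class = "cbs_pipeline_result"
  )
}
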