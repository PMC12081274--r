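# Mutability-adjusted proportion of singletons (MAPS).
#
# Raw singleton proportion of a variant class, minus the proportion expected
# from its trinucleotide mutation rates under a model calibrated on a
# neutral (synonymous) class. Positive MAPS indicates a deficit of common
# variants, i.e. negative selection.

#' Annotate variants with their trinucleotide context
#'
#' `context3` is the plus-strand literal genome[pos-1..pos+1] (no collapsing
#' to pyrimidine-centered contexts); the mutation-rate table must use the
#' same convention. Variants at a contig edge are flagged (`context3 = NA`)
#' and excluded from MAPS.
#'
#' @param variants tibble with `chrom`, `pos` (1-based), `ref`.
#' @param genome named character vector / DNAStringSet.
#' @return input with a `context3` column. A REF allele disagreeing with the
#'   genome is a hard error.
#' @export
annotate_context <- function(variants, genome) {
  stopifnot(all(c("chrom", "pos", "ref") %in% names(variants)))
  seqs <- as_genome_strings(genome)
  ctx <- rep(NA_character_, nrow(variants))
  for (chrom in unique(variants$chrom)) {
    if (!chrom %in% names(seqs)) stop("variant chromosome not in genome: ", chrom)
    idx <- which(variants$chrom == chrom)
    len <- nchar(seqs[[chrom]])
    pos <- variants$pos[idx]
    mid <- substring(seqs[[chrom]], pos, pos)
    bad <- mid != variants$ref[idx]
    if (any(bad)) {
      k <- idx[which(bad)[1]]
      stop("REF allele mismatch with genome at ", chrom, ":", variants$pos[k],
           " (genome ", mid[which(bad)[1]], ", variant REF ", variants$ref[k], ")")
    }
    inside <- pos > 1 & pos < len
    if (any(inside)) {
      ctx[idx[inside]] <- substring(seqs[[chrom]], pos[inside] - 1L, pos[inside] + 1L)
    }
  }
  n_edge <- sum(is.na(ctx))
  if (n_edge > 0) message(n_edge, " contig-edge variant(s) flagged; excluded from MAPS")
  variants$context3 <- ctx
  tibble::as_tibble(variants)
}

# keyed merge of per-variant mu; errors on missing (context, alt) rows
merge_mu <- function(variants, rates) {
  stopifnot(all(c("context", "alt", "mu") %in% names(rates)))
  rates <- dplyr::distinct(rates, .data$context, .data$alt, .keep_all = TRUE)
  key <- paste(variants$context3, variants$alt)
  mu <- rates$mu[match(key, paste(rates$context, rates$alt))]
  missing <- is.na(mu) & !is.na(variants$context3)
  if (any(missing)) {
    stop("mutation rate missing for context/alt: ",
         paste(utils::head(unique(key[missing]), 5), collapse = ", "))
  }
  mu
}

#' Calibrate the singleton-proportion model on a neutral variant class
#'
#' Groups the calibration variants (canonically, those whose most severe
#' consequence is `synonymous_variant`) by (trinucleotide context, alt),
#' computes each group's singleton proportion, and fits a weighted least
#' squares regression of proportion on the group's mutation rate `mu`,
#' weighted by group variant counts.
#'
#' @param variants calibration tibble with `context3`, `alt`, `AC`.
#' @param rates mutation-rate tibble (`context`, `ref`, `alt`, `mu`);
#'   (context, alt) keys must be unique — duplicated rows are dropped.
#' @return object of class `cbs_maps_model`: list with `intercept`, `slope`,
#'   `fitted_on`, `n_contexts`, `groups` (per-group tibble).
#' @export
maps_calibrate <- function(variants, rates, fitted_on = "synonymous_variant") {
  stopifnot(all(c("context3", "alt", "AC") %in% names(variants)))
  variants <- variants[!is.na(variants$context3), , drop = FALSE]
  if (nrow(variants) == 0) stop("no calibration variants with trinucleotide context")
  mu <- merge_mu(variants, rates)
  groups <- tibble::tibble(
    context = variants$context3, alt = variants$alt,
    mu = mu, singleton = variants$AC == 1
  ) |>
    dplyr::group_by(.data$context, .data$alt, .data$mu) |>
    dplyr::summarise(
      n = dplyr::n(), proportion = mean(.data$singleton), .groups = "drop"
    )
  if (length(unique(groups$mu)) < 2) {
    stop("calibration requires >= 2 distinct mutation rates")
  }
  fit <- stats::lm(proportion ~ mu, data = groups, weights = groups$n)
  structure(
    list(
      intercept = unname(stats::coef(fit)[1]),
      slope = unname(stats::coef(fit)[2]),
      fitted_on = fitted_on,
      n_contexts = nrow(groups),
      groups = groups
    ),
    class = "cbs_maps_model"
  )
}

#' Expected singleton count of a variant class under the calibrated model
#'
#' Per-variant predictions `intercept + slope * mu`, clipped to [0, 1], are
#' summed. When no clipping occurs this equals `n * (intercept + slope *
#' mean(mu))` by linearity; both are computed and their agreement is
#' asserted, bridging the per-variant and per-bin-average readings of the
#' procedure.
#'
#' @param variants tibble with `context3`, `alt` (NA contexts excluded).
#' @param model a `cbs_maps_model`.
#' @param rates mutation-rate tibble.
#' @return expected singleton count (numeric scalar) with attributes
#'   `n_clipped` and `expected_at_mean_mu`.
#' @export
expected_singletons <- function(variants, model, rates) {
  stopifnot(inherits(model, "cbs_maps_model"))
  variants <- variants[!is.na(variants$context3), , drop = FALSE]
  mu <- merge_mu(variants, rates)
  pred <- model$intercept + model$slope * mu
  n_clipped <- sum(pred < 0 | pred > 1)
  expected <- sum(clip01(pred))
  at_mean <- length(mu) * (model$intercept + model$slope * mean(mu))
  if (n_clipped == 0 && length(mu) > 0) {
    stopifnot(isTRUE(all.equal(expected, at_mean, tolerance = 1e-9)))
  }
  structure(expected, n_clipped = n_clipped, expected_at_mean_mu = at_mean)
}

#' MAPS score of a variant class
#'
#' `maps = raw_proportion - expected_proportion`, where the raw proportion is
#' `n_singletons / n_variants` (singleton: AC = 1) and the expected
#' proportion comes from [expected_singletons()]. The standard error is the
#' binomial `sqrt(p (1 - p) / n)` of the raw proportion.
#'
#' @param variants tibble with `context3`, `alt`, `AC`.
#' @param model a `cbs_maps_model`.
#' @param rates mutation-rate tibble.
#' @param class_label label recorded in the result.
#' @return one-row tibble: `class_label`, `n_variants`, `n_singletons`,
#'   `raw_proportion`, `expected_proportion`, `maps`, `sem`.
#' @export
maps_score <- function(variants, model, rates, class_label = "class") {
  variants <- variants[!is.na(variants$context3), , drop = FALSE]
  n <- nrow(variants)
  if (n < 1) stop("empty variant class: ", class_label)
  n_singletons <- sum(variants$AC == 1)
  raw <- n_singletons / n
  expected <- as.numeric(expected_singletons(variants, model, rates))
  tibble::tibble(
    class_label = class_label,
    n_variants = n,
    n_singletons = n_singletons,
    raw_proportion = raw,
    expected_proportion = expected / n,
    maps = raw - expected / n,
    sem = sqrt(raw * (1 - raw) / n)
  )
}

#' MAPS by stratum
#'
#' Computes one MAPS result per non-empty stratum of the input (e.g.
#' binding_class x confident x activity decile, or consequence labels).
#' Strata smaller than `min_n` are flagged `wide_uncertainty` rather than
#' dropped.
#'
#' @param scored tibble with `context3`, `alt`, `AC` and the stratum columns.
#' @param strata character vector of column names to stratify by.
#' @param model a `cbs_maps_model`.
#' @param rates mutation-rate tibble.
#' @param min_n strata below this size are flagged (default 500).
#' @return tibble: stratum columns + MAPS result columns + `wide_uncertainty`.
#' @export
maps_by_stratum <- function(scored, strata, model, rates, min_n = 500) {
  stopifnot(all(strata %in% names(scored)))
  scored <- scored[!is.na(scored$context3), , drop = FALSE]
  complete <- rowSums(is.na(scored[, strata, drop = FALSE])) == 0
  if (any(!complete)) {
    message(sum(!complete), " row(s) with missing stratum value(s) excluded")
    scored <- scored[complete, , drop = FALSE]
  }
  keys <- unique(scored[, strata, drop = FALSE])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- rep(TRUE, nrow(scored))
    for (s in strata) sel <- sel & (scored[[s]] == keys[[s]][i])
    grp <- scored[sel, , drop = FALSE]
    if (nrow(grp) == 0) return(NULL)
    res <- maps_score(grp, model, rates,
                      class_label = paste(unlist(keys[i, ]), collapse = "/"))
    dplyr::bind_cols(keys[i, , drop = FALSE], res)
  })
  out <- dplyr::bind_rows(out)
  out$wide_uncertainty <- out$n_variants < min_n
  tibble::as_tibble(out)
}
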