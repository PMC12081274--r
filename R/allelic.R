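# Allelic dPWM scoring: REF vs ALT best log-odds over windows covering a variant.

#' Intersect QC'd variants with the CBS catalog
#'
#' Emits one row per (variant, motif) pair where the variant's position
#' (1-based, converted to 0-based internally) lies within the motif's
#' half-open interval. A variant inside k motifs yields k rows, each carrying
#' that motif's activity and quantile.
#'
#' @param variants tibble with `chrom`, `pos` (1-based) and any other columns.
#' @param cbs activity-annotated motif tibble (`chrom`, `start`, `end`,
#'   `strand`, `activity`, `quantile`, ...).
#' @return tibble: the variant columns plus `motif_chrom`, `motif_start`,
#'   `motif_end`, `motif_strand`, `motif_score`, `activity`, `quantile`.
#' @export
intersect_variants_with_cbs <- function(variants, cbs) {
  stopifnot(all(c("chrom", "pos") %in% names(variants)))
  stopifnot(all(c("chrom", "start", "end", "activity") %in% names(cbs)))
  if (nrow(variants) == 0 || nrow(cbs) == 0) {
    return(empty_pair_table(variants))
  }
  vg <- GenomicRanges::GRanges(variants$chrom, IRanges::IRanges(variants$pos, width = 1L))
  mg <- df_to_granges(cbs)
  ov <- GenomicRanges::findOverlaps(vg, mg)
  if (length(ov) == 0) return(empty_pair_table(variants))
  vi <- S4Vectors::queryHits(ov)
  mi <- S4Vectors::subjectHits(ov)
  out <- variants[vi, , drop = FALSE]
  out$motif_chrom <- cbs$chrom[mi]
  out$motif_start <- cbs$start[mi]
  out$motif_end <- cbs$end[mi]
  out$motif_strand <- if ("strand" %in% names(cbs)) cbs$strand[mi] else NA_character_
  out$motif_score <- if ("score" %in% names(cbs)) cbs$score[mi] else NA_real_
  out$activity <- cbs$activity[mi]
  out$quantile <- if ("quantile" %in% names(cbs)) cbs$quantile[mi] else NA_integer_
  if ("decile" %in% names(cbs)) out$decile <- cbs$decile[mi]
  tibble::as_tibble(out)
}

empty_pair_table <- function(variants) {
  out <- variants[integer(0), , drop = FALSE]
  out$motif_chrom <- character(0)
  out$motif_start <- integer(0)
  out$motif_end <- integer(0)
  out$motif_strand <- character(0)
  out$motif_score <- numeric(0)
  out$activity <- numeric(0)
  out$quantile <- integer(0)
  out$decile <- integer(0)
  tibble::as_tibble(out)
}

# Offsets (1-based, within a window of length w) at which an L-subwindow both
# fits in the window and covers the center position.
center_offsets <- function(w, L) {
  center <- (w + 1L) %/% 2L
  lo <- max(1L, center - L + 1L)
  hi <- min(center, w - L + 1L)
  if (hi < lo) integer(0) else lo:hi
}

# Core batched scorer. windows: n x w integer code matrix (NA = N), center base
# is column (w+1)/2 and must equal the REF allele; alt_codes: integer vector.
# Returns list(ref_best, alt_best) (NA where no valid subwindow).
best_scores_batch <- function(windows, alt_codes, pwm) {
  w <- ncol(windows)
  L <- pwm$length
  center <- (w + 1L) %/% 2L
  offs <- center_offsets(w, L)
  if (!length(offs)) stop("no motif subwindow can cover the center: flank too small")
  n <- nrow(windows)
  mats <- list(`+` = pwm$log_odds, `-` = reverse_complement_pwm(pwm)$log_odds)
  ref_best <- rep(NA_real_, n)
  alt_best <- rep(NA_real_, n)
  ref_center <- windows[, center]
  for (strand in names(mats)) {
    W <- mats[[strand]]
    for (s in offs) {
      sc <- rep(0, n)
      for (j in seq_len(L)) {
        sc <- sc + W[cbind(windows[, s + j - 1L], j)]
      }
      j0 <- center - s + 1L
      # grouped so that alt == ref gives an exactly unchanged score
      alt_sc <- sc + (W[cbind(alt_codes, j0)] - W[cbind(ref_center, j0)])
      ref_best <- pmax(ref_best, sc, na.rm = TRUE)
      alt_best <- pmax(alt_best, alt_sc, na.rm = TRUE)
    }
  }
  # pmax(na.rm=TRUE) leaves -Inf only if all inputs NA; normalize to NA
  ref_best[!is.finite(ref_best)] <- NA_real_
  alt_best[!is.finite(alt_best)] <- NA_real_
  list(ref_best = ref_best, alt_best = alt_best)
}

#' Score REF and ALT alleles of candidate SNVs against a PWM
#'
#' For each variant a (2 * flank + 1)-bp REF window centered on the variant is
#' extracted from the genome (N-padded at contig edges) and the same window
#' with the ALT base substituted is formed. Each allele's score is the maximum
#' log-odds over every motif-length subwindow that is fully contained in the
#' window and covers the variant position, on both strands. The allelic score
#' is `delta_pwm = ref_best - alt_best`: positive values predict loss of
#' binding, `<= 0` gain of binding.
#'
#' @param pairs tibble from [intersect_variants_with_cbs()] (needs `chrom`,
#'   `pos`, `ref`, `alt`; other columns are carried through), or any variant
#'   tibble with those columns.
#' @param genome named character vector / DNAStringSet.
#' @param pwm a `cbs_pwm`.
#' @param flank flanking bases on each side of the variant (default 14).
#' @return input tibble plus `ref_best`, `alt_best`, `delta_pwm`,
#'   `binding_class` ("gain" iff `delta_pwm <= 0`, else "loss"). Pairs whose
#'   window has no N-free subwindow are dropped with a message. A REF allele
#'   that does not match the genome is a hard error naming the position.
#' @export
score_alleles <- function(pairs, genome, pwm, flank = 14) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(pairs)))
  stopifnot(flank >= 0)
  seqs <- as_genome_strings(genome)
  if (nrow(pairs) == 0) {
    out <- pairs
    out$ref_best <- numeric(0); out$alt_best <- numeric(0)
    out$delta_pwm <- numeric(0); out$binding_class <- character(0)
    return(tibble::as_tibble(out))
  }
  w <- 2L * as.integer(flank) + 1L
  n <- nrow(pairs)
  windows <- matrix(NA_integer_, n, w)
  for (chrom in unique(pairs$chrom)) {
    if (!chrom %in% names(seqs)) stop("variant chromosome not in genome: ", chrom)
    idx <- which(pairs$chrom == chrom)
    codes <- seq_to_codes(seqs[[chrom]])
    len <- length(codes)
    for (k in idx) {
      pos <- pairs$pos[k]
      if (pos < 1 || pos > len) stop("variant position out of bounds: ", chrom, ":", pos)
      lo <- pos - flank
      hi <- pos + flank
      src <- max(1L, lo):min(len, hi)
      windows[k, src - lo + 1L] <- codes[src]
    }
  }
  center <- flank + 1L
  ref_codes <- match(pairs$ref, BASES)
  alt_codes <- match(pairs$alt, BASES)
  if (anyNA(ref_codes) || anyNA(alt_codes)) stop("ref/alt must be single bases A/C/G/T")
  mism <- which(windows[, center] != ref_codes)
  if (length(mism)) {
    k <- mism[1]
    stop("REF allele mismatch with genome at ", pairs$chrom[k], ":", pairs$pos[k],
         " (genome ", codes_to_seq(windows[k, center]), ", variant REF ", pairs$ref[k], ")")
  }
  best <- best_scores_batch(windows, alt_codes, pwm)
  out <- pairs
  out$ref_best <- best$ref_best
  out$alt_best <- best$alt_best
  out$delta_pwm <- best$ref_best - best$alt_best
  out$binding_class <- ifelse(out$delta_pwm <= 0, "gain", "loss")
  drop <- is.na(out$delta_pwm)
  if (any(drop)) {
    message(sum(drop), " pair(s) dropped: no N-free subwindow covering the variant")
    out <- out[!drop, , drop = FALSE]
  }
  tibble::as_tibble(out)
}

#' Floor truncated p-values at a dummy value
#'
#' Importance-sampling p-value estimates can be exactly 0 in the far tail;
#' these are encoded with a small dummy floor (default 1e-7) so that
#' `-log10(p)` rank scores remain finite.
#'
#' @param p numeric vector of p-values (>= 0).
#' @param dummy_floor floor value (default 1e-7).
#' @return `pmax(p, dummy_floor)`.
#' @export
encode_truncated_pvalues <- function(p, dummy_floor = 1e-7) {
  if (any(p < 0, na.rm = TRUE)) stop("negative p-value")
  pmax(p, dummy_floor)
}

#' Flag high-confidence allelic scores
#'
#' @param scores tibble with a `p_value` column.
#' @param alpha significance threshold; confidence is strict (`p < alpha`).
#' @return input with logical `confident` column.
#' @export
flag_confident <- function(scores, alpha = 0.05) {
  stopifnot("p_value" %in% names(scores))
  scores$confident <- scores$p_value < alpha
  tibble::as_tibble(scores)
}

#' Deduplicate (variant, motif) rows to one row per variant
#'
#' A variant inside several overlapping motifs keeps the row with the smallest
#' p-value; ties are broken by larger `|delta_pwm|`, then by motif coordinate.
#'
#' @param scores scored pair tibble with `chrom`, `pos`, `ref`, `alt`,
#'   `p_value`, `delta_pwm`, `motif_chrom`, `motif_start`.
#' @return one row per variant.
#' @export
dedupe_per_variant <- function(scores) {
  need <- c("chrom", "pos", "ref", "alt", "p_value", "delta_pwm", "motif_start")
  stopifnot(all(need %in% names(scores)))
  scores |>
    dplyr::arrange(
      .data$chrom, .data$pos, .data$ref, .data$alt,
      .data$p_value, dplyr::desc(abs(.data$delta_pwm)), .data$motif_start
    ) |>
    dplyr::distinct(.data$chrom, .data$pos, .data$ref, .data$alt, .keep_all = TRUE)
}
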