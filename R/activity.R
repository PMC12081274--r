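# Binding-activity summarization of the rDHS x biosample Z-score matrix.

MASK_SENTINEL <- -10

#' Mask zero-signal entries of a raw Z-score matrix
#'
#' Upstream processing stores rDHS-biosample combinations with zero raw ChIP
#' signal as the sentinel Z score -10. This flags those entries in an explicit
#' boolean mask; the mask, not the sentinel, is authoritative downstream.
#'
#' @param z numeric matrix (rows = rDHSs, columns = biosamples). Rownames are
#'   the rDHS ids, colnames the biosample ids.
#' @return object of class `cbs_activity_matrix`: list with `rdhs_ids`,
#'   `biosample_ids`, `z`, `masked` (logical matrix, same shape).
#' @export
mask_zero_signal <- function(z) {
  if (!is.matrix(z) || !is.numeric(z)) stop("z must be a numeric matrix")
  if (anyNA(z)) stop("z must not contain NA; use the -10 sentinel for masked entries")
  if (is.null(rownames(z))) rownames(z) <- paste0("rDHS_", seq_len(nrow(z)))
  if (is.null(colnames(z))) colnames(z) <- paste0("BS_", seq_len(ncol(z)))
  masked <- z == MASK_SENTINEL
  structure(
    list(
      rdhs_ids = rownames(z),
      biosample_ids = colnames(z),
      z = z,
      masked = masked
    ),
    class = "cbs_activity_matrix"
  )
}

#' Summarize per-rDHS binding activity across biosamples
#'
#' Meta-analyzes each rDHS's distribution of unmasked Z scores into a single
#' activity score. `"mean"` computes `sum(z_i) / N` over the N unmasked
#' biosamples; `"stouffer_sqrt"` computes the conventional Stouffer combination
#' `sum(z_i) / sqrt(N)`. Rows with no unmasked entry receive no score.
#'
#' @param mat a `cbs_activity_matrix`.
#' @param method `"mean"` (default) or `"stouffer_sqrt"`.
#' @return tibble with columns `rdhs_id`, `n_unmasked`, `activity` (`NA` when
#'   `n_unmasked == 0`).
#' @export
summarize_activity <- function(mat, method = c("mean", "stouffer_sqrt")) {
  stopifnot(inherits(mat, "cbs_activity_matrix"))
  method <- match.arg(method)
  zm <- mat$z
  zm[mat$masked] <- 0
  n <- rowSums(!mat$masked)
  total <- rowSums(zm)
  activity <- switch(method,
    mean = ifelse(n > 0, total / n, NA_real_),
    stouffer_sqrt = ifelse(n > 0, total / sqrt(n), NA_real_)
  )
  if (any(n == 0)) {
    message(sum(n == 0), " rDHS row(s) fully masked; no activity score assigned")
  }
  tibble::tibble(
    rdhs_id = mat$rdhs_ids,
    n_unmasked = unname(as.integer(n)),
    activity = unname(activity)
  )
}

#' Assign rank-based activity quantiles
#'
#' Places scored rDHSs into `k` equal-sized bins by rank: bin 1 holds the
#' lowest activities, bin `k` the highest, and bin sizes differ by at most 1.
#' Ties are broken by a stable sort on (activity, rdhs_id), making the
#' assignment deterministic.
#'
#' @param scores tibble with `rdhs_id` and `activity` (rows with `NA` activity
#'   are dropped with a message).
#' @param k number of bins (default 100).
#' @return input tibble (scored rows only) with an integer `quantile` column
#'   in `[1, k]`.
#' @export
assign_activity_quantiles <- function(scores, k = 100) {
  stopifnot(is.data.frame(scores), all(c("rdhs_id", "activity") %in% names(scores)))
  stopifnot(k >= 1)
  scored <- scores[!is.na(scores$activity), , drop = FALSE]
  if (nrow(scored) < nrow(scores)) {
    message(nrow(scores) - nrow(scored), " unscored rDHS(s) excluded from quantile binning")
  }
  n <- nrow(scored)
  if (n < k) stop("fewer scored rDHSs (", n, ") than bins (", k, ")")
  ord <- order(scored$activity, scored$rdhs_id, method = "radix")
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  # ceiling(rank * k / n) in exact integer arithmetic
  scored$quantile <- as.integer((as.numeric(rank) * k + n - 1) %/% n)
  tibble::as_tibble(scored)
}

#' Call CTCF-bound rDHSs by Z-score thresholding
#'
#' The sensitivity-analysis counterpart of the activity summary: an rDHS is
#' called bound if any unmasked biosample exceeds the threshold (strict `>`;
#' the conventional one-sided 5% normal cutoff 1.64 by default). Also reports
#' the number of biosamples exceeding the threshold (replication count).
#'
#' @param mat a `cbs_activity_matrix`.
#' @param z_threshold strict lower bound for a binding call (default 1.64).
#' @return tibble with `rdhs_id`, `bound` (logical), `n_biosamples_bound`.
#' @export
call_bound <- function(mat, z_threshold = 1.64) {
  stopifnot(inherits(mat, "cbs_activity_matrix"))
  exceed <- (mat$z > z_threshold) & !mat$masked
  tibble::tibble(
    rdhs_id = mat$rdhs_ids,
    bound = unname(rowSums(exceed) > 0),
    n_biosamples_bound = unname(as.integer(rowSums(exceed)))
  )
}

#' Annotate motif hits with the activity of their overlapping rDHS
#'
#' A motif overlapping one or more scored rDHSs (>= 1 shared base, 0-based
#' half-open coordinates) receives the maximum activity (and that rDHS's
#' quantile) among the rDHSs it overlaps — for bookended or otherwise multiply
#' overlapped loci the higher activity wins. Motifs with no overlap are
#' excluded from the returned CBS catalog.
#'
#' @param motifs tibble of motif hits (`chrom`, `start`, `end`, ...).
#' @param rdhs tibble with `rdhs_id`, `chrom`, `start`, `end`, `activity`, and
#'   optionally `quantile`; rows with `NA` activity are ignored.
#' @return the motif tibble restricted to rDHS-supported hits, with added
#'   columns `activity`, `quantile` (NA if rdhs had none), `rdhs_id`.
#' @export
annotate_motifs_with_activity <- function(motifs, rdhs) {
  stopifnot(all(c("chrom", "start", "end") %in% names(motifs)))
  stopifnot(all(c("rdhs_id", "chrom", "start", "end", "activity") %in% names(rdhs)))
  check_intervals(motifs)
  check_intervals(rdhs)
  rdhs <- rdhs[!is.na(rdhs$activity), , drop = FALSE]
  if (!"quantile" %in% names(rdhs)) rdhs$quantile <- NA_integer_
  if (nrow(motifs) == 0 || nrow(rdhs) == 0) {
    out <- motifs[integer(0), , drop = FALSE]
    out$activity <- numeric(0); out$quantile <- integer(0); out$rdhs_id <- character(0)
    return(tibble::as_tibble(out))
  }
  mg <- df_to_granges(motifs)
  rg <- df_to_granges(rdhs)
  ov <- GenomicRanges::findOverlaps(mg, rg, minoverlap = 1L)
  if (length(ov) == 0) {
    out <- motifs[integer(0), , drop = FALSE]
    out$activity <- numeric(0); out$quantile <- integer(0); out$rdhs_id <- character(0)
    return(tibble::as_tibble(out))
  }
  hit_df <- tibble::tibble(
    motif_row = S4Vectors::queryHits(ov),
    activity = rdhs$activity[S4Vectors::subjectHits(ov)],
    quantile = rdhs$quantile[S4Vectors::subjectHits(ov)],
    rdhs_id = rdhs$rdhs_id[S4Vectors::subjectHits(ov)]
  )
  best <- hit_df |>
    dplyr::arrange(.data$motif_row, dplyr::desc(.data$activity), .data$rdhs_id) |>
    dplyr::distinct(.data$motif_row, .keep_all = TRUE)
  out <- motifs[best$motif_row, , drop = FALSE]
  out$activity <- best$activity
  out$quantile <- best$quantile
  out$rdhs_id <- best$rdhs_id
  tibble::as_tibble(out)
}

# internal: data.frame (chrom/start/end, 0-based half-open) -> GRanges (1-based)
df_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

check_intervals <- function(df) {
  if (nrow(df) == 0) return(invisible(TRUE))
  bad <- which(!(df$start < df$end) | df$start < 0)
  if (length(bad)) {
    stop("malformed interval(s) at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": need 0 <= start < end")
  }
  invisible(TRUE)
}
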