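# Genome scanning: score every L-window on both strands, report hits.

# Vectorized window scores on the plus strand of `codes` for one weight matrix.
# Returns numeric vector of length n - L + 1 (NA where the window contains N).
window_scores <- function(codes, log_odds) {
  L <- ncol(log_odds)
  n <- length(codes)
  if (n < L) return(numeric(0))
  s <- numeric(n - L + 1L)
  for (j in seq_len(L)) {
    s <- s + unname(log_odds[codes[j:(n - L + j)], j])
  }
  s
}

#' Scan a sequence with a PWM on both strands
#'
#' Every window of motif length is scored on the plus strand and (via the
#' reverse-complement PWM) on the minus strand. Windows containing N are
#' skipped. Minus-strand hits are reported in plus-strand coordinates.
#'
#' @param seq nucleotide string (A/C/G/T/N).
#' @param pwm a `cbs_pwm`.
#' @param report_threshold minimum relative score of a reported hit, in [0, 1].
#' @param chrom chromosome name recorded in the output.
#' @return tibble with columns `chrom`, `start` (0-based), `end` (half-open),
#'   `strand`, `score` (bits), `relative_score`, sorted by
#'   (chrom, start, strand).
#' @export
scan_sequence <- function(seq, pwm, report_threshold = 0.8, chrom = "chr1") {
  stopifnot(inherits(pwm, "cbs_pwm"))
  stopifnot(report_threshold >= 0, report_threshold <= 1)
  codes <- seq_to_codes(seq)
  L <- pwm$length
  if (length(codes) < L) {
    return(tibble::tibble(
      chrom = character(0), start = integer(0), end = integer(0),
      strand = character(0), score = numeric(0), relative_score = numeric(0)
    ))
  }
  fwd <- window_scores(codes, pwm$log_odds)
  rev <- window_scores(codes, reverse_complement_pwm(pwm)$log_odds)
  build <- function(scores, strand) {
    rel <- relative_score(pwm, scores)
    keep <- which(!is.na(rel) & rel >= report_threshold)
    tibble::tibble(
      chrom = chrom,
      start = keep - 1L,
      end = keep - 1L + L,
      strand = strand,
      score = scores[keep],
      relative_score = rel[keep]
    )
  }
  hits <- dplyr::bind_rows(build(fwd, "+"), build(rev, "-"))
  dplyr::arrange(hits, chrom, start, strand)
}

#' Scan a multi-chromosome genome
#'
#' @param genome named character vector of sequences, or a
#'   [Biostrings::DNAStringSet].
#' @inheritParams scan_sequence
#' @return tibble as in [scan_sequence()], over all chromosomes.
#' @export
scan_genome <- function(genome, pwm, report_threshold = 0.8) {
  seqs <- as_genome_strings(genome)
  out <- lapply(names(seqs), function(chrom) {
    scan_sequence(seqs[[chrom]], pwm, report_threshold, chrom = chrom)
  })
  dplyr::bind_rows(out)
}

# Normalize a genome argument to a named character vector of sequences.
as_genome_strings <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    out <- as.character(genome)
  } else if (is.character(genome)) {
    out <- genome
  } else {
    stop("genome must be a named character vector or DNAStringSet")
  }
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    stop("genome sequences must be named by chromosome")
  }
  out
}
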