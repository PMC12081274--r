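# Position frequency matrices and their log-odds (PWM) form.

#' Construct a position frequency matrix object
#'
#' @param counts 4 x L non-negative numeric matrix with rownames A, C, G, T
#'   (rows are reordered by label if needed). Every column must have a
#'   positive sum.
#' @param motif_id identifier carried through to hits.
#' @return an object of class `cbs_pfm`: list with `motif_id`, `counts`, `length`.
#' @export
new_pfm <- function(counts, motif_id = "motif") {
  stopifnot(is.matrix(counts), nrow(counts) == 4L)
  if (is.null(rownames(counts))) rownames(counts) <- BASES
  stopifnot(setequal(rownames(counts), BASES))
  counts <- counts[BASES, , drop = FALSE]
  if (any(counts < 0)) stop("PFM counts must be non-negative")
  if (any(colSums(counts) <= 0)) stop("every PFM column must have a positive sum")
  structure(
    list(motif_id = motif_id, counts = counts, length = ncol(counts)),
    class = "cbs_pfm"
  )
}

#' Read a JASPAR-format PFM text file
#'
#' Accepts the classic JASPAR layout: an optional `>`-header line, then four
#' rows labelled A/C/G/T with counts, optionally bracketed, in any row order:
#' ```
#' >MA0000.0 NAME
#' A [ 10  5 ... ]
#' C [  3  2 ... ]
#' ...
#' ```
#'
#' @param path file path (plain text or gzip).
#' @return a `cbs_pfm`.
#' @export
read_pfm_jaspar <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  motif_id <- "motif"
  if (length(lines) > 0 && startsWith(lines[[1]], ">")) {
    motif_id <- strsplit(sub("^>\\s*", "", lines[[1]]), "\\s+")[[1]][1]
    lines <- lines[-1]
  }
  base_lines <- grepl("^\\s*[ACGTacgt]\\b", lines) | grepl("^\\s*[ACGTacgt]\\s*\\[", lines)
  lines <- lines[base_lines]
  if (length(lines) != 4L) {
    stop("JASPAR PFM must have exactly 4 base rows (A/C/G/T); found ", length(lines))
  }
  labels <- toupper(substr(trimws(lines), 1, 1))
  if (!setequal(labels, BASES)) stop("PFM rows must be labelled A, C, G, T")
  rows <- lapply(lines, function(ln) {
    body <- sub("^\\s*[ACGTacgt]", "", ln)
    body <- gsub("\\[|\\]", " ", body)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(body), "\\s+")[[1]]))
    if (anyNA(vals)) stop("non-numeric count in PFM row: ", ln)
    vals
  })
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L) {
    stop("PFM rows have unequal lengths: ", paste(lens, collapse = ", "))
  }
  counts <- do.call(rbind, rows)
  rownames(counts) <- labels
  new_pfm(counts[BASES, , drop = FALSE], motif_id = motif_id)
}

#' Write a PFM in JASPAR text format
#' @param pfm a `cbs_pfm`.
#' @param path output path.
#' @export
write_pfm_jaspar <- function(pfm, path) {
  stopifnot(inherits(pfm, "cbs_pfm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", pfm$motif_id), con)
  for (b in BASES) {
    writeLines(
      sprintf("%s  [ %s ]", b, paste(format(pfm$counts[b, ], trim = TRUE), collapse = " ")),
      con
    )
  }
  invisible(path)
}

#' Convert a PFM to a log-odds position weight matrix
#'
#' Per column j and base b, the binding probability is
#' `p[b,j] = (counts[b,j] + pseudocount * background[b]) / (colsum_j + pseudocount)`
#' and the weight is `log2(p[b,j] / background[b])` (bits). The total
#' pseudocount (default 0.8) is distributed across bases in proportion to the
#' background, a common JASPAR-ecosystem convention. `score_min`/`score_max`
#' are the sums of column minima/maxima, so the relative score
#' `(score - score_min) / (score_max - score_min)` lies in [0, 1].
#'
#' @param pfm a `cbs_pfm`.
#' @param background base composition of the null model (A, C, G, T);
#'   renormalized, must be strictly positive.
#' @param pseudocount total pseudocount added per column, > 0.
#' @return object of class `cbs_pwm`: list with `motif_id`, `log_odds` (4 x L,
#'   bits), `probs` (4 x L motif emission probabilities), `background`,
#'   `pseudocount`, `length`, `score_min`, `score_max`.
#' @export
pfm_to_pwm <- function(pfm, background = rep(0.25, 4), pseudocount = 0.8) {
  stopifnot(inherits(pfm, "cbs_pfm"))
  background <- check_background(background)
  stopifnot(is.numeric(pseudocount), length(pseudocount) == 1L, pseudocount > 0)
  counts <- pfm$counts
  adj <- counts + pseudocount * background
  probs <- sweep(adj, 2, colSums(adj), "/")
  log_odds <- log2(probs / background)
  structure(
    list(
      motif_id = pfm$motif_id,
      log_odds = log_odds,
      probs = probs,
      background = background,
      pseudocount = pseudocount,
      length = ncol(log_odds),
      score_min = sum(apply(log_odds, 2, min)),
      score_max = sum(apply(log_odds, 2, max))
    ),
    class = "cbs_pwm"
  )
}

#' Reverse-complement a PWM
#'
#' Rows are complemented (A<->T, C<->G) and columns reversed, so scoring the
#' plus strand with the result equals scoring the reverse complement of the
#' window with the original.
#' @param pwm a `cbs_pwm`.
#' @return a `cbs_pwm`.
#' @export
reverse_complement_pwm <- function(pwm) {
  stopifnot(inherits(pwm, "cbs_pwm"))
  flip <- function(m) m[4:1, rev(seq_len(ncol(m))), drop = FALSE]
  out <- pwm
  out$log_odds <- flip(pwm$log_odds)
  out$probs <- flip(pwm$probs)
  rownames(out$log_odds) <- rownames(out$probs) <- BASES
  out$background <- pwm$background[4:1]
  names(out$background) <- BASES
  out
}

#' Consensus sequence of a PWM (columnwise argmax of the weights)
#' @param pwm a `cbs_pwm`.
#' @return character string of length `pwm$length`.
#' @export
pwm_consensus <- function(pwm) {
  stopifnot(inherits(pwm, "cbs_pwm"))
  paste(BASES[apply(pwm$log_odds, 2, which.max)], collapse = "")
}

#' Log-odds score of a single window (plus strand)
#' @param pwm a `cbs_pwm`.
#' @param seq string of length `pwm$length`; returns `NA` if it contains N.
#' @return score in bits.
#' @export
pwm_score <- function(pwm, seq) {
  codes <- seq_to_codes(seq)
  if (length(codes) != pwm$length) stop("window length != motif length")
  if (anyNA(codes)) return(NA_real_)
  sum(pwm$log_odds[cbind(codes, seq_len(pwm$length))])
}

#' Relative PWM score
#'
#' `(score - score_min) / (score_max - score_min)`, the [0, 1] affinity proxy
#' used to rank motif matches. An information-free PWM (score_max == score_min)
#' gets relative score 1 by convention.
#' @param pwm a `cbs_pwm`.
#' @param score numeric vector of log-odds scores (bits).
#' @export
relative_score <- function(pwm, score) {
  rng <- pwm$score_max - pwm$score_min
  if (rng <= 0) return(rep(1, length(score)))
  (score - pwm$score_min) / rng
}
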