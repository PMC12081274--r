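# Readers/writers for on-disk formats. Internal coordinates are 0-based
# half-open (BED convention) everywhere; VCF's 1-based positions are
# converted exactly once, in the variant reader/writer pair.

#' Read a BED file (3+ columns)
#'
#' @param path BED path (plain or gzip). Columns beyond the first 6 are
#'   ignored.
#' @return tibble `chrom`, `start`, `end` (+ `name`, `score`, `strand` when
#'   present), sorted by (chrom, start, end). Malformed lines (non-integer or
#'   negative coordinates, start >= end) are an error naming the line.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (!length(lines)) {
    return(tibble::tibble(chrom = character(0), start = integer(0), end = integer(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("BED line ", line_no[which(nf < 3)[1]], " has fewer than 3 columns")
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) {
    stop("malformed BED interval at line ", line_no[bad[1]], ": ", lines[bad[1]])
  }
  out <- tibble::tibble(chrom = chrom, start = start, end = end)
  if (all(nf >= 4)) out$name <- vapply(fields, `[[`, character(1), 4)
  if (all(nf >= 5)) out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 5)))
  if (all(nf >= 6)) out$strand <- vapply(fields, `[[`, character(1), 6)
  dplyr::arrange(out, chrom, start, end)
}

#' Write intervals as BED
#'
#' @param df tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand` (written as BED6 when present).
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  check_intervals(df)
  cols <- list(df$chrom, df$start, df$end)
  has <- function(col) col %in% names(df)
  if (has("name") || has("score") || has("strand")) {
    cols <- c(cols, list(
      if (has("name")) df$name else ".",
      if (has("score")) df$score else 0,
      if (has("strand")) df$strand else "."
    ))
  }
  out <- do.call(paste, c(cols, sep = "\t"))
  readr::write_lines(out, path)
  invisible(path)
}

#' Read an rDHS-by-biosample activity matrix TSV
#'
#' First column = rDHS id, header row = biosample ids, entries = Z scores
#' with masked combinations stored as the -10 sentinel.
#'
#' @param path TSV path.
#' @return `cbs_activity_matrix` (via [mask_zero_signal()]).
#' @export
read_activity_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  mask_zero_signal(m)
}

#' @rdname read_activity_matrix
#' @param mat a `cbs_activity_matrix`.
#' @export
write_activity_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "cbs_activity_matrix"))
  df <- tibble::as_tibble(mat$z)
  df <- dplyr::bind_cols(tibble::tibble(rdhs_id = mat$rdhs_ids), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read variants from VCF or TSV
#'
#' VCF (v4.x) input goes through `VariantAnnotation::readVcf`; multi-allelic
#' rows are split into one record per ALT allele with per-allele AC/AF.
#' TSV input needs columns `chrom`, `pos`, `ref`, `alt`, `filter`, `AC`,
#' `AN`, `AF` (optional `consequence`, `cadd_phred`).
#'
#' @param path input path (`.vcf`, `.vcf.gz/.vcf.bgz`, else treated as TSV).
#' @return tibble with 1-based `pos` and the columns above.
#' @export
read_variants <- function(path) {
  if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path)) {
    read_variants_vcf(path)
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE)
    required <- c("chrom", "pos", "ref", "alt", "filter", "AC", "AN", "AF")
    missing <- setdiff(required, names(df))
    if (length(missing)) {
      stop("variant TSV missing column(s): ", paste(missing, collapse = ", "))
    }
    df
  }
}

read_variants_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  filt <- rr$FILTER %||% VariantAnnotation::filt(vcf)
  get_info <- function(key) if (key %in% names(info)) info[[key]] else NULL
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    filter = as.character(filt),
    AC = as.numeric(get_info("AC") %||% NA_real_),
    AN = as.numeric(get_info("AN") %||% NA_real_),
    AF = as.numeric(get_info("AF") %||% NA_real_)
  )
  csq <- get_info("CSQ")
  if (!is.null(csq)) out$consequence <- as.character(csq)
  cadd <- get_info("CADD")
  if (!is.null(cadd)) out$cadd_phred <- as.numeric(cadd)
  out
}

#' Write variants as a minimal VCF v4.2
#'
#' INFO carries AC, AN, AF (Number=A) and, when present, CSQ (most severe
#' consequence) and CADD (PHRED-scaled).
#'
#' @param variants tibble as returned by [read_variants()].
#' @param path output path.
#' @export
write_variants_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Allele number\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    "##INFO=<ID=CSQ,Number=A,Type=String,Description=\"Most severe consequence\">",
    "##INFO=<ID=CADD,Number=A,Type=Float,Description=\"PHRED-scaled CADD\">",
    paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
                      collapse = "\t"))
  ), con)
  info <- sprintf("AC=%d;AN=%d;AF=%s", variants$AC, variants$AN,
                  formatC(variants$AF, format = "g", digits = 8))
  if (!is.null(variants$consequence)) info <- paste0(info, ";CSQ=", variants$consequence)
  if (!is.null(variants$cadd_phred)) {
    info <- paste0(info, ";CADD=", formatC(variants$cadd_phred, format = "g", digits = 6))
  }
  writeLines(paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
                   ".", variants$filter, info, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_variants_vcf
#' @export
write_variants_tsv <- function(variants, path) {
  readr::write_tsv(variants, path)
  invisible(path)
}

#' Read a mutation-rate table TSV (`context`, `ref`, `alt`, `mu`)
#' @param path TSV path.
#' @return tibble; middle base of `context` must equal `ref` and `mu > 0`.
#' @export
read_mutation_rates <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("context", "ref", "alt", "mu")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop("rate table missing column(s): ", paste(missing, collapse = ", "))
  if (any(substr(df$context, 2, 2) != df$ref)) {
    stop("rate table: middle base of context must equal ref")
  }
  if (any(df$mu <= 0)) stop("rate table: mu must be positive")
  if (anyDuplicated(paste(df$context, df$alt))) {
    stop("rate table: duplicate (context, alt) keys")
  }
  df
}

#' Read a genome FASTA
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  out <- as.character(ss)
  out
}

#' @rdname read_genome_fasta
#' @param genome named character vector of sequences.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(as_genome_strings(genome))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a bedGraph score track into a per-base accessor
#'
#' @param path bedGraph path (0-based half-open intervals, constant score per
#'   interval).
#' @return object of class `cbs_track` queryable with [track_scores()].
#' @export
read_track <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  structure(list(granges = gr), class = "cbs_track")
}

#' Per-base scores from a track
#'
#' @param track a `cbs_track`.
#' @param chrom chromosome name.
#' @param positions0 0-based positions.
#' @return numeric vector; positions not covered by the track are `NA`, with
#'   the count attached as attribute `"n_missing"`.
#' @export
track_scores <- function(track, chrom, positions0) {
  stopifnot(inherits(track, "cbs_track"))
  gr <- track$granges
  if (!chrom %in% unique(as.character(GenomicRanges::seqnames(gr)))) {
    stop("contig not in track: ", chrom)
  }
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(positions0 + 1L, width = 1L))
  ov <- GenomicRanges::findOverlaps(q, gr, select = "first")
  out <- rep(NA_real_, length(positions0))
  hit <- !is.na(ov)
  out[hit] <- gr$score[ov[hit]]
  attr(out, "n_missing") <- sum(!hit)
  out
}

#' Write a per-base score vector as bedGraph
#'
#' Adjacent positions with equal scores are merged into intervals.
#'
#' @param scores named list: one numeric vector per chromosome (position i =
#'   0-based coordinate i - 1).
#' @param path output path.
#' @export
write_bedgraph <- function(scores, path) {
  lines <- character(0)
  for (chrom in names(scores)) {
    v <- scores[[chrom]]
    r <- rle(v)
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s", chrom, start, end,
                              formatC(r$values, format = "g", digits = 8)))
  }
  readr::write_lines(lines, path)
  invisible(path)
}
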