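# Catalog and variant filtering rules.

#' Filter motif hits by contig and exclusion tracks
#'
#' A hit is removed if its contig is not in the autosome list (non-autosomal /
#' sex contigs) or if it shares at least one base with any exclusion interval
#' (assembly gaps, blacklist, protein-coding exons, ...). Removal reasons are
#' tallied per track; a hit overlapping several tracks increments each of
#' them, so tallies can sum to more than the number of removed hits.
#'
#' @param hits motif hit tibble (`chrom`, `start`, `end`, ...).
#' @param autosomes character vector of allowed contig names.
#' @param exclusions named list of exclusion tibbles (`chrom`, `start`, `end`),
#'   e.g. `list(gap = ..., blacklist = ..., coding_exon = ...)`. May be empty.
#' @return filtered tibble, with attribute `"removal_tally"`: named integer
#'   vector `c(non_autosome = ..., <track> = ...)`.
#' @export
filter_motifs <- function(hits, autosomes, exclusions = list()) {
  stopifnot(all(c("chrom", "start", "end") %in% names(hits)))
  if (length(exclusions) && is.null(names(exclusions))) {
    stop("exclusion tracks must be named")
  }
  tally <- c(non_autosome = 0L)
  keep <- hits$chrom %in% autosomes
  tally["non_autosome"] <- sum(!keep)
  if (any(!keep)) {
    message(sum(!keep), " hit(s) on non-autosomal contig(s): ",
            paste(unique(hits$chrom[!keep]), collapse = ", "))
  }
  excluded <- rep(FALSE, nrow(hits))
  if (nrow(hits) > 0) {
    hg <- df_to_granges(hits)
    for (track in names(exclusions)) {
      ex <- exclusions[[track]]
      check_intervals(ex)
      if (nrow(ex) == 0) { tally[track] <- 0L; next }
      ov <- GenomicRanges::countOverlaps(hg, df_to_granges(ex), minoverlap = 1L) > 0
      # tally counts removed hits overlapping this track (among autosomal hits too)
      tally[track] <- sum(ov & keep)
      excluded <- excluded | ov
    }
  } else {
    for (track in names(exclusions)) tally[track] <- 0L
  }
  out <- hits[keep & !excluded, , drop = FALSE]
  attr(out, "removal_tally") <- tally
  tibble::as_tibble(out)
}

#' Apply gnomAD-style variant quality control
#'
#' Retains biallelic SNVs (single-base REF and ALT) with `AC > 0`, `AF > 0`,
#' `filter == "PASS"` and `AN > min_AN` (strict: a variant covered in exactly
#' half the cohort is removed). Removal counts per rule are attached as the
#' `"removal_counts"` attribute; rules are applied independently, so counts
#' can overlap.
#'
#' @param variants tibble with at least `chrom`, `pos`, `ref`, `alt`, `AC`,
#'   `AN`, `AF`, `filter`.
#' @param min_AN strict lower bound on allele number (default 76000,
#'   half of ~152k alleles in a 76k-genome cohort).
#' @return filtered tibble.
#' @export
filter_variants <- function(variants, min_AN = 76000) {
  required <- c("chrom", "pos", "ref", "alt", "AC", "AN", "AF", "filter")
  missing <- setdiff(required, names(variants))
  if (length(missing)) stop("missing required column(s): ", paste(missing, collapse = ", "))
  is_snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
    variants$ref %in% BASES & variants$alt %in% BASES
  ac_ok <- variants$AC > 0
  af_ok <- variants$AF > 0
  pass <- variants$filter == "PASS"
  an_ok <- variants$AN > min_AN
  counts <- c(
    not_snv = sum(!is_snv),
    ac_zero = sum(!ac_ok),
    af_zero = sum(!af_ok),
    not_pass = sum(!pass),
    low_an = sum(!an_ok)
  )
  out <- variants[is_snv & ac_ok & af_ok & pass & an_ok, , drop = FALSE]
  attr(out, "removal_counts") <- counts
  tibble::as_tibble(out)
}
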