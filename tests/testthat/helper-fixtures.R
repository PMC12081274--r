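# Fixtures built in code: toy PFMs, random PWMs, small genomes.

toy_pfm <- function(counts, id = "toy") {
  m <- matrix(counts, nrow = 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  new_pfm(m, motif_id = id)
}

# random PFM with a clear consensus in every column
random_pfm <- function(L, seed, strength = 50) {
  withr::with_seed(seed, {
    counts <- matrix(sample(1:10, 4 * L, replace = TRUE), 4, L)
    for (j in seq_len(L)) {
      counts[sample.int(4, 1), j] <- counts[sample.int(4, 1), j] + strength
    }
  })
  rownames(counts) <- c("A", "C", "G", "T")
  new_pfm(counts, motif_id = paste0("rand", seed))
}

random_genome <- function(len, seed, gc = 0.5, chrom = "chr1") {
  withr::with_seed(seed, {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
               collapse = "")
  })
  stats::setNames(s, chrom)
}

revcomp_str <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# brute-force best log-odds over all motif subwindows of `window` (a string,
# center = variant) that cover the center, both strands; independent of the
# package's vectorized path
brute_best_score <- function(window, pwm) {
  L <- pwm$length
  w <- nchar(window)
  cen <- (w + 1) %/% 2
  best <- NA_real_
  for (s in max(1, cen - L + 1):min(cen, w - L + 1)) {
    sub <- substr(window, s, s + L - 1)
    for (seq in c(sub, revcomp_str(sub))) {
      sc <- pwm_score(pwm, seq)
      if (!is.na(sc) && (is.na(best) || sc > best)) best <- sc
    }
  }
  best
}

# small shared bundle for module tests (cheap: tiny genome, few biosamples)
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(
        seed = 5, genome_length = 120000, n_chromosomes = 2, n_rdhs = 200,
        n_biosamples = 30, n_motif_instances = 120, n_variants = 3000,
        n_control_variants = 3000
      )
      cache <<- suppressMessages(simulate_cbs_bundle(cfg))
    }
    cache
  }
})

# 10-hit motif exclusion fixture: 2 in gaps (one also blacklisted), 1 in a
# coding exon, 1 on chrX -> 6 survive
exclusion_fixture <- function() {
  hits <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2",
              "chr2", "chrX", "chr2", "chr1", "chr2"),
    start = c(100, 200, 300, 500, 100, 300, 100, 600, 800, 900),
    end = start + 19,
    strand = "+"
  )
  exclusions <- list(
    gap = tibble::tibble(chrom = "chr1", start = c(150, 310), end = c(250, 400)),
    blacklist = tibble::tibble(chrom = "chr1", start = 300, end = 330),
    coding_exon = tibble::tibble(chrom = "chr2", start = 110, end = 160)
  )
  list(hits = hits, exclusions = exclusions)
}

# 8-record variant QC fixture: multi-base ref, AC=0, LowQual, AN=70000 -> 4 survive
variant_qc_fixture <- function() {
  tibble::tibble(
    chrom = "chr1",
    pos = 1:8 * 100,
    ref = c("A", "AT", "C", "G", "T", "A", "C", "G"),
    alt = c("G", "A", "T", "A", "C", "T", "A", "C"),
    AC = c(5L, 3L, 0L, 2L, 9L, 1L, 4L, 7L),
    AN = c(100000L, 100000L, 100000L, 100000L, 70000L, 100000L, 100000L, 150000L),
    AF = c(5e-5, 3e-5, 0, 2e-5, 9e-5 * 10 / 7, 1e-5, 4e-5, 7e-5 * 2 / 3),
    filter = c("PASS", "PASS", "PASS", "LowQual", "PASS", "PASS", "PASS", "PASS")
  )
}
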