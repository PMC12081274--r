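# Allelic dPWM scoring identities and the variant-motif intersection.

test_that("variant-motif intersection converts coordinates exactly once", {
  cbs <- tibble::tibble(
    chrom = "chr1", start = 100, end = 119, strand = "+",
    score = 10, activity = 4.2, quantile = 80L
  )
  v <- tibble::tibble(chrom = "chr1", pos = c(101, 100, 119, 120), ref = "A", alt = "C")
  pairs <- intersect_variants_with_cbs(v, cbs)
  # 1-based 101..119 lie in [100,119); 1-based 100 = 0-based 99 does not; 120 does not
  expect_equal(pairs$pos, c(101, 119))
  expect_equal(pairs$activity, c(4.2, 4.2))

  # a variant inside two bookended motifs yields two rows
  cbs2 <- dplyr::bind_rows(cbs, dplyr::mutate(cbs, start = 110, end = 129, activity = 9))
  pairs2 <- intersect_variants_with_cbs(tibble::tibble(chrom = "chr1", pos = 115,
                                                       ref = "A", alt = "C"), cbs2)
  expect_equal(nrow(pairs2), 2)
  expect_setequal(pairs2$activity, c(4.2, 9))
})

test_that("score_alleles matches a brute-force subwindow oracle on random fixtures", {
  pwm <- pfm_to_pwm(random_pfm(6, seed = 41))
  g <- random_genome(3000, seed = 42)
  withr::with_seed(43, {
    pos <- sample(20:2980, 300)
  })
  ref <- substring(g[[1]], pos, pos)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "x")
  pairs <- tibble::tibble(chrom = "chr1", pos = pos, ref = ref, alt = unname(alt))
  scored <- score_alleles(pairs, g, pwm, flank = 7)
  for (i in seq_len(50)) {
    win_ref <- substr(g[[1]], pos[i] - 7, pos[i] + 7)
    win_alt <- win_ref
    substr(win_alt, 8, 8) <- alt[[i]]
    expect_equal(scored$ref_best[i], brute_best_score(win_ref, pwm), tolerance = 1e-9)
    expect_equal(scored$alt_best[i], brute_best_score(win_alt, pwm), tolerance = 1e-9)
  }
  expect_equal(scored$delta_pwm, scored$ref_best - scored$alt_best)
})

test_that("dPWM identities: identity substitution, antisymmetry, strand reversal", {
  pwm <- pfm_to_pwm(random_pfm(5, seed = 51))
  g <- random_genome(2000, seed = 52)
  withr::with_seed(53, pos <- sample(10:1990, 200))
  ref <- substring(g[[1]], pos, pos)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "x")

  # ref == alt (hypothetical identity substitution): delta 0, class gain
  same <- score_alleles(tibble::tibble(chrom = "chr1", pos = pos, ref = ref, alt = ref),
                        g, pwm, flank = 6)
  expect_true(all(same$delta_pwm == 0))
  expect_true(all(same$binding_class == "gain"))

  fwd <- score_alleles(tibble::tibble(chrom = "chr1", pos = pos, ref = ref,
                                      alt = unname(alt)), g, pwm, flank = 6)

  # antisymmetry: substitute the alt allele into the genome, swap ref/alt
  g_alt <- g
  for (i in seq_along(pos)) substr(g_alt[[1]], pos[i], pos[i]) <- alt[[i]]
  swapped <- lapply(seq_along(pos), function(i) {
    g_i <- g
    substr(g_i[[1]], pos[i], pos[i]) <- alt[[i]]
    sp <- tibble::tibble(chrom = "chr1", pos = pos[i])
    sp$ref <- alt[[i]]
    sp$alt <- ref[i]
    score_alleles(sp, g_i, pwm, flank = 6)$delta_pwm
  })
  expect_equal(unlist(swapped), -fwd$delta_pwm, tolerance = 1e-9)

  # strand reversal: reverse-complement the genome, complement the alleles
  n <- nchar(g[[1]])
  g_rc <- stats::setNames(revcomp_str(g[[1]]), "chr1")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rev_pairs <- tibble::tibble(chrom = "chr1", pos = n - pos + 1,
                              ref = unname(comp[ref]), alt = unname(comp[unlist(alt)]))
  bwd <- score_alleles(rev_pairs, g_rc, pwm, flank = 6)
  expect_equal(bwd$delta_pwm, fwd$delta_pwm, tolerance = 1e-9)

  # gain/loss partitions all scored pairs
  expect_true(all(fwd$binding_class %in% c("gain", "loss")))
  expect_equal(fwd$binding_class == "gain", fwd$delta_pwm <= 0)
})

test_that("REF mismatches are hard errors and contig edges are N-padded", {
  pwm <- pfm_to_pwm(random_pfm(4, seed = 61))
  g <- c(chr1 = "ACGTACGTACGTACGTACGT")
  ref_true <- substr(g[[1]], 10, 10)
  wrong <- setdiff(c("A", "C", "G", "T"), ref_true)[1]
  expect_error(
    score_alleles(tibble::tibble(chrom = "chr1", pos = 10, ref = wrong, alt = ref_true),
                  g, pwm, flank = 3),
    "REF allele mismatch.*chr1:10"
  )
  # variant 2 bp from the edge with flank 3: window is N-padded but scoreable
  near <- score_alleles(tibble::tibble(chrom = "chr1", pos = 2, ref = "C", alt = "G"),
                        g, pwm, flank = 3)
  expect_equal(nrow(near), 1)
  expect_true(is.finite(near$delta_pwm))
})

test_that("truncated p-values are floored and confidence is strict", {
  expect_equal(encode_truncated_pvalues(0), 1e-7)
  expect_equal(-log10(encode_truncated_pvalues(0)), 7)
  expect_equal(encode_truncated_pvalues(0.05), 0.05)
  expect_equal(encode_truncated_pvalues(5e-8), 1e-7)
  expect_equal(encode_truncated_pvalues(c(0, 1e-3), dummy_floor = 1e-5),
               c(1e-5, 1e-3))
  expect_error(encode_truncated_pvalues(-0.1), "negative")

  scored <- tibble::tibble(p_value = c(0.049, 0.05, 0.051, 1e-7))
  out <- flag_confident(scored, alpha = 0.05)
  expect_equal(out$confident, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(sum(out$confident) + sum(!out$confident), nrow(out))
})

test_that("per-variant deduplication keeps the smallest p, then largest |dPWM|", {
  scored <- tibble::tibble(
    chrom = "chr1", pos = 50, ref = "A", alt = "G",
    p_value = c(0.2, 0.01, 0.01),
    delta_pwm = c(5, 1, -4),
    motif_start = c(40, 45, 35)
  )
  out <- dedupe_per_variant(scored)
  expect_equal(nrow(out), 1)
  expect_equal(out$p_value, 0.01)
  expect_equal(out$delta_pwm, -4)  # tie on p broken by larger |delta|
})
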