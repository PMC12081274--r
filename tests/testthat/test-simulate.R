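# Synthetic-data generators: determinism, composition, planted structure.

test_that("genome simulation is deterministic with the expected composition", {
  cfg <- simulation_config(seed = 1, genome_length = 1000, n_chromosomes = 1,
                           gc_content = 0.5)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  expect_equal(nchar(g1[[1]]), 1000)

  # degenerate composition: gc = 1 -> only G/C
  gc1 <- simulate_genome(simulation_config(seed = 2, genome_length = 500,
                                           n_chromosomes = 1, gc_content = 1))
  expect_false(grepl("[AT]", gc1[[1]]))

  # observed GC within 3 binomial SDs of target
  cfg3 <- simulation_config(seed = 3, genome_length = 100000, n_chromosomes = 1,
                            gc_content = 0.41)
  g3 <- simulate_genome(cfg3)[[1]]
  gc_obs <- sum(strsplit(g3, "")[[1]] %in% c("G", "C")) / nchar(g3)
  tol <- 3 * sqrt(0.41 * 0.59 / 100000)
  expect_lt(abs(gc_obs - 0.41), tol)

  expect_error(simulation_config(genome_length = -5), "positive")
})

test_that("planted motifs at fidelity 1 are exact consensus copies, recoverable by scanning", {
  pfm <- random_pfm(6, seed = 15)
  pwm <- pfm_to_pwm(pfm)
  cfg <- simulation_config(seed = 4, genome_length = 5000, n_chromosomes = 1,
                           motif_planting_fidelity = 1, n_motif_instances = 10,
                           n_rdhs = 10)
  g <- simulate_genome(cfg)
  res <- plant_motifs(g, pfm, cfg, n_instances = 10)
  expect_equal(nrow(res$motifs), 10)
  cons <- pwm_consensus(pwm)
  for (i in seq_len(10)) {
    m <- res$motifs[i, ]
    site <- substr(res$genome[[m$chrom]], m$start + 1, m$end)
    expect_equal(site, if (m$strand == "+") cons else revcomp_str(cons))
  }
  # round trip: every planted interval recovered with relative score 1
  hits <- scan_genome(res$genome, pwm, report_threshold = 0.999)
  for (i in seq_len(10)) {
    m <- res$motifs[i, ]
    match <- hits$start == m$start & hits$strand == m$strand &
      abs(hits$relative_score - 1) < 1e-9
    expect_true(any(match))
  }
  # no planting leaves the genome unchanged
  res0 <- plant_motifs(g, pfm, cfg, n_instances = 0)
  expect_identical(res0$genome, g)
  expect_equal(nrow(res0$motifs), 0)
})

test_that("activity matrix: full mask, planted means, determinism", {
  cfg <- simulation_config(seed = 6, n_rdhs = 50, n_biosamples = 40,
                           n_motif_instances = 50,
                           mask_rate_inactive = 1, z_active_mean = 6,
                           mask_rate_active = 0)
  rdhs <- tibble::tibble(rdhs_id = sprintf("r%02d", 1:50))
  all_inactive <- simulate_activity_matrix(rdhs, rep(FALSE, 50), cfg)
  expect_true(all(all_inactive$masked))
  expect_true(all(all_inactive$z == -10))

  all_active <- simulate_activity_matrix(rdhs, rep(TRUE, 50), cfg)
  expect_false(any(all_active$masked))
  z <- all_active$z
  se <- cfg$z_active_sd / sqrt(length(z))
  expect_lt(abs(mean(z) - 6), 3 * se)

  again <- simulate_activity_matrix(rdhs, rep(TRUE, 50), cfg)
  expect_identical(all_active$z, again$z)

  expect_error(simulate_activity_matrix(rdhs[0, ], logical(0), cfg), "empty")
})

test_that("simulated singleton proportions track the planted mechanism", {
  pfm <- random_pfm(8, seed = 25)
  pwm <- pfm_to_pwm(pfm)
  rates <- simulate_mutation_rates(seed = 9)
  cfg <- simulation_config(seed = 10, genome_length = 60000, n_chromosomes = 1,
                           n_rdhs = 60, n_motif_instances = 60,
                           n_variants = 12000, n_control_variants = 12000,
                           singleton_base_rate = 0.45,
                           mutation_rate_slope = 0,
                           filter_fail_rate = 0)
  g <- simulate_genome(cfg)
  planted <- plant_motifs(g, pfm, cfg, n_instances = 60)
  catalog <- planted$motifs
  catalog$decile <- 10L

  # all-zero selection effects: loss variants match the control singleton rate
  sim0 <- suppressMessages(simulate_variants(catalog, planted$genome, pwm, rates, cfg))
  loss0 <- sim0$variants[sim0$truth$truth_class == "loss", ]
  p_ctl <- mean(sim0$variants$AC[sim0$truth$truth_class == "control"] == 1)
  p_loss <- mean(loss0$AC == 1)
  tol <- 3 * sqrt(0.45 * 0.55 / nrow(loss0))
  expect_lt(abs(p_loss - p_ctl), tol + 3 * sqrt(0.45 * 0.55 / 12000))

  # planted effect of 0.05 in decile 10 appears as excess singletons
  cfg5 <- simulation_config(seed = 10, genome_length = 60000, n_chromosomes = 1,
                            n_rdhs = 60, n_motif_instances = 60,
                            n_variants = 12000, n_control_variants = 12000,
                            singleton_base_rate = 0.45, mutation_rate_slope = 0,
                            filter_fail_rate = 0,
                            selection_effect_by_decile = c(rep(0, 9), 0.05))
  sim5 <- suppressMessages(simulate_variants(catalog, planted$genome, pwm, rates, cfg5))
  loss5 <- sim5$variants[sim5$truth$truth_class == "loss", ]
  excess <- mean(loss5$AC == 1) - mean(sim5$variants$AC[sim5$truth$truth_class == "control"] == 1)
  expect_lt(abs(excess - 0.05), 3 * sqrt(0.5 * 0.5 / nrow(loss5)) +
              3 * sqrt(0.5 * 0.5 / 12000))

  # empty case
  cfg0 <- simulation_config(seed = 11, n_variants = 0, n_control_variants = 0)
  sim_empty <- simulate_variants(catalog, planted$genome, pwm, rates, cfg0)
  expect_equal(nrow(sim_empty$variants), 0)
  expect_named(sim_empty$variants,
               c("variant_id", "chrom", "pos", "ref", "alt", "AC", "AN", "AF",
                 "filter", "consequence", "cadd_phred", "context3"))

  # truth coverage: every variant has exactly one truth entry
  expect_setequal(sim0$variants$variant_id, sim0$truth$variant_id)
  expect_equal(anyDuplicated(sim0$truth$variant_id), 0)
})

test_that("conservation track covers the genome and responds to the planted effect", {
  pfm <- random_pfm(8, seed = 35)
  cfg <- simulation_config(seed = 12, genome_length = 40000, n_chromosomes = 2,
                           n_rdhs = 40, n_motif_instances = 40,
                           conservation_effect = 2, conservation_sd = 1)
  g <- simulate_genome(cfg)
  planted <- plant_motifs(g, pfm, cfg, n_instances = 40)
  in_active <- rep(c(TRUE, FALSE), length.out = 40)
  track <- simulate_conservation_track(planted$genome, planted$motifs, in_active, cfg)
  expect_equal(vapply(track, length, numeric(1)),
               vapply(planted$genome, nchar, numeric(1)), ignore_attr = TRUE)

  inside <- unlist(lapply(which(in_active), function(i) {
    m <- planted$motifs[i, ]
    track[[m$chrom]][(m$start + 1):m$end]
  }))
  outside_mask <- rep(TRUE, length(track$chr1))
  for (i in seq_len(nrow(planted$motifs))) {
    m <- planted$motifs[i, ]
    if (m$chrom == "chr1") outside_mask[(m$start + 1):m$end] <- FALSE
  }
  outside <- track$chr1[outside_mask]
  # proportion above 1 differs per the normal tail shift
  p_in <- mean(inside >= 1)
  p_out <- mean(outside >= 1)
  expect_gt(p_in - p_out, 0.5)  # pnorm(1) - pnorm(-1) ~ 0.68 expected gap

  # zero effect: distributions indistinguishable (KS)
  cfg0 <- simulation_config(seed = 12, genome_length = 40000, n_chromosomes = 2,
                            n_rdhs = 40, n_motif_instances = 40,
                            conservation_effect = 0)
  track0 <- simulate_conservation_track(planted$genome, planted$motifs, in_active, cfg0)
  inside0 <- unlist(lapply(which(in_active), function(i) {
    m <- planted$motifs[i, ]
    track0[[m$chrom]][(m$start + 1):m$end]
  }))
  ks <- suppressWarnings(stats::ks.test(inside0, track0$chr1[outside_mask]))
  expect_gt(ks$p.value, 0.01)
})

test_that("the bundle is internally consistent and deterministic", {
  b <- small_bundle()
  # truth coverage
  expect_equal(nrow(b$rdhs), b$config$n_rdhs)
  expect_equal(nrow(b$motifs), b$config$n_motif_instances)
  expect_setequal(b$variants$variant_id, b$variant_truth$variant_id)
  # motifs planted inside rDHSs carry that rDHS id
  inside <- !is.na(b$motifs$rdhs_id)
  expect_gt(mean(inside), 0.8)
  # activity recovery: active rDHSs score higher than inactive ones
  act <- b$rdhs$activity[b$rdhs$active]
  inact <- b$rdhs$activity[!b$rdhs$active]
  expect_gt(mean(act, na.rm = TRUE), mean(inact, na.rm = TRUE) + 2)
  # regenerating with the same config gives identical variants
  b2 <- suppressMessages(simulate_cbs_bundle(b$config))
  expect_identical(b$variants, b2$variants)
  expect_identical(b$genome, b2$genome)
})
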