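# Synthetic-data generator: every pipeline input with known ground truth.
#
# All generators are pure functions of (config, seed): each operation draws
# from its own fixed offset of the config seed, so regenerating any single
# input reproduces it byte-identically.

SEED_OFFSETS <- c(genome = 101L, rdhs = 202L, motifs = 303L, matrix = 404L,
                  variants = 505L, conservation = 606L, rates = 707L,
                  exclusions = 808L)

#' Simulation configuration
#'
#' Defaults emulate the statistical structure of the real inputs at desk
#' scale: a 1-Mb two-chromosome genome at 41% GC, 2,000 rDHSs profiled in
#' 214 biosamples (the biosample count of the real ChIP compendium), 30%
#' truly CTCF-active rDHSs with unmasked Z ~ N(6, 2), heavy masking of
#' zero-signal combinations, 1,000 planted motifs at 95% per-position
#' consensus fidelity (bound CBSs are high-affinity matches), and 20,000
#' candidate SNVs plus an equally sized
#' synonymous-like control set with a singleton probability that depends on
#' trinucleotide mutability and an optional planted selection effect for
#' loss-of-binding variants, by activity decile.
#'
#' @param seed master seed (integer).
#' @param genome_length total genome size in bp.
#' @param n_chromosomes number of chromosomes (autosome names chr1, chr2, ...).
#' @param gc_content expected GC fraction in (0, 1).
#' @param n_rdhs number of rDHS intervals.
#' @param rdhs_width rDHS width in bp.
#' @param n_biosamples columns of the activity matrix (>= 2).
#' @param frac_active_rdhs fraction of rDHSs that are truly CTCF-active.
#' @param z_active_mean,z_active_sd unmasked Z distribution of active rDHSs.
#' @param mask_rate_inactive,mask_rate_active per-entry masking probabilities.
#' @param n_motif_instances planted motif count (<= n_rdhs).
#' @param frac_motifs_outside_rdhs fraction of instances planted outside any
#'   rDHS (no cCRE support).
#' @param motif_planting_fidelity per-position probability of the consensus
#'   base.
#' @param n_variants candidate (motif-overlapping) SNV count.
#' @param n_control_variants synonymous-like control SNV count.
#' @param singleton_base_rate baseline singleton probability.
#' @param mutation_rate_slope change in singleton probability per unit of
#'   (mu - mean mu); negative, since mutable sites recur and are less often
#'   singletons.
#' @param selection_effect_by_decile 10 non-negative fractions: planted
#'   excess singleton probability for loss-of-binding variants, by activity
#'   decile of their motif's rDHS.
#' @param an_value constant allele number.
#' @param filter_fail_rate fraction of variants spiked with a non-PASS filter.
#' @param conservation_effect,conservation_sd mean shift inside motifs of
#'   active rDHSs / per-base noise SD of the conservation track.
#' @return validated list of class `cbs_sim_config`.
#' @export
simulation_config <- function(seed = 1,
                              genome_length = 1e6,
                              n_chromosomes = 2,
                              gc_content = 0.41,
                              n_rdhs = 2000,
                              rdhs_width = 300,
                              n_biosamples = 214,
                              frac_active_rdhs = 0.3,
                              z_active_mean = 6,
                              z_active_sd = 2,
                              mask_rate_inactive = 0.9,
                              mask_rate_active = 0.2,
                              n_motif_instances = 1000,
                              frac_motifs_outside_rdhs = 0.1,
                              motif_planting_fidelity = 0.95,
                              n_variants = 20000,
                              n_control_variants = 20000,
                              singleton_base_rate = 0.45,
                              mutation_rate_slope = -0.02,
                              selection_effect_by_decile = rep(0, 10),
                              an_value = 152312,
                              filter_fail_rate = 0.02,
                              conservation_effect = 2,
                              conservation_sd = 1) {
  cfg <- as.list(environment())
  fracs <- c(gc_content, frac_active_rdhs, mask_rate_inactive, mask_rate_active,
             frac_motifs_outside_rdhs, motif_planting_fidelity,
             singleton_base_rate, filter_fail_rate)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0, 1]")
  if (length(selection_effect_by_decile) != 10 || any(selection_effect_by_decile < 0)) {
    stop("selection_effect_by_decile must have exactly 10 non-negative entries")
  }
  if (genome_length <= 0) stop("genome_length must be positive")
  if (n_biosamples < 2) stop("n_biosamples must be >= 2")
  if (n_motif_instances > n_rdhs) stop("n_motif_instances must be <= n_rdhs")
  structure(cfg, class = "cbs_sim_config")
}

#' Simulate a random genome
#'
#' iid bases with P(G) = P(C) = gc_content / 2.
#'
#' @param config a `cbs_sim_config`.
#' @return named character vector (chr1, chr2, ...).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "cbs_sim_config"))
  lens <- chromosome_lengths(config)
  prob <- c((1 - config$gc_content) / 2, config$gc_content / 2,
            config$gc_content / 2, (1 - config$gc_content) / 2)
  withr::with_seed(config$seed + SEED_OFFSETS["genome"], {
    out <- vapply(lens, function(len) {
      paste(sample(BASES, len, replace = TRUE, prob = prob), collapse = "")
    }, character(1))
  })
  out
}

chromosome_lengths <- function(config) {
  n <- config$n_chromosomes
  base <- floor(config$genome_length / n)
  lens <- rep(base, n)
  lens[n] <- config$genome_length - base * (n - 1)
  names(lens) <- paste0("chr", seq_len(n))
  lens
}

#' Simulate non-overlapping rDHS intervals
#'
#' The genome is divided into `n_rdhs` equal slots and one `rdhs_width`
#' interval is jittered uniformly within each slot, guaranteeing
#' non-overlap.
#'
#' @param config a `cbs_sim_config`.
#' @return tibble `rdhs_id`, `chrom`, `start`, `end` (0-based half-open).
#' @export
simulate_rdhs_intervals <- function(config) {
  stopifnot(inherits(config, "cbs_sim_config"))
  lens <- chromosome_lengths(config)
  per_chrom <- round(config$n_rdhs * lens / sum(lens))
  per_chrom[length(per_chrom)] <- config$n_rdhs - sum(per_chrom[-length(per_chrom)])
  withr::with_seed(config$seed + SEED_OFFSETS["rdhs"], {
    rows <- lapply(names(lens), function(chrom) {
      k <- per_chrom[[chrom]]
      if (k == 0) return(NULL)
      slot <- floor(lens[[chrom]] / k)
      if (slot <= config$rdhs_width) {
        stop("genome too small for ", k, " rDHSs of width ", config$rdhs_width,
             " on ", chrom)
      }
      jitter <- sample.int(slot - config$rdhs_width, k, replace = TRUE) - 1L
      start <- (seq_len(k) - 1L) * slot + jitter
      tibble::tibble(chrom = chrom, start = start, end = start + config$rdhs_width)
    })
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_cols(
    tibble::tibble(rdhs_id = sprintf("rDHS_%05d", seq_len(nrow(out)))), out
  )
  out
}

#' Plant motif instances into a genome
#'
#' Overwrites `n_motif_instances` non-overlapping intervals with sequences
#' drawn per position as: consensus base with probability
#' `motif_planting_fidelity`, otherwise one of the other three bases
#' uniformly. Strand is chosen uniformly; minus-strand instances are
#' reverse-complemented before insertion. Intervals are recorded in BED
#' convention (0-based half-open).
#'
#' @param genome named character vector.
#' @param pfm a `cbs_pfm`.
#' @param config a `cbs_sim_config`.
#' @param regions optional tibble (`chrom`, `start`, `end`) restricting
#'   placement: each instance is placed fully inside a uniformly chosen
#'   region.
#' @param n_instances overrides `config$n_motif_instances`.
#' @param seed overrides the derived planting seed (used when planting in
#'   several batches).
#' @return list with `genome` (modified) and `motifs` (tibble `chrom`,
#'   `start`, `end`, `strand`, `planted`). Fails after bounded retries if
#'   non-overlapping placement is impossible.
#' @export
plant_motifs <- function(genome, pfm, config, regions = NULL, n_instances = NULL,
                         seed = NULL) {
  stopifnot(inherits(pfm, "cbs_pfm"))
  seqs <- as_genome_strings(genome)
  L <- pfm$length
  if (sum(nchar(seqs)) < 10 * L) stop("genome shorter than 10 motif lengths")
  n <- n_instances %||% config$n_motif_instances
  empty <- tibble::tibble(chrom = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          planted = logical(0))
  if (n == 0) return(list(genome = seqs, motifs = empty))
  consensus <- apply(pfm$counts, 2, which.max)
  lens <- nchar(seqs)
  placed <- empty
  withr::with_seed(seed %||% (config$seed + SEED_OFFSETS["motifs"]), {
    attempts <- 0L
    max_attempts <- 200L * n
    while (nrow(placed) < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("could not place ", n, " non-overlapping motif instances after ",
             max_attempts, " attempts")
      }
      if (is.null(regions)) {
        chrom <- sample(names(seqs), 1, prob = lens)
        if (lens[[chrom]] < L) next
        start <- sample.int(lens[[chrom]] - L + 1L, 1) - 1L
      } else {
        ri <- sample.int(nrow(regions), 1)
        span <- regions$end[ri] - regions$start[ri]
        if (span < L) next
        chrom <- regions$chrom[ri]
        start <- regions$start[ri] + sample.int(span - L + 1L, 1) - 1L
      }
      if (nrow(placed) > 0) {
        clash <- placed$chrom == chrom & placed$start < start + L & placed$end > start
        if (any(clash)) next
      }
      strand <- sample(c("+", "-"), 1)
      hit <- stats::runif(L) < config$motif_planting_fidelity
      codes <- ifelse(hit, consensus,
                      ((consensus - 1L + sample.int(3L, L, replace = TRUE)) %% 4L) + 1L)
      if (strand == "-") codes <- rev(complement_codes(codes))
      substr(seqs[[chrom]], start + 1L, start + L) <- codes_to_seq(codes)
      placed <- dplyr::bind_rows(placed, tibble::tibble(
        chrom = chrom, start = as.integer(start), end = as.integer(start + L),
        strand = strand, planted = TRUE
      ))
    }
  })
  placed <- dplyr::arrange(placed, chrom, start)
  list(genome = seqs, motifs = placed)
}

#' Simulate the rDHS x biosample activity matrix
#'
#' Active rDHSs are unmasked in `1 - mask_rate_active` of biosamples with
#' Z ~ N(z_active_mean, z_active_sd); inactive rDHSs are mostly masked, with
#' unmasked entries ~ N(0, 1). Masked entries carry the -10 sentinel plus
#' the explicit mask flag.
#'
#' @param rdhs tibble with `rdhs_id`.
#' @param active logical vector (TRUE = truly active), same length.
#' @param config a `cbs_sim_config`.
#' @return a `cbs_activity_matrix`.
#' @export
simulate_activity_matrix <- function(rdhs, active, config) {
  stopifnot(inherits(config, "cbs_sim_config"))
  n <- nrow(rdhs)
  if (n == 0) stop("empty rDHS set")
  stopifnot(length(active) == n)
  m <- config$n_biosamples
  withr::with_seed(config$seed + SEED_OFFSETS["matrix"], {
    mask_p <- ifelse(active, config$mask_rate_active, config$mask_rate_inactive)
    masked <- matrix(stats::runif(n * m) < rep(mask_p, m), n, m)
    z <- matrix(0, n, m)
    act_rows <- matrix(rep(active, m), n, m)
    z[act_rows] <- stats::rnorm(sum(act_rows), config$z_active_mean, config$z_active_sd)
    z[!act_rows] <- stats::rnorm(sum(!act_rows), 0, 1)
  })
  z[masked] <- MASK_SENTINEL
  rownames(z) <- rdhs$rdhs_id
  colnames(z) <- sprintf("BS_%03d", seq_len(m))
  mask_zero_signal(z)
}

#' Simulate a trinucleotide mutation-rate table
#'
#' All 64 contexts x 3 alts, with transitions elevated 3x and CpG transitions
#' (C>T in a CG dinucleotide, and its G>A mirror) 8x, plus lognormal jitter;
#' rates are scaled to mean 1.
#'
#' @param seed integer seed.
#' @return tibble `context`, `ref`, `alt`, `mu`.
#' @export
simulate_mutation_rates <- function(seed = 1) {
  ctx <- expand.grid(up = BASES, ref = BASES, down = BASES,
                     stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(ctx)), function(i) {
    ref <- ctx$ref[i]
    data.frame(
      context = paste0(ctx$up[i], ref, ctx$down[i]),
      ref = ref,
      alt = setdiff(BASES, ref),
      stringsAsFactors = FALSE
    )
  }))
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  is_ts <- rows$alt == transitions[rows$ref]
  is_cpg <- (rows$ref == "C" & rows$alt == "T" & substr(rows$context, 3, 3) == "G") |
    (rows$ref == "G" & rows$alt == "A" & substr(rows$context, 1, 1) == "C")
  base <- ifelse(is_cpg & is_ts, 8, ifelse(is_ts, 3, 1))
  withr::with_seed(seed + SEED_OFFSETS["rates"], {
    mu <- base * exp(stats::rnorm(nrow(rows), 0, 0.2))
  })
  mu <- unname(mu / mean(mu))
  tibble::tibble(context = rows$context, ref = rows$ref, alt = rows$alt, mu = mu)
}

#' Simulate gnomAD-like SNVs with a planted singleton mechanism
#'
#' Places `n_variants` SNVs at uniform positions inside catalog motifs and
#' `n_control_variants` synonymous-like control SNVs outside them. Each
#' variant's singleton indicator is Bernoulli with
#' `p = singleton_base_rate + mutation_rate_slope * (mu - mean mu) +
#' effect[decile]` (effect only for truth loss-of-binding variants), clipped
#' to [0, 1]; clipping is reported. Singletons get AC = 1, others AC >= 2;
#' AN is constant; FILTER is PASS except a spiked fraction.
#'
#' @param cbs_catalog motif tibble with `chrom`, `start`, `end`, `strand` and
#'   optionally `decile` (activity decile of the supporting rDHS).
#' @param genome named character vector (REF alleles are read from it).
#' @param pwm a `cbs_pwm`; used to decide each variant's truth binding class
#'   from the planted motif's column weights.
#' @param rates mutation-rate tibble.
#' @param config a `cbs_sim_config`.
#' @return list with `variants` (tibble) and `truth` (tibble `variant_id`,
#'   `planted_effect`, `true_singleton_prob`, `truth_class`).
#' @export
simulate_variants <- function(cbs_catalog, genome, pwm, rates, config) {
  stopifnot(inherits(config, "cbs_sim_config"))
  seqs <- as_genome_strings(genome)
  n_cbs <- config$n_variants
  n_ctl <- config$n_control_variants
  if (n_cbs > 0 && nrow(cbs_catalog) == 0) stop("empty CBS catalog")
  if (n_cbs + n_ctl == 0) {
    return(list(variants = empty_variant_table(), truth = empty_truth_table()))
  }
  mu_bar <- mean(rates$mu)
  L <- pwm$length
  rc_lo <- reverse_complement_pwm(pwm)$log_odds
  withr::with_seed(config$seed + SEED_OFFSETS["variants"], {
    cbs <- NULL
    if (n_cbs > 0) {
      mi <- sample.int(nrow(cbs_catalog), n_cbs, replace = TRUE)
      off <- sample.int(L, n_cbs, replace = TRUE)          # 1-based offset in motif
      chrom <- cbs_catalog$chrom[mi]
      pos <- cbs_catalog$start[mi] + off                   # 1-based genome position
      ref <- substring_by_chrom(seqs, chrom, pos)
      ref_code <- match(ref, BASES)
      alt_code <- ((ref_code - 1L + sample.int(3L, n_cbs, replace = TRUE)) %% 4L) + 1L
      alt <- BASES[alt_code]
      strand <- cbs_catalog$strand[mi]
      col_plus <- off
      w_ref <- ifelse(strand == "+",
                      pwm$log_odds[cbind(ref_code, col_plus)],
                      rc_lo[cbind(ref_code, col_plus)])
      w_alt <- ifelse(strand == "+",
                      pwm$log_odds[cbind(alt_code, col_plus)],
                      rc_lo[cbind(alt_code, col_plus)])
      truth_class <- ifelse(w_ref - w_alt > 0, "loss", "gain")
      decile <- if ("decile" %in% names(cbs_catalog)) cbs_catalog$decile[mi] else NA_integer_
      cbs <- tibble::tibble(
        chrom = chrom, pos = pos, ref = ref, alt = alt,
        consequence = "regulatory_region_variant",
        truth_class = truth_class, decile = decile
      )
    }
    ctl <- NULL
    if (n_ctl > 0) {
      ctl <- draw_control_positions(seqs, cbs_catalog, n_ctl)
      ctl$consequence <- "synonymous_variant"
      ctl$truth_class <- "control"
      ctl$decile <- NA_integer_
    }
    all <- dplyr::bind_rows(cbs, ctl)
    all$context3 <- trinucleotide_context(seqs, all$chrom, all$pos)
    mu <- merge_mu_sim(all, rates)
    effect <- rep(0, nrow(all))
    has_eff <- all$truth_class == "loss" & !is.na(all$decile)
    effect[has_eff] <- config$selection_effect_by_decile[all$decile[has_eff]]
    p_raw <- config$singleton_base_rate +
      config$mutation_rate_slope * (mu - mu_bar) + effect
    p <- clip01(p_raw)
    n_clip <- sum(p != p_raw, na.rm = TRUE)
    if (n_clip > 0) message(n_clip, " singleton probabilit(ies) clipped to [0, 1]")
    singleton <- stats::runif(nrow(all)) < p
    ac <- ifelse(singleton, 1L, 2L + stats::rpois(nrow(all), 2))
    filt <- ifelse(stats::runif(nrow(all)) < config$filter_fail_rate, "LowQual", "PASS")
    variants <- tibble::tibble(
      variant_id = sprintf("var%07d", seq_len(nrow(all))),
      chrom = all$chrom, pos = all$pos, ref = all$ref, alt = all$alt,
      AC = as.integer(ac), AN = as.integer(config$an_value),
      AF = ac / config$an_value,
      filter = filt,
      consequence = all$consequence,
      cadd_phred = pmax(0, stats::rnorm(nrow(all), 5 + 40 * effect, 3)),
      context3 = all$context3
    )
    truth <- tibble::tibble(
      variant_id = variants$variant_id,
      planted_effect = effect,
      true_singleton_prob = p,
      truth_class = all$truth_class,
      decile = all$decile
    )
  })
  list(variants = variants, truth = truth)
}

empty_variant_table <- function() {
  tibble::tibble(
    variant_id = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0), AC = integer(0), AN = integer(0),
    AF = numeric(0), filter = character(0), consequence = character(0),
    cadd_phred = numeric(0), context3 = character(0)
  )
}

empty_truth_table <- function() {
  tibble::tibble(
    variant_id = character(0), planted_effect = numeric(0),
    true_singleton_prob = numeric(0), truth_class = character(0),
    decile = integer(0)
  )
}

substring_by_chrom <- function(seqs, chrom, pos) {
  out <- character(length(chrom))
  for (cn in unique(chrom)) {
    idx <- chrom == cn
    out[idx] <- substring(seqs[[cn]], pos[idx], pos[idx])
  }
  out
}

trinucleotide_context <- function(seqs, chrom, pos) {
  out <- rep(NA_character_, length(chrom))
  for (cn in unique(chrom)) {
    idx <- which(chrom == cn)
    len <- nchar(seqs[[cn]])
    inside <- pos[idx] > 1 & pos[idx] < len
    out[idx[inside]] <- substring(seqs[[cn]], pos[idx][inside] - 1L,
                                  pos[idx][inside] + 1L)
  }
  out
}

# like merge_mu but keyed on a bare tibble with context3/alt
merge_mu_sim <- function(df, rates) {
  mu <- rates$mu[match(paste(df$context3, df$alt), paste(rates$context, rates$alt))]
  if (anyNA(mu[!is.na(df$context3)])) stop("context/alt missing from rate table")
  # contig-edge variants (NA context) get the mean rate; they are excluded
  # from MAPS downstream anyway
  mu[is.na(mu)] <- mean(rates$mu)
  mu
}

# uniform positions outside motif intervals (interior of contigs)
draw_control_positions <- function(seqs, motifs, n) {
  lens <- nchar(seqs)
  chrom <- sample(names(seqs), n, replace = TRUE, prob = lens)
  pos <- integer(n)
  for (cn in unique(chrom)) {
    idx <- which(chrom == cn)
    pos[idx] <- sample(seq.int(2L, lens[[cn]] - 1L), length(idx), replace = TRUE)
  }
  if (nrow(motifs)) {
    in_motif <- rep(FALSE, n)
    for (cn in unique(chrom)) {
      m <- motifs[motifs$chrom == cn, , drop = FALSE]
      if (!nrow(m)) next
      idx <- which(chrom == cn)
      ir <- IRanges::IRanges(m$start + 1L, m$end)
      qr <- IRanges::IRanges(pos[idx], width = 1L)
      in_motif[idx] <- IRanges::overlapsAny(qr, ir)
    }
    for (k in which(in_motif)) {
      repeat {
        p <- sample(seq.int(2L, lens[[chrom[k]]] - 1L), 1)
        m <- motifs[motifs$chrom == chrom[k], , drop = FALSE]
        if (!nrow(m) || !any(m$start < p & p <= m$end)) { pos[k] <- p; break }
      }
    }
  }
  ref <- substring_by_chrom(seqs, chrom, pos)
  ref_code <- match(ref, BASES)
  alt_code <- ((ref_code - 1L + sample.int(3L, n, replace = TRUE)) %% 4L) + 1L
  tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = BASES[alt_code])
}

#' Simulate a per-base conservation track
#'
#' Per-base N(0, conservation_sd) noise, shifted upward by
#' `conservation_effect` inside planted motifs that fall in truly active
#' rDHSs.
#'
#' @param genome named character vector.
#' @param motifs planted motif tibble (`chrom`, `start`, `end`).
#' @param in_active logical: motif lies in a truth-active rDHS.
#' @param config a `cbs_sim_config`.
#' @return named list of per-base numeric vectors (one per chromosome),
#'   bedGraph-writable with [write_bedgraph()].
#' @export
simulate_conservation_track <- function(genome, motifs, in_active, config) {
  seqs <- as_genome_strings(genome)
  stopifnot(nrow(motifs) == length(in_active))
  withr::with_seed(config$seed + SEED_OFFSETS["conservation"], {
    out <- lapply(names(seqs), function(cn) {
      v <- stats::rnorm(nchar(seqs[[cn]]), 0, config$conservation_sd)
      m <- motifs[motifs$chrom == cn & in_active, , drop = FALSE]
      for (i in seq_len(nrow(m))) {
        rng <- (m$start[i] + 1L):m$end[i]
        v[rng] <- v[rng] + config$conservation_effect
      }
      v
    })
  })
  names(out) <- names(seqs)
  out
}

SEED_OFFSETS <- c(SEED_OFFSETS, truth = 909L)

#' Simulate a complete input bundle with ground truth
#'
#' Orchestrates every generator into the full set of pipeline inputs:
#' genome, rDHS intervals with truth activity status, planted motifs (most
#' inside rDHSs, a configurable fraction outside), the activity matrix,
#' gnomAD-like variants (candidate set inside motifs + synonymous-like
#' control set), mutation rates, a conservation track, exclusion tracks, and
#' truth tables. The activity summary and its decile binning are computed on
#' the realized matrix so that planted selection effects are keyed to the
#' same deciles the analysis recovers.
#'
#' @param config a `cbs_sim_config`.
#' @param pfm a `cbs_pfm` (default: the package's synthetic CTCF-like PFM).
#' @return list of class `cbs_bundle`.
#' @export
simulate_cbs_bundle <- function(config = simulation_config(), pfm = synthetic_ctcf_pfm()) {
  stopifnot(inherits(config, "cbs_sim_config"))
  genome <- simulate_genome(config)
  rdhs <- simulate_rdhs_intervals(config)
  n_out <- round(config$n_motif_instances * config$frac_motifs_outside_rdhs)
  n_in <- config$n_motif_instances - n_out
  withr::with_seed(config$seed + SEED_OFFSETS["truth"], {
    active <- stats::runif(nrow(rdhs)) < config$frac_active_rdhs
    host_rows <- sample.int(nrow(rdhs), n_in)
  })
  planted_in <- plant_motifs(genome, pfm, config,
                             regions = rdhs[host_rows, ], n_instances = n_in)
  gaps <- interval_gaps(rdhs, genome)
  planted_out <- plant_motifs(planted_in$genome, pfm, config, regions = gaps,
                              n_instances = n_out,
                              seed = config$seed + SEED_OFFSETS["motifs"] + 1L)
  genome <- planted_out$genome
  motifs <- dplyr::bind_rows(planted_in$motifs, planted_out$motifs)
  motifs <- dplyr::arrange(motifs, chrom, start)

  mat <- simulate_activity_matrix(rdhs, active, config)
  scores <- summarize_activity(mat, method = "mean")
  q100 <- assign_activity_quantiles(scores, k = min(100, nrow(rdhs)))
  q10 <- assign_activity_quantiles(scores, k = 10)
  rdhs$active <- active
  rdhs$activity <- scores$activity[match(rdhs$rdhs_id, scores$rdhs_id)]
  rdhs$quantile <- q100$quantile[match(rdhs$rdhs_id, q100$rdhs_id)]
  rdhs$decile <- q10$quantile[match(rdhs$rdhs_id, q10$rdhs_id)]

  # truth catalog: host rDHS (if any) of each planted motif
  host <- rep(NA_integer_, nrow(motifs))
  ov <- GenomicRanges::findOverlaps(df_to_granges(motifs), df_to_granges(rdhs),
                                    minoverlap = 1L)
  host[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)
  motifs$rdhs_id <- ifelse(is.na(host), NA_character_, rdhs$rdhs_id[host])
  motifs$decile <- rdhs$decile[host]
  motifs$in_active_rdhs <- !is.na(host) & rdhs$active[host]

  rates <- simulate_mutation_rates(config$seed)
  sim_var <- simulate_variants(motifs, genome, pfm_to_pwm(pfm), rates, config)
  conservation <- simulate_conservation_track(genome, motifs,
                                              motifs$in_active_rdhs, config)
  exclusions <- simulate_exclusions(rdhs, genome, config)

  structure(
    list(
      config = config,
      pfm = pfm,
      genome = genome,
      rdhs = rdhs,
      motifs = motifs,
      activity_matrix = mat,
      variants = sim_var$variants,
      variant_truth = sim_var$truth,
      rates = rates,
      conservation = conservation,
      exclusions = exclusions,
      autosomes = names(genome)
    ),
    class = "cbs_bundle"
  )
}

# complement of intervals within contig bounds
interval_gaps <- function(intervals, genome) {
  seqs <- as_genome_strings(genome)
  out <- lapply(names(seqs), function(cn) {
    len <- nchar(seqs[[cn]])
    sub <- intervals[intervals$chrom == cn, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(sub$start + 1L, sub$end))
    gap <- IRanges::gaps(ir, start = 1L, end = len)
    tibble::tibble(chrom = cn, start = IRanges::start(gap) - 1L,
                   end = IRanges::end(gap))
  })
  dplyr::bind_rows(out)
}

# small random exclusion tracks (assembly gaps, blacklist, coding exons)
simulate_exclusions <- function(rdhs, genome, config) {
  seqs <- as_genome_strings(genome)
  lens <- nchar(seqs)
  draw <- function(k, width) {
    chrom <- sample(names(seqs), k, replace = TRUE, prob = lens)
    start <- vapply(chrom, function(cn) {
      sample.int(max(1L, lens[[cn]] - width), 1) - 1L
    }, integer(1))
    tibble::tibble(chrom = chrom, start = start, end = start + width)
  }
  withr::with_seed(config$seed + SEED_OFFSETS["exclusions"], {
    out <- list(
      gap = draw(5, 500L),
      blacklist = draw(5, 400L),
      coding_exon = draw(10, 200L)
    )
  })
  out
}

#' The package's synthetic CTCF-like position frequency matrix
#'
#' A 19-bp PFM constructed for this package (not a database motif): a
#' strongly constrained core with degenerate flanks, emulating the shape of
#' the canonical CTCF motif. Stored as a JASPAR-format text file under
#' `inst/extdata/synthetic_ctcf.jaspar`.
#'
#' @return a `cbs_pfm`.
#' @export
synthetic_ctcf_pfm <- function() {
  read_pfm_jaspar(system.file("extdata", "synthetic_ctcf.jaspar",
                              package = "cbsprio", mustWork = TRUE))
}
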