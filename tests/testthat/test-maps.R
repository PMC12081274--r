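# MAPS: context annotation, calibration, expectation, scoring, strata.

test_that("trinucleotide context is a literal plus-strand read-off", {
  g <- c(chr1 = "ACGTA")
  v <- tibble::tibble(chrom = "chr1", pos = 3, ref = "G")
  out <- annotate_context(v, g)
  expect_equal(out$context3, "CGT")

  # edge variants flagged NA
  edge <- tibble::tibble(chrom = "chr1", pos = c(1, 5), ref = c("A", "A"))
  out2 <- suppressMessages(annotate_context(edge, g))
  expect_true(all(is.na(out2$context3)))

  # ref mismatch is a hard error
  expect_error(
    annotate_context(tibble::tibble(chrom = "chr1", pos = 3, ref = "T"), g),
    "REF allele mismatch"
  )
})

two_point_fixture <- function() {
  # two contexts, equal weights: exact line through (1, 0.4) and (3, 0.6)
  rates <- tibble::tibble(
    context = c("ACA", "ACG"), ref = "C", alt = "T", mu = c(1, 3)
  )
  v1 <- tibble::tibble(context3 = "ACA", alt = "T",
                       AC = rep(c(1L, 5L), c(40, 60)))
  v2 <- tibble::tibble(context3 = "ACG", alt = "T",
                       AC = rep(c(1L, 5L), c(60, 40)))
  list(rates = rates, calib = dplyr::bind_rows(v1, v2))
}

test_that("calibration recovers the exact line through two equally weighted groups", {
  fx <- two_point_fixture()
  model <- maps_calibrate(fx$calib, fx$rates)
  expect_equal(model$slope, 0.1, tolerance = 1e-12)
  expect_equal(model$intercept, 0.3, tolerance = 1e-12)
  expect_equal(model$n_contexts, 2)

  # flat response: slope 0, intercept = common proportion
  flat <- fx$calib
  flat$AC <- rep(c(1L, 5L), length.out = nrow(flat))  # proportion 0.5 in both
  m2 <- maps_calibrate(flat, fx$rates)
  expect_equal(m2$slope, 0, tolerance = 1e-12)
  expect_equal(m2$intercept, 0.5, tolerance = 1e-12)

  # three collinear groups: exact fit
  rates3 <- tibble::tibble(context = c("AAA", "AAC", "AAG"), ref = "A",
                           alt = "C", mu = c(1, 2, 3))
  calib3 <- dplyr::bind_rows(
    tibble::tibble(context3 = "AAA", alt = "C", AC = rep(c(1L, 9L), c(20, 80))),
    tibble::tibble(context3 = "AAC", alt = "C", AC = rep(c(1L, 9L), c(30, 70))),
    tibble::tibble(context3 = "AAG", alt = "C", AC = rep(c(1L, 9L), c(40, 60)))
  )
  m3 <- maps_calibrate(calib3, rates3)
  expect_equal(m3$slope, 0.1, tolerance = 1e-12)
  expect_equal(m3$intercept, 0.1, tolerance = 1e-12)

  # singular fit rejected
  expect_error(maps_calibrate(fx$calib[fx$calib$context3 == "ACA", ], fx$rates),
               "distinct")
})

test_that("expected singletons: plug-in arithmetic, linear identity, clipping", {
  fx <- two_point_fixture()
  model <- maps_calibrate(fx$calib, fx$rates)
  # 50 variants at mu=1 and 50 at mu=3: 50*0.4 + 50*0.6 = 50
  cls <- tibble::tibble(context3 = rep(c("ACA", "ACG"), each = 50), alt = "T",
                        AC = 2L)
  exp_n <- expected_singletons(cls, model, fx$rates)
  expect_equal(as.numeric(exp_n), 50, tolerance = 1e-9)
  expect_equal(attr(exp_n, "n_clipped"), 0L)
  expect_equal(attr(exp_n, "expected_at_mean_mu"), 50, tolerance = 1e-9)

  # slope 0: expected = n * intercept
  m0 <- structure(list(intercept = 0.25, slope = 0), class = "cbs_maps_model")
  expect_equal(as.numeric(expected_singletons(cls, m0, fx$rates)), 25)

  # predictions beyond 1 are clipped and counted
  mhot <- structure(list(intercept = 0.9, slope = 0.2), class = "cbs_maps_model")
  exp_hot <- expected_singletons(cls, mhot, fx$rates)
  expect_gt(attr(exp_hot, "n_clipped"), 0)
  expect_equal(as.numeric(exp_hot), 50 * 1 + 50 * 1)  # mu=1 -> 1.1 -> 1; mu=3 -> 1.5 -> 1
})

test_that("the worked MAPS example and the self-null identity hold", {
  fx <- two_point_fixture()
  model <- maps_calibrate(fx$calib, fx$rates)
  # 100 variants (50 at each mu), 60 singletons: raw 0.6, expected 0.5
  cls <- tibble::tibble(
    context3 = rep(c("ACA", "ACG"), each = 50), alt = "T",
    AC = c(rep(1L, 30), rep(4L, 20), rep(1L, 30), rep(4L, 20))
  )
  res <- maps_score(cls, model, fx$rates, class_label = "worked")
  expect_equal(res$raw_proportion, 0.6)
  expect_equal(res$expected_proportion, 0.5, tolerance = 1e-9)
  expect_equal(res$maps, 0.1, tolerance = 1e-9)
  expect_equal(res$sem, sqrt(0.6 * 0.4 / 100), tolerance = 1e-12)
  expect_equal(res$sem, 0.049, tolerance = 1e-3)

  # calibration class scored against its own model: MAPS = 0 to precision
  self <- maps_score(fx$calib, model, fx$rates, class_label = "self")
  expect_lt(abs(self$maps), 1e-12)

  # degenerate n = 1
  one <- maps_score(tibble::tibble(context3 = "ACA", alt = "T", AC = 1L),
                    model, fx$rates, class_label = "one")
  expect_equal(one$raw_proportion, 1)
  expect_equal(one$sem, 0)

  expect_error(maps_score(fx$calib[0, ], model, fx$rates), "empty")
})

test_that("MAPS is invariant to duplicated mutation-rate rows (keyed merge)", {
  fx <- two_point_fixture()
  model <- maps_calibrate(fx$calib, fx$rates)
  dup_rates <- dplyr::bind_rows(fx$rates, fx$rates, fx$rates)
  res1 <- maps_score(fx$calib, model, fx$rates, "x")
  res2 <- maps_score(fx$calib, model, dup_rates, "x")
  expect_equal(res1, res2)
  m_dup <- maps_calibrate(fx$calib, dup_rates)
  expect_equal(m_dup$slope, model$slope)
})

test_that("maps_by_stratum partitions, flags small strata, and drops empties", {
  fx <- two_point_fixture()
  model <- maps_calibrate(fx$calib, fx$rates)
  df <- dplyr::bind_rows(
    dplyr::mutate(fx$calib, cls = "a"),
    dplyr::mutate(fx$calib[1:5, ], cls = "b")
  )
  out <- maps_by_stratum(df, "cls", model, fx$rates, min_n = 50)
  expect_equal(nrow(out), 2)
  expect_equal(sum(out$n_variants), nrow(df))
  expect_false(out$wide_uncertainty[out$cls == "a"])
  expect_true(out$wide_uncertainty[out$cls == "b"])
})
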