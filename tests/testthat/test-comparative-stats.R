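test_that("bootstrapped chi2 separates disjoint distributions decisively", {
  withr::with_seed(91, {
    a <- rnorm(800, 0, 0.5)
    b <- rnorm(800, 50, 0.5)
    res <- bootstrap_chi2(a, b, n_resamples = 200)
    expect_lt(res$p_value, 1e-10)
    expect_equal(res$df, 9L)
    expect_equal(res$mean_shift, mean(a) - mean(b))
  })
})

test_that("bootstrapped chi2 statistic is symmetric in its two samples", {
  withr::with_seed(92, {
    a <- rnorm(600)
    b <- rnorm(600, 0.3)
  })
  # the statistic is symmetric in the two binned samples; only Monte-Carlo
  # noise from the resampling stream distinguishes the two orderings
  r1 <- withr::with_seed(7, bootstrap_chi2(a, b, n_resamples = 400))
  r2 <- withr::with_seed(7, bootstrap_chi2(b, a, n_resamples = 400))
  expect_equal(r1$statistic, r2$statistic, tolerance = 0.05)
  expect_equal(r1$mean_shift, -r2$mean_shift)
  # and exactly symmetric when the samples are literally the same vector
  r3 <- withr::with_seed(8, bootstrap_chi2(a, a, n_resamples = 50))
  r4 <- withr::with_seed(8, bootstrap_chi2(a, a, n_resamples = 50))
  expect_identical(r3$statistic, r4$statistic)
})

test_that("degenerate constant input is refused", {
  expect_error(bootstrap_chi2(rep(1, 100), rep(1, 100)), "constant")
})

test_that("equal-width binning is available as an alternative", {
  withr::with_seed(93, {
    a <- rnorm(600); b <- rnorm(600, 2)
    r <- bootstrap_chi2(a, b, n_resamples = 50, binning = "width")
    expect_lt(r$p_value, 0.05)
  })
})

test_that("length-matched bootstrap covers zero when target comes from reference", {
  withr::with_seed(94, {
    reference <- tibble::tibble(
      sequence_length = round(rlnorm(3000, 6, 0.4)),
      exon_count = pmax(1, round(rlnorm(3000, 6, 0.4) / 50 + rnorm(3000, 0, 2)))
    )
    covered <- vapply(1:20, function(i) {
      target <- reference[sample.int(3000, 250), ]
      est <- length_matched_bootstrap(target, reference, "exon_count",
                                      n_draws = 100)
      est$conf_low <= 0 && est$conf_high >= 0
    }, logical(1))
    expect_gte(mean(covered), 0.9)
  })
})

test_that("length-matched bootstrap recovers a planted exon-count shift", {
  withr::with_seed(95, {
    reference <- tibble::tibble(
      sequence_length = round(rlnorm(4000, 6, 0.4)),
      exon_count = pmax(1, round(rlnorm(4000, 6, 0.4) / 60 + rnorm(4000, 0, 2)))
    )
    target <- reference[sample.int(4000, 300), ]
    target$exon_count <- target$exon_count + 3.7
    est <- length_matched_bootstrap(target, reference, "exon_count",
                                    n_draws = 200)
    expect_gte(3.7, est$conf_low)
    expect_lte(3.7, est$conf_high)
    expect_lt(abs(est$shift - 3.7), 1)

    # duplicating the reference leaves the estimate's distribution unchanged
    est2 <- length_matched_bootstrap(target,
                                     dplyr::bind_rows(reference, reference),
                                     "exon_count", n_draws = 200)
    se <- stats::sd(est$draw_means) / sqrt(200)
    expect_lt(abs(est2$shift - est$shift), 6 * se + 0.2)
  })
})

test_that("ortholog species counting is a distinct-species group-by", {
  tbl <- tibble::tibble(
    protein_id = c("P1", "P1", "P1", "P2"),
    species = c("mouse", "mouse", "rat", "mouse"),
    ortholog_id = c("m1", "m2", "r1", "m3")
  )
  expect_equal(count_ortholog_species(tbl, "P1"), 2L)
  expect_equal(count_ortholog_species(tbl, "P2"), 1L)
  expect_equal(count_ortholog_species(tbl, "P3"), 0L)
  expect_equal(count_ortholog_species(tbl[0, ], "P1"), 0L)
  withr::with_seed(96, {
    big <- tibble::tibble(
      protein_id = sample(paste0("P", 1:40), 300, replace = TRUE),
      species = sample(paste0("sp", 1:12), 300, replace = TRUE),
      ortholog_id = paste0("o", 1:300)
    )
    got <- count_ortholog_species(big)
    ref <- tapply(big$species, big$protein_id,
                  function(s) length(unique(s)))
    expect_equal(got$n_species, as.integer(ref[got$protein_id]),
                 ignore_attr = TRUE)
  })
})

test_that("set association flags overlap and is symmetric; null is conservative", {
  u <- paste0("P", 1:1000)
  half <- u[1:500]
  r <- withr::with_seed(5, set_association(half, half, u, n_resamples = 200))
  expect_lt(r$p_value, 0.01)
  expect_equal(r$df, 1L)

  a <- u[1:300]; b <- u[201:500]
  r1 <- withr::with_seed(6, set_association(a, b, u, n_resamples = 100))
  r2 <- withr::with_seed(6, set_association(b, a, u, n_resamples = 100))
  expect_equal(r1$statistic, r2$statistic)

  expect_error(set_association("x", "x", character(0)), "empty universe")

  # independent sets: rejections stay at or below the nominal level
  withr::with_seed(97, {
    rej <- vapply(1:40, function(i) {
      aa <- sample(u, 200); bb <- sample(u, 300)
      set_association(aa, bb, u, n_resamples = 100)$p_value < 0.05
    }, logical(1))
  })
  expect_lte(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 40))
})

test_that("term coverage is the annotated-intersection fraction", {
  ann <- tibble::tibble(
    protein_id = c("P1", "P2", "P3", "P4"),
    term = c("t1", "t1", "t1", "t2")
  )
  expect_equal(term_coverage(c("P1", "P2", "P3", "P4"), "t1", ann), 1)
  expect_equal(term_coverage("P4", "t1", ann), 0)
  expect_equal(term_coverage(c("P1", "P9"), "t1", ann), 1 / 3)
  expect_error(term_coverage("P1", "t9", ann), "no annotations")

  # descendants contribute when a slim is supplied
  slim <- go_slim(tibble::tibble(term = "t2", parent = "t1"))
  expect_equal(term_coverage("P4", "t1", ann, slim), 1 / 4)
  withr::with_seed(98, {
    for (i in 1:10) {
      set <- sample(ann$protein_id, 2)
      annotated <- unique(ann$protein_id[ann$term == "t1"])
      expect_equal(term_coverage(set, "t1", ann),
                   length(intersect(annotated, set)) / length(annotated))
    }
  })
})
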