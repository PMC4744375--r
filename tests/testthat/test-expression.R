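test_that("leave-one-out z-score matches the hand-computed example", {
  expect_equal(zscore_relative(c(1, 2, 3, 4, 10), 5),
               (10 - 2.5) / sd(1:4), tolerance = 1e-12)
  expect_equal(round(zscore_relative(c(1, 2, 3, 4, 10), 5), 5), 5.80948)
  # focal equal to the reference mean scores 0
  expect_equal(zscore_relative(c(1, 3, 2), 3), 0)
  # constant reference: degenerate, not infinite
  expect_true(is.na(zscore_relative(c(5, 5, 5, 5, 7), 5)))
  expect_error(zscore_relative(c(1, 2), 1), ">= 3")
})

test_that("leave-one-out z-scores equal brute-force recomputation", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(3:40, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 50))
    for (i in sample(n, min(n, 5))) {
      expect_equal(zscore_relative(x, i), loo_z_brute(x, i), tolerance = 1e-8)
    }
  }
})

test_that("z-scores are location-scale invariant", {
  set.seed(8)
  x <- rlnorm(25, 7, 1)
  z0 <- vapply(seq_along(x), function(i) zscore_relative(x, i), numeric(1))
  z_shift <- vapply(seq_along(x), function(i) zscore_relative(x + 1000, i),
                    numeric(1))
  z_scale <- vapply(seq_along(x), function(i) zscore_relative(x * 3.7, i),
                    numeric(1))
  expect_equal(z0, z_shift, tolerance = 1e-8)
  expect_equal(z0, z_scale, tolerance = 1e-8)
})

test_that("fold change follows the pseudocount rule", {
  expect_equal(fold_change_relative(c(1, 2, 3, 4, 10), 5, pseudocount = 0), 4)
  expect_equal(fold_change_relative(c(2.5, 2.5, 2.5, 2.5), 1, pseudocount = 0), 1)
  expect_equal(fold_change_relative(c(0, 0, 0, 0), 1, pseudocount = 1), 1)
  expect_error(fold_change_relative(c(0, 0, 0, 0), 1, pseudocount = 0), "zero")
})

test_that("expression calls classify by threshold and exclude normals", {
  d <- withr::local_tempdir()
  set.seed(21)
  tumor_bc <- toy_barcodes(1:20, "01")
  normal_bc <- toy_barcodes(1:5, "11")
  vals <- matrix(rnorm(2 * 25, 100, 10), nrow = 2)
  vals[vals < 0] <- 0
  vals[1, 3] <- 100 + 6 * 10       # clear over-expressor among tumors
  vals[2, 21:25] <- 1e5            # extreme normals must not matter
  p <- write_toy_rsem(file.path(d, "a.rsem"), c("A|1", "B|2"),
                      c(tumor_bc, normal_bc), vals)
  em <- read_rsem_matrix(p, "LUAD")
  calls <- expression_calls(em, c("A", "B"), threshold = 2)
  expect_equal(nrow(calls), 40L)  # 2 genes x 20 tumor samples
  expect_false(any(calls$sample_key %in% parse_barcode(normal_bc)$sample_key))
  a3 <- calls[calls$gene == "A" & calls$barcode == tumor_bc[3], ]
  expect_equal(a3$call, "over")
  # normals excluded from the reference too: B stays mostly neutral
  expect_true(mean(calls$call[calls$gene == "B"] == "neutral") > 0.8)
  expect_error(expression_calls(em, "MISSING"), "MISSING")

  fc <- expression_calls(em, "A", method = "foldchange", threshold = 2)
  expect_true(all(fc$call[!is.na(fc$call) & fc$score <= 0.5] == "under"))
  expect_true(all(fc$call[!is.na(fc$call) & fc$score >= 2] == "over"))
})

test_that("waterfall data filters neutrals and orders panels", {
  d <- withr::local_tempdir()
  tumor_bc <- toy_barcodes(1:10, "01")
  set.seed(5)
  vals <- matrix(rnorm(10, 100, 10), nrow = 1)
  vals[1, 1] <- 200; vals[1, 2] <- 10
  p <- write_toy_rsem(file.path(d, "a.rsem"), "A|1", tumor_bc, vals)
  em <- read_rsem_matrix(p, "LUAD")
  calls <- expression_calls(em, "A", threshold = 2)
  wf <- waterfall_data(calls)
  expect_true(all(wf$call != "neutral"))
  expect_true(all(diff(wf$score[wf$panel == "LUAD"]) <= 0))
  expect_equal(wf$rank, seq_len(nrow(wf)))
  # gene-centric view panels by gene
  wf2 <- waterfall_data(calls, axis = "gene_centric")
  expect_equal(unique(wf2$panel), "A")
  # empty after filtering: empty frame, not an error
  calls_hi <- expression_calls(em, "A", threshold = 50)
  expect_equal(nrow(waterfall_data(calls_hi)), 0L)
})

test_that("box-plot summaries use linear-interpolation quartiles", {
  d <- withr::local_tempdir()
  tumor_bc <- toy_barcodes(1:9, "01")
  p <- write_toy_rsem(file.path(d, "a.rsem"), "A|1",
                      tumor_bc, matrix(1:9, nrow = 1))
  em <- read_rsem_matrix(p, "LUAD")
  s <- entity_boxplot_summary(em, "A")
  expect_equal(s$median, 5)
  expect_equal(s$q1, 3)
  expect_equal(s$q3, 7)
  expect_equal(s$whisker_low, 1)
  expect_equal(s$whisker_high, 9)

  # single extreme outlier excluded from the whisker range
  p2 <- write_toy_rsem(file.path(d, "b.rsem"), "A|1",
                       toy_barcodes(1:10, "01"),
                       matrix(c(1:9, 100), nrow = 1))
  s2 <- entity_boxplot_summary(read_rsem_matrix(p2, "LUAD"), "A")
  expect_lt(s2$whisker_high, 100)
})

test_that("planted +4sd outliers are recovered at threshold 2", {
  d <- withr::local_tempdir()
  spec <- cohort_spec(seed = 13)
  g <- generate_cohort(spec, d)
  em <- read_rsem_matrix(g$paths$rsem, "SYNT")
  calls <- expression_calls(em, "KRAS", threshold = 2, log2 = TRUE)
  planted <- vapply(g$truth$expression_outliers,
                    function(o) o$barcode, character(1))
  planted <- planted[vapply(g$truth$expression_outliers,
                            function(o) o$gene == "KRAS", logical(1))]
  got <- calls$barcode[calls$call == "over" & !is.na(calls$call)]
  expect_true(all(planted %in% got))
})
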