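test_that("pairing matches participants and tie-breaks deterministically", {
  bc <- c("TCGA-AB-0001-01A-11D-A001-01",  # P1 tumor
          "TCGA-AB-0001-11A-11D-A001-01",  # P1 normal
          "TCGA-AB-0002-01A-11D-A001-01")  # P2 tumor, unpaired
  pr <- build_pairing(bc)
  expect_equal(nrow(pr$pairs), 1L)
  expect_equal(pr$pairs$tumor_key, "TCGA-AB-0001-01")
  expect_equal(pr$pairs$normal_key, "TCGA-AB-0001-11")
  expect_equal(pr$unpaired_tumors, "TCGA-AB-0002-01")

  # participant with two tumor sample types: smallest key joins the pair
  bc2 <- c("TCGA-AB-0001-06A-11D-A001-01", "TCGA-AB-0001-01A-11D-A001-01",
           "TCGA-AB-0001-11A-11D-A001-01")
  pr2 <- build_pairing(bc2)
  expect_equal(nrow(pr2$pairs), 1L)
  expect_equal(pr2$pairs$tumor_key, "TCGA-AB-0001-01")
  expect_equal(pr2$unpaired_tumors, "TCGA-AB-0001-06")

  # no normals: no pairs
  pr3 <- build_pairing(bc[c(1, 3)])
  expect_equal(nrow(pr3$pairs), 0L)
})

test_that("signed-rank test matches its stated examples and flags", {
  w <- wilcoxon_paired(c(1, 2, 3, 4, 5))
  expect_equal(w$statistic, 15)
  expect_equal(w$p_value, 2 / 32)
  expect_true(w$exact)

  # symmetric {+d, -d} differences sit deep in the null
  w2 <- wilcoxon_paired(c(0.1, -0.1, 0.2, -0.2, 0.3, -0.3))
  expect_gte(w2$p_value, 0.5)

  w3 <- wilcoxon_paired(c(0, 0, 0))
  expect_equal(w3$p_value, 1)
  expect_true(w3$degenerate)

  expect_true(wilcoxon_paired(c(1, 2, 3))$underpowered)
  # zeros dropped before ranking
  expect_equal(wilcoxon_paired(c(0, 1, 2, 3, 4, 5))$n, 5L)
})

test_that("exact signed-rank p equals sign-flip enumeration", {
  set.seed(31)
  for (n in 3:8) {
    for (rep in 1:5) {
      d <- round(rnorm(n), 3)
      while (any(d == 0) || anyDuplicated(abs(d))) d <- round(rnorm(n), 3)
      expect_equal(wilcoxon_paired(d)$p_value, paired_enum_p(d),
                   tolerance = 1e-12)
    }
  }
})

test_that("rank-sum test matches its stated examples and enumeration", {
  w <- wilcoxon_unpaired(c(10, 11, 12), c(1, 2, 3))
  expect_equal(w$p_value, 0.1)
  expect_true(w$exact)
  expect_equal(wilcoxon_unpaired(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # one observation per group can never separate: p = 1
  expect_equal(wilcoxon_unpaired(0.3, 0.8)$p_value, unpaired_enum_p(0.3, 0.8))
  expect_equal(wilcoxon_unpaired(0.3, 0.8)$p_value, 1)
  expect_error(wilcoxon_unpaired(numeric(0), 1), "nonempty")

  set.seed(32)
  for (m in 2:5) for (n in 2:5) {
    x <- rnorm(m); y <- rnorm(n)
    expect_equal(wilcoxon_unpaired(x, y)$p_value, unpaired_enum_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the step-up oracle and is monotone", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")

  set.seed(33)
  for (rep in 1:50) {
    p <- runif(sample(1:200, 1))
    expect_lt(max(abs(bh_adjust(p) - bh_oracle(p))), 1e-12)
  }
  # adding a strictly larger p never decreases any adjusted value
  for (rep in 1:20) {
    p <- runif(sample(2:50, 1), 0, 0.9)
    q1 <- bh_adjust(p)
    q2 <- bh_adjust(c(p, max(p) + 0.05))
    expect_true(all(q2[seq_along(p)] >= q1 - 1e-12))
  }
})

test_that("differential methylation recovers a planted shift, paired mode", {
  d <- withr::local_tempdir()
  g <- generate_cohort(cohort_spec(seed = 41), d)
  mt <- read_methylation(g$paths$methylation, "SYNT")
  res <- differential_methylation(mt, mode = "paired")
  hit <- res[res$gene == "SFRP1" & res$region == "Body", ]
  expect_lt(hit$p_adj, 0.05)
  expect_equal(hit$direction, "hyper")
  expect_gt(hit$delta_beta, 0.2)
  # control gene's Body region stays quiet
  ctrl <- res[res$gene == "SFRP4" & res$region == "Body", ]
  expect_gt(ctrl$p_adj, 0.05)
  expect_true(all(res$p_adj >= res$p_raw - 1e-12, na.rm = TRUE))

  # unpaired mode agrees on the planted region
  res_u <- differential_methylation(mt, mode = "unpaired")
  expect_lt(res_u$p_adj[res_u$gene == "SFRP1" & res_u$region == "Body"], 0.05)
})

test_that("direction comes from delta-beta alone", {
  set.seed(44)
  rows <- data.frame(gene = paste0("G", 1:10), region = "Body",
                     stringsAsFactors = FALSE)
  betas <- matrix(rbeta(10 * 12, 2, 2), nrow = 10)
  delta <- seq(-0.45, 0.45, length.out = 10)
  betas[, 1:6] <- pmin(1, pmax(0, betas[, 1:6] + delta))
  mt <- make_meth_table(betas, rows, nt = 6, nn = 6)
  res <- differential_methylation(mt, mode = "unpaired")
  expect_equal(res$direction, ifelse(res$delta_beta > 0, "hyper",
                                     ifelse(res$delta_beta < 0, "hypo", "none")))
  # directions are untouched by how (in)significant the p-values are
  res2 <- differential_methylation(mt, mode = "unpaired", alpha = 1e-9)
  expect_equal(res2$direction, res$direction)
})

test_that("insufficient data yields missing p outside the BH family", {
  rows <- data.frame(gene = c("A", "B"), region = c("Body", "Body"),
                     stringsAsFactors = FALSE)
  betas <- rbind(c(0.8, 0.9, 0.85, 0.1, 0.2, 0.15),
                 rep(NA_real_, 6))
  mt <- make_meth_table(betas, rows, nt = 3, nn = 3)
  res <- differential_methylation(mt, mode = "unpaired")
  expect_true(is.na(res$p_raw[res$gene == "B"]))
  expect_true(is.na(res$p_adj[res$gene == "B"]))
  # family size 1: adjusted equals raw for the tested row
  expect_equal(res$p_adj[res$gene == "A"], res$p_raw[res$gene == "A"])

  # paired mode without pairs errors
  bc <- toy_barcodes(1:6, "01")
  mt2 <- methylation_table("X", rows, bc, betas)
  expect_error(differential_methylation(mt2, mode = "paired"), "pair")
})

test_that("delta histograms bin pair differences on [-1, 1] by 0.05", {
  rows <- data.frame(gene = "G", region = "Body", stringsAsFactors = FALSE)
  nt <- 10
  tumor <- 0.5 + 0.12
  betas <- matrix(c(rep(tumor, nt), rep(0.5, nt)), nrow = 1)
  mt <- make_meth_table(betas, rows, nt = nt, nn = nt)
  h <- delta_histogram(mt, "G", "Body")
  expect_equal(sum(h$count), 10L)
  expect_equal(h$count[h$bin_low == 0.10], 10L)  # +0.12 in [0.10, 0.15)
  expect_equal(attr(h, "n_pairs"), 10L)

  # symmetric +-0.22 differences fill two mirrored bins
  betas2 <- matrix(c(rep(0.72, 5), rep(0.28, 5), rep(0.5, 10)), nrow = 1)
  mt2 <- make_meth_table(betas2, rows, nt = 10, nn = 10)
  h2 <- delta_histogram(mt2, "G", "Body")
  expect_equal(h2$count[h2$bin_low == 0.20], 5L)
  expect_equal(h2$count[h2$bin_low == -0.25], 5L)

  bc <- toy_barcodes(1:4, "01")
  mt3 <- methylation_table("X", rows, bc, matrix(0.5, 1, 4))
  expect_error(delta_histogram(mt3, "G", "Body"), "pairs")
})
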