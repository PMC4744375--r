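test_that("MAF reader drops unknown symbols and enforces its contract", {
  d <- withr::local_tempdir()
  bc <- toy_barcodes(1:3)
  p <- write_toy_maf(file.path(d, "a.maf"), list(
    c("TP53", "7157", "Missense_Mutation", bc[1]),
    c("?", "0", "Silent", bc[2]),
    c("VHL", "7428", "Nonsense_Mutation", bc[3])
  ))
  rec <- read_maf(p, "BRCA")
  expect_equal(nrow(rec), 2L)
  expect_equal(attr(rec, "reader_report")$dropped_unknown_symbol, 1L)
  expect_equal(rec$variant_class, c("Missense_Mutation", "Nonsense_Mutation"))

  # header-only file: empty result, no error
  p2 <- write_toy_maf(file.path(d, "empty.maf"), list())
  expect_equal(nrow(read_maf(p2, "BRCA")), 0L)

  # missing mandatory column
  p3 <- write_toy_maf(file.path(d, "bad.maf"),
                      list(c("TP53", "x", bc[1])),
                      header = c("Hugo_Symbol", "Entrez_Gene_Id",
                                 "Tumor_Sample_Barcode"))
  expect_error(read_maf(p3, "BRCA"), "Variant_Classification")

  # unparseable barcode: row skipped with warning, counted
  p4 <- write_toy_maf(file.path(d, "skip.maf"), list(
    c("TP53", "7157", "Missense_Mutation", bc[1]),
    c("TP53", "7157", "Missense_Mutation", "not-a-barcode")
  ))
  expect_warning(rec4 <- read_maf(p4, "BRCA"), "unparseable")
  expect_equal(nrow(rec4), 1L)
  expect_equal(attr(rec4, "reader_report")$skipped_bad_barcode, 1L)
})

test_that("RSEM reader handles ids, the measure-name line and bad cells", {
  d <- withr::local_tempdir()
  bc <- toy_barcodes(1:3)
  vals <- matrix(c(1.5, 2, 3, 10, 20, 30, 5, 5, 5), nrow = 3, byrow = TRUE)
  p <- write_toy_rsem(file.path(d, "a.rsem"),
                      c("TP53|7157", "?|100130426", "KRAS|3845"), bc, vals)
  em <- read_rsem_matrix(p, "LUAD")
  expect_equal(em$genes$symbol, c("TP53", "KRAS"))
  expect_equal(em$genes$gene_id, c("7157", "3845"))
  expect_equal(em$report$dropped_unknown_symbol, 1L)
  expect_equal(unname(em$values["TP53", ]), c(1.5, 2, 3))

  # identical result without the measure-name line
  p2 <- write_toy_rsem(file.path(d, "b.rsem"),
                       c("TP53|7157", "?|100130426", "KRAS|3845"), bc, vals,
                       measure_line = FALSE)
  em2 <- read_rsem_matrix(p2, "LUAD")
  expect_equal(em2$values, em$values)

  # duplicate symbols are disambiguated by numeric id
  p3 <- write_toy_rsem(file.path(d, "c.rsem"),
                       c("DUP|1", "DUP|2"), bc, vals[1:2, ])
  em3 <- read_rsem_matrix(p3, "LUAD")
  expect_setequal(em3$genes$row_id, c("DUP|1", "DUP|2"))

  # non-numeric cell is a format error with coordinates
  writeLines(c(paste(c("Hybridization REF", bc), collapse = "\t"),
               paste(c("TP53|7157", "1", "oops", "3"), collapse = "\t")),
             file.path(d, "bad.rsem"))
  expect_error(read_rsem_matrix(file.path(d, "bad.rsem"), "LUAD"),
               "row 1, sample column 2")
})

test_that("GISTIC reader validates categories and duplicate symbols", {
  d <- withr::local_tempdir()
  bc <- toy_barcodes(1:3)
  cats <- matrix(c(2L, 0L, -1L, 1L, -2L, 0L), nrow = 2, byrow = TRUE)
  p <- write_toy_gistic(file.path(d, "a.gistic"), c("FGFR1", "PIK3CA"), bc, cats)
  cm <- read_gistic_thresholded(p, "LUSC")
  expect_equal(dim(cm$categories), c(2L, 3L))
  expect_equal(unname(cm$categories[1, ]), c(2L, 0L, -1L))
  expect_equal(cm$annotation$cytoband, c("1q21", "1q21"))

  cats_bad <- cats; cats_bad[1, 2] <- 3L
  p2 <- write_toy_gistic(file.path(d, "b.gistic"), c("FGFR1", "PIK3CA"), bc,
                         cats_bad)
  expect_error(read_gistic_thresholded(p2, "LUSC"), "outside \\{-2,-1,0,1,2\\}")

  p3 <- write_toy_gistic(file.path(d, "c.gistic"), c("FGFR1", "FGFR1"), bc, cats)
  expect_error(read_gistic_thresholded(p3, "LUSC"), "FGFR1")
})

test_that("methylation reader aggregates probes and respects missingness", {
  d <- withr::local_tempdir()
  bc <- toy_barcodes(1:2)
  # two probes of (SFRP1, Body): 0.2 and 0.4 -> mean 0.3;
  # second sample: one probe missing -> mean of the other; gene2 all-missing
  betas <- rbind(c(0.2, 0.5), c(0.4, NA), c(NA, NA))
  p <- write_toy_methylation(file.path(d, "a.meth"),
                             c("cg01", "cg02", "cg03"),
                             c("SFRP1", "SFRP1", "SFRP4"),
                             c("Body", "Body", "TSS200"), bc, betas)
  mt <- read_methylation(p, "COAD")
  i <- which(mt$rows$gene == "SFRP1" & mt$rows$region == "Body")
  expect_equal(unname(mt$betas[i, ]), c(0.3, 0.5))
  j <- which(mt$rows$gene == "SFRP4")
  expect_true(all(is.na(mt$betas[j, ])))  # missing, not zero

  # composite region annotation contributes to each region
  p2 <- write_toy_methylation(file.path(d, "b.meth"), "cg01", "SFRP1",
                              "Body;3'UTR", bc, rbind(c(0.25, 0.75)))
  mt2 <- read_methylation(p2, "COAD")
  expect_setequal(mt2$rows$region, c("Body", "3'UTR"))
  expect_equal(unname(mt2$betas[, 1]), c(0.25, 0.25))

  # beta outside [0,1] is a format error; unknown region is skipped
  p3 <- write_toy_methylation(file.path(d, "c.meth"), "cg01", "SFRP1",
                              "Body", bc, rbind(c(1.2, 0.5)))
  expect_error(read_methylation(p3, "COAD"), "outside \\[0,1\\]")
  p4 <- write_toy_methylation(file.path(d, "d.meth"), c("cg01", "cg02"),
                              c("SFRP1", "SFRP1"), c("Body", "Promoter"), bc,
                              rbind(c(0.2, 0.3), c(0.2, 0.3)))
  expect_warning(mt4 <- read_methylation(p4, "COAD"), "unknown region")
  expect_equal(nrow(mt4$rows), 1L)
})

test_that("probe aggregation commutes with sample subsetting", {
  d <- withr::local_tempdir()
  set.seed(42)
  bc <- toy_barcodes(1:6)
  n_probe <- 10L
  betas <- matrix(round(runif(n_probe * 6), 6), nrow = n_probe)
  betas[sample(length(betas), 8)] <- NA
  p <- write_toy_methylation(file.path(d, "a.meth"),
                             sprintf("cg%02d", seq_len(n_probe)),
                             rep(c("A", "B"), each = 5),
                             rep(c("Body", "TSS200"), 5), bc, betas)
  full <- read_methylation(p, "X")
  for (cols in list(1:3, c(2L, 5L), 6L)) {
    p_sub <- write_toy_methylation(file.path(d, "sub.meth"),
                                   sprintf("cg%02d", seq_len(n_probe)),
                                   rep(c("A", "B"), each = 5),
                                   rep(c("Body", "TSS200"), 5),
                                   bc[cols], betas[, cols, drop = FALSE])
    sub <- read_methylation(p_sub, "X")
    expect_equal(sub$betas, full$betas[, cols, drop = FALSE])
  }
})

test_that("summary tables round-trip with empty cells for missing", {
  d <- withr::local_tempdir()
  rows <- data.frame(gene = c("TP53", "VHL"), frequency = c(0.331, NA),
                     n = c(992L, NA), stringsAsFactors = FALSE)
  p <- write_summary_table(rows, file.path(d, "t.tsv"))
  raw <- readLines(p)
  expect_equal(raw[1], "gene\tfrequency\tn")
  expect_equal(raw[3], "VHL\t\t")  # empty cells, not "NA"
  back <- utils::read.delim(p, stringsAsFactors = FALSE)
  expect_equal(back$frequency, c(0.331, NA))

  # empty input: header-only file
  p2 <- write_summary_table(rows[0, ], file.path(d, "e.tsv"))
  expect_equal(length(readLines(p2)), 1L)
})

test_that("every generated dialect re-reads to the generator's truth", {
  d <- withr::local_tempdir()
  g <- generate_cohort(cohort_spec(n_participants = 15, seed = 5), d)
  em <- read_rsem_matrix(g$paths$rsem, "SYNT")
  expect_equal(max(abs(em$values - g$truth$rsem$values) /
                     pmax(1, abs(g$truth$rsem$values))), 0, tolerance = 1e-9)
  cm <- read_gistic_thresholded(g$paths$gistic, "SYNT")
  expect_identical(unname(cm$categories), g$truth$gistic$categories)
  tc <- truth_check(d)
  expect_true(tc$pass)
})
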