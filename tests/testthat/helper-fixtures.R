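# Programmatic fixtures: tiny files in the pinned Firehose dialects.

write_toy_maf <- function(path, rows,
                          header = c("Hugo_Symbol", "Entrez_Gene_Id",
                                     "Variant_Classification",
                                     "Tumor_Sample_Barcode")) {
  lines <- c(paste(header, collapse = "\t"),
             vapply(rows, paste, character(1L), collapse = "\t"))
  writeLines(lines, path)
  path
}

toy_barcodes <- function(i, type = "01") {
  sprintf("TCGA-AB-%04d-%sA-11D-A001-01", i, type)
}

# the 4-sample cohort with gene G: S1 has 2 missense, S2 one nonsense
toy_maf_example <- function() {
  bc <- toy_barcodes(1:4)
  path <- tempfile("toy", fileext = ".maf.txt")
  write_toy_maf(path, list(
    c("G", "1", "Missense_Mutation", bc[1]),
    c("G", "1", "Missense_Mutation", bc[1]),
    c("G", "1", "Nonsense_Mutation", bc[2])
  ))
  list(path = path, barcodes = bc)
}

write_toy_gistic <- function(path, genes, barcodes, categories) {
  lines <- c(
    paste(c("Gene Symbol", "Locus ID", "Cytoband", barcodes), collapse = "\t"),
    vapply(seq_along(genes), function(i) {
      paste(c(genes[i], as.character(i), "1q21", as.character(categories[i, ])),
            collapse = "\t")
    }, character(1L))
  )
  writeLines(lines, path)
  path
}

write_toy_rsem <- function(path, ids, barcodes, values, measure_line = TRUE) {
  lines <- c(
    paste(c("Hybridization REF", barcodes), collapse = "\t"),
    if (measure_line) {
      paste(c("gene_id", rep("normalized_count", length(barcodes))),
            collapse = "\t")
    },
    vapply(seq_along(ids), function(i) {
      paste(c(ids[i], sprintf("%.15g", values[i, ])), collapse = "\t")
    }, character(1L))
  )
  writeLines(lines, path)
  path
}

write_toy_methylation <- function(path, probe, gene, region, barcodes, betas) {
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.15g", x))
  lines <- c(
    paste(c("Probe_ID", "Gene_Symbol", "Gene_Region", barcodes), collapse = "\t"),
    vapply(seq_along(probe), function(i) {
      paste(c(probe[i], gene[i], region[i], fmt(betas[i, ])), collapse = "\t")
    }, character(1L))
  )
  writeLines(lines, path)
  path
}

# in-memory methylation table with nt tumors / nn normals and given rows
make_meth_table <- function(betas, rows, nt, nn, entity = "TEST") {
  bc <- c(toy_barcodes(seq_len(nt), "01"), toy_barcodes(seq_len(nn), "11"))
  methylation_table(entity, rows, bc, betas)
}
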