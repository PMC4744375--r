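#' Read a Firehose-style MAF somatic mutation table
#'
#' Reads a tab-separated Mutation Annotation Format file (level-2 somatic
#' calls). Lines starting with \code{#} are treated as comments. The header
#' must contain at least \code{Hugo_Symbol}, \code{Variant_Classification}
#' and \code{Tumor_Sample_Barcode}; any further columns are ignored.
#'
#' Rows whose symbol is \code{"Unknown"} or \code{"?"} are dropped; rows whose
#' barcode does not parse are skipped with a warning. Both counts are kept in
#' the reader report (\code{attr(x, "reader_report")}).
#'
#' @param path path to the MAF file.
#' @param entity cohort label (e.g. \code{"BRCA"}) attached to every record.
#' @return data.frame of class \code{"maf_records"} with columns
#'   \code{entity}, \code{gene}, \code{variant_class}, \code{barcode},
#'   \code{sample_key}, \code{is_tumor}.
#' @export
read_maf <- function(path, entity) {
  stopifnot(is.character(path), length(path) == 1L)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("Hugo_Symbol", "Variant_Classification", "Tumor_Sample_Barcode")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("MAF file '", path, "' is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  unknown <- df$Hugo_Symbol %in% c("Unknown", "?") | df$Hugo_Symbol == ""
  dropped_unknown <- sum(unknown)
  df <- df[!unknown, , drop = FALSE]

  skipped_barcode <- 0L
  if (nrow(df)) {
    ub <- unique(df$Tumor_Sample_Barcode)
    ok <- barcode_is_valid(ub)
    if (any(!ok)) {
      bad <- ub[!ok]
      skipped_barcode <- sum(df$Tumor_Sample_Barcode %in% bad)
      warning("skipped ", skipped_barcode, " MAF row(s) with unparseable barcode(s): ",
              paste(utils::head(bad, 5L), collapse = ", "))
      df <- df[!df$Tumor_Sample_Barcode %in% bad, , drop = FALSE]
    }
  }
  bc <- parse_barcode(df$Tumor_Sample_Barcode)
  records <- data.frame(
    entity = rep_len(entity, nrow(df)),
    gene = df$Hugo_Symbol,
    variant_class = df$Variant_Classification,
    barcode = df$Tumor_Sample_Barcode,
    sample_key = bc$sample_key,
    is_tumor = bc$is_tumor,
    stringsAsFactors = FALSE
  )
  rownames(records) <- NULL
  attr(records, "reader_report") <- list(
    dropped_unknown_symbol = dropped_unknown,
    skipped_bad_barcode = skipped_barcode
  )
  class(records) <- c("maf_records", "data.frame")
  records
}

#' Read a Firehose RSEM normalized gene-expression matrix
#'
#' Reads the RNA-SeqV2 level-3 dialect: the first column holds gene
#' identifiers as \code{"SYMBOL|NUMID"}, remaining columns are TCGA barcodes.
#' An optional second header line of per-column measure names
#' (e.g. \code{normalized_count}) is detected and skipped. Rows whose symbol
#' is \code{"?"} are dropped and counted.
#'
#' @param path path to the expression file.
#' @param entity cohort label.
#' @return object of class \code{"expression_matrix"}: a list with
#'   \code{entity}, \code{genes} (data.frame \code{symbol}, \code{gene_id},
#'   \code{row_id}), \code{samples} (a \code{tcga_barcodes} frame) and
#'   \code{values} (genes x samples numeric matrix, RSEM normalized counts).
#' @export
read_rsem_matrix <- function(path, entity) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("RSEM file '", path, "' has no sample columns")
  # optional second header line: value cells all non-numeric
  if (nrow(df) >= 1L) {
    first_vals <- suppressWarnings(as.numeric(unlist(df[1L, -1L], use.names = FALSE)))
    if (identical(df[[1L]][1L], "gene_id") || all(is.na(first_vals))) {
      df <- df[-1L, , drop = FALSE]
    }
  }
  ids <- df[[1L]]
  parts <- strsplit(ids, "|", fixed = TRUE)
  symbol <- vapply(parts, `[[`, character(1L), 1L)
  gene_id <- vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else NA_character_,
                    character(1L))
  drop <- symbol %in% c("?", "")
  n_dropped <- sum(drop)
  df <- df[!drop, , drop = FALSE]
  symbol <- symbol[!drop]
  gene_id <- gene_id[!drop]

  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("RSEM file '", path, "': non-numeric value '", vals[idx[1L], idx[2L]],
         "' at data row ", idx[1L], ", sample column ", idx[2L])
  }
  if (any(num < 0)) {
    idx <- which(num < 0, arr.ind = TRUE)[1L, ]
    stop("RSEM file '", path, "': negative expression value at data row ",
         idx[1L], ", sample column ", idx[2L])
  }
  # duplicate symbols are disambiguated by their numeric id
  row_id <- symbol
  dup <- symbol %in% symbol[duplicated(symbol)]
  row_id[dup] <- paste0(symbol[dup], "|", gene_id[dup])
  if (anyDuplicated(row_id)) {
    stop("RSEM file '", path, "': duplicate gene identifier(s): ",
         paste(unique(row_id[duplicated(row_id)]), collapse = ", "))
  }
  samples <- parse_barcode(colnames(df)[-1L])
  dimnames(num) <- list(row_id, samples$raw)
  out <- list(
    entity = entity,
    genes = data.frame(symbol = symbol, gene_id = gene_id, row_id = row_id,
                       stringsAsFactors = FALSE),
    samples = samples,
    values = num,
    report = list(dropped_unknown_symbol = n_dropped)
  )
  class(out) <- "expression_matrix"
  out
}

#' Read a GISTIC2.0 thresholded copy-number table
#'
#' Reads the level-4 \code{all_thresholded.by_genes} dialect: leading columns
#' \code{Gene Symbol}, \code{Locus ID}, \code{Cytoband}, then one column per
#' barcode with integer categories in \{-2, -1, 0, 1, 2\} (homozygous
#' deletion, heterozygous deletion, normal copy number, low-level and
#' high-level amplification).
#'
#' @param path path to the table.
#' @param entity cohort label.
#' @return object of class \code{"cnv_matrix"}: list with \code{entity},
#'   \code{genes}, \code{annotation} (locus id, cytoband), \code{samples}
#'   (\code{tcga_barcodes}) and \code{categories} (genes x samples integer
#'   matrix).
#' @export
read_gistic_thresholded <- function(path, entity) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("Gene Symbol", "Locus ID", "Cytoband")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("GISTIC file '", path, "' is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  genes <- df[["Gene Symbol"]]
  if (anyDuplicated(genes)) {
    stop("GISTIC file '", path, "': duplicate gene symbol(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  value_cols <- setdiff(names(df), need)
  if (!length(value_cols)) stop("GISTIC file '", path, "' has no sample columns")
  vals <- as.matrix(df[, value_cols, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- is.na(num) | !(num %in% c(-2, -1, 0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("GISTIC file '", path, "': value '", vals[idx[1L], idx[2L]],
         "' outside {-2,-1,0,1,2} at gene '", genes[idx[1L]],
         "', sample '", value_cols[idx[2L]], "'")
  }
  cat_mat <- matrix(as.integer(num), nrow = nrow(num))
  samples <- parse_barcode(value_cols)
  dimnames(cat_mat) <- list(genes, samples$raw)
  out <- list(
    entity = entity,
    genes = genes,
    annotation = data.frame(gene = genes, locus_id = df[["Locus ID"]],
                            cytoband = df[["Cytoband"]], stringsAsFactors = FALSE),
    samples = samples,
    categories = cat_mat
  )
  class(out) <- "cnv_matrix"
  out
}

# Six Illumina 450k gene-group region tokens.
METH_REGIONS <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR")

#' Read a level-3 450k methylation beta-value table
#'
#' Reads the pinned tab-separated dialect: annotation columns
#' \code{Gene_Symbol} and \code{Gene_Region}, optionally preceded by a
#' \code{Probe_ID} column, then one beta-value column per barcode. The
#' presence of the probe-id column marks probe-level data, which is
#' aggregated to (gene, region, sample) by the mean over probes, ignoring
#' missing betas; a cell whose probes are all missing stays missing.
#' Composite region annotations (\code{"Body;3'UTR"}) are split and the probe
#' contributes to each region. Rows with a region token outside the six 450k
#' gene groups are skipped with a warning.
#'
#' @param path path to the table.
#' @param entity cohort label.
#' @return object of class \code{"methylation_table"}: list with
#'   \code{entity}, \code{rows} (data.frame \code{gene}, \code{region}),
#'   \code{samples} (\code{tcga_barcodes}) and \code{betas}
#'   (rows x samples matrix in [0,1], NA allowed).
#' @export
read_methylation <- function(path, entity) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("Gene_Symbol", "Gene_Region")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("methylation file '", path, "' is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  probe_level <- "Probe_ID" %in% names(df)
  value_cols <- setdiff(names(df), c("Probe_ID", need))
  if (!length(value_cols)) stop("methylation file '", path, "' has no sample columns")

  vals <- as.matrix(df[, value_cols, drop = FALSE])
  vals[vals == "" | vals == "NA"] <- NA_character_
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  newly_na <- is.na(num) & !is.na(vals)
  if (any(newly_na)) {
    idx <- which(newly_na, arr.ind = TRUE)[1L, ]
    stop("methylation file '", path, "': non-numeric beta '",
         vals[idx[1L], idx[2L]], "' at data row ", idx[1L])
  }
  out_of_range <- !is.na(num) & (num < 0 | num > 1)
  if (any(out_of_range)) {
    idx <- which(out_of_range, arr.ind = TRUE)[1L, ]
    stop("methylation file '", path, "': beta value ", num[idx[1L], idx[2L]],
         " outside [0,1] at data row ", idx[1L])
  }

  # expand composite region annotations ("Body;3'UTR")
  region_lists <- strsplit(df$Gene_Region, ";", fixed = TRUE)
  reps <- lengths(region_lists)
  gene <- rep(df$Gene_Symbol, reps)
  region <- unlist(region_lists, use.names = FALSE)
  num <- num[rep(seq_len(nrow(num)), reps), , drop = FALSE]

  known <- region %in% METH_REGIONS
  n_skipped <- sum(!known)
  if (n_skipped) {
    warning("methylation file '", path, "': skipped ", n_skipped,
            " row(s) with unknown region token(s): ",
            paste(unique(region[!known]), collapse = ", "))
    gene <- gene[known]
    region <- region[known]
    num <- num[known, , drop = FALSE]
  }

  key <- paste(gene, region, sep = "\r")
  if (probe_level || anyDuplicated(key)) {
    groups <- split(seq_along(key), key)
    agg <- do.call(rbind, lapply(groups, function(i) {
      m <- num[i, , drop = FALSE]
      cnt <- colSums(!is.na(m))
      s <- colSums(m, na.rm = TRUE)
      ifelse(cnt > 0L, s / cnt, NA_real_)
    }))
    keys <- names(groups)
  } else {
    agg <- num
    keys <- key
  }
  parts <- strsplit(keys, "\r", fixed = TRUE)
  rows <- data.frame(
    gene = vapply(parts, `[[`, character(1L), 1L),
    region = vapply(parts, `[[`, character(1L), 2L),
    stringsAsFactors = FALSE
  )
  ord <- order(rows$gene, match(rows$region, METH_REGIONS))
  rows <- rows[ord, , drop = FALSE]
  agg <- agg[ord, , drop = FALSE]
  rownames(rows) <- NULL
  samples <- parse_barcode(value_cols)
  dimnames(agg) <- list(paste(rows$gene, rows$region, sep = ":"), samples$raw)
  out <- list(
    entity = entity,
    rows = rows,
    samples = samples,
    betas = agg,
    report = list(skipped_unknown_region = n_skipped)
  )
  class(out) <- "methylation_table"
  out
}

#' Construct a methylation table programmatically
#'
#' Builds the container returned by \code{\link{read_methylation}} from
#' in-memory pieces, for simulation and testing without file round-trips.
#'
#' @param entity cohort label.
#' @param rows data.frame with columns \code{gene} and \code{region}.
#' @param samples barcodes: character vector or \code{tcga_barcodes} frame.
#' @param betas rows x samples numeric matrix in [0,1]; NA allowed.
#' @return object of class \code{"methylation_table"}.
#' @export
methylation_table <- function(entity, rows, samples, betas) {
  if (is.character(samples)) samples <- parse_barcode(samples)
  stopifnot(is.data.frame(rows), all(c("gene", "region") %in% names(rows)),
            nrow(betas) == nrow(rows), ncol(betas) == nrow(samples))
  if (!all(rows$region %in% METH_REGIONS)) {
    stop("unknown region token(s): ",
         paste(setdiff(rows$region, METH_REGIONS), collapse = ", "))
  }
  if (any(!is.na(betas) & (betas < 0 | betas > 1))) {
    stop("beta values must lie in [0,1]")
  }
  dimnames(betas) <- list(paste(rows$gene, rows$region, sep = ":"), samples$raw)
  out <- list(entity = entity, rows = rows, samples = samples, betas = betas,
              report = list(skipped_unknown_region = 0L))
  class(out) <- "methylation_table"
  out
}

#' Write a tab-separated summary table
#'
#' Writes a UTF-8 TSV with header and stable column order. Floating-point
#' columns are rendered with 6 significant digits; missing values become
#' empty cells.
#'
#' @param rows data.frame of result rows sharing one schema.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_summary_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  fmt <- lapply(rows, function(col) {
    if (is.double(col)) {
      out <- trimws(formatC(col, digits = 6L, format = "g"))
      out[is.na(col)] <- ""
      out
    } else {
      out <- as.character(col)
      out[is.na(col)] <- ""
      out
    }
  })
  lines <- c(
    paste(names(rows), collapse = "\t"),
    if (nrow(rows)) do.call(paste, c(fmt, sep = "\t"))
  )
  con <- tryCatch(file(path, open = "wb", encoding = "UTF-8"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}
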