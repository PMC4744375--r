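#' Per-gene parameters for a synthetic cohort
#'
#' Bundles the planted parameters of one gene across the four data types:
#' mutation rate and variant-class mix for the MAF; category probabilities
#' for the GISTIC table; log-normal expression location/spread plus planted
#' outliers for the RSEM matrix; per-region baseline beta, tumor delta-beta
#' and Beta-distribution precision for the methylation table.
#'
#' Expression outliers are planted deterministically: the chosen tumor
#' sample's log-value is set to \code{expr_log_mean + offset * expr_log_sd},
#' so a +4 sd outlier sits at exactly four reference standard deviations.
#'
#' @param name HUGO-style symbol.
#' @param mutation_rate per-tumor-sample mutation probability in [0,1].
#' @param variant_class_weights named nonnegative weights over Firehose
#'   variant classes (normalized internally).
#' @param cnv_probs probabilities over categories -2,-1,0,1,2 (length 5,
#'   sums to 1).
#' @param expr_log_mean,expr_log_sd natural-log location and spread of the
#'   RSEM values.
#' @param outliers list of \code{list(sample = i, offset = k)} entries:
#'   tumor sample index and sd offset on the log scale.
#' @param meth_baseline baseline beta per region: scalar, or named vector
#'   over the region tokens.
#' @param meth_delta tumor-minus-normal beta shift: scalar or named vector.
#' @param meth_dispersion Beta-distribution precision phi
#'   (variance = m(1-m)/(1+phi)).
#' @param regions gene-group regions this gene carries (default all six).
#' @return list of class \code{"gene_spec"}.
#' @export
make_gene_spec <- function(name,
                           mutation_rate = 0.1,
                           variant_class_weights = c(
                             Missense_Mutation = 0.50, Nonsense_Mutation = 0.12,
                             Frame_Shift_Del = 0.08, Frame_Shift_Ins = 0.05,
                             Splice_Site = 0.07, Silent = 0.12,
                             In_Frame_Del = 0.03, In_Frame_Ins = 0.03),
                           cnv_probs = c(`-2` = 0.02, `-1` = 0.10, `0` = 0.72,
                                         `1` = 0.12, `2` = 0.04),
                           expr_log_mean = log(1000), expr_log_sd = 0.7,
                           outliers = list(),
                           meth_baseline = c(TSS1500 = 0.15, TSS200 = 0.10,
                                             `5'UTR` = 0.20, `1stExon` = 0.20,
                                             Body = 0.45, `3'UTR` = 0.50),
                           meth_delta = 0,
                           meth_dispersion = 20,
                           regions = METH_REGIONS) {
  g <- list(name = name, mutation_rate = mutation_rate,
            variant_class_weights = variant_class_weights,
            cnv_probs = cnv_probs, expr_log_mean = expr_log_mean,
            expr_log_sd = expr_log_sd, outliers = outliers,
            meth_baseline = meth_baseline, meth_delta = meth_delta,
            meth_dispersion = meth_dispersion, regions = regions)
  class(g) <- "gene_spec"
  g
}

#' Specification of a synthetic multi-omics cohort
#'
#' Defines one seeded synthetic cancer entity: the participant roster (how
#' many participants, what fraction carries a matched normal sample) and the
#' planted per-gene parameters. \code{\link{generate_cohort}} turns the spec
#' into the four Firehose-dialect files plus a machine-readable truth
#' sidecar.
#'
#' The defaults describe the package's reference study conditions: 60
#' participants with a matched normal for half of them (30 tumor/normal
#' pairs) and the showcase gene panel of \code{\link{default_gene_panel}}.
#'
#' @param entity cohort label.
#' @param n_participants number of participants (each contributes a tumor
#'   sample).
#' @param normal_fraction fraction of participants with a matched normal.
#' @param genes list of \code{\link{make_gene_spec}} objects.
#' @param seed master seed; one RNG stream per file type is derived from it.
#' @param meth_probes_per_region probes simulated per (gene, region).
#' @param meth_missing_rate per-probe-cell masking probability.
#' @param extra_record_rate probability that a mutated sample carries a
#'   second MAF record for the gene.
#' @return list of class \code{"cohort_spec"} (validated).
#' @export
cohort_spec <- function(entity = "SYNT", n_participants = 60,
                        normal_fraction = 0.5,
                        genes = default_gene_panel(), seed = 1L,
                        meth_probes_per_region = 2L,
                        meth_missing_rate = 0.01,
                        extra_record_rate = 0.15) {
  spec <- list(entity = entity, n_participants = as.integer(n_participants),
               normal_fraction = normal_fraction, genes = genes,
               seed = as.integer(seed),
               meth_probes_per_region = as.integer(meth_probes_per_region),
               meth_missing_rate = meth_missing_rate,
               extra_record_rate = extra_record_rate)
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

#' The default showcase gene panel
#'
#' Eight genes mirroring the kinds of alterations the analyses are built
#' for: a frequently mutated gene (TP53-like, rate 0.33), a rarely mutated
#' one, a mutation-free control; a high-level-amplified gene (FGFR1-like)
#' and a mixed-gain gene (PIK3CA-like); a Body-hypermethylated gene
#' (SFRP1-like, delta-beta +0.30) with an unshifted control (SFRP4-like);
#' and an expression gene with planted +4 sd outliers (KRAS-like).
#'
#' @return list of \code{gene_spec} objects.
#' @export
default_gene_panel <- function() {
  list(
    make_gene_spec("TP53", mutation_rate = 0.33),
    make_gene_spec("VHL", mutation_rate = 0.02),
    make_gene_spec("TSHZ3", mutation_rate = 0.005),
    make_gene_spec("FGFR1", mutation_rate = 0.05,
                   cnv_probs = c(`-2` = 0.01, `-1` = 0.05, `0` = 0.40,
                                 `1` = 0.24, `2` = 0.30)),
    make_gene_spec("PIK3CA", mutation_rate = 0.08,
                   cnv_probs = c(`-2` = 0.01, `-1` = 0.07, `0` = 0.62,
                                 `1` = 0.20, `2` = 0.10)),
    make_gene_spec("SFRP1", meth_delta = c(Body = 0.30)),
    make_gene_spec("SFRP4", meth_delta = 0),
    make_gene_spec("KRAS", expr_log_mean = log(3000), expr_log_sd = 0.6,
                   outliers = list(list(sample = 2L, offset = 4),
                                   list(sample = 5L, offset = 4),
                                   list(sample = 9L, offset = 4)))
  )
}

validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_participants < 1L) stop("n_participants must be >= 1")
  if (spec$normal_fraction < 0 || spec$normal_fraction > 1) {
    stop("normal_fraction must lie in [0, 1]")
  }
  if (!length(spec$genes)) stop("spec must contain at least one gene")
  if (spec$meth_missing_rate < 0 || spec$meth_missing_rate >= 1) {
    stop("meth_missing_rate must lie in [0, 1)")
  }
  for (g in spec$genes) {
    if (g$mutation_rate < 0 || g$mutation_rate > 1) {
      stop("gene '", g$name, "': mutation_rate outside [0, 1]")
    }
    w <- g$variant_class_weights
    if (any(w < 0) || sum(w) <= 0 || is.null(names(w))) {
      stop("gene '", g$name, "': invalid variant_class_weights")
    }
    p <- g$cnv_probs
    if (length(p) != 5L || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("gene '", g$name, "': cnv_probs must be 5 probabilities summing to 1")
    }
    if (g$expr_log_sd <= 0) stop("gene '", g$name, "': expr_log_sd must be > 0")
    if (!all(g$regions %in% METH_REGIONS)) {
      stop("gene '", g$name, "': unknown methylation region(s)")
    }
    mb <- region_param(g$meth_baseline, g$regions, "meth_baseline")
    if (any(mb <= 0 | mb >= 1)) {
      stop("gene '", g$name, "': meth_baseline must lie strictly in (0, 1)")
    }
    md <- region_param(g$meth_delta, g$regions, "meth_delta")
    if (any(abs(md) > 1)) {
      stop("gene '", g$name, "': meth_delta must lie in [-1, 1]")
    }
    if (g$meth_dispersion <= 0) {
      stop("gene '", g$name, "': meth_dispersion must be > 0")
    }
    for (o in g$outliers) {
      if (is.null(o$sample) || is.null(o$offset) || o$sample < 1L ||
          o$sample > spec$n_participants) {
        stop("gene '", g$name, "': outlier sample index outside the roster")
      }
    }
  }
  invisible(spec)
}

# expand a scalar or partially named per-region parameter to `regions`
region_param <- function(x, regions, what) {
  if (length(x) == 1L && is.null(names(x))) {
    return(stats::setNames(rep(as.numeric(x), length(regions)), regions))
  }
  if (is.null(names(x))) stop(what, " must be a scalar or a named vector")
  out <- stats::setNames(rep(0, length(regions)), regions)
  if ("default" %in% names(x)) out[] <- x[["default"]]
  hit <- intersect(names(x), regions)
  out[hit] <- x[hit]
  out
}

fmt_real <- function(x) {
  out <- sprintf("%.15g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Generate a synthetic cohort on disk
#'
#' Samples one cohort from a \code{\link{cohort_spec}} and writes the four
#' pinned Firehose dialects — MAF, GISTIC2.0 thresholded, RSEM and
#' probe-level 450k methylation — with a coherent barcode roster, plus a
#' \code{truth.json} sidecar recording every planted parameter and every
#' sampled ground-truth value. Identical spec and seed give byte-identical
#' files; each file type draws from its own RNG stream derived from the
#' master seed.
#'
#' @param spec a \code{cohort_spec}.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the file paths and the truth object.
#' @export
generate_cohort <- function(spec, outdir) {
  validate_cohort_spec(spec)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  n <- spec$n_participants
  set.seed(spec$seed)
  streams <- sample.int(2147483646L, 4L)

  participants <- sprintf("%04d", seq_len(n))
  n_normal <- round(spec$normal_fraction * n)
  tumor_bc <- sprintf("TCGA-SX-%s-01A-11D-A001-01", participants)
  normal_bc <- if (n_normal > 0) {
    sprintf("TCGA-SX-%s-11A-11D-A001-01", participants[seq_len(n_normal)])
  } else character(0L)
  all_bc <- c(tumor_bc, normal_bc)
  genes <- vapply(spec$genes, `[[`, character(1L), "name")

  ## --- MAF stream -----------------------------------------------------
  set.seed(streams[1L])
  maf_rows <- list()
  maf_truth <- list()
  for (gi in seq_along(spec$genes)) {
    g <- spec$genes[[gi]]
    mutated <- if (g$mutation_rate >= 1) rep(TRUE, n) else
      stats::runif(n) < g$mutation_rate
    idx <- which(mutated)
    w <- g$variant_class_weights / sum(g$variant_class_weights)
    for (i in idx) {
      k <- 1L + stats::rbinom(1L, 1L, spec$extra_record_rate)
      cls <- sample(names(w), k, replace = TRUE, prob = w)
      for (cl in cls) {
        maf_rows[[length(maf_rows) + 1L]] <-
          c(g$name, as.character(gi), cl, tumor_bc[i])
      }
    }
    maf_truth[[g$name]] <- list(
      mutation_rate = g$mutation_rate,
      mutated_samples = tumor_bc[idx]
    )
  }
  maf_path <- file.path(outdir, paste0(spec$entity, ".maf.txt"))
  maf_lines <- c(
    "#synthetic somatic MAF",
    paste("Hugo_Symbol", "Entrez_Gene_Id", "Variant_Classification",
          "Tumor_Sample_Barcode", sep = "\t"),
    vapply(maf_rows, paste, character(1L), collapse = "\t")
  )
  writeLines(maf_lines, maf_path)

  ## --- GISTIC stream --------------------------------------------------
  set.seed(streams[2L])
  cnv <- matrix(0L, nrow = length(genes), ncol = n,
                dimnames = list(genes, tumor_bc))
  for (gi in seq_along(spec$genes)) {
    g <- spec$genes[[gi]]
    cnv[gi, ] <- sample(CNV_CATEGORIES, n, replace = TRUE, prob = g$cnv_probs)
  }
  gistic_path <- file.path(outdir, paste0(spec$entity, ".gistic_thresholded.txt"))
  gistic_lines <- c(
    paste(c("Gene Symbol", "Locus ID", "Cytoband", tumor_bc), collapse = "\t"),
    vapply(seq_along(genes), function(gi) {
      paste(c(genes[gi], as.character(gi), "1p36.1", as.character(cnv[gi, ])),
            collapse = "\t")
    }, character(1L))
  )
  writeLines(gistic_lines, gistic_path)

  ## --- RSEM stream ----------------------------------------------------
  set.seed(streams[3L])
  ns <- length(all_bc)
  expr <- matrix(0, nrow = length(genes), ncol = ns,
                 dimnames = list(genes, all_bc))
  outlier_truth <- list()
  for (gi in seq_along(spec$genes)) {
    g <- spec$genes[[gi]]
    lv <- stats::rnorm(ns, g$expr_log_mean, g$expr_log_sd)
    for (o in g$outliers) {
      lv[o$sample] <- g$expr_log_mean + o$offset * g$expr_log_sd
      outlier_truth[[length(outlier_truth) + 1L]] <- list(
        gene = g$name, barcode = tumor_bc[o$sample], offset = o$offset)
    }
    expr[gi, ] <- exp(lv)
  }
  rsem_path <- file.path(outdir, paste0(spec$entity, ".rsem.txt"))
  rsem_lines <- c(
    paste(c("Hybridization REF", all_bc), collapse = "\t"),
    paste(c("gene_id", rep("normalized_count", ns)), collapse = "\t"),
    vapply(seq_along(genes), function(gi) {
      paste(c(sprintf("%s|%d", genes[gi], gi), fmt_real(expr[gi, ])),
            collapse = "\t")
    }, character(1L))
  )
  writeLines(rsem_lines, rsem_path)

  ## --- methylation stream ---------------------------------------------
  set.seed(streams[4L])
  P <- spec$meth_probes_per_region
  tumor_cols <- seq_len(n)
  meth_rows <- list()   # probe-level file rows
  agg_rows <- list()    # (gene, region) truth
  agg_labels <- list()
  n_clipped <- 0L
  probe_counter <- 0L
  for (gi in seq_along(spec$genes)) {
    g <- spec$genes[[gi]]
    mb <- region_param(g$meth_baseline, g$regions, "meth_baseline")
    md <- region_param(g$meth_delta, g$regions, "meth_delta")
    for (r in g$regions) {
      probes <- matrix(NA_real_, nrow = P, ncol = ns)
      for (p in seq_len(P)) {
        m <- mb[[r]]
        b <- stats::rbeta(ns, m * g$meth_dispersion, (1 - m) * g$meth_dispersion)
        b[tumor_cols] <- b[tumor_cols] + md[[r]]
        clip <- b < 0 | b > 1
        n_clipped <- n_clipped + sum(clip)
        b[b < 0] <- 0
        b[b > 1] <- 1
        if (spec$meth_missing_rate > 0) {
          b[stats::runif(ns) < spec$meth_missing_rate] <- NA_real_
        }
        probes[p, ] <- b
        probe_counter <- probe_counter + 1L
        meth_rows[[length(meth_rows) + 1L]] <-
          paste(c(sprintf("cg%08d", probe_counter), g$name, r, fmt_real(b)),
                collapse = "\t")
      }
      cnt <- colSums(!is.na(probes))
      s <- colSums(probes, na.rm = TRUE)
      agg_rows[[length(agg_rows) + 1L]] <- ifelse(cnt > 0L, s / cnt, NA_real_)
      agg_labels[[length(agg_labels) + 1L]] <- c(g$name, r)
    }
  }
  meth_path <- file.path(outdir, paste0(spec$entity, ".methylation.txt"))
  meth_lines <- c(
    paste(c("Probe_ID", "Gene_Symbol", "Gene_Region", all_bc), collapse = "\t"),
    unlist(meth_rows)
  )
  writeLines(meth_lines, meth_path)

  agg <- do.call(rbind, agg_rows)
  lab <- do.call(rbind, agg_labels)

  truth <- list(
    entity = spec$entity,
    seed = spec$seed,
    n_participants = n,
    normal_fraction = spec$normal_fraction,
    roster = list(tumor_barcodes = tumor_bc, normal_barcodes = normal_bc),
    files = list(maf = basename(maf_path), gistic = basename(gistic_path),
                 rsem = basename(rsem_path), methylation = basename(meth_path)),
    genes = lapply(spec$genes, function(g) {
      list(name = g$name, mutation_rate = g$mutation_rate,
           cnv_probs = as.numeric(g$cnv_probs),
           expr_log_mean = g$expr_log_mean, expr_log_sd = g$expr_log_sd,
           meth_delta = as.list(region_param(g$meth_delta, g$regions, "meth_delta")),
           regions = g$regions)
    }),
    maf = list(
      records = if (length(maf_rows)) {
        data.frame(gene = vapply(maf_rows, `[[`, character(1L), 1L),
                   variant_class = vapply(maf_rows, `[[`, character(1L), 3L),
                   barcode = vapply(maf_rows, `[[`, character(1L), 4L),
                   stringsAsFactors = FALSE)
      } else NULL,
      per_gene = maf_truth
    ),
    gistic = list(genes = genes, samples = tumor_bc, categories = unname(cnv)),
    rsem = list(genes = genes, samples = all_bc, values = unname(expr)),
    methylation = list(gene = lab[, 1L], region = lab[, 2L],
                       samples = all_bc, betas = unname(agg),
                       n_clipped = n_clipped),
    expression_outliers = outlier_truth
  )
  truth_path <- file.path(outdir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(list(
    paths = list(maf = maf_path, gistic = gistic_path, rsem = rsem_path,
                 methylation = meth_path, truth = truth_path),
    truth = truth
  ))
}

#' Verify a generated cohort against its truth sidecar
#'
#' Re-reads the four files of a generated cohort through the format readers
#' and checks them against \code{truth.json}: mutation records as a multiset,
#' GISTIC categories exactly, expression values and aggregated methylation
#' betas to 1e-9 relative tolerance, and barcode coherence (every sample
#' column parses and belongs to the roster).
#'
#' @param outdir directory written by \code{\link{generate_cohort}}.
#' @return list with \code{pass} (logical) and \code{mismatches}
#'   (character vector naming the offending file/row/cell).
#' @export
truth_check <- function(outdir) {
  mism <- character(0L)
  note <- function(msg) mism <<- c(mism, msg)
  truth_path <- file.path(outdir, "truth.json")
  if (!file.exists(truth_path)) {
    return(list(pass = FALSE, mismatches = "truth.json: missing"))
  }
  truth <- jsonlite::fromJSON(truth_path, simplifyVector = TRUE)
  entity <- truth$entity
  roster <- as.character(unlist(c(truth$roster$tumor_barcodes,
                                  truth$roster$normal_barcodes)))

  near <- function(a, b) {
    (is.na(a) & is.na(b)) |
      (!is.na(a) & !is.na(b) & abs(a - b) <= 1e-9 * pmax(1, abs(b)))
  }

  ## MAF
  p <- file.path(outdir, truth$files$maf)
  if (!file.exists(p)) note(paste0(truth$files$maf, ": missing file")) else {
    rec <- tryCatch(read_maf(p, entity), error = function(e) e)
    if (inherits(rec, "error")) {
      note(paste0(truth$files$maf, ": read error: ", conditionMessage(rec)))
    } else {
      got <- rec[order(rec$gene, rec$barcode, rec$variant_class),
                 c("gene", "variant_class", "barcode")]
      tr <- truth$maf$records
      if (is.null(tr)) tr <- data.frame(gene = character(0L),
                                        variant_class = character(0L),
                                        barcode = character(0L))
      tr <- tr[order(tr$gene, tr$barcode, tr$variant_class), , drop = FALSE]
      if (nrow(got) != nrow(tr)) {
        note(sprintf("%s: %d records read, %d expected",
                     truth$files$maf, nrow(got), nrow(tr)))
      } else if (nrow(got) && !all(got$gene == tr$gene &
                                   got$variant_class == tr$variant_class &
                                   got$barcode == tr$barcode)) {
        i <- which(!(got$gene == tr$gene & got$variant_class == tr$variant_class &
                       got$barcode == tr$barcode))[1L]
        note(sprintf("%s: record mismatch at sorted row %d (%s %s %s)",
                     truth$files$maf, i, got$gene[i], got$variant_class[i],
                     got$barcode[i]))
      }
      if (nrow(rec) && !all(rec$barcode %in% roster)) {
        note(paste0(truth$files$maf, ": barcode outside roster"))
      }
    }
  }

  ## GISTIC
  p <- file.path(outdir, truth$files$gistic)
  if (!file.exists(p)) note(paste0(truth$files$gistic, ": missing file")) else {
    cm <- tryCatch(read_gistic_thresholded(p, entity), error = function(e) e)
    if (inherits(cm, "error")) {
      note(paste0(truth$files$gistic, ": read error: ", conditionMessage(cm)))
    } else {
      want <- truth$gistic$categories
      if (!identical(dim(cm$categories), dim(want)) ||
          !identical(cm$genes, truth$gistic$genes) ||
          !identical(cm$samples$raw, truth$gistic$samples)) {
        note(paste0(truth$files$gistic, ": shape or label mismatch"))
      } else if (any(cm$categories != want)) {
        idx <- which(cm$categories != want, arr.ind = TRUE)[1L, ]
        note(sprintf("%s: category mismatch at gene '%s', sample '%s' (%d vs %d)",
                     truth$files$gistic, truth$gistic$genes[idx[1L]],
                     truth$gistic$samples[idx[2L]],
                     cm$categories[idx[1L], idx[2L]], want[idx[1L], idx[2L]]))
      }
      if (!all(cm$samples$raw %in% roster)) {
        note(paste0(truth$files$gistic, ": sample outside roster"))
      }
    }
  }

  ## RSEM
  p <- file.path(outdir, truth$files$rsem)
  if (!file.exists(p)) note(paste0(truth$files$rsem, ": missing file")) else {
    em <- tryCatch(read_rsem_matrix(p, entity), error = function(e) e)
    if (inherits(em, "error")) {
      note(paste0(truth$files$rsem, ": read error: ", conditionMessage(em)))
    } else {
      want <- truth$rsem$values
      if (!identical(dim(em$values), dim(want)) ||
          !identical(em$genes$symbol, truth$rsem$genes) ||
          !identical(em$samples$raw, truth$rsem$samples)) {
        note(paste0(truth$files$rsem, ": shape or label mismatch"))
      } else {
        ok <- near(em$values, want)
        if (!all(ok)) {
          idx <- which(!ok, arr.ind = TRUE)[1L, ]
          note(sprintf("%s: value mismatch at gene '%s', sample '%s'",
                       truth$files$rsem, truth$rsem$genes[idx[1L]],
                       truth$rsem$samples[idx[2L]]))
        }
      }
      if (!all(em$samples$raw %in% roster)) {
        note(paste0(truth$files$rsem, ": sample outside roster"))
      }
    }
  }

  ## methylation
  p <- file.path(outdir, truth$files$methylation)
  if (!file.exists(p)) note(paste0(truth$files$methylation, ": missing file")) else {
    mt <- tryCatch(read_methylation(p, entity), error = function(e) e)
    if (inherits(mt, "error")) {
      note(paste0(truth$files$methylation, ": read error: ", conditionMessage(mt)))
    } else {
      want_lab <- paste(truth$methylation$gene, truth$methylation$region, sep = ":")
      got_lab <- paste(mt$rows$gene, mt$rows$region, sep = ":")
      if (!setequal(want_lab, got_lab) ||
          !identical(mt$samples$raw, truth$methylation$samples)) {
        note(paste0(truth$files$methylation, ": row or sample label mismatch"))
      } else {
        want <- truth$methylation$betas[match(got_lab, want_lab), , drop = FALSE]
        ok <- near(mt$betas, want)
        if (!all(ok)) {
          idx <- which(!ok, arr.ind = TRUE)[1L, ]
          note(sprintf("%s: beta mismatch at row '%s', sample '%s'",
                       truth$files$methylation, got_lab[idx[1L]],
                       truth$methylation$samples[idx[2L]]))
        }
      }
      if (!all(mt$samples$raw %in% roster)) {
        note(paste0(truth$files$methylation, ": sample outside roster"))
      }
    }
  }

  list(pass = length(mism) == 0L, mismatches = mism)
}
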