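ANALYSIS_SUBCOMMANDS <- c("mutation", "expression", "methylation", "cnv")

#' Run one batch analysis and write its artifacts
#'
#' The batch counterpart of the interactive workflow: validates the
#' configuration, computes the analysis tables, writes them as TSV, renders
#' the figures from those tables, and records a run manifest (inputs,
#' options, library versions, table checksums, collected warnings). Tables
#' are always written before plots, and plots are drawn only from the table
#' contents.
#'
#' @param config named list: \code{subcommand} (one of mutation, expression,
#'   methylation, cnv, simulate); input paths (\code{maf}, \code{rsem},
#'   \code{meth}, \code{gistic} — one file per entity, matched by position);
#'   \code{entities}; \code{genes}; \code{method}, \code{threshold},
#'   \code{log2}, \code{pseudocount} (expression); \code{mode}, \code{alpha}
#'   (methylation); \code{subset} (cnv); \code{exclude_classes} (mutation);
#'   \code{view} (\code{entity_centric}/\code{gene_centric});
#'   \code{out} output directory; \code{format} (\code{pdf} or \code{png});
#'   \code{seed} and \code{spec_file} (simulate only).
#' @return invisibly, list with \code{status} (0 on success), \code{tables},
#'   \code{plots} and \code{manifest} path.
#' @export
run_analysis <- function(config) {
  config <- validate_run_config(config)
  warnings_seen <- character(0L)
  tables <- withCallingHandlers(
    compute_tables(config),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  table_paths <- character(0L)
  for (nm in names(tables)) {
    p <- file.path(config$out, paste0(nm, ".tsv"))
    write_summary_table(tables[[nm]], p)
    table_paths[nm] <- p
  }
  plots <- if (config$subcommand %in% ANALYSIS_SUBCOMMANDS) {
    render_plots(tables, config$subcommand, config$out, config$format)
  } else character(0L)

  manifest <- list(
    subcommand = config$subcommand,
    options = config[setdiff(names(config), c("subcommand", "out"))],
    inputs = lapply(input_paths(config), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    versions = list(r = R.version.string,
                    oncoprofiler = as.character(utils::packageVersion("oncoprofiler"))),
    tables = lapply(names(table_paths), function(nm)
      list(name = nm, path = unname(table_paths[nm]),
           md5 = unname(tools::md5sum(table_paths[nm])))),
    plots = as.character(plots),
    warnings = warnings_seen
  )
  manifest_path <- file.path(config$out, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(list(status = 0L, tables = table_paths, plots = plots,
                 manifest = manifest_path))
}

input_paths <- function(config) {
  unlist(config[intersect(c("maf", "rsem", "meth", "gistic", "spec_file"),
                          names(config))], use.names = FALSE)
}

validate_run_config <- function(config) {
  if (is.null(config$subcommand) ||
      !config$subcommand %in% c(ANALYSIS_SUBCOMMANDS, "simulate")) {
    stop("unknown subcommand '", config$subcommand %||% "", "'")
  }
  defaults <- list(method = "zscore", threshold = 2, pseudocount = 1,
                   log2 = FALSE, mode = "unpaired", alpha = 0.05,
                   subset = c(-2L, -1L, 1L, 2L), view = "entity_centric",
                   format = "pdf", exclude_classes = character(0L))
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (is.null(config$out)) stop("an output directory (--out) is required")
  if (config$subcommand %in% ANALYSIS_SUBCOMMANDS) {
    if (!length(config$entities)) stop("at least one entity is required")
    if (!length(config$genes)) stop("at least one gene is required")
    key <- switch(config$subcommand, mutation = "maf", expression = "rsem",
                  methylation = "meth", cnv = "gistic")
    paths <- config[[key]]
    if (!length(paths)) stop("subcommand '", config$subcommand,
                             "' requires --", key, " input file(s)")
    missing_files <- paths[!file.exists(paths)]
    if (length(missing_files)) {
      stop("input file(s) not found: ", paste(missing_files, collapse = ", "))
    }
    if (length(paths) != length(config$entities)) {
      stop("need one --", key, " file per entity (", length(config$entities),
           " entities, ", length(paths), " files)")
    }
    if (config$subcommand == "methylation" && length(config$entities) != 1L) {
      stop("methylation profiling handles one entity per invocation")
    }
  } else {
    if (!is.null(config$spec_file) && !file.exists(config$spec_file)) {
      stop("spec file not found: ", config$spec_file)
    }
  }
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

compute_tables <- function(config) {
  switch(config$subcommand,
    mutation = compute_mutation_tables(config),
    expression = compute_expression_tables(config),
    methylation = compute_methylation_tables(config),
    cnv = compute_cnv_tables(config),
    simulate = compute_simulate_tables(config)
  )
}

compute_mutation_tables <- function(config) {
  recs <- do.call(rbind, Map(read_maf, config$maf, config$entities))
  class(recs) <- c("maf_records", "data.frame")
  class_filter <- NULL
  if (length(config$exclude_classes)) {
    class_filter <- setdiff(unique(recs$variant_class), config$exclude_classes)
  }
  cohorts <- lapply(config$entities, function(e) cohort_index(recs, e))
  names(cohorts) <- config$entities
  freq <- global_mutation_profile(recs, cohorts, config$genes, class_filter)
  global <- do.call(rbind, lapply(config$entities, function(e) {
    data.frame(entity = e, gene = config$genes,
               n_samples = length(cohorts[[e]]$tumor_samples),
               frequency = freq[, e], stringsAsFactors = FALSE)
  }))
  classes <- do.call(rbind, lapply(config$entities, function(e) {
    do.call(rbind, lapply(config$genes, function(g) {
      bd <- class_breakdown(mutation_frequency(recs, cohorts[[e]], g,
                                               class_filter))
      if (!nrow(bd)) return(NULL)
      cbind(data.frame(entity = e, gene = g, stringsAsFactors = FALSE), bd)
    }))
  }))
  if (is.null(classes)) {
    classes <- data.frame(entity = character(0L), gene = character(0L),
                          variant_class = character(0L),
                          slice_proportion = numeric(0L),
                          sample_percentage = numeric(0L))
  }
  list(mutation_global = global, mutation_classes = classes)
}

compute_expression_tables <- function(config) {
  mats <- Map(read_rsem_matrix, config$rsem, config$entities)
  calls <- do.call(rbind, lapply(mats, function(m)
    expression_calls(m, config$genes, method = config$method,
                     threshold = config$threshold,
                     pseudocount = config$pseudocount, log2 = config$log2)))
  class(calls) <- c("expression_calls", "data.frame")
  attr(calls, "threshold") <- config$threshold
  wf <- waterfall_data(calls, axis = config$view)
  summaries <- do.call(rbind, lapply(mats, function(m) {
    do.call(rbind, lapply(config$genes, function(g)
      entity_boxplot_summary(m, g, threshold = config$threshold,
                             method = config$method,
                             pseudocount = config$pseudocount,
                             log2 = config$log2)))
  }))
  list(
    expression_calls = as.data.frame(calls),
    expression_waterfall = as.data.frame(wf),
    expression_summary = as.data.frame(summaries)
  )
}

compute_methylation_tables <- function(config) {
  mt <- read_methylation(config$meth, config$entities[1L])
  res <- differential_methylation(mt, config$genes, mode = config$mode,
                                  alpha = config$alpha)
  pairing <- build_pairing(mt$samples, mt$entity)
  hists <- NULL
  if (nrow(pairing$pairs)) {
    keep <- !is.na(res$p_raw)
    hists <- do.call(rbind, lapply(which(keep), function(i) {
      h <- delta_histogram(mt, res$gene[i], res$region[i], pairing)
      cbind(data.frame(entity = mt$entity, gene = res$gene[i],
                       region = res$region[i], stringsAsFactors = FALSE),
            as.data.frame(h))
    }))
  }
  if (is.null(hists)) {
    hists <- data.frame(entity = character(0L), gene = character(0L),
                        region = character(0L), bin_low = numeric(0L),
                        bin_high = numeric(0L), count = integer(0L))
  }
  list(methylation_results = as.data.frame(res),
       methylation_histograms = hists)
}

compute_cnv_tables <- function(config) {
  mats <- Map(read_gistic_thresholded, config$gistic, config$entities)
  frac <- global_cnv_profile(unname(mats), config$genes, config$subset)
  global <- do.call(rbind, lapply(seq_along(config$entities), function(j) {
    data.frame(entity = config$entities[j], gene = config$genes,
               subset = paste(config$subset, collapse = ","),
               altered_fraction = frac[, j], stringsAsFactors = FALSE)
  }))
  cats <- do.call(rbind, lapply(seq_along(mats), function(j) {
    do.call(rbind, lapply(config$genes, function(g) {
      prof <- cnv_profile(mats[[j]], g)
      data.frame(entity = config$entities[j], gene = g,
                 category = CNV_CATEGORIES,
                 count = as.integer(prof$counts),
                 fraction = as.numeric(prof$counts) / prof$n_samples,
                 stringsAsFactors = FALSE)
    }))
  }))
  list(cnv_global = global, cnv_categories = cats)
}

compute_simulate_tables <- function(config) {
  spec <- if (!is.null(config$spec_file)) {
    cohort_spec_from_yaml(config$spec_file, seed = config$seed)
  } else {
    cohort_spec(seed = config$seed %||% 1L)
  }
  generate_cohort(spec, config$out)
  report <- truth_check(config$out)
  list(simulate_report = data.frame(
    entity = spec$entity, n_participants = spec$n_participants,
    normal_fraction = spec$normal_fraction, seed = spec$seed,
    truth_check_pass = report$pass, stringsAsFactors = FALSE))
}

#' Build a cohort spec from a declarative YAML document
#'
#' The YAML mirrors \code{\link{cohort_spec}}: top-level keys
#' \code{entity}, \code{n_participants}, \code{normal_fraction},
#' \code{seed}, and a \code{genes} list whose entries hold
#' \code{\link{make_gene_spec}} arguments.
#'
#' @param path YAML file.
#' @param seed optional seed overriding the document's.
#' @return a validated \code{cohort_spec}.
#' @export
cohort_spec_from_yaml <- function(path, seed = NULL) {
  doc <- yaml::read_yaml(path)
  genes <- if (!is.null(doc$genes)) {
    lapply(doc$genes, function(g) {
      g <- lapply(g, function(v) if (is.list(v) && !is.null(names(v))) unlist(v) else v)
      if (!is.null(g$outliers)) {
        g$outliers <- lapply(g$outliers, as.list)
      }
      do.call(make_gene_spec, g)
    })
  } else default_gene_panel()
  cohort_spec(
    entity = doc$entity %||% "SYNT",
    n_participants = doc$n_participants %||% 60,
    normal_fraction = doc$normal_fraction %||% 0.5,
    genes = genes,
    seed = seed %||% doc$seed %||% 1L
  )
}

#' Render the figure set of one analysis from its tables
#'
#' Draws every panel of an analysis purely from the emitted tables, with
#' deterministic file names \code{<analysis>_<entity>[_<gene>].<ext>}.
#' Empty tables yield a "no data" placeholder panel.
#'
#' @param tables named list of data.frames as produced by the analysis
#'   subcommands.
#' @param kind one of \code{"mutation"}, \code{"expression"},
#'   \code{"methylation"}, \code{"cnv"}.
#' @param outdir output directory.
#' @param format \code{"pdf"} (vector, default) or \code{"png"} (raster).
#' @return character vector of the files written.
#' @export
render_plots <- function(tables, kind, outdir, format = c("pdf", "png")) {
  format <- match.arg(format)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ext <- format
  files <- character(0L)
  add <- function(f) files <<- c(files, f)

  if (kind == "mutation") {
    g <- tables$mutation_global
    f <- file.path(outdir, paste0("mutation_global.", ext))
    if (nrow(g)) {
      mat <- stats::xtabs(frequency ~ gene + entity, data = g)
      plot_profile_grid(unclass(mat), f, format, "Global mutation profile",
                        "cell: fraction of assayed tumor samples mutated")
    } else placeholder_panel(f, format)
    add(f)
    cl <- tables$mutation_classes
    for (e in unique(cl$entity)) for (gn in unique(cl$gene[cl$entity == e])) {
      f <- file.path(outdir, sprintf("mutation_%s_%s.%s", e, gn, ext))
      plot_class_pie(cl[cl$entity == e & cl$gene == gn, , drop = FALSE],
                     f, format, sprintf("%s in %s", gn, e))
      add(f)
    }
  } else if (kind == "expression") {
    wf <- tables$expression_waterfall
    panels <- unique(wf$panel)
    if (!length(panels)) {
      f <- file.path(outdir, paste0("expression_waterfall.", ext))
      placeholder_panel(f, format)
      add(f)
    }
    for (p in panels) {
      f <- file.path(outdir, sprintf("expression_waterfall_%s.%s", p, ext))
      plot_waterfall_panel(wf[wf$panel == p, , drop = FALSE], f, format,
                           paste("Waterfall:", p))
      add(f)
    }
    sm <- tables$expression_summary
    for (i in seq_len(nrow(sm))) {
      f <- file.path(outdir, sprintf("expression_box_%s_%s.%s",
                                     sm$entity[i], sm$gene[i], ext))
      plot_entity_box(sm[i, , drop = FALSE], f, format,
                      sprintf("%s in %s", sm$gene[i], sm$entity[i]))
      add(f)
    }
  } else if (kind == "methylation") {
    res <- tables$methylation_results
    ent <- if (nrow(res)) res$entity[1L] else "none"
    f <- file.path(outdir, sprintf("methylation_%s.%s", ent, ext))
    plot_methylation_grid(res, f, format,
                          paste("Differential methylation:", ent))
    add(f)
    hi <- tables$methylation_histograms
    if (nrow(hi)) {
      combos <- unique(hi[, c("entity", "gene", "region")])
      for (i in seq_len(nrow(combos))) {
        sel <- hi$entity == combos$entity[i] & hi$gene == combos$gene[i] &
          hi$region == combos$region[i]
        f <- file.path(outdir, sprintf("methylation_%s_%s_%s.%s",
                                       combos$entity[i], combos$gene[i],
                                       gsub("[^A-Za-z0-9]", "", combos$region[i]),
                                       ext))
        plot_delta_hist(hi[sel, , drop = FALSE], f, format,
                        sprintf("%s %s (%s)", combos$gene[i],
                                combos$region[i], combos$entity[i]))
        add(f)
      }
    }
  } else if (kind == "cnv") {
    g <- tables$cnv_global
    f <- file.path(outdir, paste0("cnv_global.", ext))
    if (nrow(g)) {
      mat <- stats::xtabs(altered_fraction ~ gene + entity, data = g)
      plot_profile_grid(unclass(mat), f, format, "Global CNV profile",
                        "cell: fraction of tumor samples altered")
    } else placeholder_panel(f, format)
    add(f)
    ct <- tables$cnv_categories
    combos <- unique(ct[, c("entity", "gene")])
    for (i in seq_len(nrow(combos))) {
      sel <- ct$entity == combos$entity[i] & ct$gene == combos$gene[i]
      f <- file.path(outdir, sprintf("cnv_%s_%s.%s", combos$entity[i],
                                     combos$gene[i], ext))
      plot_cnv_bars(ct[sel, , drop = FALSE], f, format,
                    sprintf("%s in %s", combos$gene[i], combos$entity[i]))
      add(f)
    }
  } else {
    stop("unknown plot kind '", kind, "'")
  }
  files
}
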