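#' Define the assayed tumor cohort of an entity
#'
#' The denominator of every mutation frequency is the set of assayed tumor
#' samples of the entity, not only the mutated ones. MAFs list mutated
#' samples only, so by default the cohort is the set of distinct tumor
#' sample keys appearing anywhere in the entity's records; when the assayed
#' cohort is known (e.g. from a sample manifest) pass it via \code{samples}.
#'
#' @param records \code{maf_records} frame (used when \code{samples} is NULL).
#' @param entity cohort label; defaults to the records' single entity.
#' @param samples optional explicit cohort: character sample keys or barcodes,
#'   or a \code{tcga_barcodes} frame (tumor samples are selected).
#' @return object of class \code{"cohort_index"}: list with \code{entity} and
#'   sorted unique \code{tumor_samples} keys.
#' @export
cohort_index <- function(records = NULL, entity = NULL, samples = NULL) {
  if (!is.null(samples)) {
    if (inherits(samples, "tcga_barcodes")) {
      keys <- samples$sample_key[samples$is_tumor]
    } else if (is.character(samples)) {
      keys <- samples
      looks_full <- any(!barcode_key_like(keys))
      if (looks_full) {
        bc <- parse_barcode(keys)
        keys <- bc$sample_key[bc$is_tumor]
      }
    } else {
      stop("samples must be a character vector or a tcga_barcodes frame")
    }
  } else {
    if (is.null(records)) stop("either records or samples must be supplied")
    stopifnot(inherits(records, "maf_records"))
    if (is.null(entity)) entity <- unique(records$entity)
    if (length(entity) != 1L) stop("entity must be a single label")
    sel <- records$entity == entity & records$is_tumor
    keys <- records$sample_key[sel]
  }
  keys <- sort(unique(keys))
  if (!length(keys)) stop("empty cohort: no tumor samples for entity '", entity, "'")
  out <- list(entity = entity, tumor_samples = keys)
  class(out) <- "cohort_index"
  out
}

# sample keys look like PROJECT-TSS-PART-NN (exactly four fields)
barcode_key_like <- function(x) {
  grepl("^[^-]+-[^-]{2}-[^-]{4}-[0-9]{2}$", x)
}

#' Mutation frequency and variant-class breakdown of one gene
#'
#' Counts, within one entity's cohort, the distinct tumor samples carrying at
#' least one qualifying record for \code{gene}; the frequency is that count
#' over the full assayed cohort size. A sample with several records for the
#' gene is counted once. Per-variant-class tallies are kept both as mutation
#' counts (circle-chart slice sizes) and as distinct-sample counts
#' (percentages of the cohort).
#'
#' @param records \code{maf_records} frame.
#' @param cohort \code{cohort_index} of the entity (see
#'   \code{\link{cohort_index}}).
#' @param gene HUGO symbol.
#' @param class_filter optional character vector of variant classes to keep;
#'   default keeps every class present in the records. Classes not present
#'   anywhere in the records raise an error.
#' @return object of class \code{"mutation_profile"}: list with
#'   \code{entity}, \code{gene}, \code{n_samples}, \code{n_mutated},
#'   \code{frequency}, \code{class_counts}, \code{class_sample_counts},
#'   \code{n_outside_cohort}.
#' @examples
#' \dontrun{
#' prof <- mutation_frequency(recs, cohort_index(recs), "TP53")
#' prof$frequency
#' }
#' @export
mutation_frequency <- function(records, cohort, gene, class_filter = NULL) {
  stopifnot(inherits(records, "maf_records"), inherits(cohort, "cohort_index"))
  if (!length(cohort$tumor_samples)) stop("empty cohort")
  if (!is.null(class_filter)) {
    unknown <- setdiff(class_filter, unique(records$variant_class))
    if (length(unknown)) {
      stop("unknown variant class(es) in class_filter: ",
           paste(unknown, collapse = ", "))
    }
  }
  sel <- records$entity == cohort$entity & records$gene == gene & records$is_tumor
  sub <- records[sel, , drop = FALSE]
  mutation_profile_from_subset(sub, cohort, gene, class_filter)
}

# shared tally over a pre-selected record subset of one (entity, gene)
mutation_profile_from_subset <- function(sub, cohort, gene, class_filter) {
  if (!is.null(class_filter)) {
    sub <- sub[sub$variant_class %in% class_filter, , drop = FALSE]
  }
  inside <- sub$sample_key %in% cohort$tumor_samples
  n_outside <- sum(!inside)
  if (n_outside) {
    warning("ignored ", n_outside, " record(s) for gene '", gene,
            "' from samples outside the '", cohort$entity, "' cohort")
  }
  sub <- sub[inside, , drop = FALSE]
  n_samples <- length(cohort$tumor_samples)
  mutated <- unique(sub$sample_key)
  if (nrow(sub)) {
    class_counts <- table(sub$variant_class)
    class_counts <- stats::setNames(as.integer(class_counts), names(class_counts))
    pair <- unique(sub[, c("variant_class", "sample_key")])
    csc <- table(pair$variant_class)
    class_sample_counts <- stats::setNames(as.integer(csc), names(csc))
  } else {
    class_counts <- stats::setNames(integer(0L), character(0L))
    class_sample_counts <- class_counts
  }
  out <- list(
    entity = cohort$entity,
    gene = gene,
    n_samples = n_samples,
    n_mutated = length(mutated),
    frequency = length(mutated) / n_samples,
    class_counts = class_counts,
    class_sample_counts = class_sample_counts,
    n_outside_cohort = n_outside
  )
  class(out) <- "mutation_profile"
  out
}

#' @export
print.mutation_profile <- function(x, ...) {
  cat(sprintf("Mutation profile %s / %s: %d of %d samples mutated (%.1f%%)\n",
              x$entity, x$gene, x$n_mutated, x$n_samples, 100 * x$frequency))
  if (length(x$class_counts)) {
    cat("  classes:", paste(names(x$class_counts), x$class_counts,
                            sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Global mutation profile across genes and entities
#'
#' Frequency matrix behind the global mutational profile grid: one row per
#' gene, one column per entity, each cell the mutation frequency of the gene
#' in that entity's cohort. Genes absent from an entity's records get 0.
#'
#' @param records \code{maf_records} frame (may span several entities).
#' @param cohorts named list of \code{cohort_index} objects, one per entity.
#' @param genes character vector of HUGO symbols (row order preserved).
#' @param class_filter optional variant-class filter, as in
#'   \code{\link{mutation_frequency}}.
#' @return numeric genes x entities matrix of frequencies in [0,1].
#' @export
global_mutation_profile <- function(records, cohorts, genes, class_filter = NULL) {
  stopifnot(length(genes) >= 1L, length(cohorts) >= 1L)
  if (is.null(names(cohorts))) {
    names(cohorts) <- vapply(cohorts, `[[`, character(1L), "entity")
  }
  if (!is.null(class_filter)) {
    unknown <- setdiff(class_filter, unique(records$variant_class))
    if (length(unknown)) {
      stop("unknown variant class(es) in class_filter: ",
           paste(unknown, collapse = ", "))
    }
  }
  out <- matrix(0, nrow = length(genes), ncol = length(cohorts),
                dimnames = list(genes, names(cohorts)))
  for (e in names(cohorts)) {
    cohort <- cohorts[[e]]
    if (!inherits(cohort, "cohort_index")) {
      stop("no cohort index supplied for entity '", e, "'")
    }
    sel <- records$entity == cohort$entity & records$is_tumor &
      records$gene %in% genes
    sub <- records[sel, , drop = FALSE]
    by_gene <- split(seq_len(nrow(sub)), factor(sub$gene, levels = genes))
    for (g in genes) {
      prof <- mutation_profile_from_subset(sub[by_gene[[g]], , drop = FALSE],
                                           cohort, g, class_filter)
      out[g, e] <- prof$frequency
    }
  }
  out
}

#' Variant-class breakdown of a mutation profile
#'
#' For each variant class present in the profile: the slice proportion
#' (class mutation count over all mutation counts of the gene, the circle
#' chart's slice size) and the sample percentage (distinct mutated samples of
#' that class over the cohort size). Classes without any mutation are
#' omitted.
#'
#' @param profile a \code{mutation_profile}.
#' @return data.frame with columns \code{variant_class},
#'   \code{slice_proportion}, \code{sample_percentage}; zero rows when the
#'   profile holds no mutations.
#' @export
class_breakdown <- function(profile) {
  stopifnot(inherits(profile, "mutation_profile"))
  cc <- profile$class_counts
  cc <- cc[cc > 0L]
  if (!length(cc)) {
    return(data.frame(variant_class = character(0L),
                      slice_proportion = numeric(0L),
                      sample_percentage = numeric(0L),
                      stringsAsFactors = FALSE))
  }
  total <- sum(cc)
  data.frame(
    variant_class = names(cc),
    slice_proportion = as.numeric(cc) / total,
    sample_percentage = as.numeric(profile$class_sample_counts[names(cc)]) /
      profile$n_samples,
    stringsAsFactors = FALSE
  )
}
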