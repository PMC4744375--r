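CNV_CATEGORIES <- c(-2L, -1L, 0L, 1L, 2L)

#' Copy-number category profile of one gene
#'
#' Tallies the GISTIC2.0 thresholded categories of one gene over the tumor
#' samples of an entity: -2 homozygous deletion, -1 heterozygous deletion,
#' 0 normal copy number, +1 low-level gain, +2 high-level amplification.
#' Normal-tissue barcodes occasionally present in GISTIC matrices are
#' excluded.
#'
#' @param matrix a \code{cnv_matrix}.
#' @param gene HUGO symbol; must be present.
#' @return object of class \code{"cnv_profile"}: list with \code{entity},
#'   \code{gene}, \code{n_samples} and \code{counts} (named integer vector
#'   over \code{"-2" ... "2"}, summing to \code{n_samples}).
#' @export
cnv_profile <- function(matrix, gene) {
  stopifnot(inherits(matrix, "cnv_matrix"))
  if (!gene %in% matrix$genes) {
    stop("gene '", gene, "' absent from CNV matrix of entity '",
         matrix$entity, "'")
  }
  tumor <- matrix$samples$is_tumor
  v <- matrix$categories[match(gene, matrix$genes), tumor]
  counts <- vapply(CNV_CATEGORIES, function(k) sum(v == k), integer(1L))
  names(counts) <- as.character(CNV_CATEGORIES)
  out <- list(entity = matrix$entity, gene = gene,
              n_samples = length(v), counts = counts)
  class(out) <- "cnv_profile"
  out
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat(sprintf("CNV profile %s / %s over %d tumor samples\n",
              x$entity, x$gene, x$n_samples))
  print(x$counts)
  invisible(x)
}

#' Fraction of samples altered in a category subset
#'
#' @param profile a \code{cnv_profile}.
#' @param subset categories counted as altered; any subset of
#'   \{-2, -1, 1, 2\} (default all four: any gain or loss). 0 is normal copy
#'   number and not an alteration.
#' @return fraction in [0, 1].
#' @export
altered_fraction <- function(profile, subset = c(-2L, -1L, 1L, 2L)) {
  stopifnot(inherits(profile, "cnv_profile"))
  validate_cnv_subset(subset)
  sum(profile$counts[as.character(subset)]) / profile$n_samples
}

validate_cnv_subset <- function(subset) {
  if (!length(subset)) stop("subset must contain at least one category")
  if (any(subset == 0)) stop("category 0 (normal copy number) is not an alteration")
  if (!all(subset %in% c(-2L, -1L, 1L, 2L))) {
    stop("subset must be contained in {-2, -1, 1, 2}")
  }
  if (anyDuplicated(subset)) stop("subset categories must be distinct")
  invisible(subset)
}

#' Global copy-number alteration profile
#'
#' Altered-fraction matrix behind the global CNV grid: one row per gene, one
#' column per entity, each cell the fraction of the entity's tumor samples
#' whose category for the gene falls in \code{subset}.
#'
#' @param matrices list of \code{cnv_matrix} objects (one per entity).
#' @param genes HUGO symbols (row order preserved).
#' @param subset alteration categories, as in \code{\link{altered_fraction}}.
#' @return numeric genes x entities matrix of fractions.
#' @export
global_cnv_profile <- function(matrices, genes, subset = c(-2L, -1L, 1L, 2L)) {
  stopifnot(length(genes) >= 1L, length(matrices) >= 1L)
  validate_cnv_subset(subset)
  if (inherits(matrices, "cnv_matrix")) matrices <- list(matrices)
  entities <- vapply(matrices, `[[`, character(1L), "entity")
  out <- matrix(NA_real_, nrow = length(genes), ncol = length(entities),
                dimnames = list(genes, entities))
  for (j in seq_along(matrices)) {
    for (g in genes) {
      out[g, j] <- altered_fraction(cnv_profile(matrices[[j]], g), subset)
    }
  }
  out
}

#' Per-category bar series of a CNV profile
#'
#' The fine-grained view of one gene in one entity: one bar per category in
#' the fixed order -2, -1, 0, 1, 2, as counts or cohort fractions.
#'
#' @param profile a \code{cnv_profile}.
#' @param as_fraction if TRUE, divide by the cohort size (fractions sum
#'   to 1); default FALSE returns integer counts.
#' @return data.frame with columns \code{category} and \code{count} or
#'   \code{fraction}.
#' @export
category_bars <- function(profile, as_fraction = FALSE) {
  stopifnot(inherits(profile, "cnv_profile"))
  if (as_fraction) {
    data.frame(category = CNV_CATEGORIES,
               fraction = as.numeric(profile$counts) / profile$n_samples)
  } else {
    data.frame(category = CNV_CATEGORIES,
               count = as.integer(profile$counts))
  }
}
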