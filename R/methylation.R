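#' Pair tumor and normal samples by participant
#'
#' Matches each participant's tumor sample with their normal sample via the
#' TCGA barcode. When a participant has several tumor (or normal) sample
#' keys, the lexicographically smallest key is used, so pairing is
#' deterministic; every participant contributes at most one pair. Samples
#' left without a partner land in the unpaired lists.
#'
#' @param samples barcodes: character vector or \code{tcga_barcodes} frame.
#' @param entity optional cohort label carried through.
#' @return object of class \code{"sample_pairing"}: list with \code{entity},
#'   \code{pairs} (data.frame \code{participant_id}, \code{tumor_key},
#'   \code{normal_key}), \code{unpaired_tumors}, \code{unpaired_normals}.
#' @export
build_pairing <- function(samples, entity = NULL) {
  if (is.character(samples)) samples <- parse_barcode(samples)
  stopifnot(inherits(samples, "tcga_barcodes"))
  tum <- unique(samples[samples$is_tumor, c("participant_id", "sample_key")])
  nor <- unique(samples[samples$is_normal, c("participant_id", "sample_key")])
  pick_min <- function(df) {
    if (!nrow(df)) {
      return(stats::setNames(character(0L), character(0L)))
    }
    vapply(split(df$sample_key, df$participant_id), min, character(1L))
  }
  t_min <- pick_min(tum)
  n_min <- pick_min(nor)
  both <- sort(intersect(names(t_min), names(n_min)))
  pairs <- data.frame(
    participant_id = both,
    tumor_key = unname(t_min[both]),
    normal_key = unname(n_min[both]),
    stringsAsFactors = FALSE
  )
  out <- list(
    entity = entity,
    pairs = pairs,
    unpaired_tumors = sort(setdiff(unique(tum$sample_key), pairs$tumor_key)),
    unpaired_normals = sort(setdiff(unique(nor$sample_key), pairs$normal_key))
  )
  class(out) <- "sample_pairing"
  out
}

#' Two-sided Wilcoxon signed-rank test on paired differences
#'
#' Tests whether tumor-normal beta differences are centered at zero. Zero
#' differences are dropped before ranking. The exact signed-rank null is used
#' for n <= 25 remaining differences without ties in |d|; otherwise the
#' normal approximation with continuity and tie corrections. Fewer than 5
#' nonzero differences flags the result as underpowered (still computed);
#' all-zero differences give p = 1 with a degenerate flag.
#'
#' @param differences numeric vector of paired differences (NA dropped).
#' @return list with \code{statistic} (signed-rank V), \code{p_value},
#'   \code{n} (nonzero differences used), \code{exact}, \code{underpowered},
#'   \code{degenerate}.
#' @export
wilcoxon_paired <- function(differences) {
  d <- differences[!is.na(differences)]
  dnz <- d[d != 0]
  n <- length(dnz)
  if (n == 0L) {
    return(list(statistic = NA_real_, p_value = 1, n = 0L, exact = FALSE,
                underpowered = TRUE, degenerate = TRUE))
  }
  exact <- n <= 25L && !anyDuplicated(abs(dnz))
  ht <- suppressWarnings(stats::wilcox.test(dnz, mu = 0, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, n = n,
       exact = exact, underpowered = n < 5L, degenerate = FALSE)
}

#' Two-sided Wilcoxon rank-sum test between two groups
#'
#' Rank-sum (Mann-Whitney) test of tumor vs normal beta values. The exact
#' null is used when m + n <= 20 and the pooled values carry no ties;
#' otherwise the tie-corrected normal approximation with continuity
#' correction.
#'
#' @param tumor_betas,normal_betas numeric vectors (NA dropped); both must be
#'   nonempty.
#' @return list with \code{statistic} (Mann-Whitney U of the tumor group),
#'   \code{p_value}, \code{n_tumor}, \code{n_normal}, \code{exact}.
#' @export
wilcoxon_unpaired <- function(tumor_betas, normal_betas) {
  x <- tumor_betas[!is.na(tumor_betas)]
  y <- normal_betas[!is.na(normal_betas)]
  if (!length(x) || !length(y)) {
    stop("both groups must be nonempty for the rank-sum test")
  }
  exact <- (length(x) + length(y)) <= 20L && !anyDuplicated(c(x, y))
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_tumor = length(x), n_normal = length(y), exact = exact)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a family of p-values to control the false discovery rate:
#' sorted ascending, \eqn{q_i = \min_{j \ge i} \min(1, m p_j / j)}, mapped
#' back to input order.
#'
#' @param p_values numeric vector with every element in (0, 1].
#' @return adjusted p-values in input order.
#' @examples
#' bh_adjust(c(0.005, 0.01, 0.03, 0.04))  # 0.02 0.02 0.04 0.04
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) stop("p-values must be numeric")
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Differential methylation of gene regions within one entity
#'
#' For every (gene, region) row of the table, tests tumor against normal
#' beta values with a Wilcoxon test — signed-rank over participant-matched
#' pairs in paired mode, rank-sum over all tumor vs all normal samples in
#' unpaired mode — and adjusts the p-values jointly across all tests of the
#' invocation by Benjamini-Hochberg. The delta-beta (mean tumor beta minus
#' mean normal beta) quantifies magnitude, and its sign alone determines the
#' direction (hyper/hypo): p-values carry no directional information. Rows
#' with insufficient data are reported with missing p and excluded from the
#' BH family.
#'
#' @param table a \code{methylation_table}.
#' @param genes optional HUGO symbols to restrict to (default: all).
#' @param mode \code{"unpaired"} (default) or \code{"paired"}.
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @return data.frame of class \code{"methylation_results"} with columns
#'   \code{entity}, \code{gene}, \code{region}, \code{mode}, \code{n_tumor},
#'   \code{n_normal}, \code{n_pairs}, \code{p_raw}, \code{p_adj},
#'   \code{delta_beta}, \code{direction}, \code{significant},
#'   \code{underpowered}, \code{degenerate}.
#' @export
differential_methylation <- function(table, genes = NULL,
                                     mode = c("unpaired", "paired"),
                                     alpha = 0.05) {
  stopifnot(inherits(table, "methylation_table"))
  mode <- match.arg(mode)
  rows <- table$rows
  keep <- if (is.null(genes)) seq_len(nrow(rows)) else which(rows$gene %in% genes)
  if (!is.null(genes)) {
    missing_genes <- setdiff(genes, rows$gene)
    if (length(missing_genes)) {
      stop("gene(s) absent from methylation table: ",
           paste(missing_genes, collapse = ", "))
    }
  }
  samples <- table$samples
  pairing <- build_pairing(samples, table$entity)
  if (mode == "paired" && nrow(pairing$pairs) == 0L) {
    stop("paired mode requires at least one tumor/normal pair; none found")
  }
  # first column per sample key
  key_col <- match(unique(samples$sample_key), samples$sample_key)
  names(key_col) <- samples$sample_key[key_col]
  tumor_cols <- which(samples$is_tumor)
  normal_cols <- which(samples$is_normal)
  t_pair_cols <- key_col[pairing$pairs$tumor_key]
  n_pair_cols <- key_col[pairing$pairs$normal_key]

  n <- length(keep)
  p_raw <- rep(NA_real_, n)
  delta <- rep(NA_real_, n)
  n_tum <- integer(n); n_nor <- integer(n); n_pairs <- integer(n)
  underp <- logical(n); degen <- logical(n)

  for (i in seq_len(n)) {
    b <- table$betas[keep[i], ]
    if (mode == "paired") {
      tb <- b[t_pair_cols]; nb <- b[n_pair_cols]
      ok <- !is.na(tb) & !is.na(nb)
      n_pairs[i] <- sum(ok)
      n_tum[i] <- sum(ok); n_nor[i] <- sum(ok)
      if (n_pairs[i] >= 1L) {
        w <- wilcoxon_paired(tb[ok] - nb[ok])
        p_raw[i] <- w$p_value
        delta[i] <- mean(tb[ok] - nb[ok])
        underp[i] <- w$underpowered
        degen[i] <- w$degenerate
      }
    } else {
      tb <- b[tumor_cols]; nb <- b[normal_cols]
      tb <- tb[!is.na(tb)]; nb <- nb[!is.na(nb)]
      n_tum[i] <- length(tb); n_nor[i] <- length(nb)
      if (length(tb) && length(nb)) {
        w <- wilcoxon_unpaired(tb, nb)
        p_raw[i] <- w$p_value
        delta[i] <- mean(tb) - mean(nb)
        underp[i] <- length(tb) < 5L || length(nb) < 5L
      }
    }
  }
  p_adj <- rep(NA_real_, n)
  tested <- !is.na(p_raw)
  if (any(tested)) p_adj[tested] <- bh_adjust(p_raw[tested])
  direction <- ifelse(is.na(delta), NA_character_,
                      ifelse(delta > 0, "hyper", ifelse(delta < 0, "hypo", "none")))
  out <- data.frame(
    entity = table$entity,
    gene = rows$gene[keep],
    region = rows$region[keep],
    mode = mode,
    n_tumor = n_tum,
    n_normal = n_nor,
    n_pairs = if (mode == "paired") n_pairs else NA_integer_,
    p_raw = p_raw,
    p_adj = p_adj,
    delta_beta = delta,
    direction = direction,
    significant = !is.na(p_adj) & p_adj < alpha,
    underpowered = underp,
    degenerate = degen,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "mode") <- mode
  attr(out, "n_pairs_available") <- nrow(pairing$pairs)
  class(out) <- c("methylation_results", "data.frame")
  out
}

#' Histogram of per-pair beta differences
#'
#' Bins the tumor-normal beta differences of one (gene, region) over the
#' participant-matched pairs into width-0.05 bins spanning [-1, 1]
#' (left-closed intervals). The counts sum to the number of pairs with a
#' non-missing difference; the shape shows whether the region is hyper-,
#' hypo-methylated or both.
#'
#' @param table a \code{methylation_table}.
#' @param gene HUGO symbol.
#' @param region one of the six 450k gene-group tokens.
#' @param pairing optional \code{sample_pairing}; built from the table's
#'   samples when omitted.
#' @return data.frame of class \code{"delta_histogram"} with columns
#'   \code{bin_low}, \code{bin_high}, \code{count}; attribute
#'   \code{n_pairs}.
#' @export
delta_histogram <- function(table, gene, region, pairing = NULL) {
  stopifnot(inherits(table, "methylation_table"))
  if (is.null(pairing)) pairing <- build_pairing(table$samples, table$entity)
  if (nrow(pairing$pairs) == 0L) {
    stop("delta histogram requires tumor/normal pairs; none found")
  }
  i <- which(table$rows$gene == gene & table$rows$region == region)
  if (!length(i)) {
    stop("no row for gene '", gene, "', region '", region, "'")
  }
  samples <- table$samples
  key_col <- match(unique(samples$sample_key), samples$sample_key)
  names(key_col) <- samples$sample_key[key_col]
  b <- table$betas[i[1L], ]
  d <- b[key_col[pairing$pairs$tumor_key]] - b[key_col[pairing$pairs$normal_key]]
  d <- d[!is.na(d)]
  breaks <- round(seq(-1, 1, by = 0.05), 2)
  h <- graphics::hist(d, breaks = breaks, right = FALSE, include.lowest = TRUE,
                      plot = FALSE)
  out <- data.frame(
    bin_low = utils::head(breaks, -1L),
    bin_high = breaks[-1L],
    count = h$counts
  )
  attr(out, "n_pairs") <- length(d)
  attr(out, "gene") <- gene
  attr(out, "region") <- region
  class(out) <- c("delta_histogram", "data.frame")
  out
}
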