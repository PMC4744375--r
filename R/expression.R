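#' Leave-one-out z-score of one sample
#'
#' Relative expression of a gene in one tumor sample against the remaining
#' samples of the same entity: the focal value minus the mean of the
#' reference set (all other samples), divided by the reference's sample
#' standard deviation (n-1 denominator). A reference with zero spread makes
#' the score undefined; such degenerate cases return \code{NA} and are
#' excluded from threshold calls.
#'
#' @param values numeric vector: the gene's expression across all samples of
#'   the entity (length >= 3).
#' @param index position of the focal sample in \code{values}.
#' @return the z-score, or \code{NA_real_} when the reference spread is zero.
#' @examples
#' zscore_relative(c(1, 2, 3, 4, 10), 5)  # 5.80948
#' @export
zscore_relative <- function(values, index) {
  stopifnot(is.numeric(values), length(index) == 1L,
            index >= 1L, index <= length(values))
  if (length(values) < 3L) stop("leave-one-out z-score requires >= 3 samples")
  loo_zscores(values)[index]
}

# vectorized leave-one-out z-scores for every position of x;
# centered-sum formulation keeps the computation O(n) and stable
loo_zscores <- function(x) {
  n <- length(x)
  if (n < 3L) stop("leave-one-out z-score requires >= 3 samples")
  x0 <- x - mean(x)
  s <- sum(x0)
  ss <- sum(x0^2)
  m_ref <- (s - x0) / (n - 1)
  var_ref <- (ss - x0^2 - (n - 1) * m_ref^2) / (n - 2)
  var_ref[var_ref < 0] <- 0
  # zero-spread reference: variance indistinguishable from rounding noise
  scale2 <- (ss - x0^2) / (n - 2)
  degenerate <- var_ref <= scale2 * 1e-12
  sd_ref <- sqrt(var_ref)
  z <- (x0 - m_ref) / sd_ref
  z[degenerate] <- NA_real_
  z
}

#' Leave-one-out fold change of one sample
#'
#' Ratio of the focal sample's (pseudocounted) expression to the
#' pseudocounted mean of the remaining samples of the entity.
#'
#' @param values numeric vector of the gene's expression across the entity.
#' @param index position of the focal sample.
#' @param pseudocount epsilon >= 0 added to numerator and denominator
#'   (default 1), so all-zero references stay defined.
#' @return the fold change.
#' @export
fold_change_relative <- function(values, index, pseudocount = 1) {
  stopifnot(is.numeric(values), length(index) == 1L,
            index >= 1L, index <= length(values), pseudocount >= 0)
  if (length(values) < 3L) stop("fold change requires >= 3 samples")
  ref_mean <- mean(values[-index])
  denom <- ref_mean + pseudocount
  if (denom == 0) stop("reference mean plus pseudocount is zero")
  (values[index] + pseudocount) / denom
}

# all leave-one-out fold changes of x at once
loo_foldchanges <- function(x, pseudocount) {
  n <- length(x)
  m_ref <- (sum(x) - x) / (n - 1)
  denom <- m_ref + pseudocount
  if (any(denom == 0)) stop("reference mean plus pseudocount is zero")
  (x + pseudocount) / denom
}

#' Relative-expression calls across an entity
#'
#' Scores every (gene, tumor sample) pair of an entity by leave-one-out
#' z-score or fold change and classifies it against a threshold \code{t}:
#' z-scores call \emph{over} at score >= t and \emph{under} at score <= -t;
#' fold changes call \emph{over} at score >= t and \emph{under} at
#' score <= 1/t (symmetric on the ratio scale). Normal samples
#' (barcode sample-type 10-19) are excluded from both the focal and the
#' reference sets.
#'
#' @param matrix an \code{expression_matrix}.
#' @param genes HUGO symbols to score; default all genes in the matrix.
#' @param method \code{"zscore"} (default) or \code{"foldchange"}.
#' @param threshold positive call threshold \code{t} (default 2).
#' @param pseudocount fold-change pseudocount (default 1).
#' @param log2 if TRUE, apply \code{log2(x + 1)} before scoring.
#' @return data.frame of class \code{"expression_calls"} with columns
#'   \code{entity}, \code{gene}, \code{sample_key}, \code{barcode},
#'   \code{raw_value}, \code{score}, \code{method}, \code{call}
#'   (\code{over}/\code{under}/\code{neutral}, NA when degenerate) and
#'   \code{degenerate}.
#' @export
expression_calls <- function(matrix, genes = NULL,
                             method = c("zscore", "foldchange"),
                             threshold = 2, pseudocount = 1, log2 = FALSE) {
  stopifnot(inherits(matrix, "expression_matrix"), threshold > 0)
  method <- match.arg(method)
  if (is.null(genes)) genes <- unique(matrix$genes$symbol)
  missing_genes <- setdiff(genes, matrix$genes$symbol)
  if (length(missing_genes)) {
    stop("gene(s) absent from expression matrix: ",
         paste(missing_genes, collapse = ", "))
  }
  tumor <- matrix$samples$is_tumor
  if (sum(tumor) < 3L) stop("entity has fewer than 3 tumor samples")
  tumor_keys <- matrix$samples$sample_key[tumor]
  tumor_bars <- matrix$samples$raw[tumor]

  gene_col <- list(); raw_col <- list(); score_col <- list()
  for (k in seq_along(genes)) {
    g <- genes[k]
    row_ids <- matrix$genes$row_id[matrix$genes$symbol == g]
    for (rid in row_ids) {
      raw <- matrix$values[rid, tumor, drop = TRUE]
      x <- if (log2) log2(raw + 1) else raw
      score <- if (method == "zscore") loo_zscores(x)
      else loo_foldchanges(x, pseudocount)
      i <- length(gene_col) + 1L
      gene_col[[i]] <- g
      raw_col[[i]] <- raw
      score_col[[i]] <- score
    }
  }
  n_tum <- sum(tumor)
  score <- unlist(score_col, use.names = FALSE)
  degenerate <- is.na(score)
  call <- rep("neutral", length(score))
  if (method == "zscore") {
    call[!degenerate & score >= threshold] <- "over"
    call[!degenerate & score <= -threshold] <- "under"
  } else {
    call[!degenerate & score >= threshold] <- "over"
    call[!degenerate & score <= 1 / threshold] <- "under"
  }
  call[degenerate] <- NA_character_
  out <- data.frame(
    entity = matrix$entity,
    gene = rep(unlist(gene_col), each = n_tum),
    sample_key = rep(tumor_keys, times = length(gene_col)),
    barcode = rep(tumor_bars, times = length(gene_col)),
    raw_value = unlist(raw_col, use.names = FALSE),
    score = score, method = method, call = call, degenerate = degenerate,
    stringsAsFactors = FALSE
  )
  attr(out, "threshold") <- threshold
  attr(out, "method") <- method
  attr(out, "log2") <- log2
  class(out) <- c("expression_calls", "data.frame")
  out
}

#' Waterfall series of non-neutral expression calls
#'
#' Orders the calls the way the waterfall plot draws them: one panel per
#' entity (entity-centric view) or per gene (gene-centric view), records
#' sorted by descending score within the panel, ties broken by sample key,
#' and only calls exceeding the threshold (call != neutral) retained.
#'
#' @param calls an \code{expression_calls} frame.
#' @param axis \code{"entity_centric"} (default) or \code{"gene_centric"}.
#' @return data.frame of class \code{"waterfall_data"} with a \code{panel}
#'   column and a within-panel \code{rank}.
#' @export
waterfall_data <- function(calls, axis = c("entity_centric", "gene_centric")) {
  stopifnot(inherits(calls, "expression_calls"))
  axis <- match.arg(axis)
  keep <- !is.na(calls$call) & calls$call != "neutral"
  out <- calls[keep, , drop = FALSE]
  out$panel <- if (axis == "entity_centric") out$entity else out$gene
  ord <- order(out$panel, -out$score, out$sample_key, method = "radix")
  out <- out[ord, , drop = FALSE]
  ranks <- stats::ave(seq_len(nrow(out)), out$panel, FUN = seq_along)
  out$rank <- if (nrow(out)) as.integer(ranks) else integer(0L)
  rownames(out) <- NULL
  attr(out, "axis") <- axis
  class(out) <- c("waterfall_data", "data.frame")
  out
}

#' Entity-wise box-plot summary of one gene
#'
#' Five-number summary of the gene's expression over the entity's tumor
#' samples: quartiles by the linear-interpolation convention, whiskers at the
#' most extreme observations within 1.5 IQR of the quartiles, plus the
#' number of over/under calls at the given threshold.
#'
#' @param matrix an \code{expression_matrix}.
#' @param gene HUGO symbol.
#' @param threshold call threshold (default 2).
#' @param method scoring method for the call counts (default zscore).
#' @param pseudocount fold-change pseudocount.
#' @param log2 apply log2(x+1) before scoring (summary stays on the raw scale).
#' @return one-row data.frame of class \code{"entity_expression_summary"}:
#'   \code{entity}, \code{gene}, \code{n}, \code{median}, \code{q1},
#'   \code{q3}, \code{whisker_low}, \code{whisker_high}, \code{n_over},
#'   \code{n_under}.
#' @export
entity_boxplot_summary <- function(matrix, gene, threshold = 2,
                                   method = c("zscore", "foldchange"),
                                   pseudocount = 1, log2 = FALSE) {
  stopifnot(inherits(matrix, "expression_matrix"))
  method <- match.arg(method)
  calls <- expression_calls(matrix, gene, method = method,
                            threshold = threshold, pseudocount = pseudocount,
                            log2 = log2)
  v <- calls$raw_value
  q <- stats::quantile(v, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3L] - q[1L]
  in_lo <- v[v >= q[1L] - 1.5 * iqr]
  in_hi <- v[v <= q[3L] + 1.5 * iqr]
  out <- data.frame(
    entity = matrix$entity, gene = gene, n = length(v),
    median = q[2L], q1 = q[1L], q3 = q[3L],
    whisker_low = min(in_lo), whisker_high = max(in_hi),
    n_over = sum(calls$call == "over", na.rm = TRUE),
    n_under = sum(calls$call == "under", na.rm = TRUE),
    stringsAsFactors = FALSE
  )
  class(out) <- c("entity_expression_summary", "data.frame")
  out
}
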