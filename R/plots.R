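# Plot rendering. Every plot is a pure function of an emitted table:
# the analysis tables are written first and the figures are drawn only from
# their contents, so re-rendering from tables reproduces the same data.

open_device <- function(file, format) {
  if (format == "pdf") {
    grDevices::pdf(file, width = 7, height = 5)
  } else {
    grDevices::png(file, width = 900, height = 640, res = 110)
  }
}

placeholder_panel <- function(file, format, msg = "no data") {
  open_device(file, format)
  on.exit(grDevices::dev.off())
  graphics::plot.new()
  graphics::text(0.5, 0.5, msg, cex = 1.4, col = "grey40")
  invisible(file)
}

# gene x entity grid colored by a fraction in [0,1]
plot_profile_grid <- function(mat, file, format, main, legend_label) {
  if (!length(mat) || all(is.na(mat))) {
    return(placeholder_panel(file, format))
  }
  open_device(file, format)
  on.exit(grDevices::dev.off())
  ramp <- grDevices::colorRampPalette(c("#f7f7f7", "#b2182b"))(100)
  op <- graphics::par(mar = c(5, 7, 3, 2))
  on.exit(graphics::par(op), add = TRUE)
  graphics::image(seq_len(ncol(mat)), seq_len(nrow(mat)), t(mat),
                  col = ramp, zlim = c(0, 1), axes = FALSE,
                  xlab = "entity", ylab = "", main = main)
  graphics::axis(1, at = seq_len(ncol(mat)), labels = colnames(mat))
  graphics::axis(2, at = seq_len(nrow(mat)), labels = rownames(mat), las = 1)
  for (i in seq_len(nrow(mat))) {
    for (j in seq_len(ncol(mat))) {
      graphics::text(j, i, sprintf("%.1f%%", 100 * mat[i, j]), cex = 0.8)
    }
  }
  graphics::mtext(legend_label, side = 1, line = 3.5, cex = 0.8)
  invisible(file)
}

plot_class_pie <- function(breakdown, file, format, main) {
  if (!nrow(breakdown)) return(placeholder_panel(file, format))
  open_device(file, format)
  on.exit(grDevices::dev.off())
  labs <- sprintf("%s (%.1f%%)", breakdown$variant_class,
                  100 * breakdown$sample_percentage)
  graphics::pie(breakdown$slice_proportion, labels = labs, main = main,
                col = grDevices::hcl.colors(nrow(breakdown), "Set 2"))
  invisible(file)
}

plot_waterfall_panel <- function(panel_df, file, format, main) {
  if (!nrow(panel_df)) return(placeholder_panel(file, format))
  open_device(file, format)
  on.exit(grDevices::dev.off())
  cols <- ifelse(panel_df$call == "over", "#b2182b", "#2166ac")
  graphics::barplot(panel_df$score, col = cols, border = NA,
                    main = main, xlab = "samples beyond threshold",
                    ylab = "relative expression score")
  graphics::abline(h = 0)
  invisible(file)
}

plot_entity_box <- function(summary_row, file, format, main) {
  if (!nrow(summary_row)) return(placeholder_panel(file, format))
  open_device(file, format)
  on.exit(grDevices::dev.off())
  stats_mat <- matrix(c(summary_row$whisker_low, summary_row$q1,
                        summary_row$median, summary_row$q3,
                        summary_row$whisker_high), ncol = 1)
  bx <- list(stats = stats_mat, n = summary_row$n, conf = NULL,
             out = numeric(0L), names = summary_row$gene)
  graphics::bxp(bx, main = main, ylab = "RSEM normalized count")
  invisible(file)
}

plot_delta_hist <- function(histdf, file, format, main) {
  if (!nrow(histdf) || sum(histdf$count) == 0) {
    return(placeholder_panel(file, format))
  }
  open_device(file, format)
  on.exit(grDevices::dev.off())
  graphics::barplot(histdf$count, width = 0.05, space = 0,
                    col = "#5a9bd4", border = "white", main = main,
                    xlab = "tumor - normal beta difference",
                    ylab = "number of samples")
  ticks <- seq(0, nrow(histdf), by = 8)
  graphics::axis(1, at = ticks * 0.05,
                 labels = sprintf("%.1f", -1 + ticks * 0.05))
  invisible(file)
}

plot_methylation_grid <- function(results, file, format, main) {
  if (!nrow(results)) return(placeholder_panel(file, format))
  open_device(file, format)
  on.exit(grDevices::dev.off())
  genes <- unique(results$gene)
  regions <- METH_REGIONS[METH_REGIONS %in% results$region]
  mat <- matrix(NA_real_, length(genes), length(regions),
                dimnames = list(genes, regions))
  for (i in seq_len(nrow(results))) {
    mat[results$gene[i], results$region[i]] <- results$delta_beta[i]
  }
  ramp <- grDevices::colorRampPalette(c("#2166ac", "#f7f7f7", "#b2182b"))(100)
  op <- graphics::par(mar = c(5, 7, 3, 2))
  on.exit(graphics::par(op), add = TRUE)
  graphics::image(seq_along(regions), seq_along(genes), t(mat), col = ramp,
                  zlim = c(-1, 1), axes = FALSE, xlab = "gene region",
                  ylab = "", main = main)
  graphics::axis(1, at = seq_along(regions), labels = regions, cex.axis = 0.8)
  graphics::axis(2, at = seq_along(genes), labels = genes, las = 1)
  sig <- results$significant & !is.na(results$significant)
  for (i in which(sig)) {
    graphics::text(match(results$region[i], regions),
                   match(results$gene[i], genes), "*", cex = 1.5)
  }
  invisible(file)
}

plot_cnv_bars <- function(bars, file, format, main) {
  if (!nrow(bars)) return(placeholder_panel(file, format))
  open_device(file, format)
  on.exit(grDevices::dev.off())
  value <- if ("fraction" %in% names(bars)) bars$fraction else bars$count
  cols <- c("#2166ac", "#92c5de", "#bababa", "#f4a582", "#b2182b")
  graphics::barplot(value, names.arg = as.character(bars$category),
                    col = cols, main = main, xlab = "GISTIC category",
                    ylab = if ("fraction" %in% names(bars)) "fraction of samples"
                    else "number of samples")
  invisible(file)
}
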