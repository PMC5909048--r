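# BAF-style visualization of allele balance and window peaks.

#' Plot allele balance and window peaks for one sample and chromosome
#'
#' Left panel: per-variant dominant (light blue, above 1/2) and secondary
#' (dark blue, below 1/2) allele balances along the chromosome, horizontal
#' bars spanning each window at its called peak, and dashed lines at the
#' expected dosage ratios. Right panel: the marginal allele-balance
#' histogram at the same bin width. Headless-safe (base graphics).
#'
#' @param balance An \code{"allele_balance"} object.
#' @param pos Per-variant positions aligned with the balance rows.
#' @param wp_dom \code{"window_peaks"} result for the dominant matrix.
#' @param wp_sec Optional \code{"window_peaks"} result for the secondary
#'   matrix (its peak bars are drawn too).
#' @param sample Column index or name to plot (default first).
#' @param chrom Per-variant chromosome vector; needed when the balance
#'   matrices span several chromosomes. \code{which_chrom} selects one.
#' @param which_chrom Chromosome to draw (default the first present).
#' @param main Plot title.
#' @return Invisibly, \code{NULL}.
#' @export
plot_window_peaks <- function(balance, pos, wp_dom, wp_sec = NULL,
                              sample = 1L, chrom = NULL,
                              which_chrom = NULL, main = NULL) {
  stopifnot(inherits(balance, "allele_balance"),
            inherits(wp_dom, "window_peaks"))
  if (is.character(sample)) {
    sample <- match(sample, colnames(balance$dominant))
  }
  if (is.null(chrom)) chrom <- rep("1", length(pos))
  if (is.null(which_chrom)) which_chrom <- chrom[1L]
  sel <- chrom == which_chrom
  if (is.null(main)) {
    main <- paste0(which_chrom, " / ",
                   colnames(balance$dominant)[sample] %||% sample)
  }

  dom <- balance$dominant[sel, sample]
  sec <- balance$secondary[sel, sample]
  p <- pos[sel]
  bw <- wp_dom$bin_width
  wtab <- wp_dom$windows[wp_dom$windows$chrom == which_chrom, , drop = FALSE]
  widx <- as.integer(rownames(wtab))

  op <- par(no.readonly = TRUE)
  on.exit(par(op))
  layout(matrix(1:2, nrow = 1L), widths = c(4, 1))
  par(mar = c(4, 4, 2.5, 0.5))
  plot(NULL, xlim = range(p, wtab$end, na.rm = TRUE), ylim = c(0, 1),
       xlab = paste0("position on ", which_chrom, " (bp, 1-based)"),
       ylab = "allele balance", main = main)
  abline(h = balance_expectations()$expectation, lty = 3, col = "grey60")
  points(p, sec, pch = 20, cex = 0.4, col = "#27408B66")
  points(p, dom, pch = 20, cex = 0.4, col = "#1E90FF66")
  segments(wtab$start, wp_dom$peaks[widx, sample],
           wtab$end, wp_dom$peaks[widx, sample], lwd = 2, col = "black")
  if (!is.null(wp_sec)) {
    segments(wtab$start, wp_sec$peaks[widx, sample],
             wtab$end, wp_sec$peaks[widx, sample], lwd = 2, col = "grey30")
  }
  par(mar = c(4, 0.5, 2.5, 1))
  h <- hist(c(dom, sec), breaks = seq(0, 1, by = bw), plot = FALSE)
  barplot(h$counts, horiz = TRUE, space = 0, axes = FALSE,
          col = "#4682B4", border = NA)
  invisible(NULL)
}
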