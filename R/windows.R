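# Fixed-width genomic windows, histogram binning, and modal peak calling.

#' Assign sorted positions to fixed-width windows
#'
#' Windows are anchored at position 1 and tile the chromosome without
#' overlap: window k covers [(k-1)*window_size + 1, k*window_size], 1-based
#' inclusive. Every window up to the last occupied one is present, so
#' empty interior windows appear with zero variants downstream.
#'
#' @param pos Integer vector of 1-based positions, sorted ascending.
#' @param window_size Window width in bases, >= 1.
#' @return List with \code{index} (1-based window index per position) and
#'   \code{windows} (data.frame \code{window}, \code{start}, \code{end}).
#' @examples
#' assign_windows(c(1, 40000, 40001), 40000)$index  # 1 1 2
#' @export
assign_windows <- function(pos, window_size) {
  stopifnot(window_size >= 1)
  if (is.unsorted(pos)) {
    i <- which(diff(pos) < 0)[1L] + 1L
    stop("positions must be sorted ascending within a chromosome; ",
         "element ", i, " (", pos[i], ") is out of order")
  }
  idx <- as.integer(floor((pos - 1) / window_size)) + 1L
  k <- if (length(pos)) max(idx) else 0L
  w <- seq_len(k)
  list(index = idx,
       windows = data.frame(window = w,
                            start = (w - 1) * window_size + 1,
                            end = w * window_size))
}

#' Bin allele-balance values on (0, 1]
#'
#' Half-open bins \code{(lo, hi]} of the given width; a value of exactly 0
#' (impossible for a genuine heterozygote) falls in no bin, a value of
#' exactly 1/2 falls in the bin ending at 0.5. Bin membership is computed
#' with a small tolerance (1e-9 of a bin) so that values lying on an edge
#' up to floating-point error bin deterministically.
#'
#' @param values Numeric vector of balances in [0, 1]; \code{NA} dropped.
#' @param bin_width Bin width in (0, 0.5].
#' @return List with \code{counts} (occupancy per bin), \code{mid} (bin
#'   midpoints) and \code{edges}.
#' @export
bin_balance <- function(values, bin_width) {
  stopifnot(bin_width > 0, bin_width <= 0.5)
  nb <- as.integer(ceiling(1 / bin_width - 1e-9))
  v <- values[!is.na(values)]
  if (any(v < 0 | v > 1 + 1e-9)) {
    stop("balance values must lie in [0, 1]")
  }
  b <- ceiling(v / bin_width - 1e-9)
  b <- b[b >= 1L & b <= nb]
  list(counts = tabulate(b, nbins = nb),
       mid = (seq_len(nb) - 0.5) * bin_width,
       edges = seq_len(nb + 1L) * bin_width - bin_width)
}

# modal bin -> midpoint; ties resolved toward 0.5, then toward the lower bin
.peak_from_counts <- function(counts, mid) {
  m <- max(counts)
  if (m == 0L) return(NA_real_)
  cand <- which(counts == m)
  if (length(cand) > 1L) {
    d <- abs(mid[cand] - 0.5)
    cand <- cand[d - min(d) < 1e-12]
  }
  mid[cand[1L]]
}

#' Window the genome and call the modal allele-balance bin per window
#'
#' The windowed peak caller: variants are assigned to fixed-width windows
#' per chromosome, each window's non-missing balance values are summarized
#' in histogram bins of width \code{bin_width}, and the most occupied bin's
#' midpoint is reported as the window's peak, per sample. Windows with
#' fewer than \code{min_count} binned variants report their count but a
#' missing peak — such windows (e.g. runs of loss of heterozygosity) carry
#' too little support for a determination.
#'
#' @param balance Variants x samples numeric matrix of balances (typically
#'   the \code{dominant} matrix of [depths_to_balance()]); a vector is
#'   treated as one sample.
#' @param pos 1-based positions aligned with the rows of \code{balance},
#'   sorted ascending within each chromosome.
#' @param chrom Optional per-variant chromosome; default one chromosome.
#'   Windows restart at each chromosome and never span a boundary.
#' @param window_size Window width in bases (default 40000).
#' @param bin_width Histogram bin width in (0, 0.5] (default 0.02).
#' @param min_count Minimum binned variants for a peak (default 20).
#' @return An object of class \code{"window_peaks"}: list with
#'   \code{windows} (data.frame \code{chrom}, \code{window}, \code{start},
#'   \code{end}, \code{first_row}, \code{last_row}, \code{first_pos},
#'   \code{last_pos}; row indices refer to the input matrix), \code{counts}
#'   and \code{peaks} (windows x samples matrices), and the parameters.
#' @export
window_peaks <- function(balance, pos, chrom = NULL, window_size = 40000,
                         bin_width = 0.02, min_count = 20) {
  if (is.null(dim(balance))) balance <- matrix(balance, ncol = 1L)
  stopifnot(nrow(balance) == length(pos), min_count >= 1)
  if (bin_width <= 0 || bin_width > 0.5) {
    stop("bin_width must be in (0, 0.5]")
  }
  if (is.null(chrom)) chrom <- rep("1", length(pos))
  stopifnot(length(chrom) == length(pos))

  nb <- as.integer(ceiling(1 / bin_width - 1e-9))
  mid <- (seq_len(nb) - 0.5) * bin_width
  nsamp <- ncol(balance)

  win_rows <- list()
  counts <- NULL
  peaks <- NULL
  for (cc in unique(chrom)) {
    sel <- which(chrom == cc)
    aw <- assign_windows(pos[sel], window_size)
    k <- nrow(aw$windows)
    cnt <- matrix(0L, k, nsamp, dimnames = list(NULL, colnames(balance)))
    pk <- matrix(NA_real_, k, nsamp, dimnames = list(NULL, colnames(balance)))
    first_row <- last_row <- rep(NA_integer_, k)
    first_pos <- last_pos <- rep(NA_integer_, k)
    for (w in seq_len(k)) {
      rows <- sel[aw$index == w]
      if (length(rows)) {
        first_row[w] <- rows[1L]
        last_row[w] <- rows[length(rows)]
        first_pos[w] <- pos[rows[1L]]
        last_pos[w] <- pos[rows[length(rows)]]
        for (j in seq_len(nsamp)) {
          v <- balance[rows, j]
          v <- v[!is.na(v)]
          b <- ceiling(v / bin_width - 1e-9)
          b <- b[b >= 1L & b <= nb]
          occ <- tabulate(b, nbins = nb)
          cnt[w, j] <- sum(occ)
          if (cnt[w, j] >= min_count) {
            pk[w, j] <- .peak_from_counts(occ, mid)
          }
        }
      }
    }
    win_rows[[cc]] <- data.frame(chrom = cc, aw$windows,
                                 first_row = first_row, last_row = last_row,
                                 first_pos = first_pos, last_pos = last_pos,
                                 stringsAsFactors = FALSE)
    counts <- rbind(counts, cnt)
    peaks <- rbind(peaks, pk)
  }
  structure(list(windows = do.call(rbind, c(win_rows, make.row.names = FALSE)),
                 counts = counts, peaks = peaks,
                 window_size = window_size, bin_width = bin_width,
                 min_count = min_count),
            class = "window_peaks")
}

#' @export
print.window_peaks <- function(x, ...) {
  cat("window_peaks: ", nrow(x$windows), " window(s) x ",
      ncol(x$counts), " sample(s); window_size=", x$window_size,
      ", bin_width=", x$bin_width, ", min_count=", x$min_count, "\n",
      sep = "")
  cat("peaks called: ", sum(!is.na(x$peaks)), "/", length(x$peaks), "\n",
      sep = "")
  invisible(x)
}

#' Flatten chromosomal positions onto one non-overlapping genomic axis
#'
#' For multi-chromosome plots and tables it is convenient to lay the
#' chromosomes end to end. The first chromosome is unshifted; each
#' subsequent one is shifted by the cumulative span of all prior
#' chromosomes (declared length if given, else the maximum observed
#' position) plus an optional buffer. Within-chromosome order is preserved.
#'
#' @param chrom Per-variant chromosome, grouped in a stable order.
#' @param pos Per-variant 1-based position.
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @param buffer Gap in bases inserted between chromosomes (default 0).
#' @return Numeric vector of genomic (non-overlapping) positions.
#' @export
genomic_positions <- function(chrom, pos, chrom_lengths = NULL, buffer = 0) {
  stopifnot(length(chrom) == length(pos))
  uc <- unique(chrom)
  span <- vapply(uc, function(cc) {
    if (!is.null(chrom_lengths) && cc %in% names(chrom_lengths)) {
      as.numeric(chrom_lengths[[cc]])
    } else {
      max(pos[chrom == cc])
    }
  }, numeric(1L))
  offset <- c(0, cumsum(span + buffer))[seq_along(uc)]
  unname(pos + offset[match(chrom, uc)])
}
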