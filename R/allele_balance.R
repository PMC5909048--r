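# From AD strings at heterozygous genotypes to allele-balance matrices.

#' Ordered allele depths at heterozygous genotypes
#'
#' Takes the raw AD and GT string matrices from [read_vcf()] and returns the
#' depths of the two most abundant alleles at each heterozygous genotype.
#' Homozygous, half-missing and missing genotypes are masked to \code{NA}
#' so the analysis is restricted to informative (heterozygous) sites.
#' Multiallelic AD cells are handled by keeping the two largest entries.
#'
#' @param ad Character matrix of AD strings (comma-delimited depths).
#' @param gt Character matrix of GT strings, same dimensions.
#' @return An object of class \code{"allele_depths"}: a list of two numeric
#'   matrices \code{d1} (most abundant) and \code{d2} (second most
#'   abundant), with \code{d1 >= d2} wherever both are defined.
#' @export
ad_to_depths <- function(ad, gt) {
  if (!all(dim(ad) == dim(gt))) {
    stop("AD and GT matrices have different dimensions")
  }
  het <- is_het(gt)
  keep <- !is.na(het) & het
  d1 <- field_element(ad, record = 1L, sort_desc = TRUE)
  d2 <- field_element(ad, record = 2L, sort_desc = TRUE)
  d1[!keep] <- NA_real_
  d2[!keep] <- NA_real_
  structure(list(d1 = d1, d2 = d2), class = "allele_depths")
}

#' Allele balance of the two most abundant alleles
#'
#' Divides each allele's depth by the summed depth of the two most abundant
#' alleles, giving the frequency at which each allele was sequenced. The
#' dominant balance lies in [1/2, 1], the secondary in [0, 1/2], and the two
#' sum to 1 wherever defined; cells with zero total depth are \code{NA}.
#'
#' @param depths An \code{"allele_depths"} object from [ad_to_depths()].
#' @return An object of class \code{"allele_balance"}: list of matrices
#'   \code{dominant} and \code{secondary}.
#' @export
depths_to_balance <- function(depths) {
  stopifnot(inherits(depths, "allele_depths"))
  tot <- depths$d1 + depths$d2
  tot[!is.na(tot) & tot == 0] <- NA_real_
  structure(list(dominant = depths$d1 / tot,
                 secondary = depths$d2 / tot),
            class = "allele_balance")
}

#' Censor genotypes of unusual sequencing depth
#'
#' Per sample, genotypes whose total depth (d1 + d2) falls outside the given
#' empirical quantiles of that sample's non-missing totals are set missing.
#' This trims the long tails of very low and very high coverage that
#' otherwise contaminate the allele-balance histograms. Quantiles are
#' computed per sample because coverage differs among samples.
#'
#' @param depths An \code{"allele_depths"} object.
#' @param lower_q,upper_q Quantile bounds in [0, 1], \code{lower_q <
#'   upper_q}; defaults 0.05 and 0.95. \code{c(0, 1)} is the identity.
#' @return A censored \code{"allele_depths"} object; the number of censored
#'   cells is reported via \code{message()}. A sample with no non-missing
#'   totals is left unchanged with a warning.
#' @export
censor_by_depth <- function(depths, lower_q = 0.05, upper_q = 0.95) {
  stopifnot(inherits(depths, "allele_depths"),
            lower_q >= 0, upper_q <= 1, lower_q < upper_q)
  d1 <- depths$d1
  d2 <- depths$d2
  tot <- d1 + d2
  ncens <- 0L
  for (j in seq_len(ncol(d1))) {
    v <- tot[, j]
    ok <- !is.na(v)
    if (!any(ok)) {
      warning("sample ", colnames(d1)[j] %||% j,
              ": all depths missing, nothing to censor")
      next
    }
    q <- quantile(v[ok], c(lower_q, upper_q), names = FALSE)
    drop <- ok & (v < q[1L] | v > q[2L])
    ncens <- ncens + sum(drop)
    d1[drop, j] <- NA_real_
    d2[drop, j] <- NA_real_
  }
  message("censor_by_depth: ", ncens, " genotype(s) censored")
  structure(list(d1 = d1, d2 = d2), class = "allele_depths")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
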