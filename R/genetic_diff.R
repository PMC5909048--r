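# Allele-count-weighted genetic differentiation for mixed-ploidy
# populations.
#
# Heterozygosity-based differentiation (Nei's Gst, Hedrick's G'st) needs no
# assumption about ploidy: every observed allele, whatever the copy number
# of the genotype carrying it, contributes one count. Populations are
# weighted by the number of alleles actually observed at each variant,
# which corrects at once for unequal sample sizes and for samples of
# unequal copy number (a tetraploid individual carries twice the
# information of a diploid one).

#' Per-population allele counts and frequencies
#'
#' Every non-missing allele in every genotype contributes one count to its
#' sample's population; genotypes may be of any ploidy (1, 2, 3, ... allele
#' calls) and ploidies may mix freely across samples.
#'
#' @param gt Variants x samples character matrix of GT strings.
#' @param pops Population assignment: either a named character vector
#'   (names = sample names) or a two-column data.frame (sample,
#'   population). Every column of \code{gt} must be assigned.
#' @return List with \code{n} (variants x populations matrix of observed
#'   allele counts), \code{freq} (variants x alleles x populations array of
#'   allele frequencies; rows with zero count are \code{NA}), and
#'   \code{alleles} (the allele labels).
#' @export
count_alleles <- function(gt, pops) {
  pops <- .as_pop_vector(pops)
  samples <- colnames(gt)
  if (is.null(samples)) samples <- names(pops)[seq_len(ncol(gt))]
  unassigned <- setdiff(samples, names(pops))
  if (length(unassigned)) {
    stop("sample(s) without population assignment: ",
         paste(unassigned, collapse = ", "))
  }
  pop_of <- pops[samples]
  pop_levels <- unique(unname(pops))
  nvar <- nrow(gt)

  sp <- strsplit(as.character(gt), "[/|]")
  len <- lengths(sp)
  cell <- rep(seq_along(sp), len)
  allele <- unlist(sp, use.names = FALSE)
  keep <- nzchar(allele) & allele != "." & !is.na(allele)
  allele <- allele[keep]
  cell <- cell[keep]
  var_i <- (cell - 1L) %% nvar + 1L
  samp_i <- (cell - 1L) %/% nvar + 1L

  allele_levels <- sort(unique(allele))
  cnt <- table(factor(var_i, levels = seq_len(nvar)),
               factor(allele, levels = allele_levels),
               factor(pop_of[samp_i], levels = pop_levels))
  cnt <- array(as.integer(cnt), dim = dim(cnt),
               dimnames = list(NULL, allele_levels, pop_levels))
  n <- apply(cnt, c(1L, 3L), sum)
  if (nvar == 1L) {
    n <- matrix(n, nrow = 1L, dimnames = list(NULL, pop_levels))
  }
  freq <- array(NA_real_, dim = dim(cnt), dimnames = dimnames(cnt))
  for (k in seq_along(pop_levels)) {
    freq[, , k] <- cnt[, , k] / ifelse(n[, k] > 0, n[, k], NA_real_)
  }
  list(n = n, freq = freq, alleles = allele_levels)
}

.as_pop_vector <- function(pops) {
  if (is.data.frame(pops)) {
    stopifnot(ncol(pops) >= 2L)
    out <- setNames(as.character(pops[[2L]]), as.character(pops[[1L]]))
  } else {
    out <- setNames(as.character(pops), names(pops))
  }
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    stop("population assignment must carry sample names")
  }
  if (length(unique(out)) < 2L) {
    stop("at least two populations are required")
  }
  out
}

# Htmax: the total heterozygosity that would be observed if the
# populations shared no alleles, under allele-count weights
# w_k = n_k / sum(n):  Htmax = 1 - sum_k w_k^2 (1 - Hs_k).
# With equal weights this reduces to Hedrick's HT(max) = (k - 1 + Hs) / k.
# hs, n: variants x populations matrices. Terms with n_k = 0 drop out.
.htmax <- function(hs, n) {
  w <- n / rowSums(n)
  term <- w^2 * (1 - hs)
  term[n == 0] <- 0
  out <- 1 - rowSums(term)
  out[rowSums(n) == 0] <- NA_real_
  out
}

.weighted_hs <- function(hs, n) {
  w <- n / rowSums(n)
  term <- w * hs
  term[n == 0] <- 0
  out <- rowSums(term)
  out[rowSums(n) == 0] <- NA_real_
  out
}

#' Differentiation statistics from summary heterozygosities
#'
#' The formula layer of [genetic_diff()], exposed so the statistics can be
#' computed directly from per-population gene diversities and observed
#' allele counts (e.g. values taken from a published table). Weights are
#' \code{w_k = n_k / sum(n)}; \code{Hs} is the weighted mean of the
#' \code{hs}; \code{Htmax = 1 - sum(w^2 (1 - hs))}; \code{Gst = (Ht - Hs) /
#' Ht}; \code{Gstmax = (Htmax - Hs) / Htmax}; \code{Gprimest = Gst /
#' Gstmax}. Ratios with zero denominators are \code{NA}.
#'
#' @param hs Numeric vector (one variant) or matrix (variants x
#'   populations) of within-population gene diversities.
#' @param n Observed allele counts, same shape as \code{hs}.
#' @param ht Total heterozygosity per variant; required for \code{Gst} and
#'   \code{Gprimest} (it depends on the allele frequencies, not only on
#'   \code{hs}), otherwise \code{NA}.
#' @return data.frame with columns \code{Hs}, \code{Ht}, \code{Gst},
#'   \code{Htmax}, \code{Gstmax}, \code{Gprimest}.
#' @examples
#' gst_stats(hs = c(0.42, 0.42), n = c(20, 40), ht = 0.46)
#' @export
gst_stats <- function(hs, n, ht = NA_real_) {
  if (is.null(dim(hs))) hs <- matrix(hs, nrow = 1L)
  if (is.null(dim(n))) n <- matrix(n, nrow = 1L)
  stopifnot(all(dim(hs) == dim(n)))
  Hs <- .weighted_hs(hs, n)
  Htmax <- .htmax(hs, n)
  Gst <- ifelse(!is.na(ht) & ht > 0, (ht - Hs) / ht, NA_real_)
  Gstmax <- ifelse(Htmax > 0, (Htmax - Hs) / Htmax, NA_real_)
  Gprimest <- ifelse(!is.na(Gstmax) & Gstmax > 0, Gst / Gstmax, NA_real_)
  data.frame(Hs = Hs, Ht = ht, Gst = Gst, Htmax = Htmax,
             Gstmax = Gstmax, Gprimest = Gprimest)
}

#' Per-variant genetic differentiation for mixed-ploidy populations
#'
#' For each variant: per-population gene diversities \code{Hs_k = 1 -
#' sum(p_ki^2)} and observed allele counts \code{n_k}; allele-count
#' weights \code{w_k = n_k / sum(n)}; pooled frequencies \code{pbar_i =
#' sum_k w_k p_ki}; \code{Ht = 1 - sum(pbar^2)}; Nei's \code{Gst = (Ht -
#' Hs) / Ht}; the maximum total heterozygosity \code{Htmax} attainable if
#' no alleles were shared between populations; \code{Gstmax} and Hedrick's
#' standardized \code{Gprimest = Gst / Gstmax}. Monomorphic variants
#' (\code{Ht = 0}) yield \code{NA} for the ratio statistics.
#'
#' @param gt Variants x samples character matrix of GT strings (any
#'   ploidy; "/" and "|" equivalent).
#' @param pops Population assignment as in [count_alleles()].
#' @param chrom,pos Optional per-variant coordinates for the output table.
#' @return data.frame with columns \code{CHROM}, \code{POS},
#'   \code{Hs_<pop>} per population, \code{Ht}, \code{n_<pop>} per
#'   population, \code{Gst}, \code{Htmax}, \code{Gstmax}, \code{Gprimest}.
#' @export
genetic_diff <- function(gt, pops, chrom = NULL, pos = NULL) {
  ca <- count_alleles(gt, pops)
  n <- ca$n
  npop <- ncol(n)
  if (npop < 2L) stop("at least two populations are required")
  nvar <- nrow(gt)

  hs <- matrix(NA_real_, nvar, npop, dimnames = dimnames(n))
  for (k in seq_len(npop)) {
    hs[, k] <- 1 - rowSums(ca$freq[, , k, drop = FALSE]^2)
  }
  w <- n / rowSums(n)
  pbar <- matrix(0, nvar, dim(ca$freq)[2L])
  for (k in seq_len(npop)) {
    fk <- ca$freq[, , k]
    if (is.null(dim(fk))) fk <- matrix(fk, nrow = nvar)
    fk[n[, k] == 0, ] <- 0
    pbar <- pbar + w[, k] * fk
  }
  ht <- 1 - rowSums(pbar^2)

  st <- gst_stats(hs, n, ht)
  out <- data.frame(
    CHROM = if (is.null(chrom)) rep(NA_character_, nvar) else chrom,
    POS = if (is.null(pos)) seq_len(nvar) else pos,
    stringsAsFactors = FALSE)
  for (k in seq_len(npop)) out[[paste0("Hs_", colnames(n)[k])]] <- hs[, k]
  out$Ht <- ht
  for (k in seq_len(npop)) out[[paste0("n_", colnames(n)[k])]] <- n[, k]
  out$Gst <- st$Gst
  out$Htmax <- st$Htmax
  out$Gstmax <- st$Gstmax
  out$Gprimest <- st$Gprimest
  out
}

#' Read a sample-to-population mapping file
#'
#' Two-column headerless plain text: sample name then population label,
#' whitespace- or comma-delimited.
#'
#' @param path File path.
#' @return Named character vector, names = samples.
#' @export
read_populations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(gsub(",", " ", lines, fixed = TRUE))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    stop("population file line ", bad[1L], ": expected two columns")
  }
  setNames(vapply(parts, `[`, character(1L), 2L),
           vapply(parts, `[`, character(1L), 1L))
}
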