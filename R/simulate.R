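# Synthetic VCF generator with known ploidy structure.
#
# The simulator targets the VCF layer the method consumes: heterozygous
# sites at a configurable density, per-site read depths drawn from a
# negative binomial (high-throughput sequencing coverage is overdispersed
# relative to Poisson), allele depths binomial around the true dosage
# ratio, and a uniform-noise fraction of sites whose balance carries no
# dosage signal (mapping artifacts, paralogs, contamination). Ploidy is a
# piecewise-constant track per sample, so sub-genomic segments of altered
# copy number can be planted and recovered.

#' Build a simulation configuration
#'
#' Defaults describe a typical single-sample high-coverage experiment:
#' one 1-Mbp chromosome, 5 heterozygous sites per kbp, mean depth 100 with
#' negative-binomial dispersion size 10, and a 5\% uniform-noise fraction.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bases).
#' @param samples Character vector of sample names.
#' @param ploidy_track Optional data.frame with columns \code{chrom},
#'   \code{start}, \code{end}, \code{sample}, \code{copy_number} (2--5) and
#'   optionally \code{alt_dose} (copies carrying the alternate allele;
#'   default \code{copy_number - 1}, putting the dominant balance at
#'   (n-1)/n). Intervals must tile each chromosome per sample; the default
#'   track is diploid everywhere.
#' @param density Heterozygous sites per kbp (> 0).
#' @param mean_depth Mean total read depth per genotype.
#' @param dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param noise Fraction of genotypes whose balance is uniform on (0, 1).
#' @param hom_fraction Fraction of genotypes emitted as homozygous
#'   reference (exercises heterozygote masking); default 0.
#' @param seed Random seed; the same seed gives byte-identical output.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 1e6),
                       samples = "S1",
                       ploidy_track = NULL,
                       density = 5,
                       mean_depth = 100,
                       dispersion = 10,
                       noise = 0.05,
                       hom_fraction = 0,
                       seed = 1L) {
  stopifnot(length(chrom_lengths) >= 1L, all(chrom_lengths >= 1),
            !is.null(names(chrom_lengths)),
            density > 0, mean_depth > 0, dispersion > 0,
            noise >= 0, noise <= 1, hom_fraction >= 0, hom_fraction < 1)
  if (is.null(ploidy_track)) {
    ploidy_track <- expand.grid(chrom = names(chrom_lengths),
                                sample = samples,
                                stringsAsFactors = FALSE)
    ploidy_track$start <- 1
    ploidy_track$end <- chrom_lengths[ploidy_track$chrom]
    ploidy_track$copy_number <- 2L
  }
  if (is.null(ploidy_track$alt_dose)) {
    ploidy_track$alt_dose <- ploidy_track$copy_number - 1L
  }
  stopifnot(all(ploidy_track$copy_number >= 2L),
            all(ploidy_track$copy_number <= 5L),
            all(ploidy_track$alt_dose >= 1L),
            all(ploidy_track$alt_dose < ploidy_track$copy_number))
  structure(list(chrom_lengths = chrom_lengths, samples = samples,
                 ploidy_track = ploidy_track, density = density,
                 mean_depth = mean_depth, dispersion = dispersion,
                 noise = noise, hom_fraction = hom_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# copy number / alt dose at (chrom, pos) for one sample, from the track
.track_lookup <- function(track, chrom, pos, sample) {
  tr <- track[track$sample == sample & track$chrom == chrom, , drop = FALSE]
  i <- which(tr$start <= pos & pos <= tr$end)[1L]
  if (is.na(i)) {
    stop("ploidy track does not cover ", chrom, ":", pos,
         " for sample ", sample)
  }
  c(tr$copy_number[i], tr$alt_dose[i])
}

#' Simulate a VCF with known copy-number structure
#'
#' Site positions are drawn uniformly at the configured density along each
#' chromosome. At each site and sample, the total depth is negative
#' binomial around \code{mean_depth}; the alternate-allele depth is
#' binomial at the true dosage ratio \code{alt_dose / copy_number} from the
#' ploidy track, except for a \code{noise} fraction of genotypes whose
#' underlying balance is drawn uniform on (0, 1). Genotypes are written as
#' diploid-style heterozygotes ("0/1", as a diploid-model caller reports
#' them) with AD = "ref_depth,alt_depth".
#'
#' @param config A \code{"sim_config"} object.
#' @param path Output VCF path.
#' @return Invisibly, a list with \code{path}, \code{truth} (long
#'   data.frame: chrom, pos, sample, copy_number, ratio, noise — ratio is
#'   \code{NA} for homozygous-emitted genotypes) and \code{track}.
#' @export
simulate_vcf <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  all_chrom <- character()
  all_pos <- integer()
  for (cc in names(config$chrom_lengths)) {
    L <- config$chrom_lengths[[cc]]
    nsite <- max(1L, round(L / 1000 * config$density))
    pos <- sort(sample.int(L, min(nsite, L)))
    all_chrom <- c(all_chrom, rep(cc, length(pos)))
    all_pos <- c(all_pos, pos)
  }
  nvar <- length(all_pos)
  nsamp <- length(config$samples)

  gt <- matrix(NA_character_, nvar, nsamp,
               dimnames = list(NULL, config$samples))
  ad <- gt
  truth <- vector("list", nsamp)
  for (j in seq_len(nsamp)) {
    s <- config$samples[j]
    cn_dose <- vapply(seq_len(nvar), function(i) {
      .track_lookup(config$ploidy_track, all_chrom[i], all_pos[i], s)
    }, numeric(2L))
    cn <- cn_dose[1L, ]
    ratio <- cn_dose[2L, ] / cn
    is_noise <- runif(nvar) < config$noise
    ratio_eff <- ifelse(is_noise, runif(nvar), ratio)
    total <- rnbinom(nvar, size = config$dispersion, mu = config$mean_depth)
    is_hom <- config$hom_fraction > 0 & runif(nvar) < config$hom_fraction
    d_alt <- rbinom(nvar, size = total, prob = ratio_eff)
    d_alt[is_hom] <- 0L
    gt[, j] <- ifelse(is_hom, "0/0", "0/1")
    ad[, j] <- paste0(total - d_alt, ",", d_alt)
    truth[[j]] <- data.frame(chrom = all_chrom, pos = all_pos, sample = s,
                             copy_number = as.integer(cn),
                             ratio = ifelse(is_hom, NA_real_, ratio_eff),
                             noise = is_noise & !is_hom,
                             stringsAsFactors = FALSE)
  }

  variants <- data.frame(chrom = all_chrom, pos = all_pos,
                         id = ".", ref = "A", alt = "T", qual = ".",
                         filter = "PASS", info = ".",
                         stringsAsFactors = FALSE)
  write_vcf(variants, list(GT = gt, AD = ad), path,
            contig_lengths = config$chrom_lengths)
  invisible(list(path = path,
                 truth = do.call(rbind, c(truth, make.row.names = FALSE)),
                 track = config$ploidy_track))
}

#' Simulate genotypes for populations of mixed ploidy
#'
#' At each variant, each sample's alleles are drawn independently from its
#' population's allele-frequency vector, at the sample's own ploidy, and
#' written as a sorted unphased GT string (e.g. "0/1/1" for a triploid).
#' This is the test bed for allele-count-weighted differentiation: a
#' tetraploid sample contributes 4 alleles where a diploid contributes 2.
#'
#' @param freqs Named list, one numeric allele-frequency vector per
#'   population (each summing to 1; positions index alleles 0, 1, ...).
#' @param n_samples Samples per population (scalar or per-population).
#' @param ploidy Alleles per genotype (scalar, per-population, or a list of
#'   per-sample vectors per population).
#' @param n_variants Number of variants to draw.
#' @param seed Random seed.
#' @return List with \code{gt} (variants x samples character matrix),
#'   \code{pops} (named assignment vector) and \code{freqs}.
#' @export
simulate_populations <- function(freqs, n_samples, ploidy = 2L,
                                 n_variants = 1L, seed = 1L) {
  stopifnot(is.list(freqs), !is.null(names(freqs)))
  for (f in freqs) {
    if (abs(sum(f) - 1) > 1e-8) stop("allele frequencies must sum to 1")
  }
  npop <- length(freqs)
  n_samples <- rep_len(n_samples, npop)
  if (!is.list(ploidy)) {
    ploidy <- lapply(seq_len(npop), function(k) {
      rep_len(rep_len(ploidy, npop)[k], n_samples[k])
    })
  }
  set.seed(as.integer(seed))
  samp_names <- unlist(lapply(seq_len(npop), function(k) {
    paste0(names(freqs)[k], "_", seq_len(n_samples[k]))
  }))
  pops <- setNames(rep(names(freqs), n_samples), samp_names)
  gt <- matrix(NA_character_, n_variants, length(samp_names),
               dimnames = list(NULL, samp_names))
  col <- 0L
  for (k in seq_len(npop)) {
    f <- freqs[[k]]
    alleles <- as.character(seq_along(f) - 1L)
    for (s in seq_len(n_samples[k])) {
      col <- col + 1L
      pl <- ploidy[[k]][s]
      gt[, col] <- vapply(seq_len(n_variants), function(i) {
        a <- sample(alleles, pl, replace = TRUE, prob = f)
        paste(sort(a), collapse = "/")
      }, character(1L))
    }
  }
  list(gt = gt, pops = pops, freqs = freqs)
}
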