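# VCF text I/O and the genotype-string matrix layer.
#
# The copy-number method consumes the raw per-sample FORMAT strings (GT
# "0/1", AD "12,7") as variants x samples character matrices, so the reader
# keeps cells verbatim and leaves all interpretation to is_het() /
# field_element() downstream. Coordinates are 1-based per the VCF spec.

#' Read genotype-field matrices from a VCF file
#'
#' Parses a VCF v4.x file (plain text or gzip/bgzip compressed) and returns
#' the variant table together with one variants x samples character matrix
#' per requested FORMAT key. Cells hold the raw per-sample strings; a key
#' absent from a record's FORMAT, a sample cell of \code{"."}, or a trailing
#' field dropped from a cell all yield \code{NA}. Zero data rows (header-only
#' VCF) give a zero-row table and zero-row matrices.
#'
#' @param path Path to a VCF file (\code{.vcf} or \code{.vcf.gz}).
#' @param samples Optional character vector restricting to a subset of the
#'   samples named in the VCF header; an unknown name is an error.
#' @param format_keys FORMAT keys to extract, default \code{c("GT", "AD")}.
#' @return A list with elements \code{variants} (data.frame with columns
#'   \code{chrom}, \code{pos}, \code{id}, \code{ref}, \code{alt},
#'   \code{qual}, \code{filter}, \code{info}), \code{samples}, and
#'   \code{geno}, a named list with one character matrix per requested key
#'   (rows = variants, columns = samples).
#' @examples
#' vcf <- system.file("extdata", "mini_synthetic.vcf", package = "abploidy")
#' v <- read_vcf(vcf)
#' dim(v$geno$AD)
#' @export
read_vcf <- function(path, samples = NULL, format_keys = c("GT", "AD")) {
  if (!file.exists(path)) {
    stop("cannot read VCF file: ", path)
  }
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)

  hdr_idx <- which(startsWith(lines, "#CHROM"))
  if (length(hdr_idx) == 0L) {
    stop("not a VCF: no #CHROM header line in ", path)
  }
  hdr_idx <- hdr_idx[1L]
  cols <- strsplit(sub("^#", "", lines[hdr_idx]), "\t", fixed = TRUE)[[1L]]
  if (length(cols) < 9L || cols[9L] != "FORMAT") {
    stop("VCF has no FORMAT column; per-sample fields are required")
  }
  all_samples <- cols[-(1:9)]
  if (is.null(samples)) {
    samples <- all_samples
  } else {
    unknown <- setdiff(samples, all_samples)
    if (length(unknown)) {
      stop("sample(s) not present in VCF header: ",
           paste(unknown, collapse = ", "))
    }
  }

  body_ln <- if (hdr_idx < length(lines)) seq.int(hdr_idx + 1L, length(lines)) else integer()
  body_ln <- body_ln[nzchar(lines[body_ln])]
  n <- length(body_ln)
  nk <- length(format_keys)

  if (n == 0L) {
    variants <- data.frame(chrom = character(), pos = integer(),
                           id = character(), ref = character(),
                           alt = character(), qual = character(),
                           filter = character(), info = character(),
                           stringsAsFactors = FALSE)
    geno <- lapply(setNames(format_keys, format_keys), function(k) {
      matrix(NA_character_, 0L, length(samples),
             dimnames = list(NULL, samples))
    })
    return(list(variants = variants, samples = samples, geno = geno))
  }

  parts <- strsplit(lines[body_ln], "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != length(cols))
  if (length(bad)) {
    stop("malformed VCF line ", body_ln[bad[1L]], ": expected ",
         length(cols), " fields, found ", nf[bad[1L]])
  }
  M <- matrix(unlist(parts, use.names = FALSE), nrow = n, byrow = TRUE)

  pos <- suppressWarnings(as.integer(M[, 2L]))
  if (anyNA(pos)) {
    stop("malformed VCF line ", body_ln[which(is.na(pos))[1L]],
         ": POS is not an integer")
  }
  variants <- data.frame(chrom = M[, 1L], pos = pos, id = M[, 3L],
                         ref = M[, 4L], alt = M[, 5L], qual = M[, 6L],
                         filter = M[, 7L], info = M[, 8L],
                         stringsAsFactors = FALSE)

  fmt <- strsplit(M[, 9L], ":", fixed = TRUE)
  si <- match(samples, cols)
  # split each selected sample column once, then pick out each key
  cells <- lapply(si, function(j) strsplit(M[, j], ":", fixed = TRUE))
  geno <- lapply(setNames(format_keys, format_keys), function(key) {
    ki <- vapply(fmt, function(f) match(key, f), integer(1L))
    out <- matrix(NA_character_, n, length(samples),
                  dimnames = list(NULL, samples))
    for (j in seq_along(samples)) {
      cj <- cells[[j]]
      out[, j] <- vapply(seq_len(n), function(i) {
        k <- ki[i]
        if (is.na(k) || k > length(cj[[i]])) return(NA_character_)
        v <- cj[[i]][k]
        if (identical(v, ".")) NA_character_ else v
      }, character(1L))
    }
    out
  })

  list(variants = variants, samples = samples, geno = geno)
}

#' Write a variant table and genotype matrices back to VCF
#'
#' Inverse of [read_vcf()]: emits a minimal VCF v4.2 with the given FORMAT
#' matrices, so that re-reading reproduces the matrices exactly. \code{NA}
#' cells become \code{"."}. Positions are written 1-based as stored.
#'
#' @param variants Data frame with at least \code{chrom} and \code{pos};
#'   \code{id}, \code{ref}, \code{alt}, \code{qual}, \code{filter},
#'   \code{info} default to \code{"."} (\code{ref}/\code{alt}: "A"/"T").
#' @param geno Named list of variants x samples character matrices; names
#'   are the FORMAT keys, in output order.
#' @param path Output file path.
#' @param contig_lengths Optional named vector of chromosome lengths for
#'   \code{##contig} header lines.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(variants, geno, path, contig_lengths = NULL) {
  stopifnot(is.list(geno), length(geno) >= 1L, !is.null(names(geno)))
  n <- nrow(variants)
  samples <- colnames(geno[[1L]])
  for (g in geno) {
    if (!all(dim(g) == c(n, length(samples)))) {
      stop("genotype matrix dimensions do not match the variant table")
    }
  }
  col_or <- function(name, default) {
    if (name %in% names(variants)) as.character(variants[[name]]) else
      rep(default, n)
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=abploidy")
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths),
                          as.integer(contig_lengths)))
  }
  fmt_defs <- c(
    GT = "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    AD = paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
                "\"Allelic depths for the ref and alt alleles\">"))
  hdr <- c(hdr, unname(fmt_defs[intersect(names(geno), names(fmt_defs))]))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", samples),
                      collapse = "\t"))

  fmt_str <- paste(names(geno), collapse = ":")
  cell <- matrix("", n, length(samples))
  for (j in seq_along(samples)) {
    parts <- do.call(cbind, lapply(geno, function(g) {
      x <- g[, j]
      x[is.na(x)] <- "."
      x
    }))
    cell[, j] <- apply(parts, 1L, paste, collapse = ":")
  }
  # a fully missing cell collapses to "." on re-read anyway; keep explicit
  body <- paste(variants$chrom, variants$pos, col_or("id", "."),
                col_or("ref", "A"), col_or("alt", "T"),
                col_or("qual", "."), col_or("filter", "."),
                col_or("info", "."), fmt_str,
                apply(cell, 1L, paste, collapse = "\t"),
                sep = "\t")
  if (n == 0L) body <- character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Classify genotype strings as heterozygous
#'
#' A genotype is heterozygous when at least two distinct non-missing allele
#' indices appear, regardless of phasing ("/" and "|" are equivalent) or
#' ploidy ("0/1/1" is heterozygous). All-missing genotypes (e.g. "./.") are
#' \code{NA}. Half-missing genotypes such as "./1" expose a single allele
#' class and are classified \code{FALSE}.
#'
#' @param gt Character vector or matrix of GT strings (\code{NA} allowed).
#' @return Logical of the same shape: \code{TRUE}/\code{FALSE}/\code{NA}.
#' @examples
#' is_het(c("0/1", "1|1|1", "./.", "./1"))
#' @export
is_het <- function(gt) {
  x <- as.character(gt)
  res <- rep(NA, length(x))
  ok <- !is.na(x)
  if (any(ok)) {
    al <- strsplit(x[ok], "[/|]")
    res[ok] <- vapply(al, function(a) {
      a <- a[nzchar(a) & a != "."]
      if (length(a) == 0L) return(NA)
      length(unique(a)) >= 2L
    }, logical(1L))
  }
  if (!is.null(dim(gt))) {
    dim(res) <- dim(gt)
    dimnames(res) <- dimnames(gt)
  }
  res
}

#' Extract one numeric element from delimited-string cells
#'
#' Matrices extracted from VCF FORMAT fields often hold several values per
#' cell (e.g. AD \code{"12,7,0"}). This isolates one element per cell as a
#' number, optionally after sorting the elements in decreasing order so that
#' \code{record = 1} is the largest.
#'
#' @param x Character vector or matrix of delimited cells (\code{NA} allowed).
#' @param record Which element to keep (1-based ordinal).
#' @param delim Single-character delimiter, default \code{","}.
#' @param sort_desc Sort each cell's elements in decreasing numeric order
#'   before taking \code{record}? Default \code{TRUE}.
#' @return Numeric of the same shape. A missing cell, or a cell with fewer
#'   than \code{record} elements, yields \code{NA} (the short-cell count is
#'   reported via \code{message()}).
#' @examples
#' field_element(c("7,4", "4,7,2"), record = 2)    # 4 4
#' field_element("4,7,2", record = 2, sort_desc = FALSE)  # 7
#' @export
field_element <- function(x, record = 1L, delim = ",", sort_desc = TRUE) {
  stopifnot(length(record) == 1L, record >= 1L)
  s <- as.character(x)
  res <- rep(NA_real_, length(s))
  ok <- !is.na(s)
  short <- 0L
  if (any(ok)) {
    sp <- strsplit(s[ok], delim, fixed = TRUE)
    res[ok] <- vapply(sp, function(v) {
      v <- suppressWarnings(as.numeric(v))
      if (sort_desc) v <- sort(v, decreasing = TRUE, na.last = TRUE)
      if (record > length(v)) return(NA_real_)
      v[record]
    }, numeric(1L))
    short <- sum(vapply(sp, length, integer(1L)) < record)
  }
  if (short > 0L) {
    message("field_element: ", short, " cell(s) had fewer than ", record,
            " element(s); returned NA")
  }
  if (!is.null(dim(x))) {
    dim(res) <- dim(x)
    dimnames(res) <- dimnames(x)
  }
  res
}

#' Export a per-variant matrix as TSV with coordinates
#'
#' Writes CHROM and POS (1-based, inclusive) as leading columns followed by
#' one column per sample.
#'
#' @param x Variants x samples matrix.
#' @param chrom,pos Per-variant coordinates, recycled if scalar.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_variant_tsv <- function(x, chrom, pos, path) {
  df <- data.frame(CHROM = rep_len(chrom, nrow(x)), POS = pos, x,
                   check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("# coordinates are 1-based, inclusive", con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}
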