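# Mapping window peaks to integer copy number via expected dosage ratios.
#
# A heterozygous site in a genome with n copies, carrying one allele at
# dose d and the other at n - d, is sequenced at balances d/n and
# (n - d)/n. The supported expectations are therefore
# 1/5, 1/4, 1/3, 1/2, 2/3, 3/4, 4/5 for copy numbers 5, 4, 3, 2, 3, 4, 5.
# Critical values halfway between adjacent expectations partition the peak
# axis into assignment intervals; the outer bounds extend one half-gap
# (1/40) beyond 1/5 and 4/5, past which a peak is closer to homozygosity
# than to any supported ratio and no call is made.

.EXP <- c(1/5, 1/4, 1/3, 1/2, 2/3, 3/4, 4/5)
.CN <- c(5L, 4L, 3L, 2L, 3L, 4L, 5L)
.CRIT <- c(0.175, 9/40, 7/24, 5/12, 7/12, 17/24, 31/40, 0.825)

#' Expected allele-balance ratios and their critical values
#'
#' @return A list with \code{expectation} (the supported dosage ratios),
#'   \code{copy_number} (their copy numbers), and \code{critical} (the
#'   interval bounds: outer limits plus the midpoints between adjacent
#'   expectations).
#' @export
balance_expectations <- function() {
  list(expectation = .EXP, copy_number = .CN, critical = .CRIT)
}

#' Convert allele-balance peaks to copy-number calls
#'
#' Each peak within [0.175, 0.825] is assigned its nearest expected ratio
#' (equivalently, the expectation whose critical-value interval contains
#' it; a peak exactly on a critical value goes to the expectation nearer
#' 1/2, keeping calls symmetric under p <-> 1-p). Confidence is expressed
#' as the distance from expectation (dfe): the absolute difference between
#' peak and assigned expectation, divided by the distance from that
#' expectation to the critical value on the side where the peak lies. dfe
#' is 0 exactly on an expectation and 1 halfway between two expectations.
#' Peaks outside [0.175, 0.825], or missing, give a missing call.
#'
#' @param peak Numeric vector or matrix of peaks, each in (0, 1) or
#'   \code{NA}. A peak of exactly 0 or 1 is an error: such values indicate
#'   homozygous artifacts that must be excluded upstream.
#' @return An object of class \code{"copy_calls"}: list of
#'   \code{peak}, \code{expectation}, \code{copy_number}, \code{dfe},
#'   each shaped like the input.
#' @examples
#' cc <- assign_copy_number(c(0.5, 0.66, 0.58))
#' cc$copy_number  # 2 3 2
#' round(cc$dfe, 2)  # 0.00 0.08 0.96
#' @export
assign_copy_number <- function(peak) {
  p <- as.numeric(peak)
  if (any(!is.na(p) & (p <= 0 | p >= 1))) {
    stop("peak outside (0, 1): balances of 0 or 1 are homozygous ",
         "artifacts and must be excluded upstream")
  }
  expectation <- rep(NA_real_, length(p))
  cn <- rep(NA_integer_, length(p))
  dfe <- rep(NA_real_, length(p))
  valid <- !is.na(p) & p >= .CRIT[1L] & p <= .CRIT[8L]
  if (any(valid)) {
    pv <- p[valid]
    # nearest expectation; distance ties broken toward 1/2
    j <- vapply(pv, function(x) {
      d <- abs(x - .EXP)
      cand <- which(d - min(d) < 1e-12)
      if (length(cand) > 1L) cand <- cand[which.min(abs(.EXP[cand] - 0.5))]
      cand
    }, integer(1L))
    e <- .EXP[j]
    side <- ifelse(pv >= e, .CRIT[j + 1L], .CRIT[j])
    expectation[valid] <- e
    cn[valid] <- .CN[j]
    dfe[valid] <- abs(pv - e) / abs(side - e)
  }
  shape <- function(v) {
    if (!is.null(dim(peak))) {
      dim(v) <- dim(peak)
      dimnames(v) <- dimnames(peak)
    }
    v
  }
  structure(list(peak = shape(p), expectation = shape(expectation),
                 copy_number = shape(cn), dfe = shape(dfe)),
            class = "copy_calls")
}

#' Remove low-confidence (border-case) copy-number calls
#'
#' Calls whose distance from expectation exceeds \code{max_dfe} are set
#' missing; a peak intermediate between two expectations (dfe near 1) is a
#' border case in which the determination has low confidence.
#'
#' @param calls A \code{"copy_calls"} object from [assign_copy_number()].
#' @param max_dfe Threshold in [0, 1]; 1 is the identity.
#' @return A filtered \code{"copy_calls"} object; the number of removed
#'   calls is reported via \code{message()}.
#' @export
filter_copy_calls <- function(calls, max_dfe) {
  stopifnot(inherits(calls, "copy_calls"),
            max_dfe >= 0, max_dfe <= 1)
  drop <- !is.na(calls$dfe) & calls$dfe > max_dfe
  for (f in c("expectation", "copy_number", "dfe")) {
    calls[[f]][drop] <- NA
  }
  message("filter_copy_calls: ", sum(drop), " call(s) removed at max_dfe = ",
          max_dfe)
  calls
}

#' @export
print.copy_calls <- function(x, ...) {
  n <- length(x$peak)
  cat("copy_calls: ", n, " peak(s), ", sum(!is.na(x$copy_number)),
      " assigned\n", sep = "")
  if (sum(!is.na(x$copy_number))) {
    print(table(copy_number = x$copy_number))
  }
  invisible(x)
}
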