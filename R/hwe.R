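# Hardy-Weinberg equilibrium screening of control genotypes.

#' Hardy-Weinberg equilibrium test on control genotype counts
#'
#' Pearson chi-square goodness-of-fit test (1 df, no continuity
#' correction) of observed genotype counts against the Hardy-Weinberg
#' expectations `n*p^2, 2*n*p*q, n*q^2`, with the allele frequency
#' estimated from the same counts.  In genetic association meta-analysis
#' the test is applied to the control arm: departure from equilibrium in
#' population-based controls flags genotyping error or sampling problems,
#' and studies failing the screen (P <= 0.05) are set aside in
#' equilibrium-restricted ("Y") subgroup analyses.
#'
#' Monomorphic samples fit the equilibrium expectation trivially and
#' return `chi_square = 0`, `p_value = 1`.
#'
#' @param x either a genotype-resolution row of a [study_table] (the
#'   control counts are tested) or the XX count, with `xy` and `yy`
#'   supplied as well.
#' @param xy,yy heterozygote and variant-homozygote counts when `x` is
#'   the reference-homozygote count.
#' @return an `hwe_result`: list with `study_id`, `chi_square`, `df`,
#'   `p_value` and `in_hwe` (`p_value > 0.05`).
#' @examples
#' hwe_test(25, 50, 25)  # exact equilibrium: chi-square 0, P 1
#' @export
hwe_test <- function(x, xy = NULL, yy = NULL) {
  if (is.data.frame(x)) {
    r <- as.list(x[1, ])
    if (r$resolution != "genotype")
      stop("HWE is not testable for resolution '", r$resolution,
           "' (genotype counts required)", call. = FALSE)
    counts <- c(r$control_xx, r$control_xy, r$control_yy)
    id <- r$study_id
  } else {
    counts <- c(x, xy, yy)
    id <- NA_character_
  }
  if (length(counts) != 3 || anyNA(counts) || any(counts < 0))
    stop("three non-negative genotype counts required", call. = FALSE)
  n <- sum(counts)
  if (n == 0) stop("degenerate input: no subjects", call. = FALSE)
  q <- (2 * counts[3] + counts[2]) / (2 * n)
  p <- 1 - q
  if (q == 0 || q == 1) {
    chi2 <- 0
  } else {
    expected <- n * c(p^2, 2 * p * q, q^2)
    chi2 <- sum((counts - expected)^2 / expected)
  }
  pval <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  structure(list(study_id = id, chi_square = chi2, df = 1L,
                 p_value = pval, in_hwe = pval > 0.05),
            class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE chi-square = %.4f (1 df), P = %.4g -> %s\n",
              x$chi_square, x$p_value,
              if (x$in_hwe) "consistent with equilibrium (P > 0.05)"
              else "departure (P <= 0.05)"))
  invisible(x)
}

#' Hardy-Weinberg screen over a study table
#'
#' Applies [hwe_test()] to the control arm of every genotype-resolution
#' record; other resolutions are reported as untestable.
#'
#' @param table a [study_table].
#' @return data frame with one row per record: `study_id`, `snp`,
#'   `testable`, `chi_square`, `p_value`, `in_hwe`, `hwe_p_reported`.
#' @export
hwe_screen <- function(table) {
  stopifnot(inherits(table, "study_table"))
  out <- data.frame(study_id = table$study_id, snp = table$snp,
                    testable = table$resolution == "genotype",
                    chi_square = NA_real_, p_value = NA_real_,
                    in_hwe = NA, hwe_p_reported = table$hwe_p_reported,
                    stringsAsFactors = FALSE)
  for (i in which(out$testable)) {
    h <- hwe_test(as.data.frame(table)[i, , drop = FALSE])
    out$chi_square[i] <- h$chi_square
    out$p_value[i] <- h$p_value
    out$in_hwe[i] <- h$in_hwe
  }
  out
}

# Equilibrium status used for "Y" subgrouping: recomputed control HWE P
# where genotypes are available, otherwise the reported value or bound.
# Returns TRUE / FALSE / NA per record.
.hwe_keep <- function(table) {
  scr <- hwe_screen(table)
  keep <- scr$in_hwe
  rep_ <- scr$hwe_p_reported
  fallback <- !scr$testable
  keep[fallback & !is.na(rep_) & rep_ == ">0.05"] <- TRUE
  keep[fallback & !is.na(rep_) & rep_ == "<0.05"] <- FALSE
  num <- suppressWarnings(as.numeric(rep_))
  keep[fallback & !is.na(num)] <- num[fallback & !is.na(num)] > 0.05
  keep
}
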