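# Data model and validated I/O for study tables.
#
# A study table holds one row per (study, SNP) with case/control genotype
# counts in reference-homozygote / heterozygote / variant-homozygote order
# (XX, XY, YY).  Three resolutions are supported: full "genotype" triples,
# "allele_only" pairs of allele tallies (X count in the xx column, Y count
# in the yy column, xy empty), and "dominant_collapsed" pairs (XX count in
# xx, combined XY+YY count in xy, yy empty).

.study_cols <- c("study_id", "snp", "resolution",
                 "control_xx", "control_xy", "control_yy",
                 "case_xx", "case_xy", "case_yy",
                 "ethnicity", "country", "control_source")
.count_cols <- c("control_xx", "control_xy", "control_yy",
                 "case_xx", "case_xy", "case_yy")
.resolutions <- c("genotype", "allele_only", "dominant_collapsed")
.control_sources <- c("population_based", "hospital_based")

#' Construct a validated study table
#'
#' @param x data frame with the columns `study_id`, `snp`, `resolution`,
#'   `control_xx`, `control_xy`, `control_yy`, `case_xx`, `case_xy`,
#'   `case_yy`, `ethnicity`, `country`, `control_source` and (optionally)
#'   `hwe_p_reported`.  Count columns not used by a row's resolution must
#'   be `NA`.
#' @param provenance free-text note on where the rows came from.
#' @return an object of class `study_table` (a data frame).
#' @examples
#' tab <- study_table(data.frame(
#'   study_id = "S1", snp = "rs1", resolution = "genotype",
#'   control_xx = 25, control_xy = 50, control_yy = 25,
#'   case_xx = 20, case_xy = 50, case_yy = 30,
#'   ethnicity = "Asian", country = "Korea",
#'   control_source = "population_based"))
#' @export
study_table <- function(x, provenance = "") {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!"hwe_p_reported" %in% names(x)) x$hwe_p_reported <- NA_character_
  missing <- setdiff(.study_cols, names(x))
  if (length(missing) > 0)
    stop("study table schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  x <- x[c(.study_cols, "hwe_p_reported")]
  for (col in setdiff(names(x), .count_cols))
    x[[col]] <- as.character(x[[col]])
  for (col in .count_cols)
    x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
  problems <- .validate_rows(x)
  if (nrow(x) == 0) stop("study table contains no records", call. = FALSE)
  if (length(problems) > 0)
    stop("invalid study table:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  dup <- duplicated(x[c("study_id", "snp")])
  if (any(dup))
    stop("duplicate (study_id, snp) pair(s): ",
         paste(unique(paste(x$study_id[dup], x$snp[dup])), collapse = ", "),
         call. = FALSE)
  rownames(x) <- NULL
  structure(x, provenance = provenance,
            class = c("study_table", "data.frame"))
}

.validate_rows <- function(x) {
  problems <- character(0)
  bad <- function(i, msg) sprintf("row %d (%s, %s): %s",
                                  i, x$study_id[i], x$snp[i], msg)
  need <- list(genotype = .count_cols,
               allele_only = c("control_xx", "control_yy",
                               "case_xx", "case_yy"),
               dominant_collapsed = c("control_xx", "control_xy",
                                      "case_xx", "case_xy"))
  for (i in seq_len(nrow(x))) {
    res <- x$resolution[i]
    if (!res %in% .resolutions) {
      problems <- c(problems, bad(i, paste0("unknown resolution '", res, "'")))
      next
    }
    req <- need[[res]]
    cnt <- unlist(x[i, req])
    if (anyNA(cnt)) {
      problems <- c(problems, bad(i, "missing count(s)"))
    } else if (any(cnt < 0) || any(cnt != round(cnt))) {
      problems <- c(problems, bad(i, "counts must be non-negative integers"))
    } else if (all(cnt[grepl("^case", req)] == 0) ||
               all(cnt[grepl("^control", req)] == 0)) {
      problems <- c(problems, bad(i, "an arm has no subjects"))
    }
    unused <- unlist(x[i, setdiff(.count_cols, req)])
    if (length(unused) > 0 && !all(is.na(unused)))
      problems <- c(problems, bad(i, paste0(
        "count columns not used by resolution '", res, "' must be empty")))
    if (is.na(x$ethnicity[i]) || !nzchar(x$ethnicity[i]))
      problems <- c(problems, bad(i, "empty ethnicity"))
    if (is.na(x$country[i]) || !nzchar(x$country[i]))
      problems <- c(problems, bad(i, "empty country"))
    if (!x$control_source[i] %in% .control_sources)
      problems <- c(problems, bad(i, "unknown control_source"))
    hwe <- x$hwe_p_reported[i]
    if (!is.na(hwe) && !hwe %in% c("<0.05", ">0.05")) {
      hnum <- suppressWarnings(as.numeric(hwe))
      if (is.na(hnum) || hnum <= 0 || hnum > 1)
        problems <- c(problems, bad(i, paste0(
          "hwe_p_reported must be a probability or a '<0.05'/'>0.05' bound, got '",
          hwe, "'")))
    }
  }
  problems
}

#' Read a study table from TSV or CSV
#'
#' @param path file path.
#' @param format `"tsv"` or `"csv"`; the default guesses from the file
#'   extension (anything not ending in `.csv` is read as tab-separated).
#' @return a validated [study_table].
#' @export
read_study_table <- function(path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  sep <- if (format == "csv") "," else "\t"
  x <- tryCatch(
    utils::read.table(path, sep = sep, header = TRUE,
                      colClasses = "character", na.strings = c("NA", ""),
                      check.names = TRUE, quote = "", comment.char = ""),
    error = function(e) stop("study table contains no records (",
                             conditionMessage(e), ")", call. = FALSE))
  if (nrow(x) == 0) stop("study table contains no records", call. = FALSE)
  study_table(x, provenance = path)
}

#' Write a study table to TSV or CSV
#'
#' Writes the documented schema; [read_study_table()] round-trips the
#' counts and metadata exactly.
#'
#' @param x a [study_table].
#' @param path output file path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(x, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "study_table"))
  out <- as.data.frame(x)
  for (col in .count_cols) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.na(v), "", format(v, scientific = FALSE, trim = TRUE))
  }
  utils::write.table(out, path, sep = if (format == "csv") "," else "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' IL-10 promoter polymorphism studies in atopic dermatitis
#'
#' The bundled worked data set: 16 published case-control studies of the
#' IL-10 promoter SNPs -1082 A/G, -819 T/C and -592 A/C in clinical atopic
#' dermatitis (33 study-by-SNP records; 15 for -1082, 9 each for -819 and
#' -592).  Counts are stored with the first-named allele of the SNP label
#' as the reference X and the second as the variant Y, so for -1082 A/G
#' the XX column is the AA genotype and YY is GG.  One study (Chang 2006)
#' reports allele tallies only; one (Babic 2016) reports the AG+GG
#' genotypes combined.  Lesiak 2011 and Zakrzewski 2010 print identical
#' counts; both are retained (they enter the "Poland" subgroup as separate
#' studies) and flagged as suspected duplicates here.
#'
#' @return a [study_table] with 33 records.
#' @examples
#' tab <- il10_ad_studies()
#' table(tab$snp)
#' @export
il10_ad_studies <- function() {
  path <- system.file("extdata", "il10_ad_studies.tsv", package = "snpmeta",
                      mustWork = TRUE)
  out <- read_study_table(path, "tsv")
  attr(out, "provenance") <-
    paste("Published genotype counts of 16 IL-10 promoter SNP case-control",
          "studies in atopic dermatitis (suspected duplicate counts:",
          "Lesiak2011 / Zakrzewski2010)")
  out
}

#' @export
print.study_table <- function(x, ...) {
  cat(sprintf("Study table: %d record(s), %d stud(ies), SNP(s): %s\n",
              nrow(x), length(unique(x$study_id)),
              paste(unique(x$snp), collapse = ", ")))
  prov <- attr(x, "provenance")
  if (!is.null(prov) && nzchar(prov)) cat("Provenance:", prov, "\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

# subjects per arm of one record: c(cases, controls)
.record_subjects <- function(r) {
  switch(r$resolution,
    genotype = c(r$case_xx + r$case_xy + r$case_yy,
                 r$control_xx + r$control_xy + r$control_yy),
    allele_only = c((r$case_xx + r$case_yy) / 2,
                    (r$control_xx + r$control_yy) / 2),
    dominant_collapsed = c(r$case_xx + r$case_xy,
                           r$control_xx + r$control_xy))
}
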