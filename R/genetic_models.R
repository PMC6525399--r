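# Derivation of per-study 2x2 tables under the six genetic models.

#' Derive the 2x2 table of one study under a genetic model
#'
#' Builds the case/control exposed/unexposed table for one study record.
#' For genotype-resolution records (XX, XY, YY counts per arm):
#' allele uses `2*YY + XY` Y alleles vs `2*XX + XY` X alleles; homozygote
#' contrasts YY vs XX (heterozygotes dropped); heterozygote XY vs XX;
#' dominant XY+YY vs XX; recessive YY vs XX+XY; carrier tallies carriers
#' of Y (XY+YY) against carriers of X (XX+XY), counting heterozygotes on
#' both sides.  Allele-only records support only the allele model and
#' dominant-collapsed records only the dominant model.
#'
#' A study is *ineligible* for a model when a required class is empty in
#' both arms (an all-zero column, e.g. no YY subjects anywhere) or when
#' its resolution cannot supply the contrast; an ineligibility marker
#' carrying the reason is returned instead of a table.
#'
#' @param record one row of a [study_table].
#' @param model one of [genetic_models].
#' @return a `table2x2` (list with `study_id`, `model`, `case_exposed`,
#'   `case_unexposed`, `control_exposed`, `control_unexposed`, `unit`) or
#'   an object of class `ineligible` with a `reason` field.
#' @seealso [model_tables()] to derive all eligible tables of an analysis.
#' @export
derive_table <- function(record, model) {
  if (!model %in% genetic_models)
    stop("unknown genetic model '", model, "'", call. = FALSE)
  r <- as.list(as.data.frame(record)[1, ])
  inel <- function(reason)
    structure(list(study_id = r$study_id, model = model, reason = reason),
              class = "ineligible")
  if (r$resolution == "allele_only" && model != "allele")
    return(inel("allele-only record supports only the allele model"))
  if (r$resolution == "dominant_collapsed" && model != "dominant")
    return(inel("dominant-collapsed record supports only the dominant model"))
  cells <- switch(r$resolution,
    allele_only = list(a = r$case_yy, b = r$case_xx,
                       c = r$control_yy, d = r$control_xx, unit = "alleles"),
    dominant_collapsed = list(a = r$case_xy, b = r$case_xx,
                              c = r$control_xy, d = r$control_xx,
                              unit = "subjects"),
    genotype = {
      cs <- c(r$case_xx, r$case_xy, r$case_yy)
      ct <- c(r$control_xx, r$control_xy, r$control_yy)
      switch(model,
        allele = list(a = 2 * cs[3] + cs[2], b = 2 * cs[1] + cs[2],
                      c = 2 * ct[3] + ct[2], d = 2 * ct[1] + ct[2],
                      unit = "alleles"),
        homozygote = list(a = cs[3], b = cs[1], c = ct[3], d = ct[1],
                          unit = "subjects"),
        heterozygote = list(a = cs[2], b = cs[1], c = ct[2], d = ct[1],
                            unit = "subjects"),
        dominant = list(a = cs[2] + cs[3], b = cs[1],
                        c = ct[2] + ct[3], d = ct[1], unit = "subjects"),
        recessive = list(a = cs[3], b = cs[1] + cs[2],
                         c = ct[3], d = ct[1] + ct[2], unit = "subjects"),
        carrier = list(a = cs[2] + cs[3], b = cs[1] + cs[2],
                       c = ct[2] + ct[3], d = ct[1] + ct[2],
                       unit = "carrier_tallies"))
    })
  if (cells$a + cells$c == 0 || cells$b + cells$d == 0)
    return(inel("required genotype class empty in both arms"))
  if (cells$a + cells$b == 0 || cells$c + cells$d == 0)
    return(inel("an arm is empty under this model"))
  structure(list(study_id = r$study_id, model = model,
                 case_exposed = cells$a, case_unexposed = cells$b,
                 control_exposed = cells$c, control_unexposed = cells$d,
                 unit = cells$unit),
            class = "table2x2")
}

#' Test whether a derivation result is an ineligibility marker
#' @param x result of [derive_table()].
#' @export
is_ineligible <- function(x) inherits(x, "ineligible")

#' Derive all eligible 2x2 tables for one SNP and genetic model
#'
#' @param table a [study_table].
#' @param snp SNP label to select.
#' @param model one of [genetic_models].
#' @return data frame with one row per eligible study (`study_id`,
#'   `case_exposed`, `case_unexposed`, `control_exposed`,
#'   `control_unexposed`, `unit`, `n_cases`, `n_controls`) and an
#'   `excluded` attribute listing ineligible studies with reasons.
#' @export
model_tables <- function(table, snp, model) {
  stopifnot(inherits(table, "study_table"))
  d <- table[table$snp == snp, , drop = FALSE]
  rows <- list(); excl <- list()
  for (i in seq_len(nrow(d))) {
    r <- d[i, , drop = FALSE]
    t2 <- derive_table(r, model)
    if (is_ineligible(t2)) {
      excl[[length(excl) + 1]] <- data.frame(
        study_id = t2$study_id, snp = snp, model = model,
        reason = t2$reason, stringsAsFactors = FALSE)
      next
    }
    subj <- .record_subjects(as.list(as.data.frame(r)[1, ]))
    rows[[length(rows) + 1]] <- data.frame(
      study_id = t2$study_id,
      case_exposed = t2$case_exposed, case_unexposed = t2$case_unexposed,
      control_exposed = t2$control_exposed,
      control_unexposed = t2$control_unexposed,
      unit = t2$unit, n_cases = subj[1], n_controls = subj[2],
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(study_id = character(0), case_exposed = numeric(0),
               case_unexposed = numeric(0), control_exposed = numeric(0),
               control_unexposed = numeric(0), unit = character(0),
               n_cases = numeric(0), n_controls = numeric(0))
  attr(out, "excluded") <- if (length(excl) > 0) do.call(rbind, excl) else
    data.frame(study_id = character(0), snp = character(0),
               model = character(0), reason = character(0))
  out
}

#' Eligibility summary for one SNP x genetic model analysis
#'
#' Counts the studies whose records can supply the requested contrast and
#' totals their case and control subjects (allele-model totals are
#' reported as subjects, not allele tallies).
#'
#' @inheritParams model_tables
#' @return an `eligibility_report`: list with `snp`, `model`, `k`,
#'   `case_total`, `control_total`, `included`, `excluded`.
#' @export
eligibility_report <- function(table, snp, model) {
  tabs <- model_tables(table, snp, model)
  structure(list(snp = snp, model = model, k = nrow(tabs),
                 case_total = sum(tabs$n_cases),
                 control_total = sum(tabs$n_controls),
                 included = tabs$study_id,
                 excluded = attr(tabs, "excluded")),
            class = "eligibility_report")
}

#' @export
print.eligibility_report <- function(x, ...) {
  cat(sprintf("%s, %s model: %d eligible stud(ies), %d cases / %d controls\n",
              x$snp, x$model, x$k, x$case_total, x$control_total))
  if (nrow(x$excluded) > 0) {
    cat("Excluded:\n")
    for (i in seq_len(nrow(x$excluded)))
      cat(sprintf("  %s: %s\n", x$excluded$study_id[i], x$excluded$reason[i]))
  }
  invisible(x)
}
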