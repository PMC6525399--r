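# Whole-pipeline orchestration: subgroup grids, bias and sensitivity
# attachments, and deterministic report export.

#' Specify a full meta-analysis run
#'
#' @param snp SNP label to analyse.
#' @param models genetic models to fit (default all six).
#' @param subgroups list of subgroup filters, each a list with a `name`
#'   and any of `ethnicity`, `country`, `hwe_only`; `NULL` (default)
#'   builds the standard grid with [default_subgroups()] when the
#'   analysis runs.
#' @param min_k minimum studies per reported pooling (default 3).
#' @param correction zero-cell handling (see [study_effect()]).
#' @return an `analysis_spec` list.
#' @export
analysis_spec <- function(snp, models = genetic_models, subgroups = NULL,
                          min_k = 3, correction = "haldane_half") {
  stopifnot(all(models %in% genetic_models), min_k >= 2)
  structure(list(snp = snp, models = models, subgroups = subgroups,
                 min_k = min_k, correction = correction),
            class = "analysis_spec")
}

#' Standard subgroup grid for one SNP
#'
#' Overall, plus every ethnicity and country represented by at least
#' `min_k` records of the SNP, plus the Hardy-Weinberg-restricted ("Y")
#' variant of each of those groups.
#'
#' @param table a [study_table].
#' @param snp SNP label.
#' @param min_k minimum records for a metadata value to form a subgroup.
#' @return list of subgroup filters as used by [analysis_spec()].
#' @export
default_subgroups <- function(table, snp, min_k = 3) {
  d <- table[table$snp == snp, , drop = FALSE]
  groups <- list(list(name = "Overall"))
  eths <- names(which(table(d$ethnicity) >= min_k))
  ctys <- names(which(table(d$country) >= min_k))
  for (e in eths) groups <- c(groups, list(list(name = e, ethnicity = e)))
  for (cy in ctys) groups <- c(groups, list(list(name = cy, country = cy)))
  groups <- c(groups, list(list(name = "Y", hwe_only = TRUE)))
  for (e in eths)
    groups <- c(groups, list(list(name = paste0(e, "/Y"), ethnicity = e,
                                  hwe_only = TRUE)))
  for (cy in ctys)
    groups <- c(groups, list(list(name = paste0(cy, "/Y"), country = cy,
                                  hwe_only = TRUE)))
  groups
}

#' Run the full meta-analysis pipeline for one SNP
#'
#' For every genetic model and subgroup: filters the records, applies
#' model eligibility, enforces the minimum study count, and pools with
#' the heterogeneity-driven fixed/random choice.  Publication-bias tests
#' (Egger and Begg) are attached to the Overall group of each model, and
#' a leave-one-out sensitivity analysis to the Overall allelic analysis.
#' Every excluded study is logged with a reason.
#'
#' @param table a [study_table].
#' @param spec an [analysis_spec()] (or a SNP label, for defaults).
#' @return a `snp_report`: list with `snp`, `pooled` (one row per model
#'   x group), `fits` (the [snp_meta] objects), `bias`, `loo`,
#'   `exclusions`.
#' @examples
#' rep <- run_analysis(il10_ad_studies(), analysis_spec("-592A/C"))
#' subset(rep$pooled, group == "Overall")
#' @export
run_analysis <- function(table, spec) {
  stopifnot(inherits(table, "study_table"))
  if (is.character(spec)) spec <- analysis_spec(spec)
  stopifnot(inherits(spec, "analysis_spec"))
  subgroups <- spec$subgroups
  if (is.null(subgroups))
    subgroups <- default_subgroups(table, spec$snp, spec$min_k)
  fits <- list(); rows <- list(); bias <- list(); excl <- list()
  loo <- NULL
  for (model in spec$models) {
    # The fixed/random choice is made once per model on the Overall
    # analysis and carried into its subgroups, the way heterogeneity
    # tables assign one method per model x SNP.
    overall <- snp_meta(table, spec$snp, model, min_k = spec$min_k,
                        correction = spec$correction)
    sub_method <- switch(overall$method, fixed_MH = "fixed",
                         random_DL = "random", "auto")
    for (g in subgroups) {
      is_overall <- is.null(g$ethnicity) && is.null(g$country) &&
        !isTRUE(g$hwe_only)
      fit <- if (is_overall) {
        overall$group <- g$name
        overall
      } else snp_meta(table, spec$snp, model,
                      ethnicity = g$ethnicity, country = g$country,
                      hwe_only = isTRUE(g$hwe_only), method = sub_method,
                      min_k = spec$min_k, correction = spec$correction,
                      group_label = g$name)
      key <- paste(model, g$name, sep = ".")
      fits[[key]] <- fit
      rows[[key]] <- as.data.frame(fit)
      if (!is.null(fit$excluded) && nrow(fit$excluded) > 0) {
        log <- fit$excluded
        log$group <- g$name
        excl[[key]] <- log
      }
      if (identical(g$name, "Overall") && fit$method != "not_computed") {
        eg <- egger_test(fit, spec$min_k)
        bg <- begg_test(fit, spec$min_k)
        bias[[model]] <- data.frame(
          snp = spec$snp, model = model, k = fit$k,
          egger_intercept = eg$intercept, egger_p = eg$p,
          begg_tau = bg$kendall_tau, begg_p = bg$p,
          stringsAsFactors = FALSE)
        if (model == "allele") loo <- leave_one_out(fit, spec$min_k)
      }
    }
  }
  structure(list(snp = spec$snp, spec = spec,
                 pooled = do.call(rbind, c(rows, make.row.names = FALSE)),
                 fits = fits,
                 bias = if (length(bias) > 0) do.call(rbind, c(bias, make.row.names = FALSE)) else NULL,
                 loo = loo,
                 exclusions = if (length(excl) > 0)
                   do.call(rbind, c(excl, make.row.names = FALSE)) else NULL),
            class = "snp_report")
}

#' @export
print.snp_report <- function(x, ...) {
  cat(sprintf("Meta-analysis report for %s: %d model x group analyses (%d pooled)\n",
              x$snp, nrow(x$pooled), sum(x$pooled$method != "not_computed")))
  print(.rounded_pooled(x$pooled), row.names = FALSE)
  invisible(x)
}

.rounded_pooled <- function(pooled) {
  out <- pooled
  for (col in c("or", "ci_low", "ci_high"))
    out[[col]] <- round(out[[col]], 2)
  for (col in c("p", "p_q"))
    out[[col]] <- round(out[[col]], 3)
  out$q <- round(out$q, 2)
  out$i2 <- round(out$i2, 1)
  out$tau2 <- round(out$tau2, 4)
  out
}

.report_checksum <- function(pooled) {
  txt <- paste(utils::capture.output(utils::write.csv(pooled, stdout())),
               collapse = "\n")
  sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %% 2147483647
}

#' Write a report bundle to disk
#'
#' Deterministic export (fixed column order, OR/CI rounded to 2 decimals
#' and P values to 3) so that repeated writes of the same bundle are
#' byte-identical and diffs against checked-in expected tables are
#' stable.  Each file carries a provenance header with the package
#' version and an input checksum.
#'
#' @param bundle a `snp_report` from [run_analysis()].
#' @param dir output directory (created if missing).
#' @param format `"tsv"`, `"json"` or `"markdown"`.
#' @return character vector of files written, invisibly.
#' @export
write_report <- function(bundle, dir, format = c("tsv", "json", "markdown")) {
  format <- match.arg(format)
  stopifnot(inherits(bundle, "snp_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pooled <- .rounded_pooled(bundle$pooled)
  version <- as.character(utils::packageVersion("snpmeta"))
  checksum <- .report_checksum(bundle$pooled)
  prov <- sprintf("snpmeta %s | snp %s | checksum %d",
                  version, bundle$snp, checksum)
  slug <- gsub("[^A-Za-z0-9]+", "", bundle$snp)
  files <- character(0)
  loo_df <- if (is.data.frame(bundle$loo)) {
    l <- as.data.frame(bundle$loo)
    l$or <- round(l$or, 2); l$ci_low <- round(l$ci_low, 2)
    l$ci_high <- round(l$ci_high, 2); l$p <- round(l$p, 3)
    l$i2 <- round(l$i2, 1); l
  } else NULL
  if (format == "tsv") {
    write_one <- function(df, name) {
      path <- file.path(dir, sprintf("%s_%s.tsv", slug, name))
      con <- file(path, "w")
      writeLines(paste0("# ", prov), con)
      utils::write.table(df, con, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "")
      close(con)
      path
    }
    files <- c(files, write_one(pooled, "pooled"))
    if (!is.null(bundle$bias)) {
      b <- bundle$bias
      for (col in c("egger_intercept", "egger_p", "begg_tau", "begg_p"))
        b[[col]] <- round(b[[col]], 3)
      files <- c(files, write_one(b, "bias"))
    }
    if (!is.null(loo_df)) files <- c(files, write_one(loo_df, "loo"))
  } else if (format == "json") {
    path <- file.path(dir, sprintf("%s_report.json", slug))
    payload <- list(provenance = prov, snp = bundle$snp, pooled = pooled,
                    bias = bundle$bias, leave_one_out = loo_df)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    files <- path
  } else {
    path <- file.path(dir, sprintf("%s_report.md", slug))
    fmt_tbl <- function(df) {
      c(paste("|", paste(names(df), collapse = " | "), "|"),
        paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
        apply(df, 1, function(r)
          paste("|", paste(ifelse(is.na(r), "", r), collapse = " | "), "|")))
    }
    lines <- c(sprintf("# Meta-analysis report: %s", bundle$snp), "",
               paste0("_", prov, "_"), "", "## Pooled results", "",
               fmt_tbl(pooled))
    if (!is.null(bundle$bias)) {
      b <- bundle$bias
      for (col in c("egger_intercept", "egger_p", "begg_tau", "begg_p"))
        b[[col]] <- round(b[[col]], 3)
      lines <- c(lines, "", "## Publication bias (Overall groups)", "",
                 fmt_tbl(b))
    }
    if (!is.null(loo_df))
      lines <- c(lines, "", "## Sensitivity analysis (allelic, Overall)", "",
                 sprintf("Leave-one-out OR range: %.2f-%.2f",
                         attr(bundle$loo, "or_range")[1],
                         attr(bundle$loo, "or_range")[2]), "",
                 fmt_tbl(loo_df))
    writeLines(lines, path)
    files <- path
  }
  invisible(files)
}
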