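# The user-facing fit: filter a study table, derive 2x2 tables under a
# genetic model, pool, and return a classed result.

#' Fit a case-control SNP meta-analysis
#'
#' The front end of the package: selects the records of one SNP
#' (optionally restricted to a subgroup), derives the per-study 2x2
#' tables under the requested genetic model (see [derive_table()] for
#' eligibility), and pools them by the Mantel-Haenszel fixed-effect or
#' DerSimonian-Laird random-effects method.  With `method = "auto"`
#' (default) the choice is driven by the heterogeneity of the per-study
#' log odds ratios as in [select_and_pool()].
#'
#' @param data a [study_table].
#' @param snp SNP label to analyse.
#' @param model one of [genetic_models].
#' @param ethnicity,country optional subgroup filters on the metadata.
#' @param hwe_only if `TRUE`, keep only studies whose control genotypes
#'   are consistent with Hardy-Weinberg equilibrium (recomputed P > 0.05
#'   where genotype counts are available; records reporting only an
#'   equilibrium bound are classified by that bound).
#' @param method `"auto"`, `"fixed"` (Mantel-Haenszel) or `"random"`
#'   (DerSimonian-Laird).
#' @param min_k minimum number of studies to report a pooling (default 3);
#'   smaller analyses return a "not computed" record.
#' @param correction zero-cell handling passed to the pooling functions.
#' @param group_label label stored on the result; composed from the
#'   filters when omitted (e.g. `"Asian/Y"`).
#' @return an object of class `snp_meta` with components `or`, `ci`, `z`,
#'   `p`, `q`, `p_q`, `i2`, `tau2`, `method`, `k`, `case_total`,
#'   `control_total`, per-study `effects`, and the `excluded` log.
#' @examples
#' fit <- snp_meta(il10_ad_studies(), "-1082A/G", "allele")
#' fit
#' coef(fit)
#' @seealso [egger_test()], [begg_test()], [leave_one_out()],
#'   [run_analysis()]
#' @export
snp_meta <- function(data, snp, model = "allele",
                     ethnicity = NULL, country = NULL, hwe_only = FALSE,
                     method = c("auto", "fixed", "random"),
                     min_k = 3, correction = "haldane_half",
                     group_label = NULL) {
  stopifnot(inherits(data, "study_table"))
  method <- match.arg(method)
  if (!model %in% genetic_models)
    stop("unknown genetic model '", model, "'", call. = FALSE)
  keep <- rep(TRUE, nrow(data))
  parts <- character(0)
  if (!is.null(ethnicity)) {
    keep <- keep & data$ethnicity %in% ethnicity
    parts <- c(parts, paste(ethnicity, collapse = "+"))
  }
  if (!is.null(country)) {
    keep <- keep & data$country %in% country
    parts <- c(parts, paste(country, collapse = "+"))
  }
  hwe_excl <- NULL
  if (isTRUE(hwe_only)) {
    ok <- .hwe_keep(data)
    drop <- keep & data$snp == snp & (!ok | is.na(ok))
    if (any(drop))
      hwe_excl <- data.frame(study_id = data$study_id[drop], snp = snp,
                             model = model,
                             reason = ifelse(is.na(ok[drop]),
                                             "HWE status unknown",
                                             "control HWE P <= 0.05"),
                             stringsAsFactors = FALSE)
    keep <- keep & (!is.na(ok) & ok)
    parts <- c(parts, "Y")
  }
  if (is.null(group_label))
    group_label <- if (length(parts) == 0) "Overall"
                   else paste(parts, collapse = "/")
  sub <- data[keep, , drop = FALSE]
  class(sub) <- class(data)
  tabs <- model_tables(sub, snp, model)
  excluded <- rbind(attr(tabs, "excluded"), hwe_excl)
  fit <- switch(method,
    auto = select_and_pool(tabs, min_k, correction),
    fixed = pool_fixed_mh(tabs, min_k, correction),
    random = pool_random_dl(tabs, min_k, correction))
  fit$snp <- snp
  fit$model <- model
  fit$group <- group_label
  fit$excluded <- excluded
  fit$call <- match.call()
  fit
}

.model_label <- function(model) {
  c(allele = "allele Y vs X", homozygote = "YY vs XX",
    heterozygote = "XY vs XX", dominant = "XY+YY vs XX",
    recessive = "YY vs XX+XY", carrier = "carrier Y vs X")[model]
}

#' @export
print.snp_meta <- function(x, digits = 3, ...) {
  head <- "Case-control meta-analysis"
  if (!is.na(x$snp))
    head <- sprintf("%s: %s, %s model (%s)", head, x$snp, x$model,
                    .model_label(x$model))
  cat(head, "\n")
  cat(sprintf("Group: %s   Studies: %d", x$group, x$k))
  if (!is.na(x$case_total))
    cat(sprintf("   Cases/Controls: %.0f/%.0f", x$case_total, x$control_total))
  cat("\n")
  if (x$method == "not_computed") {
    cat("Not computed:", x$reason, "\n")
    return(invisible(x))
  }
  meth <- if (x$method == "fixed_MH") "fixed effect, Mantel-Haenszel"
          else "random effects, DerSimonian-Laird"
  cat(sprintf("Pooled OR (%s): %.2f (95%% CI %.2f-%.2f), z = %.2f, P = %.3f\n",
              meth, x$or, x$ci[1], x$ci[2], x$z, x$p))
  cat(sprintf("Heterogeneity: Q = %.2f on %d df (P = %.3f), I2 = %.1f%%, tau2 = %.4f\n",
              x$q, x$q_df, x$p_q, x$i2, x$tau2))
  invisible(x)
}

#' @export
summary.snp_meta <- function(object, ...) {
  structure(list(fit = object), class = "summary.snp_meta")
}

#' @export
print.summary.snp_meta <- function(x, ...) {
  print(x$fit)
  fit <- x$fit
  if (!is.null(fit$effects) && nrow(fit$effects) > 0) {
    cat("\nPer-study odds ratios:\n")
    eff <- fit$effects
    out <- data.frame(study = eff$study_id,
                      OR = round(eff$or, 3),
                      `CI95.low` = round(eff$ci_low, 3),
                      `CI95.high` = round(eff$ci_high, 3),
                      `weight.pct` = round(eff$weight_pct, 1),
                      corrected = eff$corrected)
    print(out, row.names = FALSE)
  }
  if (!is.null(fit$excluded) && nrow(fit$excluded) > 0) {
    cat("\nExcluded studies:\n")
    for (i in seq_len(nrow(fit$excluded)))
      cat(sprintf("  %s: %s\n", fit$excluded$study_id[i],
                  fit$excluded$reason[i]))
  }
  invisible(x)
}

#' @export
coef.snp_meta <- function(object, ...) {
  c(log_or = object$log_or)
}

#' @export
confint.snp_meta <- function(object, parm = "log_or", level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- matrix(object$log_or + c(-1, 1) * zq * object$se, nrow = 1,
                dimnames = list("log_or",
                                sprintf("%g %%", c((1 - level) / 2,
                                                   1 - (1 - level) / 2) * 100)))
  out
}

#' Forest plot of a fitted meta-analysis
#'
#' Per-study odds ratios with 95% confidence intervals (log scale) and
#' the pooled estimate as a diamond-style summary row.
#'
#' @param x an object of class [snp_meta].
#' @param ... passed to [graphics::plot()].
#' @export
plot.snp_meta <- function(x, ...) {
  if (x$method == "not_computed" || is.null(x$effects))
    stop("nothing to plot: analysis was not computed", call. = FALSE)
  eff <- x$effects
  k <- nrow(eff)
  ylim <- c(0, k + 2)
  xlim <- range(c(eff$ci_low, eff$ci_high, x$ci), 1)
  graphics::plot(NA, xlim = xlim, ylim = ylim, log = "x",
                 xlab = "Odds ratio (log scale)", ylab = "",
                 yaxt = "n", ...)
  graphics::axis(2, at = k:1, labels = eff$study_id, las = 1, cex.axis = 0.7)
  graphics::abline(v = 1, lty = 3, col = "grey40")
  graphics::segments(eff$ci_low, k:1, eff$ci_high, k:1)
  graphics::points(eff$or, k:1, pch = 15,
                   cex = 0.5 + 1.5 * eff$weight_pct / max(eff$weight_pct))
  graphics::segments(x$ci[1], 0, x$ci[2], 0, lwd = 2)
  graphics::points(x$or, 0, pch = 18, cex = 2)
  graphics::axis(2, at = 0, labels = "Pooled", las = 1, cex.axis = 0.8)
  invisible(x)
}

#' @export
as.data.frame.snp_meta <- function(x, ...) {
  data.frame(snp = x$snp, model = x$model, group = x$group, k = x$k,
             case_total = x$case_total, control_total = x$control_total,
             p = x$p, or = x$or, ci_low = unname(x$ci[1]),
             ci_high = unname(x$ci[2]), q = x$q, p_q = x$p_q, i2 = x$i2,
             tau2 = x$tau2, method = x$method, stringsAsFactors = FALSE)
}
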