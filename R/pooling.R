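# Per-study odds ratios and fixed/random-effects pooling.
#
# Per-study effects are crude log odds ratios with the Haldane-Anscombe
# correction (0.5 added to all four cells) for studies containing a zero
# cell.  The same corrected cells feed the Mantel-Haenszel sums, matching
# the default behaviour of the meta-analysis software generation these
# pipelines are compared against.  Cochran's Q is computed from
# inverse-variance weights on the per-study log odds ratios; the
# fixed/random decision compares I-squared with 50% and the heterogeneity
# P value (at its three-decimal reporting precision) with 0.05.

.as_tables_df <- function(tables) {
  if (inherits(tables, "table2x2")) tables <- list(tables)
  if (is.list(tables) && !is.data.frame(tables) &&
      all(vapply(tables, inherits, logical(1), "table2x2"))) {
    tables <- do.call(rbind, lapply(tables, function(t2)
      data.frame(study_id = t2$study_id,
                 case_exposed = t2$case_exposed,
                 case_unexposed = t2$case_unexposed,
                 control_exposed = t2$control_exposed,
                 control_unexposed = t2$control_unexposed,
                 stringsAsFactors = FALSE)))
  }
  stopifnot(is.data.frame(tables),
            all(c("case_exposed", "case_unexposed", "control_exposed",
                  "control_unexposed") %in% names(tables)))
  if (!"study_id" %in% names(tables))
    tables$study_id <- sprintf("study%02d", seq_len(nrow(tables)))
  tables
}

# corrected cells: Haldane-Anscombe 0.5 on every cell of zero-cell studies
.corrected_cells <- function(tables, correction = "haldane_half") {
  a <- tables$case_exposed; b <- tables$case_unexposed
  cc <- tables$control_exposed; d <- tables$control_unexposed
  zero <- (a == 0 | b == 0 | cc == 0 | d == 0)
  if (identical(correction, "haldane_half")) {
    a <- a + 0.5 * zero; b <- b + 0.5 * zero
    cc <- cc + 0.5 * zero; d <- d + 0.5 * zero
  } else if (any(zero)) {
    stop("zero cell yields an undefined odds ratio without correction",
         call. = FALSE)
  }
  data.frame(a = a, b = b, c = cc, d = d, corrected = zero & identical(correction, "haldane_half"))
}

#' Crude odds ratio of one 2x2 table
#'
#' `log_or = log(a*d / (b*c))`, `se = sqrt(1/a + 1/b + 1/c + 1/d)` with
#' cells a = exposed cases, b = unexposed cases, c = exposed controls,
#' d = unexposed controls.  If any cell is zero and
#' `correction = "haldane_half"`, 0.5 is added to all four cells first and
#' the estimate is flagged as corrected.
#'
#' @param table a `table2x2` from [derive_table()], or a numeric vector
#'   `c(a, b, c, d)`.
#' @param correction `"haldane_half"` (default) or `"none"`.
#' @return an `effect_estimate`: list with `study_id`, `log_or`, `se`,
#'   `or`, `ci95`, `corrected`.
#' @examples
#' study_effect(c(10, 10, 10, 10))  # OR 1, se sqrt(0.4)
#' @export
study_effect <- function(table, correction = c("haldane_half", "none")) {
  correction <- match.arg(correction)
  if (is.numeric(table) && length(table) == 4)
    table <- data.frame(study_id = NA_character_, case_exposed = table[1],
                        case_unexposed = table[2], control_exposed = table[3],
                        control_unexposed = table[4])
  tables <- .as_tables_df(table)[1, , drop = FALSE]
  cells <- .corrected_cells(tables, correction)
  y <- log(cells$a * cells$d / (cells$b * cells$c))
  se <- sqrt(1 / cells$a + 1 / cells$b + 1 / cells$c + 1 / cells$d)
  if (!is.finite(y))
    stop("zero cell yields an undefined odds ratio without correction",
         call. = FALSE)
  structure(list(study_id = tables$study_id, log_or = y, se = se,
                 or = exp(y), ci95 = exp(y + c(-1, 1) * 1.96 * se),
                 corrected = cells$corrected),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("OR = %.4f (95%% CI %.4f-%.4f), log OR = %.4f, se = %.4f%s\n",
              x$or, x$ci95[1], x$ci95[2], x$log_or, x$se,
              if (x$corrected) " [Haldane 0.5 correction]" else ""))
  invisible(x)
}

# per-study log ORs + variances for a tables data frame
.effects_df <- function(tables, correction = "haldane_half") {
  cells <- .corrected_cells(tables, correction)
  y <- log(cells$a * cells$d / (cells$b * cells$c))
  v <- 1 / cells$a + 1 / cells$b + 1 / cells$c + 1 / cells$d
  data.frame(study_id = tables$study_id, log_or = y, se = sqrt(v),
             or = exp(y), ci_low = exp(y - 1.96 * sqrt(v)),
             ci_high = exp(y + 1.96 * sqrt(v)),
             corrected = cells$corrected, stringsAsFactors = FALSE)
}

# Cochran Q against the inverse-variance mean, I^2, DL tau^2
.heterogeneity <- function(y, v) {
  w <- 1 / v
  ybar <- sum(w * y) / sum(w)
  q <- sum(w * (y - ybar)^2)
  df <- length(y) - 1L
  p_q <- stats::pchisq(q, df, lower.tail = FALSE)
  i2 <- if (q > 0) max(0, 100 * (q - df) / q) else 0
  tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  list(q = q, q_df = df, p_q = p_q, i2 = i2, tau2 = tau2)
}

.new_snp_meta <- function(tables, effects, het, log_or, se, method,
                          snp = NA_character_, model = NA_character_,
                          group = "Overall", reason = NA_character_,
                          excluded = NULL, call = sys.call(-1)) {
  k <- if (is.null(tables)) 0L else nrow(tables)
  case_total <- if (!is.null(tables) && "n_cases" %in% names(tables))
    sum(tables$n_cases) else NA_real_
  control_total <- if (!is.null(tables) && "n_controls" %in% names(tables))
    sum(tables$n_controls) else NA_real_
  or <- exp(log_or)
  ci <- exp(log_or + c(-1, 1) * 1.96 * se)
  z <- log_or / se
  p <- 2 * stats::pnorm(-abs(z))
  if (!is.null(effects) && nrow(effects) > 0) {
    w <- if (method == "random_DL") 1 / (effects$se^2 + het$tau2)
         else 1 / effects$se^2
    effects$weight_pct <- 100 * w / sum(w)
  }
  structure(list(snp = snp, model = model, group = group, k = k,
                 case_total = case_total, control_total = control_total,
                 data = tables, effects = effects,
                 log_or = log_or, se = se, or = or,
                 ci = c(low = ci[1], high = ci[2]), z = z, p = p,
                 q = het$q, q_df = het$q_df, p_q = het$p_q,
                 i2 = het$i2, tau2 = if (method == "fixed_MH") 0 else het$tau2,
                 method = method, reason = reason,
                 excluded = excluded, call = call),
            class = "snp_meta")
}

.not_computed <- function(tables, reason, snp = NA_character_,
                          model = NA_character_, group = "Overall",
                          excluded = NULL) {
  out <- .new_snp_meta(tables, NULL,
                       list(q = NA_real_, q_df = NA_integer_, p_q = NA_real_,
                            i2 = NA_real_, tau2 = NA_real_),
                       NA_real_, NA_real_, "not_computed",
                       snp = snp, model = model, group = group,
                       reason = reason, excluded = excluded)
  out
}

#' Mantel-Haenszel fixed-effect pooled odds ratio
#'
#' `OR_MH = sum(a_i d_i / n_i) / sum(b_i c_i / n_i)` with the
#' Robins-Breslow-Greenland variance for its log; studies containing a
#' zero cell enter with 0.5 added to all four cells.  Cochran's Q and
#' I-squared are computed from inverse-variance weights on the per-study
#' log odds ratios.  Analyses with fewer than `min_k` studies return a
#' "not computed" record rather than an error, mirroring the convention
#' that only poolings of at least three case-control studies are
#' reported.
#'
#' @param tables data frame of 2x2 tables as produced by [model_tables()]
#'   (columns `case_exposed`, `case_unexposed`, `control_exposed`,
#'   `control_unexposed`, optionally `study_id`, `n_cases`,
#'   `n_controls`), or a list of `table2x2` objects.
#' @param min_k minimum number of studies (default 3).
#' @param correction zero-cell handling, `"haldane_half"` or `"none"`.
#' @return an object of class [snp_meta].
#' @export
pool_fixed_mh <- function(tables, min_k = 3, correction = "haldane_half") {
  tables <- .as_tables_df(tables)
  if (nrow(tables) < min_k)
    return(.not_computed(tables, sprintf("fewer than %d studies (k = %d)",
                                         min_k, nrow(tables))))
  cells <- .corrected_cells(tables, correction)
  n <- cells$a + cells$b + cells$c + cells$d
  R <- cells$a * cells$d / n
  S <- cells$b * cells$c / n
  if (sum(R) == 0 || sum(S) == 0)
    stop("undefined Mantel-Haenszel odds ratio: a pooled margin is zero",
         call. = FALSE)
  or_mh <- sum(R) / sum(S)
  P <- (cells$a + cells$d) / n
  Q <- (cells$b + cells$c) / n
  var_log <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  effects <- .effects_df(tables, correction)
  het <- .heterogeneity(effects$log_or, effects$se^2)
  .new_snp_meta(tables, effects, het, log(or_mh), sqrt(var_log), "fixed_MH")
}

#' DerSimonian-Laird random-effects pooled odds ratio
#'
#' Moment estimator of the between-study variance from Cochran's Q on
#' inverse-variance weights,
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`, followed by
#' inverse-variance pooling with weights `1 / (se_i^2 + tau2)`.  When
#' `Q <= k - 1` the estimator returns `tau2 = 0` and the result equals
#' plain inverse-variance fixed pooling.
#'
#' @param x 2x2 tables as in [pool_fixed_mh()], or a data frame of
#'   per-study effects with columns `log_or` and `se`.
#' @inheritParams pool_fixed_mh
#' @return an object of class [snp_meta].
#' @export
pool_random_dl <- function(x, min_k = 3, correction = "haldane_half") {
  tables <- NULL
  if (is.data.frame(x) && all(c("log_or", "se") %in% names(x))) {
    effects <- x
    if (!"study_id" %in% names(effects))
      effects$study_id <- sprintf("study%02d", seq_len(nrow(effects)))
    if (!"corrected" %in% names(effects)) effects$corrected <- FALSE
  } else {
    tables <- .as_tables_df(x)
    effects <- .effects_df(tables, correction)
  }
  if (nrow(effects) < min_k)
    return(.not_computed(tables, sprintf("fewer than %d studies (k = %d)",
                                         min_k, nrow(effects))))
  v <- effects$se^2
  het <- .heterogeneity(effects$log_or, v)
  w_star <- 1 / (v + het$tau2)
  log_or <- sum(w_star * effects$log_or) / sum(w_star)
  se <- 1 / sqrt(sum(w_star))
  .new_snp_meta(tables, effects, het, log_or, se, "random_DL")
}

#' Pool with heterogeneity-driven choice of fixed or random effects
#'
#' Computes Cochran's Q and I-squared once from inverse-variance weights
#' on the per-study log odds ratios, then pools by
#' [pool_random_dl()] when heterogeneity is high -- I-squared above 50%
#' or heterogeneity P below 0.05, the P value compared at the
#' three-decimal precision at which such tables report it -- and by
#' [pool_fixed_mh()] otherwise.
#'
#' @inheritParams pool_fixed_mh
#' @return an object of class [snp_meta]; its `method` field records the
#'   path taken.
#' @export
select_and_pool <- function(tables, min_k = 3, correction = "haldane_half") {
  tables <- .as_tables_df(tables)
  if (nrow(tables) < min_k)
    return(.not_computed(tables, sprintf("fewer than %d studies (k = %d)",
                                         min_k, nrow(tables))))
  effects <- .effects_df(tables, correction)
  het <- .heterogeneity(effects$log_or, effects$se^2)
  if (.use_random(het)) pool_random_dl(tables, min_k, correction)
  else pool_fixed_mh(tables, min_k, correction)
}

.use_random <- function(het) het$i2 > 50 || round(het$p_q, 3) < 0.05
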