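# Publication-bias tests and leave-one-out sensitivity analysis.

# normalise input (snp_meta fit, effects data frame, or tables) to a
# data frame with log_or / se / study_id
.as_effects <- function(x, correction = "haldane_half") {
  if (inherits(x, "snp_meta")) {
    if (is.null(x$effects))
      stop("fit carries no per-study effects (not computed)", call. = FALSE)
    return(x$effects)
  }
  if (is.data.frame(x) && all(c("log_or", "se") %in% names(x))) {
    if (!"study_id" %in% names(x))
      x$study_id <- sprintf("study%02d", seq_len(nrow(x)))
    return(x)
  }
  .effects_df(.as_tables_df(x), correction)
}

#' Egger regression test for funnel-plot asymmetry
#'
#' Ordinary least squares of the standardized effect `log_or/se` on the
#' precision `1/se` (the classic 1997 formulation).  Under a symmetric
#' funnel the intercept is zero; the test statistic is the intercept's t
#' with k-2 degrees of freedom, two-sided.
#'
#' @param x a [snp_meta] fit, a data frame of effects (`log_or`, `se`),
#'   or 2x2 tables as in [pool_fixed_mh()].
#' @param min_k minimum number of studies (default 3); below it a
#'   "not computed" marker is returned.
#' @return a `bias_result`: list with `test = "egger"`, `k`, `intercept`,
#'   `statistic` (intercept t), `se_intercept`, `slope`, `p`.
#' @export
egger_test <- function(x, min_k = 3) {
  eff <- .as_effects(x)
  k <- nrow(eff)
  if (k < min_k)
    return(structure(list(test = "egger", k = k, statistic = NA_real_,
                          p = NA_real_, intercept = NA_real_,
                          reason = sprintf("fewer than %d studies", min_k)),
                     class = "bias_result"))
  prec <- 1 / eff$se
  if (stats::var(prec) == 0)
    stop("degenerate input: all precisions identical", call. = FALSE)
  fit <- stats::lm(I(eff$log_or / eff$se) ~ prec)
  sm <- summary(fit)$coefficients
  structure(list(test = "egger", k = k,
                 intercept = sm[1, 1], se_intercept = sm[1, 2],
                 statistic = sm[1, 3], slope = sm[2, 1],
                 p = 2 * stats::pt(-abs(sm[1, 3]), df = k - 2)),
            class = "bias_result")
}

#' Begg-Mazumdar rank-correlation test for publication bias
#'
#' Kendall rank correlation between the variance-standardized deviates
#' `(y_i - y_bar_IV) / sqrt(v_i - 1/sum(1/v))` and the variances `v_i`.
#' The normal deviate uses the tie-corrected variance of Kendall's S and
#' a continuity correction: `z = (|S| - 1) / sd(S)`.
#'
#' @inheritParams egger_test
#' @param continuity apply the continuity correction (default `TRUE`).
#' @return a `bias_result`: list with `test = "begg"`, `k`,
#'   `kendall_tau`, `statistic` (normalized z), `p`.
#' @export
begg_test <- function(x, min_k = 3, continuity = TRUE) {
  eff <- .as_effects(x)
  k <- nrow(eff)
  if (k < min_k)
    return(structure(list(test = "begg", k = k, statistic = NA_real_,
                          p = NA_real_, kendall_tau = NA_real_,
                          reason = sprintf("fewer than %d studies", min_k)),
                     class = "bias_result"))
  v <- eff$se^2
  w <- 1 / v
  ybar <- sum(w * eff$log_or) / sum(w)
  dev <- (eff$log_or - ybar) / sqrt(v - 1 / sum(w))
  # Kendall's S over all pairs, with tie counts for the variance
  s <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    s <- s + sign(dev[j] - dev[i]) * sign(v[j] - v[i])
  }
  n0 <- k * (k - 1) / 2
  tie_term <- function(u) {
    t <- table(u); sum(t * (t - 1) / 2)
  }
  t1 <- tie_term(dev); t2 <- tie_term(v)
  tau <- s / sqrt((n0 - t1) * (n0 - t2))
  var_s <- (k * (k - 1) * (2 * k + 5) -
            sum(sapply(table(dev), function(t) t * (t - 1) * (2 * t + 5))) -
            sum(sapply(table(v), function(t) t * (t - 1) * (2 * t + 5)))) / 18
  z <- if (var_s > 0) (abs(s) - if (continuity) 1 else 0) / sqrt(var_s) else 0
  z <- max(z, 0)
  structure(list(test = "begg", k = k, kendall_tau = tau,
                 statistic = z * sign(s),
                 p = 2 * stats::pnorm(-z)),
            class = "bias_result")
}

#' @export
print.bias_result <- function(x, ...) {
  if (is.na(x$statistic)) {
    cat(sprintf("%s test: not computed (%s)\n", x$test, x$reason))
    return(invisible(x))
  }
  if (x$test == "egger")
    cat(sprintf("Egger test: intercept = %.3f, t = %.3f (%d df), P = %.3f\n",
                x$intercept, x$statistic, x$k - 2, x$p))
  else
    cat(sprintf("Begg test: Kendall tau = %.3f, z = %.3f, P = %.3f\n",
                x$kendall_tau, x$statistic, x$p))
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Repeats the pooling with each study omitted in turn; every reduced
#' analysis re-applies the heterogeneity-driven fixed/random choice of
#' [select_and_pool()], so the method may differ across omissions and is
#' reported per row.  Requires at least `min_k + 1` studies so each
#' reduced analysis keeps `min_k`.
#'
#' @param x a [snp_meta] fit or 2x2 tables as in [pool_fixed_mh()].
#' @param min_k minimum studies per reduced analysis (default 3).
#' @return a `snp_loo` object: data frame with one row per omitted study
#'   (`omitted`, `k`, `or`, `ci_low`, `ci_high`, `p`, `i2`, `method`)
#'   plus attributes `or_range` and `full` (the all-studies fit).
#' @export
leave_one_out <- function(x, min_k = 3) {
  tables <- if (inherits(x, "snp_meta")) x$data else .as_tables_df(x)
  if (is.null(tables))
    stop("no per-study tables available", call. = FALSE)
  k <- nrow(tables)
  if (k < min_k + 1)
    return(structure(list(reason = sprintf(
      "fewer than %d studies (k = %d): leave-one-out not computed",
      min_k + 1, k)), class = "snp_loo"))
  full <- if (inherits(x, "snp_meta")) x else select_and_pool(tables, min_k)
  rows <- lapply(seq_len(k), function(i) {
    fit <- select_and_pool(tables[-i, , drop = FALSE], min_k)
    data.frame(omitted = tables$study_id[i], k = fit$k, or = fit$or,
               ci_low = unname(fit$ci[1]), ci_high = unname(fit$ci[2]),
               p = fit$p, i2 = fit$i2, method = fit$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, or_range = range(out$or), full = full,
            class = c("snp_loo", "data.frame"))
}

#' @export
print.snp_loo <- function(x, ...) {
  if (!is.data.frame(x)) {
    cat(x$reason, "\n")
    return(invisible(x))
  }
  full <- attr(x, "full")
  cat(sprintf("Leave-one-out sensitivity analysis (%d omissions)\n", nrow(x)))
  cat(sprintf("Full analysis OR %.3f; leave-one-out OR range %.3f-%.3f\n",
              full$or, attr(x, "or_range")[1], attr(x, "or_range")[2]))
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Funnel-plot-ready table of per-study effects
#'
#' @param x a [snp_meta] fit or effects/tables accepted by [egger_test()].
#' @return data frame with `study_id`, `log_or`, `se`, `precision` and
#'   `standardized` (log OR / se) columns for external plotting.
#' @export
funnel_data <- function(x) {
  eff <- .as_effects(x)
  data.frame(study_id = eff$study_id, log_or = eff$log_or, se = eff$se,
             precision = 1 / eff$se, standardized = eff$log_or / eff$se,
             stringsAsFactors = FALSE)
}
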