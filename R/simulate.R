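# Simulation of case-control genetic association studies with known truth.
#
# Control genotype frequencies follow an allele frequency q with an
# optional inbreeding coefficient f deforming Hardy-Weinberg proportions:
#   P(YY) = q^2 + f*q*(1-q),  P(XY) = 2*q*(1-q)*(1-f),
#   P(XX) = (1-q)^2 + f*q*(1-q).
# Case genotype probabilities are induced by multiplicative per-allele
# odds exp(theta): P_case(g) proportional to P_control(g) * exp(theta*g),
# g = number of variant alleles, so with controls in equilibrium the
# allelic-model odds ratio equals exp(theta) exactly.  Per-study effects
# theta_i = log(true_or) + Normal(0, tau^2) give between-study
# heterogeneity.

#' Configuration for the study simulator
#'
#' @param k_studies number of studies to generate.
#' @param true_or true per-allele (allelic-model) odds ratio.
#' @param control_allele_freq variant allele frequency in controls,
#'   strictly inside (0, 1).
#' @param inbreeding_f inbreeding coefficient in `[0, 1)`; positive
#'   values deplete heterozygotes, i.e. deviate controls from
#'   Hardy-Weinberg equilibrium.
#' @param n_cases,n_controls integer ranges (length-2 vectors) from which
#'   per-study arm sizes are drawn uniformly.
#' @param tau between-study standard deviation of the log odds ratio.
#' @param snp,ethnicity,country metadata stamped on the simulated rows;
#'   `ethnicity`/`country` are recycled across studies, so a vector of
#'   labels yields subgroup structure.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(k_studies = 10, true_or = 1,
                       control_allele_freq = 0.3, inbreeding_f = 0,
                       n_cases = c(200, 500), n_controls = c(200, 500),
                       tau = 0, snp = "simSNP", ethnicity = "Simulated",
                       country = "Simulated") {
  if (length(n_cases) == 1) n_cases <- c(n_cases, n_cases)
  if (length(n_controls) == 1) n_controls <- c(n_controls, n_controls)
  stopifnot(k_studies >= 1, true_or > 0,
            n_cases[1] >= 1, n_cases[2] >= n_cases[1],
            n_controls[1] >= 1, n_controls[2] >= n_controls[1],
            tau >= 0, inbreeding_f >= 0, inbreeding_f < 1)
  if (control_allele_freq <= 0 || control_allele_freq >= 1)
    stop("degenerate control allele frequency (must be inside (0,1))",
         call. = FALSE)
  structure(list(k_studies = as.integer(k_studies), true_or = true_or,
                 control_allele_freq = control_allele_freq,
                 inbreeding_f = inbreeding_f,
                 n_cases = round(n_cases), n_controls = round(n_controls),
                 tau = tau, snp = snp, ethnicity = ethnicity,
                 country = country),
            class = "sim_config")
}

.genotype_probs <- function(q, f) {
  p <- 1 - q
  c(xx = p^2 + f * p * q, xy = 2 * p * q * (1 - f), yy = q^2 + f * p * q)
}

# independent per-study RNG substream, so generating k+1 studies leaves
# the first k untouched
.study_seed <- function(seed, i) (abs(seed) + 104729 * i) %% 2147483629

#' Simulate a table of case-control genetic association studies
#'
#' Draws `k_studies` studies under the model described in [sim_config()]:
#' per-study log odds ratio `log(true_or) + Normal(0, tau^2)`, arm sizes
#' uniform on the configured ranges, genotype counts multinomial.  The
#' random stream of each study is derived from the master seed and the
#' study index, so the output is reproducible and extending `k_studies`
#' does not perturb earlier studies.
#'
#' @param config a [sim_config()].
#' @param seed master seed (integer).
#' @return a genotype-resolution [study_table].
#' @export
simulate_study_table <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  q <- config$control_allele_freq
  p0 <- .genotype_probs(q, config$inbreeding_f)
  rows <- vector("list", config$k_studies)
  for (i in seq_len(config$k_studies)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(.study_seed(seed, i))
    theta <- log(config$true_or) + stats::rnorm(1, 0, config$tau)
    n_ca <- sample(seq(config$n_cases[1], config$n_cases[2]), 1)
    n_co <- sample(seq(config$n_controls[1], config$n_controls[2]), 1)
    p1 <- p0 * exp(theta * (0:2))
    p1 <- p1 / sum(p1)
    co <- stats::rmultinom(1, n_co, p0)[, 1]
    ca <- stats::rmultinom(1, n_ca, p1)[, 1]
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    rows[[i]] <- data.frame(
      study_id = sprintf("sim%03d", i), snp = config$snp,
      resolution = "genotype",
      control_xx = co[1], control_xy = co[2], control_yy = co[3],
      case_xx = ca[1], case_xy = ca[2], case_yy = ca[3],
      ethnicity = rep_len(config$ethnicity, config$k_studies)[i],
      country = rep_len(config$country, config$k_studies)[i],
      control_source = "population_based",
      hwe_p_reported = NA_character_, stringsAsFactors = FALSE)
  }
  study_table(do.call(rbind, rows),
              provenance = sprintf("simulated (seed %d)", seed))
}

#' Simulate a corpus with small-study publication suppression
#'
#' Generates a study table with [simulate_study_table()], then censors
#' it: each study whose allelic-model effect is non-significant at
#' `alpha` (two-sided Wald test on its crude log odds ratio, matching
#' the configured `side`) is omitted with probability `p_omit`.  The
#' censoring decisions use their own seed-derived random stream.
#'
#' @param config a [sim_config()].
#' @param p_omit probability of suppressing a censorable study.
#' @param alpha significance threshold defining "non-significant".
#' @param side which non-significant studies are censorable: `"both"`,
#'   or only those with `"positive"` / `"negative"` log odds ratios.
#' @param seed master seed.
#' @return the censored [study_table]; the attribute `censoring_log` is a
#'   data frame with per-study effect, p value and omission flag.
#' @export
simulate_biased_corpus <- function(config, p_omit = 0.8, alpha = 0.05,
                                   side = c("both", "positive", "negative"),
                                   seed = 1) {
  side <- match.arg(side)
  stopifnot(p_omit >= 0, p_omit <= 1)
  tab <- simulate_study_table(config, seed)
  tabs <- model_tables(tab, config$snp, "allele")
  eff <- .effects_df(tabs)
  pvals <- 2 * stats::pnorm(-abs(eff$log_or / eff$se))
  censorable <- pvals >= alpha & switch(side,
    both = TRUE, positive = eff$log_or > 0, negative = eff$log_or < 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(.study_seed(seed, 0))
  omit <- censorable & stats::runif(nrow(eff)) < p_omit
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  if (all(omit))
    stop("suppression rule censored every study", call. = FALSE)
  log <- data.frame(study_id = eff$study_id, log_or = eff$log_or,
                    p = pvals, censorable = censorable, omitted = omit,
                    stringsAsFactors = FALSE)
  out <- tab[!tab$study_id %in% eff$study_id[omit], , drop = FALSE]
  class(out) <- class(tab)
  attr(out, "provenance") <- sprintf("simulated, censored (seed %d)", seed)
  attr(out, "censoring_log") <- log
  out
}
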