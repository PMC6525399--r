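# shared test fixtures, built in code

# random small 2x2 tables without zero cells
random_tables <- function(k, seed, max_cell = 60) {
  set.seed(seed)
  data.frame(study_id = sprintf("t%02d", seq_len(k)),
             case_exposed = sample(1:max_cell, k, replace = TRUE),
             case_unexposed = sample(1:max_cell, k, replace = TRUE),
             control_exposed = sample(1:max_cell, k, replace = TRUE),
             control_unexposed = sample(1:max_cell, k, replace = TRUE),
             stringsAsFactors = FALSE)
}

# one-row study table record
make_record <- function(study_id = "S1", snp = "rs1", resolution = "genotype",
                        control = c(25, 50, 25), case = c(20, 50, 30),
                        ethnicity = "Asian", country = "Korea",
                        hwe = NA_character_) {
  pad <- function(x) c(x, rep(NA, 3 - length(x)))
  if (resolution == "allele_only") {
    control <- c(control[1], NA, control[2])
    case <- c(case[1], NA, case[2])
  } else {
    control <- pad(control); case <- pad(case)
  }
  data.frame(study_id = study_id, snp = snp, resolution = resolution,
             control_xx = control[1], control_xy = control[2],
             control_yy = control[3], case_xx = case[1], case_xy = case[2],
             case_yy = case[3], ethnicity = ethnicity, country = country,
             control_source = "population_based", hwe_p_reported = hwe,
             stringsAsFactors = FALSE)
}

# reference transcription of the published pooled rows (Tables 2-4 layout)
expected_pooled_rows <- function() {
  out <- utils::read.csv(test_path("expected_pooled_rows.csv"),
                         stringsAsFactors = FALSE)
  out$note[is.na(out$note)] <- ""
  out
}

# direct transcription of the DerSimonian-Laird formulas (independent of
# the package's pooling code path)
dl_oracle <- function(y, v) {
  w <- 1 / v
  ybar <- sum(w * y) / sum(w)
  q <- sum(w * (y - ybar)^2)
  tau2 <- max(0, (q - (length(y) - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (v + tau2)
  list(est = sum(ws * y) / sum(ws), se = 1 / sqrt(sum(ws)), tau2 = tau2, q = q)
}
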