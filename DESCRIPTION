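Package: snpmeta
Title: Meta-Analysis of Case-Control SNP Association Studies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pools case-control single-nucleotide polymorphism association
    studies across six genetic models (allelic, homozygote, heterozygote,
    dominant, recessive, carrier). Implements Mantel-Haenszel fixed-effect
    and DerSimonian-Laird random-effects pooling with Cochran Q and
    I-squared heterogeneity statistics and automatic model selection,
    Hardy-Weinberg equilibrium screening of control genotypes, Egger
    regression and Begg rank-correlation tests for publication bias,
    leave-one-out sensitivity analysis, subgroup analyses by ethnicity,
    country and Hardy-Weinberg status, and a multinomial simulator of
    genetic association studies with known truth. Ships a worked data set
    of IL-10 promoter polymorphism studies in atopic dermatitis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, utils, jsonlite
Suggests: testthat (>= 3.0.0), metafor, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
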