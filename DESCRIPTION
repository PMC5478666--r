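Package: methcycle
Title: Paired Differential DNA Methylation Analysis for the Endometrial
    Receptivity Transition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for 450K-style methylation array
    analysis of paired (pre-receptive vs receptive endometrium) designs:
    beta/M-value computation from probe intensities, staged probe filtering
    with per-rule accounting, per-sample scaling normalization, descriptive
    methylome profiling (hyper/hypomethylation fractions, CpG-island and
    gene-subregion distributions, Kolmogorov-Smirnov and chi-square
    comparisons, sample clustering), a three-method consensus for site-level
    differential methylation (empirical-Bayes moderated paired test,
    Wilcoxon signed-rank, spatial segment test), windowed differentially
    methylated region calling with BED export, and cis methylation-expression
    Spearman correlation with permutation p-values and region-level
    summaries. Includes a fully specified synthetic-data generator that
    emulates the paired study design, so the whole pipeline is testable
    without array or sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
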