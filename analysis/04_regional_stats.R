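#!/usr/bin/env Rscript

# Stage 4: regional statistics.
#
# Sex comparisons of regional BP_ND (Welch t, two-tailed, alpha 0.05),
# VOI-level trait regressions for the configured links, and the hormone
# null check (estradiol in females, free testosterone in males).

suppressPackageStartupMessages(library(petkin))

regional <- utils::read.csv("results/regional_bpnd.csv")
regional$sex <- factor(regional$sex, c("F", "M"))
cohort <- read_cohort_table("results/cohort.csv")

sex_tests <- sex_difference_tests(regional)
utils::write.csv(sex_tests, "results/sex_tests.csv", row.names = FALSE)
higher_m <- mean(sex_tests$mean_m > sex_tests$mean_f)
cat(sprintf("Males show higher regional BP_ND in %d/%d regions (generator encodes the exception in the right hypothalamus).\n",
            sum(sex_tests$mean_m > sex_tests$mean_f), nrow(sex_tests)))
sig <- sex_tests[sex_tests$significant, "region"]
cat("Regions with a significant sex difference at P < 0.05:",
    if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")

links <- list(
  list(trait = "baq_total", region = "amygdala_l", sex = "F"),
  list(trait = "tci_cooperativeness", region = "thalamus", sex = NULL))
regressions <- do.call(rbind, lapply(links, function(lk)
  voi_trait_regression(regional, cohort, lk$trait, lk$region, sex = lk$sex)))
utils::write.csv(regressions, "results/trait_regressions.csv", row.names = FALSE)
cat("VOI trait regressions:\n")
print(transform(regressions, slope = round(slope, 2), r2 = round(r2, 3),
                p = signif(p, 3), intercept = round(intercept, 1)),
      row.names = FALSE)

hormones <- list(
  estradiol = hormone_association_check(regional, cohort, "estradiol", "F"),
  free_testosterone = hormone_association_check(regional, cohort,
                                                "free_testosterone", "M"))
hs <- do.call(rbind, lapply(names(hormones), function(h)
  cbind(hormone = h, hormones[[h]]$results)))
utils::write.csv(hs, "results/hormone_checks.csv", row.names = FALSE)
cat("Hormone-BP_ND associations after Bonferroni:",
    if (any(vapply(hormones, `[[`, logical(1), "any_significant")))
      "some region significant" else "no region significant", "\n")
cat("Wrote results/sex_tests.csv, results/trait_regressions.csv, results/hormone_checks.csv\n")
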