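#!/usr/bin/env Rscript
# Identify hubs in each group (degree centrality > mean + 1 SD, integrated
# over the density sweep) and classify every ROI as lost / preserved /
# reconfigured / non-hub; check against the planted truth.

library(metconn)

out <- "results/synthetic_study"
truth <- read.csv(file.path(out, "planted_truth.csv"))

report <- function(tax, label) {
  cat(sprintf("\n-- %s --\n", label))
  cnt <- attr(tax, "counts")
  cat("category counts:",
      paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "), "\n")
  for (lab in c("lost", "reconfigured")) {
    planted <- truth$roi[truth$planted == lab]
    found <- tax$roi[tax$category == lab]
    cat(sprintf("  %-13s planted: %-8s recovered: %s\n", lab,
                paste(planted, collapse = ","),
                paste(found, collapse = ",")))
  }
  tax
}

# powered cohort: the planted reorganisation should be recovered
powered <- read_suvr_table(file.path(out, "powered_suvr.csv"))
tax_p <- suppressWarnings(hub_taxonomy(subset_group(powered, "control"),
                                       subset_group(powered, "carrier")))
report(tax_p, "powered cohort (50 vs 50)")
write.csv(as.data.frame(tax_p), file.path(out, "hub_taxonomy_powered.csv"),
          row.names = FALSE)

# study-sized cohort: the same analysis at 6 vs 12 subjects — expect a
# noisy hub map; this is the cautionary comparison, not the validation
cohort <- read_suvr_table(file.path(out, "cohort_suvr.csv"))
tax_s <- suppressWarnings(hub_taxonomy(subset_group(cohort, "control"),
                                       subset_group(cohort, "carrier")))
report(tax_s, "study-sized cohort (6 vs 12)")
write.csv(as.data.frame(tax_s), file.path(out, "hub_taxonomy.csv"),
          row.names = FALSE)

agree <- mean((tax_s$category == "non-hub") == (tax_p$category == "non-hub"))
cat(sprintf("\nhub/non-hub agreement between cohorts: %.2f — hub maps at the\n", agree))
cat("study's own sample sizes are exploratory; the powered cohort shows the\n")
cat("pipeline recovers the planted truth when the data allow it.\n")
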