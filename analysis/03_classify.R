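#!/usr/bin/env Rscript
# Step 3: classify the simulated panel by the published repeat-length
# thresholds: chiropteran call-type regions on (sum, ratio), the
# mammal-wide FOXP2 ratio bands, and the FOXP1 bands.

suppressPackageStartupMessages(library(polyqvoc))

calls <- read.csv("results/repeat_calls.csv")
cls <- classification_table(calls)
write.csv(cls, "results/classification.csv", row.names = FALSE)

cat("USV-type regions (sum/ratio thresholds):\n")
print(table(cls$usv_type))
cat("\nFOXP2 mammal-wide ratio bands (<=3.5 / 3.5-4.5 / >4.5):\n")
print(table(cls$foxp2_band))

# Collen call-type code mapping used when phenotype tables carry raw codes
codes <- c(3, 4, 5, 6, 7, 8, 9, 10)
cat("\nCollen FM code mapping:\n")
print(data.frame(code = codes, group = call_type_from_collen(codes)))
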