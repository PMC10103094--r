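#!/usr/bin/env Rscript

# Stage 5: head-to-head (active comparator) design.
#
# Every ordered pair among a six-drug panel spanning the four classes:
# treated = users of the row drug, comparator = users of the column
# drug, dual users excluded. Cells whose bootstrap CI excludes zero are
# flagged. The full 16x16 grid is the same loop over all retained
# drugs; six keep this stage quick.

suppressMessages(library(ehrcausal))

seed <- 922
data <- read_ehr_tables("scratch/run/data")
eligible <- apply_eligibility(data$persons)
vocab <- build_vocabulary(data$code_events, data$persons)

panel <- c("fluoxetine", "sertraline", "duloxetine", "trazodone",
           "bupropion", "amitriptyline")
cm <- comparator_matrix(eligible, data, panel, vocab,
                        spec = propensity_spec("lr", lambda = 3e-4,
                                               thresh = 1e-5,
                                               seed = seed),
                        B = 25, seed = seed + 900)

write.csv(cm$table, "results/05_comparator_cells.csv", row.names = FALSE)
write.csv(round(cm$ate, 4), "results/05_comparator_matrix_wide.csv")
print(cm)
cat(sprintf("max antisymmetry gap |ate(A,B) + ate(B,A)|: %.4f\n",
            cm$max_antisymmetry_gap))
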