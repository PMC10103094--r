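#!/usr/bin/env Rscript

# Stage 2: eligibility, drug retention and cohort construction.
#
# Applies the study filters (age > 13, >= 1 year of history, valid
# 3-digit zip), retains drugs with more than 50 users (the scaled-down
# analogue of the full study's 5000-user rule), and builds the
# any-drug-versus-nonuser cohort pair plus per-drug pairs under the
# clean-comparator rule.

suppressMessages(library(ehrcausal))

data <- read_ehr_tables("scratch/run/data")
eligible <- apply_eligibility(data$persons)
retained <- retain_common_drugs(data$exposures, 50)
pair <- build_any_drug_cohorts(eligible, data$exposures, retained)

attrition <- data.frame(
  step = c("generated", "eligible", "any_drug_treated",
           "any_drug_comparator"),
  n = c(nrow(data$persons), length(eligible),
        length(pair$treated_ids), length(pair$comparator_ids))
)
write.csv(attrition, "results/02_attrition.csv", row.names = FALSE)

users <- tapply(data$exposures$person_id, data$exposures$drug,
                function(x) length(unique(x)))
write.csv(data.frame(drug = names(users), users = as.integer(users),
                     retained = names(users) %in% retained),
          "results/02_drug_users.csv", row.names = FALSE)

write.csv(cohort_table(pair), "scratch/run/cohort_any_drug.csv",
          row.names = FALSE)

cat("eligible:", length(eligible), "of", nrow(data$persons), "\n")
cat("drugs retained (>50 users):", length(retained), "\n")
print(attrition, row.names = FALSE)
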