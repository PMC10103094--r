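#!/usr/bin/env Rscript

# Stage 1: generate the reference synthetic EHR study population.
#
# The generator encodes the study conditions everything downstream is
# tested against: 20,000 persons, a 500-code concept ontology, three
# latent health factors driving code histories, demographics, drug
# exposure (16 antidepressants, 4 classes) and the hospitalization
# outcome, with both potential outcomes stored. Person-level tables go
# to scratch/run/data (they are bulky and reproducible); small
# summaries go to results/.

suppressMessages(library(ehrcausal))

seed <- 20260922 %% 1000  # root seed for the whole analysis run
dir.create("results", showWarnings = FALSE)
data_dir <- "scratch/run/data"

cfg <- sim_config(seed = seed)
graph <- generate_ontology(cfg$n_codes, branching = 3, seed = seed)
data <- generate_population(graph, cfg)
write_synthetic_ehr(data, data_dir, graph = graph)

hosp <- binarize_outcome(data$severities$level)
summary_tab <- data.frame(
  n_persons = nrow(data$persons),
  n_codes = length(graph$nodes),
  n_code_events = nrow(data$code_events),
  n_drugs = cfg$n_drugs,
  treated_any = sum(data$truth$treated),
  hospitalization_rate = mean(hosp),
  missing_severity = mean(is.na(data$severities$level)),
  true_ate = true_ate(data)
)
write.csv(summary_tab, "results/01_population_summary.csv",
          row.names = FALSE)

cat("population:", summary_tab$n_persons, "persons,",
    summary_tab$n_code_events, "code events\n")
cat("any-drug users:", summary_tab$treated_any,
    sprintf("(%.1f%%)\n", 100 * summary_tab$treated_any /
              summary_tab$n_persons))
cat(sprintf("hospitalization rate: %.3f (target base rate %.2f)\n",
            summary_tab$hospitalization_rate, cfg$base_outcome_rate))
cat(sprintf("true (potential-outcome) ATE: %.4f\n", summary_tab$true_ate))
cat("tables written to", data_dir, "\n")
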