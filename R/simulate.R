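#' Simulation configuration for the synthetic EHR generator
#'
#' Collects and validates the parameters of the synthetic cohort:
#' population size, concept vocabulary, the latent health state that
#' drives both code histories and treatment assignment (hence
#' confounding), the true treatment effect on the log-odds of
#' hospitalization, and the exposure drug set.
#'
#' The defaults define the package's reference study conditions: 20,000
#' persons, 500 concept codes, 3 latent health factors of which two are
#' shared between the treatment and outcome models (so treatment is
#' genuinely confounded), a hospitalization base rate of 0.20, 16 study
#' drugs in 4 pharmacological classes, and a protective treatment effect
#' of -0.5 on the log-odds scale.
#'
#' @param n_persons Number of persons.
#' @param n_codes Number of concept codes used from the ontology.
#' @param n_latent Number of latent health factors.
#' @param treat_coefs Per-factor log-odds coefficients of the treatment
#'   assignment model (length `n_latent`).
#' @param outcome_coefs Per-factor log-odds coefficients of the outcome
#'   model (length `n_latent`).
#' @param treatment_effect Log-odds shift of hospitalization under
#'   treatment (negative = protective).
#' @param base_outcome_rate Marginal P(hospitalization) without
#'   treatment; the outcome intercept is calibrated to it.
#' @param n_drugs Number of study drugs (>= 2).
#' @param drug_class_map Named character vector mapping drug name to
#'   class; default: 16 antidepressants in the SSRI / SNRI / atypical /
#'   tricyclic classes.
#' @param drug_intercept Baseline per-drug log-odds of use.
#' @param code_base_logit Baseline log-odds of a code occurring.
#' @param code_loading Log-odds increase of a code's occurrence per unit
#'   of its latent factor.
#' @param n_negative_controls Number of designated negative-control
#'   codes, generated independent of everything else.
#' @param nc_prob Occurrence probability of each negative-control code.
#' @param missing_severity_frac Fraction of nonhospitalized persons whose
#'   severity score is missing.
#' @param seed Integer seed; fully determines the generated tables.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_persons = 20000,
                       n_codes = 500,
                       n_latent = 3,
                       treat_coefs = c(0.3, 0.3, 0),
                       outcome_coefs = c(1.0, 1.0, 0.5),
                       treatment_effect = -0.5,
                       base_outcome_rate = 0.2,
                       n_drugs = 16,
                       drug_class_map = default_drug_classes(),
                       drug_intercept = -3.9,
                       code_base_logit = -2.2,
                       code_loading = 1.5,
                       n_negative_controls = 5,
                       nc_prob = 0.15,
                       missing_severity_frac = 0.3,
                       seed = 1) {
  stopifnot(n_persons >= 1, n_codes >= 50, n_latent >= 1)
  if (n_drugs < 2) stop("n_drugs must be at least 2")
  if (length(treat_coefs) != n_latent || length(outcome_coefs) != n_latent) {
    stop("treat_coefs and outcome_coefs must each have length n_latent (",
         n_latent, ")")
  }
  if (!(base_outcome_rate > 0 && base_outcome_rate < 1)) {
    stop("base_outcome_rate must lie in (0, 1)")
  }
  if (!(nc_prob > 0 && nc_prob < 1)) {
    stop("nc_prob must lie in (0, 1)")
  }
  if (missing_severity_frac < 0 || missing_severity_frac >= 1) {
    stop("missing_severity_frac must lie in [0, 1)")
  }
  if (length(drug_class_map) < n_drugs) {
    stop("drug_class_map must name at least n_drugs drugs")
  }
  drug_class_map <- drug_class_map[seq_len(n_drugs)]
  if (n_codes - n_negative_controls < n_latent) {
    stop("too few codes to express the latent factors")
  }
  structure(
    list(n_persons = n_persons, n_codes = n_codes, n_latent = n_latent,
         treat_coefs = treat_coefs, outcome_coefs = outcome_coefs,
         treatment_effect = treatment_effect,
         base_outcome_rate = base_outcome_rate,
         n_drugs = n_drugs, drug_class_map = drug_class_map,
         drug_intercept = drug_intercept,
         code_base_logit = code_base_logit, code_loading = code_loading,
         n_negative_controls = n_negative_controls, nc_prob = nc_prob,
         missing_severity_frac = missing_severity_frac, seed = seed),
    class = "sim_config"
  )
}

#' Default 16-drug / 4-class study drug map
#'
#' The common antidepressants by pharmacological class: selective
#' serotonin reuptake inhibitors (SSRI), serotonin-norepinephrine
#' reuptake inhibitors (SNRI), atypicals, and tricyclics (TCA).
#' @return Named character vector drug -> class.
#' @export
default_drug_classes <- function() {
  c(fluoxetine = "SSRI", paroxetine = "SSRI", sertraline = "SSRI",
    citalopram = "SSRI", escitalopram = "SSRI",
    duloxetine = "SNRI", venlafaxine = "SNRI", desvenlafaxine = "SNRI",
    trazodone = "atypical", mirtazapine = "atypical",
    vortioxetine = "atypical", vilazodone = "atypical",
    bupropion = "atypical",
    nortriptyline = "TCA", amitriptyline = "TCA", doxepin = "TCA")
}

#' Generate a synthetic EHR population with known potential outcomes
#'
#' Draws a population whose code histories, demographics, drug exposures
#' and hospitalization outcome are all driven by a shared latent health
#' state, so that treatment assignment is confounded by construction.
#' Both potential outcomes (with and without treatment) are stored for
#' every person, which makes the finite-sample true average treatment
#' effect exactly computable by [true_ate()].
#'
#' Mechanics, per person i with latent factors `z_i ~ N(0, I)`:
#' * each concept code loads on one latent factor; its occurrence
#'   probability is `plogis(code_base_logit + jitter + code_loading * z_if)`;
#' * each drug is used with probability
#'   `plogis(drug_intercept + jitter_d + treat_coefs . z_i)`; a person is
#'   "treated" if they use any study drug;
#' * potential outcomes use a shared uniform draw `u_i`:
#'   `y0 = u_i < plogis(a + outcome_coefs . z_i)` and
#'   `y1 = u_i < plogis(a + outcome_coefs . z_i + treatment_effect)`,
#'   with the intercept `a` calibrated so `mean P(y0) = base_outcome_rate`;
#'   the observed outcome is `y1` for treated persons and `y0` otherwise;
#' * severity is 5-level: hospitalized persons draw level 3, 4 or 5;
#'   nonhospitalized draw 1 or 2, with `missing_severity_frac` of them
#'   missing;
#' * age and gender are correlated with the latent state (true
#'   demographic confounders); race, ethnicity and 3-digit zip are
#'   independent categoricals, with a small fraction of missing zips and
#'   short histories so the eligibility filters have work to do;
#' * the last `n_negative_controls` codes are generated independent of
#'   everything, giving truly null negative-control outcomes.
#'
#' @param graph A `concept_graph` with at least `config$n_codes` nodes.
#' @param config A [sim_config()].
#' @return A list of class `synthetic_ehr` with data frames `persons`
#'   (person_id, age, gender, race, ethnicity, zip3, history_days),
#'   `code_events` (person_id, code, days_before_index), `exposures`
#'   (person_id, drug), `severities` (person_id, level), `truth`
#'   (person_id, y0, y1, treated, p_treat: the generator's true
#'   any-drug propensity), plus `nc_codes` and the `config`.
#' @export
generate_population <- function(graph, config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(graph$nodes) < config$n_codes) {
    stop("graph has ", length(graph$nodes), " nodes but config requires ",
         config$n_codes, " codes")
  }
  set.seed(config$seed)
  n <- config$n_persons
  k <- config$n_latent
  codes <- graph$nodes[seq_len(config$n_codes)]
  n_nc <- config$n_negative_controls
  nc_codes <- if (n_nc > 0) codes[(length(codes) - n_nc + 1):length(codes)]
              else character(0)
  signal_codes <- setdiff(codes, nc_codes)

  z <- matrix(stats::rnorm(n * k), n, k)

  # code histories: contiguous blocks of the (BFS-ordered) vocabulary load
  # on each factor, mimicking disease-area subtrees
  factor_of <- rep(seq_len(k), length.out = length(signal_codes))
  base_jit <- stats::runif(length(signal_codes), -0.5, 0.5)
  ev_pid <- vector("list", length(codes))
  ev_code <- vector("list", length(codes))
  for (j in seq_along(signal_codes)) {
    p <- stats::plogis(config$code_base_logit + base_jit[j] +
                         config$code_loading * z[, factor_of[j]])
    hit <- which(stats::runif(n) < p)
    ev_pid[[j]] <- hit
    ev_code[[j]] <- rep.int(j, length(hit))
  }
  # negative-control codes: independent of z, treatment and outcome
  for (j in seq_along(nc_codes)) {
    hit <- which(stats::runif(n) < config$nc_prob)
    jj <- length(signal_codes) + j
    ev_pid[[jj]] <- hit
    ev_code[[jj]] <- rep.int(jj, length(hit))
  }
  pid <- unlist(ev_pid)
  cidx <- unlist(ev_code)
  code_events <- data.frame(
    person_id = pid,
    code = codes[cidx],
    days_before_index = sample.int(730, length(pid), replace = TRUE),
    stringsAsFactors = FALSE
  )
  code_events <- code_events[order(code_events$person_id, code_events$code), ]
  rownames(code_events) <- NULL

  # demographics: age and gender track the latent state (true confounders)
  age <- pmax(0L, as.integer(round(stats::rnorm(n, 46 + 6 * z[, 1], 16))))
  gender <- ifelse(stats::runif(n) < stats::plogis(0.2 + 0.5 * z[, 2]),
                   "F", "M")
  race <- sample(c("white", "black", "asian", "other"), n, replace = TRUE,
                 prob = c(0.60, 0.20, 0.10, 0.10))
  ethnicity <- sample(c("not_hispanic", "hispanic"), n, replace = TRUE,
                      prob = c(0.82, 0.18))
  zip_levels <- sprintf("%03d", c(191, 212, 277, 303, 331, 482,
                                  606, 752, 852, 902, 941, 981))
  zip3 <- sample(zip_levels, n, replace = TRUE)
  zip3[stats::runif(n) < 0.03] <- NA_character_
  history_days <- ifelse(stats::runif(n) < 0.9,
                         sample(365:1095, n, replace = TRUE),
                         sample(30:364, n, replace = TRUE))
  persons <- data.frame(
    person_id = seq_len(n), age = age, gender = gender, race = race,
    ethnicity = ethnicity, zip3 = zip3, history_days = history_days,
    stringsAsFactors = FALSE
  )

  # exposures: every drug shares the confounded assignment model, with a
  # per-drug intercept jitter giving varied prevalences
  drugs <- names(config$drug_class_map)
  eta_t <- drop(z %*% config$treat_coefs)
  drug_jit <- stats::runif(config$n_drugs, -0.4, 0.4)
  exp_pid <- vector("list", config$n_drugs)
  log1m_p <- numeric(n)
  for (d in seq_len(config$n_drugs)) {
    p_d <- stats::plogis(config$drug_intercept + drug_jit[d] + eta_t)
    exp_pid[[d]] <- which(stats::runif(n) < p_d)
    log1m_p <- log1m_p + log1p(-p_d)
  }
  exposures <- data.frame(
    person_id = unlist(exp_pid),
    drug = rep(drugs, vapply(exp_pid, length, 1L)),
    stringsAsFactors = FALSE
  )
  exposures <- exposures[order(exposures$person_id, exposures$drug), ]
  rownames(exposures) <- NULL
  treated <- seq_len(n) %in% exposures$person_id
  p_treat <- 1 - exp(log1m_p)

  # outcome: intercept calibrated so the untreated rate hits the target
  eta_y <- drop(z %*% config$outcome_coefs)
  alpha <- stats::uniroot(
    function(a) mean(stats::plogis(a + eta_y)) - config$base_outcome_rate,
    interval = c(-25, 25)
  )$root
  u <- stats::runif(n)
  y0 <- as.integer(u < stats::plogis(alpha + eta_y))
  y1 <- as.integer(u < stats::plogis(alpha + eta_y + config$treatment_effect))
  hosp <- ifelse(treated, y1, y0)

  level <- integer(n)
  n_h <- sum(hosp == 1)
  level[hosp == 1] <- sample(3:5, n_h, replace = TRUE,
                             prob = c(0.70, 0.22, 0.08))
  level[hosp == 0] <- sample(1:2, n - n_h, replace = TRUE,
                             prob = c(0.75, 0.25))
  level <- as.integer(level)
  miss <- hosp == 0 & stats::runif(n) < config$missing_severity_frac
  level[miss] <- NA_integer_
  severities <- data.frame(person_id = seq_len(n), level = level)

  truth <- data.frame(person_id = seq_len(n), y0 = y0, y1 = y1,
                      treated = as.integer(treated), p_treat = p_treat)
  attr(truth, "latent") <- z

  structure(
    list(persons = persons, code_events = code_events,
         exposures = exposures, severities = severities, truth = truth,
         nc_codes = nc_codes, config = config),
    class = "synthetic_ehr"
  )
}

#' @export
print.synthetic_ehr <- function(x, ...) {
  cat("<synthetic_ehr> ", nrow(x$persons), " persons, ",
      nrow(x$code_events), " code events, ",
      nrow(x$exposures), " exposures, ",
      length(x$nc_codes), " negative-control codes\n", sep = "")
  invisible(x)
}

#' Finite-sample true average treatment effect
#'
#' The mean difference of the stored potential outcomes,
#' `mean(y1) - mean(y0)`, over a population or any subset of it. This is
#' the oracle every estimator in the package is judged against on
#' synthetic data.
#'
#' @param truth A `synthetic_ehr` object, or its `truth` data frame
#'   (columns `y0`, `y1`).
#' @param ids Optional person ids restricting the estimand to a
#'   subpopulation (e.g. an analysis cohort).
#' @return A single number.
#' @export
true_ate <- function(truth, ids = NULL) {
  if (inherits(truth, "synthetic_ehr")) truth <- truth$truth
  stopifnot(all(c("y0", "y1") %in% names(truth)), nrow(truth) > 0)
  if (!is.null(ids)) {
    truth <- truth[truth$person_id %in% ids, ]
    if (nrow(truth) == 0) stop("no persons left after id restriction")
  }
  mean(truth$y1) - mean(truth$y0)
}

#' Write / read the synthetic EHR tables
#'
#' Writes the four pipeline input tables as CSV (`persons.csv`,
#' `code_events.csv`, `exposures.csv`, `severities.csv`), the ontology
#' edge list (`graph_edges.tsv`) and, kept separate from the pipeline
#' inputs, the potential-outcome truth table (`truth.csv`).
#'
#' @param data A `synthetic_ehr` object.
#' @param dir Output directory (created if absent).
#' @param graph Optional `concept_graph` to write alongside.
#' @export
write_synthetic_ehr <- function(data, dir, graph = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("persons", "code_events", "exposures", "severities")) {
    utils::write.csv(data[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, na = "")
  }
  utils::write.csv(data$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  writeLines(data$nc_codes, file.path(dir, "negative_control_codes.txt"))
  if (!is.null(graph)) write_ontology(graph, file.path(dir, "graph_edges.tsv"))
  invisible(dir)
}

#' @rdname write_synthetic_ehr
#' @export
read_ehr_tables <- function(dir) {
  rd <- function(f, ...) utils::read.csv(file.path(dir, f),
                                         stringsAsFactors = FALSE, ...)
  persons <- rd("persons.csv", na.strings = "",
                colClasses = c(zip3 = "character"))
  sev <- rd("severities.csv", na.strings = "")
  out <- list(
    persons = persons,
    code_events = rd("code_events.csv"),
    exposures = rd("exposures.csv"),
    severities = sev
  )
  tf <- file.path(dir, "truth.csv")
  if (file.exists(tf)) out$truth <- utils::read.csv(tf)
  nf <- file.path(dir, "negative_control_codes.txt")
  if (file.exists(nf)) out$nc_codes <- readLines(nf)
  out
}
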