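pipeline_keys <- c(
  "synth", "input_dir", "ontology", "embedding", "embedding_table",
  "contrasts", "nonuser_drugs", "comparator_pairs", "methods",
  "min_users", "eps", "B", "seed", "negative_controls", "comparator",
  "lambda"
)

#' Validate a pipeline run configuration
#'
#' A run configuration is a plain named list (or a YAML file holding
#' one). Unknown keys are rejected before any computation; cross-field
#' requirements (an input source; an embedding source when the
#' embedding method is requested) are checked here too.
#'
#' @param config Named list or path to a YAML file.
#' @return The validated configuration list (with defaults filled in).
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), pipeline_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  defaults <- list(
    contrasts = "any_drug", methods = c("unadjusted", "one_hot_lr"),
    min_users = 50, eps = 0.01, B = 100, seed = 1,
    negative_controls = FALSE, comparator = "clean",
    ontology = list(branching = 3), embedding = list()
  )
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  if (is.null(config$synth) && is.null(config$input_dir)) {
    stop("config must provide either synth parameters or input_dir")
  }
  bad_c <- setdiff(config$contrasts,
                   c("any_drug", "nonuser", "active_comparator"))
  if (length(bad_c)) stop("unknown contrast(s): ", paste(bad_c, collapse = ", "))
  bad_m <- setdiff(config$methods,
                   c("unadjusted", "one_hot_lr", "embedding_rf"))
  if (length(bad_m)) stop("unknown method(s): ", paste(bad_m, collapse = ", "))
  if ("embedding_rf" %in% config$methods &&
      is.null(config$synth) && is.null(config$embedding_table)) {
    stop("method embedding_rf needs an embedding source: either synth ",
         "(embeddings trained on the generated ontology) or an ",
         "embedding_table file")
  }
  stopifnot(config$eps > 0, config$eps < 0.5, config$B >= 2,
            config$min_users >= 1)
  if (!is.null(config$lambda)) stopifnot(config$lambda > 0)
  config$comparator <- match.arg(config$comparator, c("clean", "drug_only"))
  config
}

pipeline_stage <- function(name, log, expr) {
  res <- tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  res
}

#' Run the full estimation pipeline from one configuration
#'
#' Orchestrates the end-to-end analysis: synthesize (or read) the input
#' tables, apply eligibility, retain common drugs, build the requested
#' cohort contrasts, estimate ATEs with the requested methods
#' (bootstrap CIs with per-replicate refitting), run the
#' negative-control suite and active-comparator matrix where requested,
#' and write all results, a run manifest and an attrition log under
#' `out_dir`. Deterministic given the config (all randomness expands
#' from `config$seed`).
#'
#' @param config Named list or YAML path, see [validate_run_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with the in-memory results.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  logf <- function(...) cat(paste0(..., "\n"), file = log_path,
                            append = TRUE)
  cat("", file = log_path)

  # ---- inputs -------------------------------------------------------
  graph <- NULL
  if (!is.null(config$synth)) {
    data <- pipeline_stage("synth", logf, {
      sc <- do.call(sim_config, config$synth)
      onto <- config$ontology
      graph <- generate_ontology(
        n_codes = sc$n_codes,
        branching = if (is.null(onto$branching)) 3 else onto$branching,
        seed = sc$seed)
      generate_population(graph, sc)
    })
    write_synthetic_ehr(data, out_dir, graph = graph)
  } else {
    data <- pipeline_stage("read_inputs", logf,
                           read_ehr_tables(config$input_dir))
  }
  logf("persons: ", nrow(data$persons))

  # ---- cohorts ------------------------------------------------------
  eligible <- pipeline_stage("eligibility", logf,
                             apply_eligibility(data$persons))
  logf("eligible (age > 13, history >= 365 d, valid zip): ",
       length(eligible))
  retained <- pipeline_stage("drug_retention", logf,
                             retain_common_drugs(data$exposures,
                                                 config$min_users))
  logf("drugs retained (> ", config$min_users, " users): ",
       length(retained))
  if (length(retained) == 0) stop("stage 'drug_retention' failed: no drug ",
                                  "passes the user threshold")

  vocab <- pipeline_stage("vocabulary", logf,
                          build_vocabulary(data$code_events, data$persons))
  logf("one-hot vocabulary: ", length(vocab$keys), " keys")

  emb <- NULL
  if ("embedding_rf" %in% config$methods) {
    emb <- pipeline_stage("embeddings", logf, {
      if (!is.null(config$embedding_table)) {
        read_embeddings(config$embedding_table)
      } else {
        ea <- config$embedding
        do.call(train_embeddings, c(list(graph = graph),
                                    ea[setdiff(names(ea), "graph")],
                                    list(seed = config$seed + 1)))
      }
    })
    logf("embedding table: ", nrow(emb), " codes x ", ncol(emb), " dims")
  }

  pairs <- list()
  if ("any_drug" %in% config$contrasts) {
    pairs <- c(pairs, list(build_any_drug_cohorts(eligible,
                                                  data$exposures,
                                                  retained)))
  }
  if ("nonuser" %in% config$contrasts) {
    nud <- config$nonuser_drugs
    if (is.null(nud)) nud <- retained
    for (d in intersect(nud, retained)) {
      pairs <- c(pairs, list(
        build_nonuser_cohorts(eligible, data$exposures, d,
                              retained = retained,
                              comparator = config$comparator)))
    }
  }
  cohort_rows <- do.call(rbind, lapply(pairs, cohort_table))
  if (!is.null(cohort_rows)) {
    utils::write.csv(cohort_rows, file.path(out_dir, "cohorts.csv"),
                     row.names = FALSE)
  }
  for (p in pairs) {
    logf("cohort ", p$contrast_name, ": ", length(p$treated_ids),
         " treated / ", length(p$comparator_ids), " comparator")
  }

  # ---- estimation ---------------------------------------------------
  results <- list()
  balance_rows <- list()
  arm_rows <- list()
  boot_seed <- config$seed + 100
  for (p in pairs) {
    for (m in config$methods) {
      boot_seed <- boot_seed + 1
      est <- pipeline_stage(paste0("estimate:", m, ":", p$contrast_name),
                            logf, {
        if (m == "unadjusted") {
          dm <- list(person_ids = c(p$treated_ids, p$comparator_ids),
                     labels = rep(c(1L, 0L), c(length(p$treated_ids),
                                               length(p$comparator_ids))),
                     x = NULL)
          spec <- NULL
        } else if (m == "one_hot_lr") {
          dm <- build_design_matrices(p, "one_hot", data$persons,
                                      data$code_events, vocab = vocab)
          spec <- propensity_spec("lr", lambda = config$lambda, seed = config$seed)
        } else {
          dm <- build_design_matrices(p, "embedding", data$persons,
                                      data$code_events, table = emb)
          spec <- propensity_spec("rf", seed = config$seed)
        }
        h <- outcome_for(data$severities, dm$person_ids)
        es <- bootstrap_ate(h, dm$labels, dm$x, spec, B = config$B,
                            seed = boot_seed, eps = config$eps,
                            contrast_name = p$contrast_name, method = m)
        if (m != "unadjusted") {
          fit <- fit_propensity(dm$x, dm$labels, spec)
          w <- compute_weights(
            predict_propensity(fit, eps = config$eps), dm$labels)
          bd <- balance_diagnostics(dm$x, dm$labels, w)
          bd_un <- balance_diagnostics(dm$x, dm$labels)
          balance_rows[[paste(p$contrast_name, m)]] <- data.frame(
            contrast = p$contrast_name, method = m,
            covariate = bd$covariate, smd_unweighted = bd_un$smd,
            smd_weighted = bd$smd, stringsAsFactors = FALSE)
          asu <- arm_summary(h, dm$labels, w)
        } else {
          asu <- arm_summary(h, dm$labels)
        }
        arm_rows[[paste(p$contrast_name, m)]] <-
          cbind(contrast = p$contrast_name, method = m, asu)
        es
      })
      results <- c(results, list(est))
      utils::write.csv(ate_table(results),
                       file.path(out_dir, "results.csv"),
                       row.names = FALSE)
    }
  }
  if (length(balance_rows)) {
    utils::write.csv(do.call(rbind, balance_rows),
                     file.path(out_dir, "balance.csv"), row.names = FALSE)
  }
  if (length(arm_rows)) {
    utils::write.csv(do.call(rbind, arm_rows),
                     file.path(out_dir, "arm_summary.csv"),
                     row.names = FALSE)
  }

  nc_res <- NULL
  if (isTRUE(config$negative_controls)) {
    nc_res <- pipeline_stage("negative_controls", logf, {
      base_pair <- pairs[[1]]
      nc <- data$nc_codes
      if (is.null(nc)) stop("no negative-control codes available")
      negative_control_suite(base_pair, data, nc_codes = nc,
                             vocab = vocab,
                             spec = propensity_spec("lr",
                                                    seed = config$seed),
                             B = config$B, seed = config$seed + 500,
                             eps = config$eps)
    })
    utils::write.csv(ate_table(nc_res),
                     file.path(out_dir, "negative_controls.csv"),
                     row.names = FALSE)
  }

  cmp <- NULL
  if ("active_comparator" %in% config$contrasts) {
    cmp <- pipeline_stage("active_comparator", logf, {
      cp <- config$comparator_pairs
      drugs <- if (is.null(cp)) retained else unique(unlist(cp))
      comparator_matrix(eligible, data, drugs, vocab,
                        spec = propensity_spec("lr", lambda = config$lambda, seed = config$seed),
                        B = config$B, seed = config$seed + 1000,
                        eps = config$eps)
    })
    utils::write.csv(as.data.frame(cmp$ate),
                     file.path(out_dir, "comparator_matrix_wide.csv"))
    utils::write.csv(cmp$table,
                     file.path(out_dir, "comparator_matrix.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    config = config[setdiff(pipeline_keys, c("synth", "ontology",
                                             "embedding"))],
    synth = config$synth, ontology = config$ontology,
    embedding = config$embedding,
    n_persons = nrow(data$persons), n_eligible = length(eligible),
    drugs_retained = retained,
    vocabulary_size = length(vocab$keys),
    package_version = as.character(utils::packageVersion("ehrcausal"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  logf("done")
  invisible(list(results = results, negative_controls = nc_res,
                 comparator = cmp, eligible = eligible,
                 retained = retained, data = data, vocab = vocab,
                 embeddings = emb))
}
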